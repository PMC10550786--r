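#' Best response of one phenotype to the other's tactic frequency
#'
#' For a fixed producer frequency of the opposing phenotype, finds the
#' own-phenotype producer frequency at which producing and scrounging pay the
#' same. The payoff gap \eqn{D(q) = I_P(q) - I_S(q)} is evaluated on a uniform
#' grid of candidate frequencies; if it is positive throughout the best
#' response is pure producing (1), if negative throughout pure scrounging (0),
#' and any sign change is refined to a root with \code{\link[stats]{uniroot}}.
#'
#' @param phenotype \code{"strong"} or \code{"weak"}: the phenotype whose
#'   frequency is being optimised.
#' @param opponent_freq fixed producer frequency of the other phenotype.
#' @param eco an \code{\link{eco_params}} object.
#' @param pheno a \code{\link{pheno_params}} object.
#' @param p frequency of the strong phenotype in the group.
#' @param grid_n number of grid points used to bracket roots (default 101).
#' @param payoff_tol absolute payoff tolerance below which producing and
#'   scrounging are treated as equal (energy units, default 1e-9).
#' @param prev previous iterate of the own frequency, used as tie-break when
#'   the payoff gap vanishes identically and to select among multiple roots.
#' @return A producer frequency in \code{[0, 1]}.
#' @examples
#' # weak best response when all strong competitors scrounge
#' best_response("weak", 0, eco_params(), pheno_params(), p = 0.5)
#' @export
best_response <- function(phenotype = c("strong", "weak"), opponent_freq,
                          eco, pheno, p,
                          grid_n = 101, payoff_tol = 1e-9, prev = NULL) {
  phenotype <- match.arg(phenotype)
  stopifnot(inherits(eco, "eco_params"), inherits(pheno, "pheno_params"))
  opponent_freq <- check_probability(opponent_freq, "opponent_freq")
  p <- check_probability(p, "p")
  if (grid_n < 3) stop("`grid_n` must be at least 3", call. = FALSE)

  gap <- payoff_gap_fn(phenotype, opponent_freq, eco, pheno, p)
  qs <- seq(0, 1, length.out = grid_n)
  d <- gap(qs)

  if (all(abs(d) <= payoff_tol)) {
    # degenerate: both tactics pay the same at every frequency
    if (is.null(prev)) {
      warning("payoff gap vanishes identically; returning 0.5", call. = FALSE)
      return(0.5)
    }
    return(prev)
  }
  if (all(d >= -payoff_tol)) return(1)  # producing never worse
  if (all(d <= payoff_tol)) return(0)   # scrounging never worse

  roots <- numeric()
  for (i in seq_len(grid_n - 1L)) {
    if (d[i] == 0) {
      roots <- c(roots, qs[i])
    } else if (d[i] * d[i + 1L] < 0) {
      roots <- c(roots, stats::uniroot(gap, c(qs[i], qs[i + 1L]),
                                       f.lower = d[i], f.upper = d[i + 1L],
                                       tol = 1e-12)$root)
    }
  }
  if (d[grid_n] == 0) roots <- c(roots, 1)
  if (!length(roots))  # sign pattern without bracketed change: fall back
    return(if (mean(d) > 0) 1 else 0)
  roots <- sort(unique(roots))
  if (length(roots) > 1L && diff(range(roots)) > 1e-8) {
    warning(sprintf(
      "payoff gap has %d sign changes; taking the root nearest the previous iterate",
      length(roots)), call. = FALSE)
    anchor <- if (is.null(prev)) roots[1L] else prev
    roots <- roots[which.min(abs(roots - anchor))]
  }
  roots[1L]
}

# Payoff gap D(q) = producer - scrounger intake for the focal phenotype as a
# function of its own population frequency q (vectorised over q).
payoff_gap_fn <- function(phenotype, opponent_freq, eco, pheno, p) {
  if (phenotype == "strong") {
    function(q) {
      pay <- payoff_core_params(eco, pheno, p, x = q, y = opponent_freq)
      pay$ip_strong - pay$is_strong
    }
  } else {
    function(q) {
      pay <- payoff_core_params(eco, pheno, p, x = opponent_freq, y = q)
      pay$ip_weak - pay$is_weak
    }
  }
}

#' Nash equilibrium tactic profile at fixed group composition
#'
#' Alternates best responses — weak given strong, then strong given weak —
#' until the profile \code{(x, y)} stops changing, yielding the Nash
#' equilibrium producer frequencies \code{(x*, y*)} at the current strong
#' frequency \code{p}. At the fixed point the profile is checked against the
#' brute-force no-profitable-deviation oracle
#' (\code{\link{verify_no_profitable_deviation}}).
#'
#' When the two phenotypes are payoff-identical (\code{omega = 1} and
#' \code{delta = 1}) the equilibrium set is a line in \code{(x, y)} pinned
#' down only by the mean producer frequency; the solver then reports the
#' symmetric member \code{x = y} of that set, after re-verifying it.
#'
#' @inheritParams best_response
#' @param p frequency of the strong phenotype (held fixed; the short-term
#'   game).
#' @param x_init starting producer frequency for strong competitors
#'   (default 1: all-produce).
#' @param tol fixed-point tolerance on \code{max(|dx|, |dy|)} (default 1e-8).
#' @param max_sweeps cap on best-reply alternations (default 500).
#' @param verify_grid,verify_tol grid size and payoff tolerance for the
#'   no-deviation check.
#' @return An object of class \code{"ps_equilibrium"}: a list with
#'   \code{x_star}, \code{y_star}, \code{gamma}, \code{payoffs} (a
#'   \code{\link{payoff_quartet}} at the equilibrium), \code{converged},
#'   \code{iterations}, \code{deviation_ok}, \code{worst_deviation}, and the
#'   inputs \code{p}, \code{eco}, \code{pheno}.
#' @examples
#' eq <- solve_nash(eco_params(), pheno_params(), p = 0.5)
#' c(eq$x_star, eq$y_star, eq$gamma)
#' @export
solve_nash <- function(eco, pheno, p, x_init = 1,
                       tol = 1e-8, max_sweeps = 500,
                       grid_n = 101, payoff_tol = 1e-9,
                       verify_grid = 101, verify_tol = 1e-6) {
  stopifnot(inherits(eco, "eco_params"), inherits(pheno, "pheno_params"))
  p <- check_probability(p, "p")
  x_init <- check_probability(x_init, "x_init")

  x <- x_init
  y <- NULL
  converged <- FALSE
  it <- 0L
  while (it < max_sweeps) {
    it <- it + 1L
    y_new <- best_response("weak", x, eco, pheno, p,
                           grid_n = grid_n, payoff_tol = payoff_tol,
                           prev = if (is.null(y)) x else y)
    x_new <- best_response("strong", y_new, eco, pheno, p,
                           grid_n = grid_n, payoff_tol = payoff_tol,
                           prev = x)
    delta_xy <- if (is.null(y)) abs(x_new - x) else max(abs(x_new - x), abs(y_new - y))
    x <- x_new
    y <- y_new
    if (delta_xy < tol) {
      converged <- TRUE
      break
    }
  }

  if (converged && pheno$omega == 1 && pheno$delta == 1) {
    # phenotypes indistinguishable: select the symmetric equilibrium
    m <- p * x + (1 - p) * y
    sym <- verify_no_profitable_deviation(eco, pheno, p, m, m,
                                          grid_size = verify_grid,
                                          tol = verify_tol)
    if (sym$pass) x <- y <- m
  }

  check <- verify_no_profitable_deviation(eco, pheno, p, x, y,
                                          grid_size = verify_grid,
                                          tol = verify_tol)
  structure(list(
    x_star = x,
    y_star = y,
    gamma = specialization_index(x, y),
    payoffs = payoff_quartet(eco, pheno, p, x, y),
    converged = converged,
    iterations = it,
    deviation_ok = check$pass,
    worst_deviation = check$worst,
    p = p, eco = eco, pheno = pheno
  ), class = "ps_equilibrium")
}

#' Specialization index
#'
#' The magnitude of the difference between the phenotypes' producer
#' frequencies: 0 when both phenotypes use the tactics at the same rate, 1
#' when each phenotype is locked exclusively onto the opposite role.
#'
#' @param x producer frequency of strong competitors (or an object of class
#'   \code{"ps_equilibrium"}, in which case \code{y} is ignored).
#' @param y producer frequency of weak competitors.
#' @return gamma in \code{[0, 1]}.
#' @examples
#' specialization_index(0, 1)    # full specialization
#' specialization_index(0.3, 0.8)
#' @export
specialization_index <- function(x, y = NULL) {
  if (inherits(x, "ps_equilibrium")) {
    y <- x$y_star
    x <- x$x_star
  }
  x <- check_probability(x, "x")
  y <- check_probability(y, "y")
  abs(x - y)
}

#' Brute-force no-profitable-deviation check
#'
#' Verifies a candidate equilibrium: for each phenotype, the payoff of every
#' unilateral deviation (a grid of alternative mixed tactics, the population
#' profile held fixed) must not exceed the payoff of the candidate mixture by
#' more than \code{tol}. Because a single deviant does not move the
#' population profile, its payoff is linear in its own mixing probability;
#' the grid makes the check an explicit enumeration rather than an argument.
#'
#' @inheritParams best_response
#' @param x,y candidate producer frequencies for strong and weak competitors.
#' @param grid_size number of candidate deviation frequencies per phenotype
#'   (>= 3; default 101).
#' @param tol payoff slack allowed before a deviation counts as profitable
#'   (energy units, default 1e-6).
#' @return A list with \code{pass} (logical), \code{worst} (largest payoff
#'   gain any deviation achieves; can be negative) and per-phenotype gains
#'   \code{worst_strong}, \code{worst_weak}.
#' @examples
#' verify_no_profitable_deviation(eco_params(), pheno_params(), 0.5, 1, 1)$pass
#' @export
verify_no_profitable_deviation <- function(eco, pheno, p, x, y,
                                           grid_size = 101, tol = 1e-6) {
  stopifnot(inherits(eco, "eco_params"), inherits(pheno, "pheno_params"))
  p <- check_probability(p, "p")
  x <- check_probability(x, "x")
  y <- check_probability(y, "y")
  if (grid_size < 3) stop("`grid_size` must be at least 3", call. = FALSE)
  pay <- payoff_core_params(eco, pheno, p, x, y)
  qs <- seq(0, 1, length.out = grid_size)
  gain_strong <- max(qs * pay$ip_strong + (1 - qs) * pay$is_strong) -
    (x * pay$ip_strong + (1 - x) * pay$is_strong)
  gain_weak <- max(qs * pay$ip_weak + (1 - qs) * pay$is_weak) -
    (y * pay$ip_weak + (1 - y) * pay$is_weak)
  worst <- max(gain_strong, gain_weak)
  list(pass = worst <= tol, worst = worst,
       worst_strong = gain_strong, worst_weak = gain_weak)
}

#' @export
print.ps_equilibrium <- function(x, ...) {
  cat(sprintf("Nash equilibrium at p = %g:\n", x$p))
  cat(sprintf("  x* (strong producer freq) = %.6g\n", x$x_star))
  cat(sprintf("  y* (weak producer freq)   = %.6g\n", x$y_star))
  cat(sprintf("  gamma (specialization)    = %.6g\n", x$gamma))
  cat(sprintf("  converged: %s in %d sweeps; no-deviation check: %s\n",
              x$converged, x$iterations,
              if (x$deviation_ok) "pass" else "FAIL"))
  invisible(x)
}

#' @export
as.data.frame.ps_equilibrium <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(
    p = x$p, x_star = x$x_star, y_star = x$y_star, gamma = x$gamma,
    ip_strong = x$payoffs$ip_strong, is_strong = x$payoffs$is_strong,
    ip_weak = x$payoffs$ip_weak, is_weak = x$payoffs$is_weak,
    converged = x$converged, iterations = x$iterations,
    stringsAsFactors = FALSE, row.names = row.names
  )
}
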