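#' Specify a parameter sweep
#'
#' Describes a one-dimensional sweep over an ecological or phenotypic
#' parameter, with every other parameter held at the supplied values.
#' \code{mode = "short_term"} solves the tactic equilibrium once at fixed
#' group composition (the first-time-step prediction); \code{mode =
#' "long_term"} runs the full evolutionary dynamic and reports the final
#' state.
#'
#' @param varied which parameter varies: \code{"p"}, \code{"delta"},
#'   \code{"omega"}, \code{"a"} or \code{"G"}. Varying \code{"p"} in
#'   long-term mode varies the initial frequency \code{p0}.
#' @param grid ordered numeric vector of values for the varied parameter.
#' @param eco,pheno parameter sets for the non-varied entries.
#' @param mode \code{"short_term"} or \code{"long_term"}.
#' @param t_max evolutionary horizon for long-term sweeps (default 1000).
#' @return An object of class \code{"ps_sweep_spec"}.
#' @examples
#' sweep_spec("p", seq(0.05, 0.95, by = 0.05))
#' sweep_spec("a", seq(0, 10, by = 2), mode = "long_term")
#' @export
sweep_spec <- function(varied = c("p", "delta", "omega", "a", "G"), grid,
                       eco = eco_params(), pheno = pheno_params(),
                       mode = c("short_term", "long_term"), t_max = 1000) {
  varied <- match.arg(varied)
  mode <- match.arg(mode)
  stopifnot(inherits(eco, "eco_params"), inherits(pheno, "pheno_params"))
  if (!is.numeric(grid) || !length(grid) || any(!is.finite(grid)))
    stop("`grid` must be a non-empty finite numeric vector", call. = FALSE)
  structure(list(varied = varied, grid = as.numeric(grid),
                 eco = eco, pheno = pheno, mode = mode, t_max = t_max),
            class = "ps_sweep_spec")
}

#' Run a parameter sweep
#'
#' Evaluates the model once per grid value of a \code{\link{sweep_spec}} and
#' returns a tidy table, ordered as the grid. Short-term rows hold the Nash
#' equilibrium at fixed composition; long-term rows hold the final state of a
#' full evolutionary run, with \code{p} reporting the final strong frequency.
#' The computation is deterministic, so repeated runs (and their CSVs) are
#' identical. A solver failure in one row is recorded (\code{converged =
#' FALSE}, payoff columns \code{NA}) without aborting the sweep.
#'
#' @param spec a \code{\link{sweep_spec}} object.
#' @param ... further arguments passed to \code{\link{solve_nash}} or
#'   \code{\link{run_evolution}}.
#' @return A data frame of class \code{"ps_sweep"} with columns
#'   \code{param}, \code{value}, \code{p}, \code{x_star}, \code{y_star},
#'   \code{gamma}, \code{ip_strong}, \code{is_strong}, \code{ip_weak},
#'   \code{is_weak}, \code{mode}, \code{converged}, \code{degenerate}.
#' @examples
#' tab <- run_sweep(sweep_spec("p", c(0.2, 0.5, 0.8)))
#' tab[, c("value", "x_star", "y_star", "gamma")]
#' @export
run_sweep <- function(spec, ...) {
  stopifnot(inherits(spec, "ps_sweep_spec"))
  rows <- lapply(spec$grid, function(v) sweep_row(spec, v, ...))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ps_sweep", "data.frame")
  out
}

sweep_row <- function(spec, value, ...) {
  eco <- spec$eco
  pheno <- spec$pheno
  p <- pheno$p0
  res <- tryCatch({
    switch(spec$varied,
      p = p <- check_probability(value, "p"),
      delta = pheno <- pheno_params(omega = pheno$omega, delta = value,
                                    p0 = pheno$p0),
      omega = pheno <- pheno_params(omega = value, delta = pheno$delta,
                                    p0 = pheno$p0),
      a = eco <- eco_params(F = eco$F, a = value, G = eco$G),
      G = eco <- eco_params(F = eco$F, a = eco$a, G = value)
    )
    if (spec$varied == "p") pheno <- pheno_params(pheno$omega, pheno$delta, p)
    if (spec$mode == "short_term") {
      eq <- solve_nash(eco, pheno, p, ...)
      data.frame(param = spec$varied, value = value, p = p,
                 x_star = eq$x_star, y_star = eq$y_star, gamma = eq$gamma,
                 ip_strong = eq$payoffs$ip_strong,
                 is_strong = eq$payoffs$is_strong,
                 ip_weak = eq$payoffs$ip_weak, is_weak = eq$payoffs$is_weak,
                 mode = spec$mode, converged = eq$converged,
                 stringsAsFactors = FALSE)
    } else {
      traj <- run_evolution(eco, pheno, t_max = spec$t_max, ...)
      pay <- payoff_quartet(eco, pheno, traj$ess_p, traj$ess_x, traj$ess_y)
      data.frame(param = spec$varied, value = value, p = traj$ess_p,
                 x_star = traj$ess_x, y_star = traj$ess_y,
                 gamma = traj$ess_gamma,
                 ip_strong = pay$ip_strong, is_strong = pay$is_strong,
                 ip_weak = pay$ip_weak, is_weak = pay$is_weak,
                 mode = spec$mode, converged = TRUE,
                 stringsAsFactors = FALSE)
    }
  }, error = function(e) {
    warning(sprintf("sweep row %s = %g failed: %s", spec$varied, value,
                    conditionMessage(e)), call. = FALSE)
    data.frame(param = spec$varied, value = value, p = NA_real_,
               x_star = NA_real_, y_star = NA_real_, gamma = NA_real_,
               ip_strong = NA_real_, is_strong = NA_real_,
               ip_weak = NA_real_, is_weak = NA_real_,
               mode = spec$mode, converged = FALSE, stringsAsFactors = FALSE)
  })
  omega <- if (spec$varied == "omega") value else spec$pheno$omega
  delta <- if (spec$varied == "delta") value else spec$pheno$delta
  res$degenerate <- identical(omega, 0) || identical(delta, 0) ||
    omega == 0 || delta == 0
  res
}

#' Equal-competitor (single-phenotype) producer equilibrium
#'
#' The classic one-phenotype reduction of the game: with all competitors
#' identical (weight 1, detection 1), the stable producer frequency
#' \code{q*} makes producing and scrounging pay the same,
#' \deqn{a + (F-a)/(1 + (G-1)(1-q)) = G q (F-a)/(2 + (G-2)(1-q)),}
#' solved by root bracketing on \code{(0, 1)}; when no interior root exists
#' the better pure strategy is returned. Used as the external benchmark the
#' two-phenotype model must reduce to when \code{omega = delta = 1}.
#'
#' @param eco an \code{\link{eco_params}} object.
#' @return The equilibrium producer frequency \code{q*} in \code{[0, 1]}.
#' @examples
#' single_phenotype_equilibrium(eco_params())   # defaults F=10, a=2, G=10
#' single_phenotype_equilibrium(eco_params(a = 10))  # a = F: all produce
#' @export
single_phenotype_equilibrium <- function(eco) {
  stopifnot(inherits(eco, "eco_params"))
  F <- eco$F
  a <- eco$a
  G <- eco$G
  if (a == F) return(1)
  gap <- function(q) {
    a + (F - a) / (1 + (G - 1) * (1 - q)) -
      G * q * (F - a) / (2 + (G - 2) * (1 - q))
  }
  d0 <- gap(0)
  d1 <- gap(1)
  if (d0 <= 0) return(0)      # scrounging at least as good even with no producers
  if (d1 >= 0) return(1)      # producing at least as good even when all produce
  stats::uniroot(gap, c(0, 1), f.lower = d0, f.upper = d1, tol = 1e-12)$root
}

#' Mean producer frequency in the group
#'
#' The expected proportion of group members playing producer,
#' \code{p x + (1 - p) y}.
#'
#' @param p strong-phenotype frequency.
#' @param x,y producer frequencies of strong and weak competitors.
#' @return A probability; vectorised.
#' @examples
#' mean_producer_frequency(0.5, 0, 1)
#' @export
mean_producer_frequency <- function(p, x, y) {
  p <- check_probability(p, "p")
  x <- check_probability(x, "x")
  y <- check_probability(y, "y")
  p * x + (1 - p) * y
}
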