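#' Mean payoff of a phenotype at a tactic equilibrium
#'
#' The expected intake of a phenotype is the convex combination of its
#' producing and scrounging payoffs, weighted by its equilibrium tactic use:
#' for strong competitors \eqn{\bar I_{strong} = x^* I_{P,strong} +
#' (1-x^*) I_{S,strong}}, and analogously for weak competitors with
#' \eqn{y^*}.
#'
#' @param phenotype \code{"strong"} or \code{"weak"}.
#' @param equilibrium a \code{"ps_equilibrium"} object from
#'   \code{\link{solve_nash}}.
#' @return Expected intake (energy units).
#' @examples
#' eq <- solve_nash(eco_params(), pheno_params(), p = 0.5)
#' mean_payoff("strong", eq)
#' mean_payoff("weak", eq)
#' @export
mean_payoff <- function(phenotype = c("strong", "weak"), equilibrium) {
  phenotype <- match.arg(phenotype)
  stopifnot(inherits(equilibrium, "ps_equilibrium"))
  pay <- equilibrium$payoffs
  if (phenotype == "strong") {
    equilibrium$x_star * pay$ip_strong + (1 - equilibrium$x_star) * pay$is_strong
  } else {
    equilibrium$y_star * pay$ip_weak + (1 - equilibrium$y_star) * pay$is_weak
  }
}

#' Survival/replacement update of the strong-phenotype frequency
#'
#' Between consecutive time steps 99 percent of the group survives and the
#' remaining 1 percent is replaced by individuals of the phenotype with the
#' higher mean payoff: \code{p} maps to \code{0.99 p + 0.01} when strong
#' competitors earn more, to \code{0.99 p} (floored at 0) when weak
#' competitors earn more, and is unchanged when the mean payoffs are equal
#' within \code{tol}. The boundaries 0 and 1 are absorbing: an extinct
#' phenotype cannot be re-seeded.
#'
#' @param p current strong-phenotype frequency (in \code{[0, 1]}).
#' @param i_strong,i_weak mean payoffs of the two phenotypes (energy units).
#' @param tol absolute payoff tolerance treated as equality (default 1e-9).
#' @return Updated frequency in \code{[0, 1]}. Either branch satisfies
#'   \code{|p' - 0.99 p| = 0.01} (before flooring), i.e. up-steps move
#'   \code{p} by \code{0.01(1-p)} and down-steps by \code{0.01(1+p)}.
#' @examples
#' update_proportion(0.5, 3, 3)    # equal payoffs: unchanged
#' update_proportion(0.5, 4, 3)    # strong favoured: 0.505
#' update_proportion(0.005, 3, 4)  # weak favoured, floored at 0
#' @export
update_proportion <- function(p, i_strong, i_weak, tol = 1e-9) {
  p <- check_probability(p, "p")
  if (!is_scalar_number(i_strong) || !is_scalar_number(i_weak))
    stop("mean payoffs must be single finite numbers", call. = FALSE)
  if (p == 0 || p == 1) return(p)                 # absorbing boundaries
  if (abs(i_strong - i_weak) <= tol) return(p)
  if (i_strong > i_weak) 0.99 * p + 0.01 else max(0.99 * p - 0.01, 0)
}

#' Coupled short-term/long-term dynamics to the ESS
#'
#' Runs the full model: at each time step the tactic equilibrium
#' \code{(x*, y*)} is solved at the current strong frequency \code{p} by best
#' reply dynamics, the mean phenotype payoffs are computed, and \code{p} is
#' updated by the 1 percent replacement rule. The run stops after
#' \code{t_max} updates or as soon as \code{p} has moved by at most
#' \code{ess_tol} for \code{ess_run} consecutive updates (the evolutionarily
#' stable state \code{\{p*, x*, y*\}}).
#'
#' The model is fully deterministic: there is no random number generation
#' anywhere, and repeated runs are bit-identical.
#'
#' @inheritParams solve_nash
#' @param t_max maximum number of replacement updates (default 1000).
#' @param warm_start start each Nash solve from the previous step's
#'   \code{x*} (default) instead of from \code{x_init}; a pure efficiency
#'   device, the trajectory is unchanged.
#' @param x_init starting strong producer frequency for the first (or, with
#'   \code{warm_start = FALSE}, every) Nash solve.
#' @param payoff_tol payoff-equality tolerance of the replacement rule.
#' @param ess_tol,ess_run stopping rule: \code{|dp| <= ess_tol} for
#'   \code{ess_run} consecutive updates declares the ESS reached.
#' @return An object of class \code{"ps_trajectory"}: a list with
#'   \code{records} (data frame with one row per time step: \code{t},
#'   \code{p}, \code{x_star}, \code{y_star}, \code{gamma}, \code{i_strong},
#'   \code{i_weak}, \code{iterations}), \code{ess_p}, \code{ess_x},
#'   \code{ess_y}, \code{ess_gamma}, \code{steps_run}, \code{ess_reached},
#'   and the inputs \code{eco}, \code{pheno}.
#' @examples
#' traj <- run_evolution(eco_params(), pheno_params(omega = 0.5), t_max = 25)
#' tail(traj$records, 3)
#' @export
run_evolution <- function(eco, pheno, t_max = 1000,
                          warm_start = TRUE, x_init = 1,
                          tol = 1e-8, max_sweeps = 500, grid_n = 101,
                          payoff_tol = 1e-9, ess_tol = 1e-10, ess_run = 5,
                          verify_grid = 101, verify_tol = 1e-6) {
  stopifnot(inherits(eco, "eco_params"), inherits(pheno, "pheno_params"))
  if (!is_scalar_number(t_max) || t_max < 1)
    stop("`t_max` must be a positive count", call. = FALSE)
  t_max <- as.integer(t_max)

  p <- pheno$p0
  rec <- matrix(NA_real_, nrow = t_max + 1L, ncol = 8L,
                dimnames = list(NULL, c("t", "p", "x_star", "y_star", "gamma",
                                        "i_strong", "i_weak", "iterations")))
  consec <- 0L
  ess_reached <- FALSE
  start_x <- x_init
  eq <- NULL
  n_rows <- 0L
  for (t in 0:t_max) {
    eq <- solve_nash(eco, pheno, p, x_init = start_x,
                     tol = tol, max_sweeps = max_sweeps, grid_n = grid_n,
                     payoff_tol = payoff_tol,
                     verify_grid = verify_grid, verify_tol = verify_tol)
    if (!eq$converged)
      stop(sprintf("best-reply dynamics failed to converge at time step %d", t),
           call. = FALSE)
    i_s <- mean_payoff("strong", eq)
    i_w <- mean_payoff("weak", eq)
    n_rows <- n_rows + 1L
    rec[n_rows, ] <- c(t, p, eq$x_star, eq$y_star, eq$gamma, i_s, i_w,
                       eq$iterations)
    if (t == t_max) break
    p_new <- update_proportion(p, i_s, i_w, tol = payoff_tol)
    consec <- if (abs(p_new - p) <= ess_tol) consec + 1L else 0L
    p <- p_new
    if (consec >= ess_run) {
      ess_reached <- TRUE
      break
    }
    if (warm_start) start_x <- eq$x_star
  }

  records <- as.data.frame(rec[seq_len(n_rows), , drop = FALSE])
  structure(list(
    records = records,
    ess_p = p,
    ess_x = eq$x_star,
    ess_y = eq$y_star,
    ess_gamma = eq$gamma,
    steps_run = n_rows - 1L,
    ess_reached = ess_reached,
    eco = eco, pheno = pheno
  ), class = "ps_trajectory")
}

#' @export
print.ps_trajectory <- function(x, ...) {
  cat(sprintf("Producer-scrounger evolutionary trajectory (%d steps%s)\n",
              x$steps_run,
              if (x$ess_reached) ", ESS reached" else ""))
  cat(sprintf("  final state: p* = %.6g, x* = %.6g, y* = %.6g, gamma = %.6g\n",
              x$ess_p, x$ess_x, x$ess_y, x$ess_gamma))
  invisible(x)
}

#' @export
as.data.frame.ps_trajectory <- function(x, row.names = NULL, optional = FALSE, ...) {
  x$records
}
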