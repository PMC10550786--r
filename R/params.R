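#' Ecological parameters of the producer-scrounger game
#'
#' Bundles the three ecological constants of the foraging game: the energetic
#' value of a prey item, the finder's advantage (the portion of each prey the
#' finder consumes exclusively before any scrounger arrives) and the group
#' size. All payoffs are expected energy intakes per time step in the same
#' units as \code{F}.
#'
#' @param F energetic value of one prey item (energy units, \code{F > 0}).
#' @param a finder's advantage (energy units, \code{0 <= a <= F}).
#' @param G group size (integer, \code{G >= 2}; the focal-exclusion weight
#'   uses \code{G - 2}, so two foragers is the smallest meaningful group).
#'
#' @return An object of class \code{"eco_params"}: a named list with elements
#'   \code{F}, \code{a}, \code{G}.
#' @examples
#' eco_params()             # defaults: F = 10, a = 2, G = 10
#' eco_params(F = 20, a = 5)
#' @export
eco_params <- function(F = 10, a = 2, G = 10) {
  problems <- character()
  if (!is_scalar_number(F) || F <= 0)
    problems <- c(problems, "`F` (prey value) must be a single number > 0")
  if (!is_scalar_number(a) || a < 0)
    problems <- c(problems, "`a` (finder's advantage) must be a single number >= 0")
  if (is_scalar_number(F) && is_scalar_number(a) && a > F)
    problems <- c(problems,
      sprintf("finder's advantage a = %g cannot exceed prey value F = %g", a, F))
  if (!is_scalar_number(G) || G < 2 || abs(G - round(G)) > 1e-8)
    problems <- c(problems, "`G` (group size) must be a single integer >= 2")
  if (length(problems))
    stop(paste(problems, collapse = "; "), call. = FALSE)
  structure(list(F = as.numeric(F), a = as.numeric(a), G = as.numeric(round(G))),
            class = "eco_params")
}

#' Phenotypic parameters of the two competitor types
#'
#' The group holds two phenotypes. Strong competitors have competitive weight
#' 1 but detect prey only with probability \code{delta}; weak competitors
#' have competitive weight \code{omega} but detect prey with probability 1.
#' \code{omega < 1} together with \code{delta < 1} is the skill trade-off:
#' better fighters are worse finders.
#'
#' @param omega competitive weight of weak competitors (dimensionless,
#'   in \code{[0, 1]}; strong weight is fixed at 1).
#' @param delta prey-detection probability of strong competitors (in
#'   \code{[0, 1]}; weak detection is fixed at 1).
#' @param p0 initial frequency of the strong phenotype (in \code{[0, 1]}).
#'
#' @return An object of class \code{"pheno_params"}: a named list with
#'   elements \code{omega}, \code{delta}, \code{p0}.
#' @examples
#' pheno_params()                 # defaults: omega = 0.8, delta = 0.8, p0 = 0.5
#' pheno_params(omega = 0.5)      # stronger trade-off
#' @export
pheno_params <- function(omega = 0.8, delta = 0.8, p0 = 0.5) {
  problems <- character()
  if (!is_probability(omega))
    problems <- c(problems, "`omega` (weak competitive weight) must be in [0, 1]")
  if (!is_probability(delta))
    problems <- c(problems, "`delta` (strong detection probability) must be in [0, 1]")
  if (!is_probability(p0))
    problems <- c(problems, "`p0` (initial strong frequency) must be in [0, 1]")
  if (length(problems))
    stop(paste(problems, collapse = "; "), call. = FALSE)
  structure(list(omega = as.numeric(omega), delta = as.numeric(delta),
                 p0 = as.numeric(p0)),
            class = "pheno_params")
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

is_probability <- function(x) {
  is_scalar_number(x) && x >= 0 && x <= 1
}

check_probability <- function(x, name) {
  if (!all(is.numeric(x)) || any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(sprintf("`%s` must be in [0, 1]", name), call. = FALSE)
  as.numeric(x)
}

#' @export
print.eco_params <- function(x, ...) {
  cat(sprintf("Ecological parameters: F = %g, a = %g (a/F = %g%%), G = %d\n",
              x$F, x$a, 100 * x$a / x$F, as.integer(x$G)))
  invisible(x)
}

#' @export
print.pheno_params <- function(x, ...) {
  cat(sprintf(
    "Phenotypes: strong (weight 1, detection %g), weak (weight %g, detection 1), p0 = %g\n",
    x$delta, x$omega, x$p0))
  invisible(x)
}
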