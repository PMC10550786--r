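#' @title Phenotype-specific foraging payoffs
#' @description Expected energy intake per time step for each phenotype x
#'   tactic combination. A producer that captures a prey keeps the finder's
#'   advantage \code{a} plus a competitive-weight share of the contested
#'   remainder \code{F - a}; a scrounger joins every discovery and takes its
#'   weight share of each remainder.
#' @name payoffs
NULL

# Competitive-weight share with the uncontested convention: a claimant facing
# total opposing weight 0 keeps everything, including the 0/0 corner.
#' Share of a contested resource
#'
#' An individual's share of a contested resource equals its competitive weight
#' divided by the summed weights of all contestants. When the focal weight and
#' the opposing weight are both zero the resource is uncontested and the share
#' is 1 by convention (continuity with the no-scrounger limit).
#'
#' @param focal_weight competitive weight of the focal individual (>= 0);
#'   vectorised.
#' @param opponent_weight_sum summed competitive weights of all other
#'   contestants (>= 0); vectorised.
#' @return Numeric vector of shares in \code{[0, 1]}.
#' @examples
#' contested_share(1, 4.5)   # 1/5.5
#' contested_share(0.8, 0)   # uncontested: 1
#' @export
contested_share <- function(focal_weight, opponent_weight_sum) {
  if (any(focal_weight < 0) || any(opponent_weight_sum < 0))
    stop("competitive weights must be non-negative", call. = FALSE)
  tot <- focal_weight + opponent_weight_sum
  out <- ifelse(tot == 0, 1, focal_weight / tot)
  as.numeric(out)
}

#' Summed competitive weight of joining scroungers
#'
#' \code{joiner_weight_total} returns
#' \eqn{W = (G-1)[p(1-x) + \omega(1-p)(1-y)]}, the expected summed weight of
#' all scroungers joining a discovery, seen from the finder.
#' \code{joiner_weight_excl_focal} returns the same mixture over \eqn{G-2}
#' individuals, \eqn{W_{-1}}, i.e. excluding a focal scrounger.
#'
#' @param eco an \code{\link{eco_params}} object.
#' @param pheno a \code{\link{pheno_params}} object.
#' @param p frequency of the strong phenotype in the group (in \code{[0, 1]});
#'   vectorised.
#' @param x producer frequency among strong competitors; vectorised.
#' @param y producer frequency among weak competitors; vectorised.
#' @return Numeric vector of non-negative weights (\code{<= G-1}, resp.
#'   \code{<= G-2}).
#' @examples
#' joiner_weight_total(eco_params(), pheno_params(), p = 0.5, x = 0, y = 1)
#' @export
joiner_weight_total <- function(eco, pheno, p, x, y) {
  scrounger_mix(eco, pheno, p, x, y, exclude_focal = FALSE)
}

#' @rdname joiner_weight_total
#' @export
joiner_weight_excl_focal <- function(eco, pheno, p, x, y) {
  scrounger_mix(eco, pheno, p, x, y, exclude_focal = TRUE)
}

scrounger_mix <- function(eco, pheno, p, x, y, exclude_focal) {
  stopifnot(inherits(eco, "eco_params"), inherits(pheno, "pheno_params"))
  p <- check_probability(p, "p")
  x <- check_probability(x, "x")
  y <- check_probability(y, "y")
  n <- eco$G - if (exclude_focal) 2 else 1
  n * (p * (1 - x) + pheno$omega * (1 - p) * (1 - y))
}

# Internal fast path: all four payoffs, no class checks, fully vectorised
# over p, x, y. The divisors in the scrounger terms are (focal weight +
# finder weight + W_-1), written via contested_share so the 0/0 corner is
# handled once.
payoff_core <- function(F, a, G, omega, delta, p, x, y) {
  mix <- p * (1 - x) + omega * (1 - p) * (1 - y)
  W   <- (G - 1) * mix
  Wm1 <- (G - 2) * mix
  rem <- F - a
  n_strong <- p * G * x * delta        # expected discoveries by strong producers
  n_weak   <- (1 - p) * G * y          # expected discoveries by weak producers
  list(
    ip_strong = delta * (a + rem * contested_share(1, W)),
    ip_weak   = a + rem * contested_share(omega, W),
    is_strong = n_strong * rem * contested_share(1, 1 + Wm1) +
                n_weak   * rem * contested_share(1, omega + Wm1),
    is_weak   = n_strong * rem * contested_share(omega, 1 + Wm1) +
                n_weak   * rem * contested_share(omega, omega + Wm1)
  )
}

payoff_core_params <- function(eco, pheno, p, x, y) {
  payoff_core(eco$F, eco$a, eco$G, pheno$omega, pheno$delta, p, x, y)
}

#' Producer payoff of a phenotype
#'
#' Expected intake of an individual playing producer, given the group
#' composition \code{p} and the population tactic profile \code{(x, y)}.
#' A strong producer detects a prey with probability \code{delta} and then
#' keeps \code{a} plus the share \code{1/(1+W)} of the remainder; a weak
#' producer always detects and keeps \code{a} plus \code{omega/(omega+W)} of
#' the remainder, where \code{W} is the summed weight of joining scroungers.
#'
#' @param phenotype \code{"strong"} or \code{"weak"}.
#' @inheritParams joiner_weight_total
#' @return Numeric vector of expected intakes (energy units, in
#'   \code{[0, F]}).
#' @examples
#' producer_payoff("weak", eco_params(), pheno_params(), p = 0.5, x = 0, y = 1)
#' @export
producer_payoff <- function(phenotype = c("strong", "weak"), eco, pheno, p, x, y) {
  phenotype <- match.arg(phenotype)
  stopifnot(inherits(eco, "eco_params"), inherits(pheno, "pheno_params"))
  p <- check_probability(p, "p")
  x <- check_probability(x, "x")
  y <- check_probability(y, "y")
  q <- payoff_core_params(eco, pheno, p, x, y)
  if (phenotype == "strong") q$ip_strong else q$ip_weak
}

#' Scrounger payoff of a phenotype
#'
#' Expected intake of an individual playing scrounger: it joins every
#' discovery, so the payoff sums, over the two producer classes, the expected
#' number of discoveries times the focal's weight share of the remainder
#' \code{F - a}. The divisor of each share is focal weight + finder weight +
#' \code{W_-1}, where \code{W_-1} is the summed weight of the other joining
#' scroungers (mixture over \code{G - 2} individuals).
#'
#' @inheritParams producer_payoff
#' @return Numeric vector of expected intakes (energy units, >= 0; zero when
#'   nobody produces or when \code{a = F}).
#' @examples
#' scrounger_payoff("strong", eco_params(), pheno_params(), p = 0.5, x = 0, y = 1)
#' @export
scrounger_payoff <- function(phenotype = c("strong", "weak"), eco, pheno, p, x, y) {
  phenotype <- match.arg(phenotype)
  stopifnot(inherits(eco, "eco_params"), inherits(pheno, "pheno_params"))
  p <- check_probability(p, "p")
  x <- check_probability(x, "x")
  y <- check_probability(y, "y")
  q <- payoff_core_params(eco, pheno, p, x, y)
  if (phenotype == "strong") q$is_strong else q$is_weak
}

#' All four phenotype x tactic payoffs at once
#'
#' @inheritParams producer_payoff
#' @return A named list (class \code{"payoff_quartet"}) with elements
#'   \code{ip_strong}, \code{ip_weak}, \code{is_strong}, \code{is_weak}.
#' @examples
#' payoff_quartet(eco_params(), pheno_params(), p = 0.5, x = 0, y = 1)
#' @export
payoff_quartet <- function(eco, pheno, p, x, y) {
  stopifnot(inherits(eco, "eco_params"), inherits(pheno, "pheno_params"))
  p <- check_probability(p, "p")
  x <- check_probability(x, "x")
  y <- check_probability(y, "y")
  structure(payoff_core_params(eco, pheno, p, x, y), class = "payoff_quartet")
}

#' @export
print.payoff_quartet <- function(x, ...) {
  cat("Expected intake per time step (energy units):\n")
  cat(sprintf("  producer : strong %.6g, weak %.6g\n", x$ip_strong, x$ip_weak))
  cat(sprintf("  scrounger: strong %.6g, weak %.6g\n", x$is_strong, x$is_weak))
  invisible(x)
}
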