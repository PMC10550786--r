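# Shared fixtures and independent oracles for the test suite.

default_eco <- function(...) eco_params(...)
default_pheno <- function(...) pheno_params(...)

# Independent brute-force oracle for the best response: scan the payoff gap
# of one phenotype on a fine grid and locate its smallest zero by bisection,
# using only the public payoff functions (not the solver).
brute_best_response <- function(phenotype, opponent_freq, eco, pheno, p,
                                n = 2001) {
  gap <- function(q) {
    if (phenotype == "strong") {
      producer_payoff("strong", eco, pheno, p, x = q, y = opponent_freq) -
        scrounger_payoff("strong", eco, pheno, p, x = q, y = opponent_freq)
    } else {
      producer_payoff("weak", eco, pheno, p, x = opponent_freq, y = q) -
        scrounger_payoff("weak", eco, pheno, p, x = opponent_freq, y = q)
    }
  }
  qs <- seq(0, 1, length.out = n)
  d <- vapply(qs, gap, numeric(1))
  if (all(d > 0)) return(1)
  if (all(d < 0)) return(0)
  i <- which(d[-n] * d[-1] <= 0)[1]
  lo <- qs[i]; hi <- qs[i + 1]
  for (k in 1:60) {
    mid <- (lo + hi) / 2
    if (gap(lo) * gap(mid) <= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Enumerate an integer contest (1 finder + k strong + m weak joiners) and
# return every contestant's share of the contested remainder.
enumerate_shares <- function(finder_weight, k_strong, m_weak, omega) {
  opp_of <- function(own) finder_weight + k_strong + m_weak * omega - own
  finder <- contested_share(finder_weight, opp_of(finder_weight))
  strong <- if (k_strong) rep(contested_share(1, opp_of(1)), k_strong) else numeric()
  weak <- if (m_weak) rep(contested_share(omega, opp_of(omega)), m_weak) else numeric()
  c(finder, strong, weak)
}
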