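test_that("parameter constructors validate and report all violations", {
  eco <- eco_params()
  expect_equal(c(eco$F, eco$a, eco$G), c(10, 2, 10))
  ph <- pheno_params()
  expect_equal(c(ph$omega, ph$delta, ph$p0), c(0.8, 0.8, 0.5))

  expect_error(eco_params(F = 10, a = 12), "cannot exceed prey value")
  expect_error(eco_params(G = 1), "integer >= 2")
  expect_error(pheno_params(omega = 1.2), "omega")
  # aggregated: both problems named in one error
  expect_error(pheno_params(omega = -1, delta = 2), "omega.*delta")
})

test_that("joiner weights match hand-evaluated mixtures", {
  eco <- default_eco()
  ph <- default_pheno()
  # 9 others, half strong all scrounging (weight 1), half weak all producing
  expect_equal(joiner_weight_total(eco, ph, p = 0.5, x = 0, y = 1), 4.5)
  expect_equal(joiner_weight_excl_focal(eco, ph, p = 0.5, x = 0, y = 1), 4.0)
  # no scroungers
  expect_equal(joiner_weight_total(eco, ph, p = 0.5, x = 1, y = 1), 0)
  expect_equal(joiner_weight_excl_focal(eco, ph, p = 0.5, x = 1, y = 1), 0)
  # all others are strong scroungers of weight 1
  expect_equal(joiner_weight_total(eco, ph, p = 1, x = 0, y = 1), eco$G - 1)
  # a pair has no other scroungers
  expect_equal(
    joiner_weight_excl_focal(eco_params(G = 2), ph, p = 0.5, x = 0, y = 0), 0)
})

test_that("contested share covers the degenerate uncontested corner", {
  expect_equal(contested_share(1, 4.5), 1 / 5.5)
  expect_equal(contested_share(0.8, 0), 1)
  expect_equal(contested_share(0, 0), 1)
  expect_equal(contested_share(0, 3), 0)
  expect_error(contested_share(-1, 0), "non-negative")
})

test_that("payoffs reproduce hand-evaluated worked cases", {
  eco <- default_eco()
  ph <- default_pheno()
  # p = 0.5, x = 0, y = 1: W = 4.5, W_-1 = 4
  expect_equal(producer_payoff("weak", eco, ph, 0.5, 0, 1),
               2 + 8 * 0.8 / 5.3, tolerance = 1e-12)
  expect_equal(producer_payoff("strong", eco, ph, 0.5, 0, 1),
               0.8 * 2 + 0.8 * 8 / 5.5, tolerance = 1e-12)
  expect_equal(scrounger_payoff("strong", eco, ph, 0.5, 0, 1),
               5 * 8 / 5.8, tolerance = 1e-12)
  expect_equal(scrounger_payoff("weak", eco, ph, 0.5, 0, 1),
               5 * 8 * 0.8 / 5.6, tolerance = 1e-12)
  q <- payoff_quartet(eco, ph, 0.5, 0, 1)
  expect_equal(unname(unlist(q[c("ip_strong", "ip_weak", "is_strong", "is_weak")])),
               c(0.8 * 2 + 6.4 / 5.5, 2 + 6.4 / 5.3, 40 / 5.8, 32 / 5.6),
               tolerance = 1e-12)
})

test_that("payoff edge cases collapse as the equations dictate", {
  ph <- default_pheno()
  eco_af <- eco_params(F = 10, a = 10)
  # a = F: producers keep everything, scroungers get nothing
  expect_equal(producer_payoff("weak", eco_af, ph, 0.5, 0.3, 0.7), 10)
  expect_equal(scrounger_payoff("strong", eco_af, ph, 0.5, 0.3, 0.7), 0)
  expect_equal(scrounger_payoff("weak", eco_af, ph, 0.5, 0.3, 0.7), 0)
  # delta = 0: strong producers earn nothing
  ph0 <- pheno_params(delta = 0)
  expect_equal(producer_payoff("strong", default_eco(), ph0, 0.5, 0.5, 0.5), 0)
  # nobody produces: nothing to scrounge
  expect_equal(scrounger_payoff("strong", default_eco(), ph, 0.5, 0, 0), 0)
  expect_equal(scrounger_payoff("weak", default_eco(), ph, 0.5, 0, 0), 0)
})

test_that("identical phenotypes collapse the quartet to two payoffs", {
  eco <- default_eco()
  ph <- pheno_params(omega = 1, delta = 1)
  for (p in c(0.1, 0.5, 0.9)) {
    for (q in c(0, 0.3, 0.8, 1)) {
      pay <- payoff_quartet(eco, ph, p, q, q)
      expect_equal(pay$ip_strong, pay$ip_weak)
      expect_equal(pay$is_strong, pay$is_weak)
    }
  }
})

test_that("prey-share conservation holds for enumerated integer contests", {
  rem <- 8  # contested remainder F - a
  for (omega in c(0.3, 0.8, 1)) {
    for (finder_w in c(1, omega)) {
      for (k in 0:4) {
        for (m in 0:4) {
          shares <- enumerate_shares(finder_w, k, m, omega)
          expect_equal(sum(shares) * rem, rem, tolerance = 1e-12)
        }
      }
    }
  }
  # omega = 0 with a single positive-weight claimant: finder keeps all
  expect_equal(sum(enumerate_shares(1, 0, 3, 0)), 1)
})

test_that("payoffs stay within bounds and are monotone in producer use", {
  eco <- default_eco()
  ph <- default_pheno()
  grid <- seq(0, 1, by = 0.25)
  for (p in grid) for (x in grid) for (y in grid) {
    pay <- payoff_quartet(eco, ph, p, x, y)
    v <- unlist(pay[c("ip_strong", "ip_weak", "is_strong", "is_weak")])
    expect_true(all(v >= 0))
    expect_true(all(v <= eco$G * eco$F))
    expect_lte(pay$ip_strong, eco$F)
    expect_lte(pay$ip_weak, eco$F)
  }
  # non-decreasing in x and y for all four payoffs
  xs <- seq(0, 1, by = 0.1)
  for (pheno_tactic in list(c("strong", "producer"), c("weak", "producer"),
                            c("strong", "scrounger"), c("weak", "scrounger"))) {
    f <- if (pheno_tactic[2] == "producer") producer_payoff else scrounger_payoff
    along_x <- f(pheno_tactic[1], eco, ph, 0.5, xs, 0.4)
    along_y <- f(pheno_tactic[1], eco, ph, 0.5, 0.4, xs)
    expect_true(all(diff(along_x) >= -1e-9))
    expect_true(all(diff(along_y) >= -1e-9))
  }
})
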