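test_that("best response is pure producing when scrounging pays nothing", {
  eco <- eco_params(F = 10, a = 10)
  ph <- default_pheno()
  expect_equal(best_response("strong", 0.5, eco, ph, 0.5), 1)
  expect_equal(best_response("weak", 0.5, eco, ph, 0.5), 1)
})

test_that("mixed best response agrees with an independent grid-and-bisection oracle", {
  eco <- default_eco()
  ph <- default_pheno()
  cases <- list(
    list(phen = "weak", opp = 0, p = 0.5),
    list(phen = "weak", opp = 0.3, p = 0.2),
    list(phen = "strong", opp = 1, p = 0.9),
    list(phen = "weak", opp = 0.1, p = 0.7)
  )
  for (cs in cases) {
    br <- best_response(cs$phen, cs$opp, eco, ph, cs$p)
    oracle <- brute_best_response(cs$phen, cs$opp, eco, ph, cs$p)
    expect_equal(br, oracle, tolerance = 1e-6)
    if (br > 0 && br < 1) {
      # interior response satisfies payoff indifference
      gap <- if (cs$phen == "weak") {
        producer_payoff("weak", eco, ph, cs$p, cs$opp, br) -
          scrounger_payoff("weak", eco, ph, cs$p, cs$opp, br)
      } else {
        producer_payoff("strong", eco, ph, cs$p, br, cs$opp) -
          scrounger_payoff("strong", eco, ph, cs$p, br, cs$opp)
      }
      expect_lt(abs(gap), 1e-6)
    }
  }
})

test_that("best responses are phenotype-symmetric for identical phenotypes", {
  eco <- default_eco()
  ph <- pheno_params(omega = 1, delta = 1)
  for (q in c(0, 0.25, 0.6, 1)) {
    expect_equal(best_response("strong", q, eco, ph, 0.5),
                 best_response("weak", q, eco, ph, 0.5), tolerance = 1e-9)
  }
})

test_that("solve_nash finds verified equilibria with correct boundary logic", {
  eco <- default_eco()
  ph <- default_pheno()
  eq <- solve_nash(eco, ph, 0.5)
  expect_true(eq$converged)
  expect_true(eq$deviation_ok)
  expect_true(verify_no_profitable_deviation(eco, ph, 0.5, eq$x_star,
                                             eq$y_star)$pass)
  pay <- eq$payoffs
  # indifference at interior components, weak-preference at boundaries
  if (eq$x_star > 0 && eq$x_star < 1) {
    expect_lt(abs(pay$ip_strong - pay$is_strong), 1e-6)
  } else if (eq$x_star == 0) {
    expect_gte(pay$is_strong, pay$ip_strong - 1e-6)
  } else {
    expect_gte(pay$ip_strong, pay$is_strong - 1e-6)
  }
  if (eq$y_star > 0 && eq$y_star < 1) {
    expect_lt(abs(pay$ip_weak - pay$is_weak), 1e-6)
  } else if (eq$y_star == 0) {
    expect_gte(pay$is_weak, pay$ip_weak - 1e-6)
  } else {
    expect_gte(pay$ip_weak, pay$is_weak - 1e-6)
  }

  # a = F: both phenotypes produce purely, no specialization
  eq_af <- solve_nash(eco_params(F = 10, a = 10), ph, 0.5)
  expect_equal(c(eq_af$x_star, eq_af$y_star, eq_af$gamma), c(1, 1, 0))
  expect_true(verify_no_profitable_deviation(eco_params(F = 10, a = 10), ph,
                                             0.5, 1, 1)$pass)
})

test_that("all-produce is refuted by the deviation oracle when scrounging pays", {
  eco <- default_eco()
  ph <- default_pheno()
  chk <- verify_no_profitable_deviation(eco, ph, 0.5, 1, 1)
  expect_false(chk$pass)
  expect_gt(chk$worst, 0)
  # direct payoff comparison: a lone scrounger beats producing at (1, 1)
  expect_gt(scrounger_payoff("strong", eco, ph, 0.5, 1, 1),
            producer_payoff("strong", eco, ph, 0.5, 1, 1))
})

test_that("equilibria pass the no-deviation oracle across the trade-off plane", {
  eco <- default_eco()
  for (om in c(0.1, 0.4, 0.7, 1)) {
    for (de in c(0.1, 0.4, 0.7, 1)) {
      ph <- pheno_params(omega = om, delta = de)
      eq <- solve_nash(eco, ph, 0.5)
      expect_true(eq$converged, info = sprintf("omega=%g delta=%g", om, de))
      expect_true(eq$deviation_ok, info = sprintf("omega=%g delta=%g", om, de))
      # strong rely more on scrounging under the trade-off orientation
      if (om < 1 || de < 1)
        expect_lte(eq$x_star, eq$y_star + 1e-6)
      expect_gte(eq$gamma, 0)
      expect_lte(eq$gamma, 1)
    }
  }
})

test_that("specialization index is the magnitude of the frequency difference", {
  expect_equal(specialization_index(0, 1), 1)
  expect_equal(specialization_index(0.7, 0.7), 0)
  expect_equal(specialization_index(0.3, 0.8), 0.5)
  expect_equal(specialization_index(0.8, 0.3), 0.5)
  eq <- solve_nash(default_eco(), default_pheno(), 0.5)
  expect_equal(specialization_index(eq), abs(eq$x_star - eq$y_star))
})

test_that("solver is insensitive to the starting point at default parameters", {
  eco <- default_eco()
  ph <- default_pheno()
  eq1 <- solve_nash(eco, ph, 0.5, x_init = 1)
  eq0 <- solve_nash(eco, ph, 0.5, x_init = 0)
  eqh <- solve_nash(eco, ph, 0.5, x_init = 0.37)
  expect_equal(eq0$x_star, eq1$x_star, tolerance = 1e-7)
  expect_equal(eq0$y_star, eq1$y_star, tolerance = 1e-7)
  expect_equal(eqh$y_star, eq1$y_star, tolerance = 1e-7)
})
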