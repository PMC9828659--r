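test_that("covariogram matches the lagged-sum definition", {
  expect_identical(covariogram(c(0, 5, 0), 2), c(25, 0, 0))
  expect_identical(covariogram(c(0, 2, 3, 0), 2), c(13, 6, 0))
  expect_identical(covariogram(rep(0, 5), 3), rep(0, 4))
  g <- covariogram(c(0, 1, 4, 2, 0), 4)
  expect_identical(g, c(21, 12, 2, 0, 0))
  expect_true(all(g <= g[1]))
  expect_error(covariogram(c(0, 1, 0), 3), "max_lag")
})

test_that("gamma moments: worked values and the constant-gap identity", {
  expect_equal(gamma_moment(c(1, 3), 1, 2), 2.5, tolerance = 1e-14)
  expect_equal(gamma_moment(c(1, 3), 2, 1), 2, tolerance = 1e-14)
  expect_equal(gamma_moment(c(1, 1, 2), 1, 3), 2.5, tolerance = 1e-14)
  for (Tg in c(0.5, 1, 2.5)) {
    gaps <- rep(Tg, 7)
    for (i in 1:3) for (j in 1:5)
      expect_equal(gamma_moment(gaps, i, j), i^j * Tg^(j - 1),
                   tolerance = 1e-13)
  }
  expect_error(gamma_moment(c(1, 1), 3, 2), "between 1 and")
  expect_error(gamma_moment(c(1, 1), 1, 0), "at least 1")
})

test_that("perturbed-model thickness moments and refined corrections", {
  m <- perturbed_moments(c(1, 1, 2))
  expect_equal(m$T_hat, 4 / 3, tolerance = 1e-14)
  expect_equal(m$theta2, 2 / 9, tolerance = 1e-14)
  mc <- perturbed_moments(rep(2, 5), refined = TRUE)
  expect_identical(mc$theta2, 0)
  expect_identical(mc$theta4, 0)
  expect_identical(mc$theta2_refined, 0)
  expect_equal(mc$T2_refined, 4, tolerance = 1e-14)
  mr <- perturbed_moments(c(1, 1, 2), refined = TRUE)
  expect_equal(mr$theta2_refined, (2 / 9) * 9 / 8, tolerance = 1e-14)
  expect_equal(mr$T2_refined, 16 / 9 - (2 / 9) / 8, tolerance = 1e-14)
  expect_error(perturbed_moments(1), "at least 2")
})

test_that("cumulative-model raw moments", {
  nu <- cumulative_moments(c(1, 1, 2))
  expect_equal(nu[["nu2"]], 2, tolerance = 1e-14)
  expect_equal(nu[["nu3"]], 10 / 3, tolerance = 1e-14)
  expect_equal(nu[["nu1"]], perturbed_moments(c(1, 1, 2))$T_hat,
               tolerance = 1e-14)
  expect_equal(unname(cumulative_moments(rep(1.5, 4))), 1.5^(1:5),
               tolerance = 1e-13)
  expect_error(cumulative_moments(numeric(0)), "at least 1")
})

test_that("variance estimators reproduce the hand-worked values", {
  # constant gaps: both orientations
  expect_equal(varest_model_free(toy_const, 0)$value, 1.25, tolerance = 1e-13)
  expect_equal(varest_model_free(toy_const, 1)$value, 0.0625,
               tolerance = 1e-13)
  # unequal gaps (1,1,2)
  expect_equal(varest_model_free(toy_uneq, 0)$value, 3.125, tolerance = 1e-13)
  expect_equal(varest_perturbed(toy_uneq, 0)$value, 55 / 18,
               tolerance = 1e-13)
  expect_equal(varest_cumulative(toy_uneq, 0)$value, 3.125, tolerance = 1e-13)
  # equidistant closed forms
  expect_equal(varest_equidistant(c(0, 2, 3, 0), 1, 0)$value, 1.25,
               tolerance = 1e-13)
  expect_equal(varest_equidistant(c(0, 2, 3, 0), 1, 1)$value, 0.0625,
               tolerance = 1e-13)
  # m = 0 vs m = 1 equidistant ratio is 240/12 = 20 for any input
  set.seed(601)
  for (i in 1:5) {
    a <- c(0, runif(4, 0, 3), 0)
    Tg <- runif(1, 0.2, 2)
    expect_equal(varest_equidistant(a, Tg, 0)$value /
                   varest_equidistant(a, Tg, 1)$value, 20, tolerance = 1e-12)
  }
})

test_that("refined corrections leave constant-gap estimates unchanged", {
  expect_equal(varest_perturbed(toy_const, 0, refined = TRUE)$value,
               varest_perturbed(toy_const, 0)$value, tolerance = 1e-14)
  # and differ (slightly) for unequal gaps
  expect_false(isTRUE(all.equal(
    varest_perturbed(toy_uneq, 0, refined = TRUE)$value,
    varest_perturbed(toy_uneq, 0)$value)))
})

test_that("conservative x2 bound applies to 1-oriented estimates only", {
  est <- varest_model_free(toy_const, 1)
  cons <- conservative_bound(est)
  expect_equal(cons$value, 0.125, tolerance = 1e-13)
  expect_true(cons$conservative)
  expect_false(est$conservative)
  expect_error(conservative_bound(varest_model_free(toy_const, 0)),
               "1-oriented")
})

test_that("model-specific estimators refuse thinned series; model-free does not", {
  thin <- apply_dropout(section_series(0:4, c(0, 2, 5, 3, 0)), 0.3, seed = 2)
  expect_error(varest_perturbed(thin, 1), "dropout")
  expect_error(varest_cumulative(thin, 1), "dropout")
  expect_s3_class(varest_after_dropout(thin, 1), "variance_estimate")
  # delegation: identical to the model-free value on the same series
  expect_identical(varest_after_dropout(toy_uneq, 0)$value,
                   varest_model_free(toy_uneq, 0)$value)
  expect_equal(varest_after_dropout(toy_uneq, 0)$value, 3.125,
               tolerance = 1e-13)
  # smallest valid input: one interior section
  tiny <- section_series(c(0, 1, 3, 4), c(0, 0, 3, 0))
  expect_true(is.finite(varest_after_dropout(tiny, 0)$value))
})

test_that("plug-in variance estimators track the extension term of the ball", {
  # perturbed-model sampling of the unit ball at small T: the mean of the
  # model-specific m = 1 estimator stays within a factor [1, 2] of the
  # equidistant extension term (pi^2/90) T^4 that the estimators target
  set.seed(602)
  Tg <- 2 / 24
  sig <- calibrate_dispersion("perturbed", Tg, 0.05)
  vals <- vapply(1:3000, function(i) {
    s <- trapvol:::simulate_series(unit_ball, "perturbed", Tg, sig)
    trapvol:::varest_value(s, 1, "perturbed")
  }, numeric(1))
  ext <- pi^2 / 90 * Tg^4
  expect_gte(mean(vals) / ext, 1)
  expect_lte(mean(vals) / ext, 2)
})
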