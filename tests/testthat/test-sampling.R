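test_that("dispersion calibration hits the target average relative deviation", {
  expect_identical(calibrate_dispersion("perturbed", 1, 0), 0)
  expect_identical(calibrate_dispersion("equidistant", 1, 0.05), 0)
  # linear scale equivariance
  s1 <- calibrate_dispersion("perturbed", 1, 0.05)
  expect_equal(calibrate_dispersion("perturbed", 2, 0.05), 2 * s1,
               tolerance = 1e-12)
  sc <- calibrate_dispersion("cumulative", 1, 0.05)
  expect_equal(calibrate_dispersion("cumulative", 3.5, 0.05), 3.5 * sc,
               tolerance = 1e-12)
  # Monte Carlo oracle: E|D - D'|/T for iid truncated-normal perturbations
  set.seed(401)
  D <- trapvol:::rtruncnorm(1e6, s1, 0.5)
  Dp <- trapvol:::rtruncnorm(1e6, s1, 0.5)
  expect_lt(abs(mean(abs(D - Dp)) - 0.05), 1e-3)
  # cumulative: E|h - T|/T for the centred truncated-normal gap law
  X <- trapvol:::rtruncnorm(1e6, sc, 0.5)
  expect_lt(abs(mean(abs(X)) - 0.05), 1e-3)
  # unattainable targets under truncation fail loudly
  expect_error(calibrate_dispersion("perturbed", 1, 0.4), "calibration failure")
  expect_error(calibrate_dispersion("cumulative", 1, 0.3), "calibration failure")
  expect_error(calibrate_dispersion("perturbed", 1, 0.6), "rel_dev")
})

test_that("sampled positions are ordered, cover the window and have mean gap T", {
  for (model in c("equidistant", "perturbed", "cumulative")) {
    spec <- sampling_spec(model, mean_gap = 0.7, rel_dev = 0.05, seed = 5)
    pos <- sample_positions(spec, c(-2, 3))
    expect_true(all(diff(pos) > 0))
    expect_lt(min(pos), -2)
    expect_gt(max(pos), 3)
  }
  # degenerate perturbations reproduce the equidistant draw seed-for-seed
  eq <- sample_positions(sampling_spec("equidistant", 1, seed = 9), c(0, 10))
  pe <- sample_positions(
    sampling_spec("perturbed", 1, rel_dev = 0, seed = 9), c(0, 10))
  expect_identical(eq, pe)
  # perturbed gaps stay positive (truncation at +-T/2 forces ordering)
  set.seed(17)
  spec <- sampling_spec("perturbed", 1, rel_dev = 0.2)
  for (i in 1:50)
    expect_true(all(diff(sample_positions(spec, c(0, 20))) > 0))
  # law of large numbers for the mean gap, both random models
  set.seed(402)
  for (model in c("perturbed", "cumulative")) {
    spec <- sampling_spec(model, mean_gap = 0.5, rel_dev = 0.05)
    gaps <- unlist(replicate(200, diff(sample_positions(spec, c(0, 300))),
                             simplify = FALSE))
    expect_gt(length(gaps), 1e5)
    expect_lt(abs(mean(gaps) - 0.5) / 0.5, 0.01)
    if (model == "cumulative")
      expect_true(all(gaps > 0.25 & gaps < 0.75))
  }
  expect_error(sample_positions(sampling_spec("equidistant", 1), c(0, 1.5)),
               "window")
})

test_that("the start phase is uniform: stationarity of the sampling models", {
  set.seed(403)
  Tg <- 1
  for (model in c("equidistant", "perturbed")) {
    spec <- sampling_spec(model, Tg, rel_dev = 0.05)
    phase <- vapply(1:10000, function(i)
      min(sample_positions(spec, c(0.3, 5.7))) %% Tg, numeric(1))
    expect_gt(stats::ks.test(phase, "punif", 0, Tg)$p.value, 0.01)
  }
})

test_that("sections_from_area_function evaluates, trims and is estimation-ready", {
  s <- sections_from_area_function(unit_ball, c(-1.2, -0.4, 0.4, 1.2))
  expect_equal(s$areas, c(0, 0.84 * pi, 0.84 * pi, 0), tolerance = 1e-12)
  expect_equal(s$gaps, c(0.8, 0.8, 0.8), tolerance = 1e-12)
  # several leading/trailing non-hitting planes are trimmed to exactly one
  s2 <- sections_from_area_function(
    unit_ball, c(-3, -2.5, -2, -1.2, -0.4, 0.4, 1.2, 2, 2.8))
  expect_identical(s2$positions, c(-1.2, -0.4, 0.4, 1.2))
  expect_error(sections_from_area_function(unit_ball, c(-0.5, 0, 0.5, 1.5)),
               "cover")
  expect_error(sections_from_area_function(unit_ball, c(-2, -1.5, 1.5, 2)),
               "no section plane hits")
  # every simulated series is estimation-ready
  set.seed(404)
  for (model in c("equidistant", "perturbed", "cumulative")) {
    spec <- sampling_spec(model, 0.3, rel_dev = 0.05)
    for (i in 1:20) {
      s <- sections_from_area_function(unit_ball,
                                       sample_positions(spec, c(-1.6, 1.6)))
      expect_identical(s$areas[c(1, length(s$areas))], c(0, 0))
      expect_true(all(s$areas[-c(1, length(s$areas))] >= 0))
    }
  }
})

test_that("dropout thinning merges gaps additively and spares the end planes", {
  s <- section_series(0:4, c(0, 2, 5, 3, 0))
  expect_identical(apply_dropout(s, 0), s)
  # force removal of the middle section only
  set.seed(1); u <- stats::runif(3)
  thin <- apply_dropout(s, dropout_prob = sort(u)[2], seed = 1)
  expect_identical(length(thin$positions), 4L)
  expect_identical(sum(thin$gaps), sum(s$gaps))  # total span preserved
  expect_true(all(thin$positions %in% s$positions))
  expect_identical(thin$positions[c(1, 4)], c(0, 4))
  expect_true(thin$dropouts)
  # binomial oracle for the retained interior count
  set.seed(405)
  big <- section_series(0:21, c(0, rep(1, 20), 0))
  kept <- vapply(1:2000, function(i)
    length(apply_dropout(big, 0.3)$positions) - 2L, numeric(1))
  se <- sqrt(20 * 0.3 * 0.7 / 2000)
  expect_lt(abs(mean(kept) - 20 * 0.7), 3 * se)
  expect_error(apply_dropout(section_series(0:2, c(1, 2, 1)), 0.2),
               "estimation-ready")
})

test_that("estimates are invariant under joint translation of object and window", {
  spec1 <- sampling_spec("perturbed", 0.25, rel_dev = 0.05, seed = 31)
  d <- 3 * 0.25   # lattice-commensurate shift: draws coincide seed-for-seed
  shifted <- area_function(function(x) unit_ball$fun(x - d),
                           unit_ball$support + d, m = 1)
  s1 <- sections_from_area_function(unit_ball,
                                    sample_positions(spec1, c(-1.4, 1.4)))
  spec2 <- sampling_spec("perturbed", 0.25, rel_dev = 0.05, seed = 31)
  s2 <- sections_from_area_function(shifted,
                                    sample_positions(spec2, c(-1.4, 1.4) + d))
  expect_equal(trapezoidal_estimate(s1)$value, trapezoidal_estimate(s2)$value,
               tolerance = 1e-12)
})
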