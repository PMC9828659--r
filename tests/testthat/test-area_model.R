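test_that("ball area function matches pi*(r^2 - x^2) and its analytic volume", {
  b <- ball_area_function(1)
  expect_identical(b$fun(0), pi)
  expect_identical(b$fun(c(-1, 1)), c(0, 0))
  expect_identical(b$fun(c(-1.5, 2)), c(0, 0))
  expect_equal(b$volume, 4 * pi / 3, tolerance = 1e-12)
  x <- seq(-0.9, 0.9, by = 0.1)
  expect_equal(b$fun(x), pi * (1 - x^2), tolerance = 1e-15)
  b2 <- ball_area_function(2.5)
  expect_equal(b2$fun(1), pi * (2.5^2 - 1), tolerance = 1e-15)
  expect_equal(b2$volume, 4 * pi * 2.5^3 / 3, tolerance = 1e-12)
  expect_identical(b$m, 1L)
  expect_error(ball_area_function(0), "positive")
  expect_error(ball_area_function(-1), "positive")
})

test_that("spline area function interpolates, clips and has quadrature-consistent volume", {
  af <- spline_area_function(0:4, c(0, 3, 5, 3, 0))
  expect_equal(af$fun(1), 3, tolerance = 1e-12)
  expect_equal(af$fun(2), 5, tolerance = 1e-12)
  expect_identical(af$fun(c(-0.5, 4.5)), c(0, 0))
  expect_true(all(af$fun(seq(-1, 5, by = 0.01)) >= 0))
  expect_equal(af$volume, trapz_quad(af$fun, 0, 4), tolerance = 1e-6)
  expect_error(spline_area_function(c(0, 1, 2), c(0, 1, 0)), "at least 4")
  expect_error(spline_area_function(c(0, 2, 1, 3), c(0, 1, 1, 0)), "increasing")
  expect_error(spline_area_function(0:3, c(0, -1, 1, 0)), "nonnegative")
  expect_error(spline_area_function(0:3, c(1, 2, 2, 0)), "zero")
})

test_that("truncation preserves values left of the cut and creates a jump", {
  half <- truncate_area_function(unit_ball, 0)
  x <- seq(-0.99, -0.01, by = 0.01)
  expect_equal(half$fun(x), unit_ball$fun(x), tolerance = 1e-15)
  expect_equal(half$fun(0), pi, tolerance = 1e-15)        # left limit
  expect_identical(half$fun(1e-9), 0)                      # beyond the cut
  expect_equal(half$volume, 2 * pi / 3, tolerance = 1e-9)
  expect_identical(half$m, 0L)
  expect_error(truncate_area_function(unit_ball, 1), "inside the support")
  expect_error(truncate_area_function(unit_ball, -2), "inside the support")
  sp <- spline_area_function(0:4, c(0, 3, 0, 3, 0))
  expect_error(truncate_area_function(sp, 2), "positive at")
})

test_that("any area function integrates to its stored volume", {
  fns <- list(unit_ball, ball_area_function(0.3),
              truncate_area_function(unit_ball, 0.5),
              spline_area_function(c(0, 2, 3, 5, 9), c(0, 4, 7, 2, 0)),
              synthesize_lobe_profile(seed = 3)$true_area_function)
  for (fn in fns)
    expect_equal(trapz_quad(fn$fun, fn$support[1], fn$support[2]),
                 fn$volume, tolerance = 1e-6)
})

test_that("point counts convert to areas by the grid constant", {
  expect_identical(point_counts_to_areas(c(0, 10, 0), 2.29), c(0, 22.9, 0))
  expect_identical(point_counts_to_areas(c(0, 0, 0), 2.29), c(0, 0, 0))
  expect_identical(point_counts_to_areas(c(3, 7), 1), c(3, 7))
  expect_error(point_counts_to_areas(c(-1, 2), 2.29), "nonnegative")
  expect_error(point_counts_to_areas(c(1, 2), 0), "positive")
})

test_that("lobe synthesizer is reproducible and matches the point-count budget", {
  l1 <- synthesize_lobe_profile(seed = 1, n_slabs = 13, nominal_gap = 2.5,
                                area_per_point = 2.29)
  l2 <- synthesize_lobe_profile(seed = 1, n_slabs = 13, nominal_gap = 2.5,
                                area_per_point = 2.29)
  expect_identical(l1$table, l2$table)
  expect_identical(nrow(l1$table), 14L)                    # n_slabs + 1 cuts
  expect_identical(l1$table$area_mm2[c(1, 14)], c(0, 0))
  expect_identical(l1$table$area_mm2, l1$table$points * 2.29)
  expect_s3_class(l1$area_function, "area_function")
  # expected total point count is calibrated to 645 across all slabs
  tot <- vapply(1:150, function(s)
    sum(synthesize_lobe_profile(seed = s)$table$points), numeric(1))
  se <- stats::sd(tot) / sqrt(length(tot))
  expect_lt(abs(mean(tot) - 645), 3 * se)
  expect_error(synthesize_lobe_profile(seed = 1, n_slabs = 2), "at least 4")
})
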