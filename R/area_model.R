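#' Area functions of three-dimensional objects
#'
#' An `area_function` represents the cross-sectional area \eqn{f(x)} of a
#' bounded object along a chosen sampling axis: \eqn{f(x)} is the area of the
#' intersection of the object with the plane orthogonal to the axis at
#' position \eqn{x}. The function is nonnegative, compactly supported, and its
#' integral over the support is the volume of the object.
#'
#' The smoothness index `m` records the orientation class of the object with
#' respect to the sampling axis: `m = 1` means the area function is continuous
#' with a derivative that may jump (typical for smooth convex objects),
#' `m = 0` means the area function itself jumps (a flat face parallel to the
#' sections). The index governs the decrease rate \eqn{T^{2m+2}} of the
#' variance of the trapezoidal estimator as the mean section spacing \eqn{T}
#' shrinks.
#'
#' @param fun vectorised function of axial position (mm) returning area (mm^2);
#'   must be zero outside `support`.
#' @param support numeric length-2, `c(lo, hi)` with `lo < hi` (mm).
#' @param m smoothness/orientation index, 0 or 1.
#' @param volume optional known volume (mm^3); computed by quadrature when
#'   omitted.
#' @return An object of class `area_function`: a list with elements `fun`,
#'   `support`, `m` (smoothness index) and `volume`.
#' @seealso [ball_area_function()], [spline_area_function()],
#'   [truncate_area_function()]
#' @export
area_function <- function(fun, support, m = 1, volume = NULL) {
  stopifnot(is.function(fun), length(support) == 2, is.numeric(support))
  if (!support[1] < support[2])
    stop("'support' must satisfy lo < hi", call. = FALSE)
  if (!m %in% c(0, 1))
    stop("smoothness index 'm' must be 0 or 1", call. = FALSE)
  if (is.null(volume))
    volume <- integrate_area(fun, support[1], support[2])
  structure(
    list(fun = fun, support = as.numeric(support), m = as.integer(m),
         volume = volume),
    class = "area_function")
}

#' @export
print.area_function <- function(x, ...) {
  cat(sprintf(
    "Area function on [%.4g, %.4g] mm, smoothness m = %d, volume %.6g mm^3\n",
    x$support[1], x$support[2], x$m, x$volume))
  invisible(x)
}

# Quadrature of an area profile. Adaptive quadrature first; clipped splines
# have kinks that can defeat it, so fall back to composite Simpson on a fine
# grid (error O(h^4) between kinks, O(h^2) at isolated kinks -- ample for the
# 1e-6 relative tolerance the class guarantees).
integrate_area <- function(fun, lo, hi, n = 200001L) {
  val <- tryCatch(
    stats::integrate(fun, lo, hi, subdivisions = 2000L,
                     rel.tol = 1e-10, stop.on.error = TRUE)$value,
    error = function(e) NA_real_)
  simp <- simpson_quad(fun, lo, hi, n)
  if (is.na(val) || abs(val - simp) > 1e-6 * max(abs(simp), 1e-12)) simp else val
}

simpson_quad <- function(fun, lo, hi, n = 200001L) {
  if (n %% 2L == 0L) n <- n + 1L
  x <- seq(lo, hi, length.out = n)
  y <- fun(x)
  h <- (hi - lo) / (n - 1L)
  w <- rep(c(4, 2), length.out = n - 2L)
  h / 3 * (y[1L] + y[n] + sum(w * y[2:(n - 1L)]))
}

#' Area function of a ball
#'
#' The ball of radius \eqn{r} has area function
#' \eqn{f(x) = \pi (r^2 - x^2)} on \eqn{[-r, r]}. It is the canonical
#' 1-oriented benchmark object: \eqn{f} is continuous and its derivative jumps
#' at the two support endpoints, so the variance of the trapezoidal estimator
#' carries a non-vanishing oscillating component (Zitterbewegung).
#'
#' @param radius ball radius (mm), positive.
#' @return An [area_function()] with `m = 1` and volume \eqn{4\pi r^3/3}.
#' @examples
#' b <- ball_area_function(1)
#' b$fun(0)      # pi
#' b$volume      # 4*pi/3
#' @export
ball_area_function <- function(radius) {
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) ||
      radius <= 0)
    stop("'radius' must be a positive number", call. = FALSE)
  r <- radius
  f <- function(x) ifelse(abs(x) <= r, pi * (r^2 - x^2), 0)
  area_function(f, c(-r, r), m = 1, volume = 4 * pi * r^3 / 3)
}

#' Area function by cubic spline interpolation of section data
#'
#' Builds a smooth area profile through observed (position, area) pairs using
#' a natural cubic interpolating spline, clipped below at zero (areas cannot
#' be negative) and set to zero outside the data range. The first and last
#' areas must be zero so the profile has compact support.
#'
#' Spline interpolation of section data is a device for constructing
#' evaluable area functions for simulation studies, not an estimation tool:
#' randomised sampling locations require the area function to be evaluable at
#' arbitrary positions.
#'
#' @param positions strictly increasing axial positions (mm), at least 4.
#' @param areas nonnegative areas (mm^2), same length; first and last zero.
#' @return An [area_function()] with `m = 1`.
#' @examples
#' af <- spline_area_function(0:4, c(0, 3, 5, 3, 0))
#' af$fun(1)   # 3, interpolation
#' @export
spline_area_function <- function(positions, areas) {
  positions <- as.numeric(positions); areas <- as.numeric(areas)
  if (length(positions) < 4L)
    stop("need at least 4 interpolation points", call. = FALSE)
  if (length(areas) != length(positions))
    stop("'positions' and 'areas' must have equal length", call. = FALSE)
  if (any(diff(positions) <= 0))
    stop("'positions' must be strictly increasing", call. = FALSE)
  if (any(areas < 0))
    stop("'areas' must be nonnegative", call. = FALSE)
  if (areas[1L] != 0 || areas[length(areas)] != 0)
    stop("first and last areas must be zero (compact support)", call. = FALSE)
  sp <- stats::splinefun(positions, areas, method = "natural")
  lo <- positions[1L]; hi <- positions[length(positions)]
  f <- function(x) ifelse(x >= lo & x <= hi, pmax(sp(x), 0), 0)
  area_function(f, c(lo, hi), m = 1)
}

#' Truncate an area function to create a 0-oriented object
#'
#' Restricts an area function to `[support_lo, cut]`, setting it to zero
#' beyond the cut. If the function is positive at the cut this introduces a
#' single jump discontinuity, turning a 1-oriented object into a 0-oriented
#' one (the standard way to obtain an `m = 0` example: the truncation plane
#' acts like a flat face parallel to the sections).
#'
#' @param fn an [area_function()].
#' @param cut axial position strictly inside the support with `fn$fun(cut) > 0`.
#' @return An [area_function()] with `m = 0` and recomputed volume.
#' @examples
#' half <- truncate_area_function(ball_area_function(1), 0)
#' half$volume  # 2*pi/3
#' @export
truncate_area_function <- function(fn, cut) {
  stopifnot(inherits(fn, "area_function"))
  if (!is.numeric(cut) || length(cut) != 1L ||
      cut <= fn$support[1] || cut >= fn$support[2])
    stop("'cut' must lie strictly inside the support", call. = FALSE)
  if (fn$fun(cut) <= 0)
    stop("'fn' must be positive at 'cut' (no discontinuity created otherwise)",
         call. = FALSE)
  g <- fn$fun
  f <- function(x) ifelse(x <= cut, g(x), 0)
  vol <- integrate_area(g, fn$support[1], cut)
  area_function(f, c(fn$support[1], cut), m = 0, volume = vol)
}

#' Convert point counts to area estimates
#'
#' Area estimation by point counting: a transparent grid with a known area
#' per point is superimposed uniformly at random on the section and the
#' points hitting the profile are counted. The unbiased area estimate is
#' count times area-per-point.
#'
#' @param counts nonnegative integer point counts.
#' @param area_per_point grid constant \eqn{a} (mm^2 per point), positive.
#' @return Numeric vector of areas (mm^2).
#' @examples
#' point_counts_to_areas(c(0, 10, 0), 2.29)
#' @export
point_counts_to_areas <- function(counts, area_per_point) {
  if (!is.numeric(counts) || any(counts < 0) ||
      any(counts != round(counts), na.rm = TRUE))
    stop("'counts' must be nonnegative integers", call. = FALSE)
  if (!is.numeric(area_per_point) || length(area_per_point) != 1L ||
      area_per_point <= 0)
    stop("'area_per_point' must be positive", call. = FALSE)
  as.numeric(counts) * area_per_point
}

#' Synthesise a lobe-like section table and area profile
#'
#' Generates a synthetic specimen emulating agar-embedded primate parietal
#' lobes cut into nominally 2.5-mm slabs whose cut-surface areas are
#' estimated by point counting with an area per point of 2.29 mm^2. The
#' defaults are calibrated so that the expected total number of counted
#' points per specimen is `total_points` (645 by default, across all slabs).
#'
#' The underlying "true" profile is a smooth, mildly asymmetric bump (a
#' scaled beta-density shape) whose integral equals
#' `total_points * area_per_point * nominal_gap`, placed with a uniform
#' random shift relative to the cut lattice so the section process is
#' stationary. Cut positions follow the perturbed sampling model (intended
#' equidistant cuts displaced by independent truncated-normal errors), and
#' each interior cut surface yields a Poisson point count with mean
#' area / area-per-point. Poisson counting noise is a standard stand-in for
#' the systematic uniform grid used at the bench; the synthetic profiles
#' match published summary characteristics (slab count, nominal gap, point
#' budget), not any real specimen.
#'
#' @param seed integer seed; the output is reproducible given the seed.
#' @param n_slabs number of slabs (12-15 recommended).
#' @param nominal_gap intended slab thickness (mm).
#' @param area_per_point point-counting grid constant (mm^2).
#' @param rel_dev average relative deviation of slab thickness from
#'   `nominal_gap` (the cut-position perturbation level).
#' @param total_points expected total point count across all slabs.
#' @return A list with `table` (data frame `position_mm`, `points`,
#'   `area_mm2`, one row per cut surface, `n_slabs + 1` rows), `area_function`
#'   (the spline profile rebuilt from the noisy table, as an analysis would
#'   see it) and `true_area_function` (the noise-free generating profile).
#' @examples
#' lobe <- synthesize_lobe_profile(seed = 1)
#' head(lobe$table)
#' @export
synthesize_lobe_profile <- function(seed, n_slabs = 13L, nominal_gap = 2.5,
                                    area_per_point = 2.29, rel_dev = 0.05,
                                    total_points = 645) {
  if (!is.numeric(n_slabs) || n_slabs < 4L)
    stop("'n_slabs' must be at least 4", call. = FALSE)
  if (nominal_gap <= 0) stop("'nominal_gap' must be positive", call. = FALSE)
  if (area_per_point <= 0)
    stop("'area_per_point' must be positive", call. = FALSE)
  if (!missing(seed) && !is.null(seed)) set.seed(seed)
  n_slabs <- as.integer(n_slabs)
  gap <- nominal_gap

  # target volume making the expected total point count exact under
  # stationary placement: E[sum areas] = V / gap
  V <- total_points * area_per_point * gap

  # smooth asymmetric unimodal bump with support strictly inside the cut
  # range and nonzero boundary slopes, so the profile is genuinely
  # 1-oriented (the derivative jumps at both support ends, as it does for
  # spline profiles through zero end areas); a uniform shift over one
  # period makes the section process stationary
  L <- (n_slabs - 3) * gap
  shift <- stats::runif(1, 0, gap)
  lo <- gap + shift
  kappa <- 0.6                          # mild asymmetry
  bnorm <- 1 / 6 + kappa / 12           # int_0^1 u(1-u)(1+k u) du
  profile <- function(x) {
    u <- (x - lo) / L
    ifelse(u > 0 & u < 1, V / (L * bnorm) * u * (1 - u) * (1 + kappa * u), 0)
  }
  truth <- area_function(profile, c(lo, lo + L), m = 1, volume = V)

  # perturbed cut positions: intended lattice 0, gap, ..., n_slabs*gap
  sigma <- calibrate_dispersion("perturbed", gap, rel_dev)
  cuts <- (0:n_slabs) * gap + rtruncnorm(n_slabs + 1L, sigma, gap / 2)

  lambda <- profile(cuts) / area_per_point
  counts <- stats::rpois(length(cuts), lambda)
  areas <- point_counts_to_areas(counts, area_per_point)
  tab <- data.frame(position_mm = cuts, points = counts, area_mm2 = areas)
  fit <- spline_area_function(tab$position_mm, tab$area_mm2)
  list(table = tab, area_function = fit, true_area_function = truth)
}
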