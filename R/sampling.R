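#' Sampling specification for section positions
#'
#' Describes how the random positions of the section planes arise. Three
#' stationary models are supported:
#' \describe{
#'   \item{equidistant}{a lattice `{U + j T}` with uniform start `U`, the
#'     classical Cavalieri design;}
#'   \item{perturbed}{equidistant intended positions each displaced by an
#'     independent zero-mean truncated-normal error (a knife drifting
#'     independently at each cut);}
#'   \item{cumulative}{consecutive slice thicknesses independent and
#'     identically distributed, so placement errors accumulate (free-hand
#'     slicing against a stop).}
#' }
#' The dispersion is parameterised by the average relative deviation of the
#' slice thickness from its mean `T`, i.e. `E|h - T| / T`.
#'
#' @param model `"equidistant"`, `"perturbed"` or `"cumulative"`.
#' @param mean_gap mean section spacing `T` (mm), positive.
#' @param rel_dev average relative deviation of slice thickness from
#'   `mean_gap`; in `[0, 0.5)`. Default 0.05.
#' @param dropout_prob probability in `[0, 1)` that an interior section is
#'   lost (independent thinning). Default 0.
#' @param seed optional integer seed consumed when positions are drawn.
#' @return An object of class `sampling_spec`.
#' @export
sampling_spec <- function(model = c("equidistant", "perturbed", "cumulative"),
                          mean_gap, rel_dev = 0.05, dropout_prob = 0,
                          seed = NULL) {
  model <- match.arg(model)
  if (!is.numeric(mean_gap) || length(mean_gap) != 1L || mean_gap <= 0)
    stop("'mean_gap' must be a positive number", call. = FALSE)
  if (rel_dev < 0 || rel_dev >= 0.5)
    stop("'rel_dev' must be in [0, 0.5)", call. = FALSE)
  if (dropout_prob < 0 || dropout_prob >= 1)
    stop("'dropout_prob' must be in [0, 1)", call. = FALSE)
  structure(list(model = model, mean_gap = mean_gap, rel_dev = rel_dev,
                 dropout_prob = dropout_prob, seed = seed),
            class = "sampling_spec")
}

#' @export
print.sampling_spec <- function(x, ...) {
  cat(sprintf("Sampling model '%s': T = %g mm, rel_dev = %g, dropout = %g\n",
              x$model, x$mean_gap, x$rel_dev, x$dropout_prob))
  invisible(x)
}

# Draw from N(0, sd^2) truncated to (-bound, bound), by inverse CDF.
rtruncnorm <- function(n, sd, bound) {
  if (sd == 0) return(numeric(n))
  plo <- stats::pnorm(-bound / sd)
  stats::qnorm(plo + stats::runif(n) * (1 - 2 * plo)) * sd
}

# CDF of the truncated normal above.
ptruncnorm <- function(x, sd, bound) {
  plo <- stats::pnorm(-bound / sd)
  p <- (stats::pnorm(x / sd) - plo) / (1 - 2 * plo)
  pmin(pmax(p, 0), 1)
}

# E|X| for X ~ N(0, sd^2) truncated to (-bound, bound); closed form.
etrunc_abs <- function(sd, bound) {
  if (sd == 0) return(0)
  z <- bound / sd
  2 * sd * (stats::dnorm(0) - stats::dnorm(z)) / (2 * stats::pnorm(z) - 1)
}

# E|X - X'| for iid X, X' ~ N(0, sd^2) truncated to (-bound, bound),
# via E|X - X'| = 2 int F(t)(1 - F(t)) dt.
etrunc_absdiff <- function(sd, bound) {
  if (sd == 0) return(0)
  2 * stats::integrate(function(t) {
    Ft <- ptruncnorm(t, sd, bound)
    Ft * (1 - Ft)
  }, -bound, bound, rel.tol = 1e-10)$value
}

# cache for unit-gap calibrations, keyed by "<model>:<rel_dev>"
.calib_cache <- new.env(parent = emptyenv())

#' Calibrate the dispersion parameter of a sampling model
#'
#' Solves for the standard deviation of the underlying truncated-normal law
#' such that the average relative deviation of the slice thickness from the
#' mean gap equals `rel_dev`.
#'
#' Under the perturbed model the slice thickness is
#' \eqn{h = T + D_k - D_{k-1}} with iid perturbations `D` following a
#' zero-mean normal truncated to \eqn{(-T/2, T/2)} (the largest symmetric
#' bound that guarantees ordered positions); the returned `sigma` satisfies
#' \eqn{E|D - D'|/T = } `rel_dev`. Under the cumulative model the gaps are iid
#' normal with mean `T` truncated to \eqn{(T/2, 3T/2)}; the returned scale
#' satisfies \eqn{E|h - T|/T = } `rel_dev`. Both calibrations scale linearly
#' in `T` and are solved once per `rel_dev` on the unit gap.
#'
#' @param model `"perturbed"` or `"cumulative"` (`"equidistant"` returns 0).
#' @param mean_gap mean gap `T` (mm).
#' @param rel_dev target average relative deviation, in `[0, 0.5)`.
#' @return The calibrated standard deviation (mm).
#' @export
calibrate_dispersion <- function(model, mean_gap, rel_dev) {
  stopifnot(mean_gap > 0)
  if (rel_dev < 0 || rel_dev >= 0.5)
    stop("'rel_dev' must be in [0, 0.5)", call. = FALSE)
  if (model == "equidistant" || rel_dev == 0) return(0)
  if (!model %in% c("perturbed", "cumulative"))
    stop("unknown sampling model: ", model, call. = FALSE)
  key <- paste0(model, ":", format(rel_dev, digits = 15))
  if (!is.null(.calib_cache[[key]]))
    return(.calib_cache[[key]] * mean_gap)
  # unit gap: truncation bound 1/2 in both models
  target <- function(s) {
    if (model == "perturbed") etrunc_absdiff(s, 0.5) - rel_dev
    else etrunc_abs(s, 0.5) - rel_dev
  }
  # suprema as s -> Inf: uniform(-1/2,1/2) gives E|D-D'| = 1/3, E|X| = 1/4
  sup <- if (model == "perturbed") 1 / 3 else 1 / 4
  if (rel_dev >= sup - 1e-9)
    stop(sprintf(
      "calibration failure: rel_dev = %g not attainable under truncation (max %.4g)",
      rel_dev, sup), call. = FALSE)
  s <- stats::uniroot(target, c(1e-10, 200), tol = 1e-12)$root
  .calib_cache[[key]] <- s
  s * mean_gap
}

# Positions on a window, spilling over by >= 2T on each side so that the
# object support is always covered with non-hitting planes to spare.
positions_lattice <- function(mean_gap, lo, hi, U) {
  j <- seq(floor((lo - 2 * mean_gap) / mean_gap),
           ceiling((hi + 2 * mean_gap) / mean_gap))
  U + j * mean_gap
}

#' Draw random section positions
#'
#' Generates one realisation of the section-plane positions on (a cover of)
#' the given window under the model in `spec`. All three models are
#' stationary: no part of the axis is systematically over- or under-sampled,
#' which is what makes the volume estimators unbiased. The returned positions
#' always extend at least one plane beyond each end of the window.
#'
#' @param spec a [sampling_spec()].
#' @param window numeric length-2 interval (mm) to cover; must be longer than
#'   `2 * spec$mean_gap`.
#' @return Strictly increasing numeric vector of positions (mm).
#' @export
sample_positions <- function(spec, window) {
  stopifnot(inherits(spec, "sampling_spec"), length(window) == 2)
  lo <- window[1]; hi <- window[2]; Tg <- spec$mean_gap
  if (hi - lo <= 2 * Tg)
    stop("window must be longer than twice the mean gap", call. = FALSE)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  U <- stats::runif(1, 0, Tg)
  if (spec$model == "cumulative") {
    sigma <- calibrate_dispersion("cumulative", Tg, spec$rel_dev)
    start <- lo - 2 * Tg + U
    # gaps lie in (T/2, 3T/2); this count is guaranteed to overshoot hi + 2T
    ngap <- ceiling((hi + 2 * Tg - start) / (Tg / 2)) + 1L
    gaps <- Tg + rtruncnorm(ngap, sigma, Tg / 2)
    pos <- start + c(0, cumsum(gaps))
    pos <- pos[pos <= hi + 2 * Tg]
  } else {
    pos <- positions_lattice(Tg, lo, hi, U)
    if (spec$model == "perturbed" && spec$rel_dev > 0) {
      sigma <- calibrate_dispersion("perturbed", Tg, spec$rel_dev)
      pos <- pos + rtruncnorm(length(pos), sigma, Tg / 2)
    }
  }
  pos
}

#' Ordered section series with areas and slice thicknesses
#'
#' Container for an ordered stack of sections: positions
#' \eqn{x_0 < \dots < x_N}, their areas, and the derived slice thicknesses
#' \eqn{h_k = x_k - x_{k-1}}. A series is *estimation-ready* when its first
#' and last areas are zero, i.e. the object lies strictly between the two end
#' planes -- the contract the trapezoidal estimator relies on.
#'
#' @param positions strictly increasing axial positions (mm).
#' @param areas nonnegative areas (mm^2), same length.
#' @param dropouts logical flag recording that the series has been thinned
#'   (model-specific variance estimators refuse such series).
#' @return An object of class `section_series` with elements `positions`,
#'   `areas`, `gaps`, `dropouts`.
#' @export
section_series <- function(positions, areas, dropouts = FALSE) {
  positions <- as.numeric(positions); areas <- as.numeric(areas)
  if (length(positions) != length(areas))
    stop("'positions' and 'areas' must have equal length", call. = FALSE)
  if (length(positions) < 2L)
    stop("need at least two sections", call. = FALSE)
  gaps <- diff(positions)
  if (any(gaps <= 0))
    stop("'positions' must be strictly increasing", call. = FALSE)
  if (any(areas < 0) || any(!is.finite(areas)))
    stop("'areas' must be finite and nonnegative", call. = FALSE)
  structure(list(positions = positions, areas = areas, gaps = gaps,
                 dropouts = isTRUE(dropouts)),
            class = "section_series")
}

#' @export
print.section_series <- function(x, ...) {
  N <- length(x$gaps)
  cat(sprintf(
    "Section series: %d sections, mean gap %.4g mm, total area %.6g mm^2%s\n",
    N + 1L, mean(x$gaps), sum(x$areas),
    if (x$dropouts) " (dropouts)" else ""))
  if (!is_estimation_ready(x))
    cat("  note: first/last area nonzero -- not estimation-ready\n")
  invisible(x)
}

is_estimation_ready <- function(series) {
  a <- series$areas
  a[1L] == 0 && a[length(a)] == 0
}

#' Intersect an area function with sampled section planes
#'
#' Evaluates the area function at the given plane positions and trims the
#' result to an estimation-ready series: exactly one zero-area plane is kept
#' before the first hitting plane and one after the last, so the slice
#' thicknesses adjacent to every hitting section are known.
#'
#' @param fn an [area_function()].
#' @param positions strictly increasing plane positions that cover the
#'   support of `fn` with at least one non-hitting plane on each side.
#' @return A [section_series()].
#' @export
sections_from_area_function <- function(fn, positions) {
  stopifnot(inherits(fn, "area_function"))
  a <- fn$fun(positions)
  hit <- which(a > 0)
  if (length(hit) == 0L)
    stop("no section plane hits the object: support not covered", call. = FALSE)
  if (hit[1L] == 1L || hit[length(hit)] == length(positions))
    stop("positions do not cover the support with a non-hitting plane on each side",
         call. = FALSE)
  keep <- (hit[1L] - 1L):(hit[length(hit)] + 1L)
  series <- section_series(positions[keep], a[keep])
  series$areas[c(1L, length(keep))] <- 0  # guard against evaluation fuzz
  series
}

#' Thin a section series by independent dropout
#'
#' Models lost sections: each interior section is removed independently with
#' probability `dropout_prob`; the two zero-area end planes are always
#' retained. The gaps of removed sections merge additively, so the positions
#' of the surviving sections are unchanged. The result is flagged with
#' `dropouts = TRUE`; model-specific variance estimators refuse such series
#' while the model-free estimator remains valid.
#'
#' Because a trimmed series carries no planes beyond its two end planes,
#' those end planes are spared here. In a physically thinned stack every
#' plane is at risk, and sparing the terminal planes slightly under-weights
#' the boundary sections of the trapezoidal estimator; the simulation
#' engine therefore thins the full plane process *before* trimming, which
#' preserves stationarity exactly.
#'
#' @param series an estimation-ready [section_series()].
#' @param dropout_prob probability in `[0, 1)` of losing each interior section.
#' @param seed optional integer seed.
#' @return A [section_series()] with `dropouts = TRUE` (unless
#'   `dropout_prob = 0`, where the input is returned unchanged).
#' @export
apply_dropout <- function(series, dropout_prob, seed = NULL) {
  stopifnot(inherits(series, "section_series"))
  if (dropout_prob < 0 || dropout_prob >= 1)
    stop("'dropout_prob' must be in [0, 1)", call. = FALSE)
  if (!is_estimation_ready(series))
    stop("series must be estimation-ready (zero first/last area)", call. = FALSE)
  if (dropout_prob == 0) return(series)
  if (!is.null(seed)) set.seed(seed)
  n <- length(series$positions)
  keep <- c(TRUE, stats::runif(n - 2L) >= dropout_prob, TRUE)
  section_series(series$positions[keep], series$areas[keep], dropouts = TRUE)
}
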