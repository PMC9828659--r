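#' @title Variance estimation for the trapezoidal estimator
#' @description The variance of the trapezoidal estimator is approximated by
#'   its leading *extension term* \eqn{c\,T^{2m+2}} and estimated from the
#'   data through the empirical covariogram of the section areas combined
#'   with moment estimates of the slice-thickness distribution. Three routes
#'   are available: a model-free estimator (valid under dropouts), and
#'   model-specific estimators for the perturbed and cumulative sampling
#'   models (valid only without dropouts). With constant gaps all three
#'   reduce exactly to the classical variance estimates of the Cavalieri
#'   estimator.
#' @name variance-estimation
NULL

variance_estimate <- function(value, method, m, conservative = FALSE,
                              clamped = FALSE) {
  structure(list(value = value, method = method, m = as.integer(m),
                 conservative = conservative, clamped = clamped),
            class = "variance_estimate")
}

#' @export
print.variance_estimate <- function(x, ...) {
  cat(sprintf("Variance estimate (%s, m = %d%s): %.6g mm^6\n",
              x$method, x$m,
              if (x$conservative) ", conservative x2" else "", x$value))
  if (x$clamped)
    cat("  note: raw covariogram combination was negative; clamped to 0\n")
  invisible(x)
}

#' Empirical covariogram of section areas
#'
#' Estimates the covariogram \eqn{g(x) = \int f(x+y) f(y)\,dy} of the area
#' function at integer lags:
#' \deqn{\hat g(k) = \sum_{j=0}^{N-k} Area(S_j)\,Area(S_{k+j}).}
#' It captures the autocorrelation of the cross-sectional areas and drives
#' all variance formulas, which only use lags 0, 1 and 2.
#'
#' @param areas section areas (mm^2), length `N + 1`.
#' @param max_lag largest lag `K <= N` to compute.
#' @return Numeric vector `c(g(0), ..., g(K))` (mm^4).
#' @examples
#' covariogram(c(0, 2, 3, 0), 2)  # 13 6 0
#' @export
covariogram <- function(areas, max_lag = 2L) {
  if (any(areas < 0)) stop("'areas' must be nonnegative", call. = FALSE)
  n <- length(areas)           # N + 1
  if (max_lag > n - 1L)
    stop("'max_lag' must not exceed the number of gaps N", call. = FALSE)
  vapply(0:max_lag, function(k)
    sum(areas[1:(n - k)] * areas[(1 + k):n]), numeric(1))
}

#' Empirical gamma moments of the slice thicknesses
#'
#' Model-free estimate of the moment \eqn{\gamma_{i,j}}, where
#' \eqn{T\gamma_{i,j}} is the expected `j`-th power of the distance from a
#' typical section to its `i`-th neighbour:
#' \deqn{\hat\gamma_{i,j} = \frac{N}{N-i+1}
#'   \frac{\sum_{k=0}^{N-i} (h_{k+1}+\dots+h_{k+i})^j}{h_1+\dots+h_N}.}
#' For constant gaps `T` this equals \eqn{i^j T^{j-1}} exactly.
#'
#' @param gaps slice thicknesses \eqn{h_1..h_N} (mm).
#' @param i neighbour order, `1 <= i <= N`.
#' @param j power, `>= 1`.
#' @return The estimate \eqn{\hat\gamma_{i,j}} (mm^(j-1)).
#' @examples
#' gamma_moment(c(1, 3), 1, 2)  # 2.5
#' @export
gamma_moment <- function(gaps, i, j) {
  N <- length(gaps)
  if (i < 1L || i > N)
    stop("'i' must be between 1 and the number of gaps N", call. = FALSE)
  if (j < 1L) stop("'j' must be at least 1", call. = FALSE)
  cs <- cumsum(c(0, gaps))
  w <- cs[(i + 1L):(N + 1L)] - cs[1:(N - i + 1L)]  # rolling sums of width i
  N / (N - i + 1) * sum(w^j) / sum(gaps)
}

#' Thickness moments under the perturbed model
#'
#' The mean, variance and fourth centred moment of the thickness of a
#' typical slice,
#' \deqn{\hat T = \frac1N \sum h_k,\quad
#'   \hat\theta_2 = \frac1N \sum (h_k - \hat T)^2,\quad
#'   \hat\theta_4 = \frac1N \sum (h_k - \hat T)^4.}
#' With `refined = TRUE` the slightly debiased alternatives
#' \eqn{\hat\theta_2 N^2/(N^2-1)} for \eqn{\theta_2} and
#' \eqn{\hat T^2 - \hat\theta_2/(N^2-1)} for \eqn{T^2} are also returned;
#' in practice they are indistinguishable from the plain estimates unless
#' `N` is very small.
#'
#' @param gaps slice thicknesses (mm), at least 2.
#' @param refined also return the refined \eqn{\theta_2} and \eqn{T^2}.
#' @return List with `T_hat`, `theta2`, `theta4` and, if refined,
#'   `theta2_refined`, `T2_refined`.
#' @examples
#' perturbed_moments(c(1, 1, 2))  # T_hat 4/3, theta2 2/9
#' @export
perturbed_moments <- function(gaps, refined = FALSE) {
  N <- length(gaps)
  if (N < 2L) stop("need at least 2 gaps", call. = FALSE)
  T_hat <- mean(gaps)
  d <- gaps - T_hat
  out <- list(T_hat = T_hat, theta2 = mean(d^2), theta4 = mean(d^4))
  if (refined) {
    out$theta2_refined <- out$theta2 * N^2 / (N^2 - 1)
    out$T2_refined <- T_hat^2 - out$theta2 / (N^2 - 1)
  }
  out
}

#' Raw thickness moments under the cumulative model
#'
#' \deqn{\hat\nu_j = \frac1N \sum_k h_k^j, \qquad j = 1..5.}
#' \eqn{\hat\nu_1} coincides with the mean thickness \eqn{\hat T}.
#'
#' @param gaps slice thicknesses (mm), nonempty.
#' @return Named numeric vector `nu1..nu5` (mm^j).
#' @examples
#' cumulative_moments(c(1, 1, 2))[["nu3"]]  # 10/3
#' @export
cumulative_moments <- function(gaps) {
  if (length(gaps) < 1L) stop("need at least 1 gap", call. = FALSE)
  v <- vapply(1:5, function(j) mean(gaps^j), numeric(1))
  names(v) <- paste0("nu", 1:5)
  v
}

check_varest_input <- function(series, m) {
  stopifnot(inherits(series, "section_series"))
  if (!m %in% c(0, 1))
    stop("smoothness index 'm' must be 0 or 1", call. = FALSE)
  if (!is_estimation_ready(series))
    stop("series must be estimation-ready (zero first/last area)", call. = FALSE)
  if (length(series$gaps) < 2L)
    stop("need at least 2 gaps for variance estimation", call. = FALSE)
}

clamp_variance <- function(v, method, m, what = "variance estimate") {
  clamped <- FALSE
  if (v < 0) {
    warning(sprintf("negative %s (%.4g) clamped to 0", what, v), call. = FALSE)
    v <- 0; clamped <- TRUE
  }
  variance_estimate(v, method, m, clamped = clamped)
}

#' Model-free variance estimation
#'
#' Estimates the variance of the trapezoidal estimator without any model for
#' the slice thicknesses, from the covariogram and the empirical gamma
#' moments. For a 0-oriented object (`m = 0`):
#' \deqn{\widehat{var} = (3\hat g(0) - 4\hat g(1) + \hat g(2)) \cdot
#'   \tfrac{1}{12}\hat\gamma_{1,3};}
#' for a 1-oriented object (`m = 1`):
#' \deqn{\widehat{var} =
#'   \frac{\hat g(0)(\hat\gamma_{2,2}-\hat\gamma_{1,2})
#'         - \hat g(1)\hat\gamma_{2,2} + \hat g(2)\hat\gamma_{1,2}}
#'        {\hat\gamma_{1,2}\hat\gamma_{2,3} - \hat\gamma_{2,2}\hat\gamma_{1,3}}
#'   \cdot \tfrac{1}{120}(12\hat\gamma_{1,5} - 10\hat\gamma_{1,3}^2).}
#' Valid with or without dropouts; with constant gaps both reduce exactly to
#' the classical equidistant estimates (see [varest_equidistant()]).
#'
#' @param series an estimation-ready [section_series()].
#' @param m orientation/smoothness index, 0 or 1.
#' @return A `variance_estimate` (mm^6). Negative covariogram combinations
#'   (possible on pathological inputs) are clamped to 0 with a warning.
#' @examples
#' s <- section_series(c(0, 1, 2, 4), c(0, 2, 3, 0))
#' varest_model_free(s, m = 0)$value  # 3.125
#' @export
varest_model_free <- function(series, m = 1) {
  check_varest_input(series, m)
  g <- covariogram(series$areas, 2L)
  h <- series$gaps
  if (m == 0) {
    v <- (3 * g[1] - 4 * g[2] + g[3]) * gamma_moment(h, 1, 3) / 12
  } else {
    g12 <- gamma_moment(h, 1, 2); g22 <- gamma_moment(h, 2, 2)
    g13 <- gamma_moment(h, 1, 3); g23 <- gamma_moment(h, 2, 3)
    g15 <- gamma_moment(h, 1, 5)
    den <- g12 * g23 - g22 * g13
    if (abs(den) < 1e-14 * max(g12 * g23, g22 * g13, 1e-300))
      stop("degenerate gamma moments: denominator of the m = 1 formula vanishes",
           call. = FALSE)
    v <- (g[1] * (g22 - g12) - g[2] * g22 + g[3] * g12) / den *
      (12 * g15 - 10 * g13^2) / 120
  }
  clamp_variance(unname(v), "model_free", m)
}

#' Variance estimation under the perturbed model (no dropouts)
#'
#' Model-specific variance estimator assuming the section positions arise
#' from independent perturbations of an equidistant lattice, using the
#' covariogram together with the thickness moments \eqn{\hat T},
#' \eqn{\hat\theta_2}, \eqn{\hat\theta_4}. For `m = 0`:
#' \deqn{\widehat{var} = (3\hat g(0)-4\hat g(1)+\hat g(2)) \cdot
#'   \tfrac{1}{12}(\hat T^2 + 3\hat\theta_2);}
#' for `m = 1`:
#' \deqn{\widehat{var} =
#'   \frac{3\hat g(0)\hat T^2 - \hat g(1)(4\hat T^2+\hat\theta_2)
#'         + \hat g(2)(\hat T^2+\hat\theta_2)}
#'        {3\hat\theta_2^2 + \hat\theta_2\hat T^2 + 4\hat T^4}
#'   \cdot \tfrac{1}{60}(\hat T^4 + 30\hat\theta_2\hat T^2 + 30\hat\theta_4
#'         - 45\hat\theta_2^2).}
#' The formulas are only valid for sampling *without* dropouts; thinned
#' series are refused (use [varest_after_dropout()] instead). With
#' `refined = TRUE` (m = 0 only, where the corrections are available) the
#' slightly debiased \eqn{\theta_2} and \eqn{T^2} estimates are substituted.
#'
#' @inheritParams varest_model_free
#' @param refined use the refined moment corrections in the `m = 0` formula.
#' @return A `variance_estimate` (mm^6).
#' @examples
#' s <- section_series(c(0, 1, 2, 4), c(0, 2, 3, 0))
#' varest_perturbed(s, m = 0)$value  # 55/18
#' @export
varest_perturbed <- function(series, m = 1, refined = FALSE) {
  check_varest_input(series, m)
  if (series$dropouts)
    stop("perturbed-model variance formulas are not valid after dropouts; ",
         "use varest_after_dropout()", call. = FALSE)
  g <- covariogram(series$areas, 2L)
  mom <- perturbed_moments(series$gaps, refined = refined)
  T2 <- mom$T_hat^2; th2 <- mom$theta2; th4 <- mom$theta4
  if (m == 0) {
    if (refined) { T2 <- mom$T2_refined; th2 <- mom$theta2_refined }
    v <- (3 * g[1] - 4 * g[2] + g[3]) * (T2 + 3 * th2) / 12
  } else {
    v <- (3 * g[1] * T2 - g[2] * (4 * T2 + th2) + g[3] * (T2 + th2)) /
      (3 * th2^2 + th2 * T2 + 4 * T2^2) *
      (T2^2 + 30 * th2 * T2 + 30 * th4 - 45 * th2^2) / 60
  }
  clamp_variance(unname(v), "perturbed", m)
}

#' Variance estimation under the cumulative model (no dropouts)
#'
#' Model-specific variance estimator assuming independent identically
#' distributed slice thicknesses, using the covariogram together with the raw
#' moments \eqn{\hat\nu_j}. For `m = 0`:
#' \deqn{\widehat{var} = (3\hat g(0)-4\hat g(1)+\hat g(2)) \cdot
#'   \tfrac{1}{12}\,\hat\nu_3/\hat T;}
#' for `m = 1`:
#' \deqn{\widehat{var} =
#'   \frac{\hat g(0)(2\hat T^2+\hat\nu_2) - \hat g(1)(2\hat T^2+2\hat\nu_2)
#'         + \hat g(2)\hat\nu_2}
#'        {6\hat\nu_2^2\hat T^2 - 2\hat\nu_3\hat T^3}
#'   \cdot \tfrac{1}{120}(12\hat\nu_5\hat T - 10\hat\nu_3^2).}
#' Not valid after dropouts; thinned series are refused.
#'
#' @inheritParams varest_model_free
#' @return A `variance_estimate` (mm^6).
#' @examples
#' s <- section_series(c(0, 1, 2, 4), c(0, 2, 3, 0))
#' varest_cumulative(s, m = 0)$value  # 3.125
#' @export
varest_cumulative <- function(series, m = 1) {
  check_varest_input(series, m)
  if (series$dropouts)
    stop("cumulative-model variance formulas are not valid after dropouts; ",
         "use varest_after_dropout()", call. = FALSE)
  g <- covariogram(series$areas, 2L)
  nu <- cumulative_moments(series$gaps)
  T_hat <- nu[["nu1"]]; n2 <- nu[["nu2"]]; n3 <- nu[["nu3"]]; n5 <- nu[["nu5"]]
  if (m == 0) {
    v <- (3 * g[1] - 4 * g[2] + g[3]) * (n3 / T_hat) / 12
  } else {
    T2 <- T_hat^2
    v <- (g[1] * (2 * T2 + n2) - g[2] * (2 * T2 + 2 * n2) + g[3] * n2) /
      (6 * n2^2 * T2 - 2 * n3 * T_hat^3) *
      (12 * n5 * T_hat - 10 * n3^2) / 120
  }
  clamp_variance(unname(v), "cumulative", m)
}

#' Classical equidistant variance estimates
#'
#' The standard variance estimates of the Cavalieri estimator for sections a
#' fixed distance `T` apart:
#' \deqn{\tfrac{T^2}{12}(3\hat g(0)-4\hat g(1)+\hat g(2)) \quad (m=0), \qquad
#'   \tfrac{T^2}{240}(3\hat g(0)-4\hat g(1)+\hat g(2)) \quad (m=1).}
#' All non-equidistant estimators in this package reduce exactly to these
#' when the gaps are constant.
#'
#' @param areas section areas (mm^2).
#' @param T section spacing (mm), positive.
#' @param m orientation/smoothness index, 0 or 1.
#' @return A `variance_estimate` (mm^6).
#' @examples
#' varest_equidistant(c(0, 2, 3, 0), 1, m = 0)$value  # 1.25
#' varest_equidistant(c(0, 2, 3, 0), 1, m = 1)$value  # 0.0625
#' @export
varest_equidistant <- function(areas, T, m = 1) {
  if (!is.numeric(T) || length(T) != 1L || T <= 0)
    stop("'T' must be a positive number", call. = FALSE)
  if (!m %in% c(0, 1))
    stop("smoothness index 'm' must be 0 or 1", call. = FALSE)
  g <- covariogram(areas, 2L)
  S <- 3 * g[1] - 4 * g[2] + g[3]
  v <- if (m == 0) T^2 / 12 * S else T^2 / 240 * S
  clamp_variance(unname(v), "equidistant", m)
}

#' Conservative variance bound for 1-oriented objects
#'
#' The oscillating Zitterbewegung component of the variance of the
#' trapezoidal estimator can never exceed the extension term for a large
#' class of 1-oriented objects, so doubling the estimated extension term is
#' a conservative variance estimate that accounts for the oscillation. The
#' bound is only stated for `m = 1`; `m = 0` inputs are refused.
#'
#' @param est a `variance_estimate` with `m = 1`.
#' @return The input with `value` doubled and `conservative = TRUE`.
#' @export
conservative_bound <- function(est) {
  stopifnot(inherits(est, "variance_estimate"))
  if (est$m != 1)
    stop("the conservative x2 bound is only available for 1-oriented objects",
         call. = FALSE)
  est$value <- 2 * est$value
  est$conservative <- TRUE
  est
}

#' Variance estimation after dropouts
#'
#' When sections are lost, the model-free estimator remains applicable by
#' simply disregarding the planes where the area is unknown: the thinned
#' series (with additively merged gaps) is fed to [varest_model_free()].
#' Model-specific estimators must not be used because thinning destroys the
#' sampling-model assumptions.
#'
#' @param series a thinned, estimation-ready [section_series()] (as returned
#'   by [apply_dropout()]).
#' @inheritParams varest_model_free
#' @return A `variance_estimate` (mm^6) with method `"model_free"`.
#' @export
varest_after_dropout <- function(series, m = 1) {
  varest_model_free(series, m)
}
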