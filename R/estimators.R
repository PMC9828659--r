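#' @title Volume estimators from planar sections
#' @description Point estimators of object volume from an ordered series of
#'   parallel planar sections. All three estimators are unbiased when the
#'   section positions arise from a stationary (translation-invariant)
#'   sampling mechanism, but their variances differ sharply once the sections
#'   are not exactly equidistant.
#' @name volume-estimators
NULL

volume_estimate <- function(value, method, n_sections) {
  structure(list(value = value, method = method,
                 n_sections = as.integer(n_sections)),
            class = "volume_estimate")
}

#' @export
print.volume_estimate <- function(x, ...) {
  cat(sprintf("Volume estimate (%s): %.6g mm^3 from %d sections\n",
              x$method, x$value, x$n_sections))
  invisible(x)
}

#' Classical Cavalieri volume estimator
#'
#' \eqn{\hat Q = T \sum_k Area(S_k)}: the fixed spacing times the sum of the
#' section areas. Exact and unbiased for equidistant sections with spacing
#' `T` and uniform random start; applying it with non-equidistant sections
#' requires `T` to be supplied explicitly and inflates the variance.
#'
#' @param T section spacing (mm), positive.
#' @param areas nonnegative section areas (mm^2).
#' @return A `volume_estimate` (fields `value`, `method`, `n_sections`).
#' @examples
#' cavalieri_estimate(1, c(0, 5, 0))$value  # 5
#' @export
cavalieri_estimate <- function(T, areas) {
  if (!is.numeric(T) || length(T) != 1L || T <= 0)
    stop("'T' must be a positive number", call. = FALSE)
  if (any(areas < 0)) stop("'areas' must be nonnegative", call. = FALSE)
  volume_estimate(T * sum(areas), "cavalieri", length(areas))
}

#' Generalized Cavalieri estimator
#'
#' The Cavalieri form with the *average* observed gap substituted for the
#' fixed spacing: \eqn{\bar h \sum_k Area(S_k)}. Still unbiased under
#' stationary sampling, but its variance can be far larger than in the
#' equidistant case; the trapezoidal estimator is preferable whenever the
#' individual slice thicknesses are known.
#'
#' @param series an estimation-ready [section_series()].
#' @return A `volume_estimate`.
#' @examples
#' s <- section_series(c(0, 1, 3, 4), c(0, 2, 3, 0))
#' generalized_cavalieri_estimate(s)$value  # 20/3
#' @export
generalized_cavalieri_estimate <- function(series) {
  stopifnot(inherits(series, "section_series"))
  if (length(series$gaps) < 2L)
    stop("need at least two gaps", call. = FALSE)
  volume_estimate(mean(series$gaps) * sum(series$areas),
                  "generalized_cavalieri", length(series$areas))
}

#' Trapezoidal volume estimator
#'
#' \deqn{\hat Q_1 = \sum_{k=1}^{N} \frac{h_k + h_{k+1}}{2} Area(S_k),}
#' each section area weighted by the mean of its two adjacent slice
#' thicknesses. This equals the trapezoid-rule integral of the observed
#' (position, area) profile, and uses the actual sampling locations to adapt
#' to non-equidistant sections. Since \eqn{Area(S_N) = 0} the `k = N` term
#' vanishes and the sum is implemented over \eqn{k = 1..N-1}, which is
#' algebraically identical.
#'
#' Requires an estimation-ready series (zero first and last area, i.e. the
#' object strictly contained between the end planes, with all gaps known).
#' Coincides with the classical Cavalieri estimator when the gaps are
#' constant, and remains unbiased under stationary sampling with or without
#' dropouts.
#'
#' @param series an estimation-ready [section_series()].
#' @return A `volume_estimate`.
#' @examples
#' s <- section_series(c(0, 1, 2), c(0, 5, 0))
#' trapezoidal_estimate(s)$value  # 5
#' @export
trapezoidal_estimate <- function(series) {
  stopifnot(inherits(series, "section_series"))
  if (!is_estimation_ready(series))
    stop("first and last areas must be zero: object not strictly contained ",
         "between the end planes", call. = FALSE)
  volume_estimate(trap_value(series$gaps, series$areas), "trapezoidal",
                  length(series$areas))
}

# bare-vector fast path shared with the simulation engine
trap_value <- function(gaps, areas) {
  N <- length(gaps)
  if (N < 2L) return(0)
  sum((gaps[-N] + gaps[-1L]) / 2 * areas[2:N])
}
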