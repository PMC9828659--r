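#' Read a section table from CSV
#'
#' Expects a comma-separated file with a header and dot decimals. Positions
#' come from a `position_mm` column, or from a `thickness_mm` column holding
#' the thickness of the slice *preceding* each section (first entry 0 or
#' empty), converted by cumulative summation. Areas come from `area_mm2`, or
#' from a `points` column multiplied by `area_per_point` when `area_mm2` is
#' absent. All units are fixed: mm, mm^2.
#'
#' If the first or last area is nonzero the series is not estimation-ready
#' (the object may not be strictly contained between the end planes) and a
#' warning is raised; the trapezoidal estimator will refuse such series.
#'
#' @param path CSV file path.
#' @param area_per_point grid constant (mm^2) required when only `points` is
#'   present.
#' @return A [section_series()].
#' @export
read_section_table <- function(path, area_per_point = NULL) {
  tab <- utils::read.csv(path, header = TRUE)
  if (!nrow(tab)) stop("empty section table: ", path, call. = FALSE)
  if ("position_mm" %in% names(tab)) {
    pos <- as.numeric(tab$position_mm)
    if (anyNA(pos))
      stop("non-numeric position_mm at row(s) ",
           paste(which(is.na(pos)), collapse = ", "), call. = FALSE)
  } else if ("thickness_mm" %in% names(tab)) {
    th <- as.numeric(tab$thickness_mm)
    if (is.na(th[1L]) || th[1L] == 0) th[1L] <- 0
    else stop("first thickness_mm entry must be 0 or empty (no slice ",
              "precedes the first section)", call. = FALSE)
    if (anyNA(th))
      stop("non-numeric thickness_mm at row(s) ",
           paste(which(is.na(th)), collapse = ", "), call. = FALSE)
    if (any(th[-1L] <= 0))
      stop("non-positive thickness_mm at row(s) ",
           paste(which(th <= 0)[-1L], collapse = ", "), call. = FALSE)
    pos <- cumsum(th)
  } else {
    stop("need a 'position_mm' or 'thickness_mm' column", call. = FALSE)
  }
  if (any(diff(pos) <= 0))
    stop("positions not strictly increasing at row(s) ",
         paste(which(diff(pos) <= 0) + 1L, collapse = ", "), call. = FALSE)
  if ("area_mm2" %in% names(tab)) {
    areas <- as.numeric(tab$area_mm2)
  } else if ("points" %in% names(tab)) {
    if (is.null(area_per_point))
      stop("table has point counts only; supply 'area_per_point'",
           call. = FALSE)
    areas <- point_counts_to_areas(tab$points, area_per_point)
  } else {
    stop("need an 'area_mm2' or 'points' column", call. = FALSE)
  }
  if (any(areas < 0))
    stop("negative area at row(s) ",
         paste(which(areas < 0), collapse = ", "), call. = FALSE)
  series <- section_series(pos, areas)
  if (!is_estimation_ready(series))
    warning("first/last area nonzero: series is not estimation-ready ",
            "(object may not be strictly contained between the end planes)",
            call. = FALSE)
  series
}

#' Write a section table to CSV
#'
#' Writes the `position_mm,area_mm2` dialect read by [read_section_table()];
#' `write_section_table(read_section_table(p), p)` is the identity on valid
#' tables.
#'
#' @param series a [section_series()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_section_table <- function(series, path) {
  stopifnot(inherits(series, "section_series"))
  utils::write.csv(
    data.frame(position_mm = series$positions, area_mm2 = series$areas),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Estimate volume and its variance from a section series
#'
#' The main estimation workflow: computes the trapezoidal volume estimate,
#' the variance estimate by the selected method, and the coefficient of
#' error `sqrt(variance) / volume`. The model-free method is the safe
#' default and the only one valid when dropouts occurred; the perturbed and
#' cumulative methods may only be requested when the user asserts that no
#' sections were lost. For 1-oriented objects the conservative x2 bound
#' accounting for the oscillating variance component can be requested.
#'
#' @param series an estimation-ready [section_series()].
#' @param method variance method: `"model_free"` (default), `"perturbed"`,
#'   `"cumulative"` or `"equidistant"` (the latter requires near-constant
#'   gaps only in spirit; it uses the mean gap as `T`).
#' @param m orientation/smoothness index: 1 (default) for objects without a
#'   flat face parallel to the sections, 0 otherwise (must be chosen
#'   deliberately; it changes the variance formula).
#' @param refined use refined moment corrections (perturbed, `m = 0` only).
#' @param conservative apply the x2 Zitterbewegung bound (`m = 1` only).
#' @return An object of class `volume_report`: list with `volume` (mm^3),
#'   `variance` (mm^6), `ce`, `n_sections`, `mean_gap`, `method`, `m`, and
#'   `details` (covariogram and moment estimates).
#' @examples
#' s <- section_series(c(0, 1, 2, 4), c(0, 2, 3, 0))
#' estimate_volume(s, method = "model_free", m = 0)
#' @export
estimate_volume <- function(series,
                            method = c("model_free", "perturbed",
                                       "cumulative", "equidistant"),
                            m = 1, refined = FALSE, conservative = FALSE) {
  stopifnot(inherits(series, "section_series"))
  method <- match.arg(method)
  if (!m %in% c(0, 1))
    stop("smoothness index 'm' must be 0 or 1", call. = FALSE)
  if (series$dropouts && method %in% c("perturbed", "cumulative"))
    stop("the '", method, "' variance formulas are not valid for series ",
         "with dropouts; use method = \"model_free\"", call. = FALSE)
  vol <- trapezoidal_estimate(series)
  var_est <- switch(method,
    model_free = varest_model_free(series, m),
    perturbed = varest_perturbed(series, m, refined = refined),
    cumulative = varest_cumulative(series, m),
    equidistant = varest_equidistant(series$areas, mean(series$gaps), m))
  if (conservative) var_est <- conservative_bound(var_est)
  mom <- perturbed_moments(series$gaps)
  out <- list(
    volume = vol$value,
    variance = var_est$value,
    ce = if (vol$value > 0) sqrt(var_est$value) / vol$value else NA_real_,
    n_sections = length(series$areas),
    mean_gap = mean(series$gaps),
    method = method, m = m, conservative = var_est$conservative,
    details = list(covariogram = covariogram(series$areas, 2L),
                   T_hat = mom$T_hat, theta2 = mom$theta2,
                   theta4 = mom$theta4,
                   nu = cumulative_moments(series$gaps)))
  class(out) <- "volume_report"
  out
}

#' @export
print.volume_report <- function(x, ...) {
  cat(sprintf("Trapezoidal volume estimate: %.6g mm^3 (%d sections, mean gap %.4g mm)\n",
              x$volume, x$n_sections, x$mean_gap))
  cat(sprintf("Variance (%s, m = %d%s): %.6g mm^6  |  CE = %.4g\n",
              x$method, x$m, if (x$conservative) ", conservative" else "",
              x$variance, x$ce))
  invisible(x)
}
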