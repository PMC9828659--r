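#' @title Monte Carlo variance studies
#' @description Tools to measure, by simulation, how the variances of the
#'   volume estimators decrease with the mean section spacing `T`: empirical
#'   variance curves over a grid of `T`, log-log least-squares decrease
#'   rates, extension-term fits, and the spacing at which perturbed sampling
#'   doubles the variance of the Cavalieri estimator relative to equidistant
#'   sampling.
#' @name variance-studies
NULL

# One simulated estimation-ready series. sigma is pre-calibrated.
#
# Dropouts are applied as independent thinning of the *full* plane process
# before trimming: every section, hitting or not, is dropped with the same
# probability, which preserves stationarity and hence the unbiasedness of
# the trapezoidal estimator (thinning only interior sections while sparing
# the terminal zero-area planes would under-weight boundary hits). The
# lattice is padded when thinning so that a retained non-hitting plane
# survives on each side with overwhelming probability.
simulate_series <- function(fn, model, Tg, sigma, dropout_prob = 0) {
  lo <- fn$support[1]; hi <- fn$support[2]
  pad <- if (dropout_prob > 0) 20 * Tg else 0
  loP <- lo - pad; hiP <- hi + pad
  if (model == "cumulative") {
    start <- loP - 2 * Tg + stats::runif(1, 0, Tg)
    ngap <- ceiling((hiP + 2 * Tg - start) / (Tg / 2)) + 1L
    gaps <- Tg + rtruncnorm(ngap, sigma, Tg / 2)
    pos <- start + c(0, cumsum(gaps))
  } else {
    pos <- positions_lattice(Tg, loP, hiP, stats::runif(1, 0, Tg))
    if (model == "perturbed" && sigma > 0)
      pos <- pos + rtruncnorm(length(pos), sigma, Tg / 2)
  }
  if (dropout_prob > 0)
    pos <- pos[stats::runif(length(pos)) >= dropout_prob]
  series <- sections_from_area_function(fn, pos)
  if (dropout_prob > 0) series$dropouts <- TRUE
  series
}

#' Run a Monte Carlo variance study
#'
#' For each mean spacing in `T_grid`, draws `reps` independent section
#' series of the object under the given sampling model, computes the
#' requested volume estimators on each, and records their empirical means
#' and variances (measured about the true volume, which the estimators are
#' unbiased for). Optionally also evaluates the variance *estimators* per
#' replicate to study their bias and coefficient of error.
#'
#' The coefficient of error of a variance estimator is defined as its
#' empirical standard deviation divided by the extension term
#' \eqn{c\,T^{2m+2}} (with `c` fitted from the empirical trapezoidal
#' variances), i.e. it describes the variability of the *variance* estimates,
#' not of the volume estimates.
#'
#' @param fn an [area_function()].
#' @param model `"equidistant"`, `"perturbed"` or `"cumulative"`.
#' @param T_grid mean spacings (mm) to study; each must be below a quarter of
#'   the support length.
#' @param reps Monte Carlo replicates per spacing (at least 100).
#' @param rel_dev average relative thickness deviation (see
#'   [calibrate_dispersion()]).
#' @param dropout_prob independent thinning probability applied to each
#'   simulated series.
#' @param estimators subset of `"trapezoidal"`, `"generalized_cavalieri"`,
#'   `"cavalieri"` (the latter uses the intended `T`, not the observed gaps).
#' @param m orientation index used for the extension exponent `2m + 2` and
#'   the variance estimators; defaults to the object's.
#' @param variance_estimators if `TRUE`, evaluate the model-free and (when
#'   `model` is not equidistant and no dropouts occur) the model-specific
#'   variance estimators per replicate.
#' @param seed optional integer seed for the whole study.
#' @return An object of class `variance_study`: a list with `table` (tidy
#'   data frame `T`, `mean_sections`, `estimator`, `mean`, `variance`),
#'   `alpha_hat` (log-log decrease rate per estimator), `extension_fit`
#'   (fitted `c` per estimator for exponent `2m + 2`), and when requested
#'   `ce_table` (per-`T` mean, SD and coefficient of error of each variance
#'   estimator along with the empirical trapezoidal variance).
#' @export
run_variance_study <- function(fn, model = c("perturbed", "cumulative",
                                             "equidistant"),
                               T_grid, reps = 5000L, rel_dev = 0.05,
                               dropout_prob = 0,
                               estimators = c("trapezoidal",
                                              "generalized_cavalieri",
                                              "cavalieri"),
                               m = fn$m, variance_estimators = FALSE,
                               seed = NULL) {
  stopifnot(inherits(fn, "area_function"))
  model <- match.arg(model)
  bad <- setdiff(estimators, c("trapezoidal", "generalized_cavalieri",
                               "cavalieri"))
  if (length(bad))
    stop("unknown estimator tag(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (reps < 2L) stop("'reps' must be at least 2", call. = FALSE)
  if (reps < 100L)
    warning("fewer than 100 replicates: variance output will be very noisy",
            call. = FALSE)
  L <- diff(fn$support)
  if (any(T_grid <= 0) || any(T_grid >= L / 4))
    stop("'T_grid' must lie in (0, support length / 4)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  Q <- fn$volume
  model_varest <- variance_estimators && model != "equidistant" &&
    dropout_prob == 0

  rows <- list(); ce_rows <- list()
  for (Tg in sort(T_grid, decreasing = TRUE)) {
    sigma <- calibrate_dispersion(
      if (model == "equidistant") "equidistant" else model, Tg, rel_dev)
    est <- matrix(NA_real_, reps, length(estimators),
                  dimnames = list(NULL, estimators))
    ve <- if (variance_estimators)
      matrix(NA_real_, reps, 2L, dimnames = list(NULL, c("model_free", model)))
    for (r in seq_len(reps)) {
      s <- simulate_series(fn, model, Tg, sigma, dropout_prob)
      if ("trapezoidal" %in% estimators)
        est[r, "trapezoidal"] <- trap_value(s$gaps, s$areas)
      if ("generalized_cavalieri" %in% estimators)
        est[r, "generalized_cavalieri"] <- mean(s$gaps) * sum(s$areas)
      if ("cavalieri" %in% estimators)
        est[r, "cavalieri"] <- Tg * sum(s$areas)
      if (variance_estimators) {
        ve[r, 1L] <- varest_value(s, m, "model_free")
        if (model_varest) ve[r, 2L] <- varest_value(s, m, model)
      }
    }
    for (e in estimators)
      rows[[length(rows) + 1L]] <- data.frame(
        T = Tg, mean_sections = L / Tg, estimator = e,
        mean = mean(est[, e]), variance = mean((est[, e] - Q)^2))
    if (variance_estimators) {
      emp_var <- mean((est[, "trapezoidal"] - Q)^2)
      for (v in colnames(ve)) {
        x <- ve[, v]
        if (all(is.na(x))) next
        ce_rows[[length(ce_rows) + 1L]] <- data.frame(
          T = Tg, estimator = v, mean = mean(x), sd = stats::sd(x),
          empirical_variance = emp_var)
      }
    }
  }
  tab <- do.call(rbind, rows)
  alpha <- vapply(estimators, function(e) {
    sub <- tab[tab$estimator == e, ]
    if (nrow(sub) >= 3L && all(sub$variance > 0))
      estimate_decrease_rate(sub$T, sub$variance) else NA_real_
  }, numeric(1))
  cfit <- vapply(estimators, function(e) {
    sub <- tab[tab$estimator == e, ]
    fit_extension_term(sub$T, sub$variance, m)
  }, numeric(1))

  out <- list(table = tab, alpha_hat = alpha, extension_fit = cfit,
              model = model, m = m, reps = reps, rel_dev = rel_dev,
              dropout_prob = dropout_prob, seed = seed)
  if (variance_estimators && length(ce_rows)) {
    ce <- do.call(rbind, ce_rows)
    ce$extension_term <- cfit[["trapezoidal"]] * ce$T^(2 * m + 2)
    ce$ce <- ce$sd / ce$extension_term
    out$ce_table <- ce
  }
  class(out) <- "variance_study"
  out
}

# silent numeric value of a variance estimator (clamp warnings suppressed:
# in bulk simulation the clamped-to-zero events are recorded in the value)
varest_value <- function(series, m, method) {
  suppressWarnings(switch(method,
    model_free = varest_model_free(series, m)$value,
    perturbed = varest_perturbed(series, m)$value,
    cumulative = varest_cumulative(series, m)$value,
    stop("unknown variance estimator: ", method, call. = FALSE)))
}

#' @export
print.variance_study <- function(x, ...) {
  cat(sprintf("Variance study: model '%s', m = %d, %d reps, %d spacings\n",
              x$model, x$m, x$reps, length(unique(x$table$T))))
  cat("Fitted decrease rates alpha_hat:\n")
  print(round(x$alpha_hat, 3))
  invisible(x)
}

#' Least-squares variance decrease rate
#'
#' Fits \eqn{\log(variance) = const + \hat\alpha \log(T)} by ordinary least
#' squares and returns the slope \eqn{\hat\alpha}; a variance decreasing
#' like \eqn{T^\alpha} as `T` shrinks yields a positive rate.
#'
#' @param T_grid spacings (mm), at least 3.
#' @param variances positive empirical variances, same length.
#' @return The fitted rate \eqn{\hat\alpha}.
#' @examples
#' Tg <- 2^-(1:6)
#' estimate_decrease_rate(Tg, 7 * Tg^4)  # 4
#' @export
estimate_decrease_rate <- function(T_grid, variances) {
  if (length(T_grid) < 3L)
    stop("need at least 3 grid points", call. = FALSE)
  if (length(variances) != length(T_grid))
    stop("'T_grid' and 'variances' must have equal length", call. = FALSE)
  if (any(variances <= 0))
    stop("'variances' must be positive", call. = FALSE)
  unname(stats::coef(stats::lm(log(variances) ~ log(T_grid)))[2L])
}

#' Fit the extension-term constant
#'
#' Least-squares fit through the origin of the empirical variances against
#' \eqn{T^{2m+2}}, returning the constant `c` of the leading variance term
#' \eqn{c\,T^{2m+2}}. The constant is not available in closed form for a
#' general area function, so it is estimated empirically.
#'
#' @param T_grid spacings (mm), nonempty.
#' @param variances empirical variances, same length.
#' @param m orientation index, 0 or 1.
#' @return The fitted constant `c` (mm^(6-(2m+2))).
#' @examples
#' Tg <- 2^-(1:6)
#' fit_extension_term(Tg, 7 * Tg^4, m = 1)  # 7
#' @export
fit_extension_term <- function(T_grid, variances, m) {
  if (length(T_grid) < 1L) stop("empty grid", call. = FALSE)
  if (length(variances) != length(T_grid))
    stop("'T_grid' and 'variances' must have equal length", call. = FALSE)
  if (!m %in% c(0, 1))
    stop("smoothness index 'm' must be 0 or 1", call. = FALSE)
  x <- T_grid^(2 * m + 2)
  unname(sum(x * variances) / sum(x^2))
}

# Exact (quadrature) variance of the equidistant Cavalieri estimator:
# average of (T sum f(u + jT) - Q)^2 over the uniform start u in [0, T).
equidistant_cavalieri_variance <- function(fn, Tg, n_offsets = 4096L) {
  lo <- fn$support[1]; hi <- fn$support[2]
  u <- (seq_len(n_offsets) - 0.5) / n_offsets * Tg
  j <- seq(floor((lo - Tg) / Tg), ceiling((hi + Tg) / Tg))
  M <- outer(j * Tg, u, "+")          # planes x offsets
  Qhat <- Tg * colSums(matrix(fn$fun(M), nrow = length(j)))
  mean((Qhat - fn$volume)^2)
}

#' Section count at which perturbed sampling doubles the Cavalieri variance
#'
#' Scans a fine grid of mean section counts `n = (support length) / T` and
#' locates the count at which the variance of the fixed-`T` Cavalieri
#' estimator under perturbed sampling reaches twice its variance under
#' equidistant sampling at the same `T`. The equidistant variance is
#' computed essentially exactly by quadrature over the uniform start offset;
#' the perturbed variance by Monte Carlo.
#'
#' For 1-oriented objects whose derivative jumps at two points a distance
#' `L` apart (such as a ball, where `L` is the support length), both
#' variances carry a Zitterbewegung oscillating with period 1 in `n`, so
#' the pointwise ratio swings wildly within each period and has no single
#' well-defined crossing. The doubling point therefore compares the *smooth*
#' variance components: both curves are de-trended by `T^(2m+2)`, averaged
#' over a moving window of one oscillation period, and the crossing of the
#' resulting (monotonised) ratio through 2 is located by linear
#' interpolation. This matches how the two curves separate on a log-log
#' plot, with the oscillation appearing as a symmetric wiggle around the
#' trends.
#'
#' @param fn an [area_function()] (intended: a smooth 1-oriented object such
#'   as the unit ball).
#' @param rel_dev average relative thickness deviation, in (0, 0.5).
#' @param section_range range of mean section counts to scan.
#' @param step fine scan step in mean section count (several points per
#'   oscillation period).
#' @param reps Monte Carlo replicates per scanned count (default 1e5; the
#'   variance ratio is noisy).
#' @param seed optional integer seed.
#' @return A list with `n_star` (interpolated doubling count), `T_star`,
#'   `grid` (data frame `n`, `T`, `var_equidistant`, `var_perturbed`,
#'   pointwise `ratio`) and `smooth` (data frame `n`, phase-averaged
#'   `ratio`).
#' @export
doubling_point <- function(fn, rel_dev = 0.05, section_range = c(3, 11),
                           step = 0.1, reps = 1e5, seed = NULL) {
  stopifnot(inherits(fn, "area_function"))
  if (rel_dev <= 0 || rel_dev >= 0.5)
    stop("'rel_dev' must be in (0, 0.5): degenerate perturbations admit no ",
         "doubling point", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  L <- diff(fn$support); lo <- fn$support[1]; hi <- fn$support[2]
  Q <- fn$volume
  sig1 <- calibrate_dispersion("perturbed", 1, rel_dev)
  nf <- seq(section_range[1], section_range[2], by = step)
  res <- vapply(nf, function(n) {
    Tg <- L / n
    veq <- equidistant_cavalieri_variance(fn, Tg)
    sigma <- sig1 * Tg
    j <- seq(floor((lo - Tg) / Tg), ceiling((hi + Tg) / Tg))
    U <- stats::runif(reps, 0, Tg)
    P <- outer(U, j * Tg, "+") +
      matrix(rtruncnorm(reps * length(j), sigma, Tg / 2), nrow = reps)
    Qhat <- Tg * rowSums(matrix(fn$fun(P), nrow = reps))
    c(veq, mean((Qhat - Q)^2))
  }, numeric(2))
  grid <- data.frame(n = nf, T = L / nf, var_equidistant = res[1, ],
                     var_perturbed = res[2, ])
  grid$ratio <- grid$var_perturbed / grid$var_equidistant
  # smooth components: de-trend by T^(2m+2), average over one period in n
  ex <- 2 * fn$m + 2
  trend <- grid$T^ex
  half <- 0.5
  ns0 <- nf[nf >= min(nf) + half & nf <= max(nf) - half]
  sm_ratio <- vapply(ns0, function(n0) {
    w <- abs(nf - n0) <= half
    mean(grid$var_perturbed[w] / trend[w]) /
      mean(grid$var_equidistant[w] / trend[w])
  }, numeric(1))
  iso <- stats::isoreg(ns0, sm_ratio)$yf
  smooth <- data.frame(n = ns0, ratio = iso)
  i <- which(iso >= 2)[1L]
  if (is.na(i))
    stop(sprintf(
      "smoothed variance ratio never reaches 2 on the scanned range (max %.3f)",
      max(iso)), call. = FALSE)
  if (i == 1L)
    stop(sprintf(
      "smoothed variance ratio already %.3f >= 2 at the smallest scanned count n = %.3g",
      iso[1L], ns0[1L]), call. = FALSE)
  n_star <- stats::approx(iso[(i - 1L):i], ns0[(i - 1L):i], xout = 2,
                          ties = "ordered")$y
  list(n_star = n_star, T_star = L / n_star, grid = grid, smooth = smooth)
}
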