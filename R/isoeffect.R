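#' Invert an LQ curve to the isoeffective dose
#'
#' Solves \eqn{aD + bD^2 = -\ln(y)} for the unique non-negative dose at which
#' the fitted curve passes through fraction `y`: \eqn{D = -\ln(y)/a} when
#' \eqn{b = 0}, otherwise the positive root
#' \eqn{D = (-a + \sqrt{a^2 - 4b\ln y})/(2b)}. A fraction at or above 1 means
#' no effect was observed and maps to dose 0.
#'
#' @param fit An [fit_lq()] object with `a + b > 0`.
#' @param fraction Observed fraction(s) of control, positive.
#' @return Isoeffective dose(s) in Gy.
#' @export
#' @examples
#' f <- fit_lq(c(2, 5, 10), exp(-0.1 * c(2, 5, 10)))
#' invert_lq(f, 0.5)  # -log(0.5)/0.1 = 6.93 Gy
invert_lq <- function(fit, fraction) {
  stopifnot(inherits(fit, "lq_fit"))
  if (any(fraction <= 0)) abort("fraction must be positive")
  a <- fit$a
  b <- fit$b
  if (a <= 0 && b <= 0 && any(fraction < 1)) {
    abort("curve cannot produce effect: a = b = 0")
  }
  effect <- -log(pmin(fraction, 1)) # >= 0; fraction >= 1 -> 0 Gy
  # stable form of the positive quadratic root (-a + sqrt(a^2 + 4b*e))/(2b):
  # avoids cancellation for b near 0 and reduces to e/a at b = 0
  out <- 2 * effect / (a + sqrt(a^2 + 4 * b * effect))
  out[effect == 0] <- 0
  out
}

#' Default test-to-reference time-point pairing
#'
#' Blood draws in the proton (test) schedule happened on day 4 where the
#' electron (reference) schedule sampled day 7; RBE comparisons pair those two
#' days and match all other time-points identically.
#'
#' @return A named character vector mapping test time-points to reference
#'   time-points.
#' @export
default_pairing_map <- function() {
  c("4h" = "4h", d1 = "d1", d4 = "d7", d14 = "d14", d30 = "d30")
}

#' Per-animal RBE from a reference-arm dose-response curve
#'
#' For each test-arm animal, the reference dose producing the animal's
#' observed fraction of control is read off the fitted reference curve
#' ([invert_lq()]); the RBE is that isoeffective dose divided by the dose the
#' animal actually received. A fraction at or above 1 (no observed effect)
#' gives isoeffective dose 0 and RBE 0. Records for which the inversion fails
#' are flagged rather than aborting the batch.
#'
#' @param reference_fit The reference-arm [fit_lq()] for the time-point that
#'   `pairing` maps the test records' time-point to.
#' @param test_records Normalized test-arm records of a single cell type and
#'   a single time-point (`animal_id`, `dose_gy`, `timepoint`, `cell_type`,
#'   `fraction`).
#' @param pairing Test-to-reference time-point map (see
#'   [default_pairing_map()]).
#' @return A tibble of RBE points: `animal_id`, `cell_type`,
#'   `timepoint_test`, `timepoint_reference`, `dose_test`,
#'   `fraction_observed`, `dose_isoeffective`, `rbe`, `ok`, `note`.
#' @export
rbe_per_animal <- function(reference_fit, test_records,
                           pairing = default_pairing_map()) {
  stopifnot(inherits(reference_fit, "lq_fit"))
  test_records <- tibble::as_tibble(test_records)
  tp <- unique(test_records$timepoint)
  ct <- unique(test_records$cell_type)
  if (length(tp) != 1 || length(ct) != 1) {
    abort("test_records must hold a single cell type and time-point")
  }
  if (!tp %in% names(pairing)) {
    abort(paste0("no reference pairing declared for test timepoint '", tp, "'"))
  }
  if (any(test_records$dose_gy <= 0)) {
    abort("test doses must be positive (exclude sham animals)")
  }
  iso <- rep(NA_real_, nrow(test_records))
  note <- rep(NA_character_, nrow(test_records))
  for (i in seq_len(nrow(test_records))) {
    res <- tryCatch(invert_lq(reference_fit, test_records$fraction[i]),
                    error = function(e) e)
    if (inherits(res, "error")) note[i] <- conditionMessage(res) else iso[i] <- res
  }
  tibble::tibble(
    animal_id = test_records$animal_id,
    cell_type = ct,
    timepoint_test = tp,
    timepoint_reference = unname(pairing[tp]),
    dose_test = test_records$dose_gy,
    fraction_observed = test_records$fraction,
    dose_isoeffective = iso,
    rbe = iso / test_records$dose_gy,
    ok = is.na(note),
    note = note)
}

#' Quadratic RBE-versus-dose trend
#'
#' Ordinary least squares of per-animal RBE values on dose and dose squared,
#' \eqn{RBE(D) = c_0 + c_1 D + c_2 D^2}. With the usual design of three test
#' doses and three animals per dose the quadratic saturates the design: the
#' fitted value at each dose is the per-dose replicate mean, and the residual
#' degrees of freedom (n - 3) feed the confidence intervals of
#' [fitted_rbe_with_ci()].
#'
#' @param points RBE points (see [rbe_per_animal()]); flagged records
#'   (`ok == FALSE`) are dropped.
#' @return An object of class `rbe_trend` with coefficients `c0`, `c1`, `c2`,
#'   their covariance, `residual_variance`, `df` and `ci_enabled`.
#' @export
fit_rbe_trend <- function(points) {
  points <- tibble::as_tibble(points)
  if ("ok" %in% names(points)) points <- points[points$ok, ]
  if (length(unique(points$dose_test)) < 3) {
    abort("need at least 3 distinct test doses for the quadratic trend")
  }
  if (nrow(points) < 3) abort("need at least 3 RBE points")
  m <- lm(rbe ~ dose_test + I(dose_test^2), data = points)
  df <- m$df.residual
  cf <- unname(coef(m))
  s2 <- if (df > 0) sum(m$residuals^2) / df else NA_real_
  X <- stats::model.matrix(m)
  # sigma^2 (X'X)^-1 computed directly: vcov() warns on zero-residual fits
  xtx_inv <- chol2inv(chol(crossprod(X)))
  structure(list(
    c0 = cf[1], c1 = cf[2], c2 = cf[3],
    cov = if (df > 0) s2 * xtx_inv else matrix(NA_real_, 3, 3),
    residual_variance = s2,
    df = df,
    n_points = nrow(points),
    ci_enabled = df >= 1,
    model = m), class = "rbe_trend")
}

#' @export
print.rbe_trend <- function(x, ...) {
  cat(sprintf("RBE trend: %.4g %+.4g D %+.4g D^2 (%d points, df %d)\n",
              x$c0, x$c1, x$c2, x$n_points, x$df))
  invisible(x)
}

#' Fitted RBE with a confidence interval at given test doses
#'
#' Evaluates the quadratic trend at each dose and attaches a t-based
#' confidence interval for the mean response,
#' \eqn{\hat{RBE}(D) \pm t_{1-(1-level)/2, df} \sqrt{x^T \Sigma x}} with
#' \eqn{x = (1, D, D^2)}. Negative fitted values or limits are reported as-is
#' (they occur when the trend is flat and noisy) rather than clamped.
#'
#' @param trend An [fit_rbe_trend()] object.
#' @param dose_test Test doses in Gy.
#' @param level Confidence level (default 0.95).
#' @return A tibble with `dose_test`, `rbe_fitted`, `ci_low`, `ci_high`
#'   (interval columns are `NA` when the trend has no residual degrees of
#'   freedom).
#' @export
fitted_rbe_with_ci <- function(trend, dose_test, level = 0.95) {
  stopifnot(inherits(trend, "rbe_trend"))
  X <- cbind(1, dose_test, dose_test^2)
  fitted <- drop(X %*% c(trend$c0, trend$c1, trend$c2))
  if (trend$ci_enabled) {
    se <- sqrt(rowSums((X %*% trend$cov) * X))
    tq <- qt(1 - (1 - level) / 2, trend$df)
    lo <- fitted - tq * se
    hi <- fitted + tq * se
  } else {
    lo <- hi <- rep(NA_real_, length(fitted))
  }
  tibble::tibble(dose_test = dose_test, rbe_fitted = fitted,
                 ci_low = lo, ci_high = hi)
}

#' Average RBE over selected endpoints
#'
#' Arithmetic mean and standard error of the mean of fitted RBE values across
#' the selected dose x time-point x cell-type combinations. The default
#' selection used by [run_pipeline()] is every combination where both arms'
#' dose responses were significant; here any pre-filtered table is accepted.
#'
#' @param rows A tibble with an `rbe_fitted` column (e.g. stacked
#'   [fitted_rbe_with_ci()] rows), at least 2 of them.
#' @return A list with `mean`, `sem` and `n`.
#' @export
average_rbe <- function(rows) {
  rows <- tibble::as_tibble(rows)
  v <- rows$rbe_fitted
  v <- v[!is.na(v)]
  if (length(v) < 2) abort("need at least 2 RBE values to average")
  list(mean = mean(v), sem = sd(v) / sqrt(length(v)), n = length(v))
}
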