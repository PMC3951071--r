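#' Fit the linear-quadratic exponential dose-response model
#'
#' Fits \eqn{y = e^{-aD - bD^2}} to fraction-of-control responses by least
#' squares on the untransformed fraction scale, with both sensitivity
#' coefficients constrained to be non-negative. The objective is
#' \deqn{\sum_g w_g (y_g - e^{-aD_g - bD_g^2})^2,}
#' with weights equal to group size, which makes fitting group means
#' equivalent to fitting the individual animals (the within-group sum of
#' squares does not depend on the parameters). The optimizer is L-BFGS-B with
#' an analytic gradient, multi-started from the through-origin log-scale
#' regression estimate and from (0, 0); the lowest weighted SSR wins, ties
#' going to the smaller quadratic coefficient.
#'
#' The parameter covariance is the Gauss-Newton approximation
#' \eqn{\hat\sigma^2 (J^T W J)^{-1}} at the optimum with
#' \eqn{\hat\sigma^2 = SSR/df} and, by reporting convention, \eqn{df =
#' n_{points} - 2} regardless of active bounds. The covariance is restricted
#' to the coefficients away from their bounds: a coefficient sitting at zero
#' is treated as fixed there (zero variance), because the dose and
#' dose-squared regressors are nearly collinear over a typical design and the
#' unrestricted two-parameter covariance wildly inflates the variance of the
#' coefficient that is actually driving the curve.
#'
#' Dose-response significance is an F-type test of the fitted curve against
#' the flat null \eqn{y \equiv 1} (i.e. \eqn{a = b = 0}). The F statistic uses
#' the *sign-unconstrained* least-squares fit, because under the null the
#' non-negativity bounds are active and a bounded-fit statistic would be
#' conservative; when group SEs are supplied, the within-group sum of squares
#' they encode is pooled into the error term and the error degrees of freedom
#' count individual animals (\eqn{N - 2}).
#'
#' @param dose Radiation doses in Gy (at least 3 distinct, all positive;
#'   sham/0 Gy points carry no information about (a, b) since the model forces
#'   y(0) = 1, and are excluded upstream by convention).
#' @param fraction Observed fraction of control per dose entry (group mean or
#'   individual animal).
#' @param weights Least-squares weights; use the group size when `fraction`
#'   holds group means. Default 1 (individual observations).
#' @param se Optional standard errors of the group means, used only to
#'   reconstruct the within-group variability for the significance test.
#' @param alpha Significance level for the `significant` flag.
#' @return An object of class `lq_fit`: a list with elements `a`, `b` (Gy^-1,
#'   Gy^-2), `cov` (2x2), `ssr`, `df`, `n_points`, `p_value`, `significant`,
#'   `sigma2` and the fitting data.
#' @seealso [evaluate_lq()], [invert_lq()], [effective_dose()]
#' @export
#' @examples
#' d <- c(5, 7.5, 7.7, 10, 15, 20)
#' fit <- fit_lq(d, exp(-0.06 * d), weights = rep(3, 6))
#' c(fit$a, fit$b)
fit_lq <- function(dose, fraction, weights = NULL, se = NULL, alpha = 0.05) {
  if (length(dose) != length(fraction)) {
    abort("`dose` and `fraction` must have the same length")
  }
  if (any(dose <= 0)) abort("all doses must be positive (0 Gy points are excluded from fits)")
  if (any(fraction <= 0)) abort("all fractions must be positive")
  if (length(unique(dose)) < 3) {
    abort("need at least 3 distinct positive doses to fit the LQ model")
  }
  if (is.null(weights)) weights <- rep(1, length(dose))
  if (!is.null(se) && length(se) != length(dose)) {
    abort("`se` must match `dose` in length")
  }

  ssr_fn <- function(p) {
    sum(weights * (fraction - exp(-p[1] * dose - p[2] * dose^2))^2)
  }
  grad_fn <- function(p) {
    f <- exp(-p[1] * dose - p[2] * dose^2)
    r <- fraction - f
    c(sum(2 * weights * r * f * dose), sum(2 * weights * r * f * dose^2))
  }

  # log-scale through-origin regression: the optimizer's starting point only
  log_start <- tryCatch({
    m <- lm(log(fraction) ~ 0 + dose + I(dose^2), weights = weights)
    unname(-coef(m))
  }, error = function(e) c(0, 0))

  run_bounded <- function(start) {
    tryCatch(
      optim(pmax(start, 0), ssr_fn, grad_fn, method = "L-BFGS-B",
            lower = c(0, 0),
            control = list(factr = 1e1, pgtol = 1e-14, maxit = 500)),
      error = function(e) NULL)
  }
  cands <- Filter(Negate(is.null),
                  lapply(list(c(0, 0), log_start), run_bounded))
  if (length(cands) == 0) {
    abort("LQ fit failed to converge from all starting points")
  }
  vals <- vapply(cands, `[[`, numeric(1), "value")
  bs <- vapply(cands, function(o) o$par[2], numeric(1))
  best <- cands[[order(vals, bs)[1]]] # ties broken toward smaller b
  a <- max(best$par[1], 0)
  b <- max(best$par[2], 0)
  ssr <- best$value

  n_points <- length(dose)
  df <- n_points - 2L
  sigma2 <- if (df > 0) ssr / df else NA_real_

  # Gauss-Newton covariance restricted to the active set: a coefficient
  # pinned at its bound is treated as fixed (zero variance) rather than
  # letting the near-collinear (D, D^2) pair inflate the free one
  fhat <- exp(-a * dose - b * dose^2)
  J <- cbind(-dose * fhat, -dose^2 * fhat)
  free <- c(a, b) > 0
  cov <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  if (any(free)) {
    Jf <- J[, free, drop = FALSE]
    cov[free, free] <- tryCatch(
      sigma2 * solve(crossprod(Jf, weights * Jf)),
      error = function(e) NA_real_)
  }

  # sign-unconstrained refit, used only inside the significance test
  run_free <- function(start) {
    tryCatch(
      optim(start, ssr_fn, grad_fn, method = "BFGS",
            control = list(reltol = 1e-14, maxit = 500)),
      error = function(e) NULL)
  }
  free <- Filter(Negate(is.null),
                 lapply(list(c(a, b), log_start, c(0, 0)), run_free))
  ssr_free <- min(ssr, vapply(free, `[[`, numeric(1), "value"))

  ssr_null <- sum(weights * (fraction - 1)^2)
  if (!is.null(se)) {
    n_g <- weights
    ssw <- sum(pmax(n_g - 1, 0) * (se * sqrt(n_g))^2)
    df_err <- sum(n_g) - 2
  } else {
    ssw <- 0
    df_err <- df
  }
  if (df_err > 0) {
    denom <- (ssr_free + ssw) / df_err
    f_stat <- if (denom > 0) ((ssr_null - ssr_free) / 2) / denom else
      ifelse(ssr_null > ssr_free, Inf, 0)
    p_value <- pf(f_stat, 2, df_err, lower.tail = FALSE)
  } else {
    f_stat <- NA_real_
    p_value <- NA_real_
  }

  # a significant *dose response* needs both a small p and an actual decay:
  # the two-sided F also fires when counts rise with dose, but then the
  # bounded fit is degenerate (a = b = 0) and no effective dose exists
  decaying <- a + b > 0
  structure(list(
    a = a, b = b, cov = cov, ssr = ssr, df = df, n_points = n_points,
    sigma2 = sigma2, f_stat = f_stat, df_error = df_err, decaying = decaying,
    p_value = p_value,
    significant = isTRUE(p_value < alpha) && decaying, alpha = alpha,
    data = tibble::tibble(dose = dose, fraction = fraction,
                          weights = weights,
                          se = if (is.null(se)) NA_real_ else se)
  ), class = "lq_fit")
}

#' Evaluate a fitted LQ curve
#'
#' @param fit An [fit_lq()] object.
#' @param dose Doses in Gy (non-negative).
#' @return The fitted fraction of control \eqn{e^{-aD - bD^2}}, in (0, 1].
#' @export
evaluate_lq <- function(fit, dose) {
  stopifnot(inherits(fit, "lq_fit"))
  if (any(dose < 0)) abort("dose must be non-negative")
  exp(-fit$a * dose - fit$b * dose^2)
}

#' Dose-response significance of an LQ fit
#'
#' Extracts (or re-thresholds) the F-type test of the fitted curve against the
#' flat null described in [fit_lq()].
#'
#' @param fit An [fit_lq()] object.
#' @param alpha Significance level.
#' @return A list with `p_value` and `significant`. When the error degrees of
#'   freedom are zero the test is undeterminable and `significant` is `NA`.
#' @export
dose_response_significance <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "lq_fit"))
  if (is.na(fit$p_value)) {
    return(list(p_value = NA_real_, significant = NA))
  }
  list(p_value = fit$p_value,
       significant = fit$p_value < alpha && fit$decaying)
}

#' @export
print.lq_fit <- function(x, ...) {
  cat(sprintf("LQ fit: a = %.4g Gy^-1, b = %.4g Gy^-2 (%d points, ssr %.4g)\n",
              x$a, x$b, x$n_points, x$ssr))
  cat(sprintf("dose-response p = %.4g (%ssignificant at alpha = %g)\n",
              x$p_value, if (isTRUE(x$significant)) "" else "not ", x$alpha))
  invisible(x)
}

#' Fit LQ dose-response curves for every stratum of a summary table
#'
#' Applies [fit_lq()] to each (arm, cell type, time-point) stratum of a group
#' summary table, excluding pre-irradiation rows and 0 Gy groups. Strata with
#' fewer than 3 distinct positive doses are dropped with a message.
#'
#' @param groups Group summaries as produced by [summarize_groups()] or
#'   [electron_fixtures()].
#' @param alpha Significance level passed to [fit_lq()].
#' @return A tibble with one row per stratum: `arm`, `cell_type`, `timepoint`,
#'   `a`, `b`, `p_value`, `significant` and a list-column `fit`.
#' @export
fit_dose_responses <- function(groups, alpha = 0.05) {
  groups <- tibble::as_tibble(groups)
  usable <- groups |>
    dplyr::filter(.data$timepoint != "pre", .data$dose_gy > 0)
  nested <- usable |>
    dplyr::group_by(.data$arm, .data$cell_type, .data$timepoint) |>
    tidyr::nest() |>
    dplyr::ungroup()
  fits <- lapply(nested$data, function(d) {
    if (length(unique(d$dose_gy)) < 3) return(NULL)
    fit_lq(d$dose_gy, d$mean_fraction, weights = d$n,
           se = d$se_fraction, alpha = alpha)
  })
  keep <- !vapply(fits, is.null, logical(1))
  if (any(!keep)) {
    message(sum(!keep), " stratum/strata dropped (fewer than 3 distinct doses)")
  }
  out <- nested[keep, c("arm", "cell_type", "timepoint")]
  out$fit <- fits[keep]
  out$a <- vapply(out$fit, `[[`, numeric(1), "a")
  out$b <- vapply(out$fit, `[[`, numeric(1), "b")
  out$p_value <- vapply(out$fit, `[[`, numeric(1), "p_value")
  out$significant <- vapply(out$fit, function(f) isTRUE(f$significant),
                            logical(1))
  out
}
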