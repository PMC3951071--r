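#' Effective dose ED_p
#'
#' The dose at which the fitted fraction of control drops by `p` percent,
#' i.e. the solution of \eqn{e^{-aD - bD^2} = 1 - p/100}. ED10 is the dose
#' reducing the count to 0.9 of control, ED50 to half.
#'
#' @param fit An [fit_lq()] object with `a + b > 0`.
#' @param p Percent reduction, in (0, 100). Vectorized.
#' @return Dose(s) in Gy.
#' @export
#' @examples
#' f <- fit_lq(c(5, 10, 20), exp(-0.0866 * c(5, 10, 20)))
#' effective_dose(f, 50)  # log(2)/0.0866 = 8.0 Gy
effective_dose <- function(fit, p) {
  if (any(p <= 0 | p >= 100)) abort("p must be in (0, 100)")
  invert_lq(fit, 1 - p / 100)
}

#' Confidence interval for an effective dose
#'
#' Two methods:
#' \describe{
#'   \item{delta}{first-order propagation of the fit covariance through
#'     \eqn{ED_p(a, b)}. From \eqn{aD + bD^2 = c} the gradient is
#'     \eqn{\partial D/\partial a = -D/(a + 2bD)},
#'     \eqn{\partial D/\partial b = -D^2/(a + 2bD)}; the interval is
#'     \eqn{ED \pm z_{1-(1-level)/2} \cdot SE}. For a pure exponential
#'     (\eqn{b = 0}) this reduces to \eqn{SE(ED) = ED \cdot SE(a)/a}.}
#'   \item{bootstrap}{parametric resampling: group means are redrawn from
#'     Normal(fitted value, \eqn{\hat\sigma^2}/weight), the bounded LQ model
#'     is refitted, and the percentile interval of the resampled \eqn{ED_p} is
#'     returned. Deterministic given `seed`.}
#' }
#' A singular or undefined fit covariance makes the delta method fall back to
#' the bootstrap with a warning.
#'
#' @param fit An [fit_lq()] object.
#' @param p Percent reduction in (0, 100), scalar.
#' @param level Confidence level.
#' @param method `"delta"` or `"bootstrap"`.
#' @param reps Bootstrap replicates.
#' @param seed Seed for the bootstrap resampling (required for
#'   reproducibility there; ignored by the delta method).
#' @return `c(low, high)` in Gy.
#' @export
ed_confidence_interval <- function(fit, p, level = 0.95,
                                   method = c("delta", "bootstrap"),
                                   reps = 2000, seed = NULL) {
  stopifnot(inherits(fit, "lq_fit"), length(p) == 1)
  method <- match.arg(method)
  ed <- effective_dose(fit, p)

  if (method == "delta") {
    if (any(!is.finite(fit$cov))) {
      warning("fit covariance is undefined; falling back to bootstrap")
      return(ed_confidence_interval(fit, p, level, "bootstrap", reps, seed))
    }
    denom <- fit$a + 2 * fit$b * ed
    grad <- c(-ed / denom, -ed^2 / denom)
    # a coefficient pinned at its non-negativity bound does not vary to first
    # order; drop it from the propagation (so b = 0 gives SE = ED * SE(a)/a)
    grad[c(fit$a, fit$b) <= 0] <- 0
    v <- drop(t(grad) %*% fit$cov %*% grad)
    se <- sqrt(max(v, 0))
    z <- qnorm(1 - (1 - level) / 2)
    return(c(low = ed - z * se, high = ed + z * se))
  }

  # parametric bootstrap on the group means
  d <- fit$data
  sigma2 <- fit$sigma2
  if (!is.finite(sigma2)) abort("bootstrap needs residual degrees of freedom")
  fitted <- exp(-fit$a * d$dose - fit$b * d$dose^2)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  eds <- vapply(seq_len(reps), function(i) {
    y <- rnorm(nrow(d), fitted, sqrt(sigma2 / d$weights))
    y <- pmax(y, 1e-6)
    f <- tryCatch(fit_lq(d$dose, y, weights = d$weights),
                  error = function(e) NULL)
    if (is.null(f) || f$a + f$b <= 0) return(NA_real_)
    effective_dose(f, p)
  }, numeric(1))
  qs <- quantile(eds, c((1 - level) / 2, 1 - (1 - level) / 2),
                 na.rm = TRUE, names = FALSE)
  c(low = qs[1], high = qs[2])
}

#' Effective-dose grid with censoring
#'
#' Builds the ED table for a set of fitted strata, applying the reporting
#' conventions of acute-hematology dose-response studies:
#' \itemize{
#'   \item a stratum whose dose-response slope is not significant is
#'     "not meaningful" (`NM`) -- no dose is reported;
#'   \item a point estimate beyond the highest tested dose of the arm is
#'     censored and rendered `">Dmax"` (e.g. `">20.0"`) to avoid extrapolating
#'     the curve beyond the tested range;
#'   \item ED90 values are suppressed entirely (no `">Dmax"` cell) whenever
#'     they exceed the tested range, and reported numerically otherwise.
#' }
#'
#' @param fits Stratum fits from [fit_dose_responses()].
#' @param p_levels Percent reductions to tabulate (default 10, 50, 90).
#' @param max_dose Highest tested dose per arm: a single number or a named
#'   vector/list keyed by arm label.
#' @param level,ci_method,reps,seed Interval options passed to
#'   [ed_confidence_interval()].
#' @return A tibble with one row per stratum x p: `arm`, `cell_type`,
#'   `timepoint`, `p`, `value`, `ci_low`, `ci_high`, `status`
#'   (`reported` / `exceeds_max_dose` / `not_meaningful`), `max_dose` and the
#'   human-readable `rendered` cell.
#' @export
ed_table <- function(fits, p_levels = c(10, 50, 90), max_dose,
                     level = 0.95, ci_method = "delta", reps = 2000,
                     seed = NULL) {
  fits <- tibble::as_tibble(fits)
  get_max <- function(arm) {
    if (length(max_dose) == 1 && is.null(names(max_dose))) return(as.numeric(max_dose))
    if (!arm %in% names(max_dose)) abort(paste0("no max_dose given for arm '", arm, "'"))
    as.numeric(max_dose[[arm]])
  }
  rows <- list()
  for (i in seq_len(nrow(fits))) {
    f <- fits$fit[[i]]
    dmax <- get_max(fits$arm[i])
    for (p in p_levels) {
      if (!isTRUE(fits$significant[i])) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          arm = fits$arm[i], cell_type = fits$cell_type[i],
          timepoint = fits$timepoint[i], p = p,
          value = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
          status = "not_meaningful", max_dose = dmax,
          rendered = "NM")
        next
      }
      val <- effective_dose(f, p)
      ci <- tryCatch(
        ed_confidence_interval(f, p, level, ci_method, reps, seed),
        error = function(e) c(NA_real_, NA_real_))
      exceeded <- val > dmax
      status <- if (exceeded) "exceeds_max_dose" else "reported"
      rendered <- if (exceeded) {
        if (p == 90) NA_character_ else sprintf(">%.1f", dmax)
      } else {
        format_ed_cell(val, ci[1], ci[2])
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        arm = fits$arm[i], cell_type = fits$cell_type[i],
        timepoint = fits$timepoint[i], p = p,
        value = val, ci_low = ci[1], ci_high = ci[2],
        status = status, max_dose = dmax, rendered = rendered)
    }
  }
  dplyr::bind_rows(rows)
}

format_ed_cell <- function(value, lo, hi) {
  if (is.na(lo) || is.na(hi)) return(sprintf("%.1f", value))
  sprintf("%.1f (%.1f-%.1f)", value, lo, hi)
}

#' Reshape an ED grid to the familiar wide report layout
#'
#' Rows are cell type x time-point; columns are one per arm x ED level with
#' the rendered cells (`"x.x (lo-hi)"`, `">Dmax"` or `"NM"`). Suppressed ED90
#' cells come out as `NA`.
#'
#' @param ed An [ed_table()] result.
#' @return A wide tibble.
#' @export
ed_table_wide <- function(ed) {
  ed |>
    dplyr::mutate(col = paste0(.data$arm, "_ED", .data$p)) |>
    dplyr::select("cell_type", "timepoint", "col", "rendered") |>
    tidyr::pivot_wider(names_from = "col", values_from = "rendered")
}
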