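record_cols <- c("experiment_id", "arm", "animal_id", "dose_gy",
                 "timepoint", "cell_type")

#' Validate a table of blood-count records
#'
#' A record is one animal x time-point x cell-type measurement. It carries
#' either an absolute `count` (cells per unit volume) or a pre-computed
#' `fraction` of the pre-irradiation control -- exactly one of the two must be
#' populated on input; [normalize_to_fraction()] fills `fraction` from
#' `count`.
#'
#' @param records A data frame with columns `experiment_id`, `arm`,
#'   `animal_id`, `dose_gy`, `timepoint`, `cell_type` and `count` and/or
#'   `fraction`.
#' @return The records as a tibble, invisibly validated: doses non-negative,
#'   counts/fractions positive, time-points and cell types from the declared
#'   vocabulary, `(experiment_id, animal_id, timepoint, cell_type)` unique.
#' @export
as_count_records <- function(records) {
  records <- tibble::as_tibble(records)
  missing <- setdiff(record_cols, names(records))
  if (length(missing) > 0) {
    abort(paste0("records are missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  has_count <- "count" %in% names(records)
  has_frac <- "fraction" %in% names(records)
  if (!has_count && !has_frac) {
    abort("records need a `count` or a `fraction` column")
  }
  if (!has_count) records$count <- NA_real_
  if (!has_frac) records$fraction <- NA_real_

  bad_tp <- !records$timepoint %in% hem_timepoints
  if (any(bad_tp)) {
    abort(paste0("unknown timepoint(s) in row(s) ",
                 paste(head(which(bad_tp), 5), collapse = ", "), ": ",
                 paste(unique(records$timepoint[bad_tp]), collapse = ", ")))
  }
  bad_ct <- !records$cell_type %in% hem_cell_types
  if (any(bad_ct)) {
    abort(paste0("unknown cell_type(s) in row(s) ",
                 paste(head(which(bad_ct), 5), collapse = ", "), ": ",
                 paste(unique(records$cell_type[bad_ct]), collapse = ", ")))
  }
  if (any(is.na(records$dose_gy) | records$dose_gy < 0)) {
    abort(paste0("negative or missing dose_gy in row(s) ",
                 paste(head(which(is.na(records$dose_gy) | records$dose_gy < 0), 5),
                       collapse = ", ")))
  }
  neither <- is.na(records$count) & is.na(records$fraction)
  if (any(neither)) {
    abort(paste0("row(s) with neither count nor fraction: ",
                 paste(head(which(neither), 5), collapse = ", ")))
  }
  nonpos <- (!is.na(records$count) & records$count <= 0) |
    (!is.na(records$fraction) & records$fraction <= 0)
  if (any(nonpos)) {
    abort(paste0("non-positive count/fraction in row(s) ",
                 paste(head(which(nonpos), 5), collapse = ", ")))
  }
  key <- paste(records$experiment_id, records$animal_id,
               records$timepoint, records$cell_type, sep = "\r")
  if (anyDuplicated(key)) {
    abort(paste0("duplicated (experiment, animal, timepoint, cell_type) in row(s) ",
                 paste(head(which(duplicated(key)), 5), collapse = ", ")))
  }
  records
}

#' Normalize counts to fraction of the pre-irradiation control
#'
#' For each experiment and cell type, the baseline control value is the mean
#' pre-irradiation count over *all* animals of that experiment; every record's
#' count is divided by it. Already-normalized input (fraction populated, no
#' counts) is returned unchanged, so the operation is idempotent.
#'
#' @param records Blood-count records (see [as_count_records()]).
#' @return The records with `fraction` populated (and the `count` kept).
#' @export
#' @examples
#' rec <- tibble::tibble(
#'   experiment_id = "e1", arm = "reference",
#'   animal_id = rep(c("p1", "p2", "p3"), 2),
#'   dose_gy = rep(c(0, 0, 0, 10, 10, 10), length.out = 6),
#'   timepoint = rep(c("pre", "d1"), each = 3),
#'   cell_type = "WBC", count = c(10, 12, 8, 5, 5, 5))
#' normalize_to_fraction(rec)$fraction
normalize_to_fraction <- function(records) {
  records <- as_count_records(records)
  if (all(is.na(records$count))) {
    return(records) # already a fraction-of-control table
  }
  baselines <- records |>
    dplyr::filter(.data$timepoint == "pre") |>
    dplyr::group_by(.data$experiment_id, .data$cell_type) |>
    dplyr::summarise(baseline = mean(.data$count), .groups = "drop")

  need <- dplyr::distinct(records, .data$experiment_id, .data$cell_type)
  joined <- dplyr::left_join(need, baselines,
                             by = c("experiment_id", "cell_type"))
  gap <- joined[is.na(joined$baseline), , drop = FALSE]
  if (nrow(gap) > 0) {
    abort(paste0("no pre-irradiation baseline for ",
                 paste(sprintf("%s/%s", gap$experiment_id, gap$cell_type),
                       collapse = ", ")))
  }
  if (any(joined$baseline <= 0)) {
    bad <- joined[joined$baseline <= 0, ]
    abort(paste0("non-positive baseline for ",
                 paste(sprintf("%s/%s", bad$experiment_id, bad$cell_type),
                       collapse = ", ")))
  }
  records |>
    dplyr::left_join(baselines, by = c("experiment_id", "cell_type")) |>
    dplyr::mutate(fraction = .data$count / .data$baseline) |>
    dplyr::select(-"baseline")
}

#' Percent change from the pre-irradiation control
#'
#' Converts a fraction of control to the signed percent-change convention used
#' in blood-count reporting: a decrease is negative.
#'
#' @param fraction Fraction-of-control values (positive).
#' @return `(fraction - 1) * 100`.
#' @export
percent_change <- function(fraction) {
  (fraction - 1) * 100
}

#' Group summaries (mean +/- SE of the fraction of control)
#'
#' Collapses normalized records to one row per (arm, dose, time-point,
#' cell type): group size, mean fraction and its standard error (sample
#' SD / sqrt(n)). A single-animal group has no defined SE; it is reported as 0
#' with `se_defined = FALSE`.
#'
#' @param records Normalized records (`fraction` populated).
#' @return A tibble with columns `arm`, `cell_type`, `timepoint`, `dose_gy`,
#'   `n`, `mean_fraction`, `se_fraction`, `se_defined`.
#' @export
summarize_groups <- function(records) {
  records <- as_count_records(records)
  if (any(is.na(records$fraction))) {
    abort("records must be normalized first (see normalize_to_fraction)")
  }
  records |>
    dplyr::group_by(.data$arm, .data$cell_type, .data$timepoint, .data$dose_gy) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_fraction = mean(.data$fraction),
      se_fraction = ifelse(dplyr::n() > 1,
                           sd(.data$fraction) / sqrt(dplyr::n()), 0),
      se_defined = dplyr::n() > 1,
      .groups = "drop")
}

#' Read and write blood-count CSV files
#'
#' The on-disk schema is one row per record with columns `experiment_id`,
#' `arm`, `animal_id`, `dose_gy`, `timepoint`, `cell_type` and `count` or
#' `fraction` (decimal point, UTF-8). Unknown cell types or time-points,
#' duplicated keys, and negative doses are rejected with row numbers.
#'
#' @param path File path.
#' @param records Records to write.
#' @return `load_counts_csv()` returns validated records;
#'   `write_counts_csv()` returns `path` invisibly.
#' @export
load_counts_csv <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           experiment_id = readr::col_character(),
                           arm = readr::col_character(),
                           animal_id = readr::col_character(),
                           timepoint = readr::col_character(),
                           cell_type = readr::col_character(),
                           .default = readr::col_double()))
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    abort(paste0("malformed value(s) at row(s) ",
                 paste(head(prob$row, 5), collapse = ", "), " of ", path))
  }
  if (all(c("count", "fraction") %in% names(raw))) {
    both <- !is.na(raw$count) & !is.na(raw$fraction)
    if (any(both)) {
      abort(paste0("row(s) with both count and fraction populated: ",
                   paste(head(which(both), 5), collapse = ", ")))
    }
  }
  as_count_records(raw)
}

#' @rdname load_counts_csv
#' @export
write_counts_csv <- function(records, path) {
  records <- as_count_records(records)
  readr::write_csv(records, path, na = "")
  invisible(path)
}

#' Tukey comparison of dose groups against the pre-irradiation baseline
#'
#' Tukey's HSD computed from summary statistics: group SDs are recovered from
#' the reported SEs (`SD = SE * sqrt(n)`), pooled into a within-group mean
#' square, and each dose group at one time-point is compared with the
#' pre-irradiation baseline using the studentized range with the full family
#' (all dose groups plus baseline). Significance tiers follow the usual
#' annotation ladder: `#` p < 0.10, `*` < 0.05, `**` < 0.01, `***` < 0.001.
#'
#' @param groups Group summaries for one cell type and one post-irradiation
#'   time-point, plus the baseline row(s) (`timepoint == "pre"`). Repeated
#'   identical baseline rows (as printed once per dose column in count tables)
#'   are collapsed to a single baseline group.
#' @return A tibble with one row per dose group: `dose_gy`, `p_value`, `tier`,
#'   `testable`. Groups with `n < 2` anywhere make the family untestable
#'   (flagged, not an error).
#' @export
tukey_vs_baseline <- function(groups) {
  groups <- tibble::as_tibble(groups)
  base <- dplyr::distinct(groups[groups$timepoint == "pre", ],
                          .data$n, .data$mean_fraction, .data$se_fraction)
  dosed <- groups[groups$timepoint != "pre", ]
  if (nrow(base) == 0) abort("no pre-irradiation baseline row in `groups`")
  if (length(unique(dosed$timepoint)) > 1) {
    abort("`groups` must contain a single post-irradiation timepoint")
  }
  if (nrow(base) > 1) { # distinct baseline summaries: pool them
    base <- tibble::tibble(
      n = sum(base$n),
      mean_fraction = weighted.mean(base$mean_fraction, base$n),
      se_fraction = sqrt(sum(base$n * base$se_fraction^2)) / sum(base$n))
  }
  out <- tibble::tibble(dose_gy = dosed$dose_gy,
                        p_value = NA_real_, tier = NA_character_,
                        testable = TRUE)
  if (any(c(base$n, dosed$n) < 2)) {
    out$testable <- FALSE
    return(out)
  }
  all_n <- c(base$n, dosed$n)
  all_sd <- c(base$se_fraction, dosed$se_fraction) * sqrt(all_n)
  df <- sum(all_n - 1)
  mse <- sum((all_n - 1) * all_sd^2) / df
  k <- nrow(dosed) + 1
  if (mse <= 0) { # degenerate: all groups noise-free
    ident <- dosed$mean_fraction == base$mean_fraction
    out$p_value <- ifelse(ident, 1, 0)
  } else {
    q <- abs(dosed$mean_fraction - base$mean_fraction) /
      sqrt(mse / 2 * (1 / dosed$n + 1 / base$n))
    out$p_value <- ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
  }
  out$tier <- significance_tier(out$p_value)
  out
}

significance_tier <- function(p) {
  dplyr::case_when(
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    p < 0.10 ~ "#",
    TRUE ~ "")
}
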