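#' Reference-arm (electron) group-mean fixtures
#'
#' The published group means +/- SE of blood-cell fractions of control in
#' Yucatan minipigs after 6 + 12 MeV electron irradiation, transcribed from
#' the source count tables: six dose groups (5, 7.5, 7.7, 10, 15, 20 Gy;
#' pooled from two experiments of three animals per group) at five
#' post-irradiation time-points plus the pre-irradiation baseline. The
#' `change_pct` and `sig` columns reproduce the printed "Change (%)" values
#' and Tukey annotation symbols.
#'
#' @param cell_types Cell types to load (default: all seven).
#' @return A tibble of group summaries with columns `arm` (always
#'   `"reference"`), `cell_type`, `timepoint`, `dose_gy`, `n`,
#'   `mean_fraction`, `se_fraction`, `change_pct`, `sig`.
#' @export
#' @examples
#' wbc <- electron_fixtures("WBC")
#' subset(wbc, timepoint == "d1", c(dose_gy, mean_fraction))
electron_fixtures <- function(cell_types = hem_cell_types) {
  bad <- setdiff(cell_types, hem_cell_types)
  if (length(bad) > 0) {
    abort(paste0("unknown cell type(s): ", paste(bad, collapse = ", ")))
  }
  files <- system.file("extdata",
                       sprintf("electron_counts_%s.csv", tolower(cell_types)),
                       package = "hemrbe", mustWork = TRUE)
  out <- dplyr::bind_rows(lapply(files, function(f) {
    readr::read_csv(f, show_col_types = FALSE,
                    col_types = readr::cols(
                      cell_type = readr::col_character(),
                      timepoint = readr::col_character(),
                      sig = readr::col_character(),
                      .default = readr::col_double()))
  }))
  out$sig[is.na(out$sig) & out$timepoint != "pre"] <- ""
  tibble::as_tibble(cbind(arm = "reference", out))
}
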