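# Reconstruct per-animal pseudo-records consistent with a group-summary table:
# three animals {m, m - d, m + d} with d = SE * sqrt(3) have sample mean m and
# SE exactly as printed; counts are fractions scaled by a common baseline, and
# each dose group's three pre-irradiation counts are spread the same way so the
# experiment-wide pre mean equals the baseline exactly.
records_from_summaries <- function(groups, baseline = 10,
                                   arm = "reference", experiment_id = "recon") {
  rows <- list()
  for (i in seq_len(nrow(groups))) {
    g <- groups[i, ]
    d <- g$se_fraction * sqrt(3)
    fr <- c(g$mean_fraction, g$mean_fraction - d, g$mean_fraction + d)
    stopifnot(all(fr > 0))
    rows[[i]] <- tibble::tibble(
      experiment_id = experiment_id, arm = arm,
      animal_id = sprintf("%s_%g_%d", g$cell_type, g$dose_gy, 1:3),
      dose_gy = g$dose_gy, timepoint = g$timepoint, cell_type = g$cell_type,
      count = fr * baseline)
  }
  dplyr::bind_rows(rows)
}

# noise-free group means on the LQ curve
lq_means <- function(doses, a, b = 0) exp(-a * doses - b * doses^2)

groups_tbl <- function(doses, means, n = 3, se = 0, arm = "reference",
                       cell_type = "WBC", timepoint = "d1") {
  tibble::tibble(arm = arm, cell_type = cell_type, timepoint = timepoint,
                 dose_gy = doses, n = n, mean_fraction = means,
                 se_fraction = se)
}
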