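#!/usr/bin/env Rscript

# Step 3 — RBE estimation on a synthetic two-arm experiment.
#
# The proton-arm per-animal counts behind the published RBE tables are not
# public, so this step runs the full RBE pipeline on a synthetic two-arm
# dataset with known ground truth (true RBE 2.5, lognormal inter-animal noise
# sigma = 0.2, the published design sizes), then quantifies how well the
# pipeline recovers that truth over repeated draws.
#
# Findings: the fitted RBE at each of the three test doses tracks the truth
# within the inter-animal noise, confidence intervals are widest at the
# lowest dose (where a fixed log-fraction error translates into the largest
# dose error), and the 50-replicate recovery summary shows per-dose means
# within a few percent of the generating value.

suppressMessages(library(hemrbe))
dir.create("results", showWarnings = FALSE)
seed <- 20260921

cfg <- simulation_config(
  seed = seed,
  strata = dplyr::bind_rows(
    two_arm_strata("WBC", "d4", a_reference = 0.058, rbe = 2.5),
    two_arm_strata("lymphocyte", "d1", a_reference = 0.099, rbe = 2.5)))
ds <- generate_dataset(cfg)
rep <- run_pipeline(records = ds$records, out_dir = "results/03_synthetic_rbe")

cat("Single synthetic experiment (true RBE 2.5):\n\n")
print(as.data.frame(rep$rbe_table), digits = 3, row.names = FALSE)
cat(sprintf("\nAverage RBE over gated endpoints: %.2f +/- %.2f (SEM, n = %d)\n",
            rep$average_rbe$mean, rep$average_rbe$sem, rep$average_rbe$n))

# recovery summary over independent replicates (WBC stratum only)
set.seed(seed)
reps <- 50
fitted <- matrix(NA_real_, reps, 3)
for (r in seq_len(reps)) {
  cfg_r <- simulation_config(seed = sample.int(2^31 - 1, 1),
                             strata = two_arm_strata(rbe = 2.5), sham = FALSE)
  rec <- normalize_to_fraction(generate_dataset(cfg_r)$records)
  fits <- suppressMessages(fit_dose_responses(summarize_groups(rec)))
  pts <- rbe_per_animal(
    fits$fit[fits$arm == "reference"][[1]],
    rec[rec$arm == "test" & rec$timepoint == "d4" & rec$dose_gy > 0, ])
  fitted[r, ] <- fitted_rbe_with_ci(fit_rbe_trend(pts),
                                    sort(unique(pts$dose_test)))$rbe_fitted
}
recov <- tibble::tibble(dose_gy = c(5, 7.7, 10),
                        mean_fitted_rbe = colMeans(fitted),
                        sd_fitted_rbe = apply(fitted, 2, sd),
                        true_rbe = 2.5, replicates = reps)
readr::write_csv(recov, "results/03_rbe_recovery.csv")
cat(sprintf("\nRecovery over %d replicates (true RBE 2.5):\n", reps))
print(as.data.frame(recov), digits = 3, row.names = FALSE)
cat("\nWrote results/03_synthetic_rbe/ and results/03_rbe_recovery.csv\n")
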