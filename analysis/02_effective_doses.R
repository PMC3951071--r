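#!/usr/bin/env Rscript

# Step 2 — effective doses with censoring.
#
# Inverts every significant reference-arm curve at 10%, 50% and 90% count
# reduction and applies the reporting conventions: strata with no significant
# decay are "NM", point estimates beyond the 20 Gy tested range render as
# ">20.0", and ED90 values beyond the range are suppressed to avoid
# extrapolating the curves.
#
# Findings: early WBC ED10 sits near 3 Gy and ED50 near 20 Gy; lymphocytes
# halve at 7-8 Gy within a day of exposure; by day 14 most ED50 values are
# censored beyond the tested range as counts begin to recover.

suppressMessages(library(hemrbe))
dir.create("results", showWarnings = FALSE)

fits <- fit_dose_responses(electron_fixtures())
ed <- ed_table(fits, p_levels = c(10, 50, 90), max_dose = c(reference = 20))
readr::write_csv(ed, "results/02_effective_doses.csv", na = "")
wide <- ed_table_wide(ed)
readr::write_csv(wide, "results/02_effective_doses_wide.csv", na = "")

cat("Electron-arm effective doses (Gy), delta-method 95% intervals:\n\n")
print(as.data.frame(wide), right = FALSE, row.names = FALSE)
cat("\n", sum(ed$status == "not_meaningful") / 3, "strata NM;",
    sum(ed$status == "exceeds_max_dose"), "estimates censored beyond 20 Gy.\n")
cat("Wrote results/02_effective_doses*.csv\n")
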