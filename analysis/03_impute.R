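#!/usr/bin/env Rscript
# Step 3: event-conditioned single imputation.
#
# Fills every missing patient-cycle up to cycle 40 or death (never after
# death) with a pooled linear model conditioning on the cycle, the last
# available QoL value, and PD/TD/death proximity, with seeded residual
# draws. Writes the completed dataset, the model log, and a comparison of
# available-data vs imputed-data per-cycle means.

library(proestimand)

dir.create("results/impute", recursive = TRUE, showWarnings = FALSE)
obs <- read_qol_data("results/data/qol_observed.csv")
tl <- read_timelines("results/data/timelines.csv")

imp <- impute_single(obs, tl, impute_spec(seed = 20260928L), max_cycle = 40)
print(imp)
write_qol_data(imp$data, "results/impute/qol_imputed.csv")
write_imputation_log(imp, "results/impute/imputation_log.txt")

avail <- summarize_available(
  transform(collapse_within_cycle(obs), value = qol))
full <- summarize_available(transform(imp$data, value = qol))
cmp <- merge(avail[c("cycle", "mean", "n")], full[c("cycle", "mean", "n")],
             by = "cycle", suffixes = c("_available", "_imputed"))
write.csv(cmp, "results/impute/available_vs_imputed_means.csv",
          row.names = FALSE)

late <- cmp$cycle >= 20
cat(sprintf("\nMean QoL cycles >= 20: available %.1f vs completed %.1f\n",
            mean(cmp$mean_available[late]), mean(cmp$mean_imputed[late])))
cat("The completed dataset sits below the available data late in follow-up:\n")
cat("missingness concentrates near death and after PD, and the model\n")
cat("conditions on those events.\n")
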