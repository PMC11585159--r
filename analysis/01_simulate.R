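#!/usr/bin/env Rscript
# Step 1: simulate the single-arm trial.
#
# Generates the study cohort (876 patients, 3-week cycles, QoL-linked
# mortality, PD-then-TD, administrative censoring), writes the observed and
# complete latent long datasets, the per-patient timeline table and a run
# manifest under results/data/.

library(proestimand)

cfg_path <- system.file("extdata", "default_trial.yaml",
                        package = "proestimand")
res <- run_simulation(cfg_path, out_dir = "results/data")

trial <- res$trial
tl <- trial$timelines
cat(sprintf("Simulated %d patients over cycles 1-%d\n",
            trial$config$n_patients, trial$config$max_cycle))
cat(sprintf("  observed deaths: %d (%.0f%%), PD: %d, TD: %d, censored: %d\n",
            sum(!is.na(tl$death_cycle)), 100 * mean(!is.na(tl$death_cycle)),
            sum(!is.na(tl$pd_cycle)), sum(!is.na(tl$td_cycle)),
            sum(!is.na(tl$censor_cycle))))
cat(sprintf("  observed PRO rows: %d of %d latent patient-cycles\n",
            nrow(trial$observed), nrow(trial$complete)))
cat("Files written:\n")
for (p in res$paths) cat(" ", p, "\n")
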