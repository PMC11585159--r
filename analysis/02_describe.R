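#!/usr/bin/env Rscript
# Step 2: describe PRO availability and the candidate variables of interest.
#
# Tabulates the six availability states per cycle (alive on/off treatment
# with/without QoL, lost to follow-up, deceased), and summarizes the three
# candidate variables — absolute QoL, change from baseline, responder
# status — within the available (unimputed) data. Writes tables under
# results/describe/ and the state chart / variable figures.

library(proestimand)

dir.create("results/describe", recursive = TRUE, showWarnings = FALSE)
obs <- read_qol_data("results/data/qol_observed.csv")
tl <- read_timelines("results/data/timelines.csv")
validate_dataset(obs, tl)
obs <- collapse_within_cycle(obs)

states <- classify_states(obs, tl, max_cycle = 40)
write.csv(states, "results/describe/state_summary.csv", row.names = FALSE)
cat("Six-state availability at selected cycles:\n")
print(states[states$cycle %in% c(1, 4, 10, 20, 40), ], row.names = FALSE)

png("results/describe/state_summary.png", width = 1400, height = 900,
    res = 150)
print(plot_state_summary(states))
dev.off()

for (kind in c("absolute", "change_from_baseline", "responder")) {
  dv <- derive_variable(obs, variable_spec(kind))
  sm <- summarize_available(dv)
  write.csv(sm, sprintf("results/describe/available_%s.csv", kind),
            row.names = FALSE)
  cat(sprintf("\n%s within available data (cycles 1, 4, 10, 20, 40):\n",
              kind))
  print(sm[sm$cycle %in% c(1, 4, 10, 20, 40), ], row.names = FALSE,
        digits = 3)
  if (length(attr(dv, "excluded_patients")))
    cat(sprintf("  (%d patients without a cycle-1 value excluded)\n",
                length(attr(dv, "excluded_patients"))))
}

cat("\nA responder definition of +10 points is impossible for integer\n")
cat(sprintf("baselines of %d or more on the 0-100 scale.\n",
            responder_ceiling(10, 100)))
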