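# Shared fixtures and independent oracles for the test suite.

# small, fast simulation config; overrides pass through to sim_config()
quick_config <- function(n = 100, seed = 1, ...) {
  sim_config(n_patients = n, seed = seed, ...)
}

# a config with no intercurrent events and no missingness: every patient
# contributes a full cycle grid
eventfree_config <- function(n = 60, seed = 1, max_cycle = 40,
                             missing_prob_base = 0, ...) {
  sim_config(n_patients = n, seed = seed, max_cycle = max_cycle,
             death_hazard_base = -1e6, death_hazard_qol_coef = 0,
             pd_hazard = 0, td_no_pd_prob = 0,
             missing_prob_base = missing_prob_base,
             missing_prob_event_bump = 0, ...)
}

# complete rectangular dataset with arbitrary values (for estimator oracles)
random_complete_data <- function(n_patients, cycles, seed) {
  set.seed(seed)
  data.frame(
    patient_id = rep(seq_len(n_patients), each = length(cycles)),
    cycle = rep(cycles, n_patients),
    qol = round(runif(n_patients * length(cycles), 0, 100), 2))
}

no_event_timelines <- function(n_patients, censor = 60L) {
  data.frame(patient_id = seq_len(n_patients),
             death_cycle = NA_integer_, pd_cycle = NA_integer_,
             td_cycle = NA_integer_, censor_cycle = censor)
}

# independent descriptive oracle: per-cycle arithmetic means
descriptive_means <- function(data, max_cycle) {
  val <- if ("value" %in% names(data)) data$value else data$qol
  vapply(seq_len(max_cycle), function(t) {
    v <- val[data$cycle == t]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
}

# brute-force product-limit oracle: risk set = {time >= u}, events at u
# remove from the risk set after u (events precede censoring within a cycle)
km_brute <- function(time, status, grid) {
  vapply(grid, function(t) {
    s <- 1
    for (u in sort(unique(time[status == 1 & time <= t]))) {
      n_u <- sum(time >= u)
      d_u <- sum(time == u & status == 1)
      s <- s * (1 - d_u / n_u)
    }
    s
  }, numeric(1))
}
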