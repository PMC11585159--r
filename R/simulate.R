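#' Population mean QoL curve
#'
#' Linear rise from `baseline_mean` at cycle 1 to `plateau_mean` at cycle
#' `rise_cycles`, flat thereafter (before frailty, event effects, noise and
#' clipping).
#'
#' @param cycles integer vector of cycles (>= 1).
#' @param config a [sim_config()].
#' @return Numeric vector of population means.
#' @export
population_curve <- function(cycles, config) {
  stopifnot(all(cycles >= 1))
  r <- config$rise_cycles
  if (r == 1) return(rep(config$plateau_mean, length(cycles)))
  frac <- pmin(cycles - 1, r - 1) / (r - 1)
  config$baseline_mean + (config$plateau_mean - config$baseline_mean) * frac
}

# Structural draws shared by simulate_trial() and compute_ground_truth().
# Uses the current RNG stream. Returns latent components so callers can
# reconstruct counterfactual (no-death) trajectories from the same draws.
sim_structure <- function(config, n = config$n_patients) {
  maxc <- config$max_cycle
  censor <- draw_dist(config$censor_cycle_distribution, n)
  horizon <- max(maxc, censor)

  u <- stats::rnorm(n, 0, config$frailty_sd)
  curve_ext <- population_curve(seq_len(horizon), config)

  # death: per-cycle logistic hazard on the smooth latent level (curve +
  # frailty); the pre-death drop and post-TD decrement are excluded from the
  # hazard to avoid a circular definition
  smooth <- outer(u, curve_ext, `+`)
  haz <- stats::plogis(config$death_hazard_base -
                       config$death_hazard_qol_coef * (smooth - 50))
  hit <- matrix(stats::runif(n * horizon), n) < haz
  any_hit <- rowSums(hit) > 0
  death_true <- ifelse(any_hit, max.col(hit, ties.method = "first"), NA_integer_)

  # disease progression: constant per-cycle hazard, independent of QoL
  pd0 <- if (config$pd_hazard > 0) 1L + stats::rgeom(n, config$pd_hazard)
         else rep(Inf, n)
  # treatment discontinuation: PD plus a lag; a small fraction discontinue
  # without PD (same per-cycle rate as PD, e.g. toxicity-driven)
  lag <- draw_dist(config$td_lag_distribution, n)
  td_after_pd <- pd0 + pmax(lag, 0)
  no_pd_td <- stats::runif(n) < config$td_no_pd_prob
  td_alt <- if (config$pd_hazard > 0) 1L + stats::rgeom(n, config$pd_hazard)
            else rep(Inf, n)
  td0 <- ifelse(no_pd_td, pmin(td_after_pd, td_alt), td_after_pd)

  eps <- matrix(stats::rnorm(n * maxc, 0, config$residual_sd), n)

  # latent QoL values for cycles 1 .. min(max_cycle, death - 1)
  tt <- seq_len(maxc)
  base_mat <- outer(u, population_curve(tt, config), `+`)
  td_mat <- config$td_decrement *
    outer(td0, tt, function(td, t) as.numeric(t > td))
  w <- config$predeath_window
  drop_start <- death_true - w  # drop applies at cycles in [d - w, d - 1]
  drop_mat <- config$predeath_drop * outer(
    drop_start, tt, function(s, t) pmax(0, pmin(t - s + 1, w)))
  drop_mat[is.na(drop_mat)] <- 0
  latent <- clip_scale(base_mat - td_mat - drop_mat + eps)
  alive <- outer(death_true, tt, function(d, t) is.na(d) | t < d)
  latent[!alive] <- NA_real_

  # observed timeline: events recorded only while under follow-up
  death_obs <- ifelse(!is.na(death_true) & death_true <= censor,
                      death_true, NA_integer_)
  follow_end <- ifelse(is.na(death_true), censor, pmin(censor, death_true))
  pd_obs <- ifelse(is.finite(pd0) & !is.na(death_true) & pd0 >= death_true,
                   NA_real_, pd0)
  pd_obs <- ifelse(!is.na(pd_obs) & pd_obs <= follow_end, pd_obs, NA_real_)
  td_obs <- ifelse(is.finite(td0) & !is.na(death_true) & td0 >= death_true,
                   NA_real_, td0)
  td_obs <- ifelse(!is.na(td_obs) & td_obs <= follow_end, td_obs, NA_real_)

  list(
    n = n,
    u = u, eps = eps, curve = population_curve(tt, config),
    death_true = death_true, pd0 = pd0, td0 = td0, censor = censor,
    latent = latent, alive = alive,
    timelines = data.frame(
      patient_id = seq_len(n),
      death_cycle = as.integer(death_obs),
      pd_cycle = as.integer(pd_obs),
      td_cycle = as.integer(td_obs),
      censor_cycle = as.integer(ifelse(is.na(death_obs), censor, NA_integer_))
    )
  )
}

structure_to_long <- function(latent) {
  n <- nrow(latent); maxc <- ncol(latent)
  df <- data.frame(
    patient_id = rep(seq_len(n), maxc),
    cycle = rep(seq_len(maxc), each = n),
    qol = as.vector(latent))
  df <- df[!is.na(df$qol), ]
  df <- df[order(df$patient_id, df$cycle), ]
  rownames(df) <- NULL
  df
}

#' Simulate a single-arm trial with intercurrent events
#'
#' Generates a complete (latent) dataset — one QoL value per patient per
#' cycle from 1 until death or `max_cycle`, whichever comes first — and an
#' observed dataset obtained by applying the measurement schedule,
#' end-of-collection at treatment discontinuation, loss to follow-up and
#' item missingness via [apply_collection_design()]. The observed timeline
#' table records each patient's death, disease-progression (PD),
#' treatment-discontinuation (TD) and censoring cycles as seen under
#' follow-up (death after censoring is not recorded).
#'
#' @param config a [sim_config()].
#' @return A list of class `sim_trial` with elements `complete` and
#'   `observed` (long data frames: `patient_id`, `cycle`, `qol`),
#'   `timelines` (one row per patient: `patient_id`, `death_cycle`,
#'   `pd_cycle`, `td_cycle`, `censor_cycle`; `NA` = event not observed), and
#'   `config`. The latent structural draws are attached as attribute
#'   `"structure"` for ground-truth computations.
#' @examples
#' trial <- simulate_trial(sim_config(n_patients = 50, seed = 7))
#' head(trial$observed)
#' @export
simulate_trial <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  s <- sim_structure(config)
  complete <- structure_to_long(s$latent)
  observed <- apply_collection_design(complete, s$timelines, config)
  out <- list(complete = complete, observed = observed,
              timelines = s$timelines, config = config)
  attr(out, "structure") <- s[c("death_true", "pd0", "td0", "censor")]
  class(out) <- "sim_trial"
  out
}

#' @export
print.sim_trial <- function(x, ...) {
  cat(sprintf("Simulated single-arm PRO trial: %d patients, cycles 1-%d\n",
              x$config$n_patients, x$config$max_cycle))
  cat(sprintf("  complete rows: %d; observed rows: %d\n",
              nrow(x$complete), nrow(x$observed)))
  tl <- x$timelines
  cat(sprintf("  observed deaths: %d (%.0f%%); PD: %d; TD: %d; censored: %d\n",
              sum(!is.na(tl$death_cycle)),
              100 * mean(!is.na(tl$death_cycle)),
              sum(!is.na(tl$pd_cycle)), sum(!is.na(tl$td_cycle)),
              sum(!is.na(tl$censor_cycle))))
  invisible(x)
}

#' Apply the PRO collection design and missingness to complete data
#'
#' Implements the trial's measurement design: questionnaires are scheduled
#' every cycle through cycle 10 and on alternate cycles thereafter
#' ([scheduled_cycles()]); PRO collection ends at treatment discontinuation
#' except for a single final questionnaire at the TD cycle itself; no values
#' are collected after loss to follow-up; and each eligible value is missing
#' with probability `missing_prob_base`, increased by
#' `missing_prob_event_bump` within `predeath_window` cycles of an observed
#' death or on/after observed PD.
#'
#' Draws from the current RNG stream; [simulate_trial()] calls it under the
#' config seed. Call `set.seed()` first for reproducible stand-alone use.
#'
#' @param complete long data frame `patient_id`, `cycle`, `qol` with no
#'   values at or after death.
#' @param timelines observed timeline table (see [simulate_trial()]).
#' @param config a [sim_config()].
#' @return The observed long data frame (a subset of `complete`'s rows).
#' @export
apply_collection_design <- function(complete, timelines, config) {
  stopifnot(all(c("patient_id", "cycle", "qol") %in% names(complete)))
  sched <- scheduled_cycles(config$max_cycle)
  idx <- match(complete$patient_id, timelines$patient_id)
  if (anyNA(idx)) stop("complete data contain patients missing from timelines",
                       call. = FALSE)
  death <- timelines$death_cycle[idx]
  pd <- timelines$pd_cycle[idx]
  td <- timelines$td_cycle[idx]
  censor <- timelines$censor_cycle[idx]
  t <- complete$cycle

  eligible <- (is.na(censor) | t <= censor) &
    (is.na(td) | t <= td) &
    (t %in% sched | (!is.na(td) & t == td))

  p_miss <- config$missing_prob_base +
    config$missing_prob_event_bump *
      ((!is.na(death) & t >= death - config$predeath_window) |
       (!is.na(pd) & t >= pd))
  keep <- eligible & stats::runif(nrow(complete)) >= pmin(p_miss, 1)
  out <- complete[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Monte Carlo ground truth for a simulation configuration
#'
#' Estimates, on a large latent population simulated from `config` with its
#' own seed, the per-cycle true while-alive mean QoL (average latent value
#' among patients truly alive at the cycle, regardless of censoring), the
#' true hypothetical no-death mean (latent trajectories reconstructed from
#' the same draws with death — and hence the pre-death drop — switched off),
#' and the true survival probability, each with its Monte Carlo standard
#' error. Used as the oracle in estimator-recovery tests.
#'
#' @param config a [sim_config()].
#' @param n_oracle number of simulated patients; should be at least 10 times
#'   the trial size of interest (a warning is raised otherwise).
#' @param oracle_seed seed for the oracle draw, separate from `config$seed`.
#' @return Data frame of class `ground_truth`: `cycle`, `while_alive_mean`,
#'   `while_alive_se`, `n_alive`, `hypothetical_mean`, `hypothetical_se`,
#'   `survival`, `survival_se`.
#' @export
compute_ground_truth <- function(config, n_oracle = 20000L,
                                 oracle_seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"), n_oracle >= 1)
  if (n_oracle < 10 * config$n_patients)
    warning("n_oracle is less than 10x the configured trial size; ",
            "ground-truth Monte Carlo error may be non-negligible")
  set.seed(oracle_seed)
  s <- sim_structure(config, n = n_oracle)
  maxc <- config$max_cycle
  tt <- seq_len(maxc)

  n_alive <- colSums(s$alive)
  wa_mean <- colSums(s$latent, na.rm = TRUE) / n_alive
  wa_se <- vapply(tt, function(t) {
    v <- s$latent[s$alive[, t], t]
    if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  }, numeric(1))

  # no-death counterfactual from the same structural draws: no truncation,
  # no pre-death drop; the TD decrement still applies (treatment-policy view)
  td_mat <- config$td_decrement *
    outer(s$td0, tt, function(td, t) as.numeric(t > td))
  hyp <- clip_scale(outer(s$u, s$curve, `+`) - td_mat + s$eps)
  hyp_mean <- colMeans(hyp)
  hyp_se <- apply(hyp, 2, stats::sd) / sqrt(n_oracle)

  surv <- n_alive / n_oracle
  surv_se <- sqrt(surv * (1 - surv) / n_oracle)

  structure(data.frame(
    cycle = tt,
    while_alive_mean = wa_mean, while_alive_se = wa_se, n_alive = n_alive,
    hypothetical_mean = hyp_mean, hypothetical_se = hyp_se,
    survival = surv, survival_se = surv_se
  ), class = c("ground_truth", "data.frame"))
}
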