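#' Simulation configuration for a single-arm PRO trial
#'
#' Full parameterization of the data-generating process used by
#' [simulate_trial()]. Time is discrete in 3-week treatment cycles. Each
#' patient carries a latent global quality-of-life (QoL) trajectory on the
#' 0-100 scale: a population curve rising from `baseline_mean` at cycle 1 to
#' `plateau_mean` at cycle `rise_cycles` and flat thereafter, plus a normal
#' patient-level frailty, a linear drop over the final `predeath_window`
#' cycles before death, a step decrement after treatment discontinuation, and
#' residual noise, clipped to \[0, 100\].
#'
#' Death follows a per-cycle discrete hazard with a logistic link to the
#' current smooth latent QoL (curve + frailty), so lower QoL means higher
#' mortality and baseline QoL is positively associated with survival.
#' Disease progression (PD) has a constant per-cycle hazard; treatment
#' discontinuation (TD) occurs a lagged number of cycles after PD (or, for a
#' small fraction, without PD), truncated at death. Censoring is purely
#' administrative: a cycle drawn independently of everything else.
#'
#' @param n_patients number of patients (positive integer).
#' @param max_cycle last analyzed cycle (default 40).
#' @param cycle_weeks weeks per cycle (default 3).
#' @param baseline_mean,baseline_sd population mean and SD of QoL at cycle 1
#'   (defaults 54 and 25 points).
#' @param plateau_mean population mean after the initial rise (default 67).
#' @param rise_cycles cycle at which the plateau is reached (default 4).
#' @param frailty_sd SD of the patient-level random intercept; default
#'   `sqrt(baseline_sd^2 - residual_sd^2)` so that the cycle-1 SD matches
#'   `baseline_sd` before clipping.
#' @param residual_sd SD of the within-patient residual (default 12 points).
#' @param predeath_drop QoL points lost per cycle over the final
#'   `predeath_window` cycles before death (default 4).
#' @param predeath_window number of pre-death cycles over which the drop
#'   accumulates (default 5).
#' @param death_hazard_base,death_hazard_qol_coef per-cycle discrete death
#'   hazard `plogis(base - coef * (latent QoL - 50))`; `coef >= 0` makes the
#'   hazard increase as latent QoL decreases.
#' @param pd_hazard constant per-cycle hazard of disease progression.
#' @param td_lag_distribution distribution of the cycle lag from PD to TD
#'   (list, see Details of [simulate_trial()]).
#' @param td_no_pd_prob probability of TD without preceding PD (default 0.05).
#' @param td_decrement step drop in latent QoL after TD (default 5 points).
#' @param censor_cycle_distribution distribution of the administrative
#'   censoring cycle (default uniform on cycles 41-60, i.e. beyond the
#'   analysis window, emulating end-of-study censoring).
#' @param missing_prob_base probability a scheduled PRO is missing.
#' @param missing_prob_event_bump extra missingness probability when within
#'   `predeath_window` cycles of an observed death or on/after PD.
#' @param seed integer seed; the whole simulation is reproducible given the
#'   seed.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_trial()], [read_sim_config()]
#' @export
sim_config <- function(n_patients = 876L,
                       max_cycle = 40L,
                       cycle_weeks = 3L,
                       baseline_mean = 54,
                       baseline_sd = 25,
                       plateau_mean = 67,
                       rise_cycles = 4L,
                       frailty_sd = NULL,
                       residual_sd = 12,
                       predeath_drop = 4,
                       predeath_window = 5L,
                       death_hazard_base = -3.5,
                       death_hazard_qol_coef = 0.03,
                       pd_hazard = 0.05,
                       td_lag_distribution = list(name = "geometric",
                                                  prob = 0.3, offset = 1L),
                       td_no_pd_prob = 0.05,
                       td_decrement = 5,
                       censor_cycle_distribution = list(name = "uniform_int",
                                                        min = 41L, max = 60L),
                       missing_prob_base = 0.07,
                       missing_prob_event_bump = 0.15,
                       seed = 1L) {
  if (is.null(frailty_sd)) {
    if (residual_sd >= baseline_sd)
      stop("residual_sd must be < baseline_sd when frailty_sd is derived",
           call. = FALSE)
    frailty_sd <- sqrt(baseline_sd^2 - residual_sd^2)
  }
  cfg <- list(
    n_patients = n_patients, max_cycle = max_cycle, cycle_weeks = cycle_weeks,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    plateau_mean = plateau_mean, rise_cycles = rise_cycles,
    frailty_sd = frailty_sd, residual_sd = residual_sd,
    predeath_drop = predeath_drop, predeath_window = predeath_window,
    death_hazard_base = death_hazard_base,
    death_hazard_qol_coef = death_hazard_qol_coef,
    pd_hazard = pd_hazard,
    td_lag_distribution = td_lag_distribution,
    td_no_pd_prob = td_no_pd_prob, td_decrement = td_decrement,
    censor_cycle_distribution = censor_cycle_distribution,
    missing_prob_base = missing_prob_base,
    missing_prob_event_bump = missing_prob_event_bump,
    seed = seed)
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!isTRUE(ok))
      stop(sprintf("invalid simulation config: '%s' %s", field, msg),
           call. = FALSE)
  }
  num1 <- function(f) {
    chk(is.numeric(cfg[[f]]) && length(cfg[[f]]) == 1 && is.finite(cfg[[f]]),
        f, "must be a single finite number")
  }
  for (f in c("n_patients", "max_cycle", "cycle_weeks", "baseline_mean",
              "baseline_sd", "plateau_mean", "rise_cycles", "frailty_sd",
              "residual_sd", "predeath_drop", "predeath_window",
              "death_hazard_base", "death_hazard_qol_coef", "pd_hazard",
              "td_no_pd_prob", "td_decrement", "missing_prob_base",
              "missing_prob_event_bump", "seed")) num1(f)
  chk(cfg$n_patients >= 1, "n_patients", "must be >= 1")
  chk(cfg$max_cycle >= 1, "max_cycle", "must be >= 1")
  chk(cfg$cycle_weeks >= 1, "cycle_weeks", "must be >= 1")
  chk(cfg$rise_cycles >= 1 && cfg$rise_cycles <= cfg$max_cycle,
      "rise_cycles", "must lie in [1, max_cycle]")
  chk(cfg$baseline_mean >= 0 && cfg$baseline_mean <= 100,
      "baseline_mean", "must lie in [0, 100]")
  chk(cfg$plateau_mean >= 0 && cfg$plateau_mean <= 100,
      "plateau_mean", "must lie in [0, 100]")
  chk(cfg$baseline_sd > 0, "baseline_sd", "must be > 0")
  chk(cfg$frailty_sd >= 0, "frailty_sd", "must be >= 0")
  chk(cfg$residual_sd >= 0, "residual_sd", "must be >= 0")
  chk(cfg$predeath_drop >= 0, "predeath_drop", "must be >= 0")
  chk(cfg$predeath_window >= 1, "predeath_window", "must be >= 1")
  for (p in c("pd_hazard", "td_no_pd_prob", "missing_prob_base",
              "missing_prob_event_bump"))
    chk(cfg[[p]] >= 0 && cfg[[p]] <= 1, p, "must be a probability in [0, 1]")
  chk(cfg$death_hazard_qol_coef >= 0, "death_hazard_qol_coef", "must be >= 0")
  chk(cfg$seed == round(cfg$seed), "seed", "must be an integer")
  cfg$td_lag_distribution <-
    validate_dist(cfg$td_lag_distribution, "td_lag_distribution")
  cfg$censor_cycle_distribution <-
    validate_dist(cfg$censor_cycle_distribution, "censor_cycle_distribution")
  structure(cfg, class = "sim_config")
}

#' Read / write a simulation configuration as YAML
#'
#' Unspecified fields take the [sim_config()] defaults; unknown fields are
#' rejected.
#'
#' @param path path to a YAML file.
#' @return `read_sim_config()` returns a validated `sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown simulation config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @param config a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Single-arm PRO trial simulation config\n")
  cat(sprintf("  %d patients, cycles 1-%d (%d weeks each), seed %d\n",
              x$n_patients, x$max_cycle, x$cycle_weeks, as.integer(x$seed)))
  cat(sprintf("  QoL curve: %.0f -> %.0f by cycle %d; frailty SD %.1f, residual SD %.1f\n",
              x$baseline_mean, x$plateau_mean, x$rise_cycles,
              x$frailty_sd, x$residual_sd))
  cat(sprintf("  death hazard: plogis(%.2f - %.3f * (QoL - 50)); PD hazard %.3f\n",
              x$death_hazard_base, x$death_hazard_qol_coef, x$pd_hazard))
  cat(sprintf("  pre-death drop %.1f pts/cycle over %d cycles; post-TD decrement %.1f\n",
              x$predeath_drop, x$predeath_window, x$td_decrement))
  cat(sprintf("  missingness: base %.2f + %.2f near events\n",
              x$missing_prob_base, x$missing_prob_event_bump))
  invisible(x)
}
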