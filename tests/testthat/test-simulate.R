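test_that("simulation is reproducible and structurally valid", {
  cfg <- quick_config(n = 120, seed = 42)
  tr1 <- simulate_trial(cfg)
  tr2 <- simulate_trial(cfg)
  expect_identical(tr1$complete, tr2$complete)
  expect_identical(tr1$observed, tr2$observed)
  expect_identical(tr1$timelines, tr2$timelines)

  for (seed in c(7, 8, 9)) {
    tr <- simulate_trial(quick_config(n = 80, seed = seed))
    death <- tr$timelines$death_cycle[
      match(tr$complete$patient_id, tr$timelines$patient_id)]
    # no QoL value exists at or after any death cycle
    expect_true(all(is.na(death) | tr$complete$cycle < death))
    # observed values are a subset of complete values
    key_c <- paste(tr$complete$patient_id, tr$complete$cycle)
    key_o <- paste(tr$observed$patient_id, tr$observed$cycle)
    expect_true(all(key_o %in% key_c))
    expect_equal(tr$observed$qol,
                 tr$complete$qol[match(key_o, key_c)])
    expect_true(all(tr$complete$qol >= 0 & tr$complete$qol <= 100))
    # timeline invariants
    tl <- tr$timelines
    expect_false(any(!is.na(tl$death_cycle) & !is.na(tl$censor_cycle)))
    expect_true(all(tl$td_cycle < tl$death_cycle, na.rm = TRUE))
    expect_true(all(tl$pd_cycle < tl$death_cycle, na.rm = TRUE))
  }
})

test_that("invalid configs are rejected with the offending field named", {
  expect_error(quick_config(missing_prob_base = 1.5), "missing_prob_base")
  expect_error(quick_config(baseline_mean = 130), "baseline_mean")
  expect_error(quick_config(rise_cycles = 50, max_cycle = 40), "rise_cycles")
  expect_error(quick_config(residual_sd = -1), "residual_sd")
  expect_error(quick_config(td_lag_distribution = list(name = "geometric",
                                                       prob = 2)),
               "td_lag_distribution")
})

test_that("collection design enforces schedule, TD stop and follow-up end", {
  cfg <- quick_config(missing_prob_base = 0, missing_prob_event_bump = 0)
  # patient discontinues at cycle 8 and dies at cycle 20: observable values
  # exist only at cycles 1-8 (collection ends at TD except its own cycle)
  complete <- data.frame(patient_id = 1L, cycle = 1:19,
                         qol = seq(40, 80, length.out = 19))
  tl <- data.frame(patient_id = 1L, death_cycle = 20L, pd_cycle = 5L,
                   td_cycle = 8L, censor_cycle = NA_integer_)
  obs <- apply_collection_design(complete, tl, cfg)
  expect_identical(obs$cycle, 1:8)

  # on-treatment patient: alternate cycles after cycle 10 never observed
  complete2 <- data.frame(patient_id = 1L, cycle = 1:14, qol = rep(50, 14))
  tl2 <- no_event_timelines(1)
  obs2 <- apply_collection_design(complete2, tl2, cfg)
  expect_identical(obs2$cycle, c(1:10, 12L, 14L))

  # the final TD-cycle questionnaire is kept even off-schedule
  tl3 <- data.frame(patient_id = 1L, death_cycle = NA_integer_,
                    pd_cycle = 9L, td_cycle = 13L, censor_cycle = 60L)
  obs3 <- apply_collection_design(complete2, tl3, cfg)
  expect_true(13L %in% obs3$cycle)
  expect_false(11L %in% obs3$cycle)

  # loss to follow-up ends observation
  tl4 <- no_event_timelines(1, censor = 6L)
  obs4 <- apply_collection_design(complete2, tl4, cfg)
  expect_identical(obs4$cycle, 1:6)
})

test_that("with no coupling, baseline QoL and survival are uncorrelated", {
  # hazard decoupled from QoL and the pre-death drop disabled: no mechanism
  # links baseline values to survival
  cfg <- quick_config(n = 2000, seed = 11, death_hazard_qol_coef = 0,
                      frailty_sd = 0, predeath_drop = 0,
                      death_hazard_base = -3)
  tr <- simulate_trial(cfg)
  s <- attr(tr, "structure")
  base <- tr$complete$qol[tr$complete$cycle == 1]
  ids <- tr$complete$patient_id[tr$complete$cycle == 1]
  surv_time <- ifelse(is.na(s$death_true), 99L, s$death_true)[ids]
  expect_lt(abs(cor(base, surv_time)), 2.5 / sqrt(length(base)))
})

test_that("with the drop disabled and hazard decoupled, the dying look like survivors", {
  cfg <- quick_config(n = 1500, seed = 21, predeath_drop = 0,
                      death_hazard_qol_coef = 0, frailty_sd = 0,
                      death_hazard_base = -3)
  tr <- simulate_trial(cfg)
  s <- attr(tr, "structure")
  d <- s$death_true[tr$complete$patient_id]
  near <- !is.na(d) & tr$complete$cycle >= d - 5
  # compare pre-death values with contemporaneous survivor values, cyclewise
  diffs <- sapply(5:25, function(t) {
    at_t <- tr$complete$cycle == t
    if (sum(at_t & near) < 10) return(NA_real_)
    mean(tr$complete$qol[at_t & near]) - mean(tr$complete$qol[at_t & !near])
  })
  expect_lt(abs(mean(diffs, na.rm = TRUE)), 1.5)

  # calibration of the cycle-1 mean (drop disabled so early deaths do not
  # pull cycle 1 down); tolerance is 2 SEM plus the small clipping shift
  base <- tr$complete$qol[tr$complete$cycle == 1]
  expect_lt(abs(mean(base) - cfg$baseline_mean),
            2 * cfg$baseline_sd / sqrt(length(base)) + 0.3)
})

test_that("ground truth oracle behaves at its analytic limits", {
  # no deaths: survival one everywhere
  gt0 <- suppressWarnings(compute_ground_truth(
    eventfree_config(n = 50, seed = 3), n_oracle = 2000, oracle_seed = 5))
  expect_true(all(gt0$survival == 1))
  expect_true(all(gt0$n_alive == 2000))

  # no frailty, no pre-death drop, decoupled hazard: the while-alive mean
  # tracks the population curve (no selection is possible)
  cfg <- quick_config(n = 50, seed = 3, frailty_sd = 0, predeath_drop = 0,
                      death_hazard_qol_coef = 0, td_decrement = 0)
  gt1 <- suppressWarnings(compute_ground_truth(cfg, n_oracle = 4000,
                                               oracle_seed = 5))
  curve <- population_curve(1:40, cfg)
  expect_lt(max(abs(gt1$while_alive_mean - curve)), 1.2)

  # default selection mechanism: survivors are a favourable subset, so the
  # while-alive mean exceeds the no-death hypothetical mean late on
  gt2 <- suppressWarnings(compute_ground_truth(quick_config(n = 100, seed = 3),
                                               n_oracle = 6000,
                                               oracle_seed = 5))
  expect_gt(gt2$while_alive_mean[40], gt2$hypothetical_mean[40])
  expect_true(all(diff(gt2$survival) <= 0))
  expect_true(all(gt2$while_alive_mean >= 0 & gt2$while_alive_mean <= 100))
})

test_that("config YAML round-trips and rejects unknown fields", {
  cfg <- quick_config(n = 33, seed = 9, pd_hazard = 0.08)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  cfg2 <- read_sim_config(path)
  expect_equal(unclass(cfg), unclass(cfg2), tolerance = 1e-9)
  writeLines("not_a_field: 3", path)
  expect_error(read_sim_config(path), "unknown")
})
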