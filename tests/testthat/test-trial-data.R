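obs1 <- function(...) data.frame(patient_id = 1L, ...)

test_that("validation enforces the data model", {
  tl <- data.frame(patient_id = 1L, death_cycle = 10L, pd_cycle = 4L,
                   td_cycle = 6L, censor_cycle = NA_integer_)
  # a PRO at or after death is a hard error: not observable, not defined
  expect_error(
    validate_dataset(obs1(cycle = 12L, qol = 50), tl),
    "neither observable nor defined")
  expect_error(
    validate_dataset(obs1(cycle = 10L, qol = 50), tl),
    "neither observable nor defined")
  # boundary values are valid
  expect_silent(validate_dataset(obs1(cycle = 9L, qol = 100), tl))
  expect_silent(validate_dataset(obs1(cycle = 1L, qol = 0), tl))
  # empty dataset is valid
  expect_silent(validate_dataset(
    data.frame(patient_id = integer(), cycle = integer(), qol = numeric()),
    tl))
  # out-of-range, duplicates, death+censor both set
  expect_error(validate_dataset(obs1(cycle = 2L, qol = 101), tl), "0, 100")
  expect_error(validate_dataset(obs1(cycle = 2L, qol = 50), rbind(tl, tl)),
               "duplicate")
  tl_bad <- tl; tl_bad$censor_cycle <- 12L
  expect_error(validate_dataset(obs1(cycle = 2L, qol = 50), tl_bad),
               "both")
  # collect mode returns violations instead of stopping
  v <- validate_dataset(obs1(cycle = 2L, qol = -5), rbind(tl, tl),
                        collect = TRUE)
  expect_length(v, 2)
})

test_that("within-cycle collapsing averages duplicates and is idempotent", {
  obs <- data.frame(patient_id = c(1, 1, 2, 3, 3, 3),
                    cycle = c(2, 2, 1, 4, 4, 4),
                    qol = c(40, 60, 73, 0, 100, 50))
  out <- collapse_within_cycle(obs)
  expect_equal(out$qol[out$patient_id == 1], 50)
  expect_equal(out$qol[out$patient_id == 2], 73)
  expect_equal(out$qol[out$patient_id == 3], 50)
  expect_identical(collapse_within_cycle(out), out)
})

test_that("six-state classification follows the event timeline", {
  tl <- data.frame(
    patient_id = 1:3,
    death_cycle = c(5L, NA, NA),
    pd_cycle = c(2L, NA, 6L),
    td_cycle = c(3L, NA, 8L),
    censor_cycle = c(NA, 20L, 50L))
  obs <- data.frame(patient_id = c(1L, 3L, 3L), cycle = c(2L, 8L, 12L),
                    qol = c(50, 60, 55))
  ss <- classify_states(obs, tl, max_cycle = 25L)
  state_of <- function(pid, t) {
    # recover the patient state by classifying each patient alone
    ss1 <- classify_states(obs[obs$patient_id == pid, , drop = FALSE],
                           tl[tl$patient_id == pid, , drop = FALSE], 25L)
    unname(which(unlist(ss1[ss1$cycle == t, -1]) == 1))
  }
  # deceased from the death cycle onward
  expect_equal(state_of(1, 5), 6)
  expect_equal(state_of(1, 25), 6)
  # on treatment with QoL at cycle 2; pre-death, off-treatment at cycle 4
  expect_equal(state_of(1, 2), 1)
  expect_equal(state_of(1, 4), 4)
  # lost to follow-up strictly after the censoring cycle
  expect_equal(state_of(2, 20), 2)
  expect_equal(state_of(2, 21), 5)
  # TD-cycle questionnaire counts as on treatment; afterwards off treatment
  expect_equal(state_of(3, 8), 1)
  expect_equal(state_of(3, 9), 4)
  expect_equal(state_of(3, 12), 3)
  # partition: states sum to n at every cycle
  expect_true(all(rowSums(ss[, -1]) == nrow(tl)))
})

test_that("state counts partition simulated cohorts", {
  tr <- simulate_trial(quick_config(n = 150, seed = 13))
  ss <- classify_states(collapse_within_cycle(tr$observed), tr$timelines, 40L)
  expect_true(all(rowSums(ss[, -1]) == 150))
  expect_true(all(diff(ss$state6) >= 0))  # deaths accumulate
})

test_that("variable derivation handles baseline, bounds and ceilings", {
  obs <- data.frame(
    patient_id = c(1, 1, 2, 2, 3, 3, 4),
    cycle = c(1, 5, 1, 5, 1, 5, 5),
    qol = c(91, 100, 0, 30, 54, 67, 70))
  chg <- derive_variable(obs, variable_spec("change_from_baseline"))
  # change is bounded by [-baseline, 100 - baseline]
  expect_true(all(chg$value >= -chg$baseline & chg$value <= 100 - chg$baseline))
  # a floor baseline cannot produce a negative change
  expect_true(all(chg$value[chg$patient_id == 2] >= 0))
  expect_equal(chg$value[chg$patient_id == 3 & chg$cycle == 5], 13)
  # patient 4 has no cycle-1 value: excluded and flagged
  expect_false(4 %in% chg$patient_id)
  expect_equal(attr(chg, "excluded_patients"), 4)

  resp <- derive_variable(obs, variable_spec("responder"))
  # baseline 91: a >=10-point response is impossible (max change 9)
  expect_true(all(resp$value[resp$patient_id == 1] == 0))
  expect_equal(resp$value[resp$patient_id == 3 & resp$cycle == 5], 1)

  abs_v <- derive_variable(obs, variable_spec("absolute"))
  expect_equal(abs_v$value, collapse_within_cycle(obs)$qol)
})

test_that("available-data summaries report mean, CI and n per cycle", {
  d <- data.frame(cycle = c(1, 1, 2, 3, 3, 3, 3, 4),
                  value = c(50, 70, 80, 1, 0, 0, 1, 55))
  s <- summarize_available(d)
  expect_equal(s$mean[s$cycle == 1], 60)
  expect_equal(s$n[s$cycle == 1], 2)
  expect_equal(s$mean[s$cycle == 3], 0.5)  # responder proportion
  # single value: mean without a CI
  expect_equal(s$mean[s$cycle == 4], 55)
  expect_true(is.na(s$se[s$cycle == 4]))
  # constant values: zero-width CI
  s2 <- summarize_available(data.frame(cycle = 1, value = rep(42, 5)))
  expect_equal(s2$lcl, s2$ucl)
  # a cycle with no data emits no row
  expect_false(5 %in% s$cycle)
})

test_that("schedule arithmetic and responder ceiling helpers", {
  expect_identical(scheduled_cycles(14), c(1:10, 12L, 14L))
  expect_identical(scheduled_cycles(9), 1:9)
  expect_equal(elapsed_weeks(4, 3), 12)
  expect_equal(responder_ceiling(20, 100), 81)
  expect_error(variable_spec("responder", responder_threshold = 0))
})

test_that("long and timeline CSVs round-trip with empty fields as NA", {
  tr <- simulate_trial(quick_config(n = 20, seed = 31))
  qp <- withr::local_tempfile(fileext = ".csv")
  tp <- withr::local_tempfile(fileext = ".csv")
  write_qol_data(tr$observed, qp)
  write_timelines(tr$timelines, tp)
  expect_equal(read_qol_data(qp), tr$observed)
  expect_equal(read_timelines(tp), tr$timelines)
})
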