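test_that("dataset restriction implements each inclusion rule", {
  tl <- data.frame(
    patient_id = 1:4,
    death_cycle = c(12L, NA, 4L, NA),
    pd_cycle = c(3L, 5L, NA, NA),
    td_cycle = c(6L, 9L, NA, NA),
    censor_cycle = c(NA, 30L, NA, 8L))
  data <- do.call(rbind, lapply(1:4, function(p)
    data.frame(patient_id = p, cycle = 1:40, qol = 50)))

  # treatment policy keeps everything to death/censoring
  tp <- restrict_dataset(data, tl, estimand_spec())
  expect_identical(tp$cycle[tp$patient_id == 1], 1:11)
  expect_identical(tp$cycle[tp$patient_id == 2], 1:30)
  expect_identical(tp$cycle[tp$patient_id == 4], 1:8)

  # while on treatment drops rows strictly after TD (TD-cycle row kept)
  wot <- restrict_dataset(data, tl,
                          estimand_spec(td_strategy = "while_on_treatment"))
  expect_identical(wot$cycle[wot$patient_id == 1], 1:6)
  expect_identical(wot$cycle[wot$patient_id == 3], 1:3)

  # while progression-free drops rows after PD
  wpf <- restrict_dataset(data, tl,
    estimand_spec(pd_strategy = "while_progression_free"))
  expect_identical(wpf$cycle[wpf$patient_id == 1], 1:3)

  # composite appends the assigned value from death through cycle 40
  cmp <- restrict_dataset(data, tl, estimand_spec(death_strategy = "composite",
                                                  composite_value = 0))
  p3 <- cmp[cmp$patient_id == 3, ]
  expect_identical(p3$cycle, 1:40)
  expect_true(all(p3$value[p3$cycle >= 4] == 0))
  expect_true(all(p3$value[p3$cycle < 4] == 50))
})

test_that("independence GEE reproduces descriptive means with robust SEs", {
  d <- random_complete_data(40, 1:12, seed = 101)
  names(d)[3] <- "value"
  s <- estimate_gee_independence(d, max_cycle = 12)
  expect_equal(s$estimate, descriptive_means(d, 12), tolerance = 1e-12)
  expect_true(all(s$n == 40))
  # robust clustered SE approximates the per-cycle sample SE of the mean
  sem <- vapply(1:12, function(t) {
    v <- d$value[d$cycle == t]; sd(v) / sqrt(length(v))
  }, numeric(1))
  expect_equal(s$se, sem, tolerance = 0.05)

  # a cycle with one observation flags its SE; an empty cycle warns
  d1 <- data.frame(patient_id = 1:3, cycle = c(1, 1, 2),
                   value = c(10, 30, 50))
  expect_warning(s1 <- estimate_gee_independence(d1, max_cycle = 3),
                 "cycle")
  expect_equal(s1$estimate[1:2], c(20, 50))
  expect_true(is.na(s1$se[2]))
  expect_true(is.na(s1$estimate[3]))
})

test_that("balanced-data LMM fixed effects equal per-cycle means", {
  d <- random_complete_data(30, 1:8, seed = 55)
  names(d)[3] <- "value"
  for (rs in c("intercept", "intercept_slope")) {
    fit <- suppressWarnings(fit_lmm(d, rs, max_cycle = 8))
    mm <- lmm_marginal_means(fit)
    expect_equal(mm$estimate, descriptive_means(d, 8), tolerance = 1e-6)
  }
})

test_that("LMM recovers its own variance components", {
  # balanced generating model: value = cycle mean + patient intercept + noise
  sd0 <- 10; sig <- 5
  ests <- t(replicate(5, {
    n <- 200; cyc <- 1:10
    b <- rnorm(n, 0, sd0)
    d <- data.frame(patient_id = rep(1:n, each = length(cyc)),
                    cycle = rep(cyc, n))
    d$value <- 50 + 2 * d$cycle + b[d$patient_id] +
      rnorm(nrow(d), 0, sig)
    fit <- fit_lmm(d, "intercept", max_cycle = 10)
    c(sqrt(fit$varcorr$vcov[1]), fit$sigma)
  }))
  expect_lt(abs(mean(ests[, 1]) / sd0 - 1), 0.15)
  expect_lt(abs(mean(ests[, 2]) / sig - 1), 0.05)
})

test_that("zero between-patient variance yields a boundary fit", {
  set.seed(9)
  d <- data.frame(patient_id = rep(1:60, each = 6), cycle = rep(1:6, 60))
  d$value <- 40 + d$cycle + rnorm(nrow(d), 0, 3)  # no patient effect
  expect_warning(fit <- fit_lmm(d, "intercept", max_cycle = 6), "boundary|singular")
  expect_lt(fit$varcorr$vcov[1], 0.5)
})

test_that("survivor averaging equals marginal means without deaths or censoring", {
  d <- random_complete_data(25, 1:10, seed = 77)
  names(d)[3] <- "value"
  tl <- no_event_timelines(25, censor = 12L)
  fit <- suppressWarnings(fit_lmm(d, "intercept_slope", max_cycle = 10))
  mm <- lmm_marginal_means(fit)
  sa <- lmm_survivor_averaged_means(fit, tl)
  expect_equal(sa$estimate, mm$estimate, tolerance = 1e-8)
  expect_true(all(sa$n == 25, na.rm = TRUE))
})

test_that("on complete data the survivor-averaged LMM is the per-cycle mean", {
  # with one row per alive patient-cycle and saturated categorical time,
  # Henderson's equations make beta_t + mean(EB effects of those with data
  # at t) equal the observed cycle mean; the averaging set coincides with
  # the patients contributing rows, so the identity is exact
  tr <- simulate_trial(quick_config(n = 150, seed = 3))
  sa <- estimate(tr$complete, tr$timelines,
                 estimand_spec(estimator = "lmm_survivor_averaged"))
  wa <- estimate(tr$complete, tr$timelines, estimand_spec())
  expect_equal(sa$series$estimate, wa$series$estimate, tolerance = 1e-6)
})

test_that("composite identity: appended zeros scale the mean by survival", {
  tl <- data.frame(patient_id = 1:10,
                   death_cycle = c(rep(3L, 5), rep(NA, 5)),
                   pd_cycle = NA_integer_, td_cycle = NA_integer_,
                   censor_cycle = c(rep(NA, 5), rep(45L, 5)))
  data <- do.call(rbind, lapply(1:10, function(p) {
    upper <- if (p <= 5) 2 else 40
    data.frame(patient_id = p, cycle = 1:upper, qol = 60 + p)
  }))
  cm <- estimate(data, tl, estimand_spec(death_strategy = "composite"))
  wa <- estimate(data, tl, estimand_spec())
  # at cycle 10 half the cohort is dead and no one is censored
  expect_equal(cm$series$estimate[10], wa$series$estimate[10] * 0.5)
})

test_that("random-structure comparison is an ML likelihood-ratio test", {
  set.seed(4)
  n <- 80; cyc <- 1:8
  d <- data.frame(patient_id = rep(1:n, each = length(cyc)),
                  cycle = rep(cyc, n))
  slope <- rnorm(n, 0, 4); b <- rnorm(n, 0, 8)
  d$value <- 50 + b[d$patient_id] +
    slope[d$patient_id] * (d$cycle - 4) / 4 + rnorm(nrow(d), 0, 5)
  f1 <- suppressWarnings(fit_lmm(d, "intercept", max_cycle = 8))
  f2 <- suppressWarnings(fit_lmm(d, "intercept_slope", max_cycle = 8))
  cmp <- compare_random_structures(f1, f2)
  expect_gt(cmp$lrt_statistic, 0)
  expect_gt(cmp$delta_AIC, 0)  # true slope variance: slope model fits better
  expect_lt(cmp$p_value, 0.01)
  expect_equal(cmp$df, 2L)
  # mismatched data are refused
  d2 <- d; d2$value <- d2$value + 1
  f3 <- suppressWarnings(fit_lmm(d2, "intercept_slope", max_cycle = 8))
  expect_error(compare_random_structures(f1, f3), "identical data")
  expect_error(compare_random_structures(f2, f1), "intercept fit")
})

test_that("the dispatch engine attaches the required companion curves", {
  tr <- simulate_trial(quick_config(n = 80, seed = 37))
  e_tp <- estimate(tr$complete, tr$timelines, estimand_spec())
  expect_named(e_tp$survival, "death")
  e_wot <- estimate(tr$complete, tr$timelines,
                    estimand_spec(td_strategy = "while_on_treatment"))
  expect_setequal(names(e_wot$survival), c("death", "td_or_death"))
  e_h <- estimate(tr$complete, tr$timelines,
                  estimand_spec(death_strategy = "hypothetical",
                                td_strategy = "hypothetical",
                                pd_strategy = "hypothetical",
                                estimator = "lmm_marginal"))
  expect_setequal(names(e_h$survival),
                  c("death", "td_or_death", "pd_or_death"))
  expect_s3_class(e_h$fit, "lmm_fit")
})

test_that("hypothetical-TD marginal and while-alive survivor series differ under death", {
  tr <- simulate_trial(quick_config(n = 200, seed = 41))
  h_marg <- suppressWarnings(
    estimate(tr$complete, tr$timelines,
             estimand_spec(death_strategy = "hypothetical",
                           td_strategy = "hypothetical",
                           estimator = "lmm_marginal")))
  h_sa <- suppressWarnings(
    estimate(tr$complete, tr$timelines,
             estimand_spec(death_strategy = "while_alive",
                           td_strategy = "hypothetical",
                           estimator = "lmm_survivor_averaged")))
  diffs <- abs(h_marg$series$estimate - h_sa$series$estimate)
  expect_gt(max(diffs, na.rm = TRUE), 1)
})

test_that("per-cycle SEs are commensurate across estimator families", {
  tr <- simulate_trial(quick_config(n = 250, seed = 43))
  imp <- tr$complete
  se_g <- estimate(imp, tr$timelines, estimand_spec())$series$se
  se_m <- estimate(imp, tr$timelines,
                   estimand_spec(death_strategy = "hypothetical",
                                 estimator = "lmm_marginal"))$series$se
  ratio <- se_g / se_m
  expect_true(all(ratio[!is.na(ratio)] > 1 / 5 & ratio[!is.na(ratio)] < 5))
})
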