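#' Restrict a complete dataset to the rows an estimand uses
#'
#' Applies the "QoL data included in the analysis" rule of each strategy
#' combination to a complete (imputed or latent) dataset:
#'
#' * treatment policy (TD and PD): all rows up to death/censoring are kept,
#'   including outcomes after TD or PD;
#' * while on treatment: rows strictly after the TD cycle are removed (the
#'   final questionnaire at the TD cycle is kept);
#' * while progression-free: rows strictly after the PD cycle are removed;
#' * hypothetical TD/PD: the same pre-event restriction is applied to the
#'   fitting data — the model is later predicted beyond the event;
#' * composite death: rows with value `composite_value` are appended from
#'   each observed death cycle through `max_cycle`.
#'
#' @param data complete long data (`patient_id`, `cycle`, and `qol` or
#'   `value`).
#' @param timelines timeline table.
#' @param spec an [estimand_spec()].
#' @return A long data frame `patient_id`, `cycle`, `value`.
#' @export
restrict_dataset <- function(data, timelines, spec) {
  stopifnot(inherits(spec, "estimand_spec"))
  val <- if ("value" %in% names(data)) data$value else data$qol
  df <- data.frame(patient_id = data$patient_id, cycle = data$cycle,
                   value = val)
  idx <- match(df$patient_id, timelines$patient_id)
  death <- timelines$death_cycle[idx]
  censor <- timelines$censor_cycle[idx]
  td <- timelines$td_cycle[idx]
  pd <- timelines$pd_cycle[idx]

  keep <- df$cycle <= spec$max_cycle &
    (is.na(death) | df$cycle < death) &
    (is.na(censor) | df$cycle <= censor)
  if (spec$td_strategy %in% c("while_on_treatment", "hypothetical"))
    keep <- keep & (is.na(td) | df$cycle <= td)
  if (spec$pd_strategy %in% c("while_progression_free", "hypothetical"))
    keep <- keep & (is.na(pd) | df$cycle <= pd)
  df <- df[keep, , drop = FALSE]

  if (spec$death_strategy == "composite") {
    dead <- timelines[!is.na(timelines$death_cycle) &
                        timelines$death_cycle <= spec$max_cycle, ]
    if (nrow(dead)) {
      extra <- do.call(rbind, lapply(seq_len(nrow(dead)), function(i) {
        data.frame(patient_id = dead$patient_id[i],
                   cycle = seq.int(dead$death_cycle[i], spec$max_cycle),
                   value = spec$composite_value)
      }))
      df <- rbind(df, extra)
    }
  }
  df <- df[order(df$patient_id, df$cycle), ]
  rownames(df) <- NULL
  df
}

# membership sets on the cycle grid
alive_at <- function(timelines, t) {
  (is.na(timelines$death_cycle) | t < timelines$death_cycle) &
    (is.na(timelines$censor_cycle) | t <= timelines$censor_cycle)
}

#' Per-cycle means via GEE with independence working correlation
#'
#' With cycle as a saturated categorical covariate and an independence
#' working correlation, the GEE point estimates are exactly the per-cycle
#' arithmetic means of the included rows — the descriptive estimator.
#' Standard errors are robust (sandwich) SEs clustered on patient,
#' computed from an OLS fit of the saturated cycle-mean model.
#'
#' @param analysis long data `patient_id`, `cycle`, `value` (from
#'   [restrict_dataset()]).
#' @param max_cycle last cycle of the reported grid.
#' @param conf_level confidence level for normal-approximation CIs.
#' @return Data frame `cycle`, `estimate`, `se`, `lcl`, `ucl`, `n`
#'   (contributing rows). Cycles with no rows are reported as `NA` with a
#'   warning; cycles with one row report the value without an SE.
#' @export
estimate_gee_independence <- function(analysis, max_cycle = 40L,
                                      conf_level = 0.95) {
  stopifnot(all(c("patient_id", "cycle", "value") %in% names(analysis)))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  n_per <- table(factor(analysis$cycle, levels = seq_len(max_cycle)))
  empty <- which(as.integer(n_per) == 0)
  if (length(empty))
    warning("no data at cycle(s) ", paste(empty, collapse = ", "),
            "; estimates skipped there")

  cyc_f <- factor(analysis$cycle)
  fit <- stats::lm(value ~ 0 + cyc_f, data = analysis)
  vc <- sandwich::vcovCL(fit, cluster = analysis$patient_id)
  est <- stats::coef(fit)
  se <- sqrt(diag(vc))
  lev <- as.integer(levels(cyc_f))

  out <- data.frame(cycle = seq_len(max_cycle), estimate = NA_real_,
                    se = NA_real_, lcl = NA_real_, ucl = NA_real_,
                    n = as.integer(n_per))
  out$estimate[lev] <- unname(est)
  out$se[lev] <- unname(se)
  out$se[out$n <= 1] <- NA_real_  # a single row gives no SE
  out$lcl <- out$estimate - z * out$se
  out$ucl <- out$estimate + z * out$se
  out
}

#' Fit the linear mixed model for QoL over cycles
#'
#' REML fit of `value ~ 0 + factor(cycle) + (1 | patient)` or, with a
#' random slope, `(1 + ct | patient)` where `ct = (cycle - max_cycle/2) /
#' (max_cycle/2)` is a centered, scaled continuous cycle (conditioning
#' stability; the fixed effects stay categorical). Random effects are
#' jointly normal with unstructured covariance; residuals independent
#' normal.
#'
#' @param analysis long data `patient_id`, `cycle`, `value`.
#' @param random_structure `"intercept"` or `"intercept_slope"`.
#' @param max_cycle last cycle of the grid (used for the slope scaling and
#'   downstream prediction).
#' @return A list of class `lmm_fit`: the `lme4` fit, the random structure,
#'   the represented cycles, variance components, convergence diagnostics
#'   and per-patient empirical-Bayes random-effect predictions.
#' @export
fit_lmm <- function(analysis,
                    random_structure = c("intercept_slope", "intercept"),
                    max_cycle = 40L) {
  random_structure <- match.arg(random_structure)
  stopifnot(nrow(analysis) > 0)
  if (length(unique(analysis$patient_id)) < 2 ||
      length(unique(analysis$cycle)) < 2)
    stop("LMM fitting needs at least 2 patients and 2 cycles", call. = FALSE)
  d <- data.frame(
    value = analysis$value,
    cycle_f = factor(analysis$cycle),
    ct = (analysis$cycle - max_cycle / 2) / (max_cycle / 2),
    patient_id = factor(analysis$patient_id))
  form <- if (random_structure == "intercept")
    value ~ 0 + cycle_f + (1 | patient_id)
  else
    value ~ 0 + cycle_f + (1 + ct | patient_id)
  fit <- lme4::lmer(form, data = d, REML = TRUE,
                    control = lme4::lmerControl(calc.derivs = FALSE))
  opt <- fit@optinfo$conv$opt
  if (!is.null(opt) && opt != 0)
    stop("LMM optimizer failed to converge (code ", opt, "): ",
         paste(unlist(fit@optinfo$message), collapse = "; "), call. = FALSE)
  if (lme4::isSingular(fit))
    warning("LMM variance components on the boundary (singular fit)")
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    fit = fit,
    random_structure = random_structure,
    cycles = as.integer(levels(d$cycle_f)),
    max_cycle = as.integer(max_cycle),
    n_patients = lme4::ngrps(fit)[["patient_id"]],
    varcorr = vc,
    sigma = stats::sigma(fit),
    singular = lme4::isSingular(fit),
    ranef = lme4::ranef(fit)$patient_id,
    logLik_reml = as.numeric(stats::logLik(fit))
  ), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("LMM fit (REML): random %s, %d patients, %d cycles represented\n",
              sub("_", "+", x$random_structure), x$n_patients,
              length(x$cycles)))
  cat(sprintf("  residual SD %.2f%s\n", x$sigma,
              if (x$singular) " [boundary fit]" else ""))
  invisible(x)
}

series_frame <- function(max_cycle, conf_level = 0.95) {
  data.frame(cycle = seq_len(max_cycle), estimate = NA_real_, se = NA_real_,
             lcl = NA_real_, ucl = NA_real_, n = NA_integer_)
}

#' Marginal means from a fitted LMM (hypothetical strategy)
#'
#' The cycle fixed effects are the model's marginal means (random effects
#' have mean zero). With data truncated by death, these means extrapolate
#' each patient's trajectory beyond death and so target the hypothetical
#' no-death estimand. SEs come from the fixed-effect covariance.
#'
#' @param lmm a [fit_lmm()] result.
#' @param conf_level confidence level.
#' @return Data frame `cycle`, `estimate`, `se`, `lcl`, `ucl`, `n` (the
#'   number of patients in the fit); cycles with no represented fixed
#'   effect are `NA`.
#' @export
lmm_marginal_means <- function(lmm, conf_level = 0.95) {
  stopifnot(inherits(lmm, "lmm_fit"))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- series_frame(lmm$max_cycle, conf_level)
  beta <- lme4::fixef(lmm$fit)
  se <- sqrt(diag(as.matrix(stats::vcov(lmm$fit))))
  out$estimate[lmm$cycles] <- unname(beta)
  out$se[lmm$cycles] <- unname(se)
  out$lcl <- out$estimate - z * out$se
  out$ucl <- out$estimate + z * out$se
  out$n <- lmm$n_patients
  out
}

#' Survivor-averaged predictions from a fitted LMM (while-alive strategy)
#'
#' Individual model predictions (fixed effect plus empirical-Bayes random
#' effects) are averaged at each cycle over only the patients alive and
#' under follow-up at that cycle. SEs are delta-method SEs on the fixed
#' effects, treating the empirical-Bayes predictions as fixed — a
#' documented approximation.
#'
#' @param lmm a [fit_lmm()] result.
#' @param timelines timeline table defining the alive-and-followed set per
#'   cycle.
#' @param conf_level confidence level.
#' @return Data frame `cycle`, `estimate`, `se`, `lcl`, `ucl`, `n` (alive
#'   set size); cycles with an empty alive set are skipped (`NA`).
#' @export
lmm_survivor_averaged_means <- function(lmm, timelines, conf_level = 0.95) {
  stopifnot(inherits(lmm, "lmm_fit"))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- series_frame(lmm$max_cycle, conf_level)
  beta <- lme4::fixef(lmm$fit)
  se_fix <- sqrt(diag(as.matrix(stats::vcov(lmm$fit))))
  re <- lmm$ranef
  b0 <- stats::setNames(re[["(Intercept)"]], rownames(re))
  b1 <- if ("ct" %in% names(re)) stats::setNames(re[["ct"]], rownames(re))

  for (t in lmm$cycles) {
    ids <- as.character(timelines$patient_id[alive_at(timelines, t)])
    if (!length(ids)) next
    ct <- (t - lmm$max_cycle / 2) / (lmm$max_cycle / 2)
    dev0 <- b0[ids]; dev0[is.na(dev0)] <- 0  # patients with no fitted rows
    dev <- dev0
    if (!is.null(b1)) {
      dev1 <- b1[ids]; dev1[is.na(dev1)] <- 0
      dev <- dev + dev1 * ct
    }
    k <- match(t, lmm$cycles)
    out$estimate[t] <- unname(beta[k]) + mean(dev)
    out$se[t] <- se_fix[k]
    out$n[t] <- length(ids)
  }
  out$lcl <- out$estimate - z * out$se
  out$ucl <- out$estimate + z * out$se
  out
}

#' Compare random-intercept and random-slope LMMs
#'
#' Likelihood-ratio test and AIC difference on ML refits of the two
#' models. The reference distribution is a plain chi-square with 2 degrees
#' of freedom (slope variance + intercept-slope covariance); at the
#' variance boundary this is conservative (the true reference is a
#' chi-square mixture), so reported p-values are upper bounds.
#'
#' @param fit_intercept,fit_slope [fit_lmm()] results for the same data
#'   with `random_structure` `"intercept"` and `"intercept_slope"`.
#' @return List with `delta_AIC` (AIC(intercept) - AIC(slope); positive
#'   favors the slope model), `lrt_statistic`, `df` and `p_value`.
#' @export
compare_random_structures <- function(fit_intercept, fit_slope) {
  stopifnot(inherits(fit_intercept, "lmm_fit"), inherits(fit_slope, "lmm_fit"))
  if (fit_intercept$random_structure != "intercept" ||
      fit_slope$random_structure != "intercept_slope")
    stop("arguments must be an intercept fit and an intercept+slope fit",
         call. = FALSE)
  y1 <- lme4::getME(fit_intercept$fit, "y")
  y2 <- lme4::getME(fit_slope$fit, "y")
  if (length(y1) != length(y2) || !isTRUE(all.equal(sum(y1), sum(y2))) ||
      !isTRUE(all.equal(sum(y1^2), sum(y2^2))))
    stop("the two fits are not on identical data", call. = FALSE)
  ml1 <- lme4::refitML(fit_intercept$fit)
  ml2 <- lme4::refitML(fit_slope$fit)
  stat <- max(0, 2 * (as.numeric(stats::logLik(ml2)) -
                        as.numeric(stats::logLik(ml1))))
  list(delta_AIC = stats::AIC(ml1) - stats::AIC(ml2),
       lrt_statistic = stat, df = 2L,
       p_value = stats::pchisq(stat, df = 2, lower.tail = FALSE))
}

#' Estimate a fully specified estimand
#'
#' The dispatch engine: derives the variable of interest, restricts the
#' complete dataset per the intercurrent-event strategies, runs the matched
#' estimator, and attaches the companion product-limit curves — the death
#' curve always, plus the TD-or-death / PD-or-death curves whenever the
#' respective strategy is not treatment policy.
#'
#' @param data complete long dataset (`patient_id`, `cycle`, `qol`), e.g.
#'   from [impute_single()] or the latent arm of [simulate_trial()].
#' @param timelines timeline table.
#' @param spec an [estimand_spec()].
#' @param conf_level confidence level for all intervals.
#' @return An object of class `qol_estimates`: list with `series` (per-cycle
#'   `estimate`, `se`, `lcl`, `ucl`, `n`), `spec`, `label`, `survival` (named
#'   list of [km_curve()] companions) and `fit` (estimator diagnostics; the
#'   `lmm_fit` for LMM estimators).
#' @export
estimate <- function(data, timelines, spec = estimand_spec(),
                     conf_level = 0.95) {
  stopifnot(inherits(spec, "estimand_spec"))
  derived <- derive_variable(data, spec$variable)
  analysis <- restrict_dataset(derived, timelines, spec)

  fit_info <- NULL
  if (spec$estimator == "gee_independence") {
    series <- estimate_gee_independence(analysis, spec$max_cycle, conf_level)
  } else {
    lmm <- fit_lmm(analysis, spec$random_structure, spec$max_cycle)
    fit_info <- lmm
    series <- if (spec$estimator == "lmm_marginal")
      lmm_marginal_means(lmm, conf_level)
    else
      lmm_survivor_averaged_means(lmm, timelines, conf_level)
  }

  curves <- list(death = km_curve(timelines, "death", spec$max_cycle))
  if (spec$td_strategy != "treatment_policy")
    curves$td_or_death <- km_curve(timelines, "td_or_death", spec$max_cycle)
  if (spec$pd_strategy != "treatment_policy")
    curves$pd_or_death <- km_curve(timelines, "pd_or_death", spec$max_cycle)

  structure(list(series = series, spec = spec, label = estimand_label(spec),
                 survival = curves, fit = fit_info),
            class = "qol_estimates")
}

#' @export
print.qol_estimates <- function(x, ...) {
  cat("Per-cycle mean QoL estimates\n")
  cat("  estimand:", x$label, "\n")
  ok <- !is.na(x$series$estimate)
  cat(sprintf("  %d of %d cycles estimated; companions: %s\n",
              sum(ok), nrow(x$series),
              paste(names(x$survival), collapse = ", ")))
  print(utils::head(x$series[ok, ], 5), row.names = FALSE)
  if (sum(ok) > 5) cat("  ...\n")
  invisible(x)
}

#' @rdname read_qol_data
#' @param estimates a `qol_estimates` object.
#' @export
write_estimate_series <- function(estimates, path) {
  stopifnot(inherits(estimates, "qol_estimates"))
  df <- estimates$series
  df$estimand_label <- estimates$label
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
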