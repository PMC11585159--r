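#' Imputation model specification
#'
#' Settings for the event-conditioned single imputation of missing QoL
#' values. The model conditions on the cycle number (categorical), the most
#' recent available QoL value and its distance in cycles, indicators of
#' disease progression and treatment discontinuation having occurred by the
#' cycle, and — for patients whose death was observed — proximity to death
#' (an indicator of being within `predeath_window` cycles of death, and the
#' number of cycles until death). For censored patients no anticipation of
#' an unobserved death enters the model.
#'
#' @param residual_draw add a seeded normal residual draw to each imputed
#'   value (default `TRUE`; avoids variance deflation of per-cycle means).
#'   `FALSE` gives conditional-mean imputation.
#' @param seed integer seed; required when `residual_draw = TRUE`.
#' @param predeath_window cycles before death over which QoL is assumed to
#'   drop (default 5).
#' @return An object of class `impute_spec`.
#' @export
impute_spec <- function(residual_draw = TRUE, seed = NULL,
                        predeath_window = 5L) {
  if (residual_draw && is.null(seed))
    stop("'seed' must be set when residual_draw is on", call. = FALSE)
  stopifnot(predeath_window >= 1)
  structure(list(residual_draw = residual_draw, seed = seed,
                 predeath_window = as.integer(predeath_window)),
            class = "impute_spec")
}

#' Per patient-cycle predictor table for the imputation model
#'
#' One row per patient per cycle that requires a value — all cycles from 1
#' to `min(max_cycle, death_cycle - 1, censor_cycle)`; never at or after
#' death, never after censoring. Missing values are imputed before and
#' after PD and/or TD, but not after death, so unscheduled cycles appear
#' here like any other missing cycle.
#'
#' Predictors: `pd_now` (PD on or before the cycle), `td_now` (strictly
#' after the TD cycle, whose final questionnaire counts as on-treatment),
#' `death_observed`, `near_death` (within `predeath_window` cycles of an
#' observed death), `cycles_to_death` (0 for censored patients),
#' `last_obs_qol` and `gap` (cycles since that observation; negative when
#' only a later observation exists, as for missing leading cycles).
#'
#' @param observations observed (collapsed) long data.
#' @param timelines timeline table.
#' @param max_cycle last cycle of the grid (default 40).
#' @param predeath_window window for the near-death indicator (default 5).
#' @return Data frame with one row per required patient-cycle: `patient_id`,
#'   `cycle`, `qol` (`NA` where missing), `observed`, and the predictors.
#' @export
build_feature_table <- function(observations, timelines, max_cycle = 40L,
                                predeath_window = 5L) {
  obs <- collapse_within_cycle(observations)
  rows <- lapply(seq_len(nrow(timelines)), function(i) {
    tl <- timelines[i, ]
    upper <- min(max_cycle,
                 if (!is.na(tl$death_cycle)) tl$death_cycle - 1L else max_cycle,
                 if (!is.na(tl$censor_cycle)) tl$censor_cycle else max_cycle)
    if (upper < 1) return(NULL)
    t <- seq_len(upper)
    p_obs <- obs[obs$patient_id == tl$patient_id, ]
    qol <- p_obs$qol[match(t, p_obs$cycle)]
    dobs <- !is.na(tl$death_cycle)
    data.frame(
      patient_id = tl$patient_id,
      cycle = t,
      qol = qol,
      observed = !is.na(qol),
      pd_now = as.numeric(!is.na(tl$pd_cycle) & t >= tl$pd_cycle),
      td_now = as.numeric(!is.na(tl$td_cycle) & t > tl$td_cycle),
      death_observed = as.numeric(dobs),
      near_death = as.numeric(dobs & t >= tl$death_cycle - predeath_window),
      cycles_to_death = if (dobs) tl$death_cycle - t else 0
    )
  })
  ft <- do.call(rbind, rows)
  rownames(ft) <- NULL

  # last available QoL and its distance, from observed values only (the
  # forward pass in impute_single() recomputes these with imputed values
  # chained in); the convention for rows before a patient's first
  # observation is the nearest later observation, giving a negative gap
  ft$last_obs_qol <- NA_real_
  ft$gap <- NA_real_
  for (pid in unique(ft$patient_id)) {
    sel <- which(ft$patient_id == pid)
    p_obs <- obs[obs$patient_id == pid, ]
    if (!nrow(p_obs)) next
    for (k in sel) {
      t <- ft$cycle[k]
      prev <- p_obs[p_obs$cycle < t, ]
      if (nrow(prev)) {
        j <- which.max(prev$cycle)
        ft$last_obs_qol[k] <- prev$qol[j]
        ft$gap[k] <- t - prev$cycle[j]
      } else {
        other <- p_obs[p_obs$cycle != t, ]
        if (nrow(other)) {
          j <- which.min(other$cycle)
          ft$last_obs_qol[k] <- other$qol[j]
          ft$gap[k] <- t - other$cycle[j]
        }
      }
    }
  }
  ft
}

# fit the pooled linear imputation model on observed rows; constant
# predictors are dropped silently (e.g. death_observed in a dataset without
# deaths) and predictors aliased with the remaining design are dropped with
# a warning; a design that remains rank-deficient is a degenerate dataset
fit_imputation_model <- function(ft) {
  fit_rows <- ft[ft$observed & !is.na(ft$last_obs_qol), ]
  if (nrow(fit_rows) < 5)
    stop("too few observed values to fit the imputation model ",
         "(degenerate design, e.g. all values at one cycle)", call. = FALSE)
  fit_rows$cycle_cat <- factor(fit_rows$cycle)
  num_terms <- c("last_obs_qol", "gap", "pd_now", "td_now", "near_death",
                 "death_observed", "cycles_to_death")
  keep <- num_terms[vapply(num_terms,
                           function(v) stats::var(fit_rows[[v]]) > 0,
                           logical(1))]
  repeat {
    form <- stats::as.formula(paste(
      "qol ~ cycle_cat", if (length(keep)) "+" else "",
      paste(keep, collapse = " + ")))
    fit <- stats::lm(form, data = fit_rows)
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    if (!length(aliased)) break
    drop <- keep[keep %in% aliased]
    if (!length(drop))
      stop("singular imputation model fit: the cycle effects are collinear ",
           "on the observed rows (degenerate design)", call. = FALSE)
    warning("imputation model: dropping predictor(s) collinear with the ",
            "cycle effects: ", paste(drop, collapse = ", "))
    keep <- setdiff(keep, drop)
  }
  list(fit = fit, kept_terms = keep,
       cycle_levels = as.integer(levels(fit_rows$cycle_cat)),
       sigma = summary(fit)$sigma, n_obs = nrow(fit_rows))
}

# linear predictor evaluated without predict() for speed in the forward pass
imputation_coefs <- function(model, max_cycle) {
  cf <- stats::coef(model$fit)
  lev <- model$cycle_levels
  cyc_eff <- cf[["(Intercept)"]] +
    c(0, cf[paste0("cycle_cat", lev[-1])])
  names(cyc_eff) <- lev
  # a cycle with no observed data borrows the nearest observed cycle's effect
  nearest <- vapply(seq_len(max_cycle),
                    function(t) lev[which.min(abs(lev - t))], integer(1))
  b <- function(nm) if (nm %in% names(cf)) cf[[nm]] else 0
  list(cyc_eff_full = unname(cyc_eff[as.character(nearest)]),
       b = vapply(c("last_obs_qol", "gap", "pd_now", "td_now", "near_death",
                    "death_observed", "cycles_to_death"), b, numeric(1)))
}

#' Event-conditioned single imputation of missing QoL values
#'
#' Fits one pooled linear regression of observed QoL on the predictor set
#' of [build_feature_table()] and fills every missing patient-cycle in
#' cycle order with the fitted value plus (by default) a seeded residual
#' draw, clipped to \[0, 100\]. Imputation is forward-chained: an imputed
#' value serves as the "last available QoL" for later cycles of the same
#' patient. Observed values are never altered and nothing is imputed at or
#' after death. The output is complete: every patient has a value at every
#' cycle from 1 to `min(max_cycle, death_cycle - 1, censor_cycle)`.
#'
#' Patients with no observed values at all are imputed from the population
#' model (the overall observed mean standing in for their last available
#' value) and flagged.
#'
#' @param observations observed long data (`patient_id`, `cycle`, `qol`).
#' @param timelines timeline table.
#' @param spec an [impute_spec()].
#' @param max_cycle last cycle of the grid (default 40).
#' @return A list of class `imputed_data`: `data` (long data frame with
#'   `provenance` column `observed`/`imputed`), `model` (coefficients,
#'   residual SD, number of fitting rows), `n_imputed_per_cycle`, and
#'   `flagged_patients` (patients imputed with no observed values).
#' @export
impute_single <- function(observations, timelines, spec = impute_spec(seed = 1L),
                          max_cycle = 40L) {
  stopifnot(inherits(spec, "impute_spec"))
  validate_dataset(observations, timelines)
  ft <- build_feature_table(observations, timelines, max_cycle,
                            spec$predeath_window)
  if (is.null(ft) || !nrow(ft))
    return(structure(list(
      data = data.frame(patient_id = integer(), cycle = integer(),
                        qol = numeric(), provenance = character()),
      model = NULL, n_imputed_per_cycle = integer(),
      flagged_patients = integer()), class = "imputed_data"))

  if (all(ft$observed)) {
    # nothing to impute: return the (collapsed) data unchanged
    data <- data.frame(patient_id = ft$patient_id, cycle = ft$cycle,
                       qol = ft$qol, provenance = "observed")
    return(structure(list(
      data = data, model = NULL,
      n_imputed_per_cycle = rep(0L, max_cycle),
      flagged_patients = integer()), class = "imputed_data"))
  }

  model <- fit_imputation_model(ft)
  co <- imputation_coefs(model, max_cycle)
  pop_mean <- mean(ft$qol[ft$observed])
  if (spec$residual_draw) set.seed(spec$seed)

  ft <- ft[order(ft$patient_id, ft$cycle), ]
  qol_out <- ft$qol
  prov <- ifelse(ft$observed, "observed", "imputed")
  flagged <- integer(0)

  for (pid in unique(ft$patient_id)) {
    sel <- which(ft$patient_id == pid)
    if (all(ft$observed[sel])) next
    p_obs_cycles <- ft$cycle[sel][ft$observed[sel]]
    if (!length(p_obs_cycles)) flagged <- c(flagged, pid)
    last_val <- NA_real_; last_cyc <- NA_real_
    for (k in sel) {
      t <- ft$cycle[k]
      if (ft$observed[k]) {
        last_val <- qol_out[k]; last_cyc <- t
        next
      }
      if (is.na(last_val)) {
        later <- p_obs_cycles[p_obs_cycles > t]
        if (length(later)) {
          lc <- min(later)
          lv <- qol_out[sel[ft$cycle[sel] == lc]]
        } else { lv <- pop_mean; lc <- t }
      } else { lv <- last_val; lc <- last_cyc }
      x <- c(lv, t - lc, ft$pd_now[k], ft$td_now[k], ft$near_death[k],
             ft$death_observed[k], ft$cycles_to_death[k])
      pred <- co$cyc_eff_full[t] + sum(co$b * x)
      if (spec$residual_draw) pred <- pred + stats::rnorm(1, 0, model$sigma)
      qol_out[k] <- clip_scale(pred)
      last_val <- qol_out[k]; last_cyc <- t
    }
  }

  data <- data.frame(patient_id = ft$patient_id, cycle = ft$cycle,
                     qol = qol_out, provenance = prov)
  rownames(data) <- NULL
  n_imp <- table(factor(data$cycle[data$provenance == "imputed"],
                        levels = seq_len(max_cycle)))
  structure(list(
    data = data,
    model = list(coefficients = stats::coef(model$fit), sigma = model$sigma,
                 n_obs = model$n_obs, kept_terms = model$kept_terms),
    n_imputed_per_cycle = as.integer(n_imp),
    flagged_patients = flagged
  ), class = "imputed_data")
}

#' @export
print.imputed_data <- function(x, ...) {
  n_imp <- sum(x$data$provenance == "imputed")
  cat(sprintf("Imputed PRO dataset: %d rows (%d observed, %d imputed)\n",
              nrow(x$data), nrow(x$data) - n_imp, n_imp))
  if (!is.null(x$model))
    cat(sprintf("  imputation model: %d fitting rows, residual SD %.2f\n",
                x$model$n_obs, x$model$sigma))
  if (length(x$flagged_patients))
    cat("  patients imputed without any observed value: ",
        paste(x$flagged_patients, collapse = ", "), "\n")
  invisible(x)
}

#' Write a plain-text log of an imputation run
#'
#' Records the model coefficients, residual SD and the number of imputed
#' values per cycle.
#'
#' @param imputed an `imputed_data` object from [impute_single()].
#' @param path output text file.
#' @return `path`, invisibly.
#' @export
write_imputation_log <- function(imputed, path) {
  stopifnot(inherits(imputed, "imputed_data"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("Event-conditioned single imputation log", con)
  if (is.null(imputed$model)) {
    writeLines("no imputation was required (dataset already complete)", con)
    return(invisible(path))
  }
  writeLines(sprintf("fitting rows: %d; residual SD: %.4f",
                     imputed$model$n_obs, imputed$model$sigma), con)
  writeLines("coefficients:", con)
  cf <- imputed$model$coefficients
  writeLines(sprintf("  %-24s %10.4f", names(cf), cf), con)
  writeLines("imputed values per cycle:", con)
  writeLines(sprintf("  cycle %2d: %d", seq_along(imputed$n_imputed_per_cycle),
                     imputed$n_imputed_per_cycle), con)
  invisible(path)
}
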