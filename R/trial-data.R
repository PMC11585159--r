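#' Variable-of-interest specification
#'
#' Three candidate variables for a 0-100 QoL score measured over cycles:
#' the absolute value, the change from baseline (the cycle-1 value), and a
#' binary responder classification (change of at least
#' `responder_threshold` points above baseline).
#'
#' @param kind one of `"absolute"`, `"change_from_baseline"`, `"responder"`.
#' @param responder_threshold minimum increase from baseline defining
#'   response (default 10 points; must be > 0).
#' @return An object of class `variable_spec`.
#' @export
variable_spec <- function(kind = c("absolute", "change_from_baseline",
                                   "responder"),
                          responder_threshold = 10) {
  kind <- match.arg(kind)
  if (responder_threshold <= 0)
    stop("responder_threshold must be > 0", call. = FALSE)
  structure(list(kind = kind, responder_threshold = responder_threshold),
            class = "variable_spec")
}

#' Validate a PRO dataset against its timeline table
#'
#' Checks structural validity of a long QoL table and a per-patient
#' timeline table: values on the 0-100 scale, 1-based integer cycles,
#' unique timeline rows per patient, death and censoring not both recorded,
#' PD/TD cycles not after death, and — as a hard error in all modes — no
#' QoL value at or after a patient's death cycle (outcomes after death are
#' neither observable nor defined).
#'
#' @param observations long data frame `patient_id`, `cycle`, `qol`.
#' @param timelines data frame `patient_id`, `death_cycle`, `pd_cycle`,
#'   `td_cycle`, `censor_cycle` (`NA` = event not observed).
#' @param collect if `TRUE`, return a character vector of violations
#'   instead of stopping (QoL at/after death still stops).
#' @return Invisibly, a list with `observations` and `timelines` when valid;
#'   with `collect = TRUE`, a character vector of violations (length 0 when
#'   valid).
#' @export
validate_dataset <- function(observations, timelines, collect = FALSE) {
  need_obs <- c("patient_id", "cycle", "qol")
  need_tl <- c("patient_id", "death_cycle", "pd_cycle", "td_cycle",
               "censor_cycle")
  if (!all(need_obs %in% names(observations)))
    stop("observations must have columns ", paste(need_obs, collapse = ", "),
         call. = FALSE)
  if (!all(need_tl %in% names(timelines)))
    stop("timelines must have columns ", paste(need_tl, collapse = ", "),
         call. = FALSE)

  # PROs at or after death are a hard error regardless of mode
  idx <- match(observations$patient_id, timelines$patient_id)
  death <- timelines$death_cycle[idx]
  bad_death <- !is.na(death) & observations$cycle >= death
  if (any(bad_death, na.rm = TRUE))
    stop(sprintf(
      "QoL value at or after death for patient(s) %s: PROs after death are neither observable nor defined",
      paste(unique(observations$patient_id[which(bad_death)]), collapse = ", ")),
      call. = FALSE)

  v <- character(0)
  if (anyDuplicated(timelines$patient_id))
    v <- c(v, "duplicate patient_id in timelines")
  if (nrow(observations)) {
    if (any(is.na(observations$qol)))
      v <- c(v, "missing qol values in observations (omit unobserved rows)")
    out_of_range <- !is.na(observations$qol) &
      (observations$qol < 0 | observations$qol > 100)
    if (any(out_of_range))
      v <- c(v, sprintf("%d qol value(s) outside [0, 100]", sum(out_of_range)))
    if (any(observations$cycle < 1 | observations$cycle != round(observations$cycle)))
      v <- c(v, "cycles must be 1-based integers")
    if (anyNA(idx))
      v <- c(v, "observations contain patients absent from timelines")
  }
  tl_cyc <- timelines[c("death_cycle", "pd_cycle", "td_cycle", "censor_cycle")]
  if (any(unlist(tl_cyc) < 1, na.rm = TRUE))
    v <- c(v, "timeline cycles must be >= 1")
  if (any(!is.na(timelines$death_cycle) & !is.na(timelines$censor_cycle)))
    v <- c(v, "death_cycle and censor_cycle must not both be recorded")
  if (any(timelines$td_cycle > timelines$death_cycle, na.rm = TRUE))
    v <- c(v, "td_cycle after death_cycle")
  if (any(timelines$pd_cycle > timelines$death_cycle, na.rm = TRUE))
    v <- c(v, "pd_cycle after death_cycle")

  if (collect) return(v)
  if (length(v))
    stop("invalid dataset: ", paste(v, collapse = "; "), call. = FALSE)
  invisible(list(observations = observations, timelines = timelines))
}

#' Average multiple PRO reports within one patient-cycle
#'
#' When a patient reports more than one measurement in a cycle, the
#' measurements in that cycle are replaced by their arithmetic mean;
#' singleton values are unchanged. Idempotent.
#'
#' @param observations long data frame `patient_id`, `cycle`, `qol`.
#' @return Long data frame with at most one row per patient-cycle, sorted by
#'   patient then cycle.
#' @export
collapse_within_cycle <- function(observations) {
  if (!nrow(observations)) return(observations[c("patient_id", "cycle", "qol")])
  agg <- stats::aggregate(qol ~ patient_id + cycle, data = observations,
                          FUN = mean)
  agg <- agg[order(agg$patient_id, agg$cycle), c("patient_id", "cycle", "qol")]
  rownames(agg) <- NULL
  agg
}

#' Six-state classification of PRO availability per cycle
#'
#' Assigns every patient exactly one state at every cycle:
#' 1 alive, on treatment, QoL available; 2 alive, on treatment, QoL not
#' available; 3 alive, off treatment, QoL available; 4 alive, off
#' treatment, QoL not available; 5 lost to follow-up; 6 deceased.
#' A patient is deceased from the death cycle on, lost to follow-up
#' strictly after the censoring cycle, and off treatment strictly after the
#' TD cycle (the final questionnaire at the TD cycle counts as on
#' treatment).
#'
#' @param observations available (observed, collapsed) long data.
#' @param timelines timeline table.
#' @param max_cycle last cycle to classify.
#' @return Data frame `cycle`, `state1` .. `state6`; rows sum to the number
#'   of patients in `timelines`.
#' @export
classify_states <- function(observations, timelines, max_cycle = 40L) {
  n <- nrow(timelines)
  tt <- seq_len(max_cycle)
  death <- timelines$death_cycle
  censor <- timelines$censor_cycle
  td <- timelines$td_cycle

  avail <- matrix(FALSE, n, max_cycle)
  if (nrow(observations)) {
    keep <- observations$cycle <= max_cycle
    i <- match(observations$patient_id[keep], timelines$patient_id)
    avail[cbind(i, observations$cycle[keep])] <- TRUE
  }

  state <- matrix(NA_integer_, n, max_cycle)
  for (t in tt) {
    dead <- !is.na(death) & t >= death
    ltfu <- !dead & !is.na(censor) & t > censor
    off <- !is.na(td) & t > td
    a <- avail[, t]
    state[, t] <- ifelse(dead, 6L,
                  ifelse(ltfu, 5L,
                  ifelse(!off & a, 1L,
                  ifelse(!off & !a, 2L,
                  ifelse(a, 3L, 4L)))))
  }
  counts <- t(apply(state, 2, tabulate, nbins = 6L))
  out <- data.frame(cycle = tt, counts)
  names(out) <- c("cycle", paste0("state", 1:6))
  out
}

#' Derive the variable of interest from raw QoL values
#'
#' Applies a [variable_spec()] to (collapsed) observations. Baseline is the
#' cycle-1 value after within-cycle averaging. For change-from-baseline and
#' responder variables, patients with no cycle-1 value are excluded and
#' listed in the `"excluded_patients"` attribute. Change from baseline is
#' bounded in `[-baseline, 100 - baseline]`; the responder indicator is 1
#' when the change is at least the threshold — so integer baselines of
#' `responder_ceiling()` or more can never respond.
#'
#' @param observations long data frame `patient_id`, `cycle`, `qol`.
#' @param spec a [variable_spec()].
#' @return Long data frame `patient_id`, `cycle`, `value` (plus `baseline`
#'   for derived kinds), with attribute `excluded_patients`.
#' @export
derive_variable <- function(observations, spec = variable_spec()) {
  stopifnot(inherits(spec, "variable_spec"))
  obs <- collapse_within_cycle(observations)
  if (spec$kind == "absolute") {
    out <- data.frame(patient_id = obs$patient_id, cycle = obs$cycle,
                      value = obs$qol)
    attr(out, "excluded_patients") <- integer(0)
    return(out)
  }
  base <- obs[obs$cycle == 1L, c("patient_id", "qol")]
  names(base)[2] <- "baseline"
  out <- merge(obs, base, by = "patient_id")
  excluded <- setdiff(unique(obs$patient_id), base$patient_id)
  chg <- out$qol - out$baseline
  out$value <- if (spec$kind == "change_from_baseline") chg
               else as.numeric(chg >= spec$responder_threshold)
  out <- out[order(out$patient_id, out$cycle),
             c("patient_id", "cycle", "value", "baseline")]
  rownames(out) <- NULL
  attr(out, "excluded_patients") <- excluded
  out
}

#' Per-cycle summary of the available (unimputed) data
#'
#' Arithmetic mean with a normal-approximation 95% confidence interval and
#' the contributing n at each cycle, computed on available data only.
#' Cycles with no values are omitted; cycles with a single value report the
#' mean without a CI.
#'
#' @param derived output of [derive_variable()] (columns `cycle`, `value`).
#' @param conf_level confidence level (default 0.95).
#' @return Data frame `cycle`, `mean`, `se`, `lcl`, `ucl`, `n`.
#' @export
summarize_available <- function(derived, conf_level = 0.95) {
  stopifnot(all(c("cycle", "value") %in% names(derived)))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  cyc <- sort(unique(derived$cycle))
  rows <- lapply(cyc, function(t) {
    v <- derived$value[derived$cycle == t]
    n <- length(v)
    m <- mean(v)
    se <- if (n > 1) stats::sd(v) / sqrt(n) else NA_real_
    data.frame(cycle = t, mean = m, se = se,
               lcl = m - z * se, ucl = m + z * se, n = n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- CSV interfaces --------------------------------------------------------

#' Read and write the long QoL and timeline CSV formats
#'
#' Long QoL CSV: columns `patient_id`, `cycle`, `qol` and optionally
#' `provenance` (`observed`/`imputed`). Timeline CSV: `patient_id`,
#' `death_cycle`, `pd_cycle`, `td_cycle`, `censor_cycle`, with empty fields
#' for unobserved events. Cycles are 1-based integers.
#'
#' @param path file path.
#' @return The data frame read, or (for writers) `path` invisibly.
#' @export
read_qol_data <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("patient_id", "cycle", "qol") %in% names(df)))
  df$cycle <- as.integer(df$cycle)
  df$qol <- as.numeric(df$qol)
  df
}

#' @rdname read_qol_data
#' @param data data frame to write.
#' @export
write_qol_data <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname read_qol_data
#' @export
read_timelines <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "death_cycle", "pd_cycle", "td_cycle",
            "censor_cycle")
  stopifnot(all(need %in% names(df)))
  for (f in need[-1]) df[[f]] <- as.integer(df[[f]])
  df
}

#' @rdname read_qol_data
#' @export
write_timelines <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, na = "")
  invisible(path)
}
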