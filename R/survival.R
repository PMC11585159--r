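#' Discrete-cycle Kaplan-Meier curve for death or composite events
#'
#' Product-limit estimate on the integer cycle grid for one of three event
#' types: death, PD-or-death, or TD-or-death (composite events use the
#' earlier of the component cycles). Patients without the event are censored
#' at their censoring cycle; within a cycle, events precede censoring (the
#' standard risk-set convention). These curves are the mandatory companions
#' of while-alive QoL estimates: the probability of being alive, of
#' remaining progression-free, and of remaining on protocol treatment.
#'
#' @param timelines timeline table (`patient_id`, `death_cycle`, `pd_cycle`,
#'   `td_cycle`, `censor_cycle`).
#' @param event one of `"death"`, `"pd_or_death"`, `"td_or_death"`.
#' @param max_cycle last cycle of the reported grid (default 40).
#' @param conf_type `"log-log"` (default; respects \[0,1\]) or `"plain"`
#'   Greenwood.
#' @return Data frame of class `survival_curve` with columns `cycle`
#'   (0..`max_cycle`; the cycle-0 row is the unit starting point), `at_risk`,
#'   `events`, `estimate`, `se` (Greenwood SE of the survival probability),
#'   `lcl`, `ucl`; the event type is kept in attribute `"event"`.
#' @export
km_curve <- function(timelines,
                     event = c("death", "pd_or_death", "td_or_death"),
                     max_cycle = 40L,
                     conf_type = c("log-log", "plain")) {
  event <- match.arg(event)
  conf_type <- match.arg(conf_type)
  death <- timelines$death_cycle
  comp <- switch(event,
    death = death,
    pd_or_death = pmin(timelines$pd_cycle, death, na.rm = TRUE),
    td_or_death = pmin(timelines$td_cycle, death, na.rm = TRUE))
  has_event <- !is.na(comp)
  time <- ifelse(has_event, comp, timelines$censor_cycle)
  if (any(is.na(time)))
    stop("each patient needs an event cycle or a censor_cycle", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, as.numeric(has_event)) ~ 1,
                           conf.type = if (conf_type == "plain") "plain"
                                       else "log-log")
  sm <- summary(fit, times = 0:max_cycle, extend = TRUE)
  out <- data.frame(
    cycle = sm$time,
    at_risk = sm$n.risk,
    events = sm$n.event,
    estimate = sm$surv,
    se = sm$std.err,
    lcl = clip_scale(sm$lower, 0, 1),
    ucl = clip_scale(sm$upper, 0, 1))
  # survfit omits CI limits where S is 0; keep NA there
  attr(out, "event") <- event
  class(out) <- c("survival_curve", "data.frame")
  out
}

#' Median event cycle from a product-limit curve
#'
#' The first cycle at which the estimated survival probability is at or
#' below one half (the "at or below" convention: a cycle where the estimate
#' equals 0.5 exactly is the median).
#'
#' @param curve a [km_curve()] result.
#' @return A list with `cycle` (integer, `NA` when the curve never reaches
#'   0.5) and `defined` (logical flag).
#' @export
median_survival <- function(curve) {
  stopifnot(inherits(curve, "survival_curve"))
  hit <- which(curve$estimate <= 0.5 & curve$cycle > 0)
  if (!length(hit)) return(list(cycle = NA_integer_, defined = FALSE))
  list(cycle = as.integer(curve$cycle[hit[1]]), defined = TRUE)
}

#' @rdname read_qol_data
#' @export
write_survival_curve <- function(data, path) {
  stopifnot(inherits(data, "survival_curve"))
  df <- as.data.frame(data)
  df$event <- attr(data, "event")
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
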