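#' Estimand specification for per-cycle mean QoL
#'
#' The five-attribute target of estimation for a longitudinal PRO in a
#' single-arm trial: the variable of interest, one handling strategy per
#' intercurrent event (death, treatment discontinuation, disease
#' progression), and the matched estimator. Only the strategy/estimator
#' combinations of the case-study mapping are valid:
#'
#' * `while_alive` death strategy pairs with the independence GEE (a
#'   descriptive per-cycle mean among those alive) or the survivor-averaged
#'   LMM;
#' * `composite` (death absorbed into the outcome at `composite_value`,
#'   default 0) pairs with the independence GEE; composite handling is
#'   offered for death only — assigning a single QoL value to TD or PD is
#'   not meaningful;
#' * `hypothetical` death strategy (a counterfactual without deaths) pairs
#'   with marginal means from an LMM, whose implicit extrapolation after
#'   death is exactly what targets that counterfactual;
#' * `while_on_treatment` (TD) and `while_progression_free` (PD) imply a
#'   while-alive handling of death, since neither state continues after
#'   death;
#' * a `hypothetical` strategy for TD or PD requires an LMM estimator
#'   (fitted to pre-event data and predicted beyond it).
#'
#' @param variable a [variable_spec()] (default: absolute QoL value).
#' @param death_strategy `"while_alive"`, `"composite"` or `"hypothetical"`.
#' @param td_strategy `"treatment_policy"`, `"while_on_treatment"` or
#'   `"hypothetical"`.
#' @param pd_strategy `"treatment_policy"`, `"while_progression_free"` or
#'   `"hypothetical"`.
#' @param estimator `"gee_independence"`, `"lmm_marginal"` or
#'   `"lmm_survivor_averaged"`.
#' @param random_structure LMM random effects: `"intercept"` or
#'   `"intercept_slope"` (random slope on a centered, scaled cycle; fixed
#'   effects stay categorical).
#' @param composite_value outcome value assigned after death under the
#'   composite strategy (default 0; always report it with the results).
#' @param max_cycle last analyzed cycle (default 40).
#' @return An object of class `estimand_spec`.
#' @examples
#' estimand_spec()  # while-alive death, treatment-policy TD and PD, GEE
#' @export
estimand_spec <- function(variable = variable_spec(),
                          death_strategy = c("while_alive", "composite",
                                             "hypothetical"),
                          td_strategy = c("treatment_policy",
                                          "while_on_treatment",
                                          "hypothetical"),
                          pd_strategy = c("treatment_policy",
                                          "while_progression_free",
                                          "hypothetical"),
                          estimator = c("gee_independence", "lmm_marginal",
                                        "lmm_survivor_averaged"),
                          random_structure = c("intercept_slope", "intercept"),
                          composite_value = 0,
                          max_cycle = 40L) {
  spec <- structure(list(
    variable = variable,
    death_strategy = match.arg(death_strategy),
    td_strategy = match.arg(td_strategy),
    pd_strategy = match.arg(pd_strategy),
    estimator = match.arg(estimator),
    random_structure = match.arg(random_structure),
    composite_value = composite_value,
    max_cycle = as.integer(max_cycle)), class = "estimand_spec")
  validate_estimand_spec(spec)
}

validate_estimand_spec <- function(spec) {
  stopifnot(inherits(spec$variable, "variable_spec"), spec$max_cycle >= 1)
  bad <- function(msg) stop("invalid estimand: ", msg, call. = FALSE)
  if (spec$death_strategy == "while_alive" &&
      !spec$estimator %in% c("gee_independence", "lmm_survivor_averaged"))
    bad(paste("a while-alive strategy for death is estimated with the",
              "independence GEE or the survivor-averaged LMM",
              "(strategy/method mapping, while-alive rows)"))
  if (spec$death_strategy == "composite" && spec$estimator != "gee_independence")
    bad(paste("the composite strategy for death is estimated with the",
              "independence GEE (strategy/method mapping, composite row)"))
  if (spec$death_strategy == "hypothetical" && spec$estimator != "lmm_marginal")
    bad(paste("a hypothetical strategy for death is estimated with marginal",
              "means from an LMM (strategy/method mapping, hypothetical rows)"))
  if (spec$td_strategy == "while_on_treatment" &&
      spec$death_strategy != "while_alive")
    bad(paste("a while-on-treatment strategy for TD implies a while-alive",
              "strategy for death, since treatment does not continue after",
              "death"))
  if (spec$pd_strategy == "while_progression_free" &&
      spec$death_strategy != "while_alive")
    bad(paste("a while-progression-free strategy for PD implies a",
              "while-alive strategy for death"))
  if ((spec$td_strategy == "hypothetical" || spec$pd_strategy == "hypothetical") &&
      spec$estimator == "gee_independence")
    bad(paste("a hypothetical strategy for TD or PD requires an LMM",
              "estimator fitted to pre-event data (strategy/method mapping,",
              "hypothetical TD/PD rows)"))
  spec
}

#' Human-readable estimand label
#'
#' The full estimand description — variable, per-event strategies (with the
#' composite value where applicable) and estimator — for use in figure
#' legends, table captions and reports. Every presented result should carry
#' this label.
#'
#' @param spec an [estimand_spec()].
#' @return A single string.
#' @export
estimand_label <- function(spec) {
  stopifnot(inherits(spec, "estimand_spec"))
  var_lab <- switch(spec$variable$kind,
    absolute = "absolute QoL",
    change_from_baseline = "change from baseline",
    responder = sprintf("responder (>= %g points)",
                        spec$variable$responder_threshold))
  death_lab <- switch(spec$death_strategy,
    while_alive = "while alive",
    composite = sprintf("composite (value %g)", spec$composite_value),
    hypothetical = "hypothetical")
  est_lab <- switch(spec$estimator,
    gee_independence = "GEE (independence)",
    lmm_marginal = sprintf("LMM marginal means (random %s)",
                           sub("_", "+", spec$random_structure)),
    lmm_survivor_averaged = sprintf("LMM survivor-averaged (random %s)",
                                    sub("_", "+", spec$random_structure)))
  sprintf("%s | death: %s | TD: %s | PD: %s | %s",
          var_lab, death_lab, gsub("_", " ", spec$td_strategy),
          gsub("_", " ", spec$pd_strategy), est_lab)
}

#' @export
print.estimand_spec <- function(x, ...) {
  cat("Estimand:", estimand_label(x), "\n")
  cat(sprintf("  cycles 1-%d; per-cycle population summary: mean\n",
              x$max_cycle))
  invisible(x)
}

#' Read estimand specifications from YAML
#'
#' The file holds either one spec (a mapping) or a list of specs. Fields
#' mirror the arguments of [estimand_spec()]; the variable is given as
#' `variable: {kind: ..., responder_threshold: ...}`.
#'
#' @param path YAML file path.
#' @return A list of `estimand_spec` objects.
#' @export
read_estimand_specs <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(names(raw))) raw <- list(raw)
  lapply(raw, function(r) {
    if (!is.null(r$variable)) r$variable <- do.call(variable_spec, r$variable)
    do.call(estimand_spec, r)
  })
}

# all valid strategy/estimator combinations (used in tests and reports)
valid_estimand_grid <- function(max_cycle = 40L) {
  grid <- expand.grid(
    death_strategy = c("while_alive", "composite", "hypothetical"),
    td_strategy = c("treatment_policy", "while_on_treatment", "hypothetical"),
    pd_strategy = c("treatment_policy", "while_progression_free",
                    "hypothetical"),
    estimator = c("gee_independence", "lmm_marginal",
                  "lmm_survivor_averaged"),
    stringsAsFactors = FALSE)
  specs <- list()
  for (i in seq_len(nrow(grid))) {
    s <- try(estimand_spec(
      death_strategy = grid$death_strategy[i],
      td_strategy = grid$td_strategy[i],
      pd_strategy = grid$pd_strategy[i],
      estimator = grid$estimator[i],
      max_cycle = max_cycle), silent = TRUE)
    if (!inherits(s, "try-error")) specs[[length(specs) + 1]] <- s
  }
  specs
}
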