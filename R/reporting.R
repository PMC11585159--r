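#' Overlay plot of estimand series
#'
#' One curve per estimand, each legend entry carrying the full estimand
#' label (variable, per-event strategies including any composite value, and
#' estimator), with 95% CI ribbons. Use [plot_survival_companions()] for
#' the matching event-free curves.
#'
#' @param estimates_list a list of `qol_estimates` objects (or a single
#'   one).
#' @param title plot title.
#' @return A `ggplot` object.
#' @export
plot_estimate_series <- function(estimates_list, title = "Estimated mean QoL per cycle") {
  if (inherits(estimates_list, "qol_estimates"))
    estimates_list <- list(estimates_list)
  df <- do.call(rbind, lapply(estimates_list, function(e) {
    s <- e$series
    s$estimand <- e$label
    s
  }))
  df <- df[!is.na(df$estimate), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cycle, y = .data$estimate,
                                   colour = .data$estimand,
                                   fill = .data$estimand)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lcl, ymax = .data$ucl),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(title = title, x = "Cycle", y = "Mean global QoL (0-100)",
                  colour = "Estimand", fill = "Estimand") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom",
                   legend.direction = "vertical")
}

#' Companion event-free probability curves
#'
#' Kaplan-Meier companions for a set of estimates: survival, and where the
#' estimands call for them, remaining-on-treatment and
#' remaining-progression-free probabilities.
#'
#' @param estimates_list a list of `qol_estimates` objects (or one).
#' @return A `ggplot` object.
#' @export
plot_survival_companions <- function(estimates_list) {
  if (inherits(estimates_list, "qol_estimates"))
    estimates_list <- list(estimates_list)
  curves <- list()
  for (e in estimates_list) curves[names(e$survival)] <- e$survival
  lab <- c(death = "alive",
           td_or_death = "alive and on treatment",
           pd_or_death = "alive and progression-free")
  df <- do.call(rbind, lapply(names(curves), function(nm) {
    d <- as.data.frame(curves[[nm]])
    d$event <- lab[[nm]]
    d
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cycle, y = .data$estimate,
                                   colour = .data$event)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Cycle", y = "Probability", colour = "Event-free for") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}

#' Stacked six-state availability chart
#'
#' Per-cycle counts of the six availability states (alive on/off treatment
#' with/without QoL, lost to follow-up, deceased) as a stacked area chart.
#'
#' @param state_summary output of [classify_states()].
#' @return A `ggplot` object.
#' @export
plot_state_summary <- function(state_summary) {
  labs <- c(state1 = "1 alive, on treatment, QoL available",
            state2 = "2 alive, on treatment, QoL not available",
            state3 = "3 alive, off treatment, QoL available",
            state4 = "4 alive, off treatment, QoL not available",
            state5 = "5 lost to follow-up",
            state6 = "6 deceased")
  long <- do.call(rbind, lapply(names(labs), function(s) {
    data.frame(cycle = state_summary$cycle, state = labs[[s]],
               n = state_summary[[s]])
  }))
  long$state <- factor(long$state, levels = rev(unname(labs)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cycle, y = .data$n,
                                     fill = .data$state)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "Cycle", y = "Patients", fill = "State",
                  title = "Availability of PROs over time") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom",
                   legend.direction = "vertical")
}

#' Run manifest for a pipeline step
#'
#' Records configuration paths, seeds and an MD5 digest per output file so
#' a run can be audited and reproduced (fixed seeds give byte-identical
#' data files, hence identical digests).
#'
#' @param files character vector of output file paths.
#' @param seeds named list/vector of seeds used.
#' @param config_paths character vector of configuration files used.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(files, seeds = list(), config_paths = character()) {
  files <- files[file.exists(files)]
  list(
    config_paths = as.character(config_paths),
    seeds = seeds,
    files = lapply(files, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)),
           bytes = file.size(f))),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ) -> m
  class(m) <- "run_manifest"
  m
}

#' @rdname run_manifest
#' @param manifest a `run_manifest`.
#' @param path output JSON path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Simulate a trial and write its dataset files
#'
#' Thin pipeline wrapper around [simulate_trial()]: writes the observed and
#' complete long CSVs, the timeline CSV and a run manifest into `out_dir`.
#'
#' @param config a [sim_config()] or the path to its YAML file.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the `sim_trial` object and the file paths.
#' @export
run_simulation <- function(config, out_dir) {
  config_path <- character()
  if (is.character(config)) {
    config_path <- config
    config <- read_sim_config(config)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  trial <- simulate_trial(config)
  paths <- c(
    observed = file.path(out_dir, "qol_observed.csv"),
    complete = file.path(out_dir, "qol_complete_latent.csv"),
    timelines = file.path(out_dir, "timelines.csv"))
  write_qol_data(trial$observed, paths[["observed"]])
  write_qol_data(trial$complete, paths[["complete"]])
  write_timelines(trial$timelines, paths[["timelines"]])
  mf <- run_manifest(paths, seeds = list(simulation = config$seed),
                     config_paths = config_path)
  write_manifest(mf, file.path(out_dir, "manifest.json"))
  invisible(list(trial = trial, paths = paths,
                 manifest = file.path(out_dir, "manifest.json")))
}

#' Estimate a set of estimands and write series, figures and manifest
#'
#' Runs [estimate()] for each spec on a complete dataset. If the supplied
#' data are not complete on the required cycle grid, they are imputed first
#' with [impute_single()] (and this is logged in the returned object).
#'
#' @param data long QoL data (complete, or observed — see Details).
#' @param timelines timeline table.
#' @param specs a list of [estimand_spec()] objects (or one).
#' @param out_dir output directory.
#' @param impute_seed seed for imputation when it is needed.
#' @return Invisibly, a list with the `qol_estimates` objects, the file
#'   paths, and whether imputation was run.
#' @export
run_estimation <- function(data, timelines, specs, out_dir,
                           impute_seed = 1L) {
  if (inherits(specs, "estimand_spec")) specs <- list(specs)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  max_cycle <- max(vapply(specs, function(s) s$max_cycle, integer(1)))

  imputed <- FALSE
  ft <- build_feature_table(data, timelines, max_cycle)
  if (any(!ft$observed)) {
    message("input data are incomplete on the cycle grid; running ",
            "event-conditioned single imputation first")
    imp <- impute_single(data, timelines,
                         impute_spec(seed = impute_seed), max_cycle)
    data <- imp$data
    imputed <- TRUE
  }

  ests <- lapply(specs, function(s) estimate(data, timelines, s))
  paths <- vapply(seq_along(ests), function(i) {
    p <- file.path(out_dir, sprintf("series_%02d.csv", i))
    write_estimate_series(ests[[i]], p)
    p
  }, character(1))
  fig_path <- file.path(out_dir, "estimates.png")
  grDevices::png(fig_path, width = 1400, height = 900, res = 150)
  print(plot_estimate_series(ests))
  grDevices::dev.off()
  mf <- run_manifest(c(paths, fig_path),
                     seeds = list(impute = if (imputed) impute_seed))
  write_manifest(mf, file.path(out_dir, "manifest.json"))
  invisible(list(estimates = ests, paths = paths, figure = fig_path,
                 imputed = imputed))
}

#' Markdown summary report of a set of estimand results
#'
#' A human-readable report in which every number is traceable to a series
#' CSV: one section per estimand (labelled verbatim), a side-by-side
#' per-cycle estimate table, contributing n, and convergence diagnostics
#' for LMM-based estimators. Regenerating the report from the same inputs
#' gives identical output (no timestamps in the body).
#'
#' @param estimates_list list of `qol_estimates` objects (may be empty).
#' @param path output markdown file (optional).
#' @param cycles which cycles to tabulate (default every 4th plus the
#'   last).
#' @return The report as a character vector of lines; written to `path`
#'   when given.
#' @export
report_markdown <- function(estimates_list, path = NULL, cycles = NULL) {
  if (inherits(estimates_list, "qol_estimates"))
    estimates_list <- list(estimates_list)
  lines <- c("# Estimand report", "")
  if (!length(estimates_list)) {
    lines <- c(lines, "## No estimates",
               "", "No estimand series were supplied to this report.")
  } else {
    max_cycle <- max(vapply(estimates_list,
                            function(e) nrow(e$series), integer(1)))
    if (is.null(cycles))
      cycles <- sort(unique(c(seq(1, max_cycle, by = 4), max_cycle)))
    lines <- c(lines, "## Estimands", "")
    for (i in seq_along(estimates_list)) {
      e <- estimates_list[[i]]
      lines <- c(lines, sprintf("%d. %s", i, e$label))
      if (inherits(e$fit, "lmm_fit"))
        lines <- c(lines, sprintf(
          "   - LMM diagnostics: %d patients, residual SD %.2f%s",
          e$fit$n_patients, e$fit$sigma,
          if (e$fit$singular) ", variance component on boundary" else ""))
    }
    lines <- c(lines, "", "## Per-cycle estimates (mean [95% CI], n)", "",
               paste0("| cycle | ",
                      paste(sprintf("estimand %d", seq_along(estimates_list)),
                            collapse = " | "), " |"),
               paste0("|", paste(rep("---", length(estimates_list) + 1),
                                 collapse = "|"), "|"))
    for (t in cycles) {
      cells <- vapply(estimates_list, function(e) {
        r <- e$series[e$series$cycle == t, ]
        if (!nrow(r) || is.na(r$estimate)) return("--")
        if (is.na(r$se)) sprintf("%.1f (n=%d)", r$estimate, r$n)
        else sprintf("%.1f [%.1f, %.1f] (n=%d)", r$estimate, r$lcl, r$ucl, r$n)
      }, character(1))
      lines <- c(lines, paste0("| ", t, " | ",
                               paste(cells, collapse = " | "), " |"))
    }
    lines <- c(lines, "",
               "Composite series use the value printed in their label for",
               "cycles after death; while-alive series must be read jointly",
               "with the companion survival curves.")
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
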