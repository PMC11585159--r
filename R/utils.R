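#' Scheduled PRO assessment cycles
#'
#' The questionnaire is scheduled on the first day of every treatment cycle
#' up to `switch_after` cycles, and on alternate cycles thereafter. With the
#' default 3-week cycle and a switch after cycle 10 this reproduces the
#' common oncology design of tri-weekly assessment for 30 weeks followed by
#' six-weekly assessment.
#'
#' @param max_cycle last cycle of the schedule (integer >= 1).
#' @param switch_after last cycle of the every-cycle phase (default 10).
#' @return Integer vector of scheduled cycle numbers (1-based).
#' @examples
#' scheduled_cycles(14)  # 1..10, 12, 14
#' @export
scheduled_cycles <- function(max_cycle, switch_after = 10L) {
  stopifnot(max_cycle >= 1, switch_after >= 1)
  max_cycle <- as.integer(max_cycle)
  switch_after <- as.integer(switch_after)
  if (max_cycle <= switch_after) return(seq_len(max_cycle))
  c(seq_len(switch_after), seq.int(switch_after + 2L, max_cycle, by = 2L))
}

#' Elapsed weeks after a number of completed treatment cycles
#'
#' @param n_cycles number of completed cycles.
#' @param cycle_weeks length of one cycle in weeks (default 3).
#' @return Elapsed weeks (numeric).
#' @examples
#' elapsed_weeks(10)  # 30: the point at which assessment switches to
#'                    # alternate cycles
#' @export
elapsed_weeks <- function(n_cycles, cycle_weeks = 3) {
  stopifnot(n_cycles >= 0, cycle_weeks > 0)
  n_cycles * cycle_weeks
}

#' Smallest baseline score for which response is impossible
#'
#' A responder is a patient whose score increases from baseline by at least
#' `threshold` points. On a bounded scale the largest achievable increase
#' from baseline `b` is `scale_max - b`, so every integer baseline at or
#' above the returned value can never be classified as a responder (a
#' ceiling effect of responder definitions on bounded instruments).
#'
#' @param threshold minimum increase defining response (default 10 points).
#' @param scale_max upper bound of the score scale (default 100).
#' @return Smallest integer baseline score at which response is impossible.
#' @examples
#' responder_ceiling()  # 91 on the 0-100 scale with a 10-point definition
#' @export
responder_ceiling <- function(threshold = 10, scale_max = 100) {
  stopifnot(threshold > 0, scale_max > threshold)
  # impossible iff b + threshold > scale_max, i.e. b > scale_max - threshold
  as.integer(floor(scale_max - threshold)) + 1L
}

# clip a numeric vector to the score scale
clip_scale <- function(x, lo = 0, hi = 100) pmax(pmin(x, hi), lo)

# --- small discrete-distribution helpers -----------------------------------
# Distributions are plain lists so they round-trip through YAML:
#   list(name = "geometric", prob = p, offset = k)   -> k + rgeom(prob)
#   list(name = "uniform_int", min = a, max = b)
#   list(name = "fixed", value = v)

validate_dist <- function(dist, what) {
  if (!is.list(dist) || is.null(dist$name))
    stop(sprintf("'%s' must be a list with a 'name' field", what), call. = FALSE)
  switch(dist$name,
    geometric = {
      if (is.null(dist$prob) || dist$prob <= 0 || dist$prob > 1)
        stop(sprintf("'%s': geometric 'prob' must be in (0, 1]", what), call. = FALSE)
      if (is.null(dist$offset)) dist$offset <- 0L
    },
    uniform_int = {
      if (is.null(dist$min) || is.null(dist$max) || dist$min > dist$max)
        stop(sprintf("'%s': uniform_int needs min <= max", what), call. = FALSE)
    },
    fixed = {
      if (is.null(dist$value))
        stop(sprintf("'%s': fixed needs a 'value'", what), call. = FALSE)
    },
    stop(sprintf("'%s': unknown distribution '%s'", what, dist$name), call. = FALSE)
  )
  dist
}

draw_dist <- function(dist, n) {
  switch(dist$name,
    geometric   = (if (is.null(dist$offset)) 0L else dist$offset) +
                  stats::rgeom(n, dist$prob),
    uniform_int = sample(seq.int(dist$min, dist$max), n, replace = TRUE),
    fixed       = rep(dist$value, n)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
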