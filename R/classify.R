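# Habituation-scenario classification of effectiveness trends:
#   least habituation - effectiveness always high (or rising to high);
#   slow habituation  - high plateau at first, then a clear decline;
#   fast habituation  - decline from early on, or never reaching high
#                       effectiveness at all.
# Counter-productivity (terminal effectiveness below zero, i.e. the
# intervention increased damage) is an orthogonal flag, not a fourth
# scenario.

#' Classify a trend line into a habituation scenario
#'
#' Applies a rule cascade on the defined points of the trend, consulting
#' the fitted segmented model for decline detection when one is supplied:
#'
#' 1. **least**: every defined point is at or above `e_high`, *or* the
#'    trend is non-decreasing and ends at or above `e_high` (an
#'    intervention imperfect at first whose performance improves).
#' 2. **slow**: the first `h` defined points are all at or above `e_high`
#'    *and* a decline steeper than `s_min` per period occurs afterwards —
#'    a fitted segment beyond the first breakpoint with slope
#'    `<= -s_min` when the fit has breakpoints, otherwise a raw first
#'    difference `<= -s_min` beyond point `h`.
#' 3. **fast**: otherwise (decline begins within the first `h` points, or
#'    effectiveness never reaches `e_high`).
#'
#' The `counterproductive` flag is set independently whenever the terminal
#' (pooled, all-data) percent damage reduction is negative.
#'
#' @param trend A `trend_line` with at least 2 defined points.
#' @param fit Optional `segfit` computed on the same trend (typically from
#'   [select_segmented()]); when absent or with `k = 0`, decline detection
#'   falls back on raw first differences.
#' @param e_high "High effectiveness" threshold, in damage-reduction
#'   percent (default 80).
#' @param h Length of the initial window, in defined points (default 3).
#' @param s_min Minimum decline slope, damage-reduction percent per time
#'   unit (default 2).
#' @return An object of class `scenario_label`: list with `scenario`
#'   (`"least"`, `"slow"` or `"fast"`, `NA` if unclassifiable),
#'   `counterproductive`, `classifiable`, and a `rationale` record
#'   (`initial_effectiveness`, `first_decline_time`, `terminal_slope`) plus
#'   the thresholds used.
#' @examples
#' tr <- trend_line(1:6, c(100, 100, 100, 90, 75, 60))
#' classify_scenario(tr)$scenario  # "slow"
#' @export
classify_scenario <- function(trend, fit = NULL, e_high = 80, h = 3,
                              s_min = 2) {
  stopifnot(inherits(trend, "trend_line"))
  r <- trend$points$reduction_pct
  t <- trend$points$time
  n <- length(r)
  mk <- function(scenario, counter, classifiable, rationale) {
    structure(list(case_id = trend$case_id, scenario = scenario,
                   counterproductive = counter, classifiable = classifiable,
                   rationale = rationale,
                   thresholds = c(e_high = e_high, h = h, s_min = s_min)),
              class = "scenario_label")
  }
  if (n < 2L)
    return(mk(NA_character_, NA, FALSE,
              list(initial_effectiveness = if (n) r[1] else NA_real_,
                   first_decline_time = NA_real_,
                   terminal_slope = NA_real_)))
  counter <- r[n] < 0

  # decline evidence: fitted segments beyond the first breakpoint when the
  # selected model has one, raw first differences otherwise
  diffs <- diff(r) / diff(t)
  use_fit <- !is.null(fit) && inherits(fit, "segfit") && fit$k > 0
  if (use_fit) {
    sl <- segment_slopes(fit)
    post <- sl[-1]                       # slopes after each breakpoint
    decline_idx <- which(post <= -s_min)
    first_decline_time <- if (length(decline_idx))
      fit$psi[decline_idx[1], "psi"] else NA_real_
    terminal_slope <- unname(sl[length(sl)])
  } else {
    decline_idx <- which(diffs <= -s_min)
    first_decline_time <- if (length(decline_idx))
      t[decline_idx[1]] else NA_real_
    terminal_slope <- diffs[length(diffs)]
  }
  rationale <- list(initial_effectiveness = r[1],
                    first_decline_time = first_decline_time,
                    terminal_slope = terminal_slope)

  if (all(r >= e_high) || (all(diffs >= -1e-9) && r[n] >= e_high))
    return(mk("least", counter, TRUE, rationale))

  plateau <- n >= h && all(r[seq_len(h)] >= e_high)
  late_decline <- if (use_fit) length(decline_idx) > 0 else
    any(diffs[-seq_len(min(h - 1L, length(diffs)))] <= -s_min)
  if (plateau && late_decline)
    return(mk("slow", counter, TRUE, rationale))

  mk("fast", counter, TRUE, rationale)
}

#' @export
print.scenario_label <- function(x, ...) {
  if (!isTRUE(x$classifiable)) {
    cat(sprintf("Case '%s': unclassifiable (fewer than 2 defined points)\n",
                x$case_id))
    return(invisible(x))
  }
  cat(sprintf("Case '%s': %s habituation%s\n", x$case_id, x$scenario,
              if (isTRUE(x$counterproductive))
                " (counter-productive: terminal damage increase)" else ""))
  cat(sprintf("  initial effectiveness %.1f%%, first decline at %s, terminal slope %.2f %%/unit\n",
              x$rationale$initial_effectiveness,
              if (is.na(x$rationale$first_decline_time)) "none"
              else sprintf("%.2f", x$rationale$first_decline_time),
              x$rationale$terminal_slope))
  invisible(x)
}
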