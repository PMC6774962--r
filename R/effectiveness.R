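# Relative-risk effectiveness: % damage reduction = 100 * (1 - RR), with
# RR = (A/Nt) / (B/Nc). RR is undefined while the control has recorded no
# damage (B = 0); those points are excluded from trend lines.

#' Percent damage reduction from treatment/control counts
#'
#' Computes `100 * (1 - RR)` where `RR = (A/Nt) / (B/Nc)` is the relative
#' risk of damage under the intervention. 100 means complete protection
#' (`A = 0`); 0 means no effect (`RR = 1`); negative values mean the
#' intervention increased damage (`RR > 1`). When the control recorded no
#' damage (`B = 0`) the relative risk is undefined and `NA` is returned.
#'
#' @param A Treatment damage count(s), non-negative.
#' @param Nt Treatment exposure(s), positive.
#' @param B Control damage count(s), non-negative.
#' @param Nc Control exposure(s), positive.
#' @return Numeric vector of percent damage reduction, `NA` where `B = 0`.
#'   Always `<= 100`; unbounded below.
#' @examples
#' damage_reduction(A = 0, Nt = 100, B = 5, Nc = 100)  # 100: full protection
#' damage_reduction(A = 4, Nt = 100, B = 2, Nc = 100)  # -100: damage doubled
#' damage_reduction(A = 1, Nt = 50, B = 0, Nc = 50)    # NA: RR undefined
#' @export
damage_reduction <- function(A, Nt, B, Nc) {
  if (any(!is.finite(Nt)) || any(!is.finite(Nc)) || any(Nt <= 0) || any(Nc <= 0))
    stop("exposures Nt and Nc must be positive and finite", call. = FALSE)
  if (any(A < 0) || any(B < 0))
    stop("damage counts A and B must be non-negative", call. = FALSE)
  rr <- (A / Nt) / (B / Nc)
  ifelse(B == 0, NA_real_, 100 * (1 - rr))
}

# Reduce a case's intervals to (treatment numerator/weight, control
# numerator/weight) pairs so both input modes share one cumulative path:
# counts mode accumulates (A, Nt); percentages mode accumulates
# (rate/100, 1), i.e. unit-weighted running means of reported rates.
.case_increments <- function(case) {
  iv <- case$intervals
  if (case$mode == "counts") {
    list(at = iv$A, wt = iv$Nt, ac = iv$B, wc = iv$Nc)
  } else {
    list(at = iv$rate_treatment_pct / 100, wt = rep(1, nrow(iv)),
         ac = iv$rate_control_pct / 100, wc = rep(1, nrow(iv)))
  }
}

#' Incremental effectiveness trend line of a case
#'
#' Builds the effectiveness series by pooling all monitoring data from the
#' first period up to each successive period: point *k* uses cumulative
#' sums of damage counts and exposures over intervals `1..k`, incrementing
#' control and treatment simultaneously, and evaluates
#' [damage_reduction()] on the pooled totals. Points whose cumulative
#' control damage is zero are undefined and excluded from the trend.
#'
#' @param case A [case_study()].
#' @param exclusion How the undefined-relative-risk rule is applied:
#'   `"cumulative"` (default) keeps all intervals in the running sums and
#'   drops only points where the cumulative control damage is still zero;
#'   `"interval"` drops intervals with per-interval `B = 0` from the sums
#'   and the time grid altogether.
#' @return An object of class `trend_line`: list with `case_id`,
#'   `time_unit`, `n_defined`, `points` (data frame of defined points with
#'   columns `time, cum_A, cum_Nt, cum_B, cum_Nc, rr, reduction_pct`) and
#'   `full` (same grid including undefined points, `rr`/`reduction_pct`
#'   `NA` there).
#' @details Because the series is cumulative, its final point equals the
#'   pooled whole-study effectiveness estimate. In percentages mode the
#'   `cum_*` columns hold unit-weighted rate sums (see the package
#'   vignette).
#' @examples
#' cs <- case_study("demo",
#'   data.frame(period_index = 1:2, A = c(0, 1), Nt = 1, B = c(2, 1), Nc = 1),
#'   design = "before_after", time_unit = "year")
#' incremental_trend(cs)$points$reduction_pct  # 100, 66.67
#' @export
incremental_trend <- function(case, exclusion = c("cumulative", "interval")) {
  exclusion <- match.arg(exclusion)
  validate_case(case)
  inc <- .case_increments(case)
  time <- case$intervals$period_index
  if (exclusion == "interval") {
    keep <- if (case$mode == "counts") case$intervals$B > 0 else inc$ac > 0
    inc <- lapply(inc, `[`, keep)
    time <- time[keep]
  }
  cum_at <- cumsum(inc$at); cum_wt <- cumsum(inc$wt)
  cum_ac <- cumsum(inc$ac); cum_wc <- cumsum(inc$wc)
  rate_t <- cum_at / cum_wt
  rate_c <- cum_ac / cum_wc
  rr <- ifelse(cum_ac == 0, NA_real_, rate_t / rate_c)
  reduction <- 100 * (1 - rr)
  full <- data.frame(time = time, cum_A = cum_at, cum_Nt = cum_wt,
                     cum_B = cum_ac, cum_Nc = cum_wc,
                     rr = rr, reduction_pct = reduction)
  pts <- full[!is.na(full$rr), , drop = FALSE]
  rownames(pts) <- NULL
  structure(
    list(case_id = case$case_id, time_unit = case$time_unit,
         exclusion = exclusion, points = pts, full = full,
         n_defined = nrow(pts)),
    class = "trend_line")
}

#' Assemble a trend line from raw time/effectiveness values
#'
#' Lower-level constructor used when effectiveness values come from a
#' source other than [incremental_trend()] (e.g. a noise-free expected
#' trend). Undefined (`NA`) values are dropped.
#'
#' @param time Numeric times (in `time_unit`s), strictly increasing.
#' @param reduction_pct Percent damage reduction at each time.
#' @param case_id,time_unit Metadata carried along.
#' @return A `trend_line` object (without cumulative count columns).
#' @export
trend_line <- function(time, reduction_pct, case_id = "trend",
                       time_unit = "month") {
  ok <- !is.na(reduction_pct)
  time <- time[ok]; reduction_pct <- reduction_pct[ok]
  if (is.unsorted(time, strictly = TRUE))
    stop("time must be strictly increasing", call. = FALSE)
  pts <- data.frame(time = time, cum_A = NA_real_, cum_Nt = NA_real_,
                    cum_B = NA_real_, cum_Nc = NA_real_, rr = NA_real_,
                    reduction_pct = reduction_pct)
  structure(list(case_id = case_id, time_unit = time_unit,
                 exclusion = "cumulative", points = pts, full = pts,
                 n_defined = nrow(pts)),
            class = "trend_line")
}

#' @export
print.trend_line <- function(x, ...) {
  cat(sprintf("Effectiveness trend for case '%s' (%d defined points, %ss)\n",
              x$case_id, x$n_defined, x$time_unit))
  if (x$n_defined > 0) {
    rng <- range(x$points$reduction_pct)
    cat(sprintf("  damage reduction %% in [%.1f, %.1f], final %.1f at %s %g\n",
                rng[1], rng[2],
                x$points$reduction_pct[x$n_defined], x$time_unit,
                x$points$time[x$n_defined]))
  }
  invisible(x)
}

#' @export
as.data.frame.trend_line <- function(x, ..., full_grid = FALSE) {
  df <- if (full_grid) x$full else x$points
  cbind(case_id = x$case_id, df, time_unit = x$time_unit,
        stringsAsFactors = FALSE)
}

#' Plot an effectiveness trend line
#'
#' @param x A `trend_line`.
#' @param fit Optional [fit_segmented()] result drawn over the points, with
#'   breakpoint markers.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.trend_line <- function(x, fit = NULL, ...) {
  p <- x$points
  graphics::plot(p$time, p$reduction_pct, type = "b", pch = 15,
                 xlab = sprintf("time (%ss)", x$time_unit),
                 ylab = "damage reduction (%)",
                 main = sprintf("case %s", x$case_id), ...)
  graphics::abline(h = 0, lty = 3, col = "grey50")
  if (!is.null(fit)) {
    tt <- seq(min(p$time), max(p$time), length.out = 200)
    graphics::lines(tt, predict(fit, tt), col = "firebrick", lwd = 2)
    if (fit$k > 0)
      graphics::abline(v = fit$psi[, "psi"], lty = 2, col = "firebrick")
  }
  invisible(x)
}
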