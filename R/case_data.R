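# Case tables: one monitored intervention case = metadata + an ordered series
# of monitoring intervals with treatment (A, Nt) and control (B, Nc) damage
# counts and exposures. CSV interchange is long format, one row per interval.

.case_csv_columns <- c(
  "case_id", "source_ref", "intervention", "predators", "asset",
  "design", "time_unit", "period_index", "A", "Nt", "B", "Nc",
  "rate_treatment_pct", "rate_control_pct"
)

#' Construct a monitored case study
#'
#' A case study is the unit of analysis: one intervention protecting one
#' asset from one or more predator species, monitored over consecutive
#' periods. Each interval carries the damage count with the intervention
#' (`A`) out of exposure `Nt`, and the control damage count (`B`) out of
#' exposure `Nc`. For before-after designs the control is the same sample
#' before the intervention, so `Nt = Nc` is required on every interval.
#'
#' @param case_id Short unique identifier.
#' @param intervals Data frame with column `period_index` (1-based,
#'   consecutive integers) and, in `"counts"` mode, columns `A`, `Nt`, `B`,
#'   `Nc`; in `"percentages"` mode, columns `rate_treatment_pct` and
#'   `rate_control_pct` (pre-computed `100*A/Nt` and `100*B/Nc` as reported
#'   by a study's authors, exposures unknown).
#' @param design `"control_treatment"` (separate control sample) or
#'   `"before_after"` (same sample before the intervention).
#' @param time_unit `"month"` or `"year"`; the unit of `period_index`.
#' @param mode `"counts"` or `"percentages"`; how damage rates are supplied.
#' @param source_ref,intervention,asset Free-text metadata.
#' @param predators Character vector of predator species names (labels only).
#' @return An object of class `case_study`.
#' @examples
#' cs <- case_study("demo",
#'   data.frame(period_index = 1:3, A = c(0, 1, 2), Nt = 100,
#'              B = c(4, 5, 3), Nc = 100),
#'   design = "control_treatment", time_unit = "month")
#' cs
#' @export
case_study <- function(case_id, intervals,
                       design = c("control_treatment", "before_after"),
                       time_unit = c("month", "year"),
                       mode = c("counts", "percentages"),
                       source_ref = "", intervention = "",
                       predators = character(), asset = "") {
  design <- match.arg(design)
  time_unit <- match.arg(time_unit)
  mode <- match.arg(mode)
  stopifnot(is.character(case_id), length(case_id) == 1L, nzchar(case_id))
  intervals <- as.data.frame(intervals)
  x <- structure(
    list(case_id = case_id, source_ref = source_ref,
         intervention = intervention, predators = as.character(predators),
         asset = asset, design = design, time_unit = time_unit,
         mode = mode, intervals = intervals),
    class = "case_study"
  )
  validate_case(x)
  x
}

#' Validate a case study against its invariants
#'
#' Checks that the interval table is non-empty with at least two periods,
#' that `period_index` is consecutive from 1, that counts are non-negative
#' integers with positive exposures (counts mode) or rates within their
#' domains (percentages mode), and that before-after cases have `Nt = Nc`.
#'
#' @param x A `case_study`.
#' @param rows Optional vector of source row numbers (same length as the
#'   interval table) used to report violations by input row.
#' @return `x`, invisibly. Errors describe the violated invariant and name
#'   the case.
#' @export
validate_case <- function(x, rows = NULL) {
  iv <- x$intervals
  id <- x$case_id
  if (is.null(rows)) rows <- seq_len(nrow(iv))
  fail <- function(msg, bad = NULL) {
    where <- if (length(bad)) paste0(" (rows ", paste(rows[bad], collapse = ", "), ")") else ""
    stop(sprintf("case '%s': %s%s", id, msg, where), call. = FALSE)
  }
  if (nrow(iv) < 2L)
    fail("needs at least two monitoring intervals")
  pidx <- iv$period_index
  if (is.null(pidx) || anyNA(pidx))
    fail("period_index missing")
  if (!isTRUE(all(pidx == seq_along(pidx))))
    fail("period_index must be consecutive integers starting at 1")
  if (x$mode == "counts") {
    need <- c("A", "Nt", "B", "Nc")
    miss <- setdiff(need, names(iv))
    if (length(miss))
      fail(paste("missing columns:", paste(miss, collapse = ", ")))
    num <- vapply(iv[need], function(v) all(is.finite(v)), logical(1))
    if (!all(num)) fail("non-finite values in A/Nt/B/Nc")
    bad <- which(iv$A < 0 | iv$B < 0)
    if (length(bad)) fail("negative damage counts", bad)
    bad <- which(iv$A != round(iv$A) | iv$B != round(iv$B))
    if (length(bad)) fail("damage counts A, B must be integers", bad)
    bad <- which(iv$Nt <= 0 | iv$Nc <= 0)
    if (length(bad)) fail("exposures Nt, Nc must be positive", bad)
    if (x$design == "before_after") {
      bad <- which(iv$Nt != iv$Nc)
      if (length(bad)) fail("before_after design requires Nt = Nc", bad)
    }
  } else {
    need <- c("rate_treatment_pct", "rate_control_pct")
    miss <- setdiff(need, names(iv))
    if (length(miss))
      fail(paste("missing columns:", paste(miss, collapse = ", ")))
    bad <- which(!is.finite(iv$rate_treatment_pct) | iv$rate_treatment_pct < 0)
    if (length(bad)) fail("treatment rate must be a non-negative percentage", bad)
    bad <- which(!is.finite(iv$rate_control_pct) |
                   iv$rate_control_pct < 0 | iv$rate_control_pct > 100)
    if (length(bad)) fail("control rate must be a percentage in [0, 100]", bad)
  }
  invisible(x)
}

#' @export
print.case_study <- function(x, ...) {
  cat(sprintf("Case '%s': %s vs %s (%s design, %ss)\n",
              x$case_id,
              if (nzchar(x$intervention)) x$intervention else "intervention",
              if (length(x$predators)) paste(x$predators, collapse = "; ") else "predators",
              x$design, x$time_unit))
  cat(sprintf("  %d monitoring intervals, %s mode\n", nrow(x$intervals), x$mode))
  invisible(x)
}

#' Read case studies from a long-format CSV
#'
#' The CSV has one row per (case, monitoring interval) with columns
#' `case_id, source_ref, intervention, predators, asset, design, time_unit,
#' period_index, A, Nt, B, Nc, rate_treatment_pct, rate_control_pct`.
#' Rows are grouped by `case_id` and sorted by `period_index`; every case is
#' validated and violations are reported with the offending input rows.
#' Species in `predators` are semicolon-delimited within one cell.
#'
#' @param path CSV file path.
#' @param mode `"counts"` (default) uses `A, Nt, B, Nc`; `"percentages"`
#'   uses the pre-computed rate columns with exposures left blank.
#' @return A named list of [case_study()] objects, in first-appearance order.
#' @seealso [write_cases()] for the inverse operation.
#' @export
read_cases <- function(path, mode = c("counts", "percentages")) {
  mode <- match.arg(mode)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.case_csv_columns, names(df))
  if (length(miss))
    stop("case CSV is missing required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0L) return(structure(list(), names = character()))
  ids <- unique(df$case_id)
  cases <- lapply(ids, function(id) {
    sel <- which(df$case_id == id)
    sub <- df[sel, , drop = FALSE]
    ord <- order(sub$period_index)
    sub <- sub[ord, , drop = FALSE]
    rows <- sel[ord] + 1L  # +1: CSV header line
    meta <- sub[1L, ]
    cs <- structure(
      list(case_id = id,
           source_ref = as.character(meta$source_ref),
           intervention = as.character(meta$intervention),
           predators = strsplit(as.character(meta$predators), ";", fixed = TRUE)[[1]],
           asset = as.character(meta$asset),
           design = as.character(meta$design),
           time_unit = as.character(meta$time_unit),
           mode = mode,
           intervals = sub[, c("period_index", "A", "Nt", "B", "Nc",
                               "rate_treatment_pct", "rate_control_pct")]),
      class = "case_study")
    rownames(cs$intervals) <- NULL
    if (!cs$design %in% c("control_treatment", "before_after"))
      stop(sprintf("case '%s': unknown design '%s'", id, cs$design), call. = FALSE)
    if (!cs$time_unit %in% c("month", "year"))
      stop(sprintf("case '%s': unknown time_unit '%s'", id, cs$time_unit), call. = FALSE)
    validate_case(cs, rows = rows)
    cs
  })
  names(cases) <- ids
  cases
}

#' Write case studies to the long-format CSV
#'
#' Inverse of [read_cases()]: `read_cases(write_cases(x, f), mode)` recovers
#' the same cases with exact field equality. An empty list produces a
#' header-only file.
#'
#' @param cases List of `case_study` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cases <- function(cases, path) {
  rows <- lapply(cases, function(cs) {
    validate_case(cs)
    iv <- cs$intervals
    n <- nrow(iv)
    get <- function(col) if (col %in% names(iv)) iv[[col]] else rep(NA_real_, n)
    data.frame(
      case_id = rep(cs$case_id, n),
      source_ref = rep(cs$source_ref, n),
      intervention = rep(cs$intervention, n),
      predators = rep(paste(cs$predators, collapse = ";"), n),
      asset = rep(cs$asset, n),
      design = rep(cs$design, n),
      time_unit = rep(cs$time_unit, n),
      period_index = iv$period_index,
      A = get("A"), Nt = get("Nt"), B = get("B"), Nc = get("Nc"),
      rate_treatment_pct = get("rate_treatment_pct"),
      rate_control_pct = get("rate_control_pct"),
      stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(.case_csv_columns))),
                    .case_csv_columns)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
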