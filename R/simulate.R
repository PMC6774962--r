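# Synthetic monitoring cases with known ground truth. Control damage counts
# follow a constant per-period risk p0; treatment counts follow
# p0 * (1 - e(t)) where e(t) is a time-varying intervention efficacy curve
# realizing one of the habituation scenarios (plus a counter-productive
# variant with negative efficacy). Counts are binomial over the per-period
# exposures, the minimal generative model consistent with the relative-risk
# definition over Nt and Nc.

#' Configuration of a synthetic monitoring case
#'
#' @param scenario `"least"` (constant efficacy), `"slow"` (plateau of
#'   length `tau`, then linear decline at `decline_rate` per period),
#'   `"fast"` (exponential decay with timescale `tau`), or
#'   `"counterproductive"` (negative efficacy growing linearly to
#'   `-|e_max|` by the last period).
#' @param n_periods Number of monitoring periods (default 24).
#' @param Nt,Nc Treatment and control exposures per period (default 100
#'   each).
#' @param p0 Per-period control damage probability, in (0, 1). Default
#'   0.25: a heavily depredated herd, so that control damage accrues from
#'   the first periods and the relative risk is defined early.
#' @param e_max Peak efficacy in `[-1, 1]` (default 0.95: a strongly
#'   effective intervention).
#' @param tau Scenario timescale in periods: plateau length for `"slow"`
#'   (default 12), exponential decay constant for `"fast"` (default 3).
#' @param decline_rate Efficacy lost per period after the plateau in the
#'   `"slow"` scenario (default 0.08).
#' @param floor Lower bound for the declining `"slow"` efficacy curve
#'   (default -1, the smallest valid efficacy).
#' @param seed Integer seed; identical configurations with identical seeds
#'   yield identical cases.
#' @param case_id Optional identifier (default derived from scenario and
#'   seed).
#' @param time_unit Label for the monitoring period (default `"month"`).
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("least", "slow", "fast",
                                         "counterproductive"),
                            n_periods = 24L, Nt = 100, Nc = 100, p0 = 0.25,
                            e_max = 0.95,
                            tau = if (match.arg(scenario) == "fast") 3 else 12,
                            decline_rate = 0.08, floor = -1, seed = 1L,
                            case_id = NULL, time_unit = "month") {
  scenario <- match.arg(scenario)
  stopifnot(n_periods >= 2, Nt > 0, Nc > 0, p0 > 0, p0 < 1,
            e_max >= -1, e_max <= 1, tau > 0, decline_rate >= 0,
            floor >= -1)
  if (is.null(case_id))
    case_id <- sprintf("%s_seed%d", scenario, as.integer(seed))
  structure(list(scenario = scenario, n_periods = as.integer(n_periods),
                 Nt = Nt, Nc = Nc, p0 = p0, e_max = e_max, tau = tau,
                 decline_rate = decline_rate, floor = floor,
                 seed = as.integer(seed), case_id = case_id,
                 time_unit = time_unit),
            class = "scenario_config")
}

#' Intervention efficacy curve of a scenario
#'
#' The proportional reduction in damage risk at period `t`:
#' treatment risk is `p0 * (1 - e(t))` (clipped to `[0, 1]`).
#' * least: `e(t) = e_max`, constant.
#' * slow: `e_max` for `t <= tau`, then `e_max - decline_rate * (t - tau)`
#'   floored at `floor`.
#' * fast: `e_max * exp(-t / tau)`.
#' * counterproductive: `-|e_max| * t / n_periods` (damage amplification
#'   growing over time).
#'
#' @param config A [scenario_config()].
#' @param t Period(s), in `1..n_periods`.
#' @return Efficacy value(s) in `[-1, 1]`.
#' @examples
#' cfg <- scenario_config("slow", e_max = 1, tau = 12, decline_rate = 0.1)
#' efficacy_curve(cfg, c(12, 17))  # 1.0, 0.5
#' @export
efficacy_curve <- function(config, t) {
  stopifnot(inherits(config, "scenario_config"))
  if (any(t < 1 | t > config$n_periods))
    stop("t must lie within 1..n_periods", call. = FALSE)
  with(config, switch(scenario,
    least = rep(e_max, length(t)),
    slow = pmax(ifelse(t <= tau, e_max, e_max - decline_rate * (t - tau)),
                floor),
    fast = e_max * exp(-t / tau),
    counterproductive = -abs(e_max) * t / n_periods,
    stop("unknown scenario", call. = FALSE)))
}

# expected per-period counts (non-integer): the noise-free limit
.expected_counts <- function(config) {
  t <- seq_len(config$n_periods)
  e <- efficacy_curve(config, t)
  p_treat <- pmin(pmax(config$p0 * (1 - e), 0), 1)
  list(t = t, A = config$Nt * p_treat, B = rep(config$Nc * config$p0,
                                               config$n_periods))
}

#' Simulate one synthetic monitoring case
#'
#' For each period `t`, draws the control count
#' `B_t ~ Binomial(Nc, p0)` and the treatment count
#' `A_t ~ Binomial(Nt, p0 * (1 - e(t)))` (success probability clipped to
#' `[0, 1]`). The global RNG state is left untouched.
#'
#' @param config A [scenario_config()].
#' @return List with `case` (a [case_study()]) and `truth` (one-row data
#'   frame: scenario, generator parameters, seed, and the true per-period
#'   efficacy curve as attribute `"efficacy"`).
#' @export
simulate_case <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  t <- seq_len(config$n_periods)
  e <- efficacy_curve(config, t)
  p_treat <- pmin(pmax(config$p0 * (1 - e), 0), 1)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(config$seed)
  B <- stats::rbinom(config$n_periods, size = round(config$Nc), prob = config$p0)
  A <- stats::rbinom(config$n_periods, size = round(config$Nt), prob = p_treat)
  case <- case_study(
    config$case_id,
    data.frame(period_index = t, A = A, Nt = config$Nt, B = B,
               Nc = config$Nc),
    design = "control_treatment", time_unit = config$time_unit,
    intervention = "synthetic intervention",
    predators = "synthetic predator", asset = "livestock",
    source_ref = "synthetic")
  truth <- data.frame(case_id = config$case_id, scenario = config$scenario,
                      e_max = config$e_max, tau = config$tau,
                      decline_rate = config$decline_rate, p0 = config$p0,
                      Nt = config$Nt, Nc = config$Nc,
                      n_periods = config$n_periods, seed = config$seed)
  attr(truth, "efficacy") <- e
  list(case = case, truth = truth)
}

#' Noise-free expected effectiveness trend of a scenario
#'
#' Applies the incremental (cumulative) effectiveness computation to the
#' *expected* per-period counts `Nt * p0 * (1 - e(t))` and `Nc * p0`. This
#' is the large-exposure limit of the simulated trends and the reference
#' against which breakpoint recovery is judged: cumulative pooling shifts
#' the apparent breakpoint relative to the kink of the efficacy curve, so
#' the recoverable target lives on this trend, not at `tau` itself.
#'
#' @param config A [scenario_config()].
#' @return A `trend_line` built from the expected counts.
#' @export
expected_trend <- function(config) {
  ec <- .expected_counts(config)
  cumB <- cumsum(ec$B)
  red <- ifelse(cumB == 0, NA_real_,
                100 * (1 - (cumsum(ec$A) / (config$Nt * ec$t)) /
                         (cumB / (config$Nc * ec$t))))
  trend_line(ec$t, red, case_id = paste0(config$case_id, "_expected"),
             time_unit = config$time_unit)
}

#' Ground-truth breakpoint of a scenario's noise-free trend
#'
#' The breakpoint of the one-breakpoint segmented fit to
#' [expected_trend()]. A single dominant threshold is used (rather than an
#' AIC-selected multi-breakpoint fit) because the noise-free cumulative
#' trend is smooth, so AIC on it degenerates toward the largest model; the
#' one-breakpoint fit summarizes the single plateau-to-decline transition
#' the generator encodes. Returns `NA` when no one-breakpoint fit is
#' feasible (e.g. a constant trend).
#'
#' @param config A [scenario_config()].
#' @param min_seg_points Passed to the fitter.
#' @return The breakpoint time, or `NA`.
#' @export
psi_true_of_trend <- function(config, min_seg_points = 3L) {
  tr <- expected_trend(config)
  if (tr$n_defined < 2 * min_seg_points) return(NA_real_)
  y <- tr$points$reduction_pct
  if (stats::var(y) < 1e-12) return(NA_real_)
  # an exactly linear trend (e.g. steadily growing damage amplification)
  # has no breakpoint: the one-breakpoint fit would be degenerate
  line <- stats::lm.fit(cbind(1, tr$points$time), y)
  if (sum(line$residuals^2) <= 1e-12 * sum((y - mean(y))^2))
    return(NA_real_)
  f <- tryCatch(
    suppressWarnings(grid_segmented(tr, k = 1L,
                                    min_seg_points = min_seg_points)),
    error = function(e) NULL)
  if (is.null(f)) NA_real_ else unname(f$psi[1, "psi"])
}

#' Simulate a suite of synthetic cases across all scenarios
#'
#' Generates `n_cases_per_scenario` cases for each of the four scenario
#' variants (least, slow, fast, counterproductive) under deterministic
#' derived seeds `base_seed + index`, optionally writing the case CSV and
#' a ground-truth CSV.
#'
#' @param n_cases_per_scenario Number of cases per scenario, `>= 1`.
#' @param base_seed Base integer seed.
#' @param dir Optional output directory; when given, writes `cases.csv`
#'   and `truth.csv` there.
#' @param ... Overrides passed to [scenario_config()] (e.g. `n_periods`).
#' @return List with `cases` (list of `case_study`) and `truth` (data
#'   frame, one row per case, including `psi_true_of_trend`).
#' @export
simulate_suite <- function(n_cases_per_scenario, base_seed = 1L, dir = NULL,
                           ...) {
  if (n_cases_per_scenario < 1)
    stop("n_cases_per_scenario must be at least 1", call. = FALSE)
  scenarios <- c("least", "slow", "fast", "counterproductive")
  cases <- list(); truth <- list()
  idx <- 0L
  for (sc in scenarios) {
    psi_t <- NULL
    for (i in seq_len(n_cases_per_scenario)) {
      idx <- idx + 1L
      cfg <- scenario_config(sc, seed = base_seed + idx,
                             case_id = sprintf("%s_%03d", sc, i), ...)
      if (is.null(psi_t)) psi_t <- psi_true_of_trend(cfg)  # seed-free
      sim <- simulate_case(cfg)
      sim$truth$psi_true_of_trend <- psi_t
      cases[[cfg$case_id]] <- sim$case
      truth[[cfg$case_id]] <- sim$truth
    }
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_cases(cases, file.path(dir, "cases.csv"))
    utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  }
  list(cases = cases, truth = truth)
}
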