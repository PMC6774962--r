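# Shared fixture builders; everything is generated in code.

# minimal valid counts-mode case
make_case <- function(A, B, Nt = 100, Nc = 100,
                      design = "control_treatment", id = "c1",
                      time_unit = "month") {
  n <- length(A)
  case_study(id,
             data.frame(period_index = seq_len(n), A = A,
                        Nt = rep_len(Nt, n), B = B, Nc = rep_len(Nc, n)),
             design = design, time_unit = time_unit,
             intervention = "test intervention",
             predators = c("coyote", "red fox"), asset = "sheep",
             source_ref = "fixture")
}

# random valid counts-mode case (for property tests)
random_case <- function(id, n = NULL) {
  n <- if (is.null(n)) sample(2:12, 1) else n
  make_case(A = rpois(n, 3), B = rpois(n, 4),
            Nt = sample(20:200, 1), Nc = sample(20:200, 1), id = id)
}

# brute-force incremental-effectiveness oracle: recompute every point from
# the raw intervals by explicit summation, independently of the package's
# cumulative implementation
oracle_trend <- function(case) {
  iv <- case$intervals
  out <- data.frame(time = numeric(0), reduction_pct = numeric(0))
  for (kk in seq_len(nrow(iv))) {
    sA <- 0; sB <- 0; sNt <- 0; sNc <- 0
    for (i in seq_len(kk)) {
      sA <- sA + iv$A[i]; sB <- sB + iv$B[i]
      sNt <- sNt + iv$Nt[i]; sNc <- sNc + iv$Nc[i]
    }
    if (sB > 0) {
      rr <- (sA / sNt) / (sB / sNc)
      out <- rbind(out, data.frame(time = iv$period_index[kk],
                                   reduction_pct = 100 * (1 - rr)))
    }
  }
  out
}

# exact two-segment data with a kink at psi0
piecewise_y <- function(t, psi0 = 5, y0 = 100, slope2 = -10) {
  ifelse(t <= psi0, y0, y0 + slope2 * (t - psi0))
}

# seeded piecewise-linear instance with identifiable segments, as used for
# the oracle-equivalence suite
seg_instance <- function() {
  n <- sample(15:30, 1)
  k <- sample(1:2, 1)
  repeat {
    psi <- sort(sample(seq(4, n - 3), k))
    if (k == 1 || diff(psi) >= 5) break
  }
  t <- 1:n
  slopes <- sample(c(-10, -8, -6, 6, 8, 10), k)
  y <- 90 + rowSums(vapply(seq_len(k), function(j)
    slopes[j] * pmax(t - psi[j], 0), numeric(n))) + rnorm(n, 0, 2)
  list(t = t, y = y, k = k, psi = psi)
}
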