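# Independent brute-force oracles, written from the definitions and kept
# structurally different from the package implementations.

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- 0
  vx <- 0
  vy <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    vx <- vx + (x[i] - mx)^2
    vy <- vy + (y[i] - my)^2
  }
  num / sqrt(vx * vy)
}

oracle_error_metrics <- function(pred, ref) {
  e <- numeric(length(pred))
  for (i in seq_along(pred)) e[i] <- pred[i] - ref[i]
  me <- sum(e) / length(e)
  sde <- sqrt(sum((e - me)^2) / (length(e) - 1))
  list(me = me, sde = sde, mad = sum(abs(e)) / length(e))
}

oracle_cumulative_pct <- function(errors, thresholds) {
  out <- numeric(length(thresholds))
  for (j in seq_along(thresholds)) {
    cnt <- 0
    for (e in errors) if (abs(e) <= thresholds[j]) cnt <- cnt + 1
    out[j] <- 100 * cnt / length(errors)
  }
  out
}

oracle_smooth <- function(times, x, window_s = 20) {
  vapply(seq_along(x), function(i)
    mean(x[abs(times - times[i]) <= window_s / 2]), numeric(1))
}

# Rule-by-rule re-implementation of the six plausibility conditions,
# evaluated beat by beat with an explicit reference-beat search.
oracle_conditions <- function(beats, bounds = condition_bounds()) {
  feats <- c("pat_abp", paste0("pat_ppg_", 1:4), paste0("ptt_", 1:4))
  valid <- if (is.null(beats$valid)) rep(TRUE, nrow(beats)) else beats$valid
  reason <- if (is.null(beats$reject_reason)) rep("", nrow(beats))
    else beats$reject_reason
  for (i in seq_len(nrow(beats))) {
    if (!valid[i]) next
    ref <- NA
    for (j in seq_len(i - 1L)) {
      if (valid[j] && beats$r_time[j] <= beats$r_time[i] - bounds$lookback_s)
        ref <- j
    }
    checks <- list(
      cond1 = beats$sbp[i] > bounds$sbp[1] && beats$sbp[i] < bounds$sbp[2],
      cond2 = beats$dbp[i] > bounds$dbp[1] && beats$dbp[i] < bounds$dbp[2],
      cond3 = beats$pp[i] > bounds$pp_min,
      cond4 = is.na(ref) ||
        (abs(beats$sbp[i] - beats$sbp[ref]) < bounds$bp_jump &&
           abs(beats$dbp[i] - beats$dbp[ref]) < bounds$bp_jump),
      cond5 = beats$pat_abp[i] > bounds$pat_abp[1] &&
        beats$pat_abp[i] < bounds$pat_abp[2],
      cond6 = is.na(ref) || all(vapply(feats, function(f)
        abs(beats[[f]][i] - beats[[f]][ref]) < bounds$feat_jump, logical(1)))
    )
    bad <- names(checks)[!vapply(checks, isTRUE, logical(1))]
    if (length(bad)) {
      valid[i] <- FALSE
      reason[i] <- bad[1]
    }
  }
  data.frame(valid = valid, reject_reason = reason)
}
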