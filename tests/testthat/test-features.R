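fs <- 100

test_that("BP extraction reads the cycle at its fiducials", {
  # full-period sinusoid: min 60, max 120, mean exactly 90
  n <- 80
  cycle <- 90 + 30 * sin(2 * pi * (0:(n - 1)) / n)
  fid <- list(present = TRUE, valley_idx = which.min(cycle),
              peak_idx = which.max(cycle))
  bp <- extract_bp(cycle, fid)
  expect_equal(bp$sbp, 120)
  expect_equal(bp$dbp, 60)
  expect_equal(bp$pp, 60)
  expect_equal(bp$mbp, 90, tolerance = 1e-12)

  flat <- rep(80, n)
  bp2 <- extract_bp(flat, list(present = TRUE, valley_idx = 10,
                               peak_idx = 30))
  expect_equal(bp2$pp, 0)
  expect_error(extract_bp(cycle, list(present = FALSE, reason = "x")),
               "absent")
})

test_that("temporal features are plain fiducial arithmetic", {
  pf <- list(present = TRUE, ppg_valley = 0.25, ppg_peak = 0.43,
             ppg_maxderiv = 0.38, ppg_it = 0.30)
  tf <- extract_temporal(0.15, pf)
  expect_equal(tf$pat_abp, 150)
  expect_equal(tf$pat_ppg, c(250, 430, 380, 300))
  expect_equal(tf$ptt, c(100, 280, 230, 150))
  expect_identical(tf$ptt, tf$pat_ppg - tf$pat_abp)
})

test_that("each plausibility condition fails at its boundary and passes just inside", {
  # probe at t = 5 s (a reference beat exists) or t = 3 s (jump conditions
  # vacuous, for pass-side probes whose BP differs a lot from baseline)
  probe <- function(overrides, t = 5) {
    d <- beat_table(baseline_beat(0), baseline_beat(t, overrides = overrides))
    out <- apply_conditions(d)
    list(valid = out$valid[2], reason = out$reject_reason[2])
  }
  cases <- list(
    list(list(sbp = 250), 5, FALSE, "cond1"),
    list(list(sbp = 249.9, dbp = 220), 5, FALSE, "cond2"), # sbp passes cond1
    list(list(sbp = 50, dbp = 40), 5, FALSE, "cond1"),
    list(list(sbp = 50.1, dbp = 40), 3, TRUE, ""),
    list(list(dbp = 160, sbp = 210), 5, FALSE, "cond2"),
    list(list(dbp = 30, sbp = 80), 5, FALSE, "cond2"),
    list(list(dbp = 30.1, sbp = 80), 3, TRUE, ""),
    list(list(sbp = 80, dbp = 70), 5, FALSE, "cond3"),     # pp exactly 10
    list(list(sbp = 80.1, dbp = 70), 5, TRUE, ""),         # pp 10.1
    list(list(sbp = 120), 5, FALSE, "cond4"),              # +30 jump
    list(list(sbp = 119.9), 5, TRUE, ""),                  # +29.9 jump
    list(list(dbp = 40, sbp = 80), 5, FALSE, "cond4"),     # -30 DBP jump
    list(list(pat_abp = 70), 5, FALSE, "cond5"),
    list(list(pat_abp = 70.1), 5, TRUE, ""),
    list(list(pat_abp = 250), 5, FALSE, "cond5"),
    list(list(pat_abp = 249.9), 5, TRUE, ""),
    list(list(ptt_3 = 380 - 150 + 300), 5, FALSE, "cond6"), # +300 ms jump
    list(list(ptt_3 = 380 - 150 + 299.9), 5, TRUE, "")
  )
  for (cs in cases) {
    got <- probe(cs[[1]], cs[[2]])
    lbl <- paste(names(cs[[1]]), unlist(cs[[1]]), collapse = " ")
    expect_identical(got$valid, cs[[3]], label = lbl)
    expect_identical(got$reason, cs[[4]], label = lbl)
  }
})

test_that("jump conditions are vacuous without a 5 s reference", {
  d <- beat_table(baseline_beat(0, sbp = 200))
  out <- apply_conditions(d)
  expect_true(out$valid[1])
  d2 <- beat_table(baseline_beat(0), baseline_beat(3, overrides = list(sbp = 130)))
  out2 <- apply_conditions(d2)   # only 3 s apart: cond4 vacuous
  expect_true(all(out2$valid))
})

test_that("a BP step inside 5 s invalidates the jumped beat only", {
  rows <- lapply(0:9, function(i) {
    sbp <- if (i == 5) 90 + 35 else 90
    baseline_beat(5 * i, overrides = list(sbp = sbp))
  })
  out <- apply_conditions(do.call(beat_table, rows))
  expect_identical(out$valid, c(rep(TRUE, 5), FALSE, rep(TRUE, 4)))
  expect_identical(out$reject_reason[6], "cond4")
})

test_that("condition evaluation matches the rule-by-rule oracle on random tables", {
  set.seed(202)
  for (rep in 1:60) {
    n <- sample(5:25, 1)
    rows <- lapply(seq_len(n), function(i) {
      baseline_beat((i - 1) * runif(1, 2, 6),
                    overrides = list(
                      sbp = runif(1, 40, 260),
                      dbp = runif(1, 20, 170),
                      pat_abp = runif(1, 50, 270),
                      ptt_2 = runif(1, -100, 500)))
    })
    d <- do.call(beat_table, rows)
    d$r_time <- cumsum(c(0, runif(n - 1, 2, 7)))
    d$pp <- d$sbp - d$dbp
    got <- apply_conditions(d)
    want <- oracle_conditions(d)
    expect_identical(got$valid, want$valid)
    expect_identical(got$reject_reason, want$reject_reason)
  }
})

test_that("validity is monotone under relaxing any single bound", {
  set.seed(99)
  # one table per bound, values clustered tightly around the probed bound
  # so the jump conditions stay inert while the bound is exercised
  cluster_table <- function(field, values, base = list()) {
    rows <- lapply(seq_along(values), function(i)
      baseline_beat(5 * i,
                    overrides = c(base, setNames(list(values[i]), field))))
    d <- do.call(beat_table, rows)
    d$pp <- d$sbp - d$dbp
    d
  }
  checks <- list(
    list(cluster_table("sbp", runif(40, 245, 255)),
         condition_bounds(sbp = c(50, 260))),
    list(cluster_table("sbp", runif(40, 45, 55), base = list(dbp = 35)),
         condition_bounds(sbp = c(40, 250))),
    list(cluster_table("dbp", runif(40, 26, 34)),
         condition_bounds(dbp = c(20, 160))),
    list(cluster_table("sbp", 70 + runif(40, 5, 15)),   # pp 5-15 mmHg
         condition_bounds(pp_min = 5)),
    list(cluster_table("pat_abp", runif(40, 62, 78)),
         condition_bounds(pat_abp = c(50, 250)))
  )
  for (ch in checks) {
    strict_n <- sum(apply_conditions(ch[[1]])$valid)
    relaxed_n <- sum(apply_conditions(ch[[1]], ch[[2]])$valid)
    expect_gte(relaxed_n, strict_n)
    expect_gt(relaxed_n, 0)
  }

  # jump bounds: alternating +/- 35 mmHg steps, all pairwise diffs 0 or 35
  sbp_alt <- 100 + 35 * (seq_len(40) %% 2)
  d_alt <- cluster_table("sbp", sbp_alt)
  expect_gte(sum(apply_conditions(d_alt, condition_bounds(bp_jump = 50))$valid),
             sum(apply_conditions(d_alt)$valid))
  ptt_alt <- 230 + 350 * (seq_len(40) %% 2)
  d_feat <- cluster_table("ptt_2", ptt_alt)
  expect_gte(sum(apply_conditions(d_feat, condition_bounds(feat_jump = 500))$valid),
             sum(apply_conditions(d_feat)$valid))
})

test_that("smoothing: identity cases, oracle match, linearity, mean", {
  expect_equal(smooth_series(c(0, 5, 10), rep(4, 3)), rep(4, 3))
  expect_equal(smooth_series(7, 3.3), 3.3)

  set.seed(17)
  t <- sort(runif(300, 0, 240))
  x <- rnorm(300)
  s <- smooth_series(t, x)
  expect_equal(s, oracle_smooth(t, x), tolerance = 1e-12)

  # variance reduction roughly by mean window occupancy
  occ <- mean(vapply(seq_along(t), function(i)
    sum(abs(t - t[i]) <= 10), numeric(1)))
  expect_lt(var(s), 3 * var(x) / occ)

  # commutes with adding a constant
  expect_equal(smooth_series(t, x + 11), s + 11, tolerance = 1e-12)

  # mean preserved within edge effects
  expect_lt(abs(mean(s) - mean(x)), 0.05)
})

test_that("subject gate: 99 valid beats exclude, 100 include", {
  mk <- function(n) {
    rows <- lapply(seq_len(n), function(i) baseline_beat(0.8 * i))
    do.call(beat_table, rows)
  }
  ex <- build_subject_series(apply_conditions(mk(99)))
  expect_true(ex$excluded)
  inc <- build_subject_series(apply_conditions(mk(100)))
  expect_s3_class(inc, "subject_series")
  expect_identical(inc$n_valid, 100L)
})

test_that("a clean generator record keeps nearly all its cycles", {
  gen <- generate_record(sim_config(duration_s = 420, hr_bpm = 70, seed = 13))
  beats <- extract_beats(gen$record)
  # about duration * HR / 60 beats minus the ensemble window loss
  expected <- 420 * 70 / 60 - 10
  expect_gt(sum(beats$valid), 0.95 * expected)
  ss <- build_subject_series(beats)
  expect_s3_class(ss, "subject_series")
})

test_that("noise-free linear coupling gives correlation exactly -1", {
  cfg <- quiet_config(duration_s = 240, seed = 21)
  cfg$sbp_osc_amp <- 12
  cfg$dbp_osc_amp <- 7
  truth <- simulate_beat_truth(cfg)
  expect_equal(pearson(truth$pat_ppg_4, truth$sbp), -1, tolerance = 1e-4)
})
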