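test_that("pearson matches hand values and the textbook formula", {
  x <- c(1, 5, 9)
  expect_equal(pearson(x, x), 1)
  expect_equal(pearson(x, -2 * x + 3), -1)
  expect_equal(pearson(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)

  set.seed(4)
  for (i in 1:20) {
    a <- rnorm(sample(3:50, 1))
    b <- rnorm(length(a))
    expect_equal(pearson(a, b), oracle_pearson(a, b), tolerance = 1e-12)
  }
})

test_that("pearson rejects degenerate inputs explicitly", {
  expect_error(pearson(c(1, 2), c(3, 4)), "at least 3")
  expect_error(pearson(1:5, 1:4), "equal length")
  expect_error(pearson(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson(1:5, c(1, 2, NA, 4, 5)), "finite")
})

test_that("pearson affine equivariance: sign flips under negative maps", {
  set.seed(8)
  x <- rnorm(30)
  y <- rnorm(30)
  r <- pearson(x, y)
  expect_equal(pearson(2.5 * x + 7, y), r, tolerance = 1e-12)
  expect_equal(pearson(x, -0.3 * y + 1), -r, tolerance = 1e-12)
})

test_that("calibrated model recovers exact linear relations", {
  pat <- c(100, 120, 140, 160)
  m1 <- fit_calibrated_model(rep("s1", 4), pat, -0.5 * pat + 100)
  expect_equal(m1$alpha1, -0.5, tolerance = 1e-12)

  # same slope, different offsets: centering removes the offsets exactly
  subj <- rep(c("a", "b"), each = 4)
  bp <- c(-0.5 * pat + 100, -0.5 * pat + 140)
  m2 <- fit_calibrated_model(subj, c(pat, pat), bp)
  expect_equal(m2$alpha1, -0.5, tolerance = 1e-12)
})

test_that("fit is invariant to per-subject constant shifts", {
  set.seed(5)
  subj <- rep(c("a", "b", "c"), each = 50)
  pat <- rnorm(150, 300, 20)
  bp <- -0.4 * pat + rnorm(150, 0, 3) + 120
  m <- fit_calibrated_model(subj, pat, bp)
  shift_bp <- bp + rep(c(13, -22, 5), each = 50)
  shift_pat <- pat + rep(c(-40, 10, 25), each = 50)
  m2 <- fit_calibrated_model(subj, shift_pat, shift_bp)
  expect_equal(m2$alpha1, m$alpha1, tolerance = 1e-12)
})

test_that("degenerate fits are errors", {
  expect_error(fit_calibrated_model(c("a", "a"), c(5, 5), c(1, 2)),
               "zero pooled PAT variance")
  expect_error(fit_calibrated_model("a", 5, 1), "at least 2 beats")
})

test_that("prediction is mean-calibrated per subject", {
  set.seed(6)
  subj <- rep(c("a", "b"), each = 40)
  pat <- rnorm(80, 300, 15)
  bp <- -0.5 * pat + rnorm(80, 0, 4) + rep(c(110, 150), each = 40)
  m <- fit_calibrated_model(subj, pat, bp)

  # at the subject's mean PAT the estimate is the subject's mean BP
  cal <- m$calibration
  est_at_mean <- predict(m, cal$subject, cal$mean_pat)
  expect_equal(est_at_mean, cal$mean_bp, tolerance = 1e-12)

  # per-subject mean error is exactly zero
  pred <- predict(m, subj, pat)
  for (s in unique(subj))
    expect_lt(abs(mean(pred[subj == s] - bp[subj == s])), 1e-10)

  # corr(estimate, reference) = -corr(pat, reference) for alpha1 < 0
  expect_lt(m$alpha1, 0)
  a <- subj == "a"
  expect_equal(pearson(pred[a], bp[a]), -pearson(pat[a], bp[a]),
               tolerance = 1e-12)

  expect_error(predict(m, "zz", 300), "calibration missing")
})

test_that("pooled slope is recovered from simulated beat cohorts", {
  sampler <- default_config_sampler(duration_s = 240, hr_bpm = 75)
  coh <- generate_cohort(12, sampler, seed = 15, waveforms = FALSE)
  pooled <- do.call(rbind, lapply(coh, function(s) {
    d <- s$truth
    data.frame(subject = s$subject_id,
               pat = smooth_series(d$r_time, d$pat_ppg_4),
               sbp = smooth_series(d$r_time, d$sbp))
  }))
  m <- fit_calibrated_model(pooled$subject, pooled$pat, pooled$sbp)
  expect_lt(abs(m$alpha1 - (-1)) / 1, 0.05)
})

test_that("correlation table separates coupled PAT from decoupled PTT", {
  ext <- fixture_small_extraction()
  ct <- correlation_table(ext$series)
  expect_identical(dim(ct$mean), c(4L, 9L))
  expect_true(all(abs(ct$mean[is.finite(ct$mean)]) <= 1))
  expect_gt(abs(ct$mean["sbp", "pat_ppg_4"]), abs(ct$mean["sbp", "ptt_4"]))
  expect_lt(ct$mean["sbp", "pat_ppg_4"], 0)
})

test_that("noiseless linear cohorts give correlation exactly -1", {
  cohort <- lapply(1:2, function(k) {
    truth <- simulate_beat_truth(quiet_config(duration_s = 180, seed = k,
                                              sbp_osc_amp = 10,
                                              dbp_osc_amp = 6,
                                              peripheral_coupling_slope = -0.1))
    structure(list(subject_id = paste0("s", k),
                   data = truth, n_valid = nrow(truth), excluded = FALSE),
              class = "subject_series")
  })
  ct <- correlation_table(cohort)
  expect_equal(unname(ct$mean["sbp", "pat_ppg_4"]), -1, tolerance = 1e-4)
})

test_that("shuffled-BP null cohorts have near-zero mean correlation", {
  set.seed(33)
  cohort <- lapply(1:30, function(k) {
    truth <- simulate_beat_truth(sim_config(duration_s = 240,
                                            baseline_wander_amp = 0,
                                            noise_sd = 0, abp_noise_sd = 0,
                                            seed = 100 + k))
    d <- as.data.frame(truth)
    perm <- sample(nrow(d))
    d$sbp <- d$sbp[perm]
    d$dbp <- d$dbp[perm]
    d$mbp <- d$mbp[perm]
    d$pp <- d$pp[perm]
    structure(list(subject_id = paste0("s", k), data = d,
                   n_valid = nrow(d), excluded = FALSE),
              class = "subject_series")
  })
  ct <- correlation_table(cohort)
  # Monte-Carlo CI: mean of 30 null correlations, each ~ N(0, 1/sqrt(n))
  n_beats <- cohort[[1]]$n_valid
  expect_lt(abs(ct$mean["sbp", "pat_ppg_4"]),
            3 / sqrt(n_beats * 30) + 0.02)
})

test_that("confounder regression: nulls, VIF, planted effect, collinearity", {
  set.seed(12)
  n <- 300
  d <- data.frame(age = rnorm(n, 58, 15),
                  gender = rbinom(n, 1, 0.53),
                  bmi = rnorm(n, 23, 4),
                  hypertension = rbinom(n, 1, 0.34),
                  diabetes = rbinom(n, 1, 0.11))
  # planted age effect on the slope response; others null
  d$slope <- -0.5 - 0.004 * d$age + rnorm(n, 0, 0.05)
  res <- confounder_regression(d, "slope")
  age_row <- res[res$covariate == "age", ]
  expect_lt(abs(age_row$beta - (-0.004)), 2 * age_row$se)
  expect_lt(age_row$p_value, 0.01)
  expect_true(all(res$vif >= 1))

  # orthogonal standardized covariates have VIF exactly 1
  m <- qr.Q(qr(cbind(1, matrix(rnorm(60 * 3), 60, 3))))
  d2 <- data.frame(x1 = m[, 2], x2 = m[, 3], x3 = m[, 4])
  d2$y <- rnorm(60)
  res2 <- confounder_regression(d2, "y", covariates = c("x1", "x2", "x3"))
  expect_equal(res2$vif, rep(1, 3), tolerance = 1e-10)

  # matches car::vif on the same fit
  if (requireNamespace("car", quietly = TRUE)) {
    fit <- attr(res, "fit")
    expect_equal(unname(res$vif),
                 unname(car::vif(fit)[res$covariate]), tolerance = 1e-10)
  }

  d$dup <- 2 * d$age
  expect_error(confounder_regression(d, "slope",
                                     covariates = c("age", "bmi", "dup")),
               "collinear")
})
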