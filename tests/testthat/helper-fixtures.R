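# Shared fixtures, built in code and memoized across test files.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# Deterministic noise-free single-subject configuration.
quiet_config <- function(duration_s = 120, hr_bpm = 75, sbp = 120,
                         dbp = 65, seed = 42, ...) {
  args <- list(duration_s = duration_s, hr_bpm = hr_bpm, sbp = sbp,
               dbp = dbp, sbp_osc_amp = 0, dbp_osc_amp = 0,
               sbp_walk_sd = 0, pat_noise_sd = 0, peripheral_noise_sd = 0,
               baseline_wander_amp = 0, noise_sd = 0, abp_noise_sd = 0,
               seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

fixture_quiet_record <- function() {
  memo("quiet_record", generate_record(quiet_config()))
}

fixture_quiet_beats <- function() {
  memo("quiet_beats", extract_beats(fixture_quiet_record()$record))
}

# Small realistic cohort (3 subjects, 6 min each) used by several files;
# extraction gate relaxed to the fixture's record length.
fixture_small_cohort <- function() {
  memo("small_cohort",
       generate_cohort(3, default_config_sampler(duration_s = 360),
                       seed = 9))
}

fixture_small_extraction <- function() {
  memo("small_extraction",
       run_extract(fixture_small_cohort(),
                   pipeline_config(min_duration_min = 5)))
}

# A hand-assembled valid beat row used to build condition-test tables.
baseline_beat <- function(r_time, sbp = 90, dbp = 70, pat_abp = 150,
                          pat_ppg = c(250, 430, 380, 300),
                          overrides = list()) {
  row <- list(beat_index = NA_integer_, r_time = r_time,
              abp_peak = 0.3, abp_valley = pat_abp / 1000,
              ppg_valley = pat_ppg[1] / 1000, ppg_peak = pat_ppg[2] / 1000,
              ppg_maxderiv = pat_ppg[3] / 1000, ppg_it = pat_ppg[4] / 1000,
              sbp = sbp, dbp = dbp, mbp = (sbp + 2 * dbp) / 3,
              pp = sbp - dbp, pat_abp = pat_abp,
              pat_ppg_1 = pat_ppg[1], pat_ppg_2 = pat_ppg[2],
              pat_ppg_3 = pat_ppg[3], pat_ppg_4 = pat_ppg[4],
              ptt_1 = pat_ppg[1] - pat_abp, ptt_2 = pat_ppg[2] - pat_abp,
              ptt_3 = pat_ppg[3] - pat_abp, ptt_4 = pat_ppg[4] - pat_abp,
              valid = TRUE, reject_reason = "")
  row[names(overrides)] <- overrides
  if (!"pp" %in% names(overrides)) row$pp <- row$sbp - row$dbp
  as.data.frame(row, stringsAsFactors = FALSE)
}

# ground-truth frame without the internal waveform-anchoring attribute
truth_frame <- function(truth) {
  d <- as.data.frame(truth)
  attr(d, "anchors") <- NULL
  d
}

beat_table <- function(...) {
  rows <- list(...)
  d <- do.call(rbind, rows)
  d$beat_index <- seq_len(nrow(d))
  d
}
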