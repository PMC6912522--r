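# Per-beat BP values and temporal features, the six plausibility
# conditions, 20 s smoothing, and the per-subject inclusion gate.

#' Blood pressure values from one averaged ABP cycle
#'
#' SBP and DBP are the cycle values at the detected peak and valley, MBP is
#' the arithmetic mean of the cycle's samples, PP is SBP - DBP.
#'
#' @param abp_cycle numeric ABP cycle (mmHg) starting at the R-peak.
#' @param fiducials result of \code{\link{detect_abp_fiducials}}.
#' @return \code{list(sbp, dbp, mbp, pp)} in mmHg.
#' @export
extract_bp <- function(abp_cycle, fiducials) {
  if (inherits(abp_cycle, "ensembled_cycle")) abp_cycle <- abp_cycle$cycle
  if (!isTRUE(fiducials$present))
    stopf("ABP fiducials absent (%s)", fiducials$reason %||% "unknown")
  sbp <- abp_cycle[fiducials$peak_idx]
  dbp <- abp_cycle[fiducials$valley_idx]
  list(sbp = sbp, dbp = dbp, mbp = mean(abp_cycle), pp = sbp - dbp)
}

#' Temporal features from one cycle's fiducials
#'
#' All features in ms: \code{pat_abp} is the R-peak to ABP-valley delay,
#' \code{pat_ppg[k]} the R-peak to PPG-point delay and \code{ptt[k]} the
#' ABP-valley to PPG-point delay, with k indexing the PPG valley (1), peak
#' (2), maximum derivative (3) and intersecting-tangent onset (4).
#'
#' @param abp_valley ABP valley time, seconds relative to the R-peak.
#' @param ppg_fiducials result of \code{\link{detect_ppg_fiducials}}.
#' @return \code{list(pat_abp, pat_ppg, ptt)} with \code{pat_ppg} and
#'   \code{ptt} length-4 numeric vectors, ms.
#' @export
extract_temporal <- function(abp_valley, ppg_fiducials) {
  if (!isTRUE(ppg_fiducials$present))
    stopf("PPG fiducials absent (%s)", ppg_fiducials$reason %||% "unknown")
  pat_abp <- abp_valley * 1000
  pat_ppg <- 1000 * c(ppg_fiducials$ppg_valley, ppg_fiducials$ppg_peak,
                      ppg_fiducials$ppg_maxderiv, ppg_fiducials$ppg_it)
  list(pat_abp = pat_abp, pat_ppg = pat_ppg, ptt = pat_ppg - pat_abp)
}

#' Plausibility condition bounds
#'
#' The six per-beat plausibility conditions with their default bounds:
#' (1) 50 < SBP < 250 mmHg; (2) 30 < DBP < 160 mmHg; (3) PP > 10 mmHg;
#' (4) |change in SBP| and |change in DBP| over the previous 5 s < 30 mmHg;
#' (5) 70 < PAT_ABP < 250 ms; (6) |change in every PAT/PTT feature| over
#' the previous 5 s < 300 ms.
#'
#' @param sbp,dbp open \code{c(lo, hi)} intervals, mmHg.
#' @param pp_min lower PP bound (exclusive), mmHg.
#' @param bp_jump maximal BP change over \code{lookback_s}, mmHg
#'   (exclusive).
#' @param pat_abp open \code{c(lo, hi)} interval, ms.
#' @param feat_jump maximal feature change over \code{lookback_s}, ms
#'   (exclusive).
#' @param lookback_s look-back horizon, seconds.
#' @return named list of bounds.
#' @export
condition_bounds <- function(sbp = c(50, 250), dbp = c(30, 160),
                             pp_min = 10, bp_jump = 30,
                             pat_abp = c(70, 250), feat_jump = 300,
                             lookback_s = 5) {
  list(sbp = sbp, dbp = dbp, pp_min = pp_min, bp_jump = bp_jump,
       pat_abp = pat_abp, feat_jump = feat_jump, lookback_s = lookback_s)
}

FEATURE_COLUMNS <- c("pat_abp", paste0("pat_ppg_", 1:4), paste0("ptt_", 1:4))

#' Apply the six per-beat plausibility conditions
#'
#' Processes beats in time order. A beat is valid iff all six conditions
#' hold; \code{reject_reason} records the first failed condition
#' (\code{"cond1"} ... \code{"cond6"}). The change conditions (4 and 6)
#' compare against the nearest already-accepted beat at least
#' \code{lookback_s} seconds earlier and pass vacuously when there is none.
#' Beats arriving already invalid (absent fiducials, artifacts) keep their
#' reason and never serve as reference beats.
#'
#' @param beats beat \code{data.frame} with columns \code{r_time},
#'   \code{sbp}, \code{dbp}, \code{pp} and the nine feature columns;
#'   optional logical \code{valid} and character \code{reject_reason}
#'   columns carry upstream invalidity.
#' @param bounds bounds list from \code{\link{condition_bounds}}.
#' @return the \code{data.frame} with updated \code{valid} and
#'   \code{reject_reason} columns.
#' @export
apply_conditions <- function(beats, bounds = condition_bounds()) {
  n <- nrow(beats)
  if (is.null(beats$valid)) beats$valid <- TRUE
  if (is.null(beats$reject_reason)) beats$reject_reason <- ""
  if (is.unsorted(beats$r_time)) stopf("beats must be ordered in time")

  acc_t <- numeric(0)
  acc_i <- integer(0)
  for (i in seq_len(n)) {
    if (!beats$valid[i]) next
    b <- beats[i, ]
    ref <- NULL
    ok <- which(acc_t <= b$r_time - bounds$lookback_s)
    if (length(ok)) ref <- beats[acc_i[ok[length(ok)]], ]

    fail <- NULL
    if (!(b$sbp > bounds$sbp[1] && b$sbp < bounds$sbp[2])) {
      fail <- "cond1"
    } else if (!(b$dbp > bounds$dbp[1] && b$dbp < bounds$dbp[2])) {
      fail <- "cond2"
    } else if (!(b$pp > bounds$pp_min)) {
      fail <- "cond3"
    } else if (!is.null(ref) &&
               !(abs(b$sbp - ref$sbp) < bounds$bp_jump &&
                 abs(b$dbp - ref$dbp) < bounds$bp_jump)) {
      fail <- "cond4"
    } else if (!(b$pat_abp > bounds$pat_abp[1] &&
                 b$pat_abp < bounds$pat_abp[2])) {
      fail <- "cond5"
    } else if (!is.null(ref)) {
      dfeat <- abs(unlist(b[FEATURE_COLUMNS]) - unlist(ref[FEATURE_COLUMNS]))
      if (!all(dfeat < bounds$feat_jump)) fail <- "cond6"
    }

    if (is.null(fail)) {
      acc_t <- c(acc_t, b$r_time)
      acc_i <- c(acc_i, i)
    } else {
      beats$valid[i] <- FALSE
      beats$reject_reason[i] <- fail
    }
  }
  beats
}

#' Smooth per-beat series with a centered moving-average window
#'
#' Each valid beat's value is replaced by the mean over valid beats within
#' +/- \code{window_s / 2} seconds (inclusive). Output length equals input
#' length; a beat with no neighbours keeps its value.
#'
#' @param times beat times, seconds (sorted).
#' @param x numeric values, same length.
#' @param window_s full window width, seconds.
#' @param centered centered window (default); if \code{FALSE}, a trailing
#'   window \code{[t - window_s, t]} is used.
#' @return smoothed numeric vector.
#' @export
smooth_series <- function(times, x, window_s = 20, centered = TRUE) {
  n <- length(x)
  if (n != length(times)) stopf("times and x must have equal length")
  if (n <= 1L) return(x)
  if (is.unsorted(times)) stopf("times must be sorted")
  half <- window_s / 2
  lo <- if (centered) times - half else times - window_s
  hi <- if (centered) times + half else times
  i1 <- findInterval(lo, times, left.open = TRUE) + 1L
  i2 <- findInterval(hi, times)
  cs <- c(0, cumsum(x))
  (cs[i2 + 1L] - cs[i1]) / (i2 - i1 + 1L)
}

#' Build a subject's analysis series (or exclude the subject)
#'
#' Keeps the valid beats, smooths every BP value and temporal feature with
#' the smoothing window, and gates the subject on the number of valid
#' beats.
#'
#' @param beats beat \code{data.frame} after \code{\link{apply_conditions}}.
#' @param subject_id subject identifier.
#' @param min_valid minimal number of valid beats for inclusion.
#' @param window_s smoothing window, seconds.
#' @param centered centered smoothing window (see
#'   \code{\link{smooth_series}}).
#' @return on inclusion an object of class \code{subject_series}:
#'   \code{list(subject_id, data, n_valid)} where \code{data} holds the
#'   smoothed series; otherwise \code{list(subject_id, excluded = TRUE,
#'   reason = "n_beats", n_valid, reject_counts)}.
#' @export
build_subject_series <- function(beats, subject_id = "S001",
                                 min_valid = 100, window_s = 20,
                                 centered = TRUE) {
  valid <- beats[beats$valid, , drop = FALSE]
  n_valid <- nrow(valid)
  if (n_valid < min_valid) {
    bad <- beats$reject_reason[!beats$valid]
    return(list(subject_id = subject_id, excluded = TRUE,
                reason = "n_beats", n_valid = n_valid,
                reject_counts = table(bad)))
  }
  cols <- c("sbp", "dbp", "mbp", "pp", FEATURE_COLUMNS)
  sm <- valid[, c("beat_index", "r_time", cols)]
  for (cc in cols)
    sm[[cc]] <- smooth_series(valid$r_time, valid[[cc]], window_s, centered)
  structure(list(subject_id = subject_id, data = sm, n_valid = n_valid,
                 excluded = FALSE),
            class = "subject_series")
}

#' @export
print.subject_series <- function(x, ...) {
  cat(sprintf("<subject_series> %s: %d valid beats, %.1f min span\n",
              x$subject_id, x$n_valid,
              diff(range(x$data$r_time)) / 60))
  invisible(x)
}
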