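# Preprocessing: nonlinear baseline removal, Pan-Tompkins R-peak detection,
# recording-level gating, automated saturation screening and 10-beat moving
# ensemble averaging.

#' Remove low-frequency baseline with cascaded median filters
#'
#' Estimates the baseline as the output of two running-median filters in
#' cascade and subtracts it. Median windows must be chosen relative to the
#' morphology to preserve: for ECG the defaults (250 ms then 600 ms) remove
#' everything slower than the QRS-T complex; for pulse waveforms (PPG) use
#' windows longer than one cardiac cycle (the pipeline default is
#' 1000/1500 ms) so the pulse morphology itself is not tracked into the
#' baseline estimate.
#'
#' @param x numeric signal vector.
#' @param fs sampling rate, Hz.
#' @param win1_ms,win2_ms widths of the first and second median windows, ms.
#' @return the baseline-removed signal (same length).
#' @export
remove_baseline <- function(x, fs, win1_ms = 250, win2_ms = 600) {
  if (length(x) < 2 * fs)
    stopf("signal too short for baseline estimation (< 2 s)")
  baseline <- runmed(runmed(x, odd_window(win1_ms, fs)),
                     odd_window(win2_ms, fs))
  as.numeric(x - baseline)
}

#' Detect ECG R-peaks (Pan-Tompkins)
#'
#' Band-pass (5-15 Hz), five-point derivative, squaring and 150 ms moving
#' window integration, followed by adaptive dual-threshold peak selection
#' with a refractory period. All filters are applied zero-phase, so
#' detections are translation-equivariant. R-peak times are refined to the
#' maximum of the band-passed ECG near each accepted integration peak.
#'
#' @param ecg baseline-removed ECG vector.
#' @param fs sampling rate, Hz.
#' @param refractory_ms minimum separation between detections, ms.
#' @return strictly increasing numeric vector of R-peak times in seconds
#'   (empty for flat or peak-free signals).
#' @export
detect_r_peaks <- function(ecg, fs, refractory_ms = 200) {
  n <- length(ecg)
  if (n < fs || sd(ecg) == 0) return(numeric(0))

  bf <- signal::butter(3, c(5, 15) / (fs / 2), type = "pass")
  bp <- as.numeric(signal::filtfilt(bf, ecg))

  drv <- stats::filter(bp, c(2, 1, 0, -1, -2) / 8, sides = 2)
  drv[is.na(drv)] <- 0
  sq <- as.numeric(drv)^2
  wi <- max(3L, as.integer(round(0.150 * fs)))
  integ <- stats::filter(sq, rep(1 / wi, wi), sides = 2)
  integ[is.na(integ)] <- 0
  integ <- as.numeric(integ)

  # candidate local maxima of the integrated signal
  cand <- which(diff(sign(diff(integ))) < 0) + 1L
  if (!length(cand)) return(numeric(0))

  refr <- as.integer(round(refractory_ms / 1000 * fs))
  init <- integ[seq_len(min(n, 2L * as.integer(fs)))]
  spki <- 0.25 * max(init)
  npki <- 0.5 * mean(init)
  peaks <- integer(0)
  for (p in cand) {
    thr <- npki + 0.25 * (spki - npki)
    if (integ[p] > thr) {
      if (length(peaks) && p - peaks[length(peaks)] <= refr) {
        if (integ[p] > integ[peaks[length(peaks)]]) {
          peaks[length(peaks)] <- p        # keep the stronger of the pair
          spki <- 0.125 * integ[p] + 0.875 * spki
        }
      } else {
        peaks <- c(peaks, p)
        spki <- 0.125 * integ[p] + 0.875 * spki
      }
    } else {
      npki <- 0.125 * integ[p] + 0.875 * npki
    }
  }
  if (!length(peaks)) return(numeric(0))

  # localize R as the band-passed maximum near each integration peak
  hw <- as.integer(round(0.10 * fs))
  r_idx <- vapply(peaks, function(p) {
    lo <- max(1L, p - hw); hi <- min(n, p + hw)
    lo + which.max(bp[lo:hi]) - 1L
  }, integer(1))
  r_idx <- unique(r_idx)
  keep <- c(TRUE, diff(r_idx) > refr)
  r_idx <- r_idx[keep]
  (r_idx - 1L) / fs
}

#' Flag saturated / flat-lined intervals
#'
#' Flags intervals where the first difference is exactly zero for longer
#' than \code{min_flat_s}, or where the signal sits at its global extreme
#' for longer than \code{min_flat_s}. Overlapping flags are merged. This is
#' the automated stand-in for visual screening of clamped or disconnected
#' transducers; it is intended for the pulse channels (ABP, PPG), whose
#' physiological signal is never flat.
#'
#' @param x numeric signal.
#' @param fs sampling rate, Hz.
#' @param min_flat_s minimum flagged duration, seconds.
#' @return \code{data.frame(start_s, end_s)}; zero rows when clean.
#' @export
detect_saturation <- function(x, fs, min_flat_s = 0.5) {
  n <- length(x)
  min_run <- as.integer(ceiling(min_flat_s * fs))
  flags <- rep(FALSE, n)

  flat <- c(diff(x) == 0, FALSE)
  r <- rle(flat)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in which(r$values & r$lengths >= min_run))
    flags[starts[j]:min(n, ends[j] + 1L)] <- TRUE

  tol <- 1e-12 * max(diff(range(x)), 1)
  for (railed in list(x >= max(x) - tol, x <= min(x) + tol)) {
    r <- rle(railed)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values & r$lengths >= min_run))
      flags[starts[j]:ends[j]] <- TRUE
  }

  if (!any(flags)) return(data.frame(start_s = numeric(0),
                                     end_s = numeric(0)))
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(start_s = (starts[keep] - 1L) / fs, end_s = ends[keep] / fs)
}

# seconds covered by a set of (already merged) intervals
interval_total <- function(iv) if (nrow(iv)) sum(iv$end_s - iv$start_s) else 0

in_intervals <- function(t, iv) {
  if (!nrow(iv)) return(rep(FALSE, length(t)))
  hit <- rep(FALSE, length(t))
  for (j in seq_len(nrow(iv)))
    hit <- hit | (t >= iv$start_s[j] & t <= iv$end_s[j])
  hit
}

#' Recording-level inclusion gate
#'
#' A recording is accepted iff its duration is at least
#' \code{min_duration_min} minutes, its mean heart rate (computed from the
#' detected beat train after removing beats inside flagged saturation
#' intervals on ABP or PPG) lies in \code{[hr_lo, hr_hi]} BPM, and no pulse
#' channel is flagged as saturated/flat for more than
#' \code{max_saturation_frac} of the record.
#'
#' @param record a \code{\link{waveform_record}}.
#' @param r_times detected R-peak times, seconds.
#' @param min_duration_min minimum duration, minutes.
#' @param hr_lo,hr_hi admissible mean heart rate range, BPM.
#' @param max_saturation_frac maximal tolerated flagged fraction per pulse
#'   channel.
#' @param min_flat_s passed to \code{\link{detect_saturation}}.
#' @return \code{list(accept, reason)}; \code{reason} is \code{""} when
#'   accepted, otherwise one of \code{"duration"}, \code{"heart_rate"},
#'   \code{"saturation"}.
#' @export
gate_recording <- function(record, r_times, min_duration_min = 30,
                           hr_lo = 40, hr_hi = 200,
                           max_saturation_frac = 0.5, min_flat_s = 0.5) {
  dur <- record_duration(record)
  if (dur < min_duration_min * 60)
    return(list(accept = FALSE, reason = "duration"))

  sat <- rbind(detect_saturation(record$abp, record$fs, min_flat_s),
               detect_saturation(record$ppg, record$fs, min_flat_s))
  if (nrow(sat)) {
    frac_abp <- interval_total(detect_saturation(record$abp, record$fs,
                                                 min_flat_s)) / dur
    frac_ppg <- interval_total(detect_saturation(record$ppg, record$fs,
                                                 min_flat_s)) / dur
    if (max(frac_abp, frac_ppg) > max_saturation_frac)
      return(list(accept = FALSE, reason = "saturation"))
  }

  r_kept <- r_times[!in_intervals(r_times, sat)]
  if (length(r_kept) < 2)
    return(list(accept = FALSE, reason = "heart_rate"))
  mean_hr <- 60 * (length(r_kept) - 1) / (max(r_kept) - min(r_kept))
  if (mean_hr < hr_lo || mean_hr > hr_hi)
    return(list(accept = FALSE, reason = "heart_rate"))

  list(accept = TRUE, reason = "")
}

#' Moving 10-beat ensemble averaging
#'
#' For every window of \code{n_beats} consecutive beats, the R-peak-aligned
#' cycles are truncated to the window's shortest RR interval and averaged
#' point-wise, giving one averaged cardiac cycle per window position (the
#' window advances one cycle at a time). Each averaged cycle is
#' time-referenced to the first R-peak of its window, which is also the
#' beat the cycle's features are attributed to.
#'
#' @param x signal vector (e.g. raw ABP or baseline-removed PPG).
#' @param r_times R-peak times, seconds; at least \code{n_beats + 1} are
#'   needed for one window.
#' @param fs sampling rate, Hz.
#' @param n_beats beats per ensemble window.
#' @return list of \code{ensembled_cycle} objects with fields
#'   \code{window_start_beat}, \code{r_time}, \code{cycle},
#'   \code{cycle_len}; empty list when there are too few beats. The number
#'   of cycles is exactly \code{max(0, length(r_times) - n_beats)}.
#' @export
ensemble_average <- function(x, r_times, fs, n_beats = 10) {
  nr <- length(r_times)
  n_win <- nr - n_beats
  if (n_win <= 0) return(list())

  r_idx <- as.integer(round(r_times * fs)) + 1L
  seg_len <- diff(r_idx)                      # nr - 1 segments
  lmax <- max(seg_len)
  nseg <- nr - 1L

  # segment matrix padded with zeros; cumulative sums over segment index
  # give every window sum in O(1). Columns up to the window's min RR are
  # guaranteed to have all n_beats segments present.
  m <- matrix(0, nseg, lmax)
  for (i in seq_len(nseg)) {
    s <- x[r_idx[i]:(r_idx[i + 1L] - 1L)]
    m[i, seq_along(s)] <- s
  }
  cs <- apply(m, 2, cumsum)
  if (nseg == 1L) cs <- matrix(cs, nrow = 1L)

  out <- vector("list", n_win)
  for (i in seq_len(n_win)) {
    hi <- i + n_beats - 1L
    sums <- if (i == 1L) cs[hi, ] else cs[hi, ] - cs[i - 1L, ]
    len <- min(seg_len[i:hi])
    out[[i]] <- structure(list(window_start_beat = i,
                               r_time = r_times[i],
                               cycle = sums[seq_len(len)] / n_beats,
                               cycle_len = len),
                          class = "ensembled_cycle")
  }
  out
}
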