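# Per-cycle fiducial detection on ensemble-averaged ABP and PPG cycles.
# All times are seconds relative to the cycle's reference R-peak (sample 1
# of the cycle). The intersecting-tangent onset is kept as a real number
# (sub-sample) because at 100 Hz the 10 ms grid quantization would
# otherwise dominate the temporal features.

#' Default fiducial gating ranges
#'
#' Admissible time windows (ms after the R-peak) for each fiducial point.
#' The PPG windows are wide to accommodate a constant acquisition delay on
#' the PPG channel of up to several hundred ms.
#'
#' @param abp_valley,ppg_valley,ppg_it,ppg_maxderiv,ppg_peak numeric
#'   \code{c(lo_ms, hi_ms)} windows.
#' @return named list of ranges.
#' @export
fiducial_ranges <- function(abp_valley = c(50, 400),
                            ppg_valley = c(50, 1200),
                            ppg_it = c(50, 1200),
                            ppg_maxderiv = c(50, 1250),
                            ppg_peak = c(80, 1500)) {
  list(abp_valley = abp_valley, ppg_valley = ppg_valley, ppg_it = ppg_it,
       ppg_maxderiv = ppg_maxderiv, ppg_peak = ppg_peak)
}

fiducial_absent <- function(reason) {
  list(present = FALSE, reason = reason)
}

#' Detect ABP fiducials on one averaged cycle
#'
#' The valley (systolic foot) is the deepest local minimum whose time falls
#' inside the gating range (ties resolved to the earliest); the peak is the
#' global maximum after the valley. Requiring a local minimum rejects
#' monotone cycles; taking the deepest rather than the first makes the foot
#' robust to shallow noise-induced minima on the diastolic tail.
#'
#' @param cycle numeric vector: one ensemble-averaged ABP cycle starting at
#'   the R-peak (or an \code{ensembled_cycle} object).
#' @param fs sampling rate, Hz.
#' @param valley_range admissible \code{c(lo_ms, hi_ms)} window for the
#'   valley.
#' @return on success \code{list(present = TRUE, abp_valley, abp_peak,
#'   valley_idx, peak_idx)} (times in seconds relative to the R-peak);
#'   otherwise \code{list(present = FALSE, reason)}.
#' @export
detect_abp_fiducials <- function(cycle, fs, valley_range = c(50, 400)) {
  if (inherits(cycle, "ensembled_cycle")) cycle <- cycle$cycle
  n <- length(cycle)
  if (n < 0.25 * fs) return(fiducial_absent("no_extremum"))

  i <- 2:(n - 1L)
  mins <- i[cycle[i] < cycle[i - 1L] & cycle[i] <= cycle[i + 1L]]
  t_ms <- (mins - 1L) / fs * 1000
  mins <- mins[t_ms >= valley_range[1] & t_ms <= valley_range[2]]
  if (!length(mins)) return(fiducial_absent("no_extremum"))
  v <- mins[which.min(cycle[mins])]

  if (v >= n) return(fiducial_absent("no_extremum"))
  p <- v + which.max(cycle[(v + 1L):n])
  if (cycle[p] <= cycle[v]) return(fiducial_absent("no_extremum"))
  list(present = TRUE,
       abp_valley = (v - 1L) / fs, abp_peak = (p - 1L) / fs,
       valley_idx = v, peak_idx = p)
}

#' Detect PPG fiducials on one averaged cycle
#'
#' The valley is the diastolic minimum (the global minimum inside the
#' gating window), the peak is the global maximum after the valley, the
#' maximum-derivative point is the maximum of the central-difference first
#' derivative between valley and peak, and the intersecting-tangent (IT)
#' onset is where the tangent at the maximum-derivative point crosses the
#' horizontal tangent through the diastolic minimum:
#' \deqn{t_{IT} = t_{md} - (y(t_{md}) - y_{min}) / y'(t_{md}).}
#' The IT time is kept sub-sample and clamped to
#' \code{[t_valley, t_maxderiv]}.
#'
#' @param cycle numeric vector: one ensemble-averaged PPG cycle starting at
#'   the R-peak (or an \code{ensembled_cycle} object).
#' @param fs sampling rate, Hz.
#' @param valley_range admissible \code{c(lo_ms, hi_ms)} search window for
#'   the diastolic minimum.
#' @return on success \code{list(present = TRUE, ppg_valley, ppg_peak,
#'   ppg_maxderiv, ppg_it, valley_idx, peak_idx, maxderiv_idx)} (times in
#'   seconds relative to the R-peak); otherwise
#'   \code{list(present = FALSE, reason)}.
#' @export
detect_ppg_fiducials <- function(cycle, fs, valley_range = c(50, 1200)) {
  if (inherits(cycle, "ensembled_cycle")) cycle <- cycle$cycle
  n <- length(cycle)
  if (n < 0.25 * fs) return(fiducial_absent("no_extremum"))

  lo <- max(1L, as.integer(floor(valley_range[1] / 1000 * fs)) + 1L)
  hi <- min(n - 2L, as.integer(ceiling(valley_range[2] / 1000 * fs)) + 1L)
  if (lo >= hi) return(fiducial_absent("no_extremum"))
  v <- lo + which.min(cycle[lo:hi]) - 1L

  if (v + 1L > n) return(fiducial_absent("no_extremum"))
  p <- v + which.max(cycle[(v + 1L):n])
  if (cycle[p] <= cycle[v]) return(fiducial_absent("no_extremum"))

  # central-difference derivative on the rising limb
  rng <- max(2L, v):min(n - 1L, p)
  d <- (cycle[rng + 1L] - cycle[rng - 1L]) * fs / 2
  md <- rng[which.max(d)]
  slope <- max(d)
  if (slope <= 0) return(fiducial_absent("nonpositive_slope"))

  t_v <- (v - 1L) / fs
  t_md <- (md - 1L) / fs
  t_it <- t_md - (cycle[md] - cycle[v]) / slope
  t_it <- min(max(t_it, t_v), t_md)

  list(present = TRUE,
       ppg_valley = t_v, ppg_peak = (p - 1L) / fs,
       ppg_maxderiv = t_md, ppg_it = t_it,
       valley_idx = v, peak_idx = p, maxderiv_idx = md)
}

#' Gate a fiducial set against pre-set time ranges
#'
#' @param fset named list with times in seconds relative to the R-peak
#'   (fields \code{abp_valley}, \code{ppg_valley}, \code{ppg_peak},
#'   \code{ppg_maxderiv}, \code{ppg_it}); missing or \code{NULL} entries
#'   fail the gate.
#' @param ranges ranges as from \code{\link{fiducial_ranges}}, in ms.
#' @return \code{TRUE} iff every point is present and inside its range.
#' @export
gate_fiducials <- function(fset, ranges = fiducial_ranges()) {
  for (nm in names(ranges)) {
    t <- fset[[nm]]
    if (is.null(t) || !is.finite(t)) return(FALSE)
    ms <- t * 1000
    if (ms < ranges[[nm]][1] || ms > ranges[[nm]][2]) return(FALSE)
  }
  TRUE
}
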