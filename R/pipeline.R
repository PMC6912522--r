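# Orchestration: record -> beat table -> subject series -> correlation
# table, calibrated models and standards evaluation.

#' Pipeline configuration
#'
#' All tunables of the extraction and analysis stages in one list.
#'
#' @param ecg_baseline,ppg_baseline \code{c(win1_ms, win2_ms)} cascaded
#'   median windows for ECG and PPG baseline removal (ABP is never
#'   baseline-filtered: its amplitudes must stay in absolute mmHg).
#' @param refractory_ms R-peak detector refractory period, ms.
#' @param n_ensemble beats per ensemble-averaging window.
#' @param min_duration_min,hr_lo,hr_hi,max_saturation_frac,min_flat_s
#'   recording gate parameters (see \code{\link{gate_recording}}).
#' @param ranges fiducial gating ranges (\code{\link{fiducial_ranges}}).
#' @param bounds plausibility condition bounds
#'   (\code{\link{condition_bounds}}).
#' @param smooth_window_s smoothing window, seconds.
#' @param smooth_centered centered (default) or trailing smoothing window.
#' @param min_valid minimal valid beats per included subject.
#' @param model_feature predictor feature for the calibrated BP models.
#' @return named configuration list.
#' @export
pipeline_config <- function(ecg_baseline = c(250, 600),
                            ppg_baseline = c(1000, 1500),
                            refractory_ms = 200,
                            n_ensemble = 10,
                            min_duration_min = 30, hr_lo = 40, hr_hi = 200,
                            max_saturation_frac = 0.5, min_flat_s = 0.5,
                            ranges = fiducial_ranges(),
                            bounds = condition_bounds(),
                            smooth_window_s = 20, smooth_centered = TRUE,
                            min_valid = 100,
                            model_feature = "pat_ppg_4") {
  list(ecg_baseline = ecg_baseline, ppg_baseline = ppg_baseline,
       refractory_ms = refractory_ms, n_ensemble = n_ensemble,
       min_duration_min = min_duration_min, hr_lo = hr_lo, hr_hi = hr_hi,
       max_saturation_frac = max_saturation_frac, min_flat_s = min_flat_s,
       ranges = ranges, bounds = bounds,
       smooth_window_s = smooth_window_s,
       smooth_centered = smooth_centered,
       min_valid = min_valid, model_feature = model_feature)
}

#' Extract the per-beat feature table from one record
#'
#' Runs baseline removal (ECG, PPG), R-peak detection, ensemble averaging
#' of ABP (raw) and PPG (baseline-removed), fiducial detection, fiducial
#' range gating, BP/temporal feature extraction, artifact masking and the
#' six plausibility conditions. The recording-level gate is applied by
#' \code{\link{run_extract}}, not here.
#'
#' @param record a \code{\link{waveform_record}}.
#' @param config a \code{\link{pipeline_config}}.
#' @return beat \code{data.frame} in the \code{\link{write_beat_table}}
#'   column layout, with attribute \code{"r_times"} (the detected beat
#'   train).
#' @export
extract_beats <- function(record, config = pipeline_config()) {
  fs <- record$fs
  ecg_f <- remove_baseline(record$ecg, fs, config$ecg_baseline[1],
                           config$ecg_baseline[2])
  ppg_f <- remove_baseline(record$ppg, fs, config$ppg_baseline[1],
                           config$ppg_baseline[2])
  r_times <- detect_r_peaks(ecg_f, fs, config$refractory_ms)

  empty <- empty_beat_table()
  attr(empty, "r_times") <- r_times
  if (length(r_times) < config$n_ensemble + 1L) return(empty)

  abp_cycles <- ensemble_average(record$abp, r_times, fs, config$n_ensemble)
  ppg_cycles <- ensemble_average(ppg_f, r_times, fs, config$n_ensemble)
  n <- length(abp_cycles)
  if (!n) return(empty)

  sat <- rbind(detect_saturation(record$abp, fs, config$min_flat_s),
               detect_saturation(record$ppg, fs, config$min_flat_s))

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ac <- abp_cycles[[i]]
    pc <- ppg_cycles[[i]]
    r <- ac$r_time
    row <- list(beat_index = i, r_time = r,
                abp_peak = NA_real_, abp_valley = NA_real_,
                ppg_valley = NA_real_, ppg_peak = NA_real_,
                ppg_maxderiv = NA_real_, ppg_it = NA_real_,
                sbp = NA_real_, dbp = NA_real_, mbp = NA_real_,
                pp = NA_real_, pat_abp = NA_real_,
                pat_ppg_1 = NA_real_, pat_ppg_2 = NA_real_,
                pat_ppg_3 = NA_real_, pat_ppg_4 = NA_real_,
                ptt_1 = NA_real_, ptt_2 = NA_real_, ptt_3 = NA_real_,
                ptt_4 = NA_real_, valid = TRUE, reject_reason = "")

    # a window overlapping a flagged artifact interval is never analyzed
    win_end <- r_times[i + config$n_ensemble]
    if (nrow(sat) && any(sat$start_s <= win_end & sat$end_s >= r)) {
      row$valid <- FALSE; row$reject_reason <- "artifact"
      rows[[i]] <- row; next
    }

    af <- detect_abp_fiducials(ac$cycle, fs, config$ranges$abp_valley)
    pf <- detect_ppg_fiducials(pc$cycle, fs, config$ranges$ppg_valley)
    if (!af$present || !pf$present) {
      row$valid <- FALSE
      row$reject_reason <- if (!af$present) af$reason else pf$reason
      rows[[i]] <- row; next
    }

    fset <- list(abp_valley = af$abp_valley, ppg_valley = pf$ppg_valley,
                 ppg_peak = pf$ppg_peak, ppg_maxderiv = pf$ppg_maxderiv,
                 ppg_it = pf$ppg_it)
    row[c("abp_peak", "abp_valley")] <- list(af$abp_peak, af$abp_valley)
    row[c("ppg_valley", "ppg_peak", "ppg_maxderiv", "ppg_it")] <-
      fset[c("ppg_valley", "ppg_peak", "ppg_maxderiv", "ppg_it")]

    if (!gate_fiducials(fset, config$ranges)) {
      row$valid <- FALSE; row$reject_reason <- "fiducial_range"
      rows[[i]] <- row; next
    }

    bp <- extract_bp(ac$cycle, af)
    tf <- extract_temporal(af$abp_valley, pf)
    row[c("sbp", "dbp", "mbp", "pp")] <- bp
    row$pat_abp <- tf$pat_abp
    row[paste0("pat_ppg_", 1:4)] <- as.list(tf$pat_ppg)
    row[paste0("ptt_", 1:4)] <- as.list(tf$ptt)
    rows[[i]] <- row
  }
  beats <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  beats <- apply_conditions(beats, config$bounds)
  attr(beats, "r_times") <- r_times
  beats
}

empty_beat_table <- function() {
  cols <- BEAT_TABLE_COLUMNS
  d <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
  d$valid <- logical(0)
  d$reject_reason <- character(0)
  d
}

#' Run extraction over a cohort of records
#'
#' Applies the recording-level gate, extracts beat tables and builds each
#' included subject's smoothed series; excluded subjects are reported with
#' the failed stage.
#'
#' @param records list of \code{\link{waveform_record}}s, or cohort entries
#'   from \code{\link{generate_cohort}} (the \code{record} field is used).
#' @param config a \code{\link{pipeline_config}}.
#' @param gate apply the recording-level gate (duration/heart-rate/
#'   saturation) before feature extraction.
#' @return \code{list(series, beats, exclusions, n_included)}:
#'   \code{series} is the list of included \code{subject_series},
#'   \code{beats} the per-subject beat tables, and \code{exclusions} a
#'   \code{data.frame(subject, reason)}.
#' @export
run_extract <- function(records, config = pipeline_config(), gate = TRUE) {
  series <- list()
  beats <- list()
  exclusions <- data.frame(subject = character(0), reason = character(0))
  for (entry in records) {
    rec <- if (inherits(entry, "waveform_record")) entry else entry$record
    if (is.null(rec)) stopf("cohort entry has no waveform record")
    sid <- rec$subject_id

    ecg_f <- remove_baseline(rec$ecg, rec$fs, config$ecg_baseline[1],
                             config$ecg_baseline[2])
    r_times <- detect_r_peaks(ecg_f, rec$fs, config$refractory_ms)
    if (gate) {
      g <- gate_recording(rec, r_times, config$min_duration_min,
                          config$hr_lo, config$hr_hi,
                          config$max_saturation_frac, config$min_flat_s)
      if (!g$accept) {
        exclusions <- rbind(exclusions,
                            data.frame(subject = sid, reason = g$reason))
        next
      }
    }

    bt <- extract_beats(rec, config)
    beats[[sid]] <- bt
    ss <- build_subject_series(bt, subject_id = sid,
                               min_valid = config$min_valid,
                               window_s = config$smooth_window_s,
                               centered = config$smooth_centered)
    if (isTRUE(ss$excluded)) {
      exclusions <- rbind(exclusions,
                          data.frame(subject = sid, reason = "n_beats"))
    } else {
      series[[sid]] <- ss
    }
  }
  list(series = series, beats = beats, exclusions = exclusions,
       n_included = length(series))
}

#' Run the correlation / modelling / evaluation study
#'
#' Computes the per-subject correlation table, fits the mean-calibrated
#' pooled linear model for SBP and DBP on the configured predictor
#' feature, predicts on the same beats, and grades both models against the
#' AAMI / BHS / IEEE 1708 standards.
#'
#' @param extraction result of \code{\link{run_extract}} (>= 2 included
#'   subjects).
#' @param config a \code{\link{pipeline_config}}.
#' @return \code{list(correlation, model_sbp, model_dbp, eval_sbp,
#'   eval_dbp, n_subjects)}.
#' @export
run_study <- function(extraction, config = pipeline_config()) {
  series <- extraction$series
  if (length(series) < 2) stopf("need at least 2 included subjects")
  corr <- correlation_table(series)

  pooled <- do.call(rbind, lapply(series, function(s)
    data.frame(subject = s$subject_id, pat = s$data[[config$model_feature]],
               sbp = s$data$sbp, dbp = s$data$dbp)))

  out <- list(correlation = corr, n_subjects = length(series))
  for (tgt in c("sbp", "dbp")) {
    model <- fit_calibrated_model(pooled$subject, pooled$pat, pooled[[tgt]],
                                  target = toupper(tgt),
                                  feature = config$model_feature)
    pred <- predict(model, pooled$subject, pooled$pat)
    out[[paste0("model_", tgt)]] <- model
    out[[paste0("eval_", tgt)]] <- evaluate_model(pred, pooled[[tgt]],
                                                  pooled$subject,
                                                  target = toupper(tgt))
  }
  out
}
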