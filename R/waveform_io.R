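# Record and table I/O. Records are stored as an inspectable pair of files:
# a JSON sidecar (format version, subject id, fs, t0, metadata) plus a CSV
# of t, ecg, ppg, abp written at full double precision so round trips are
# bit exact. Beat tables are CSV with a versioned comment header.

FORMAT_VERSION <- "patbp-record-v1"
BEAT_TABLE_VERSION <- "patbp-beat-table-v1"

REJECT_REASONS <- c("", paste0("cond", 1:6), "no_extremum",
                    "nonpositive_slope", "fiducial_range", "artifact")

BEAT_TABLE_COLUMNS <- c(
  "beat_index", "r_time",
  "abp_peak", "abp_valley", "ppg_valley", "ppg_peak", "ppg_maxderiv",
  "ppg_it",
  "sbp", "dbp", "mbp", "pp",
  "pat_abp", paste0("pat_ppg_", 1:4), paste0("ptt_", 1:4),
  "valid", "reject_reason")

#' Construct a waveform record
#'
#' One subject's synchronized ECG, PPG and ABP samples. ECG and PPG are in
#' arbitrary units, ABP in mmHg; all three channels share the sampling rate
#' \code{fs} and start time \code{t0}.
#'
#' @param subject_id subject identifier.
#' @param fs sampling rate, Hz (> 0).
#' @param t0 start time, seconds.
#' @param ecg,ppg,abp equal-length numeric sample vectors.
#' @param metadata optional list with fields \code{age} (years),
#'   \code{gender} ("male"/"female"), \code{bmi} (kg/m2),
#'   \code{hypertension}, \code{diabetes} (logical).
#' @return object of class \code{waveform_record}.
#' @export
waveform_record <- function(subject_id, fs, t0 = 0, ecg, ppg, abp,
                            metadata = NULL) {
  if (!is_scalar_num(fs) || fs <= 0) stopf("fs must be > 0")
  n <- length(ecg)
  if (length(ppg) != n || length(abp) != n)
    stopf("channels must have equal length (ecg %d, ppg %d, abp %d)",
          n, length(ppg), length(abp))
  structure(list(subject_id = as.character(subject_id), fs = fs, t0 = t0,
                 ecg = as.numeric(ecg), ppg = as.numeric(ppg),
                 abp = as.numeric(abp), metadata = metadata),
            class = "waveform_record")
}

#' @export
print.waveform_record <- function(x, ...) {
  cat(sprintf("<waveform_record> subject %s: %d samples @ %g Hz (%.1f min)\n",
              x$subject_id, length(x$ecg), x$fs,
              length(x$ecg) / x$fs / 60))
  if (!is.null(x$metadata))
    cat("  metadata:", paste(names(x$metadata),
                             unlist(lapply(x$metadata, format)),
                             sep = "=", collapse = ", "), "\n")
  invisible(x)
}

record_duration <- function(record) length(record$ecg) / record$fs

full_precision <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Write / read a waveform record
#'
#' \code{write_record} writes \code{<path>.json} (header and metadata) and
#' \code{<path>.csv} (columns t, ecg, ppg, abp at full precision);
#' \code{read_record} reverses it. Round trips are exact sample-for-sample
#' and field-for-field.
#'
#' @param record a \code{\link{waveform_record}}.
#' @param path file path without extension.
#' @return \code{read_record} returns a \code{\link{waveform_record}};
#'   \code{write_record} returns \code{path} invisibly.
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "waveform_record"))
  header <- list(format = FORMAT_VERSION, subject_id = record$subject_id,
                 fs = record$fs, t0 = record$t0,
                 n_samples = length(record$ecg),
                 metadata = record$metadata)
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  tt <- record$t0 + (seq_along(record$ecg) - 1L) / record$fs
  d <- data.frame(t = full_precision(tt),
                  ecg = full_precision(record$ecg),
                  ppg = full_precision(record$ppg),
                  abp = full_precision(record$abp))
  write.table(d, paste0(path, ".csv"), sep = ",", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_record
#' @export
read_record <- function(path) {
  jpath <- paste0(path, ".json")
  cpath <- paste0(path, ".csv")
  if (!file.exists(jpath)) stopf("record header %s not found", jpath)
  if (!file.exists(cpath)) stopf("record samples %s not found", cpath)
  header <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  for (f in c("format", "subject_id", "fs", "n_samples"))
    if (is.null(header[[f]])) stopf("record header field %s absent", f)
  if (!identical(header$format, FORMAT_VERSION))
    stopf("unsupported record format '%s'", header$format)
  d <- read.csv(cpath, colClasses = "numeric")
  for (ch in c("ecg", "ppg", "abp"))
    if (is.null(d[[ch]])) stopf("channel %s absent", ch)
  if (nrow(d) != header$n_samples)
    stopf("sample count mismatch: header %d, csv %d", header$n_samples,
          nrow(d))
  md <- header$metadata
  if (length(md) == 0) md <- NULL
  waveform_record(subject_id = header$subject_id, fs = header$fs,
                  t0 = header$t0 %||% 0,
                  ecg = d$ecg, ppg = d$ppg, abp = d$abp, metadata = md)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a per-beat feature table
#'
#' Line-oriented CSV with a fixed, documented column order and a versioned
#' comment header. Fiducial times are stored in seconds, temporal features
#' in milliseconds.
#'
#' @param beats a beat-feature \code{data.frame} (one row per cardiac
#'   cycle) as produced by \code{\link{extract_beats}}.
#' @param path output file path.
#' @return \code{read_beat_table} returns the beat \code{data.frame};
#'   \code{write_beat_table} returns \code{path} invisibly.
#' @export
write_beat_table <- function(beats, path) {
  missing_cols <- setdiff(BEAT_TABLE_COLUMNS, names(beats))
  if (length(missing_cols))
    stopf("beat table lacks columns: %s", paste(missing_cols, collapse = ", "))
  d <- beats[, BEAT_TABLE_COLUMNS, drop = FALSE]
  num <- !(names(d) %in% c("valid", "reject_reason"))
  d[num] <- lapply(d[num], full_precision)
  d$valid <- ifelse(d$valid, "TRUE", "FALSE")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", BEAT_TABLE_VERSION), con)
  write.table(d, con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_beat_table
#' @export
read_beat_table <- function(path) {
  if (!file.exists(path)) stopf("beat table %s not found", path)
  first <- readLines(path, n = 1L)
  if (!identical(first, paste0("# ", BEAT_TABLE_VERSION)))
    stopf("unsupported beat table header '%s'", first)
  num_cols <- setdiff(BEAT_TABLE_COLUMNS,
                      c("beat_index", "valid", "reject_reason"))
  d <- read.csv(path, skip = 1L, stringsAsFactors = FALSE,
                colClasses = c(setNames(rep("numeric", length(num_cols)),
                                        num_cols),
                               beat_index = "integer",
                               valid = "logical",
                               reject_reason = "character"))
  missing_cols <- setdiff(BEAT_TABLE_COLUMNS, names(d))
  if (length(missing_cols))
    stopf("beat table lacks columns: %s", paste(missing_cols, collapse = ", "))
  d$reject_reason[is.na(d$reject_reason)] <- ""
  bad <- setdiff(unique(d$reject_reason), REJECT_REASONS)
  if (length(bad))
    stopf("unknown reject_reason token(s): %s", paste(bad, collapse = ", "))
  d$valid <- as.logical(d$valid)
  d[, BEAT_TABLE_COLUMNS, drop = FALSE]
}

#' Serialize / load a calibrated BP model
#'
#' JSON with the pooled slope and the per-subject calibration table.
#'
#' @param model a \code{\link{fit_calibrated_model}} result.
#' @param path file path.
#' @return \code{read_model} returns the model; \code{write_model} returns
#'   \code{path} invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "calibrated_bp_model"))
  jsonlite::write_json(
    list(format = "patbp-model-v1", target = model$target,
         feature = model$feature, alpha1 = model$alpha1,
         calibration = model$calibration),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "patbp-model-v1"))
    stopf("unsupported model format '%s'", x$format)
  structure(list(target = x$target, feature = x$feature,
                 alpha1 = x$alpha1,
                 calibration = as.data.frame(x$calibration)),
            class = "calibrated_bp_model")
}
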