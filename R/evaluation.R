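# Error metrics and BP-monitor standards grading (AAMI, BHS, IEEE 1708).

#' Error metrics between estimated and reference BP
#'
#' Mean error \code{ME = mean(pred - ref)}, standard deviation of the error
#' \code{SDE} (sample SD, n - 1 denominator) and mean absolute difference
#' \code{MAD = mean(|pred - ref|)}.
#'
#' @param pred,ref equal-length numeric vectors (mmHg), length >= 2.
#' @return \code{list(me, sde, mad)}.
#' @export
error_metrics <- function(pred, ref) {
  if (length(pred) != length(ref)) stopf("pred and ref must match in length")
  if (length(pred) < 2) stopf("need at least 2 pairs (SDE undefined)")
  e <- pred - ref
  list(me = mean(e), sde = sd(e), mad = mean(abs(e)))
}

#' Cumulative error percentages
#'
#' Percentage of absolute errors at or below each threshold.
#'
#' @param errors numeric error vector (mmHg), nonempty.
#' @param thresholds thresholds in mmHg.
#' @return numeric vector of percentages, same length as
#'   \code{thresholds}, non-decreasing for increasing thresholds.
#' @export
cumulative_pct <- function(errors, thresholds = c(5, 10, 15)) {
  if (!length(errors)) stopf("empty error vector")
  vapply(thresholds, function(th) 100 * mean(abs(errors) <= th), numeric(1))
}

BHS_THRESHOLDS <- list(A = c(60, 85, 95), B = c(50, 75, 90),
                       C = c(40, 65, 85))

#' BHS cumulative-percentage grade
#'
#' Grade A requires at least 60/85/95 percent of absolute errors within
#' 5/10/15 mmHg, grade B 50/75/90, grade C 40/65/85, otherwise D. The best
#' grade whose three thresholds are all met is returned.
#'
#' @param cum_pct three cumulative percentages (within 5, 10, 15 mmHg).
#' @return \code{"A"}, \code{"B"}, \code{"C"} or \code{"D"}.
#' @export
grade_bhs <- function(cum_pct) {
  if (length(cum_pct) != 3) stopf("need three cumulative percentages")
  for (g in c("A", "B", "C"))
    if (all(cum_pct >= BHS_THRESHOLDS[[g]])) return(g)
  "D"
}

#' AAMI pass criterion
#'
#' Passes iff \code{|ME| <= 5} mmHg and \code{SDE <= 8} mmHg.
#'
#' @param me mean error, mmHg.
#' @param sde standard deviation of the error, mmHg.
#' @return logical.
#' @export
check_aami <- function(me, sde) {
  abs(me) <= 5 && sde <= 8
}

#' IEEE 1708 MAD grade
#'
#' Grade bands on the mean absolute difference: A <= 5, B <= 6, C <= 7,
#' D > 7 mmHg.
#'
#' @param mad mean absolute difference, mmHg (>= 0).
#' @return \code{"A"}, \code{"B"}, \code{"C"} or \code{"D"}.
#' @export
grade_ieee <- function(mad) {
  if (mad < 0) stopf("mad must be >= 0")
  if (mad <= 5) "A" else if (mad <= 6) "B" else if (mad <= 7) "C" else "D"
}

#' Evaluate model estimates against reference BP
#'
#' Pooled error metrics over all beat pairs, cumulative error percentages,
#' standards grading, the mean and SD across subjects of the per-subject
#' estimate-reference correlation, and per-recording metrics.
#'
#' @param pred,ref pooled estimate and reference vectors, mmHg.
#' @param subject subject identifier per pair.
#' @param target label ("SBP"/"DBP").
#' @return object of class \code{bp_evaluation}: \code{list(target, me,
#'   sde, mad, cum_pct, corr_mean, corr_sd, aami_pass, bhs_grade,
#'   ieee_grade, n_pairs, n_subjects, per_recording)}.
#' @export
evaluate_model <- function(pred, ref, subject, target = "SBP") {
  stopifnot(length(pred) == length(ref), length(pred) == length(subject))
  m <- error_metrics(pred, ref)
  e <- pred - ref
  cum <- cumulative_pct(e)
  subject <- as.character(subject)
  subs <- unique(subject)
  per <- do.call(rbind, lapply(subs, function(s) {
    i <- subject == s
    corr <- if (sum(i) >= 3 && sd(pred[i]) > 0 && sd(ref[i]) > 0)
      cor(pred[i], ref[i]) else NA_real_
    mm <- if (sum(i) >= 2) error_metrics(pred[i], ref[i])
      else list(me = NA_real_, sde = NA_real_, mad = NA_real_)
    data.frame(subject = s, n = sum(i), corr = corr, me = mm$me,
               sde = mm$sde, mad = mm$mad)
  }))
  structure(list(target = target, me = m$me, sde = m$sde, mad = m$mad,
                 cum_pct = cum,
                 corr_mean = mean(per$corr, na.rm = TRUE),
                 corr_sd = sd(per$corr, na.rm = TRUE),
                 aami_pass = check_aami(m$me, m$sde),
                 bhs_grade = grade_bhs(cum),
                 ieee_grade = grade_ieee(m$mad),
                 n_pairs = length(pred), n_subjects = length(subs),
                 per_recording = per),
            class = "bp_evaluation")
}

#' @export
print.bp_evaluation <- function(x, ...) {
  cat(sprintf("<bp_evaluation> %s (%d pairs, %d subjects)\n",
              x$target, x$n_pairs, x$n_subjects))
  cat(sprintf("  Correlation to reference     %.2f +/- %.2f\n",
              x$corr_mean, x$corr_sd))
  cat(sprintf("  ME (mmHg)                    %.4g\n", x$me))
  cat(sprintf("  SDE (mmHg)                   %.2f\n", x$sde))
  cat(sprintf("  Cumulative error <5 mmHg     %.1f%%\n", x$cum_pct[1]))
  cat(sprintf("  Cumulative error <10 mmHg    %.1f%%\n", x$cum_pct[2]))
  cat(sprintf("  Cumulative error <15 mmHg    %.1f%%\n", x$cum_pct[3]))
  cat(sprintf("  MAD (mmHg)                   %.2f\n", x$mad))
  cat(sprintf("  AAMI: %s | BHS: %s | IEEE 1708: %s\n",
              if (x$aami_pass) "pass" else "fail", x$bhs_grade,
              x$ieee_grade))
  invisible(x)
}

#' Stratify per-subject correlations by BP excursion
#'
#' Bins subjects by their BP range (max - min of the smoothed series) and
#' summarizes the estimate-relevant correlation per bin. Empty bins are
#' omitted.
#'
#' @param rho per-subject correlation coefficients.
#' @param delta_bp per-subject BP ranges, mmHg.
#' @param bin_width bin width in mmHg (20 for SBP, 10 for DBP).
#' @return \code{data.frame(bin_lo, bin_hi, n, mean, sd)}.
#' @export
stratify_by_delta_bp <- function(rho, delta_bp, bin_width = 20) {
  stopifnot(length(rho) == length(delta_bp))
  keep <- is.finite(rho) & is.finite(delta_bp)
  rho <- rho[keep]; delta_bp <- delta_bp[keep]
  if (!length(rho)) return(data.frame(bin_lo = numeric(0),
                                      bin_hi = numeric(0), n = integer(0),
                                      mean = numeric(0), sd = numeric(0)))
  bin <- floor(delta_bp / bin_width)
  out <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    v <- rho[bin == b]
    data.frame(bin_lo = b * bin_width, bin_hi = (b + 1) * bin_width,
               n = length(v), mean = mean(v),
               sd = if (length(v) > 1) sd(v) else NA_real_)
  }))
  out
}
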