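# Per-subject correlation analysis, the mean-calibrated pooled linear BP
# model, and the confounder regression of per-subject slopes/correlations.

BP_COLUMNS <- c("sbp", "dbp", "mbp", "pp")

#' Pearson correlation coefficient
#'
#' Thin, validating wrapper around the product-moment correlation: both
#' inputs must have at least 3 finite values and nonzero variance (a
#' zero-variance input makes the coefficient undefined and is an error
#' here, not an NA).
#'
#' @param x,y equal-length numeric vectors.
#' @return correlation in [-1, 1].
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) < 3) stopf("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stopf("inputs must be finite")
  if (sd(x) == 0 || sd(y) == 0)
    stopf("undefined correlation: zero variance input")
  cor(x, y)
}

#' Per-subject and cohort correlation table
#'
#' For each subject, the Pearson correlations between the four BP values
#' (SBP, DBP, MBP, PP) and the nine temporal features (PAT_ABP,
#' PAT_PPG_1-4, PTT_1-4) computed on the subject's smoothed series; the
#' cohort summary is the unweighted mean and SD of each coefficient across
#' subjects. Undefined correlations (zero variance) become NA entries,
#' excluded from the summary and counted.
#'
#' @param series_list list of included \code{subject_series}.
#' @return \code{list(per_subject, mean, sd, n_missing, n_subjects)}:
#'   \code{per_subject} is a named list of 4 x 9 matrices (rows BP values,
#'   columns features); \code{mean}/\code{sd}/\code{n_missing} are 4 x 9
#'   summary matrices.
#' @export
correlation_table <- function(series_list) {
  series_list <- Filter(function(s) inherits(s, "subject_series"),
                        series_list)
  if (!length(series_list)) stopf("no included subjects")
  per_subject <- lapply(series_list, function(s) {
    m <- matrix(NA_real_, length(BP_COLUMNS), length(FEATURE_COLUMNS),
                dimnames = list(BP_COLUMNS, FEATURE_COLUMNS))
    for (b in BP_COLUMNS) for (f in FEATURE_COLUMNS) {
      x <- s$data[[f]]; y <- s$data[[b]]
      if (sd(x) > 0 && sd(y) > 0) m[b, f] <- cor(x, y)
    }
    m
  })
  names(per_subject) <- vapply(series_list, `[[`, "", "subject_id")
  arr <- simplify2array(per_subject)
  list(per_subject = per_subject,
       mean = apply(arr, c(1, 2), mean, na.rm = TRUE),
       sd = apply(arr, c(1, 2), sd, na.rm = TRUE),
       n_missing = apply(arr, c(1, 2), function(v) sum(is.na(v))),
       n_subjects = length(per_subject))
}

#' Fit the mean-calibrated pooled linear BP model
#'
#' The model is \code{BP = alpha1 * PAT + alpha0(subject)}: within each
#' subject the mean BP and mean PAT are subtracted, the pooled slope
#' \code{alpha1} is the ordinary-least-squares slope through the origin on
#' the pooled mean-centered pairs, and each subject's calibration offset
#' returns its mean BP. By construction the fitted intercept of the
#' centered regression is zero and the per-subject mean prediction error
#' is exactly zero.
#'
#' @param subject subject identifier per observation.
#' @param pat predictor values (ms), e.g. smoothed PAT_PPG_4.
#' @param bp reference BP values (mmHg).
#' @param target label of the modelled target ("SBP" or "DBP").
#' @param feature label of the predictor feature.
#' @return object of class \code{calibrated_bp_model} with fields
#'   \code{alpha1} (mmHg per ms) and \code{calibration} (per-subject mean
#'   PAT and mean BP).
#' @export
fit_calibrated_model <- function(subject, pat, bp, target = "SBP",
                                 feature = "pat_ppg_4") {
  if (length(subject) != length(pat) || length(pat) != length(bp))
    stopf("subject, pat and bp must have equal length")
  if (!all(is.finite(pat)) || !all(is.finite(bp)))
    stopf("pat and bp must be finite")
  subject <- as.character(subject)
  subs <- unique(subject)
  if (length(subs) < 1L) stopf("no data")
  counts <- table(subject)
  if (any(counts < 2)) stopf("every subject needs at least 2 beats")

  mean_pat <- tapply(pat, subject, mean)
  mean_bp <- tapply(bp, subject, mean)
  xc <- pat - mean_pat[subject]
  yc <- bp - mean_bp[subject]
  sxx <- sum(xc^2)
  if (sxx == 0) stopf("zero pooled PAT variance after centering")
  alpha1 <- sum(xc * yc) / sxx

  structure(list(alpha1 = alpha1, target = target, feature = feature,
                 calibration = data.frame(subject = subs,
                                          mean_pat = as.numeric(mean_pat[subs]),
                                          mean_bp = as.numeric(mean_bp[subs]),
                                          row.names = NULL)),
            class = "calibrated_bp_model")
}

#' @export
print.calibrated_bp_model <- function(x, ...) {
  cat(sprintf("<calibrated_bp_model> %s ~ %s: alpha1 = %.5f mmHg/ms, %d subjects\n",
              x$target, x$feature, x$alpha1, nrow(x$calibration)))
  invisible(x)
}

#' Predict BP from a calibrated model
#'
#' \code{alpha1 * (pat - mean_pat_subject) + mean_bp_subject}. The subject
#' must have been present at fit time (its calibration means are needed).
#'
#' @param object a \code{calibrated_bp_model}.
#' @param subject subject identifier per observation.
#' @param pat predictor values, ms.
#' @param ... unused.
#' @return numeric BP estimates, mmHg.
#' @export
predict.calibrated_bp_model <- function(object, subject, pat, ...) {
  subject <- as.character(subject)
  cal <- object$calibration
  idx <- match(subject, cal$subject)
  if (anyNA(idx))
    stopf("calibration missing for subject(s): %s",
          paste(unique(subject[is.na(idx)]), collapse = ", "))
  object$alpha1 * (pat - cal$mean_pat[idx]) + cal$mean_bp[idx]
}

#' Multivariate confounder regression
#'
#' Ordinary least squares of a per-subject response (e.g. the PAT-BP slope
#' or correlation) on subject-level risk factors, with per-covariate
#' coefficient, standard error, two-sided t p-value and variance inflation
#' factor. Gender is encoded male = 1, female = 0; hypertension and
#' diabetes as 0/1; continuous covariates are left unstandardized, so
#' coefficients are per-unit effects.
#'
#' @param data data.frame with the response column and covariate columns.
#' @param response name of the response column.
#' @param covariates covariate column names.
#' @return \code{data.frame(covariate, beta, se, p_value, vif)} with the
#'   fitted model attached as attribute \code{"fit"}.
#' @export
confounder_regression <- function(data, response,
                                  covariates = c("age", "gender", "bmi",
                                                 "hypertension", "diabetes")) {
  if (!response %in% names(data)) stopf("response column %s absent", response)
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov))
    stopf("covariate column(s) absent: %s",
          paste(missing_cov, collapse = ", "))
  d <- data[, c(response, covariates)]
  if (is.character(d$gender) || is.factor(d$gender))
    d$gender <- as.numeric(as.character(d$gender) == "male")
  for (cc in covariates) d[[cc]] <- as.numeric(d[[cc]])
  d <- d[complete.cases(d), ]
  if (nrow(d) <= length(covariates) + 2)
    stopf("need more subjects than covariates + 2")

  x <- as.matrix(d[, covariates])
  qrx <- qr(cbind(1, x))
  if (qrx$rank < ncol(x) + 1) {
    aliased <- covariates[qrx$pivot[-seq_len(qrx$rank)] - 1L]
    stopf("collinear design; offending column(s): %s",
          paste(aliased, collapse = ", "))
  }

  fml <- stats::as.formula(paste(response, "~",
                                 paste(covariates, collapse = " + ")))
  fit <- lm(fml, data = d)
  sm <- summary(fit)$coefficients[covariates, , drop = FALSE]

  vif <- vapply(covariates, function(cc) {
    others <- setdiff(covariates, cc)
    r2 <- summary(lm(stats::as.formula(
      paste(cc, "~", paste(others, collapse = " + "))), data = d))$r.squared
    1 / (1 - r2)
  }, numeric(1))

  out <- data.frame(covariate = covariates, beta = sm[, 1], se = sm[, 2],
                    p_value = sm[, 4], vif = as.numeric(vif),
                    row.names = NULL)
  attr(out, "fit") <- fit
  out
}
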