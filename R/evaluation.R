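#' Pixelwise confusion counts
#'
#' Foreground = vessel; returns true/false positives/negatives between a
#' predicted and a ground-truth mask.
#'
#' @param pred_mask,gt_mask Logical matrices of equal shape.
#' @return Named list \code{tp}, \code{fp}, \code{tn}, \code{fn}.
#' @export
confusion_counts <- function(pred_mask, gt_mask) {
  if (!identical(dim(pred_mask), dim(gt_mask))) {
    stopf("mask shapes differ")
  }
  list(
    tp = sum(pred_mask & gt_mask),
    fp = sum(pred_mask & !gt_mask),
    tn = sum(!pred_mask & !gt_mask),
    fn = sum(!pred_mask & gt_mask)
  )
}

#' Segmentation-accuracy report from confusion counts
#'
#' Sensitivity \code{tp/(tp+fn)}, specificity \code{tn/(tn+fp)}, accuracy,
#' Dice similarity coefficient \code{2tp/(2tp+fp+fn)}, Matthews correlation
#' coefficient (0 when any marginal is empty), and the vessel volume
#' difference \code{|(tp+fp)-(tp+fn)|/(tp+fn)} relative to ground-truth
#' volume. With empty ground-truth foreground, SE, DSC and VVD are NaN.
#'
#' @param tp,fp,tn,fn Non-negative pixel counts.
#' @return Object of class \code{eval_report}.
#' @export
eval_metrics <- function(tp, fp, tn, fn) {
  tp <- as.numeric(tp)
  fp <- as.numeric(fp)
  tn <- as.numeric(tn)
  fn <- as.numeric(fn)
  total <- tp + fp + tn + fn
  gt_vol <- tp + fn
  se <- if (gt_vol > 0) tp / gt_vol else NaN
  sp <- if (tn + fp > 0) tn / (tn + fp) else NaN
  acc <- (tp + tn) / total
  dsc <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NaN
  if (gt_vol == 0) dsc <- NaN
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / sqrt(denom) else 0
  vvd <- if (gt_vol > 0) abs((tp + fp) - (tp + fn)) / gt_vol else NaN
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn, sensitivity = se,
         specificity = sp, accuracy = acc, dsc = dsc, mcc = mcc, vvd = vvd),
    class = "eval_report"
  )
}

#' Evaluate a predicted mask against ground truth
#'
#' @param pred_mask,gt_mask Logical matrices of equal shape.
#' @return An \code{eval_report}.
#' @export
eval_masks <- function(pred_mask, gt_mask) {
  cc <- confusion_counts(pred_mask, gt_mask)
  eval_metrics(cc$tp, cc$fp, cc$tn, cc$fn)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "Segmentation evaluation (tp %d, fp %d, tn %d, fn %d):\n",
    x$tp, x$fp, x$tn, x$fn))
  cat(sprintf(
    "  SE %.4f  SP %.4f  ACC %.4f  DSC %.4f  MCC %.4f  VVD %.4f\n",
    x$sensitivity, x$specificity, x$accuracy, x$dsc, x$mcc, x$vvd))
  invisible(x)
}

#' Within-subject standard deviation (Sw)
#'
#' Square root of the mean over subjects of the per-subject sample variance
#' (denominator n-1); for balanced tables this equals the square root of the
#' one-way ANOVA within-subject mean square.
#'
#' @param values Numeric matrix, rows = subjects, columns = repeats.
#' @return Sw, in the metric's units.
#' @export
within_subject_sd <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) < 1L) stopf("need at least one subject")
  if (any(rowSums(!is.na(values)) < 2L)) {
    stopf("every subject needs at least 2 repeats")
  }
  sqrt(mean(apply(values, 1L, stats::var, na.rm = TRUE)))
}

#' Coefficient of variation (percent)
#'
#' \code{100 * sw / overall_mean}; NaN when the overall mean is zero.
#'
#' @param sw Within-subject SD.
#' @param overall_mean Grand mean of the metric.
#' @return CoV in percent.
#' @export
coefficient_of_variation <- function(sw, overall_mean) {
  if (overall_mean == 0) return(NaN)
  100 * sw / overall_mean
}

#' One-way intraclass correlation ICC(1,1)
#'
#' One-way random-effects single-measurement ICC,
#' \code{(MSB - MSW) / (MSB + (k-1) MSW)}, from the between- and
#' within-subject mean squares of a balanced subjects x repeats table; the
#' standard reliability estimator for repeated scans of the same eye on the
#' same device. Can be slightly negative when within-variance dominates.
#' Returns NaN (with a warning) when all values are equal.
#'
#' @param values Numeric matrix, rows = subjects, columns = repeats.
#' @return ICC in [-1, 1], or NaN.
#' @export
intraclass_correlation <- function(values) {
  values <- as.matrix(values)
  n <- nrow(values)
  k <- ncol(values)
  if (n < 2L || k < 2L) stopf("need >= 2 subjects and >= 2 repeats")
  if (anyNA(values)) stopf("balanced complete table required")
  grand <- mean(values)
  if (all(values == values[1])) {
    warning("all values equal: ICC undefined")
    return(NaN)
  }
  subj_means <- rowMeans(values)
  msb <- k * sum((subj_means - grand)^2) / (n - 1)
  msw <- sum((values - subj_means)^2) / (n * (k - 1))
  (msb - msw) / (msb + (k - 1) * msw)
}

#' Repeatability report over a table of repeated metric measurements
#'
#' For each metric, computes the within-subject SD (Sw), the coefficient of
#' variation (CoV, percent of the grand mean) and the one-way ICC(1,1).
#'
#' @param metric_table Data frame in long layout with columns
#'   \code{subject}, \code{repeat} (or \code{rep}) and one numeric column
#'   per metric; or a 3-d array subjects x repeats x metrics.
#' @return Data frame with one row per metric: \code{metric}, \code{sw},
#'   \code{cov_pct}, \code{icc}, \code{n_subjects}, \code{n_repeats}.
#' @export
repeatability_report <- function(metric_table) {
  if (is.array(metric_table) && length(dim(metric_table)) == 3L) {
    mets <- dimnames(metric_table)[[3]]
    if (is.null(mets)) mets <- paste0("metric_", seq_len(dim(metric_table)[3]))
    tabs <- lapply(seq_len(dim(metric_table)[3]), function(i) {
      metric_table[, , i]
    })
    names(tabs) <- mets
  } else {
    df <- as.data.frame(metric_table)
    sub_col <- intersect(c("subject", "id"), names(df))[1]
    rep_col <- intersect(c("repeat.", "repeat", "rep"), names(df))[1]
    if (is.na(sub_col) || is.na(rep_col)) {
      stopf("long table needs 'subject' and 'repeat' columns")
    }
    mets <- setdiff(names(df), c(sub_col, rep_col))
    tabs <- lapply(mets, function(m) {
      wide <- stats::reshape(
        df[, c(sub_col, rep_col, m)],
        idvar = sub_col, timevar = rep_col, direction = "wide")
      as.matrix(wide[, -1, drop = FALSE])
    })
    names(tabs) <- mets
  }
  rows <- lapply(names(tabs), function(m) {
    v <- tabs[[m]]
    sw <- within_subject_sd(v)
    icc <- tryCatch(
      suppressWarnings(intraclass_correlation(v)),
      error = function(e) NaN)
    data.frame(metric = m, sw = sw,
               cov_pct = coefficient_of_variation(sw, mean(v)),
               icc = icc, n_subjects = nrow(v), n_repeats = ncol(v),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
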