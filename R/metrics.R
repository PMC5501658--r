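# Confusion-matrix statistics with the pathogenic class as positive.
# All metrics are computed over the variants for which a prediction
# exists (N_predicted), matching published evaluation tables where
# predictors with missing calls are scored on fewer than the full set.

#' Build a confusion matrix
#'
#' Positions where the call is missing (`NA`, "no prediction") are
#' excluded from the counts; `n_predicted` reports how many remain.
#'
#' @param truth true labels: `"pathogenic"`/`"neutral"`, +1/-1, or
#'   `"P"`/`"N"`.
#' @param calls predicted labels in the same vocabularies, `NA`
#'   allowed.
#' @return an object of class `confusion_matrix` with fields `tp`,
#'   `tn`, `fp`, `fn`, `n_predicted`.
#' @export
confusion <- function(truth, calls) {
  if (length(truth) != length(calls))
    validation_error("truth and calls must be aligned vectors")
  t_pos <- .as_positive(truth)
  c_pos <- .as_positive(calls)
  keep <- !is.na(c_pos) & !is.na(t_pos)
  t_pos <- t_pos[keep]; c_pos <- c_pos[keep]
  confusion_matrix(tp = sum(t_pos & c_pos), tn = sum(!t_pos & !c_pos),
                   fp = sum(!t_pos & c_pos), fn = sum(t_pos & !c_pos))
}

.as_positive <- function(x) {
  if (is.numeric(x)) return(ifelse(is.na(x), NA, x == -1))
  x <- as.character(x)
  out <- rep(NA, length(x))
  out[x %in% c("pathogenic", "P", "harmful")] <- TRUE
  out[x %in% c("neutral", "N", "harmless")] <- FALSE
  bad <- !is.na(x) & is.na(out)
  if (any(bad))
    validation_error(paste0("unrecognized label value(s): ",
                            paste(unique(x[bad]), collapse = ", ")))
  out
}

#' Construct a confusion matrix from counts
#'
#' @param tp,tn,fp,fn non-negative integer counts (pathogenic =
#'   positive class).
#' @return an object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != floor(counts)))
    validation_error("confusion counts must be non-negative integers")
  if (sum(counts) < 1)
    validation_error("at least one predicted instance required")
  structure(as.list(counts), n_predicted = sum(counts),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("confusion_matrix: TP %d TN %d FP %d FN %d (N predicted %d)\n",
              x$tp, x$tn, x$fp, x$fn, attr(x, "n_predicted")))
  invisible(x)
}

#' Evaluation statistics from a confusion matrix
#'
#' The seven statistics of the published evaluation table:
#' specificity TN/(FP+TN), sensitivity TP/(TP+FN), accuracy
#' (TP+TN)/N, precision TP/(TP+FP), FDR FP/(TP+FP) (the complement of
#' precision, not a multiple-testing quantity), Matthews correlation
#' coefficient, and the misclassification rate MCR = 100(FP+FN)/N,
#' all over the N predicted instances. A zero denominator yields `NaN`
#' (never an error), except the MCC denominator where the conventional
#' value 0 is returned. Full precision is retained; use
#' [round_half_up()] for display.
#'
#' @param cm a [confusion_matrix()].
#' @return an object of class `metrics_report` (a one-row data.frame
#'   with `specificity`, `sensitivity`, `accuracy`, `precision`,
#'   `fdr`, `mcc`, `mcr`, `n_predicted`).
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- as.numeric(cm$tp); tn <- as.numeric(cm$tn)
  fp <- as.numeric(cm$fp); fn <- as.numeric(cm$fn)
  n <- tp + tn + fp + fn
  div <- function(a, b) if (b > 0) a / b else NaN
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  out <- data.frame(
    specificity = div(tn, fp + tn),
    sensitivity = div(tp, tp + fn),
    accuracy = (tp + tn) / n,
    precision = div(tp, tp + fp),
    fdr = div(fp, tp + fp),
    mcc = if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den,
    mcr = 100 * (fp + fn) / n,
    n_predicted = as.integer(n))
  class(out) <- c("metrics_report", "data.frame")
  out
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the distinct probability values as decision thresholds
#' (pathogenic when probability >= threshold), returning the ordered
#' (FPR, TPR) points from (0, 0) to (1, 1) and the trapezoid-rule AUC.
#'
#' @param probabilities P(pathogenic), finite numeric vector.
#' @param truth true labels, both classes present.
#' @return data.frame with `threshold`, `fpr`, `tpr`; the AUC is in
#'   `attr(, "auc")`.
#' @export
roc_curve <- function(probabilities, truth) {
  if (length(probabilities) != length(truth))
    validation_error("probabilities and truth must be aligned")
  if (any(!is.finite(probabilities)))
    validation_error("probabilities must be finite")
  pos <- .as_positive(truth)
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0)
    apogee_error("ROC/AUC undefined with a single-class truth vector",
                 "apogee_undefined_auc_error")
  ord <- order(probabilities, decreasing = TRUE)
  p_sorted <- probabilities[ord]
  pos_sorted <- pos[ord]
  # collapse tied thresholds: step after the last instance of each value
  last_of_value <- c(diff(p_sorted) != 0, TRUE)
  tpr <- cumsum(pos_sorted)[last_of_value] / n_pos
  fpr <- cumsum(!pos_sorted)[last_of_value] / n_neg
  out <- data.frame(threshold = c(Inf, p_sorted[last_of_value]),
                    fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(out$fpr) * (utils::head(out$tpr, -1) +
                              utils::tail(out$tpr, -1)) / 2)
  attr(out, "auc") <- auc
  out
}

#' Pairwise concordance of two call vectors
#'
#' Fraction of positions where both predictors made a call and the
#' calls agree; positions with one-sided missingness only shrink the
#' denominator.
#'
#' @param calls_a,calls_b aligned call vectors (`NA` = no call).
#' @return agreement fraction in \[0, 1\], or `NaN` when no position
#'   is jointly called.
#' @export
pairwise_concordance <- function(calls_a, calls_b) {
  if (length(calls_a) != length(calls_b))
    validation_error("call vectors must be aligned")
  a <- .as_positive(calls_a); b <- .as_positive(calls_b)
  joint <- !is.na(a) & !is.na(b)
  if (!any(joint)) return(NaN)
  mean(a[joint] == b[joint])
}

#' Format metric reports as an evaluation table
#'
#' One row per classifier, mirroring the published column order, with
#' display rounding to two decimals.
#'
#' @param reports named list of [compute_metrics()] results (or
#'   `confusion_matrix` objects, which are converted).
#' @return data.frame ready for [utils::write.table()].
#' @export
metrics_table <- function(reports) {
  rows <- lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    if (inherits(r, "confusion_matrix")) r <- compute_metrics(r)
    data.frame(classifier = nm,
               specificity = round_half_up(r$specificity),
               sensitivity = round_half_up(r$sensitivity),
               accuracy = round_half_up(r$accuracy),
               precision = round_half_up(r$precision),
               fdr = round_half_up(r$fdr),
               mcc = round_half_up(r$mcc),
               mcr = round_half_up(r$mcr),
               n_predicted = r$n_predicted,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
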