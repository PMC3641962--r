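#' Confusion counts for binary substrate classification
#'
#' @param truth,pred Equal-length label vectors from the
#'   substrate/non-substrate vocabulary.
#' @param positive The positive class; default `"substrate"`.
#' @return Object of class `confusion_counts`: list with integer `tp`, `fn`,
#'   `tn`, `fp`.
#' @export
confusion_counts <- function(truth, pred, positive = LABEL_SUBSTRATE) {
  if (length(truth) == 0)
    stop("cannot compute confusion counts on empty input", call. = FALSE)
  if (length(truth) != length(pred))
    stop("truth and prediction differ in length", call. = FALSE)
  truth <- normalize_labels(truth)
  pred <- normalize_labels(pred)
  t_pos <- truth == positive
  p_pos <- pred == positive
  structure(list(tp = sum(t_pos & p_pos), fn = sum(t_pos & !p_pos),
                 tn = sum(!t_pos & !p_pos), fp = sum(!t_pos & p_pos)),
            class = "confusion_counts")
}

#' Performance metrics from confusion counts
#'
#' Computes the four standard metrics:
#' \deqn{ACC = 100 (TP+TN)/(TP+TN+FP+FN)}
#' \deqn{SE = 100\, TP/(TP+FN), \quad SP = 100\, TN/(FP+TN)}
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN) / \sqrt{(TP+FN)(TP+FP)(TN+FP)(TN+FN)}}
#' ACC, SE and SP are percentages in `[0, 100]`; MCC lies in `[-1, 1]`.
#' A zero denominator makes the corresponding metric undefined: it is
#' reported as `NA` (never silently coerced to 0); pass
#' `mcc_zero_convention = TRUE` to use the common MCC = 0 convention for
#' degenerate marginals.
#'
#' @param x A `confusion_counts` object, or the TP count when the four counts
#'   are given separately.
#' @param fn,tn,fp Remaining counts when `x` is given as TP.
#' @param mcc_zero_convention Report degenerate MCC as 0 instead of `NA`.
#' @return Object of class `performance_report`: counts plus `acc`, `se`,
#'   `sp` (percent) and `mcc`, at full precision.
#' @examples
#' performance(89, 15, 38, 25)  # ACC 76.0, SE 85.6, SP 60.3, MCC 0.478
#' @export
performance <- function(x, fn = NULL, tn = NULL, fp = NULL,
                        mcc_zero_convention = FALSE) {
  if (inherits(x, "confusion_counts")) {
    tp <- x$tp; fn <- x$fn; tn <- x$tn; fp <- x$fp
  } else {
    tp <- x
    if (is.null(fn) || is.null(tn) || is.null(fp))
      stop("provide a confusion_counts object or all four counts", call. = FALSE)
  }
  counts <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers", call. = FALSE)
  total <- sum(counts)
  if (total < 1) stop("confusion counts sum to zero", call. = FALSE)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  acc <- 100 * (tp + tn) / total
  se <- 100 * ratio(tp, tp + fn)
  sp <- 100 * ratio(tn, fp + tn)
  mcc_den_sq <- (tp + fn) * (tp + fp) * (tn + fp) * (tn + fn)
  mcc <- if (mcc_den_sq == 0) {
    if (mcc_zero_convention) 0 else NA_real_
  } else {
    (tp * tn - fp * fn) / sqrt(mcc_den_sq)
  }
  structure(list(tp = tp, fn = fn, tn = tn, fp = fp,
                 acc = acc, se = se, sp = sp, mcc = mcc),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  # display rounding: percentages to 1 decimal, MCC to 3 (raw values retained)
  fmt <- function(v, d) if (is.na(v)) "undef." else formatC(v, format = "f", digits = d)
  cat(sprintf("TP %d  FN %d  TN %d  FP %d | ACC %s  SE %s  SP %s  MCC %s\n",
              x$tp, x$fn, x$tn, x$fp,
              fmt(x$acc, 1), fmt(x$se, 1), fmt(x$sp, 1), fmt(x$mcc, 3)))
  invisible(x)
}

#' @export
as.data.frame.performance_report <- function(x, ...) {
  data.frame(tp = x$tp, fn = x$fn, tn = x$tn, fp = x$fp,
             acc = x$acc, se = x$se, sp = x$sp, mcc = x$mcc)
}

#' Evaluate predictions against truth
#'
#' Convenience wrapper: [confusion_counts()] followed by [performance()].
#'
#' @inheritParams confusion_counts
#' @return A `performance_report`.
#' @export
evaluate_predictions <- function(truth, pred, positive = LABEL_SUBSTRATE) {
  performance(confusion_counts(truth, pred, positive))
}

#' Classification overlap between two models' predictions
#'
#' Percentage of compounds identically predicted by two models over the same
#' compound set. Symmetric; 100 for identical vectors.
#'
#' @param pred_a,pred_b Equal-length label vectors over the same compounds
#'   (if both are named, names must match as sets and are aligned).
#' @return Percentage in `[0, 100]`.
#' @export
classification_overlap <- function(pred_a, pred_b) {
  if (length(pred_a) == 0)
    stop("cannot compute overlap on empty predictions", call. = FALSE)
  if (length(pred_a) != length(pred_b))
    stop("prediction vectors differ in length", call. = FALSE)
  if (!is.null(names(pred_a)) && !is.null(names(pred_b))) {
    if (!setequal(names(pred_a), names(pred_b)))
      stop("prediction vectors cover different compound sets", call. = FALSE)
    pred_b <- pred_b[names(pred_a)]
  }
  100 * mean(normalize_labels(pred_a) == normalize_labels(pred_b))
}
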