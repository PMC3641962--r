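#' F-score of a single feature
#'
#' Discrimination score of one descriptor between the positive (substrate)
#' and negative (non-substrate) classes:
#' \deqn{F = \frac{(\bar x^{+} - \bar x)^2 + (\bar x^{-} - \bar x)^2}
#'                {s^2_{+} + s^2_{-}}}
#' where \eqn{\bar x} is the pooled mean and \eqn{s^2_\pm} the within-class
#' sample variances (divisor n-1). The larger the F-score, the more
#' discriminative the feature. When both within-class variances are zero the
#' score is `Inf` if the class means differ (a perfect separator) and 0
#' otherwise.
#'
#' @param pos,neg Numeric values of the feature in each class, at least 2
#'   observations per class.
#' @return Non-negative F-score (possibly `Inf`).
#' @examples
#' f_score(c(2, 4), c(0, 2))  # 0.5
#' @export
f_score <- function(pos, neg) {
  if (length(pos) < 2 || length(neg) < 2)
    stop("f_score needs at least 2 observations per class", call. = FALSE)
  xbar <- mean(c(pos, neg))
  num <- (mean(pos) - xbar)^2 + (mean(neg) - xbar)^2
  den <- stats::var(pos) + stats::var(neg)
  if (den == 0) {
    if (num == 0) return(0)
    return(Inf)
  }
  num / den
}

#' Rank descriptors by F-score
#'
#' @param dm Numeric descriptor matrix (compounds x descriptors).
#' @param labels Class labels, named by compound id or aligned to the rows.
#' @param positive The positive class; default `"substrate"`.
#' @return Data frame with columns `descriptor` and `f_score`, sorted by
#'   descending score; ties broken lexicographically by descriptor name so
#'   the ranking is deterministic.
#' @export
rank_features <- function(dm, labels, positive = LABEL_SUBSTRATE) {
  check_matrix(dm)
  labels <- check_labels(labels, rownames(dm))
  is_pos <- labels == positive
  if (all(is_pos) || !any(is_pos))
    stop("both classes must be present to rank features", call. = FALSE)
  scores <- apply(dm, 2, function(col) f_score(col[is_pos], col[!is_pos]))
  out <- data.frame(descriptor = colnames(dm), f_score = unname(scores),
                    stringsAsFactors = FALSE)
  out[order(-out$f_score, out$descriptor), , drop = FALSE]
}

#' Prune correlated descriptors, keeping the higher F-score
#'
#' Single greedy pass in descending F-score order (ties lexicographic): each
#' candidate is compared against the already-retained descriptors and dropped
#' if its absolute Pearson correlation with any of them reaches
#' `r_threshold`. Among correlated descriptors, the one with the higher
#' F-score is therefore always the one kept.
#'
#' @param dm Numeric descriptor matrix.
#' @param scores Ranking from [rank_features()] covering all columns of `dm`.
#' @param r_threshold Absolute-correlation threshold; default 0.9.
#' @return List with `retained` (descriptor names in descending F-score
#'   order) and `pruned` (data frame: kept, dropped, correlation).
#' @export
prune_correlated <- function(dm, scores, r_threshold = 0.9) {
  check_matrix(dm)
  if (!all(colnames(dm) %in% scores$descriptor))
    stop("scores must cover every column of the matrix", call. = FALSE)
  sds <- apply(dm, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance column reached correlation pruning (filtering ",
         "contract violated): ", colnames(dm)[sds == 0][1], call. = FALSE)
  ord <- scores$descriptor[scores$descriptor %in% colnames(dm)]
  cm <- abs(stats::cor(dm))
  retained <- character(0)
  kept_v <- character(0); dropped_v <- character(0); corr_v <- numeric(0)
  for (cand in ord) {
    r_with_retained <- if (length(retained)) cm[cand, retained] else numeric(0)
    if (length(r_with_retained) && max(r_with_retained) >= r_threshold) {
      hit <- retained[which.max(r_with_retained)]
      kept_v <- c(kept_v, hit)
      dropped_v <- c(dropped_v, cand)
      corr_v <- c(corr_v, stats::cor(dm[, hit], dm[, cand]))
    } else {
      retained <- c(retained, cand)
    }
  }
  list(retained = retained,
       pruned = data.frame(kept = kept_v, dropped = dropped_v,
                           correlation = corr_v, stringsAsFactors = FALSE))
}

#' Greedy forward selection in F-score order
#'
#' Features are added one at a time in ranking order; after each addition the
#' `evaluate` callback reports validation accuracy for the current set. The
#' walk stops at the first strict decrease and the set before the decrease is
#' returned. The selected set never shrinks below one feature; if even the
#' first feature scores below the majority-class baseline this is flagged in
#' the trace rather than returning an empty model.
#'
#' @param ranked Character vector of candidate feature names in descending
#'   rank order.
#' @param evaluate Function taking a character vector of feature names and
#'   returning a validation accuracy (any consistent scale). Must be
#'   deterministic for reproducible selection.
#' @param baseline Optional accuracy of the trivial majority-class model, used
#'   only to flag a weak single-feature start.
#' @param max_features Cap on the number of addition steps; default all.
#' @param patience With the default `patience = 0`, the walk stops at the
#'   first strict decrease relative to the previous step (plateaus continue).
#'   With `patience = p >= 1`, it instead stops after `p` consecutive steps
#'   without a new accuracy maximum and returns the set at the first maximum
#'   — useful when validation accuracy saturates and plateaus indefinitely.
#' @return Object of class `selection_trace`: list with `selected` (feature
#'   names), `steps` (data frame: step, feature, accuracy), `stopped_early`
#'   (logical) and `below_baseline` (logical flag).
#' @export
greedy_forward_selection <- function(ranked, evaluate, baseline = NULL,
                                     max_features = length(ranked),
                                     patience = 0) {
  stopifnot(length(ranked) >= 1, patience >= 0)
  kmax <- min(length(ranked), max_features)
  acc <- numeric(0)
  stopped <- FALSE
  k_best <- 1L
  for (k in seq_len(kmax)) {
    a <- evaluate(ranked[seq_len(k)])
    if (!is.numeric(a) || length(a) != 1 || is.na(a))
      stop("evaluator returned a non-numeric accuracy for feature set of size ",
           k, call. = FALSE)
    acc <- c(acc, a)
    if (a > acc[k_best] + 1e-12) k_best <- k
    if (patience == 0) {
      if (k > 1 && acc[k] < acc[k - 1]) {
        stopped <- TRUE
        break
      }
    } else if (k - k_best >= patience) {
      stopped <- TRUE
      break
    }
  }
  n_sel <- if (patience > 0) k_best
           else if (stopped) length(acc) - 1L
           else length(acc)
  structure(list(
    selected = ranked[seq_len(n_sel)],
    steps = data.frame(step = seq_along(acc),
                       feature = ranked[seq_along(acc)],
                       accuracy = acc),
    stopped_early = stopped,
    below_baseline = !is.null(baseline) && acc[1] < baseline),
    class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("<selection_trace> %d feature(s) selected%s%s\n",
              length(x$selected),
              if (x$stopped_early) " (stopped at first accuracy decrease)" else "",
              if (isTRUE(x$below_baseline)) " [first feature below baseline]" else ""))
  print(x$steps, row.names = FALSE)
  invisible(x)
}

#' Serialize a selection trace to delimited text
#'
#' @param trace A `selection_trace`.
#' @param path Output path (tab-separated: step, feature, accuracy).
#' @return Invisibly, `path`.
#' @export
write_selection_trace <- function(trace, path) {
  utils::write.table(trace$steps, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
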