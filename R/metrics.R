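#' Tally a confusion matrix from truth and prediction labels
#'
#' @param truth,predicted vectors of equal length; coerced to character.
#' @param positive the label counted as positive (default `"cleavage"`).
#' @return List with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(truth, predicted, positive = "cleavage") {
  truth <- as.character(truth); predicted <- as.character(predicted)
  stopifnot(length(truth) == length(predicted))
  tpos <- truth == positive
  ppos <- predicted == positive
  list(tp = sum(tpos & ppos), fp = sum(!tpos & ppos),
       tn = sum(!tpos & !ppos), fn = sum(tpos & !ppos))
}

#' Classification performance: Sn, Sp, Ac, MCC
#'
#' Sensitivity `100 * TP / (TP + FN)`, specificity `100 * TN / (TN + FP)`,
#' accuracy `100 * (TP + TN) / total`, and the Matthews correlation
#' coefficient `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' A metric whose denominator is zero is reported as `NA` (never silently
#' zeroed) and listed in the `undefined` element.
#'
#' @param cc list with `tp`, `fp`, `tn`, `fn` (e.g. from
#'   [confusion_counts()]), or the `tp` count if the four counts are given
#'   separately.
#' @param fp,tn,fn individual counts when `cc` is the `tp` count.
#' @return Object of class `"dicer_metrics"`: list with `sn`, `sp`, `ac`
#'   (percentages), `mcc`, the four counts, and `undefined` (character
#'   vector of metrics with zero denominators).
#' @examples
#' compute_metrics(list(tp = 3, fp = 1, tn = 4, fn = 2))
#' @export
compute_metrics <- function(cc, fp = NULL, tn = NULL, fn = NULL) {
  if (!is.list(cc)) cc <- list(tp = cc, fp = fp, tn = tn, fn = fn)
  stopifnot(all(c("tp", "fp", "tn", "fn") %in% names(cc)))
  tp <- cc$tp; fp <- cc$fp; tn <- cc$tn; fn <- cc$fn
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0, tp + fp + tn + fn > 0)
  undefined <- character(0)
  sn <- if (tp + fn > 0) 100 * tp / (tp + fn) else { undefined <- c(undefined, "sn"); NA_real_ }
  sp <- if (tn + fp > 0) 100 * tn / (tn + fp) else { undefined <- c(undefined, "sp"); NA_real_ }
  ac <- 100 * (tp + tn) / (tp + fp + tn + fn)
  denom <- prod(c(tp + fp, tp + fn, tn + fp, tn + fn))
  mcc <- if (denom > 0) (tp * tn - fp * fn) / sqrt(denom) else { undefined <- c(undefined, "mcc"); NA_real_ }
  structure(list(sn = sn, sp = sp, ac = ac, mcc = mcc,
                 tp = tp, fp = fp, tn = tn, fn = fn, undefined = undefined),
            class = "dicer_metrics")
}

#' @export
print.dicer_metrics <- function(x, ...) {
  cat(sprintf("Sn %.2f%%  Sp %.2f%%  Ac %.2f%%  MCC %.3f  (tp %d fp %d tn %d fn %d)\n",
              x$sn, x$sp, x$ac, x$mcc, x$tp, x$fp, x$tn, x$fn))
  if (length(x$undefined)) {
    cat(" undefined (zero denominator):", paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Area under the ROC curve by the rank formulation
#'
#' Equals the probability that a random positive scores above a random
#' negative, counting ties as one half — identical to the trapezoidal area
#' under the empirical ROC curve, and invariant under strictly monotone
#' transforms of the scores.
#'
#' @param scores numeric scores, higher = more positive-like.
#' @param labels vector of labels, same length.
#' @param positive the positive label (default `"cleavage"`).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels, positive = "cleavage") {
  labels <- as.character(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores))
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    stop("roc_auc requires both classes to be present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Balance a dataset by subsampling the negative class
#'
#' Keeps every positive and draws `length(pos)` negatives without
#' replacement, deterministically for a given seed.
#'
#' @param pos,neg vectors (typically row indices) of positive and negative
#'   items; requires `length(neg) >= length(pos)`.
#' @param seed integer RNG seed.
#' @return List with `pos` (unchanged) and `neg` (the subsample).
#' @export
balanced_subsample <- function(pos, neg, seed = 1) {
  if (length(neg) < length(pos)) {
    stop("fewer negatives than positives; cannot balance", call. = FALSE)
  }
  keep <- with_seed(seed, sample(seq_along(neg), length(pos)))
  list(pos = pos, neg = neg[sort(keep)])
}

# Evaluate expr under a temporary RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}
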