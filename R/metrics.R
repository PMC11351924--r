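#' Confusion matrix with a fixed label set
#'
#' Rows are truth, columns prediction, in the order of `labels`.
#'
#' @param truth,pred vectors of the same length.
#' @param labels ordered category labels; values outside it are an error.
#' @return An integer matrix of class `table`-like counts.
#' @export
confusion_matrix <- function(truth, pred, labels = sort(unique(c(truth, pred)))) {
  stopifnot(length(truth) == length(pred))
  if (!all(truth %in% labels) || !all(pred %in% labels))
    stop("values outside the label set")
  t <- factor(truth, levels = labels)
  p <- factor(pred, levels = labels)
  unclass(table(truth = t, pred = p))
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement \eqn{(p_0 - p_e) / (1 - p_e)}, where
#' \eqn{p_0} is the observed agreement (trace over total) and \eqn{p_e}
#' the agreement expected from the marginals,
#' \eqn{p_e = \sum_k n_{k.} n_{.k} / n^2}.  Unweighted; categories are
#' treated as nominal.
#'
#' @param cm square count matrix, rows truth, columns prediction.
#' @return Kappa in [-1, 1]; `NA` with a warning when \eqn{p_e = 1}
#'   (all mass in a single category, agreement is undefined).
#' @export
kappa_statistic <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm), all(cm >= 0))
  n <- sum(cm)
  if (n == 0) stop("empty confusion matrix")
  p0 <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (abs(1 - pe) < 1e-12) {
    warning("kappa undefined: expected agreement is 1 (single category)")
    return(NA_real_)
  }
  (p0 - pe) / (1 - pe)
}

#' Binary classification rates from counts
#'
#' Accuracy (TP+TN)/(TP+TN+FP+FN), sensitivity TP/(TP+FN), specificity
#' TN/(TN+FP), precision TP/(TP+FP), and F1 = 2 * precision *
#' sensitivity / (precision + sensitivity).  A metric whose denominator
#' is zero is returned as `NA` without invalidating the others.
#'
#' @param tp,tn,fp,fn non-negative counts; alternatively pass a 2x2
#'   confusion matrix as `cm` with rows/cols ordered (negative, positive).
#' @param cm optional 2x2 matrix, rows truth, columns prediction.
#' @return Named list: `accuracy`, `sensitivity`, `specificity`,
#'   `precision`, `f1`.
#' @export
binary_rates <- function(tp = NULL, tn = NULL, fp = NULL, fn = NULL, cm = NULL) {
  if (!is.null(cm)) {
    cm <- as.matrix(cm)
    stopifnot(all(dim(cm) == 2))
    tn <- cm[1, 1]; fp <- cm[1, 2]; fn <- cm[2, 1]; tp <- cm[2, 2]
  }
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0, tp + tn + fp + fn > 0)
  sdiv <- function(num, den) if (den == 0) NA_real_ else num / den
  acc <- (tp + tn) / (tp + tn + fp + fn)
  sens <- sdiv(tp, tp + fn)
  spec <- sdiv(tn, tn + fp)
  prec <- sdiv(tp, tp + fp)
  f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) NA_real_
  else 2 * prec * sens / (prec + sens)
  list(accuracy = acc, sensitivity = sens, specificity = spec,
       precision = prec, f1 = f1)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps all distinct score thresholds (ties grouped), accumulating
#' (FPR, TPR) points, and integrates by the trapezoid rule.  This equals
#' the Mann-Whitney rank statistic
#' \eqn{\Pr(s_+ > s_-) + \tfrac12 \Pr(s_+ = s_-)} exactly.
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels binary truth (logical, or 0/1).
#' @return List with `auc` and a data frame `roc` of columns
#'   `threshold`, `fpr`, `tpr`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0 || nn == 0) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  grp <- cumsum(!duplicated(s))
  tp <- tapply(y, grp, sum)
  fp <- tapply(!y, grp, sum)
  tpr <- c(0, cumsum(tp)) / np
  fpr <- c(0, cumsum(fp)) / nn
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(auc = as.numeric(auc),
       roc = data.frame(threshold = c(Inf, s[!duplicated(s)]),
                        fpr = as.numeric(fpr), tpr = as.numeric(tpr)))
}

#' Bootstrap confidence interval for AUC
#'
#' Stratified percentile bootstrap: positives and negatives are resampled
#' with replacement within class (so each replicate retains both classes),
#' AUC recomputed per replicate, and the 2.5/97.5 percentiles reported.
#' Deterministic given `seed`.
#'
#' @param scores,labels as in [roc_auc()].
#' @param reps number of bootstrap replicates (>= 200).
#' @param seed integer RNG seed.
#' @param level confidence level.
#' @return Numeric vector `c(low, high)`.
#' @export
auc_ci <- function(scores, labels, reps = 2000, seed = 1, level = 0.95) {
  labels <- as.logical(labels)
  stopifnot(reps >= 200)
  pos <- which(labels); neg <- which(!labels)
  if (length(pos) == 0 || length(neg) == 0) stop("both classes must be present")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  vals <- vapply(seq_len(reps), function(i) {
    ip <- sample(pos, length(pos), replace = TRUE)
    ineg <- sample(neg, length(neg), replace = TRUE)
    idx <- c(ip, ineg)
    roc_auc(scores[idx], labels[idx])$auc
  }, numeric(1))
  a <- (1 - level) / 2
  stats::quantile(vals, c(a, 1 - a), names = FALSE, type = 7)
}

#' Specificity with recall fixed at 1
#'
#' For screening, the operating threshold is lowered until every true
#' severe case is captured (sensitivity 1); the reported number is the
#' specificity that remains at that threshold: the fraction of negatives
#' scoring strictly below the minimum positive score.
#'
#' @param scores,labels as in [roc_auc()].
#' @return Specificity in [0, 1] at the full-recall threshold.
#' @export
specificity_at_full_recall <- function(scores, labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) stop("both classes must be present")
  thr <- min(scores[labels])
  mean(scores[!labels] < thr)
}

#' Full metrics report for a binary task
#'
#' @param truth logical truth; `pred` logical predictions; `scores`
#'   optional continuous scores for ROC/AUC (defaults to `pred`).
#' @param reps,seed bootstrap settings for the AUC interval.
#' @return List with the binary rates, `auc`, `auc_ci`,
#'   `specificity_at_full_recall` and `n`.
#' @export
metrics_report <- function(truth, pred, scores = NULL, reps = 2000, seed = 1) {
  truth <- as.logical(truth); pred <- as.logical(pred)
  if (is.null(scores)) scores <- as.numeric(pred)
  cm <- confusion_matrix(truth, pred, labels = c(FALSE, TRUE))
  rates <- binary_rates(cm = cm)
  both <- any(truth) && !all(truth)
  ra <- if (both) roc_auc(scores, truth) else NULL
  c(rates,
    list(auc = if (both) ra$auc else NA_real_,
         auc_ci = if (both) auc_ci(scores, truth, reps = reps, seed = seed)
         else c(NA_real_, NA_real_),
         specificity_at_full_recall =
           if (both) specificity_at_full_recall(scores, truth) else NA_real_,
         confusion = cm, n = length(truth)))
}
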