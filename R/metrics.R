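# Evaluation indexes: per-label AUC and F1, plus the multi-label ranking
# metrics (Hamming distance, one-error, ranking loss, coverage) and the
# sensitivity/specificity/precision panel for risk-level evaluation.

#' Rank-based AUC
#'
#' Mann-Whitney AUC of a score column against binary labels; tied scores
#' contribute half credit.
#'
#' @param scores Numeric score vector.
#' @param labels Binary (0/1 or logical) relevance vector.
#' @return AUC in `[0, 1]`.
#' @export
metric_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' F1 over binary label matrices
#'
#' Macro: per-label F1 = 2TP / (2TP + FP + FN) averaged over labels;
#' labels with no positives in either matrix carry no information and are
#' excluded from the average (all excluded means the matrices agree
#' everywhere, F1 = 1).  Micro: F1 from globally pooled counts; 0 when
#' the pooled denominator is 0 and a mismatch exists.
#'
#' @param pred,truth Binary matrices (or vectors) of identical shape.
#' @param average `"macro"` or `"micro"`.
#' @return F1 in `[0, 1]`.
#' @export
metric_f1 <- function(pred, truth, average = c("macro", "micro")) {
  average <- match.arg(average)
  if (!is.matrix(pred)) pred <- matrix(pred, ncol = 1L)
  if (!is.matrix(truth)) truth <- matrix(truth, ncol = 1L)
  stopifnot(all(dim(pred) == dim(truth)))
  pred <- pred != 0; truth <- truth != 0
  if (average == "micro") {
    tp <- sum(pred & truth); fp <- sum(pred & !truth); fn <- sum(!pred & truth)
    den <- 2 * tp + fp + fn
    return(if (den == 0) 1 else 2 * tp / den)
  }
  f1s <- vapply(seq_len(ncol(pred)), function(j) {
    tp <- sum(pred[, j] & truth[, j]); fp <- sum(pred[, j] & !truth[, j])
    fn <- sum(!pred[, j] & truth[, j])
    den <- 2 * tp + fp + fn
    if (den == 0) NA_real_ else 2 * tp / den
  }, numeric(1))
  if (all(is.na(f1s))) 1 else mean(f1s, na.rm = TRUE)
}

#' Hamming distance
#'
#' Fraction of label slots where prediction and truth disagree.
#'
#' @inheritParams metric_f1
#' @return Value in `[0, 1]`.
#' @export
hamming_distance <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  mean((pred != 0) != (truth != 0))
}

check_score_shape <- function(scores, truth) {
  if (!is.matrix(scores)) scores <- matrix(scores, nrow = 1L)
  if (!is.matrix(truth)) truth <- matrix(truth, nrow = 1L)
  stopifnot(all(dim(scores) == dim(truth)))
  list(scores = scores, truth = truth != 0)
}

#' One-error
#'
#' Fraction of samples whose top-scored label is not relevant.  Samples
#' with no relevant label are excluded with a warning.
#'
#' @param scores Numeric matrix `n x L`.
#' @param truth Binary matrix `n x L`.
#' @return Value in `[0, 1]`.
#' @export
one_error <- function(scores, truth) {
  z <- check_score_shape(scores, truth)
  valid <- rowSums(z$truth) > 0
  if (!all(valid)) warning(sum(!valid), " sample(s) with no relevant label excluded")
  if (!any(valid)) stop("one-error undefined: no sample has a relevant label")
  miss <- vapply(which(valid), function(i) {
    top <- which.max(z$scores[i, ])
    !z$truth[i, top]
  }, logical(1))
  mean(miss)
}

#' Label ranking loss
#'
#' Mean over samples of the fraction of (relevant, irrelevant) label
#' pairs ranked incorrectly; ties count half.  Samples lacking either a
#' relevant or an irrelevant label are excluded with a warning.
#'
#' @inheritParams one_error
#' @return Value in `[0, 1]`.
#' @export
ranking_loss <- function(scores, truth) {
  z <- check_score_shape(scores, truth)
  valid <- rowSums(z$truth) > 0 & rowSums(!z$truth) > 0
  if (!all(valid)) warning(sum(!valid), " degenerate sample(s) excluded")
  if (!any(valid)) stop("ranking loss undefined on this input")
  per <- vapply(which(valid), function(i) {
    s_rel <- z$scores[i, z$truth[i, ]]
    s_irr <- z$scores[i, !z$truth[i, ]]
    cmp <- outer(s_rel, s_irr, function(a, b) (a < b) + 0.5 * (a == b))
    mean(cmp)
  }, numeric(1))
  mean(per)
}

#' Coverage
#'
#' Mean over samples of (rank of the worst-ranked relevant label - 1),
#' ranks 1-based by descending score; a tied label's rank is the count of
#' labels scoring at least as high.  `normalized = TRUE` divides by the
#' number of labels L, giving a value in `[0, 1)`.
#'
#' @inheritParams one_error
#' @param normalized Divide by L?
#' @return Value in `[0, L - 1]` (raw) or `[0, 1)` (normalized).
#' @export
coverage <- function(scores, truth, normalized = FALSE) {
  z <- check_score_shape(scores, truth)
  valid <- rowSums(z$truth) > 0
  if (!all(valid)) warning(sum(!valid), " sample(s) with no relevant label excluded")
  if (!any(valid)) stop("coverage undefined: no sample has a relevant label")
  per <- vapply(which(valid), function(i) {
    s <- z$scores[i, ]
    worst <- min(s[z$truth[i, ]])
    sum(s >= worst) - 1
  }, numeric(1))
  out <- mean(per)
  if (normalized) out / ncol(z$scores) else out
}

#' Sensitivity, specificity and precision of a binary prediction
#'
#' `TP/(TP+FN)`, `TN/(TN+FP)`, `TP/(TP+FP)`; a ratio with zero
#' denominator is reported as `NA`.
#'
#' @param pred,truth Logical vectors.
#' @return Named list `sensitivity`, `specificity`, `precision`.
#' @export
binary_panel <- function(pred, truth) {
  pred <- as.logical(pred); truth <- as.logical(truth)
  stopifnot(length(pred) == length(truth), length(pred) > 0)
  tp <- sum(pred & truth); tn <- sum(!pred & !truth)
  fp <- sum(pred & !truth); fn <- sum(!pred & truth)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  list(sensitivity = ratio(tp, tp + fn),
       specificity = ratio(tn, tn + fp),
       precision = ratio(tp, tp + fp))
}

#' Multi-label metric report
#'
#' Computes the full index panel over a score matrix, a thresholded (or
#' argmax-derived) prediction matrix and the truth matrix, in the
#' conventional column order AUC, HD, RL, Cov, OE, F1.
#'
#' @param scores `n x L` score matrix.
#' @param pred `n x L` binary prediction matrix.
#' @param truth `n x L` binary truth matrix.
#' @param f1_average Passed to [metric_f1()].
#' @param cov_normalized Passed to [coverage()].
#' @return Named list of the six metrics (`auc` is the mean of per-label
#'   AUCs over labels where both outcomes occur; `NA` if none).
#' @export
metric_report <- function(scores, pred, truth, f1_average = "macro",
                          cov_normalized = FALSE) {
  aucs <- vapply(seq_len(ncol(truth)), function(j) {
    lab <- truth[, j] != 0
    if (all(lab) || !any(lab)) return(NA_real_)
    metric_auc(scores[, j], lab)
  }, numeric(1))
  list(auc = if (all(is.na(aucs))) NA_real_ else mean(aucs, na.rm = TRUE),
       hd = hamming_distance(pred, truth),
       rl = ranking_loss(scores, truth),
       cov = coverage(scores, truth, normalized = cov_normalized),
       oe = one_error(scores, truth),
       f1 = metric_f1(pred, truth, average = f1_average))
}
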