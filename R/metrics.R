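# Evaluation metrics: ROC and precision-recall curves, AUC as the
# Mann-Whitney probability (ties counted 1/2), step-sum average precision,
# top-fraction lift, and Kruskal-Wallis with an eta-squared effect size.
# Thresholds sit between distinct score values only, so tied scores enter a
# curve as a single point.

check_scored_labels <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  if (anyNA(scores)) stop("scores contain NA", call. = FALSE)
  labels
}

#' ROC curve and area under it
#'
#' AUC equals the probability that a random positive outscores a random
#' negative, with ties counted 1/2 (the Mann-Whitney statistic). The curve is
#' evaluated at thresholds between distinct score values and runs monotonely
#' from (0,0) to (1,1).
#'
#' @param scores numeric vector; higher = more positive.
#' @param labels binary vector (1 = positive).
#' @return list with `fpr`, `tpr` (curve points) and `auc`.
#' @export
roc_curve_auc <- function(scores, labels) {
  labels <- check_scored_labels(scores, labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores) # midranks: ties counted 1/2
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  l <- labels[o]
  last <- cumsum(rle(s)$lengths) # one point per distinct score
  tp <- cumsum(l)[last]
  fp <- (last - cumsum(l)[last])
  list(
    fpr = c(0, fp / n0, 1),
    tpr = c(0, tp / n1, 1),
    auc = auc
  )
}

#' Precision-recall curve and average precision
#'
#' Average precision is the interpolation-free step sum
#' `AP = sum_i (R_i - R_{i-1}) P_i` over thresholds at distinct score values
#' in descending order; tied scores are grouped at one threshold.
#'
#' @inheritParams roc_curve_auc
#' @return list with `recall`, `precision` (curve points) and
#'   `average_precision`.
#' @export
pr_curve_ap <- function(scores, labels) {
  labels <- check_scored_labels(scores, labels)
  n1 <- sum(labels == 1L)
  if (n1 == 0) stop("no positive instances", call. = FALSE)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  l <- labels[o]
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(l)[last]
  prec <- tp / last
  rec <- tp / n1
  ap <- sum(diff(c(0, rec)) * prec)
  list(recall = rec, precision = prec, average_precision = ap)
}

#' Positives captured in the top fraction of scores
#'
#' Counts positives among the top `ceiling(fraction * n)` scores; ties are
#' broken by stable input order.
#'
#' @inheritParams roc_curve_auc
#' @param fraction fraction of the ranking to inspect, in (0, 1].
#' @return list with `captured` (count) and `capture_rate`
#'   (captured / total positives).
#' @export
lift_topk <- function(scores, labels, fraction) {
  labels <- check_scored_labels(scores, labels)
  stopifnot(fraction > 0, fraction <= 1)
  k <- ceiling(fraction * length(scores))
  top <- order(-scores)[seq_len(k)] # order() is stable: input order breaks ties
  captured <- sum(labels[top])
  list(captured = captured, capture_rate = captured / sum(labels))
}

#' Kruskal-Wallis test with eta-squared effect size
#'
#' H is the tie-corrected rank statistic with a chi-square approximation on
#' k - 1 degrees of freedom; the effect size is the rank-based estimator
#' `eta2 = (H - k + 1) / (n - k)`, clipped to \[0, 1\].
#'
#' @param values numeric vector.
#' @param groups categorical vector parallel to `values`.
#' @return list with `H`, `p`, `eta2`, `k`, `n`.
#' @export
kruskal_wallis_eta2 <- function(values, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) == 0)) stop("empty group", call. = FALSE)
  kt <- stats::kruskal.test(values, groups)
  k <- nlevels(groups)
  n <- length(values)
  h <- unname(kt$statistic)
  list(
    H = h,
    p = kt$p.value,
    eta2 = min(max((h - k + 1) / (n - k), 0), 1),
    k = k,
    n = n
  )
}

#' Apply benchmark exclusion filters to a scored peptide table
#'
#' Removes recorded non-immunogenic peptides that have a positive
#' immunogenicity assay elsewhere: they are neither trustworthy negatives nor
#' part of the positive set, so they leave the evaluation entirely.
#'
#' @param table data.frame with columns `peptide` and `label` (1 = immunogenic).
#' @param positive_elsewhere character vector of peptides with positive assays
#'   in other sources.
#' @return the filtered data.frame.
#' @export
filter_benchmark_peptides <- function(table, positive_elsewhere = character()) {
  stopifnot(all(c("peptide", "label") %in% names(table)))
  drop <- table$label == 0L & table$peptide %in% positive_elsewhere
  table[!drop, , drop = FALSE]
}
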