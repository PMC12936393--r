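#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with midrank tie handling: the probability
#' that a random positive scores above a random negative, counting ties as
#' one half.
#'
#' @param labels 0/1 vector.
#' @param scores Numeric scores (any monotone scale).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' True skill statistic and true positive rate at a threshold
#'
#' Predicted positive iff `score > threshold` (a score exactly at the
#' threshold is predicted negative). `tss = tpr + tnr - 1`. The maximum TSS
#' over all score thresholds is reported as a secondary value.
#'
#' @param labels 0/1 vector.
#' @param scores Scores in any order.
#' @param threshold Classification threshold (default 0.5).
#' @return List: `tss`, `tpr`, `tnr`, `max_tss`, `max_tss_threshold`,
#'   `threshold`.
#' @export
tss_tpr <- function(labels, scores, threshold = 0.5) {
  stopifnot(length(labels) == length(scores))
  pos <- labels == 1
  pred <- scores > threshold
  tpr <- if (any(pos)) sum(pred & pos) / sum(pos) else NA_real_
  tnr <- if (any(!pos)) sum(!pred & !pos) / sum(!pos) else NA_real_
  # max-TSS sweep over the distinct scores as candidate thresholds
  ths <- sort(unique(scores))
  best <- -Inf; best_th <- threshold
  for (th in ths) {
    pr <- scores > th
    v <- sum(pr & pos) / sum(pos) + sum(!pr & !pos) / sum(!pos) - 1
    if (v > best) { best <- v; best_th <- th }
  }
  list(tss = tpr + tnr - 1, tpr = tpr, tnr = tnr,
       max_tss = best, max_tss_threshold = best_th, threshold = threshold)
}

#' Percent deviance explained under the Bernoulli likelihood
#'
#' `(D_null - D_model) / D_null` with
#' `D(p) = -2 * sum(y log p + (1 - y) log(1 - p))`; the null model predicts
#' the evaluation set's own label mean. Scores exactly 0 or 1 are clipped
#' with a warning.
#'
#' @param labels 0/1 vector.
#' @param scores Probabilities in (0, 1).
#' @return Value in `(-Inf, 1]`; 0 for the null predictor.
#' @export
deviance_explained <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  if (any(scores <= 0 | scores >= 1)) {
    warning("scores at 0 or 1 clipped")
    scores <- pmin(pmax(scores, 1e-12), 1 - 1e-12)
  }
  ybar <- mean(labels)
  ybar <- pmin(pmax(ybar, 1e-12), 1 - 1e-12)
  dev <- function(p) -2 * sum(labels * log(p) + (1 - labels) * log(1 - p))
  d_null <- dev(rep(ybar, length(labels)))
  if (d_null == 0) return(0)
  (d_null - dev(scores)) / d_null
}

#' Combined metric report
#' @param labels 0/1 vector.
#' @param scores Probabilities.
#' @param threshold Confusion threshold (default 0.5, the suitability
#'   cutoff).
#' @return List: `auc`, `tss`, `tpr`, `tnr`, `max_tss`,
#'   `deviance_explained`, `threshold`, `n`.
#' @export
metric_report <- function(labels, scores, threshold = 0.5) {
  tt <- tss_tpr(labels, scores, threshold)
  list(auc = auc(labels, scores), tss = tt$tss, tpr = tt$tpr, tnr = tt$tnr,
       max_tss = tt$max_tss,
       deviance_explained = deviance_explained(labels, scores),
       threshold = threshold, n = length(labels))
}
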