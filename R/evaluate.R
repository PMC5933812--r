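#' ROC curve and area under the curve
#'
#' Builds the ROC curve of a score against binary labels (higher score =
#' more introgression-like) by sweeping thresholds over the observed
#' scores, and integrates it by the trapezoid rule.
#'
#' @param scores numeric vector (for the classifier, 1 minus the posterior
#'   probability of no introgression).
#' @param labels logical or 0/1 vector: `TRUE`/1 for windows simulated with
#'   introgression.
#' @return list with `roc` (data.frame of fpr, tpr) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (all(labels) || !any(labels)) stop("need both classes in labels")
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  s <- scores[ord]
  n <- length(s)
  tpr <- c(0, cumsum(lab) / sum(lab))
  fpr <- c(0, cumsum(!lab) / sum(!lab))
  ## one ROC point per distinct threshold (tied scores collapse, so tie
  ## groups contribute diagonal segments, matching the rank statistic)
  keep <- c(TRUE, if (n > 1) s[-n] != s[-1], TRUE)
  tpr <- tpr[keep]; fpr <- fpr[keep]
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Single-statistic outlier classifier (d_min / G_min baseline)
#'
#' Calibrates a detection threshold as the lower `alpha` tail of a
#' statistic's distribution under complete isolation (fixing the false
#' positive rate at `alpha`), then classifies test windows as introgressed
#' when the statistic falls below the threshold.
#'
#' @param null_values statistic values on no-migration simulations.
#' @param alpha lower-tail false positive rate (default 0.05).
#' @return list with `threshold` and function `classify(values)` returning
#'   logical calls.
#' @export
single_stat_classifier <- function(null_values, alpha = 0.05) {
  threshold <- unname(stats::quantile(null_values, alpha, type = 1))
  list(threshold = threshold,
       classify = function(values) values < threshold)
}

#' Sensitivity and direction accuracy over the (T_M, P_M) grid
#'
#' @param calls data.frame from [predict.introscan_model()] on test
#'   examples.
#' @param truth data.frame with columns `tm`, `pm`, `label` for the same
#'   examples (introgression direction labels `mig12`/`mig21`).
#' @return data.frame per (tm, pm) cell: replicate count `n`, `sensitivity`
#'   (fraction called introgressed), `direction_correct` (fraction called
#'   with the true direction), and binomial standard errors.
#' @export
sensitivity_grid <- function(calls, truth) {
  stopifnot(nrow(calls) == nrow(truth))
  cell <- interaction(truth$tm, truth$pm, drop = TRUE)
  out <- do.call(rbind, lapply(split(seq_len(nrow(truth)), cell), function(i) {
    sens <- mean(calls$call[i])
    dirc <- mean(calls$call[i] &
                   !is.na(calls$direction[i]) &
                   calls$direction[i] == truth$label[i])
    data.frame(tm = truth$tm[i[1]], pm = truth$pm[i[1]], n = length(i),
               sensitivity = sens, direction_correct = dirc,
               se = sqrt(sens * (1 - sens) / length(i)))
  }))
  rownames(out) <- NULL
  out[order(out$tm, out$pm), , drop = FALSE]
}

#' False positive rate on a no-migration test set
#'
#' @param model an `introscan_model`.
#' @param null_features feature table of no-migration simulations.
#' @param cutoff posterior cutoff on the no-introgression class.
#' @return fraction of null windows called introgressed.
#' @export
false_positive_rate <- function(model, null_features, cutoff = NULL) {
  pred <- stats::predict(model, null_features, cutoff = cutoff)
  mean(pred$call)
}

#' Base-pair-level accuracy of predicted introgressed intervals
#'
#' @param predicted interval matrix/data.frame of predicted introgressed
#'   regions (bp, 0-based half-open).
#' @param truth interval matrix of truly introgressed tracts.
#' @param contig_length contig length in bp.
#' @return list with `sensitivity` (`|pred & truth| / |truth|`), `fpr`
#'   (`|pred \ truth| / |contig \ truth|`), and `ppv`
#'   (`|pred & truth| / |pred|`, reported as 0 when nothing is predicted);
#'   components are `NA` when their denominator is empty (no truth for
#'   sensitivity).
#' @export
bp_metrics <- function(predicted, truth, contig_length) {
  pred <- ivl_normalize(predicted)
  tr <- ivl_normalize(truth)
  tp <- ivl_length(ivl_intersect(pred, tr))
  fp <- ivl_length(ivl_subtract(pred, tr))
  truth_len <- ivl_length(tr)
  neg_len <- contig_length - truth_len
  list(sensitivity = if (truth_len > 0) tp / truth_len else NA_real_,
       fpr = if (neg_len > 0) fp / neg_len else NA_real_,
       ppv = if (ivl_length(pred) > 0) tp / ivl_length(pred) else 0)
}

#' Aggregate base-pair metrics over many contigs
#'
#' Pools true/false positive base counts over replicates before forming
#' rates (the aggregate convention for summing over a simulation grid).
#'
#' @param results list of lists with elements `predicted`, `truth`
#'   (interval sets) and `contig_length`.
#' @return list with pooled `sensitivity`, `fpr`, `ppv`.
#' @export
aggregate_bp_metrics <- function(results) {
  tp <- fp <- truth_len <- neg_len <- pred_len <- 0
  for (r in results) {
    pred <- ivl_normalize(r$predicted)
    tr <- ivl_normalize(r$truth)
    tp <- tp + ivl_length(ivl_intersect(pred, tr))
    fp <- fp + ivl_length(ivl_subtract(pred, tr))
    truth_len <- truth_len + ivl_length(tr)
    neg_len <- neg_len + r$contig_length - ivl_length(tr)
    pred_len <- pred_len + ivl_length(pred)
  }
  list(sensitivity = if (truth_len > 0) tp / truth_len else NA_real_,
       fpr = if (neg_len > 0) fp / neg_len else NA_real_,
       ppv = if (pred_len > 0) tp / pred_len else 0)
}
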