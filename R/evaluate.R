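# Classification metrics, rank-based ROC-AUC, step-wise PR-AUC, percentile
# bootstrap confidence intervals (1000 replicates, 95%) and paired bootstrap
# significance tests on shared resample indices.

#' Prediction set
#'
#' @param scores Predicted abnormal probabilities in `[0, 1]`.
#' @param labels Binary ground truth (0 normal, 1 abnormal).
#' @param threshold Decision cutoff (default 0.5; score >= threshold is
#'   called abnormal).
#' @param ids Optional sample identifiers.
#' @return Object of class `prediction_set`.
#' @export
prediction_set <- function(scores, labels, threshold = 0.5, ids = NULL) {
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]")
  if (any(!labels %in% c(0, 1))) stop("labels must be 0/1")
  structure(list(scores = as.numeric(scores), labels = as.integer(labels),
                 threshold = threshold, ids = ids),
            class = "prediction_set")
}

#' Confusion counts at the decision threshold
#'
#' TP: abnormal correctly called abnormal; TN: normal correctly called
#' normal; FP: normal called abnormal; FN: abnormal called normal.
#'
#' @param preds A [prediction_set()].
#' @return Named list with integer `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(preds) {
  if (length(preds$scores) == 0) stop("empty prediction set")
  pred <- as.integer(preds$scores >= preds$threshold)
  y <- preds$labels
  list(TP = sum(pred == 1 & y == 1), TN = sum(pred == 0 & y == 0),
       FP = sum(pred == 1 & y == 0), FN = sum(pred == 0 & y == 1))
}

#' Threshold metrics from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, recall `TP/(TP+FN)`, precision
#' `TP/(TP+FP)`, and F1 as the harmonic mean of precision and recall.
#' Degenerate zero denominators yield `NA` (flagged undefined) rather than a
#' silent zero.
#'
#' @param c Confusion counts from [confusion()].
#' @return Named numeric vector `(accuracy, recall, precision, f1)`.
#' @export
basic_metrics <- function(c) {
  total <- c$TP + c$TN + c$FP + c$FN
  if (total == 0) stop("no evaluated samples")
  acc <- (c$TP + c$TN) / total
  rec <- if (c$TP + c$FN > 0) c$TP / (c$TP + c$FN) else NA_real_
  prec <- if (c$TP + c$FP > 0) c$TP / (c$TP + c$FP) else NA_real_
  f1 <- if (!is.na(rec) && !is.na(prec) && (prec + rec) > 0)
    2 * prec * rec / (prec + rec) else NA_real_
  c(accuracy = acc, recall = rec, precision = prec, f1 = f1)
}

#' ROC-AUC via the rank statistic
#'
#' Mann-Whitney U normalization with average ranks for ties: a perfect
#' classifier scores 1, a random one 0.5.
#'
#' @param preds A [prediction_set()] containing both classes.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(preds) {
  y <- preds$labels
  n1 <- as.numeric(sum(y == 1)); n0 <- as.numeric(sum(y == 0))
  if (n1 == 0 || n0 == 0) stop("ROC-AUC needs both classes present")
  r <- rank(preds$scores)  # average ranks for ties
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' Precision-recall AUC (step-wise summation)
#'
#' Area under the precision-recall curve by summing precision over recall
#' increments at every distinct score threshold (average-precision form,
#' no trapezoids).
#'
#' @param preds A [prediction_set()] with at least one positive.
#' @return PR-AUC in `[0, 1]`.
#' @export
prc_auc <- function(preds) {
  y <- preds$labels
  n1 <- sum(y == 1)
  if (n1 == 0) stop("PR-AUC needs at least one positive sample")
  ord <- order(preds$scores, decreasing = TRUE)
  s <- preds$scores[ord]; y <- y[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  # evaluate at the last index of each tie group (distinct thresholds)
  last <- which(!duplicated(s, fromLast = TRUE))
  tp <- tp[last]; fp <- fp[last]
  recall <- tp / n1
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

metric_value <- function(preds, metric) {
  switch(metric,
         accuracy = basic_metrics(confusion(preds))[["accuracy"]],
         recall = basic_metrics(confusion(preds))[["recall"]],
         precision = basic_metrics(confusion(preds))[["precision"]],
         f1 = basic_metrics(confusion(preds))[["f1"]],
         roc_auc = roc_auc(preds),
         prc_auc = prc_auc(preds),
         stop("unknown metric: ", metric))
}

resample_preds <- function(preds, idx)
  prediction_set(preds$scores[idx], preds$labels[idx], preds$threshold)

# metric over B seeded bootstrap replicates; NA replicates tracked
bootstrap_replicates <- function(preds, metric, B, seed) {
  n <- length(preds$scores)
  with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(metric_value(resample_preds(preds, idx), metric),
               error = function(e) NA_real_)
    }, numeric(1))
  })
}

# Percentile interval endpoints as order statistics of the replicate sample.
# The upper index mirrors the lower (B + 1 - lo), so negating the replicates
# exactly negates and swaps the interval.
percentile_ci <- function(reps, alpha) {
  r <- sort(reps[!is.na(reps)])
  B <- length(r)
  lo_idx <- min(max(1L, ceiling(B * alpha / 2)), B)
  c(r[lo_idx], r[B + 1L - lo_idx])
}

#' Percentile bootstrap confidence interval for a metric
#'
#' Non-parametric bootstrap: resample indices with replacement, recompute the
#' metric per replicate, take the `alpha/2` and `1 - alpha/2` order statistics.
#'
#' @param preds A [prediction_set()].
#' @param metric One of `"accuracy"`, `"recall"`, `"precision"`, `"f1"`,
#'   `"roc_auc"`, `"prc_auc"`.
#' @param B Replicates (default 1000).
#' @param alpha Interval level complement (default 0.05 for 95%).
#' @param seed Resampling seed.
#' @return Named vector `(point, low, high)`; aborts if the metric is
#'   undefined on more than half of the replicates.
#' @export
bootstrap_ci <- function(preds, metric, B = 1000L, alpha = 0.05, seed = 1L) {
  if (B < 1) stop("B must be >= 1")
  reps <- bootstrap_replicates(preds, metric, B, seed)
  if (mean(is.na(reps)) > 0.5)
    stop(sprintf("metric '%s' undefined on %.0f%% of replicates", metric,
                 100 * mean(is.na(reps))))
  ci <- percentile_ci(reps, alpha)
  c(point = metric_value(preds, metric), low = ci[1], high = ci[2])
}

#' Paired bootstrap significance test
#'
#' Evaluates two prediction sets on the *same* resampled indices per
#' replicate, forms the metric-difference distribution
#' \eqn{\Delta m = m_A - m_B}, and reports the two-sided p-value
#' \eqn{p = 2\min\{\Pr(\Delta m \le 0), \Pr(\Delta m \ge 0)\}} with each tail
#' probability floored at `1/B` (so p lies in `(1/B, 1]`), plus the 95%
#' percentile interval of the difference.
#'
#' @param predsA,predsB [prediction_set()]s over identical samples (same
#'   labels, same order).
#' @param metric Metric name as in [bootstrap_ci()].
#' @param B Replicates.
#' @param alpha CI level complement.
#' @param seed Resampling seed.
#' @return List with `delta_point`, `delta_ci`, `p_value`, `B`.
#' @export
paired_bootstrap_test <- function(predsA, predsB, metric, B = 1000L,
                                  alpha = 0.05, seed = 1L) {
  if (length(predsA$scores) != length(predsB$scores) ||
      any(predsA$labels != predsB$labels))
    stop("paired test requires identical samples and labels")
  n <- length(predsA$scores)
  delta <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      metric_value(resample_preds(predsA, idx), metric) -
        metric_value(resample_preds(predsB, idx), metric)
    }, numeric(1))
  })
  p_le <- max(mean(delta <= 0, na.rm = TRUE), 1 / B)
  p_ge <- max(mean(delta >= 0, na.rm = TRUE), 1 / B)
  p <- min(1, 2 * min(p_le, p_ge))
  list(delta_point = metric_value(predsA, metric) - metric_value(predsB, metric),
       delta_ci = percentile_ci(delta, alpha), p_value = p, B = B)
}

#' Metric report with bootstrap intervals
#'
#' Point estimates and 95% percentile bootstrap intervals for accuracy,
#' recall, precision, F1, ROC-AUC and PR-AUC, plus confusion counts and
#' class-wise recalls.
#'
#' @param preds A [prediction_set()].
#' @param B Bootstrap replicates.
#' @param alpha Interval level complement.
#' @param seed Resampling seed.
#' @return Object of class `metric_report`: data frame `metrics`
#'   (metric, point, low, high), `confusion`, `class_recall` (normal and
#'   abnormal), `B`.
#' @export
metric_report <- function(preds, B = 1000L, alpha = 0.05, seed = 1L) {
  metrics <- c("accuracy", "recall", "precision", "f1", "roc_auc", "prc_auc")
  rows <- lapply(metrics, function(m)
    as.list(bootstrap_ci(preds, m, B, alpha, seed)))
  df <- data.frame(metric = metrics,
                   point = vapply(rows, `[[`, numeric(1), "point"),
                   low = vapply(rows, `[[`, numeric(1), "low"),
                   high = vapply(rows, `[[`, numeric(1), "high"))
  cm <- confusion(preds)
  class_recall <- c(
    normal = if (cm$TN + cm$FP > 0) cm$TN / (cm$TN + cm$FP) else NA_real_,
    abnormal = if (cm$TP + cm$FN > 0) cm$TP / (cm$TP + cm$FN) else NA_real_)
  structure(list(metrics = df, confusion = cm, class_recall = class_recall,
                 B = B), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> B = %d bootstrap replicates\n", x$B))
  df <- x$metrics
  for (k in seq_len(nrow(df)))
    cat(sprintf("  %-9s %.4f [%.4f, %.4f]\n", df$metric[k], df$point[k],
                df$low[k], df$high[k]))
  cat(sprintf("  confusion TP=%d TN=%d FP=%d FN=%d | class recall: normal %.4f, abnormal %.4f\n",
              x$confusion$TP, x$confusion$TN, x$confusion$FP, x$confusion$FN,
              x$class_recall[["normal"]], x$class_recall[["abnormal"]]))
  invisible(x)
}

#' Full evaluation report across model variants
#'
#' Renders per-variant metric reports and pairwise significance rows (first
#' variant against each other variant), optionally writing CSV/JSON files.
#'
#' @param preds_by_variant Named list of [prediction_set()]s on identical
#'   test samples.
#' @param B Bootstrap replicates.
#' @param seed Resampling seed.
#' @param out_dir Optional output directory for `metrics.csv`,
#'   `pairwise.csv`, `confusion.csv` and `report.json`.
#' @return List with `reports` (per variant), `pairwise` data frame, and the
#'   reference variant name.
#' @export
full_report <- function(preds_by_variant, B = 1000L, seed = 1L, out_dir = NULL) {
  stopifnot(length(preds_by_variant) >= 1, !is.null(names(preds_by_variant)))
  reports <- lapply(preds_by_variant, metric_report, B = B, seed = seed)
  ref <- names(preds_by_variant)[1]
  pairwise <- NULL
  if (length(preds_by_variant) > 1) {
    rows <- list()
    for (v in names(preds_by_variant)[-1]) {
      for (m in c("f1", "roc_auc", "prc_auc")) {
        tt <- paired_bootstrap_test(preds_by_variant[[ref]],
                                    preds_by_variant[[v]], m, B, seed = seed)
        rows[[length(rows) + 1]] <- data.frame(
          comparison = sprintf("%s vs %s", ref, v), metric = m,
          delta = tt$delta_point, ci_low = tt$delta_ci[1],
          ci_high = tt$delta_ci[2], p_value = tt$p_value)
      }
    }
    pairwise <- do.call(rbind, rows)
  }
  out <- list(reports = reports, pairwise = pairwise, reference = ref)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    met <- do.call(rbind, lapply(names(reports), function(v)
      cbind(variant = v, reports[[v]]$metrics)))
    write.csv(met, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    cms <- do.call(rbind, lapply(names(reports), function(v)
      data.frame(variant = v, as.data.frame(reports[[v]]$confusion))))
    write.csv(cms, file.path(out_dir, "confusion.csv"), row.names = FALSE)
    if (!is.null(pairwise))
      write.csv(pairwise, file.path(out_dir, "pairwise.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(metrics = met, pairwise = pairwise, reference = ref),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}
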