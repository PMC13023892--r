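test_that("confusion counts follow the abnormal-positive convention", {
  p <- prediction_set(c(0.9, 0.8, 0.7, 0.1, 0.2), c(1, 1, 1, 0, 0))
  cm <- confusion(p)
  expect_identical(cm, list(TP = 3L, TN = 2L, FP = 0L, FN = 0L))
  # flipping the labels (predictions fixed) swaps TP<->FP and TN<->FN
  pf <- prediction_set(p$scores, 1 - p$labels)
  cmf <- confusion(pf)
  expect_identical(cmf$TP, cm$FP)
  expect_identical(cmf$FP, cm$TP)
  expect_identical(cmf$TN, cm$FN)
  expect_identical(cmf$FN, cm$TN)
  # brute-force tally oracle on 100 random pairs
  set.seed(20)
  sc <- runif(100); y <- rbinom(100, 1, 0.4)
  cm2 <- confusion(prediction_set(sc, y))
  pred <- ifelse(sc >= 0.5, 1L, 0L)
  expect_identical(cm2$TP, sum(pred == 1 & y == 1))
  expect_identical(cm2$TN, sum(pred == 0 & y == 0))
  expect_identical(cm2$FP, sum(pred == 1 & y == 0))
  expect_identical(cm2$FN, sum(pred == 0 & y == 1))
  expect_error(confusion(prediction_set(numeric(0), integer(0))), "empty")
})

test_that("threshold metrics match hand arithmetic and flag degeneracies", {
  bm <- basic_metrics(list(TP = 39L, TN = 58L, FP = 2L, FN = 1L))
  expect_equal(bm[["accuracy"]], 0.97)
  expect_equal(bm[["recall"]], 0.975)
  expect_equal(bm[["precision"]], 39 / 41)
  expect_equal(bm[["f1"]], 2 * (39 / 41) * 0.975 / (39 / 41 + 0.975),
               tolerance = 1e-12)
  # perfect classifier
  expect_equal(unname(basic_metrics(list(TP = 5L, TN = 5L, FP = 0L, FN = 0L))),
               rep(1, 4))
  # degenerate: no predicted positives -> precision flagged NA, recall 0
  deg <- basic_metrics(list(TP = 0L, TN = 3L, FP = 0L, FN = 2L))
  expect_true(is.na(deg[["precision"]]))
  expect_equal(deg[["recall"]], 0)
  # F1 equals the 2TP/(2TP+FP+FN) identity on random counts
  set.seed(21)
  for (k in 1:20) {
    c4 <- as.list(rmultinom(1, 200, c(.3, .4, .15, .15))[, 1])
    names(c4) <- c("TP", "TN", "FP", "FN")
    if (c4$TP == 0) next
    bm <- basic_metrics(c4)
    expect_equal(bm[["f1"]], 2 * c4$TP / (2 * c4$TP + c4$FP + c4$FN),
                 tolerance = 1e-12)
  }
})

test_that("rank-based ROC-AUC matches its reference behavior", {
  # perfect separation
  expect_equal(roc_auc(prediction_set(c(.9, .8, .2, .1), c(1, 1, 0, 0))), 1.0)
  # all scores tied -> 0.5 exactly under average ranks
  expect_equal(roc_auc(prediction_set(rep(0.5, 10), rep(c(0, 1), 5))), 0.5)
  # invariance under strictly monotone transforms
  set.seed(22)
  sc <- runif(200); y <- rbinom(200, 1, 0.5)
  expect_equal(roc_auc(prediction_set(sc, y)),
               roc_auc(prediction_set(plogis(5 * sc - 2), y)), tolerance = 1e-12)
  # independent cross-check against pROC
  skip_if_not_installed("pROC")
  auc_ref <- as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE,
                                            direction = "<")))
  expect_equal(roc_auc(prediction_set(sc, y)), auc_ref, tolerance = 1e-10)
  expect_error(roc_auc(prediction_set(sc, rep(1, 200))), "both classes")
})

test_that("PR-AUC agrees with an exhaustive threshold sweep", {
  expect_equal(prc_auc(prediction_set(c(.9, .8, .2, .1), c(1, 1, 0, 0))), 1.0)
  # brute-force oracle: step-wise sum over every distinct threshold
  pr_brute <- function(sc, y) {
    ths <- sort(unique(sc), decreasing = TRUE)
    n1 <- sum(y)
    r_prev <- 0; area <- 0
    for (th in ths) {
      pred <- sc >= th
      tp <- sum(pred & y == 1); fp <- sum(pred & y == 0)
      r <- tp / n1; p <- tp / (tp + fp)
      area <- area + (r - r_prev) * p
      r_prev <- r
    }
    area
  }
  set.seed(23)
  for (k in 1:5) {
    sc <- round(runif(50), 2)  # induce ties
    y <- rbinom(50, 1, 0.4)
    if (sum(y) == 0) next
    expect_equal(prc_auc(prediction_set(sc, y)), pr_brute(sc, y),
                 tolerance = 1e-10)
  }
  expect_error(prc_auc(prediction_set(c(.1, .2), c(0, 0))), "positive")
})

test_that("bootstrap CIs are seeded order statistics of the replicates", {
  # constant metric: zero-width interval at 1
  perfect <- prediction_set(c(rep(0.9, 10), rep(0.1, 10)),
                            c(rep(1, 10), rep(0, 10)))
  ci <- bootstrap_ci(perfect, "accuracy", B = 200, seed = 4)
  expect_equal(unname(ci), c(1, 1, 1))
  # determinism
  set.seed(24)
  sc <- runif(80); y <- rbinom(80, 1, 0.5)
  p <- prediction_set(sc, y)
  expect_identical(bootstrap_ci(p, "f1", B = 100, seed = 9),
                   bootstrap_ci(p, "f1", B = 100, seed = 9))
  # endpoints are order statistics of the replicate sample at small B
  nn <- asNamespace("mwstroke")
  reps <- nn$bootstrap_replicates(p, "accuracy", B = 25, seed = 5)
  ci2 <- bootstrap_ci(p, "accuracy", B = 25, seed = 5)
  expect_true(ci2[["low"]] %in% reps)
  expect_true(ci2[["high"]] %in% reps)
  expect_lte(ci2[["low"]], ci2[["high"]])
})

test_that("paired bootstrap test honors its symmetry and clipping rules", {
  set.seed(25)
  sc <- runif(60); y <- rbinom(60, 1, 0.5)
  A <- prediction_set(sc, y)
  # identical predictions: every replicate difference is zero, p clips to 1
  t0 <- paired_bootstrap_test(A, A, "accuracy", B = 200, seed = 2)
  expect_equal(t0$delta_point, 0)
  expect_equal(t0$p_value, 1)
  # strict one-sided dominance: p = 2/B
  Bad <- prediction_set(1 - y, y)     # wrong on every sample
  Good <- prediction_set(y, y)        # right on every sample
  t1 <- paired_bootstrap_test(Good, Bad, "accuracy", B = 500, seed = 3)
  expect_equal(t1$p_value, 2 / 500)
  expect_equal(t1$delta_point, 1)
  # antisymmetry under swapping A and B
  B2 <- prediction_set(pmin(pmax(sc + 0.2 * (y - 0.5), 0), 1), y)
  ta <- paired_bootstrap_test(A, B2, "f1", B = 300, seed = 6)
  tb <- paired_bootstrap_test(B2, A, "f1", B = 300, seed = 6)
  expect_equal(ta$delta_point, -tb$delta_point, tolerance = 1e-12)
  expect_equal(sort(ta$delta_ci), sort(-tb$delta_ci), tolerance = 1e-12)
  expect_equal(ta$p_value, tb$p_value, tolerance = 1e-12)
  expect_error(paired_bootstrap_test(A, prediction_set(sc[1:10], y[1:10]),
                                     "accuracy"), "identical")
})

test_that("full report is internally consistent and deterministic", {
  set.seed(26)
  y <- rbinom(100, 1, 0.5)
  good <- prediction_set(pmin(pmax(y + rnorm(100, sd = 0.3), 0), 1), y)
  weak <- prediction_set(pmin(pmax(y + rnorm(100, sd = 0.8), 0), 1), y)
  rep1 <- full_report(list(fused = good, baseline = weak), B = 100, seed = 1)
  expect_named(rep1$reports, c("fused", "baseline"))
  # class-wise recalls for both classes
  expect_named(rep1$reports$fused$class_recall, c("normal", "abnormal"))
  # report metrics equal basic_metrics recomputed from stored confusion
  bm <- basic_metrics(rep1$reports$fused$confusion)
  df <- rep1$reports$fused$metrics
  expect_equal(df$point[df$metric == "accuracy"], bm[["accuracy"]])
  expect_equal(df$point[df$metric == "f1"], bm[["f1"]])
  # pairwise rows exist with p-values in (0, 1]
  expect_true(all(rep1$pairwise$p_value > 0 & rep1$pairwise$p_value <= 1))
  rep2 <- full_report(list(fused = good, baseline = weak), B = 100, seed = 1)
  expect_identical(rep1$pairwise, rep2$pairwise)
  # file outputs
  od <- tempfile("report")
  full_report(list(fused = good), B = 50, seed = 1, out_dir = od)
  expect_true(file.exists(file.path(od, "metrics.csv")))
  expect_true(file.exists(file.path(od, "report.json")))
})
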