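test_that("stratified folds deviate from perfect stratification by at most 1", {
  f1 <- stratified_folds(c(rep(1, 10), rep(0, 10)), k = 10, seed = 1)
  tab1 <- table(f1, c(rep(1, 10), rep(0, 10)))
  expect_true(all(tab1 == 1))

  lab2 <- c(rep(1, 7), rep(0, 70))
  f2 <- stratified_folds(lab2, k = 7, seed = 2)
  tab2 <- table(f2, lab2)
  expect_true(all(tab2[, "1"] == 1))
  expect_true(all(tab2[, "0"] == 10))

  # the human-scale bookkeeping: 1406 positives over 10 folds -> 140 or 141
  lab3 <- c(rep(1, 1406), rep(0, 81228))
  f3 <- stratified_folds(lab3, k = 10, seed = 3)
  pos_per_fold <- table(f3[lab3 == 1])
  expect_true(all(pos_per_fold %in% c(140, 141)))
  neg_per_fold <- table(f3[lab3 == 0])
  expect_true(all(neg_per_fold %in% c(8122, 8123)))

  expect_error(stratified_folds(c(1, 1, 0, 0, 0), k = 3, seed = 1), "smaller k")
  expect_identical(stratified_folds(lab2, 7, seed = 9),
                   stratified_folds(lab2, 7, seed = 9))
})

test_that("a leaked perfect feature saturates the pipeline at Gm = 100", {
  d <- gauss_problem(12, 60, seed = 5)
  d$f1 <- as.numeric(d$label)   # leak
  ev <- evaluate_pipeline(d[, c("id", "label", "f1")], identity_trainer(),
                          k_outer = 3, k1 = 3, seed = 1)
  expect_equal(ev$metrics$gm, 100)
  expect_equal(ev$metrics$se, 100)
  expect_equal(ev$metrics$sp, 100)
})

test_that("threshold selection beats the default threshold on imbalanced data", {
  d <- gauss_problem(30, 600, delta = 2, seed = 12)
  tr <- rf_trainer(ntree = 25)
  iv <- evaluate_pipeline(d, tr, k_outer = 3, k1 = 5, seed = 2,
                          threshold = "roc_select")
  iii <- evaluate_pipeline(d, tr, k_outer = 3, k1 = 5, seed = 2,
                           threshold = "default")
  expect_gt(iv$metrics$gm, iii$metrics$gm)
  # aggregated confusion counts sum to the dataset size
  expect_equal(sum(iv$folds$tp + iv$folds$fp + iv$folds$tn + iv$folds$fn),
               nrow(d))
})

test_that("aggregated metrics are invariant to instance order", {
  d <- gauss_problem(15, 90, seed = 20)
  ev1 <- evaluate_pipeline(d, rf_trainer(ntree = 15), k_outer = 3, k1 = 3, seed = 4)
  set.seed(1)
  ev2 <- evaluate_pipeline(d[sample.int(nrow(d)), ], rf_trainer(ntree = 15),
                           k_outer = 3, k1 = 3, seed = 4)
  expect_equal(ev1$metrics, ev2$metrics)
  expect_equal(ev1$folds, ev2$folds)
})

test_that("macro averaging is available and differs in general", {
  d <- gauss_problem(12, 60, delta = 1, seed = 30)
  evmi <- evaluate_pipeline(d, rf_trainer(ntree = 15), k_outer = 3, k1 = 3,
                            seed = 5, averaging = "micro")
  evma <- evaluate_pipeline(d, rf_trainer(ntree = 15), k_outer = 3, k1 = 3,
                            seed = 5, averaging = "macro")
  expect_equal(evma$metrics$se, mean(evma$folds$se))
  expect_true(is.finite(evmi$metrics$gm) && is.finite(evma$metrics$gm))
})

test_that("Friedman/Nemenyi reproduce the published classifier ordering", {
  bm <- mirhunt_benchmarks()$classification
  main <- c("naive_bayes", "perceptron", "svm", "random_forest")
  keep <- (bm$classifier %in% main & bm$variant == "IV") |
    (bm$classifier %in% c("aplsc", "smote_svm") & bm$variant == "III")
  tab <- tidyr::pivot_wider(bm[keep & bm$dataset != "microPred",
                               c("dataset", "classifier", "gm")],
                            names_from = "classifier", values_from = "gm")
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab$dataset
  fr <- friedman_nemenyi(m, alpha = 0.05)
  expect_equal(names(fr$avg_ranks)[1], "random_forest")
  expect_equal(names(fr$avg_ranks)[length(fr$avg_ranks)], "smote_svm")
  expect_equal(unname(fr$avg_ranks["random_forest"]), 1.9)
  expect_equal(unname(fr$avg_ranks["smote_svm"]), 5.4)
  # closed-form critical difference for k = 6, N = 5 at alpha = 0.05
  expect_equal(fr$cd, 2.850 * sqrt(42 / 30), tolerance = 1e-12)
  expect_equal(fr$cd, 3.37, tolerance = 0.002)
})

test_that("Friedman statistic matches the reference implementation", {
  set.seed(77)
  m <- matrix(rnorm(28), nrow = 7, ncol = 4,
              dimnames = list(NULL, paste0("m", 1:4)))
  fr <- friedman_nemenyi(m)
  ref <- stats::friedman.test(m)
  expect_equal(fr$statistic, unname(ref$statistic))
  expect_equal(fr$p_value, unname(ref$p.value))
  # rank bookkeeping: average ranks sum to k(k+1)/2 per construction
  expect_equal(sum(fr$avg_ranks), 4 * 5 / 2)
  # identical columns -> all average ranks (k+1)/2
  same <- matrix(rep(c(1, 2, 3), 4), ncol = 4,
                 dimnames = list(NULL, paste0("m", 1:4)))
  expect_true(all(friedman_nemenyi(same)$avg_ranks == 2.5))
  expect_error(friedman_nemenyi(matrix(c(1, NA, 2, 3), 2)), "finite")
})

test_that("paired Wilcoxon: exact small-sample p-values and antisymmetry", {
  r <- wilcoxon_paired(c(2, 3, 4, 5, 6), c(1, 2, 3, 4, 5) - c(0, .1, .2, .3, .4))
  expect_equal(r$statistic, 15)
  expect_equal(r$p_value, 0.0625)   # 2 / 2^5, the extreme permutation
  expect_equal(r$method, "exact")

  # hand-computed mixed-sign case: d = (1, 2, 3, -4, 5), V = 1+2+3+5 = 11,
  # P(W >= 11) = #subsets of {1..5} summing <= 4 / 32 = 7/32
  r2 <- wilcoxon_paired(c(2, 4, 6, 0, 10), c(1, 2, 3, 4, 5))
  expect_equal(r2$statistic, 11)
  expect_equal(r2$p_value, 14 / 32)

  x <- c(5, 1, 7, 2, 9, 4)
  y <- c(4, 3, 2, 8, 1, 6)
  expect_equal(wilcoxon_paired(x, y)$statistic + wilcoxon_paired(y, x)$statistic,
               6 * 7 / 2)
  expect_equal(wilcoxon_paired(x, y)$p_value, wilcoxon_paired(y, x)$p_value)
  expect_error(wilcoxon_paired(c(1, 2), c(1, 2)), "degenerate")
})

test_that("Wilcoxon agrees with the reference implementation", {
  set.seed(14)
  x <- rnorm(12)
  y <- rnorm(12)
  mine <- wilcoxon_paired(x, y)
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
  expect_equal(mine$statistic, unname(ref$statistic))
  expect_equal(mine$p_value, unname(ref$p.value))
  # large-sample normal approximation stays close to the exact reference
  set.seed(15)
  x2 <- rnorm(40)
  y2 <- rnorm(40)
  mine2 <- wilcoxon_paired(x2, y2)
  ref2 <- stats::wilcox.test(x2, y2, paired = TRUE, exact = FALSE,
                             correct = FALSE)
  expect_equal(mine2$p_value, unname(ref2$p.value), tolerance = 1e-6)
})
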