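test_that("pooled scores are a partition scored out-of-fold", {
  d <- gauss_problem(20, 60, seed = 4)
  ps <- pooled_scores(d, identity_trainer(), k1 = 5, seed = 1)
  expect_equal(nrow(ps), nrow(d))
  expect_setequal(ps$id, d$id)
  expect_error(pooled_scores(d, identity_trainer(), k1 = 25, seed = 1), "smaller k")
  # a trainer that leaks the true label separates perfectly
  d2 <- d
  d2$f1 <- as.numeric(d2$label)
  ps2 <- pooled_scores(d2, identity_trainer(col = 1), k1 = 5, seed = 1)
  expect_true(min(ps2$score[ps2$label == 1]) > max(ps2$score[ps2$label == 0]))
})

test_that("pooled-score AUC matches the closed form for two Gaussians", {
  # single feature ~ N(delta, 1) vs N(0, 1); identity trainer passes the
  # feature through, so pooled AUC ~ Phi(delta / sqrt(2))
  delta <- 1.5
  d <- gauss_problem(4000, 4000, delta = delta, seed = 10)[, c("id", "label", "f1")]
  ps <- pooled_scores(d, identity_trainer(), k1 = 5, seed = 2)
  auc <- {
    r <- rank(ps$score)
    n1 <- sum(ps$label == 1)
    n0 <- sum(ps$label == 0)
    (sum(r[ps$label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  expect_equal(auc, pnorm(delta / sqrt(2)), tolerance = 0.02)
})

test_that("the ROC curve enumerates exactly the achievable operating points", {
  r1 <- roc_curve_points(tibble::tibble(score = c(1, 0), label = c(1, 0)))
  expect_setequal(round(r1$gm, 6), c(0, 100))
  expect_equal(select_threshold(r1)$threshold, 1)
  expect_equal(select_threshold(r1)$gm, 100)

  r2 <- roc_curve_points(tibble::tibble(score = c(.9, .8, .7, .6),
                                        label = c(1, 0, 1, 0)))
  expect_equal(nrow(r2), 5)
  bf <- brute_force_best(c(.9, .8, .7, .6), c(1, 0, 1, 0))
  expect_equal(max(r2$gm), bf$best)

  r3 <- roc_curve_points(tibble::tibble(score = rep(0.4, 6),
                                        label = c(1, 1, 0, 0, 0, 0)))
  expect_equal(nrow(r3), 2)   # all-positive and all-negative only

  expect_error(roc_curve_points(tibble::tibble(score = 1:3, label = c(1, 1, 1))),
               "both classes")
})

test_that("threshold selection maximises the metric with the stated tie-break", {
  r <- roc_curve_points(tibble::tibble(score = c(.9, .8, .7, .6),
                                       label = c(1, 0, 1, 0)))
  sel <- select_threshold(r)
  expect_equal(sel$threshold, 0.7)       # highest-sensitivity maximiser
  expect_equal(sel$gm, sqrt(100 * 50), tolerance = 1e-12)
  # sensitivity-only metric degenerates to classify-all-positive
  sel_se <- select_threshold(r, metric = metric_se)
  expect_equal(sel_se$threshold, 0.6)    # lowest threshold: everything >= T
  expect_equal(sel_se$se, 100)
})

test_that("ROC-select equals the exhaustive cutpoint oracle on small sets", {
  set.seed(31)
  for (rep in 1:60) {
    n <- sample(2:20, 1)
    lab <- integer(n)
    while (length(unique(lab)) < 2) lab <- rbinom(n, 1, 0.5)
    sc <- round(rnorm(n), sample(0:2, 1))   # coarse rounding forces ties
    sel <- select_threshold(roc_curve_points(tibble::tibble(score = sc, label = lab)))
    bf <- brute_force_best(sc, lab)
    expect_equal(sel$gm, bf$best, tolerance = 1e-9)
  }
})

test_that("ROC is monotone along decreasing thresholds", {
  set.seed(8)
  sc <- tibble::tibble(score = round(rnorm(200), 1),
                       label = rbinom(200, 1, 0.3))
  r <- roc_curve_points(sc)
  expect_true(all(diff(r$tp) >= 0))
  expect_true(all(diff(r$fp) >= 0))
  expect_true(all(diff(r$threshold) < 0))
})

test_that("Gm and F1 optima differ on an asymmetric score set", {
  sc <- tibble::tibble(
    score = c(10, 1.5, 9, 2, 2, 2, rep(1, 95)),
    label = c(1, 1, rep(0, 99))
  )
  r <- roc_curve_points(sc)
  sel_gm <- select_threshold(r, metric_gm)
  sel_f1 <- select_threshold(r, metric_f1)
  expect_equal(sel_gm$threshold, 1.5)    # tolerates 4 fp among 99 tn
  expect_equal(sel_f1$threshold, 10)     # precision-bound
  # F1 agrees with its own brute-force enumeration
  bf_f1 <- 0
  for (thr in unique(sc$score)) {
    tp <- sum(sc$score >= thr & sc$label == 1)
    fp <- sum(sc$score >= thr & sc$label == 0)
    fn <- sum(sc$score < thr & sc$label == 1)
    bf_f1 <- max(bf_f1, 100 * 2 * tp / (2 * tp + fp + fn))
  }
  expect_equal(sel_f1$metric, bf_f1)
})

test_that("roc_select_fit beats the default threshold on imbalanced data", {
  d <- gauss_problem(50, 2500, delta = 2, seed = 17)
  tr <- rf_trainer(ntree = 25)
  fit <- roc_select_fit(d, tr, k1 = 10, seed = 3)
  # training-set comparison at the two thresholds
  s <- score_rows <- predict(fit, d)$score
  mets <- function(thr) {
    cc <- confusion(as.integer(s >= thr), d$label)
    classification_metrics(cc)$gm
  }
  expect_gte(mets(fit$threshold), mets(0.5))
  # determinism: same seed, same threshold
  fit2 <- roc_select_fit(d, tr, k1 = 10, seed = 3)
  expect_equal(fit2$threshold, fit$threshold)
  expect_equal(predict(fit2, d)$score, predict(fit, d)$score)
})

test_that("stored threshold is the midpoint to the next higher distinct score", {
  sc <- tibble::tibble(id = as.character(1:6), label = c(1, 1, 1, 0, 0, 0),
                       f1 = c(5, 4, 3, 2, 1, 0))
  fit <- roc_select_fit(sc, identity_trainer(), k1 = 3, seed = 1)
  pooled <- fit$pooled
  sel <- fit$selected$threshold
  higher <- min(pooled$score[pooled$score > sel])
  expect_equal(fit$threshold, (sel + higher) / 2)
})

test_that("a constant score degenerates gracefully", {
  d <- gauss_problem(10, 40, seed = 9)
  fit <- roc_select_fit(d, constant_trainer(0.5), k1 = 5, seed = 1)
  expect_true(is.finite(fit$threshold) || is.infinite(fit$threshold))
  p <- predict(fit, d)
  expect_equal(nrow(p), 50)
  expect_true(all(p$label %in% c("positive", "negative")))
})
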