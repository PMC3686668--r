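#' Pool out-of-fold classifier scores via internal cross-validation
#'
#' The first step of ROC-select. The training data are split into `k1`
#' stratified folds; for each fold the classifier is trained on the
#' remaining folds and scores the held-out instances, so every instance is
#' scored exactly once by a model trained without it. All scored instances
#' are then gathered into a single pooled set on which the ROC curve is
#' built, which averages the fold ROC curves in the straightforward pooled
#' sense and prevents the threshold from overfitting the training data.
#'
#' @param data Modelling tibble: a `label` column (1 = miRNA), numeric
#'   feature columns, optional `id`.
#' @param trainer A [make_trainer()] object; [rf_trainer()] by default.
#' @param k1 Internal folds for threshold selection (default 10).
#' @param seed Seed controlling the fold split and classifier training.
#' @return Tibble with columns `id`, `label`, `score`, `fold`, one row per
#'   input instance (pooling order: fold by fold, deterministic given seed).
#' @export
pooled_scores <- function(data, trainer = rf_trainer(), k1 = 10, seed = 1) {
  y <- as_binary_label(data$label)
  if (length(unique(y)) < 2) stop("both classes must be present", call. = FALSE)
  data <- dplyr::mutate(data, label = y)
  if (!"id" %in% names(data)) data$id <- as.character(seq_len(nrow(data)))
  folds <- stratified_folds(y, k = k1, seed = seed)
  out <- vector("list", k1)
  for (f in seq_len(k1)) {
    train <- data[folds != f, , drop = FALSE]
    test <- data[folds == f, , drop = FALSE]
    if (length(unique(train$label)) < 2 || nrow(test) == 0) {
      stop("fold ", f, " lost a class after stratification; use a smaller k1",
           call. = FALSE)
    }
    fit <- fit_trainer(trainer, train, seed = seed_stream(seed, paste0("fold", f)))
    out[[f]] <- tibble::tibble(id = test$id, label = test$label,
                               score = score_rows(fit, test), fold = f)
  }
  dplyr::bind_rows(out)
}

#' ROC curve over pooled scores
#'
#' Builds the full ROC curve of the decision rule "classify as miRNA iff
#' `s(x) >= T`" by sorting the scored instances and updating the
#' true-positive and false-positive counts at each distinct score. One
#' point is emitted per distinct score value (tied scores move together)
#' plus the all-negative point at `T = +Inf`; together these are exactly
#' the achievable confusion matrices of threshold rules on this set.
#'
#' @param scored Tibble with columns `score` and `label` (1 = miRNA), e.g.
#'   from [pooled_scores()] or [make_score_problem()].
#' @return A tibble of class `mirhunt_roc`, ordered by decreasing
#'   threshold, with columns `threshold`, `tp`, `fp`, `tn`, `fn`, `se`,
#'   `sp`, `gm` (percent scale).
#' @export
roc_curve_points <- function(scored) {
  y <- as_binary_label(scored$label)
  if (length(unique(y)) < 2) stop("both classes must be present", call. = FALSE)
  if (any(!is.finite(scored$score))) stop("scores must be finite", call. = FALSE)
  n_pos <- sum(y == 1)
  n_neg <- sum(y == 0)
  ord <- order(scored$score, decreasing = TRUE)
  s <- scored$score[ord]
  yy <- y[ord]
  cum_tp <- cumsum(yy == 1)
  cum_fp <- cumsum(yy == 0)
  last <- which(s != c(s[-1], NA) | seq_along(s) == length(s))  # last index of each tie group
  thr <- c(Inf, s[last])
  tp <- c(0L, cum_tp[last])
  fp <- c(0L, cum_fp[last])
  se <- 100 * tp / n_pos
  sp <- 100 * (n_neg - fp) / n_neg
  out <- tibble::tibble(threshold = thr, tp = tp, fp = fp,
                        tn = n_neg - fp, fn = n_pos - tp,
                        se = se, sp = sp, gm = sqrt(se * sp))
  class(out) <- c("mirhunt_roc", class(out))
  out
}

#' Evaluation functionals for threshold selection
#'
#' Functions mapping ROC points to the value maximised by ROC-select.
#' `metric_gm` (the default everywhere) is the geometric mean of
#' sensitivity and specificity; `metric_f1` and `metric_se` are provided
#' for users optimising a different trade-off.
#'
#' @param roc A [roc_curve_points()] tibble (or any tibble with the
#'   confusion-count columns).
#' @return Numeric vector, one value per ROC point (percent scale).
#' @export
metric_gm <- function(roc) roc$gm

#' @rdname metric_gm
#' @export
metric_f1 <- function(roc) 100 * 2 * roc$tp / (2 * roc$tp + roc$fp + roc$fn)

#' @rdname metric_gm
#' @export
metric_se <- function(roc) roc$se

#' Select the decision threshold maximising an evaluation metric
#'
#' Picks the ROC point with the highest metric value (`Gm` by default) and
#' reports its threshold. Ties on the metric are broken towards the highest
#' sensitivity (the lowest maximising threshold): in miRNA screening a
#' missed precursor is costlier than a false candidate.
#'
#' @param roc A [roc_curve_points()] tibble.
#' @param metric Evaluation functional, e.g. [metric_gm()].
#' @return One-row tibble: the selected ROC point plus a `metric` column.
#' @export
select_threshold <- function(roc, metric = metric_gm) {
  if (nrow(roc) == 0) stop("empty ROC", call. = FALSE)
  m <- metric(roc)
  best <- which(m == max(m))
  if (length(best) > 1) best <- best[order(roc$se[best], -roc$threshold[best],
                                           decreasing = TRUE)][1]
  out <- roc[best, ]
  out$metric <- m[best]
  out
}

# Stored classification threshold: midpoint between the selected distinct
# score and the next higher distinct score (the score itself at the
# extreme), making classification robust to score jitter after retraining.
midpoint_threshold <- function(roc, selected_threshold) {
  if (!is.finite(selected_threshold)) return(selected_threshold)
  higher <- roc$threshold[is.finite(roc$threshold) & roc$threshold > selected_threshold]
  if (length(higher) == 0) return(selected_threshold)
  (selected_threshold + min(higher)) / 2
}

#' Fit a classifier with a ROC-selected decision threshold
#'
#' The complete ROC-select procedure for class-imbalanced classification:
#' pool out-of-fold scores from a `k1`-fold internal cross-validation
#' ([pooled_scores()]), trace the ROC curve ([roc_curve_points()]), select
#' the threshold maximising the evaluation metric ([select_threshold()]),
#' then retrain the classifier on the full training data. The stored
#' threshold is the midpoint between the selected distinct score and the
#' next higher one. Classification of new instances is "miRNA iff
#' `s(x) >= T`".
#'
#' @inheritParams pooled_scores
#' @param metric Evaluation functional maximised on the ROC curve.
#' @return An object of class `roc_select_fit` holding the refitted
#'   classifier, the threshold, the pooled ROC curve and reproducibility
#'   metadata (`k1`, `seed`, metric name). Supports [predict()],
#'   [generics::tidy()] (ROC points), [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @examples
#' prob <- make_score_problem(30, 300, seed = 7)
#' prob$f1 <- prob$score + stats::rnorm(nrow(prob), sd = 0.2)
#' fit <- roc_select_fit(prob[c("label", "f1")], logistic_trainer(), k1 = 5)
#' glance(fit)
#' @export
roc_select_fit <- function(data, trainer = rf_trainer(), k1 = 10, seed = 1,
                           metric = metric_gm) {
  data <- dplyr::mutate(data, label = as_binary_label(label))
  scored <- pooled_scores(data, trainer, k1 = k1, seed = seed)
  roc <- roc_curve_points(scored)
  sel <- select_threshold(roc, metric = metric)
  thr <- midpoint_threshold(roc, sel$threshold)
  full_fit <- fit_trainer(trainer, data, seed = seed_stream(seed, "final"))
  structure(
    list(fit = full_fit, threshold = thr, selected = sel, roc = roc,
         pooled = scored, k1 = k1, seed = seed,
         metric_name = deparse(substitute(metric)),
         metric = metric, trainer_name = trainer$name,
         n_pos = sum(data$label == 1), n_neg = sum(data$label == 0)),
    class = "roc_select_fit"
  )
}

#' @export
print.roc_select_fit <- function(x, ...) {
  cat("<roc_select_fit>", x$trainer_name, "| threshold", format(x$threshold),
      "| pooled", x$n_pos, "pos /", x$n_neg, "neg | k1 =", x$k1, "\n")
  cat("  pooled-ROC optimum: se", format(x$selected$se), " sp",
      format(x$selected$sp), " gm", format(round(x$selected$gm, 2)), "\n")
  invisible(x)
}

#' Predict miRNA labels for new instances
#'
#' @param object A [roc_select_fit()] model.
#' @param newdata Tibble with the training feature columns (optional `id`).
#' @param ... Unused.
#' @return Tibble with `id`, `score`, `threshold` and `label`
#'   (`"positive"` iff `score >= threshold`, i.e. predicted miRNA).
#' @export
predict.roc_select_fit <- function(object, newdata, ...) {
  id <- if ("id" %in% names(newdata)) newdata$id else as.character(seq_len(nrow(newdata)))
  if (nrow(newdata) == 0) {
    return(tibble::tibble(id = character(), score = numeric(),
                          threshold = numeric(), label = character()))
  }
  s <- score_rows(object$fit, newdata[setdiff(names(newdata), c("id", "label", "fold"))])
  tibble::tibble(id = id, score = s, threshold = object$threshold,
                 label = ifelse(s >= object$threshold, "positive", "negative"))
}

#' @importFrom generics tidy
#' @export
tidy.roc_select_fit <- function(x, ...) tibble::as_tibble(x$roc)

#' @importFrom generics glance
#' @export
glance.roc_select_fit <- function(x, ...) {
  tibble::tibble(trainer = x$trainer_name, threshold = x$threshold,
                 pooled_se = x$selected$se, pooled_sp = x$selected$sp,
                 pooled_gm = x$selected$gm, k1 = x$k1, seed = x$seed,
                 n_pos = x$n_pos, n_neg = x$n_neg)
}
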