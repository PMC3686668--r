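#' Stratified fold assignment
#'
#' Assigns instances to `k` cross-validation folds preserving the class
#' proportions: per class, the fold counts differ from perfect
#' stratification by at most one. With strongly imbalanced hairpin data
#' this is what keeps every test fold representative of the deployment
#' class ratio.
#'
#' @param labels Binary label vector.
#' @param k Number of folds (each class count must be at least `k`).
#' @param seed Seed; the assignment is deterministic given `seed`.
#' @return Integer vector of fold indices in `1..k`.
#' @export
stratified_folds <- function(labels, k, seed = 1) {
  y <- as_binary_label(labels)
  counts <- table(y)
  if (any(counts < k)) {
    stop("class count ", min(counts), " is below k = ", k,
         "; choose a smaller k", call. = FALSE)
  }
  folds <- integer(length(y))
  with_rng_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(sample.int(k), length(idx))
    }
  })
  folds
}

#' Nested cross-validated evaluation of the full pipeline
#'
#' Estimates deployment performance with an outer stratified `k_outer`-fold
#' cross-validation around the complete training procedure: on each outer
#' training part, tune parameters by [grid_search()] (`k2` internal folds),
#' fit with [roc_select_fit()] (`k1` internal folds) or at the default
#' threshold, then score and threshold the held-out outer fold. No instance
#' ever influences the model that scores it (asserted per fold). Confusion
#' counts are pooled over outer folds before computing SE/SP/Gm
#' (micro-averaging, stable when folds contain few positives); set
#' `averaging = "macro"` to average per-fold metrics instead.
#'
#' `threshold = "roc_select"` is the full pipeline (parameter + threshold
#' selection); `threshold = "default"` is parameter selection only, the
#' standard baseline that overlearns the majority class on imbalanced data.
#'
#' @param data Modelling tibble (`label`, feature columns, optional `id`).
#' @param trainer Base trainer.
#' @param grid Optional [param_grid()]; `NULL` skips parameter tuning.
#' @param k_outer,k1,k2 Outer evaluation folds, internal threshold-selection
#'   folds, internal tuning folds (defaults 10, 10, 5).
#' @param seed Master seed.
#' @param metric Evaluation functional.
#' @param threshold `"roc_select"` or `"default"`.
#' @param averaging `"micro"` (pool counts) or `"macro"` (mean of per-fold
#'   metrics).
#' @return Object of class `mirhunt_eval`: `metrics` (one-row tibble `se`,
#'   `sp`, `gm`), `folds` (per-fold detail), `config`.
#' @export
evaluate_pipeline <- function(data, trainer = rf_trainer(), grid = NULL,
                              k_outer = 10, k1 = 10, k2 = 5, seed = 1,
                              metric = metric_gm,
                              threshold = c("roc_select", "default"),
                              averaging = c("micro", "macro")) {
  threshold <- match.arg(threshold)
  averaging <- match.arg(averaging)
  data <- dplyr::mutate(data, label = as_binary_label(label))
  if (!"id" %in% names(data)) data$id <- as.character(seq_len(nrow(data)))
  data <- data[order(data$id), , drop = FALSE]   # id-keyed determinism
  outer <- stratified_folds(data$label, k = k_outer, seed = seed)
  fold_rows <- vector("list", k_outer)
  for (f in seq_len(k_outer)) {
    train <- data[outer != f, , drop = FALSE]
    test <- data[outer == f, , drop = FALSE]
    stopifnot(length(intersect(train$id, test$id)) == 0)   # leakage guard
    fseed <- seed_stream(seed, paste0("outer", f))
    tr <- trainer
    params_lab <- NA_character_
    if (!is.null(grid)) {
      gs <- grid_search(train, trainer, grid, k2 = k2, seed = fseed, metric = metric)
      tr <- set_params(trainer, gs$best_params)
      params_lab <- paste(names(gs$best_params), format(unlist(gs$best_params)),
                          sep = "=", collapse = ",")
    }
    if (threshold == "roc_select") {
      m <- roc_select_fit(train, tr, k1 = k1, seed = fseed, metric = metric)
      fit <- m$fit
      thr <- m$threshold
    } else {
      fit <- fit_trainer(tr, train, seed = seed_stream(fseed, "fit"))
      thr <- tr$default_threshold
    }
    s <- score_rows(fit, test)
    cc <- confusion(as.integer(s >= thr), test$label)
    fold_rows[[f]] <- dplyr::bind_cols(
      tibble::tibble(fold = f, threshold = thr, params = params_lab),
      cc, classification_metrics(cc)
    )
  }
  folds_tbl <- dplyr::bind_rows(fold_rows)
  metrics <- if (averaging == "micro") {
    classification_metrics(dplyr::summarise(
      folds_tbl, tp = sum(tp), fp = sum(fp), tn = sum(tn), fn = sum(fn)))
  } else {
    tibble::tibble(se = mean(folds_tbl$se), sp = mean(folds_tbl$sp),
                   gm = mean(folds_tbl$gm))
  }
  structure(
    list(metrics = metrics, folds = folds_tbl,
         config = list(trainer = trainer$name, k_outer = k_outer, k1 = k1,
                       k2 = k2, seed = seed, threshold = threshold,
                       averaging = averaging, tuned = !is.null(grid))),
    class = "mirhunt_eval"
  )
}

#' @export
print.mirhunt_eval <- function(x, ...) {
  cat("<mirhunt_eval>", x$config$trainer,
      "| threshold:", x$config$threshold,
      "| k_outer =", x$config$k_outer, "\n")
  cat(sprintf("  SE %.2f  SP %.2f  Gm %.2f (%s-averaged)\n",
              x$metrics$se, x$metrics$sp, x$metrics$gm, x$config$averaging))
  invisible(x)
}

#' @export
tidy.mirhunt_eval <- function(x, ...) x$folds

#' @export
glance.mirhunt_eval <- function(x, ...) {
  dplyr::bind_cols(x$metrics,
                   tibble::as_tibble(x$config[c("trainer", "threshold",
                                                "k_outer", "seed")]))
}

# Critical values of the studentized range statistic / sqrt(2) for the
# Nemenyi post-hoc test, k = 2..10 methods.
nemenyi_q <- list(
  "0.05" = c(`2` = 1.960, `3` = 2.343, `4` = 2.569, `5` = 2.728, `6` = 2.850,
             `7` = 2.949, `8` = 3.031, `9` = 3.102, `10` = 3.164),
  "0.1"  = c(`2` = 1.645, `3` = 2.052, `4` = 2.291, `5` = 2.459, `6` = 2.589,
             `7` = 2.693, `8` = 2.780, `9` = 2.855, `10` = 2.920)
)

#' Friedman rank test with Nemenyi critical difference
#'
#' Compares classifiers across datasets on a performance matrix (rows =
#' datasets, columns = methods; higher = better, e.g. Gm). Methods are
#' ranked per dataset (rank 1 = best, ties averaged), the Friedman
#' chi-square statistic is computed over the average ranks, and the Nemenyi
#' critical difference `CD = q_alpha * sqrt(k (k + 1) / (6 N))` gives the
#' margin by which two average ranks must differ to be significantly
#' different — the quantity drawn in critical-difference diagrams.
#'
#' @param performance Numeric matrix or data frame, datasets x methods,
#'   with column names; all entries finite.
#' @param alpha Significance level, 0.05 or 0.10 (Nemenyi table).
#' @return Object of class `mirhunt_friedman`: `avg_ranks` (named, sorted
#'   best first), `ranks` (per-dataset matrix), `statistic`, `df`,
#'   `p_value`, `cd`, `q_alpha`, `k`, `n`.
#' @examples
#' bm <- mirhunt_benchmarks()$classification
#' @export
friedman_nemenyi <- function(performance, alpha = 0.05) {
  m <- as.matrix(performance)
  if (!is.numeric(m) || any(!is.finite(m))) {
    stop("performance matrix must be finite numeric", call. = FALSE)
  }
  n <- nrow(m)
  k <- ncol(m)
  if (k < 2 || n < 2) stop("need at least 2 methods and 2 datasets", call. = FALSE)
  ranks <- t(apply(m, 1, function(row) rank(-row)))   # 1 = best
  colnames(ranks) <- colnames(m)
  avg <- colMeans(ranks)
  # chi^2_F = 12 / (n k (k+1)) * sum_j Rj^2 - 3 n (k+1), Rj = rank sums
  stat <- 12 / (n * k * (k + 1)) * sum((avg * n)^2) - 3 * n * (k + 1)
  df <- k - 1
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  qtab <- nemenyi_q[[as.character(alpha)]]
  if (is.null(qtab) || is.na(qtab[as.character(k)])) {
    stop("Nemenyi q tabulated only for alpha in {0.05, 0.1} and k <= 10",
         call. = FALSE)
  }
  q <- unname(qtab[as.character(k)])
  cd <- q * sqrt(k * (k + 1) / (6 * n))
  structure(list(avg_ranks = sort(avg), ranks = ranks, statistic = stat,
                 df = df, p_value = p, cd = cd, q_alpha = q, alpha = alpha,
                 k = k, n = n),
            class = "mirhunt_friedman")
}

#' @export
print.mirhunt_friedman <- function(x, ...) {
  cat("<mirhunt_friedman> chi^2 =", format(round(x$statistic, 3)),
      " df =", x$df, " p =", format.pval(x$p_value), "\n")
  cat("  CD(alpha=", x$alpha, ") = ", format(round(x$cd, 3)), "\n", sep = "")
  print(round(x$avg_ranks, 2))
  invisible(x)
}

#' @export
tidy.mirhunt_friedman <- function(x, ...) {
  tibble::tibble(method = names(x$avg_ranks), avg_rank = unname(x$avg_ranks))
}

#' @export
glance.mirhunt_friedman <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
                 cd = x$cd, k = x$k, n = x$n, alpha = x$alpha)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided paired comparison of performance values across datasets. Zero
#' differences are dropped; with `n <= 25` untied absolute differences the
#' exact null distribution of the signed-rank statistic is used, otherwise
#' the normal approximation with tie correction.
#'
#' @param x,y Equal-length paired numeric vectors.
#' @return One-row tibble: `statistic` (sum of positive-difference ranks),
#'   `p_value`, `n` (non-zero pairs), `method`.
#' @examples
#' wilcoxon_paired(c(2, 3, 4, 5, 6), c(1, 2, 3, 4, 5))  # exact p = 0.0625
#' @export
wilcoxon_paired <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("degenerate comparison: all differences are zero", call. = FALSE)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (n <= 25 && !ties) {
    p <- 2 * min(stats::psignrank(v, n), stats::psignrank(v - 1, n, lower.tail = FALSE))
    p <- min(1, p)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tt <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tt^3 - tt) / 48
    z <- (v - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  tibble::tibble(statistic = v, p_value = p, n = n, method = method)
}
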