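#' Parameter grid for classifier tuning
#'
#' A search space is declared by a finite ordered list of values per
#' parameter; the grid is their Cartesian product, of size
#' `lambda = prod(axis sizes)`.
#'
#' @param ... Named axes, each a non-empty vector of unique values.
#' @return An object of class `param_grid`.
#' @examples
#' param_grid(ntree = seq(10, 219, by = 11))   # lambda = 20
#' @export
param_grid <- function(...) {
  axes <- list(...)
  if (length(axes) == 0 || is.null(names(axes)) || any(!nzchar(names(axes)))) {
    stop("all grid axes must be named", call. = FALSE)
  }
  for (nm in names(axes)) {
    if (length(axes[[nm]]) == 0) stop("empty grid axis: ", nm, call. = FALSE)
    if (anyDuplicated(axes[[nm]])) stop("duplicated values on axis ", nm, call. = FALSE)
  }
  structure(list(axes = axes, lambda = prod(lengths(axes))), class = "param_grid")
}

#' @export
print.param_grid <- function(x, ...) {
  cat("<param_grid> lambda =", x$lambda, "\n")
  for (nm in names(x$axes)) cat("  ", nm, ": ", paste(format(x$axes[[nm]]), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' The tuning grid used for the default random forest
#'
#' Number of trees 10, 21, ..., 219 (20 points).
#' @return A [param_grid()].
#' @export
default_rf_grid <- function() param_grid(ntree = seq(10, 219, by = 11))

#' Enumerate grid points
#'
#' Deterministic lexicographic order with the first declared axis most
#' significant, so runs are reproducible and ties in the search resolve to
#' the first-declared combination.
#'
#' @param grid A [param_grid()].
#' @return Tibble with one column per axis and `lambda` rows.
#' @export
grid_points <- function(grid) {
  stopifnot(inherits(grid, "param_grid"))
  do.call(tidyr::expand_grid, grid$axes)
}

#' Grid search over classifier parameters by internal cross-validation
#'
#' Parameter selection precedes threshold selection in the pipeline. For
#' every grid point the classifier is evaluated by a `k2`-fold stratified
#' cross-validation at its default threshold, and the combination with the
#' highest mean evaluation metric is retained. The same fold split is
#' reused across grid points, so the per-point table is deterministic given
#' the seed and points are compared on identical partitions. Evaluating
#' each point at the classifier's default threshold keeps tuning
#' independent of (and cheaper than) ROC-select; set
#' `threshold = "roc_select"` to nest full threshold selection inside the
#' tuning loop at `k1`-fold cost per point.
#'
#' @param data Modelling tibble (`label` + feature columns).
#' @param trainer Base trainer whose `params` the grid overrides.
#' @param grid A [param_grid()]; axes must name trainer parameters.
#' @param k2 Internal folds for parameter tuning (default 5).
#' @param seed Seed for the shared fold split and training.
#' @param metric Evaluation functional (default [metric_gm()]).
#' @param threshold `"default"` or `"roc_select"` (see above).
#' @param k1 Internal folds for nested ROC-select (only used when
#'   `threshold = "roc_select"`).
#' @return An object of class `mirhunt_grid_search`: `best_params` (named
#'   list), `table` (tibble of `lambda` rows: axes, `mean_metric`, `rank`).
#' @export
grid_search <- function(data, trainer = rf_trainer(), grid = default_rf_grid(),
                        k2 = 5, seed = 1, metric = metric_gm,
                        threshold = c("default", "roc_select"), k1 = 10) {
  threshold <- match.arg(threshold)
  data <- dplyr::mutate(data, label = as_binary_label(label))
  if (length(unique(data$label)) < 2) stop("both classes must be present", call. = FALSE)
  pts <- grid_points(grid)
  folds <- stratified_folds(data$label, k = k2, seed = seed)
  vals <- numeric(nrow(pts))
  for (gp in seq_len(nrow(pts))) {
    tr <- set_params(trainer, as.list(pts[gp, ]))
    fold_metric <- numeric(k2)
    for (f in seq_len(k2)) {
      train <- data[folds != f, , drop = FALSE]
      test <- data[folds == f, , drop = FALSE]
      fseed <- seed_stream(seed, paste0("grid", gp, "fold", f))
      if (threshold == "default") {
        fit <- fit_trainer(tr, train, seed = fseed)
        thr <- tr$default_threshold
      } else {
        rsf <- roc_select_fit(train, tr, k1 = k1, seed = fseed, metric = metric)
        fit <- rsf$fit
        thr <- rsf$threshold
      }
      s <- score_rows(fit, test)
      cc <- confusion(as.integer(s >= thr), test$label)
      point <- dplyr::bind_cols(cc, classification_metrics(cc))
      fold_metric[f] <- metric(point)
    }
    vals[gp] <- mean(fold_metric)
  }
  tab <- dplyr::mutate(pts, mean_metric = vals,
                       rank = rank(-vals, ties.method = "min"))
  best <- as.list(pts[which.max(vals), ])   # ties -> first point in grid order
  structure(list(best_params = best, table = tab, k2 = k2, seed = seed,
                 threshold = threshold, trainer_name = trainer$name),
            class = "mirhunt_grid_search")
}

#' @export
print.mirhunt_grid_search <- function(x, ...) {
  cat("<mirhunt_grid_search>", x$trainer_name, "| lambda =", nrow(x$table),
      "| k2 =", x$k2, "| threshold:", x$threshold, "\n")
  cat("  best:", paste(names(x$best_params), format(unlist(x$best_params)),
                       sep = "=", collapse = ", "),
      " mean metric", format(round(max(x$table$mean_metric), 2)), "\n")
  invisible(x)
}

#' @export
tidy.mirhunt_grid_search <- function(x, ...) x$table

#' @export
glance.mirhunt_grid_search <- function(x, ...) {
  tibble::tibble(trainer = x$trainer_name, lambda = nrow(x$table),
                 k2 = x$k2, seed = x$seed,
                 best_metric = max(x$table$mean_metric))
}
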