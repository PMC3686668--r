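#' Score-producing classifier contract
#'
#' ROC-select works on top of any classifier that emits a continuous score
#' `s(x)` where a higher value means "more miRNA-like"; only the ranking of
#' instances matters, not calibration. A trainer bundles a fitting function
#' and a scoring function behind that contract. `make_trainer()` builds a
#' custom trainer; [rf_trainer()] (the default throughout the package) and
#' [logistic_trainer()] are provided.
#'
#' @param name Trainer name (recorded in model bundles).
#' @param fit `function(x, y, params, seed)` returning a fitted state;
#'   `x` is a numeric matrix, `y` an integer 0/1 vector (1 = miRNA).
#' @param score `function(state, x)` returning a numeric score per row.
#' @param params Named list of tunable parameters (grid-search axes address
#'   these by name).
#' @param default_threshold The classifier's conventional decision threshold
#'   on its score scale, used when ROC-select is disabled.
#' @return An object of class `mirhunt_trainer`.
#' @export
make_trainer <- function(name, fit, score, params = list(),
                         default_threshold = 0.5) {
  stopifnot(is.function(fit), is.function(score))
  structure(list(name = name, fit = fit, score = score, params = params,
                 default_threshold = default_threshold),
            class = "mirhunt_trainer")
}

#' @export
print.mirhunt_trainer <- function(x, ...) {
  ps <- if (length(x$params)) {
    paste(names(x$params), vapply(x$params, function(p) paste(format(p), collapse = "/"),
                                  character(1)), sep = "=", collapse = ", ")
  } else "none"
  cat("<mirhunt_trainer>", x$name, "| params:", ps, "\n")
  invisible(x)
}

# Replace tunable parameters (used by grid search).
set_params <- function(trainer, params) {
  trainer$params[names(params)] <- params
  trainer
}

#' Random forest trainer
#'
#' The package's default base classifier: a classification random forest
#' (bootstrap-aggregated CART trees with gini splits and a random feature
#' subset drawn at every node). The score is the fraction of trees voting
#' for the miRNA class, in `[0, 1]`, with a default decision threshold of
#' 0.5. Training is deterministic given `seed` (the forest uses its own
#' xorshift generator, independent of R's RNG).
#'
#' No decision-tree learner is assumed from the environment; the forest is
#' implemented in compiled code inside the package.
#'
#' @param ntree Number of trees (the tunable axis used in parameter
#'   selection; see [default_rf_grid()]).
#' @param mtry Features tried per node; default `floor(sqrt(p))`.
#' @param min_split Minimum node size eligible for splitting.
#' @param max_depth Depth cap per tree.
#' @return A `mirhunt_trainer`.
#' @export
rf_trainer <- function(ntree = 100, mtry = NULL, min_split = 2, max_depth = 30) {
  make_trainer(
    name = "random_forest",
    fit = function(x, y, params, seed) {
      mtry_eff <- params$mtry %||% max(1L, floor(sqrt(ncol(x))))
      list(
        trees = grow_forest_cpp(x, as.integer(y), as.integer(params$ntree),
                                as.integer(mtry_eff), as.integer(params$min_split),
                                as.integer(params$max_depth), as.numeric(seed)),
        p = ncol(x)
      )
    },
    score = function(state, x) {
      if (ncol(x) != state$p) stop("feature count mismatch", call. = FALSE)
      as.numeric(predict_forest_cpp(state$trees, x))
    },
    params = list(ntree = ntree, mtry = mtry, min_split = min_split,
                  max_depth = max_depth),
    default_threshold = 0.5
  )
}

#' Logistic regression trainer
#'
#' A simple probabilistic baseline: binomial GLM whose score is the fitted
#' miRNA-class probability. Useful for tests and as a sanity baseline;
#' separable problems are handled by capping iterations and suppressing the
#' attendant convergence warnings.
#'
#' @return A `mirhunt_trainer` with no tunable parameters.
#' @export
logistic_trainer <- function() {
  make_trainer(
    name = "logistic",
    fit = function(x, y, params, seed) {
      df <- as.data.frame(x)
      names(df) <- paste0("f", seq_len(ncol(x)))
      df$.y <- y
      suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial(),
                                  control = list(maxit = 50)))
    },
    score = function(state, x) {
      df <- as.data.frame(x)
      names(df) <- paste0("f", seq_len(ncol(x)))
      suppressWarnings(as.numeric(stats::predict(state, newdata = df,
                                                 type = "response")))
    },
    params = list(),
    default_threshold = 0.5
  )
}

# Fit a trainer on a modelling tibble; returns a fitted-classifier wrapper.
fit_trainer <- function(trainer, data, seed) {
  y <- as_binary_label(data$label)
  x <- feature_matrix(data)
  state <- trainer$fit(x, y, trainer$params, seed)
  structure(list(trainer = trainer, state = state,
                 feature_names = colnames(x), seed = seed),
            class = "mirhunt_fit")
}

# Score new rows with a fitted classifier.
score_rows <- function(fit, data) {
  x <- feature_matrix(data)
  if (!identical(colnames(x), fit$feature_names)) {
    stop("feature columns differ from training (",
         paste(setdiff(fit$feature_names, colnames(x)), collapse = ", "),
         " missing)", call. = FALSE)
  }
  fit$trainer$score(fit$state, x)
}
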