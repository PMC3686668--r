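#' Train a full hairpin-classification model
#'
#' The end-to-end training pipeline on labelled FASTA-style records:
#' extract features for positives and negatives, optionally tune classifier
#' parameters by internal `k2`-fold grid search, then fit with ROC-select
#' (`k1` internal folds) and package the result as a portable model bundle
#' with a human-readable manifest.
#'
#' @param positives,negatives Tibbles with `id`, `seq` (see [read_fasta()]).
#' @param spec A [feature_spec()]; its backend tag is recorded in the
#'   bundle, and [classify_candidates()] refuses a mismatching runtime.
#' @param trainer Base trainer (default [rf_trainer()]).
#' @param grid Optional [param_grid()] for parameter selection; `NULL`
#'   skips tuning.
#' @param k1,k2 Internal fold counts for threshold selection and parameter
#'   tuning (defaults 10 and 5).
#' @param seed Master seed; training twice with the same seed reproduces
#'   the same parameters and threshold.
#' @param metric Evaluation functional maximised in tuning and ROC-select.
#' @return Object of class `mirhunt_model`: the fitted [roc_select_fit()],
#'   the feature spec, tuned parameters, tuning table (if any), and a
#'   manifest of reproducibility metadata.
#' @export
train_model <- function(positives, negatives, spec = feature_spec(),
                        trainer = rf_trainer(), grid = NULL,
                        k1 = 10, k2 = 5, seed = 1, metric = metric_gm) {
  if (nrow(positives) == 0 || nrow(negatives) == 0) {
    stop("both a positive and a negative set are required", call. = FALSE)
  }
  fp <- extract_features(positives, spec, seed = seed_stream(seed, "feat_pos"))
  fn <- extract_features(negatives, spec, seed = seed_stream(seed, "feat_neg"))
  data <- dplyr::bind_rows(
    dplyr::mutate(fp, label = 1L),
    dplyr::mutate(fn, label = 0L)
  )
  tuning <- NULL
  if (!is.null(grid)) {
    tuning <- grid_search(data, trainer, grid, k2 = k2,
                          seed = seed_stream(seed, "tuning"), metric = metric)
    trainer <- set_params(trainer, tuning$best_params)
  }
  fit <- roc_select_fit(data, trainer, k1 = k1,
                        seed = seed_stream(seed, "rocselect"), metric = metric)
  manifest <- list(
    package = "mirhunt",
    version = as.character(utils::packageVersion("mirhunt")),
    trainer = trainer$name,
    params = trainer$params[!vapply(trainer$params, is.null, logical(1))],
    threshold = fit$threshold,
    feature_names = spec$feature_names,
    backend = spec$backend,
    tier = spec$tier,
    k1 = k1, k2 = k2, seed = seed,
    metric = fit$metric_name,
    n_pos = sum(data$label == 1), n_neg = sum(data$label == 0),
    training_fingerprint = rlang::hash(list(positives$seq, negatives$seq))
  )
  structure(list(fit = fit, spec = spec, tuning = tuning, manifest = manifest),
            class = "mirhunt_model")
}

#' @export
print.mirhunt_model <- function(x, ...) {
  m <- x$manifest
  cat("<mirhunt_model>", m$trainer, "| backend:", m$backend,
      "| threshold", format(m$threshold), "\n")
  cat("  trained on", m$n_pos, "pos /", m$n_neg, "neg; k1 =", m$k1,
      if (!is.null(x$tuning)) paste0("; tuned over lambda = ", nrow(x$tuning$table)) else "",
      "\n")
  invisible(x)
}

#' @export
tidy.mirhunt_model <- function(x, ...) tidy(x$fit)

#' @export
glance.mirhunt_model <- function(x, ...) {
  dplyr::bind_cols(glance(x$fit),
                   tibble::tibble(backend = x$manifest$backend,
                                  fingerprint = x$manifest$training_fingerprint))
}

#' Save / load a model bundle
#'
#' A bundle is a single gzipped tar archive containing `manifest.json`
#' (plain text, readable without this package: version, feature spec,
#' backend tag, tuned parameters, threshold, fold counts, seed, training
#' fingerprint) and the serialized classifier state. Scores are
#' reproducible across machines given the same backend tag (documented
#' floating-point tolerance 1e-9).
#'
#' @param model A [train_model()] result.
#' @param path Output path (conventionally `.tar.gz`).
#' @return `save_model()`: `path`, invisibly. `load_model()`: the
#'   `mirhunt_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "mirhunt_model"))
  dir <- tempfile("bundle")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  jsonlite::write_json(model$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  saveRDS(model, file.path(dir, "state.rds"))
  # resolve to an absolute path before changing directory (normalizePath
  # leaves nonexistent relative paths untouched on some platforms)
  path <- file.path(normalizePath(dirname(path), mustWork = TRUE),
                    basename(path))
  old <- setwd(dir)
  on.exit(setwd(old), add = TRUE)
  utils::tar(path, files = c("manifest.json", "state.rds"), compression = "gzip")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  dir <- tempfile("bundle")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  utils::untar(path, exdir = dir)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  model <- readRDS(file.path(dir, "state.rds"))
  if (!identical(manifest$backend, model$manifest$backend)) {
    stop("bundle manifest/state backend mismatch; corrupted bundle?", call. = FALSE)
  }
  model
}

#' Classify candidate sequences with a trained model
#'
#' Extracts features for the candidates with the model's own feature spec
#' (same backend, same ordering) and applies the stored decision rule
#' "miRNA iff `score >= threshold`". A precomputed feature table may be
#' supplied instead of raw sequences; its columns must match the model's
#' feature spec exactly, and a mismatch is refused with the differing
#' names. Records skipped by feature extraction (e.g. containing `N`)
#' surface in the `failures` attribute.
#'
#' @param model A [train_model()] result (or one from [load_model()]).
#' @param candidates Tibble with `id`, `seq`; or a feature table whose
#'   non-`id` columns are the model's features.
#' @param backend Runtime folding backend; must equal the bundle's backend
#'   tag (mixing backends between training and classification is refused).
#' @return Tibble `id`, `score`, `threshold`, `label` (`"positive"` iff
#'   `score >= threshold`), in input order.
#' @export
classify_candidates <- function(model, candidates, backend = "nussinov") {
  stopifnot(inherits(model, "mirhunt_model"))
  if (!identical(backend, model$manifest$backend)) {
    stop("backend mismatch: bundle was trained with '", model$manifest$backend,
         "' but the runtime offers '", backend,
         "'; refusing to mix folding backends", call. = FALSE)
  }
  if (nrow(candidates) == 0) {
    return(tibble::tibble(id = character(), score = numeric(),
                          threshold = numeric(), label = character()))
  }
  if ("seq" %in% names(candidates)) {
    feats <- extract_features(candidates, model$spec,
                              seed = model$manifest$seed)
  } else {
    feats <- candidates
    have <- setdiff(names(feats), "id")
    want <- model$spec$feature_names
    if (!identical(sort(have), sort(want))) {
      stop("feature table does not match the model's feature spec\n",
           "  missing: ", paste(setdiff(want, have), collapse = ", "), "\n",
           "  extra:   ", paste(setdiff(have, want), collapse = ", "),
           call. = FALSE)
    }
    feats <- feats[c("id", want)]
  }
  out <- predict(model$fit, feats)
  attr(out, "failures") <- attr(feats, "failures")
  out
}
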