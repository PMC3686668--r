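# Internal helpers shared across modules.

# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_rng_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env)
  } else NULL
  set.seed(as.integer(seed))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    } else {
      assign(".Random.seed", old, envir = env)
    }
  }, add = TRUE)
  force(code)
}

# Derive a reproducible sub-seed from a master seed and a call-site tag, so
# adding generator calls never perturbs other fixtures (kept below 2^31).
seed_stream <- function(seed, tag) {
  h <- 0
  for (cp in utf8ToInt(tag)) h <- (h * 131 + cp) %% 2147483629
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629 + 1)
}

# Coerce labels to integer 0/1 with 1 = the miRNA (positive) class.
as_binary_label <- function(label, positive = NULL) {
  if (is.logical(label)) return(as.integer(label))
  if (is.numeric(label)) {
    if (!all(label %in% c(0, 1))) {
      stop("numeric labels must be 0/1 (1 = miRNA class)", call. = FALSE)
    }
    return(as.integer(label))
  }
  lab <- as.character(label)
  vals <- unique(lab)
  if (length(vals) > 2) stop("labels must be binary", call. = FALSE)
  if (is.null(positive)) {
    hit <- intersect(c("positive", "mirna", "miRNA", "TRUE", "1"), vals)
    if (length(hit) == 0) {
      stop("cannot infer the positive class from labels ",
           paste(vals, collapse = ", "), "; pass `positive`", call. = FALSE)
    }
    positive <- hit[[1]]
  }
  as.integer(lab == positive)
}

# Extract the numeric feature matrix from a modelling tibble (everything
# except bookkeeping columns), preserving column order.
feature_matrix <- function(data, drop = c("id", "label", "fold")) {
  keep <- setdiff(names(data), drop)
  bad <- keep[!vapply(data[keep], is.numeric, logical(1))]
  if (length(bad) > 0) {
    stop("non-numeric feature columns: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(data[keep])
  storage.mode(m) <- "double"
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
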