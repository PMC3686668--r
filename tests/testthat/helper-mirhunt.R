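# Shared fixtures and oracles, all built in code at test time.

# Tabular two-Gaussian modelling problem: both features shifted by `delta`
# in the positive class, so the classes overlap controllably.
gauss_problem <- function(n_pos, n_neg, delta = 2, sd = 1, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    id = sprintf("i%05d", sample.int(n_pos + n_neg)),
    label = c(rep(1L, n_pos), rep(0L, n_neg)),
    f1 = c(rnorm(n_pos, delta, sd), rnorm(n_neg, 0, sd)),
    f2 = c(rnorm(n_pos, delta, sd), rnorm(n_neg, 0, sd))
  )
}

# Trainer whose score is simply one feature column: turns pooled_scores
# into a deterministic pass-through of the data.
identity_trainer <- function(col = 1) {
  make_trainer(
    name = "identity",
    fit = function(x, y, params, seed) list(col = params$col),
    score = function(state, x) x[, state$col],
    params = list(col = col),
    default_threshold = 0
  )
}

# Trainer emitting a constant score (degenerate ranking).
constant_trainer <- function(value = 0.5) {
  make_trainer(
    name = "constant",
    fit = function(x, y, params, seed) params$value,
    score = function(state, x) rep(state, nrow(x)),
    params = list(value = value)
  )
}

# Brute-force threshold oracle: enumerate every cutpoint between sorted
# distinct scores (plus the extremes) under the rule "positive iff s >= T"
# and return the maximal metric value. Independent of roc_curve_points().
brute_force_best <- function(score, label, metric_fun = function(se, sp) sqrt(se * sp)) {
  stopifnot(length(score) == length(label))
  u <- sort(unique(score))
  cands <- c(u, max(u) + 1, (u[-1] + u[-length(u)]) / 2)
  n_pos <- sum(label == 1)
  n_neg <- sum(label == 0)
  best <- -Inf
  best_thr <- NA_real_
  for (thr in cands) {
    pred <- as.integer(score >= thr)
    se <- 100 * sum(pred == 1 & label == 1) / n_pos
    sp <- 100 * sum(pred == 0 & label == 0) / n_neg
    val <- metric_fun(se, sp)
    if (val > best) {
      best <- val
      best_thr <- thr
    }
  }
  list(best = best, threshold = best_thr)
}

# A perfect 20-bp stem fixture built by reverse complement.
perfect_hairpin_seq <- function(stem = 20, loop = 4, seed = 11) {
  make_hairpin(stem_len = stem, loop_len = loop, n_mismatches = 0,
               n_bulges = 0, seed = seed)$seq
}

# de Bruijn sequence of order 3 over ACGT (length 64): every triplet occurs
# at most once in any window, so DUST masks nothing.
debruijn64 <- function() {
  alph <- c("A", "C", "G", "T")
  k <- 4L; n <- 3L
  a <- integer(k * n)
  out <- integer(0)
  db <- function(t, p) {
    if (t > n) {
      if (n %% p == 0) out <<- c(out, a[2:(p + 1)])
    } else {
      a[t + 1] <<- a[t - p + 1]
      db(t + 1, p)
      j <- a[t - p + 1] + 1
      while (j < k) {
        a[t + 1] <<- j
        db(t + 1, t)
        j <- j + 1
      }
    }
  }
  db(1L, 1L)
  paste(alph[out + 1], collapse = "")
}
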