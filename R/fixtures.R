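# Synthetic data generators. Fixtures follow explicit generative rules
# rather than resampling real miRNA statistics, so test expectations are
# derivable; every generator is a pure function of its seed, with one
# derived RNG stream per call site.

rna_complement <- c(A = "U", U = "A", G = "C", C = "G")

sample_bases <- function(n, gc_bias) {
  probs <- c(A = (1 - gc_bias) / 2, C = gc_bias / 2,
             G = gc_bias / 2, U = (1 - gc_bias) / 2)
  sample(names(probs), n, replace = TRUE, prob = probs)
}

#' Generate a synthetic hairpin sequence
#'
#' Builds a pre-miRNA-like stem-loop: a random 5' arm (GC content set by
#' `gc_bias`), a random loop, and a 3' arm that is the reverse complement
#' of the 5' arm with `n_mismatches` point changes and `n_bulges` inserted
#' bases. Total length is `2 * stem_len + loop_len + n_bulges`. With no
#' mismatches the sequence folds into an essentially perfect stem under any
#' backend; mismatches and bulges degrade pairing controllably.
#'
#' @param stem_len Stem length in base pairs (>= 4).
#' @param loop_len Loop length in nucleotides (>= 3).
#' @param n_mismatches Point changes in the 3' arm (< `stem_len`).
#' @param n_bulges Bases inserted into the 3' arm.
#' @param gc_bias Probability that a stem base is G or C, in `[0, 1]`.
#' @param seed Integer seed; same seed, same sequence.
#' @param id Record id (default derived from the seed).
#' @return One-row tibble with `id`, `seq`.
#' @examples
#' make_hairpin(stem_len = 20, loop_len = 4, seed = 1)
#' @export
make_hairpin <- function(stem_len = 20, loop_len = 4, n_mismatches = 0,
                         n_bulges = 0, gc_bias = 0.5, seed = 1, id = NULL) {
  stopifnot(stem_len >= 4, loop_len >= 3, n_mismatches < stem_len)
  with_rng_seed(seed_stream(seed, "make_hairpin"), {
    arm5 <- sample_bases(stem_len, gc_bias)
    loop <- sample_bases(loop_len, gc_bias)
    arm3 <- rev(unname(rna_complement[arm5]))
    if (n_mismatches > 0) {
      pos <- sample.int(stem_len, n_mismatches)
      for (p in pos) {
        arm3[p] <- sample(setdiff(c("A", "C", "G", "U"), arm3[p]), 1)
      }
    }
    if (n_bulges > 0) {
      for (b in seq_len(n_bulges)) {
        at <- sample.int(length(arm3) + 1, 1)
        arm3 <- append(arm3, sample_bases(1, gc_bias), after = at - 1)
      }
    }
    tibble::tibble(
      id = id %||% paste0("hairpin_s", seed),
      seq = paste(c(arm5, loop, arm3), collapse = "")
    )
  })
}

#' Generate a random (non-hairpin) sequence
#'
#' I.i.d. nucleotides with the given GC bias; the synthetic stand-in for
#' genome-derived negative windows.
#'
#' @param length Sequence length (>= 1).
#' @param gc_bias Probability of G or C per position.
#' @param seed Integer seed.
#' @param id Record id.
#' @return One-row tibble with `id`, `seq`.
#' @export
make_negative_seq <- function(length, gc_bias = 0.5, seed = 1, id = NULL) {
  stopifnot(length >= 1)
  with_rng_seed(seed_stream(seed, "make_negative_seq"), {
    tibble::tibble(
      id = id %||% paste0("negative_s", seed),
      seq = paste(sample_bases(length, gc_bias), collapse = "")
    )
  })
}

#' Generate a synthetic scored-instance problem
#'
#' Draws classifier scores directly from two Gaussian class distributions,
#' exercising the ROC-select machinery without any classifier: `n_pos`
#' scores from `Normal(pos_mean, pos_sd)` labelled 1 and `n_neg` from
#' `Normal(neg_mean, neg_sd)` labelled 0.
#'
#' @param n_pos,n_neg Class sizes (>= 1).
#' @param pos_mean,pos_sd,neg_mean,neg_sd Score distribution parameters.
#' @param seed Integer seed.
#' @return Tibble with `id`, `score`, `label` (integer, 1 = positive).
#' @export
make_score_problem <- function(n_pos, n_neg, pos_mean = 1, pos_sd = 1,
                               neg_mean = -1, neg_sd = 1, seed = 1) {
  stopifnot(n_pos >= 1, n_neg >= 1)
  with_rng_seed(seed_stream(seed, "make_score_problem"), {
    tibble::tibble(
      id = c(paste0("pos", seq_len(n_pos)), paste0("neg", seq_len(n_neg))),
      score = c(stats::rnorm(n_pos, pos_mean, pos_sd),
                stats::rnorm(n_neg, neg_mean, neg_sd)),
      label = c(rep(1L, n_pos), rep(0L, n_neg))
    )
  })
}

#' Generate a labelled synthetic hairpin dataset
#'
#' Produces `n_pos` hairpin-like positives (configs drawn uniformly from
#' the stated ranges) and `n_neg` random negatives whose lengths are drawn
#' from the empirical positive length distribution, mimicking the
#' length-matched construction of real negative sets. Record ids carry a
#' shuffled running number so lexicographic id order leaks no class
#' information. Optionally writes `positives.fasta`, `negatives.fasta` and
#' a `manifest.tsv` to a directory.
#'
#' Defaults state a realistic candidate-hairpin world: stems of 15-30 bp,
#' loops of 3-10 nt, up to 4 stem mismatches and 2 bulges, GC content
#' 30-70% — the length range (33-72 nt) sits in the short tail of real
#' precursor lengths, and mismatch counts keep positives clearly
#' hairpin-like while negatives are unconstrained random sequence.
#'
#' @param n_pos,n_neg Class sizes.
#' @param stem,loop,mismatches,bulges Two-element integer ranges for the
#'   hairpin generator.
#' @param gc Two-element GC-bias range (applies to both classes).
#' @param seed Master seed; regeneration is byte-identical.
#' @param dir Optional output directory for the FASTA pair + manifest.
#' @return List with tibbles `positives` and `negatives` (columns `id`,
#'   `seq`), and `manifest` (id, class, length).
#' @export
make_dataset <- function(n_pos, n_neg, stem = c(15, 30), loop = c(3, 10),
                         mismatches = c(0, 4), bulges = c(0, 2),
                         gc = c(0.3, 0.7), seed = 1, dir = NULL) {
  cfg_seed <- seed_stream(seed, "make_dataset")
  with_rng_seed(cfg_seed, {
    stems <- sample(stem[1]:stem[2], n_pos, replace = TRUE)
    loops <- sample(loop[1]:loop[2], n_pos, replace = TRUE)
    mms <- sample(mismatches[1]:mismatches[2], n_pos, replace = TRUE)
    bls <- sample(bulges[1]:bulges[2], n_pos, replace = TRUE)
    gcs <- stats::runif(n_pos, gc[1], gc[2])
    neg_gcs <- stats::runif(n_neg, gc[1], gc[2])
    tags <- sample.int(n_pos + n_neg)   # shuffled ids
  })
  pos <- dplyr::bind_rows(lapply(seq_len(n_pos), function(i) {
    make_hairpin(stems[i], loops[i], mms[i], bls[i], gcs[i],
                 seed = seed_stream(seed, paste0("pos", i)),
                 id = sprintf("seq_%05d", tags[i]))
  }))
  pos_lens <- nchar(pos$seq)
  with_rng_seed(seed_stream(seed, "neglens"), {
    neg_lens <- sample(pos_lens, n_neg, replace = TRUE)
  })
  neg <- dplyr::bind_rows(lapply(seq_len(n_neg), function(i) {
    make_negative_seq(neg_lens[i], neg_gcs[i],
                      seed = seed_stream(seed, paste0("neg", i)),
                      id = sprintf("seq_%05d", tags[n_pos + i]))
  }))
  manifest <- tibble::tibble(
    id = c(pos$id, neg$id),
    class = c(rep("mirna", n_pos), rep("pseudo", n_neg)),
    length = c(nchar(pos$seq), nchar(neg$seq))
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_fasta(pos, file.path(dir, "positives.fasta"))
    write_fasta(neg, file.path(dir, "negatives.fasta"))
    readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  }
  list(positives = pos, negatives = neg, manifest = manifest)
}
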