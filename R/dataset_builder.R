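#' Sample pseudo-hairpin negative windows from genomic sequence
#'
#' Draws candidate negative sequences from a genome so that their length
#' distribution matches the positive (known pre-miRNA) set: for each sample
#' a target length is drawn uniformly with replacement from the empirical
#' positive lengths, a source sequence is drawn proportionally to its
#' length, and a start position uniformly at random; windows overrunning
#' the sequence end or containing `N` (assembly gaps fold undefined) are
#' rejected and redrawn up to a retry budget. Windows are taken from the
#' given strand. Emitted ids encode `source:start-end` with 1-based
#' inclusive coordinates.
#'
#' @param genome Tibble with `id`, `seq` (see [read_fasta()]).
#' @param positive_lengths Integer vector of positive-set lengths (the
#'   empirical length distribution to match).
#' @param n Number of windows to sample.
#' @param seed Seed; the sample is fully reproducible.
#' @param max_retries Redraw budget per window before giving up.
#' @return Tibble with `id`, `seq`; sequences contain only `A,C,G,U`.
#' @export
sample_negatives <- function(genome, positive_lengths, n, seed = 1,
                             max_retries = 1000) {
  stopifnot(length(positive_lengths) > 0, n >= 0)
  if (n == 0) return(tibble::tibble(id = character(), seq = character()))
  glens <- nchar(genome$seq)
  if (max(glens) < max(positive_lengths)) {
    stop("no genome sequence is as long as the longest requested window",
         call. = FALSE)
  }
  with_rng_seed(seed, {
    ids <- character(n)
    seqs <- character(n)
    for (s in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(max_retries)) {
        L <- positive_lengths[sample.int(length(positive_lengths), 1)]
        chrom <- sample.int(nrow(genome), 1, prob = glens)
        if (glens[chrom] < L) next
        start <- sample.int(glens[chrom] - L + 1, 1)
        window <- substr(genome$seq[chrom], start, start + L - 1)
        if (grepl("N", window, fixed = TRUE)) next
        ids[s] <- paste0(genome$id[chrom], ":", start, "-", start + L - 1)
        seqs[s] <- window
        ok <- TRUE
        break
      }
      if (!ok) {
        stop("could not draw window ", s, " within ", max_retries,
             " retries (N runs or short sequences)", call. = FALSE)
      }
    }
    tibble::tibble(id = ids, seq = seqs)
  })
}

#' Remove candidate negatives homologous to known miRNA hairpins
#'
#' Candidate negatives that resemble known precursors may be unannotated
#' homologs and must not enter the negative class. Two modes:
#'
#' * `method = "kmer"` (default, dependency-free, deterministic): a
#'   seed-and-extend scan over shared k-mers (`k = 11`); a candidate is
#'   removed when its longest exact-match run with any reference reaches
#'   `min_run` nucleotides (default 20).
#' * `method = "blastn"`: delegate to an external `blastn` executable and
#'   remove candidates producing an E-value at or below `evalue`
#'   (default 1e-2). E-values are database- and version-dependent, which is
#'   why this mode requires the external tool; if the executable is missing
#'   the call errors rather than silently switching modes.
#'
#' @param candidates,references Tibbles with `id`, `seq`.
#' @param method `"kmer"` or `"blastn"`.
#' @param k Seed k-mer length for the built-in mode.
#' @param min_run Removal threshold on the longest exact-match run.
#' @param evalue E-value cutoff for the blastn mode.
#' @param blastn Path to the blastn executable (blastn mode only).
#' @return List with `kept` (tibble of retained candidates) and `removed`
#'   (removal log: `id`, `matched_ref`, `statistic`). Together they
#'   partition the candidates.
#' @export
homology_filter <- function(candidates, references, method = c("kmer", "blastn"),
                            k = 11, min_run = 20, evalue = 1e-2,
                            blastn = "blastn") {
  method <- match.arg(method)
  stopifnot(nrow(references) > 0)
  if (method == "blastn") {
    return(blast_filter(candidates, references, evalue, blastn))
  }
  index <- new.env(hash = TRUE, parent = emptyenv())
  for (r in seq_len(nrow(references))) {
    s <- references$seq[r]
    L <- nchar(s)
    if (L < k) next
    for (p in 1:(L - k + 1)) {
      km <- substr(s, p, p + k - 1)
      index[[km]] <- rbind(index[[km]], c(r, p))
    }
  }
  removed <- list()
  keep <- logical(nrow(candidates))
  for (ci in seq_len(nrow(candidates))) {
    cs <- candidates$seq[ci]
    Lc <- nchar(cs)
    best_run <- 0L
    best_ref <- NA_character_
    if (Lc >= k) {
      for (p in 1:(Lc - k + 1)) {
        km <- substr(cs, p, p + k - 1)
        hits <- index[[km]]
        if (is.null(hits)) next
        for (h in seq_len(nrow(hits))) {
          rr <- hits[h, 1]
          rp <- hits[h, 2]
          rs <- references$seq[rr]
          # extend exact match left and right of the seed
          left <- 0L
          while (p - left - 1 >= 1 && rp - left - 1 >= 1 &&
                 substr(cs, p - left - 1, p - left - 1) ==
                 substr(rs, rp - left - 1, rp - left - 1)) left <- left + 1L
          right <- 0L
          while (p + k + right <= Lc && rp + k + right <= nchar(rs) &&
                 substr(cs, p + k + right, p + k + right) ==
                 substr(rs, rp + k + right, rp + k + right)) right <- right + 1L
          run <- k + left + right
          if (run > best_run) {
            best_run <- run
            best_ref <- references$id[rr]
          }
        }
        if (best_run >= min_run) break   # decision settled for this candidate
      }
    }
    if (best_run >= min_run) {
      removed[[length(removed) + 1]] <- tibble::tibble(
        id = candidates$id[ci], matched_ref = best_ref,
        statistic = as.numeric(best_run))
    } else {
      keep[ci] <- TRUE
    }
  }
  removed_tbl <- if (length(removed)) dplyr::bind_rows(removed) else
    tibble::tibble(id = character(), matched_ref = character(), statistic = numeric())
  list(kept = candidates[keep, , drop = FALSE], removed = removed_tbl)
}

# External-BLAST homology filter; errors if the executable is absent.
blast_filter <- function(candidates, references, evalue, blastn) {
  if (Sys.which(blastn) == "" && !file.exists(blastn)) {
    stop("configured blastn executable '", blastn, "' not found; ",
         "install it or use method = \"kmer\"", call. = FALSE)
  }
  dir <- tempfile("blastdb")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  qf <- file.path(dir, "query.fa")
  rf <- file.path(dir, "ref.fa")
  # BLASTN expects DNA spelling
  write_fasta(dplyr::mutate(candidates, seq = chartr("U", "T", seq)), qf)
  write_fasta(dplyr::mutate(references, seq = chartr("U", "T", seq)), rf)
  db <- file.path(dir, "refdb")
  mk <- system2(Sys.which("makeblastdb"), c("-in", rf, "-dbtype", "nucl", "-out", db),
                stdout = FALSE, stderr = FALSE)
  if (mk != 0) stop("makeblastdb failed", call. = FALSE)
  out <- system2(Sys.which(blastn), c("-query", qf, "-db", db, "-outfmt", "6",
                                      "-evalue", format(evalue, scientific = FALSE)),
                 stdout = TRUE, stderr = FALSE)
  hits <- if (length(out) > 0) {
    utils::read.table(text = out, sep = "\t", stringsAsFactors = FALSE)[, c(1, 2, 11)]
  } else data.frame(V1 = character(), V2 = character(), V11 = numeric())
  names(hits) <- c("id", "matched_ref", "statistic")
  hits <- dplyr::slice_min(dplyr::group_by(hits, id), statistic, n = 1,
                           with_ties = FALSE)
  hits <- dplyr::ungroup(hits)
  removed_ids <- unique(hits$id[hits$statistic <= evalue])
  list(
    kept = candidates[!candidates$id %in% removed_ids, , drop = FALSE],
    removed = tibble::as_tibble(hits[hits$id %in% removed_ids, ])
  )
}

#' Structural quality control of a candidate set
#'
#' Real pre-miRNA hairpins are thermodynamically stable and well paired.
#' This report measures, per record, the length-normalised minimum free
#' energy `mfe / L` and the pairing density `n_bp / L`, and reports the
#' fractions passing the two structural criteria for miRNA-like hairpins:
#' `mfe / L < -0.05` and `n_bp / L > 0.15`. A well-constructed negative set
#' should mostly pass both (pseudo hairpins are chosen to look like real
#' precursors), as should nearly all known precursors.
#'
#' @param records Tibble with `id`, `seq`.
#' @param backend Folding backend.
#' @return One-row tibble: `fraction_mfe_pass`, `fraction_pairing_pass`,
#'   `fraction_both_pass` (percentages; `both <= min(mfe, pairing)`), with
#'   the per-record detail in attribute `detail`. Records that fail to fold
#'   count as failing both criteria.
#' @export
structural_qc <- function(records, backend = "nussinov") {
  if (nrow(records) == 0) stop("empty input: QC fractions undefined", call. = FALSE)
  detail <- vector("list", nrow(records))
  for (r in seq_len(nrow(records))) {
    detail[[r]] <- tryCatch({
      fr <- fold_rna(records$seq[r], backend = backend)
      st <- parse_structure(fr$structure)
      L <- nchar(records$seq[r])
      tibble::tibble(id = records$id[r], mfe_per_len = fr$mfe / L,
                     pairings_per_len = st$n_bp / L,
                     mfe_pass = fr$mfe / L < -0.05,
                     pairing_pass = st$n_bp / L > 0.15)
    }, error = function(e) tibble::tibble(
      id = records$id[r], mfe_per_len = NA_real_, pairings_per_len = NA_real_,
      mfe_pass = FALSE, pairing_pass = FALSE))
  }
  d <- dplyr::bind_rows(detail)
  out <- tibble::tibble(
    fraction_mfe_pass = 100 * mean(d$mfe_pass),
    fraction_pairing_pass = 100 * mean(d$pairing_pass),
    fraction_both_pass = 100 * mean(d$mfe_pass & d$pairing_pass)
  )
  attr(out, "detail") <- d
  out
}

#' Keep experimentally confirmed positives
#'
#' Positive training sets should contain only precursors with experimental
#' support; unsupported annotations risk seeding the positive class with
#' false positives. Evidence flags come in a sidecar table keyed by record
#' id.
#'
#' @param records Tibble with `id`, `seq`.
#' @param evidence Tibble with `id` and logical `evidence`.
#' @return The confirmed records; a message reports kept/total counts and a
#'   warning is raised when nothing survives.
#' @export
filter_positives <- function(records, evidence) {
  stopifnot(all(c("id", "evidence") %in% names(evidence)))
  missing <- setdiff(records$id, evidence$id)
  if (length(missing) > 0) {
    stop("record(s) missing from the evidence sidecar: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  flags <- evidence$evidence[match(records$id, evidence$id)]
  kept <- records[flags, , drop = FALSE]
  message("filter_positives: kept ", nrow(kept), " of ", nrow(records),
          " records with experimental support")
  if (nrow(kept) == 0) warning("no experimentally confirmed records remain",
                               call. = FALSE)
  kept
}
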