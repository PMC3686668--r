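#' Declare the feature set for hairpin classification
#'
#' The data representation couples a configurable base set of
#' sequence/structure features with seven extended attributes specific to
#' pre-miRNA discrimination (`tri_a`, `tri_u`, `tri_g`, `tri_c`, `orf`,
#' `loops`, `dm`). The base set is tiered by what the folding backend can
#' deliver:
#'
#' * Tier A (always computable from an MFE structure): `gc_content`,
#'   normalised free energy `dg = mfe / L`, the MFE indices
#'   `mfei1 = dg / gc_content`, `mfei2 = dg / n_stems`, `mfei4 = mfe / n_bp`,
#'   pairing density `dp = n_bp / L`, per-type pair densities `au_per_len`,
#'   `gc_per_len`, `gu_per_len`, and `avg_bp_stem = n_bp / n_stems`.
#' * Tier B (ensemble features) requires a partition-function backend, which
#'   the built-in maximum-pairing folder does not provide; requesting it
#'   without one is an error.
#' * Tier C: z-scores `z_dg`, `z_dp` of `dg` and `dp` against `n_shuffle`
#'   dinucleotide-preserving shuffles of the sequence (seeded; a zero
#'   shuffle standard deviation yields a z-score of 0).
#'
#' The base set is a documented stand-in for the 21 microPred-selected
#' attributes, which are not enumerated in the source literature; users with
#' the microPred scripts can inject those columns and train on them instead.
#'
#' @param tier `"A"`, `"AC"`, `"AB"` or `"ABC"` (Tier A is always included;
#'   `"AC"` adds the shuffle z-scores without the ensemble tier, the only
#'   extension the built-in backend can serve).
#' @param extended Include the seven extended features (default `TRUE`).
#' @param backend Folding backend tag the features will be computed with.
#' @param n_shuffle Number of dinucleotide shuffles for Tier C.
#' @return An object of class `feature_spec` with the ordered feature names.
#' @export
feature_spec <- function(tier = c("A", "AC", "AB", "ABC"), extended = TRUE,
                         backend = "nussinov", n_shuffle = 100) {
  tier <- match.arg(tier)
  names <- c("gc_content", "dg", "mfei1", "mfei2", "mfei4", "dp",
             "au_per_len", "gc_per_len", "gu_per_len", "avg_bp_stem")
  if (grepl("B", tier)) {
    names <- c(names, "ens_dg", "mfe_freq", "ens_diversity", "pair_entropy")
  }
  if (grepl("C", tier)) names <- c(names, "z_dg", "z_dp")
  if (extended) names <- c(names, "tri_a", "tri_u", "tri_g", "tri_c",
                           "orf", "loops", "dm")
  structure(
    list(feature_names = names, tier = tier, extended = extended,
         backend = backend, n_shuffle = n_shuffle),
    class = "feature_spec"
  )
}

#' @export
print.feature_spec <- function(x, ...) {
  cat("<feature_spec> tier", x$tier,
      if (x$extended) "+ 7 extended features" else "(base only)",
      "| backend:", x$backend, "\n")
  cat("  ", paste(x$feature_names, collapse = ", "), "\n")
  invisible(x)
}

#' Secondary-structure triplet frequencies
#'
#' Frequencies of the four structure triplets with the highest information
#' gain for hairpin discrimination: `"A((("`, `"U((("`, `"G((("`, `"C((("`.
#' Following the triplet-element convention, `)` is first mapped to `(`;
#' for each interior position the element is the three adjacent structure
#' characters plus the middle nucleotide, and each frequency is the pattern
#' count divided by the number of interior windows (`L - 2`).
#'
#' @param seq,structure Equal-length sequence and dot-bracket strings,
#'   length >= 3.
#' @return One-row tibble with `tri_a`, `tri_u`, `tri_g`, `tri_c` in `[0, 1]`.
#' @examples
#' triplet_features("AAAA", "((((")
#' @export
triplet_features <- function(seq, structure) {
  L <- nchar(seq)
  if (L != nchar(structure)) stop("seq and structure lengths differ", call. = FALSE)
  if (L < 3) stop("sequence shorter than 3", call. = FALSE)
  st <- chartr(")", "(", structure)
  sch <- strsplit(toupper(seq), "")[[1]]
  tch <- strsplit(st, "")[[1]]
  inner <- 2:(L - 1)
  win <- paste0(tch[inner - 1], tch[inner], tch[inner + 1])
  hit <- win == "((("
  mid <- sch[inner]
  tibble::tibble(
    tri_a = sum(hit & mid == "A") / (L - 2),
    tri_u = sum(hit & mid == "U") / (L - 2),
    tri_g = sum(hit & mid == "G") / (L - 2),
    tri_c = sum(hit & mid == "C") / (L - 2)
  )
}

#' Longest open reading frame across three forward frames
#'
#' The maximal length, in codons (amino acids), of a run of consecutive
#' non-stop codons (`UAA`, `UAG`, `UGA`) over the three reading frames of
#' the given strand. A hairpin candidate has a defined orientation, so the
#' reverse complement is not scanned. Incomplete trailing codons are
#' dropped; sequences shorter than one codon return 0.
#'
#' @param seq RNA sequence.
#' @return Non-negative integer, at most `floor(L / 3)`.
#' @examples
#' orf_feature("AUGAAAUGA")   # AUG AAA | UGA -> 2
#' @export
orf_feature <- function(seq) {
  s <- chartr("T", "U", toupper(seq))
  L <- nchar(s)
  best <- 0L
  for (frame in 0:2) {
    n_codon <- (L - frame) %/% 3
    if (n_codon < 1) next
    starts <- frame + seq(1, by = 3, length.out = n_codon)
    codons <- substring(s, starts, starts + 2)
    is_stop <- codons %in% c("UAA", "UAG", "UGA")
    run <- 0L
    for (stop_flag in is_stop) {
      run <- if (stop_flag) 0L else run + 1L
      if (run > best) best <- run
    }
  }
  best
}

#' Cumulative internal-loop size
#'
#' The `loops` feature: total number of unpaired bases in internal loops and
#' bulges of the structure (see [parse_structure()] for the loop
#' decomposition). Hairpin loops, multiloops and exterior bases do not
#' contribute.
#'
#' @param stats A row (or rows) from [parse_structure()].
#' @return Integer vector of cumulative internal-loop sizes.
#' @export
loops_feature <- function(stats) {
  stopifnot("internal_loop_total" %in% names(stats))
  stats$internal_loop_total
}

# Tier A base features from a fold + structure stats row; degenerate
# structures (no pairs or stems) define division-by-zero features as 0 so
# genome-window negatives never crash extraction.
tier_a_features <- function(seq, mfe, st) {
  L <- nchar(seq)
  n <- sapply(c("A", "C", "G", "U"), function(b) {
    lengths(regmatches(seq, gregexpr(b, seq, fixed = TRUE)))
  })
  gc <- (n[["G"]] + n[["C"]]) / L
  dg <- mfe / L
  tibble::tibble(
    gc_content = gc,
    dg = dg,
    mfei1 = if (gc > 0) dg / gc else 0,
    mfei2 = if (st$n_stems > 0) dg / st$n_stems else 0,
    mfei4 = if (st$n_bp > 0) mfe / st$n_bp else 0,
    dp = st$n_bp / L,
    au_per_len = st$bp_au / L,
    gc_per_len = st$bp_gc / L,
    gu_per_len = st$bp_gu / L,
    avg_bp_stem = if (st$n_stems > 0) st$n_bp / st$n_stems else 0
  )
}

# Tier C folding z-scores against dinucleotide-preserving shuffles.
tier_c_features <- function(seq, dg, dp, n_shuffle, seed, backend) {
  shuf <- dinucleotide_shuffle(seq, n = n_shuffle, seed = seed)
  fr <- fold_rna(shuf, backend = backend)
  L <- nchar(seq)
  s_dg <- fr$mfe / L
  st <- parse_structure(fr$structure)
  s_dp <- st$n_bp / L
  zf <- function(x, xs) {
    sdv <- stats::sd(xs)
    if (!is.finite(sdv) || sdv == 0) 0 else (x - mean(xs)) / sdv
  }
  tibble::tibble(z_dg = zf(dg, s_dg), z_dp = zf(dp, s_dp))
}

#' Extract feature vectors for candidate sequences
#'
#' Assembles the full fixed-order feature table for a set of candidate
#' hairpin sequences: fold (or reuse supplied structures), decompose the
#' structure, and compute the configured base tiers plus the seven extended
#' features. Records that cannot be processed (containing `N`, or too short
#' to fold) are skipped with a warning and reported in the `failures`
#' attribute; the run continues for the remaining records.
#'
#' @param records Tibble with columns `id` and `seq` (see [read_fasta()]);
#'   an optional `structure` column supplies precomputed dot-brackets, in
#'   which case an `mfe` column is used when present.
#' @param spec A [feature_spec()].
#' @param seed Integer seed driving the Tier C shuffles (one derived stream
#'   per record, so the table is deterministic given `seed` and backend).
#' @return Tibble with column `id` followed by one numeric column per
#'   feature in spec order; attributes `feature_spec` and `failures`
#'   (tibble of `id`, `reason` for skipped records).
#' @examples
#' extract_features(tibble::tibble(id = "h1", seq = strrep("GCA", 12)))
#' @export
extract_features <- function(records, spec = feature_spec(), seed = 1) {
  stopifnot(inherits(spec, "feature_spec"))
  if (grepl("B", spec$tier)) {
    stop("Tier B ensemble features require a partition-function backend, ",
         "which backend '", spec$backend, "' does not provide", call. = FALSE)
  }
  has_structure <- "structure" %in% names(records)
  failures <- list()
  rows <- vector("list", nrow(records))
  for (r in seq_len(nrow(records))) {
    id <- records$id[r]
    seq <- toupper(records$seq[r])
    res <- tryCatch({
      if (grepl("N", seq, fixed = TRUE)) {
        stop("contains N; excluded from feature extraction", call. = FALSE)
      }
      if (has_structure && !is.na(records$structure[r])) {
        structure_str <- records$structure[r]
        mfe <- if ("mfe" %in% names(records) && !is.na(records$mfe[r])) {
          records$mfe[r]
        } else {
          -parse_structure(structure_str)$n_bp
        }
      } else {
        fr <- fold_rna(seq, backend = spec$backend)
        structure_str <- fr$structure
        mfe <- fr$mfe
      }
      st <- parse_structure(structure_str, seq)
      vals <- tier_a_features(seq, mfe, st)
      if (grepl("C", spec$tier)) {
        vals <- dplyr::bind_cols(vals, tier_c_features(
          seq, dg = mfe / nchar(seq), dp = st$n_bp / nchar(seq),
          n_shuffle = spec$n_shuffle,
          seed = seed_stream(seed, paste0("tierC:", id)),
          backend = spec$backend
        ))
      }
      if (spec$extended) {
        vals <- dplyr::bind_cols(
          vals,
          triplet_features(seq, structure_str),
          tibble::tibble(orf = orf_feature(seq),
                         loops = as.numeric(loops_feature(st)),
                         dm = dust_fraction(seq))
        )
      }
      dplyr::bind_cols(tibble::tibble(id = id), vals[spec$feature_names])
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      failures[[length(failures) + 1]] <- tibble::tibble(id = id, reason = res)
    } else {
      rows[[r]] <- res
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::as_tibble(c(list(id = character()),
      stats::setNames(rep(list(numeric()), length(spec$feature_names)),
                      spec$feature_names)))
  }
  fail_tbl <- dplyr::bind_rows(failures)
  if (nrow(fail_tbl) > 0) {
    warning(nrow(fail_tbl), " record(s) skipped during feature extraction: ",
            paste(utils::head(fail_tbl$id, 5), collapse = ", "),
            if (nrow(fail_tbl) > 5) ", ..." else "", call. = FALSE)
  } else {
    fail_tbl <- tibble::tibble(id = character(), reason = character())
  }
  attr(out, "feature_spec") <- spec
  attr(out, "failures") <- fail_tbl
  out
}
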