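#' Predict a secondary structure for candidate hairpins
#'
#' Folds RNA sequences into a single minimum-energy dot-bracket structure.
#' The built-in backend (`"nussinov"`) is a maximum base-pairing dynamic
#' program with canonical Watson-Crick plus G-U wobble pairs, a minimum
#' hairpin loop of 3 unpaired bases, and an energy proxy of -1 kcal/mol per
#' pair, so `mfe == -n_bp`. It exists so the whole pipeline runs with zero
#' external dependencies; structures from a thermodynamic folder can be
#' supplied instead via [read_structures()]. Every feature table and model
#' bundle is tagged with the backend that produced its structures, and
#' mixing backends between training and classification is refused.
#'
#' @param seq Character vector of RNA sequences (alphabet `{A, C, G, U}`,
#'   length >= 10, no `N`).
#' @param backend Folding backend tag; only `"nussinov"` is built in.
#' @return A tibble with columns `seq`, `structure` (dot-bracket, same
#'   length), and `mfe` (kcal/mol; 0 for a structure with no pairs), with
#'   attribute `backend`. Deterministic for a fixed backend.
#' @examples
#' fold_rna("GGGGGAAAACCCCC")
#' @export
fold_rna <- function(seq, backend = "nussinov") {
  if (!identical(backend, "nussinov")) {
    stop("folding backend '", backend, "' is not available; use backend = ",
         "\"nussinov\" or supply precomputed structures via read_structures()",
         call. = FALSE)
  }
  seq <- toupper(seq)
  for (i in seq_along(seq)) {
    if (grepl("N", seq[i], fixed = TRUE)) {
      stop("sequence ", i, " contains N; folding is undefined on N", call. = FALSE)
    }
    if (grepl("[^ACGU]", seq[i])) stop("sequence ", i, " is not RNA", call. = FALSE)
    if (nchar(seq[i]) < 10) {
      stop("sequence ", i, " is shorter than 10 nt; too short to fold", call. = FALSE)
    }
  }
  res <- lapply(seq, nussinov_fold_cpp)
  out <- tibble::tibble(
    seq = seq,
    structure = vapply(res, `[[`, character(1), "structure"),
    mfe = -vapply(res, `[[`, numeric(1), "n_bp")
  )
  attr(out, "backend") <- backend
  out
}

#' Read precomputed dot-bracket structures
#'
#' Parses three-line records (id line, sequence line, structure line in the
#' Vienna dialect). The structure line may carry a trailing energy in
#' parentheses, e.g. `"((....)) (-3.20)"`; when absent the energy is `NA`.
#'
#' @param path Path to the structure file.
#' @param backend Backend tag recorded for the structures.
#' @return A tibble with columns `id`, `seq`, `structure`, `mfe`, tagged
#'   with attribute `backend`.
#' @export
read_structures <- function(path, backend = "external") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) %% 3 != 0) {
    stop("structure file must consist of 3-line records (id/seq/structure)",
         call. = FALSE)
  }
  idx <- seq(1, length(lines), by = 3)
  ids <- sub("^>", "", trimws(lines[idx]))
  seqs <- chartr("T", "U", toupper(trimws(lines[idx + 1])))
  raw <- trimws(lines[idx + 2])
  m <- regmatches(raw, regexec("^([.()]+)(\\s+\\((-?[0-9.]+)\\))?$", raw))
  bad <- which(vapply(m, length, integer(1)) == 0)
  if (length(bad) > 0) stop("record ", bad[1], ": malformed structure line", call. = FALSE)
  structure_str <- vapply(m, `[[`, character(1), 2)
  mfe <- vapply(m, function(x) {
    if (length(x) >= 4 && nzchar(x[4])) as.numeric(x[4]) else NA_real_
  }, numeric(1))
  if (any(nchar(structure_str) != nchar(seqs))) {
    stop("record ", which(nchar(structure_str) != nchar(seqs))[1],
         ": structure and sequence lengths differ", call. = FALSE)
  }
  out <- tibble::tibble(id = ids, seq = seqs, structure = structure_str, mfe = mfe)
  attr(out, "backend") <- backend
  out
}

# Pair table of a dot-bracket string: partner index per position, 0 when
# unpaired. Errors with the first offending index on unbalanced input.
pair_table <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  partner <- integer(length(ch))
  stack <- integer(0)
  for (k in seq_along(ch)) {
    if (ch[k] == "(") {
      stack <- c(stack, k)
    } else if (ch[k] == ")") {
      if (length(stack) == 0) {
        stop("unbalanced structure: unmatched ')' at index ", k, call. = FALSE)
      }
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- k
      partner[k] <- i
    } else if (ch[k] != ".") {
      stop("illegal structure character '", ch[k], "' at index ", k, call. = FALSE)
    }
  }
  if (length(stack) > 0) {
    stop("unbalanced structure: unmatched '(' at index ", stack[1], call. = FALSE)
  }
  partner
}

#' Structural statistics of a dot-bracket structure
#'
#' Decomposes a secondary structure into its loop tree and reports the
#' counts used by the feature set and the structural quality criteria.
#' A stem is a maximal stack of consecutive pairs `(i, j), (i+1, j-1), ...`
#' with no intervening unpaired base on either side. Loops are classified by
#' the number of helices they enclose: a loop with no enclosed helix is a
#' hairpin loop; one enclosed helix plus at least one unpaired base is an
#' internal loop or bulge, and all its unpaired bases count towards
#' `internal_loop_total`; two or more enclosed helices form a multiloop.
#' Unpaired bases outside any pair (the exterior) belong to no loop.
#'
#' @param structure Character vector of balanced dot-bracket strings.
#' @param seq Optional matching sequences; required for the base-pair type
#'   counts (`bp_au`, `bp_gc`, `bp_gu`), which are `NA` otherwise.
#' @return A tibble with one row per structure: `n_bp`, `n_stems`,
#'   `n_loops` (hairpin + internal/bulge + multiloop count),
#'   `internal_loop_total` (cumulative unpaired bases in internal loops and
#'   bulges), `bp_au`, `bp_gc`, `bp_gu`, and `pairings_per_len = n_bp / L`.
#' @examples
#' parse_structure("((..((...))..))")
#' @export
parse_structure <- function(structure, seq = NULL) {
  if (!is.null(seq) && length(seq) != length(structure)) {
    stop("seq and structure lengths differ", call. = FALSE)
  }
  rows <- lapply(seq_along(structure), function(r) {
    st <- structure[r]
    partner <- pair_table(st)
    L <- length(partner)
    opens <- which(strsplit(st, "")[[1]] == "(")
    n_bp <- length(opens)

    # stems: an opening pair starts a new stem unless (i-1, j+1) is a pair
    n_stems <- 0L
    for (i in opens) {
      j <- partner[i]
      if (!(i > 1 && partner[i - 1] == j + 1)) n_stems <- n_stems + 1L
    }

    # loop tree walk over closing pairs
    n_loops <- 0L
    internal_total <- 0L
    for (i in opens) {
      j <- partner[i]
      k <- i + 1
      children <- 0L
      unpaired <- 0L
      while (k < j) {
        if (partner[k] == 0) {
          unpaired <- unpaired + 1L
          k <- k + 1
        } else {
          children <- children + 1L
          k <- partner[k] + 1
        }
      }
      if (children == 0L) {
        n_loops <- n_loops + 1L                       # hairpin loop
      } else if (children == 1L && unpaired > 0L) {
        n_loops <- n_loops + 1L                       # internal loop / bulge
        internal_total <- internal_total + unpaired
      } else if (children >= 2L) {
        n_loops <- n_loops + 1L                       # multiloop
      }
    }

    bp_au <- bp_gc <- bp_gu <- NA_integer_
    if (!is.null(seq)) {
      s <- strsplit(toupper(seq[r]), "")[[1]]
      if (length(s) != L) stop("row ", r, ": seq and structure lengths differ", call. = FALSE)
      pairs <- paste0(s[opens], s[partner[opens]])
      bp_au <- sum(pairs %in% c("AU", "UA"))
      bp_gc <- sum(pairs %in% c("GC", "CG"))
      bp_gu <- sum(pairs %in% c("GU", "UG"))
      if (bp_au + bp_gc + bp_gu != n_bp) {
        stop("row ", r, ": non-canonical pair in structure", call. = FALSE)
      }
    }
    tibble::tibble(
      n_bp = n_bp, n_stems = n_stems, n_loops = n_loops,
      internal_loop_total = internal_total,
      bp_au = bp_au, bp_gc = bp_gc, bp_gu = bp_gu,
      pairings_per_len = if (L > 0) n_bp / L else 0
    )
  })
  dplyr::bind_rows(rows)
}
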