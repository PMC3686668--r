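#' Read candidate RNA sequences from a FASTA file
#'
#' Reads a FASTA file into a tibble of identified RNA sequences. DNA input is
#' accepted: any `T` is mapped to `U` at parse time, and lowercase letters are
#' uppercased. Characters outside the `{A, C, G, U, N}` alphabet are rejected
#' with the offending record and position. `N` is tolerated here because
#' genome windows may contain assembly gaps, but records containing `N` are
#' excluded from feature extraction by default (folding is undefined on `N`);
#' see [extract_features()].
#'
#' @param path Path to a FASTA file. An empty file yields an empty tibble.
#' @return A tibble with columns `id` (character) and `seq` (character over
#'   the RNA alphabet), one row per FASTA record in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "ACGT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0) return(tibble::tibble(id = character(), seq = character()))
  set <- Biostrings::readBStringSet(path)
  ids <- names(set) %||% rep("", length(set))
  ids <- sub("\\s.*$", "", ids)
  seqs <- toupper(as.character(set))
  seqs <- chartr("T", "U", seqs)
  for (i in seq_along(seqs)) {
    if (is.na(ids[i]) || !nzchar(ids[i])) {
      stop("record ", i, ": malformed or empty FASTA header", call. = FALSE)
    }
    if (!nzchar(seqs[i])) {
      stop("record ", i, " (", ids[i], "): empty sequence", call. = FALSE)
    }
    bad <- regexpr("[^ACGUN]", seqs[i])
    if (bad > 0) {
      stop("record ", i, " (", ids[i], "): illegal character '",
           substr(seqs[i], bad, bad), "' at position ", bad, call. = FALSE)
    }
  }
  tibble::tibble(id = unname(ids), seq = unname(seqs))
}

#' Write sequence records to a FASTA file
#'
#' Inverse of [read_fasta()]: writing then reading reproduces the records
#' exactly (sequences are already on the RNA alphabet).
#'
#' @param records Tibble with columns `id` and `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  set <- Biostrings::BStringSet(stats::setNames(records$seq, records$id))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Confusion counts for binary classification
#'
#' Tallies true/false positives and negatives. The positive class is the
#' miRNA class throughout the package; this orientation is fixed.
#'
#' @param predicted,truth Equal-length binary label vectors (logical, 0/1
#'   numeric, or two-valued character/factor; see `positive`).
#' @param positive For character/factor labels, the value denoting the miRNA
#'   class. Inferred for common encodings (`"positive"`, `"mirna"`).
#' @return One-row tibble with columns `tp`, `fp`, `tn`, `fn`. The counts
#'   partition the instances: `tp + fp + tn + fn` equals the input length.
#' @examples
#' confusion(c(1, 1, 0, 0), c(1, 0, 1, 0))
#' @export
confusion <- function(predicted, truth, positive = NULL) {
  if (length(predicted) != length(truth)) {
    stop("predicted and truth have different lengths (",
         length(predicted), " vs ", length(truth), ")", call. = FALSE)
  }
  p <- as_binary_label(predicted, positive)
  t <- as_binary_label(truth, positive)
  tibble::tibble(
    tp = sum(p == 1 & t == 1),
    fp = sum(p == 1 & t == 0),
    tn = sum(p == 0 & t == 0),
    fn = sum(p == 0 & t == 1)
  )
}

#' Sensitivity, specificity and their geometric mean
#'
#' Computes the three evaluation quantities used throughout the package, on
#' the percent scale (0-100): sensitivity `SE = 100 * tp / (tp + fn)`,
#' specificity `SP = 100 * tn / (tn + fp)`, and their geometric mean
#' `Gm = sqrt(SE * SP)`. `Gm` is the headline metric for imbalanced hairpin
#' classification because it penalises sacrificing the minority (miRNA)
#' class: it is zero whenever either SE or SP is zero.
#'
#' @param counts Tibble (or data frame) of confusion counts with columns
#'   `tp`, `fp`, `tn`, `fn`; may have several rows.
#' @return Tibble with columns `se`, `sp`, `gm`, one row per input row.
#' @examples
#' classification_metrics(confusion(c(1, 0, 1), c(1, 0, 0)))
#' @export
classification_metrics <- function(counts) {
  stopifnot(all(c("tp", "fp", "tn", "fn") %in% names(counts)))
  if (any(counts$tp + counts$fn == 0) || any(counts$tn + counts$fp == 0)) {
    stop("metric undefined for single-class sample", call. = FALSE)
  }
  se <- 100 * counts$tp / (counts$tp + counts$fn)
  sp <- 100 * counts$tn / (counts$tn + counts$fp)
  tibble::tibble(se = se, sp = sp, gm = sqrt(se * sp))
}

#' Class imbalance ratio
#'
#' Negative-to-positive count ratio of a dataset, the standard description of
#' how strongly a pre-miRNA classification problem is imbalanced.
#'
#' @param n_pos,n_neg Class counts; `n_pos` must be positive.
#' @return `n_neg / n_pos` as a double.
#' @examples
#' imbalance_ratio(1406, 81228)
#' @export
imbalance_ratio <- function(n_pos, n_neg) {
  if (any(n_pos <= 0)) stop("n_pos must be > 0", call. = FALSE)
  n_neg / n_pos
}
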