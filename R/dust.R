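#' Low-complexity masking (symmetric DUST)
#'
#' Detects low-complexity regions with a symmetric DUST algorithm: within
#' every sliding window the triplet composition of each subwindow is scored
#' as `sum(c_t * (c_t - 1) / 2) / (l - 1)` where `c_t` are triplet counts and
#' `l` the number of triplets; subwindows whose score exceeds `level / 10`
#' are masked, and overlapping masked subwindows are merged. The `dm`
#' feature is the masked percentage of the sequence. Scoring is performed on
#' the `U -> T` transcription, so it is invariant to U/T spelling. The
#' subwindow score threshold defaults to 15 (the tuned value for hairpin
#' candidates) rather than DUST's usual 20; the window is 64 nt.
#'
#' `dust_intervals()` returns the merged masked intervals (1-based,
#' inclusive); `dust_fraction()` returns `100 * masked_bases / L`.
#'
#' @param seq A single sequence (RNA or DNA spelling).
#' @param level Subwindow score threshold; a subwindow is masked when its
#'   score exceeds `level / 10`.
#' @param window Sliding window size in bases.
#' @return `dust_fraction()`: a percentage in `[0, 100]`. `dust_intervals()`:
#'   a tibble with columns `start`, `end`.
#' @examples
#' dust_fraction(strrep("A", 64))   # 100: maximal triplet repetition
#' dust_fraction("ACGUACGGUCAGUCAGGCAUGCAUGGA")
#' @export
dust_fraction <- function(seq, level = 15, window = 64) {
  L <- nchar(seq)
  if (L < 1) stop("empty sequence", call. = FALSE)
  iv <- dust_intervals(seq, level = level, window = window)
  if (nrow(iv) == 0) return(0)
  100 * sum(iv$end - iv$start + 1) / L
}

#' @rdname dust_fraction
#' @export
dust_intervals <- function(seq, level = 15, window = 64) {
  s <- chartr("U", "T", toupper(seq))
  L <- nchar(s)
  empty <- tibble::tibble(start = integer(), end = integer())
  if (L < 4) return(empty)
  codes <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T")) - 1L
  if (anyNA(codes)) codes[is.na(codes)] <- 0L  # N and friends scored as A
  ntrip <- L - 2
  trip <- codes[1:ntrip] * 16L + codes[2:(ntrip + 1)] * 4L + codes[3:(ntrip + 2)]
  thr <- level / 10

  # The union of masked subwindows over all sliding windows equals the union
  # over all subwindows of length <= window: scan each anchor once,
  # extending right up to the window size with incremental triplet counts.
  masked <- logical(L)
  win <- min(window, L)
  for (a in 1:(L - 3)) {
    counts <- integer(64)
    score_num <- 0
    l <- 0L
    hi <- min(a + win - 3, ntrip)   # last triplet start within the window
    for (b3 in a:hi) {
      t <- trip[b3] + 1L
      score_num <- score_num + counts[t]
      counts[t] <- counts[t] + 1L
      l <- l + 1L
      if (l >= 2 && score_num / (l - 1) > thr) {
        masked[a:(b3 + 2)] <- TRUE
      }
    }
  }
  if (!any(masked)) return(empty)
  r <- rle(masked)
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= 3   # discard masked runs shorter than 3
  tibble::tibble(start = begins[keep], end = ends[keep])
}
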