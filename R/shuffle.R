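#' Dinucleotide-preserving sequence shuffle
#'
#' Permutes a sequence while preserving its exact dinucleotide count
#' multiset (Altschul-Erickson Euler-path shuffle). Used to build the null
#' distribution for the folding z-score features: dinucleotide stacking
#' dominates RNA folding energetics, so mononucleotide shuffles would
#' overstate the stability of real hairpins.
#'
#' The dinucleotide multiset of every shuffle is asserted against the input;
#' a violation is a package bug and raises an error.
#'
#' @param seq A single RNA sequence.
#' @param n Number of shuffles to return.
#' @param seed Integer seed; the result is a pure function of `(seq, n, seed)`.
#' @return Character vector of `n` shuffled sequences.
#' @examples
#' dinucleotide_shuffle("GGCAUACGGCAUAC", n = 2, seed = 1)
#' @export
dinucleotide_shuffle <- function(seq, n = 1, seed = 1) {
  s <- strsplit(toupper(seq), "")[[1]]
  L <- length(s)
  if (L <= 3) return(rep(seq, n))
  ref_counts <- dinuc_counts(s)
  with_rng_seed(seed, {
    out <- character(n)
    for (r in seq_len(n)) {
      out[r] <- one_shuffle(s)
      if (!identical(dinuc_counts(strsplit(out[r], "")[[1]]), ref_counts)) {
        stop("internal error: shuffle altered dinucleotide counts", call. = FALSE)
      }
    }
    out
  })
}

dinuc_counts <- function(chars) {
  L <- length(chars)
  table(paste0(chars[-L], chars[-1]))
}

# One Altschul-Erickson shuffle of a character vector. Vertices are the
# distinct letters; edges the consecutive pairs. A random "last edge" tree
# pointing at the terminal vertex is drawn by rejection, the remaining edges
# of each vertex are permuted, and the Euler path is walked.
one_shuffle <- function(s) {
  L <- length(s)
  verts <- unique(s)
  first <- s[1]
  last <- s[L]
  edges <- split(s[-1], factor(s[-L], levels = verts))

  repeat {
    last_edge <- vapply(verts, function(v) {
      if (v == last && length(edges[[v]]) == 0) return(NA_character_)
      if (v == last) return(NA_character_)      # terminal vertex has no last edge
      e <- edges[[v]]
      if (length(e) == 0) return(NA_character_)
      e[sample.int(length(e), 1)]
    }, character(1))
    # check: following last edges from every non-terminal vertex reaches `last`
    ok <- TRUE
    for (v in verts) {
      if (v == last || is.na(last_edge[[v]])) next
      seen <- character(0)
      cur <- v
      while (cur != last) {
        if (cur %in% seen || is.na(last_edge[[cur]])) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- last_edge[[cur]]
      }
      if (!ok) break
    }
    if (ok) break
  }

  # order each vertex's out-edges: random permutation, its last edge final
  pools <- lapply(verts, function(v) {
    e <- edges[[v]]
    le <- last_edge[[v]]
    if (!is.na(le)) {
      k <- match(le, e)
      e <- c(e[-k], le)
      head <- e[-length(e)]
      if (length(head) > 1) head <- head[sample.int(length(head))]
      c(head, le)
    } else {
      if (length(e) > 1) e[sample.int(length(e))] else e
    }
  })
  names(pools) <- verts

  ptr <- stats::setNames(rep(1L, length(verts)), verts)
  out <- character(L)
  out[1] <- first
  cur <- first
  for (k in 2:L) {
    nxt <- pools[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[k] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}
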