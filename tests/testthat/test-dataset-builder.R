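# A small synthetic "genome" for window sampling: three chromosomes of
# random sequence, one with an N run.
make_genome <- function(seed = 1, with_n = FALSE) {
  set.seed(seed)
  g <- tibble::tibble(
    id = c("chr1", "chr2", "chr3"),
    seq = vapply(c(4000, 2500, 1500), function(L) {
      paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = "")
    }, character(1))
  )
  if (with_n) {
    substr(g$seq[1], 1000, 1400) <- strrep("N", 401)
  }
  g
}

test_that("negative windows match the requested length distribution", {
  g <- make_genome()
  expect_equal(nrow(sample_negatives(g, c(80, 90), 0)), 0)

  fixed <- sample_negatives(g, rep(80, 5), 200, seed = 2)
  expect_true(all(nchar(fixed$seq) == 80))
  expect_false(any(grepl("[^ACGU]", fixed$seq)))

  pos_lengths <- sample(c(55:70, 100:140), 400, replace = TRUE)
  neg <- sample_negatives(g, pos_lengths, 5000, seed = 3)
  ks <- suppressWarnings(stats::ks.test(nchar(neg$seq), pos_lengths))
  expect_gt(ks$p.value, 0.01)
})

test_that("window ids encode 1-based source coordinates and sampling is reproducible", {
  g <- make_genome()
  a <- sample_negatives(g, c(60, 75), 50, seed = 7)
  b <- sample_negatives(g, c(60, 75), 50, seed = 7)
  expect_identical(a, b)
  m <- regmatches(a$id, regexec("^(chr[123]):([0-9]+)-([0-9]+)$", a$id))
  expect_true(all(lengths(m) == 4))
  start <- as.integer(vapply(m, `[[`, character(1), 3))
  end <- as.integer(vapply(m, `[[`, character(1), 4))
  expect_equal(end - start + 1, nchar(a$seq))
  for (k in 1:5) {   # the id really addresses the window
    chrom <- vapply(m, `[[`, character(1), 2)[k]
    expect_equal(substr(g$seq[g$id == chrom], start[k], end[k]), a$seq[k])
  }
})

test_that("windows containing N are rejected, impossible requests error", {
  g <- make_genome(with_n = TRUE)
  neg <- sample_negatives(g, rep(120, 3), 300, seed = 5)
  expect_false(any(grepl("N", neg$seq, fixed = TRUE)))
  all_n <- tibble::tibble(id = "chrN", seq = strrep("N", 500))
  expect_error(sample_negatives(all_n, 60, 1, seed = 1, max_retries = 50),
               "retries")
})

test_that("k-mer homology stand-in removes near-identical candidates", {
  set.seed(11)
  ref <- make_hairpin(25, 6, seed = 99, id = "mir-ref")
  # candidate 1: is the reference; candidate 2: one central mismatch in a
  # 56-nt copy (longest run >= 28 >= 20); candidate 3: unrelated
  cand2 <- ref$seq
  mid <- nchar(cand2) %/% 2
  substr(cand2, mid, mid) <- setdiff(c("A", "C", "G", "U"),
                                     substr(cand2, mid, mid))[1]
  cands <- tibble::tibble(
    id = c("c_same", "c_mismatch", "c_unrelated"),
    seq = c(ref$seq, cand2, make_negative_seq(60, seed = 123)$seq)
  )
  res <- homology_filter(cands, ref)
  expect_setequal(res$removed$id, c("c_same", "c_mismatch"))
  expect_equal(res$kept$id, "c_unrelated")
  expect_true(all(res$removed$statistic >= 20))
  expect_equal(res$removed$matched_ref, c("mir-ref", "mir-ref"))
  # partition invariant: nothing lost
  expect_setequal(c(res$kept$id, res$removed$id), cands$id)
})

test_that("a candidate sharing no seed k-mer is always kept", {
  ref <- tibble::tibble(id = "r", seq = strrep("AC", 30))
  cand <- tibble::tibble(id = "c", seq = strrep("GU", 30))
  res <- homology_filter(cand, ref)
  expect_equal(res$kept$id, "c")
  expect_equal(nrow(res$removed), 0)
})

test_that("blastn mode uses the external tool and refuses silently switching", {
  expect_error(homology_filter(tibble::tibble(id = "c", seq = strrep("GCAU", 15)),
                               tibble::tibble(id = "r", seq = strrep("GCAU", 15)),
                               method = "blastn", blastn = "/no/such/blastn"),
               "not found")
  if (nzchar(Sys.which("blastn"))) {
    ref <- make_hairpin(30, 8, seed = 5, id = "ref1")
    cands <- tibble::tibble(id = c("hit", "miss"),
                            seq = c(ref$seq, make_negative_seq(70, seed = 6)$seq))
    res <- homology_filter(cands, ref, method = "blastn")
    expect_true("hit" %in% res$removed$id)
    expect_true(all(res$removed$statistic <= 1e-2))
  }
})

test_that("structural QC reports the two hairpin criteria", {
  hps <- dplyr::bind_rows(lapply(1:10, function(i) {
    make_hairpin(20, 5, seed = i, id = paste0("h", i))
  }))
  qc <- structural_qc(hps)
  expect_equal(qc$fraction_both_pass, 100)
  expect_lte(qc$fraction_both_pass,
             min(qc$fraction_mfe_pass, qc$fraction_pairing_pass))

  homo <- tibble::tibble(id = c("a", "b"), seq = c(strrep("A", 60), strrep("C", 60)))
  qc0 <- structural_qc(homo)
  expect_equal(qc0$fraction_both_pass, 0)
  expect_error(structural_qc(tibble::tibble(id = character(), seq = character())),
               "empty")
})

test_that("pairing density degrades with stem mismatches", {
  # directional counterpart of the QC criteria under the built-in backend:
  # max-pairing keeps even mismatched hairpins above the absolute
  # thresholds, but the densities separate cleanly
  perfect <- dplyr::bind_rows(lapply(1:15, function(i) {
    make_hairpin(15, 5, 0, 0, seed = i, id = paste0("p", i))
  }))
  noisy <- dplyr::bind_rows(lapply(1:15, function(i) {
    make_hairpin(15, 5, 14, 0, seed = i, id = paste0("n", i))
  }))
  dp <- function(x) attr(structural_qc(x), "detail")$pairings_per_len
  expect_gt(mean(dp(perfect)), mean(dp(noisy)) + 0.08)
})

test_that("evidence filtering keeps confirmed positives only", {
  recs <- tibble::tibble(id = c("a", "b", "c"), seq = rep(strrep("GCA", 10), 3))
  ev <- tibble::tibble(id = c("a", "b", "c"), evidence = c(TRUE, FALSE, TRUE))
  expect_message(kept <- filter_positives(recs, ev), "kept 2 of 3")
  expect_equal(kept$id, c("a", "c"))
  expect_message(
    expect_warning(filter_positives(recs, dplyr::mutate(ev, evidence = FALSE)),
                   "no experimentally confirmed"))
  expect_error(filter_positives(recs, ev[1:2, ]), "missing.*: c")
})
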