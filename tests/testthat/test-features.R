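test_that("triplet features match hand enumeration", {
  expect_equal(triplet_features("AAAA", "(((("),
               tibble::tibble(tri_a = 1, tri_u = 0, tri_g = 0, tri_c = 0))
  expect_equal(unlist(triplet_features("GCAU", "....")), c(tri_a = 0, tri_u = 0,
                                                           tri_g = 0, tri_c = 0))
  # after ')' -> '(' mapping "(..)" has no interior "(((" window
  expect_true(all(triplet_features("GCGC", "(..)") == 0))
  expect_error(triplet_features("AC", "(("), "shorter")
  expect_error(triplet_features("ACG", "(("), "differ")
})

test_that("triplet frequencies sum to at most 1", {
  set.seed(13)
  for (i in 1:15) {
    s <- make_negative_seq(sample(12:60, 1), seed = i)$seq
    fr <- fold_rna(s)
    expect_lte(sum(triplet_features(fr$seq, fr$structure)), 1)
  }
})

test_that("orf counts the longest stop-free codon run over three frames", {
  expect_equal(orf_feature("AUGAAAUGA"), 2L)
  expect_equal(orf_feature("UAAUAAUAA"), 2L)
  expect_equal(orf_feature("AC"), 0L)
  # bound: at most floor(L/3) codons
  set.seed(21)
  for (i in 1:15) {
    s <- make_negative_seq(sample(3:80, 1), seed = i + 100)$seq
    expect_lte(orf_feature(s), nchar(s) %/% 3)
  }
})

test_that("loops feature returns the cumulative internal-loop size", {
  expect_equal(loops_feature(parse_structure("((((...))))")), 0L)
  expect_equal(loops_feature(parse_structure("((..((...))))")), 2L)
  expect_equal(loops_feature(parse_structure("((..((...))..))")), 4L)
})

test_that("DUST masks homopolymers fully and de Bruijn sequences not at all", {
  expect_equal(dust_fraction(strrep("A", 64)), 100)
  expect_equal(dust_fraction(debruijn64()), 0)
  # U/T invariance by construction
  s <- "ACGUUUUUUUUUUUUUUUUUUUUUUACG"
  expect_equal(dust_fraction(s), dust_fraction(chartr("U", "T", s)))
})

test_that("DUST agrees with the external dustmasker oracle on clear cases", {
  dm <- Sys.which("dustmasker")
  expect_true(nzchar(dm))  # shipped with the BLAST suite in this image
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">homo", strrep("A", 64), ">db", debruijn64()), fa)
  out <- system2(dm, c("-in", fa, "-level", "15", "-outfmt", "acclist"),
                 stdout = TRUE)
  # oracle masks the homopolymer end to end and leaves the de Bruijn alone
  expect_equal(out, ">homo\t0\t63")
  expect_equal(dust_fraction(strrep("A", 64), level = 15), 100)
  expect_equal(dust_fraction(debruijn64(), level = 15), 0)
})

test_that("DUST masked count never decreases when appending a masked block", {
  set.seed(5)
  for (i in 1:8) {
    s <- make_negative_seq(50, seed = i + 300)$seq
    base <- dust_fraction(s) * nchar(s) / 100
    ext <- paste0(s, strrep("AU", 32))
    expect_gte(dust_fraction(ext) * nchar(ext) / 100, base)
  }
})

test_that("dinucleotide shuffle preserves the dinucleotide multiset", {
  set.seed(2)
  for (i in 1:10) {
    s <- make_negative_seq(sample(20:80, 1), gc_bias = runif(1, .2, .8),
                           seed = i + 40)$seq
    counts <- function(x) {
      ch <- strsplit(x, "")[[1]]
      sort(table(paste0(ch[-length(ch)], ch[-1])))
    }
    for (sh in dinucleotide_shuffle(s, n = 3, seed = i)) {
      expect_identical(counts(sh), counts(s))
    }
  }
  expect_identical(dinucleotide_shuffle("AAAAAAAA", 2, seed = 1),
                   c("AAAAAAAA", "AAAAAAAA"))
})

test_that("degenerate structures yield zeroed normalised features", {
  ft <- extract_features(tibble::tibble(id = "h", seq = strrep("A", 20)))
  expect_equal(ft$dg, 0)
  expect_equal(ft$dp, 0)
  expect_equal(ft$mfei1, 0)
  expect_equal(ft$mfei2, 0)
  expect_equal(ft$mfei4, 0)
  expect_equal(ft$avg_bp_stem, 0)
})

test_that("a pure G-C stem gives the expected pairing densities", {
  # 20 G + 4 A loop + 20 C: only G-C pairs are possible
  seqs <- paste0(strrep("G", 20), "AAAA", strrep("C", 20))
  ft <- extract_features(tibble::tibble(id = "gc", seq = seqs))
  expect_equal(ft$dp, 20 / 44)
  expect_equal(ft$gc_per_len, 20 / 44)
  expect_equal(ft$au_per_len, 0)
})

test_that("extraction has the declared arity, determinism, and error collection", {
  spec <- feature_spec()
  recs <- tibble::tibble(
    id = c("a", "b", "bad", "dup"),
    seq = c(perfect_hairpin_seq(seed = 1), perfect_hairpin_seq(seed = 2),
            "ACGUNACGUACGUA", perfect_hairpin_seq(seed = 1))
  )
  expect_warning(ft <- extract_features(recs, spec), "skipped")
  expect_equal(ncol(ft), 1 + 10 + 7)   # id + tier A + 7 extended
  expect_equal(names(ft)[-1], spec$feature_names)
  expect_equal(nrow(ft), 3)
  expect_equal(attr(ft, "failures")$id, "bad")
  # identical sequences yield identical vectors
  expect_equal(unlist(ft[ft$id == "a", -1]), unlist(ft[ft$id == "dup", -1]))
  expect_true(all(is.finite(as.matrix(ft[-1]))))
})

test_that("feature tables survive a TSV round trip to 12 significant digits", {
  recs <- dplyr::bind_rows(lapply(1:4, function(i) {
    make_hairpin(12, 5, 2, 1, seed = i, id = paste0("h", i))
  }))
  ft <- extract_features(recs)
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(ft, f)
  back <- readr::read_tsv(f, show_col_types = FALSE)
  for (cn in names(ft)[-1]) {
    expect_equal(back[[cn]], ft[[cn]], tolerance = 1e-12)
  }
})

test_that("feature tiers gate on backend capability", {
  expect_error(extract_features(tibble::tibble(id = "x", seq = strrep("GCA", 8)),
                                feature_spec(tier = "AB")),
               "partition-function")
  spec_c <- feature_spec(tier = "AC", n_shuffle = 10)
  ft <- extract_features(tibble::tibble(id = "x", seq = perfect_hairpin_seq(seed = 3)),
                         spec_c, seed = 5)
  expect_true(all(c("z_dg", "z_dp") %in% names(ft)))
  # a stable hairpin is far more paired than its dinucleotide shuffles
  expect_lt(ft$z_dg, 0)
  # shuffle fixed point: homopolymer has sd 0 across shuffles -> z = 0
  ft0 <- extract_features(tibble::tibble(id = "h", seq = strrep("A", 20)),
                          spec_c, seed = 5)
  expect_equal(ft0$z_dg, 0)
  expect_equal(ft0$z_dp, 0)
})
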