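test_that("window extraction matches direct substring of the genome", {
  set.seed(1)
  contig <- paste(sample(c("A", "C", "G", "T"), 1e4, replace = TRUE),
                  collapse = "")
  genome <- Biostrings::DNAStringSet(setNames(contig, "chrT"))
  v <- tibble::tibble(variant_id = c("a", "b"), chrom = "chrT",
                      pos = c(100L, 30L))
  w <- extract_windows(v, genome, flank = 75)
  expect_equal(w$start, c(25L, 1L))
  expect_equal(w$end, c(175L, 105L))
  expect_equal(nchar(w$sequence), c(151L, 105L))
  expect_equal(w$clipped, c(FALSE, TRUE))
  expect_equal(w$sequence[1], substr(contig, 25, 175))
  expect_equal(w$sequence[2], substr(contig, 1, 105))

  vb <- tibble::tibble(variant_id = "x", chrom = "chrT", pos = 2e4L)
  expect_error(extract_windows(vb, genome), "x")
  vz <- tibble::tibble(variant_id = "z", chrom = "chrZ", pos = 5L)
  expect_error(extract_windows(vz, genome), "chrZ")
})

test_that("planted k-mer recovery under the random background", {
  w <- simulate_motif_windows(200, 151, "TCAAGTG", 0.4, seed = 3)
  km <- kmer_overrepresentation(w, 6:8, background = "random", seed = 3)
  top7 <- km$kmer[km$k == 7][1]
  expect_true(top7 %in% c("TCAAGTG", "CACTTGA"))  # motif or its rev comp
  expect_true(km$significant[km$kmer == top7][1])
  # E-value bookkeeping: e = p * number of distinct canonical words per k
  for (kk in 6:8) {
    sub <- km[km$k == kk, ]
    expect_equal(sub$e_value, sub$p * nrow(sub))
  }
})

test_that("null windows yield no significant k-mers", {
  n_sig <- vapply(1:10, function(s) {
    w <- simulate_motif_windows(100, 151, "TCAAGTG", 0, seed = 100 + s)
    km <- kmer_overrepresentation(w, 6:7, background = "random",
                                  seed = 100 + s)
    sum(km$significant)
  }, numeric(1))
  expect_gte(mean(n_sig == 0), 0.9)
})

test_that("significant k-mer families are reverse-complement invariant", {
  w <- simulate_motif_windows(120, 101, "TCAAGTG", 0.5, seed = 4)
  rc <- dplyr::mutate(w, sequence = as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(sequence))))
  k1 <- kmer_overrepresentation(w, 6:7)
  k2 <- kmer_overrepresentation(rc, 6:7)
  expect_setequal(k1$kmer[k1$significant], k2$kmer[k2$significant])
  # counts are identical word by word under canonical collapsing
  m <- match(k1$kmer, k2$kmer)
  expect_equal(k1$observed, k2$observed[m])
})

test_that("intrinsic Markov background predicts iid composition", {
  w <- simulate_motif_windows(150, 151, "TCAAGTG", 0, seed = 5)
  km <- kmer_overrepresentation(w, 6, background = "intrinsic")
  n_trials <- 150 * (151 - 6 + 1)
  # canonical 6-mers pool a word and its reverse complement: ~2/4^6 each
  expect_equal(median(km$expected), n_trials * 2 / 4^6, tolerance = 0.25)
  expect_error(kmer_overrepresentation(w[1:5, ], 6), "at least 10")
  expect_error(kmer_overrepresentation(w, 200), "shortest window")
})

test_that("PSSM assembly merges overlapping words into one consensus", {
  km <- tibble::tibble(kmer = c("TCAAGT", "CAAGTG"), k = 6L,
                       observed = c(90L, 80L), expected = 10,
                       p = c(1e-20, 1e-15), e_value = c(1e-17, 1e-12),
                       significant = TRUE)
  ps <- assemble_pssms(km)
  expect_length(ps, 1)
  expect_equal(ps[[1]]$width, 7L)
  expect_equal(ps[[1]]$consensus, "TCAAGTG")
  expect_equal(colSums(ps[[1]]$mat), rep(1, 7), tolerance = 1e-9,
               ignore_attr = TRUE)

  # single k-mer: width-k near-degenerate PSSM
  one <- assemble_pssms(km[1, ])
  expect_equal(one[[1]]$width, 6L)
  expect_gt(min(apply(one[[1]]$mat, 2, max)), 0.9)

  # no qualifying overlap: two separate PSSMs
  km2 <- tibble::tibble(kmer = c("AAAAAA", "GTGTGC"), k = 6L,
                        observed = c(50L, 40L), expected = 5,
                        p = c(1e-10, 1e-8), e_value = c(1e-7, 1e-5),
                        significant = TRUE)
  expect_length(assemble_pssms(km2), 2)

  expect_error(assemble_pssms(dplyr::mutate(km, significant = FALSE)),
               "no significant")
})

test_that("reverse-complement words merge into the same cluster", {
  km <- tibble::tibble(kmer = c("TCAAGT", "ACTTGA"), k = 6L,
                       observed = c(90L, 80L), expected = 10,
                       p = c(1e-20, 1e-15), e_value = c(1e-17, 1e-12),
                       significant = TRUE)
  ps <- assemble_pssms(km)  # ACTTGA is the reverse complement of TCAAGT
  expect_length(ps, 1)
  expect_equal(ps[[1]]$consensus, "TCAAGT")
})

test_that("annotation self- and reverse-complement matches score 1", {
  lib <- list(m1 = consensus_pssm("TCAAGTG", "m1"),
              m2 = consensus_pssm("GGGATTAC", "m2"))
  q <- consensus_pssm("TCAAGTG", "query")
  a <- annotate_pssms(q, lib)
  expect_equal(a$match_id, "m1")
  expect_equal(a$score, 1, tolerance = 1e-9)
  expect_equal(a$orientation, "forward")

  qrc <- consensus_pssm("CACTTGA", "query_rc")
  arc <- annotate_pssms(qrc, lib)
  expect_equal(arc$match_id, "m1")
  expect_equal(arc$score, 1, tolerance = 1e-9)
  expect_equal(arc$orientation, "reverse")
})

test_that("column-shuffled queries rarely reach high similarity", {
  lib <- list(m1 = consensus_pssm("TCAAGTG", "m1"))
  q <- consensus_pssm("TCAAGTG", "q")
  set.seed(6)
  n_high <- 0L
  for (i in 1:50) {
    perm <- sample(7)
    # shuffle columns until the motif order is actually broken
    while (all(perm == 1:7)) perm <- sample(7)
    qs <- pssm(q$mat[, perm], "shuffled")
    sc <- annotate_pssms(qs, lib)$score
    if (sc >= 0.75) n_high <- n_high + 1L
  }
  expect_gte((50 - n_high) / 50, 0.9)
})

test_that("pssm constructor validates probability columns", {
  bad <- matrix(0.3, 4, 5)
  expect_error(pssm(bad, "bad"), "sum to 1")
  ok <- matrix(0.25, 4, 5)
  p <- pssm(ok, "flat")
  expect_equal(p$width, 5L)
})
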