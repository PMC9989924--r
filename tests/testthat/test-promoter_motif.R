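test_that("read_promoters parses tss tokens and validates sequences", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">prom1 tss=40", paste(rep("ACGT", 12), collapse = ""),
               ">prom2", "acgtacgtn"), fa)
  proms <- read_promoters(fa)
  expect_named(proms, c("prom1", "prom2"))
  expect_equal(proms$prom1$tss_offset, 40L)
  # lacking a tss token the whole record is upstream: offset = length
  expect_equal(proms$prom2$tss_offset, 9L)
  # lowercase input uppercased, length preserved
  expect_equal(proms$prom2$sequence, "ACGTACGTN")

  writeLines(c(">bad tss=5", "ACGU"), fa)
  expect_error(read_promoters(fa), "position")
  writeLines(c(">bad tss=99", "ACGT"), fa)
  expect_error(read_promoters(fa), "tss_offset out of range")
})

test_that("interval_length counts closed no-zero intervals", {
  # the TSS-crossing promoter fragment: 969 positions
  expect_equal(interval_length(-931, 38), 969L)
  expect_equal(interval_length(-210, -203), 8L)
  expect_equal(interval_length(1, 5), 5L)
  expect_equal(interval_length(-1, 1), 2L)
  expect_error(interval_length(0, 5), "no position 0")
  expect_error(interval_length(-5, 0), "no position 0")
  expect_error(interval_length(5, 1), "start")

  # brute-force enumeration oracle over random pairs
  set.seed(99)
  for (i in 1:1000) {
    a <- sample(c(-500:-1, 1:500), 1)
    b <- sample(c(-500:-1, 1:500), 1)
    lo <- min(a, b); hi <- max(a, b)
    expect_identical(interval_length(lo, hi),
                     as.integer(oracle_interval_length(lo, hi)))
  }
})

test_that("TSS-relative coordinate mapping is a bijection with no zero", {
  prom <- promoter_sequence("p", paste(rep("ACGTA", 10), collapse = ""),
                            tss_offset = 30)
  expect_equal(to_tss_relative(prom, 30), 1L)
  expect_equal(to_tss_relative(prom, 29), -1L)
  expect_equal(to_tss_relative(prom, 50), 21L)
  expect_equal(to_tss_relative(prom, 1), -29L)
  coords <- to_tss_relative(prom, 1:50)
  expect_false(0 %in% coords)
  expect_identical(from_tss_relative(prom, coords), 1:50)
  expect_error(to_tss_relative(prom, 51), "out of range")
  expect_error(from_tss_relative(prom, 0), "no position 0")
})

test_that("iupac_edit_distance matches the DP oracle", {
  expect_equal(iupac_edit_distance("TGATGNAAN", "TGATGCAAT"), 0L)
  d <- iupac_edit_distance("TGATGNAAN", "TCAGCAAA")
  expect_identical(d, oracle_edit_distance("TGATGNAAN", "TCAGCAAA"))
  set.seed(21)
  for (i in 1:50) {
    pat <- paste(sample(c("A", "C", "G", "T", "N", "R", "Y", "W", "S"),
                        sample(4:9, 1), replace = TRUE), collapse = "")
    win <- random_dna(sample(3:11, 1))
    expect_identical(iupac_edit_distance(pat, win),
                     oracle_edit_distance(pat, win))
  }
})

test_that("scan_consensus reports exact degenerate matches with coordinates", {
  prom <- promoter_sequence("p", paste0(strrep("C", 20), "TGATGCAAT",
                                        strrep("G", 20)), tss_offset = 45)
  pat <- motif_pattern("TGATGNAAN", 0)
  hits <- scan_consensus(prom, pat)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$edit_distance, 0L)
  expect_equal(hits$matched, "TGATGCAAT")
  expect_equal(interval_length(hits$start, hits$end), 9L)
  expect_equal(hits$start, to_tss_relative(prom, 21))

  # forward-strand contract: the reverse complement is not found
  rc_prom <- promoter_sequence("rc", paste0(strrep("C", 20), "ATTGCATCA",
                                            strrep("G", 20)), tss_offset = 45)
  expect_equal(nrow(scan_consensus(rc_prom, pat)), 0)
  expect_equal(nrow(scan_consensus(rc_prom, pat, both_strands = TRUE)), 1)
  expect_equal(scan_consensus(rc_prom, pat, both_strands = TRUE)$strand, "-")

  # pattern longer than the sequence: empty result, not an error
  tiny <- promoter_sequence("t", "ACGT", tss_offset = 4)
  expect_equal(nrow(scan_consensus(tiny, motif_pattern("TGATGNAAN", 0))), 0)
})

test_that("a planted CARE-like site is recovered at its exact TSS span", {
  # 300-nt synthetic promoter, TSS at string index 260, so string positions
  # 50..57 are TSS-relative -210..-203 -- the span of the reported 8-mer
  set.seed(31)
  site <- "TCAGCAAA"
  d <- oracle_edit_distance("TGATGNAAN", site)
  repeat {
    bg <- random_dna(300)
    seq <- paste0(substr(bg, 1, 49), site, substr(bg, 58, 300))
    prom <- promoter_sequence("planted", seq, tss_offset = 260)
    hits <- scan_consensus(prom, motif_pattern("TGATGNAAN", d))
    # regenerate in the (unlikely) event the random flanks spawn a
    # second, closer hit overlapping the planted span
    planted <- hits[hits$start == -210 & hits$end == -203, ]
    if (nrow(planted) == 1) break
  }
  expect_equal(planted$matched, site)
  expect_equal(planted$edit_distance, d)
  expect_equal(interval_length(planted$start, planted$end), 8L)
})

test_that("zero-edit scanning agrees with the naive degenerate matcher", {
  set.seed(41)
  pat <- motif_pattern("TGASNRAA", 0)
  for (i in 1:30) {
    seq <- random_dna(150)
    prom <- promoter_sequence(paste0("r", i), seq, tss_offset = 75)
    hits <- scan_consensus(prom, pat)
    starts_impl <- sort(from_tss_relative(prom, hits$start))
    expect_identical(starts_impl, sort(oracle_naive_match(seq, "TGASNRAA")))
    if (nrow(hits)) expect_true(all(hits$edit_distance == 0L))
  }
})
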