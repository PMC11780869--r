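test_that("UMI collapse removes Hamming<=1 duplicates and keeps distinct reads", {
  rec <- alignmentRecords(strand = "+", fivePrimePos = c(100L, 100L),
                          threePrimePos = c(150L, 150L),
                          umi = "AAAACCCC",
                          readSeq = c("ACGTACGT", "ACGTACGA"))
  expect_equal(nrow(collapseUmis(rec)), 1L)

  rec2 <- alignmentRecords(strand = "+", fivePrimePos = c(100L, 100L),
                           threePrimePos = c(150L, 150L),
                           umi = "AAAACCCC",
                           readSeq = c("ACGTACGT", "ACGTAGGA"))
  expect_equal(nrow(collapseUmis(rec2)), 2L)

  # different UMIs never collapse
  rec3 <- alignmentRecords(strand = "+", fivePrimePos = c(100L, 100L),
                           threePrimePos = c(150L, 150L),
                           umi = c("AAAACCCC", "AAAACCCG"),
                           readSeq = c("ACGTACGT", "ACGTACGT"))
  expect_equal(nrow(collapseUmis(rec3)), 2L)
})

test_that("UMI collapse matches the exhaustive pairwise clustering oracle", {
  set.seed(42)
  n <- 100L
  baseSeqs <- vapply(seq_len(50), function(i)
    paste(sample(c("A", "C", "G", "T"), 12, replace = TRUE), collapse = ""),
    character(1))
  # 50 exact duplicate pairs
  rec <- alignmentRecords(
    strand = "+",
    fivePrimePos = rep(sample(1000:2000, 50L), each = 2L),
    threePrimePos = 3000L,
    umi = rep(vapply(seq_len(50), function(i)
      paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE),
            collapse = ""), character(1)), each = 2L),
    readSeq = rep(baseSeqs, each = 2L))
  out <- collapseUmis(rec)
  expect_equal(nrow(out), 50L)
  expect_equal(nrow(out), oracleUmiClusterCount(rec))

  # idempotence
  expect_identical(collapseUmis(out), out)

  # random messy pool against the oracle
  set.seed(7)
  pool <- alignmentRecords(
    strand = "+",
    fivePrimePos = sample(100:105, 80L, replace = TRUE),
    threePrimePos = 500L,
    umi = sample(c("AAAAAAAA", "CCCCCCCC", "GGGGGGGG"), 80L, replace = TRUE),
    readSeq = vapply(seq_len(80), function(i) {
      s <- rep("A", 10); s[sample(10, sample(0:2, 1))] <- "G"
      paste(s, collapse = "")
    }, character(1)))
  expect_equal(nrow(collapseUmis(pool)), oracleUmiClusterCount(pool))
})

test_that("mixed UMI presence is rejected", {
  expect_error(
    alignmentRecords(strand = "+", fivePrimePos = c(1L, 2L),
                     threePrimePos = c(10L, 11L),
                     umi = c("AAAACCCC", NA), readSeq = c("AC", "AC")),
    "mixed")
  rec <- alignmentRecords(strand = "+", fivePrimePos = c(1L, 2L),
                          threePrimePos = c(10L, 11L),
                          umi = "AAAACCCC", readSeq = c("AC", "AC"))
  rec$umi[2] <- NA
  expect_error(collapseUmis(rec), "UMI")
})

test_that("end-track construction places termini and reattributes first-position mismatches", {
  genome <- GenomeRef("g", paste(rep("A", 300), collapse = ""))
  rec <- alignmentRecords(strand = "+", fivePrimePos = 100L,
                          threePrimePos = 150L, firstPosMismatch = FALSE)
  tr <- buildEndTracks(rec, genome)
  expect_equal(trackValues(tr[["rend5p.+"]])[100], 1)
  expect_equal(trackValues(tr[["rend3p.+"]])[150], 1)

  # mismatch at the first read position moves the 5' count 1 nt 3'-ward
  recM <- alignmentRecords(strand = "+", fivePrimePos = 100L,
                           threePrimePos = 150L, firstPosMismatch = TRUE)
  trM <- buildEndTracks(recM, genome)
  expect_equal(trackValues(trM[["rend5p.+"]])[101], 1)
  expect_equal(trackValues(trM[["rend5p.+"]])[100], 0)

  # strand symmetry: 3' direction is decreasing coordinates on the minus strand
  recMin <- alignmentRecords(strand = "-", fivePrimePos = 200L,
                             threePrimePos = 150L, firstPosMismatch = TRUE)
  trMin <- buildEndTracks(recMin, genome)
  expect_equal(trackValues(trMin[["rend5p.-"]])[199], 1)

  # read-count conservation over a random pool
  set.seed(3)
  pool <- alignmentRecords(strand = sample(c("+", "-"), 200, replace = TRUE),
                           fivePrimePos = sample(50:250, 200, replace = TRUE),
                           threePrimePos = sample(50:250, 200, replace = TRUE),
                           firstPosMismatch = sample(c(TRUE, FALSE), 200,
                                                     replace = TRUE))
  trs <- buildEndTracks(pool, genome)
  expect_equal(sum(trackValues(trs[["rend5p.+"]])) +
               sum(trackValues(trs[["rend5p.-"]])), 200)
  expect_equal(sum(vapply(trs, function(t) sum(trackValues(t)),
                          numeric(1))), 400)

  # termini outside the genome are skipped with a warning
  recBad <- alignmentRecords(strand = "+", fivePrimePos = c(100L, 299L),
                             threePrimePos = c(150L, 350L))
  expect_warning(trB <- buildEndTracks(recBad, genome), "skipped")
  expect_equal(sum(trackValues(trB[["rend5p.+"]])), 1)
})

test_that("RPM normalization scales by millions of CDS-mapped reads", {
  tr <- EndTrack("endseq5p", "+", c(5, 0, 3))
  expect_equal(trackValues(normalizeRpm(tr, 1e6)), c(5, 0, 3))
  expect_equal(trackValues(normalizeRpm(tr, 5e5)), c(10, 0, 6))
  expect_equal(trackUnits(normalizeRpm(tr, 5e5)), "RPM")
  expect_error(normalizeRpm(normalizeRpm(tr, 1e6), 1e6), "already")
  expect_error(normalizeRpm(tr, 0), "cdsMappedTotal")
})

test_that("wig round-trip reproduces track values", {
  genome <- GenomeRef("g", paste(rep("A", 500), collapse = ""))
  set.seed(5)
  v <- numeric(500)
  v[sample(500, 40)] <- round(rlnorm(40, 1, 1), 4)
  tr <- EndTrack("rend3p", "+", v)
  path <- tempfile(fileext = ".wig")
  writeTrackWig(tr, path)
  back <- readTrackWig(path, genome, "rend3p", "+")
  expect_equal(trackValues(back), v, tolerance = 1e-6)
})

test_that("SAM records parse termini, UMIs, and first-position mismatches", {
  sam <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:genome\tLN:1000",
    paste("r1_UMI:ACGTACGT", 0, "genome", 101, 42, "10M", "*", 0, 0,
          "AAAAAAAAAA", "*", "MD:Z:10", sep = "\t"),
    paste("r2_UMI:TTTTCCCC", 16, "genome", 201, 42, "10M", "*", 0, 0,
          "AAAAAAAAAA", "*", "MD:Z:9A0", sep = "\t"),
    paste("r3_UMI:GGGGCCCC", 0, "genome", 301, 42, "10M", "*", 0, 0,
          "AAAAAAAAAA", "*", "MD:Z:0T9", sep = "\t"))
  path <- tempfile(fileext = ".sam")
  writeLines(sam, path)
  rec <- readSamRecords(path)
  expect_equal(nrow(rec), 3L)
  r1 <- rec[rec$umi == "ACGTACGT", ]
  expect_equal(r1$strand, "+")
  expect_equal(r1$fivePrimePos, 101L)
  expect_equal(r1$threePrimePos, 110L)
  expect_false(r1$firstPosMismatch)
  # minus-strand read: 5' terminus at the reference end; MD ending in
  # <base>0 marks a mismatch at the read's first position
  r2 <- rec[rec$umi == "TTTTCCCC", ]
  expect_equal(r2$strand, "-")
  expect_equal(r2$fivePrimePos, 210L)
  expect_equal(r2$threePrimePos, 201L)
  expect_true(r2$firstPosMismatch)
  r3 <- rec[rec$umi == "GGGGCCCC", ]
  expect_true(r3$firstPosMismatch)
})

test_that("strain manifest round-trips a simulated strain", {
  sim <- simulateScenario(syntheticScenario(
    seed = 2L, genomeLength = 12000L, nTranscripts = 6L, nSitesY = 3L,
    nPairsIII = 0L, nSitesEndoA = 0L))
  strain <- simulateStrainTracks(sim, "rnjA")
  dir <- tempfile()
  man <- writeStrainManifest(list(strain), dir)
  back <- readStrainManifest(man, sim$genome)
  expect_equal(names(back), strain@strain)
  expect_equal(genotype(back[[1]]), "rnjA")
  for (key in c("endseq5p.+", "rend3p.-")) {
    ch <- strsplit(key, ".", fixed = TRUE)[[1]]
    expect_equal(trackValues(getTrack(back[[1]], ch[1], ch[2])),
                 trackValues(getTrack(strain, ch[1], ch[2])),
                 tolerance = 1e-5)
  }
})
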