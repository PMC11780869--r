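test_that("folding engine reproduces hand-checked structures", {
  f <- foldRegion("GGGGAAAACCCC")
  expect_equal(pairingMap(f)[1:4], c(12L, 11L, 10L, 9L))
  expect_equal(foldEnergy(f), -9) # three stacked G-C pairs
  expect_equal(dotBracket(f), "((((....))))")

  hp <- foldRegion("AAAAAAAAAA")
  expect_equal(foldEnergy(hp), 0)
  expect_true(all(pairingMap(hp) == 0L))

  expect_error(foldRegion("ACGX"), "non-RNA")
})

test_that("folding equals the exhaustive-enumeration optimum on short sequences", {
  set.seed(23)
  for (i in 1:14) {
    n <- sample(8:14, 1)
    seq <- randomRna(n)
    expect_equal(foldEnergy(foldRegion(seq)), oracleEnumMfe(seq),
                 info = seq)
  }
})

test_that("folding MFE is symmetric under sequence reversal", {
  # the symmetric stacking model maps each pair class onto an equal-energy
  # class under reversal (G.U <-> U.G etc.); note reverse COMPLEMENT is not
  # a symmetry of any wobble-containing model, since G.U complements to the
  # unpairable A.C
  set.seed(29)
  for (i in 1:10) {
    seq <- randomRna(sample(10:14, 1))
    rev <- paste(rev(strsplit(seq, "")[[1]]), collapse = "")
    mfe <- foldEnergy(foldRegion(seq))
    expect_equal(mfe, foldEnergy(foldRegion(rev)), info = seq)
    expect_equal(mfe, oracleEnumMfe(seq), info = seq)
  }
})

test_that("co-occurring sites pair within 1 kb on the same strand", {
  sites <- rbind(toySite(100L), toySite(400L), toySite(1200L))
  pairs <- pairCooccurringSites(sites)
  expect_equal(nrow(pairs), 2L) # 100-400 and 400-1200; 100-1200 too far
  p1 <- pairs[pairs$junction1 == 100L, ]
  expect_equal(p1$genomicDistance, 300L)

  none <- pairCooccurringSites(rbind(toySite(100L), toySite(1200L)))
  expect_equal(nrow(none), 0L)

  # three mutually close sites give all three pairs
  three <- pairCooccurringSites(rbind(toySite(100L), toySite(200L),
                                      toySite(300L)))
  expect_equal(nrow(three), 3L)

  # minus strand: the transcript-upstream site is the larger coordinate
  minus <- pairCooccurringSites(rbind(toySite(100L, "-"),
                                      toySite(400L, "-")))
  expect_equal(minus$junction1, 400L)
})

test_that("structural distance recovers overhangs from the pairing map", {
  # 24-mer, positions 1..10 paired with 24..15 (perfect stem)
  f <- foldFromPairs(24L, lapply(1:10, function(k) c(k, 25L - k)))
  expect_equal(structuralDistance(f, 6L, 20L), 2L)  # 2-nt 3' overhang
  expect_equal(structuralDistance(f, 6L, 18L), 0L)  # blunt
  expect_equal(structuralDistance(f, 6L, 17L), -1L) # 1-nt 5' overhang

  # the canonical register is invariant to sliding both cuts along the stem
  expect_equal(structuralDistance(f, 8L, 18L), 2L)
  expect_equal(structuralDistance(f, 4L, 22L), 2L)

  # fully unpaired anchors: undefined
  open <- foldFromPairs(24L, list())
  expect_true(is.na(structuralDistance(open, 6L, 20L)))
})

test_that("structural distance steps past unpaired anchors with correction", {
  # perfect stem with the pair at position 7 melted out (7 and 18 unpaired)
  pairs <- lapply(c(1:6, 8:10), function(k) c(k, 25L - k))
  f <- foldFromPairs(24L, pairs)
  # cut after 6: anchor 7 unpaired, step to 8 (partner 17), correct by 1;
  # the reverse direction is unaffected and must agree
  expect_equal(structuralDistance(f, 6L, 20L), 2L)
})

test_that("duplex length extends across small interruptions only", {
  perfect <- foldFromPairs(24L, lapply(1:10, function(k) c(k, 25L - k)))
  expect_equal(duplexLength(perfect, 5L, 20L), 10L)

  # two 5-bp helices separated by a 2-nt bulge on the left strand
  bulged <- foldFromPairs(
    26L, c(lapply(1:5, function(k) c(k, 27L - k)),
           lapply(8:12, function(k) c(k, 29L - k))))
  expect_equal(duplexLength(bulged, 3L, 24L), 10L)

  # a 3-nt interruption terminates the helix
  split3 <- foldFromPairs(
    28L, c(lapply(1:5, function(k) c(k, 29L - k)),
           lapply(9:13, function(k) c(k, 31L - k))))
  expect_equal(duplexLength(split3, 3L, 26L), 5L)

  # fully unpaired cleavage region
  expect_equal(duplexLength(foldFromPairs(24L, list()), 5L, 20L), 0L)
})

test_that("generator-planted RNase III pairs yield their planted stagger end-to-end", {
  sim <- simulateScenario(syntheticScenario(
    seed = 41L, genomeLength = 25000L, nTranscripts = 12L,
    nSitesY = 0L, nPairsIII = 4L, nSitesEndoA = 0L))
  truth <- sim$truth
  pairs <- split(truth, truth$pair)
  expect_length(pairs, 4L)
  for (p in pairs) {
    sd <- with(p, {
      reg <- foldDuplexRegion(sim$genome, junction[1], junction[2],
                              strand[1])
      structuralDistance(reg$fold, reg$cut1, reg$cut2)
    })
    expect_equal(sd, 2L)
  }
  # duplex length covers the full planted stem through the cleavage point
  reg <- foldDuplexRegion(sim$genome, pairs[[1]]$junction[1],
                          pairs[[1]]$junction[2], pairs[[1]]$strand[1])
  expect_gte(duplexLength(reg$fold, reg$cut1, reg$cut2), 10L)
})

test_that("base-pair motif frequencies sum to the paired fraction everywhere", {
  sim <- simulateScenario(syntheticScenario(
    seed = 43L, genomeLength = 25000L, nTranscripts = 12L,
    nSitesY = 0L, nPairsIII = 5L, nSitesEndoA = 0L))
  truth <- sim$truth
  duplexes <- lapply(split(truth, truth$pair), function(p)
    foldDuplexRegion(sim$genome, p$junction[1], p$junction[2], p$strand[1]))
  keep <- vapply(duplexes, function(d)
    identical(structuralDistance(d$fold, d$cut1, d$cut2), 2L), logical(1))
  motif <- buildPairMotif(duplexes[keep])
  expect_equal(motif$nSites, sum(keep))
  expect_equal(unname(rowSums(motif$freq)), unname(motif$fractionPaired),
               tolerance = 1e-12)
  expect_true(all(motif$fractionPaired <= 1))
  # the planted stems are perfect duplexes: positions just 5' of the cut
  # are paired in every retained duplex
  expect_equal(unname(motif$fractionPaired[c("-1", "-2", "-3")]),
               rep(1, 3))
})

test_that("single perfect A-U stem gives an all-A-U motif", {
  # arm A = 8 A's paired to arm B = 8 U's across a loop
  n <- 20L
  pairs <- lapply(1:8, function(k) c(k, 21L - k))
  seq <- paste(c(rep("A", 8), rep("C", 4), rep("U", 8)), collapse = "")
  f <- foldFromPairs(n, pairs, seq = seq)
  motif <- buildPairMotif(list(list(fold = f, cut1 = 4L, cut2 = 14L)),
                          relRange = c(-4L, 2L))
  expect_equal(unname(motif$freq["-1", "A-U"]), 1)
  expect_equal(unname(motif$fractionPaired["-1"]), 1)
})

test_that("motif comparison reports differences and missing positions", {
  m <- list(freq = matrix(c(0.6, 0.4), nrow = 1,
                          dimnames = list("-3", c("G-C", "C-G"))),
            fractionPaired = c("-3" = 1), nSites = 5L)
  ref <- matrix(c(0.4, 0.4, 0.1, 0.2), nrow = 2, byrow = TRUE,
                dimnames = list(c("-3", "7"), c("G-C", "C-G")))
  cmp <- compareMotifs(m, ref)
  expect_equal(unname(cmp$diff["-3", "G-C"]), 0.2)
  expect_equal(unname(cmp$diff["-3", "C-G"]), 0)
  expect_equal(cmp$missing, "7")

  expect_equal(max(abs(compareMotifs(
    m, matrix(c(0.6, 0.4), nrow = 1,
              dimnames = list("-3", c("G-C", "C-G"))))$diff)), 0)
})
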