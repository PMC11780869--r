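test_that("tiled folding assigns each 40-mer's MFE to its centre", {
  polyA <- GenomeRef("a", paste(rep("A", 120), collapse = ""))
  tr <- tileFoldTrack(polyA, k = 40L)
  expect_length(tr, 120L)
  expect_true(all(is.na(tr[1:19])))           # no complete window
  expect_true(all(tr[20:100] == 0))           # unstructured
  expect_true(all(is.na(tr[101:120])))        # last 40-mer centres at 100

  set.seed(31)
  g <- GenomeRef("g", paste(sample(c("A", "C", "G", "T"), 400,
                                   replace = TRUE), collapse = ""))
  tr <- tileFoldTrack(g, k = 40L)
  for (p in sample(40:360, 20)) {
    # centre p corresponds to the 40-mer starting at p - 19
    kmer <- substr(genomeSequence(g), p - 19L, p + 20L)
    expect_equal(tr[p], foldEnergy(foldRegion(kmer)), info = p)
  }
})

test_that("structure profile averages oriented windows and excludes boundary sites", {
  v <- as.numeric(1:2000)
  tracks <- list("+" = v, "-" = v)
  sites <- rbind(toySite(500L), toySite(800L))
  prof <- siteStructureProfile(tracks, sites, window = 75L)
  expect_equal(prof$nSites, 2L)
  # per-offset mean of two linear ramps is the ramp at the mean junction
  expect_equal(prof$meanMfe, 650 + prof$offsets)

  # a site within 75 nt of a wild-type end is excluded
  ends <- data.frame(strand = "+", pos = 850L)
  prof2 <- siteStructureProfile(tracks, sites, window = 75L, wtEnds = ends)
  expect_equal(prof2$nSites, 1L)
  expect_equal(prof2$meanMfe, 500 + prof2$offsets)

  # minus-strand sites read the window in transcript orientation
  profM <- siteStructureProfile(tracks, toySite(600L, "-"), window = 75L)
  expect_equal(profM$meanMfe, 600 - profM$offsets)

  expect_error(siteStructureProfile(tracks, sites, window = 75L,
                                    wtEnds = data.frame(
                                      strand = "+", pos = c(500L, 800L))),
               "no sites")
})

test_that("GA background band is seeded, ordered, and collapses at one iteration", {
  sim <- simulateScenario(syntheticScenario(
    seed = 47L, genomeLength = 15000L, nTranscripts = 8L, nSitesY = 5L,
    nPairsIII = 0L, nSitesEndoA = 0L))
  v <- rep(-5, length(sim$genome))
  tracks <- list("+" = v, "-" = v)
  b1 <- gaBackgroundProfile(tracks, sim$genome, sim$features, nSites = 5L,
                            iterations = 10L, seed = 9L)
  b2 <- gaBackgroundProfile(tracks, sim$genome, sim$features, nSites = 5L,
                            iterations = 10L, seed = 9L)
  expect_identical(b1, b2)
  expect_true(all(b1$q25 <= b1$q75))
  expect_true(all(b1$q25 == -5)) # constant track: band is degenerate

  single <- gaBackgroundProfile(tracks, sim$genome, sim$features,
                                nSites = 5L, iterations = 1L, seed = 2L)
  expect_equal(single$q25, single$q75)

  expect_error(gaBackgroundProfile(tracks, sim$genome, sim$features,
                                   nSites = 1e6L, iterations = 2L),
               "eligible")
})

test_that("GC profile reports per-offset G+C fractions in transcript orientation", {
  g <- GenomeRef("g", paste(c(rep("G", 100), rep("A", 100)), collapse = ""))
  profGC <- gcProfile(toySite(50L), g, window = 10L)
  expect_true(all(profGC$gc == 1))

  # single site is a 0/1 indicator of its sequence
  profAT <- gcProfile(toySite(150L), g, window = 10L)
  expect_true(all(profAT$gc == 0))

  # a site at the boundary mixes the two at the right offsets
  profMix <- gcProfile(toySite(100L), g, window = 5L)
  expect_equal(profMix$gc, c(1, 1, 1, 1, 1, 1, 0, 0, 0, 0, 0))
})

test_that("site windows place the junction at position 15 of 30", {
  seq <- paste(rep("A", 100), collapse = "")
  substr(seq, 50, 51) <- "GT" # junction G at 50, downstream A->T at 51
  g <- GenomeRef("g", seq)
  w <- siteWindows(toySite(50L), g)
  expect_equal(nchar(w), 30L)
  expect_equal(substr(w, 15L, 16L), "GU")

  # minus strand: reverse complement, junction still at 15
  seq2 <- paste(rep("A", 100), collapse = "")
  substr(seq2, 49, 50) <- "TC" # on minus strand reads G|A at 50|49
  gm <- GenomeRef("g", seq2)
  wm <- siteWindows(toySite(50L, "-"), gm)
  expect_equal(substr(wm, 15L, 16L), "GA")
})

test_that("motif statistics match closed-form binomial tails and IC limits", {
  # 20 identical windows with GA at the junction; uniform-ish background
  win <- paste(c(rep("A", 14), "G", "A", rep("C", 14)), collapse = "")
  sites <- rep(win, 20)
  set.seed(3)
  bg <- vapply(1:50, function(i)
    paste(sample(c("A", "C", "G", "U"), 30, replace = TRUE), collapse = ""),
    character(1))
  ms <- motifStats(sites, bg, maxK = 2L)
  expect_equal(unname(ms$freq["G", 15]), 1)
  expect_equal(unname(ms$ic[15]), 2) # one base fixed: maximal information

  # the junction-spanning GA 2-mer: tail probability matches pbinom and the
  # direct summation oracle
  row <- ms$kmers[ms$kmers$k == 2 & ms$kmers$pos == 15 &
                  ms$kmers$kmer == "GA", ]
  expect_equal(row$count, 20L)
  expect_equal(row$pRaw, oracleBinomTail(20L, 20L, row$bgProb))
  expect_equal(row$pRaw, row$bgProb^20)
  expect_true(row$significant)

  # frequencies equal to background are not significant
  unif <- vapply(1:40, function(i)
    paste(sample(c("A", "C", "G", "U"), 30, replace = TRUE), collapse = ""),
    character(1))
  msU <- motifStats(unif, bg, maxK = 1L)
  expect_false(any(msU$kmers$significant))

  expect_error(motifStats(sites[1:5], bg), "at least 10")
  expect_error(motifStats(sites, character(0)), "background")
})

test_that("binomial tails equal the summation oracle across a grid", {
  set.seed(13)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    x <- sample(0:n, 1)
    p <- runif(1, 0.01, 0.6)
    expect_equal(pbinom(x - 1, n, p, lower.tail = FALSE),
                 oracleBinomTail(x, n, p), tolerance = 1e-12)
  }
})

test_that("planted RNase Y sites show the GA junction motif and weak local folding", {
  sim <- simulateScenario(syntheticScenario(
    seed = 53L, genomeLength = 25000L, nTranscripts = 14L, nSitesY = 14L,
    nPairsIII = 0L, nSitesEndoA = 0L))
  sites <- sim$truth[sim$truth$enzyme == "rny", ]
  sites <- data.frame(junction = sites$junction, strand = sites$strand)
  win <- siteWindows(sites, sim$genome)
  bg <- sampleBackgroundWindows(sim$genome, sim$features)
  ms <- motifStats(win, bg, maxK = 2L)
  top2 <- ms$kmers[ms$kmers$k == 2, ]
  # the planted junction dinucleotide is the top-enriched 2-mer
  expect_equal(top2$kmer[1], "GA")
  expect_equal(top2$pos[1], 15L)

  # AU-rich planted flanks fold more weakly than the GC-normal background:
  # the structure profile has a local MFE maximum (closer to zero) at the
  # junction relative to distal offsets
  tracks <- list("+" = tileFoldTrack(sim$genome, strand = "+"),
                 "-" = tileFoldTrack(sim$genome, strand = "-"))
  prof <- siteStructureProfile(tracks, sites, window = 75L)
  atJunction <- prof$meanMfe[prof$offsets == 0]
  distal <- mean(prof$meanMfe[abs(prof$offsets) > 60], na.rm = TRUE)
  expect_gt(atJunction, distal)
})
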