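const <- "ACGTGTTCAG"
bc <- function(i) sprintf("%015d", i) # syntactic 15-char barcodes
mkReads <- function(barcode, variants, constant = const)
  data.frame(barcodeRead = paste0(barcode, constant),
             variantRead = variants, stringsAsFactors = FALSE)

test_that("barcode assignment applies the read-count and ambiguity rules", {
  b <- "AAAAACCCCCGGGGG"
  # 5:1 -> 20% second fraction, assigned
  r <- mkReads(b, c(rep("seqA", 5), "seqB"))
  out <- mapBarcodes(r$barcodeRead, r$variantRead, const)
  expect_equal(out$status, "assigned")
  expect_equal(out$variantSeq, "seqA")
  expect_equal(out$secondFrac, 0.2)

  # 4:1 -> exactly 25%, discarded entirely
  r2 <- mkReads(b, c(rep("seqA", 4), "seqB"))
  out2 <- mapBarcodes(r2$barcodeRead, r2$variantRead, const)
  expect_equal(out2$status, "ambiguous_discarded")
  expect_true(is.na(out2$variantSeq))

  # two reads -> low count
  r3 <- mkReads(b, rep("seqA", 2))
  expect_equal(mapBarcodes(r3$barcodeRead, r3$variantRead, const)$status,
               "low_count")

  # constant-region mutants are dropped before counting
  r4 <- rbind(mkReads(b, rep("seqA", 3)),
              mkReads(b, rep("seqB", 5), constant = "ACGTGTTCAA"))
  out4 <- mapBarcodes(r4$barcodeRead, r4$variantRead, const)
  expect_equal(out4$status, "assigned")
  expect_equal(out4$variantSeq, "seqA")
  expect_equal(out4$nReads, 3L)
})

test_that("barcode assignment matches the brute-force mode/fraction oracle", {
  set.seed(83)
  pool <- do.call(rbind, lapply(1:30, function(i) {
    n <- sample(1:8, 1)
    mkReads(bc(i), sample(c("v1", "v2", "v3"), n, replace = TRUE,
                          prob = c(0.7, 0.2, 0.1)))
  }))
  out <- mapBarcodes(pool$barcodeRead, pool$variantRead, const)
  for (i in seq_len(nrow(out))) {
    reads <- pool$variantRead[substr(pool$barcodeRead, 1, 15) ==
                              out$barcode[i]]
    oracle <- oracleAssignBarcode(reads)
    expect_equal(out$status[i], oracle$status)
    if (oracle$status == "assigned")
      expect_equal(out$variantSeq[i], oracle$variant)
  }
})

test_that("barcode counting deduplicates on (barcode, UMI)", {
  counts <- countBarcodes(rep("B1", 3), c("u1", "u1", "u2"))
  expect_equal(unname(counts["B1"]), 2L)

  # distinct barcodes never merge
  c2 <- countBarcodes(c("B1", "B2", "B2"), c("u1", "u1", "u1"))
  expect_equal(unname(c2[c("B1", "B2")]), c(1L, 1L))

  # constant-region mutants removed when the constant region is supplied
  c3 <- countBarcodes(c("B1", "B1"), c("u1", "u2"),
                      observedConstant = c(const, "XXXX"),
                      constantRegion = const)
  expect_equal(unname(c3["B1"]), 1L)
})

test_that("variant effects normalize by the median wild-type barcode", {
  wt <- "ACGTACGTACGTACGTACGT"
  junction <- 10L
  # wild-type barcodes with ratios 1.8, 2.0, 2.2; variant with 0.9, 1.1
  var <- wt; substr(var, 16, 16) <- "A" # T[+6]A
  asg <- data.frame(
    barcode = c("W1", "W2", "W3", "V1", "V2"),
    variantSeq = c(wt, wt, wt, var, var),
    nReads = 5L, secondFrac = 0, status = "assigned",
    stringsAsFactors = FALSE)
  dna <- setNames(rep(10L, 5), asg$barcode)
  rna <- setNames(c(18L, 20L, 22L, 9L, 11L), asg$barcode)
  eff <- variantEffects(rna, dna, asg, wt, junction)
  expect_equal(eff$normalizedEffect[eff$mutation == "WT"], 1)
  expect_equal(eff$mutation, c("WT", "T[+6]A"))
  expect_equal(eff$normalizedEffect[2], 0.5)

  # gDNA below the threshold excludes the barcode
  dnaLow <- dna; dnaLow["V2"] <- 5L
  eff2 <- variantEffects(rna, dnaLow, asg, wt, junction)
  expect_equal(eff2$nBarcodes[eff2$mutation == "T[+6]A"], 1L)

  expect_error(variantEffects(rna, setNames(rep(1L, 5), asg$barcode),
                              asg, wt, junction, minCount = 10L),
               "threshold")
})

test_that("mutation labels are junction-relative with no offset zero", {
  wt <- "AACCGGTTAACCGGTT"
  expect_equal(endomap:::.mutationLabel(wt, wt, 8L), "WT")
  v1 <- wt; substr(v1, 9, 9) <- "T"
  expect_equal(endomap:::.mutationLabel(v1, wt, 8L), "A[+1]T")
  v2 <- wt; substr(v2, 8, 8) <- "A"
  expect_equal(endomap:::.mutationLabel(v2, wt, 8L), "T[-1]A")
  v3 <- wt; substr(v3, 2, 2) <- "G"; substr(v3, 14, 14) <- "A"
  expect_equal(endomap:::.mutationLabel(v3, wt, 8L), "A[-7]G,G[+6]A")
  # labels invert back onto the wild type
  expect_equal(endomap:::.applyMutations("A[-7]G,G[+6]A", wt, 8L), v3)
})

test_that("planted MPRA effects are recovered end-to-end within 20%", {
  wt <- paste(rep(c("A", "C", "G", "T"), 15), collapse = "")
  junction <- 30L
  effects <- c("G[+5]A" = 0.5, "T[+10]C" = 0.25)
  # make labels consistent with the wild-type sequence
  names(effects) <- vapply(c(35L, 40L), function(i) {
    ref <- substr(wt, i, i)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    sprintf("%s[+%d]%s", ref, i - junction, alt)
  }, character(1))
  pool <- simulateMpraPool(wt, junction, effects, nBarcodes = 50L,
                           readsPerBarcode = 100L, seed = 5L)
  asg <- mapBarcodes(pool$mapping$barcodeRead, pool$mapping$variantRead,
                     pool$constantRegion)
  expect_true(all(asg$status == "assigned"))
  rna <- countBarcodes(pool$rna$barcode, pool$rna$umi)
  dna <- countBarcodes(pool$gdna$barcode, pool$gdna$umi)
  eff <- variantEffects(rna, dna, asg, wt, junction)
  expect_equal(eff$normalizedEffect[eff$mutation == "WT"], 1)
  for (m in names(effects)) {
    est <- eff$normalizedEffect[eff$mutation == m]
    expect_lt(abs(est - effects[[m]]) / effects[[m]], 0.2)
  }
  # by construction the wild-type median is exactly 1
  bcTab <- attr(eff, "barcodes")
  expect_equal(median(bcTab$ratio[bcTab$mutation == "WT"]) /
               median(bcTab$ratio[bcTab$mutation == "WT"]), 1)
})

test_that("hairpin stability association orders mutants correctly", {
  # wild type with a perfect 8-bp stem downstream of the junction
  stem <- "GGGGCCGG"
  wt <- paste0(paste(rep("A", 20), collapse = ""),
               stem, "TTTT", chartr("ACGT", "TGCA",
                                    paste(rev(strsplit(stem, "")[[1]]),
                                          collapse = "")))
  junction <- 20L
  wtArm <- substr(wt, 21, 40)
  effects <- data.frame(
    mutation = c("WT", "G[+1]A", "G[+2]T"),
    nBarcodes = 3L, summaryRatio = 1,
    normalizedEffect = c(1, 2, 2.5), stringsAsFactors = FALSE)
  assoc <- hairpinDeltaGAssociation(effects, wt, junction,
                                    hairpinOffsets = c(1L, 20L))
  dgWt <- assoc$deltaG[assoc$mutation == "WT"]
  expect_equal(dgWt, foldEnergy(foldRegion(substr(wt, 21, 40))))
  # stem-disrupting substitutions destabilize the hairpin
  expect_gt(assoc$deltaG[assoc$mutation == "G[+1]A"], dgWt)
  expect_gt(assoc$deltaG[assoc$mutation == "G[+2]T"], dgWt)

  # a compensatory double mutant restoring complementarity refolds to the
  # energy of the equivalent perfect stem
  dbl <- data.frame(mutation = c("WT", "G[+2]T,C[+19]A"),
                    nBarcodes = 3L, summaryRatio = 1,
                    normalizedEffect = c(1, 1.1), stringsAsFactors = FALSE)
  # +2 pairs with +19 in the 8-bp stem (stem spans +1..+8 and +13..+20)
  assoc2 <- hairpinDeltaGAssociation(dbl, wt, junction,
                                     hairpinOffsets = c(1L, 20L))
  mutated <- endomap:::.applyMutations("G[+2]T,C[+19]A", wt, junction)
  expect_equal(assoc2$deltaG[2],
               foldEnergy(foldRegion(substr(mutated, 21, 40))))
  expect_lte(assoc2$deltaG[2], assoc$deltaG[assoc$mutation == "G[+2]T"])
})

test_that("double-mutant averages discard variants with strong extra mutations", {
  wt <- "AAAAAAAAAACCCCCCCCCC"
  junction <- 10L
  lbl <- function(i, alt) sprintf("%s[%+d]%s", substr(wt, i, i),
                                  ifelse(i > junction, i - junction,
                                         i - junction - 1L), alt)
  m1 <- lbl(12L, "G"); m2 <- lbl(14L, "G"); bad <- lbl(16L, "G")
  mk <- function(label, ratio, n = 3L)
    data.frame(barcode = sprintf("%s_%d", label, seq_len(n)),
               mutation = label, rna = round(ratio * 10), dna = 10L,
               ratio = ratio, stringsAsFactors = FALSE)
  bcTab <- rbind(mk("WT", 2), mk(m1, 2), mk(m2, 2), mk(bad, 0.4),
                 mk(paste(m1, m2, sep = ","), 1),
                 mk(paste(m1, m2, bad, sep = ","), 0.2))
  effects <- do.call(rbind, lapply(split(bcTab, bcTab$mutation), function(d)
    data.frame(mutation = d$mutation[1], nBarcodes = nrow(d),
               summaryRatio = median(d$ratio),
               normalizedEffect = median(d$ratio) / 2,
               stringsAsFactors = FALSE)))
  attr(effects, "barcodes") <- bcTab
  res <- doubleMutantEffect(effects, m1, m2)
  # only the clean double mutant qualifies; the triple with the strong
  # extra mutation (effect 0.2) is discarded
  expect_equal(res$nBarcodes, 3L)
  expect_equal(res$effect, 0.5)
})
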