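## synth module: seeded synthetic scenarios -- genomes with planted
## transcripts and cleavage sites, strain-genotype-dependent end tracks,
## and MPRA read pools. The generator encodes the causal model the analysis
## assumes: ablating 3'- or 5'-exonucleolytic activity stabilizes cleavage
## products whose termini mark the cleavage junction; knocking out an
## endonuclease removes its sites' signal; EndoA leaves hydroxylated 5'
## ends invisible to monophosphate-specific 5'-end sequencing, with
## discrete downstream trimming producing monophosphorylated ends.

#' Define a synthetic scenario
#'
#' Defaults give a desk-scale study: a 100-kb genome, 60 transcripts with
#' log-normal expression, Poisson read noise, and roughly 40 planted
#' cleavage sites -- 20 RNase Y sites (G|A junction in AU-rich flanks),
#' 5 RNase III inverted-repeat pairs with the canonical 2-nt 3'-overhang
#' register, and 12 EndoA UACAUA sites (5'-hydroxyl moiety, downstream
#' trimming to monophosphorylated ends at +2 and, for downstream U/C/A, +4).
#' Decay fragments shorter than 35 nt are not capturable and contribute no
#' end signal.
#'
#' @param seed integer seed; all outputs are bit-reproducible given it.
#' @param genomeLength genome size (nt).
#' @param nTranscripts transcripts to place.
#' @param exprMeanlog,exprSdlog log-normal expression parameters.
#' @param nSitesY,nPairsIII,nSitesEndoA planted site counts (each RNase III
#'   pair contributes two junctions).
#' @param stemLen,loopLen,stagger RNase III inverted-repeat geometry.
#' @param strengthRange expected planted-peak read counts (uniform draw).
#' @param covScale expected Rend-seq reads per covered nt per unit
#'   expression.
#' @param endNoiseFrac background end-sequencing rate as a fraction of
#'   coverage.
#' @param boundaryScale expected reads in transcript-boundary end peaks per
#'   unit expression.
#' @param minFragment minimum capturable fragment length (nt).
#' @param trimmedFrac expected trimmed-read fraction per trimming offset.
#' @param trimmingModel named list: downstream base (after the 6-mer EndoA
#'   motif) -> trimming offsets, in nt past the nascent 5' end.
#' @return scenario configuration list.
#' @export
syntheticScenario <- function(seed = 1L, genomeLength = 100000L,
                              nTranscripts = 60L, exprMeanlog = 0,
                              exprSdlog = 0.8, nSitesY = 20L,
                              nPairsIII = 5L, nSitesEndoA = 12L,
                              stemLen = 20L, loopLen = 6L, stagger = 2L,
                              strengthRange = c(80, 300), covScale = 0.5,
                              endNoiseFrac = 0.02, boundaryScale = 200,
                              minFragment = 35L, trimmedFrac = 0.4,
                              trimmingModel = list(A = c(2L, 4L),
                                                   C = c(2L, 4L),
                                                   G = 2L,
                                                   U = c(2L, 4L))) {
  as.list(environment())
}

## write `replacement` into `seq` at 1-based position `at`
.spliceSeq <- function(seq, at, replacement) {
  paste0(substr(seq, 1L, at - 1L), replacement,
         substr(seq, at + nchar(replacement), nchar(seq)))
}

#' Simulate a scenario: genome, features and planted-site truth
#'
#' Builds the genome with planted transcript and site sequences and the
#' truth table listing every planted site (enzyme, junction, strand, 5'
#' moiety, expected peak strength, stratum for EndoA, pair identity and
#' stagger for RNase III). Sites are spaced so their signal windows do not
#' overlap other planted elements, and kept away from transcript ends so
#' they survive the boundary filters; a pair of intergenic tRNAs exercises
#' the non-coding-RNA exclusion.
#'
#' @param config from \code{\link{syntheticScenario}}.
#' @return list: \code{genome} (\code{GenomeRef}), \code{features}
#'   (\code{GRanges}), \code{transcripts} (data.frame), \code{truth}
#'   (data.frame), \code{config}.
#' @export
simulateScenario <- function(config = syntheticScenario()) {
  set.seed(config$seed)
  L <- config$genomeLength
  seq <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                      prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
  ## place transcripts left to right with random gaps
  tx <- list()
  pos <- 200L
  for (i in seq_len(config$nTranscripts)) {
    gap <- sample(150:400, 1L)
    len <- sample(900:2200, 1L)
    start <- pos + gap
    end <- start + len - 1L
    if (end > L - 200L) break
    tx[[i]] <- data.frame(id = sprintf("tx%02d", i), start = start,
                          end = end, strand = sample(.STRANDS, 1L),
                          expression = rlnorm(1, config$exprMeanlog,
                                              config$exprSdlog))
    pos <- end
  }
  transcripts <- do.call(rbind, tx)
  ## CDS inset 30 nt from transcript ends; two intergenic tRNAs
  feat <- data.frame(type = "CDS", strand = transcripts$strand,
                     start = transcripts$start + 30L,
                     end = transcripts$end - 30L,
                     id = paste0(transcripts$id, "_cds"))
  gaps <- data.frame(start = head(transcripts$end, -1L) + 20L,
                     end = transcripts$start[-1L] - 20L)
  gaps <- gaps[gaps$end - gaps$start > 80L, , drop = FALSE]
  if (nrow(gaps) >= 2L) {
    pickGap <- gaps[sample.int(nrow(gaps), 2L), , drop = FALSE]
    feat <- rbind(feat, data.frame(
      type = "tRNA", strand = "+", start = pickGap$start,
      end = pickGap$start + 75L, id = c("trna1", "trna2")))
  }
  ## allocate planted-site anchor positions within transcripts
  margin <- 220L
  spacing <- 160L
  usedBy <- lapply(seq_len(nrow(transcripts)), function(i) integer(0))
  claim <- function(width) {
    for (try in 1:500) {
      ti <- sample.int(nrow(transcripts), 1L)
      a <- transcripts$start[ti] + margin
      b <- transcripts$end[ti] - margin - width
      if (b <= a) next
      p <- sample(a:b, 1L)
      if (all(abs(usedBy[[ti]] - p) > spacing + width)) {
        usedBy[[ti]] <<- c(usedBy[[ti]], p)
        return(list(ti = ti, pos = p))
      }
    }
    stop("could not place a site; genome too crowded")
  }
  truth <- list()
  strength <- function() round(runif(1, config$strengthRange[1],
                                     config$strengthRange[2]))
  addTruth <- function(...) truth[[length(truth) + 1L]] <<-
    data.frame(..., stringsAsFactors = FALSE)
  ## RNase Y: G|A junction in an AU-rich 30-nt flank on the coding strand
  for (i in seq_len(config$nSitesY)) {
    cl <- claim(34L)
    s <- transcripts$strand[cl$ti]
    flank <- paste(sample(c("A", "T", "G", "C"), 32L, replace = TRUE,
                          prob = c(0.4, 0.4, 0.1, 0.1)), collapse = "")
    core <- paste0(substr(flank, 1L, 15L), "GA", substr(flank, 16L, 30L))
    ins <- if (s == "+") core else .revcomp(core)
    seq <- .spliceSeq(seq, cl$pos, ins)
    junction <- if (s == "+") cl$pos + 15L else cl$pos + 16L
    addTruth(enzyme = "rny", junction = junction, strand = s,
             moiety = "P", strength = strength(),
             transcript = transcripts$id[cl$ti], stratum = NA, pair = NA,
             stagger = NA)
  }
  ## RNase III: perfect inverted repeat, cleaved at the canonical register
  ## leaving `stagger`-nt 3' overhangs
  stem <- config$stemLen; loop <- config$loopLen
  for (i in seq_len(config$nPairsIII)) {
    width <- 2L * stem + loop
    cl <- claim(width + 4L)
    s <- transcripts$strand[cl$ti]
    armA <- paste(sample(c("G", "C", "A", "T"), stem, replace = TRUE,
                         prob = c(0.35, 0.35, 0.15, 0.15)), collapse = "")
    loopSeq <- paste(sample(c("A", "T"), loop, replace = TRUE), collapse = "")
    hp <- paste0(armA, loopSeq, .revcomp(armA))
    ins <- if (s == "+") hp else .revcomp(hp)
    seq <- .spliceSeq(seq, cl$pos, ins)
    ## transcript-orientation coordinates of the hairpin within the genome:
    ## oriented position q (1..width) maps to genomic
    ##   cl$pos + q - 1 (+) or cl$pos + width - q (-)
    toGenomic <- function(q) if (s == "+") cl$pos + q - 1L
                             else cl$pos + width - q
    ## oriented pairing: q (arm A) pairs with width - q + 1 (arm B)
    cut1 <- sample((stem %/% 2 - 2L):(stem %/% 2 + 2L), 1L) # within arm A
    partnerOfNext <- width - (cut1 + 1L) + 1L
    cut2 <- partnerOfNext + config$stagger
    st <- strength()
    pid <- sprintf("pair%02d", i)
    addTruth(enzyme = "rnc", junction = toGenomic(cut1), strand = s,
             moiety = "P", strength = st,
             transcript = transcripts$id[cl$ti], stratum = NA, pair = pid,
             stagger = config$stagger)
    addTruth(enzyme = "rnc", junction = toGenomic(cut2), strand = s,
             moiety = "P", strength = st,
             transcript = transcripts$id[cl$ti], stratum = NA, pair = pid,
             stagger = config$stagger)
  }
  ## EndoA: UACAUA motif (cleaved U|A), downstream base cycles the strata
  strata <- rep(names(config$trimmingModel),
                length.out = config$nSitesEndoA)
  for (i in seq_len(config$nSitesEndoA)) {
    cl <- claim(10L)
    s <- transcripts$strand[cl$ti]
    down <- strata[i]
    core <- paste0("TACATA", chartr("U", "T", down))
    ins <- if (s == "+") core else .revcomp(core)
    seq <- .spliceSeq(seq, cl$pos, ins)
    junction <- if (s == "+") cl$pos else cl$pos + 6L
    addTruth(enzyme = "ndoA", junction = junction, strand = s,
             moiety = "OH", strength = strength(),
             transcript = transcripts$id[cl$ti], stratum = down,
             pair = NA, stagger = NA)
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  genome <- GenomeRef("synthetic_genome", seq)
  features <- featureSet(feat$type, feat$strand, feat$start, feat$end,
                         feat$id, genomeLength = L)
  list(genome = genome, features = features, transcripts = transcripts,
       truth = truth, config = config)
}

## deterministic per-genotype seed offset
.genotypeSeed <- function(seed, genotype) {
  gt <- paste(sort(genotype), collapse = ",")
  (seed + sum(utf8ToInt(gt) * seq_len(nchar(gt))) * 131L) %% 2147483647L
}

#' Simulate the end tracks of one strain
#'
#' Generates the four channels x two strands of end-signal tracks implied
#' by the genotype. Planted sites contribute a 3'-end-sequencing peak at
#' the junction only when all 3' exonucleases are ablated (\code{"4exo"})
#' and a 5' peak at the first downstream nucleotide only when RNase J1
#' (\code{"rnjA"}) is ablated; sites of a knocked-out endonuclease
#' contribute nothing. EndoA's hydroxylated 5' ends appear in 5'-mapped
#' Rend-seq but never in monophosphate-specific 5'-end sequencing, while
#' its trimmed products contribute monophosphorylated ends at the
#' configured downstream offsets. Background coverage is Poisson over
#' log-normal transcript expression; fragments shorter than the capture
#' limit contribute no signal.
#'
#' @param sim result of \code{\link{simulateScenario}}.
#' @param genotypeGenes character vector of ablated genes (e.g.
#'   \code{c("rnjA")}, \code{c("rnjA", "rny")}, \code{"4exo"},
#'   \code{character(0)} for wild type).
#' @param strainId strain label (derived from the genotype by default).
#' @param seed RNG seed (derived from the scenario seed and genotype by
#'   default, so every strain is reproducible independently).
#' @return a \code{\link{StrainSample}} with RPM-normalized tracks.
#' @export
simulateStrainTracks <- function(sim, genotypeGenes,
                                 strainId = NULL, seed = NULL) {
  config <- sim$config
  if (is.null(seed)) seed <- .genotypeSeed(config$seed, genotypeGenes)
  if (is.null(strainId))
    strainId <- if (length(genotypeGenes))
      paste0("d_", paste(sort(genotypeGenes), collapse = "_")) else "wt"
  set.seed(seed)
  L <- length(sim$genome)
  tracks <- list()
  for (ch in .CHANNELS) for (s in .STRANDS)
    tracks[[paste(ch, s, sep = ".")]] <- numeric(L)
  bump <- function(ch, s, pos, reads) {
    key <- paste(ch, s, sep = ".")
    tracks[[key]][pos] <<- tracks[[key]][pos] + reads
  }
  tr <- sim$transcripts
  for (i in seq_len(nrow(tr))) {
    s <- tr$strand[i]
    idx <- tr$start[i]:tr$end[i]
    rate <- tr$expression[i] * config$covScale
    bump("rend5p", s, idx, rpois(length(idx), rate))
    bump("rend3p", s, idx, rpois(length(idx), rate))
    bump("endseq5p", s, idx, rpois(length(idx), rate * config$endNoiseFrac))
    bump("endseq3p", s, idx, rpois(length(idx), rate * config$endNoiseFrac))
    p5end <- if (s == "+") tr$start[i] else tr$end[i]
    p3end <- if (s == "+") tr$end[i] else tr$start[i]
    bStrength <- tr$expression[i] * config$boundaryScale
    bump("rend5p", s, p5end, rpois(1, bStrength))
    bump("rend3p", s, p3end, rpois(1, bStrength))
    bump("endseq3p", s, p3end, rpois(1, bStrength))
  }
  stab5 <- "rnjA" %in% genotypeGenes
  stab3 <- "4exo" %in% genotypeGenes
  truth <- sim$truth
  txIdx <- match(truth$transcript, tr$id)
  for (k in seq_len(nrow(truth))) {
    if (truth$enzyme[k] %in% genotypeGenes) next
    s <- truth$strand[k]
    step <- .dirStep(s)
    j <- truth$junction[k]
    st <- truth$strength[k]
    t3end <- if (s == "+") tr$end[txIdx[k]] else tr$start[txIdx[k]]
    t5end <- if (s == "+") tr$start[txIdx[k]] else tr$end[txIdx[k]]
    downLen <- abs(t3end - (j + step)) + 1L
    upLen <- abs(j - t5end) + 1L
    if (stab5 && downLen >= config$minFragment) {
      p5 <- j + step
      bump("rend5p", s, p5, rpois(1, st))
      if (truth$moiety[k] == "P") {
        bump("endseq5p", s, p5, rpois(1, st))
      } else {
        offs <- config$trimmingModel[[truth$stratum[k]]]
        for (off in offs) {
          reads <- rpois(1, st * config$trimmedFrac)
          pos <- j + step * (1L + off)
          bump("endseq5p", s, pos, reads)
          bump("rend5p", s, pos, reads)
        }
      }
    }
    if (stab3 && upLen >= config$minFragment) {
      bump("endseq3p", s, j, rpois(1, st))
      bump("rend3p", s, j, rpois(1, st))
    }
  }
  total <- sum(tracks[["rend5p.+"]]) + sum(tracks[["rend5p.-"]]) +
    sum(tracks[["rend3p.+"]]) + sum(tracks[["rend3p.-"]])
  total <- max(total, 1)
  endTracks <- list()
  for (key in names(tracks)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    endTracks[[key]] <- normalizeRpm(
      EndTrack(parts[1], parts[2], tracks[[key]]), total)
  }
  StrainSample(strainId, genotypeGenes, endTracks, total)
}

#' Call cleavage sites from a pair of exonuclease-deficient strains
#'
#' Convenience pipeline over both strands: 5' peaks are called in the
#' 5'-exonuclease-deficient strain's 5'-end sequencing, paired with 3'-end
#' ratios in the 3'-exonuclease-deficient strain's 3'-end sequencing,
#' depth-checked against the 5'-deficient strain's 3'-mapped Rend-seq, and
#' passed through the RNA-3'-end, non-coding-RNA and CDS-distance filters.
#'
#' @param fiveSample 5'-exonuclease-deficient \code{StrainSample} (RNase J1
#'   ablated).
#' @param threeSample 3'-exonuclease-deficient \code{StrainSample} (4-exo).
#' @param features feature \code{GRanges}.
#' @param params from \code{\link{peakParams}}.
#' @param background background label for the called sites.
#' @return list with \code{sites} (retained), \code{audit} (filtered, with
#'   reasons), and \code{ends3p} (detected RNA 3' ends).
#' @export
callCleavageSites <- function(fiveSample, threeSample, features,
                              params = peakParams(),
                              background = fiveSample@strain) {
  allSites <- list()
  allAudit <- list()
  allEnds <- list()
  for (s in .STRANDS) {
    five <- getTrack(fiveSample, "endseq5p", s)
    three <- getTrack(threeSample, "endseq3p", s)
    rendRef <- getTrack(fiveSample, "rend3p", s)
    peaks <- callFivePrimePeaks(five, params)
    sites <- pairPeaks(peaks, three, rendRef, params,
                       background = background)
    ends <- callThreePrimeEndsZscore(rendRef, params)
    endsDf <- data.frame(strand = rep(s, length(ends)), pos = ends)
    filtered <- applySiteFilters(sites, features, endsDf, params)
    allSites[[s]] <- filtered$retained
    allAudit[[s]] <- filtered$audit
    allEnds[[s]] <- endsDf
  }
  list(sites = do.call(rbind, allSites),
       audit = do.call(rbind, allAudit),
       ends3p = do.call(rbind, allEnds))
}

#' Simulate an MPRA barcode pool
#'
#' Draws unique randomized barcodes for the wild type and each mutation,
#' Poisson gDNA reads per barcode, Poisson RNA (cleaved-isoform) reads
#' scaled by the mutation's cleavage efficiency, UMIs per read, and
#' mapping read pairs linking each barcode to its variant sequence through
#' the declared constant region.
#'
#' @param wildtypeSeq wild-type variant-region sequence.
#' @param junctionPos junction position within \code{wildtypeSeq}.
#' @param effects named numeric vector: mutation label -> relative cleaved
#'   RNA accumulation (wild type, effect 1, is always included).
#' @param nBarcodes barcodes per variant (default 50).
#' @param readsPerBarcode expected gDNA reads per barcode (default 100).
#' @param seed RNG seed.
#' @param barcodeLength barcode length (default 15).
#' @param constantRegion constant region following the barcode.
#' @param mappingReadsPerBarcode mapping reads per barcode (default 5).
#' @return list: \code{truth} (barcode, mutation, effect),
#'   \code{mapping} (barcodeRead, variantRead), \code{gdna} and \code{rna}
#'   (barcode, umi read tables), plus the declared \code{wildtypeSeq},
#'   \code{junctionPos}, \code{constantRegion}.
#' @export
simulateMpraPool <- function(wildtypeSeq, junctionPos, effects,
                             nBarcodes = 50L, readsPerBarcode = 100L,
                             seed = 1L, barcodeLength = 15L,
                             constantRegion = "ACGTGTTCAG",
                             mappingReadsPerBarcode = 5L) {
  stopifnot(all(effects > 0))
  set.seed(seed)
  muts <- c("WT", names(effects))
  eff <- c(1, unname(effects))
  nVar <- length(muts)
  drawBarcodes <- function(n) {
    seen <- character(0)
    while (length(seen) < n) {
      need <- n - length(seen)
      cand <- vapply(seq_len(need * 2L), function(i)
        paste(sample(c("A", "C", "G", "T"), barcodeLength,
                     replace = TRUE), collapse = ""), character(1))
      seen <- unique(c(seen, cand))
    }
    seen[seq_len(n)]
  }
  barcodes <- drawBarcodes(nVar * nBarcodes)
  truth <- data.frame(
    barcode = barcodes,
    mutation = rep(muts, each = nBarcodes),
    effect = rep(eff, each = nBarcodes),
    stringsAsFactors = FALSE)
  truth$variantSeq <- vapply(truth$mutation, .applyMutations, character(1),
                             wildtype = wildtypeSeq,
                             junctionPos = junctionPos, USE.NAMES = FALSE)
  randUmi <- function(n) vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 8L, replace = TRUE),
          collapse = ""), character(1))
  gdna <- list(); rna <- list()
  for (i in seq_len(nrow(truth))) {
    ng <- rpois(1, readsPerBarcode)
    nr <- rpois(1, readsPerBarcode * truth$effect[i])
    if (ng > 0)
      gdna[[length(gdna) + 1L]] <- data.frame(
        barcode = truth$barcode[i], umi = randUmi(ng),
        stringsAsFactors = FALSE)
    if (nr > 0)
      rna[[length(rna) + 1L]] <- data.frame(
        barcode = truth$barcode[i], umi = randUmi(nr),
        stringsAsFactors = FALSE)
  }
  mapping <- data.frame(
    barcodeRead = paste0(rep(truth$barcode, each = mappingReadsPerBarcode),
                         constantRegion),
    variantRead = rep(truth$variantSeq, each = mappingReadsPerBarcode),
    stringsAsFactors = FALSE)
  list(truth = truth, mapping = mapping,
       gdna = do.call(rbind, gdna), rna = do.call(rbind, rna),
       wildtypeSeq = wildtypeSeq, junctionPos = junctionPos,
       constantRegion = constantRegion)
}

#' Write a simulated scenario to pipeline input files
#'
#' Emits the FASTA genome, GFF3 features, per-strain wig tracks with a
#' manifest, and the planted-site truth table, so a simulated study can be
#' re-read through the standard file interfaces.
#'
#' @param sim result of \code{\link{simulateScenario}}.
#' @param samples list of \code{StrainSample}s.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
writeScenario <- function(sim, samples, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeGenomeFasta(sim$genome, file.path(dir, "genome.fasta"))
  writeFeaturesGff(sim$features, file.path(dir, "features.gff3"))
  writeStrainManifest(samples, dir)
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
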