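## mpra module: barcode-to-variant mapping, UMI-aware barcode counting,
## per-mutation normalized RNA:gDNA effects, and hairpin-stability
## association.

#' Map barcodes to variant sequences
#'
#' Reads whose observed constant region (immediately following the barcode)
#' carries any mismatch are discarded. Per barcode, the modal variant
#' sequence is assigned when the barcode has at least \code{minReads} valid
#' reads and the second-most frequent sequence is under 25% as frequent as
#' the top one; barcodes failing the 25% rule are discarded entirely
#' (\code{ambiguous_discarded}), under-covered ones are \code{low_count},
#' and barcodes whose every read had a mutated constant region are
#' \code{constant_region_mutant}.
#'
#' @param barcodeReads character vector: reads carrying the barcode at a
#'   fixed position followed by the constant region.
#' @param variantReads character vector, same length: the mate capturing
#'   the variable region.
#' @param constantRegion declared constant-region sequence.
#' @param barcodeLength barcode length (default 15).
#' @param minReads minimum valid reads per barcode (default 3).
#' @param maxSecondFrac ambiguity threshold (default 0.25, inclusive).
#' @return data.frame: \code{barcode}, \code{variantSeq} (NA unless
#'   assigned), \code{nReads}, \code{secondFrac}, \code{status}.
#' @export
mapBarcodes <- function(barcodeReads, variantReads, constantRegion,
                        barcodeLength = 15L, minReads = 3L,
                        maxSecondFrac = 0.25) {
  stopifnot(length(barcodeReads) == length(variantReads))
  bc <- substr(barcodeReads, 1L, barcodeLength)
  obsConst <- substr(barcodeReads, barcodeLength + 1L,
                     barcodeLength + nchar(constantRegion))
  valid <- obsConst == constantRegion
  rows <- lapply(split(seq_along(bc), bc), function(idx) {
    ok <- idx[valid[idx]]
    if (!length(ok)) {
      return(data.frame(barcode = bc[idx[1]], variantSeq = NA_character_,
                        nReads = 0L, secondFrac = NA_real_,
                        status = "constant_region_mutant",
                        stringsAsFactors = FALSE))
    }
    tab <- sort(table(variantReads[ok]), decreasing = TRUE)
    n <- length(ok)
    second <- if (length(tab) > 1L) as.integer(tab[2]) / as.integer(tab[1])
              else 0
    if (n < minReads) status <- "low_count"
    else if (second >= maxSecondFrac) status <- "ambiguous_discarded"
    else status <- "assigned"
    data.frame(barcode = bc[idx[1]],
               variantSeq = if (status == "assigned") names(tab)[1]
                            else NA_character_,
               nReads = n, secondFrac = second, status = status,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count unique barcode observations
#'
#' Reads with identical barcode and UMI are counted as a single
#' observation. Reads with a mutated constant region (when supplied) are
#' discarded first.
#'
#' @param barcodes,umis character vectors, one entry per read.
#' @param observedConstant optional per-read observed constant region.
#' @param constantRegion declared constant region (required with
#'   \code{observedConstant}).
#' @return named integer vector of unique-read counts per barcode.
#' @export
countBarcodes <- function(barcodes, umis, observedConstant = NULL,
                          constantRegion = NULL) {
  stopifnot(length(barcodes) == length(umis))
  if (!is.null(observedConstant)) {
    if (is.null(constantRegion))
      stop("constantRegion required to check observed constant regions")
    keep <- observedConstant == constantRegion
    barcodes <- barcodes[keep]; umis <- umis[keep]
  }
  if (!length(barcodes)) return(setNames(integer(0), character(0)))
  uniq <- !duplicated(paste(barcodes, umis, sep = "\r"))
  tab <- table(barcodes[uniq])
  setNames(as.integer(tab), names(tab))
}

## junction-relative mutation labels: <ref>[<signed offset>]<alt>,
## offsets negative upstream of the junction, no offset 0
.mutationLabel <- function(variant, wildtype, junctionPos) {
  if (nchar(variant) != nchar(wildtype)) return(NA_character_)
  vb <- strsplit(variant, "")[[1]]
  wb <- strsplit(wildtype, "")[[1]]
  d <- which(vb != wb)
  if (!length(d)) return("WT")
  off <- ifelse(d > junctionPos, d - junctionPos, d - junctionPos - 1L)
  paste(sprintf("%s[%+d]%s", wb[d], off, vb[d]), collapse = ",")
}

## inverse: apply a mutation label to the wild-type sequence
.applyMutations <- function(label, wildtype, junctionPos) {
  if (label == "WT") return(wildtype)
  vb <- strsplit(wildtype, "")[[1]]
  for (m in strsplit(label, ",")[[1]]) {
    parts <- regmatches(m, regexec("^([ACGTU])\\[([+-]\\d+)\\]([ACGTU])$", m))[[1]]
    if (length(parts) != 4L) stop("malformed mutation label: ", m)
    off <- as.integer(parts[3])
    idx <- if (off > 0L) junctionPos + off else junctionPos + off + 1L
    if (vb[idx] != parts[2])
      stop("reference base mismatch applying ", m)
    vb[idx] <- parts[4]
  }
  paste(vb, collapse = "")
}

#' Per-mutation normalized variant effects
#'
#' Each assigned barcode's effect is its RNA-to-gDNA unique-read ratio;
#' barcodes are grouped by their mutation call (differences from the
#' declared wild-type sequence, labelled relative to the cleavage junction,
#' e.g. \code{A[+6]G}), summarized by the median across barcodes, and
#' normalized by the median ratio of the wild-type barcodes, so the
#' wild-type normalized effect is exactly 1.
#'
#' @param rnaCounts,dnaCounts named integer vectors (per-barcode unique
#'   reads) from \code{\link{countBarcodes}}; missing RNA barcodes count 0.
#' @param assignments data.frame from \code{\link{mapBarcodes}}.
#' @param wildtypeSeq declared wild-type variant-region sequence.
#' @param junctionPos 1-based position in \code{wildtypeSeq} of the
#'   nucleotide 5' of the cleavage junction.
#' @param minCount minimum gDNA unique reads per barcode (default 10).
#' @param summary \code{"median"} (default) or \code{"mean"} per-mutation
#'   summary statistic.
#' @return data.frame: \code{mutation}, \code{nBarcodes},
#'   \code{summaryRatio}, \code{normalizedEffect}; the per-barcode table is
#'   attached as attribute \code{"barcodes"}.
#' @export
variantEffects <- function(rnaCounts, dnaCounts, assignments, wildtypeSeq,
                           junctionPos, minCount = 10L,
                           summary = c("median", "mean")) {
  summary <- match.arg(summary)
  asg <- assignments[assignments$status == "assigned", , drop = FALSE]
  dna <- dnaCounts[asg$barcode]
  dna[is.na(dna)] <- 0L
  keep <- dna >= minCount & dna > 0L
  asg <- asg[keep, , drop = FALSE]
  dna <- dna[keep]
  if (!nrow(asg)) stop("no barcode passes the gDNA read-count threshold")
  rna <- rnaCounts[asg$barcode]
  rna[is.na(rna)] <- 0L
  ratio <- as.numeric(rna) / as.numeric(dna)
  mutation <- vapply(asg$variantSeq, .mutationLabel, character(1),
                     wildtype = wildtypeSeq, junctionPos = junctionPos,
                     USE.NAMES = FALSE)
  bcTab <- data.frame(barcode = asg$barcode, mutation = mutation,
                      rna = as.integer(rna), dna = as.integer(dna),
                      ratio = ratio, stringsAsFactors = FALSE)
  bcTab <- bcTab[!is.na(bcTab$mutation), , drop = FALSE]
  wtRatios <- bcTab$ratio[bcTab$mutation == "WT"]
  if (!length(wtRatios))
    stop("no wild-type barcode passes the threshold")
  wtMed <- median(wtRatios)
  stat <- if (summary == "median") median else mean
  agg <- lapply(split(bcTab, bcTab$mutation), function(d)
    data.frame(mutation = d$mutation[1], nBarcodes = nrow(d),
               summaryRatio = stat(d$ratio),
               normalizedEffect = stat(d$ratio) / wtMed,
               stringsAsFactors = FALSE))
  out <- do.call(rbind, agg)
  out <- out[order(out$mutation != "WT", out$mutation), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "barcodes") <- bcTab
  out
}

#' Double-mutant averages
#'
#' Average normalized effect over variants carrying both indicated single
#' mutations, discarding variants that contain additional mutations whose
#' single-mutation effect deviates from neutrality by more than
#' \code{maxOtherEffect}.
#'
#' @param effects result of \code{\link{variantEffects}} (with barcode
#'   attribute).
#' @param mut1,mut2 single-mutation labels.
#' @param maxOtherEffect tolerated deviation |effect - 1| for additional
#'   mutations (default 0.10).
#' @return list with \code{effect} (median of qualifying barcode ratios,
#'   wild-type normalized) and \code{nBarcodes}.
#' @export
doubleMutantEffect <- function(effects, mut1, mut2, maxOtherEffect = 0.10) {
  bc <- attr(effects, "barcodes")
  singles <- setNames(effects$normalizedEffect, effects$mutation)
  wtMed <- median(bc$ratio[bc$mutation == "WT"])
  qual <- vapply(bc$mutation, function(lbl) {
    if (lbl == "WT") return(FALSE)
    muts <- strsplit(lbl, ",")[[1]]
    if (!(mut1 %in% muts && mut2 %in% muts)) return(FALSE)
    others <- setdiff(muts, c(mut1, mut2))
    all(vapply(others, function(o) {
      e <- singles[o]
      !is.na(e) && abs(e - 1) <= maxOtherEffect
    }, logical(1)))
  }, logical(1), USE.NAMES = FALSE)
  if (!any(qual)) return(list(effect = NA_real_, nBarcodes = 0L))
  list(effect = median(bc$ratio[qual]) / wtMed, nBarcodes = sum(qual))
}

#' Predicted hairpin stability versus variant effect
#'
#' For each mutation, applies it to the wild-type sequence, folds the
#' declared hairpin region, and joins the predicted free energy with the
#' measured normalized effect. The Spearman rank correlation between
#' stability and effect is attached.
#'
#' @param effects result of \code{\link{variantEffects}}.
#' @param wildtypeSeq wild-type variant-region sequence.
#' @param junctionPos junction position within \code{wildtypeSeq}.
#' @param hairpinOffsets integer c(from, to): hairpin region in
#'   junction-relative offsets (positive downstream).
#' @param backend folding backend.
#' @return data.frame: \code{mutation}, \code{deltaG},
#'   \code{normalizedEffect}; Spearman rho as attribute \code{"rho"}.
#' @export
hairpinDeltaGAssociation <- function(effects, wildtypeSeq, junctionPos,
                                     hairpinOffsets,
                                     backend = foldBackendDefault()) {
  toIdx <- function(off) if (off > 0L) junctionPos + off
                         else junctionPos + off + 1L
  a <- toIdx(hairpinOffsets[1]); b <- toIdx(hairpinOffsets[2])
  dg <- vapply(effects$mutation, function(lbl) {
    seqv <- .applyMutations(lbl, wildtypeSeq, junctionPos)
    foldEnergy(foldRegion(substr(seqv, a, b), backend))
  }, numeric(1), USE.NAMES = FALSE)
  out <- data.frame(mutation = effects$mutation, deltaG = dg,
                    normalizedEffect = effects$normalizedEffect,
                    stringsAsFactors = FALSE)
  if (nrow(out) > 2L && var(out$deltaG) > 0 &&
      var(out$normalizedEffect) > 0) {
    attr(out, "rho") <- suppressWarnings(
      stats::cor(out$deltaG, out$normalizedEffect, method = "spearman"))
  } else {
    attr(out, "rho") <- NA_real_
  }
  out
}
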