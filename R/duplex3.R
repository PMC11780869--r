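## duplex3 module: RNase III duplex analysis -- co-occurring site pairing,
## fold of the intervening region, overhang ("structural distance") and
## duplex-length determination, and the base-pair motif.

#' Pair co-occurring cleavage sites
#'
#' All unordered same-strand pairs of (typically RNase III-dependent) sites
#' whose junctions lie within \code{maxDist} nt of one another in the
#' primary sequence. Site 1 is the transcript-upstream member of each pair.
#'
#' @param sites cleavage-site data.frame.
#' @param maxDist maximum genomic distance (default 1000 nt).
#' @return data.frame with \code{junction1}, \code{junction2} (site1
#'   upstream in transcript orientation), \code{strand},
#'   \code{genomicDistance}.
#' @export
pairCooccurringSites <- function(sites, maxDist = 1000L) {
  out <- data.frame(junction1 = integer(0), junction2 = integer(0),
                    strand = character(0), genomicDistance = integer(0))
  for (s in unique(sites$strand)) {
    j <- sort(sites$junction[sites$strand == s])
    if (length(j) < 2L) next
    cmb <- combn(j, 2L)
    d <- abs(cmb[2, ] - cmb[1, ])
    keep <- d <= maxDist & d > 0L
    if (!any(keep)) next
    lo <- cmb[1, keep]; hi <- cmb[2, keep]
    # transcript-upstream member: smaller coordinate on "+", larger on "-"
    j1 <- if (s == "+") lo else hi
    j2 <- if (s == "+") hi else lo
    out <- rbind(out, data.frame(junction1 = j1, junction2 = j2,
                                 strand = s, genomicDistance = d[keep]))
  }
  rownames(out) <- NULL
  out
}

#' Extract and fold the region spanning a site pair
#'
#' Extracts the intervening sequence between the two junctions plus
#' \code{context} nt on either side (clipped at genome edges), oriented
#' along the transcript, folds it, and returns the fold together with the
#' junction offsets within the folded sequence (1-based position of the
#' nucleotide 5' of each cleaved bond; \code{cut1 < cut2}).
#'
#' @param genome a \code{\link{GenomeRef}}.
#' @param junction1,junction2 genomic junctions (site 1 transcript-upstream).
#' @param strand strand of both sites.
#' @param context flank width (default 50 nt).
#' @param backend folding backend.
#' @return list with \code{fold} (\code{FoldResult}), \code{cut1},
#'   \code{cut2}, and the genomic interval \code{gStart}, \code{gEnd}.
#' @export
foldDuplexRegion <- function(genome, junction1, junction2, strand,
                             context = 50L, backend = foldBackendDefault()) {
  L <- length(genome)
  jA <- min(junction1, junction2)
  jB <- max(junction1, junction2)
  if (strand == "+") {
    gStart <- max(1L, jA + 1L - context)
    gEnd <- min(L, jB + context)
  } else {
    # transcript-upstream junction is jB; bond lies between j and j-1
    gStart <- max(1L, jA - context)
    gEnd <- min(L, jB - 1L + context)
  }
  seq <- .orientedSubseq(genome, gStart, gEnd, strand)
  fold <- foldRegion(seq, backend)
  off <- function(j) if (strand == "+") j - gStart + 1L else gEnd - j + 1L
  cuts <- sort(c(off(junction1), off(junction2)))
  list(fold = fold, cut1 = cuts[1], cut2 = cuts[2],
       gStart = gStart, gEnd = gEnd)
}

## nearest paired position at or inward of `start` (steps of +1), up to
## maxStep steps; NULL when none
.pairedAnchor <- function(pm, start, maxStep = 2L) {
  for (s in 0:maxStep) {
    p <- start + s
    if (p >= 1L && p <= length(pm) && pm[p] > 0L)
      return(list(p = p, steps = s))
  }
  NULL
}

#' Structural distance (overhang) of a cleaved duplex
#'
#' Signed length of the single-stranded overhang produced by cleaving both
#' strands of the folded duplex at \code{cut1} and \code{cut2}: positive for
#' a 3' overhang (the canonical RNase III product is +2), zero for blunt
#' ends, negative for a 5' overhang. Computed in both directions -- from the
#' first nucleotide downstream of cut1 and from the last nucleotide upstream
#' of cut2 -- stepping up to 2 nt inward when the anchor nucleotide is
#' unpaired (correcting the count by the steps taken). When both directions
#' are computable they must agree; disagreement returns \code{NA} with a
#' diagnostic attribute.
#'
#' @param fold a \code{\link{FoldResult}}.
#' @param cut1,cut2 junction offsets within the folded sequence
#'   (\code{cut1 < cut2}).
#' @param maxStep how far to step inward past unpaired anchors (default 2).
#' @return integer overhang, or \code{NA} when undefined.
#' @export
structuralDistance <- function(fold, cut1, cut2, maxStep = 2L) {
  stopifnot(cut1 < cut2)
  pm <- pairingMap(fold)
  n <- length(pm)
  if (cut1 < 1L || cut2 > n) stop("cuts outside folded sequence")
  fwd <- NA_integer_
  anc <- .pairedAnchor(pm, cut1 + 1L, maxStep)
  if (!is.null(anc)) fwd <- cut2 - pm[anc$p] - anc$steps
  rev <- NA_integer_
  anc2 <- .pairedAnchor(pm, cut2 + 1L, maxStep)
  if (!is.null(anc2)) rev <- cut1 - pm[anc2$p] - anc2$steps
  if (!is.na(fwd) && !is.na(rev)) {
    if (fwd != rev) {
      out <- NA_integer_
      attr(out, "diagnostic") <- sprintf(
        "direction disagreement: forward %d vs reverse %d", fwd, rev)
      return(out)
    }
    return(fwd)
  }
  if (!is.na(fwd)) return(fwd)
  if (!is.na(rev)) return(rev)
  NA_integer_
}

#' Duplex length at a cleaved site pair
#'
#' Number of base pairs in the maximal helix containing the
#' cleavage-adjacent pair, extended across interruptions of at most
#' \code{maxGap} consecutive unpaired bases on either strand; longer
#' interruptions terminate the helix. Returns 0 when the region adjacent to
#' the cuts is entirely unpaired.
#'
#' @param fold a \code{\link{FoldResult}}.
#' @param cut1,cut2 junction offsets within the folded sequence.
#' @param maxGap maximum unpaired interruption (default 2).
#' @return base-pair count.
#' @export
duplexLength <- function(fold, cut1, cut2, maxGap = 2L) {
  pm <- pairingMap(fold)
  anc <- .pairedAnchor(pm, cut1 + 1L, maxGap)
  if (is.null(anc)) return(0L)
  p0 <- anc$p; q0 <- pm[p0]
  count <- 1L
  # extend inward: p increasing, partner decreasing
  p <- p0; q <- q0
  repeat {
    nxt <- NULL
    for (pp in (p + 1L):(p + 1L + maxGap)) {
      if (pp >= q) break
      if (pm[pp] > 0L && pm[pp] < q && pm[pp] > pp &&
          (q - pm[pp] - 1L) <= maxGap) { nxt <- pp; break }
    }
    if (is.null(nxt)) break
    p <- nxt; q <- pm[nxt]; count <- count + 1L
  }
  # extend outward: p decreasing, partner increasing
  p <- p0; q <- q0
  repeat {
    nxt <- NULL
    for (pp in (p - 1L):max(1L, p - 1L - maxGap)) {
      if (pp < 1L) break
      if (pm[pp] > 0L && pm[pp] > q && (pm[pp] - q - 1L) <= maxGap) {
        nxt <- pp; break
      }
    }
    if (is.null(nxt) || p == 1L) break
    p <- nxt; q <- pm[nxt]; count <- count + 1L
  }
  count
}

.PAIR_CLASSES <- c("A-U", "U-A", "G-C", "C-G", "U-G", "G-U")

#' Base-pair motif of cleaved duplexes
#'
#' For pairs retained after filtering (canonically those producing a 2-bp 3'
#' overhang), positions on the transcript-upstream arm are indexed relative
#' to its cleavage point (-1 = immediately 5' of the cut; there is no
#' position 0) and, for each relative position, the frequency of each
#' base-pairing class (A-U, U-A, G-C, C-G, U-G, G-U; first base from the
#' upstream arm) and the fraction of duplexes in which the position is
#' paired are tabulated. Asymmetric bulges appear naturally as unpaired
#' positions rather than being skipped.
#'
#' @param duplexes list of results from \code{\link{foldDuplexRegion}}
#'   (already filtered to the retained overhang class).
#' @param relRange integer range of relative positions to report
#'   (default -15..10).
#' @return list with \code{freq} (matrix positions x 6 pair classes),
#'   \code{fractionPaired}, \code{nSites}.
#' @export
buildPairMotif <- function(duplexes, relRange = c(-15L, 10L)) {
  if (!length(duplexes)) stop("need at least one retained duplex")
  rels <- seq(relRange[1], relRange[2])
  rels <- rels[rels != 0L]
  freq <- matrix(0, nrow = length(rels), ncol = length(.PAIR_CLASSES),
                 dimnames = list(rels, .PAIR_CLASSES))
  paired <- setNames(numeric(length(rels)), rels)
  for (d in duplexes) {
    pm <- pairingMap(d$fold)
    bases <- strsplit(d$fold@sequence, "")[[1]]
    for (ri in seq_along(rels)) {
      rel <- rels[ri]
      p <- d$cut1 + rel + (if (rel < 0L) 1L else 0L)
      if (p < 1L || p > length(pm)) next
      if (pm[p] > 0L) {
        paired[ri] <- paired[ri] + 1
        cls <- paste(bases[p], bases[pm[p]], sep = "-")
        if (cls %in% .PAIR_CLASSES)
          freq[ri, cls] <- freq[ri, cls] + 1
      }
    }
  }
  n <- length(duplexes)
  list(freq = freq / n, fractionPaired = paired / n, nSites = n)
}

#' Compare a base-pair motif against a reference table
#'
#' Elementwise frequency differences (motif minus reference) at relative
#' positions present in both tables; positions present in only one are
#' reported as missing. The reference uses the same matrix layout as
#' \code{\link{buildPairMotif}}: rows named by cut-relative position,
#' columns the six pair classes.
#'
#' @param motif result of \code{\link{buildPairMotif}}.
#' @param reference numeric matrix of per-position pair-class frequencies.
#' @return list with \code{diff} (matrix over shared positions) and
#'   \code{missing} (positions present in only one table).
#' @export
compareMotifs <- function(motif, reference) {
  if (!all(colnames(reference) %in% .PAIR_CLASSES))
    stop("reference columns must be the six pair classes")
  m <- motif$freq
  shared <- intersect(rownames(m), rownames(reference))
  if (!length(shared)) stop("no shared cut-relative positions")
  miss <- union(setdiff(rownames(m), rownames(reference)),
                setdiff(rownames(reference), rownames(m)))
  cols <- intersect(colnames(m), colnames(reference))
  list(diff = m[shared, cols, drop = FALSE] -
         reference[shared, cols, drop = FALSE],
       missing = miss)
}
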