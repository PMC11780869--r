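## peakcall module: winsorized-ratio peak detection, z-score 3' ends,
## 3'/5' peak pairing into cleavage sites, and the site filters.

#' Peak-calling parameters
#'
#' Defaults follow the published analysis: a 50-nt background window with a
#' 2-nt gap on either side of the examined position, 90% winsorization of the
#' window, a signal-to-background ratio threshold of 7.5, a minimum 5'-end
#' signal of 10 RPM per position (2 RPM for the expanded RNase III set), a
#' minimum local Rend-seq depth of 0.05 RPM, exclusion of sites within 40 nt
#' of a detected RNA 3' end or 150 nt of a mature rRNA/tRNA/scRNA, removal of
#' sites more than 500 nt from a coding region, and a z-score threshold of 8
#' for RNA 3'-end detection.
#'
#' @param window background window width (nt).
#' @param gap excluded gap on either side of the examined position (nt).
#' @param ratioThreshold peak ratio threshold.
#' @param winsorLevel winsorization level (fraction of values retained).
#' @param min5pRpm minimum 5'-end signal per position (RPM).
#' @param minLocalDepthRpm minimum mean local Rend-seq depth (RPM).
#' @param endExclusion3p exclusion distance from detected RNA 3' ends (nt).
#' @param ncrnaExclusion exclusion distance from rRNA/tRNA/scRNA (nt).
#' @param cdsMaxDist maximum distance from a coding region (nt).
#' @param zscoreThreshold z-score threshold for 3'-end detection.
#' @param minUsable minimum usable background-window positions at genome
#'   edges for a ratio to be defined.
#' @return a list of validated parameters.
#' @export
peakParams <- function(window = 50L, gap = 2L, ratioThreshold = 7.5,
                       winsorLevel = 0.90, min5pRpm = 10,
                       minLocalDepthRpm = 0.05, endExclusion3p = 40L,
                       ncrnaExclusion = 150L, cdsMaxDist = 500L,
                       zscoreThreshold = 8, minUsable = 10L) {
  p <- list(window = as.integer(window), gap = as.integer(gap),
            ratioThreshold = ratioThreshold, winsorLevel = winsorLevel,
            min5pRpm = min5pRpm, minLocalDepthRpm = minLocalDepthRpm,
            endExclusion3p = as.integer(endExclusion3p),
            ncrnaExclusion = as.integer(ncrnaExclusion),
            cdsMaxDist = as.integer(cdsMaxDist),
            zscoreThreshold = zscoreThreshold,
            minUsable = as.integer(minUsable))
  stopifnot(p$window > 0, p$gap >= 0, p$ratioThreshold > 0,
            p$winsorLevel > 0, p$winsorLevel < 1, p$min5pRpm > 0,
            p$minLocalDepthRpm > 0, p$zscoreThreshold > 0)
  p
}

#' Winsorized mean
#'
#' With \code{k = floor(((1 - level) / 2) * n)}, the k smallest values are
#' clamped to the (k+1)-th smallest and the k largest to the (k+1)-th
#' largest before averaging. At the default level of 0.90 and a 50-value
#' window this clamps 2 values per tail.
#'
#' @param values non-empty numeric vector.
#' @param level fraction of values retained unclamped (in (0, 1)).
#' @return the winsorized arithmetic mean.
#' @export
winsorizedMean <- function(values, level = 0.90) {
  n <- length(values)
  if (n == 0L) stop("cannot winsorize an empty vector")
  k <- floor(((1 - level) / 2) * n)
  if (k == 0L) return(mean(values))
  s <- sort(values)
  lo <- s[k + 1L]
  hi <- s[n - k]
  mean(pmin(pmax(values, lo), hi))
}

## background-window positions for `pos` on the stated transcript-orientation
## side; truncated at genome edges. Returns integer positions (possibly empty).
.windowPositions <- function(pos, side, strand, window, gap, L) {
  step <- .dirStep(strand)
  dir <- if (side == "downstream") step else -step
  idx <- pos + dir * (gap + seq_len(window))
  idx[idx >= 1L & idx <= L]
}

#' Signal-to-background peak ratio
#'
#' Ratio of the signal at a position to the winsorized mean of a background
#' window on the stated side (transcript orientation), excluding a gap on
#' either side of the position. The denominator is floored at the RPM
#' equivalent of one read spread over the window, so empty windows cannot
#' yield infinite ratios.
#'
#' @param track an \code{EndTrack}.
#' @param pos 1-based genomic position.
#' @param side \code{"upstream"} (used for 3' ends) or \code{"downstream"}
#'   (used for 5' ends).
#' @param params from \code{\link{peakParams}}.
#' @return the ratio, or \code{NA} when fewer than \code{minUsable} window
#'   positions are available.
#' @export
peakRatio <- function(track, pos, side = c("downstream", "upstream"),
                      params = peakParams()) {
  side <- match.arg(side)
  v <- trackValues(track)
  idx <- .windowPositions(pos, side, track@strand, params$window,
                          params$gap, length(v))
  if (length(idx) < params$minUsable) return(NA_real_)
  sc <- if (trackUnits(track) == "RPM") track@scale else 1
  floorVal <- sc / params$window
  v[pos] / max(winsorizedMean(v[idx], params$winsorLevel), floorVal)
}

#' Call 5'-end peaks
#'
#' Positions whose 5'-end signal exceeds \code{min5pRpm} and whose
#' downstream-window ratio exceeds \code{ratioThreshold} are grouped,
#' allowing a single 1-nt internal gap between adjacent qualifying
#' positions. Each group's signal is the sum over grouped positions and its
#' anchor is the 5'-most grouped position in transcript orientation.
#'
#' @param track \code{endseq5p} track in RPM.
#' @param params from \code{\link{peakParams}}.
#' @return data.frame with columns \code{anchor}, \code{strand},
#'   \code{signalSum}, \code{n}, \code{maxRatio} and a list column
#'   \code{positions}.
#' @export
callFivePrimePeaks <- function(track, params = peakParams()) {
  v <- trackValues(track)
  cand <- which(v > params$min5pRpm)
  empty <- data.frame(anchor = integer(0), strand = character(0),
                      signalSum = numeric(0), n = integer(0),
                      maxRatio = numeric(0))
  empty$positions <- list()
  if (!length(cand)) return(empty)
  ratio <- vapply(cand, function(p)
    peakRatio(track, p, "downstream", params), numeric(1))
  qual <- cand[!is.na(ratio) & ratio > params$ratioThreshold]
  qratio <- ratio[!is.na(ratio) & ratio > params$ratioThreshold]
  if (!length(qual)) return(empty)
  ord <- order(qual)
  qual <- qual[ord]; qratio <- qratio[ord]
  grp <- cumsum(c(1L, diff(qual) > 2L))
  out <- lapply(split(seq_along(qual), grp), function(ii) {
    pp <- qual[ii]
    anchor <- if (track@strand == "+") min(pp) else max(pp)
    df <- data.frame(anchor = anchor, strand = track@strand,
                     signalSum = sum(v[pp]), n = length(pp),
                     maxRatio = max(qratio[ii]))
    df$positions <- list(pp)
    df
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Detect RNA 3' ends by z-score
#'
#' At each position the z-score is the signal minus the mean over a combined
#' window of 50 nt on either side (excluding 2-nt gaps), divided by the
#' sample standard deviation within that window. Positions with z above the
#' threshold are flagged. A zero standard deviation yields z = +Inf when the
#' signal exceeds the window mean and 0 otherwise, so spikes on exactly flat
#' background are still flagged.
#'
#' @param track 3'-mapped Rend-seq \code{EndTrack} in RPM.
#' @param params from \code{\link{peakParams}}.
#' @return integer vector of flagged positions (sorted).
#' @export
callThreePrimeEndsZscore <- function(track, params = peakParams()) {
  v <- trackValues(track)
  L <- length(v)
  w <- params$window; g <- params$gap
  cs <- c(0, cumsum(v))
  cs2 <- c(0, cumsum(v^2))
  rngSum <- function(a, b) { # inclusive, clipped; returns sums and counts
    a <- pmax(a, 1L); b <- pmin(b, L)
    n <- pmax(b - a + 1L, 0L)
    b <- pmax(b, 1L) # safe index; masked by n == 0 below
    s <- ifelse(n > 0, cs[b + 1L] - cs[a], 0)
    s2 <- ifelse(n > 0, cs2[b + 1L] - cs2[a], 0)
    list(s = s, s2 = s2, n = n)
  }
  p <- seq_len(L)
  left <- rngSum(p - g - w, p - g - 1L)
  right <- rngSum(p + g + 1L, p + g + w)
  n <- left$n + right$n
  s <- left$s + right$s
  s2 <- left$s2 + right$s2
  ok <- n >= params$minUsable
  mu <- ifelse(ok, s / pmax(n, 1L), NA_real_)
  varv <- ifelse(n > 1, pmax(s2 - n * mu^2, 0) / (n - 1L), NA_real_)
  sdv <- sqrt(varv)
  z <- ifelse(sdv > 0, (v - mu) / sdv,
              ifelse(v > mu, Inf, 0))
  z[!ok] <- NA_real_
  sort(which(!is.na(z) & z > params$zscoreThreshold))
}

#' Pair 5' peaks with abutting 3' ends into cleavage sites
#'
#' For each 5'-peak anchor the equivalent 3'-end ratio is evaluated at the
#' position one nucleotide upstream (transcript orientation) in the 3'-end
#' sequencing of the 3'-exonuclease-deficient strain. A cleavage site is
#' emitted when that ratio exceeds the threshold and the mean 3'-mapped
#' Rend-seq depth of the 5'-exonuclease-deficient strain over the 50-nt
#' window downstream of the anchor exceeds the minimum local depth
#' (restricting calls to expressed genes). The junction coordinate is the
#' position of the 3'-peak nucleotide, i.e. the nucleotide 5' of the cleaved
#' bond.
#'
#' @param fivePeaks peaks from \code{\link{callFivePrimePeaks}} on the
#'   5'-exonuclease-deficient strain.
#' @param threeTrack \code{endseq3p} RPM track (same strand) from the
#'   3'-exonuclease-deficient strain.
#' @param rendRef 3'-mapped Rend-seq RPM track from the
#'   5'-exonuclease-deficient strain.
#' @param params from \code{\link{peakParams}}.
#' @param background strain/background label stored with the sites.
#' @return cleavage-site data.frame: \code{junction}, \code{strand},
#'   \code{fiveSignal}, \code{threeRatio}, \code{localDepth},
#'   \code{background}, plus the grouped 5' \code{positions} (list column).
#' @export
pairPeaks <- function(fivePeaks, threeTrack, rendRef,
                      params = peakParams(), background = NA_character_) {
  rv <- trackValues(rendRef)
  L <- length(rv)
  rows <- lapply(seq_len(nrow(fivePeaks)), function(i) {
    a <- fivePeaks$anchor[i]
    strand <- fivePeaks$strand[i]
    step <- .dirStep(strand)
    junction <- a - step
    if (junction < 1L || junction > L) return(NULL)
    r3 <- peakRatio(threeTrack, junction, "upstream", params)
    if (is.na(r3) || r3 <= params$ratioThreshold) return(NULL)
    depthIdx <- a + step * seq_len(params$window)
    depthIdx <- depthIdx[depthIdx >= 1L & depthIdx <= L]
    depth <- if (length(depthIdx)) mean(rv[depthIdx]) else 0
    if (depth <= params$minLocalDepthRpm) return(NULL)
    df <- data.frame(junction = junction, strand = strand,
                     fiveSignal = fivePeaks$signalSum[i],
                     threeRatio = r3, localDepth = depth,
                     background = background)
    df$positions <- fivePeaks$positions[i]
    df
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    out <- data.frame(junction = integer(0), strand = character(0),
                      fiveSignal = numeric(0), threeRatio = numeric(0),
                      localDepth = numeric(0), background = character(0))
    out$positions <- list()
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## distance from a point to a set of closed intervals (0 when inside)
.distToIntervals <- function(pos, starts, ends) {
  if (!length(starts)) return(Inf)
  d <- pmax(starts - pos, pos - ends)
  max(0, min(d))
}

#' Apply the site filters
#'
#' Removes sites within \code{endExclusion3p} nt of a detected RNA 3' end
#' (same strand; short decay fragments are not captured by the library
#' preparation), within \code{ncrnaExclusion} nt of a mature rRNA, tRNA or
#' scRNA, or more than \code{cdsMaxDist} nt from a coding region. Each
#' removal is recorded with its reason in the returned audit table.
#'
#' @param sites cleavage-site data.frame from \code{\link{pairPeaks}}.
#' @param features feature \code{GRanges} from \code{\link{featureSet}}.
#' @param detected3pEnds data.frame with columns \code{strand}, \code{pos}:
#'   RNA 3' ends from \code{\link{callThreePrimeEndsZscore}} on the
#'   5'-exonuclease-deficient strain.
#' @param params from \code{\link{peakParams}}.
#' @return list with \code{retained} (sites passing all filters) and
#'   \code{audit} (removed sites with a \code{reason} column).
#' @export
applySiteFilters <- function(sites, features, detected3pEnds,
                             params = peakParams()) {
  type <- S4Vectors::mcols(features)$type
  nc <- features[type %in% .NCRNA_TYPES]
  cds <- features[type == "CDS"]
  ncS <- GenomicRanges::start(nc); ncE <- GenomicRanges::end(nc)
  cdsS <- GenomicRanges::start(cds); cdsE <- GenomicRanges::end(cds)
  reasons <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    j <- sites$junction[i]
    ends <- detected3pEnds$pos[detected3pEnds$strand == sites$strand[i]]
    if (length(ends) && min(abs(ends - j)) <= params$endExclusion3p) {
      reasons[i] <- "end_exclusion"
    } else if (.distToIntervals(j, ncS, ncE) <= params$ncrnaExclusion) {
      reasons[i] <- "ncrna"
    } else if (.distToIntervals(j, cdsS, cdsE) > params$cdsMaxDist) {
      reasons[i] <- "cds_dist"
    }
  }
  keep <- reasons == ""
  audit <- sites[!keep, , drop = FALSE]
  if (nrow(audit)) audit$reason <- reasons[!keep]
  list(retained = sites[keep, , drop = FALSE], audit = audit)
}

#' Merge site calls across genetic backgrounds
#'
#' Takes the union of per-background site lists; sites at identical or
#' adjacent junctions (|difference| <= 1 nt, same strand) across sets are
#' counted once, keeping the junction from the first-listed set.
#'
#' @param siteSets list of cleavage-site data.frames (order gives priority).
#' @return merged cleavage-site data.frame.
#' @export
mergeBackgrounds <- function(siteSets) {
  if (!length(siteSets)) stop("need at least one site set")
  merged <- siteSets[[1]]
  for (k in seq_along(siteSets)[-1]) {
    cand <- siteSets[[k]]
    for (i in seq_len(nrow(cand))) {
      dup <- any(merged$strand == cand$strand[i] &
                 abs(merged$junction - cand$junction[i]) <= 1L)
      if (!dup) merged <- rbind(merged, cand[i, , drop = FALSE])
    }
  }
  rownames(merged) <- NULL
  merged
}

#' Export cleavage sites as BED6
#'
#' One 1-nt interval per junction; score is the grouped 5'-end signal.
#'
#' @param sites cleavage-site data.frame.
#' @param path output path.
#' @param genomeName chromosome name.
#' @export
exportSitesBed <- function(sites, path, genomeName = "genome") {
  df <- data.frame(chrom = genomeName,
                   start = sites$junction - 1L, end = sites$junction,
                   name = sprintf("site_%d", seq_len(nrow(sites))),
                   score = sites$fiveSignal, strand = sites$strand)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
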