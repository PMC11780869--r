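## endoa module: motif-anchored metagene profiles of EndoA cleavage and
## detection of the downstream 5'-trimming signature.

#' Find motif-anchored cleavage sites
#'
#' Locates all instances of a cleavage motif (default the EndoA motif
#' \code{UACAU}, cleaved within the first U|A bond) on both strands,
#' allowing overlaps, and stratifies them by the nucleotide(s) immediately
#' following the motif in transcript orientation -- the stratification that
#' shows only \code{UACAU} followed by A is cleaved, and that the downstream
#' base controls trimming.
#'
#' @param genome a \code{\link{GenomeRef}}.
#' @param motif RNA motif (T and U interchangeable).
#' @param junctionOffset position within the motif of the nucleotide 5' of
#'   the cleaved bond (default 1: cleavage after the first motif base).
#' @param stratifyBy how many downstream nucleotides key the strata
#'   (default 1).
#' @return data.frame with \code{junction}, \code{strand}, \code{stratum}
#'   (RNA alphabet; \code{NA} when the motif abuts the genome end).
#' @export
findMotifSites <- function(genome, motif = "UACAU", junctionOffset = 1L,
                           stratifyBy = 1L) {
  dnaMotif <- chartr("Uu", "Tt", toupper(motif))
  L <- length(genome)
  len <- nchar(dnaMotif)
  subj <- Biostrings::DNAString(genomeSequence(genome))
  rows <- list()
  plus <- Biostrings::matchPattern(dnaMotif, subj)
  if (length(plus)) {
    m <- BiocGenerics::start(plus)
    j <- m + junctionOffset - 1L
    sa <- m + len
    sb <- sa + stratifyBy - 1L
    strat <- ifelse(sb <= L,
                    chartr("T", "U", substring(genomeSequence(genome), sa, sb)),
                    NA_character_)
    rows[[1]] <- data.frame(junction = j, strand = "+", stratum = strat,
                            stringsAsFactors = FALSE)
  }
  minus <- Biostrings::matchPattern(
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(dnaMotif))), subj)
  if (length(minus)) {
    m <- BiocGenerics::start(minus)
    j <- m + len - junctionOffset
    sb <- m - 1L
    sa <- m - stratifyBy
    strat <- ifelse(sa >= 1L,
                    chartr("T", "U",
                           .revcomp(substring(genomeSequence(genome), sa, sb))),
                    NA_character_)
    rows[[2]] <- data.frame(junction = j, strand = "-", stratum = strat,
                            stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(junction = integer(0), strand = character(0),
                      stratum = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Motif-anchored metagene profile
#'
#' Extracts the signal in a window around each site's anchor -- offset 0 is
#' the first nucleotide of the downstream cleavage product (junction + 1 in
#' transcript orientation) -- normalizes each window, filters weakly covered
#' instances, and returns the position-wise 90%-winsorized mean and
#' standard deviation across retained instances.
#'
#' Normalization modes: \code{edge8} divides by the mean of the 8 window
#' positions at the edge distal to the signal (the first 8 positions for
#' 3'-mapped channels, the last 8 for 5'-mapped ones, in transcript window
#' order); \code{max20} divides by the maximum over the central 20-nt
#' window. Instances with a mean below \code{minMeanPerPos} raw reads per
#' position are dropped -- evaluated on \code{coverageTrack} when supplied
#' (local Rend-seq density for sparse monophosphate 5'-end metagenes) and on
#' the profiled track itself otherwise; under \code{edge8} the
#' normalization-window raw sum must reach \code{minNormSum} reads; a zero
#' denominator drops the instance with a logged reason.
#'
#' @param track an \code{EndTrack} (raw counts or RPM; raw-scale filters use
#'   the track's RPM scale when normalized).
#' @param sites data.frame with \code{junction}, \code{strand} (for example
#'   from \code{\link{findMotifSites}}); sites on other strands are ignored.
#' @param window half-width of the profile window (default 50).
#' @param mode \code{"edge8"} or \code{"max20"}.
#' @param anchorOffset offset of the anchor from the junction (default 1).
#' @param minMeanPerPos,minNormSum raw-read filters.
#' @param coverageTrack optional \code{EndTrack} (same strand) carrying the
#'   expression density used for the coverage filter.
#' @param winsorLevel winsorization level across sites (default 0.90).
#' @return list with \code{offsets}, \code{mean}, \code{sd}, \code{n},
#'   \code{mode}, \code{dropped} (per-site reason, NA when retained).
#' @export
metageneProfile <- function(track, sites, window = 50L,
                            mode = c("edge8", "max20"),
                            anchorOffset = 1L, minMeanPerPos = 1,
                            minNormSum = 10, coverageTrack = NULL,
                            winsorLevel = 0.90) {
  mode <- match.arg(mode)
  v <- trackValues(track)
  sc <- if (trackUnits(track) == "RPM") track@scale else 1
  if (!is.null(coverageTrack)) {
    cv <- trackValues(coverageTrack)
    csc <- if (trackUnits(coverageTrack) == "RPM") coverageTrack@scale else 1
  }
  L <- length(v)
  offsets <- seq(-window, window)
  sites <- sites[sites$strand == track@strand, , drop = FALSE]
  rowsKept <- list()
  dropped <- rep(NA_character_, nrow(sites))
  fivePrime <- grepl("5p", track@channel)
  for (i in seq_len(nrow(sites))) {
    step <- .dirStep(sites$strand[i])
    anchor <- sites$junction[i] + step * anchorOffset
    idx <- anchor + step * offsets
    if (any(idx < 1L | idx > L)) { dropped[i] <- "edge"; next }
    vals <- v[idx]
    raw <- vals / sc
    covRaw <- if (is.null(coverageTrack)) raw else cv[idx] / csc
    if (mean(covRaw) < minMeanPerPos) { dropped[i] <- "low_coverage"; next }
    if (mode == "edge8") {
      normIdx <- if (fivePrime) (length(vals) - 7L):length(vals)
                 else 1:8
      if (sum(raw[normIdx]) < minNormSum) {
        dropped[i] <- "low_norm_window"; next
      }
      denom <- mean(vals[normIdx])
    } else {
      mid <- which(offsets >= -10L & offsets <= 9L)
      denom <- max(vals[mid])
    }
    if (denom <= 0) { dropped[i] <- "zero_denominator"; next }
    rowsKept[[length(rowsKept) + 1L]] <- vals / denom
  }
  n <- length(rowsKept)
  if (n == 0L)
    return(list(offsets = offsets, mean = rep(NA_real_, length(offsets)),
                sd = rep(NA_real_, length(offsets)), n = 0L, mode = mode,
                dropped = dropped))
  m <- do.call(rbind, rowsKept)
  k <- floor(((1 - winsorLevel) / 2) * n)
  winsCol <- function(x) {
    if (k > 0L) {
      s <- sort(x)
      x <- pmin(pmax(x, s[k + 1L]), s[n - k])
    }
    x
  }
  wm <- apply(m, 2, function(x) mean(winsCol(x)))
  ws <- apply(m, 2, function(x) if (n > 1) sd(winsCol(x)) else 0)
  list(offsets = offsets, mean = wm, sd = ws, n = n, mode = mode,
       dropped = dropped)
}

#' Metagene profile across both strands of a strain
#'
#' Builds \code{\link{metageneProfile}} per strand from one channel of a
#' \code{\link{StrainSample}} and combines the per-offset means as a
#' site-weighted average across strands.
#'
#' @param sample a \code{StrainSample}.
#' @param channel track channel to profile.
#' @param sites data.frame with \code{junction}, \code{strand}.
#' @param coverageChannel optional channel supplying the coverage filter
#'   (e.g. \code{"rend3p"} when profiling sparse \code{endseq5p} signal).
#' @param ... passed to \code{\link{metageneProfile}}.
#' @return list with \code{offsets}, \code{mean}, \code{n}.
#' @export
strainMetagene <- function(sample, channel, sites,
                           coverageChannel = NULL, ...) {
  profs <- list()
  for (s in .STRANDS) {
    sub <- sites[sites$strand == s, , drop = FALSE]
    if (!nrow(sub)) next
    cov <- if (is.null(coverageChannel)) NULL
           else getTrack(sample, coverageChannel, s)
    p <- metageneProfile(getTrack(sample, channel, s), sub,
                         coverageTrack = cov, ...)
    if (p$n > 0) profs[[s]] <- p
  }
  if (!length(profs))
    return(list(offsets = integer(0), mean = numeric(0), n = 0L))
  w <- vapply(profs, `[[`, numeric(1), "n")
  meanComb <- Reduce(`+`, Map(function(p, wi) p$mean * wi, profs, w)) /
    sum(w)
  list(offsets = profs[[1]]$offsets, mean = meanComb, n = sum(w))
}

#' Detect downstream 5'-trimming offsets
#'
#' Scans the positive-offset side of a monophosphate-specific 5'-end
#' metagene profile for discrete peaks marking post-cleavage 5' trimming
#' (the signature is monophosphorylated ends 2 and, for some downstream
#' sequences, 4 nt beyond the nascent hydroxylated 5' end). An offset is
#' reported when its winsorized mean exceeds \code{factor} times the median
#' of the positive-offset baseline and also reaches \code{minRelPeak} of
#' the positive-offset maximum -- the second condition keeps stray
#' low-level reads from registering when most of the baseline is empty,
#' since discrete trimming peaks carry an order-one share of a
#' max-normalized profile.
#'
#' @param profile result of \code{\link{metageneProfile}} built from a
#'   5'-monophosphate-specific (\code{endseq5p}) track.
#' @param factor peak-over-baseline factor (default 3; the published
#'   metagenes were read qualitatively, so this constant is configurable).
#' @param minRelPeak minimum peak height relative to the positive-offset
#'   maximum (default 0.25).
#' @return increasing integer vector of trimming offsets (possibly empty).
#' @export
detectTrimmingOffsets <- function(profile, factor = 3, minRelPeak = 0.25) {
  pos <- profile$offsets > 0L
  mu <- profile$mean[pos]
  off <- profile$offsets[pos]
  if (!length(mu) || all(!is.finite(mu))) return(integer(0))
  baseline <- median(mu, na.rm = TRUE)
  top <- max(mu, na.rm = TRUE)
  if (!is.finite(baseline) || !is.finite(top) || top <= 0)
    return(integer(0))
  hits <- is.finite(mu) & mu > 0 & mu >= minRelPeak * top &
    (baseline == 0 | mu > factor * baseline)
  sort(off[hits])
}
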