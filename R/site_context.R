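## site_context module: tiled-MFE structure profiles with GA-dinucleotide
## background resampling, GC profiles, and nucleotide/IC/k-mer statistics.

#' Tile a genome with folded k-mers
#'
#' Every k-mer along the strand is folded and its minimum free energy is
#' assigned to the k-mer's centre position (the 20th nucleotide of a 40-mer;
#' 0-based offset k/2 - 1 for even k). Positions without a complete window
#' are \code{NA}. For the minus strand the reverse complement is tiled and
#' the resulting values are mirrored back onto genomic coordinates.
#'
#' @param genome a \code{\link{GenomeRef}}.
#' @param k k-mer width (default 40).
#' @param strand strand to tile.
#' @param backend folding backend; the compiled built-in model is used
#'   directly when NULL (fastest).
#' @return numeric vector of per-position MFE values (genomic coordinates).
#' @export
tileFoldTrack <- function(genome, k = 40L, strand = "+", backend = NULL) {
  seq <- genomeSequence(genome)
  if (nchar(seq) < k) stop("genome shorter than k")
  if (strand == "-") seq <- .revcomp(seq)
  rna <- chartr("T", "U", seq)
  if (is.null(backend)) {
    vals <- .tile_fold_cpp(rna, as.integer(k))
  } else {
    n <- nchar(rna)
    vals <- rep(NA_real_, n)
    centre <- if (k %% 2 == 0) k %/% 2 else k %/% 2 + 1L
    for (i in seq_len(n - k + 1L)) {
      sub <- substr(rna, i, i + k - 1L)
      if (grepl("N", sub)) next
      vals[i + centre - 1L] <- foldEnergy(foldRegion(sub, backend))
    }
  }
  if (strand == "-") vals <- rev(vals)
  vals
}

#' Structure profile around cleavage sites
#'
#' Extracts tiled-MFE values in windows centred on cleavage junctions
#' (transcript orientation) and averages position-wise across sites. Sites
#' within \code{window} nt of an RNA end detected in wild-type Rend-seq are
#' excluded, since transcript boundaries impose their own structure signal.
#'
#' @param mfeTracks named list of per-strand MFE vectors from
#'   \code{\link{tileFoldTrack}} (names \code{"+"}, \code{"-"}).
#' @param sites cleavage-site data.frame.
#' @param window half-width (default 75, i.e. 150-nt windows).
#' @param wtEnds data.frame(\code{strand}, \code{pos}) of wild-type 5'/3'
#'   ends, or NULL to skip the exclusion.
#' @return list with \code{offsets}, \code{meanMfe}, \code{nSites},
#'   \code{used} (logical per input site).
#' @export
siteStructureProfile <- function(mfeTracks, sites, window = 75L,
                                 wtEnds = NULL) {
  used <- rep(TRUE, nrow(sites))
  if (!is.null(wtEnds) && nrow(wtEnds)) {
    for (i in seq_len(nrow(sites))) {
      e <- wtEnds$pos[wtEnds$strand == sites$strand[i]]
      if (length(e) && min(abs(e - sites$junction[i])) <= window)
        used[i] <- FALSE
    }
  }
  if (!any(used)) stop("no sites retained for the structure profile")
  offsets <- seq(-window, window)
  acc <- matrix(NA_real_, nrow = sum(used), ncol = length(offsets))
  r <- 0L
  for (i in which(used)) {
    r <- r + 1L
    strand <- sites$strand[i]
    v <- mfeTracks[[strand]]
    idx <- sites$junction[i] + .dirStep(strand) * offsets
    inb <- idx >= 1L & idx <= length(v)
    acc[r, inb] <- v[idx[inb]]
  }
  list(offsets = offsets, meanMfe = colMeans(acc, na.rm = TRUE),
       nSites = sum(used), used = used)
}

## eligible GA-dinucleotide positions on the coding strand within CDS
.gaPositionsInCds <- function(genome, features) {
  seq <- genomeSequence(genome)
  type <- S4Vectors::mcols(features)$type
  cds <- features[type == "CDS"]
  out <- list()
  for (i in seq_along(cds)) {
    s <- as.character(GenomicRanges::strand(cds[i]))
    a <- GenomicRanges::start(cds[i]); b <- GenomicRanges::end(cds[i])
    pos <- seq(a, b)
    if (s == "+") {
      ok <- pos < nchar(seq) &
        substring(seq, pos, pos) == "G" &
        substring(seq, pos + 1L, pos + 1L) == "A"
    } else {
      # G|A read on the minus strand: genomic C at p, T at p-1
      ok <- pos > 1L &
        substring(seq, pos, pos) == "C" &
        substring(seq, pos - 1L, pos - 1L) == "T"
    }
    if (any(ok))
      out[[length(out) + 1L]] <- data.frame(strand = s, pos = pos[ok])
  }
  if (!length(out)) return(data.frame(strand = character(0), pos = integer(0)))
  unique(do.call(rbind, out))
}

#' GA-dinucleotide background structure band
#'
#' Controls the structure profile for the sequence context at the cleavage
#' junction: repeatedly samples (without replacement within an iteration)
#' the same number of random coding-region positions centred on G|A
#' dinucleotides on the coding strand -- the most enriched junction
#' dinucleotide -- excluding called cleavage positions, recomputes the
#' per-offset mean MFE curve, and returns the 25th/75th percentile band
#' across iterations.
#'
#' @param mfeTracks per-strand MFE vectors.
#' @param genome a \code{\link{GenomeRef}}.
#' @param features feature \code{GRanges} (CDS intervals used).
#' @param nSites number of positions per iteration (match the real profile).
#' @param iterations resampling iterations (default 100).
#' @param seed RNG seed.
#' @param window half-width (default 75).
#' @param excludeSites cleavage-site data.frame whose junctions are excluded.
#' @return list with \code{offsets}, \code{q25}, \code{q75},
#'   \code{iterations}.
#' @export
gaBackgroundProfile <- function(mfeTracks, genome, features, nSites,
                                iterations = 100L, seed = 1L, window = 75L,
                                excludeSites = NULL) {
  elig <- .gaPositionsInCds(genome, features)
  if (!is.null(excludeSites) && nrow(excludeSites)) {
    key <- paste(elig$strand, elig$pos)
    drop <- key %in% paste(excludeSites$strand, excludeSites$junction)
    elig <- elig[!drop, , drop = FALSE]
  }
  if (nrow(elig) < nSites)
    stop("only ", nrow(elig), " eligible GA-centred positions; need ", nSites)
  offsets <- seq(-window, window)
  set.seed(seed)
  curves <- matrix(NA_real_, nrow = iterations, ncol = length(offsets))
  for (it in seq_len(iterations)) {
    pick <- elig[sample.int(nrow(elig), nSites), , drop = FALSE]
    acc <- matrix(NA_real_, nrow = nSites, ncol = length(offsets))
    for (i in seq_len(nSites)) {
      v <- mfeTracks[[pick$strand[i]]]
      idx <- pick$pos[i] + .dirStep(pick$strand[i]) * offsets
      inb <- idx >= 1L & idx <= length(v)
      acc[i, inb] <- v[idx[inb]]
    }
    curves[it, ] <- colMeans(acc, na.rm = TRUE)
  }
  list(offsets = offsets,
       q25 = apply(curves, 2, quantile, probs = 0.25, na.rm = TRUE),
       q75 = apply(curves, 2, quantile, probs = 0.75, na.rm = TRUE),
       iterations = iterations)
}

#' GC-content profile around cleavage sites
#'
#' Per-offset fraction of G or C (strand-symmetric) across sites, in
#' transcript orientation.
#'
#' @param sites cleavage-site data.frame.
#' @param genome a \code{\link{GenomeRef}}.
#' @param window half-width (default 75).
#' @return list with \code{offsets} and \code{gc}.
#' @export
gcProfile <- function(sites, genome, window = 75L) {
  seq <- genomeSequence(genome)
  offsets <- seq(-window, window)
  acc <- matrix(NA_real_, nrow = nrow(sites), ncol = length(offsets))
  for (i in seq_len(nrow(sites))) {
    idx <- sites$junction[i] + .dirStep(sites$strand[i]) * offsets
    inb <- idx >= 1L & idx <= nchar(seq)
    b <- substring(seq, idx[inb], idx[inb])
    acc[i, inb] <- as.numeric(b %in% c("G", "C"))
  }
  list(offsets = offsets, gc = colMeans(acc, na.rm = TRUE))
}

#' Extract oriented site windows
#'
#' The 30-nt window (default) places the junction nucleotide at window
#' position \code{halfWidth} so the cleaved bond lies between positions 15
#' and 16.
#'
#' @param sites cleavage-site data.frame.
#' @param genome a \code{\link{GenomeRef}}.
#' @param halfWidth half window width (window = 2 * halfWidth).
#' @return character vector of RNA windows (sites running off the genome are
#'   dropped).
#' @export
siteWindows <- function(sites, genome, halfWidth = 15L) {
  L <- length(genome)
  out <- character(0)
  for (i in seq_len(nrow(sites))) {
    j <- sites$junction[i]; s <- sites$strand[i]
    if (s == "+") { a <- j - halfWidth + 1L; b <- j + halfWidth }
    else { a <- j - halfWidth; b <- j + halfWidth - 1L }
    if (a < 1L || b > L) next
    out <- c(out, chartr("T", "U", .orientedSubseq(genome, a, b, s)))
  }
  out
}

#' Sample background windows from coding regions
#'
#' k-mers evenly sampled every \code{every} nt from coding regions on the
#' coding strand, with sampling beginning after the start codon.
#'
#' @param genome a \code{\link{GenomeRef}}.
#' @param features feature \code{GRanges}.
#' @param k window width (default 30).
#' @param every sampling stride (default 100 nt).
#' @return character vector of RNA windows.
#' @export
sampleBackgroundWindows <- function(genome, features, k = 30L,
                                    every = 100L) {
  type <- S4Vectors::mcols(features)$type
  cds <- features[type == "CDS"]
  out <- character(0)
  for (i in seq_along(cds)) {
    s <- as.character(GenomicRanges::strand(cds[i]))
    a <- GenomicRanges::start(cds[i]); b <- GenomicRanges::end(cds[i])
    len <- b - a + 1L
    starts <- seq(3L, len - k, by = every) # 0-based offset past start codon
    for (off in starts) {
      if (s == "+") sub <- .orientedSubseq(genome, a + off, a + off + k - 1L, s)
      else sub <- .orientedSubseq(genome, b - off - k + 1L, b - off, s)
      out <- c(out, chartr("T", "U", sub))
    }
  }
  out
}

#' Write sequence windows to FASTA
#' @param windows character vector of sequences.
#' @param path output path.
#' @export
writeWindowsFasta <- function(windows, path) {
  ss <- Biostrings::RNAStringSet(windows)
  names(ss) <- sprintf("window_%d", seq_along(windows))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Nucleotide, information-content and k-mer enrichment statistics
#'
#' Per-position nucleotide frequencies and information content
#' (uniform-background convention, IC = 2 + sum f log2 f, in bits) over the
#' site windows, plus positional k-mer enrichment for k up to \code{maxK}:
#' for each k-mer observed at each window position, a one-sided binomial
#' tail P(X >= x | n sites, background probability) against background k-mer
#' frequencies estimated from the supplied background windows with a
#' pseudocount, Bonferroni-corrected over the full universe of
#' (position, k-mer) tests.
#'
#' @param siteWindows character vector of equal-length site windows (RNA).
#' @param background character vector of background windows.
#' @param maxK maximum k-mer length (default 4).
#' @param pseudocount background pseudocount (default 0.01).
#' @param alpha corrected significance level (default 0.01).
#' @return list with \code{freq} (4 x width matrix), \code{ic} (bits per
#'   position), \code{kmers} (data.frame of tests), \code{nSites},
#'   \code{nTests}.
#' @export
motifStats <- function(siteWindows, background, maxK = 4L,
                       pseudocount = 0.01, alpha = 0.01) {
  if (length(siteWindows) < 10L) stop("need at least 10 site windows")
  if (!length(background)) stop("background set is empty")
  width <- unique(nchar(siteWindows))
  if (length(width) != 1L) stop("site windows must have equal length")
  n <- length(siteWindows)
  alphabet <- c("A", "C", "G", "U")
  mat <- do.call(rbind, strsplit(siteWindows, ""))
  freq <- vapply(seq_len(width), function(j) {
    tab <- table(factor(mat[, j], levels = alphabet))
    as.numeric(tab) / n
  }, numeric(4))
  rownames(freq) <- alphabet
  ic <- apply(freq, 2, function(f) {
    h <- -sum(ifelse(f > 0, f * log2(f), 0))
    2 - h
  })
  # background k-mer probabilities at any position
  bgProb <- list()
  for (k in seq_len(maxK)) {
    counts <- new.env(hash = TRUE)
    total <- 0L
    for (s in background) {
      L <- nchar(s)
      if (L < k) next
      for (p in seq_len(L - k + 1L)) {
        km <- substr(s, p, p + k - 1L)
        counts[[km]] <- (if (is.null(counts[[km]])) 0L else counts[[km]]) + 1L
        total <- total + 1L
      }
    }
    denom <- total + pseudocount * 4^k
    bgProb[[k]] <- list(counts = counts, total = total, denom = denom)
  }
  probOf <- function(km) {
    k <- nchar(km)
    cnt <- bgProb[[k]]$counts[[km]]
    if (is.null(cnt)) cnt <- 0L
    (cnt + pseudocount) / bgProb[[k]]$denom
  }
  nTests <- sum(vapply(seq_len(maxK), function(k)
    (width - k + 1L) * 4^k, numeric(1)))
  rows <- list()
  for (k in seq_len(maxK)) {
    for (p in seq_len(width - k + 1L)) {
      kms <- substr(siteWindows, p, p + k - 1L)
      tab <- table(kms)
      for (km in names(tab)) {
        x <- as.integer(tab[[km]])
        pb <- probOf(km)
        praw <- pbinom(x - 1L, n, pb, lower.tail = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          k = k, pos = p, kmer = km, count = x, bgProb = pb,
          pRaw = praw, stringsAsFactors = FALSE)
      }
    }
  }
  km <- do.call(rbind, rows)
  km$pCorr <- pmin(km$pRaw * nTests, 1)
  km$significant <- km$pCorr < alpha
  km <- km[order(km$pRaw), ]
  rownames(km) <- NULL
  list(freq = freq, ic = ic, kmers = km, nSites = n, nTests = nTests)
}
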