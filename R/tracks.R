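## tracks module: alignment records, UMI collapse, end-track construction,
## RPM normalization, and FASTA/GFF3/wig/SAM/manifest I/O.

#' Construct a feature set
#'
#' Features are held as a \code{GRanges} (1-based, closed intervals) with
#' metadata columns \code{type} (CDS, rRNA, tRNA, scRNA or other) and
#' \code{id}. Used for the non-coding-RNA proximity and CDS-distance site
#' filters and for background sampling in motif statistics.
#'
#' @param type character vector of feature types.
#' @param strand "+" or "-" per feature.
#' @param start,end 1-based closed interval bounds.
#' @param id feature identifiers.
#' @param genomeLength total genome length, for bounds checking.
#' @return a \code{GRanges}.
#' @export
featureSet <- function(type, strand, start, end, id,
                       genomeLength = NULL) {
  type <- as.character(type)
  bad <- setdiff(unique(type), .FEATURE_TYPES)
  if (length(bad))
    stop("unknown feature type(s): ", paste(bad, collapse = ", "))
  if (any(start < 1L) || any(end < start))
    stop("features must satisfy 1 <= start <= end")
  if (!is.null(genomeLength) && any(end > genomeLength))
    stop("feature end beyond genome length")
  gr <- GenomicRanges::GRanges(
    seqnames = "genome",
    ranges = IRanges::IRanges(start = start, end = end),
    strand = strand)
  S4Vectors::mcols(gr)$type <- type
  S4Vectors::mcols(gr)$id <- as.character(id)
  gr
}

#' Create a table of alignment records
#'
#' @param strand,fivePrimePos,threePrimePos per-read strand and 1-based
#'   genomic coordinates of the read termini.
#' @param firstPosMismatch logical; read had a mismatch at its first
#'   (5'-most on the read) aligned position.
#' @param umi 8-nt unique molecular identifier, or \code{NA} when the
#'   library carries none.
#' @param readSeq read sequence.
#' @return data.frame with one row per record.
#' @export
alignmentRecords <- function(strand, fivePrimePos, threePrimePos,
                             firstPosMismatch = FALSE, umi = NA_character_,
                             readSeq = NA_character_) {
  df <- data.frame(strand = strand,
                   fivePrimePos = as.integer(fivePrimePos),
                   threePrimePos = as.integer(threePrimePos),
                   firstPosMismatch = firstPosMismatch,
                   umi = umi, readSeq = readSeq,
                   stringsAsFactors = FALSE)
  if (!all(df$strand %in% .STRANDS)) stop("strand must be '+' or '-'")
  withUmi <- !is.na(df$umi)
  if (any(withUmi) && !all(withUmi))
    stop("mixed presence/absence of UMIs across records")
  if (any(withUmi) && any(nchar(df$umi[withUmi]) != 8L))
    stop("UMIs must be 8 nt")
  df
}

.hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) return(Inf)
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Collapse UMI duplicates
#'
#' Within each (UMI, 5' position) group, reads whose sequences lie within
#' Hamming distance 1 of a retained representative are removed as PCR/optical
#' duplicates. Representatives are chosen greedily by descending read-sequence
#' abundance (ties broken lexicographically), so the collapse is deterministic
#' and idempotent. Output rows are ordered by 5' position, then descending
#' cluster size, then sequence.
#'
#' @param records data.frame from \code{\link{alignmentRecords}}; all rows
#'   must carry UMIs.
#' @return collapsed records (one row per retained representative).
#' @export
collapseUmis <- function(records) {
  if (nrow(records) == 0L) return(records)
  if (anyNA(records$umi))
    stop("all records must carry UMIs for collapsing")
  key <- paste(records$umi, records$strand, records$fivePrimePos, sep = "\r")
  keep <- integer(0)
  sizes <- integer(0)
  for (idx in split(seq_len(nrow(records)), key)) {
    seqs <- records$readSeq[idx]
    tab <- table(seqs)
    uniq <- names(tab)[order(-as.integer(tab), names(tab))]
    counts <- as.integer(tab[uniq])
    repSeq <- character(0)
    repIdx <- integer(0)
    repSize <- integer(0)
    for (k in seq_along(uniq)) {
      s <- uniq[k]
      merged <- FALSE
      for (r in seq_along(repSeq)) {
        if (.hamming(s, repSeq[r]) <= 1) {
          repSize[r] <- repSize[r] + counts[k]
          merged <- TRUE
          break
        }
      }
      if (!merged) {
        repSeq <- c(repSeq, s)
        repIdx <- c(repIdx, idx[match(s, seqs)])
        repSize <- c(repSize, counts[k])
      }
    }
    keep <- c(keep, repIdx)
    sizes <- c(sizes, repSize)
  }
  out <- records[keep, , drop = FALSE]
  ord <- order(out$fivePrimePos, -sizes, out$readSeq)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build per-strand 5'/3' end tracks from alignment records
#'
#' Each record increments the 5' track at its 5' terminus and the 3' track at
#' its 3' terminus. Reads flagged with a first-position mismatch have their 5'
#' increment moved 1 nt in the 3' direction of the read (strand-aware),
#' accommodating non-templated nucleotide addition during reverse
#' transcription. Records with a terminus outside the genome are skipped with
#' a warning.
#'
#' @param records data.frame of alignment records (UMI-collapsed if the
#'   library carries UMIs).
#' @param genome a \code{\link{GenomeRef}}.
#' @param channel5p,channel3p channel labels for the output tracks.
#' @return named list of four raw-count \code{EndTrack}s:
#'   \code{<channel5p>.+/-}, \code{<channel3p>.+/-}.
#' @export
buildEndTracks <- function(records, genome,
                           channel5p = "rend5p", channel3p = "rend3p") {
  L <- length(genome)
  v5 <- list("+" = numeric(L), "-" = numeric(L))
  v3 <- list("+" = numeric(L), "-" = numeric(L))
  shift <- ifelse(records$firstPosMismatch,
                  ifelse(records$strand == "+", 1L, -1L), 0L)
  p5 <- records$fivePrimePos + shift
  p3 <- records$threePrimePos
  ok <- p5 >= 1L & p5 <= L & p3 >= 1L & p3 <= L
  if (any(!ok))
    warning(sum(!ok), " record(s) with a terminus outside the genome skipped")
  for (s in .STRANDS) {
    sel <- ok & records$strand == s
    if (any(sel)) {
      t5 <- tabulate(p5[sel], nbins = L)
      t3 <- tabulate(p3[sel], nbins = L)
      v5[[s]] <- v5[[s]] + t5
      v3[[s]] <- v3[[s]] + t3
    }
  }
  out <- list(
    EndTrack(channel5p, "+", v5[["+"]]), EndTrack(channel5p, "-", v5[["-"]]),
    EndTrack(channel3p, "+", v3[["+"]]), EndTrack(channel3p, "-", v3[["-"]]))
  names(out) <- c(paste(channel5p, .STRANDS, sep = "."),
                  paste(channel3p, .STRANDS, sep = "."))
  out
}

#' Normalize a raw-count track to RPM
#'
#' Scales values by 1e6 / CDS-mapped read total, the depth normalization used
#' throughout: reads per million CDS-mapped reads.
#'
#' @param track raw-count \code{EndTrack}.
#' @param cdsMappedTotal CDS-mapped read count (> 0).
#' @return RPM \code{EndTrack}; the per-read RPM scale is recorded in the
#'   \code{scale} slot.
#' @export
normalizeRpm <- function(track, cdsMappedTotal) {
  if (trackUnits(track) != "raw_reads")
    stop("track is already normalized")
  if (!is.numeric(cdsMappedTotal) || cdsMappedTotal <= 0)
    stop("cdsMappedTotal must be > 0")
  sc <- 1e6 / cdsMappedTotal
  EndTrack(track@channel, track@strand, track@values * sc,
           units = "RPM", scale = sc)
}

## ---- I/O -------------------------------------------------------------

#' Read a genome from FASTA
#' @param path FASTA file with a single sequence.
#' @return a \code{\link{GenomeRef}}.
#' @export
readGenomeFasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1L)
    stop("expected a single-sequence FASTA, got ", length(ss))
  GenomeRef(sub("\\s.*$", "", names(ss)[1]), as.character(ss[[1]]))
}

#' Write a genome to FASTA
#' @param genome a \code{GenomeRef}.
#' @param path output path.
#' @export
writeGenomeFasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genomeSequence(genome))
  names(ss) <- genome@name
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read features from GFF3
#'
#' Feature types are taken from GFF column 3; types outside the CDS/rRNA/
#' tRNA/scRNA vocabulary are mapped to \code{"other"}.
#'
#' @param path GFF3 file.
#' @return feature \code{GRanges} as from \code{\link{featureSet}}.
#' @export
readFeaturesGff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  type[!type %in% .FEATURE_TYPES] <- "other"
  id <- if (!is.null(gr$ID)) as.character(gr$ID) else
    paste0("feat", seq_along(gr))
  featureSet(type, as.character(GenomicRanges::strand(gr)),
             GenomicRanges::start(gr), GenomicRanges::end(gr), id)
}

#' Write features to GFF3
#' @param features feature \code{GRanges}.
#' @param path output path.
#' @export
writeFeaturesGff <- function(features, path) {
  gr <- features
  S4Vectors::mcols(gr)$ID <- S4Vectors::mcols(gr)$id
  phase <- rep(NA_integer_, length(gr))
  phase[S4Vectors::mcols(gr)$type == "CDS"] <- 0L
  S4Vectors::mcols(gr)$phase <- phase
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write an end track as wig (variableStep, span 1)
#'
#' Only non-zero positions are written; zeros are implicit.
#'
#' @param track an \code{EndTrack}.
#' @param path output path.
#' @param genomeName sequence name for the wig declaration.
#' @export
writeTrackWig <- function(track, path, genomeName = "genome") {
  v <- trackValues(track)
  nz <- which(v != 0)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=wiggle_0 name=\"%s.%s\"",
                     track@channel, track@strand), con)
  writeLines(sprintf("variableStep chrom=%s span=1", genomeName), con)
  if (length(nz))
    writeLines(sprintf("%d %.6g", nz, v[nz]), con)
  invisible(path)
}

#' Read an end track from wig
#'
#' @param path wig file (variableStep, span 1).
#' @param genome a \code{GenomeRef} providing the track length.
#' @param channel,strand track identity (not stored in wig).
#' @param units,scale units of the stored values and, for RPM, the per-read
#'   RPM scale.
#' @return an \code{EndTrack}; positions absent from the file are zero.
#' @export
readTrackWig <- function(path, genome, channel, strand,
                         units = "raw_reads", scale = NA_real_) {
  gr <- rtracklayer::import(path, format = "wig")
  v <- numeric(length(genome))
  if (length(gr)) {
    pos <- GenomicRanges::start(gr)
    if (any(pos < 1L | pos > length(genome)))
      stop("wig position outside genome")
    v[pos] <- S4Vectors::mcols(gr)$score
  }
  EndTrack(channel, strand, v, units = units, scale = scale)
}

#' Read alignment records from a SAM file
#'
#' Parses mapped single-end alignments: termini from POS and the
#' reference-consumed CIGAR width, strand from FLAG, UMI from a read-name
#' suffix \code{"_UMI:<seq>"}, and the first-position-mismatch flag from the
#' MD tag when present (a mismatch at the first aligned base of the read, in
#' read orientation).
#'
#' @param path SAM file (headered).
#' @return data.frame of alignment records.
#' @export
readSamRecords <- function(path) {
  bam <- Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "pos", "cigar"), tag = "MD")
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  mapped <- !bitwAnd(res$flag, 4L)
  qname <- res$qname[mapped]
  flag <- res$flag[mapped]
  pos <- res$pos[mapped]
  cigar <- res$cigar[mapped]
  md <- res$tag$MD[mapped]
  # reference-consumed width from CIGAR (M/D/N/=/X ops)
  refw <- vapply(cigar, function(cg) {
    m <- gregexpr("(\\d+)([MIDNSHP=X])", cg)[[1]]
    lens <- regmatches(cg, gregexpr("\\d+", cg))[[1]]
    ops <- regmatches(cg, gregexpr("[MIDNSHP=X]", cg))[[1]]
    sum(as.integer(lens)[ops %in% c("M", "D", "N", "=", "X")])
  }, numeric(1), USE.NAMES = FALSE)
  minus <- bitwAnd(flag, 16L) > 0L
  strand <- ifelse(minus, "-", "+")
  p5 <- ifelse(minus, pos + refw - 1L, pos)
  p3 <- ifelse(minus, pos, pos + refw - 1L)
  umi <- ifelse(grepl("_UMI:", qname),
                sub("^.*_UMI:", "", qname), NA_character_)
  fpm <- logical(length(qname))
  if (!is.null(md)) {
    hasMd <- !is.na(md)
    # MD is in reference order; first read base = reference start (+) or
    # reference end (-)
    fpm[hasMd & !minus] <- grepl("^0[ACGTN]", md[hasMd & !minus])
    fpm[hasMd & minus] <- grepl("[ACGTN]0$", md[hasMd & minus])
  }
  alignmentRecords(strand = strand, fivePrimePos = as.integer(p5),
                   threePrimePos = as.integer(p3), firstPosMismatch = fpm,
                   umi = umi, readSeq = NA_character_)
}

#' Read a strain manifest and its wig tracks
#'
#' The manifest is a TSV with columns \code{strain}, \code{genotype}
#' (comma-separated ablated genes; empty for wild type),
#' \code{cds_mapped_total}, and eight path columns
#' \code{<channel>_<plus|minus>} for the four channels. Tracks are read as
#' raw counts and RPM-normalized.
#'
#' @param path manifest TSV.
#' @param genome a \code{GenomeRef}.
#' @param normalize normalize tracks to RPM (default TRUE).
#' @return named list of \code{\link{StrainSample}}s.
#' @export
readStrainManifest <- function(path, genome, normalize = TRUE) {
  man <- read.delim(path, stringsAsFactors = FALSE)
  dir <- dirname(path)
  samples <- list()
  for (i in seq_len(nrow(man))) {
    gt <- man$genotype[i]
    gt <- if (is.na(gt) || gt == "") character(0)
          else strsplit(gt, ",")[[1]]
    total <- man$cds_mapped_total[i]
    tracks <- list()
    for (ch in .CHANNELS) {
      for (s in .STRANDS) {
        col <- paste0(ch, "_", if (s == "+") "plus" else "minus")
        fp <- man[[col]][i]
        if (!file.exists(fp)) fp <- file.path(dir, fp)
        tr <- readTrackWig(fp, genome, ch, s)
        if (normalize) tr <- normalizeRpm(tr, total)
        tracks[[paste(ch, s, sep = ".")]] <- tr
      }
    }
    samples[[man$strain[i]]] <-
      StrainSample(man$strain[i], gt, tracks, total)
  }
  samples
}

#' Write a strain sample's tracks and a manifest row
#'
#' Writes eight wig files named \code{<strain>.<channel>.<plus|minus>.wig}
#' under \code{dir}. Tracks are written on the raw-count scale when raw;
#' RPM tracks are converted back to raw counts first so that re-reading via
#' the manifest reproduces the sample.
#'
#' @param sample a \code{StrainSample}.
#' @param dir output directory.
#' @return one-row data.frame manifest entry (paths relative to \code{dir}).
#' @export
writeStrainSample <- function(sample, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  row <- list(strain = sample@strain,
              genotype = paste(sample@genotype, collapse = ","),
              cds_mapped_total = sample@cdsMappedTotal)
  for (ch in .CHANNELS) {
    for (s in .STRANDS) {
      tr <- getTrack(sample, ch, s)
      if (trackUnits(tr) == "RPM")
        tr <- EndTrack(ch, s, round(trackValues(tr) / tr@scale, 6))
      fn <- sprintf("%s.%s.%s.wig", sample@strain, ch,
                    if (s == "+") "plus" else "minus")
      writeTrackWig(tr, file.path(dir, fn))
      row[[paste0(ch, "_", if (s == "+") "plus" else "minus")]] <- fn
    }
  }
  as.data.frame(row, stringsAsFactors = FALSE)
}

#' Write a manifest for a set of strain samples
#' @param samples list of \code{StrainSample}s.
#' @param dir output directory (wigs are written alongside).
#' @param file manifest file name.
#' @return path to the manifest.
#' @export
writeStrainManifest <- function(samples, dir, file = "manifest.tsv") {
  rows <- lapply(samples, writeStrainSample, dir = dir)
  man <- do.call(rbind, rows)
  path <- file.path(dir, file)
  write.table(man, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
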