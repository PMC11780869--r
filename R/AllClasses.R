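#' @import methods
#' @importFrom stats dnorm kmeans median pbinom quantile rlnorm rnorm rpois
#'   runif sd setNames var
#' @importFrom utils head read.delim write.table combn
#' @importFrom BiocGenerics start
NULL

## channel vocabulary for end-signal tracks
.CHANNELS <- c("endseq5p", "endseq3p", "rend5p", "rend3p")
.STRANDS <- c("+", "-")
.NCRNA_TYPES <- c("rRNA", "tRNA", "scRNA")
.FEATURE_TYPES <- c("CDS", .NCRNA_TYPES, "other")

#' Reference genome for a single replicon
#'
#' Holds the nucleotide sequence that provides the coordinate frame for all
#' end-signal tracks and cleavage-site calls. Coordinates are 1-based.
#'
#' @slot name replicon identifier.
#' @slot sequence uppercase nucleotide string over A/C/G/T/N.
#' @export
setClass("GenomeRef",
  slots = c(name = "character", sequence = "character"))

setValidity("GenomeRef", function(object) {
  if (length(object@name) != 1L || length(object@sequence) != 1L)
    return("'name' and 'sequence' must be length 1")
  if (grepl("[^ACGTN]", object@sequence))
    return("sequence may contain only A/C/G/T/N (uppercase)")
  TRUE
})

#' @param name replicon identifier.
#' @param sequence nucleotide string (coerced to uppercase; T and U accepted).
#' @rdname GenomeRef-class
#' @export
GenomeRef <- function(name, sequence) {
  sequence <- chartr("u", "t", as.character(sequence))
  sequence <- toupper(sequence)
  sequence <- chartr("U", "T", sequence)
  new("GenomeRef", name = name, sequence = sequence)
}

#' @rdname GenomeRef-class
#' @param x,object a \code{GenomeRef}.
#' @export
setMethod("length", "GenomeRef", function(x) nchar(x@sequence))

#' @rdname GenomeRef-class
#' @export
genomeSequence <- function(x) x@sequence

setMethod("show", "GenomeRef", function(object) {
  cat("GenomeRef '", object@name, "': ", length(object), " nt\n", sep = "")
})

#' Per-position end-signal track
#'
#' One channel (5'- or 3'-end sequencing, or 5'-/3'-mapped Rend-seq) on one
#' strand, with one non-negative value per genomic position. Units are either
#' raw read counts or RPM (reads per million CDS-mapped reads). The
#' \code{scale} slot records the RPM value of a single read
#' (1e6 / CDS-mapped total) once normalized; it is \code{NA} for raw tracks.
#'
#' @slot channel one of \code{endseq5p}, \code{endseq3p}, \code{rend5p},
#'   \code{rend3p}.
#' @slot strand \code{"+"} or \code{"-"}.
#' @slot values numeric vector, one value per genomic position.
#' @slot units \code{"raw_reads"} or \code{"RPM"}.
#' @slot scale RPM per raw read, or \code{NA} while raw.
#' @export
setClass("EndTrack",
  slots = c(channel = "character", strand = "character",
            values = "numeric", units = "character", scale = "numeric"))

setValidity("EndTrack", function(object) {
  if (!object@channel %in% .CHANNELS)
    return(sprintf("channel must be one of: %s", paste(.CHANNELS, collapse = ", ")))
  if (!object@strand %in% .STRANDS)
    return("strand must be '+' or '-'")
  if (!object@units %in% c("raw_reads", "RPM"))
    return("units must be 'raw_reads' or 'RPM'")
  if (any(object@values < 0, na.rm = TRUE))
    return("track values must be non-negative")
  if (object@units == "RPM" && is.na(object@scale))
    return("RPM tracks must carry the read-to-RPM scale")
  TRUE
})

#' @param channel,strand,values,units,scale see slots.
#' @rdname EndTrack-class
#' @export
EndTrack <- function(channel, strand, values, units = "raw_reads",
                     scale = NA_real_) {
  new("EndTrack", channel = channel, strand = strand,
      values = as.numeric(values), units = units, scale = scale)
}

#' @rdname EndTrack-class
#' @param x,object an \code{EndTrack}.
#' @export
setMethod("length", "EndTrack", function(x) length(x@values))

#' @rdname EndTrack-class
#' @export
trackValues <- function(x) x@values

#' @rdname EndTrack-class
#' @export
trackUnits <- function(x) x@units

setMethod("show", "EndTrack", function(object) {
  cat("EndTrack ", object@channel, " (", object@strand, "): ",
      length(object), " positions, ", object@units,
      ", total ", format(sum(object@values), digits = 6), "\n", sep = "")
})

#' Strain sample: genotype plus its eight end-signal tracks
#'
#' Bundles the four channels x two strands of end-signal tracks measured in
#' one strain, its genotype (the set of ablated genes, e.g. \code{rnjA},
#' \code{"4exo"}, \code{rny}, \code{rnc}, \code{ndoA}), and the CDS-mapped
#' read total used for RPM normalization.
#'
#' @slot strain strain identifier.
#' @slot genotype character vector of ablated genes (empty for wild type).
#' @slot tracks named list of eight \code{EndTrack}s, names
#'   \code{"<channel>.<strand>"}.
#' @slot cdsMappedTotal CDS-mapped read count (> 0).
#' @export
setClass("StrainSample",
  slots = c(strain = "character", genotype = "character",
            tracks = "list", cdsMappedTotal = "numeric"))

setValidity("StrainSample", function(object) {
  want <- as.vector(outer(.CHANNELS, .STRANDS, paste, sep = "."))
  if (!setequal(names(object@tracks), want))
    return("tracks must be the eight '<channel>.<strand>' combinations")
  if (!all(vapply(object@tracks, is, logical(1), "EndTrack")))
    return("all tracks must be EndTrack objects")
  lens <- vapply(object@tracks, length, integer(1))
  if (length(unique(lens)) != 1L)
    return("all tracks must have equal length")
  if (object@cdsMappedTotal <= 0)
    return("cdsMappedTotal must be > 0")
  TRUE
})

#' @param strain,genotype,tracks,cdsMappedTotal see slots.
#' @rdname StrainSample-class
#' @export
StrainSample <- function(strain, genotype, tracks, cdsMappedTotal) {
  new("StrainSample", strain = strain, genotype = as.character(genotype),
      tracks = tracks, cdsMappedTotal = as.numeric(cdsMappedTotal))
}

#' @rdname StrainSample-class
#' @param x,object a \code{StrainSample}.
#' @param channel,strand which track to extract.
#' @export
getTrack <- function(x, channel, strand) {
  key <- paste(channel, strand, sep = ".")
  tr <- x@tracks[[key]]
  if (is.null(tr)) stop("no track ", key, " in strain ", x@strain)
  tr
}

#' @rdname StrainSample-class
#' @export
genotype <- function(x) x@genotype

#' @rdname StrainSample-class
#' @export
cdsMappedTotal <- function(x) x@cdsMappedTotal

setMethod("show", "StrainSample", function(object) {
  gt <- if (length(object@genotype)) paste(object@genotype, collapse = ",")
        else "wild-type"
  cat("StrainSample '", object@strain, "' [", gt, "]: ",
      length(object@tracks[[1]]), " nt genome, ",
      format(object@cdsMappedTotal, big.mark = ","),
      " CDS-mapped reads\n", sep = "")
})

#' Result of folding one RNA sequence
#'
#' Minimum-free-energy secondary structure of a single strand: dot-bracket
#' string, energy, and the 1-based pairing map (0 = unpaired). Nested
#' structures only.
#'
#' @slot sequence the folded RNA sequence (U alphabet).
#' @slot dotBracket balanced dot-bracket string, same length.
#' @slot mfe minimum free energy (model units, <= 0).
#' @slot pairingMap integer vector; \code{pairingMap[i]} is the partner of
#'   position i, or 0 when unpaired. Symmetric involution.
#' @export
setClass("FoldResult",
  slots = c(sequence = "character", dotBracket = "character",
            mfe = "numeric", pairingMap = "integer"))

setValidity("FoldResult", function(object) {
  n <- nchar(object@sequence)
  if (nchar(object@dotBracket) != n) return("dot-bracket length mismatch")
  if (length(object@pairingMap) != n) return("pairing map length mismatch")
  pm <- object@pairingMap
  paired <- which(pm > 0)
  if (any(pm[pm[paired]] != paired)) return("pairing map is not symmetric")
  if (object@mfe > 1e-9) return("MFE must be <= 0")
  TRUE
})

#' @rdname FoldResult-class
#' @param x,object a \code{FoldResult}.
#' @export
pairingMap <- function(x) x@pairingMap

#' @rdname FoldResult-class
#' @export
dotBracket <- function(x) x@dotBracket

#' @rdname FoldResult-class
#' @export
foldEnergy <- function(x) x@mfe

setMethod("show", "FoldResult", function(object) {
  cat("FoldResult: ", nchar(object@sequence), " nt, MFE ",
      format(object@mfe, digits = 4), "\n", sep = "")
  if (nchar(object@sequence) <= 80) {
    cat(" ", object@sequence, "\n ", object@dotBracket, "\n", sep = "")
  }
})

#' Two-component Gaussian mixture fit of log10 sensitivity scores
#'
#' Components are relabeled so mean1 < mean2; the threshold is on the linear
#' sensitivity scale and marks the smallest value at which the higher-mean
#' component contributes at least \code{responsibilityLevel} of the mixture
#' density.
#'
#' @slot weights,means,sds length-2 numeric (log10 units for means/sds).
#' @slot loglik log-likelihood at convergence.
#' @slot threshold linear-scale sensitivity threshold.
#' @slot responsibilityLevel the defining responsibility level (default 0.95).
#' @slot nUsed number of finite values fitted.
#' @slot lowConfidence TRUE when one component weight < 0.05.
#' @export
setClass("MixtureFit",
  slots = c(weights = "numeric", means = "numeric", sds = "numeric",
            loglik = "numeric", threshold = "numeric",
            responsibilityLevel = "numeric", nUsed = "integer",
            lowConfidence = "logical"))

setValidity("MixtureFit", function(object) {
  if (abs(sum(object@weights) - 1) > 1e-9) return("weights must sum to 1")
  if (object@means[1] > object@means[2]) return("means must satisfy mu1 <= mu2")
  if (any(object@sds <= 0)) return("sds must be > 0")
  TRUE
})

setMethod("show", "MixtureFit", function(object) {
  cat("MixtureFit (n = ", object@nUsed, "): w = (",
      paste(format(object@weights, digits = 3), collapse = ", "),
      "), mu = (", paste(format(object@means, digits = 4), collapse = ", "),
      "), sd = (", paste(format(object@sds, digits = 3), collapse = ", "),
      ")\n  threshold = ", format(object@threshold, digits = 6),
      " (responsibility ", object@responsibilityLevel, ")",
      if (object@lowConfidence) "  [low confidence]" else "", "\n", sep = "")
})

## transcript-orientation helpers: +1 on the plus strand, -1 on the minus
.dirStep <- function(strand) if (strand == "+") 1L else -1L

## revcomp for plain character strings (DNA alphabet)
.revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN",
         vapply(seq, function(s)
           paste(rev(strsplit(s, "")[[1]]), collapse = ""), character(1),
           USE.NAMES = FALSE))
}

## extract genomic subsequence in transcript orientation (1-based closed)
.orientedSubseq <- function(genome, start, end, strand) {
  s <- substr(genomeSequence(genome), start, end)
  if (strand == "-") s <- .revcomp(s)
  s
}
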