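## RNA folding: pluggable backend with a built-in deterministic
## stacking-energy dynamic program (compiled).

#' @useDynLib endomap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Built-in folding backend
#'
#' Deterministic nested-structure minimum-free-energy dynamic program over
#' Watson-Crick and G.U wobble pairs with per-stacked-pair energies
#' (GC -3, AU -2, GU -1), minimum hairpin loop of 3 nt, and ties broken
#' toward the 5'-most opening pair. A pair contributes its stacking energy
#' when its enclosed neighbours are also paired to each other; the outermost
#' pair of a helix contributes nothing, so an isolated pair has energy 0.
#'
#' @return a backend function \code{sequence -> list(structure, mfe, pairs)}.
#' @export
foldBackendDefault <- function() {
  function(seq) .fold_dp_cpp(seq)
}

#' ViennaRNA folding backend
#'
#' Wraps an external \code{RNAfold} executable for fidelity to
#' nearest-neighbour thermodynamics. Optional: the built-in backend is the
#' default everywhere and the only one exercised by the test suite.
#'
#' @param exe path to the RNAfold executable.
#' @return a backend function, or an error if the executable is missing.
#' @export
foldBackendVienna <- function(exe = "RNAfold") {
  if (Sys.which(exe) == "") stop("RNAfold executable not found")
  function(seq) {
    out <- system2(exe, args = c("--noPS"), input = seq, stdout = TRUE)
    line <- out[2]
    db <- sub("^([.()]+).*$", "\\1", line)
    mfe <- as.numeric(sub("^.*\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1", line))
    pairs <- integer(nchar(db))
    stack <- integer(0)
    chars <- strsplit(db, "")[[1]]
    for (i in seq_along(chars)) {
      if (chars[i] == "(") stack <- c(stack, i)
      else if (chars[i] == ")") {
        j <- stack[length(stack)]
        stack <- stack[-length(stack)]
        pairs[i] <- j; pairs[j] <- i
      }
    }
    list(structure = db, mfe = mfe, pairs = pairs)
  }
}

#' Fold an RNA sequence
#'
#' @param sequence RNA (or DNA; T is read as U) sequence, length >= 10 for
#'   meaningful structure (shorter sequences fold trivially open).
#' @param backend folding backend (default the built-in dynamic program).
#' @return a \code{\link{FoldResult}}.
#' @export
foldRegion <- function(sequence, backend = foldBackendDefault()) {
  rna <- chartr("Tt", "Uu", toupper(sequence))
  if (grepl("[^ACGU]", rna))
    stop("non-RNA characters in sequence")
  res <- backend(rna)
  new("FoldResult", sequence = rna, dotBracket = res$structure,
      mfe = as.numeric(res$mfe), pairingMap = as.integer(res$pairs))
}
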