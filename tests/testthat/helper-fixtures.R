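# Shared small fixtures built in code.

# RPM track with a known per-read scale (default 1 RPM per read)
rpmTrack <- function(values, channel = "endseq5p", strand = "+",
                     scale = 1) {
  EndTrack(channel, strand, values, units = "RPM", scale = scale)
}

# minimal strain sample: constant Rend-seq depth, explicit endseq5p values
toyStrain <- function(strain, genotype, L = 400, rendDepth = 3,
                      endseq5p = numeric(L), scale = 1) {
  mk <- function(ch, s, v) EndTrack(ch, s, v, units = "RPM", scale = scale)
  zero <- numeric(L)
  tracks <- list(
    "endseq5p.+" = mk("endseq5p", "+", endseq5p),
    "endseq5p.-" = mk("endseq5p", "-", zero),
    "endseq3p.+" = mk("endseq3p", "+", zero),
    "endseq3p.-" = mk("endseq3p", "-", zero),
    "rend5p.+" = mk("rend5p", "+", rep(rendDepth, L)),
    "rend5p.-" = mk("rend5p", "-", zero),
    "rend3p.+" = mk("rend3p", "+", rep(rendDepth, L)),
    "rend3p.-" = mk("rend3p", "-", zero))
  StrainSample(strain, genotype, tracks, 1e6 / scale)
}

# one-row site data.frame with grouped positions
toySite <- function(junction, strand = "+", positions = NULL) {
  if (is.null(positions))
    positions <- junction + if (strand == "+") 1L else -1L
  df <- data.frame(junction = junction, strand = strand,
                   fiveSignal = NA_real_, threeRatio = NA_real_,
                   localDepth = NA_real_, background = "test")
  df$positions <- list(as.integer(positions))
  df
}

# hand-built FoldResult from an explicit pairing map
foldFromPairs <- function(n, pairs, seq = NULL) {
  pm <- integer(n)
  for (p in pairs) { pm[p[1]] <- p[2]; pm[p[2]] <- p[1] }
  if (is.null(seq)) seq <- paste(rep("A", n), collapse = "")
  db <- rep(".", n)
  db[pm > 0 & pm > seq_len(n)] <- "("
  db[pm > 0 & pm < seq_len(n)] <- ")"
  new("FoldResult", sequence = seq, dotBracket = paste(db, collapse = ""),
      mfe = 0, pairingMap = pm)
}

# small scenario for fast end-to-end tests
smallScenario <- function(seed = 11L, ...) {
  syntheticScenario(seed = seed, genomeLength = 30000L, nTranscripts = 18L,
                    ...)
}
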