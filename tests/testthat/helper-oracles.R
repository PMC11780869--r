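# Independent brute-force oracles used to pin the implementations.

# winsorized mean by explicit sort-clamp-mean
oracleWinsorizedMean <- function(values, level = 0.90) {
  n <- length(values)
  k <- floor(((1 - level) / 2) * n)
  s <- sort(values)
  if (k > 0) {
    s[seq_len(k)] <- s[k + 1]
    s[(n - k + 1):n] <- s[n - k]
  }
  mean(s)
}

# exhaustive enumeration of all nested secondary structures (min hairpin
# loop 3) under the same stacking-energy definition as the folding engine:
# a pair contributes its energy iff its enclosed neighbours pair with each
# other. Practical for n <= 14.
oracleEnumMfe <- function(seq) {
  bases <- strsplit(chartr("Tt", "Uu", toupper(seq)), "")[[1]]
  n <- length(bases)
  ok <- c("AU", "UA", "GC", "CG", "GU", "UG")
  canPair <- function(i, j) paste0(bases[i], bases[j]) %in% ok
  enum <- function(i, j) {
    if (j - i < 4L) return(list(list()))
    out <- enum(i, j - 1L)
    for (k in i:(j - 4L)) {
      if (!canPair(k, j)) next
      inner <- enum(k + 1L, j - 1L)
      outer <- if (k - 1L >= i) enum(i, k - 1L) else list(list())
      for (a in outer) for (b in inner)
        out[[length(out) + 1L]] <- c(a, b, list(c(k, j)))
    }
    out
  }
  eVal <- c("GC" = -3, "CG" = -3, "AU" = -2, "UA" = -2,
            "GU" = -1, "UG" = -1)
  energy <- function(pairs) {
    if (!length(pairs)) return(0)
    pm <- integer(n)
    for (p in pairs) { pm[p[1]] <- p[2]; pm[p[2]] <- p[1] }
    e <- 0
    for (p in pairs) {
      if (p[1] + 1L < p[2] - 1L && pm[p[1] + 1L] == p[2] - 1L)
        e <- e + eVal[[paste0(bases[p[1]], bases[p[2]])]]
    }
    e
  }
  min(vapply(enum(1L, n), energy, numeric(1)))
}

# exhaustive pairwise UMI-duplicate clustering: greedy over abundance-sorted
# unique sequences per (UMI, strand, 5' position) group, counting clusters
oracleUmiClusterCount <- function(records) {
  ham <- function(a, b) {
    if (nchar(a) != nchar(b)) return(Inf)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  key <- paste(records$umi, records$strand, records$fivePrimePos)
  total <- 0L
  for (idx in split(seq_len(nrow(records)), key)) {
    tab <- table(records$readSeq[idx])
    uniq <- names(tab)[order(-as.integer(tab), names(tab))]
    reps <- character(0)
    for (s in uniq) {
      if (!any(vapply(reps, function(r) ham(s, r) <= 1, logical(1))))
        reps <- c(reps, s)
    }
    total <- total + length(reps)
  }
  total
}

# exact binomial upper-tail by direct summation
oracleBinomTail <- function(x, n, p) {
  if (x > n) return(0)
  sum(vapply(x:n, function(k) choose(n, k) * p^k * (1 - p)^(n - k),
             numeric(1)))
}

# brute-force barcode assignment: mode and second-fraction per barcode
oracleAssignBarcode <- function(variants, minReads = 3L, maxFrac = 0.25) {
  tab <- sort(table(variants), decreasing = TRUE)
  n <- length(variants)
  second <- if (length(tab) > 1) as.integer(tab[2]) / as.integer(tab[1]) else 0
  if (n < minReads) return(list(status = "low_count", variant = NA))
  if (second >= maxFrac) return(list(status = "ambiguous_discarded",
                                     variant = NA))
  list(status = "assigned", variant = names(tab)[1])
}

randomRna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}
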