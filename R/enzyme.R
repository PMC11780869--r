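## enzyme_assign module: expression-normalized knockout sensitivity scores
## and the two-Gaussian mixture threshold for enzyme attribution.

#' Expression-normalized 5'-end signal ratio at a site
#'
#' Ratio of the grouped 5'-end-sequencing signal at a cleavage site (summing
#' the positions flagged as grouped during peak calling) to the mean Rend-seq
#' signal of the same strain in a 50-nt window downstream of the junction,
#' excluding a 2-nt gap. The Rend-seq denominator uses the 3'-mapped channel
#' by default and is floored at the RPM equivalent of one read per window.
#'
#' @param site one row of a cleavage-site data.frame.
#' @param sample a \code{\link{StrainSample}} with RPM tracks.
#' @param params from \code{\link{peakParams}}.
#' @param rendChannel Rend-seq channel feeding the denominator
#'   (\code{"rend3p"} by default, configurable to \code{"rend5p"}).
#' @return list with \code{ratio}, \code{fiveSum} (grouped 5' RPM),
#'   \code{depth} (mean Rend-seq RPM in the window), and \code{usable}.
#' @export
siteSignalRatio <- function(site, sample, params = peakParams(),
                            rendChannel = "rend3p") {
  strand <- site$strand
  five <- getTrack(sample, "endseq5p", strand)
  rend <- getTrack(sample, rendChannel, strand)
  pos <- site$positions[[1]]
  if (is.null(pos)) pos <- site$junction + .dirStep(strand)
  fiveSum <- sum(trackValues(five)[pos])
  idx <- .windowPositions(site$junction, "downstream", strand,
                          params$window, params$gap, length(rend))
  if (length(idx) < params$minUsable)
    return(list(ratio = NA_real_, fiveSum = fiveSum, depth = NA_real_,
                usable = FALSE))
  depth <- mean(trackValues(rend)[idx])
  sc <- if (trackUnits(rend) == "RPM") rend@scale else 1
  ratio <- fiveSum / max(depth, sc / params$window)
  list(ratio = ratio, fiveSum = fiveSum, depth = depth, usable = TRUE)
}

#' Knockout sensitivity scores for a set of sites
#'
#' For each site, the expression-normalized 5' signal ratio in the
#' enzyme-expressing strain is divided by the same ratio in the enzyme
#' knockout to produce a sensitivity score. Sites whose local Rend-seq depth
#' in the knockout falls below the minimum (genes downregulated in that
#' condition) are marked \code{not_evaluable}. Sites with zero grouped 5'
#' counts in the knockout despite adequate expression receive an infinite
#' sensitivity and are deemed sensitive regardless of the threshold.
#'
#' Both samples must be 5'-exonuclease-deficient (\code{rnjA} ablated) so
#' that downstream cleavage products accumulate; the knockout sample must
#' additionally lack the scored enzyme and the expressing sample must not.
#'
#' @param sites cleavage-site data.frame.
#' @param exprSample enzyme-expressing \code{StrainSample}.
#' @param koSample enzyme-knockout \code{StrainSample}.
#' @param enzyme gene identifier of the knocked-out enzyme (e.g.
#'   \code{"rny"}, \code{"rnc"}, \code{"ndoA"}).
#' @param params from \code{\link{peakParams}}.
#' @param rendChannel Rend-seq denominator channel.
#' @return data.frame with one row per site: \code{junction}, \code{strand},
#'   \code{enzyme}, \code{ratioExpr}, \code{ratioKo}, \code{sensitivity},
#'   \code{call} (\code{NA}, later filled by \code{\link{assignEnzyme}},
#'   except \code{not_evaluable} which is final).
#' @export
sensitivityScores <- function(sites, exprSample, koSample, enzyme,
                              params = peakParams(),
                              rendChannel = "rend3p") {
  if (!"rnjA" %in% genotype(exprSample) || !"rnjA" %in% genotype(koSample))
    stop("both samples must be 5'-exonuclease (rnjA) deficient")
  if (!enzyme %in% genotype(koSample))
    stop("knockout sample does not lack ", enzyme)
  if (enzyme %in% genotype(exprSample))
    stop("expressing sample lacks ", enzyme)
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    site <- sites[i, , drop = FALSE]
    re <- siteSignalRatio(site, exprSample, params, rendChannel)
    rk <- siteSignalRatio(site, koSample, params, rendChannel)
    sens <- NA_real_
    call <- NA_character_
    if (!rk$usable || is.na(rk$depth) ||
        rk$depth < params$minLocalDepthRpm) {
      call <- "not_evaluable"
    } else if (rk$fiveSum == 0) {
      sens <- Inf
      call <- "sensitive"
    } else if (re$usable) {
      sens <- re$ratio / rk$ratio
    }
    data.frame(junction = site$junction, strand = site$strand,
               enzyme = enzyme, ratioExpr = re$ratio, ratioKo = rk$ratio,
               sensitivity = sens, call = call, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## log-likelihood of a two-component Gaussian mixture
.mixLoglik <- function(x, w, mu, sd) {
  sum(log(w[1] * dnorm(x, mu[1], sd[1]) + w[2] * dnorm(x, mu[2], sd[2])))
}

#' Fit a two-component Gaussian mixture to log10 sensitivities
#'
#' Maximum-likelihood EM fit on the log10 scale, with 10 seeded k-means
#' initializations (best log-likelihood kept, ties broken by the lower first
#' mean) and a standard-deviation floor of 1e-3 against degenerate
#' components. Components are relabeled so the first mean is the smaller.
#' Infinite sensitivities must be excluded before fitting (they are handled
#' separately as sensitive calls). The calling threshold at the requested
#' responsibility level is computed and stored in the fit.
#'
#' @param logSensitivities finite numeric vector of log10 sensitivity
#'   values; at least 50 required.
#' @param seed integer seed controlling the restarts.
#' @param level responsibility level defining the threshold (default 0.95).
#' @param nRestarts,maxIter,tol EM controls.
#' @return a \code{\link{MixtureFit}}.
#' @export
fitTwoGaussians <- function(logSensitivities, seed = 1L, level = 0.95,
                            nRestarts = 10L, maxIter = 1000L, tol = 1e-10) {
  x <- logSensitivities
  if (any(!is.finite(x)))
    stop("input contains non-finite values; exclude them before fitting")
  n <- length(x)
  if (n < 50L) stop("need at least 50 finite values, got ", n)
  sdFloor <- 1e-3
  best <- NULL
  for (r in seq_len(nRestarts)) {
    set.seed(seed + r - 1L)
    km <- suppressWarnings(kmeans(x, centers = 2L, nstart = 1L))
    mu <- as.numeric(km$centers)
    w <- as.numeric(table(factor(km$cluster, levels = 1:2))) / n
    sd2 <- vapply(1:2, function(k) {
      xs <- x[km$cluster == k]
      if (length(xs) > 1) sd(xs) else sd(x)
    }, numeric(1))
    sd2 <- pmax(sd2, sdFloor)
    w <- pmax(w, 1e-6); w <- w / sum(w)
    ll <- -Inf
    for (it in seq_len(maxIter)) {
      d1 <- w[1] * dnorm(x, mu[1], sd2[1])
      d2 <- w[2] * dnorm(x, mu[2], sd2[2])
      tot <- d1 + d2
      tot[tot == 0] <- .Machine$double.xmin
      g2 <- d2 / tot
      g1 <- 1 - g2
      w <- c(mean(g1), mean(g2))
      mu <- c(sum(g1 * x) / sum(g1), sum(g2 * x) / sum(g2))
      sd2 <- sqrt(c(sum(g1 * (x - mu[1])^2) / sum(g1),
                    sum(g2 * (x - mu[2])^2) / sum(g2)))
      sd2 <- pmax(sd2, sdFloor)
      llNew <- .mixLoglik(x, w, mu, sd2)
      if (!is.finite(llNew)) stop("EM failed to converge (loglik not finite)")
      if (abs(llNew - ll) < tol) { ll <- llNew; break }
      ll <- llNew
    }
    cand <- list(w = w, mu = mu, sd = sd2, ll = ll)
    if (is.null(best) || cand$ll > best$ll + 1e-12 ||
        (abs(cand$ll - best$ll) <= 1e-12 &&
         min(cand$mu) < min(best$mu))) best <- cand
  }
  ord <- order(best$mu)
  fit <- new("MixtureFit",
             weights = best$w[ord], means = best$mu[ord],
             sds = best$sd[ord], loglik = best$ll,
             threshold = NA_real_, responsibilityLevel = level,
             nUsed = n, lowConfidence = min(best$w) < 0.05)
  fit@threshold <- tryCatch(mixtureThreshold(fit, level),
                            error = function(e) NA_real_)
  # components too similar (or upper weight too small) to define the
  # responsibility threshold: flag rather than fail
  if (is.na(fit@threshold)) fit@lowConfidence <- TRUE
  fit
}

## responsibility of the higher-mean component at log10 value x
.responsibility <- function(fit, x) {
  w <- fit@weights; mu <- fit@means; s <- fit@sds
  d1 <- w[1] * dnorm(x, mu[1], s[1])
  d2 <- w[2] * dnorm(x, mu[2], s[2])
  d2 / (d1 + d2)
}

#' Mixture-defined sensitivity threshold
#'
#' The threshold is the smallest sensitivity at which the higher-mean
#' Gaussian contributes at least \code{level} of the mixture density, with
#' the condition required to hold persistently up to 6 standard deviations
#' beyond the higher mean (guarding against non-monotone responsibilities
#' when the component variances differ). Solved by a grid scan plus
#' bisection to 1e-6 on the log10 scale; returned on the linear scale.
#'
#' @param fit a \code{\link{MixtureFit}}.
#' @param level responsibility level (default 0.95).
#' @return linear-scale sensitivity threshold.
#' @export
mixtureThreshold <- function(fit, level = 0.95) {
  lo <- fit@means[1]
  hi <- fit@means[2] + 6 * fit@sds[2]
  grid <- seq(lo, hi, length.out = 4001L)
  ok <- .responsibility(fit, grid) >= level
  persist <- rev(cumprod(rev(ok))) > 0 # ok from here to the end of range
  i <- which(persist)[1]
  if (is.na(i)) stop("responsibility never reaches ", level, " in range")
  if (i == 1L) return(10^lo)
  a <- grid[i - 1L]; b <- grid[i]
  while (b - a > 1e-6) {
    m <- (a + b) / 2
    if (.responsibility(fit, m) >= level) b <- m else a <- m
  }
  10^b
}

#' Assign enzyme sensitivity calls
#'
#' Sites with a sensitivity strictly above the threshold (or infinite) are
#' called sensitive for the scored enzyme; others insensitive. Sites already
#' marked \code{not_evaluable} are left unchanged. The published threshold
#' of 10.69 (derived from the RNase Y mixture fit) is the default.
#'
#' @param records data.frame from \code{\link{sensitivityScores}}.
#' @param threshold linear-scale sensitivity threshold.
#' @return records with the \code{call} column filled; a per-call summary is
#'   attached as attribute \code{"summary"}.
#' @export
assignEnzyme <- function(records, threshold = 10.69) {
  stopifnot(threshold > 0)
  call <- records$call
  open <- which(is.na(call))
  sens <- records$sensitivity[open]
  call[open] <- ifelse(is.na(sens), "not_evaluable",
                       ifelse(sens > threshold, "sensitive", "insensitive"))
  records$call <- call
  attr(records, "summary") <- table(factor(
    call, levels = c("sensitive", "insensitive", "not_evaluable")))
  records
}
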