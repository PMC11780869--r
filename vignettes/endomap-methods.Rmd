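---
title: "Methods: mapping endoribonuclease cleavage from stabilized end-sequencing"
author: "endomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping endoribonuclease cleavage from stabilized end-sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameters, numerical choices and
limitations of `endomap`. It states no empirical result that the test
suite and `scripts/acceptance.R` do not themselves compute.

# The measurement model

Endoribonuclease cleavage of an mRNA produces an upstream fragment ending
in a 3′-hydroxyl and a downstream fragment beginning, for most enzymes,
with a 5′-monophosphate. At steady state both are degraded within moments
by exoribonucleases. The strategy the package analyzes removes those
exonucleases genetically: in an RNase J1 knockout (`rnjA`, the only known
5′→3′ exonuclease in *B. subtilis*) the downstream products accumulate and
ligation-based 5′-end sequencing maps their monophosphorylated 5′ ends; in
a knockout of all four 3′→5′ exonucleases ("4-exo") the upstream products
accumulate and 3′-end sequencing maps their hydroxylated 3′ ends. A
cleavage event between genomic positions $p$ and $p+1$ (transcript
orientation) therefore appears as a 3′ peak at $p$ in one strain abutting
a 5′ peak at $p+1$ in the other. End-enriched RNA sequencing (Rend-seq)
provides expression levels and a moiety-agnostic view of 5′ ends, which
matters for enzymes such as EndoA that leave 5′-hydroxyls invisible to
ligation-based 5′ capture.

Assumptions inherited from this design: cleavage products are stable in
the respective knockout (no redundant unknown exonucleases), knockouts do
not re-route cleavage itself, and read depth is normalized comparably
across strains (reads per million CDS-mapped reads, RPM).

# Peak-pair calling

For a position $p$ with signal $x_p$, the peak ratio is
$$ r_p = \frac{x_p}{\max(W_p,\; f)} $$
with $W_p$ the 90% winsorized mean of a 50-nt window on the background
side (downstream of $p$ for 5′ ends, upstream for 3′ ends, both in
transcript orientation) excluding a 2-nt gap on either side of $p$.

Parameters, all exposed in `peakParams()`:

| parameter | default | units | role |
|---|---|---|---|
| `window` | 50 | nt | background window width |
| `gap` | 2 | nt | excluded flank around the examined position |
| `winsorLevel` | 0.90 | — | winsorization level |
| `ratioThreshold` | 7.5 | — | peak ratio cutoff (both ends) |
| `min5pRpm` | 10 (alt. 2) | RPM | minimum 5′ signal per position |
| `minLocalDepthRpm` | 0.05 | RPM | minimum local Rend-seq density |
| `endExclusion3p` | 40 | nt | exclusion around detected RNA 3′ ends |
| `ncrnaExclusion` | 150 | nt | exclusion around rRNA/tRNA/scRNA |
| `cdsMaxDist` | 500 | nt | maximum distance from a coding region |
| `zscoreThreshold` | 8 | — | RNA 3′-end detection |

Numerical choices:

* **Winsorization tail split.** "90% winsorized" clamps
  $k=\lfloor 0.05\,n\rfloor$ values at *each* tail (2 per tail for a 50-nt
  window) — the standard symmetric reading. This is what makes the caller
  robust to a second genuine peak inside the background window, e.g. the
  partner site of an RNase III duplex ~25 nt away.
* **Denominator floor.** Empty windows would give infinite ratios; the
  denominator is floored at the RPM equivalent of one read spread over the
  window (`scale / window`, where `scale` is the RPM value of a single
  read). A documented constant, not fitted.
* **Threshold order.** The `min5pRpm` cutoff applies per position *before*
  grouping; adjacent qualifying positions (≤ 1-nt gap) are then grouped,
  their signal summed, and the junction assigned one nucleotide upstream
  (transcript orientation) of the 5′-most grouped position.
* **z-score ends.** RNA 3′ ends are positions where
  $(x_p-\bar x)/s > 8$ over the combined 50-nt windows both sides (2-nt
  gaps excluded), with sample standard deviation. $s=0$ maps to $z=+\infty$
  when $x_p>\bar x$ and $0$ otherwise, so spikes on exactly flat synthetic
  background are still detected.
* **Genome edges.** Windows truncate at genome boundaries; a ratio or
  z-score is only defined with at least 10 usable window positions
  (`minUsable`). The genome is treated as linear.
* **Coordinates.** 1-based, closed — the native R/Bioconductor convention
  (GRanges, Biostrings). The junction coordinate is the position of the
  nucleotide 5′ of the cleaved bond; on the minus strand the paired 5′
  peak lies at `junction - 1`.

# Knockout sensitivity and the mixture threshold

The expression-normalized site ratio divides the grouped 5′ signal by the
mean 3′-mapped Rend-seq density in a 50-nt downstream window (2-nt gap),
floored as above. The 3′-mapped channel is the default denominator
(configurable to 5′-mapped); the choice follows the normalization stated
in the source data presentations. Sensitivity is the expressing-strain
ratio over the knockout ratio; a knockout ratio built on zero 5′ counts
with local depth ≥ 0.05 RPM yields $+\infty$ (called sensitive); local
depth < 0.05 RPM yields `not_evaluable`.

Log₁₀ sensitivities (base 10 chosen for readability; the linear-scale
threshold is base-invariant) are fitted by maximum-likelihood EM with two
Gaussian components, 10 seeded k-means initializations, best
log-likelihood kept (ties to the lower first mean), and a standard
deviation floor of $10^{-3}$. ML was chosen over least squares to a
histogram — both give similar thresholds for well-separated modes, and ML
needs no binning choice. Infinite values are excluded from the fit and
handled at the calling stage.

The calling threshold is the smallest $x$ at which the higher-mean
component's responsibility
$w_2\phi_2(x) / (w_1\phi_1(x)+w_2\phi_2(x))$ reaches 0.95 *and keeps*
holding up to $\mu_2+6\sigma_2$ — the persistence clause guards against
non-monotone responsibilities when $\sigma_2>\sigma_1$. Solved by a
4001-point grid scan plus bisection to $10^{-6}$ on the log scale. For
near-coincident components the level may never be reached; the fit is
then returned with an `NA` threshold and a low-confidence flag instead of
an error, so degenerate inputs remain inspectable. With equal weights and
variances the threshold has the closed form
$x^\ast = \tfrac{\mu_1+\mu_2}{2} + \sigma^2\ln 19/(\mu_2-\mu_1)$, which
the tests pin.

A note on attainable accuracy: mixture parameters are only weakly
identifiable when the component separation approaches $2\sigma$; at
sample size ~1500 both this EM and an independent implementation (mclust)
show mean errors of ~0.15 there. The parameter-recovery tests therefore
run at separations of $3\sigma$ and above.

# RNA folding and RNase III duplex geometry

The built-in folding backend is a deterministic dynamic program over
nested structures with Watson–Crick and G·U pairs, minimum hairpin loop
of 3 nt, and a stacking-only energy model: a pair $(i,j)$ contributes
$-3$ (G-C), $-2$ (A-U) or $-1$ (G·U) exactly when its enclosed neighbours
$(i+1,j-1)$ are also paired to each other; the outermost pair of a helix
contributes nothing, so isolated pairs are energetically neutral.
Traceback ties break toward the 5′-most opening pair. The backend is
pluggable (`foldBackendVienna()` wraps an external RNAfold for
nearest-neighbour fidelity), but all tests run on the built-in model,
which is verified against exhaustive enumeration of all nested structures
for sequences up to 14 nt. One property worth recording: this model is
symmetric under sequence *reversal* (pair classes map G·U↔U·G, A-U↔U-A),
but not under reverse *complement* — the complement of a G·U pair is the
unpairable A·C. Tiled genome folding (40-mers, energy assigned to the
20th nucleotide) is implemented in C++; the center convention is pinned
by a worked test.

Duplex analysis pairs same-strand sites within 1 kb, folds the
intervening sequence ± 50 nt (clipped at genome edges), and computes:

* **Structural distance** (overhang): with cuts at offsets $c_1<c_2$ in
  the folded sequence, forward $= c_2 - \mathrm{partner}(c_1+1)$ and
  reverse $= c_1 - \mathrm{partner}(c_2+1)$; an unpaired anchor steps up
  to 2 nt inward with the step count subtracted. Both directions must
  agree when computable; disagreement (typically an asymmetric bulge at
  the cut) returns `NA` with a diagnostic — such ambiguous-register cases
  are excluded from motif building.
* **Duplex length**: base pairs of the maximal helix containing the
  cleavage-adjacent pair, extended across interruptions of ≤ 2 unpaired
  bases on either strand. This formalizes what was a manual determination
  in the source analysis and may differ on pathological folds.
* **Base-pair motif**: for pairs retained at the canonical +2 overhang,
  positions on the upstream arm are indexed relative to the cut (−1
  immediately 5′ of it, no position 0) and per-position pair-class
  frequencies (A-U, U-A, G-C, C-G, U-G, G-U) and paired fractions are
  tabulated; bulged bases appear as unpaired positions rather than being
  skipped. Frequencies summing to the paired fraction at every position
  is asserted in every run.

# Sequence and structure context

The structure profile extracts tiled-MFE values in 150-nt windows around
junctions (sites within 75 nt of a wild-type-detected RNA end excluded,
since transcript boundaries carry their own structure signal). The
background band resamples, 100 times, an equal number of coding-strand
G|A-dinucleotide positions inside CDS (the most enriched junction
dinucleotide), excluding called sites — sampling without replacement
within an iteration, independent across iterations, fully seeded — and
reports the 25th/75th percentile band of the per-offset means.

Motif statistics use 30-nt windows with the junction nucleotide at
position 15 (the cleaved bond between 15 and 16). Information content
uses the uniform-background convention $IC_j = 2 + \sum_b f_{bj}\log_2
f_{bj}$ (bits). k-mer enrichment ($k \le 4$) tests each observed
(k-mer, position) against background k-mer frequencies estimated from
coding-region windows sampled every 100 nt after the start codon, with
pseudocount 0.01, by a one-sided binomial tail; Bonferroni correction
uses the full universe $\sum_k (31-k)4^k$ of possible tests. These are
standard, testable statistics; they are not expected to reproduce the
exact p-values of specialized logo software, whose test and
multiple-testing universe differ.

# EndoA metagenes and 5′ trimming

Motif sites (`UACAU`, cleaved at the first U|A; overlapping matches on
both strands) are stratified by the following nucleotide(s). Metagene
windows anchor at the first nucleotide of the downstream product
(junction + 1); offsets are in transcript orientation. Normalization
modes: `edge8` divides by the mean of the 8 window positions distal to
the mapped end (first 8 for 3′-mapped channels, last 8 for 5′-mapped, in
transcript window order — pinned by a fixture); `max20` divides by the
maximum over the central 20 nt. Coverage filters are in raw reads: mean
≥ 1 read/position (mean, not minimum, where the rule was ambiguous),
evaluated on a separate Rend-seq coverage track when profiling sparse
monophosphate signal, and ≥ 10 reads in the `edge8` normalization window.
Profiles are 90%-winsorized means and standard deviations across retained
instances.

Trimming detection reports positive offsets whose winsorized mean exceeds
3× the median of the positive-offset baseline *and* 25% of the
positive-offset maximum. Both constants are this package's own detector
design — the source analysis read these peaks from plots — and both are
configurable; the second condition exists because with few retained
instances the baseline median is near zero and the ratio rule alone would
register stray single reads.

# MPRA quantification

Barcode→variant mapping discards reads with any mismatch in the declared
constant region, requires ≥ 3 valid reads per barcode, and discards
barcodes whose second-most frequent variant reaches 25% of the top (the
boundary is inclusive: exactly 25% discards). Counting deduplicates on
(barcode, UMI). Effects: per-barcode RNA:gDNA unique-read ratio, barcodes
grouped by their full mutation set relative to the declared wild type
(labels `ref[±offset]alt` relative to the junction, no offset 0),
summarized by the median (mean available), normalized by the median
wild-type barcode — so the wild type is exactly 1 by construction. The
gDNA threshold (10 unique reads) quantifies an unquantified "thresholded
based on read count" step and is configurable. Double-mutant averages
include only variants whose additional mutations individually stay within
10% of neutral (constant exposed). The hairpin-stability table folds the
declared junction-relative hairpin region per mutation and reports the
Spearman correlation with effects.

# The synthetic generator

`simulateScenario()` emulates the statistical structure the analysis
assumes, not library chemistry. Defaults define the study conditions: a
100-kb genome, up to 60 non-overlapping transcripts (0.9–2.2 kb) with
log-normal expression (meanlog 0, sdlog 0.8), uniform Poisson coverage at
0.5 expected Rend-seq reads per covered nt per unit expression, spurious
end-sequencing background at 2% of coverage, transcript-boundary end
peaks at 200 expected reads per unit expression, and planted sites of
80–300 expected peak reads: 20 RNase Y sites (G|A junction in AU-rich
flanks), 5 RNase III perfect inverted repeats (20-bp stem, 6-nt loop)
cleaved at the register leaving 2-nt 3′ overhangs, and 12 EndoA `UACAUA`
sites (5′-hydroxyl; monophosphorylated trimmed ends at +2, plus +4 for
most downstream bases, at 40% of site strength each). Fragments shorter
than 35 nt contribute no end signal. Strain tracks follow the causal
model exactly: 3′ peaks only under 4-exo, 5′ peaks only under `rnjA`,
nothing from knocked-out enzymes, hydroxylated ends never in
monophosphate channels (asserted in tests).

What it does **not** model: positional fragmentation bias, ligation
preferences, rRNA depletion artifacts, contaminant genomes, partial
knockdowns, or co-transcriptional effects — so passing tests demonstrate
the *logic* of the pipeline under its stated assumptions, not robustness
to those real-data complications.

A depth interaction worth knowing: the published 10-RPM threshold
presumes realistic library depth. The default scenario produces a
per-read RPM scale of ~6, so single spurious background reads stay below
threshold, as in real libraries. Shrinking the genome (hence read total)
raises the per-read scale above 10 RPM and single-read noise begins to
qualify, occasionally shifting grouped peak anchors. End-to-end recovery
is therefore validated at the default scenario size.

# Problem sizes and runtimes

The test suite (~590 assertions) runs in about half a minute on one CPU:
enumeration oracles fold sequences ≤ 14 nt; tiled folding runs on 25–30-kb
genomes; end-to-end recovery simulates four 100-kb strains; the MPRA
recovery uses 50 barcodes per variant at 100 reads per barcode. The
acceptance script recomputes its three quantities in under a minute, all
randomness derived from `--seed`.

# Known limitations

* The folding model is a teaching-grade stacking approximation; absolute
  energies are not thermodynamic. Duplex geometry (overhang, duplex
  length) depends only on the pairing pattern of strong planted stems and
  is robust to this; borderline natural duplexes may fold differently
  under nearest-neighbour rules (plug in `foldBackendVienna()`).
* The duplex-length rule is an automated formalization of a manual call.
* Multi-enzyme joint attribution is out of scope: each knockout is scored
  independently.
* Trans (intermolecular) duplexes and pseudoknots are not searched.
* The generator's uniform-coverage model understates background variance
  relative to real fragmentation; thresholds that pass here can need
  recalibration on real libraries with strong positional bias.
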