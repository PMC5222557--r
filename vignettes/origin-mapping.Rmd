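---
title: "Mapping replication origins from Okazaki fragment strand bias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping replication origins from Okazaki fragment strand bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(okseqr)
```

## The measurement

During S phase each replication origin that fires sends two forks in
opposite directions. Okazaki fragments are synthesized on the lagging
strand, so a fragment's genomic strand records the direction of the fork
that made it: Watson (forward, "+") fragments come from leftward-moving
forks, Crick ("-") fragments from rightward-moving forks. In a population
of cells, the fraction of Watson-strand fragments at a locus,

$$f_W(x) = \frac{W(x)}{W(x) + C(x)},$$

is the probability that the locus is replicated by a leftward fork, i.e.
that the nearest *fired* origin lies to its right. An origin therefore
appears as a sharp transition from Watson-dominated to Crick-dominated
signal, and the height of that transition measures how often the origin
fires.

## The calling pipeline

`map_origins()` runs the standard OK-seq chain:

1. **Binning** (`bin_fragments()`): each fragment's 5' end (strand-aware:
   `start` for Watson, `end - 1` for Crick) increments one 100 bp bin on
   its strand. The 5' end marks where each Okazaki fragment was initiated;
   whether the original analyses counted whole fragments per bin or one
   endpoint each is not documented anywhere we know of, so the choice is
   recorded in the track metadata.
2. **Smoothing** (`smooth_track()`): a centered 1.5 kb rolling *median*
   per strand. Medians suppress isolated high-count bins (ligation
   artifacts, mapping pile-ups) that a mean would smear. Edge bins use the
   truncated window; zero-coverage bins are masked and never contribute.
3. **Normalization** (`normalize_track()`): per-bin strand fractions
   $f_W$, $f_C$ with $f_W + f_C = 1$; empty bins stay masked rather than
   being read as $f_W = 0$, which would fabricate Crick signal in gaps.
4. **Transition metric** (`origin_transition_metric()`): for every bin,
   the aggregate Watson fraction of the 12 kb immediately to its left
   minus the same for the 12 kb to its right. The metric lives in
   $[-1, 1]$, peaks at origins, and is antisymmetric under swapping the
   strand labels.
5. **Calling** (`call_origins()`): local maxima above 0.1, maxima closer
   than 12 kb merged keeping the larger (ties keep the leftmost —
   determinism over elegance). The threshold and merge distance are
   package defaults, exposed in `run_config()`; at desk-scale coverage
   the metric's noise floor is ~0.02, so 0.1 is a conservative ~5x
   margin.

## Efficiency: why the default is a transition amplitude

The classical operationalization of origin efficiency is "the maximum
normalized strand fraction within 20 kb of the origin". We implement it
(`annotate_efficiency(mode = "max_strand_aware")`, with a strand-blind
variant) but it is not the default, for a reason worth spelling out.

The per-bin fraction $f_W$ estimates a probability with only the handful
of reads in one bin (about 10 at desk coverage). The maximum of two
hundred such noisy ratios is badly upward-biased, and whenever the
minority strand's rolling median is zero anywhere in the window — common
at realistic coverage — the max saturates at exactly 1. Worse, the bias
is structural, not just statistical: when origins sit closer together
than the 20 kb search radius, the window contains the flanks of
*neighboring* origins, and the max reports the strongest origin in the
neighborhood. On simulated data with known firing probabilities the max
estimator's rank correlation with truth plateaus well below 0.5 even
with unlimited coverage.

The default (`mode = "amplitude"`) instead measures the height of the
Watson-to-Crick transition at the call:

$$\hat e = \tfrac12\left(F_W^{\text{left}} + F_C^{\text{right}}\right)
         = \tfrac12 + \tfrac12\left(F_W^{\text{left}} - F_W^{\text{right}}\right),$$

where $F$ are aggregate fractions of the raw counts over 4 kb flanks
adjacent to the midpoint. Crossing a fired origin flips the local fork
direction, so the expectation of this amplitude is exactly the
probability that the origin fires in a cycle (conditional on its
chromosome replicating at all), independent of the neighborhood. It
stays on the same 0-1 "normalized reads" scale, and a strand-balanced
track still yields exactly 0.5. The 4 kb flank width balances
statistical noise (about 400 reads per flank at desk coverage) against
contamination from origins closer than the flank; 2-8 kb flanks behave
similarly, with 4 kb the best compromise in our recovery experiments.

Transition zones (`annotate_transition_zone()`) are the distance between
the flanking Watson and Crick maxima within 25 kb. The argmaxes are
located on 1.5 kb window-aggregated fractions for the same sparse-count
reason: a single lucky bin should not pin the initiation-zone boundary.
Ties are resolved toward the midpoint, so a point-source origin has a
near-zero zone. With broad initiation zones the flanking plateaus
flatten and the located maxima carry an offset set by the noise, so
absolute zone widths at low coverage overstate narrow zones; the
*ordering* across origins (what the ranked heatmap
`origin_strand_heatmap()` displays) is what the estimator preserves, and
what the tests assert (mean zone width is non-decreasing in the
simulated initiation-zone jitter over 0-10 kb).

## The simulator and what it does (not) emulate

`simulate_genome_model()` / `simulate_fragments()` provide ground truth
for every stage. Per cell, each origin fires independently with its
firing probability; chromosomes with no firing are redrawn (every
chromosome replicates every cycle — this conditions low-efficiency
origins slightly upward, and the closed-form oracle
`expected_watson_fraction()` reproduces exactly that conditioning by
renormalizing away the all-unfired event). Fork direction at a position
follows from the nearest fired origin, with exact ties split uniformly —
the oracle's half-weight. Fragment 5' anchors are uniform over the
genome; lengths follow a three-component mixture at 1-3 times a 172 bp
nucleosome repeat with 12 bp Gaussian jitter, bounded to 100-600 bp,
emulating the periodic Okazaki ladder without modeling gel physics.

The default desk-scale conditions are 2 chromosomes x 5 Mb, 125 origins
per chromosome (about 40 kb mean spacing), beta(2,2) firing
probabilities (median 0.5, matching the ~50% median efficiency regime of
worm embryo maps), 2000 cells x 500 fragments — one million fragments,
generated and analyzed in a few seconds. Companion generators emit
enhancer-mark ChIP peaks whose fold-enrichment rises linearly with
firing probability plus Gaussian noise (`simulate_chip_peaks()`), and a
50-time-point embryonic expression matrix (`simulate_timecourse()`) with
maternal transcripts decaying over the first five time points,
early-zygotic genes placed within 25 kb of (preferentially efficient)
origins and expressed mid-course, and late-zygotic genes at least 15 kb
from any origin expressed from time point 40 on, with a configurable
co-directional strand bias inside the coupling window.

Deliberately absent: replication timing structure, fork stalling or
variable fork speed, sequence-level reads, GC/mappability artifacts, and
any dependence between origin firing and chromatin state beyond the
built-in intensity scaling. Passing recovery tests on this generator
shows the estimators are consistent under the stated stochastic model —
not that real data meet that model.

## Downstream statistics

* **Peak association**: peaks are filtered at strictly >5-fold
  enrichment, distances measured to 5 kb origin windows (overlap =
  distance 0), and the distance x intensity association grid accumulates
  peaks by maximum distance. The placement p-value is analytic: the
  probability that a uniformly placed interval of the same length on the
  same chromosome lands at least as close to an origin window, computed
  as an interval-union measure (a simplified, dependency-free form of
  interval-association testing; verified against Monte-Carlo placement).
* **Gene context**: orientation bias profiles count "+"/"-" genes in
  2.5 kb signed-distance bins around origins (log2 ratios only where
  both strands are observed); positional gene-set enrichment uses exact
  hypergeometric tails (upper for enrichment, lower for depletion,
  signed), with Benjamini-Hochberg adjustment across the full set x bin
  grid — raw p-values are also reported since classical GO-style figures
  show them unadjusted. The gene anchor defaults to the midpoint (start
  and strand-aware 5' end available) — nothing in the source analyses
  pins this, so it is a flag, not a constant.
* **Time-course coupling**: rows are normalized to sum to one across the
  50 time points; all-zero genes are flagged unexpressed. The
  maternal/zygotic split clusters normalized profiles with k-means
  (k = 6) whose initial centers are mean profiles of argmax-time
  quantile groups, making the result deterministic and invariant to gene
  order; a cluster is maternal when its centroid holds more mass in time
  points 1-5 than in any other 5-point window. A per-gene `argmax <= 5`
  rule is available (`rule = "argmax"`) for audits. The coupling heatmap
  sums normalized zygotic expression in signed-distance bins around the
  top-1000 origins by efficiency (genes in two origins' flanks count in
  both; a nearest-origin dedupe flag exists), and the scalar coupling
  statistic is the per-time-point log2 ratio of mean proximal (±5 kb) to
  mean distal (15-25 kb) abundance with a pseudo-count of 1e-6 of total
  heatmap mass guarding empty zones.

## Numerical conventions and degenerate inputs

All coordinates are 0-based half-open, matching BED and bedGraph. Window
lengths are coerced to odd multiples of the bin size (with a message).
Equal-score call maxima keep the leftmost; argmax ties inside efficiency
and transition-zone windows resolve toward the midpoint. Zero-coverage
bins are masked (NA) rather than zero-filled everywhere a ratio is
taken. Degenerate cases return flagged values rather than errors: empty
origin sets write header-only BED files, single-origin chromosomes yield
empty spacing samples, constant heatmap rows become zero vectors and are
flagged, and negative transition zones are kept but flagged and excluded
from ranked displays.

## Problem sizes used in the tests

The test-suite and acceptance analyses run the default desk-scale model
above (1e6 fragments), a 2 Mb 20-origin model for the initiation-zone
jitter series (4 runs x 6e5 fragments), 5000 single-cell simulations for
the strand-bias oracle check, and 1e4-draw Monte-Carlo placements for
the p-value check. These sizes keep each property's sampling error well
inside the asserted tolerances while the whole suite completes in under
a minute.

## Known limitations

Efficiency estimates are conditional on chromosome replication, so on
chromosomes with few, weak origins they run slightly above the raw
firing probability. Transition-zone widths at desk coverage carry a
noise floor of a few kb and should be read comparatively. The placement
null for peak association assumes uniform placement on the same
chromosome — no GC, mappability or chromatin-accessibility matching.
The maternal/zygotic split is a two-class summary of a continuum; genes
with bimodal profiles follow their dominant mode.
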