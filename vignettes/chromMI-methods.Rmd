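---
title: "Detecting classification-informative chromatin-state windows with chromMI"
author: "chromMI maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting classification-informative chromatin-state windows with chromMI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromMI)
```

## The problem

Consortium-scale epigenomics (e.g. the Roadmap Epigenomics collection of
127 consolidated epigenomes) summarizes each sample's chromatin as a
genome-wide segmentation into discrete chromatin states — ChromHMM
"mnemonics" such as `TssA`, `Tx`, `Enh`, `Het`, `Quies` — at 200 bp
resolution. When the samples can be classified into biologically
meaningful groups (brain vs. other tissues, cancer vs. normal, fetal
vs. adult), genomic regions whose chromatin state *co-varies with the
classification* are candidates for involvement in the classified
phenomenon: a window that is actively transcribed in every brain sample
but heterochromatic elsewhere is a strong lead even when it contains no
annotated gene.

chromMI scans a genome of chromatin-state tracks for exactly such
windows. It is a supervised method: the user supplies the grouping, and
the scan scores every window against it.

## The statistic

For each window, each sample's segmentation is collapsed to a single
state: the state with the highest frequency among the window's
segments, required to reach at least 80% (`min_fraction`); otherwise the
sample's window state is *undefined*. This yields the window's profile
vector $S_i$ (one state per sample) which is compared with the group
vector $G$ through their mutual information

$$MI(G:S_i) = \sum_{k=1}^{n}\sum_{l=1}^{m} P(G_k, S_{il})\,
\log_2 \frac{P(G_k, S_{il})}{P(G_k)\,P(S_{il})},$$

in bits, where the sums run over the $n$ groups and the $m$ states.
Undefined samples are removed *before* any frequency is computed, so the
group marginal $P(G_k)$ is window-specific; zero-probability terms are
skipped. MI is 0 when the profile is constant or the retained sample set
is degenerate (fewer than two samples, or one group), and is bounded by
$\min(H(G), \log_2 m)$. A perfectly separating profile attains $H(G)$:
for two groups of 5 and 6 samples this is 0.994 bits, which is why 0.994
is the highest score a two-group scan of an 11-sample (or 5-vs-6
effective) dataset can report.

Significance comes from a composition-preserving permutation null: the
full profile vector — undefined entries included — is shuffled against
the fixed classification (10,000 times by default), each shuffle's MI is
recomputed with the same undefined-exclusion rule, and the empirical
p-value is the fraction of shuffles with MI greater than or equal to the
observed value. Under this convention `p_raw` can be exactly 0. The
alternative $(r+1)/(n+1)$ estimator is available via
`mi_params(p_add_one = TRUE)`. P-values are adjusted genome-wide across
*all* scanned windows with the Benjamini–Hochberg step-up FDR (windows
where every sample is undefined are kept in the family with MI 0 and
p 1, flagged in the output, so the family size is stable). The default
significance filter keeps windows with MI ≥ 0.3 and adjusted p ≤ 1e-4.

### A statistical subtlety worth knowing

Because tied shuffles count towards the p-value, a window whose profile
separates two groups of sizes $a$ and $b$ perfectly still has exact
permutation p-value $\ge \binom{a+b}{a}^{-1}$ (twice that for $a=b$): the
shuffle can reproduce the perfect alignment by chance. With 10-vs-10
groups this is $2/184756 \approx 1.1\times10^{-5}$, so roughly one in ten
such windows will draw a tying shuffle among 10,000 permutations and
receive `p_raw` = 1e-4 instead of 0 — usually enough, after BH
adjustment, to miss a 1e-4 FDR cut-off. Detection of even *perfect*
windows at very strict FDR thresholds is therefore probabilistic, with
per-window success probability $\exp(-n_{perm} p_{exact})$, and small
sample sets (e.g. 6-vs-6, exact p $\approx 2.2\times10^{-3}$) cannot
clear such thresholds at all. This is a property of tie-inclusive
permutation tests, not an implementation artifact; it should guide the
choice of `fdr_threshold` relative to the group sizes at hand.

## Windowing choices

* Windows are enumerated per chromosome from 0 in steps of `step`
  (default: non-overlapping windows of `window_length` = 5000 bp);
  trailing fragments shorter than a full window are dropped so every
  window has the same denominator.
* The majority is computed by bp of overlap rather than by counting
  segments; the two coincide on the aligned 200 bp grid of ChromHMM
  output, and the bp rule extends cleanly to arbitrary segmentations.
* If the top two states tie in coverage, the sample's window is
  undefined (a tie cannot reach 80% anyway unless `min_fraction` ≤ 0.5).
* Assembly gaps: when less than `min_fraction` of the window's length is
  covered at all, the window is undefined for that sample; otherwise
  uncovered bp are excluded from the frequency denominator. The
  treatment of gaps is a deliberate package choice; alternatives (e.g.
  counting gaps as a pseudo-state) would only make windows *more*
  conservative.

## Reproducibility

All randomness flows from one master seed. Each window's permutation
stream is seeded deterministically from (seed, chromosome, window
start), so results are identical regardless of window iteration order,
chromosome order, or any future parallelization. The permutation loop is
implemented in C++ but draws from R's own RNG, so `set.seed()` semantics
are preserved end-to-end. The downsampling experiment derives one seed
per (fraction, replicate) pair the same way.

## State vocabularies and reductions

The 15 Roadmap mnemonics are bundled (`roadmap15_vocabulary()`), and
scans are typically run after reducing them to 5 functional classes
(TSS, transcription, enhancer, bivalent, heterochromatin) or 2 (active
vs. inactive). The bundled 15→5 and 15→2 maps
(`roadmap_reduction(5)`, `roadmap_reduction(2)`) are editable text files
under `inst/extdata/`; they are *documented approximations* of
groupings commonly used for the Roadmap model, and users with a
preferred grouping should supply their own two-column map via
`load_reduction()`. The reserved label for "no dominant state" is
spelled `undefined` by default and is configurable; it is never a member
of a vocabulary.

## Pattern summaries

Each significant window's change pattern is the tuple of per-group
majority states (computed over defined samples only; a tie or an
all-undefined group yields `undefined`). The pattern distribution
divides pattern counts by the number of windows whose pattern is fully
defined, so proportions always sum to 1 over that denominator. Ties are
never broken arbitrarily — determinism is preferred over completeness.

## Gene retrieval and enrichment

Genes are read from GFF3/GTF (rows of type `gene`; 1-based coordinates
converted to the package's 0-based half-open convention) or BED. A gene
is retrieved when it intersects a significant window by at least 1 bp,
strand-agnostic; per-gene window counts expose the "concentration" of
informative windows along long genes. Enrichment of a study gene set
against the whole annotation uses the one-sided (over-representation)
Fisher exact test — computed as the hypergeometric upper tail — per
term, with BH adjustment within each GO namespace; this mirrors the
classic independent-per-term algorithm, without elim/weight-style
decorrelation. A minimal OBO parser (`is_a` edges) and
`propagate_terms()` provide the ancestor closure when only direct
annotations are available; `min_term_size` (default 1, i.e. no filter)
is available because very small terms yield unstable p-values.

## Downsampling evaluation

`downsample_performance()` repeats the full scan→genes→enrichment
pipeline after removing 20–80% of the epigenomes uniformly at random
(5 replicates per fraction by default). Performance is the mean of
$-\log_{10} p$ over "positive" terms — those whose name contains one of
the user's keywords ("brain", "neuron", ...) — with the best single
term also reported. Aggregating several positive terms into one number
is not uniquely defined; the mean was chosen, and the per-term maximum
is reported alongside so either view is available. A replicate
that loses an entire group (possible at high removal fractions, since
removal is deliberately *not* stratified by group) or whose tested terms
contain no positive term is recorded as `NA` and excluded from the
per-fraction mean, matching the behavior where extreme removal leaves no
result at all.

## The synthetic-data generator

`synthetic_spec()`/`simulate_tracks()` build toy multi-sample datasets
with known truth: background segments drawn i.i.d. from a configurable
state distribution (uniform over the vocabulary by default), and planted
windows in which each sample of group $g$ receives the group's target
state with probability equal to the window's association strength (1.0 =
perfect alignment), a random other state otherwise, or — with
probability `undefined_rate` — an alternating 50/50 two-state fill that
is guaranteed to fail the 80% rule. `simulate_annotation()` adds genes
spanning the planted windows, background genes on free grid cells, one
"positive" term containing exactly the planted genes, and random
background terms, so the annotation and evaluation modules can run
end-to-end with no external data.

What the generator does *not* emulate: the strong spatial
autocorrelation of real chromatin-state tracks (real segments form long
runs, not i.i.d. draws), realistic state frequencies (Quies dominates
real genomes), assembly gaps, or correlated samples (replicates,
related tissues). Passing tests on synthetic data therefore demonstrate
the correctness of the statistics and the plumbing — not that the
default thresholds are well-calibrated for real epigenomes, where
neighboring windows are dependent and the effective number of tests is
smaller than the window count.

## Problem sizes used in the test-suite

The bundled tests exercise the scan on toy genomes of one to two
chromosomes of 0.04–2 Mb at 200 bp segment resolution with 4–20
samples, 200–10,000 permutations per window, and full-enumeration
oracles up to 7 samples (5040 arrangements). These sizes were chosen so
each property is measured at the smallest scale where it is
statistically resolvable; the package itself streams windows and has no
scale-dependent logic, and the genome-scale entry point is the same
`scan_windows()` call on larger layouts.

## Known limitations

* Analytical MI significance (χ²-style approximations) is deliberately
  not offered; only the permutation null.
* BH is applied genome-wide in one family; per-chromosome adjustment is
  not implemented.
* Permutations are drawn independently per window; sharing one
  permutation set across windows would correlate decisions and is not
  supported.
* The 15→5/15→2 reduction defaults are approximations (see above).
* topGO-style elim/weight decorrelated enrichment is out of scope.
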