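---
title: "Correlation-network hub analysis for small multi-omics designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlation-network hub analysis for small multi-omics designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hubnet)
```

## Scope and model

`hubnet` asks one question of a multi-omics dataset: *is a designated focal
feature a hub of the abundance correlation network?* The intended regime is
a small, group-structured design — the package's defaults mirror a
15-sample tomato experiment (wild type and a variegated chloroplast mutant;
green leaf, white leaf and stem; three replicates; five genotype-by-tissue
groups in total) profiled for transcripts, proteins and three metabolite
classes.

The network model is deliberately plain: vertices are features from any
omics layer, and an undirected edge joins two features when the absolute
Spearman correlation of their abundances across the common samples reaches
a threshold. Edge weight is `|rho|`; the sign is retained as an attribute
but never enters distances. There is no soft thresholding, no partial
correlation, no layer-specific normalisation of edge weights — with 15
samples a rank correlation is about as much structure as the data can
support, and rank correlations are invariant to any monotone per-feature
transform, which makes the pipeline insensitive to whether abundances come
in counts, intensities or ratios.

## Why exactness matters at n = 15

For tie-free data with 15 samples every Spearman value lies on the lattice
`1 - 6 d2 / 3360` with `d2` an even integer: the spacing is 1/560. A
published neighbor table quotes values such as 0.975 and 0.953571429, and
those are exactly lattice points (`d2` = 14 and 26). One published neighbor
value, 0.967432647, is *off* the lattice — the signature of tied values
(a protein with tied intensities, e.g. from shared imputation). The
correlation engine therefore computes Pearson correlation of average
fractional ranks from first principles rather than the tie-free closed
form, so that on-lattice values are reproduced bit-for-bit on clean data
and off-lattice values arise exactly when ties are present, as in the
published table. `generate_rank_pair()` constructs permutation pairs with a
requested `d2` (a complete depth-first search with rearrangement-inequality
bounds and parity pruning; infeasible targets are reported as such), which
gives the test suite exact, hand-checkable oracle inputs.

## Blocked all-pairs computation

The study-scale problem ("all pairwise combinations" of tens of thousands
of features, over 9·10⁸ pairs) does not fit an F×F matrix in memory. Each
feature row is rank-transformed once (average ranks for ties), centred and
scaled to unit sum of squares; the correlation of any two features is then
an inner product, and `all_pairs_correlations()` walks block pairs of the
standardized rank matrix, keeping memory at `O(block_size × (n_samples +
block_size))`. The prefilter retains pairs with `|rho| >= 0.75` (inclusive:
the convention is that values *below* the threshold are discarded).
Zero-variance features carry no rank information and are skipped, with a
count; emitting NaN edges would poison the downstream graph. Emission order
is by block and then canonical pair order — consumers must treat the edge
stream as unordered. The test suite proves blocked output equal to a naive
per-pair oracle for every block size, including the degenerate
`block_size = 1`.

## Graph, centralities and distance convention

`build_graph()` keeps `|rho| >= 0.95` by default (the stricter of the two
published thresholds); vertices are features incident to at least one
surviving edge. Degree is the unweighted neighbor count — the published
"degree of 29" for the focal transcript is a neighbor count, so a weighted
degree would not reproduce it. For closeness and betweenness a distance per
edge is needed, and correlation weights admit two readings. The default,
`d(e) = 1/weight`, treats a strong correlation as a short distance, which
matches the visual convention of laying out such networks by inverse edge
weight; `raw_weight` (`d(e) = weight`) is also implemented since the
published methods never state the metric convention, and the choice is
recorded in the metrics table's metadata. Degree, the one number printed in
the source study, is identical under both. Closeness of `v` is
`(number of vertices reachable from v) / (sum of distances to them)` with 0
for isolated vertices, and betweenness uses the undirected convention
(each unordered pair counted once); both are checked against exhaustive
path enumeration on small random graphs.

Centralities and the hub test run on the full thresholded graph by default
(`component = "full"`): the published comparison is against "the overall
network", while the largest connected component is what one draws. Both are
available, and `largest_component()` breaks size ties deterministically by
the lexicographically smallest member id.

## The hub test

Whether the focal centrality is unusual is judged by a one-sample Wilcoxon
signed-rank test of all *non-focal* node values against the focal value
(the focal node itself is excluded — including it would add a guaranteed
zero difference and only blunt the test). Zero differences are dropped and
tied absolute differences receive average ranks. With up to 25 nonzero
differences the exact null distribution of the positive-rank sum is built
by dynamic programming over doubled ranks (doubling puts average ranks on
an integer lattice), which remains exact under ties where the classical
tables do not apply; the test suite checks it against full 2^n sign
enumeration. Beyond 25 a normal approximation is used with three
refinements: the tie-corrected variance, a continuity correction at the
actual lattice spacing of the statistic (ties halve the spacing), and a
fourth-cumulant Edgeworth term (the distribution is symmetric, so the
skewness term vanishes). At the branch boundary the approximation is within
0.005 of the exact two-sided p in the suite's stress tests; far in the
tails (|z| > 8) the correction term is numerically meaningless and the
plain normal tail is used instead.

The location summary reported alongside is the Hodges–Lehmann
pseudo-median of the non-focal values — the median of all Walsh averages
`(x_i + x_j)/2`, the natural estimand of the signed-rank test and robust to
the extreme right tails centrality distributions have. It is computed
exactly up to 2000 nodes and from a fixed-seed subsample of Walsh averages
beyond, so results are reproducible either way. The reported `direction`
(above/below/none) compares the focal value to this pseudo-median; `none`
is reserved for exact coincidence, as in a perfectly symmetric network.

## Preprocessing conventions

*Half-minimum imputation* replaces a feature's missing entries by half the
minimum of its observed entries, per feature (the "per protein" reading),
the standard left-censoring heuristic for intensities below detection.
Zeros count as observed by default; `zero_as_missing = TRUE` recodes them
first, the variant needed for count matrices where zero means undetected.
Features with no observed value cannot be imputed and are dropped with a
record rather than failing the run. *Reference normalization* divides each
feature by the arithmetic mean of its raw values over the wild-type
samples; it is scale-equivariant and idempotent on its own output, and —
because ranks are unchanged — provably irrelevant to the correlation
network itself (a property the suite asserts). It matters only for
downstream ratio displays, and the pipeline defaults to imputing before
normalizing.

## Companion statistics

The differential filter keeps features with `|log2FC| >= 1` *and*
BH-adjusted `p <= 0.1`, both inclusive; the absolute-value reading of the
fold-change bound is deliberate, since both regulation directions are
reported downstream. Benjamini–Hochberg is implemented directly (step-up,
`q_(i) = min_{j>=i} m p_(j)/j`, stable under ties) and cross-checked
against `p.adjust` in the tests. The enrichment-direction z-score
`z = (up - down)/sqrt(count)` decorates gene-set results with a direction;
its invariants (`|z| <= sqrt(count)`, sign follows `up - down`, quadrupling
the term size halves `|z|`) are asserted property-style. The canalization
statistic is the scaled absolute deviation from the median,
`|x_i - median|/median` — a per-observation, CV-comparable relative spread
that behaves under small unbalanced designs where a variance would not;
the scaling location (median vs mean) is exposed. Pigment quantification
divides measured 470/652/665 nm absorbances by the 0.51 pathlength
correction of a 96-well plate and applies the standard pure-methanol
chlorophyll/carotenoid equations, scaling by the dilution factor; the
coefficient set is attached to every result for audit, and negative
concentrations are reported as computed with a warning flag rather than
clipped.

## The synthetic generator

`generate_multiomics()` emulates the statistical structure the analysis
assumes, not the biology. Log-abundances are Gaussian: a per-feature
baseline (log-scale mean 5, sd 1), plus an independent genotype-by-tissue
group effect per feature (sd 1 by default — an e-fold typical group
separation, typical of tissue contrasts), plus residual noise. The hub
module consists of the focal transcript, which carries a per-sample latent
factor directly, and `hub_size` member transcripts whose signal is
`sign * (loading * factor + sqrt(1 - loading^2) * idiosyncratic)`. This
geometry is the point: focal–member correlation is about `loading` while
member–member correlation is about `loading^2`, so the focal feature — not
an arbitrary clique member — is the degree hub the pipeline should find.
Protein-layer values below a per-feature quantile (default 0.2) are
censored to missing, exercising half-minimum imputation in its intended
left-censored regime.

Defaults are the study conditions the package validates against: the
15-sample design, `hub_size = 29`, `hub_negative_fraction = 6/29`,
`hub_loading = 0.99`, `noise_sd = 0.05`, and 600 features across five
layers — large enough that the 0.95 network has hundreds of background
vertices, small enough that a 100-seed recovery experiment runs in seconds.
Two emergent behaviours of the generator are worth knowing. First, with
five groups of three near-identical replicates, many *unrelated* features
end up highly rank-correlated simply because their five group means happen
to order the same way — the thresholded graph is therefore dense far beyond
the planted hub, which mirrors the real study (3×10⁵ edges at 0.95) and is
why hub status must be judged against the network distribution rather than
by edge count alone. Second, at n = 15 the sample Spearman of a
`loading = 0.99` pair still fluctuates: the focal feature recovers on
average about 24 of its 29 members at the 0.95 threshold, seed depending.
What the generator does *not* model: read-level count noise, spatial
structure of variegation, batch effects, or cross-layer technical
covariance — passing recovery tests therefore demonstrates correctness of
the machinery under the assumed structure, not robustness to every
pathology of real data.

## Numerical choices and edge cases

- Correlations are clipped to `[-1, 1]` after the inner product to absorb
  last-ulp float excess; the prefilter and threshold comparisons are `>=`.
- Degenerate inputs fail loudly and early: zero-variance vectors in
  `spearman_rho()`, missing values in the correlation engine, an absent
  focal feature, a network threshold below the prefilter, all-zero
  differences in the signed-rank test. Degenerate *features* (all-missing,
  zero reference mean, zero variance) are dropped with counts instead,
  since one bad feature should not abort a pipeline.
- All TSV exports print floats with 9 decimals, enough to round-trip the
  published correlation values exactly; the typographic minus sign (U+2212)
  that such tables use is normalized to ASCII on every numeric parse.
- Identical input and configuration give byte-identical artifacts; the run
  manifest records configuration, drop counts and per-file checksums.

## Problem sizes used in validation

The shipped validation uses: the packaged 29-row published neighbor table
(reconstructed exactly); 50 random matrices up to 60 features for
blocked-vs-naive equality at block sizes {1, 7, F}; 100 random weighted
graphs of up to 7 vertices against exhaustive path enumeration; sign
enumeration up to 2^12 for the exact Wilcoxon branch and 500 null
simulations for BH calibration; and 100 generator seeds at the default
study conditions for end-to-end hub recovery, where the focal feature
exceeds the median network degree with `p < 0.05` in at least 90 of 100
runs. These sizes keep the whole suite under a minute while covering every
code path; nothing in the implementation is specific to them.

## Known limitations

Spearman correlation at n = 15 has coarse resolution (1/560) and heavy
threshold-boundary noise; neighbor counts should be read with that in mind.
The pipeline tests one focal feature against the network — it does not
perform de novo hub discovery with multiplicity control, though
`node_metrics()` output makes that straightforward. Closeness and
betweenness depend on the distance convention; only degree is
convention-free. The hub test treats network node values as exchangeable
observations, ignoring graph dependence between centralities of adjacent
nodes — the same simplification the motivating analysis makes — so its p
is a calibrated summary of "how extreme is the focal node here", not a
generative-model tail probability.
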