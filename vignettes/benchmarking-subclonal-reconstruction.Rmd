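---
title: "Benchmarking single-sample tumor subclonal reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking single-sample tumor subclonal reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetbench)
```

## The problem

A bulk tumor sample is a mixture: normal cells, a dominant clone, and
possibly several subclones, each defined by the set of somatic mutations its
cells inherit from a common ancestor. Subclonal reconstruction algorithms
invert the mixture from SNV allele frequencies and copy-number calls,
reporting (i) tumor purity, (ii) the number of subclonal lineages, (iii) a
cellular-prevalence (CP) profile of mutation clusters, (iv) which SNVs
co-occur in a cluster, and (v) a clone phylogeny. `hetbench` scores each of
these outputs against a known truth, and supplies everything needed to run a
full benchmark offline: reference baselines, normalization and rank
statistics, consensus ensembles and a synthetic cohort generator.

Throughout, the canonical mutation-prevalence scale is **CP** — the fraction
of *all* sampled cells carrying a mutation. The cancer cell fraction is
CCF = CP/ρ where ρ is the purity; conversions happen only at input/output
boundaries (`vaf_to_ccf()`, the `purity` argument of `random_1c()`), never
inside the metrics.

## Truth model

A truth (`phylogeny_truth`) is a rooted clone tree plus an SNV assignment.
The germline root is a sentinel (id 0) that never enters any scored matrix;
exactly one clonal node hangs off it and carries CP equal to ρ. Every node
obeys the pigeonhole principle — its children's CPs cannot sum beyond its
own, because a cell carrying a child clone's mutations also carries the
parent's. The constructor enforces all of this, so malformed truths fail at
load, not at scoring time. Multi-root *predictions* are still accepted: the
reconciliation step attaches extra roots to the sentinel.

## The metrics and their conventions

The seven metrics are exact transcriptions of the benchmark's definitions;
the conventions below fill in what a formula alone leaves open.

**1A, purity.** `1 - |rho - c|`, both values required in [0, 1].

**1B, subclone count.** `(L - d + 1)/(L + 1)` with
`d = min(|kappa - L|, L + 1)`. Capping `d` keeps the score non-negative;
`scripts/acceptance.R` verifies the zero lower bound by enumerating
L in 1..10 against every κ in 0..100.

**1C, CP profile.** `1 - EMD`, where EMD is the first Wasserstein distance
between the SNV-mass-weighted discrete CP distributions, with ground
distance |x − y| on [0, 1] and masses normalized to 1. On the unit interval
this distance is automatically ≤ 1, so no further scaling constant is
needed to keep the score in [0, 1]; we compute it exactly as the integrated
absolute CDF difference and cross-check against an independent greedy
transport solver (exact in one dimension) in the test suite.

**2A/2B, coclustering.** Both the truth and the prediction are rendered as
SNV×SNV coclustering matrices (hard labels give 0/1 entries; a soft
assignment gives row dot products, with a unit diagonal by definition). Over
the unordered off-diagonal pairs we compute:

- **AUPR** — area under the precision–recall curve for predicting "same
  cluster", as average precision: pairs sorted by decreasing predicted
  probability, tied scores grouped at one threshold, precision summed over
  recall increments. If the truth has no coclustered pair at all the PR
  curve is undefined; the component is flagged and contributes 0.
- **AJSD** — the per-pair Jensen–Shannon divergence (base 2) between
  Bernoulli(p_pred) and Bernoulli(p_true), averaged over pairs. This is the
  simplest reading of an "average JSD" between coclustering probabilities
  and lies in [0, 1].

Each component is then normalized against the *worse* of two extreme
reference predictions computed on the same truth — all SNVs in one cluster,
and every SNV a singleton — by an affine rescaling that maps the worse
extreme to 0 and perfection to 1, clamped below at 0. The extremes are
recomputed per tumor; caching them by truth size would give identical
results. The final score is the mean of the two normalized components.

**3A/3B, phylogeny.** The tree plus assignment expands into three pairwise
relation matrices — cocluster, ancestor–descendant (entry (i, j) = 1 when
i's clone is a strict ancestor of j's) and cousin — which partition all
ordered SNV pairs together with the transposed ancestor–descendant matrix.
The score is a *single* Pearson correlation over the concatenated
off-diagonal entries of the four predicted versus four true matrices (the
definition names one correlation coefficient, so we do not average
per-matrix correlations). Diagonals are excluded: they are constant by
construction and would only dilute the correlation. A stacked vector with
zero variance (possible only for degenerate soft predictions that spread
probability equally over all four relations) yields a defined score of 0
with a `zero_variance` flag. The hard task derives the prediction's
matrices from its tree; the soft task takes the submitted
ancestor-probability matrix directly and borrows the coclustering matrix
from the soft clustering task, completing the cousin matrix as the clamped
remaining probability mass.

## Reconciliation

Algorithms rarely report exactly the truth's SNV set. Before scoring,
`reconcile_prediction()` makes the universes match:

- **False negatives** (truth-only SNVs) are added as *one* new cluster with
  CP 0, derived from the normal: a leaf child of the germline sentinel. Its
  SNVs cocluster with one another, are ancestors and descendants of
  nothing, and are cousins of every somatic SNV.
- **False positives** (prediction-only SNVs) are excluded; their rows and
  columns are removed from matrix predictions.

For CP profiles, which carry no SNV identities, reconciliation is by mass:
if the predicted profile covers fewer SNVs than the truth, the shortfall is
added as the zero-CP cluster; a surplus simply renormalizes, since the EMD
works on normalized masses.

Missing outputs are recorded as missing, not zero — the cohort scorer keeps
the failure reason per row, and `rank_algorithms(zero_fill = TRUE)` exists
for users who prefer the harsher convention.

## Baselines

The five random reference predictors draw purity from U(0.2, 0.99), the
subclone count from {1, 2, 3, 4} with probabilities {0.2, 0.3, 0.3, 0.2}, a
profile with one cluster at CCF 1 and the rest at U(0.2, 0.9) with 1–10
SNVs each, hard assignments from per-cluster weights drawn uniformly from
1–10, and a coclustering matrix as the coassignment proportions over 100
random assignment vectors (kept as an attribute so tests can recount them).
The one-cluster method puts every SNV in a single cluster at twice the VAF
mode; we estimate the mode by the maximum of a Gaussian kernel density
(Silverman's bandwidth) on [0, 1] and clip the doubled mode at 1, assuming
diploid heterozygous SNVs — the definition names the mode but not the
estimator, and the diploid doubling rule is the conservative mapping from a
VAF mode to a purity-scale CP without copy-number information.

## Normalization, ranking and rank significance

Raw scores are min–max normalized within each {tumor, subchallenge} group so
the worst method maps to 0 and the best to 1; tumors belonging to a
titration series (one tumor sequenced at several depths) share a single
min/max across depths. A degenerate group where every method scored the
same normalizes to 1 — everyone is equally best, and the alternative
(0 or NA) would punish ties. Normalization is idempotent and invariant to
affine increasing transforms of the raw scores; a *non-affine* monotone
transform preserves within-group ordering but can in principle reorder
cross-tumor medians, which is why the package normalizes raw metric values
and nothing else.

Algorithms are ranked by median normalized score over the tumors they
completed, ties sharing the minimum rank. Significance against the best
entry uses a bootstrap over tumors: resample tumors with replacement,
recompute medians and ranks within each resample, and report the fraction
of resamples in which the entry's rank is at most the original best
method's recomputed rank. Entries with P > 0.1 are flagged statistically
indistinguishable from the best. The default is 10,000 seeded resamples —
the test itself is defined by the resampling scheme, not the count, and the
suite uses fewer for speed.

## Decision space and weight stability

To compare methods across subchallenges, the algorithm × subchallenge
matrix of (tumor-weighted) mean scores is projected onto its first two
principal components; subchallenge axes are the PCA loadings and the
decision axis is the weighted-mean direction mapped through them. Ranking
by projection onto the equal-weight decision axis equals ranking by
unweighted mean score. Stability is assessed two ways: perturbed decision
axes (±50% uniform changes to the subchallenge weights, 3,000 axes by
default) and fully random uniform weights over tumors and subchallenges
(200 draws each, crossed into 40,000 independent rankings), from which
per-algorithm rank distributions and ever-ranked-first flags are reported.

## Ensembles

Consensus methods exist for the four tasks where outputs are commensurable:
median purity (1A), floor-of-median count (1B), WeMe (1C) and CICC (2A);
soft matrices and phylogenies are deliberately out of scope. WeMe renders
each profile as an inverse CDF of SNV mass over CP, takes the pointwise
weighted median across methods on a grid of 1,001 mass quantiles, and reads
consensus clusters off the steps of the result; the grid makes the median
of step functions well defined, and weighted-median ties are resolved by
averaging the two bracketing values (so two single-cluster profiles at 0.6
and 0.8 yield 0.7). Cluster masses are converted back to SNV counts by
largest-remainder rounding. CICC clusters SNVs by average-linkage
hierarchical clustering on coassignment distances (1 − fraction of methods
coassigning the pair), cut at the floor-of-median of the inputs' cluster
counts; average linkage is the natural choice for proportion-valued
distances, and on small structured instances the cut recovers the
exhaustive-search optimum (verified against brute force in the tests —
being agglomerative, it carries no global guarantee on adversarial
instances). When ensembles are run over method subsets, all C(m, n)
combinations are used up to 200, beyond which 200 distinct subsets are
sampled without replacement.

## Tumor features

`nrpcc()` implements ρd/(ρΨ + 2(1 − ρ)), the purity- and ploidy-adjusted
read depth that proxies statistical power for subclonal reconstruction.
`pga()` counts bases in segments whose total copy number deviates from the
rounded tumor ploidy — subclonal segments count their full length, since
the definition counts bases within CNAs without fractional weighting.
`clonal_fraction()` is the truncal share of mutations. `peak_overlap()`
fits a Gaussian kernel density (Silverman bandwidth, 512-point grid on
[0, 1.25]) per subclone in CCF space and integrates, by the trapezoidal
rule, the second-largest density envelope relative to the summed densities;
the second-largest envelope rather than a pairwise minimum generalizes
"CCF space covered by more than one subclone" to any number of subclones,
and gives exactly 0.5 for two identical densities. `vaf_to_ccf()` uses
multiplicity 1 by default — the conservative standard convention.

## The synthetic cohort generator

The generator emulates the benchmark's design space: 1–5 subclones, mixed
linear and branching topologies, purity 0.3–0.95, depth levels
8×–128× (with a titration subset sharing one truth across all depths),
500–5,000 SNVs and a 0.3 whole-genome-doubling probability (doubling is
common enough in the cancer types the design space covers that a cohort
without it would be unrealistically easy; it enters through ploidy and
hence NRPCC). Cluster CPs are drawn by stick-breaking within the parent's
CP budget with a minimum separation of 0.05 between parent/child and among
siblings, so generated truths are resolvable — without the gap, arbitrarily
close clusters make rank-recovery experiments meaningless. Read counts are
binomial draws at Poisson-distributed depth with the expected VAF implied
by CP, purity and (diploid) copy number.

Synthetic "algorithms" are noise specifications applied to the truth:
cluster merges and splits change the subclone count, CP jitter moves
cluster locations, misassignment relabels SNVs, and false-negative /
false-positive rates shrink or inflate the reported SNV universe to
exercise reconciliation. A zero-noise specification reproduces the truth
and scores 1 on all seven tasks — the calibration anchor for every
end-to-end test.

What the generator does **not** emulate: read-level artifacts (mapping
error, strand bias), realistic CNA segmentation, neutral-tail mutations
accumulating below the subclone clusters, and caller-specific
false-positive profiles. Passing rank-recovery tests on this cohort shows
the *framework* orders methods by injected quality; it does not certify how
any real algorithm behaves on real sequencing data.

## Problem sizes and numerical choices

The test and acceptance suites run the framework at desk scale, chosen as
the package's own benchmark conditions: rank-recovery uses 20 tumors with
120–320 SNVs and five noise-ordered algorithms; oracle equivalence uses
1,000 random ≤6-cluster profiles for the EMD and ≤6-SNV instances for the
pairwise metrics; ensemble monotonicity uses 10 tumors at n ∈ {1, 3, 5, 7}
inputs with a one-standard-error tolerance. Dense coclustering and
ancestry matrices grow as O(N²); the readers cap them at 20,000 SNVs with
a clear error, matrix files are streamed in row chunks, and tolerances are
1e-8 for soft row sums, 1e-6 for file-level symmetry/diagonal checks and
1e-12 for perfect-score assertions. Cluster labels are canonicalized to
1-based contiguous integers by order of first appearance; every metric is
invariant to relabeling and SNV order.

## Known limitations

- The AUPR interpolation and the EMD discretization conventions are pinned
  by this package's oracle tests; other harnesses may differ in tie
  handling at PR thresholds.
- sc3B scoring requires a coclustering matrix alongside the submitted
  ancestry matrix (from the soft clustering output, or derived from hard
  labels); an ancestry matrix alone is not scoreable.
- CICC inherits the greedy nature of agglomerative clustering; it matches
  the exhaustive optimum on coherent inputs but can miss it when methods
  disagree chaotically.
- The missing-output policy is non-penalizing by default; leaderboards over
  algorithms with very different completion rates should be read together
  with the per-algorithm tumor counts the ranking reports.
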