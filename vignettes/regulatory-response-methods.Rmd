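---
title: "Models and methods behind regunet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind regunet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

regunet analyses inducible transcription-factor perturbations in ES
cells: a factor (the motivating case is Nanog) is switched on with
doxycycline while self-renewal is controlled through LIF, and the
package asks where the factor binds, which partners join it, how
broad H3K27me3 chromatin responds, and how the transcriptome sorts
into response patterns. This vignette records the models, the
parameters that matter, and the design choices made where more than
one defensible reading existed. Everything quantitative asserted
here is computed by the test suite or by `scripts/acceptance.R`;
this document explains *why* the procedures look the way they do.

## Coordinates and formats

All internal coordinates are 0-based half-open (BED-native), because
every genomic input format the package touches (BED3/6, narrowPeak,
broadPeak, bedGraph-like tracks) is BED-family; conversion to the
1-based closed convention happens only where `GRanges` objects are
built, in one pair of internal helpers. Chromosome names are used
verbatim — no alias resolution (`chr1` and `1` are different). When
a count matrix arrives with real-valued estimated counts, they are
rounded half to even (R's `round()`), a symmetric choice where the
upstream convention is unknown.

## Consensus binding regions

Peaks from multiple samples are filtered (blacklist overlap ≥ 1 bp,
excluded chromosomes such as chrM/chrY), pooled, and union-merged:
any ≥ 1 bp overlap merges, transitively. Support is the number of
distinct samples contributing at least one peak to a merged region;
regions below `min_support` (default 2, "seen in at least two
independent samples") are dropped. Merging before height filtering
is a deliberate ordering: height is computed *on the merged region*
(the alternative — filtering raw peaks first — was not taken because
the region, not the peak call, is the unit carried forward).

Height is the **maximum** per-bp read-start count in the region,
scaled to rpm and averaged over samples — a summit height, not a
mean coverage, because a narrow binding event should not be diluted
by the width the merge happened to produce. The default threshold is
1 rpm, compared inclusively (`>=`), as are all thresholds in the
package: a region exactly at a published cutoff is kept. Summits are
the position of maximum averaged coverage with ties broken leftmost,
a deterministic rule that makes runs reproducible bit for bit.

ATAC fragments contribute two Tn5 cut sites, the leftmost and
rightmost fragment coordinates shifted 4 bp inwards symmetrically
(+4 on the left, −4 on the right end base); the cut base and its two
neighbours are each marked +1, and tracks are rpm-scaled by fragment
count then averaged over replicates. The symmetric +4/−4 was chosen
over the also-common +4/−5 variant and is stated here so users can
account for the 1 bp difference; fragments shorter than 9 bp are
rejected because their cut sites would cross.

## Co-binding traces and clustering

For each region, factor *i* and condition (±Dox), read starts are
binned over a 1 kb window centred on the summit (default bin 10 bp),
rpm-scaled per replicate and averaged within condition, giving
*h⁺ᵢⱼₖ* and *h⁻ᵢⱼₖ*. The 10 bp default keeps a region's feature
vector at 4 factors × 2 conditions × 50 bins = 400 numbers over the
±250 bp clustered flank — per-bp resolution (`bin_bp = 1`) is
available but adds nothing to profile shape at ChIP-seq fragment
sizes.

A region is **co-binding** when any factor reaches `threshold_rpm`
(default 2.7 rpm, inclusive) in any bin of either condition, else
**solo**. The threshold is a direct configurable parameter: the
exploratory pre-clustering by which such a threshold is originally
discovered is not re-enacted, since what it produces *is* the
threshold.

Clustering features are built in two normalisation steps: each
factor's concatenated (+Dox, −Dox) trace over the ±250 bp flank is
divided by that factor's +Dox occupancy score σᵢ = Σⱼₖ h⁺ᵢⱼₖ
(computed over the regions being clustered), removing global
occupancy differences *between* factors; then each region's
concatenated vector is divided by its own maximum, removing
occupancy differences *between* sites. Every clustered τ̄ⱼ therefore
has maximum exactly 1, and rescaling all of one factor's counts by a
constant changes nothing — a power-of-two rescaling changes nothing
even at the bit level, which the acceptance suite checks. Regions
whose trace is identically zero cannot be max-normalised and are
excluded and reported. σᵢ = 0 is an error naming the factor.

k-means uses Lloyd iterations with k-means++ seeding, best of
`n_init = 10` restarts by inertia, `max_iter = 300`, and a relative
inertia tolerance of 1e-6; ties in assignment break to the
lowest-index centroid. An emptied cluster is reseeded from the point
farthest from its centroid (among points at positive distance in
clusters of size ≥ 2); when the data are exact duplicates there is
nothing to reseed from, the effective number of clusters is smaller
than k, and partitions collapse consistently — which is also why a
degenerate all-duplicates input yields Rand index 1 across k.

Model selection clusters at every k in range with the *same* seed
policy and reports the Rand index between the partitions at k and
k+1: (pairs together in both + pairs apart in both) / C(n,2). The
standard Rand index (including the apart–apart term) is used because
partitions with different k have no canonical label matching;
without the apart–apart term the statistic is not comparable across
k. The recommended k is the smallest with RI(k, k+1) ≥ 0.9, but the
report carries the whole trace — the final choice is the analyst's,
because stability alone cannot distinguish "one real cluster split
in two" from "a new co-binding mode resolved". Only the TF traces
enter the feature space; accessibility tracks are summarised
alongside clusters but deliberately not clustered on, keeping the
partition interpretable as a co-binding taxonomy.

## Broad H3K27me3 domains

Pooled broad peaks merge transitively across gaps ≤ 3 kb
(inclusive), and merged domains must be supported (≥ 1 bp overlap)
by at least 8 of the samples. The count-based "≥ 8 samples" rule is
used rather than the stricter "all four replicates of at least two
conditions": the two differ once replicates have been excluded, and
the count rule degrades gracefully under QC loss.

Replicate QC: within each condition, the sample whose count is the
**strict** maximum (ties count for no sample) is tallied per domain;
a sample holding that maximum in ≥ 60 % of domains is excluded.
Under exchangeability with four replicates each sample expects ~25 %,
so 60 % is far outside noise; with strictness, an all-tied matrix
excludes nobody.

Dynamics clustering takes **condition means over the retained
replicates** (not totals — unbalanced replicate loss after QC would
otherwise bias a condition), max-normalises each domain's profile
across conditions, and k-means-clusters with k = 3 (sharing the
co-binding k-means). Cluster labels are assigned from centroid
shape: the centroid with the lowest −LIF-minus-+LIF mean difference
is `lif_loss`, the highest `lif_gain`, the remainder `stable` — a
repository convention making the narrative classes operational.

A gene is embedded in a domain if its body overlaps the domain by
≥ 1 bp, or a domain lies within 4 kb of its TSS *and* that domain
overlaps no gene at all — so a promoter-proximal domain is never
borrowed across a neighbouring gene.

## Negative-binomial contrasts and the response taxonomy

Counts are normalised by median-of-ratios size factors (geometric
mean reference over genes with all-positive counts); a gene is
tested when at least one condition has every replicate at ≥ 10
normalised counts. Per gene, an NB GLM with log link is fitted by
IRLS (`glm.fit` with the fixed-θ negative-binomial family) with
log size factors as offsets. Wald statistics for a contrast vector
c are (c·β̂)/√(cᵀΣ̂c) against the standard normal — matching the
convention of the count-model packages this module approximates —
with no independent filtering and no fold-change shrinkage; BH
adjustment is applied within each contrast over the converged genes,
and non-convergent genes are flagged and excluded from the FDR
universe with a logged count.

**Dispersion.** The moments estimator on normalised counts within
design cells, floored at 1e-8, is the building block. Used per gene
at 4 replicates it is noisy enough to make the Wald test visibly
anti-conservative (the plug-in noise acts like losing the normal
reference's tails). The default is therefore
`dispersion_method = "common"`: one dispersion for the whole matrix,
obtained by pooling the per-gene moment numerators and denominators —
in the spirit of tools that share dispersion information across
genes, but without any empirical-Bayes shrinkage machinery, which is
deliberately out of scope. `"per_gene"` is available when gene-wise
dispersions are genuinely heterogeneous, and a fixed `dispersion`
overrides both. With the common estimator, the null calibration and
power checks in the acceptance suite pass at their stated bands.

The three contrasts of the 2×2 LIF×Dox design are: the
LIF-withdrawal effect (the −LIF coefficient; positive = up after
withdrawal — the direction is explicit in output names to avoid
silent sign flips), the Dox effect in +LIF (Dox coefficient), and
the Dox effect in −LIF (Dox **plus** interaction coefficients, as a
single Wald contrast). States (up / down / ns at FDR < 0.05) over
the three contrasts give one of 27 triples; all 27 are reported with
zeros included, rather than only the patterns that happen to be
occupied in a given dataset. Rescue categories read off the triple:
`rescued_up` = up on withdrawal with a down Dox-in-−LIF state,
`rescued_down` the mirror image, `not_rescued_*` when the
Dox-in-−LIF state is ns, `other` otherwise.

Cross-system concordance uses the Pearson χ² (no continuity
correction) on the 3×3 up/down/ns table, df = 4, with Cramér's
V = √(χ²/(N·2)); a zero margin makes χ² not-applicable rather than
an arbitrary number, and a one-sided Fisher exact test on the 2×2
responsive-vs-not collapse is reported alongside. The
likelihood-ratio test compares nested NB models (same per-gene
dispersion under the full design) with 2Δℓ against χ² on the
coefficient-count difference. The union of responsive genes keeps
provenance flags and flags sign conflicts between systems instead of
dropping them. Compensation by a second guide is called when a gene
with a non-ns Dox-in-−LIF state under the first guide becomes ns or
flips sign under the dual guide; partial compensation is testable
separately via the between-guide Wald contrast on the combined
`~ LIF + DoxGuide + LIF:DoxGuide` design. Gene-level z-scores use
the population (n) denominator; constant rows map to zero.

## Proximity enrichment

Distances run from each TSS to the nearest region summit on its
chromosome (0 when the TSS sits inside a region; +Inf when the
chromosome has no region). Summits, not peak edges, keep the
distance definition aligned with the summit-centred convention used
everywhere else. At each of 50 log-spaced thresholds x ∈ [1, 10⁸] bp
the 2×2 table (responsive within x / beyond × non-responsive
within / beyond) is tested one-sided for enrichment with the
hypergeometric tail — identical to the one-sided Fisher exact test,
and cross-checked against direct tail summation in the tests. The
universe is all tested genes globally; restricting it per
chromosome was considered and rejected as it changes the question
from "near a peak" to "near a peak given the chromosome". The
sliding-window statistic is a plain windowed mean of binary labels
along a ranked list (default window 500 genes, step 1).

## gRNA candidates

Enumeration finds every 20-mer followed by NGG on the + strand and,
via the reverse complement, every CCN-prefixed site on the − strand;
`position` is always the 0-based protospacer start on the +
reference. Filters: GC within [35, 85] % inclusive, and no
single-base run of 4 or more ("a stretch of 4 or more repeated
nucleotides" read as a homopolymer). Off-target counting slides the
guide over both strands of user-supplied subjects, requires the NGG
PAM (first PAM base matches anything including N; the two Gs must be
literal — an N in the subject never matches anywhere), and returns
the mismatch histogram 0..4. The published ranking by 5′-end and
seed mismatches depends on an undefined seed length, so ranking is
left to the caller on top of the histogram; predictive efficiency
scores are out of scope.

## The synthetic cohort

The generators are pure functions of (parameters, seed) — each saves
and restores the caller's RNG state — and all counts are negative
binomial with Var = μ + αμ², one dispersion per generator, matching
the downstream model.

`simulate_binding` plants regions 3 kb apart on one synthetic
chromosome: a solo fraction of 0.49 (the roughly half-and-half
solo/co-binding split typical of this system), and co-binding
regions drawn from eight archetypes over Esrrb/Oct4/Sox2/Brg1 — four
Dox-dependent (partner signal collapses from 12 to 1 rpm on
withdrawal) and four Dox-independent, differing in which factor set
is bound. Per-bin means follow a Gaussian bump (sd = window/8, i.e.
62.5 bp for the 500 bp signal window, keeping signal inside
±250 bp) on a 0.05 reads/bin background; the induced factor itself
sits at 15 rpm everywhere. Amplitudes are calibrated so an "on"
factor clears the 2.7 rpm threshold essentially always and an "off"
factor (0.2 rpm) essentially never. Six pseudo peak-call samples
each recall a random ≥ 80 % subset of regions so the support filter
has real work; only on-region reads are materialised, with each
track's `library_size` set to the nominal depth (10⁶) that the
un-materialised rest of the genome would absorb.

`simulate_k27` plants broad domains (5–15 kb, ≥ 10 kb apart so
distinct domains never merge at the 3 kb gap) in three classes —
stable; LIF-loss (−LIF −Dox at 25 % of baseline, partially retained
at 75 % under Dox, the rescue signature); LIF-gain (the mirror) —
across 4 conditions × 4 replicates, with one designated replicate
inflated 3× to exercise the outlier QC, and per-sample broad peaks
that occasionally split in two with a sub-3 kb gap to exercise
merging.

`simulate_expression` draws baselines log-normally around 300 counts
(floored above the expression filter), realises each gene's planted
triple at ±2 log2 units through the L, D and D+I coefficients, and
varies library factors uniformly in [0.7, 1.3] so size factors are
non-trivial. The default pattern mixture mirrors the frequencies
reported for this biology: ~52 % non-responsive, ~18 %/17 % up/down
on LIF withdrawal without a Dox response, ~4.7 %/3.4 % rescued in
each direction, and a few percent of Dox-only responses. With
`peak_link`, Dox-responsive genes get TSSs placed beyond the summit
span at exactly U(0, d0] from the nearest summit (an interior
placement would land next to a *neighbouring* summit 3 kb away and
destroy the planted distance), and all other genes sit farther than
10·d0. With `otx2`, a second guide is simulated in which a planted
fraction of Dox-responsive genes have their Dox effects cancelled.

What the generators do **not** emulate: mappability and GC bias,
fragment-length structure, read-level errors, correlated dispersion
across genes, spatial autocorrelation of peaks, and annotation
ambiguity. Passing tests therefore demonstrate that the algorithms
recover what they are defined to recover under the stated noise
model — not that any particular biological dataset will behave as
cleanly.

## Problem sizes and determinism

The test and acceptance workloads use 2,000 binding regions, 2,000
genes × 16 samples, 300 domains × 16 samples, and 100-seed QC
replications — sizes chosen so the full suite exercises every
stage at meaningful scale while remaining a desk-scale run (the
whole suite completes in about a minute on one core). Stage seeds in
`run_pipeline` fan out from the single configured seed by fixed
offsets, so any stage can be re-run in isolation and byte-identical
artifacts are reproduced for identical configs.

## Known limitations

* The NB approximation has no dispersion trend or shrinkage; datasets
  with strongly gene-dependent dispersion should use
  `dispersion_method = "per_gene"` and expect somewhat conservative
  power, or import externally computed contrast tables into the
  classification layer.
* `build_consensus` treats any ≥ 1 bp overlap as co-occurrence;
  fragmented peak callers can inflate support.
* The k-means empty-cluster repair cannot split exact duplicates, so
  the returned model's effective k can be smaller than requested on
  degenerate inputs (reported via the cluster sizes).
* Off-target counting is exact-window Hamming matching; it is meant
  for promoter-scale subjects, not genome-scale scans.
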