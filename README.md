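# regunet

Analysis toolkit for inducible transcription-factor perturbation
experiments in embryonic stem (ES) cells — the setting where a factor
such as Nanog is switched on with doxycycline (±Dox) while
self-renewal is controlled through LIF (±LIF), and the question is
what the factor binds, with whom, and what it does to chromatin and
transcription.

The package covers the computational arc of such a study:

1. **Consensus binding regions** from multi-sample ChIP-seq peak
   calls: blacklist/chromosome filtering, union-merging across
   samples (≥ 1 bp overlap), a minimum-support filter, summit
   location from averaged coverage, and a mean peak-height filter in
   reads per million (rpm).
2. **Co-binding clustering.** Signal for factors *i* at regions *j*
   and positions *k* is quantified in ±Dox conditions as
   depth-normalised bin counts *h⁺ᵢⱼₖ*, *h⁻ᵢⱼₖ* over 1 kb around each
   summit. Regions split into *solo* (no partner factor reaches
   2.7 rpm in any condition) and *co-binding*. For clustering, each
   factor's concatenated ±Dox trace over ±250 bp is scaled by its
   +Dox occupancy score σᵢ = Σⱼₖ h⁺ᵢⱼₖ, and each region's vector
   τⱼ = (t₁ⱼ/σ₁, …, tₙⱼ/σₙ) is max-normalised to τ̄ⱼ = τⱼ / maxₖ τⱼₖ,
   so the features encode binding *pattern*, not occupancy level.
   k-means (k-means++ seeding, best of 10 restarts) clusters the τ̄ⱼ;
   the number of clusters is chosen where the Rand index between the
   partitions at *k* and *k*+1 — the fraction of region pairs on
   which the two partitions agree — exceeds 0.9.
3. **Broad H3K27me3 domains**: pooled broad peaks merged across gaps
   ≤ 3 kb, kept when supported by ≥ 8 samples; replicate QC that
   excludes a sample holding the strict within-condition maximum in
   ≥ 60 % of domains; k = 3 dynamics clustering of max-normalised
   condition means into stable / LIF-loss / LIF-gain classes; and
   gene embedding (body overlap ≥ 1 bp, or a gene-free domain within
   4 kb of the TSS).
4. **Response taxonomy.** Per-gene negative-binomial GLMs (log link,
   median-of-ratios size factors as offsets, moments dispersion) are
   Wald-tested on three contrasts — the LIF-withdrawal effect, the
   Dox effect in +LIF, and the Dox effect in −LIF (the Dox plus
   interaction coefficients) — with BH correction and no fold-change
   shrinkage. Each gene gets a triple of states in {up, down, ns},
   one of 27 patterns, and a rescue category (e.g. *rescued_up*: up
   on LIF withdrawal, pushed down by induction in −LIF). Cross-system
   agreement is summarised by a 3×3 contingency χ² with Cramér's
   V = √(χ²/2N); nested models are compared by likelihood-ratio
   tests; a second guide (Nanog+Otx2) supports compensation calls and
   a between-guide Wald contrast.
5. **Proximity enrichment**: TSS-to-nearest-summit distances and
   one-sided Fisher (hypergeometric) enrichment of a responsive gene
   set among genes within *x* bp of a peak, over a log-spaced grid
   x ∈ [1, 10⁸]; plus a 500-gene sliding-window fraction along ranked
   lists.
6. **ATAC cut sites** (+4/−4 bp inward shift, cut base ± 1 marked,
   rpm-scaled) and **SpCas9 gRNA design** (20-mer + NGG enumeration
   on both strands, GC 35–85 % inclusive, no homopolymer run ≥ 4,
   mismatch-histogram off-target counting).

A synthetic-data module (`simulate_genome`, `simulate_binding`,
`simulate_k27`, `simulate_expression`) generates every input with
planted ground truth, so the whole pipeline runs and is tested
without external data. Chromosome names are taken verbatim from
inputs (no alias resolution); all internal coordinates are 0-based
half-open.

## Worked example

```r
library(regunet)

sim     <- simulate_binding(n_regions = 500, seed = 1)
regions <- build_consensus(sim$peak_sets, min_support = 2)
nanog   <- c(sim$reads$Nanog$plus, sim$reads$Nanog$minus)
regions <- height_filter(locate_summits(regions, nanog), nanog, min_rpm = 1)
nrow(regions)
#> consensus regions: 500

tf <- sim$reads[c("Esrrb", "Oct4", "Sox2", "Brg1")]
sm <- quantify_traces(regions, tf, window_bp = 1000, bin_bp = 10)
sp <- split_solo_cobinding(sm, threshold_rpm = 2.7)
#> solo: 245   co-binding: 255

ts <- normalize_traces(subset_regions(sm, sp$cobinding), flank_bp = 250)
select_k(ts, k_range = c(6, 9), seed = 1)$table
#>  k rand_next
#>  6 0.9634399
#>  7 0.9731975
#>  8 0.9921260
#>  9 0.9773043

km <- kmeans_cluster(ts, k = 8, seed = 1)
table(km$assignment)
#>  1  2  3  4  5  6  7  8
#> 31 28 34 31 32 37 31 31
```

All 500 planted regions pass the support and 1-rpm height filters;
the solo/co-binding split matches the planted half-and-half design;
the Rand-index trace is ≥ 0.96 everywhere and peaks at the planted
k = 8, where the eight archetypes come back as eight clusters of
roughly equal size.

`run_pipeline(config)` (a named list or YAML path; see
`default_config()`) chains all stages — simulation, consensus,
co-binding clustering, domain dynamics, differential expression,
pattern classification and proximity enrichment — into an output
directory with per-stage TSV/JSON artifacts, a resolved config copy
and a checksummed manifest, deterministically per seed.

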