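---
title: "Reconstructing genotype-dependent mortality from pooled allele-frequency time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing genotype-dependent mortality from pooled allele-frequency time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolsel)
```

## The problem

Broadcast-spawning marine invertebrates such as the Pacific oyster
(*Crassostrea gigas*) suffer extreme type-III survivorship: only a few
percent of a larval cohort survives the three weeks from fertilization to
settlement. When survival depends on genotype, allele frequencies in the
surviving pool shift over development. Pooled sequencing (pool-seq) of
replicate cultures measures those shifts cheaply — read counts of the two
alleles at each biallelic SNP — but destroys individual genotype
information. `poolsel` implements an analysis chain that starts from a
merged allele-count table and ends with per-locus reconstructions of
genotype-frequency and genotype-fitness trajectories, together with a
classification of how each locus departs from Hardy–Weinberg expectations
at settlement.

The package is organised around a motivating experimental design: a
factorial cross of 5 sires × 19 dams (95 full-sibling families pooled in
equal proportions), five replicate larval cultures sampled on days 0, 2,
6, 10, 14, 16 and 22 post-fertilization, and on the order of 750 filtered
biallelic SNPs. All of these are parameters, not hard-wired constants.

## The model

The core quantity is the Hardy–Weinberg fitness update. Let
`(f_AA, f_AB, f_BB)` be the genotype composition of the cohort at one
locus and `w_AA, w_AB, w_BB ∈ [0, 1]` the relative viabilities over one
inter-sample interval. Mean fitness — the fraction of the cohort that
survives the interval — is

    w̄ = f_AA·w_AA + f_AB·w_AB + f_BB·w_BB

which equals the textbook `p²w_AA + 2pq·w_AB + q²w_BB` whenever the state
is at Hardy–Weinberg proportions. After the selective episode the
composition is `f_g' = f_g·w_g / w̄` and the minor allele frequency is
`f_AB'/2 + f_BB'`. We normalise by the composition-weighted mean rather
than the `p², 2pq, q²`-weighted form because the former keeps states on
the simplex for *any* composition; the two coincide exactly on the HWE
states the pipeline actually starts from, so this is a numerical
robustness choice, not a change of model.

`advance_interval()` implements one episode; `propagate_truth()` iterates
it deterministically (the synthetic ground truth); `forecast_locus()`
inverts it stochastically.

## Stages

1. **Filtering** (`apply_filters()`): per-sample depth within [50, 1000]
   (boundaries retained — "less than 50 or greater than 1000" excludes
   strictly), at most two alleles, one SNP per 36-bp tag, at least three
   replicates at every replicated time point, and egg-pool (day 0) minor
   allele frequency strictly above 1%. The depth rule removes single
   locus × replicate × day observations; the presence rule then handles
   the induced missingness. The minor allele is designated once per locus
   from the mean per-sample fraction across *all* samples and never
   re-flipped, so late-development values above 0.5 are preserved.
2. **Per-locus testing** (`test_age_effect()`): a binomial GLM of
   minor-vs-major counts on day-as-factor, with the age effect tested by
   the deviance (likelihood-ratio) statistic against the intercept-only
   model and Benjamini–Hochberg control at 5% FDR across loci. Age is a
   factor because mortality-driven change is typically non-monotone; a
   linear term would miss a rise-then-fall locus entirely. A
   quasi-binomial flag exists for sensitivity analysis but the reference
   analysis is plain binomial.
3. **Categorization** (`categorize_locus()`): one-way ANOVA of replicate
   MAFs across days, Tukey studentized-range comparisons over all day
   pairs, with only sequential pairs feeding the category: gradual (no
   significant sequential step), uni-directional, bi-directional. Day 0 is
   a single unreplicated egg sample and is excluded here (it still enters
   the GLM); sequential comparisons start at day 2. Tukey runs on raw
   frequencies: with depths bounded in [50, 1000] the binomial variance
   heterogeneity is modest, and an arcsine-square-root flag is provided.
4. **Clustering** (`delta_af_matrix()`, `select_k()`,
   `cluster_trajectories()`): each significant locus is represented by its
   vector of inter-interval changes in mean MAF (ΔAF), from day 2 onward
   by default. `select_k` scores seeded k-means partitions for k = 2…20
   with three internal validity indices — mean silhouette width on a
   Manhattan dissimilarity, Calinski–Harabasz, Davies–Bouldin — and takes
   the majority vote, ties toward smaller k. Pairing a Manhattan
   dissimilarity for k selection with plain Euclidean k-means for the
   final partition is deliberate, mirroring common practice with
   `NbClust`-style index scans followed by `kmeans`. The scan starts at
   k = 2 because all three indices are undefined at k = 1; k = 1 is
   reachable only through the degenerate identical-rows path, which is
   flagged. Cluster labels are renumbered by descending membership, and
   rows are put in canonical order before the seeded restarts so results
   are independent of input row order.
5. **Egg-pool genotype composition** (`simulate_egg_genotypes()`): the
   factorial cross is replayed in silico. Per simulation,
   `round(q·2N)` minor-allele copies (N = 24 parents; the count is held
   exact rather than re-sampled, isolating composition uncertainty from
   allele-frequency uncertainty) are placed uniformly at random among the
   48 parental allele slots; every sire × dam family contributes equally
   and the Mendelian offspring expectation is averaged over the 95
   families. Because all families are crossed, the family average
   factorises into products of mean sire and dam transmission
   probabilities, which makes the simulation exact and fast. A subtlety
   worth knowing: fixing the total copy count induces a negative
   hypergeometric covariance between sire and dam transmission, so the
   expected egg composition carries a small inherent heterozygote excess
   (≈ +0.011 at q = 0.5 for the 5 × 19 design) relative to strict HWE.
   The simulated states are nonetheless well inside Monte-Carlo spread of
   HWE, which is the sense in which the design is "HWE-consistent".
6. **Trajectory forecasting** (`forecast_locus()`): rejection sampling.
   For each interval a fitness vector is drawn with independent
   uniform(0, 1) components, the state advanced, and the proposal kept
   only if simulated MAF and cumulative survival match the empirical
   means among replicates within the tolerance (default 0.10). The MAF
   check is absolute and the survival check relative: cumulative survival
   is ≈ 0.04 at day 22, where a 0.10 absolute window would accept
   anything, while a relative window on MAF degenerates as MAF → 0. Both
   scales are switchable. Constrained days default to 2, 6, 10, 14 and 22
   — day 16 is sampled in the motivating design but sits days from the
   metamorphosis-dominated final interval and is excluded from the
   forecaster, giving six states per trajectory including the day-0
   initial state. A rejected interval is re-drawn up to 10 000 times;
   exhaustion restarts the trajectory from day 0 (up to 1 000 restarts)
   before the slot is abandoned with a diagnostic — infeasible constraint
   sets produce a partial ensemble and a report, never a hang. Proposals
   are evaluated in vectorized batches (default 256); batching changes
   speed only, not the accepted sample path given the seed.
7. **Distortion analysis** (`fit_distortion_models()`, `flag_outliers()`,
   `classify_distortions()`): simulated settlement-stage genotype
   frequencies are regressed, per genotype class, on (a) the egg-pool
   frequency and (b) the HWE expectation from the settlement-stage MAF;
   the formulation with better summed AIC/BIC is selected (on data like
   the motivating study's this is the HWE formulation). "Significantly
   differed" is operationalised as lying outside the two-sided 95%
   prediction interval of the selected model — no sharper test statistic
   is implied by the design. Loci whose flagged genotypes show the major
   homozygote up and the others not up are `fixation_skew` (the load
   signature, concentrated below 20% initial MAF); heterozygote-up loci
   are `heterozygote_excess`; the 20% threshold stratifies reporting only.
8. **Linkage bridging** (`bridge_to_map()`, `intermarker_distances()`):
   SNPs inherit the centimorgan position of the nearest mapped marker on
   their scaffold (ties toward the smaller base-pair position); scaffolds
   absent from the map or spanning multiple linkage groups are omitted
   with reason codes. Inter-marker distance is the mean adjacent gap
   within a linkage group, summarised as a mean over groups with the
   standard deviation taken among groups; an all-pairs variant sits
   behind a flag.
9. **Orchestration** (`run_pipeline()`): filter → test → categorize →
   cluster → egg simulation → forecast → distortion → linkage, with every
   stage's table written to the run directory and a JSON manifest of
   seeds, per-stage locus counts and the headline integer percentages
   (via `percent_of()`), so a run's summary numbers are recomputable from
   the manifest alone. All seeds are explicit; two runs of the same
   configuration are identical.

## The synthetic-data generator

`simulate_pool_study()` emulates the motivating design so every stage is
testable with known ground truth: 751 loci, five replicate cultures, days
0–22 as above, uniform integer depths in [50, 1000] (uniform keeps every
depth exercisable by the filter tests), and binomial read sampling at the
true MAF — replicates descend from one embryo pool, so they share the
true MAF and all replicate variation is sampling noise (an optional
beta-binomial overdispersion parameter exists for robustness checks, off
by default). Four mortality regimes are available — neutral, directional
(load-like), temporally balanced, overdominant — with per-interval
viabilities drawn from ranges centred so mean fitness per interval is
about 0.6, which compounds to the observed ~4% cumulative survival by day
22. The emitted survival series is the across-locus mean of cumulative
mean fitness, perturbed per replicate by lognormal noise (σ = 0.05) and
forced non-increasing. Initial minor allele frequencies default to
uniform on [0.05, 0.5].

What the generator does *not* emulate: linkage between loci (loci are
independent), replicate-level biological divergence in true allele
frequency, mapping or sequencing error, and reference bias. Passing tests
therefore demonstrate correctness of the inference machinery under the
stated model, not robustness to those real-data complications.

## Numerical choices and known limitations

* **Prior pull on weakly represented genotypes.** Under uniform(0, 1)
  proposals, a genotype carrying little cohort weight (f_BB = q² when the
  minor allele is rare) constrains acceptance almost not at all, so its
  accepted-fitness mean sits near the proposal mean 0.5 rather than near
  the empirical mean fitness (~0.6 per interval in a cohort declining to
  4%). Fitness estimates for rare genotype classes are therefore
  prior-dominated; trajectory (frequency) estimates do not suffer from
  this, and the recovery tests show the truth inside the ensemble 95%
  interval in ≳95% of calls. This is a property of the accept/reject
  scheme itself, inherited by design.
* **Degenerate inputs** are explicit: zero mean fitness raises an error
  in deterministic propagation and counts as a rejection in the
  forecaster; zero within-day variance with unequal means is treated as a
  significant change with a warning; identical ΔAF rows yield k = 1 with
  a degeneracy flag; monomorphic-in-parents loci return (1, 0, 0) with a
  warning; more than one consecutive missing time point excludes a locus
  from clustering (a single interior gap is linearly interpolated and
  flagged).
* **Ties** break deterministically everywhere: smaller k in the index
  vote, smaller base-pair position in linkage bridging, first-seen order
  for equal cluster sizes.
* **Problem sizes in the shipped checks.** The test suite and the
  acceptance script exercise the pipeline at 40–500 loci, 10–50 accepted
  trajectories per locus, 200–500 cross simulations, and 400-locus
  clustering problems — sizes chosen so the full pipeline's statistical
  properties (FDR control, interval coverage, outlier calibration,
  cluster recovery) are measurable with Monte-Carlo error small relative
  to the tolerances being checked, while a complete run stays fast enough
  to be re-run habitually. The defaults of the user-facing functions are
  the full motivating-design sizes.
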