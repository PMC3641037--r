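---
title: "Dominant-marker phylogeography with aflpscape: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dominant-marker phylogeography with aflpscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

aflpscape analyses the population structure of a species scored with
anonymous dominant markers (AFLP band presence/absence) alongside a coding
mitochondrial alignment. Its question is the classic phylogeographic one:
is genetic variation structured into clusters separated by barriers, does
it accumulate smoothly with distance (isolation by distance, IBD), and do
rare long-distance dispersal (LDD) events and past range expansion leave
detectable signatures? This vignette documents the models behind each
stage, the parameters that matter, what the synthetic-data generator does
and does not emulate, and the numerical choices made where the design was
genuinely open.

## The admixture model for dominant markers

Bands are modelled as haploid Bernoulli characters. With `K` clusters,
individual `i` carries ancestry proportions `q_i` (a point on the
`K`-simplex, Dirichlet(`alpha`) prior); at each locus `l` a latent source
`z_il ~ Categorical(q_i)` picks the cluster whose band frequency
`p_kl ~ Beta(1, 1)` generates the observed band. All full conditionals are
conjugate, so `fit_admixture()` is a plain Gibbs sampler (implemented in
C++, seeded through R's RNG so runs are exactly reproducible). Posterior
means of `q` and `p` over post-burn-in sweeps are reported.

This deliberately simplifies the recessive-genotype treatment that
STRUCTURE applies to dominant data under Hardy-Weinberg assumptions. The
quantities the downstream analyses need — the number of clusters and the
individual memberships — are driven by cluster-specific band frequencies,
which the Bernoulli model captures directly; the package's validation
surface is recovery on synthetic data with known truth, not reproduction
of STRUCTURE's exact log-probabilities.

The per-run model log-probability reported to the cluster-number
diagnostic is `mean(lnL) - var(lnL)/2` over the post-burn-in trace, the
same penalised-mean family of estimator STRUCTURE prints.

**Choosing K.** `delta_k()` implements the Evanno statistic: the absolute
second difference of the mean model log-probability across consecutive
`K`, divided by the across-run standard deviation at `K`. The numerator
uses the second difference of per-K means (the common reading); the mean
of per-run second differences is available via `per_run_numerator = TRUE`.
Degenerate cases are defined explicitly: a linear profile gives 0, zero
run variance with non-zero curvature gives an `Inf` sentinel with a
warning, and the statistic is undefined at the grid edges.

The statistic is known to favour the uppermost level of hierarchical
structure. Two protocol choices matter and are exposed as arguments:

* **Runs per K.** The denominator is an across-run standard deviation;
  with fewer than ~6 runs it is itself so noisy that the argmax is
  unstable. The pipeline default is 6 runs of 300 burn-in + 200 kept
  sweeps per K over K = 2..8.
* **`alpha`.** With `alpha = 1` the model happily represents `K_true`
  clusters at smaller `K` by giving individuals fractional memberships,
  which flattens the log-probability profile and draws the Evanno maximum
  toward small K. The scan therefore defaults to `alpha = 0.2`, which
  favours near-pure ancestry — appropriate for taxa with distinct clusters
  and narrow contact zones. `fit_admixture()` itself keeps the neutral
  default `alpha = 1`.

**Cross-check.** `nmds()` (Kruskal stress-1 via vegan's monoMDS with a
classical-scaling start and jittered restarts) embeds the Jaccard
distances in two dimensions — two dimensions because that is what is
inspected visually and cluster recovery on the synthetic data does not
improve beyond it — and `gaussian_mixture_clusters()` fits
full-covariance Gaussian mixtures by EM (mclust), selecting K by BIC.
Agreement between the model-based and the assumption-free cluster count is
the package's internal consistency check.

## Distances

* **Jaccard** (`jaccard_matrix()`): `d = 1 - a/(a+b+c)` over band
  presences; loci missing in either individual are dropped from all three
  counts. A pair with no scorable information gets distance 0 with a
  warning rather than an error, so one bad pair does not kill a matrix.
* **Geographic** (`geographic_matrix()`): great-circle on the sphere
  (R = 6371.0088 km) by default. At a ~250 km island extent the choice
  between great-circle and an equirectangular projection shifts distances
  by well under 0.5%, which is why the projection used by the original GIS
  workflow does not need to be recovered exactly.
* **GTR+Γ** (`fit_gtr_gamma()`, `gtr_gamma_matrix()`): pairwise
  maximum-likelihood branch lengths under a general time-reversible model
  with 4-category discrete gamma rates (mean-per-category). Base
  frequencies are empirical counts; exchangeabilities and the gamma shape
  are shared across all pairs and estimated by maximising the sum of
  pairwise log-likelihoods. Branch lengths are profiled by an alternating
  scheme — initialise at Jukes-Cantor estimates, optimise the shared
  parameters with branch lengths fixed, re-optimise each pair's branch
  length, repeat three times — which converges to the same optimum as a
  nested optimisation at a fraction of the cost and is fully
  deterministic. Per-pair free shape parameters would not be identifiable
  and are not offered. For large alignments the fitting objective uses an
  evenly spaced subset of sequences (`max_fit_sequences = 30`); distances
  are always computed for every pair. Pairs with fewer than 50 comparable
  sites are reported as missing.

## Geographic concordance and variance partitioning

`anosim()` is the rank-based analysis of similarities:
`R = (rB - rW) / (M/2)` with mean tie-ranks, and a label-permutation p
with the +1 correction (a permutation p can never be exactly zero).
`anosim_pairwise()` runs every unordered group pair on its sub-matrix and
Bonferroni-corrects over the number of pairs; singleton groups are skipped
with a warning.

`dbrda()` implements the McArdle-Anderson form of distance-based
redundancy analysis: Gower-centre `G = C(-d^2/2)C`, take hat matrices of
column-centred predictors, and form
`pseudo-F = [tr(HGH)/m] / [tr((I-H)G(I-H))/(n-m-1)]`.
Negative eigenvalues of `G` (expected for Jaccard distances, which are not
Euclidean-embeddable) are kept in the traces, following the original
formulation; their share of total eigenvalue mass is reported as a
diagnostic rather than truncated away. With covariates the predictors are
residualised on the covariates, the denominator uses the joint hat matrix,
and permutation is Freedman-Lane style (permute the residualised
predictors, re-residualise, recompute); raw-row permutation is available
as an option because distance-based-regression software offers several
schemes and they differ only in higher-order accuracy. The geographic
predictors are latitude and longitude in decimal degrees, not projected
kilometres, matching common practice for this analysis.

`ibd_cluster_report()` composes the three analyses that together separate
IBD from subdivision: space alone, cluster dummies with space partialled
out (n-1 dummy columns; the nth would be redundant), and space within each
cluster separately. Clusters with fewer than 4 members are skipped — with
two spatial predictors and fewer than 4 points the residual degrees of
freedom are exhausted — and the skip is logged.

## The quartile screen for barriers and LDD

`screen_pairs()` flags pairs jointly extreme in the two distances: barrier
pairs sit in the top quartile of genetic and bottom quartile of geographic
distance; LDD pairs the reverse. The percentile convention is
nearest-rank with inclusive comparisons — deterministic under ties —
with linear interpolation available, since flagged-pair counts can hinge
on the convention. The screen is descriptive: no significance test is
attached, and pairs from the same locality (geographic distance 0) are
legal barrier candidates.

## Sequence tests

`fu_fs()` follows the original construction: estimate θ from the mean
pairwise difference (π, pairwise deletion), count distinct haplotypes
after removing alignment columns containing any gap (ambiguity codes
count as mismatches; both conventions are logged choices since reference
implementations do not document theirs), set `S'` to the Ewens-formula
probability of at least that many haplotypes, and report
`Fs = ln(S'/(1-S'))`. The Ewens distribution is built from unsigned
Stirling numbers of the first kind via the standard recurrence in log
space, exact and overflow-safe to large n. The p-value is the left-tail
probability under neutral constant-size coalescent simulations (C++, same
n, θ = π, infinite-sites haplotype counting), left-tailed because the
statistic is used as an expansion detector. θ is taken from all sites by
default; a silent-site-only estimate can be substituted by passing a
pre-filtered alignment.

`mcdonald_kreitman()` classifies each variable codon by enumerating
minimal mutational pathways between the two observed codon states and
averaging synonymous/nonsynonymous counts over orderings (paths through
stop codons are discarded unless all paths hit one). Strictness rules:
"fixed" requires monomorphism within both ingroup and outgroup; codons
with gaps or N, more than two states, outgroup polymorphism, or a mixture
of polymorphic and fixed sites in the same codon are excluded and logged
with reasons. The Fisher exact test is computed by direct hypergeometric
enumeration (two-sided: summing probabilities not exceeding the observed
table's).

## The association scan

`logistic_assoc()` fits presence ~ environment by ordinary logistic
regression and reports both the likelihood-ratio G and the Wald statistic;
`sam_scan()` calls a locus significant only when **both** fall below the
Bonferroni threshold `(1 - confidence)/n_tests` for at least one variable.
Complete or quasi-complete separation is detected (non-convergence,
fitted probabilities at the boundary, or runaway slope/SE) and the test is
skipped with a flag rather than rescued by penalised regression — the
scan's definition stays plain logistic regression. `n_tests` counts all
attempted locus-by-variable pairs by default; a switch recomputes the
threshold over completed tests only, and both counts are reported, because
the multiple-testing denominator used by legacy scan software is ambiguous
at exactly this point. Note the Wald statistic saturates for very strong
effects (the Hauck-Donner effect), so the dual gate is conservative at
genome-scan thresholds; this is a property of the test definition, not of
the implementation.

## The synthetic-data generator

`simulate_dataset()` builds the study conditions end to end: an elongated
250 × 60 km island cut into `n_clusters` longitudinal bands by linear
barriers, 84 sampling localities, and 100 individuals spread evenly over
the bands (a geographically stratified survey design).

* **Markers.** Cluster band frequencies are Beta(0.5, 0.5) — the U-shaped
  spectrum typical of scored dominant markers, clamped to (0.01, 0.99) so
  no locus is degenerate by construction. Within clusters, frequencies
  drift linearly with distance from the cluster centroid
  (`ibd_gradient_strength`, default 0.001 per km — a mild cline that
  leaves clusters recognisable). Individuals within
  `admixture_zone_width` (default 8 km) of a barrier draw each band from
  a mixture of the two adjacent clusters, a narrow contact zone: wider
  zones blur the cluster signal enough that no cluster-number diagnostic
  behaves sensibly. A fraction `ldd_rate` (default 0.02) of individuals is
  relocated to a locality beyond half the map diagonal with genotype
  unchanged — dispersal by passive transport moves animals, not allele
  frequencies.
* **Environment.** Environmental surfaces are low-order polynomials of
  the north-south coordinate plus noise, standardised at the localities.
  Running the gradients along the short axis keeps them orthogonal to the
  west-east cluster structure, so the association scan's null is clean by
  design; with environment confounded with structure, a univariate scan
  has no defence and flags hundreds of loci — a real limitation of the
  method, demonstrated rather than hidden if you rotate the surfaces.
  `n_env_selected_loci` loci (default 4) ignore cluster structure
  entirely: their band probability is logistic in the first variable with
  slope `env_effect_size` (default 2 per SD).
* **Sequences.** Each cluster's sample coalesces under exponential growth
  (`growth_factor`; waiting times by the standard time-rescaling), its
  root sequence sits on a deep branch (`cluster_divergence` = 0.02
  substitutions/site) from the common ancestor, and two outgroups branch
  off at `outgroup_divergence` = 0.15. Mutations carry a 4:1 transition
  bias; proposals creating stop codons are rejected and nonsynonymous
  proposals are accepted with probability `omega` (default 0.2) on every
  branch alike, so polymorphism and divergence have the same
  synonymous/nonsynonymous composition and the McDonald-Kreitman null
  holds by construction. The default sequence length is 633 bp — a codon
  multiple near the typical length of a barcoding fragment. Between-cluster
  migration during coalescence, recombination and indels are out of scope.

All randomness flows from a single seed through deterministic per-stage
seeds, so every output is byte-identical under a fixed configuration.

**What passing tests do and do not show.** The generator draws cluster
frequencies independently, so all cluster pairs are equally diverged *in
expectation* but not in realisation: with a few hundred loci, two clusters
can land close together by chance, which occasionally produces
false-positive "LDD" pairs between genuinely similar distant clusters and
can shift the Evanno maximum to a coarser level of structure. Real
dominant-marker datasets carry more loci (the motivating scale is >1300)
and their cluster divergences are shaped by shared history rather than
independent draws. Test problem sizes (100 individuals × 300 loci, K
scans over 2..8 with 6 runs, permutation counts in the hundreds) are the
package's desk-scale choices; all of them are arguments, not constants.

## Numerical conventions

* Permutation p-values always use the +1 correction.
* Nearest-rank percentiles break quartile ties deterministically.
* The Gibbs sampler, coalescent simulator and all generators draw from
  R's RNG (also from C++), so `set.seed()` governs everything.
* Ewens probabilities, Stirling numbers and Fisher tail sums are computed
  in log space.
* Jaccard pairs with no comparable loci, single-haplotype alignments, and
  zero-variance delta-K denominators all produce explicit sentinels with
  warnings instead of silent NaNs.

## Known limitations

* The dominant-marker admixture model ignores diploidy; membership
  proportions are comparable to, but not numerically identical with,
  recessive-genotype STRUCTURE output.
* The Evanno diagnostic inherits its known bias toward the uppermost
  hierarchical level; on iid-frequency synthetic data with few loci its
  replicate-to-replicate argmax is noticeably noisier than on strongly
  differentiated empirical data.
* The association scan performs no correction for population structure;
  its clean behaviour on the synthetic data depends on the designed
  orthogonality of environment and structure.
* Coalescent p-values for Fu's Fs assume infinite sites; at very high θ on
  short sequences, recurrent mutation makes them slightly conservative.
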