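---
title: "Trait-based functional groups of mesozooplankton: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait-based functional groups of mesozooplankton: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(planktraits)
```

## The analysis in one paragraph

Mesozooplankton communities can be described not by who is there but by
what the organisms *do*: their body size class, how they feed, what
trophic role they play, and how they reproduce. `planktraits` codes each
taxon by one modality per trait across four categorical traits, measures
pairwise ecological distance between taxa with Gower dissimilarity,
clusters them into functional groups with Ward's minimum-variance
agglomeration, screens taxa for numerical dominance, tabulates the
relative abundance of taxa, trait modalities and functional groups by
season and station, and relates functional-group abundances to
hydrography (temperature, salinity, chlorophyll *a*) with redundancy
analysis (RDA). A seeded simulator generates seasonal cruise data with
known (planted) structure so every stage can be validated end to end.

## Trait coding

Four traits with a closed vocabulary of 17 modalities: body length class
(small < 1 mm, medium 1–2 mm, large 2–5 mm, giant > 5 mm; boundaries are
half-open and lower-inclusive, so a 2.0 mm copepod is *large*), feeding
type (active ambush, passive ambush, current, mixed), trophic group
(carnivore, omnivore, omnivore–carnivore, omnivore–herbivore,
omnivore–detritivore), and reproductive mode (free spawner, egg
brooding, parthenogenesis, alternation of generations).
`encode_traits()` produces a binary species × modality matrix with
exactly one 1 per trait block per species; matrices violating the
one-hot structure are rejected rather than silently reinterpreted.
Planktonic larvae, which cannot be trait-coded at species level, are
carried in abundance tables but excluded from trait analyses through an
explicit exclusion list — never by a name heuristic.

## Gower dissimilarity

For purely categorical one-hot data, Gower dissimilarity reduces to a
scaled mismatch count, and there are two defensible column weightings:

* `categorical_traits`: `d = m / 4`, `m` = number of traits that differ;
  every trait carries equal weight (the default);
* `binary_columns`: `d = (1/17) Σ|x_a − x_b|`, every binary column
  carries equal weight, which weights the 5-modality trophic block
  slightly more.

On one-hot input the two are exactly proportional, `d_bin = (8/17)
d_cat`, and because Ward tree topology is invariant to uniform positive
rescaling of the input, both modes produce the identical dendrogram.
This is asserted in the test suite, so the choice is cosmetic here; both
are kept because they stop being equivalent the moment a user adds a
non-categorical trait upstream.

## Ward clustering

`ward_cluster()` implements the Lance–Williams recurrence. The default
`ward.D2` variant squares the input dissimilarities before the
recurrence and reports heights on the original scale, which is the
common default of modern hierarchical-clustering workflows applied to
Gower matrices; the classic unsquared `ward.D` is available behind a
flag. Gower dissimilarities on categorical data are not Euclidean, so
Ward's variance interpretation is approximate either way — the method is
used here, as in practice, as a variance-motivated agglomeration
heuristic.

Determinism matters for reproducible group numbering, so exact cost ties
are broken by merging the pair whose clusters were created earliest
(smallest creation indices, row before column). Trait matrices generate
many exact ties (all distances are multiples of 1/4), which is why the
tie rule is part of the contract and not an implementation detail. The
merge sequence is checked in the tests against a from-scratch oracle
that recomputes the Ward cost of every candidate merge from the raw
pairwise squared dissimilarities at every step, and against
`stats::hclust` on tie-free random instances.

`cut_tree(dendrogram, k)` undoes the last `k − 1` merges and numbers
groups by decreasing size (ties by first species appearance), so group 1
is always the largest group.

## How many groups? The elbow rule

`elbow_select()` computes the within-cluster dispersion
`wss(k) = Σ_clusters (1 / 2n_c) Σ_{i,j∈c} d²_ij` along the dendrogram's
nested partitions for `k = 2..k_max` (default `k_max = min(n − 1, 15)`)
and selects `k` in two stages:

1. **Zero floor.** If some `k` attains numerically zero dispersion, the
   smallest such `k` is selected. When `k` clusters already explain all
   dispersion, every larger `k` is redundant and the curve's bend is
   exactly at the floor; a pure curvature rule can otherwise be
   distracted by steep early descent and pick a smaller `k` even when a
   perfect partition exists.
2. **Maximum curvature.** Otherwise the `k` in `3..k_max − 1` maximizing
   the second difference `wss(k−1) − 2 wss(k) + wss(k+1)` is selected.

The full curve is always returned, and `run_pipeline()` accepts a `k`
override, because the elbow is ultimately a reading aid: practitioners
inspect the curve, and an automated rule is only a reproducible
operationalization of that inspection.

## The packaged fixture and what recovery tests show

`table3_fixture()` builds a deterministic, seed-free 98-species trait
table whose eight groups (sizes 30, 7, 29, 12, 9, 2, 3, 6) carry the
trait-modality sets of the published eight-group summary for the South
Yellow Sea mesozooplankton. Two variants exist, and the distinction is a
deliberate design decision:

* `coverage = "full"` assigns modalities per-trait round-robin so that
  *every* listed modality of every group is represented (per-trait
  rather than cartesian enumeration, because a group of 2 species must
  still display 2 feeding and 2 trophic modalities). This variant feeds
  encoding checks, group summaries and the community simulator.
* `coverage = "modal"` gives every species of a group the group's single
  representative profile, producing eight internally homogeneous planted
  profiles.

Cluster-recovery checks (adjusted Rand index 1 at `k = 8`, elbow
selecting 8) use the **modal** variant. With full modality coverage the
planted partition is *not* recoverable by any equal-weight
distance-based clustering — the largest group spans profiles differing
in three of four traits, while between-group neighbors can differ in
only one — and that is informative in itself: the published groups
summarize a dendrogram fitted to one particular species pool, not a
separable planted structure. Passing recovery tests on the modal fixture
therefore demonstrates correctness of the clustering machinery, not that
any 98-species pool with these modality sets would cluster into these
eight groups.

## Dominance and composition

Dominance of species *i* in a season is `Y = (n_i/N) · f_i`: its share
of the summed abundance over that season's stations times its occurrence
frequency (fraction of stations with abundance > 0; presence means
strictly positive standardized abundance, no detection-limit threshold).
`Y ≥ 0.02` flags a dominant species, threshold inclusive. `Y` is
invariant to uniform rescaling of abundances and to station reordering.

The packaged dominance table of the twelve recurrent dominant taxa
stores the *printed* seasonal `Y` values of the source survey and the
package counts dominants from them as given. The printed values are not
exactly recomputable from the printed abundances under any convention
for `n_i/N` and `f_i` (e.g. a printed spring `Y` of 0.52 against an
abundance share of ≈ 0.35 would force `f_i > 1`), so recomputing them
would be a pretense of precision; threshold counting is the check the
data supports. Abundances printed as "< 0.1" and dominance values
printed as "< 0.01" are stored as midpoints (0.05, 0.005) and flagged
`below_detection`; no threshold decision rests on a flagged value.

Composition tables normalize summed abundance within each season or
station over the mapped, non-excluded species, so shares always sum to 1
within a stratum. The seasonal mean-abundance summary is normalized over
its component taxon groups; the printed grand totals are carried for
reference but are not used as denominators because the autumn components
do not sum to the printed total in the source.

## Redundancy analysis

Functional-group abundances are `ln(x + 1)`-transformed and
column-centered; predictors are standardized. Natural log is used: the
base only rescales centered columns by a constant and cancels in the
explained fraction, so the choice is cosmetic for the statistics
reported here. Constant predictors are dropped; perfect collinearity is
pruned by repeatedly dropping the later column of the most correlated
pair, with a warning naming the casualties.

The fit is the multivariate regression `Ŷ = Z(ZᵀZ)⁻¹ZᵀY`; constrained
axes are the singular axes of `Ŷ`, residual axes those of `Y − Ŷ`, and
eigenvalues are squared singular values over `n − 1`, so constrained
plus unconstrained eigenvalues sum to the total variance of the
transformed response (asserted to 1e−9 relative in the tests). The
explained fraction `trace(ŶᵀŶ)/trace(YᵀY)` is reported for all
constrained axes; the first two axes dominate in practice but the
package does not conflate "explained by the constraints" with
"displayed in a biplot".

One score convention is supported, deterministically: site scores `U D`,
species scores `V diag(d)/√(n−1)` (covariances with the unit-variance
axes, i.e. correlation-style scaling), biplot scores = correlations of
standardized predictors with site scores, and axis signs fixed so the
largest-magnitude species loading per axis is positive. Configurable
scalings multiply conventions without adding information.

Significance is assessed by `rda_permutation_test()`: station rows of
the response are permuted, the explained fraction recomputed, and
`p = (1 + #{perm ≥ obs}) / (1 + n_perm)`. Its type-I error at nominal
0.05 is verified to lie in [0.01, 0.10] over 200 null simulations in the
acceptance tests.

## The cruise simulator

`simulation_config()` defaults describe the study conditions the
analysis assumes: three seasonal cruises of 11/16/16 stations; the
98-species pool of the full-coverage fixture in its eight planted
groups; seasonal environment draws `Normal(mean, sd)` per variable with
the published seasonal means and standard deviations for temperature and
chlorophyll (salinity summaries were not published numerically, so
regional values with surface slightly above bottom salinity were chosen
once: spring 31.5/31.2, summer 31.0/30.6, autumn 31.8/31.4, sd ≤ 0.8);
chlorophyll truncated at 0.

Abundance follows a presence-thinned log-normal: species `s` of group
`g` at station `i` is present with the group's seasonal occupancy
probability, and if present has abundance
`max(exp(μ_g + Σ_v β_gv z_iv + ε) − 1, 0)`, `ε ~ N(0, 0.6)` on the log
scale. The planted coupling matrix `β` transcribes the reported
group–environment correlation signs (group 1 positive on SST and
surface chlorophyll; group 2 positive on SST, negative on surface
salinity; group 3 positive on SST; group 4 positive on SST and surface
chlorophyll; group 5 positive on SST and bottom temperature; group 6
positive on SST and surface chlorophyll; groups 7–8 uncoupled) at
magnitude 0.8, a strong effect appropriate for parameter-recovery
validation. Baselines `μ = (4.0, 1.0, 0.5, 1.5, 1.0, 1.5, 0.5, 0.0)`
make the omnivore–herbivore group hold well over 60% of total
abundance, as observed in the field. Occupancy peaks in summer for the
warm-season groups (cladocerans, detritivores, gelatinous carnivores),
mirroring the reported seasonality.

What the simulator does *not* emulate: spatial autocorrelation between
stations, hydrographic water-mass structure, larval ontogeny,
species-level (as opposed to group-level) environmental responses, and
zero-inflation beyond independent Bernoulli occupancy. Passing recovery
tests on simulated cruises therefore validates the estimators under the
assumed generative structure; they do not certify performance on field
data with spatially structured noise.

All generators are deterministic under the config seed; the community
stream uses `seed + 1` so environment and community draws are
independent streams.

## Numerical choices and degenerate inputs

* Dissimilarity validation: symmetry to 1e−12, zero diagonal, values
  finite and non-negative; `n < 2` is an error for clustering.
* Ward heights are monotone by reducibility of the Ward update; the
  tests assert non-decreasing heights to 1e−10.
* The elbow zero floor uses a relative tolerance of `1e−10 · max(wss(2),
  1)`.
* `wilcoxon_rank_sum()` enumerates all `C(n, n_x)` assignments exactly
  for pooled `n ≤ 12` — enumeration remains valid under ties because
  mid-ranks are fixed — and otherwise uses the normal approximation with
  tie and continuity corrections; the two agree within 0.05 at `n = 6 +
  6` in the tests. Zero-variance degenerate cases return `p = 1`.
* One-way ANOVA requires at least two observations per season and is run
  on untransformed abundances.
* Newick serialization labels internal nodes `m1..m(n−1)` so a re-import
  restores the exact merge order; bare newick cannot order tied merge
  heights, which trait data produce in quantity. Leaf order is supplied
  at import because newick does not record it.

## Problem sizes

The validation suite runs at deliberately modest sizes chosen to
exercise every code path: Ward-oracle equivalence on 100 random
instances of up to 10 items; recovery on the 98-species fixture;
parameter recovery over 20 simulated 43-station cruise sets;
permutation-test calibration over 200 null datasets at 199 permutations.

## Known limitations

* The elbow rule is an operationalization of a visual heuristic; for
  curves with two comparable kinks the reported curve, not the selected
  `k`, is the trustworthy output.
* Ward on non-Euclidean Gower input has no strict variance
  decomposition; group shapes are driven by the mismatch metric.
* The dominance convention (`n_i/N` as share of summed abundance, `f_i`
  as occurrence frequency) is the standard one in the regional
  literature, but printed dominance values in the packaged summary are
  internally inconsistent with it, so they are used as given.
* Per-season RDA with 11–16 stations and six predictors is close to
  saturation; the pooled analysis is the stable one, and the package
  warns when `n < p + 2`.
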