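# planktraits

Trait-based analysis of mesozooplankton community structure.

Community ecologists increasingly describe zooplankton not by taxonomy
alone but by functional traits — body size, feeding strategy, trophic
role, reproductive mode — because traits, not names, determine how a
community moves carbon and responds to hydrography. `planktraits`
implements that workflow end to end for seasonal cruise data:

1. **Trait coding.** Each taxon gets one modality per trait across four
   categorical traits (4 body-length + 4 feeding + 5 trophic + 4
   reproductive modalities); `encode_traits()` builds the binary
   species × trait matrix.
2. **Functional groups.** `gower_dissimilarity()` measures trait
   distance (for one-hot traits, a scaled mismatch count);
   `ward_cluster()` runs Ward agglomeration via the Lance–Williams
   recurrence with deterministic tie-breaking; `elbow_select()` picks
   the number of groups from the within-cluster dispersion curve;
   `cut_tree()` yields the groups.
3. **Dominance.** For species *i* over a season's stations,
   `Y = (n_i/N) · f_i` — abundance share times occurrence frequency —
   with `Y ≥ 0.02` flagging dominant species (`dominance()`,
   `count_dominant_taxa()`).
4. **Composition.** Relative abundance of taxa, trait modalities, or
   functional groups per season or station (`composition()`), plus
   per-station functional richness (`functional_richness()`).
5. **Group–environment relationships.** `rda_fit()` performs redundancy
   analysis of `ln(x + 1)`-transformed group abundances on standardized
   hydrographic predictors (SST, SBT, SSS, SBS, surface/bottom
   chlorophyll *a*), reporting eigenvalues, explained variance, and
   site/species/biplot scores; `rda_permutation_test()` supplies a
   permutation p value.
6. **Seasonal tests.** `anova_seasons()` (one-way F) and
   `wilcoxon_rank_sum()` (exact enumeration for small samples, tie- and
   continuity-corrected normal approximation otherwise).

A seeded simulator (`simulation_config()`, `generate_env()`,
`generate_community()`) produces three-cruise datasets (11/16/16
stations) with planted functional groups and group–environment
couplings, and `table3_fixture()` provides a deterministic 98-species
trait table whose eight groups mirror a published South Yellow Sea
functional-group summary. `run_pipeline()` orchestrates everything from
a config list or YAML file and writes per-stage artifacts.

## Worked example

```r
library(planktraits)

## eight functional groups from the planted-profile fixture
fx   <- table3_fixture(coverage = "modal")
d    <- gower_dissimilarity(fx$trait_matrix)
dend <- ward_cluster(d)
(el  <- elbow_select(d, dend))
#> elbow_curve: k in 2..15, selected k = 8 (zero_floor)
groups <- cut_tree(dend, el$selected_k)
head(summarize_groups(groups, fx$assignments)[, 1:3])
#>   group size                                     taxa
#> 1     1   30           Copepods; Cumaceans; Tunicates
#> 2     2   29 Ctenophores; Hydromedusae; Siphonophorae
#> 3     3   12                                 Copepods
#> 4     4    9                      Copepods; Ostracods
#> 5     5    7     Amphipods; Chaetognaths; Polychaetes
#> 6     6    6            Decapods; Euphausiids; Mysids

## dominant taxa from the packaged seasonal dominance summary
pub <- published_dominance()
count_dominant_taxa(split(pub, pub$season))
#> [1] 12

## simulated cruises: group abundances vs hydrography
cfg <- simulation_config(seed = 1)
env <- generate_env(cfg)
com <- generate_community(cfg, env)
ga  <- group_abundance(com$abundance, com$truth$groups)
rda_fit(ga, env$values)
#> rda_result: 6 constrained axes, 90.8% variance explained
round(rda_fit(ga, env$values)$biplot_scores[, 1:2], 2)
#>        RDA1  RDA2
#> SST    0.97 -0.16
#> SBT    0.59 -0.43
#> SSS   -0.36  0.18
#> SBS   -0.35  0.18
#> SChla  0.50  0.82
#> BChla -0.11  0.12
```

Reading the output: the elbow rule finds the zero-dispersion floor at
`k = 8`, i.e. eight clusters already explain all trait dispersion of
the planted profiles, and the recovered groups (numbered by decreasing
size) carry the expected taxa. Twelve taxa cross the `Y ≥ 0.02`
dominance threshold in at least one season of the packaged summary. On
the simulated cruises the six hydrographic variables explain ~91% of
the variance in log group abundance, and the biplot scores point the
planted way: axis 1 is a temperature axis (SST 0.97) separating warm
summer communities, axis 2 a surface-chlorophyll axis (SChla 0.82).

## Learn more

The methods vignette (`vignettes/functional-groups.Rmd`) documents the
model conventions (Ward variant, elbow rule, RDA score scaling), the
simulator's assumptions and defaults, the design decisions behind the
packaged fixtures, and known limitations.
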