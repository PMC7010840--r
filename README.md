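# endosurvey

Community analysis of culturable endophytic fungus surveys: from
segment-level isolation records to colonization statistics, constrained
ordination, and permutation-based host/tissue preference tests.

## What it is for

Surveys of culturable endophytes incubate surface-sterilized tissue
segments — for example 10 halophyte species x 10 individuals x 2 tissue
types (stem, root) x 8 segments = 1600 segments — and record which fungal
taxon (if any) emerges from each. `endosurvey` is for the people who run
such surveys and need the downstream statistics reproducible and tested:

* **Survey metrics** — colonization rate (infected / incubated segments),
  per-sample richness, relative abundance — with the standard comparison
  battery (one-way ANOVA + Tukey HSD with compact letters, tie-corrected
  Kruskal–Wallis + Dunn, Welch *t*).
* **Community composition** — canonical correspondence analysis and
  distance-based PermANOVA (Bray–Curtis or Jaccard), both implemented from
  first principles with an exact-enumeration mode for small designs.
* **Host/tissue preference** — the package's core. From a binarized sample
  x taxon matrix collapsed to a plant-species x taxon co-occurrence
  ("species-level") matrix it computes, against a plant-label-shuffling
  permutation null (1000 shuffles by default):

  * the Kullback–Leibler specialization index
    *d*ʹ = (*d* − *d*min) / (*d*max − *d*min), with
    *d* = Σⱼ *p*ʹᵢⱼ ln(*p*ʹᵢⱼ/*q*ⱼ), *d*max = ln(*m*/*A*ᵢ) and the exact
    discrete *d*min,
  * **standardized *d*ʹ** = (*d*ʹobs − mean *d*ʹrand) / SD *d*ʹrand per
    plant species and per fungal taxon, and
  * the **two-dimensional preference** z-score per (plant, fungus) pair,
    2DP(i, j) = (Nobs(i, j) − mean Nrand(i, j)) / SD Nrand(i, j),

  with permutation and normal-tail p-values and Benjamini–Hochberg FDR
  control in three separate families (plants, fungi, pairs). Rare taxa
  (below a 5%-prevalence floor) are flagged and kept out of the FDR
  families because their shuffled counts are too discrete for stable
  z-scores.
* **A synthetic survey generator** with the study design above as its
  default, controllable colonization probabilities and per-taxon
  host/tissue preference weights — the ground-truth test bed for
  everything else.

## Worked example

```r
library(endosurvey)

cfg <- surveyConfig(seed = 1L)   # 10 species x 10 ind x {stem, root} x 8 segments
sv  <- generateSurvey(cfg)
sv
#> SurveyTable: 1600 segment records
#>   10 plant species, 30 fungal taxa
#>   colonized segments: 904 (56.5%)

cr <- colonizationRate(sv)
anovaOneway(cr$colonization_rate, cr$plant_species)
#> one-way ANOVA: F = 31.92, p = 1.335e-33
#>   note: shapiro_p=0.09328; levene_p=0.1224
```

The species effect on colonization is strong by construction: the default
generator gives each species its own stem and root colonization
probability. Community partition:

```r
stm <- sampleTaxonMatrix(sv, mode = "count")
fac <- as.data.frame(SummarizedExperiment::colData(stm))[, c("tissue", "plant_species")]
permanova(stm, fac, nPermutations = 999, seed = 1)
#> PermANOVA (bray_curtis, 999 permutations)
#>           term  df sum_of_squares r_squared pseudo_f p_value
#>         tissue   1         0.3628  0.006216    1.229   0.285
#>  plant_species   9         5.1761  0.088679    1.949   0.001
#>       residual 179        52.8298  0.905105       NA      NA
#>          total 189        58.3687  1.000000       NA      NA
```

Plant species structure the community (R² = 0.089, p = 0.001, the smallest
attainable value at 999 permutations); tissue does not here, because the
default generator varies colonization *rates* by tissue but draws taxa
from the same pool in stems and roots. Preference analysis:

```r
pref <- preferenceAnalysis(sv, nPermutations = 1000, seed = 1)
pref
#> PreferenceResult (1000 permutations, seed 1)
#>   plant-axis d': 10 species, 0 with P_FDR < 0.05
#>   fungus-axis d': 30 taxa, 0 with P_FDR < 0.05
#>   pairwise 2DP: 300 pairs, 3 with P_FDR < 0.05

pp <- as.data.frame(pairPreferences(pref))
head(pp[order(pp$p_fdr), c("plant_species", "taxon", "n_observed",
    "null_mean", "two_dp", "p_fdr", "flag")], 4)
#>     plant_species    taxon n_observed null_mean two_dp    p_fdr flag
#> 21       plant_01 taxon_01          1     10.48  -4.61 0.000725   ok
#> 170      plant_10 taxon_10          9      2.99   3.82 0.011803   ok
#> 40       plant_10 taxon_03         15      7.66   3.66 0.015081   ok
#> 111      plant_01 taxon_02          2      8.56  -3.12 0.080132   ok
```

`taxon_01` occurs in only 1 of the 20 `plant_01` samples against a null
expectation of 10.5 — a strong apparent avoidance (2DP = −4.6). This
survey was generated with *neutral* preference weights: the signal comes
from `plant_01` having the lowest colonization probability, a confound of
label-shuffling preference tests on hosts with unequal colonization that
the methods vignette discusses. To plant and recover a true preference,
use `plantPreference(cfg, "taxon_03", "plant_01", weight = 10)` on a
`nullConfig()` background.

A pipeline wrapper `runPipeline()` (and a thin CLI at
`inst/scripts/endosurvey`) chains simulate → metrics → ordination →
preference from a YAML config and writes TSV/JSON outputs plus a
reproducibility manifest.

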