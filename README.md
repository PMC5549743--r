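# divgrad

Hierarchical diversity analysis of herb-layer communities sampled along
crossed gradients of elevation and forest-use intensity.

Field surveys of this kind record the presence or absence of species in
replicate plots nested inside habitats (old-growth `OG`, degraded `DE`,
secondary `SE` forest), themselves nested inside locations spread along an
elevational transect. `divgrad` provides the complete analysis chain for
such data:

- **α/γ richness** — per-plot species counts and pooled species richness per
  habitat cell and per location (γ = richness of the union over a
  location's plots).
- **Pairwise β-diversity** — the Sørensen dissimilarity
  β = 1 − S with S = 2C/(A + B), where A and B are the richnesses of two
  plots and C their shared species. Plot pairs are enumerated within
  habitats (all n(n−1)/2 pairs per cell) and between habitats (full n_a ×
  n_b cross products), pooled by the six habitat transitions
  (OG-OG … SE-SE), and summarised with bootstrap standard errors obtained
  by resampling plots within each contributing cell.
- **Multiplicative partitioning** — γ = ᾱ · β_w · β_b per location, where
  ᾱ is mean plot richness, β_w = ᾱ₂/ᾱ (ᾱ₂ = mean pooled habitat
  richness) is the effective number of distinct plots per habitat, and
  β_b = γ/ᾱ₂ the effective number of distinct habitats. The product
  reconstructs γ exactly.
- **Hill-number diversity profiles** — empirical and asymptotic
  (undersampling-corrected) effective species numbers ^qD for incidence
  data over q = 0, 0.25, …, 3, including the bias-corrected Chao2
  richness estimator at q = 0.
- **Gradient GLMs** — 31 candidate models per response (α richness with a
  negative-binomial family, endemic proportion with a beta family,
  pairwise β with a log-normal family) over elevation, elevation²,
  habitat/transition, MAT, MAP and their interactions, ranked by AICc with
  a deviance-based pseudo-R².
- **Synthetic landscapes** — a generator that reproduces the nested design
  and its assumed statistical structure (hump-shaped richness along
  elevation, Gaussian elevational species ranges, habitat-driven turnover,
  elevation-dependent endemism), so every stage runs and is testable with
  no external data.

The central object is `IncidenceExperiment`, an S4 class extending
Bioconductor's `SummarizedExperiment` (binary species × plots assay, plot
metadata as `colData`, species attributes as `rowData`).

## Worked example

```r
library(divgrad)

ie <- simulateLandscape(landscapeConfig(seed = 42))
ie
#> IncidenceExperiment: 264 species x 120 plots
#>   locations: 8 (50, 650, 1000, 1500, 2100, 2500, 3100, 3500)
#>   habitats:  OG, DE, SE
#>   presences: 821; empty plots: 13

gammaRichness(ie)
#>   50  650 1000 1500 2100 2500 3100 3500
#>    5   29   39   61   89   87   72   36

transitionMeans(ie, exclude_locations = "50", reps = 200, seed = 3)
#>   transition mean_beta         se n_pairs                    locations_used
#> 1      OG-OG 0.8495983 0.04499923      70 650;1000;1500;2100;2500;3100;3500
#> 2      OG-DE 0.9210061 0.01099882     175 650;1000;1500;2100;2500;3100;3500
#> 3      OG-SE 0.9165018 0.01246519     175 650;1000;1500;2100;2500;3100;3500
#> 4      DE-DE 0.8810841 0.04487124      70 650;1000;1500;2100;2500;3100;3500
#> 5      DE-SE 0.9209730 0.01092364     174 650;1000;1500;2100;2500;3100;3500
#> 6      SE-SE 0.9074290 0.04568389      70 650;1000;1500;2100;2500;3100;3500
```

Richness pools peak at mid-to-high elevation (here 89 species at 2100 m,
87 at 2500 m, against 5 species in the semi-arid lowland belt), and every
between-habitat transition is more dissimilar than every within-habitat
one — compositional turnover, not plot richness, is what forest-use
intensity moves. The location pools decompose multiplicatively:

```r
multiplicativePartition(ie, "2500")
#>   location alpha_bar alpha2_bar beta_w   beta_b gamma defined
#> 1     2500  13.33333   47.33333   3.55 1.838028    87    TRUE
```

(13.3 species per plot × 3.55 effective plots per habitat × 1.84 effective
habitats = 87 = γ, exactly.) Asymptotic diversity profiles quantify how
much of each pool the 15 plots missed:

```r
f <- incidenceFrequencies(ie, plotIDs(ie)[plotData(ie)$location == "2500"])
asymptoticHillProfile(f, q = c(0, 1, 2))
#>   q empirical asymptotic
#> 1 0  87.00000  116.08889
#> 2 1  73.77916   99.84274
#> 3 2  64.30868   88.46761
```

AICc-ranked model selection recovers the hump-shaped elevation signal in
plot richness:

```r
sel <- runModelSelection(ie, "alpha")
head(sel$ranking, 2)
#>                       terms family k   n    loglik     aicc pseudo_r2 delta_aicc  best
#> 1 elev + elev2 + map + map2 nbinom 6 120 -247.6430 508.0293 0.8018678   0.000000  TRUE
#> 2              elev + elev2 nbinom 4 120 -253.5875 515.5228 0.7792119   7.493420 FALSE
```

`runPipeline()` chains every stage from one (YAML-able) configuration and
writes all tables plus a run log:

```r
out <- runPipeline(list(simulate = TRUE, seed = 42, reps = 1000,
                        out_dir = "results/run1"))
```

## Documentation

See the methods vignette (`vignettes/diversity-gradients.Rmd`) for the
statistical background: the comparison schemes, the bootstrap, the
partition identities, the asymptotic estimators, the candidate-model
scheme, and what the synthetic generator does and does not emulate.
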