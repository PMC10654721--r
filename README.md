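# rotapest

Does growing a more diverse sequence of crops reduce pesticide use?
`rotapest` is an R package for analysts of farm-network data (cropping
systems described field by field over time) who want to quantify
temporal crop diversification and relate it to pesticide reliance. It
implements the full analysis chain:

1. **Diversity indicators** per cropping system and time point, built on
   Hill numbers of order 1, `¹D = exp(−Σ pᵢ ln pᵢ)`, with the
   decomposition into functional diversity (effective number of
   botanical families, FD) and taxonomic diversity (average effective
   number of crops per family, `¹D_TD = Σ p_k · ¹D_k`, TD), plus the
   diversity of sowing periods and cover-crop frequency.
2. **Treatment Frequency Index** (TFI): pesticide applications at the
   full recommended dose, `TFI = Σ (Dᵢ·Sᵢ)/(Dhᵢ·S_t)` over spray
   operations, with seed-coating (+1.0 point), biocontrol-exclusion and
   reference-dose rules, decomposed into herbicide / fungicide /
   insecticide components.
3. **Space-for-time check**: PERMANOVA of the Bray–Curtis composition
   matrix on cropping-system identity with permutations restricted to
   climatic regions, multivariate dispersion diagnostics (principal
   coordinates + spatial medians), and a balanced-subset robustness
   analysis.
4. **Dilution and regulation models**: Tweedie (compound Poisson–Gamma,
   1 < p < 2) log-link regressions of crop-level TFI on climatic region,
   crop, diversity indicators and cover-crop frequency, with AIC
   candidate selection, type III Wald tests, marginalized means,
   FDR-adjusted pairwise contrasts with compact letters, per-crop slope
   tests and raw-scale percent-change effects.
5. A **synthetic network generator** with known ground truth whose spray
   decomposition round-trips exactly through the TFI scorer, used to
   validate every stage end to end.

## Worked example

```r
library(rotapest)

# the worked three-crop composition: wheat 0.5, barley 0.25, pea 0.25
comp <- c(winter_wheat = 0.5, winter_barley = 0.25, spring_pea = 0.25)
hill_shannon(comp)
#> [1] 2.828427
decompose_diversity(comp)[c("fd", "td_arith", "td_geom")]
#> $fd        [1] 1.754765
#> $td_arith  [1] 1.667411
#> $td_geom   [1] 1.611855
```

2.83 effective crops split into 1.75 effective families times 1.61
effective crops per family (geometric weighting is exact:
1.754765 × 1.611855 = 2.828427); the arithmetic TD (1.67) is the
conventionally reported indicator. A spray at half the reference dose
over 40 % of a field contributes `0.5 × 0.4 = 0.2` TFI points:

```r
spray_tfi_contribution(dose = 0.75, reference_dose = 1.5,
                       treated_ha = 4, field_area_ha = 10)
#> [1] 0.2
```

A full simulated analysis:

```r
gen <- generate_network(simulation_config(n_systems = 60, seed = 1))
head(diversity_profiles(gen$dataset$fields), 4)
#>   system_id time_point hill_d    fd td_arith cover_crop_freq ...
#> 1   sys0001       tp01  4.131 1.895    2.319             0.5
#> 2   sys0002       tp01  5.000 4.131    1.267             0.1
#> 3   sys0003       tp01  4.353 3.596    1.267             0.3
#> 4   sys0004       tp01  4.131 4.131    1.000             0.3
head(compute_tfi(gen$dataset), 4)
#>   system_id        crop tfi_total  tfi_h tfi_f tfi_i ...
#> 1   sys0001 durum_wheat    1.6628 0.0000  0.00 0.000
#> 2   sys0001   grassland    0.0154 0.0154  0.00 0.000
#> 3   sys0001      potato    4.0755 1.0000  2.08 1.000
#> 4   sys0001  spring_pea    2.3408 1.0000  0.00 0.341
```

`sys0001` grows potato with a total TFI of 4.08 (2.08 of it fungicide),
while its grassland receives almost nothing — the contrast that drives
dilution effects. The whole pipeline (indicators → TFI → filters →
stability → dilution → regulation) runs from one call:

```r
report <- run_full_analysis(list(
  simulate = list(n_systems = 100),
  out_dir = "out", seed = 1, n_permutations = 1000))
report$stability$permanova$r_squared   # variance explained by system id
```

A thin CLI wrapper lives at `inst/cli/rotapest.R`
(`Rscript rotapest.R simulate|all ...`).

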