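# camtrapniche

Spatiotemporal niche analysis for camera-trap surveys of sympatric mammals.

When a species is reintroduced into a landscape that already supports an
ecologically similar native — the motivating case is a reintroduced grazing
antelope (oryx) alongside a native gazelle in an arid steppe park — managers
need to know whether the two partition space, time, or both. This package
implements the standard camera-trap workflow for that question, end to end,
on plain CSV tables:

1. **Independence filtering.** Photo events of the same species at the same
   camera are collapsed to independent detections with the conventional
   ≥ 30-min rule (the window restarts at each *retained* event).
2. **Relative activity indices.** RAI1 = detections per 100 camera-days per
   site (spatial); RAI2 = detections per 100 camera-days per calendar month,
   pooled across years (temporal). Welch *t*-tests compare species; one-way
   ANOVA with Tukey HSD tests seasonal variation.
3. **Habitat-suitability multimodel inference.** After a Spearman
   collinearity screen (|ρ| < 0.7), all 2^p Gaussian GLMs of per-site RAI1
   on habitat covariates are ranked by small-sample AICc,
   `AICc = −2ℓ + 2k + 2k(k+1)/(n−k−1)`, with Akaike weights
   `w_i = exp(−Δ_i/2)/Σ exp(−Δ_j/2)`. Per predictor the package reports the
   selection probability (summed weights of containing models), the
   conditional model-averaged coefficient, and its unconditional SE.
4. **Spatial niche overlap.** Pianka's index on the per-site RAI1 vectors:
   `O = Σ p_i q_i / √(Σ p_i² · Σ q_i²)` ∈ [0, 1].
5. **Temporal niche overlap.** Detection times are mapped to radians
   (24 h = 2π) and smoothed with a von Mises kernel density estimator whose
   concentration comes from a plug-in rule designed for multimodal diel
   data. The overlap coefficient Δ is the area under the pointwise minimum
   of the two densities, estimated by Δ̂1 (grid integration; used when the
   smaller sample has < 75 detections) or Δ̂4 (density-ratio averaging at
   the observed times; both samples ≥ 75), with smoothed-bootstrap 95%
   confidence intervals and the conventional strength classes
   (strong > 0.75, moderate 0.5–0.75, low < 0.5).
6. **Diel-period selection.** A sunrise/sunset calendar partitions each day
   into crepuscular (±1 h around sunrise and sunset), diurnal and nocturnal
   periods; selection ratios `w_i = o_i/π_i` compare use against
   availability, with a month-replicated ANOVA for non-random use.

A synthetic survey generator with exact ground truth (known per-site
Poisson rates, known diel mixtures, known true overlap) backs every stage
with parameter-recovery tests.

## Worked example

```r
library(camtrapniche)

survey <- simulate_survey(synthetic_config(), seed = 42)
survey
#> Synthetic camera-trap survey: 26 cameras, 17300 camera-days, 2821 detections (oryx, gazelle)

res <- run_pipeline(survey, pipeline_config(seed = 42))

res$species_share
#>   species     n share
#> 1 oryx     1699  60.4
#> 2 gazelle  1116  39.6

res$temporal_overlap[, c("period", "n1", "n2", "estimator", "delta", "strength")]
#>   period              n1    n2 estimator delta strength
#> 1 winter 2020-2021   188   143 dhat4     0.901 strong
#> 2 spring 2021        185   113 dhat4     0.905 strong
#> 3 summer 2021        189   147 dhat4     0.674 moderate
#> 4 fall 2021          214   133 dhat4     0.844 strong
#> ...

tidy(res$habitat_fits[["oryx winter 2020-2021"]])
#>   predictor selection_probability coefficient       se
#> 1 SC                        0.158   0.0120    0.0623
#> 2 FC                        0.793   0.171     0.0735
#> 3 GC                        1.000   0.238     0.0487
#> ...
```

The default synthetic scenario gives the grass-driven species (oryx) higher
detection rates at grassy sites and both species crepuscular dawn/dusk
activity with a summer nocturnal shift for oryx — so the pipeline reports
exactly the qualitative pattern the method is designed to expose: high
temporal overlap (Δ̂4 ≈ 0.64–0.92, lowest in summer), lower spatial
overlap, grass cover (`GC`) as the top-supported oryx predictor
(selection probability 1.00 above), and crepuscular selection ratios
above 1. Seasonal spatial overlap sits in `res$spatial_overlap`,
diel-period ratios in `res$diel_selection`; with `out_dir=` every table is
also written as CSV.

Per-stage functions (`filter_independent()`, `rai1()`, `habitat_mmi()`,
`pianka()`, `overlap_delta()`, `selection_ratio()`, ...) are exported for
piecemeal use, and result objects have `tidy()`, `glance()`, `autoplot()`
and `plot_overlap()` methods. See the methods vignette
(`vignettes/camtrapniche-methods.Rmd`) for the statistical details and
design choices.

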