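# paleoseas

Seasonal paleotemperature reconstruction from sequentially sampled tooth
enamel oxygen isotopes.

Archaeological faunal teeth record a sub-annual climate archive: enamel
mineralizes progressively along the growth axis, so δ18O measured on
sequential drill strips traces the seasonal cycle of the animal's
drinking water and, through it, of local air temperature. `paleoseas`
turns such intra-tooth δ18O series into summer, winter and mean-annual
temperature estimates, and reproduces the supporting analyses such
studies rely on: inter-layer statistics, strontium-isotope locality
screening and bone-collagen environmental summaries.

## The model

Each tooth's series is fit by least squares with a seasonal sinusoid
along the growth axis,

δ(x) = M + A·sin(2πx/λ + φ),

profiling the wavelength λ and solving the remaining linear problem
exactly. Series whose amplitude is indistinguishable from noise are
excluded. Summer-peak and winter-trough values (fitted `M ± A`, or the
most extreme observed samples near the fitted extremum locations — the
default) are corrected for the amplitude damping caused by enamel
maturation and drill-strip averaging,

f = |sinc(L_mat/λ)| · |sinc(L_samp/λ)|,  A_corrected = A / f,

and converted to temperature through two affine calibrations (enamel
phosphate → drinking water → air temperature), stored as published in
either direction and inverted exactly. Every temperature carries a
Monte-Carlo compound error propagating measurement, fit and calibration
uncertainty. A synthetic-data generator inverts the whole chain as a
forward model, so every stage is testable with known truth and no
external data. The methods vignette
(`vignettes/enamel-paleoseasonality.Rmd`) documents the model,
parameters, defaults and limitations.

## Worked example

```r
library(paleoseas)

sc  <- paper_like_scenario(seed = 101L)   # 3-layer, 13-tooth study design
sim <- simulate_isotopes(sc)              # enamel, Sr, collagen + truth

run <- run_seasonality_pipeline(
  sim$enamel, sc$cal,
  maturation_length = sc$maturation_length,   # 12 mm
  sample_length     = sc$sample_length,       # 1.5 mm drill strips
  sr = sim$sr, collagen = sim$collagen,
  baseline = sr_baseline(0.7106, 0.0004),     # local plant 87Sr/86Sr
  n_mc = 2000, seed = 1L,
  reference = c(T_warmest_month = 20.5, T_coldest_month = 4.9)
)
run
#> Seasonality run: 13 teeth in 3 layers (1 excluded as non-sinusoidal), method = observed, damping on
#>   excluded: 2-T1
#> Layer temperatures (tooth-mean route):
#> # A tibble: 3 × 14
#>   layer_id route      n_teeth T_warmest_month_mean T_warmest_month_sd
#> 1 2        tooth_mean       4                 21.9              1.22
#> 2 5A       tooth_mean       4                 22.3              0.782
#> 3 5B       tooth_mean       4                 19.8              0.713
#> # ... T_coldest_month_mean, MAT_mean, compound errors, delta vs modern
```

One tooth was planted with no seasonal signal and is excluded by the
amplitude-vs-noise classification. Reconstructed warmest-month means sit
near the 20.5 °C modern reference the scenario encodes; the
winter-specific statistics recover the planted colder-and-more-variable
winters of the oldest layer:

```r
glance(run)
#>   n_teeth n_layers n_excluded anova_winter_p levene_winter_p winter_range  seed
#> 1      13        3          1        0.00154           0.618         3.07     1

run$stats$effect_sizes
#>   season      contrast       d     (earlier layer minus later; negative d =
#> 1 summer      2 vs 5A  -0.416      winter d18O rises from Layer 2 to 5A)
#> 2 winter      2 vs 5A  -3.00
#> 3 mean_annual 2 vs 5A  -1.73
#> ...

run$stats$winter_collagen_correlation
#>        r r_squared         p     n pairing
#> 1 -0.846     0.715 0.0000370    16 per_specimen
```

The winter ANOVA p of 0.0015 and the large negative winter effect size
(d = −3.0 for Layer 2 vs 5A) reflect the planted 3 °C winter contrast;
the winter-δ18O–collagen-δ13C correlation (R² = 0.72 across 16
specimens) reflects the planted coupling between winter temperature and
the plant baseline. `plot_seasonal_profiles()`, `plot_layer_seasons()`
and `plot_temperatures()` draw the per-tooth fits, the per-layer
seasonal ribbons and the temperature reconstruction with error bars.

Real data enter the same way through `read_samples()` (CSV; schemas in
its help page), `read_calibration()` (YAML; template in
`inst/extdata/calibration_template.yml`) and `run_from_config()`.

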