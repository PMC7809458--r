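---
title: "Reconstructing paleoseasonality from intra-tooth enamel δ18O"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing paleoseasonality from intra-tooth enamel δ18O}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoseas)
library(dplyr)
```

## The problem and the model

Large herbivore teeth mineralize progressively along the growth axis over
roughly one to two years, so enamel drilled in sequential strips records a
time series of the animal's body-water oxygen isotope composition. Body
water tracks drinking water, drinking water tracks precipitation, and
precipitation δ18O at mid latitudes tracks air temperature. An intra-tooth
δ18O series from a non-migratory animal is therefore a sub-annual local
climate archive: its oscillation records the seasonal temperature cycle
the animal lived through.

`paleoseas` models each tooth's series as a sinusoid along the growth
axis,

$$\delta(x) = M + A \sin\!\left(\frac{2\pi x}{\lambda} + \phi\right),$$

with vertical offset $M$ (the annual mean), amplitude $A$ (half the
seasonal range), wavelength $\lambda$ (the length of crown formed in one
year) and phase $\phi$ (birth seasonality). The fitted summer peak,
winter trough and their average — the mean annual value, computed the same
way modern mean annual temperatures are built from monthly extremes — are
the per-tooth seasonal estimates on which all downstream inference runs.

Fitting profiles the residual sum of squares over $\lambda$: at fixed
wavelength the model is linear in $(M, A\cos\phi, A\sin\phi)$ and solved
exactly, so the only nonlinear dimension is searched on a log grid
(default 200 points spanning a third of a cycle to three cycles over the
sampled extent) and refined locally. This avoids the initialization
sensitivity of a joint four-parameter nonlinear fit on a dozen points.

### Deciding whether a series is seasonal at all

Not every tooth yields a usable cycle; non-seasonal series must be
excluded rather than over-interpreted. Two guards apply. First, the fit
itself is flagged unconverged when the amplitude does not clear a noise
floor estimated from the second differences of the raw series (and from
the analytical replicate sd when the table carries one). The second
differences matter: a free wavelength search will happily absorb pure
noise into a spurious low-amplitude sinusoid, *deflating* the residual sd,
but it cannot deflate the curvature of the raw data. Second,
`classify_series()` labels a fit non-sinusoidal when $A < k \cdot
\mathrm{resid\ sd}$ with $k = 2$ by default — an explicit, reproducible
version of the "clearly visible cycle" judgement. Excluded teeth are
listed in the run report and never reach the seasonal statistics.

### Extracting extremes

Two extraction rules are provided because published studies typically
picked peaks and troughs by eye and the choice is consequential.
`method = "fitted"` returns $M \pm A$, the smoothed-curve extremes;
`method = "observed"` (the pipeline default, since visual picking tracks
measured extreme samples) returns the most extreme observed value within a
quarter wavelength of a fitted extremum location. Either way an extreme is
reported only when the fitted sinusoid actually places that extremum
inside the sampled span: partial series yield `peak_only` or
`trough_only`, and the mean annual value exists only when both extremes
do. Series longer than one cycle contribute their single most extreme peak
and trough.

## Damping and its correction

Enamel does not mineralize instantaneously. A finite length of crown
matures simultaneously, and each drilled strip averages a further length
along the growth axis. Both act as uniform moving-average windows on the
seasonal input, attenuating the recorded amplitude. For a sinusoid, a
uniform window of width $L$ scales the amplitude by
$|\mathrm{sinc}(L/\lambda)|$ with $\mathrm{sinc}(x) = \sin(\pi x)/(\pi
x)$, so the combined damping factor is

$$f = \left|\mathrm{sinc}\!\left(\frac{L_{mat}}{\lambda}\right)\right|
      \cdot
      \left|\mathrm{sinc}\!\left(\frac{L_{samp}}{\lambda}\right)\right|,$$

and the correction inflates the recorded half-seasonality by $1/f$ around
the (damping-invariant) mean annual value. The uniform-window form is the
package's documented model; `damping_factor()` is a small exposed surface
so that alternative attenuation coefficients — e.g. taxon-specific
geometries including appositional angle — can be substituted without
touching the rest of the pipeline. Two safeguards apply: the correction is
refused when the total window reaches the wavelength (the factor
approaches its first zero and the recorded cycle is unreliable) and when
$f$ falls below a floor (default 0.3), since dividing by a small factor
amplifies noise without bound.

No default window lengths are shipped. Maturation length is a
physiological quantity that differs between taxa and tooth positions, and
inventing a silent default would masquerade as ground truth; the run
configuration must state it. The worked examples use 12 mm maturation and
1.5 mm strip height against a 35 mm annual wavelength ($f \approx 0.81$),
plausible values for large bovid cheek teeth.

## From δ18O to temperature

Two affine stages convert corrected extremes to temperature: enamel
phosphate to drinking water, and drinking water (≈ precipitation) to air
temperature. Calibrations are stored *as published*, in either direction,
and inverted exactly — a regression published as phosphate-on-water loses
nothing in transcription. By default the annual-scale
precipitation–temperature map is applied to the seasonal extremes; a
configuration switch accepts separate warm- and cold-season regressions
when a user has them. Because the maps are affine, the mean annual
temperature equals the map of the mean annual δ value exactly, and
per-layer aggregation by averaging tooth temperatures coincides with
mapping layer-mean δ — both routes are still reported, because they
diverge as soon as seasonal maps or partial teeth enter.

No calibration coefficients are hard-coded as truth.
`example_calibration()` ships a synthetic but field-plausible set (a
large-bovid phosphate–water relation, slope 0.94 and intercept 23.3 ‰ in
the water-to-phosphate direction; a mid-latitude
precipitation–temperature relation, 0.58 ‰ per °C with intercept
−13.6 ‰), used by the examples, tests and generator; real analyses
transcribe their own coefficients through the YAML template in
`inst/extdata/`.

### Compound error

Every reconstructed temperature carries a Monte-Carlo compound error:
draws jointly perturb the input δ18O (measurement plus fit uncertainty,
one sd), the published coefficients of both stages (standard errors, with
slope–intercept covariance when provided) and the residual scatter of
each regression. The default report is the MC standard deviation
(`coverage` switches to central-interval half-widths); the default is
10,000 draws under a caller-supplied seed, and the analytic
$|a_1 a_2|\sigma$ affine case is retained as a test oracle. Monte Carlo
was chosen over first-order analytic propagation because it handles the
nested, possibly inverted calibrations and asymmetric intervals uniformly.

## Supporting analyses

*Inter-layer statistics.* Seasonal values are summarized per layer in
stratigraphic order (sd reported as absent, not zero, for singleton
layers); winter values get a one-way fixed-effects ANOVA, Levene's test
(deviations about the mean by default, median optionally), Tukey HSD with
the Tukey–Kramer adjustment for unbalanced groups, and a qqnorm-style
quantile table with a Shapiro–Wilk companion that never gates the
pipeline. Cohen's d uses the pooled sd with $(n-1)$ weights and no
small-sample correction, signed earlier-layer-minus-later so that a rise
in winter δ18O from an older to a younger layer is negative. The
winter-δ18O–collagen-δ13C correlation pairs each collagen specimen with
its layer's mean winter value by default (`per_layer` means are the
alternative); the per-specimen mode is the default because it preserves
the collagen sample size rather than collapsing to one point per layer.

*Provenance screening.* A tooth is accepted as local when all its
87Sr/86Sr measurements fall within the bioavailable plant baseline mean
± 3 sd — the overlap argument made quantitative and configurable — and
sequential Sr measurements are additionally checked for intra-tooth
homogeneity against the analytical sd, flagging seasonal movement.
Collagen is screened on the standard atomic C:N integrity window
(2.9–3.6, configurable).

## The synthetic-data generator

`seasonal_scenario()` inverts the inference chain as a forward model:
per-layer warmest/coldest-month temperatures (with tooth-level jitter for
inter-individual and inter-annual variability, default sd 0.9 °C) map
through the exact inverse calibration to an enamel sinusoid, which is
attenuated with the same moving-average forward model, sampled at
near-regular jittered positions (drill strips are near-regular; the
jitter exercises irregular-spacing handling), and perturbed with 0.2 ‰
Gaussian analytical noise — the typical replicate reproducibility of
enamel phosphate measurements. Birth phase is uniform on $[0, 2\pi)$
since birth seasonality is not modeled. Sr values are drawn around a
local baseline (with optional planted migratory excursions) and collagen
values per layer.

`paper_like_scenario()` fixes a study-design template: three layers
("2", "5A", "5B") with 5/4/4 teeth of 14 samples each (~180 samples),
one planted non-seasonal tooth, a seven-tooth Sr subset (~15
measurements) around 0.7104 ± 0.0003, and 28 collagen specimens across
layers 1–5B whose δ13C means run opposite to winter temperature (warmer
→ lower δ13C). The temperature regimes — 21.5/1.5 °C (Layer 2), 21.0/4.5
(5A), 20.5/3.5 (5B) — encode mild conditions near the modern southwest
France reference (July 20.5 °C, January 4.9 °C), winters above freezing,
the coldest and most variable winters in the oldest layer, and a slight
5A→5B cooling. Spans are drawn from 0.9–1.4 annual cycles so partial
series occur.

What passing tests on generated data do show: the estimator chain
(fit → classify → extract → damp-correct → transfer) recovers planted
layer temperatures within a few tenths of a degree at analytical noise,
correctly excludes planted non-seasonal teeth, flags planted migrants,
and preserves planted effect signs. What they do not show: robustness to
features real enamel adds — non-stationary growth rate along the crown
(wavelength drift), aridity or water-source shifts decoupling δ18O from
temperature, diagenesis, and calibration error beyond the stated
coefficient uncertainties. Those are scientific caveats of the method,
not of the implementation.

## Numerical choices

- Wavelength search: log grid of 200 points on `span/3`–`3*span`,
  refined with a bracketed 1-D optimizer; a wavelength pinned to the
  search boundary marks the fit unconverged.
- The forward convolution uses fractional edge weights so non-integer
  window/spacing ratios carry no rounding bias; it refuses signals
  sampled coarser than 50 points per cycle.
- Extremum coverage: an extremum location within half a mean sample
  spacing beyond the sampled ends still counts as covered (`edge_tol`).
- Duplicate drill positions are averaged on read with a warning; rows
  violating field invariants are rejected with row-level diagnostics
  rather than failing the load.
- Positions are measured from the enamel–root junction, increasing
  occlusally; readers flip occlusal-referenced tables per tooth.
- All Monte-Carlo stages draw from a private RNG stream seeded from the
  run seed (sub-seeds per tooth/quantity), leaving the caller's RNG state
  untouched; fixed seed implies byte-identical outputs.

Problem sizes used in the shipped tests and the acceptance script — 20
generator seeds for recovery checks, 1,000–10,000 MC draws, dense grids
of 200–500 points per cycle — were chosen as the smallest sizes at which
the checked quantities are stable to well within their tolerances.

## A worked run

```{r run}
sc <- paper_like_scenario(seed = 101L)
sim <- simulate_isotopes(sc)
run <- run_seasonality_pipeline(
  sim$enamel, sc$cal,
  maturation_length = sc$maturation_length,
  sample_length = sc$sample_length,
  sr = sim$sr, collagen = sim$collagen,
  baseline = sr_baseline(0.7106, 0.0004),
  n_mc = 2000, seed = 1L,
  reference = c(T_warmest_month = 20.5, T_coldest_month = 4.9)
)
run
glance(run)
run$stats$effect_sizes
```

```{r plots, fig.width = 7, fig.height = 5}
plot_seasonal_profiles(run$fits)
plot_layer_seasons(run$estimates)
plot_temperatures(run$tooth_temperatures,
                  reference = c(T_warmest_month = 20.5,
                                T_coldest_month = 4.9))
```

## Known limitations

- The sinusoid assumes a constant growth rate along the sampled crown;
  real enamel extension decelerates cervically, which biases $\lambda$
  and, mildly, the extreme positions. Inverse models with explicit growth
  curves are out of scope.
- The damping model treats both averaging windows as uniform and
  one-dimensional; appositional geometry is only representable through
  substituted effective window lengths.
- Temperature estimates inherit every assumption of the affine
  calibrations (animal physiology, drinking behavior, source-water and
  circulation stability); the compound error quantifies stated
  coefficient uncertainty, not structural error in those assumptions.
- Layer-level inference treats teeth as independent; repeated sampling of
  one individual across teeth is not modeled.
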