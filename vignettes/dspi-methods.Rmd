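---
title: "Models and methods behind dspi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dspi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dspi)
```

This vignette is the package's own account of the science it implements:
the photosynthesis–irradiance (PE) model and its fitting, the
saturation-time and production-index computations, the mixed-model
layer, and the synthetic-study generator — including the places where
the design was genuinely open and the choices we made there.

## The yield-normalized Webb model

PAM fluorometry measures the effective quantum yield of photosystem II,
$\Phi_{PSII}$, at each actinic step of a rapid light curve (RLC). Yields
fall with irradiance by construction, so fitting a PE model to
electron-transport rates ($E \cdot \Phi$) builds the predictor into the
response. We instead fit the Webb exponential-saturation model in its
irradiance-normalized form,

$$\Phi(E) = \alpha \frac{E_k}{E}\left(1 - e^{-E/E_k}\right),
  \qquad \Phi(0) = \alpha,$$

directly to the observed yields. $\alpha$ (dimensionless) is the
light-limited efficiency, $E_k$ (µmol photons m⁻² s⁻¹) the saturation
irradiance, and the maximum rate is the exact product
$P_{max} = \alpha E_k$ (µmol electrons m⁻² s⁻¹). Assumptions: no
photoinhibition term (the nine-step protocol tops out at
820 µmol photons m⁻² s⁻¹ and runs ~5 min, too short for strong
down-regulation), and no absorption factor, so ETRs are *relative*.

Numerical choices, all visible in `fit_webb()`:

* **The dark step participates.** $\Phi(0) = \alpha$ is the continuous
  limit of the model, so the $E = 0$ reading informs the fit rather
  than being discarded; it is the single most informative point for
  $\alpha$.
* **Bounded Levenberg–Marquardt.** Start values are
  $\alpha_0 = \Phi$ at the lowest nonzero irradiance and $E_{k,0}$ =
  the irradiance where $\Phi$ first drops below $\alpha_0/2$
  (fallback 100); bounds $\alpha \in (10^{-6}, 2]$,
  $E_k \in (10^{-3}, 2000]$; convergence at $10^{-15}$ relative SSE
  change, 500 iterations. On noiseless 9-point curves this recovers
  parameters to ~$10^{-13}$, and on noisy curves it matches an
  exhaustive grid search plus simplex polish (the test suite checks
  both).
* **Unweighted least squares.** The normalization is itself the
  variance stabilization: yields have roughly constant noise across
  steps, unlike ETRs.
* **Failure semantics.** Optimizer non-convergence is reported in the
  fit object (`converged = FALSE`), never thrown. A curve whose yields
  are all zero — a depigmented plant that cannot sustain a usable
  fluorescence signal — raises a classed condition and is excluded
  downstream, mirroring how such individuals are removed from real
  studies.

`compute_retr_max()` applies the classical reliability screen: only
steps with $\Phi_{PSII} > 0.1$ may contribute, and the largest
$E \cdot \Phi$ among them is reported. At an exact tie the lower
irradiance wins — a conservative rule that avoids crediting a
photoinhibited plateau; the screen boundary is strict (a step at
exactly 0.1 never qualifies).

## From logger trace to H_sat

The irradiance module assumes a logger writing one PAR sample per
minute from 05:00 to 19:30 (≤ 871 samples/day), with times handled as
integer minutes since midnight — wall-clock local, no timezone
arithmetic anywhere.

* `condense_series()` takes a **trailing** 10-min moving average (the
  window ends at the labelled minute; loggers report at the end of an
  averaging interval) and keeps only the values at clock minutes :00,
  :10, …, :50. A window extending before the first sample uses what is
  available.
* `day_length()` is (number of condensed samples ≥ 1 µmol photons
  m⁻² s⁻¹) × 10 min. The 1-µmol threshold defines "time available for
  photosynthesis"; condensation smooths dawn/dusk flicker out of the
  count.
* `hsat_day()` counts minutes with $E \geq E_k$ on the **raw** 1-min
  trace — condensation is a day-length device only, and saturation is a
  threshold crossing better resolved at native resolution.
* Period mapping (`assign_period_ek()`): E_k is measured on days 1, 5
  and 9 only, so days 1–3 use the D1 estimate, 4–5 the D5, 6–9 the D9
  (`standard`); plants without a D5 curve use D1 for days 1–4 and D9
  for days 5–9 (`no_d5`). The pipeline applies the fallback per plant
  automatically.
* Window truncation: a plant's first experiment day starts at its D1
  RLC timestamp and its last day ends at its final RLC timestamp
  (experiments begin ~08:00 on day 1 and end by noon on day 9);
  intermediate days use the full logged span. Windows beyond the logged
  span are clipped with a warning.

**An averaging ambiguity, made explicit.** "A mean over the three
periods" can be read as the mean of the three period means (periods of
3, 2 and 4 days weighted equally) or as the mean over all nine days.
`mean_hsat()` defaults to the period-mean reading — it is the literal
reading of a period-wise procedure — but exposes `mode = "all_days"`,
and the pipeline carries the switch (`hsat_mean_mode`) so either
convention is one configuration away. The same pair of modes exists for
DSPI (`dspi_mean_mode`), where the default is the opposite
(`all_days`), because there the daily values themselves are the stated
object of averaging. Neither choice is asserted as the historically
correct one.

rel-H_sat is computed as the mean over days of the per-day percentage
$100\,H_{sat}(d)/\mathrm{daylength}(d)$ (days with zero day length are
excluded with a warning), rather than as a ratio of means; per-day
ratios keep each day's quotient inside [0, 100] by construction.

## DSPI and growth

The diurnal saturated photosynthesis index assumes the plant runs at
$P_{max}$ for exactly its saturated minutes:

$$\mathrm{DSPI}_d = P_{max}(\mathrm{period}(d)) \times 60 \times
  H_{sat}(d) \times 10^{-6} \;\; [\mathrm{mol\ m^{-2}}],$$

with the factor 60 converting $P_{max}$ from per-second to per-minute
and $10^{-6}$ from µmol to mol; the final index averages the daily
values. It deliberately ignores respiration and other non-irradiance
losses — it is an upper-envelope production index, not a carbon budget,
and electrons are not converted to carbon.

Growth over the 9-day run is
$100\,((w_f - m_p) - w_i)/w_i$ with $w_i, w_f$ the initial and final
wet weights and $m_p$ the wet mass of any epiphytic parasite removed at
final weighing. No exponential-growth assumption is made; the plain
percent change is the response.

## The mixed-model layer

Every response (P_max, E_k, H_sat, rel-H_sat, DSPI, growth) is
modelled per species as fixed effects of treatment and temperature with
random intercepts for plant identity, run, RLC measurement order and
lunar phase. Decisions:

* **ML, not REML.** All fits feeding likelihood-ratio tests are maximum
  likelihood: REML likelihoods are not comparable across fixed-effect
  structures.
* **LRTs against the term-free null.** $\chi^2 = 2(\ell_f - \ell_r)$
  clipped at zero; df = difference in fixed-parameter counts (the
  random structure is held identical between full and null), so a
  5-level treatment tests on 4 df and a 3-level temperature on 2 df.
  `lrt()` refuses non-nested fixed parts, differing data sizes, or
  differing random structures.
* **Singularity fallback.** One observation per plant makes the
  plant-level variance inherently confounded with the residual, and
  small variance components routinely hit the boundary. Singular fits
  shed random terms one at a time — lunar phase, then RLC order, then
  run — refitting after each; plant identity is never dropped, and a
  fit that remains singular is returned flagged, not errored. Grouping
  factors with a single sampled level are set aside up front.
* **Reference levels.** Treatment T0 (ambient-ocean baseline) and the
  coolest temperature, so coefficients read as effects of enrichment
  and warming.
* **R².** Nakagawa–Schielzeth for Gaussian identity links: marginal =
  fixed-effect variance over (fixed + random + residual); conditional
  adds the random-intercept variance to the numerator. The invariant
  $R^2_m \le R^2_c \le 1$ is asserted in tests.
* **No multiple-testing correction** — p-values are reported raw, one
  LRT per stated effect.

`fit_growth_regressions()` supplies the simple per-predictor OLS
screens, and `growth_dspi_lmm()` the growth ~ DSPI model with treatment
as a random intercept (collapsing, with a warning, to OLS when only one
treatment is present).

## What the generator emulates — and what it does not

`simulate_study()` reproduces the statistical *structure* the analysis
assumes: a 6-treatment × 3-temperature × 16-replicate design per
species with paired replicates sharing one of 8 runs; removal of all
Ulva T2.5 replicates and of two depigmented Hypnea individuals (240 and
286 analysable plants); per-plant (α, E_k) as cell means plus plant
intercepts plus an upward drift over the run (D1 = 0.85×, D5 = 0.95×,
D9 = 1×: plants acclimate, and the published treatment means are D9
values); Gaussian yield noise (SD 0.01) clipped into [0, 1]; half-sine
daylight of 611–688 min centered in the logging window, scaled by an
unshaded 1400 µmol peak × 0.5 shade-cloth transmission, with AR(1)
multiplicative cloud noise; and growth linear in true DSPI
(12.2 %/unit) with a treatment-level random intercept.

Calibration constants come from the published D9 treatment means:
per-treatment E_k equals those means exactly (Ulva 27.2 → 110.4 across
the gradient), and mean α is the implied ratio $P_{max}/E_k$ **capped
at 0.78**. The cap is a physical necessity: yields cannot exceed 1, yet
ratios of reported cell means exceed 1 in the lowest-nutrient cells
(mean-of-ratios and ratio-of-means need not agree), and an uncapped α
would interact with yield clipping to bias every fit. The Ulva T2.5
generating mean is a synthetic interpolation of T2 and T3 (those rows
are generated only to be excluded). The temperature effect is a
multiplier on α for Hypnea only (1.12 / 0.95 / 0.93 at 20/27/30 °C),
expressing its cool-water advantage; Ulva is temperature-neutral in the
generator.

One seed drives one generator in a fixed draw order (design exclusions
→ plant parameters → RLC yields → irradiance → growth), so studies are
bit-reproducible; true DSPI is computed between the irradiance and
growth stages with the package's own deterministic saturation code.

The generator does **not** emulate: realistic cloud statistics or
spectral effects (true H_sat means under a half-sine sky are higher
than field values at the same E_k), tidal or lunar coupling to light,
nutrient-uptake or salinity physiology (treatment effects enter only
through the calibrated means), temperature dynamics of the baths,
photoinhibition, or non-photochemical quenching. Passing tests
therefore demonstrate that the *pipeline* recovers what the generator
put in — parameter recovery, calibrated test size, CI coverage,
qualitative treatment orderings — not that any ecological conclusion
about real plants is reproduced.

## Problem sizes and test design

The suite checks exact recovery on noiseless curves (100 random
parameter pairs), agreement with independent direct-loop oracles for
condensation, day length, H_sat and DSPI (50 seeded random traces),
type-I error of the treatment LRT under a null generator (500
replicates of a 4-replicate-per-cell design, acceptance band
0.03–0.07), 95%-CI coverage of the growth~DSPI slope (200 replicates,
band 93–97%), qualitative treatment orderings on one full calibrated
study (adjacent treatment means may reverse by at most twice the
standard error of their difference — the calibrated means are closer
together than one plant-level SE in places, so strict sample-mean
monotonicity is not implied by the generator itself), and byte-identity
of identically seeded pipeline runs. These sizes keep the whole suite
around a minute on a single core while leaving Monte-Carlo error well
inside each acceptance band.

## Known limitations

* α and E_k are fitted independently per curve; no shrinkage across
  plants or days, so single-curve estimates carry full sampling noise
  into H_sat via the period map.
* The Φ > 0.1 screen is a hard threshold; near-threshold yields flip
  rETR_max discontinuously.
* H_sat is a per-minute count, so it quantizes at 1 min; day length
  quantizes at 10 min by construction.
* The LRT is asymptotic; at 4 replicates per cell its measured size
  sits near the top of the 0.03–0.07 band, consistent with the known
  mild anticonservatism of ML likelihood-ratio tests at small n.
* DSPI in mol m⁻² is electrons, not carbon, and ignores respiration;
  comparisons are internally consistent but not absolute production
  estimates.
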