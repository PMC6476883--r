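# shiverkit

Toolkit for quantifying thermogenesis in cold-exposed neonates that lack
brown adipose tissue — for example newborn wild boar piglets, where heat
production must come from shivering and from muscle nonshivering
thermogenesis (SERCA1a/sarcolipin-mediated ATP hydrolysis). The package
covers the three computational stages of such a study and ships synthetic
generators with known ground truth so the whole pipeline can be validated by
parameter recovery.

## What it computes

**Shivering from tri-axial accelerometry.** The resultant acceleration
a(t) = √(aₓ² + a_y² + a_z²) is cut into consecutive 6-s windows, each window
is mean-removed (removing the gravity component) and Fourier-transformed,
and the maximum amplitude and its frequency are extracted inside the
shivering band. The band defaults to 10–30 Hz, bracketing the allometric
prediction for shivering frequency,

log₁₀ f = 1.85 − 0.18 log₁₀ m   (f in Hz, m in g),

which gives 18.56 Hz (rounded) for a 1700 g piglet. Shivering intensity is the mean
over windows of the in-band maximum amplitude.

**Heat production from open-flow respirometry.** A shared O₂/CO₂ analyzer
cycles over six chambers plus a reference channel (one minute each). The
package demultiplexes the trace, discards a per-slot washout, corrects each
chamber reading against the interpolated reference baseline, and computes

VO₂ = FR · [(FiO₂ − FeO₂) − FeO₂ (FeCO₂ − FiCO₂)] / (1 − FeO₂)

(pull mode, water vapour scrubbed, CO₂ not scrubbed, flow metered
excurrent). Per measurement, VO₂ is the mean of the three lowest consecutive
slot values inside the analysis interval (minutes 10–40), converted to heat
as W = VO₂ · 20.1 J ml⁻¹ / 3600.

**Mixed-effects inference.** Responses (SERCA activity, gene expression,
body temperature, shivering, heat) are modelled with `nlme::lme` using
animal ID nested in mother as random intercepts, optional per-day residual
variances, type-II Wald χ² tests per fixed term, Shapiro–Wilk residual
diagnostics with optional Box-Cox transformation, a marginal pseudo-r², and
generalised-least-squares partial (added-variable) regressions whose slopes
equal the multiple-regression coefficients.

## Worked example

```r
library(shiverkit)

# simulate a shivering recording: 18 Hz tremor, amplitude 2 m/s^2,
# bursts interrupted by suspension phases, sensor noise, 4 mg quantization
sim <- gen_accel_trace(tremor_spec(tremor_freq = 18, tremor_amp = 2,
                                   tremor_axis = "gravity",
                                   duration_s = 300, seed = 1))
res <- analyze_shivering(sim$trace, mass_g = 1700,
                         analysis_start_s = 60, analysis_duration_s = 240)
res$summary
#> # A tibble: 1 x 5
#>   animal_id day   intensity mean_freq n_windows
#>   <lgl>     <lgl>     <dbl>     <dbl>     <int>
#> 1 NA        NA         1.59      18.1        40
```

The recording alternates shivering bursts (mean 20 s) with suspension
pauses (mean 5 s), so the mean in-band peak amplitude (1.59 m/s²) sits
below the burst amplitude of 2 m/s² in proportion to the suspended time;
the mean peak frequency sits within a spectral bin (1/6 Hz) of the
generated 18 Hz.

```r
# respirometry: six chambers with known VO2, recovered from the gas trace
g <- gen_gas_trace(chamber_spec(true_vo2_ml_h = seq(800, 1800, 200), seed = 1))
sm <- session_metabolic_summary(g$trace, fr_l_per_h = 250)
round(sm$summary$vo2_ml_per_h)
#> [1]  798 1000 1197 1399 1598 1799
round(sm$summary$heat_W, 2)
#> [1]  4.46  5.58  6.68  7.81  8.92 10.05

# inference: day effect on SERCA activity in a synthetic cohort
tab <- gen_cohort(cohort_spec(seed = 1))$table
fit_mixed(tab, model_spec("serca_activity", "day", weights_by_day = TRUE))
#> <shiver_fit> serca_activity ~ day
#>   day: chi^2 = 255.711, df = 1, p = 0.0000
#>   marginal pseudo-r^2 = 0.898
```

The recovered VO₂ values sit within 1% of the generated truth, the heat
column is exactly VO₂ × 20.1/3600, and the mixed model detects the injected
day-1 → day-5 increase in SERCA activity (0.36 → 0.96) against the nested
mother/animal random structure.

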