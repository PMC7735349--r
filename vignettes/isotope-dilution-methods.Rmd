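---
title: "Isotope-dilution body composition and water turnover: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isotope-dilution body composition and water turnover: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isodilute)
```

## The measurement model

isodilute implements the deuterium dilution-and-depletion workflow used to
estimate body composition and daily water flux in large mammals that cannot
be measured destructively. An animal ingests a small dose of heavy water
(²H₂O) scaled to its body mass; the tracer mixes into the body-water pool
within hours and is then washed out by normal water turnover. Blood
enrichment sampled over the following days carries two pieces of
information:

1. **Pool size.** Back-extrapolating the washout line to the dosing time
   gives the initial excess enrichment $E_0$ (the *slope-intercept
   method*). Mass balance then yields the dilution space: the body-water
   volume $V$ into which the dose's ²H atoms must have mixed to produce
   that excess. In animals measured with full guts this total body water
   (TBW) includes gut-content water.
2. **Flux.** The washout is a single exponential,
   $E(t) = E_\text{base} + E_0 e^{-k_d t}$, so ordinary least squares of
   $\ln(E - E_\text{base})$ on time gives the depletion rate constant
   $k_d$ (d⁻¹) as the negated slope. Daily water turnover is
   $r = k_d \times \mathrm{TBW}$ (L d⁻¹).

Body composition follows from a hydration ratio: fat-free mass
$\mathrm{FFM} = \mathrm{TBW} / 0.746$ (the mean TBW : FFM ratio across 15
mammal species; 0.730 is a common alternative), fat mass is scale mass
minus FFM, and body fat percent is fat mass over scale mass. Litres of
water convert to kilograms at density 1.000 kg L⁻¹, and the mass balance
uses molecular masses 18.0153 (¹H₂O) and 20.0276 (²H₂O).

```{r worked}
fit <- fit_washout(c(1, 2, 5, 8, 10),
                   155.76 + 48 * exp(-0.1 * c(1, 2, 5, 8, 10)),
                   baseline = 155.76)
fit
tbw <- dilution_space(fit, dose_mass = 176, purity = 0.998)
body_composition(4401, tbw)
```

### The mixing mass balance

The dose contains $n_d = m / M_d$ moles of water ($M_d$ the molar mass of
the dose mixture) with ²H atom fraction $p$ (the stated ²H₂O purity).
The body pool of volume $V$ holds $n_b$ moles at the baseline atom
fraction $f_b$. After complete mixing the atom fraction is

$$ f = \frac{n_d\,p + n_b\,f_b}{n_d + n_b}, $$

and inverting for $n_b$ at the fitted excess $e = E_0 / s$ (with $s$ the
unit scale, $10^6$ for ppm) gives $n_b = n_d (p - f_b - e)/e$ and
$V = n_b M_b / 1000$. Because the forward and inverse forms share the same
convention (pool composition at baseline, volume before dosing), the
round trip is exact to machine precision, which the test suite asserts.
The published protocols this mirrors do not state an explicit
dilution-space formula or enrichment unit, so the package standardises on
ppm ²H of total hydrogen and exposes `unit_scale` so that any consistent
unit gives identical volumes — TBW estimates are unit-invariant as long as
dose, baseline and fit use the same unit. No two-pool model, plateau
method, or fractionation correction is offered; the washout design with
first samples near 24 h post-dose does not identify them.

## Tunable parameters that matter

| Parameter | Default | Units | Why this value |
|---|---|---|---|
| `hydration_ratio` | 0.746 | — | mean TBW : FFM over 15 mammal species; 0.730 alternative explored via `hydration_sensitivity()` |
| `dose_rate` | 0.04 | g kg⁻¹ | standard labelled-water dose for multi-tonne subjects (≈233 g at 5815 kg) |
| `dose_purity` | 0.998 | fraction ²H₂O | commercial stock purity |
| `qc_r2_min` | 0.99 | — | well-behaved washout series show R² 0.990–1.000; lower values flag dosing problems |
| `min_time_days` | 0 | d | equilibration guard; first draws at ~24 h are already equilibrated, so all samples are kept by default |
| `window_days` | 10 | d | weather window, calendar days from (and including) the dose date; inclusivity is a package convention |
| `critical_fraction` | 0.10 | of body mass | dehydration threshold used for drinking-interval bounds |

Failing QC never silently drops data: `run_pipeline()` lists every failed
subject-period with its reason and continues with the rest, mirroring how
uningested doses are excluded but reported in field studies.

## The temperature model

Water turnover rises with air temperature through evaporative losses. The
package models natural-log turnover with a Gaussian linear mixed model:
fixed effects for body mass and mean air temperature (both z-transformed
using the observation-level mean/SD over all included subject-periods),
and a random intercept per subject, estimated by REML via lme4. Natural
log is used so coefficients read as proportional effects; the
standardization is stored in the fit so predictions are reproducible. The
mass × temperature interaction is fitted first and dropped when not
significant at 0.05 (Satterthwaite degrees of freedom via lmerTest); no
random slopes are fitted, since the repeated-measures design motivates
only subject-level intercept heterogeneity. Sex is deliberately not a
covariate — in small cohorts it is collinear with mass.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` produces ground-truthed cohorts matching the
repeated-measures design the pipeline targets: subjects dosed at 0.04
g kg⁻¹ twice a year, one pre-dose baseline and five post-dose samples at
24 h multiples over 10 days, with sampling jitter drawn lognormal on
minutes (median 40, quartiles ≈22.5/81, long tail to a few hundred
minutes, sign ±). Enrichment noise is multiplicative lognormal on the
excess (CV 0.002), consistent with analytic isotope error scaling with
signal and with washout R² concentrating in 0.990–1.000. A separate
multiplicative term (CV 0.05) on the per-period depletion rate represents
day-to-day biological variation in water flux; per-subject turnover SDs
of 2–15% of the mean in real cohorts motivate that scale. The depletion
rate responds to the period's mean air temperature as
$k_\text{eff} = k_d \exp\{c\,(T - T_\text{ref})\}$ with $c = 0.02$ per °C
by default and $T_\text{ref} = 15$ °C, the midpoint of the simulated
seasonal cycle (6–24 °C); with period temperatures spreading over that
range this corresponds to roughly 0.14–0.20 per SD of temperature on the
log scale. Body masses (males 5200–5800 kg, females 2600–4400 kg), fat
fractions (0.05–0.18) and baseline rates (0.08–0.12 d⁻¹) span the adult
African elephant range.

The generator deliberately omits several features of real data: no
behavioural or dietary structure, no gut-fill dynamics (gut parameters are
carried as static truth fields for bias analysis only), no growth in young
animals, no analyzer drift or memory effects, and weather is a smooth
seasonal cycle with Gaussian noise rather than real station data. Passing
tests therefore demonstrate that the *estimation chain* is correct and
well calibrated under the stated error model — not that any particular
real cohort satisfies that error model.

## Numerical choices and degenerate inputs

- The washout regression is computed in closed form (simple linear
  regression); R² is clamped to 1 against floating-point overshoot, and a
  residual-free series is reported as R² = 1.
- Two post-dose points are the minimum and give R² = 1 by construction;
  QC then rests on the positivity of $k_d$ and $E_0$.
- Post-dose samples at or below baseline abort the fit with an
  "uningested dose" error rather than producing NaNs from `log()`.
- Negative fat mass is flagged, not clamped — small negative values are
  informative measurement error — but fat below −5% of body mass is a
  hard error (dosing/assay failure).
- A paired first-versus-last test with identical non-zero differences has
  zero variance; the package raises a documented error instead of
  returning an infinite t.
- Weather aggregation refuses windows with missing days and lists the
  gaps; day order is irrelevant.
- `group_summary()` computes SDs over subject means with the n−1
  denominator, so each animal contributes once regardless of how often it
  was measured.

## Design choices where the design was open

- **Drinking-interval arithmetic.** `drinking_interval()` is the bare
  ratio (critical fraction × mass) / net daily loss. Published 2–3 day
  figures for hot conditions imply netting preformed and food water out
  of gross turnover; since diet data are usually unavailable, the package
  makes `net_daily_loss` the caller's input rather than guessing a diet
  correction. Gross hot-season turnover for a large male (427 L d⁻¹ at
  5815 kg) gives 1.36 d as a lower bound.
- **Gut-fill bias.** The FFM overestimate from gut water hydrated above
  the assumed ratio is computed from first principles,
  $m \cdot g \cdot (h_g - h)/h$; over the plausible ranges (gut fill
  7–17% of body mass, gut water 0.80–0.90) this spans ≈20–140 kg at
  4000 kg body mass. Published percentage ranges for the resulting fat
  underestimate are not reproducible from any single closed form over the
  same assumptions, so the package reports kg and exposes the assumptions
  as parameters instead of targeting a printed range.
- **Comparative dataset.** The cross-species table is literature data and
  is not bundled; the module ships the schema, a loader/filter with
  per-record retention logging, and a power-law fixture generator so all
  tests are self-contained. Plain OLS on log₁₀–log₁₀ axes is used — no
  phylogenetic regression, matching standard practice for this
  comparison. Multiple breeds of one species enter as separate rows.
- **Reference summary table.** `elephant_summary()` carries the printed
  per-subject means/SDs of a published five-elephant cohort as a worked
  example; per-period raw data are not public, so cohort statistics that
  require them (longitudinal deltas, the original mixed-model
  coefficients) are validated by parameter recovery on synthetic cohorts
  instead. One printed group SD (male turnover ±9) is not recoverable
  from the printed subject means (which give 8.49) and is therefore not
  asserted anywhere.

## Problem sizes

The test suite and the acceptance script use cohorts of 2–20 subjects and
1–6 periods, 500-replicate Monte-Carlo checks of the washout fit, and
100–200 replicate parameter-recovery experiments for the temperature
coefficient (20 subjects × 6 periods each); these sizes give stable pass
criteria — e.g. Wald 95% CI coverage estimated to ±3 percentage points —
while keeping a full run in the low minutes on a single core.

## Known limitations

- Single-pool, single-exponential kinetics only; no isotope fractionation
  corrections.
- The hydration ratio is taken as known; its ~2% CV across species
  propagates directly into fat estimates (explored via
  `hydration_sensitivity()`, not modelled as uncertainty).
- The temperature model assumes log-linear temperature dependence and
  Gaussian errors; it is a description of seasonal covariation, not a
  biophysical evaporation model.
- Synthetic weather is a smooth idealised cycle; models fitted to it will
  look cleaner than with real station data.
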