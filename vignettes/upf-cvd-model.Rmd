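---
title: "Modelling the premature CVD burden attributable to ultra-processed food"
author: "upfburden authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the premature CVD burden attributable to ultra-processed food}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(upfburden)
```

## The model

`upfburden` is a comparative risk assessment (CRA) model. It answers a
counterfactual question: by how much would premature cardiovascular events
(deaths, incident cases, DALYs at ages 30–69) fall if the population's
intake of ultra-processed food (UPF), expressed as a share of total dietary
energy, shifted from its observed distribution to some alternative? The
three ingredients are stratum-level intake distributions, stratum-level
baseline event counts, and a dose–response relative-risk (RR) curve per
outcome; they are combined through the potential impact fraction

$$\mathrm{PIF}_{oas} \;=\; \frac{\int_0^m RR_o(x)\,P_{as}(x)\,dx \;-\;
\int_0^m RR_o(x)\,P'_{as}(x)\,dx}{\int_0^m RR_o(x)\,P_{as}(x)\,dx},$$

evaluated per outcome $o$, age band $a$ and sex $s$, multiplied by the
stratum's baseline events, and summed over strata and outcomes. The
attributable burden is the PIF against the theoretical-minimum-risk
counterfactual (everyone at the TMREL intake); an *averted* burden under a
scenario is the PIF against that scenario's distribution times baseline
events. Averted events are therefore always bounded by the attributable
events when the scenario does not push intake below the TMREL.

### Dose–response

The RR curve is log-linear: $RR(x) = 1$ for $x \le x_{\mathrm{tmrel}}$ and

$$\log RR(x) = \frac{x - x_{\mathrm{tmrel}}}{x_{\mathrm{ref}} -
x_{\mathrm{tmrel}}}\,\log RR_{\mathrm{ref}} \qquad (x >
x_{\mathrm{tmrel}}),$$

anchored at $RR_{\mathrm{ref}}$ = 1.29 (CHD) and 1.34 (stroke) at
$x_{\mathrm{ref}} = 22$% of energy with $x_{\mathrm{tmrel}} = 0$, and
extrapolated with the same slope to 100% of energy. Two remarks on choices
that were genuinely open:

* The evidence base tabulates the curve in 0.1% intake steps. We implement
  the exact continuous log-linear function, of which such a tabulation is
  the discretisation; `rr_grid()` provides the tabulated form for fidelity
  checks, and the two agree at every grid node by construction. Whether the
  tabulated model interpolates linearly in RR or in log RR between nodes is
  not observable at the reported precision; log-linear is assumed
  throughout.
* Extrapolation above the reference intake continues the same log-linear
  slope — the only slope-preserving continuation.
* RR uncertainty is log-normal with log-scale SD
  $(\log \mathrm{CI}_{hi} - \log \mathrm{CI}_{lo})/(2 \times 1.96)$, the
  standard reconstruction from a 95% CI of a ratio measure.

### Exposure distributions

A stratum's intake is summarised by a mean and SD (% of energy). A
two-parameter specification on a positive, right-skewed quantity points to
the log-normal family, the conventional CRA exposure model; we moment-match
($\sigma^2_{\ln} = \log(1 + (s/\mu)^2)$,
$\mu_{\ln} = \log \mu - \sigma^2_{\ln}/2$) and truncate to [0, 100]% with
renormalisation (the truncated mass is $<10^{-4}$ for realistic intakes).
A zero SD degenerates to a point mass, for which all PIFs are evaluated in
closed form.

Scenarios transform each stratum's own distribution:

* **Proportional reduction** $r$: the law of $(1-r)X$ — the log-scale mean
  shifts by $\log(1-r)$, the coefficient of variation is preserved, and the
  stratum mean scales exactly by $1-r$.
* **First quintile**: the baseline distribution truncated at its own 20th
  percentile and renormalised, i.e. the whole stratum adopts the intake
  pattern of its current bottom fifth. The phrase "reduced to the first
  quintile" admits a second reading — everyone at the *mean* of the bottom
  fifth — which is available as
  `scenario_quintile(method = "point_mass")`; the truncation reading is the
  default because it preserves within-quintile heterogeneity rather than
  inventing a spike. The two readings give different averted fractions,
  and neither is pinned down by published results, so no accuracy claim is
  attached to this scenario beyond its structural invariants (mass 1,
  support bounded by the baseline quintile, stochastic dominance).

### Numerical integration

PIF integrals use the trapezoidal rule on a uniform grid. `grid_step`
(default 0.1% of energy, matching the tabulation resolution of the curve)
and the upper bound `m` (default 100%, the extrapolation limit) are
exposed. The interval count is tied to `m / grid_step`, so a counterfactual
with a narrow truncated support — the bottom-quintile shift, whose support
ends near 7–12% of energy — is integrated at a proportionally finer step
rather than losing resolution; with 1,000 intervals the result is within
$10^{-6}$ of a halved step and within $10^{-4}$ relative of an independent
Simpson integration at a 0.001% step. Point masses bypass quadrature
entirely: their integral is the exact curve value, which avoids
delta-function discretisation artefacts and makes the point-mass PIF the
closed form $1 - RR(x')/RR(x)$ to machine precision.

## Uncertainty propagation

`run_monte_carlo()` redraws, per iteration: the pooled RRs (log-normal from
their CI, one draw per outcome applied to all strata — the RR is a shared
meta-analytic parameter, so draws are synchronised); the event counts
(normal with SD = UI width / 3.92, truncated at zero — the UI source
publishes no distributional shape, and symmetric-with-floor is the least
informative choice); and the stratum intake means (normal with the supplied
survey SE, truncated to (0, 100)). Truncation is by inverse-CDF, not
censoring, so medians are not biased by a spike at the bound. The central
estimate reported is the **median** with a 2.5–97.5 percentile uncertainty
interval; the whole simulation is a pure function of (inputs, seed,
n_draws). The default draw count is 5,000.

Monotonicity note: because the PIF is increasing in the RR, a 10% higher RR
must increase the attributable burden. The package asserts this direction
in its tests; published sensitivity tables sometimes carry transposed signs
for such scenarios, and the deterministic sensitivity output here
(`run_sensitivity()`) should be read with the monotone direction in mind.

Deterministic sensitivity scenarios re-anchor the curve at alternative
(TMREL, reference) pairs — TMREL 10% or 12%, reference 20% or 24% of
energy, with the dispersions of those alternative thresholds (±4.1, ±5.0,
±8.2, ±10.6) carried as metadata only — or scale the RRs by ±10%. Output is
the percentage change of the attributable CVD totals per metric.

## The synthetic study generator

`generate_study()` produces a complete, loadable input bundle emulating the
*structure* of a national dietary survey joined to GBD-style stratified
event estimates: 8 five-year age bands × 2 sexes; intake means declining
linearly with age from 21% to 13% of energy (the published range for
adults, with the published declining trend; the decline is made linear
because only the endpoints and the trend are reported); SD = 0.45 × mean;
populations of ~7 million per stratum declining 1.5% per year of age; CVD
event rates doubling every 10 years of age (a standard feature of CVD
epidemiology — the exact doubling time affects realism, not correctness),
stroke at 0.7× the CHD death rate, incident cases 4× and DALYs 25× deaths;
symmetric 95% UIs of ±20%. The generator is deterministic given its
configuration.

What it does **not** emulate — and therefore what passing recovery tests do
not establish about real data: survey weighting and design effects, usual-
intake measurement error in 24-hour recalls, asymmetric GBD uncertainty
intervals, correlation between intake and event uncertainty, and any
sex-specific intake difference. Parameter recovery on this bundle shows the
*pipeline* is correct, not that any particular national estimate is.

Ground truth is computed at generation time by `oracle_pif()`, an
independent composite-Simpson integrator at a 0.001% step that shares no
code with the trapezoidal engine; `recovery_check()` compares every
stratum–outcome–scenario PIF and every aggregated total against it
(deterministic agreement within $10^{-4}$ relative), and optionally checks
that Monte Carlo medians recover the truth within 2% at 5,000 draws.

On the default bundle the averted/attributable ratios for the 10/20/50%
reductions fall at ~11%, ~22%, ~53% — the scale-free analogue of the
published scenario findings, insensitive to the absolute event counts.

## Reporting conventions and degenerate inputs

* Event counts are reported rounded to the nearest hundred, halves away
  from zero; rounding is applied only at the reporting layer, never inside
  the computation, and aggregated totals are exact sums of unrounded cells.
* Percentages (shares, attributable fractions of totals) are integers,
  rounded half away from zero, and are always accompanied by their
  denominators in the output tables.
* Age bands outside 30–69 and malformed strata are *rejected with the
  offending row named*, not silently dropped: silent exclusion would mask
  upstream data errors.
* A zero-width RR confidence interval is treated as a fixed RR (every draw
  equals the point estimate) rather than an error; an RR of exactly 1
  yields PIF = 0 throughout.
* `run_model()` validates everything before writing anything, so a failed
  run leaves no partial output bundle, and writes a manifest sufficient to
  reproduce the run byte-for-byte.

## Problem sizes

The shipped tests exercise the full 16-stratum bundle deterministically,
Monte Carlo at 5,000 draws for the recovery check, smaller draw counts
(25–200) for reproducibility and interval-ordering properties, a 50,000-draw
single-stratum run for quantile calibration against analytic truncated-
normal quantiles, and $10^6$ stratified exposure draws for the Monte Carlo
integration cross-check of the quadrature. These sizes were chosen so the
Monte Carlo error of each check sits well below the tolerance it asserts.

## Limitations

CRA models are static: they carry no time dimension, so results are
annualised counterfactual contrasts, not projections; lag between exposure
change and risk change, event recurrence, competing risks and interactions
between individuals are all outside the model. The RRs are assumed
portable across populations, and residual confounding in the underlying
cohorts propagates untouched. Age-standardisation, projection to future
years and subpopulation equity decompositions are explicit non-goals.
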