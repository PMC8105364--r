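---
title: "Modeling growth-factor release and degradation in culture wells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling growth-factor release and degradation in culture wells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup}
library(gfelute)
```

## Why this package exists

Eluting coatings deliver growth factors into culture media over days, but the
protein degrades on the same time scale, so neither a cumulative-release
curve nor a nominal dose tells you the concentration a cell sees.
`gfelute` couples three measurements into one real-time concentration model:
a degradation assay (to get an apparent half-life), a
sampling-with-replacement release study (to get release kinetics), and the
geometry of the culture system. Everything is expressed in canonical units —
hours, ng/mL, mL, cm² — with conversion only at the I/O boundary.

An important caveat up front: the half-life fitted here is an
*immunoassay-detectable* half-life — the rate at which the protein stops
being recognizable to the ELISA antibodies. Half-lives measured by western
blot or circular dichroism can differ severalfold, because each method
detects a different set of conformations. A concentration model meant to be
compared against ELISA release data must use an ELISA-derived half-life;
mixing methods systematically biases the profile.

## Degradation: pseudo-first-order with a burst window

Protein inactivation is well described by a two-state scheme — native ⇌
unfolded → irreversibly lost. Once the folding/unfolding step reaches
equilibrium, the overall loss is pseudo-first-order:

$$\ln N(t) = \ln N_0 - k\,t, \qquad t_{1/2} = \ln 2 / k.$$

Freshly reconstituted protein is *not* at equilibrium: the first few hours
show faster-than-first-order loss (a burst). Rather than fitting a
biexponential — which is poorly identified from the 8-point grids typical of
these assays — `fit_first_order()` simply restricts the log-linear OLS to a
window, default 8–96 h inclusive. The window is the model here: widen it into
the burst and the rate is biased upward.

Choices that matter:

* **Per-replicate fits.** Each replicate curve is fitted separately and
  aggregated by `summarize_fits()` (mean, sample SD with the n−1
  denominator). Fitting the replicate-mean curve hides between-replicate
  variability; it is available via
  `fit_replicates(..., method = "mean_curve")` for comparison only.
* **Growing data is flagged, not rejected.** Noisy near-flat replicates can
  produce a positive slope. The fit reports `k < 0` with
  `quality_flag = "nonphysical_growth"` and an infinite half-life sentinel;
  aggregation then fails loudly, naming the replicate, instead of averaging
  a nonsense value silently. A perfectly flat series gives `k = 0`,
  `r_squared = 0`.
* **Shrinking volume is ignored.** Degradation-assay aliquots are taken
  without replacement, but the model is concentration-based, so removing
  volume does not change the concentration dynamics. This is an assumption,
  valid while the aliquots are small relative to the well.

## Release: correction first, then the power law

In a sampling-with-replacement study the whole immersion volume is collected
and replaced at each time point, so aliquot `i` measures only the release in
the interval `(t_{i-1}, t_i]` — *after* that material has partially degraded
in the vial. Assuming release at a constant rate within the interval, a
parcel released uniformly over `Δt` retains a fraction
`(1 − e^{−kΔt})/(kΔt)` by sampling time, so `degradation_correct()`
multiplies each measured amount by

$$\frac{k\,\Delta t}{1 - e^{-k\,\Delta t}} \;\ge\; 1,$$

evaluated with its analytic limit 1 at `kΔt = 0` (via `expm1`, so the factor
is continuous and monotone rather than a 0/0 at small rates). The cruder
midpoint variant `exp(kΔt/2)` agrees to second order and is available with
`method = "midpoint"` for sensitivity analysis. The default correction rate
corresponds to a 22.75 h half-life — an ELISA-detectable value for FGF2 in
PBS at the concentration scale of these studies, chosen for its low relative
standard deviation — and should be overridden for any other protein/medium.

The corrected cumulative curve is fitted to the Korsmeyer–Peppas power law

$$M_t / M_\infty = K\,t^{\,n},$$

with `M_∞` defined operationally as the final corrected cumulative release
plus the protein recovered by a terminal acid–base wash of the substrate.
The default estimator is OLS of `ln(M_t/M_∞)` on `ln t` (`K` from the
intercept, `n` from the slope), which excludes `t = 0` by construction; a
nonlinear least-squares mode on untransformed fractions
(`method = "nls"`) is provided since the published analyses of such data do
not always state which was used — on noiseless data the two coincide.
Fractions above 1 indicate an inconsistent `M_∞` and are an error, not a
clamp; prediction (`predict_release()`) is capped at `M_∞`. Exponents well
below 0.45 indicate release not driven purely by Fickian diffusion, which is
typical of multilayer coatings held together by dynamic ionic/hydrogen
bonds. Replicates are corrected and fitted independently; condition-level
constants should be reported as mean ± SD across replicates.

## The well simulator

For an eluting coating the concentration obeys
`V dC/dt = R'(t) − k V C`, i.e. the convolution

$$C(t) = \frac{1}{V}\int_0^t R'(s)\,e^{-k(t-s)}\,ds,
\qquad R(s) = A_{\text{well}}\,\frac{M_\infty}{A_{\text{study}}}\,
\min(1, K s^n),$$

with release normalized per cm² of the study substrate and rescaled to the
culture geometry (defaults 1.9 cm², 600 µL — one well of a 4-well plate).
`simulate_eluting()` uses an exponential-integrator step,

$$C_{i+1} = C_i\,e^{-k\,\Delta t} + \frac{\Delta R_i}{V}\,e^{-k\,\Delta t/2},$$

decaying each step's release increment from the step midpoint. The scheme is
second-order accurate and unconditionally stable; the integrable `t = 0`
singularity of the power-law *rate* (`n < 1`) never appears because only the
finite increments `ΔR_i` are used. Default `dt = 0.05` h: halving it moves
default profiles by well under 0.1%, and the test suite checks the profile
against independent adaptive quadrature of the convolution (0.1% sup-norm)
and exact mass balance `V·C = A·M(t)` at `k = 0`.

Bolus schedules need no integration: `simulate_exogenous()` evaluates the
closed form `C(t) = Σ c_d e^{−k(t−t_d)}` over doses with `t_d ≤ t`. Profiles
store *both* one-sided values at each dose time; `condition_table()` reads
the pre-dose value (the trough, which is what matters when deciding whether
a supplementation schedule keeps the concentration above a threshold), while
`profile_stats()` extracts min/max over a window, excluding a pre-dose row
that sits exactly at the window start. Media changes are not modeled in the
default 4-day horizon — the schedules of interest supplement without full
media replacement; a reset event would be a straightforward extension.
Reported tables round to 2 decimals only in the print method; data outputs
keep full precision.

```{r example}
k <- rate_from_half_life(22.75)
mk <- function(c0) simulate_exogenous(
  data.frame(time_h = c(0, 48), conc_ng_ml = c(c0, c0)), k = k, t_end = 96)
condition_table(list(`16 ng/mL` = mk(16), `8 ng/mL` = mk(8), `4 ng/mL` = mk(4)),
                read_times_h = c(48, 96))
```

## QCM-D masses

`sauerbrey_mass()` implements the rigid-film Sauerbrey relation
`Δm = −C·Δf/n` with `C = 17.7` ng/(cm²·Hz) for 5 MHz crystals (the relation
is sometimes typeset with `n Δf` in the denominator, which is dimensionally
inconsistent with these units of `C`; the standard product form is used
here). `layer_masses()` reads each layer's end-of-step mass as the mean
Sauerbrey mass over the final 30 s of the wash step — the post-wash
convention, robust to noise — and reports increments, which may be negative
when a deposition step strips previously adsorbed material.
`rigidity_check()` computes the per-overtone ratio of dissipation to
normalized frequency shift; a relative spread under 20% across overtones and
a mean ratio under 0.4×10⁻⁶ per Hz flag the film as rigid enough for
Sauerbrey analysis. This is advisory: no viscoelastic model is attempted,
and films thicker than a few tens of nm need one.

## Synthetic data: what it emulates, and what it does not

The generators produce inputs with exactly the statistical structure the
analysis assumes, so every stage can be tested with known truth:

* `gen_degradation_assay()`: a first-order decay plus a second, faster
  exponential (defaults: 30% of the signal decaying at 0.5 1/h) — the
  simplest mechanism producing a non-first-order burst that is negligible
  past 8 h. Noise is multiplicative lognormal with unit mean, parameterized
  by CV (concentrations are positive and immunoassay error scales roughly
  with signal); additive Gaussian is available behind a flag. Defaults
  (c0 = 500 ng/mL, half-life 22.75 h, grid 1, 2, 4, 8, 24, 48, 72, 96 h,
  5 replicates, CV 10%) mirror a typical 4-day assay whose first sample is
  taken after a 1-h incubation; the exact grid is a plausible choice, not a
  measured fact, and is recorded in the output metadata.
* `gen_release_study()`: cumulative release follows `M_∞ K t^n` exactly;
  interval amounts are attenuated by the same within-interval factor the
  correction inverts, and the wash recovery is set to `M_∞ − R(t_last)` so
  the study is self-consistent. Defaults (K = 0.12, n = 0.25, M_∞ = 12 ng on
  1 cm² in 1 mL) sit in the sub-diffusive, few-ng regime typical of adsorbed
  growth factor on multilayer coatings.
* `gen_qcmd_trace()`: exponential approach to each programmed plateau during
  adsorption, exact plateau during the wash, Sauerbrey-consistent frequency
  shifts per overtone with white noise, and dissipation generated inside the
  rigid regime.

All generators are pure functions of (parameters, seed) and leave the
caller's RNG stream untouched. What passing the recovery tests shows is that
the *pipeline algebra* is right — correction inverts the attenuation it
models, fits recover parameters under the assumed noise. What it cannot show
is robustness to structure the generators omit: plate-level ELISA error
shared across replicates, adsorption losses, incomplete vial replacement,
non-lognormal outliers, or release that genuinely departs from a power law.
Real-data conclusions still need replicate counts and residual checks.

## Numerical and degenerate-input conventions

* Half-life sentinels: `k = 0` maps to `t½ = ∞`; aggregation refuses
  infinite half-lives and names the replicate.
* `r_squared` is defined as 0 when the response is constant (zero total sum
  of squares) rather than NaN.
* The correction factor uses `expm1`; `x/(1 − e^{−x})` is evaluated as the
  exact limit 1 at `x = 0` and grows like `x` for large `x`.
* Log-log power-law fitting drops zero-release points (log undefined) and
  requires two usable points; exceeding `M_∞` by more than 1e−12 relative is
  an error.
* The simulators validate `0 < dt ≤ t_end`; dose lists must be sorted;
  read times must lie within every profile's span.
* Problem sizes in the test suite are small by design — grids of ≤ 10 time
  points, 5 replicates, 10–20 seeds per property — which is the scale of the
  experiments being emulated and keeps recovery experiments exact enough to
  assert tight tolerances.

## Known limitations

* Single-state degradation only: no biexponential or multi-state fitting —
  the burst is excluded by the window, never modeled.
* One compartment, no sinks: no cell uptake, receptor binding, or
  adsorption to plasticware in the simulator.
* Power law only: no Higuchi, Weibull, or mechanistic swelling/diffusion
  release models.
* The within-interval correction assumes a constant release rate inside each
  sampling interval; with the long late intervals of a typical grid and
  `n < 1` this slightly overweights early-interval release, bounded by the
  difference between the integral and midpoint variants (use both to check).
* Sauerbrey masses are meaningless for soft films; the rigidity check flags
  but does not fix this.
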