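# gfelute

Growth-factor release and degradation kinetics for eluting coatings.

## The problem

Coatings such as polyelectrolyte multilayers (PEMs) release growth factors
(e.g. FGF2) into culture media over days, while the protein simultaneously
loses immunoassay-detectable activity. Neither the release study nor the
degradation assay alone tells you what a cell actually experiences: the
real-time concentration in the well. `gfelute` is for biomaterials and
cell-culture researchers who have (a) ELISA timecourses of a protein decaying
in buffer or media, and (b) sampling-with-replacement release-study aliquots,
and want a defensible concentration-versus-time profile for their culture
geometry — or the equivalent profile for an exogenous supplementation
schedule, for comparison.

## The model

Three pieces, combined:

1. **Pseudo-first-order degradation.** Once folding/unfolding equilibrium is
   reached, loss of detectable protein follows
   `ln N(t) = ln N0 − k t`, so `k` is the slope of a log-linear fit and the
   half-life is `t½ = ln 2 / k`. The first hours of an assay show a faster,
   non-equilibrium burst, so the fit uses a window (default 8–96 h), one fit
   per replicate, aggregated as mean ± SD.

2. **Degradation-corrected power-law release.** In a
   sampling-with-replacement study each aliquot measures only the release
   since the previous sampling, attenuated by within-interval degradation.
   Each interval of length `Δt` is inflated by `kΔt / (1 − e^{−kΔt})` (exact
   under constant within-interval release), accumulated, and fit to the
   Korsmeyer–Peppas power law `M_t / M_∞ = K t^n` by log-log regression,
   with `M_∞` = final corrected cumulative release + acid–base wash recovery.

3. **Well-concentration simulation.** For an eluting coating the
   concentration is the convolution of the release rate with first-order
   elimination, `C(t) = (1/V) ∫₀ᵗ R′(s) e^{−k(t−s)} ds`, integrated with an
   exponential-integrator scheme (release scaled from the study substrate to
   the culture geometry, default 1.9 cm² in 600 µL). Bolus schedules are
   evaluated in closed form, with pre-dose and post-dose values recorded at
   every dose time.

A QCM-D module converts layer-by-layer assembly traces to areal mass via the
Sauerbrey relation `Δm = −C Δf / n` (C = 17.7 ng/(cm²·Hz) for 5 MHz
sensors), with a rigid-film validity check. Synthetic-data generators
produce truth-known degradation assays, release studies, and QCM-D traces
for testing every stage.

## Worked example

```r
library(gfelute)

# degradation rate from a measured half-life of 22.75 h
k <- rate_from_half_life(22.75)   # 0.030468 1/h

# an exogenous schedule: 16 ng/mL bolus at t = 0 and t = 48 h
doses <- data.frame(time_h = c(0, 48), conc_ng_ml = c(16, 16))
prof  <- simulate_exogenous(doses, k = k, t_end = 96)
profile_value(prof, 48, side = "pre")   # 3.706635  -> lowest point before re-dosing
profile_value(prof, 48, side = "post")  # 19.70663  -> right after the second bolus

# compare dosing levels at day 2 and day 4 (pre-dose convention)
mk <- function(c0) simulate_exogenous(
  data.frame(time_h = c(0, 48), conc_ng_ml = c(c0, c0)), k = k, t_end = 96)
condition_table(list(`16 ng/mL` = mk(16), `8 ng/mL` = mk(8), `4 ng/mL` = mk(4)),
                read_times_h = c(48, 96))
#>  condition t48_h t96_h
#>   16 ng/mL  3.71  4.57
#>    8 ng/mL  1.85  2.28
#>    4 ng/mL  0.93  1.14
```

So a 16 ng/mL schedule swings between roughly 3.7 and 19.7 ng/mL; an
8 ng/mL schedule sits pre-dose near 1.9 ng/mL at day 2 and 2.3 ng/mL at
day 4. For an eluting coating, fit the release data instead and call
`simulate_eluting()`:

```r
studies   <- read_release_csv("release.csv", "study.yml")
corrected <- degradation_correct(studies[[1]], k = k)
fit       <- fit_power_law(corrected, m_infinity(corrected))
prof      <- simulate_eluting(fit, culture_system(1.9, 0.6), k = k, t_end = 96)
profile_stats(prof, after = 1)          # concentration range after the first hour
```

`run_pipeline()` chains all stages from a single YAML/JSON config and writes
every intermediate as CSV with a JSON metadata sidecar.

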