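# itdisp

Effective dispersion analysis for intrathecal drug administration: moment
analysis of tracer profiles, dispersion-coefficient estimation by moment
inversion, physiological dispersion correlations, and a distributed
compartmental pharmacokinetic model of the spinal canal.

## The science in brief

Drugs injected into the cerebrospinal fluid (CSF) of the spinal canal spread
along the neuraxis orders of magnitude faster than molecular diffusion: the
cardiac-driven oscillation of the CSF, stirred by nerve roots and the canal's
micro-anatomy, acts like a greatly enhanced diffusion. This package models
that transport as one-dimensional diffusion with an *effective dispersion
coefficient* `D` (cm²/min) on a bounded domain (the closed dural sac) and
provides the full analysis chain used to characterize it on a bench phantom:

1. **Moment analysis** — centroid (first moment) and *left-sided* second
   moment of axial intensity profiles; the left-sided moment handles the
   asymmetry of a lumbar bolus near the short sacral end
   (`moment_series()`, `caudocranial_velocity()`).
2. **Dispersion estimation** — the *moment inversion process* (MIP) fits `D`
   by matching observed left-sided second moments against a simulated
   bounded-domain diffusion (`mip_estimate()`); the classical method of
   moments (`mom_estimate()`, `D = slope/2`) is included as the baseline it
   outperforms once the tracer front reaches the sacral wall.
3. **Physiological correlations** — dimensional
   (`log10 D ~ f, f², log10 Urms`), dimensionless (Womersley/Péclet) and
   scale-analysis laws linking `D` to the pulsation
   (`fit_dimensional()`, `fit_dimensionless()`, `fit_scale()`,
   `csf_state()`), plus linear caudocranial-velocity laws (`fit_ccv()`).
4. **Pharmacokinetics** — a six-compartment model (distributed spinal CSF and
   tissue, lumped cranial CSF/tissue/blood/periphery) driven by the estimated
   `D`, with dose events, mass-transfer couplings and exact mass-balance
   accounting (`simulate_pk()`, `mass_balance_report()`).
5. **Synthetic data and pipeline** — a seeded generator reproducing the
   statistical structure of the bench videos
   (`simulate_tracer_experiment()`, `generate_cohort()`) and a reproducible
   end-to-end pipeline with checksummed artifacts (`run_pipeline()`), plus a
   CLI at `inst/scripts/itdisp`.

See the vignette (`vignettes/moment-inversion-methods.Rmd`) for the model,
numerical choices and limitations.

## Worked example

Simulate a tracer experiment with a known ground truth, then recover it:

```r
library(itdisp)

# bounded default domain: sacral wall at -6 cm, injection at 0, 65 cm canal
rec <- simulate_tracer_experiment(D_true = 7.4, drift_velocity = 0,
                                  noise = noise_spec(0.05, 0), seed = 42)
rec
#> <intensity_record> 11 frames x 650 positions, t = [0, 10] min
#>   D_true = 7.4 cm^2/min, drift = 0 cm/min, seed = 42

head(as.data.frame(moment_series(rec)), 4)
#>   time_min      m1_cm m2_left_cm2 total_intensity
#> 1        0 0.06243079     6.39765        1.998238
#> 2        1 0.50125001    12.96228        1.994314
#> 3        2 1.09876528    16.98403        1.976576
#> 4        3 1.68418748    20.32884        1.984221

mip_estimate(rec)
#> <dispersion_estimate> D = 7.396 cm^2/min (MIP, n = 11)

mom_estimate(rec)
#> <dispersion_estimate> D = 1.766 cm^2/min (MoM, n = 11)
```

With `D = 7.4` cm²/min the tracer front reaches the sacral wall well within
the 10-minute observation, the second-moment trajectory tapers, and the
straight-line method of moments under-reads severely — while MIP, whose
forward model honours the closed walls, recovers the truth to within a
fraction of a percent.

Physiology and correlation predictions:

```r
st <- csf_state(72, 1.0)   # 72 bpm, 1 mL stroke volume
st
#> <csf_state> f = 72 bpm, SV = 1 mL/beat
#>   omega = 7.5398 rad/s, Urms = 1.3095 cm/s
#>   alpha = 6.865, Pe = 2.027e+07, eps_amp = 0.002672

dimensional_law(st$frequency, st$urms)   # published-coefficient prediction
#> [1] 0.08913638

validation_summary(default_validation_pairs())$summary
#>   quantity n mean_pct_difference
#> 1     area 4            3.825803
#> 2 diameter 4            1.882784
```

## License

MIT (see `LICENSE`).
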