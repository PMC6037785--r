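# kinetracer

Simulation and quantification of single-molecule motor motility on
microtubules, built around the question of how a minus-end-directed
kinesin-14 (HSET/KIFC1) switches from lattice diffusion to processive
transport and aster formation when it clusters. The package is for
single-molecule TIRF labs and methods developers who want the full
quantitative stack — spot photometry, particle tracking, kymograph event
metrics, CDF fitting with bootstrap errors — as tested, scriptable code,
validated end-to-end by parameter recovery on a built-in stochastic
generator.

## What it computes

* **Diffusion**: ensemble mean-squared displacement of tracked particles
  and the diffusion constant from a linear fit over the first 5 s of lag
  (1D along the MT axis, `D = slope/2`).
* **Motility metrics** from kymograph conventions with explicit inclusion
  and censoring rules: run length (horizontal component, pauses included),
  velocity (run length / moving time, ≥5-frame pauses excluded), minus-end
  dwell time (vertical component, arrival interpolated at the kymograph
  corner), and event frequency (events · min⁻¹ · µm⁻¹).
* **Distribution fits** on empirical CDFs, as in the single-molecule
  literature:
  normal CDF for velocities and intensities,

      CDF(x) = 1/2 [1 + erf((x − µ)/√(2σ²))],

  and a minimum-corrected exponential CDF for run lengths above
  x₀ = 0.3 µm (mean = t + x₀; dwells use x₀ = 0),

      CDF(x) = 1 − e^((x₀ − x)/t),

  with bootstrap errors (200 resamples; 95% CI = 2 × SE).
* **Spot photometry**: local-maxima detection and symmetric 2D-Gaussian
  fits with local background; integrated intensity = 2πAσ²; stepwise
  photobleaching step counts via BIC-penalized changepoint search.
* **Self-organization contrast**: per-frame SD of the entire
  tubulin-channel field.
* **Synthetic data**: a seeded generator of diffusive and processive
  trajectories, cluster intensities, photobleaching traces, two-channel
  kymographs, TIRF-like movies (TIFF) and organization time-lapses, with
  ground truth attached — the test bed for everything above.

## Worked example

Simulate the motor–tubulin transport scenario, extract events under the
inclusion rules, and fit the three motility distributions at the published
sample sizes:

```r
library(kinetracer)

m <- run_scenario("tubulin_transport",
                  n_keep = list(velocity = 362, run_length = 150,
                                end_dwell = 50))
f <- m$results$fits
sprintf("velocity   %.2f +/- %.2f um/min (n = %d)",
        f$velocity$derived_mean, f$velocity$ci95, f$velocity$n)
sprintf("run length %.2f +/- %.2f um (n = %d)",
        f$run_length$derived_mean, f$run_length$ci95, f$run_length$n)
sprintf("end dwell  %.1f +/- %.1f s (n = %d)",
        f$end_dwell$derived_mean, f$end_dwell$ci95, f$end_dwell$n)
```

which prints (fixture seed 201):

```
velocity   8.81 +/- 0.23 um/min (n = 362)
run length 3.89 +/- 0.57 um (n = 150)
end dwell  25.5 +/- 8.2 s (n = 50)
```

The generator was configured with a per-event velocity of
8.9 ± 2.0 µm/min, exponential runs of mean 4.2 µm and exponential dwells
of mean 25 s — the fitted means recover them through the full
event-extraction and censoring pipeline, with bootstrap CIs of the
published magnitude. The `analysis/` directory contains numbered driver
scripts that run each study stage (diffusion MSD, tubulin transport,
QDot motility, intensity stoichiometry, organization contrast) and write
their tables under `results/`.

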