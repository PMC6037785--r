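---
title: "Quantifying single-molecule motor motility: models, estimators and their calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying single-molecule motor motility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinetracer)
```

## The scientific setting

Kinesin-14 motors such as human HSET/KIFC1 walk toward microtubule (MT)
minus ends and can focus MT arrays into asters. On its own, a single dimer
of this motor is not processive: it diffuses bidirectionally along the MT
lattice through its N-terminal tail domain. When the tail binds soluble
(non-polymer) tubulin, motors assemble into multimotor clusters that move
processively toward minus ends, dwell there, and — in a many-MT setting —
sort MTs into asters. The quantitative fingerprints of this switch are:

* **lattice diffusion constants** of single motors (MSD analysis of
  100 ms-frame TIRF movies),
* **velocity, run length, end-dwell time and event frequency** of
  processive particles (kymograph analysis of 1 s-frame movies),
* **fluorescence intensity stoichiometry** of moving particles relative to
  single fluorophores (2D-Gaussian spot photometry and stepwise
  photobleaching),
* a **field-contrast statistic** tracking self-organization of MT fields.

`kinetracer` implements this entire quantitative stack together with a
seeded stochastic generator of the underlying data, so every estimator can
be validated by parameter recovery against known ground truth.

## The generative model

`sim_config()` collects all generative parameters. Two motion modes are
simulated on 1D tracks (minus end at coordinate 0):

**Diffusive mode.** Per-frame displacements are drawn i.i.d. from
$\mathcal N(0,\, 2D\,\Delta t)$ and reflected at the MT ends; association
lifetimes are exponential, binding times and positions uniform. Defaults
mirror the single-molecule diffusion acquisitions: $\Delta t = 0.1$ s over
1 min.

**Processive mode.** Each binding event draws *one* velocity from
$\mathcal N(v, \sigma_v^2)$ (velocity heterogeneity is between events, not
within — the per-event velocity distribution is what the normal CDF is
fitted to), a run length from $\mathrm{Exp}(\bar\ell)$, and a minus-end
dwell from $\mathrm{Exp}(\bar d)$. The particle moves toward coordinate 0,
optionally stalling (Poisson pause onsets, exponential pause durations);
it detaches when the run is exhausted, or arrives at the minus end and
dwells there before detaching. Events truncated by the acquisition window
are flagged censored — flags are always recorded and the downstream
filters decide.

Cluster fluorescence is the sum of per-fluorophore intensity draws over a
stoichiometry drawn uniformly on a configured integer range; fluorescent
protein tags carry a maturation probability (default 0.8, so dimers show
1–2 photobleaching steps), chemical dyes are always bright. Photobleaching
is per-fluorophore geometric in frames.

Rendering uses symmetric Gaussian PSFs (σ = 130 nm default) on a 106.7
nm/pixel grid (100× objective, 1.5× tube lens, 16 µm EMCCD pixels), with
constant background and optional Gaussian or Poisson noise. Kymographs are
rendered as per-frame line scans integrated over a 3-pixel band, rows =
time, columns = distance.

Determinism contract: every generator derives per-particle child seeds
deterministically from the root seed, so identical config + seed gives
bit-identical output and adding particles does not perturb existing ones.

## Estimators

**MSD and D.** Per-trajectory time-averaged MSD over all overlapping
pairs, ensemble mean ± SEM across trajectories, ordinary least squares of
the mean MSD on lag over the first 5 s with a free intercept (it absorbs
the localization-noise offset). Motion along the MT axis is
one-dimensional, so $D = \text{slope}/2$; `fit_diffusion(dim = 2)` gives
the slope/4 convention for unconstrained in-plane motion.

**Spot photometry.** Local maxima above threshold are fit in a 9×9 px
window by nonlinear least squares to a symmetric 2D Gaussian plus constant
local background; the reported integrated intensity is the
background-corrected volume $2\pi A \sigma^2$. Fits never raise on bad
data; failures are flagged.

**Event metrics.** Events are extracted from trajectory tables (the
primary path; kymograph tracing from images is the verification path,
since automated tracing of kymograph images is not part of the source
procedure). Run length is the horizontal (distance) component from the
first frame to the last pre-dwell frame, *including* pauses; moving time
counts frame intervals excluding pauses of ≥ 5 frames with net
displacement below one pixel; velocity = run length / moving time. The
dwell is read at the kymograph corner: arrival is interpolated from the
last approach frame at the measured approach speed, detachment is taken
mid-way through the first particle-free frame gap. This makes the dwell
estimate unbiased under frame discretization (naive frame counting is
biased by up to one frame, which matters for the ~7 s dwells).

**Inclusion rules** (per metric, all requiring ≥ 5 frames):

* run length / velocity: event must begin during acquisition and must not
  be bound at the end of acquisition; run-length samples exclude
  end-reaching events (returned separately, as the source analysis treats
  them);
* end dwell: event must arrive *and* detach during acquisition and must
  not coincide in time with another particle dwelling at the same MT end;
  immediate sub-frame dissociations remain in the sample;
* frequency: moving (nonstationary) events per minute per µm of observed
  MT.

**CDF fits.** Velocities and intensities are fit by nonlinear least
squares of the empirical CDF to the normal CDF
$\tfrac12[1+\mathrm{erf}((x-\mu)/\sqrt{2\sigma^2})]$; run lengths to the
minimum-corrected exponential CDF $1 - e^{(x_0-x)/t}$ above
$x_0 = 0.3$ µm with mean $t + x_0$; dwells to the same form with
$x_0 = 0$. Errors come from 200 resamples-with-replacement of the raw
values: the SD of the fitted mean is the SE and the 95% CI is $2\times$SE.

*Empirical CDF convention.* We evaluate the empirical CDF at distinct
values at the middle of each jump (the Hazen plotting position,
$(i-\tfrac12)/n$ for untied data). Top-of-jump heights $i/n$ are
right-biased: they break the exact symmetry of symmetric samples and make
the fit sensitive to dataset duplication; mid-jump heights satisfy both
properties exactly, and the two conventions differ only at $O(1/n)$.

**Photobleaching step counting.** Binary-segmentation changepoint search
with a BIC penalty, followed by rejection of steps smaller than half the
single-fluorophore intensity. The source analysis counted steps by eye;
the algorithmic criterion is ours, and the amplitude floor guards against
noise splits.

**Contrast.** The population SD of all pixels of each tubulin-channel
frame. The organization renderer is phenomenological — mass-conserving
interpolation from a homogeneous field to point-like (aster) or line-like
(bundle) foci — and exists to exercise this statistic, not to model the
physics of aster assembly.

## Fixtures: what the defaults mean

The packaged fixtures (`fixture_config()`) encode the study conditions the
estimators are validated against:

| fixture | conditions |
|---|---|
| `hset_diffusion` | D = 6.3×10⁴ nm²/s, 206 tracks, 0.1 s frames |
| `dmotor_diffusion` | D = 9.4×10⁴ nm²/s, 197 tracks |
| `dtail_diffusion` | D = 1×10³ nm²/s, 200 tracks |
| `tubulin_transport` | v = 8.9 ± 2.0 µm/min, runs Exp(4.2 µm), dwells Exp(25 s) |
| `qdot_hset` | runs Exp(3.7 µm), dwells Exp(37 s) |
| `qdot_dtail` | runs Exp(4.0 µm), dwells Exp(7 s) |
| `cluster_intensity` | singles vs clusters of 3–20 dyes (expected fold 11.5) |
| `org_aster` / `org_bundle` | 15 s frames, 30 min, plateau ~10 / ~20 min |

Choices the source conditions do not pin down, and how we made them:

* **Velocity spread** σ_v = 2.0 µm/min, consistent with the width of
  published per-event velocity histograms for clustered kinesin-14.
* **MT geometry.** GMPCPP-stabilized tracks of 15–30 µm; binding positions
  uniform along the track. Event density matters: the dwell-coincidence
  rule removes *long* dwells preferentially if MT ends are crowded, so the
  processive fixtures spread events over 200–300 MT-movie tracks (~5
  events per track per movie-equivalent), the sparse regime the source
  kymographs display. Crowded fields (tens of events per MT) are not a
  regime this analysis is valid in.
* **Association lifetime** of diffusive motors: 20 s. The MSD is fit over
  5 s of lag, which requires tracks substantially longer than 5 s; short
  (≈6 s) lifetimes leave too few long lag pairs and inflate the
  seed-to-seed variance of D.
* **Run-length scale = the printed mean.** The minimum-corrected estimator
  adds $x_0$ to the fitted decay, but its selection effects (≥ 5-frame
  minimum, exclusion of end-reaching runs, frame-sampled endpoints) push
  the other way; on exponential data at these conditions the two
  approximately cancel, so the published mean run lengths are used
  directly as generative means.
* **Noise and background** are unstated in the source; defaults
  (background 200 a.u., Gaussian read noise, single-dye intensity
  1000 ± 150 a.u.) are set so detection succeeds comfortably at the
  configured SNR — they calibrate the image layer, not the statistics.
* **Pauses** are simulated as stalls (not detach/reattach cycles); the
  source does not distinguish the two. The pause rule uses *net*
  displacement over the 5-frame window, exposed in configuration.
* **Cluster stoichiometry** of the intensity fixture is Uniform{3..20}
  (mean 11.5): a uniform integer range cannot have mean exactly 11.8, and
  3–20 sits inside the plausible 3–26 tubulins-per-cluster range.

## Known estimator properties (measured, not assumed)

Parameter recovery on these fixtures shows the estimator chain is accurate
to a few percent for velocity and D, and documents three small biases that
are properties of the *procedure*, faithfully reproduced:

* recovered run-length means sit ~3–8% below the generative mean at the
  published n (residual selection effects plus sampling noise at
  n = 150–200);
* the dwell sample includes sub-frame "dwells" from runs terminating
  within the 2-pixel end tolerance (indistinguishable from immediate
  dissociation at the end) and loses a few long dwells to coincidence and
  censoring; at Exp(25 s) this nets to roughly −5–10%;
* the plain (un-shifted) exponential CDF fit overshoots the sample mean
  slightly when short dwells are under-detected, which places the
  recovered 7 s dwell near 7–8 s.

All of these are inside the published 95% CIs of the corresponding
quantities.

## What passing tests do and do not show

The generator emulates: sparse diffraction-limited emitters, Brownian vs
directed 1D motion, exponential unbinding kinetics, integer fluorophore
stoichiometry with maturation and stepwise photobleaching, camera
background and read/shot noise. It does **not** emulate EMCCD excess
noise/gain, stage drift, chromatic offsets, photoblinking, heterogeneous
per-MT surface chemistry, or mechanochemical coupling between motors in a
cluster. Recovery on these fixtures therefore validates the estimator
implementations and their inclusion logic — it does not certify accuracy
on real data whose noise violates those assumptions.

## Numerical choices

* Nonlinear least squares is Levenberg–Marquardt (`minpack.lm::nlsLM`)
  initialized at moment estimates (sample mean/SD for the normal CDF, MLE
  for the exponential), with a multi-start / golden-section fallback on
  non-convergence. Spot fits bound σ ∈ [0.3, window] px and never raise.
* The 2D-Gaussian window is 9×9 px (≈ 7σ support at the default PSF).
* Linking is greedy nearest-neighbour within
  `3·sqrt(2 D_max Δt)` (D_max = 2×10⁵ nm²/s); conflicts (two tracks
  claiming one spot, or near-equidistant candidates) terminate the tracks
  involved rather than guessing identity. Global assignment is
  deliberately avoided: at single-molecule densities greedy linking is
  adequate, deterministic and testable.
* Changepoint search is binary segmentation with a BIC penalty
  (`n log(RSS/n) + (2k+1) log n`), minimum segment length 2.
* Degenerate inputs: zero-variance samples, empty frames, all-zero traces
  and empty event sets return empty results or typed errors, never crash.

## Problem sizes

The packaged analyses run at desk scale: 200–1500 binding events per
processive fixture, ~200 trajectories per diffusive fixture, 500 + 500
rendered spots for the intensity fold, 120-frame 64×64 organization
movies, and 200 resamples per bootstrap. These sizes reproduce the
published sample sizes (n = 362/150/50 and 185/197/113/133) with
eligibility to spare.
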