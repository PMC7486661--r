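---
title: "Retinal waves and the development of orientation-specific horizontal connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retinal waves and the development of orientation-specific horizontal connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(retwave)
```

## The model

Before eye opening, the retina generates spontaneous propagating bursts of
ganglion-cell activity ("retinal waves"). In developmental Stage III these
waves are ON/OFF-asynchronous: amacrine-cell (AC) cross-inhibition delays OFF
ganglion cell bursting relative to the ON wavefront by roughly a second.
`retwave` implements a model in which these waves, propagating over the
semi-regular ON/OFF retinal ganglion cell (RGC) mosaics, first refine the
feedforward receptive fields of model V1 neurons and then — through a simple
Hebbian covariance rule acting on wave-evoked cortical responses — carve
orientation-specific long-range horizontal connections (LHCs) between
cortical sites that inherit similar orientation preference from the local
ON/OFF mosaic geometry (the statistical wiring model).

The pipeline has five stages, each exposed as ordinary functions:

1. **Mosaic** (`generate_synthetic_mosaic()`, `extend_mosaic()`): jittered
   hexagonal ON and OFF lattices over a square data window, padded out to a
   3 mm disc (so waves can travel in from far away), plus a hexagonal AC
   lattice at the combined ON + OFF density.
2. **Waves** (`simulate_wave()`, `assemble_wave_dataset()`): a discrete-time
   cellular automaton (100 ms steps). ON cells excite ON cells and ACs
   within a 400 µm dendritic radius; ACs inhibit OFF cells within 40 µm. A
   waiting ON cell bursts for 1 s when its input exceeds 14 units; an OFF
   cell is held inhibited while any coupled AC is active and bursts on
   release. 80% of ON cells start in the waiting state; per-cell input
   strengths are drawn from N(1, 0.2). Waves are ignited near the disc
   boundary, recorded over the data window, Gaussian-smoothed
   (`0.85 * d_off`), per-layer max-normalized per step, classified into 12
   propagation-direction bins, and balanced across bins.
3. **Feedforward** (`place_cortical_sites()`, `train_feedforward()`): every
   data ON/OFF pair closer than `1.5 * d_off` defines a cortical site at the
   pair midpoint; weights start as `0.05 * exp(-d / d_ff)` and develop by a
   covariance rule (peak response sampling, running-average learning
   threshold, resource limit 0.14) over 15 epochs.
4. **Horizontal network** (`init_horizontal()`, `train_horizontal()`):
   all-to-all random weights (outgoing sums 0.01), responses computed as a
   sigmoid of feedforward drive plus one-step recurrent horizontal input,
   covariance-rule updates with learning rate 2e-7 (cat/monkey) or 2e-5
   (mouse), per-connection cap 5e-4, 30 (10) epochs.
5. **Spontaneous activity and analysis** (`finalize_incoming()`,
   `simulate_spontaneous_set()`, `correlation_map()`, `cuzick_trend()`,
   `clustering_indices()`, `network_similarity()`, `map_match()`, ...).

## What the synthetic mosaic emulates — and the regime that matters

The package ships no experimental mosaics; `generate_synthetic_mosaic()`
stands in for them. Its defaults are chosen once, as the study conditions for
every test and for the acceptance analyses, with the following reasoning:

- **ON density 9.64e-5 µm^-2** (hexagonal-equivalent ON spacing ≈ 109 µm,
  OFF:ON density ratio 1.3, OFF spacing ≈ 96 µm). The wave automaton's
  fixed parameters (bursting threshold 14 units, dendritic radius 400 µm,
  80% waiting fraction) make the *ON-mosaic density* the sole determinant of
  the propagation regime: the expected waiting-cell input just behind a
  wavefront is `0.8 * rho_on * pi * R_on^2 / 2 ≈ 19` units, barely above
  threshold. At this margin waves propagate at a few hundred µm/s with
  ragged, fluctuating fronts — the biologically observed Stage III regime,
  and the regime in which wave-evoked cortical responses actually vary from
  wave to wave. At densities a third higher the same parameters give fast,
  failure-free full-field sweeps (every wave drives every site identically,
  and no covariance is available for Hebbian learning); slightly lower, and
  waves die before crossing the padded disc. We consider the fact that the
  threshold value sits exactly at this margin for realistic
  mid-peripheral cat beta-cell densities to be a deliberate feature of the
  model, and we keep the generator there.
- **Jitter fraction 0.45**: node displacements uniform in a disc of radius
  `0.45 * spacing`. This yields mosaics with regularity comparable to
  measured RGC mosaics (nearest-neighbour regularity index ≈ 3-4); nearly
  perfect lattices (jitter ≤ 0.15) make wave initiation spatially
  homogeneous and collapse the diversity of wave-evoked responses.
- **Extent 670 µm**, giving ≈ 300 cortical dipole sites, the scale of the
  reference cat-scale analysis (~68,000 directed connections).
- **Wave dataset 720 waves**, within the 500-1000 range used for the
  original analyses. This number matters: receptive-field development by the
  covariance rule is a positive-feedback process (a site's response grows →
  its response fluctuations grow → its correlated inputs potentiate faster).
  At this mosaic the feedforward stage "ignites" after roughly 7,000-10,000
  wave presentations (≈ 500-700 waves x 15 epochs); datasets much smaller
  than ~500 waves leave the cortex at the sigmoid floor and no downstream
  structure can develop at the standard horizontal learning rate of 2e-7.

What the generator does **not** emulate: real mosaics' soma-size exclusion
zones (we use jittered lattices, not pairwise-interaction point processes),
ON/OFF anti-alignment statistics, and local density gradients. Passing tests
therefore demonstrate the developmental mechanism on idealized mosaics, not
quantitative agreement with any particular retina.

## Numerical and procedural choices

Decisions the underlying description leaves open, fixed as follows:

- **Smoothing and normalization domain.** Padding cells aid propagation
  only; smoothed activations are computed from, and evaluated at, *data*
  cells, and each layer is max-normalized per step over the data window
  (steps with an empty layer stay zero). Recordings are trimmed to the span
  during which the data window carries any activity.
- **Threshold semantics.** Activation requires input strictly *exceeding*
  a threshold; OFF inhibition holds while input is strictly below -0.2 and
  rebounds at >= -0.2. Each active AC contributes -1 unit to coupled OFF
  cells (the magnitude is immaterial for a single AC as long as it exceeds
  0.2).
- **Peak sampling.** Per wave, each site's peak response over the recording
  (earliest step on ties); the running-average learning threshold is
  initialised at the first sampled peak, so the first presentation performs
  no update.
- **Recurrent horizontal input** enters the response sigmoid with a one-step
  delay, the minimal causal choice; during spontaneous activity the
  recurrence is linear (a bounded sigmoid cannot "diverge", and the
  divergence-to-the-dominant-mode readout is the natural reading of the
  procedure), with divergence declared at 1e6-fold growth of the activity
  norm relative to iteration 10, capped at 500 iterations.
- **Direction classification** uses the displacement of the ON-activity
  centroid between the first and last active steps, binned into 12 sectors
  of 30 degrees; ignition centers sit at 0.9 x boundary radius at uniform
  random angles.
- **Orientation estimates.** Before feedforward training, a site's preferred
  orientation is perpendicular to its parent ON→OFF dipole axis; after
  training, the default re-derives it from the weight-weighted ON and OFF
  centers of mass (sites whose weights have decayed to zero fall back to
  parent geometry). All orientation arithmetic runs on the doubled angle.
- **Map period.** The radially-averaged FFT peak of `exp(2i * theta)` is
  tracked across filter sizes; the period is read from the longest run of
  at least 3 consecutive filter sizes agreeing within 5%. On the ~300-site
  synthetic window the quasi-period of the dipole-orientation map is
  comparable to the window itself, no stable plateau exists, and — exactly as
  in the rodent analysis — trend tests then retain all connections rather
  than excluding those shorter than one period.
- **Trend tests.** Cuzick's trend test is implemented as the rank statistic
  `T = sum l_g R_g` with integer scores, exact permutation moments and tie
  correction; Cochran-Armitage uses the standard score-based z on three
  30-degree orientation-difference groups. Both are validated against
  permutation / exact-enumeration oracles in the test suite.
- **Hopkins clustering.** Windows of radius `2 * d_off` slide at stride
  `d_off`; each window's H uses a 10% member subset and equal-count uniform
  probes, `H = ln(sum x^2 / sum w^2)`; the clustering index (CI) is the
  median windowed H of the top 20% strongest postsynaptic locations outside
  the `2 * d_off` exclusion disc.
- **Development time** (frequency-modulation experiment). The criterion is
  the number of waves until the six-bin Cuzick z first stays below -3 for two
  consecutive checkpoints; the frequency factor `gamma_f` enters the learning
  dynamics through `tau_v1 = gamma_f * tau0` (more waves inside the averaging
  window). Because modulated waves arrive `gamma_f` times faster, the
  development *time* reported and tested is `dev_waves / gamma_f` in units of
  the baseline inter-wave interval; the raw wave count is returned alongside.
  (Measured at desk scale, the wave count to criterion is flat in `gamma_f`,
  so the time conversion carries the effect.)
- **"Parallel" vs "orthogonal"** in the direction-bias experiment is defined
  relative to the wave *front line*: a moving activity front is an oriented
  edge, and the sites it drives best are those whose preferred orientation
  matches the front, i.e. the propagation axis + 90 degrees (we measure a
  mean angle of ~83 degrees between a site's best propagation axis and its
  preferred orientation). "Parallel" sites are within 15 degrees of the front
  tilt, "orthogonal" sites within 15 degrees of the propagation axis. Biased
  training recycles the biased wave pool so each network receives the
  standard number of presentations.
- **Rodent (salt-and-pepper) variant**: 11% of dipole sites are retained,
  reproducing the reference mouse network size (~34 sites, 1122 ordered
  pairs); with ~34 sites the initial weights sit near enough the resource
  limit for Boolean coupling to saturate within the mouse protocol.

## Problem sizes used by the tests and the acceptance analyses

The shipped test-suite fixtures use a reduced geometry (boundary radius
1.2-1.5 mm, 24-600 waves, ~150-300 sites) so that the full suite runs in
minutes; the acceptance analyses use the default study conditions above
(3 mm boundary, 720 waves, ~300 sites, Table-standard learning parameters,
20 horizontal networks for the convergence analysis). The heavy 20-network
convergence analysis runs the within-wave response recurrence in single
precision (`train_horizontal(..., precision = "single")`); weights and
updates always accumulate in double precision.

## Known limitations

- **Cross-initialization convergence is under-dispersed relative to the
  full-scale reference value.** With ~300 sites and 720 waves the shared,
  wave-driven weight structure accrued at learning rate 2e-7 has a
  between-pair spread of the same order as the spread of the random initial
  weights (≈ 3e-6 at 300 sites), so the mean pairwise correlation between
  independently initialised developed networks reaches ≈ 0.5-0.65 rather
  than 0.98-0.99. The decomposition is verified in the tests: order noise is
  negligible (same-initialization, different-epoch-order networks correlate
  at > 0.999); the limit is purely the accrued-signal to initial-noise
  ratio, which grows with dataset size and site count but is far from the
  full-scale operating point at desk scale.
- Only ~20-35% of sites occupy the sensitive mid-range of the response
  sigmoid after feedforward development at any one time (receptive-field
  ignition is a positive-feedback process with heterogeneous onset); sites
  at the sigmoid floor or ceiling contribute no covariance signal.
- The cellular automaton's wavefront kinematics are not calibrated against
  measured wave-speed distributions; the model is validated by its
  state-machine invariants and the ON/OFF asynchrony property.
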