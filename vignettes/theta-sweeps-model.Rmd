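---
title: "A coupled attractor model of alternating theta sweeps: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coupled attractor model of alternating theta sweeps: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(thetasweeps)
```

## The model

`thetasweeps` simulates two coupled continuous attractor networks (CANs)
driven by a simulated animal's behavior.

**Head-direction ring.** `N` theta-modulated head-direction (HD) cells with
preferred directions equally spaced on the circle obey a rate equation with a
Gaussian recurrent kernel, divisive global inhibition, firing rate
adaptation, and a head-direction-tuned sensory input whose gain is modulated
by a medial-septal theta sinusoid:

- synaptic input: `tau * dh/dt = -h + J * f(h) - a + I(theta_hd, v, t)`
- rates: `f(h)_j = h_j^2 / (1 + k * sum(h^2))` (sums carry the ring measure
  `2*pi/N`, see *Numerics* below)
- adaptation: `tau_a * da/dt = -a + m * f(h)`
- kernel: `J(d) = J0 / (2*pi*b^2) * exp(-d^2 / (4*b^2))`, `d` the circular
  distance
- theta gain: `1 + abar * v * sin(omega_theta * t)` — the modulation depth
  scales linearly with running speed and vanishes at rest.

**Grid-cell torus.** One or more grid modules are `n_side x n_side` sheets of
preferred phases with periodic boundaries. Physical position maps to the
torus through a shear matrix with axes sixty degrees apart and a modulo by
the grid spacing `lambda`, giving hexagonal firing fields. The module is
driven by a closed-form feedforward field standing in for conjunctive
grid-by-direction cells: a sum of Gaussian bumps at the position phase, each
shifted by `w0 = 1/9` phase radians along the preferred direction of the
contributing HD cell and weighted by that cell's rate, with overall gain
`(T0*v + A) * thetagain`. Recurrence uses the same Gaussian/divisive motifs,
evaluated by FFT circular convolution (the dense weight matrix, which would
be `n_side^4` entries, is never materialized; a test checks the FFT path
against the dense product on a small torus).

With adaptation and theta modulation on, the HD bump is released from the
sensory input every theta trough and recaptured every peak; adaptation makes
the symmetric state unstable, so the bump swings alternately left and right
of the head direction. The swinging internal direction shifts the
conjunctive drive, and the grid bump inherits left-right-alternating
location sweeps.

## Parameters: printed constants and calibrated defaults

Fixed by the published model description: `N = 100` HD cells, rate time
constants 10 ms, adaptation time constant 100 ms, HD kernel width
`b = 0.4` rad, grid kernel width `b = 0.8` phase rad, conjunctive offset
`w0 = 1/9` phase rad, grid adaptation 0.7 (dorsal) to 1.8 (ventral).

The remaining strengths are not printed and were calibrated once so that the
headline quantities are reproduced, then frozen as defaults:

| parameter | default | role |
|---|---|---|
| `J0` (both) | 1 | recurrent strength (continuum units) |
| `k` (both) | 0.05 | divisive inhibition |
| `A` (HD) | 4 | sensory-input strength |
| `b_in` (HD) | 0.4 | sensory-input width (equals `b`) |
| `abar` (both) | 1.3 | theta depth per m/s |
| `m` (HD) | 0.49 | HD adaptation |
| `omega_theta` | 2*pi*9 | theta frequency (9 Hz, inside the 5–9 Hz band used by the skipping fit) |
| `T0`, `A` (grid) | 4.57, 1 | conjunctive speed gain and baseline |
| `lambda` | 0.4 m | default module spacing |
| rate scale | 4 Hz/unit | model rate to Hz for Poisson spikes |

At these defaults a fast (0.5 m/s) straight run yields a mean HD peak offset
of 17.0 degrees and a mean location sweep angle of about 27 degrees with
alternation score 0.86; the three HD-cell regimes (adaptation only, theta
only, both) give tuning widths near 115, 98 and 121 degrees.

## Numerical choices

- **Integration.** Explicit Euler at `dt = 1 ms` (a tenth of the rate time
  constant). Step-halving and sheet-resolution-doubling tests bound the
  discretization error of the bump-center traces.
- **Lattice measure.** The discrete sums in the rate, inhibition and
  conjunctive-drive terms are multiplied by the lattice cell size (`2*pi/N`
  on the ring, `(2*pi/n_side)^2` on the torus, `2*pi/N` in the conjunctive
  sum), making the dynamics invariant to the number of cells. Headline
  simulations use a 100 x 100 sheet; the test-suite and acceptance runs use
  32–48 cells per side, which the resolution-doubling test shows is already
  converged.
- **Symmetry breaking.** The left-right symmetric state is an exact unstable
  fixed point; started from it, the sweep instability must grow out of
  floating-point rounding and takes seconds to appear. The warmup therefore
  ends with a 30 ms sensory kick 0.05 rad off the head direction, and sweep
  statistics discard the first nine theta cycles as onset transient.
- **Decoding.** Internal direction and location are circular population-vector
  means; samples whose mean resultant length falls below 0.1 are flagged
  incoherent, not interpolated. The torus-to-physical inverse picks the
  lattice preimage nearest an anchor at the first sample and continues by
  nearest-preimage unwrapping, so decoded sweeps may leave the arena.
- **Skipping fit.** The autocorrelogram model (theta cosine plus a
  half-frequency interfering cosine under an exponential envelope, plus a
  narrow zero-lag Gaussian) is fit by bounded L-BFGS-B least squares from a
  deterministic multi-start grid (8 theta frequencies x 2 amplitude
  configurations, best fit re-polished). Parameter recovery on noiseless
  synthetic autocorrelograms is within 1%.

## Measurement conventions

- **Theta cycles** are delimited by the septal drive's phase
  (`omega_theta * t mod 2*pi`); the drive is the model's clock.
- **Sweep records.** Per cycle, the sweep tip is the decoded location at
  maximum displacement from the concurrent animal position (sweeps return
  within the cycle, so the tip, not the cycle end, defines the sweep);
  `alpha` is the signed angle from the instantaneous movement direction
  (left positive). Cycles with incoherent samples or median speed below
  2 cm/s are excluded. The HD sweep is summarized by the signed offset at the
  moment of peak population rate. The alternation score follows the
  three-sweep sliding-window rule with plain angle differences.
- **Tuning width.** Occupancy-normalized directional tuning curves (6-degree
  bins) from Poisson spikes, smoothed with a wrapped Gaussian, reported as
  FWHM. The paper does not define its width estimator; the smoothing
  bandwidth (30 degrees) is the one calibrated constant of the estimator,
  chosen once so the classic-regime width matches the printed 115 degrees.
  The width protocol is a constant 30 deg/s rotation at 0.7 m/s for three
  revolutions. Width values quoted anywhere in the package are specific to
  this estimator and protocol.

## What the synthetic trajectories do and do not emulate

The generators produce straight runs, constant-rate turns, chained segments
with immobility, and smooth random walks with reflective turning at the
walls of a square arena. They emulate the kinematic statistics that drive
the model (speed, heading, their continuity) but none of the postural or
sampling artifacts of real tracking (head-body dissociation, tracking noise,
variable frame rates). Tests passing on these inputs show the model and the
metrics behave as designed, not that real recordings would yield the same
numbers.

## Design choices where the design was open

- **Theta frequency.** The skipping-fit frequency band (garbled in the
  source as "[10p; 18p]") is read as 10*pi–18*pi rad/s, i.e. 5–9 Hz. The
  model's default theta is 9 Hz: within that band, and, empirically, the
  frequency at which the trough-release/peak-recapture cycle leaves the bump
  about 17 degrees off axis at the population-rate peak. At 8 Hz the bump is
  recaptured before the rate peak and the measured peak offset collapses.
- **Conjunctive offset units.** `w0 = 1/9` is interpreted as phase radians
  (1/9 rad is 1.8% of the 2*pi sheet width, matching the printed
  parenthetical).
- **Exponent signs.** The printed Gaussian kernels and inputs omit the minus
  sign in the exponent; Gaussian profiles are clearly intended and are
  implemented with negative exponents. The phase mapping likewise needs a
  division by `lambda` before scaling to phase radians for the phase to be
  dimensionless and lambda-periodic.
- **Connection noise.** The sensitivity analysis names recurrent-connection
  inhomogeneity without defining it; it is implemented as seeded
  multiplicative Gaussian jitter on kernel weights, with SD 0.05 as the
  reference (100%) level.

## Known limitations

Three published relationships are *not* reproduced at the calibrated
defaults, and the corresponding checks in the test suite fail by design
rather than being weakened:

1. **Non-skipping tuning width.** Removing adaptation leaves the bare
   attractor profile, whose width is set by `b = 0.4` rad (about 99 degrees
   under the package estimator, vs the printed 116). In this implementation
   it is adaptation that broadens the classic and skipping profiles to
   ~115/121 degrees; a regime where the no-adaptation width also reaches
   ~116 was not found at the printed `b`.
2. **Sweep length vs speed.** At parameters that reproduce the 24.6-degree
   sweep angle the conjunctive input anchors the grid bump to the position
   phase, so faster running tightens tracking and slightly shortens sweeps;
   the published increasing trend holds only in weak-input regimes whose
   sweep angles are 5–10 degrees.
3. **Angle growth along the dorsal-ventral axis.** Grid adaptation amplifies
   the forward (tracking) component of bump motion, so the location sweep
   angle decreases with `m` instead of increasing; it exceeds the direction
   sweep angle at the dorsal default but not at 1.2–1.8.

Additionally, theta phase precession of skipping cells during turning is
present only as a weak, non-significant circular-linear correlation in this
regime (the crossing phases are bimodal within the cycle), so the package
tests the precession estimator against constructed data rather than
asserting significance on model spikes.

## Reproducing the headline numbers

```{r}
# straight-run sweep statistics
tr <- make_straight_run(0.5, pi / 4, 8)
run <- run_coupled(tr, hd_params(), grid_params(), warmup = 0.5)
track <- decode_track(run)
recs <- segment_sweeps(track, tr, run$theta_phase, hd_pop_rate = run$hd$pop_rate)
sweep_stats(recs[recs$cycle_index > 9, ])
```

`scripts/acceptance.R` runs this plus the three tuning-width regimes and
writes the resulting numbers as JSON.
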