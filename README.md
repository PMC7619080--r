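# thetasweeps

Grid cells and head-direction (HD) cells do not just report where the animal
is and where it faces: within each cycle of the 8–10 Hz theta rhythm their
decoded representation sweeps away from the animal and back, alternating left
and right of the direction of travel in open environments. `thetasweeps`
implements a mechanistic account of those alternating sweeps as a pair of
coupled continuous attractor networks — a ring of theta-modulated HD cells
and a torus of grid cells — with firing rate adaptation and a speed-scaled
medial-septal theta drive, together with the analysis toolkit needed to
quantify the phenomenon (sweep segmentation, alternation score,
theta-cycle-skipping index, directional tuning width, circular-linear phase
precession). It is aimed at computational neuroscientists who want to probe
the mechanism, and at experimentalists who want to run the same spike-train
statistics on their own data.

## The model in brief

The HD ring obeys

    tau dh_i/dt = -h_i + sum_j J_ij f(h_j) - a_i + I_i(theta_HD, v, t)
    f(h_j)      = h_j^2 / (1 + k sum_j h_j^2)          (divisive inhibition)
    tau_a da_i/dt = -a_i + m f(h_i)                    (rate adaptation)
    J_ij = J0/(2 pi b^2) exp(-d(x_i, x_j)^2 / (4 b^2)) (ring Gaussian kernel)

with a Gaussian sensory input at the current head direction whose gain
`1 + abar * v * sin(omega_theta t)` oscillates at theta, deeper at higher
running speed. Adaptation destabilizes the centered bump; every theta trough
releases it and every peak recaptures it, so the *internal direction* (the
bump's circular mean) swings alternately left and right of the head axis.

Each grid module is the same dynamics on a periodic `n x n` sheet of phases.
Physical position enters through a 60-degree shear and a modulo by the grid
spacing `lambda` (hexagonal fields), as a feedforward field standing in for
conjunctive grid-by-direction cells: Gaussian bumps at the position phase,
shifted by `w0 = 1/9` phase radians along each HD cell's preferred direction
and weighted by its rate, with gain `(T0 v + A)` times the theta gain. The
swinging internal direction steers this drive, so the decoded *internal
location* sweeps left-right ahead of the animal.

Printed model constants (cell counts, time constants, kernel widths, `w0`,
the dorsal-to-ventral adaptation range) are built in; the remaining strengths
ship as calibrated defaults documented in the methods vignette
(`vignettes/theta-sweeps-model.Rmd`), which also records what the
calibration can and cannot reproduce.

## Worked example

Simulate a fast straight run, decode the grid module, and summarize the
per-theta-cycle sweeps (the first nine cycles are discarded as the
sweep-onset transient):

```r
library(thetasweeps)

tr    <- make_straight_run(0.5, pi / 4, 8)      # 0.5 m/s, heading 45 deg, 8 s
run   <- run_coupled(tr, hd_params(), grid_params(), warmup = 0.5)
track <- decode_track(run)
recs  <- segment_sweeps(track, tr, run$theta_phase, hd_pop_rate = run$hd$pop_rate)
sweep_stats(recs[recs$cycle_index > 9, ])
#> <sweep_stats> 62 cycles
#>   location sweep angle  mean|alpha| = 26.8 deg (circ. var 0.042)
#>   direction peak offset mean        = 17.0 deg
#>   sweep length          mean        = 0.006 m (0.10 phase rad)
#>   alternation score                 = 0.865
```

The location sweeps point about 27 degrees off the running direction
(published model value 24.6), the internal direction is 17.0 degrees off the
head axis at the population-rate peak (published 17.0), and the alternation
score of 0.86 says the sweeps go left-right-left-right almost perfectly.
"Clockwise" turns correspond to negative angular speed throughout (standard
counterclockwise-positive convention).

Single-cell statistics work on any spike train. For a model theta-skipping
cell whose preferred direction sits 40 degrees off a fixed heading:

```r
run  <- run_hd(make_straight_run(0.5, 0, 40), hd_params(), warmup = 0.5)
j    <- which.min(abs(hd_pref_dirs(100) - 40 * pi / 180))
spk  <- poisson_spikes(run$r[, j] * 4, run$t, seed = 1)
fit_skipping_model(autocorrelogram(spk))
#> <skipping_fit> omega=56.43 rad/s (8.98 Hz) a1=0.000 a2=0.299 b=0.339 c=-0.381 tau1=5.000 tau2=0.0022
#>   p1=0.332 p2=0.896 TS=0.629 (rss 0.496)
```

A theta-skipping index of about 0.6 (well above the 0.1 criterion) — the cell
fires on alternating theta cycles because the direction sweep only reaches it
every other swing.

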