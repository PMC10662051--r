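---
title: "Modelling the DDB–KIF16B tug-of-war: simulation, segmentation and statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the DDB-KIF16B tug-of-war}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Intracellular vesicles are hauled along microtubules by teams of
opposite-polarity motors: dynein–dynactin–BICD2N (DDB) walks towards the
minus end, kinesin-3 KIF16B towards the plus end.  When both teams engage
the same cargo they can enter a tug-of-war whose outcome — unidirectional
runs, pauses, directional reversals — depends on how many motors of each
kind are attached at any moment.  `cargotug` implements the three
computational layers needed to study this system quantitatively: a
stochastic stepping simulator of motor teams on a microtubule lattice, a
Monte-Carlo change-point segmentation of position–time tracks into runs
and pauses, and a weighted-statistics layer for classifying and comparing
track populations.

```{r setup}
library(cargotug)
```

## The stepping model

Each cargo carries a team of motors in an *attachment area* that exchanges
instantaneously with a reservoir on the vesicle surface.  The total motor
number per cargo is drawn from a Gaussian with mean $\mu$ and standard
deviation $\sigma(\mu) = 1.0683\sqrt{\mu}$ (rounded, clipped at zero), and
split binomially between DDB and KIF16B according to their mean numbers.
The microtubule is a one-dimensional lattice of 8-nm sites with seven
parallel lanes (protofilaments); a lane is drawn at each attachment from a
discrete Gaussian over lanes $-3\ldots3$ (SD one lane, mode on the central
protofilament), and at most one motor may occupy a given (lane, site) —
motors can neither attach nor step onto an occupied site.

Motors are Hookean springs with a dead zone: with deflection
$\Delta x = x_\mathrm{head} - X_V$ the force on the cargo is
$F = \kappa(\Delta x \mp L)$ for $|\Delta x| > L$ and zero otherwise.
Active motors step with a Michaelis–Menten rate in ATP whose catalytic and
ATP-binding constants are Boltzmann-distributed in the resisting load,

$$s([\mathrm{ATP}], F) = \frac{k_\mathrm{cat}(F)\,[\mathrm{ATP}]}
  {[\mathrm{ATP}] + k_\mathrm{cat}(F)/k_b(F)},\qquad
  k_m(F) = \frac{k_m^0}{p_m + q_m e^{F\delta/k_BT}},$$

with $k_\mathrm{cat}^0 = v_f/d$ set by the motor's individual maximal
velocity.  Assisting loads leave the rate at its zero-load value;
resisting loads beyond the stall force produce slow constant backward
creep at $v_b/d$.  The load distance $\delta$ is not a free parameter: it
is calibrated by root-finding so that the stepping rate at the stall force
equals 0.1 s$^{-1}$, and since $k_\mathrm{cat}^0$ differs between motors,
$\delta$ is recalibrated for every attaching motor (the calibration is a
cheap bisection and keeps the stall constraint exact per motor).  The same
$\delta$ enters $k_\mathrm{cat}$ and $k_b$; treating the two as sharing
one load distance is the simplest reading of the shared symbol and is the
choice made here.

Detachment follows a Bell law, $k_d(F) = k_d^0\,e^{|F|/F_d}$ —
*increasing* exponentially with load.  A decreasing (catch-bond-like)
variant is available via `detachment_rate(..., literal_sign = TRUE)` for
comparison, but the increasing form is the default since that is the
behaviour the model is meant to capture.  A configurable fraction of
motors is *inactive* (bound, non-stepping, with a lower force-free
detachment rate); DDB additionally has a *diffusive* class that hops along
the lattice with rates
$s_\pm(F) = s_0\,e^{\pm|F|d/2k_BT}$ biased towards its spring equilibrium
(the ratio $e^{|F|d/k_BT}$ satisfies detailed balance with respect to the
spring's Boltzmann distribution, which the test suite verifies against an
enumerated birth–death chain).  Activity class and individual maximal
velocity are redrawn at every attachment, modelling instantaneous exchange
with the reservoir.

Events (attachments, detachments, forward/backward steps, diffusive hops)
are scheduled with the Gillespie algorithm.  After each state-changing
event the overdamped cargo re-equilibrates in the potential of the
attached springs.  Because the total spring energy is convex and piecewise
quadratic in one dimension, the implementation first places the cargo at
the force-balance point nearest its current position (bisection on the
monotone total force) and then applies Metropolis proposals
(default 100 proposals of ±2 nm) to sample thermal fluctuations around the
minimum.  A fixed-length random walk started from the old position would
lag behind a motor stepping at ~100 steps/s and inject a spurious
resisting load of order 0.1–0.3 pN — enough to bias velocities by several
percent — so equilibrating deterministically first and thermalising second
is both closer to the stated physics (the cargo "diffuses around its
equilibrium position") and numerically unbiased.  With no motor attached
the cargo position is simply carried forward.

A simulation starts with no motor attached; measurement begins after a
4-s relaxation window and the run ends at 80 s or as soon as no motor is
attached.  Tracks are sampled every 0.1 s (0.3 s available), mirroring
10-fps streaming and 3.3-fps time-lapse imaging.

### Parameters and defaults

A complete per-motor constant set is not fixed by the main-text numbers
this model is anchored to, so every constant ships as a documented,
overridable default chosen from the single-molecule literature:

| parameter | KIF16B | DDB | rationale |
|---|---|---|---|
| $\kappa$ (pN/nm) | 0.3 | 0.2 | kinesin/dynein linkage stiffness range |
| $L$ (nm) | 50 | 50 | motor + adapter contour length |
| $F_s$ (pN) | 6 | 4 | kinesin-3 / activated-dynein stall forces |
| $F_d$ (pN) | 3 | 2 | Bell force scales for kinesin / dynein |
| $k_a$ (1/s) | 0.15 | 0.05 | see below |
| $k_d^0$ (1/s) | 0.880 | 0.308 | $v\ln 2/L_\mathrm{med}$ from measured medians |
| $v_b$ (nm/s) | 5 | 5 | slow super-stall creep |
| $d$ (nm) | 8 | 8 | tubulin dimer spacing |
| inactive / diffusive | 20% / — | 10% / 10% | measured non-stepping fractions |
| $s_0$ (1/s) | — | 50 | diffusive DDB mobility, $D = s_0 d^2/2 \approx 1.6\times10^{-3}\,\mu m^2/s$ |

The force-free detachment rates are derived from the measured
single-molecule medians (KIF16B: 0.80 µm/s velocity, 0.63 µm run length;
DDB: 1.46 µm/s, 3.29 µm) assuming exponential run lengths,
$k_d^0 = v\ln 2 / L_\mathrm{med}$.  Individual maximal velocities are
log-normal with median and IQR matched to the same single-molecule
velocity distributions (0.80 ± 0.63 and 1.46 ± 1.63 µm/s).  The shared
Michaelis–Menten constants ($k_b^0 = 1350\,$mM$^{-1}$s$^{-1}$,
$p_b = 0.05$, $p_\mathrm{cat} = 0.5$) put $K_M$ near 75 µM, so the
default 2.5 mM ATP (imaging-buffer concentration) is near-saturating.
$k_BT = 4.11$ pN·nm.

The attachment rates are the one genuinely free pair.  They were fixed
once so that the baseline condition (mean 8 DDB and 14 KIF16B per
attachment area) operates in the low-attached-number regime — on the order
of one attached DDB and two to three attached KIF16B at a time — which is
the regime in which mixed teams produce a mixture of minus, plus,
reversal and stationary tracks rather than a frozen tug-of-war.  Higher
attachment rates (or much lower detachment rates, or several-fold larger
motor numbers) drive the system towards persistently balanced teams and
near-stationary cargoes; the acceptance suite checks exactly this
direction of effect.

```{r}
kif16b_params()
```

## Track segmentation

A track $(t_i, x_i)$ is approximated by a piecewise-linear function
$f(t)$ through change points, minimising

$$H = \sum_i \big(x_i - f(t_i)\big)^2 + \mu N_{cp},$$

with distances in nm and $\mu = 10{,}000$ nm² per interior change point.
Minimisation is simulated annealing: change points start equally spaced in
time on the track, 4000 Metropolis updates run at $\beta = 0.005$, then
1000 updates at each tenfold increase of $\beta$ up to 50.  Moves are a
positional shift of a random change point (uniform, amplitudes
$\epsilon_x$, $\epsilon_t$), insertion of a change point at a random data
point, or removal of a random change point; proposals that break time
ordering count as rejected updates.  Acceptance is
$\min(1, e^{-\beta\Delta H})$ with $\Delta H$ computed incrementally over
the affected window and cross-checked against full recomputation every
`check_every` updates (the bookkeeping error is reported and tested to be
below $10^{-6}$ relative).

Values the cost function does not pin down were fixed as follows:
$\epsilon_x = 200$ nm and $\epsilon_t =$ two sampling intervals (large
enough to traverse a pause in a few accepted moves, small enough for
useful acceptance rates at the final $\beta$); initial change-point count
$\max(1, \lfloor \Delta T / 5\,\mathrm{s}\rfloor)$, one candidate per
plausible motility phase; move probabilities 0.8/0.1/0.1 for
shift/add/remove, favouring refinement over dimension changes.  Shifted
change points are free points in $(t, x)$; added ones sit on data points.

Segments between change points are labelled by three rules, applied to
the data points they span: a segment whose endpoint-to-endpoint speed is
below 100 nm/s is a pause; a one-data-point segment is merged into the
following segment (the trailing one into its predecessor); a run whose
travelled distance is below 500 nm becomes a pause.  The 100 nm/s rule is
applied to $|{\rm slope}|$ — a signed reading would classify every
negative run as a pause, contradicting the existence of negative runs.
The merge is performed first and labels are then computed on the merged
index ranges, so all rules act on well-defined segments.  Adjacent
segments of the same kind are *not* merged by default (merging would alter
pause counts); `anneal_config(merge_same_kind = TRUE)` enables it.  Each
track is annealed on its own RNG stream derived from the global seed, so
results are reproducible track-by-track.

One caveat worth knowing: $H$ is an un-normalised sum of squares, so its
balance against $\mu$ depends on the sampling interval and localization
noise.  The defaults are tuned for 0.1-s sampling with ~20-nm noise; for
strongly different regimes $\mu$ may need rescaling.

```{r, fig.width = 6, fig.height = 3.5}
bp <- track_blueprint(change_times = c(0, 4, 8),
                      velocities = c(800, 0, -800),
                      duration = 12, noise_sd = 20)
mk <- make_track(bp, seed = 1)
seg <- segment_track(mk$track, seed = 2)
autoplot(seg)
```

## Classification and weighted statistics

Tracks are classified from their run composition: *minus* (only negative
runs), *plus* (only positive runs), *reversal* (at least one of each),
*stationary* (no run).  Pauses flanked by opposite-sign runs are *reversal
pauses*, all others *non-reversal pauses*; adjacent opposite-sign runs
with no intervening pause are *instantaneous reversals*.

Because many tracks are short (cargoes reach microtubule ends), per-track
spatial pause frequencies $x_f = n_\mathrm{pauses}/x_d$ are averaged with
weights $w_i = x_d^i / \sum_j x_d^j$ proportional to the distance
travelled, with

$$\bar{x}_f = \sum_i w_i x_f^i,\qquad
  \sigma_f = \sqrt{\frac{\sum_i w_i (x_f^i - \bar{x}_f)^2}{(N-1)/N}},\qquad
  \sigma_{\bar{x}} = \frac{\sigma_f}{\sqrt{N-1}}.$$

The travelled distance of a track is the sum of the absolute run-segment
displacements.  At $N = 1$ the SD/SEM formulas are undefined and 0 is
returned with a warning.  Sample comparisons use a weighted two-sample
Kolmogorov–Smirnov test: the statistic is the supremum gap between
weighted ECDFs; for the p-value the weights enter through effective sample
sizes $(\sum w)^2/\sum w^2$ in the classical asymptotic formula.  The
study this follows modified a standard two-sample implementation without
stating how weights enter the null distribution; the effective-sample-size
route is the standard choice and reduces exactly to the unweighted
asymptotic test under uniform weights (verified to $10^{-9}$).  Bonferroni
correction multiplies p-values by the number of comparisons, capped at 1.
For pause velocities, the segment's endpoint slope is the default
summary (the mean instantaneous velocity is also available in the segment
table) — within a pause the slope is the quantity the 100 nm/s rule
constrains.

Simulated tracks run on effectively infinite microtubules and are longer
than experimental ones, so `resample_to_durations()` chops each simulated
track sequentially into pieces with durations drawn (with replacement)
from an experimental duration sample, discarding a trailing remainder
shorter than its drawn duration, and weights every piece by
1/(number of pieces).  Chopping order and remainder handling are
otherwise unconstrained choices; sequential-with-discard is the simplest
scheme that biases neither early nor late track portions.

## The synthetic-data generator

`track_blueprint()`/`make_track()` produce the ground-truth fixtures the
segmentation and statistics layers are tested against: piecewise-linear
position signals (piecewise-constant velocity, the model underlying the
segmentation cost) plus iid Gaussian localization noise, 20 nm by default
— consistent with sub-pixel tracking at 87-nm pixels.  For single-molecule
trajectory emulation (`simulate_single_molecules()`) the default noise is
30 nm, reflecting the poorer precision of dim single fluorophores compared
with bright vesicles.  `make_duration_sample()` supplies log-normal track
durations matched to a median and IQR, feeding the resampler.  What the
generator deliberately does *not* emulate: photophysics (blinking,
bleaching), pixelation, stage drift, curved microtubules, or correlated
noise.  Tests passing on these fixtures therefore demonstrate correct
recovery under the model's own assumptions — piecewise-constant velocity
with white Gaussian noise — not robustness to every artefact of real
imaging data.

## Numerical choices and degenerate inputs

* Root-finding (stall calibration, force balance) uses bracketed
  bisection; the stall residual is below $10^{-9}$ relative.  Motors whose
  zero-load rate falls below the 0.1 s$^{-1}$ stall target are rejected in
  the user-facing calibrator and treated as $\delta = 0$ inside the engine
  (log-normal velocity draws make this astronomically rare).
* Attachment targets the lattice site nearest the cargo (zero-deflection
  attachment); the lane is the only randomly chosen coordinate.
* Ties and degenerate tracks: tracks with fewer than two samples are
  skipped by the segmenter; a zero-duration segment reports zero slope and
  becomes a pause; empty segment lists refuse classification.
* Reproducibility: every cargo and every track segmentation runs on its
  own RNG stream derived from the global seed, so single items can be
  re-simulated in isolation and results do not depend on batch size.
* All randomness flows through R's RNG (also inside the compiled code),
  so `set.seed()` governs everything.

## Problem sizes used by the test-suite

The package's checks run at desk scale by design: 5000 single-molecule
runs and 1000 sampled trajectories per species for the calibration
medians; 200 synthetic run–pause–run tracks (20-nm noise, 0.1-s sampling)
for change-point recovery; exhaustive-enumeration comparisons on 30-sample
tracks with up to two interior change points; and 200 cargoes per
condition for the motor-number/attachment-rate contrasts.  These sizes
give Monte-Carlo errors comfortably inside the tested tolerances.

## Known limitations

* The cargo is a point in one dimension: no 3-D geometry, membrane
  deformation or hydrodynamics, so the elongation index can only be
  *consumed* (from fitted axes), not predicted.
* No microtubule ends or junctions; finite-length effects are emulated
  only through duration resampling.
* Motor parameters are literature-plausible defaults, not fits to any
  particular vesicle data set; quantitative class proportions at the
  baseline condition depend on them, and only directions of effect are
  asserted.
* The annealer optimises a local minimum of $H$; the test suite bounds its
  gap to exhaustive minimisation only on small instances.
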