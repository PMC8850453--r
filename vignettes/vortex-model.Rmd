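---
title: "The pedvortex model: collective rotation of confined self-propelled pedestrians"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The pedvortex model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedvortex)
```

## The scientific problem

Crowds of people roaming freely inside a rectangular room spontaneously
develop vortex-like collective rotation, and — strikingly — almost always
rotate counterclockwise (CCW). `pedvortex` implements a minimal
self-propelled-particle model that reproduces this behaviour with two
ingredients: dissipative pedestrian–wall interactions (which drive a
density-dependent transition to rotation of *either* sense) and an
individual turning preference at walls (a majority of left-turners, which
breaks the CW–CCW symmetry). The package also ships the full observable
stack used to analyse either simulated or externally tracked trajectories.

## The model

Each agent `i` is a disc of radius $r_0$ with unit mass, integrated by
forward Euler ($\mathrm{d}t = 0.01$ s by default) under four forces:

1. **Self-propulsion** $\mu (v_d - v_i)\,\hat v_i$: relaxation of the speed
   toward the desired walking speed $v_d$ along the current moving
   direction. There is no preferred direction of motion and no goal; the
   direction changes only through interactions. The relaxation time is
   $m/\mu = 0.25$ s.
2. **Agent–agent repulsion**: a long-range exponential
   $A_p e^{-(r_{ij}-2r_0)/B_p}$ along the centre line (emulating social
   distancing) for $r_{ij} > 2r_0$, switching to a Hertzian contact
   $\varepsilon (1 - r_{ij}/2r_0)^{3/2}$ at contact. The piecewise form is
   implemented exactly as printed, including the finite jump at
   $r_{ij} = 2 r_0$ (the long-range branch approaches $A_p$, the contact
   branch starts at 0); see "Numerical behaviour" below for the
   consequences.
3. **Wall repulsion with damping**: the same scheme against each wall,
   amplitude $A_{w1}$, decay $B_w$, plus a dissipative term
   $-\gamma v^n_i$ acting on the normal velocity component. $\gamma$ is
   the control parameter of the vortex transition.
4. **Turning preference (optional)**: a tangential wall force
   $A_{w2} e^{-(r_{iw}-r_0)/B_w} \cos\alpha \; \hat t_{\pm}$, active only
   while the agent moves toward the wall ($|\alpha| < 90^\circ$, $\alpha$
   measured between the heading and the approach direction), pushing
   CCW-preferring agents (chirality $+1$, 60% of the population by
   default) along $\hat t_+$ and CW-preferring ones along $\hat t_-$.

A note on the $\alpha$ convention: defining $\alpha$ against the *inward*
normal would make the force vanish exactly for head-on approaches,
contradicting its stated purpose (maximal head-on, zero parallel or
receding). We therefore compute $\cos\alpha = -\hat v_i \cdot \hat n$ with
$\hat n$ the inward normal, which reproduces all stated limits.

### Default parameters

| parameter | value | units | meaning |
|---|---|---|---|
| $\mu$ | 4 | 1/s (unit mass) | propulsion gain |
| $v_d$ | 1.5 | m/s | desired speed |
| $r_0$ | 0.25 | m | agent radius |
| $A_p$, $B_p$ | 13, 0.85 | –, m | social repulsion (calibrated on Voronoi-area distributions) |
| $\varepsilon$ | 200 | – | Hertzian contact strength |
| $A_{w1}$, $B_w$ | 15, 0.4 | –, m | wall repulsion |
| $A_{w2}$ | 9 | – | turning-force amplitude (calibrated so a single $\hat t_+$ agent at $\alpha = -10^\circ$ still turns CCW) |
| $\gamma$ | 0–2 | – | wall damping (transition control parameter) |
| arena | 11.4 × 6.7 | m | rectangular enclosure, origin at the centre |

Open modelling choices resolved here (the source equations are silent):

* **Spatial extent of the damping term.** As printed, $-\gamma v^n$ would
  act at any distance; summed over four walls that is a bulk drag
  $-2\gamma \vec v$, which at $\gamma = 1.5$ caps the terminal speed at
  $\mu v_d/(\mu + 2\gamma) \approx 0.86$ m/s and contradicts the observed
  near-$v_d$ bulk speeds. The default therefore restricts damping to
  within `damping_range = 1` m of a wall surface; `damping_range = Inf`
  restores the literal reading for sensitivity checks.
* **Which wall(s).** All four walls are summed (`wall_mode = "all_walls"`,
  smooth at corners); `"nearest_only"` is available.
* **Headings at rest.** Below a speed of $10^{-6}$ m/s the moving
  direction is undefined and the previous heading is held.

## The order parameter

The normalized angular momentum
$L(t) = \frac1N \sum_i (\vec r_i \times \vec v_i)_z / |\vec r_i|$
(positions from the arena centre) weighs every agent equally and has speed
units; $L > 0$ is CCW rotation, and $|L(t)| \le \max_i |v_i(t)|$. Per-run
summaries $\langle L \rangle$ exclude a burn-in (200 s at the reference
1000 s protocol). An unnormalized variant (no $1/|\vec r_i|$) is exposed
as a robustness check.

## Simulation protocol and the phase diagram

`run_sim()` reproduces the reference protocol: positions rejection-sampled
at ≥ 1 m separation and `r0 + 0.1` m wall clearance, uniform headings,
initial speed $v_d$ (all three initial-condition choices are conventions —
the burn-in removes their influence), 1000 s runs, recorded every 0.1 s.
`run_sweep()` scans (Ped × γ) cells with deterministic per-run seeds; the
full campaign is Ped = 8–34, γ = 0–2 in steps of 0.05, 100 reps, while the
desk-scale defaults (10 reps × 300 s) give a quick qualitative map.

Pooled $L(t)$ distributions are summarized by a deliberately simple
**sign-split statistic**: the fractions of post-burn-in frames with
$L > s/2$ and $L < -s/2$ ($s$ the pooled standard deviation). Calibrated
once on pilot runs: a zero-centred unimodal regime gives ≈ 0.31 per side
(0.62 total, the Gaussian value), the damped dense bimodal regime ≈ 0.8
total with both sides ≥ 0.3, and the symmetry-broken single positive peak
≈ 0.70 vs ≈ 0.08. The frozen classifier (`classify_l_shape()`) calls
"bimodal" at total ≥ 0.75 with ≥ 0.2 per side, and "unimodal positive" at
`frac_pos ≥ 0.4`, `frac_neg ≤ 0.18`, ratio ≥ 2.5.

## Analysis operators for tracked data

* `sliding_velocities()`: central differences over a 0.76 s window (long
  enough that a pedestrian moves a useful distance at 25 fps), one-sided
  at the track ends; suppresses tracking jitter to
  $\le 2\sqrt2\,\epsilon_{\mathrm{jitter}}/w$.
* `coarse_grain_fields()`: uniform-disc ("Heaviside") kernel of radius
  $\omega = 0.25$ m normalized by $1/\pi\omega^2$ — about the physical
  footprint of a person — averaged over frames; the density field
  integrates to $N$. Speed and velocity fields are occupancy-weighted
  kernel means (cells never covered are `NA`); grid spacing defaults to
  0.1 m (the kernel radius is the only stated scale).
* `voronoi_areas()`: each cell built by clipping the arena rectangle
  against the perpendicular bisectors of all other agents
  (Sutherland–Hodgman). Exact for a rectangle, no unbounded cells, and the
  areas partition the arena to $10^{-9}$ m².
* `detect_turn_events()` / `label_turn()`: a turn is counted when the
  agent is ≤ 2 m from the faced wall, > 2 m from every corner, has an
  empty field of view (2 m, ±70°) and approaches within ±10° of
  perpendicular; the signed heading change over the following 2 s gives
  the CCW/CW label (changes below $10^{-3}$ rad are "no turn").
  Conventions chosen here: the *faced* wall is the one whose inward normal
  is most anti-parallel to the velocity (unambiguous at ±10°); the event
  anchors at the first eligible frame; the same agent opens no new event
  until it retreats beyond 2.5 m from that wall (turns are discrete
  events, not frames); $\alpha > 0$ when the velocity points right of the
  perpendicular approach.

## What the synthetic fixtures do and do not establish

`make_fixture()` builds analytic tables with exact ground truth: rotating
rings ($L = \pm$ speed), radial bursts ($L = 0$), lone wall approaches
engineered to satisfy all four turn-eligibility conditions exactly once,
mirror pairs (exact $L$ negation, swapped labels) and jittered static
tracks (velocity-noise bounds). They verify the *operators* — kernels,
clipping, detection geometry, sign conventions — against closed-form
answers. They do not emulate decision-making, gait oscillations, tracking
dropouts or occlusions in real data; a green fixture test validates the
arithmetic, not the behavioural model. Claims about the model itself rest
on the simulation-based acceptance tests (symmetry breaking, transition
structure, distribution shapes).

## Numerical behaviour and known limitations

* **Integration.** Plain forward Euler, position advanced with the
  pre-step velocity, exactly as specified; a semi-implicit variant
  (`semi_implicit = TRUE`) is provided for stability experiments.
  Single-agent speed relaxation converges at first order (halving
  $\mathrm{d}t$ halves the error; asserted in the tests).
* **Contact overlaps are not dt-converged at dt = 0.01.** In damped dense
  runs (γ = 1.5, Ped = 24), contacts occur in ≈ 0.1% of frames, and at
  $\mathrm{d}t = 0.01$ a fast pair can step ballistically into the
  contact region, where the printed force jump (the contact branch at 5%
  overlap exerts ≈ 2.2, versus 13 just outside) arrests nothing; run-max
  overlaps of 10–25% of a diameter then occur, seed-dependently. At
  $\mathrm{d}t \le 0.0025$ no contact occurs at all and overlap is
  exactly 0, while speeds and all $L$-based observables are unchanged —
  i.e. only this contact statistic is unconverged. The corresponding
  acceptance assertion (≤ 5% at dt = 0.01) is therefore left red with
  this analysis rather than smoothed away.
* **Mirror symmetry is exact, not approximate.** Wall contributions are
  summed as $(E+W)+(N+S)$ so the floating-point arithmetic is bitwise
  equivariant under $y \to -y$; mirrored runs negate $L(t)$ identically,
  which the tests assert with `expect_identical()`.
* **Scope.** No flocking/alignment terms (deliberately absent), no
  non-rectangular arenas or obstacles, no torque dynamics beyond the
  velocity direction, no ingestion of raw video.

## Worked check

```{r, eval = FALSE}
p <- model_params(gamma = 1.5, tp_enabled = TRUE)
runs <- vapply(1:10, function(s) {
  traj <- run_sim(sim_config(24, duration = 300, burn_in = 100, seed = s), p)
  time_avg_L(l_series(traj), 100)
}, numeric(1))
range(runs)   # all positive: the 60/40 turning preference forces CCW rotation
```

Every quantitative claim above is recomputed by `tests/testthat/` and
`scripts/acceptance.R`; none is asserted from memory.
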