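# pedvortex

Self-propelled-agent simulation and analysis of spontaneous vortex motion
in confined pedestrian crowds.

Pedestrians roaming freely inside a rectangular room develop collective
vortex-like rotation — and, in experiments, almost exclusively
counterclockwise (CCW) rotation. `pedvortex` implements a minimal model
that reproduces this: discs of radius $r_0$ self-propel toward a desired
speed $v_d$ along their current heading, repel each other through a
long-range "social distancing" exponential plus a Hertzian contact term,
and interact with the walls through an exponential repulsion that may
include (i) a dissipative term $-\gamma v^n$ on the normal velocity and
(ii) a tangential *turning-preference* force that pushes each agent left
($\hat t_+$, CCW) or right ($\hat t_-$, CW) while it approaches a wall:

$$m\ddot{\vec r}_i = \mu (v_d - v_i)\hat v_i \;+\; \sum_{j\ne i} \vec F^{rep}_{ij} \;+\; \vec F^{wall}_i \;+\; \vec F^{turn}_i .$$

With damping alone, dense crowds undergo a transition to rotation of
either sense; a 60/40 majority of left-turners breaks the symmetry so the
crowd essentially always rotates CCW. The collective state is measured by
the normalized angular momentum

$$L(t) = \frac{1}{N}\sum_{i=1}^{N} \frac{(\vec r_i \times \vec v_i)_z}{|\vec r_i|},$$

in m/s about the arena centre ($L > 0$ = CCW). The package is aimed at
researchers in active matter / pedestrian dynamics who want a tested,
fast (compiled-core) reimplementation of the model plus the analysis
operators — coarse-grained density/velocity fields, arena-clipped Voronoi
areas, sliding-window velocity estimation, and wall-turn event detection —
which work equally on simulated tables and external tracking exports.

## Worked example

Simulate 24 agents for 300 s with wall damping γ = 1.5 and the 60/40
turning preference, then analyse the result:

```r
library(pedvortex)

p    <- model_params(gamma = 1.5, tp_enabled = TRUE)   # defaults: mu=4, v_d=1.5, r0=0.25, ...
traj <- run_sim(sim_config(24, duration = 300, burn_in = 100, seed = 42), p)

time_avg_L(l_series(traj), burn_in = 100)
#> [1] 0.2055324
```

`⟨L⟩ = 0.21 > 0`: the crowd rotates counterclockwise (with this parameter
set, every seed gives a positive value — the symmetry is broken by the
turning preference; with `tp_enabled = FALSE` runs split between ±).

```r
ev <- detect_turn_events(traj)        # eligible lone wall-approach turns
turning_preference_summary(ev)[c("n", "pct_ccw", "pct_cw")]
#> $n        [1] 296
#> $pct_ccw  [1] 58.4
#> $pct_cw   [1] 41.6
```

58.4% of the detected wall turns are CCW — close to the 57.3% observed
experimentally and to the imposed 60% of left-turning agents.

```r
last <- traj[t == 300]
va <- voronoi_areas(cbind(last$x, last$y))
c(mean = mean(va), total = sum(va))
#>  mean  total
#> 3.183 76.380    # 24 cells partition the 11.4 m x 6.7 m arena exactly
```

Other entry points: `run_sweep()` (γ × Ped phase diagrams with
deterministic per-run seeds and checkpointing), `l_distributions()`
(pooled L(t) histograms plus a documented bimodality statistic),
`coarse_grain_fields()` (0.25 m disc-kernel density/velocity maps),
`sliding_velocities()` (0.76 s window estimates for position-only
tracking data), `make_fixture()` (analytic trajectories with exact ground
truth), and `read_trajectory()`/`write_trajectory()` (CSV + JSON-sidecar
round-tripping). A command-line front end lives in
`inst/cli/pedvortex.R`:

```sh
Rscript inst/cli/pedvortex.R simulate --ped 24 --gamma 1.5 --tp --duration 300 --seed 1 --out traj.csv
Rscript inst/cli/pedvortex.R turns --traj traj.csv --out events.csv
```

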