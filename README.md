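# wigwag

Planaria placed in a featureless arena reliably end up near the wall and
stay there (thigmotaxis), yet their spontaneous locomotion is undirected:
they glide straight ahead at roughly constant speed and sway the head
sideways ("wigwag") every second or so. `wigwag` is an R package for
studying how wall preference emerges from exactly those ingredients. It
implements an agent-based model of spontaneous planarian locomotion, the
arena geometries and region partitions of open-field preference assays,
and the trajectory statistics and distribution fits used to quantify the
behavior — so the whole claim "wall preference = straight motion +
stochastic turning + wall-tangent sliding + wall curvature" can be tested
as a reproducible pipeline on synthetic data.

## The model

The agent state is position (x_t, y_t), heading θ_t (a bearing: 0 along
+y, increasing clockwise) and a turn countdown i. Each 0.1-s tick:

- if i ≠ 0: θ_{t+1} = θ_t and i ← i − 1;
- if i = 0: θ_{t+1} = θ_t + ξ with ξ ~ Normal(μ, σ) (the wigwag angle,
  radians), and i ← max(1, round(10·k)) with k ~ LogNormal(μ_log, σ_log)
  (the wigwag interval, seconds); ξ and k are rounded to two decimals;
- the agent advances one simulation unit: (x, y) ← (x + sin θ, y + cos θ).

Lengths are in simulation units, 140 units ≡ 30 mm; speed is 10 units/s.
If the proposed position crosses the arena wall it is clamped to the
nearest boundary point and the heading is realigned to the wall tangent
closest to the incoming direction, so the agent slides along the wall
until a wigwag turn points it back inside.

Measured parameter presets are built in (`preset_params()`): intact
animals (ξ: −0.01 ± 0.34 rad; k: lognormal(0.14, 0.48) log-s), head
fragments (−0.07 ± 0.36; lognormal(0.45, 0.40)) and headless fragments
(0.01 ± 0.32; lognormal(1.0, 0.59)).

Assay analytics: wall-/central-preference indices T_w/T and T_c/T over
equal-area region partitions (5-mm wall band and a concentric similar
figure of the same area; for the donut arena, the equal-area
convex/concave annulus halves), path linearity T/N (path length over net
displacement), wall contact/detachment episodes, incidence/reflection
angles at the wall, wigwag-event extraction from tracked positions,
normal/lognormal maximum-likelihood fits, occupancy maps by Gaussian KDE
with least-squares cross-validated bandwidth on a 1-mm grid, and the
Wilcoxon / χ² / KS / t test contracts used for preference assays.

## Worked example

Simulate an intact-preset animal for 600 s in a 90-mm dish and quantify
its wall preference:

```r
library(wigwag)

field <- field_preset("circle90")          # 90-mm dish, radius 210 units
part  <- partition_regions(field)          # 5-mm wall band + equal-area centre
traj  <- simulate_planarian(preset_params("intact")$params, field,
                            duration_s = 600, seed = 1)

preference_indices(traj, part)
#> <preference_result> T = 600.1 s
#>    wall_index central_index
#>        0.4159        0.1471

wall_episodes(traj, part)
#> <wall_episodes> 12 episode(s), 0 open; mean dwell 20.8 s

kinematics(traj, part)$time_to_first_wall
#> [1] 19
```

The agent spent 42% of the assay in the 5-mm wall band versus 15% in the
equal-area central region — i.e. a clear wall preference purely from
spontaneous behaviors — first reached the wall after 19 s of essentially
straight travel, and detached and returned 12 times with a mean wall
dwell of 20.8 s per episode.

Recovering the generating turn-angle distribution from the track alone
(the parameter-recovery loop used throughout the test suite):

```r
open_traj <- simulate_planarian(preset_params("intact")$params,
                                field_preset("open"), 600, seed = 1)
fit_normal_mle(extract_wigwag(open_traj)$angles)
#> <wigwag_fit> normal(location = -0.02227, scale = 0.3373), n = 418, logLik = -138.8
```

The fitted SD 0.337 rad recovers the preset's 0.34 rad from 418 extracted
turn events.

A thin command-line front end with `simulate`, `sweep`, `analyze`, `fit`
and `synth` subcommands is installed at `inst/cli/wigwag.R` (run it with
`Rscript`); YAML run configurations are described in `?load_run_config`.

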