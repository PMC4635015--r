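---
title: "The wigwag locomotion model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The wigwag locomotion model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wigwag)
```

## The behavioral model

Spontaneous planarian locomotion is modeled as a correlated random walk
with three ingredients and nothing else:

1. **Straight, constant-speed gliding.** Between turns the agent moves at
   10 simulation units/s (one unit per 0.1-s tick) along its current
   heading. Headings are bearings: 0 points along +y and increases
   clockwise, so one tick advances the position by (sin θ, cos θ).
2. **Stochastic wigwag turning.** At stochastic intervals the heading
   changes instantaneously by ξ ~ Normal(μ, σ) radians. The interval k
   between turns is lognormal in seconds. Both draws are rounded to two
   decimals, and the interval is realised as an integer tick countdown
   i = max(1, round(10·k)). Each tick either decrements a nonzero
   countdown or (at zero) applies a turn and redraws the countdown; the
   turn therefore takes effect on the step of the tick it fires.
3. **Wall-tangent sliding.** A proposed position beyond the wall is
   clamped to the nearest boundary point and the heading set to the wall
   tangent — of the two opposite tangent directions, the one closest in
   angle to the incoming heading, with exact ties broken randomly. The
   agent then hugs the wall until a wigwag turn points it back inside.

The model deliberately excludes sensory responses (photo-, chemo-,
thermotaxis), speed modulation near walls, mechanics of the body, and
quiescence: real animals tend to stop moving after roughly ten minutes,
which is why assays are limited to 600 s, but the agent itself never
stops.

### Parameters

| Parameter | Units | Intact preset | Meaning |
|---|---|---|---|
| `angle_mean`, `angle_sd` | rad | −0.01, 0.34 | wigwag turn-angle distribution |
| `interval_logmean`, `interval_logsd` | log-s | 0.14, 0.48 | lognormal turn-interval distribution |
| `speed` | units/s | 10 | gliding speed |
| `dt` | s | 0.1 | tick length (tracking frame rate) |

Presets for head fragments (−0.07 ± 0.36 rad; lognormal(0.45, 0.40)) and
headless fragments (0.01 ± 0.32 rad; lognormal(1.0, 0.59)) are also
built in, with the sample sizes behind the measurements retained in
`preset_params()$reference_n`.

The interval notation "lognormal(0.14, 0.48)" is read as log-space
location and scale, giving a median intact interval of e^0.14 ≈ 1.15 s.
The alternative reading — median 0.14 s — was rejected because it is
inconsistent with headless animals (location 1.0) pausing *longer*
between turns, which is the defining difference between the groups.

### Numerical conventions

- **Countdown integerisation.** The decrement-to-zero interval rule needs
  an integer tick count, but 10·k rounded to two decimals need not be an
  integer. We use i = max(1, round(10·k)); the max(1, ·) floor keeps a
  degenerate tiny interval from producing two turns on one tick. With the
  check-then-act tick order, successive turns are i + 1 ticks apart.
- **Rounding.** ξ is rounded to 0.01 rad and k to 0.01 s before use, as
  part of the model definition. The effect is negligible relative to the
  distribution scales (uniform rounding noise adds variance 0.01²/12),
  with one visible consequence: a turn whose angle rounds to 0.00 rad
  changes nothing and is invisible to any downstream analysis.
- **Scale.** 140 simulation units ≡ 30 mm (14/3 units per mm), the only
  scale consistent with all the standard container sizes (30 × 60 mm
  rectangle → 140 × 280; 90-mm dish → radius 210; donut 30/45 mm →
  140/210). The 200-mm dish is modelled at the same scale (radius
  466.67 units).
- **Initial conditions.** Start at the arena centre ((175, 0) for the
  donut: mid-annulus), heading uniform on [0, 2π), initial countdown
  drawn from the interval distribution. The heading and countdown
  conventions are our choice; results reported here are insensitive to
  them because assays are long relative to one interval.
- **Collision rule.** "Realign toward the wall direction" is implemented
  as *full* alignment to the nearest tangent rather than a partial
  relaxation: observed post-contact motion is tangential regardless of
  incidence angle, which full alignment reproduces exactly and a partial
  rule only asymptotically. At a rectangle corner the realignment edge is
  the one whose inward direction is angularly closest to the incoming
  heading (ties random).

## Arenas and region partitions

Wall preference is quantified over an equal-area two-region partition:
the *wall region* is the band within 5 mm of the wall, and the *central
region* is a concentric figure similar to the arena scaled so its area
equals the band's. For the 30 × 60 mm rectangle the band area is
800 mm² and the central figure a 20 × 40 mm rectangle; for the 90-mm
dish the central circle has radius √425 ≈ 20.6 mm. The donut arena is
instead split by the circle of radius √((r_in² + r_out²)/2) into
equal-area *convex* (inner-wall) and *concave* (outer-wall) halves,
562.5π mm² each for the standard 30/45 mm donut.

Two boundary conventions are fixed package-wide (neither is dictated by
the geometry, so they are stated explicitly):

- the wall band is **closed on its inner boundary** — a point exactly at
  the margin counts as wall — so a wall-sliding agent is always inside
  the wall region; the donut split circle belongs to the concave half;
- **dwell times are counted by sample**: each of the N = T/dt + 1 samples
  contributes dt to its region, so region times sum exactly to N·dt and
  an index is simply a fraction of samples. No sub-tick interpolation is
  attempted at 0.1-s resolution. Consequently the zero-wigwag circle run
  (straight to the wall in 18.7 s, then permanent sliding) has wall
  index 5814/6001, within dt/T ≈ 1.7 × 10⁻⁴ of the continuous-time
  closed form 1 − 18.7/600; tests assert the closed form at that
  discretisation tolerance.

## Trajectory analytics

- **T/N ratio**: path length over net displacement, ≥ 1, computed on the
  approach segment (truncated before first wall contact) when used as a
  linearity measure — heading dispersion accumulates, so the ratio of a
  full-length wandering trajectory is not comparable to an approach path.
- **Wall episodes** open at the first sample inside the band after being
  outside it and close at the first sample back outside; an episode still
  open at assay end is flagged and included in the mean dwell with the
  remaining time, since animals often remain at the wall when the assay
  stops.
- **Incidence/reflection angles** use the movement direction one sample
  before and after the first contacting sample, measured against the
  wall tangent direction nearest the outgoing motion. For simulated
  trajectories (which carry an event log) contact events with a nonzero
  wigwag on the outgoing step are excluded — there the post-contact
  direction measures the spontaneous turn, not the wall response. The
  residual reflection of a sliding agent on a curved wall is the chord
  half-angle, at most asin(0.5/R) ≈ 0.2° for the smallest dish; tests
  assert tangency at 0.5°.
- **Wigwag extraction** declares an event wherever the per-tick heading
  change exceeds 0.005 rad (half the rounding grid). On noise-free
  simulated open-field data this inverts the event process exactly, up to
  the inherently invisible zero-rounded turns (~1.2% of draws at
  σ = 0.34); the round-trip test compares against the event log filtered
  to visible events. Positional tracking noise inflates apparent heading
  changes, so for noisy data the threshold must be raised accordingly —
  extraction thresholds for real tracker output are the user's
  responsibility.

## Occupancy KDE

Occupancy maps use a bivariate Gaussian kernel with a single bandwidth
(mm), evaluated by binned convolution on the 1-mm analysis grid, masked
to the arena and renormalised to sum to one. The bandwidth is selected
by least-squares cross-validation: the closed-form Gaussian-kernel LSCV
score is minimised (golden-section, via `optimize`) over a log-spaced
range spanning a factor of 10 either side of the bivariate normal
reference bandwidth σ·n^(−1/6). Two pragmatic guards:

- the O(n²) score is evaluated on at most 2000 points, thinned
  deterministically from the (sorted) pooled positions, so the selector
  is invariant to trajectory ordering;
- if the score has no interior minimum in the search range — the classic
  LSCV degeneracy for heavily duplicated or grid-snapped positions, and
  common for wall-hugging trajectories whose positions pile up on the
  boundary — the reference bandwidth is used instead and a warning is
  issued.

## Statistical contracts

Turn angles are fitted by closed-form normal MLE (mean, 1/n SD — maximum
likelihood proper, not the unbiased 1/(n−1) estimator), intervals by
lognormal MLE (the normal MLE of the logs). Preference significance uses
the exact Wilcoxon signed-rank test on paired per-animal (wall, central)
indices — one-sided by default, wall > central — and a χ² goodness-of-fit
of per-region animal counts against the 50/50 null implied by the
equal-area construction. Distribution homogeneity uses the two-sample KS
test with asymptotic p-values. Group contrasts use Welch's t test. All
of these are thin wrappers over the corresponding `stats` routines; only
the MLE closed forms are computed in-package (and are cross-checked
against an independent numerical optimiser in the test suite).

## What the synthetic data does and does not emulate

`synth_tracked_trajectory()` emulates tracker output: simulated positions
plus independent isotropic Gaussian jitter per frame, with the event log
and contact flags stripped. This supports end-to-end pipeline tests
(simulate → extract → fit recovers the preset parameters within sampling
error). It does **not** emulate: animal-to-animal parameter variability
(the presets are pooled estimates), quiescence and speed fluctuations,
body shape (the agent is a point; real contact geometry differs), or
tracker artifacts such as identity jumps and autocorrelated noise.
Passing tests therefore demonstrate the internal consistency of the
model and pipeline, not the fidelity of the model to any particular
recording.

## Problem sizes

Ensemble checks in the test suite use 50 replicates of 600-s assays
(300 s for the donut) per condition — enough that the monotone effects of
turn angle, turn interval and wall curvature on the mean preference
index are unambiguous — and parameter-recovery checks run single 600–1200-s
trajectories (~350–450 turn events) or 500 direct generator draws,
asserted within three standard errors of the generating values. The
Monte-Carlo geometry oracle classifies 10⁶ uniform points per arena.

## Known limitations

- The donut and open arenas have no wall/central preference index;
  the donut reports the convex/concave split instead, and episode
  analyses there are per-wall (5-mm bands at each wall).
- LSCV bandwidth selection degenerates on boundary-piled trajectory data
  more often than on scattered points; the reference-bandwidth fallback
  (with warning) is then the norm, as it is for the classic selector.
- Arbitrary polygonal arenas, 3-D effects and meniscus climbing are out
  of scope.
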