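---
title: "Wind-informed movement analysis with windtrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wind-informed movement analysis with windtrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(windtrack)
```

## The problem

Flying animals move through a medium that moves. A satellite-tagged bird's
trajectory is the sum of its own air vector and the wind vector, so any
question about *decisions* — when to leave, which way to go, how far to fly —
has to be asked relative to the wind the animal actually experienced.
`windtrack` connects time-ordered tracking positions (nominally every 15
minutes) with gridded reanalysis-style wind fields (6-hourly, ~80 km, six
altitude levels) and provides the full analysis chain used in studies of
wind-dependent movement in Arctic-breeding shorebirds: per-segment wind
decomposition, track metrics, altitude inference, regression models,
randomization null models for departure timing, and a counterfactual
shortest-route simulator.

## The core quantities

For a segment flown in ground direction $\alpha$ (degrees clockwise from
north) with wind components $u$ (eastward) and $v$ (northward):

* **wind support** $W_s = u \sin\alpha + v \cos\alpha$ — the signed length of
  the wind vector projected on the ground vector; positive is tailwind;
* **crosswind** $C_w = |u\cos\alpha - v\sin\alpha|$ — the perpendicular
  component, side-agnostic;
* **relative wind support** $W_s / \sqrt{u^2+v^2}$ — the cosine of the
  wind–track angle, in $[-1, +1]$, with the calm-air case defined as 0 (no
  flow, no support; this avoids 0/0 without affecting any downstream
  statistic);
* **ground speed** — great-circle distance over elapsed time between
  consecutive positions; **air speed** — ground speed minus wind support, the
  field's standard scalar approximation (not the full wind-triangle
  solution, which would require heading assumptions the data cannot
  support).

These satisfy $W_s^2 + C_w^2 = u^2 + v^2$ exactly, which the test suite
checks over random draws, along with rotational equivariance and the
dot-product identity for relative support.

## Geodesy and sampling conventions

All geodesic computation is spherical with $R = 6\,371$ km. At flight scales
of a few thousand km the sphere-vs-ellipsoid discrepancy is below half a
percent — far below tag-position noise — and it keeps closed-form oracles
exact in the tests. The polar Lambert azimuthal equal-area projection is
used for plotting only; no metric is ever computed in projected space.

Wind is sampled at the grid node and time slice nearest to each position
("closest in space and time"), with exact midpoints tying toward the earlier
slice and the lower index; the tie rule is a package convention, stated
because a convention is needed, and it is exercised by the tests. Wind for a
segment is taken at the segment start by default (`sample_at = "midpoint"`
is available). There is no interpolation in time: the ±6 h shift sensitivity
check (`temporal_shift_sensitivity()`) is the instrument for judging whether
the native temporal resolution suffices, and on slowly varying synthetic
fields it yields correlations near 1. Spatial resampling to a finer grid
(`resample_spatial()`, default target 10 km) uses separable cubic splines —
a bicubic scheme that reproduces any linear field exactly, which is the
property the tests pin down. Only upsampling is supported.

Altitude levels are named by their nominal heights ("10m", "100m", "750m",
"1500m", "2250m", "3000m"), mapped from the pressure levels of
reanalysis-style files (surface, 1000, 925, 850, 775, 700 hPa) on load.
Missing cells are a hard load error: reanalysis extracts should be complete,
and silent filling hides coverage bugs.

## Track metrics and classification

Track summaries are computed on the over-ocean leg (first to last
ocean-labelled position; post-landfall positions are dropped). Residency
areas beyond landfall are out of scope here — the cut at the last ocean
position leaves a typically small over-land remainder unmodelled.
Straightness is track length divided by the departure–arrival geodesic
(1 = a direct flight; note this is the inverse of some literature
conventions). The initial direction is the bearing of the displacement
accumulated over the first 50 km of path, including the crossing segment in
full — a simple, reproducible reading of "mean over the first 50 km".
Departure "days" subtract 12 h on a fixed local clock (UTC−8 by default) so
one night of departures is one day.

Flights are classified as loops when straightness is at or above 3.0, a
threshold placed in the empty gap between directed flights (which in the
motivating system stay below about 2.3) and loops (above about 5); it is a
configurable argument, not an estimate. Directed flights split east/west by
the sign of the eastward component of the final bearing.

## Regression layer

Ground- and air-speed models are linear mixed models
(`speed ~ ws * cw`, per-track random intercept, MA(1) within-track residual
correlation, maximum likelihood) fitted with `nlme`. The interaction is
included by default because crosswind weakening of the wind-support effect
is part of the phenomenon being modelled; `interaction = FALSE` disables it.
The MA order is fixed at 1. When the mixed fit fails to converge the
function degrades to ordinary least squares and records which estimator ran
(`method` also allows forcing either). Flight-altitude selection fits one
model per fixed level plus one at the hourly "maxWs" assignment (each 1-h
window, anchored at departure, uses the level with the highest mean wind
support — an upper envelope on what hourly altitude changes could achieve)
and returns the lowest-AIC level, ties to the lower altitude. ML rather
than REML is used so AICs are comparable across the per-level covariate
sets.

The track-length model regresses over-ocean length on mean wind support
over the first half of the track with flight-class intercepts; classes with
fewer than 3 tracks are dropped with a warning. Direction models are linear
mixed models with a departure-night random intercept; directions are
angular, so each is unwrapped onto a continuous scale centred on its
night's circular-mean direction before fitting, and a circular correlation
coefficient is reported alongside as a scale-free diagnostic. This
unwrap-then-fit treatment is a deliberate design choice for data whose
directions cluster within a night; it would be inappropriate for uniformly
dispersed directions, which the degenerate-input errors guard against.

## Null models for departure timing

`random_departures()` shifts a whole track rigidly in time to random
departures within the season window and recomputes mean wind support
(first 50 km, or the full track) against the wind field each time. Draws
are uniform in continuous time by default; a day-grid mode (uniform over
nights, keeping the observed time of day) is available because the choice
between the two is a genuine modelling decision for night-departing birds.
The one-sided exceedance p counts simulated values greater than *or equal
to* the observed one — ties count against significance, the conservative
direction — and "significant" means p < 0.05. Ensembles are seeded and
reproduce bit-identically. Under a null world whose departures follow the
same uniform law, the empirical significance rate sits at the nominal 5%
(the acceptance suite checks 5% ± 2% over 200 tracks), and in a world whose
departures are timed to high-tailwind moments the test detects nearly all
of them.

`delta_wind_support()` evaluates the west-minus-east wind support contrast
for a departure night at a stated local hour (22:30 by default), and
`departure_shift_profile()` recomputes wind support toward the actual
destination at hourly offsets (±12 h, from a ground station series) and
daily offsets (±5 d, from the grid at every level); offsets without
coverage are marked missing rather than failing.

## The shortest-route counterfactual

`simulate_shortest_route()` flies a "generic bird" from departure to
arrival: at each 15-min step the bearing to the arrival point is
re-evaluated (a fixed target is not a fixed compass bearing on a sphere),
wind is sampled, the fitted speed model's fixed effects predict ground
speed, and the bird advances; a negative predicted speed holds the bird in
place for that step (the conservative stall rule), and the final step is
clamped to the arrival point so the route never overshoots. Prediction uses
fixed effects only because the counterfactual bird is population-level; the
cap on steps defaults to four times the closed-form no-wind estimate, and a
route that never arrives reports its status rather than a fabricated time.
Comparisons report mean wind support on the actual track minus the
simulated route, and actual minus simulated flight time (positive when the
direct route would have been faster), aggregated per flight class.

## The synthetic world

`synth_config()` / `gen_world()` generate everything the pipeline consumes:
a wind grid (per-level mean vectors plus a constant, 24-h sinusoid, or
AR(1)-in-time law, optionally decoupled across levels, with an optional
smooth spatial perturbation), an hourly ground-station series, a
rectangular-band coastline, and wind-coupled tracks. Movement follows the
kinematics the analysis assumes: per step, displacement = (air vector +
wind vector) × 900 s, with wind sampled from the grid exactly as the
annotation pipeline samples it, so planted quantities are recovered without
discretization mismatch. Defaults mimic the study geometry: departure at
71.3° N, 156.65° W on the southern edge of an ocean band, 15-min steps, air
speed near 11 m s⁻¹, reanalysis-like 0.75°/6-h wind. All randomness flows
from one seed, with per-track substreams derived by stable hashing of the
track index so any single track reproduces regardless of how many are
generated.

What the generator does *not* emulate: position error, group behaviour,
responses to sea ice or terrain, within-flight behavioural switches, or any
feedback from wind to the decision to continue. Passing tests therefore
demonstrate that the estimators recover what the generative model plants at
study scale — not that real birds behave like the generator.

### Problem sizes used by the recovery checks

The package's own verification worlds are chosen to be study-scaled but
economical:

* **Track-length slope**: 200 worlds of 80 eastbound tracks, planted slope
  22 km per m s⁻¹ and residual sd 50 km, wind-support spread from an AR(1)
  law with a long (10-day) correlation time so support varies across
  departures but is nearly constant within a flight (this keeps the planted
  regressor exogenous). Air speed is set to 16 m s⁻¹ here so ground speeds
  match the study scale and every planted length is reachable within the
  simulated wind record. The fitted slope is compared against the
  generator's analytic standard error, $\sigma/\sqrt{S_{xx}}$, at ±2 SE.
* **Altitude selection**: 50 worlds of 8 tracks (15 h), six decoupled
  levels, only the 750 m level driving the birds; all seven candidate
  models (six fixed levels + maxWs) are fitted per world.
* **Randomization calibration**: a 200-track null world and a 60-track
  tailwind-timed world at 1-h wind resolution (so within-night timing is
  resolvable), ensembles of 1,000 draws.

## Known limitations

* Air speed is the scalar approximation; no wind-triangle decomposition.
* The sphere, nearest-neighbour sampling and the segment-start convention
  are fixed, documented simplifications; each has a configurable
  alternative only where stated above.
* The loop/directed threshold is a convention on a bimodal quantity, not an
  estimated decision boundary.
* Mixed-model AICs compare covariate sets on identical responses; they say
  nothing about altitude use varying within a flight beyond what the maxWs
  envelope captures.
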