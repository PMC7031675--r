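# windtrack

Tools for analysing how wind shapes the flights of tracked birds.
`windtrack` connects time-ordered tracking positions (nominal 15-min
resolution) with gridded reanalysis-style wind fields (6-hourly, ~80 km,
six altitude levels) and implements the analysis chain used to study
wind-dependent movement decisions in Arctic-breeding shorebirds: which way
to depart, when to depart, how fast and how far to fly, and what a direct
route would have cost instead.

For each track segment flown in ground direction α with wind components
*u* (eastward) and *v* (northward), the package computes

* **wind support** `Ws = u·sin α + v·cos α` (positive = tailwind),
* **crosswind** `Cw = |u·cos α − v·sin α|` (side-agnostic),
* **relative wind support** `Ws / √(u² + v²)` ∈ [−1, +1],
* **ground speed** (great-circle distance / elapsed time) and **air
  speed** (ground speed − wind support).

On top of these it provides track metrics (length, detour, straightness =
length / departure–arrival geodesic; 1 = direct flight), directed/loop
flight classification, linear mixed speed models across altitude levels
with AIC-based flight-altitude selection (`nlme`, per-track random
intercept, MA(1) residual correlation), a track-length–vs–wind-support
model, direction models, a seeded 10,000-draw randomized-departure null
model for departure timing, departure-shift sensitivity profiles, and a
constant-heading shortest-route simulator with the conservative
negative-speed stall rule. A synthetic-data generator produces wind grids,
station series, coastlines and wind-coupled tracks with a planted-truth
manifest, so the entire pipeline is testable without any downloads.

## Worked example

Generate a small study-like world, annotate every track with wind at the
750 m level, summarize and classify the flights, fit the ground-speed
model, and test one bird's departure timing against 1,000 random
departures:

```r
library(windtrack)

cf <- synth_config(seed = 2012, n_tracks = 12, duration_h = 20,
                   law = "ar1", ar1_sd = 3, ar1_corr_h = 24,
                   mean_uv = c(4, 1), p_east = 0.6, loop_fraction = 0.1)
world <- gen_world(cf)

segs <- annotate_tracks(world$tracks, world$grid, "750m")
su <- summarize_tracks(world$tracks)
su$class <- classify_flight(su)
su[1:5, c("id", "flight_time_h", "track_length_km", "straightness", "class")]
#>         id flight_time_h track_length_km straightness         class
#> 1 synth001         20.00       723.77495     1.006858 directed-east
#> 2 synth002          8.00       193.69213     1.004487 directed-west
#> 3 synth003         20.00       831.20436     1.050615 directed-east
#> 4 synth004          4.75        93.52553     1.005511 directed-west
#> 5 synth005         20.00       884.10693     1.005291 directed-east

fit_speed_model(segs)
#> <speed_fit> ground speed at 750m (lme, n = 851 segments, 12 tracks)
#> (Intercept)          ws          cw       ws:cw
#>     10.3621      0.9972     -0.2508      0.0000
#> AIC: 777.42  sigma: 0.362  track-intercept sd: 1.852  MA(1): 0.096

random_departures(world$tracks[[1]], world$grid,
                  world$manifest$global$departure_window,
                  n_sim = 1000, seed = 42)
#> <null_dist> synth001 (first50, 750m, n_sim = 1000)
#>   observed -0.20 m/s vs null mean 3.19 m/s (diff -3.39)
#>   one-sided p = 0.8920
```

The generator's kinematics put ground speed = air speed + wind support
when crosswind vanishes, and the fitted wind-support coefficient (0.997)
recovers that planted unit slope; this bird departed into a slight
headwind, so its observed first-50-km wind support sits well inside the
null distribution of random departures (p = 0.89).

Real data enter through `read_tracks()` (CSV: `id`, `timestamp`, `lon`,
`lat`), `load_wind_grid()` (NetCDF u/v on time × level × lat × lon),
`read_station_wind()` (hourly station CSV) and `read_coastline()`
(GeoJSON land polygons); `inst/cli/windtrack.R` wraps the summarize and
annotate steps for shell use.

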