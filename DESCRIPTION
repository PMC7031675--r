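Package: windtrack
Title: Wind Support Analysis for Bird Tracking Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to connect animal flight tracks with gridded wind fields and
    to analyse how wind shapes movement decisions. Annotates time-ordered
    positions with wind support, crosswind and relative wind support sampled
    from reanalysis-style u/v wind grids at several altitude levels; computes
    track metrics (length, detour, straightness, initial and final direction)
    and classifies directed versus loop flights; fits ground- and air-speed
    mixed models across altitudes with AIC-based flight-altitude selection;
    runs randomized-departure and departure-shift null analyses of departure
    timing; and simulates counterfactual constant-heading shortest-route
    flights. A seeded synthetic-data generator produces wind grids, station
    series, coastlines and wind-coupled tracks with a planted-truth manifest
    so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    nlme,
    sp,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ncdf4,
    geosphere
Config/testthat/edition: 3
RoxygenNote: 7.3.3
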