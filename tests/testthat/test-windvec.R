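# Wind support / crosswind decomposition and per-segment annotation.

test_that("wind components reproduce hand-computed cases", {
  # pure tailwind flying north
  w <- wind_components(0, 10, 0)
  expect_equal(unlist(w), c(ws = 10, cw = 0, rel_ws = 1))
  # pure headwind
  w <- wind_components(0, 10, 180)
  expect_equal(w$ws, -10)
  expect_equal(w$rel_ws, -1)
  # wind (3, 4), flying east: support is u, crosswind |v|
  w <- wind_components(3, 4, 90)
  expect_equal(unlist(w), c(ws = 3, cw = 4, rel_ws = 0.6))
  # flying northeast: support is the projection onto the 45-degree unit vector
  w <- wind_components(3, 4, 45)
  expect_equal(w$ws, (3 + 4) / sqrt(2))
  # calm air: defined zero relative support
  expect_equal(wind_components(0, 0, 123)$rel_ws, 0)
})

test_that("decomposition matches a rotation-matrix oracle on random draws", {
  set.seed(101)
  n <- 10000
  u <- runif(n, -25, 25); v <- runif(n, -25, 25); a <- runif(n, 0, 360)
  got <- wind_components(u, v, a)
  # oracle: rotate the wind vector into the track frame
  ar <- a * pi / 180
  along <- u * sin(ar) + v * cos(ar)
  perp <- -u * cos(ar) + v * sin(ar) # opposite sign convention, same magnitude
  expect_equal(got$ws, along)
  expect_equal(got$cw, abs(perp))
  # Pythagoras: ws^2 + cw^2 = wind speed^2
  expect_true(all(abs(got$ws^2 + got$cw^2 - (u^2 + v^2)) < 1e-9 * pmax(1, u^2 + v^2)))
  # relative support is the cosine of the wind-track angle (dot-product oracle)
  spd <- sqrt(u^2 + v^2)
  cosang <- (u * sin(ar) + v * cos(ar)) / spd
  expect_equal(got$rel_ws, cosang)
  expect_true(all(got$rel_ws >= -1 - 1e-12 & got$rel_ws <= 1 + 1e-12))
})

test_that("decomposition is equivariant under joint rotation", {
  set.seed(5)
  for (i in 1:50) {
    u <- runif(1, -20, 20); v <- runif(1, -20, 20)
    a <- runif(1, 0, 360); rot <- runif(1, 0, 360)
    base <- wind_components(u, v, a)
    rr <- rot * pi / 180
    u2 <- u * cos(rr) + v * sin(rr) # wind rotated clockwise by rot
    v2 <- -u * sin(rr) + v * cos(rr)
    rot2 <- wind_components(u2, v2, ((a + rot) %% 360))
    expect_equal(c(rot2$ws, rot2$cw), c(base$ws, base$cw), tolerance = 1e-9)
  }
})

test_that("annotation computes ground speed and wind metrics per segment", {
  g <- const_grid(0, 10)
  # 15 km steps each 15 min, due north
  tr <- step_track("t1", -155, 70, rep(0, 4), rep(15000, 4))
  segs <- annotate_track(tr, g, "750m")
  expect_equal(nrow(segs), 4)
  expect_equal(segs$ground_speed, rep(15000 / 900, 4), tolerance = 1e-6)
  expect_equal(segs$ws, rep(10, 4), tolerance = 1e-9)
  expect_equal(segs$cw, rep(0, 4), tolerance = 1e-9)
  expect_equal(segs$air_speed, segs$ground_speed - 10, tolerance = 1e-9)

  # coverage gap names the track
  far <- step_track("far", -100, 10, rep(0, 2), rep(15000, 2))
  expect_error(annotate_track(far, g, "750m"), "far")
})

test_that("generator ground truth is recovered where crosswind vanishes", {
  cf <- synth_config(seed = 21, n_tracks = 3, duration_h = 8, law = "constant",
                     mean_uv = c(5, 0), bearing = 90,
                     air_speed_sd_track = 0, air_speed_sd_step = 0)
  w <- gen_world(cf)
  segs <- annotate_tracks(w$tracks, w$grid, "750m")
  # flying east with a pure (5, 0) tailwind: cw = 0, air speed = planted 11
  expect_true(all(segs$cw < 1e-6))
  expect_equal(mean(segs$air_speed), 11, tolerance = 1e-3)
  expect_equal(mean(segs$ws), 5, tolerance = 1e-9)
})

test_that("maxWs altitude picks the dominating level and beats fixed levels", {
  # level 10m carries ws 2, level 750m carries ws 5 for a northward track
  g <- fun_grid(function(lon, lat, l, j) 0,
                function(lon, lat, l, j) if (l == 1) 2 else 5)
  tr <- step_track("t1", -155, 70, rep(0, 26), rep(13500, 26))
  prof <- max_ws_altitude(tr, g)
  expect_true(all(prof$windows$level == "750m"))
  expect_equal(prof$maxws_mean, 5, tolerance = 1e-9)
  expect_equal(unname(prof$level_means["10m"]), 2, tolerance = 1e-9)

  # alternating superiority each 6-h slice: chosen level alternates and the
  # envelope beats both fixed assignments (brute-force over both)
  g2 <- fun_grid(function(lon, lat, l, j) 0,
                 function(lon, lat, l, j) {
                   hi <- j %% 2 == l %% 2
                   if (hi) 6 else 1
                 },
                 times = utc("2012-06-01") + seq(0, 86400, by = 21600))
  tr2 <- step_track("t2", -155, 70, rep(0, 48), rep(5000, 48), dt_s = 1800)
  prof2 <- max_ws_altitude(tr2, g2)
  expect_gt(length(unique(prof2$windows$level)), 1)
  expect_gte(prof2$maxws_mean, max(prof2$level_means))
  # brute-force oracle: per-window level means recomputed from scratch
  t0 <- as.numeric(tr2$time[1])
  by_level <- sapply(g2$level_names, function(l) {
    s <- annotate_track(tr2, g2, l)
    tapply(s$ws, floor((as.numeric(s$t_start) - t0) / 3600) + 1, mean)
  })
  expect_equal(prof2$maxws_mean, mean(apply(by_level, 1, max)), tolerance = 1e-12)

  # degenerate single level: maxWs equals that level's mean
  g1 <- const_grid(0, 3, heights = 750)
  prof1 <- max_ws_altitude(tr, g1)
  expect_equal(prof1$maxws_mean, unname(prof1$level_means["750m"]))

  # too-short track errors
  shrt <- step_track("s", -155, 70, 0, 13500)
  expect_error(max_ws_altitude(shrt, g), "spans less than")
})

test_that("maxWs dominance holds on random synthetic grids", {
  set.seed(33)
  for (i in 1:5) {
    cf <- synth_config(seed = 100 + i, n_tracks = 1, duration_h = 8,
                       level_heights = c(10, 750, 3000), decouple_levels = TRUE,
                       ar1_sd = 4, ar1_corr_h = 3)
    w <- gen_world(cf)
    prof <- max_ws_altitude(w$tracks[[1]], w$grid)
    expect_gte(prof$maxws_mean, max(prof$level_means) - 1e-9)
  }
})

test_that("maxWs annotation mixes levels as the profile dictates", {
  g2 <- fun_grid(function(lon, lat, l, j) 0,
                 function(lon, lat, l, j) if (j %% 2 == l %% 2) 6 else 1,
                 times = utc("2012-06-01") + seq(0, 86400, by = 21600))
  tr <- step_track("t1", -155, 70, rep(0, 48), rep(5000, 48), dt_s = 1800)
  segs <- annotate_track_maxws(tr, g2)
  expect_equal(unique(segs$level), "maxWs")
  expect_gt(length(unique(segs$chosen_level)), 1)
  # oracle: gather each segment's ws from its window's winning level
  t0 <- as.numeric(tr$time[1])
  seg_lev <- lapply(g2$level_names, function(l) annotate_track(tr, g2, l))
  names(seg_lev) <- g2$level_names
  win <- floor((as.numeric(seg_lev[[1]]$t_start) - t0) / 3600) + 1
  wm <- sapply(seg_lev, function(s) tapply(s$ws, win, mean))
  best <- colnames(wm)[apply(wm, 1, which.max)]
  oracle_ws <- mapply(function(i, w) seg_lev[[best[w]]]$ws[i], seq_along(win), win)
  expect_equal(segs$ws, unname(oracle_ws), tolerance = 1e-12)
})
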