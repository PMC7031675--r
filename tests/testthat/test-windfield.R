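# Wind-grid container, NetCDF round trip, resampling, sampling rules,
# regional summaries and the temporal-shift sensitivity check.

test_that("wind_grid validates shapes, time axis and missing cells", {
  lon <- 0:2; lat <- 0:2; tms <- utc("2012-06-01") + c(0, 21600)
  ok <- array(1, c(3, 3, 1, 2))
  expect_s3_class(wind_grid(lon, lat, "750m", 750, tms, ok, ok), "wind_grid")
  expect_error(wind_grid(lon, lat, "750m", 750, tms, ok, array(1, c(3, 3, 1, 3))),
               "dim")
  bad <- ok; bad[2, 3, 1, 1] <- NA
  expect_error(wind_grid(lon, lat, "750m", 750, tms, bad, ok),
               "missing/non-finite cell in u at \\[lon=2, lat=3")
  expect_error(wind_grid(lon, lat, "750m", 750, utc("2012-06-01") + c(0, 100, 300),
                         array(1, c(3, 3, 1, 3)), array(1, c(3, 3, 1, 3))),
               "equally spaced")
})

test_that("NetCDF round trip preserves the grid and its level order", {
  g <- fun_grid(function(lon, lat, l, j) l * 10 + j, heights = c(100, 3000))
  path <- tempfile(fileext = ".nc")
  write_wind_grid(g, path)
  g2 <- load_wind_grid(path)
  expect_equal(g2$level_names, c("100m", "3000m"))
  expect_equal(g2$u, g$u, tolerance = 1e-12)
  expect_equal(g2$v, g$v, tolerance = 1e-12)
  expect_equal(as.numeric(g2$times), as.numeric(g$times))
  unlink(path)
})

test_that("NetCDF load maps pressure levels and rejects missing cells", {
  # hand-written file with a pressure-level axis, deliberately out of order
  path <- tempfile(fileext = ".nc")
  dlon <- ncdf4::ncdim_def("longitude", "degrees_east", c(-156, -155))
  dlat <- ncdf4::ncdim_def("latitude", "degrees_north", c(70, 71))
  dlev <- ncdf4::ncdim_def("level", "millibars", c(700, 925))
  dtim <- ncdf4::ncdim_def("time", "hours since 2012-06-01 00:00:00", c(0, 6))
  vu <- ncdf4::ncvar_def("u", "m s**-1", list(dlon, dlat, dlev, dtim), prec = "double")
  vv <- ncdf4::ncvar_def("v", "m s**-1", list(dlon, dlat, dlev, dtim), prec = "double")
  nc <- ncdf4::nc_create(path, list(vu, vv))
  uarr <- array(0, c(2, 2, 2, 2))
  uarr[, , 1, ] <- 3    # 700 hPa slice
  uarr[, , 2, ] <- 0.75 # 925 hPa slice
  ncdf4::ncvar_put(nc, vu, uarr)
  ncdf4::ncvar_put(nc, vv, array(0, c(2, 2, 2, 2)))
  ncdf4::nc_close(nc)
  g <- load_wind_grid(path)
  expect_equal(g$level_names, c("750m", "3000m")) # ascending nominal height
  expect_equal(unique(as.vector(g$u[, , 1, ])), 0.75)  # 925 hPa -> 750 m
  expect_equal(unique(as.vector(g$u[, , 2, ])), 3)     # 700 hPa -> 3000 m
  unlink(path)

  # a missing cell is a load error naming the variable
  g0 <- const_grid(5, 0, lon = c(-156, -155), lat = c(70, 71), heights = 750,
                   times = utc("2012-06-01") + c(0, 21600))
  path2 <- tempfile(fileext = ".nc")
  write_wind_grid(g0, path2)
  nc <- ncdf4::nc_open(path2, write = TRUE)
  ncdf4::ncvar_put(nc, "v", NA_real_, start = c(1, 2, 1, 1), count = c(1, 1, 1, 1))
  ncdf4::nc_close(nc)
  expect_error(load_wind_grid(path2), "v at")
  unlink(path2)
})

test_that("station CSV reader converts the meteorological from-direction", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("timestamp,wind_speed_ms,wind_direction_from_deg",
               "2012-06-01T00:00:00,4,270",
               "2012-06-01T01:00:00,2,0"), path)
  st <- read_station_wind(path)
  expect_equal(st$direction_to, c(90, 180))
  expect_equal(st$u, c(4, 0), tolerance = 1e-12)
  expect_equal(st$v, c(0, -2), tolerance = 1e-12)
  unlink(path)
})

test_that("bicubic resampling reproduces linear fields and rejects coarsening", {
  # u = 2 lon + 3 lat (a plane) on an 80 km-ish grid
  g <- fun_grid(function(lon, lat, l, j) 2 * lon + 3 * lat,
                lon = seq(-160, -150, by = 0.75), lat = seq(68, 75, by = 0.75),
                heights = 750, times = utc("2012-06-01") + c(0, 21600))
  r <- resample_spatial(g, 10)
  expected <- outer(r$lon, r$lat, function(x, y) 2 * x + 3 * y)
  expect_equal(r$u[, , 1, 1], expected, tolerance = 1e-6)
  expect_true(all(abs(r$v) < 1e-9))

  # constant stays constant
  gc_ <- const_grid(5, -2)
  rc <- resample_spatial(gc_, 25)
  expect_true(all(abs(rc$u - 5) < 1e-9) && all(abs(rc$v + 2) < 1e-9))

  # coarser target is an error
  expect_error(resample_spatial(g, 160), "coarser")
})

test_that("sampling is nearest in space and time with earlier/lower ties", {
  tms <- utc("2012-06-01") + c(0, 21600)
  g <- fun_grid(function(lon, lat, l, j) j, times = tms, heights = 750)
  p <- c(-155.2, 70.4)
  expect_equal(sample_wind(g, p[1], p[2], utc("2012-06-01 02:59:00"), "750m")$u, 1)
  expect_equal(sample_wind(g, p[1], p[2], utc("2012-06-01 03:01:00"), "750m")$u, 2)
  # exact midpoint: earlier slice
  expect_equal(sample_wind(g, p[1], p[2], utc("2012-06-01 03:00:00"), "750m")$u, 1)
  # constant field: any point and time
  gcst <- const_grid(5, 0)
  w <- sample_wind(gcst, -151.7, 69.2, utc("2012-06-02 13:00:00"), "10m")
  expect_equal(unlist(w), c(u = 5, v = 0, speed = 5, direction_to = 90))
  # outside coverage errors
  expect_error(sample_wind(gcst, -120, 70, tms[1], "10m"), "coverage")
  expect_error(sample_wind(gcst, -155, 70, tms[1] + 10 * 86400, "10m"), "coverage")
  # resampling does not change nearest-node sampling of a constant field
  rc <- resample_spatial(gcst, 25)
  expect_equal(sample_wind(rc, -151.7, 69.2, tms[1], "10m")$u, 5)
})

test_that("regional summaries average speed and use vector-mean direction", {
  g <- const_grid(5, 0, times = utc("2012-06-01") + seq(0, 86400 * 2 - 1, by = 21600))
  poly <- cbind(c(-158, -152, -152, -158, -158), c(69, 69, 73, 73, 69))
  s <- regional_wind_summary(g, poly, as.Date("2012-06-01") + 0:1)
  expect_equal(nrow(s), 2)
  expect_equal(s$mean_speed, c(5, 5))
  expect_equal(s$mean_direction_to, c(90, 90))
  expect_error(regional_wind_summary(g, poly + 100, as.Date("2012-06-01")), "overlap")

  # opposing winds: speeds average, direction degenerates to the NA sentinel
  g2 <- fun_grid(function(lon, lat, l, j) ifelse(lat > 71, 5, -5),
                 heights = 750,
                 times = utc("2012-06-01") + seq(0, 86399, by = 21600))
  poly2 <- cbind(c(-158, -152, -152, -158, -158), c(69.5, 69.5, 73.5, 73.5, 69.5))
  s2 <- regional_wind_summary(g2, poly2, as.Date("2012-06-01"), level = "750m")
  expect_equal(s2$mean_speed, 5)
  expect_true(is.na(s2$mean_direction_to))
})

test_that("a planted windier-ocean contrast is recovered by regional summaries", {
  # ocean band 1.2 m/s windier than land, as a planted truth
  g <- fun_grid(function(lon, lat, l, j) ifelse(lat > 70.5, 6.2, 5.0),
                heights = 10,
                times = utc("2012-06-01") + seq(0, 86400 * 3 - 1, by = 21600))
  ocean <- cbind(c(-159, -151, -151, -159, -159), c(71, 71, 74.5, 74.5, 71))
  land <- cbind(c(-159, -151, -151, -159, -159), c(68.2, 68.2, 70.2, 70.2, 68.2))
  days <- as.Date("2012-06-01") + 0:2
  so <- regional_wind_summary(g, ocean, days, "10m")
  sl <- regional_wind_summary(g, land, days, "10m")
  expect_equal(mean(so$mean_speed) - mean(sl$mean_speed), 1.2, tolerance = 0.05)
})

test_that("temporal-shift sensitivity is exact for still fields and matches brute force", {
  # spatially varying but time-constant field: r = 1 at every level and shift
  g <- fun_grid(function(lon, lat, l, j) 3 + 0.5 * (lat - 70) + 0.1 * l,
                heights = c(10, 750))
  set.seed(8)
  trs <- lapply(1:4, function(i)
    step_track(paste0("t", i), -157 + i, 69.5 + i * 0.8,
               runif(8, 60, 120), rep(13000, 8)))
  names(trs) <- paste0("t", 1:4)
  out <- temporal_shift_sensitivity(trs, g, shift_h = 6)
  expect_true(all(abs(out$r - 1) < 1e-12))
  expect_error(temporal_shift_sensitivity(trs[1:2], g), "3 tracks")

  # slowly varying field: high correlation, and equal to brute-force recomputation
  cf <- synth_config(seed = 14, n_tracks = 5, duration_h = 6,
                     level_heights = c(10, 750), ar1_sd = 4, ar1_corr_h = 48)
  w <- gen_world(cf)
  out2 <- temporal_shift_sensitivity(w$tracks, w$grid, shift_h = 6)
  expect_true(all(out2$r > 0.9))
  brute <- sapply(w$tracks, function(tr) {
    tr2 <- tr; tr2$time <- tr2$time + 6 * 3600
    c(mean(annotate_track(tr, w$grid, "750m")$ws),
      mean(annotate_track(tr2, w$grid, "750m")$ws))
  })
  r_ref <- cor(brute[1, ], brute[2, ])
  expect_equal(out2$r[out2$level == "750m" & out2$shift_h == 6], r_ref, tolerance = 1e-12)
})
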