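# Shared in-code fixtures: small wind grids and tracks built directly, so no
# binary files are needed.

utc <- function(x) as.POSIXct(x, tz = "UTC")

# Constant-wind grid: every cell (u0, v0) at every level/time.
const_grid <- function(u0 = 5, v0 = 0,
                       lon = seq(-160, -150, by = 1),
                       lat = seq(68, 75, by = 1),
                       heights = c(10, 750),
                       times = utc("2012-06-01") + seq(0, 86400 * 2, by = 21600)) {
  dims <- c(length(lon), length(lat), length(heights), length(times))
  wind_grid(lon, lat, paste0(heights, "m"), heights, times,
            array(u0, dims), array(v0, dims))
}

# Grid whose u field is an arbitrary function of (lon, lat, level index,
# time index); v likewise.
fun_grid <- function(ufun, vfun = function(lon, lat, l, j) 0,
                     lon = seq(-160, -150, by = 1),
                     lat = seq(68, 75, by = 1),
                     heights = c(10, 750),
                     times = utc("2012-06-01") + seq(0, 86400 * 2, by = 21600)) {
  dims <- c(length(lon), length(lat), length(heights), length(times))
  u <- array(0, dims); v <- array(0, dims)
  for (l in seq_along(heights)) for (j in seq_along(times)) {
    u[, , l, j] <- outer(lon, lat, function(x, y) mapply(ufun, x, y, l, j))
    v[, , l, j] <- outer(lon, lat, function(x, y) mapply(vfun, x, y, l, j))
  }
  wind_grid(lon, lat, paste0(heights, "m"), heights, times, u, v)
}

# Track marching along great-circle steps of given bearings/distances from a
# start point, at fixed time spacing.
step_track <- function(id, lon0, lat0, bearings, dists_m,
                       t0 = utc("2012-06-01 06:00:00"), dt_s = 900,
                       surface = NULL) {
  n <- length(bearings)
  lon <- numeric(n + 1); lat <- numeric(n + 1)
  lon[1] <- lon0; lat[1] <- lat0
  for (i in seq_len(n)) {
    p <- destination_point(lon[i], lat[i], bearings[i], dists_m[i])
    lon[i + 1] <- p$lon; lat[i + 1] <- p$lat
  }
  track(id, t0 + (0:n) * dt_s, lon, lat, surface = surface)
}

# Hand-built segments table for model tests (bypasses wind sampling).
make_segments <- function(track_ids, ws, cw, ground_speed, air_speed = NULL,
                          u = NULL, v = NULL, distance_m = 13500) {
  n <- length(ws)
  out <- data.frame(
    track = track_ids,
    t_start = utc("2012-06-01") + (seq_len(n) - 1) * 900,
    t_end = utc("2012-06-01") + seq_len(n) * 900,
    lon_mid = -156, lat_mid = 72,
    distance_m = rep_len(distance_m, n),
    ground_speed = ground_speed,
    ground_direction = 90,
    u = u %||% ws, v = v %||% cw,
    wind_speed = sqrt((u %||% ws)^2 + (v %||% cw)^2),
    ws = ws, cw = cw,
    rel_ws = ifelse(sqrt(ws^2 + cw^2) > 0, ws / sqrt(ws^2 + cw^2), 0),
    air_speed = air_speed %||% (ground_speed - ws),
    level = "750m", stringsAsFactors = FALSE
  )
  class(out) <- c("segments", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
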