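# Synthetic world generator: seeded wind grids, an hourly ground station,
# a rectangular-band coastline, and wind-coupled tracks with a planted-truth
# manifest. The default world mimics the study geometry: a departure point
# at 71.3 N on the southern coast of an ocean band, flights over the band,
# land to the south and far north. Movement follows the kinematics the
# analysis assumes: per 15-min step the ground vector is the bird's air
# vector plus the local wind vector.

#' Configuration for a synthetic world
#'
#' All parameters have study-scaled defaults; every random element is driven
#' by `seed` (per-track substreams are derived from it by stable hashing of
#' the track index, so single tracks reproduce independently of how many are
#' generated).
#'
#' @param seed integer seed
#' @param lon_range,lat_range spatial extent, degrees
#' @param spacing_deg grid node spacing, degrees (reanalysis-like 0.75)
#' @param t0 start of the wind record (POSIXct or string, UTC)
#' @param n_days length of the wind record, days
#' @param time_step_h wind time step, hours (reanalysis-like 6)
#' @param level_heights nominal level heights, metres, ascending
#' @param mean_uv matrix (n_levels x 2) of per-level mean u,v (m/s); a
#'   single c(u, v) is recycled to all levels
#' @param law temporal wind law: "constant", "diurnal" (24-h sinusoid), or
#'   "ar1" (AR(1)-in-time noise with marginal sd `ar1_sd` and correlation
#'   time `ar1_corr_h`)
#' @param diurnal_amp,diurnal_dir,diurnal_peak_h sinusoid amplitude (m/s),
#'   the direction_to (deg) it acts along, and the UTC hour of its peak
#' @param ar1_sd,ar1_corr_h AR(1) marginal sd (m/s; a single value, or
#'   c(sd_u, sd_v) for per-component sds) and correlation time (h)
#' @param decouple_levels if TRUE each level gets an independent AR(1)
#'   draw; if FALSE all levels share one (vertically coherent wind)
#' @param spatial_amp,spatial_wavelength_km amplitude (m/s) and wavelength
#'   of a smooth stationary spatial perturbation (0 = none)
#' @param active_level name of the level whose wind moves the birds
#' @param station_lon,station_lat ground-station location (defaults: origin)
#' @param n_tracks number of tracks
#' @param origin c(lon, lat) departure point
#' @param departure_law "uniform" over `departure_window`, or
#'   "tailwind_quantile": depart at a wind-record time whose wind support
#'   toward the track's bearing exceeds the `departure_quantile` quantile
#'   (birds leaving on favourable winds)
#' @param departure_window c(start, end) POSIXct; default: the wind record
#'   minus a tail allowance for the flight itself
#' @param departure_quantile quantile for "tailwind_quantile" (default 0.97)
#' @param air_speed_mean,air_speed_sd_track,air_speed_sd_step mean air speed
#'   (m/s; shorebird-like 11), its between-track sd, and per-step jitter sd
#' @param heading_law "fixed_bearing" (each track holds `bearing`, drawn
#'   east/west with `p_east` if `bearing` is NULL), "downwind" (von Mises
#'   around the local wind direction, concentration `kappa`), or "goal"
#'   (great-circle bearing to a per-track goal point)
#' @param bearing fixed bearing in degrees, or NULL to draw east (90) /
#'   west (270) with probability `p_east`
#' @param p_east probability a fixed-bearing track flies east
#' @param kappa von Mises concentration for "downwind"
#' @param goal c(lon, lat) for "goal" headings
#' @param duration_h maximum flight duration, hours
#' @param step_s movement time step, seconds (tag-like 900)
#' @param length_slope_km if non-NULL, plant a track-length law: flights are
#'   truncated at length `length_intercept_km + length_slope_km * (mean wind
#'   support over the first half) + N(0, length_sd_km)`
#' @param length_intercept_km,length_sd_km intercept and noise sd of the
#'   planted length law (km)
#' @param loop_fraction fraction of tracks flown as loops (out
#'   `loop_out_km`, then back to a point `loop_return_km` from the origin)
#' @param loop_out_km,loop_return_km loop outbound length and return offset
#' @param coast_lat_s,coast_lat_n latitudes of the southern and northern
#'   coastlines bounding the ocean band
#' @return list of class `synth_config`
#' @export
synth_config <- function(seed = 1,
                         lon_range = c(-179.25, -110.25), lat_range = c(66, 78),
                         spacing_deg = 0.75,
                         t0 = "2012-05-27 00:00:00", n_days = 28, time_step_h = 6,
                         level_heights = c(10, 100, 750, 1500, 2250, 3000),
                         mean_uv = c(4, 1),
                         law = c("ar1", "constant", "diurnal"),
                         diurnal_amp = 4, diurnal_dir = 90, diurnal_peak_h = 6,
                         ar1_sd = 3, ar1_corr_h = 24, decouple_levels = FALSE,
                         spatial_amp = 0, spatial_wavelength_km = 600,
                         active_level = NULL,
                         station_lon = NULL, station_lat = NULL,
                         n_tracks = 20, origin = c(-156.65, 71.3),
                         departure_law = c("uniform", "tailwind_quantile"),
                         departure_window = NULL, departure_quantile = 0.97,
                         air_speed_mean = 11, air_speed_sd_track = 1,
                         air_speed_sd_step = 0.3,
                         heading_law = c("fixed_bearing", "downwind", "goal"),
                         bearing = NULL, p_east = 0.6, kappa = 8, goal = NULL,
                         duration_h = 24, step_s = 900,
                         length_slope_km = NULL, length_intercept_km = 1300,
                         length_sd_km = 50,
                         loop_fraction = 0, loop_out_km = 400, loop_return_km = 40,
                         coast_lat_s = 70.5, coast_lat_n = 77.5) {
  law <- match.arg(law)
  heading_law <- match.arg(heading_law)
  departure_law <- match.arg(departure_law)
  if (is.character(t0)) t0 <- as.POSIXct(t0, tz = "UTC")
  levels <- paste0(level_heights, "m")
  if (is.null(active_level)) {
    active_level <- if ("750m" %in% levels) "750m" else levels[length(levels)]
  }
  muv <- if (is.matrix(mean_uv)) mean_uv else
    matrix(rep(mean_uv, each = length(levels)), ncol = 2)
  if (nrow(muv) != length(levels)) stop("mean_uv rows must match levels")
  if (any(ar1_sd < 0) || air_speed_sd_track < 0 || air_speed_sd_step < 0 ||
      length_sd_km < 0 || kappa < 0) stop("variances/concentration must be >= 0")
  structure(as.list(environment()), class = "synth_config")
}

# AR(1) series on n lattice points with step dt_s, marginal sd, corr time.
ar1_series <- function(n, dt_s, sd, corr_h) {
  if (sd == 0) return(numeric(n))
  rho <- exp(-dt_s / (corr_h * 3600))
  e <- numeric(n)
  e[1] <- stats::rnorm(1, 0, sd)
  innov_sd <- sd * sqrt(1 - rho^2)
  for (i in seq_len(n)[-1]) e[i] <- rho * e[i - 1] + stats::rnorm(1, 0, innov_sd)
  e
}

#' Generate a synthetic wind grid and station series
#'
#' The field is a per-level mean vector plus the configured temporal law
#' (shared across space) plus an optional smooth stationary spatial
#' perturbation. The grid is the field on the lattice; the station series is
#' the ground-level field at the station location sampled hourly (AR(1)
#' lattice values interpolated linearly in time). Deterministic under the
#' config seed.
#'
#' @param config a [synth_config()]
#' @return list with `grid` (a [wind_grid()]) and `station` (data.frame as
#'   from [read_station_wind()])
#' @export
gen_wind <- function(config) {
  cf <- config
  lon <- seq(cf$lon_range[1], cf$lon_range[2], by = cf$spacing_deg)
  lat <- seq(cf$lat_range[1], cf$lat_range[2], by = cf$spacing_deg)
  if (!length(lon) || !length(lat) || cf$n_days <= 0) stop("zero-size grid")
  times <- cf$t0 + seq(0, cf$n_days * 86400 - 1, by = cf$time_step_h * 3600)
  nlev <- length(cf$levels); nt <- length(times)
  set.seed(cf$seed)
  # temporal anomalies on the lattice, per level and component
  anom_u <- matrix(0, nt, nlev); anom_v <- matrix(0, nt, nlev)
  if (cf$law == "ar1") {
    sd_u <- cf$ar1_sd[1]; sd_v <- cf$ar1_sd[length(cf$ar1_sd)]
    if (cf$decouple_levels) {
      for (l in seq_len(nlev)) {
        anom_u[, l] <- ar1_series(nt, cf$time_step_h * 3600, sd_u, cf$ar1_corr_h)
        anom_v[, l] <- ar1_series(nt, cf$time_step_h * 3600, sd_v, cf$ar1_corr_h)
      }
    } else {
      au <- ar1_series(nt, cf$time_step_h * 3600, sd_u, cf$ar1_corr_h)
      av <- ar1_series(nt, cf$time_step_h * 3600, sd_v, cf$ar1_corr_h)
      anom_u[] <- au; anom_v[] <- av
    }
  } else if (cf$law == "diurnal") {
    hrs <- (as.numeric(times) %% 86400) / 3600
    s <- cf$diurnal_amp * cos(2 * pi * (hrs - cf$diurnal_peak_h) / 24)
    anom_u[] <- s * sin(deg2rad(cf$diurnal_dir))
    anom_v[] <- s * cos(deg2rad(cf$diurnal_dir))
  }
  # stationary spatial perturbation (per-level random phase)
  km_per_deg <- EARTH_RADIUS_M * pi / 180 / 1000
  phase <- stats::runif(nlev, 0, 2 * pi)
  spat <- lapply(seq_len(nlev), function(l) {
    if (cf$spatial_amp == 0) return(matrix(0, length(lon), length(lat)))
    wl_lon <- cf$spatial_wavelength_km / (km_per_deg * cos(deg2rad(mean(lat))))
    wl_lat <- cf$spatial_wavelength_km / km_per_deg
    outer(lon, lat, function(x, y)
      cf$spatial_amp * sin(2 * pi * (x - lon[1]) / wl_lon + phase[l]) *
        cos(2 * pi * (y - lat[1]) / wl_lat))
  })
  u <- array(0, c(length(lon), length(lat), nlev, nt))
  v <- array(0, c(length(lon), length(lat), nlev, nt))
  for (l in seq_len(nlev)) for (j in seq_len(nt)) {
    u[, , l, j] <- cf$muv[l, 1] + anom_u[j, l] + spat[[l]]
    v[, , l, j] <- cf$muv[l, 2] + anom_v[j, l] + spat[[l]]
  }
  grid <- wind_grid(lon, lat, cf$levels, cf$level_heights, times, u, v)
  # hourly station series at ground level
  st_lon <- cf$station_lon %||% cf$origin[1]
  st_lat <- cf$station_lat %||% cf$origin[2]
  st_times <- cf$t0 + seq(0, cf$n_days * 86400 - 1, by = 3600)
  tn <- as.numeric(times); stn <- as.numeric(st_times)
  au1 <- stats::approx(tn, anom_u[, 1], xout = stn, rule = 2)$y
  av1 <- stats::approx(tn, anom_v[, 1], xout = stn, rule = 2)$y
  ilo <- nearest_idx(lon, st_lon); ila <- nearest_idx(lat, st_lat)
  su <- cf$muv[1, 1] + au1 + spat[[1]][ilo, ila]
  sv <- cf$muv[1, 2] + av1 + spat[[1]][ilo, ila]
  spd <- sqrt(su^2 + sv^2)
  dir_to <- ifelse(spd > 0, wrap360(rad2deg(atan2(su, sv))), NA_real_)
  station <- data.frame(time = st_times, speed = spd, direction_to = dir_to,
                        u = su, v = sv)
  list(grid = grid, station = station)
}

#' Synthetic coastline polygons
#'
#' Land south of `coast_lat_s` and north of `coast_lat_n` across the world's
#' longitude range; the band between is ocean.
#'
#' @param config a [synth_config()]
#' @return a `coastline` object (list of lon/lat polygons)
#' @export
gen_coastline <- function(config) {
  lr <- config$lon_range + c(-1, 1); la <- config$lat_range
  south <- cbind(c(lr[1], lr[2], lr[2], lr[1], lr[1]),
                 c(la[1] - 1, la[1] - 1, config$coast_lat_s, config$coast_lat_s, la[1] - 1))
  north <- cbind(c(lr[1], lr[2], lr[2], lr[1], lr[1]),
                 c(config$coast_lat_n, config$coast_lat_n, la[2] + 1, la[2] + 1, config$coast_lat_n))
  structure(list(south, north), class = "coastline")
}

#' Write a coastline as GeoJSON
#' @param coast a `coastline` object
#' @param path output file
#' @return `path`, invisibly
#' @export
write_coastline_geojson <- function(coast, path) {
  feats <- lapply(coast, function(poly) {
    list(type = "Feature", properties = list(surface = "land"),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(poly)),
                                                   function(i) c(poly[i, 1], poly[i, 2])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# deterministic per-track substream seed from the master seed
track_seed <- function(seed, i) {
  (as.numeric(seed) * 1000003 + i * 7919) %% 2147483629
}

#' Generate wind-coupled synthetic tracks
#'
#' Each track departs from the origin at a time drawn by the departure law
#' and moves in 15-min steps: heading from the heading law, air vector =
#' air speed times the heading unit vector, wind sampled from the grid
#' nearest in space and time at the segment start (exactly as the annotation
#' pipeline samples it), displacement = (air + wind) * step. Tracks end on
#' reaching land, on completing a loop, at the planted length target, or at
#' the maximum duration. The manifest records every latent value needed to
#' check planted effects without re-running the generator.
#'
#' @param config a [synth_config()]
#' @param wind list from [gen_wind()] (or a bare [wind_grid()])
#' @return list with `tracks` (named list of [track()]s) and `manifest`
#'   (list: `global` planted parameters, `per_track` latent values)
#' @export
gen_tracks <- function(config, wind) {
  cf <- config
  grid <- if (inherits(wind, "wind_grid")) wind else wind$grid
  ilev <- level_index(grid, cf$active_level)
  # regular-axis fast lookup
  lon0 <- grid$lon[1]; dlon <- if (length(grid$lon) > 1) diff(grid$lon)[1] else 1
  lat0 <- grid$lat[1]; dlat <- if (length(grid$lat) > 1) diff(grid$lat)[1] else 1
  t0n <- as.numeric(grid$times[1])
  dtg <- grid_time_step(grid); if (is.na(dtg)) dtg <- Inf
  nlon <- length(grid$lon); nlat <- length(grid$lat); ntim <- length(grid$times)
  uarr <- grid$u; varr <- grid$v
  # nearest regular-axis index, earlier/lower on exact ties (as sample_wind)
  near <- function(x, x0, dx, n) pmin(pmax(ceiling((x - x0) / dx - 0.5) + 1L, 1L), n)
  near1 <- function(x, x0, dx, n) {
    i <- ceiling((x - x0) / dx - 0.5) + 1L
    if (i < 1L) 1L else if (i > n) n else i
  }
  window <- cf$departure_window %||%
    c(grid$times[1], grid$times[ntim] - cf$duration_h * 3600)
  if (as.numeric(window[2]) <= as.numeric(window[1])) stop("degenerate departure window")
  max_steps <- round(cf$duration_h * 3600 / cf$step_s)

  # lean scalar destination-point (no data.frame overhead in the step loop)
  dest1 <- function(lon, lat, brg, d) {
    delta <- d / EARTH_RADIUS_M
    th <- brg * pi / 180
    phi1 <- lat * pi / 180; lam1 <- lon * pi / 180
    phi2 <- asin(sin(phi1) * cos(delta) + cos(phi1) * sin(delta) * cos(th))
    lam2 <- lam1 + atan2(sin(th) * sin(delta) * cos(phi1),
                         cos(delta) - sin(phi1) * sin(phi2))
    c(((lam2 * 180 / pi + 180) %% 360) - 180, phi2 * 180 / pi)
  }
  tracks <- list(); per_track <- list()
  step_s <- cf$step_s; heading_law <- cf$heading_law
  coast_s <- cf$coast_lat_s; coast_n <- cf$coast_lat_n
  len_slope <- cf$length_slope_km; len_int <- cf$length_intercept_km
  len_sd <- cf$length_sd_km
  air_sd_step <- cf$air_speed_sd_step
  d2r <- pi / 180
  for (i in seq_len(cf$n_tracks)) {
    set.seed(track_seed(cf$seed, i))
    is_loop <- stats::runif(1) < cf$loop_fraction
    brg <- cf$bearing %||% if (stats::runif(1) < cf$p_east) 90 else 270
    air_mean <- stats::rnorm(1, cf$air_speed_mean, cf$air_speed_sd_track)
    # departure time
    if (cf$departure_law == "uniform") {
      dep <- window[1] + stats::runif(1) * as.numeric(difftime(window[2], window[1], units = "secs"))
    } else {
      cand <- grid$times[grid$times >= window[1] & grid$times <= window[2]]
      ic <- near(cf$origin[1], lon0, dlon, nlon); ia <- near(cf$origin[2], lat0, dlat, nlat)
      itc <- near(as.numeric(cand), t0n, dtg, ntim)
      wsc <- uarr[cbind(ic, ia, ilev, itc)] * sin(deg2rad(brg)) +
        varr[cbind(ic, ia, ilev, itc)] * cos(deg2rad(brg))
      thr <- stats::quantile(wsc, cf$departure_quantile, names = FALSE)
      good <- which(wsc >= thr)
      dep <- cand[good[sample.int(length(good), 1)]]
    }
    # planted length target (resolved by fixed point after stepping)
    len_eps <- if (!is.null(cf$length_slope_km)) stats::rnorm(1, 0, cf$length_sd_km) else NA
    loop_goal <- if (is_loop) {
      g <- destination_point(cf$origin[1], cf$origin[2],
                             wrap360(brg + 90), cf$loop_return_km * 1000)
      c(g$lon, g$lat)
    } else NULL
    kret <- FALSE
    lon <- numeric(max_steps + 1); lat <- numeric(max_steps + 1)
    wsv <- numeric(max_steps); uvv <- matrix(0, max_steps, 2)
    heads <- numeric(max_steps); airs <- numeric(max_steps)
    stepd <- numeric(max_steps); gdirs <- numeric(max_steps)
    lon[1] <- cf$origin[1]; lat[1] <- cf$origin[2]
    nstep <- 0L; cum <- 0; ws_psum <- 0
    air_jit <- if (air_sd_step > 0) stats::rnorm(max_steps, 0, air_sd_step) else
      numeric(max_steps)
    depn <- as.numeric(dep)
    for (s in seq_len(max_steps)) {
      tcur <- depn + (s - 1) * step_s
      il <- near1(lon[s], lon0, dlon, nlon); ia <- near1(lat[s], lat0, dlat, nlat)
      it <- if (is.finite(dtg)) near1(tcur, t0n, dtg, ntim) else 1L
      uw <- uarr[il, ia, ilev, it]; vw <- varr[il, ia, ilev, it]
      head_deg <- if (is_loop && kret) {
        dist_bearing(lon[s], lat[s], loop_goal[1], loop_goal[2])$bearing_deg
      } else if (heading_law == "fixed_bearing" || is_loop) {
        brg
      } else if (heading_law == "downwind") {
        wd <- wrap360(rad2deg(atan2(uw, vw)))
        wrap360(wd + rad2deg(rvonmises1(cf$kappa)))
      } else {
        dist_bearing(lon[s], lat[s], cf$goal[1], cf$goal[2])$bearing_deg
      }
      if (is.na(head_deg)) head_deg <- brg
      aspd <- air_mean + air_jit[s]
      if (aspd < 0) aspd <- 0
      hr <- head_deg * d2r
      gx <- aspd * sin(hr) + uw
      gy <- aspd * cos(hr) + vw
      gnorm <- sqrt(gx * gx + gy * gy)
      gdir <- if (gnorm > 0) (atan2(gx, gy) / d2r) %% 360 else 0
      dst <- gnorm * step_s
      nxt <- dest1(lon[s], lat[s], gdir, dst)
      nstep <- s
      lon[s + 1] <- nxt[1]; lat[s + 1] <- nxt[2]
      gdirs[s] <- gdir
      ws_s <- if (gnorm > 0) (uw * gx + vw * gy) / gnorm else 0
      wsv[s] <- ws_s; ws_psum <- ws_psum + ws_s
      uvv[s, 1] <- uw; uvv[s, 2] <- vw
      heads[s] <- head_deg; airs[s] <- aspd; stepd[s] <- dst
      cum <- cum + dst
      # planted-length mode: no need to fly far beyond any plausible target
      if (!is.null(len_slope) && !is_loop && s > 4) {
        k <- ceiling(s / 2)
        bound <- (len_int + len_slope * sum(wsv[1:k]) / k + 5 * len_sd) * 1000
        if (cum >= bound) break
      }
      if (is_loop && !kret && cum >= cf$loop_out_km * 1000) kret <- TRUE
      if (is_loop && kret &&
          gc_distance(nxt[1], nxt[2], loop_goal[1], loop_goal[2]) <= dst) break
      if (nxt[2] <= coast_s || nxt[2] >= coast_n) break
    }
    n <- nstep
    t_final <- NULL
    # planted length law: truncate at the fixed-point target length, splitting
    # the crossing step so the realized length equals the target exactly
    if (!is.null(cf$length_slope_km) && !is_loop) {
      cum <- cumsum(stepd[1:n])
      half_ws <- function(L) {
        k <- which(cum >= L / 2)[1]; if (is.na(k)) k <- n
        mean(wsv[1:k])
      }
      L <- cf$length_intercept_km * 1000
      for (it2 in 1:30) {
        L <- (cf$length_intercept_km + cf$length_slope_km * half_ws(L)) * 1000 +
          len_eps * 1000
      }
      ncut <- which(cum >= L)[1]
      if (!is.na(ncut) && stepd[ncut] > 0) {
        f <- (L - if (ncut > 1) cum[ncut - 1] else 0) / stepd[ncut]
        fin <- dest1(lon[ncut], lat[ncut], gdirs[ncut], stepd[ncut] * f)
        n <- ncut
        lon[n + 1] <- fin[1]; lat[n + 1] <- fin[2]
        stepd[n] <- stepd[n] * f
        t_final <- dep + ((n - 1) + f) * cf$step_s
      }
    }
    times <- dep + (0:n) * cf$step_s
    if (!is.null(t_final)) times[n + 1] <- t_final
    surface <- ifelse(lat[1:(n + 1)] <= cf$coast_lat_s | lat[1:(n + 1)] >= cf$coast_lat_n,
                      "land", "ocean")
    id <- sprintf("synth%03d", i)
    tracks[[id]] <- track(id, times, lon[1:(n + 1)], lat[1:(n + 1)], surface = surface)
    per_track[[id]] <- list(
      class = if (is_loop) "loop" else if (sin(deg2rad(brg)) > 0) "directed-east" else "directed-west",
      bearing = brg, air_speed_mean = air_mean, departure = dep,
      air_speed = airs[1:n], heading = heads[1:n],
      wind_u = uvv[1:n, 1], wind_v = uvv[1:n, 2], ws = wsv[1:n],
      length_eps_km = len_eps
    )
  }
  manifest <- list(
    global = list(seed = cf$seed, active_level = cf$active_level,
                  air_speed_mean = cf$air_speed_mean,
                  length_slope_km = cf$length_slope_km,
                  length_intercept_km = cf$length_intercept_km,
                  length_sd_km = cf$length_sd_km,
                  departure_law = cf$departure_law,
                  heading_law = cf$heading_law,
                  departure_window = window),
    per_track = per_track
  )
  list(tracks = tracks, manifest = manifest)
}

# one draw from a centred von Mises distribution (radians), Best & Fisher
# (1979) rejection sampler; kappa = 0 degenerates to uniform on (-pi, pi).
rvonmises1 <- function(kappa) {
  if (kappa < 1e-8) return(stats::runif(1, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  repeat {
    u1 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    u2 <- stats::runif(1)
    if (c_ * (2 - c_) - u2 > 0 || log(c_ / u2) + 1 - c_ >= 0) {
      return(sign(stats::runif(1) - 0.5) * acos(pmin(1, pmax(-1, f))))
    }
  }
}

#' Generate a complete synthetic world
#'
#' Convenience wrapper: wind grid + station, coastline, tracks, manifest.
#'
#' @param config a [synth_config()]
#' @return list with `grid`, `station`, `coast`, `tracks`, `manifest`
#' @export
gen_world <- function(config) {
  w <- gen_wind(config)
  tr <- gen_tracks(config, w)
  list(grid = w$grid, station = w$station, coast = gen_coastline(config),
       tracks = tr$tracks, manifest = tr$manifest)
}
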