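# Null models for departure timing: rigid time-shifts of whole tracks to
# random departures within the season window, the west-minus-east delta wind
# support of a departure night, and the departure-shift sensitivity profile.

#' Randomized-departure null distribution for one track
#'
#' Shifts the whole track rigidly in time to `n_sim` random departures and
#' recomputes the mean wind support each time against the wind grid; the
#' track's spatial shape is held fixed (the same flight flown at other
#' times). Departures are drawn uniformly in continuous time over the season
#' window ("continuous", default) or uniformly over whole nights keeping the
#' observed time of day ("day_grid"). The one-sided exceedance p is the
#' fraction of simulated values greater than or equal to the observed one
#' (ties count against significance).
#'
#' @param t a [track()]
#' @param grid a [wind_grid()] covering the window plus the flight duration
#' @param season_window c(first, last) POSIXct departure times of the season
#' @param n_sim ensemble size (study-scale default 10000)
#' @param seed integer seed (required: seeded runs reproduce bit-identically)
#' @param statistic "first50" (mean wind support over the first 50 km,
#'   default) or "full" (whole track)
#' @param level level name (default "750m")
#' @param mode "continuous" or "day_grid"
#' @param alpha one-sided significance level (default 0.05)
#' @return object of class `null_dist`: `id`, `observed`, `sim` (ensemble),
#'   `p`, `significant`, `mean_diff` (observed minus null mean), `n_sim`,
#'   `statistic`, `level`
#' @export
random_departures <- function(t, grid, season_window, n_sim = 10000, seed,
                              statistic = c("first50", "full"), level = "750m",
                              mode = c("continuous", "day_grid"), alpha = 0.05) {
  statistic <- match.arg(statistic)
  mode <- match.arg(mode)
  if (missing(seed)) stop("a seed is required for reproducible ensembles")
  w0 <- as.numeric(season_window[1]); w1 <- as.numeric(season_window[2])
  if (w1 <= w0) stop("degenerate season window (single instant)")
  tt <- if (!is.null(t$surface)) trim_to_ocean(t) else t
  segs <- annotate_track(tt, grid, level)
  cum <- cumsum(segs$distance_m)
  use <- if (statistic == "first50") {
    k <- which(cum >= 50 * 1000)[1]
    if (is.na(k)) k <- nrow(segs)
    seq_len(k)
  } else seq_len(nrow(segs))
  observed <- mean(segs$ws[use])
  # fixed spatial part of the lookup (segment-start positions)
  sp <- grid_space_index(grid, tt$lon[use], tt$lat[use])
  ilev <- level_index(grid, level)
  a <- deg2rad(segs$ground_direction[use])
  a[is.na(a)] <- 0
  sina <- sin(a); cosa <- cos(a)
  seg_t <- as.numeric(segs$t_start[use])
  dep <- seg_t[1]
  gt <- as.numeric(grid$times); ntim <- length(gt)
  step <- grid_time_step(grid)
  set.seed(seed)
  delta <- if (mode == "continuous") {
    stats::runif(n_sim, w0, w1) - dep
  } else {
    ndays <- floor((w1 - w0) / 86400)
    if (ndays < 1) stop("window shorter than one day in day_grid mode")
    # uniform over nights, keeping the observed time of day
    day0 <- floor(w0 / 86400) * 86400
    new_dep <- day0 + 86400 * (sample.int(ndays + 1, n_sim, replace = TRUE) - 1) +
      (dep %% 86400)
    new_dep - dep
  }
  # times matrix (n_sim x m) -> nearest regular time index (earlier on ties,
  # matching sample_wind)
  m <- length(use)
  tmat <- outer(delta, seg_t, "+")
  if (any(tmat < gt[1] - step) || any(tmat > gt[ntim] + step)) {
    stop("shifted track leaves wind-grid temporal coverage; extend the grid")
  }
  it <- pmin(pmax(ceiling((tmat - gt[1]) / step - 0.5) + 1L, 1L), ntim)
  ilon <- matrix(rep(sp$ilon, each = n_sim), n_sim, m)
  ilat <- matrix(rep(sp$ilat, each = n_sim), n_sim, m)
  uu <- grid$u[cbind(as.vector(ilon), as.vector(ilat), ilev, as.vector(it))]
  vv <- grid$v[cbind(as.vector(ilon), as.vector(ilat), ilev, as.vector(it))]
  wsm <- matrix(uu, n_sim, m) * matrix(rep(sina, each = n_sim), n_sim, m) +
    matrix(vv, n_sim, m) * matrix(rep(cosa, each = n_sim), n_sim, m)
  sim <- rowMeans(wsm)
  p <- mean(sim >= observed)
  structure(
    list(id = track_id(t), observed = observed, sim = sim, p = p,
         significant = p < alpha, mean_diff = observed - mean(sim),
         n_sim = n_sim, statistic = statistic, level = level),
    class = "null_dist"
  )
}

#' @export
print.null_dist <- function(x, ...) {
  cat("<null_dist>", x$id, sprintf("(%s, %s, n_sim = %d)\n", x$statistic, x$level, x$n_sim))
  cat(sprintf("  observed %.2f m/s vs null mean %.2f m/s (diff %.2f)\n",
              x$observed, x$observed - x$mean_diff, x$mean_diff))
  cat(sprintf("  one-sided p = %.4f %s\n", x$p,
              if (x$significant) "(significant)" else ""))
  invisible(x)
}

#' Delta wind support for a departure night: west minus east
#'
#' Wind support an individual would have experienced flying west versus east
#' from a location at the mean departure hour of a night (default 22:30
#' local). Antisymmetric under swapping the reference bearings.
#'
#' @param night Date of the departure day
#' @param location c(lon, lat)
#' @param grid a [wind_grid()]
#' @param west_bearing,east_bearing reference bearings, degrees (defaults
#'   270 and 90; studies use the mean observed west- and east-track initial
#'   bearings)
#' @param local_time_hm departure clock time "HH:MM" (default "22:30")
#' @param tz_offset_h local-clock offset (default -8, AKDT)
#' @param level level name (default "750m")
#' @return one-row data.frame: `night`, `ws_west`, `ws_east`, `delta_we`,
#'   `west_bearing`, `east_bearing`
#' @export
delta_wind_support <- function(night, location, grid,
                               west_bearing = 270, east_bearing = 90,
                               local_time_hm = "22:30", tz_offset_h = -8,
                               level = "750m") {
  hm <- as.numeric(strsplit(local_time_hm, ":")[[1]])
  t_utc <- as.POSIXct(paste(as.Date(night), "00:00:00"), tz = "UTC") +
    hm[1] * 3600 + hm[2] * 60 - tz_offset_h * 3600
  w <- sample_wind(grid, location[1], location[2], t_utc, level)
  wsw <- wind_components(w$u, w$v, west_bearing)$ws
  wse <- wind_components(w$u, w$v, east_bearing)$ws
  data.frame(night = as.Date(night), ws_west = wsw, ws_east = wse,
             delta_we = wsw - wse,
             west_bearing = west_bearing, east_bearing = east_bearing)
}

#' Departure-shift sensitivity profile for one track
#'
#' Wind support toward the track's actual destination (the great-circle
#' bearing from departure to arrival location), evaluated at the departure
#' location at the actual departure time shifted by -12..+12 h in hourly
#' steps (ground-station wind) and by -5..+5 days in daily steps (wind grid,
#' every level). Offsets without coverage are marked `NA` rather than
#' failing.
#'
#' @param t a [track()]
#' @param grid a [wind_grid()]
#' @param station data.frame from [read_station_wind()] (or `gen_wind()`)
#' @param hours,days offset ranges (defaults 12 h, 5 d)
#' @param station_tol_s max station-record distance from a queried hour
#'   (default 1800 s)
#' @return object of class `shift_profile`: `hourly` (offset_h, ws),
#'   `daily` (offset_d x level), `bearing`, `id`
#' @export
departure_shift_profile <- function(t, grid, station, hours = 12, days = 5,
                                    station_tol_s = 1800) {
  tt <- if (!is.null(t$surface)) trim_to_ocean(t) else t
  n <- nrow(tt)
  brg <- dist_bearing(tt$lon[1], tt$lat[1], tt$lon[n], tt$lat[n])$bearing_deg
  if (is.na(brg)) stop("departure and arrival coincide; destination bearing undefined")
  dep <- tt$time[1]
  st_t <- as.numeric(station$time)
  hourly <- data.frame(offset_h = -hours:hours, ws = NA_real_)
  for (i in seq_len(nrow(hourly))) {
    q <- as.numeric(dep) + hourly$offset_h[i] * 3600
    if (!length(st_t)) next
    j <- nearest_idx(st_t, q)
    if (abs(st_t[j] - q) <= station_tol_s) {
      hourly$ws[i] <- wind_components(station$u[j], station$v[j], brg)$ws
    }
  }
  daily <- expand.grid(offset_d = -days:days, level = grid$level_names,
                       stringsAsFactors = FALSE)
  daily$ws <- NA_real_
  for (i in seq_len(nrow(daily))) {
    q <- dep + daily$offset_d[i] * 86400
    w <- tryCatch(sample_wind(grid, tt$lon[1], tt$lat[1], q, daily$level[i]),
                  error = function(e) NULL)
    if (!is.null(w)) daily$ws[i] <- wind_components(w$u, w$v, brg)$ws
  }
  structure(list(hourly = hourly, daily = daily, bearing = brg, id = track_id(t)),
            class = "shift_profile")
}

#' @export
print.shift_profile <- function(x, ...) {
  cat("<shift_profile>", x$id, sprintf("toward bearing %.0f deg\n", x$bearing))
  at0 <- x$hourly$ws[x$hourly$offset_h == 0]
  cat(sprintf("  hourly: ws at offset 0 = %.2f m/s; range [%.2f, %.2f]\n",
              at0, min(x$hourly$ws, na.rm = TRUE), max(x$hourly$ws, na.rm = TRUE)))
  cat("  daily offsets x levels:", nrow(x$daily), "cells,",
      sum(is.na(x$daily$ws)), "missing\n")
  invisible(x)
}
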