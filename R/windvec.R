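# Wind-vector decomposition relative to a flight direction. With u eastward
# wind, v northward wind, and alpha the ground direction (degrees clockwise
# from north), the wind vector splits into a component along the ground
# vector (wind support, positive = tailwind) and a side-agnostic
# perpendicular component (crosswind). Relative wind support is the cosine
# of the wind-track angle, bounded by -1 (exact headwind) and +1 (exact
# tailwind).

#' Wind support, crosswind and relative wind support
#'
#' Decomposes a wind vector relative to a movement direction:
#' `ws = u*sin(a) + v*cos(a)` (signed along-track component),
#' `cw = |u*cos(a) - v*sin(a)|` (perpendicular magnitude), and
#' `rel_ws = ws / wind speed` (defined as 0 in calm air: no flow, no
#' support). Total function, vectorized over all arguments.
#'
#' @param u,v wind components, m/s (eastward, northward)
#' @param alpha ground (movement) direction, degrees clockwise from north
#' @return data.frame with `ws`, `cw`, `rel_ws`
#' @examples
#' wind_components(0, 10, 0)   # pure tailwind: ws 10, rel_ws 1
#' wind_components(0, 10, 180) # pure headwind: ws -10, rel_ws -1
#' @export
wind_components <- function(u, v, alpha) {
  a <- deg2rad(alpha)
  ws <- u * sin(a) + v * cos(a)
  cw <- abs(u * cos(a) - v * sin(a))
  spd <- sqrt(u^2 + v^2)
  rel <- ifelse(spd > 0, ws / spd, 0)
  data.frame(ws = ws, cw = cw, rel_ws = rel)
}

#' Annotate a track with per-segment wind metrics
#'
#' For each pair of consecutive positions: ground speed (great-circle
#' distance over elapsed time), ground direction, the wind sampled nearest
#' in space and time at the chosen altitude level, its decomposition into
#' wind support / crosswind / relative support, and the scalar air speed
#' (ground speed minus wind support - the field's standard approximation,
#' not the full wind-triangle solution).
#'
#' @param t a [track()] (trimmed to its ocean leg if surface-labelled)
#' @param grid a [wind_grid()]
#' @param level level name (e.g. "750m")
#' @param sample_at where along the segment wind is sampled: "start"
#'   (default) or "midpoint"
#' @return data.frame of class `segments`: one row per segment with columns
#'   `track`, `t_start`, `t_end`, `lon_mid`, `lat_mid`, `distance_m`,
#'   `ground_speed`, `ground_direction`, `u`, `v`, `wind_speed`, `ws`, `cw`,
#'   `rel_ws`, `air_speed`, `level`
#' @export
annotate_track <- function(t, grid, level, sample_at = c("start", "midpoint")) {
  sample_at <- match.arg(sample_at)
  tt <- if (!is.null(t$surface)) trim_to_ocean(t) else t
  n <- nrow(tt)
  db <- dist_bearing(tt$lon[-n], tt$lat[-n], tt$lon[-1], tt$lat[-1])
  dt <- diff(as.numeric(tt$time))
  if (sample_at == "start") {
    slon <- tt$lon[-n]; slat <- tt$lat[-n]; stime <- tt$time[-n]
  } else {
    mid <- destination_point(tt$lon[-n], tt$lat[-n],
                             ifelse(is.na(db$bearing_deg), 0, db$bearing_deg),
                             db$distance_m / 2)
    slon <- mid$lon; slat <- mid$lat
    stime <- tt$time[-n] + dt / 2
  }
  w <- tryCatch(
    sample_wind(grid, slon, slat, stime, level),
    error = function(e) stop("wind coverage gap while annotating track '",
                             track_id(t), "': ", conditionMessage(e))
  )
  gd <- ifelse(is.na(db$bearing_deg), 0, db$bearing_deg) # zero-length segment: direction moot
  comp <- wind_components(w$u, w$v, gd)
  gs <- db$distance_m / dt
  midp <- destination_point(tt$lon[-n], tt$lat[-n], gd, db$distance_m / 2)
  out <- data.frame(
    track = track_id(t),
    t_start = tt$time[-n], t_end = tt$time[-1],
    lon_mid = midp$lon, lat_mid = midp$lat,
    distance_m = db$distance_m,
    ground_speed = gs, ground_direction = db$bearing_deg,
    u = w$u, v = w$v, wind_speed = w$speed,
    ws = comp$ws, cw = comp$cw, rel_ws = comp$rel_ws,
    air_speed = gs - comp$ws,
    level = level,
    stringsAsFactors = FALSE
  )
  class(out) <- c("segments", "data.frame")
  out
}

#' Annotate several tracks at once
#' @param tracks list of [track()]s
#' @inheritParams annotate_track
#' @return row-bound `segments` data.frame
#' @export
annotate_tracks <- function(tracks, grid, level, sample_at = "start") {
  out <- do.call(rbind, lapply(tracks, annotate_track, grid = grid,
                               level = level, sample_at = sample_at))
  rownames(out) <- NULL
  class(out) <- c("segments", "data.frame")
  out
}

#' Altitude profile with maximal wind support
#'
#' Splits a track into consecutive 1-h windows anchored at departure (the
#' final partial window included), computes each level's mean wind support
#' per window, and picks per window the level with the highest mean (ties to
#' the lower altitude). The resulting "maxWs" track mean - the mean over
#' windows of the winning means - is an upper envelope on the wind support
#' attainable by hourly altitude changes, and by construction is at least
#' every fixed level's mean computed the same way.
#'
#' @param t a [track()] spanning at least one hour
#' @param grid a [wind_grid()] with the candidate levels
#' @param window_h window length in hours (default 1)
#' @return object of class `altitude_profile`: list with `windows`
#'   (data.frame: window, level, mean_ws), `maxws_mean`, and `level_means`
#'   (named per-fixed-level track means over the same windows)
#' @export
max_ws_altitude <- function(t, grid, window_h = 1) {
  tt <- if (!is.null(t$surface)) trim_to_ocean(t) else t
  span_h <- as.numeric(difftime(tt$time[nrow(tt)], tt$time[1], units = "hours"))
  if (span_h < window_h) stop("track spans less than one window")
  step <- grid_time_step(grid)
  if (!is.na(step) &&
      as.numeric(difftime(tt$time[nrow(tt)], tt$time[1], units = "secs")) < step) {
    stop("track shorter than one wind time-step")
  }
  levs <- grid$level_names
  seg_list <- lapply(levs, function(l) annotate_track(tt, grid, l))
  t0 <- as.numeric(tt$time[1])
  win <- floor((as.numeric(seg_list[[1]]$t_start) - t0) / (window_h * 3600)) + 1L
  nwin <- max(win)
  wmeans <- sapply(seg_list, function(s) tapply(s$ws, win, mean)) # nwin x nlev
  wmeans <- matrix(wmeans, nrow = nwin,
                   dimnames = list(NULL, levs))
  # which.max returns the first (= lower-altitude) index on ties
  best <- apply(wmeans, 1, which.max)
  windows <- data.frame(
    window = seq_len(nwin),
    level = levs[best],
    mean_ws = wmeans[cbind(seq_len(nwin), best)]
  )
  structure(
    list(windows = windows,
         maxws_mean = mean(windows$mean_ws),
         level_means = colMeans(wmeans)),
    class = "altitude_profile"
  )
}

#' Annotate a track at the hourly maxWs altitude assignment
#'
#' Segments take their wind from whichever level [max_ws_altitude()] chose
#' for their 1-h window, so a speed model fitted to these segments is the
#' "maxWs" candidate in the altitude comparison. The `level` column is set
#' to "maxWs"; `chosen_level` records the per-segment winner.
#'
#' @inheritParams max_ws_altitude
#' @return a `segments` data.frame
#' @export
annotate_track_maxws <- function(t, grid, window_h = 1) {
  tt <- if (!is.null(t$surface)) trim_to_ocean(t) else t
  prof <- max_ws_altitude(tt, grid, window_h)
  seg_by_level <- lapply(grid$level_names, function(l) annotate_track(tt, grid, l))
  names(seg_by_level) <- grid$level_names
  t0 <- as.numeric(tt$time[1])
  win <- floor((as.numeric(seg_by_level[[1]]$t_start) - t0) / (window_h * 3600)) + 1L
  lev_for_seg <- prof$windows$level[win]
  out <- seg_by_level[[1]]
  for (l in unique(lev_for_seg)) {
    rows <- which(lev_for_seg == l)
    out[rows, ] <- seg_by_level[[l]][rows, ]
  }
  out$chosen_level <- lev_for_seg
  out$level <- "maxWs"
  class(out) <- c("segments", "data.frame")
  out
}

#' @export
print.altitude_profile <- function(x, ...) {
  cat("<altitude_profile>", nrow(x$windows), "windows\n")
  cat("  maxWs mean:", sprintf("%.2f m/s", x$maxws_mean), "\n")
  cat("  fixed-level means:",
      paste(sprintf("%s %.2f", names(x$level_means), x$level_means), collapse = ", "), "\n")
  tab <- table(x$windows$level)
  cat("  chosen:", paste(sprintf("%s x%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}
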