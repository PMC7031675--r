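# Counterfactual shortest-route simulator: fly from departure to arrival
# "heading towards" the arrival point (the great-circle bearing to it,
# re-evaluated each step - a fixed target is not a fixed compass bearing on
# a sphere), moving each 15-min step at the ground speed the fitted speed
# model predicts for the local wind support and crosswind. Negative
# predicted speeds conservatively stall the bird in place.

#' Simulate the shortest (direct) route under a speed model
#'
#' @param dep,arr c(lon, lat) departure and arrival locations
#' @param t0 departure time (POSIXct, UTC)
#' @param grid a [wind_grid()] covering the route and a generous time span
#' @param fit a [fit_speed_model()] result (fixed effects are used: the
#'   counterfactual bird is population-level)
#' @param level level name to sample wind at (default: the fit's level)
#' @param step_s step length in seconds (default 900)
#' @param max_steps hard cap; default 4x the closed-form no-wind estimate
#'   (distance over the model intercept speed)
#' @return object of class `sim_route`: `points` (data.frame time, lon,
#'   lat), `flight_time_h`, `mean_ws`, `mean_cw`, `stalled_steps`, `status`
#'   ("arrived" or "max-steps-exceeded")
#' @export
simulate_shortest_route <- function(dep, arr, t0, grid, fit, level = NULL,
                                    step_s = 900, max_steps = NULL) {
  level <- level %||% fit$level
  if (identical(level, "maxWs")) stop("route simulation needs a fixed altitude level")
  total <- gc_distance(dep[1], dep[2], arr[1], arr[2])
  if (is.null(max_steps)) {
    v0 <- fit$coefficients[["(Intercept)"]]
    max_steps <- if (v0 > 0) max(10L, ceiling(4 * total / (v0 * step_s))) else 5000L
  }
  lon <- dep[1]; lat <- dep[2]; tcur <- t0
  pts <- list(data.frame(time = t0, lon = lon, lat = lat))
  wss <- numeric(0); cws <- numeric(0)
  stalled <- 0L; status <- "max-steps-exceeded"; steps <- 0L
  if (total == 0) {
    status <- "arrived"
  } else {
    for (s in seq_len(max_steps)) {
      db <- dist_bearing(lon, lat, arr[1], arr[2])
      remaining <- db$distance_m
      brg <- db$bearing_deg
      w <- tryCatch(sample_wind(grid, lon, lat, tcur, level), error = function(e) e)
      if (inherits(w, "error")) {
        res <- structure(
          list(points = do.call(rbind, pts), flight_time_h = steps * step_s / 3600,
               mean_ws = if (length(wss)) mean(wss) else NA_real_,
               mean_cw = if (length(cws)) mean(cws) else NA_real_,
               stalled_steps = stalled, status = "coverage-exhausted"),
          class = "sim_route")
        stop(structure(class = c("windtrack_coverage_error", "error", "condition"),
                       list(message = paste("wind coverage exhausted before arrival:",
                                            conditionMessage(w)),
                            call = sys.call(-1), partial = res)))
      }
      comp <- wind_components(w$u, w$v, brg)
      speed <- predict(fit, data.frame(ws = comp$ws, cw = comp$cw))
      wss <- c(wss, comp$ws); cws <- c(cws, comp$cw)
      steps <- s
      if (speed <= 0) {
        stalled <- stalled + 1L # negative predicted speed: hold position
        tcur <- tcur + step_s
        pts[[length(pts) + 1]] <- data.frame(time = tcur, lon = lon, lat = lat)
        next
      }
      reach <- speed * step_s
      if (remaining <= reach) {
        # final step, clamped to the arrival point (no overshoot)
        tcur <- tcur + step_s
        lon <- arr[1]; lat <- arr[2]
        pts[[length(pts) + 1]] <- data.frame(time = tcur, lon = lon, lat = lat)
        status <- "arrived"
        break
      }
      nxt <- destination_point(lon, lat, brg, reach)
      lon <- nxt$lon; lat <- nxt$lat
      tcur <- tcur + step_s
      pts[[length(pts) + 1]] <- data.frame(time = tcur, lon = lon, lat = lat)
    }
  }
  structure(
    list(points = do.call(rbind, pts),
         flight_time_h = steps * step_s / 3600,
         mean_ws = if (length(wss)) mean(wss) else NA_real_,
         mean_cw = if (length(cws)) mean(cws) else NA_real_,
         stalled_steps = stalled, status = status),
    class = "sim_route"
  )
}

#' @export
print.sim_route <- function(x, ...) {
  n <- nrow(x$points)
  cat("<sim_route>", x$status, sprintf("(%d steps, %.2f h)\n", n - 1, x$flight_time_h))
  cat(sprintf("  mean ws %.2f m/s, mean cw %.2f m/s, %d stalled steps\n",
              x$mean_ws, x$mean_cw, x$stalled_steps))
  invisible(x)
}

#' Compare the actual route with the simulated direct route
#'
#' Signed per-track differences: `d_mean_ws` = mean wind support on the
#' actual track minus on the simulated shortest route (positive: the actual
#' route caught more tailwind), and `d_time_h` = actual flight time minus
#' simulated direct flight time (positive: the direct route would have been
#' faster). Routes that never arrived get `NA` time differences but keep
#' their status.
#'
#' @param t the actual [track()]
#' @param segments the actual track's `segments` (same level as the sim)
#' @param sim a [simulate_shortest_route()] result for the same
#'   departure/arrival pair
#' @param tol_km endpoint agreement tolerance (default 1 km)
#' @return one-row data.frame: `id`, `d_mean_ws`, `d_time_h`, `sim_status`
#' @export
compare_routes <- function(t, segments, sim, tol_km = 1) {
  tt <- if (!is.null(t$surface)) trim_to_ocean(t) else t
  n <- nrow(tt)
  segs <- segments[segments$track == track_id(t), , drop = FALSE]
  if (!nrow(segs)) stop("no segments for track '", track_id(t), "'")
  pts <- sim$points
  m <- nrow(pts)
  if (gc_distance(pts$lon[1], pts$lat[1], tt$lon[1], tt$lat[1]) > tol_km * 1000 ||
      (sim$status == "arrived" &&
       gc_distance(pts$lon[m], pts$lat[m], tt$lon[n], tt$lat[n]) > tol_km * 1000)) {
    stop("simulated route endpoints do not match track '", track_id(t), "'")
  }
  actual_h <- as.numeric(difftime(tt$time[n], tt$time[1], units = "hours"))
  d_time <- if (sim$status == "arrived") actual_h - sim$flight_time_h else NA_real_
  data.frame(id = track_id(t), d_mean_ws = mean(segs$ws) - sim$mean_ws,
             d_time_h = d_time, sim_status = sim$status, stringsAsFactors = FALSE)
}

#' Actual-versus-shortest comparison for a set of tracks
#'
#' Runs [simulate_shortest_route()] from each track's departure to its
#' arrival location at its departure time and compares with the observed
#' track; aggregates the signed differences per flight class.
#'
#' @param tracks list of [track()]s
#' @param segments `segments` for the same tracks
#' @param summaries [summarize_tracks()] output (class column added if
#'   absent)
#' @param grid a [wind_grid()]
#' @param fit a [fit_speed_model()] result
#' @param level fixed altitude level (default: the fit's level)
#' @return list of class `route_comparison`: `per_track` data.frame,
#'   `by_class` aggregated means
#' @export
compare_routes_all <- function(tracks, segments, summaries, grid, fit, level = NULL) {
  level <- level %||% fit$level
  s <- as.data.frame(summaries)
  if (!"class" %in% names(s)) s$class <- classify_flight(s)
  rows <- lapply(seq_len(nrow(s)), function(i) {
    tr <- tracks[[s$id[i]]]
    tt <- if (!is.null(tr$surface)) trim_to_ocean(tr) else tr
    n <- nrow(tt)
    sim <- simulate_shortest_route(c(tt$lon[1], tt$lat[1]), c(tt$lon[n], tt$lat[n]),
                                   tt$time[1], grid, fit, level)
    cmp <- compare_routes(tr, segments, sim)
    cmp$class <- s$class[i]
    cmp
  })
  per_track <- do.call(rbind, rows)
  by_class <- do.call(rbind, lapply(split(per_track, per_track$class), function(g) {
    data.frame(class = g$class[1], n = nrow(g),
               mean_d_ws = mean(g$d_mean_ws, na.rm = TRUE),
               mean_d_time_h = mean(g$d_time_h, na.rm = TRUE))
  }))
  rownames(by_class) <- NULL
  structure(list(per_track = per_track, by_class = by_class),
            class = "route_comparison")
}

#' @export
print.route_comparison <- function(x, ...) {
  cat("<route_comparison>", nrow(x$per_track), "tracks\n")
  print(transform(x$by_class, mean_d_ws = round(mean_d_ws, 2),
                  mean_d_time_h = round(mean_d_time_h, 2)), row.names = FALSE)
  invisible(x)
}
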