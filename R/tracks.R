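# Tracks: time-ordered geographic positions of one individual, nominally at
# 15-min spacing, with optional per-point ocean/land labels taken from a
# coastline polygon. Track-level metrics follow the movement-ecology
# conventions: length as summed consecutive great-circle distances,
# straightness as length over the departure-arrival geodesic (1 = direct
# flight, large values = loop flights).

#' Construct a track
#'
#' @param id track identifier (string)
#' @param time POSIXct timestamps (UTC), strictly increasing
#' @param lon,lat positions in decimal degrees
#' @param surface optional per-point labels, "ocean" or "land"
#' @param season optional season/year tag (defaults to the year of the first
#'   position)
#' @return data.frame of class `track` with attributes `id` and `season`
#' @export
track <- function(id, time, lon, lat, surface = NULL, season = NULL) {
  if (length(time) < 2) stop("track '", id, "' needs at least 2 points")
  if (any(diff(as.numeric(time)) <= 0)) {
    stop("timestamps not strictly increasing in track '", id, "'")
  }
  p <- geo_point(lon, lat)
  d <- data.frame(time = time, lon = p$lon, lat = p$lat)
  if (!is.null(surface)) {
    if (!all(surface %in% c("ocean", "land"))) stop("surface labels must be 'ocean' or 'land'")
    d$surface <- surface
  }
  attr(d, "id") <- as.character(id)
  attr(d, "season") <- season %||% as.integer(format(time[1], "%Y"))
  class(d) <- c("track", "data.frame")
  d
}

track_id <- function(t) attr(t, "id")

#' @export
print.track <- function(x, ...) {
  cat("<track>", track_id(x), " n =", nrow(x), " season =", attr(x, "season"), "\n")
  cat("  ", format(x$time[1], tz = "UTC"), "to", format(x$time[nrow(x)], tz = "UTC"), "\n")
  invisible(x)
}

#' Read tracks from CSV
#'
#' Expects columns `id`, `timestamp` (ISO-8601 UTC), `lon`, `lat`, and an
#' optional `surface` column. Rows are grouped by id and sorted by time;
#' duplicate timestamps within an id are an error.
#'
#' @param path CSV path (or a data.frame with the same columns)
#' @return named list of [track()] objects
#' @export
read_tracks <- function(path) {
  d <- if (is.data.frame(path)) path else utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "timestamp", "lon", "lat")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("track CSV lacks column(s): ", paste(miss, collapse = ", "))
  tm <- as.POSIXct(d$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  if (any(is.na(tm))) stop("unparseable timestamp(s) in track CSV")
  d$time <- tm
  out <- lapply(split(d, d$id), function(g) {
    g <- g[order(g$time), , drop = FALSE]
    if (any(diff(as.numeric(g$time)) == 0)) {
      stop("duplicated timestamp in track '", g$id[1], "'")
    }
    track(g$id[1], g$time, g$lon, g$lat,
          surface = if ("surface" %in% names(g)) g$surface else NULL)
  })
  out[order(names(out))]
}

#' Read a coastline from GeoJSON
#'
#' Accepts Polygon / MultiPolygon geometries (Feature, FeatureCollection or
#' bare geometry) in lon/lat WGS84. The polygons are interpreted as land;
#' everything else is ocean. Only outer rings are used.
#'
#' @param path GeoJSON file path (or a JSON string)
#' @return object of class `coastline`: a list of lon/lat vertex matrices
#' @export
read_coastline <- function(path) {
  g <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  polys <- list()
  grab_geom <- function(geom) {
    if (is.null(geom$type)) return()
    if (geom$type == "Polygon") {
      ring <- geom$coordinates[[1]]
      polys[[length(polys) + 1]] <<- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    } else if (geom$type == "MultiPolygon") {
      for (pg in geom$coordinates) {
        ring <- pg[[1]]
        polys[[length(polys) + 1]] <<- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
      }
    }
  }
  ty <- g$type %||% ""
  if (ty == "FeatureCollection") {
    for (f in g$features) grab_geom(f$geometry)
  } else if (ty == "Feature") {
    grab_geom(g$geometry)
  } else {
    grab_geom(g)
  }
  if (!length(polys)) stop("no Polygon/MultiPolygon geometry found in GeoJSON")
  structure(polys, class = "coastline")
}

#' Label track points as ocean or land
#'
#' Points inside (or on the boundary of) any land polygon are labelled
#' "land", all others "ocean".
#'
#' @param t a [track()]
#' @param coast a [read_coastline()] object (land polygons)
#' @return the track with a `surface` column
#' @export
label_surface <- function(t, coast) {
  land <- rep(FALSE, nrow(t))
  for (poly in coast) {
    land <- land | sp::point.in.polygon(t$lon, t$lat, poly[, 1], poly[, 2]) > 0
  }
  t$surface <- ifelse(land, "land", "ocean")
  t
}

# Indices of the over-ocean leg: first ocean position through last ocean
# position. Post-landfall positions (after the last ocean fix) are excluded;
# interior points keep their labels.
ocean_span <- function(t) {
  if (is.null(t$surface)) return(seq_len(nrow(t)))
  io <- which(t$surface == "ocean")
  if (length(io) < 2) stop("track '", track_id(t), "' has fewer than 2 ocean positions")
  io[1]:io[length(io)]
}

# Trim a track to its over-ocean leg.
trim_to_ocean <- function(t) {
  sp <- ocean_span(t)
  out <- t[sp, , drop = FALSE]
  attributes(out)[c("id", "season")] <- attributes(t)[c("id", "season")]
  class(out) <- class(t)
  out
}

# Per-segment great-circle distances (m) of consecutive positions.
segment_distances <- function(t) {
  n <- nrow(t)
  gc_distance(t$lon[-n], t$lat[-n], t$lon[-1], t$lat[-1])
}

#' Total track length
#' @param t a [track()]
#' @return sum of consecutive great-circle distances, metres
#' @export
track_length_m <- function(t) sum(segment_distances(t))

#' Apply the study-design track selection filters
#'
#' Keeps tracks that satisfy all of: (1) departure (first ocean position)
#' before `cutoff_date`; (2) departure location within `radius_km` of
#' `origin`; (3) an over-ocean departure leg (the first ocean position is
#' followed immediately by another ocean position); (4) over-ocean track
#' length greater than `min_length_km`.
#'
#' @param tracks list of labelled [track()]s
#' @param origin c(lon, lat) of the study site
#' @param cutoff_date Date; departures on/after it are dropped
#' @param min_length_km minimum over-ocean track length (default 500)
#' @param radius_km maximum departure distance from origin (default 250)
#' @param tz_offset_h local-clock offset for the departure date (default -8)
#' @return the surviving subset (possibly empty list)
#' @export
select_tracks <- function(tracks, origin, cutoff_date, min_length_km = 500,
                          radius_km = 250, tz_offset_h = -8) {
  keep <- vapply(tracks, function(t) {
    if (is.null(t$surface)) stop("tracks must be surface-labelled before selection")
    io <- which(t$surface == "ocean")
    if (length(io) < 2) return(FALSE)
    # over-ocean departure leg: the track must start over the ocean
    if (t$surface[1] != "ocean" || t$surface[2] != "ocean") return(FALSE)
    dep <- io[1]
    dep_date <- as.Date(local_time(t$time[dep], tz_offset_h), tz = "UTC")
    if (dep_date >= as.Date(cutoff_date)) return(FALSE)
    d0 <- gc_distance(t$lon[dep], t$lat[dep], origin[1], origin[2])
    if (d0 > radius_km * 1000) return(FALSE)
    track_length_m(trim_to_ocean(t)) > min_length_km * 1000
  }, logical(1))
  tracks[keep]
}

#' Summarize a track
#'
#' Computes the standard track-description variables on the over-ocean leg:
#' departure/arrival times (first/last ocean position), flight time, track
#' length, departure-arrival geodesic ("shortest") distance, detour
#' (length - shortest), percentage detour (detour / length), straightness
#' (length / shortest), departure day (local clock minus 12 h so one night is
#' one day), initial direction (bearing of the displacement accumulated over
#' the first 50 km of track length, including the crossing segment in full)
#' and final direction (departure-to-arrival bearing).
#'
#' @param t a [track()] (surface-labelled, or assumed all-ocean)
#' @param initial_km path length over which the initial direction is taken
#'   (default 50)
#' @param tz_offset_h local-clock offset in hours (default -8, AKDT)
#' @return one-row data.frame of class `track_summary`
#' @export
summarize_track <- function(t, initial_km = 50, tz_offset_h = -8) {
  tt <- trim_to_ocean(t)
  n <- nrow(tt)
  segs <- segment_distances(tt)
  len <- sum(segs)
  short <- gc_distance(tt$lon[1], tt$lat[1], tt$lon[n], tt$lat[n])
  cum <- cumsum(segs)
  k <- which(cum >= initial_km * 1000)[1]
  if (is.na(k)) k <- length(segs) # short track: use full displacement
  init <- dist_bearing(tt$lon[1], tt$lat[1], tt$lon[k + 1], tt$lat[k + 1])$bearing_deg
  fin <- dist_bearing(tt$lon[1], tt$lat[1], tt$lon[n], tt$lat[n])$bearing_deg
  straight <- if (short > 0) len / short else Inf
  out <- data.frame(
    id = track_id(t),
    season = attr(t, "season"),
    departure_time = tt$time[1],
    arrival_time = tt$time[n],
    flight_time_h = as.numeric(difftime(tt$time[n], tt$time[1], units = "hours")),
    track_length_km = len / 1000,
    shortest_km = short / 1000,
    detour_km = (len - short) / 1000,
    percent_detour = if (len > 0) 100 * (len - short) / len else 0,
    straightness = straight,
    departure_day = departure_day(tt$time[1], tz_offset_h),
    initial_direction = init,
    final_direction = fin,
    stringsAsFactors = FALSE
  )
  class(out) <- c("track_summary", "data.frame")
  out
}

#' Summarize a list of tracks
#' @param tracks list of [track()]s
#' @param ... passed to [summarize_track()]
#' @return data.frame, one row per track
#' @export
summarize_tracks <- function(tracks, ...) {
  out <- do.call(rbind, lapply(tracks, summarize_track, ...))
  rownames(out) <- NULL
  out
}

#' Classify a flight as directed-east, directed-west, or loop
#'
#' Loops are tracks whose straightness is at or above `loop_threshold`
#' (default 3, chosen inside the empty gap between typical directed
#' straightness values, which stay below ~2.3, and loop values, which start
#' above ~5). Directed flights split east/west by the sign of the eastward
#' component of the final (departure-to-arrival) bearing.
#'
#' @param s a [summarize_track()] row (or data.frame of them)
#' @param loop_threshold straightness at/above which a flight is a loop
#' @return character vector: "directed-east", "directed-west", or "loop"
#' @export
classify_flight <- function(s, loop_threshold = 3) {
  east <- sin(deg2rad(s$final_direction)) > 0
  ifelse(s$straightness >= loop_threshold, "loop",
         ifelse(east, "directed-east", "directed-west"))
}
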