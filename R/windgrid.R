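# Gridded wind fields: an ERA-Interim-like lattice of u (eastward) and v
# (northward) wind components, dimensioned (lon, lat, level, time), with a
# fixed time step (nominally 6 h) and named altitude levels. Levels carry
# nominal heights in metres mapped from pressure levels; results downstream
# are reported by height.

#' Default pressure-level to nominal-height mapping
#'
#' Ground level (10 m) plus five pressure levels and the heights they
#' roughly correspond to over the study region.
#'
#' @return data.frame with `pressure_hPa` (NA for the 10 m ground level),
#'   `height_m`, and `name`
#' @export
default_level_map <- function() {
  data.frame(
    pressure_hPa = c(NA, 1000, 925, 850, 775, 700),
    height_m = c(10, 100, 750, 1500, 2250, 3000),
    name = c("10m", "100m", "750m", "1500m", "2250m", "3000m"),
    stringsAsFactors = FALSE
  )
}

#' Construct a wind grid
#'
#' In-memory container for u/v wind components on a regular
#' lon x lat x level x time lattice. Longitudes are normalized to
#' [-180, 180) and all axes sorted ascending (times strictly increasing and
#' equally spaced). Missing cells are an error: reanalysis-style extracts
#' should be complete, and silent filling hides coverage bugs.
#'
#' @param lon,lat regular coordinate vectors (degrees)
#' @param level_names character vector of level names (e.g. "750m")
#' @param level_heights nominal heights in metres, same length, ascending
#' @param times POSIXct (UTC), strictly increasing, equally spaced
#' @param u,v arrays dim c(nlon, nlat, nlevel, ntime), m/s
#' @return object of class `wind_grid`
#' @export
wind_grid <- function(lon, lat, level_names, level_heights, times, u, v) {
  lon <- ((lon + 180) %% 360) - 180
  if (is.unsorted(lon, strictly = TRUE)) {
    o <- order(lon)
    lon <- lon[o]; u <- u[o, , , , drop = FALSE]; v <- v[o, , , , drop = FALSE]
  }
  if (is.unsorted(lat, strictly = TRUE)) {
    o <- order(lat)
    lat <- lat[o]; u <- u[, o, , , drop = FALSE]; v <- v[, o, , , drop = FALSE]
  }
  dims <- c(length(lon), length(lat), length(level_names), length(times))
  if (!identical(dim(u), as.integer(dims)) || !identical(dim(v), as.integer(dims))) {
    stop("u and v must both have dim (lon, lat, level, time) = (",
         paste(dims, collapse = ", "), ")")
  }
  if (length(level_heights) != length(level_names)) stop("level names/heights mismatch")
  if (is.unsorted(level_heights, strictly = TRUE)) stop("levels must be in ascending height order")
  if (!inherits(times, "POSIXct")) stop("times must be POSIXct")
  if (length(times) > 1) {
    dt <- diff(as.numeric(times))
    if (any(dt <= 0)) stop("times must be strictly increasing")
    if (max(dt) - min(dt) > 1e-6) stop("times must be equally spaced")
  }
  for (nm in c("u", "v")) {
    val <- get(nm)
    bad <- which(!is.finite(val))
    if (length(bad)) {
      idx <- arrayInd(bad[1], dims)
      stop(sprintf("missing/non-finite cell in %s at [lon=%d, lat=%d, level=%d, time=%d]",
                   nm, idx[1], idx[2], idx[3], idx[4]))
    }
  }
  structure(
    list(lon = lon, lat = lat, level_names = as.character(level_names),
         level_heights = as.numeric(level_heights), times = times, u = u, v = v),
    class = "wind_grid"
  )
}

#' @export
print.wind_grid <- function(x, ...) {
  cat("<wind_grid> ", length(x$lon), "lon x", length(x$lat), "lat x",
      length(x$level_names), "levels x", length(x$times), "times\n")
  cat("  lon", sprintf("[%.2f, %.2f]", min(x$lon), max(x$lon)),
      " lat", sprintf("[%.2f, %.2f]", min(x$lat), max(x$lat)), "\n")
  cat("  levels:", paste(x$level_names, collapse = ", "), "\n")
  cat("  time:", format(x$times[1], tz = "UTC"), "to",
      format(x$times[length(x$times)], tz = "UTC"),
      sprintf("(step %.1f h)", if (length(x$times) > 1)
        diff(as.numeric(x$times))[1] / 3600 else NA), "\n")
  invisible(x)
}

level_index <- function(grid, level) {
  i <- match(level, grid$level_names)
  if (is.na(i)) stop("unknown level '", level, "'; available: ",
                     paste(grid$level_names, collapse = ", "))
  i
}

grid_time_step <- function(grid) {
  if (length(grid$times) < 2) return(NA_real_)
  diff(as.numeric(grid$times))[1]
}

# Parse CF-style time units "X since YYYY-mm-dd HH:MM:SS"
parse_cf_time <- function(vals, units) {
  m <- regmatches(units, regexec("^(\\w+)s? since (.+)$", units))[[1]]
  if (length(m) != 3) stop("cannot parse time units '", units, "'")
  mult <- switch(sub("s$", "", tolower(m[2])),
                 second = 1, sec = 1, minute = 60, min = 60,
                 hour = 3600, day = 86400,
                 stop("unsupported time unit '", m[2], "'"))
  origin <- as.POSIXct(m[3], tz = "UTC")
  if (is.na(origin)) origin <- as.POSIXct(paste(m[3], "00:00:00"), tz = "UTC")
  origin + vals * mult
}

#' Read a wind grid from a NetCDF file
#'
#' Expects variables `u` and `v` with dimensions
#' (longitude, latitude, level, time), CF-style time units, and a numeric
#' level axis in hPa (or metres for files written by
#' [write_wind_grid()]). Pressure levels are renamed to nominal heights via
#' `level_map`; longitudes on [0, 360) are normalized. Any missing cell is a
#' load error.
#'
#' @param path NetCDF file path
#' @param level_map data.frame as from [default_level_map()]
#' @return a [wind_grid()]
#' @export
load_wind_grid <- function(path, level_map = default_level_map()) {
  if (!requireNamespace("ncdf4", quietly = TRUE)) {
    stop("reading NetCDF requires the 'ncdf4' package")
  }
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  for (vn in c("u", "v")) {
    if (!vn %in% names(nc$var)) stop("NetCDF file lacks variable '", vn, "'")
  }
  dimnames_ <- sapply(nc$var[["u"]]$dim, function(d) d$name)
  getdim <- function(cands) {
    i <- which(dimnames_ %in% cands)
    if (!length(i)) stop("cannot find dimension among: ", paste(cands, collapse = ", "))
    nc$var[["u"]]$dim[[i]]
  }
  dlon <- getdim(c("longitude", "lon"))
  dlat <- getdim(c("latitude", "lat"))
  dlev <- getdim(c("level", "lev", "height"))
  dtim <- getdim(c("time"))
  times <- parse_cf_time(dtim$vals, dtim$units)
  if (length(times) > 1) {
    dt <- diff(as.numeric(times))
    if (any(dt <= 0) || max(dt) - min(dt) > 1e-6) stop("irregular time axis in file")
  }
  lev_vals <- dlev$vals
  lev_units <- tolower(dlev$units %||% "")
  if (grepl("pa", lev_units) || grepl("millibar", lev_units) || grepl("hpa", lev_units)) {
    i <- match(lev_vals, level_map$pressure_hPa)
    # ground level encoded as pressure 0 or 1013 in some extracts -> 10m
    i[is.na(i) & lev_vals %in% c(0, 1013)] <- which(is.na(level_map$pressure_hPa))[1]
    if (any(is.na(i))) stop("unknown pressure level(s): ",
                            paste(lev_vals[is.na(i)], collapse = ", "))
  } else {
    i <- match(lev_vals, level_map$height_m)
    if (any(is.na(i))) stop("unknown level height(s): ",
                            paste(lev_vals[is.na(i)], collapse = ", "))
  }
  for (vn in c("u", "v")) {
    un <- ncdf4::ncatt_get(nc, vn, "units")
    if (un$hasatt && !un$value %in% c("m s**-1", "m s-1", "m/s", "meters per second")) {
      stop("variable '", vn, "' has units '", un$value, "', expected m/s")
    }
  }
  u <- ncdf4::ncvar_get(nc, "u", collapse_degen = FALSE)
  v <- ncdf4::ncvar_get(nc, "v", collapse_degen = FALSE)
  # reorder dims to (lon, lat, level, time)
  perm <- match(c(dlon$name, dlat$name, dlev$name, dtim$name), dimnames_)
  u <- aperm(u, perm); v <- aperm(v, perm)
  ord <- order(level_map$height_m[i])
  wind_grid(dlon$vals, dlat$vals,
            level_map$name[i][ord], level_map$height_m[i][ord],
            times, u[, , ord, , drop = FALSE], v[, , ord, , drop = FALSE])
}

#' Write a wind grid to NetCDF
#'
#' Inverse of [load_wind_grid()]; levels are written as nominal heights in
#' metres.
#'
#' @param grid a [wind_grid()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_wind_grid <- function(grid, path) {
  if (!requireNamespace("ncdf4", quietly = TRUE)) {
    stop("writing NetCDF requires the 'ncdf4' package")
  }
  dlon <- ncdf4::ncdim_def("longitude", "degrees_east", grid$lon)
  dlat <- ncdf4::ncdim_def("latitude", "degrees_north", grid$lat)
  dlev <- ncdf4::ncdim_def("level", "m", grid$level_heights)
  t0 <- grid$times[1]
  dtim <- ncdf4::ncdim_def(
    "time", paste("seconds since", format(t0, "%Y-%m-%d %H:%M:%S", tz = "UTC")),
    as.numeric(grid$times) - as.numeric(t0)
  )
  vu <- ncdf4::ncvar_def("u", "m s**-1", list(dlon, dlat, dlev, dtim), prec = "double")
  vv <- ncdf4::ncvar_def("v", "m s**-1", list(dlon, dlat, dlev, dtim), prec = "double")
  nc <- ncdf4::nc_create(path, list(vu, vv))
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, vu, grid$u)
  ncdf4::ncvar_put(nc, vv, grid$v)
  invisible(path)
}

#' Read an hourly ground-station wind series
#'
#' CSV with columns `timestamp` (ISO-8601 UTC), `wind_speed_ms`, and
#' `wind_direction_from_deg` (meteorological "blowing from" convention). The
#' direction is converted on load to `direction_to = from + 180` so all
#' directions in the package share one convention.
#'
#' @param path CSV path
#' @return data.frame with `time`, `speed`, `direction_to`, `u`, `v`
#' @export
read_station_wind <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "wind_speed_ms", "wind_direction_from_deg")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("station CSV lacks column(s): ", paste(miss, collapse = ", "))
  tm <- as.POSIXct(d$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  if (any(is.na(tm))) stop("unparseable timestamp in station CSV")
  dir_to <- wrap360(d$wind_direction_from_deg + 180)
  out <- data.frame(
    time = tm, speed = d$wind_speed_ms, direction_to = dir_to,
    u = d$wind_speed_ms * sin(deg2rad(dir_to)),
    v = d$wind_speed_ms * cos(deg2rad(dir_to))
  )
  out[order(out$time), , drop = FALSE]
}

# Fast internal nearest-node sampler: integer level index, vectorized over
# positions/times; no coverage checks (callers check once).
sample_uv_idx <- function(grid, ilon, ilat, ilev, itime) {
  idx <- cbind(ilon, ilat, ilev, itime)
  list(u = grid$u[idx], v = grid$v[idx])
}

grid_space_index <- function(grid, lon, lat) {
  lon <- ((lon + 180) %% 360) - 180
  list(ilon = nearest_idx(grid$lon, lon), ilat = nearest_idx(grid$lat, lat))
}

grid_time_index <- function(grid, t) {
  nearest_idx(as.numeric(grid$times), as.numeric(t))
}

check_coverage <- function(grid, lon, lat, t = NULL) {
  dlon <- if (length(grid$lon) > 1) diff(grid$lon)[1] else 0
  dlat <- if (length(grid$lat) > 1) diff(grid$lat)[1] else 0
  if (any(lon < min(grid$lon) - dlon / 2 - 1e-9) || any(lon > max(grid$lon) + dlon / 2 + 1e-9) ||
      any(lat < min(grid$lat) - dlat / 2 - 1e-9) || any(lat > max(grid$lat) + dlat / 2 + 1e-9)) {
    stop("position outside wind-grid spatial coverage")
  }
  if (!is.null(t)) {
    step <- grid_time_step(grid)
    if (is.na(step)) step <- 0
    tn <- as.numeric(t); gt <- as.numeric(grid$times)
    if (any(tn < gt[1] - step) || any(tn > gt[length(gt)] + step)) {
      stop("time outside wind-grid temporal coverage")
    }
  }
  invisible(TRUE)
}

#' Sample wind nearest in space and time
#'
#' Returns the u/v wind at the grid node nearest to each query position and
#' the time slice nearest to each query time. Exact midpoints tie toward the
#' earlier time slice and the lower spatial index.
#'
#' @param grid a [wind_grid()]
#' @param lon,lat query position(s), degrees
#' @param time query POSIXct time(s)
#' @param level level name (e.g. "750m")
#' @return data.frame with `u`, `v`, `speed`, `direction_to` (degrees the
#'   wind blows toward, `NA` in calm air)
#' @export
sample_wind <- function(grid, lon, lat, time, level) {
  check_coverage(grid, lon, lat, time)
  ilev <- level_index(grid, level)
  sp <- grid_space_index(grid, lon, lat)
  it <- grid_time_index(grid, time)
  n <- max(length(lon), length(it))
  uv <- sample_uv_idx(grid, rep_len(sp$ilon, n), rep_len(sp$ilat, n),
                      ilev, rep_len(it, n))
  spd <- sqrt(uv$u^2 + uv$v^2)
  dir <- ifelse(spd > 0, wrap360(rad2deg(atan2(uv$u, uv$v))), NA_real_)
  data.frame(u = uv$u, v = uv$v, speed = spd, direction_to = dir)
}

#' Resample a wind grid to finer spatial resolution
#'
#' Separable cubic-spline (bicubic) interpolation of each time/level slice of
#' u and v onto a finer regular lon/lat grid with approximately the requested
#' node spacing in km. Upsampling only, as coarsening would discard
#' information the nearest-node sampler depends on.
#'
#' @param grid a [wind_grid()]
#' @param target_spacing_km target node spacing in km (metric at the grid's
#'   mean latitude)
#' @return a new [wind_grid()] on the finer lattice
#' @export
resample_spatial <- function(grid, target_spacing_km) {
  km_per_deg <- EARTH_RADIUS_M * pi / 180 / 1000
  mean_lat <- mean(grid$lat)
  dlat_deg <- target_spacing_km / km_per_deg
  dlon_deg <- target_spacing_km / (km_per_deg * cos(deg2rad(mean_lat)))
  src_dlon <- diff(grid$lon)[1]; src_dlat <- diff(grid$lat)[1]
  if (dlon_deg >= src_dlon || dlat_deg >= src_dlat) {
    stop("target spacing is coarser than the source grid; upsampling only")
  }
  new_lon <- seq(grid$lon[1], grid$lon[length(grid$lon)], by = dlon_deg)
  new_lat <- seq(grid$lat[1], grid$lat[length(grid$lat)], by = dlat_deg)
  nl <- length(new_lon); na <- length(new_lat)
  nlev <- length(grid$level_names); nt <- length(grid$times)
  uo <- array(NA_real_, c(nl, na, nlev, nt))
  vo <- array(NA_real_, c(nl, na, nlev, nt))
  for (k in seq_len(nlev)) for (j in seq_len(nt)) {
    for (nm in c("u", "v")) {
      sl <- grid[[nm]][, , k, j]
      # along lon for each source lat, then along lat for each new lon
      tmp <- apply(sl, 2, function(col) stats::spline(grid$lon, col, xout = new_lon, method = "fmm")$y)
      out <- t(apply(tmp, 1, function(row) stats::spline(grid$lat, row, xout = new_lat, method = "fmm")$y))
      if (nm == "u") uo[, , k, j] <- out else vo[, , k, j] <- out
    }
  }
  wind_grid(new_lon, new_lat, grid$level_names, grid$level_heights, grid$times, uo, vo)
}

#' Daily regional wind summary over a polygon
#'
#' For each calendar day in `dates`, averages wind speed over all grid nodes
#' inside the polygon and all time slices of that day, and gives the
#' vector-mean direction (direction of the mean u/v vector; `NA` when the
#' resultant is zero).
#'
#' @param grid a [wind_grid()]
#' @param region matrix or data.frame of polygon vertices (lon, lat)
#' @param dates Date vector (each day summarized separately)
#' @param level level name (default ground level "10m")
#' @return data.frame with `date`, `mean_speed`, `mean_direction_to`,
#'   `n_nodes`, `n_times`
#' @export
regional_wind_summary <- function(grid, region, dates, level = "10m") {
  region <- as.matrix(region)
  ilev <- level_index(grid, level)
  nodes <- expand.grid(ilon = seq_along(grid$lon), ilat = seq_along(grid$lat))
  inside <- sp::point.in.polygon(grid$lon[nodes$ilon], grid$lat[nodes$ilat],
                                 region[, 1], region[, 2]) > 0
  if (!any(inside)) stop("polygon does not overlap the wind grid")
  nodes <- nodes[inside, , drop = FALSE]
  gdates <- as.Date(grid$times, tz = "UTC")
  out <- lapply(sort(unique(as.Date(dates))), function(day) {
    it <- which(gdates == day)
    if (!length(it)) stop("no grid time slices on ", day)
    idx <- cbind(rep(nodes$ilon, length(it)), rep(nodes$ilat, length(it)),
                 ilev, rep(it, each = nrow(nodes)))
    u <- grid$u[idx]; v <- grid$v[idx]
    mu <- mean(u); mv <- mean(v)
    dir <- if (sqrt(mu^2 + mv^2) < 1e-12) NA_real_ else wrap360(rad2deg(atan2(mu, mv)))
    data.frame(date = day, mean_speed = mean(sqrt(u^2 + v^2)),
               mean_direction_to = dir, n_nodes = nrow(nodes), n_times = length(it))
  })
  do.call(rbind, out)
}

#' Sensitivity of mean wind support to a temporal shift
#'
#' Recomputes each track's mean wind support with all timestamps shifted by
#' +/- `shift_h` hours and correlates (Pearson) shifted against observed
#' values across tracks, per level. High correlations indicate the wind
#' field's native temporal resolution is adequate for the tracks.
#'
#' @param tracks list of [track()] objects (at least 3)
#' @param grid a [wind_grid()]
#' @param shift_h shift magnitude in hours (default 6, the native step)
#' @param levels level names to test (default all)
#' @return data.frame with `level`, `shift_h`, `r`
#' @export
temporal_shift_sensitivity <- function(tracks, grid, shift_h = 6,
                                       levels = grid$level_names) {
  if (length(tracks) < 3) stop("need at least 3 tracks")
  shifts <- c(-shift_h, shift_h) * 3600
  out <- list()
  for (lev in levels) {
    obs <- vapply(tracks, function(tr) mean(annotate_track(tr, grid, lev)$ws), 0)
    for (s in shifts) {
      shf <- vapply(tracks, function(tr) {
        tr2 <- tr; tr2$time <- tr2$time + s
        mean(annotate_track(tr2, grid, lev)$ws)
      }, 0)
      out[[length(out) + 1]] <- data.frame(
        level = lev, shift_h = s / 3600, r = stats::cor(obs, shf)
      )
    }
  }
  do.call(rbind, out)
}
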