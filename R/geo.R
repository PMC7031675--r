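# Spherical geodesy primitives. All positions are geographic lon/lat in
# decimal degrees (lon in [-180, 180), lat in [-90, 90]); the Earth is a
# sphere of radius 6,371,000 m. At the scales handled here (flights of a few
# thousand km) the sphere-vs-ellipsoid difference is well below half a
# percent and irrelevant next to position uncertainty.

#' Mean Earth radius (metres) used by all geodesic computations
#' @export
EARTH_RADIUS_M <- 6371000

#' Validate and normalize geographic coordinates
#'
#' Longitudes are wrapped into [-180, 180); latitudes outside [-90, 90] are
#' an error.
#'
#' @param lon,lat numeric vectors of equal length, decimal degrees
#' @return list with normalized `lon` and `lat`
#' @export
geo_point <- function(lon, lat) {
  if (length(lon) != length(lat)) stop("lon and lat must have equal length")
  if (any(!is.finite(lon)) || any(!is.finite(lat))) stop("non-finite coordinates")
  if (any(lat < -90 | lat > 90)) stop("latitude outside [-90, 90]")
  lon <- ((lon + 180) %% 360) - 180
  list(lon = lon, lat = lat)
}

#' Great-circle distance and initial bearing
#'
#' Haversine distance and forward azimuth between point pairs on the sphere.
#' Identical points get distance 0 and an undefined-bearing sentinel (`NA`).
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees (vectorized)
#' @return data.frame with `distance_m` and `bearing_deg` (clockwise from
#'   north, in [0, 360), `NA` where undefined)
#' @examples
#' dist_bearing(0, 0, 1, 0) # ~111.2 km due east
#' @export
dist_bearing <- function(lon1, lat1, lon2, lat2) {
  p1 <- geo_point(lon1, lat1); p2 <- geo_point(lon2, lat2)
  phi1 <- deg2rad(p1$lat); phi2 <- deg2rad(p2$lat)
  dphi <- phi2 - phi1
  dlam <- deg2rad(ang_diff(p2$lon, p1$lon))
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  d <- 2 * EARTH_RADIUS_M * asin(pmin(1, sqrt(a)))
  y <- sin(dlam) * cos(phi2)
  x <- cos(phi1) * sin(phi2) - sin(phi1) * cos(phi2) * cos(dlam)
  brg <- wrap360(rad2deg(atan2(y, x)))
  brg[d == 0] <- NA_real_
  data.frame(distance_m = d, bearing_deg = brg)
}

#' Great-circle distance only
#' @inheritParams dist_bearing
#' @return distance in metres
#' @export
gc_distance <- function(lon1, lat1, lon2, lat2) {
  dist_bearing(lon1, lat1, lon2, lat2)$distance_m
}

#' Destination point along a great circle
#'
#' Position reached from a start point after travelling `distance_m` metres
#' along the great circle leaving with the given initial bearing. Distances
#' at or beyond the antipode (pi * R) are outside the modelled regime and
#' raise an error.
#'
#' @param lon,lat start coordinates, decimal degrees (vectorized)
#' @param bearing_deg initial bearing, degrees clockwise from north
#' @param distance_m non-negative distance in metres
#' @return data.frame with `lon`, `lat` of the destination
#' @export
destination_point <- function(lon, lat, bearing_deg, distance_m) {
  p <- geo_point(lon, lat)
  if (any(distance_m < 0)) stop("distance must be non-negative")
  if (any(distance_m >= pi * EARTH_RADIUS_M)) {
    stop("distance crosses the antipode; out of modelled regime")
  }
  delta <- distance_m / EARTH_RADIUS_M
  theta <- deg2rad(bearing_deg)
  phi1 <- deg2rad(p$lat); lam1 <- deg2rad(p$lon)
  phi2 <- asin(sin(phi1) * cos(delta) + cos(phi1) * sin(delta) * cos(theta))
  lam2 <- lam1 + atan2(
    sin(theta) * sin(delta) * cos(phi1),
    cos(delta) - sin(phi1) * sin(phi2)
  )
  out <- geo_point(rad2deg(lam2), rad2deg(phi2))
  data.frame(lon = out$lon, lat = out$lat)
}

#' Polar Lambert azimuthal equal-area projection (map output only)
#'
#' Projects lon/lat to planar x/y (metres) with the pole as projection centre
#' and a configurable longitude origin. Used for plotting; all analysis stays
#' in geographic coordinates to avoid projection-induced distance distortion.
#'
#' @param lon,lat coordinates in decimal degrees
#' @param lon0 central meridian, degrees (default -156.65, the study site)
#' @param inverse if TRUE, interpret `lon`,`lat` as x,y metres and invert
#' @return data.frame with `x`,`y` (or `lon`,`lat` when `inverse`)
#' @export
laea_polar <- function(lon, lat, lon0 = -156.65, inverse = FALSE) {
  R <- EARTH_RADIUS_M
  if (!inverse) {
    p <- geo_point(lon, lat)
    rho <- 2 * R * sin(deg2rad(90 - p$lat) / 2)
    az <- deg2rad(p$lon - lon0)
    data.frame(x = rho * sin(az), y = -rho * cos(az))
  } else {
    x <- lon; y <- lat
    rho <- sqrt(x^2 + y^2)
    latp <- 90 - 2 * rad2deg(asin(pmin(1, rho / (2 * R))))
    lonp <- lon0 + rad2deg(atan2(x, -y))
    lonp[rho == 0] <- lon0
    out <- geo_point(lonp, latp)
    data.frame(lon = out$lon, lat = out$lat)
  }
}
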