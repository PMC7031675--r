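# Shared angle and time helpers. All directions in this package are degrees
# clockwise from geographic north ("direction_to" for wind), wrapped to [0, 360).

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap an angle to [0, 360)
#' @param x angle(s) in degrees
#' @return angle(s) in [0, 360)
#' @keywords internal
wrap360 <- function(x) ((x %% 360) + 360) %% 360

# Signed smallest difference a - b in (-180, 180]
ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

# Unwrap angles onto a continuous scale centred on `centre` (degrees):
# result = centre + signed difference in (-180, 180].
unwrap_deg <- function(x, centre) centre + ang_diff(x, centre)

#' Circular (vector) mean of directions
#'
#' Mean direction of a set of bearings, via the resultant vector. Returns
#' `NA` when the resultant length is (numerically) zero, in which case the
#' mean direction is undefined.
#'
#' @param x directions in degrees clockwise from north
#' @param na.rm drop missing values first
#' @return mean direction in [0, 360), or `NA` for a zero resultant
#' @export
circ_mean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  s <- mean(sin(deg2rad(x)))
  c <- mean(cos(deg2rad(x)))
  if (sqrt(s^2 + c^2) < 1e-12) return(NA_real_)
  wrap360(rad2deg(atan2(s, c)))
}

# Jammalamadaka-SenGupta circular correlation coefficient between two
# angular variables (degrees).
circ_cor <- function(a, b) {
  a <- deg2rad(a); b <- deg2rad(b)
  am <- atan2(mean(sin(a)), mean(cos(a)))
  bm <- atan2(mean(sin(b)), mean(cos(b)))
  num <- sum(sin(a - am) * sin(b - bm))
  den <- sqrt(sum(sin(a - am)^2) * sum(sin(b - bm)^2))
  if (den == 0) return(NA_real_)
  num / den
}

# Local clock time from UTC with a fixed offset in hours (default AKDT,
# UTC-8, the study region's daylight clock).
local_time <- function(t, tz_offset_h = -8) t + tz_offset_h * 3600

# Departure "day": calendar date after moving to local clock and subtracting
# 12 h, so that all departures in one night share a day.
departure_day <- function(t, tz_offset_h = -8) {
  as.Date(local_time(t, tz_offset_h) - 12 * 3600, tz = "UTC")
}

# Nearest index in a sorted numeric vector; ties broken toward the lower index.
nearest_idx <- function(x, v) {
  i <- findInterval(v, x, all.inside = TRUE)
  lo <- abs(v - x[i])
  hi <- abs(v - x[pmin(i + 1L, length(x))])
  # strict '<' keeps the earlier/lower index on exact ties
  ifelse(hi < lo, pmin(i + 1L, length(x)), i)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
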