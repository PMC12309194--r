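# Geodesic helpers. All distances use the WGS84 mean Earth radius so that the
# forward (destination-point) and inverse (haversine) problems are mutually
# consistent on the sphere.

EARTH_RADIUS_M <- 6371008.8

#' Great-circle distance between coordinate pairs
#'
#' Haversine distance on a sphere of radius 6,371,008.8 m (the WGS84 mean
#' radius). Vectorised over all four arguments.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees (WGS84).
#' @return Distance(s) in meters.
#' @examples
#' haversine_m(19.5, 15.00, 19.5, 15.01) # ~1112 m
#' @export
haversine_m <- function(lon1, lat1, lon2, lat2) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  a <- pmin(a, 1)
  2 * EARTH_RADIUS_M * asin(sqrt(a))
}

# Destination point: start at (lon, lat), travel `dist_m` meters along initial
# bearing `bearing_rad` (radians clockwise from north) on the same sphere.
# Returns a list(lon, lat) in degrees. Vectorised.
destination_point <- function(lon, lat, bearing_rad, dist_m) {
  to_rad <- pi / 180
  phi1 <- lat * to_rad
  lam1 <- lon * to_rad
  delta <- dist_m / EARTH_RADIUS_M
  phi2 <- asin(sin(phi1) * cos(delta) + cos(phi1) * sin(delta) * cos(bearing_rad))
  lam2 <- lam1 + atan2(
    sin(bearing_rad) * sin(delta) * cos(phi1),
    cos(delta) - sin(phi1) * sin(phi2)
  )
  list(lon = ((lam2 / to_rad + 540) %% 360) - 180, lat = phi2 / to_rad)
}
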