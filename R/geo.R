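#' Great-circle (haversine) distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km.  Vectorized over the
#' coordinates; all angles in decimal degrees.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distance(s) in km.
#' @export
#' @examples
#' haversine_km(0, 0, 0, 180)  # half circumference, ~20015 km
haversine_km <- function(lat1, lon1, lat2, lon2) {
  stopifnot_finite(c(lat1, lon1, lat2, lon2), "coordinates")
  n <- max(length(lat1), length(lon1), length(lat2), length(lon2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  geosphere::distHaversine(p1, p2, r = 6371000) / 1000
}

#' Shortest distance from a station to a coastline
#'
#' Minimum haversine distance from a point to the vertices of a coastline
#' polyline.  The vertex resolution of the supplied coastline stands in for a
#' gridded 0 m isobath.
#'
#' @param lat,lon Station coordinates (scalars or vectors of equal length).
#' @param coastline Two-column matrix or data frame of `(lat, lon)` vertices.
#' @return Distance(s) in km.
#' @export
distance_to_coast <- function(lat, lon, coastline) {
  coastline <- as.matrix(coastline)
  if (nrow(coastline) == 0)
    abort("empty coastline", class = "zoopcurves_input_error")
  stopifnot_finite(coastline, "coastline")
  vapply(seq_along(lat), function(i) {
    min(haversine_km(lat[i], lon[i], coastline[, 1], coastline[, 2]))
  }, numeric(1))
}

#' Synthetic coastline for the virtual transect
#'
#' Two meridional coastlines (an "American" margin at 20 deg W shifted with
#' latitude, and an "Asian" margin at 115 deg E), sampled every 2 degrees of
#' latitude.  Entirely synthetic: a stand-in vertex list used by the
#' simulator so that distance-to-coast can be computed without any
#' bathymetric grid.
#'
#' @return Matrix with columns `lat`, `lon`.
#' @export
synthetic_coastline <- function() {
  lats <- seq(-70, 80, by = 2)
  west <- cbind(lat = lats, lon = -20 - 0.25 * lats)
  east <- cbind(lat = lats, lon = 115 + 0.15 * lats)
  rbind(west, east)
}
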