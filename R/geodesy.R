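#' Great-circle distance between points
#'
#' Haversine distance on a sphere of radius 6371 km. Inputs are recycled in
#' the usual way, so the function works on single points, on a point against
#' a vector of points (e.g. every fix against the colony), or pairwise on two
#' equal-length vectors.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees (WGS84).
#' @return Distance(s) in meters.
#' @examples
#' geodesic_distance(-6, 37, -6, 38) # ~111.2 km
#' @export
geodesic_distance <- function(lon1, lat1, lon2, lat2) {
  check_coords(lon1, lat1)
  check_coords(lon2, lat2)
  n <- max(length(lon1), length(lon2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  as.numeric(geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_M))
}

check_coords <- function(lon, lat) {
  if (any(!is.finite(lon)) || any(!is.finite(lat)) ||
      any(lon < -180 | lon > 180) || any(lat < -90 | lat > 90)) {
    stop("coordinates out of range: lon must be in [-180, 180], lat in [-90, 90]",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Accumulated path length of a fix sequence
#'
#' Sum of consecutive-fix great-circle distances, the quantity behind both
#' trip distance and daily distance. Coarser sampling of the same path can
#' only shorten it (triangle inequality), which is why sampling frequency is
#' carried as a correction factor in the statistical models.
#'
#' @param lon,lat Coordinate vectors in fix order.
#' @return Total length in meters (0 for fewer than 2 fixes).
#' @export
path_length <- function(lon, lat) {
  n <- length(lon)
  if (n < 2) return(0)
  sum(geodesic_distance(lon[-n], lat[-n], lon[-1], lat[-1]))
}

#' Step lengths between consecutive fixes
#'
#' @param lon,lat Coordinate vectors in fix order.
#' @return Numeric vector of length `length(lon) - 1`, in meters.
#' @export
step_lengths <- function(lon, lat) {
  n <- length(lon)
  if (n < 2) return(numeric(0))
  geodesic_distance(lon[-n], lat[-n], lon[-1], lat[-1])
}

# Destination point at a given bearing/distance, on the same sphere as
# geodesic_distance. Used by the track generator to lay out commutes,
# patches and jitter. Returns a matrix with columns lon, lat.
dest_point <- function(lon, lat, bearing_deg, dist_m) {
  p <- geosphere::destPoint(cbind(lon, lat), bearing_deg, dist_m,
                            r = EARTH_RADIUS_M)
  colnames(p) <- c("lon", "lat")
  p
}
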