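#' Great-circle distance between coordinate pairs
#'
#' Haversine distance on a sphere of radius 6,371,000 m, the convention used
#' throughout the pipeline for point-to-point displacements, buffer tests and
#' clustering. Vectorised over all arguments.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (WGS84).
#' @return Distance(s) in metres.
#' @examples
#' haversine_m(-54, -36, -54, -35)
#' @export
haversine_m <- function(lat1, lon1, lat2, lon2) {
  stopifnot(all(abs(lat1) <= 90, na.rm = TRUE), all(abs(lat2) <= 90, na.rm = TRUE))
  n <- max(length(lat1), length(lon1), length(lat2), length(lon2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_M)
}

EARTH_RADIUS_M <- 6371000
NM_M <- 1852 # metres per nautical mile

#' Normalise longitudes to (-180, 180]
#' @param lon Longitude(s), degrees.
#' @return Normalised longitude(s).
#' @export
normalise_lon <- function(lon) {
  out <- ((lon + 180) %% 360) - 180
  out[out == -180] <- 180
  out
}

#' Local azimuthal equidistant projection
#'
#' Forward-projects lon/lat points onto a plane centred at `centre`
#' (azimuthal equidistant, spherical form): planar distances from the centre
#' equal great-circle distances. Used to confirm that buffer/cluster
#' distances evaluated in a local projection agree with plain great-circle
#' distances at anchorage scales.
#'
#' @param lat,lon Points to project, degrees.
#' @param centre c(lat, lon) of the projection centre, degrees.
#' @return Matrix with columns x, y in metres.
#' @export
aeq_project <- function(lat, lon, centre) {
  to_rad <- pi / 180
  phi1 <- centre[1] * to_rad
  lam0 <- centre[2] * to_rad
  phi <- lat * to_rad
  lam <- lon * to_rad
  cosc <- sin(phi1) * sin(phi) + cos(phi1) * cos(phi) * cos(lam - lam0)
  cosc <- pmin(1, pmax(-1, cosc))
  c_ang <- acos(cosc)
  k <- ifelse(c_ang < 1e-12, 1, c_ang / sin(c_ang))
  x <- EARTH_RADIUS_M * k * cos(phi) * sin(lam - lam0)
  y <- EARTH_RADIUS_M * k *
    (cos(phi1) * sin(phi) - sin(phi1) * cos(phi) * cos(lam - lam0))
  cbind(x = x, y = y)
}

#' Test points against a polygon (or list of polygons)
#'
#' @param lat,lon Point coordinates, degrees.
#' @param polygon A data frame / matrix with columns `lat`, `lon` describing
#'   a closed ring, or a list of such rings (union semantics).
#' @return Logical vector, TRUE where the point falls inside.
#' @export
point_in_polygon <- function(lat, lon, polygon) {
  if (is.data.frame(polygon) || is.matrix(polygon)) polygon <- list(polygon)
  pts <- cbind(lon, lat)
  inside <- rep(FALSE, length(lat))
  for (ring in polygon) {
    ring <- as.data.frame(ring)
    if (nrow(ring) < 3) stop("degenerate polygon: fewer than 3 vertices")
    bnd <- cbind(ring$lon, ring$lat)
    inside <- inside | mgcv::in.out(bnd, pts)
  }
  inside
}

#' Distance from points to the nearest coastline
#'
#' Great-circle distance to the nearest edge of any coastline ring; points
#' lying inside a ring (on land / enclosed water) get distance 0.
#'
#' @param lat,lon Point coordinates, degrees.
#' @param coastline List of rings (data frames with `lat`, `lon`).
#' @return Distances in metres.
#' @export
dist_to_land_m <- function(lat, lon, coastline) {
  if (is.data.frame(coastline)) coastline <- list(coastline)
  n <- length(lat)
  d <- rep(Inf, n)
  pts <- cbind(lon, lat)
  for (ring in coastline) {
    ring <- as.data.frame(ring)
    line <- cbind(ring$lon, ring$lat)
    # close the ring so the last edge is included
    if (!all(line[1, ] == line[nrow(line), ])) line <- rbind(line, line[1, ])
    dd <- geosphere::dist2Line(pts, line, distfun = function(p1, p2) {
      geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_M)
    })[, "distance"]
    d <- pmin(d, dd)
  }
  d[point_in_polygon(lat, lon, coastline)] <- 0
  d
}

#' Great-circle interpolation
#'
#' Position at fraction `f` along the great circle from point 1 to point 2
#' (spherical linear interpolation). Vectorised; degenerate (coincident or
#' antipodal-safe) pairs return the destination.
#'
#' @param lat1,lon1,lat2,lon2 End points, degrees.
#' @param f Fraction(s) in [0, 1].
#' @return Matrix with columns `lat`, `lon`.
#' @export
gc_interp <- function(lat1, lon1, lat2, lon2, f) {
  to_rad <- pi / 180
  a1 <- lat1 * to_rad; b1 <- lon1 * to_rad
  a2 <- lat2 * to_rad; b2 <- lon2 * to_rad
  v1 <- cbind(cos(a1) * cos(b1), cos(a1) * sin(b1), sin(a1))
  v2 <- cbind(cos(a2) * cos(b2), cos(a2) * sin(b2), sin(a2))
  dotp <- pmin(1, pmax(-1, rowSums(v1 * v2)))
  om <- acos(dotp)
  small <- om < 1e-9
  w1 <- ifelse(small, 1 - f, sin((1 - f) * om) / sin(pmax(om, 1e-12)))
  w2 <- ifelse(small, f, sin(f * om) / sin(pmax(om, 1e-12)))
  v <- v1 * w1 + v2 * w2
  v <- v / sqrt(rowSums(v^2))
  cbind(lat = asin(v[, 3]) / to_rad, lon = atan2(v[, 2], v[, 1]) / to_rad)
}

#' Equivalent speed of a displacement threshold
#'
#' Converts a displacement-per-time stationarity threshold into knots; the
#' default 400 m over 1 h corresponds to ~0.2 kn, the conventional
#' "underway" cut-off in transit-simplification guidance.
#'
#' @param dist_m Displacement in metres (default 400).
#' @param hours Interval in hours (default 1).
#' @return Speed in knots.
#' @examples
#' stationary_speed_equivalent_kn() # ~0.216 kn
#' @export
stationary_speed_equivalent_kn <- function(dist_m = 400, hours = 1) {
  (dist_m / NM_M) / hours
}
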