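#' Great-circle distance (haversine)
#'
#' Haversine distance on a sphere of radius 6371.0 km, the convention used
#' throughout the migration-distance statistics.
#'
#' @param p,q positions as `c(lat, lon)` in decimal degrees, or two-column
#'   matrices (lat, lon) of equal or broadcastable length.
#' @return distance in km (vectorised).
#' @examples
#' gcd(c(0, 0), c(0, 180))   # pi * 6371 = 20015.1 km
#' @export
gcd <- function(p, q) {
  p <- .latlon_matrix(p)
  q <- .latlon_matrix(q)
  if (!all(is.finite(p)) || !all(is.finite(q))) {
    stop("gcd: non-finite coordinates")
  }
  lat1 <- p[, 1] * pi / 180; lon1 <- p[, 2] * pi / 180
  lat2 <- q[, 1] * pi / 180; lon2 <- q[, 2] * pi / 180
  dlat <- lat2 - lat1
  dlon <- lon2 - lon1
  a <- sin(dlat / 2)^2 + cos(lat1) * cos(lat2) * sin(dlon / 2)^2
  2 * .earth_radius_km * asin(pmin(1, sqrt(a)))
}

.earth_radius_km <- 6371.0

.latlon_matrix <- function(p) {
  if (is.matrix(p) || is.data.frame(p)) {
    p <- as.matrix(p)
  } else {
    p <- matrix(p, ncol = 2, byrow = TRUE)
  }
  storage.mode(p) <- "double"
  p
}

# Spherical linear interpolation between two lat/lon points; f in [0,1].
# Rejects (near-)antipodal endpoints, where the great circle is not unique.
gc_interpolate <- function(p, q, f) {
  v1 <- .to_unit(p[1], p[2])
  v2 <- .to_unit(q[1], q[2])
  omega <- acos(pmin(1, pmax(-1, sum(v1 * v2))))
  if (omega > pi - 1e-6) {
    stop("gc_interpolate: antipodal endpoints, path undefined")
  }
  if (omega < 1e-12) {
    v <- matrix(v1, nrow = length(f), ncol = 3, byrow = TRUE)
  } else {
    w1 <- sin((1 - f) * omega) / sin(omega)
    w2 <- sin(f * omega) / sin(omega)
    v <- cbind(w1 * v1[1] + w2 * v2[1],
               w1 * v1[2] + w2 * v2[2],
               w1 * v1[3] + w2 * v2[3])
  }
  .to_latlon(v)
}

.to_unit <- function(lat, lon) {
  phi <- lat * pi / 180
  lam <- lon * pi / 180
  c(cos(phi) * cos(lam), cos(phi) * sin(lam), sin(phi))
}

.to_latlon <- function(v) {
  v <- v / sqrt(rowSums(v^2))
  cbind(lat = asin(pmin(1, pmax(-1, v[, 3]))) * 180 / pi,
        lon = atan2(v[, 2], v[, 1]) * 180 / pi)
}

# Wrap a longitude (degrees) into (-180, 180].
wrap_lon <- function(lon) {
  w <- (lon + 180) %% 360 - 180
  ifelse(w == -180, 180, w)
}
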