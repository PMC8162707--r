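#' Read a land mask from GeoJSON
#'
#' Accepts a FeatureCollection (or single Feature) of Polygon /
#' MultiPolygon geometries in WGS-84 lon/lat order. Only outer rings are
#' used; holes are ignored. Polygons spanning the antimeridian are not
#' supported (the study region does not require it).
#'
#' @param path GeoJSON file.
#' @param waypoints optional named list of `c(lat, lon)` reroute waypoints
#'   (e.g. `list("Cape Farewell" = c(59.77, -43.93))`); defaults to the
#'   waypoints encoded in the file's `reroute_waypoints` property, if any.
#' @return a `puffin_landmask`: list with `polygons` (named list of
#'   closed lon/lat matrices) and `waypoints`.
#' @export
read_landmask <- function(path, waypoints = NULL) {
  gj <- jsonlite::read_json(path)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features else list(gj)
  polys <- list()
  for (f in feats) {
    geom <- f$geometry %||% f
    nm <- f$properties$name %||% paste0("polygon", length(polys) + 1)
    rings <- switch(geom$type,
      Polygon = list(geom$coordinates[[1]]),
      MultiPolygon = lapply(geom$coordinates, function(p) p[[1]]),
      stop("read_landmask: unsupported geometry type ", geom$type))
    for (r in rings) {
      m <- do.call(rbind, lapply(r, function(xy) c(xy[[1]], xy[[2]])))
      colnames(m) <- c("lon", "lat")
      polys[[length(polys) + 1]] <- m
      names(polys)[length(polys)] <- nm
    }
    wp <- f$properties$reroute_waypoints
    if (is.null(waypoints) && !is.null(wp)) {
      waypoints <- lapply(wp, function(w) c(w[[1]], w[[2]]))
    }
  }
  landmask(polys, waypoints)
}

#' Construct a land mask from polygon matrices
#'
#' @param polygons named list of lon/lat matrices (closed or open rings;
#'   closure is enforced).
#' @param waypoints named list of `c(lat, lon)` reroute waypoints.
#' @export
landmask <- function(polygons, waypoints = NULL) {
  polygons <- lapply(polygons, function(m) {
    m <- as.matrix(m)
    if (any(m[1, ] != m[nrow(m), ])) m <- rbind(m, m[1, ])
    m
  })
  structure(list(polygons = polygons,
                 waypoints = waypoints %||%
                   list("Cape Farewell" = c(59.77, -43.93))),
            class = "puffin_landmask")
}

#' Point-on-land test
#'
#' Even-odd ray casting in lon/lat coordinates against every polygon of
#' the mask. Topologically exact for polygons that do not cross the
#' antimeridian or enclose a pole.
#'
#' @param lat,lon coordinate vectors (degrees).
#' @param land a `puffin_landmask`.
#' @return logical vector.
#' @export
point_on_land <- function(lat, lon, land) {
  out <- rep(FALSE, length(lat))
  for (poly in land$polygons) {
    px <- poly[, 1]; py <- poly[, 2]
    n <- length(px)
    for (k in seq_along(lat)) {
      if (out[k]) next
      x <- lon[k]; y <- lat[k]
      inside <- FALSE
      j <- n
      for (i in seq_len(n)) {
        if ((py[i] > y) != (py[j] > y) &&
            x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i]) {
          inside <- !inside
        }
        j <- i
      }
      out[k] <- out[k] || inside
    }
  }
  out
}

#' Great-circle distance to the nearest coastline
#'
#' Minimum geodesic distance from each point to any boundary segment of
#' the mask's polygons (via `geosphere::dist2Line`); planar approximations
#' are deliberately avoided at these latitudes.
#'
#' @inheritParams point_on_land
#' @return distances in km.
#' @export
dist_to_coast_km <- function(lat, lon, land) {
  p <- cbind(lon, lat)
  best <- rep(Inf, length(lat))
  for (poly in land$polygons) {
    d <- geosphere::dist2Line(p, poly,
                              distfun = geosphere::distHaversine)[, "distance"]
    best <- pmin(best, d / 1000 * .earth_radius_km / 6378.137)
  }
  best
}

#' At-sea distance with land-avoidance rerouting
#'
#' Great-circle distance between two points unless the connecting great
#' circle (sampled every `step_km` km) crosses land, in which case the
#' route is deflected through the cheapest configured waypoint (default:
#' Cape Farewell, the southern tip of Greenland), giving
#' `gcd(p, w) + gcd(w, q)`. Always at least `gcd(p, q)`.
#'
#' @param p,q `c(lat, lon)` endpoints.
#' @param land a `puffin_landmask`; `NULL` disables rerouting.
#' @param step_km sampling step along the great circle (default 25).
#' @return distance in km.
#' @export
at_sea_distance <- function(p, q, land = NULL, step_km = 25) {
  d <- gcd(p, q)
  if (is.null(land) || length(land$polygons) == 0 || d < 1e-9) return(d)
  if (all(point_on_land(c(p[1], q[1]), c(p[2], q[2]), land))) {
    stop("at_sea_distance: both endpoints are on land")
  }
  n <- max(2, ceiling(d / step_km) + 1)
  f <- seq(0, 1, length.out = n)
  samp <- gc_interpolate(p, q, f)
  if (!any(point_on_land(samp[, 1], samp[, 2], land))) return(d)
  routes <- vapply(land$waypoints, function(w) {
    gcd(p, w) + gcd(w, q)
  }, numeric(1))
  max(min(routes), d)
}

#' Synthetic coarse Greenland coastline
#'
#' Loads the coarse, hand-digitised Greenland outline shipped with the
#' package (a synthetic stand-in for a full-resolution coastline: about
#' twenty vertices, adequate for the 25-km route-sampling resolution and
#' the 100-km inland threshold), with the Cape Farewell reroute waypoint.
#' @export
greenland_landmask <- function() {
  read_landmask(system.file("extdata", "greenland_coast_synthetic.geojson",
                            package = "puffinGLS", mustWork = TRUE))
}
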