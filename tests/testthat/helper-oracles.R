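# Independent oracles used across the suite.

# Meeus-style low-precision solar position (orbital elements ->
# apparent ecliptic longitude -> declination; Smart's series for the
# equation of time). Independent derivation from the package's NOAA
# Fourier fits.
meeus_solar <- function(time) {
  jd <- as.numeric(as.POSIXct(time, tz = "UTC")) / 86400 + 2440587.5
  T <- (jd - 2451545) / 36525
  deg2rad <- pi / 180
  L0 <- (280.46646 + 36000.76983 * T + 0.0003032 * T^2) %% 360
  M <- (357.52911 + 35999.05029 * T - 0.0001537 * T^2) %% 360
  e <- 0.016708634 - 0.000042037 * T
  C <- (1.914602 - 0.004817 * T) * sin(M * deg2rad) +
    (0.019993 - 0.000101 * T) * sin(2 * M * deg2rad) +
    0.000289 * sin(3 * M * deg2rad)
  true_lon <- L0 + C
  omega <- 125.04 - 1934.136 * T
  lambda <- true_lon - 0.00569 - 0.00478 * sin(omega * deg2rad)
  eps <- 23.43929111 - 0.013004167 * T + 0.00256 * cos(omega * deg2rad)
  decl <- asin(sin(eps * deg2rad) * sin(lambda * deg2rad)) / deg2rad
  y <- tan(eps / 2 * deg2rad)^2
  E <- y * sin(2 * L0 * deg2rad) - 2 * e * sin(M * deg2rad) +
    4 * e * y * sin(M * deg2rad) * cos(2 * L0 * deg2rad) -
    0.5 * y^2 * sin(4 * L0 * deg2rad) - 1.25 * e^2 * sin(2 * M * deg2rad)
  list(declination = decl, eq_of_time = E / deg2rad * 4)  # minutes
}

# Brute-force haversine on radius 6371 km via geosphere (independent code
# path; radius passed explicitly).
oracle_gcd <- function(p, q) {
  p <- matrix(p, ncol = 2, byrow = !is.matrix(p))
  q <- matrix(q, ncol = 2, byrow = !is.matrix(q))
  geosphere::distHaversine(p[, 2:1, drop = FALSE], q[, 2:1, drop = FALSE],
                           r = 6371000) / 1000
}

# Brute-force group summary (sort/sum arithmetic, no stats:: shortcuts).
oracle_group <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  s <- if (n > 1) sqrt(sum((x - m)^2) / (n - 1)) else NA_real_
  xs <- sort(x)
  list(n = n, mean = m, sd = s, min = xs[1], max = xs[n])
}

# Convenience: a stationary noise-free light series at a site.
sim_site <- function(site, from, to, angle = -3, noise = NULL, seed = NULL,
                     ...) {
  simulate_stationary(site, from, to, true_sun_angle = angle, noise = noise,
                      seed = seed, ...)
}

# A short winter transit track within 40-65 N used by pipeline tests.
winter_track <- function(bird_id = "sim") {
  wp <- data.frame(
    time = as.POSIXct(c("2014-11-05", "2014-12-01", "2015-01-15",
                        "2015-02-20"), tz = "UTC"),
    lat = c(62, 55, 50, 55),
    lon = c(-55, -50, -42, -45))
  make_track(wp, colony = c(76.47, -70.22), bird_id = bird_id)
}

# Run simulate -> detect -> locate -> qc for one seed; returns positions
# joined with the truth and their great-circle errors.
run_pipeline <- function(track, seed, sun_angle = -3,
                         noise = shading_model(), land = NULL) {
  s <- simulate_light(track, true_sun_angle = sun_angle, noise = noise,
                      seed = seed)
  ev <- detect_twilights(s)
  pos <- positions_from_twilights(ev, sun_angle = sun_angle,
                                  lat_guess = mean(track$positions$lat),
                                  bird_id = track$bird_id)
  qc <- qc_pipeline(pos, land = land)
  kept <- qc$positions[qc$positions$retained, , drop = FALSE]
  tru <- track_position_at(track, kept$midpoint_time)
  kept$true_lat <- tru$lat
  kept$true_lon <- tru$lon
  kept$err_km <- gcd(cbind(kept$lat, kept$lon), cbind(tru$lat, tru$lon))
  list(positions = kept, report = qc$report, n_raw = nrow(pos))
}

# Circular "island" polygon (lon/lat) of a given great-circle radius.
circle_island <- function(centre_lat, centre_lon, radius_km, n = 72) {
  b <- seq(0, 360, length.out = n + 1)[-(n + 1)]
  xy <- geosphere::destPoint(c(centre_lon, centre_lat), b,
                             radius_km * 1000, r = 6371000)
  landmask(list(island = xy), waypoints = list(off = c(centre_lat + 10,
                                                       centre_lon)))
}
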