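#' Detect twilight events by the threshold method
#'
#' Sunset is a falling crossing of the light threshold and sunrise a rising
#' crossing, with the crossing time linearly interpolated between the two
#' bounding samples. Dark intervals shorter than `min_dark` hours are
#' discarded entirely (neither bounding event is kept): brief light dips
#' from tag shading must not masquerade as nights.
#'
#' A constant series (polar day or polar night) yields an empty result,
#' which is a signal, not an error.
#'
#' @param series a `puffin_light` object, or a data.frame with columns
#'   `time` and `light`.
#' @param threshold detection threshold on the light scale (default 10).
#' @param min_dark minimum dark-period duration in hours (default 4).
#' @return data.frame with columns `time` (POSIXct UTC) and `kind`
#'   (`"sunrise"`/`"sunset"`), alternating in time order.
#' @export
detect_twilights <- function(series, threshold = 10, min_dark = 4) {
  df <- if (inherits(series, "puffin_light")) series$samples else series
  stopifnot(nrow(df) > 0, all(c("time", "light") %in% names(df)))
  t <- as.numeric(.as_utc(df$time))
  l <- as.numeric(df$light)
  day <- l >= threshold

  empty <- data.frame(time = .as_utc(character(0)), kind = character(0))
  if (all(day) || all(!day)) return(empty)

  flip <- which(diff(day) != 0)              # crossing between i and i+1
  cross_time <- t[flip] + (threshold - l[flip]) /
    (l[flip + 1] - l[flip]) * (t[flip + 1] - t[flip])
  kind <- ifelse(day[flip], "sunset", "sunrise")

  ev <- data.frame(time = cross_time, kind = kind,
                   stringsAsFactors = FALSE)

  # enforce minimum dark period
  keep <- rep(TRUE, nrow(ev))
  for (i in seq_len(nrow(ev))) {
    if (!keep[i] || ev$kind[i] != "sunset") next
    if (i < nrow(ev)) {
      dark_h <- (ev$time[i + 1] - ev$time[i]) / 3600
      if (dark_h < min_dark) keep[c(i, i + 1)] <- FALSE
    } else {
      # trailing partial dark interval: only the observed lower bound known
      dark_h <- (t[length(t)] - ev$time[i]) / 3600
      if (dark_h < min_dark) keep[i] <- FALSE
    }
  }
  # leading sunrise: partial dark interval at series start
  if (nrow(ev) > 0 && ev$kind[1] == "sunrise" && keep[1]) {
    if ((ev$time[1] - t[1]) / 3600 < min_dark) keep[1] <- FALSE
  }
  ev <- ev[keep, , drop = FALSE]
  data.frame(time = as.POSIXct(ev$time, origin = "1970-01-01", tz = "UTC"),
             kind = ev$kind, stringsAsFactors = FALSE)
}

#' Estimate a position from one twilight pair
#'
#' The threshold method: longitude from the timing of local solar midnight
#' (midpoint of a sunset-sunrise pair) or solar noon (sunrise-sunset pair)
#' via the equation of time; latitude from the night (or day) length by
#' solving the sunrise equation
#' `cos H = (sin a - sin phi sin delta) / (cos phi cos delta)`
#' for latitude by bisection, where `a` is the calibrated sun elevation
#' angle and `H` the hour angle at sunset. Near the equinoxes the equation
#' loses its latitude dependence; such positions are flagged invalid
#' (`"latitude indeterminate"`), never silently dropped.
#'
#' @param sunset,sunrise POSIXct times of a sunset followed by a sunrise
#'   (night shorter than 24 h).
#' @param sun_angle calibrated sun elevation angle in degrees (negative
#'   below the horizon).
#' @param lat_guess disambiguation hint when the sunrise equation has two
#'   roots in range (rare); the root nearer the hint is chosen.
#' @return one-row data.frame: `midpoint_time`, `lat`, `lon`, `source`,
#'   `valid`, `reason`.
#' @export
estimate_position <- function(sunset, sunrise, sun_angle = -3.0,
                              lat_guess = 0) {
  sunset <- .as_utc(sunset); sunrise <- .as_utc(sunrise)
  if (sunrise <= sunset) stop("estimate_position: sunrise must follow sunset")
  night_h <- as.numeric(sunrise - sunset, units = "hours")
  if (night_h >= 24) stop("estimate_position: night length must be < 24 h")
  .position_from_pair(sunset, sunrise, kind = "midnight",
                      sun_angle = sun_angle, lat_guess = lat_guess)
}

.position_from_pair <- function(t1, t2, kind, sun_angle, lat_guess = 0) {
  midpoint <- t1 + as.numeric(t2 - t1, units = "secs") / 2
  eph <- solar_ephemeris(midpoint)
  utc_min <- as.numeric(midpoint - trunc(midpoint, "days"), units = "mins")
  target <- if (kind == "midnight") 0 else 720   # true solar time, minutes
  lon <- wrap_lon((target - utc_min - eph$eq_of_time) / 4)

  span_h <- as.numeric(t2 - t1, units = "hours")
  # hour angle (degrees from solar noon) at which elevation == sun_angle
  hs <- if (kind == "midnight") 180 - 15 * span_h / 2 else 15 * span_h / 2
  root <- .solve_latitude(sun_angle, eph$declination, hs, lat_guess)

  data.frame(midpoint_time = midpoint, lat = root$lat, lon = lon,
             source = kind, valid = root$valid, reason = root$reason,
             stringsAsFactors = FALSE)
}

# Solve sin(a) = sin(phi)sin(delta) + cos(phi)cos(delta)cos(Hs) for phi by
# bracket scan + bisection on [-89.5, 89.5] to 0.01 degrees.
.solve_latitude <- function(sun_angle, declination, hs_deg,
                            lat_guess = 0, tol = 0.01) {
  dec <- declination * pi / 180
  hs <- hs_deg * pi / 180
  f <- function(phi_deg) {
    phi <- phi_deg * pi / 180
    sin(phi) * sin(dec) + cos(phi) * cos(dec) * cos(hs) -
      sin(sun_angle * pi / 180)
  }
  grid <- seq(-89.5, 89.5, by = 1)
  fg <- vapply(grid, f, numeric(1))
  if (max(abs(fg)) < 1e-3) {
    return(list(lat = NA_real_, valid = FALSE,
                reason = "latitude indeterminate"))
  }
  sgn <- sign(fg)
  br <- which(sgn[-1] * sgn[-length(sgn)] <= 0 & sgn[-length(sgn)] != 0)
  if (length(br) == 0) {
    return(list(lat = NA_real_, valid = FALSE,
                reason = "latitude indeterminate"))
  }
  roots <- vapply(br, function(i) {
    lo <- grid[i]; hi <- grid[i + 1]
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (sign(f(mid)) == sign(f(lo)) && f(mid) != 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
  lat <- roots[which.min(abs(roots - lat_guess))]
  # conditioning: near the equinox the equation flattens and the root is
  # meaningless even when it formally exists
  phi <- lat * pi / 180
  dfdphi <- cos(phi) * sin(dec) - sin(phi) * cos(dec) * cos(hs)
  if (abs(dfdphi) < 0.02) {
    return(list(lat = NA_real_, valid = FALSE,
                reason = "latitude indeterminate"))
  }
  list(lat = lat, valid = TRUE, reason = "")
}

#' Positions from an alternating twilight sequence
#'
#' Builds both daily estimates from every consecutive twilight pair: a
#' midnight position from each sunset-sunrise pair and a noon position
#' from each sunrise-sunset pair. Each carries its provenance in `source`.
#'
#' @param events data.frame from [detect_twilights()].
#' @param sun_angle calibrated sun elevation angle (degrees).
#' @param lat_guess latitude hint for root disambiguation (e.g. colony
#'   latitude).
#' @param bird_id attached to every row.
#' @return data.frame of positions with filter flags initialised to
#'   `FALSE` (`equinox_removed`, `speed_removed`, `inland_removed`) and a
#'   `smoothed` flag.
#' @export
positions_from_twilights <- function(events, sun_angle = -3.0,
                                     lat_guess = 0, bird_id = "bird") {
  if (nrow(events) < 2) {
    return(.empty_positions(bird_id))
  }
  rows <- vector("list", nrow(events) - 1)
  for (i in seq_len(nrow(events) - 1)) {
    k1 <- events$kind[i]; k2 <- events$kind[i + 1]
    if (k1 == k2) next
    span_h <- as.numeric(events$time[i + 1] - events$time[i], units = "hours")
    if (span_h >= 24) next
    kind <- if (k1 == "sunset") "midnight" else "noon"
    rows[[i]] <- .position_from_pair(events$time[i], events$time[i + 1],
                                     kind, sun_angle, lat_guess)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(.empty_positions(bird_id))
  out <- do.call(rbind, rows)
  out$bird_id <- bird_id
  out$equinox_removed <- FALSE
  out$speed_removed <- FALSE
  out$inland_removed <- FALSE
  out$smoothed <- FALSE
  out[c("bird_id", "midpoint_time", "lat", "lon", "source", "valid",
        "reason", "smoothed", "equinox_removed", "speed_removed",
        "inland_removed")]
}

.empty_positions <- function(bird_id = character(0)) {
  data.frame(bird_id = character(0),
             midpoint_time = .as_utc(character(0)),
             lat = numeric(0), lon = numeric(0), source = character(0),
             valid = logical(0), reason = character(0),
             smoothed = logical(0), equinox_removed = logical(0),
             speed_removed = logical(0), inland_removed = logical(0),
             stringsAsFactors = FALSE)
}

#' Calibrate the sun elevation angle at a known site
#'
#' Grid search over candidate sun elevation angles: for each angle, all
#' twilight pairs are converted to positions and the median great-circle
#' distance to the known deployment site (the location bias) is computed;
#' the angle with the smallest bias wins. Pairs inside the equinox windows
#' are excluded, as they would be in analysis. Ties are broken toward the
#' angle closest to -3.0 degrees, the conventional value for this tag
#' series.
#'
#' @param series a `puffin_light` calibration series recorded at `site`.
#' @param site known deployment site `c(lat, lon)`.
#' @param angle_grid candidate angles in degrees (>= 1; a useful grid has
#'   >= 5).
#' @param threshold,min_dark twilight-detection settings.
#' @param window_days,equinox_dates equinox exclusion settings (see
#'   [remove_equinox()]).
#' @return list of class `puffin_calibration`: `best_angle`, `grid`
#'   (data.frame `angle`, `median_bias_km`, `n_pairs`), `site`.
#' @export
calibrate_sun_angle <- function(series, site,
                                angle_grid = seq(-6, 0, by = 0.5),
                                threshold = 10, min_dark = 4,
                                window_days = 15,
                                equinox_dates = c("03-20", "09-22")) {
  stopifnot(length(angle_grid) >= 1)
  ev <- detect_twilights(series, threshold = threshold, min_dark = min_dark)
  grid <- data.frame(angle = sort(angle_grid), median_bias_km = NA_real_,
                     n_pairs = NA_integer_)
  for (i in seq_len(nrow(grid))) {
    pos <- positions_from_twilights(ev, sun_angle = grid$angle[i],
                                    lat_guess = site[1])
    pos <- pos[pos$valid, , drop = FALSE]
    pos <- remove_equinox(pos, window_days = window_days,
                          equinox_dates = equinox_dates)$positions
    pos <- pos[!pos$equinox_removed, , drop = FALSE]
    grid$n_pairs[i] <- nrow(pos)
    if (nrow(pos) > 0) {
      grid$median_bias_km[i] <-
        stats::median(gcd(cbind(pos$lat, pos$lon),
                          matrix(site, nrow = nrow(pos), ncol = 2,
                                 byrow = TRUE)))
    }
  }
  usable <- grid$n_pairs[which.min(grid$median_bias_km)]
  if (all(is.na(grid$median_bias_km)) || max(grid$n_pairs) < 20) {
    stop(sprintf(
      "calibrate_sun_angle: only %d valid twilight pairs outside equinox windows (>= 20 required)",
      max(0, grid$n_pairs, na.rm = TRUE)))
  }
  best_bias <- min(grid$median_bias_km, na.rm = TRUE)
  cands <- grid$angle[!is.na(grid$median_bias_km) &
                        grid$median_bias_km <= best_bias + 1e-9]
  best <- cands[which.min(abs(cands - (-3.0)))]
  structure(list(best_angle = best, grid = grid, site = site,
                 n_pairs = usable),
            class = "puffin_calibration")
}

#' Write a positions table as CSV
#'
#' Schema `bird_id,timestamp,lat,lon,source,flags`, where `flags` packs the
#' provenance flags as semicolon-separated tokens.
#' @export
write_positions_csv <- function(positions, path) {
  flags <- apply(positions[c("smoothed", "equinox_removed", "speed_removed",
                             "inland_removed")], 1, function(r) {
    paste(names(r)[as.logical(r)], collapse = ";")
  })
  df <- data.frame(bird_id = positions$bird_id,
                   timestamp = format(positions$midpoint_time,
                                      "%Y-%m-%dT%H:%M:%SZ"),
                   lat = round(positions$lat, 4),
                   lon = round(positions$lon, 4),
                   source = positions$source,
                   valid = positions$valid,
                   flags = flags)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_positions_csv
#' @export
read_positions_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- data.frame(bird_id = as.character(df$bird_id),
                    midpoint_time = as.POSIXct(df$timestamp,
                      format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                    lat = df$lat, lon = df$lon, source = df$source,
                    valid = df$valid, reason = "",
                    stringsAsFactors = FALSE)
  for (fl in c("smoothed", "equinox_removed", "speed_removed",
               "inland_removed")) {
    out[[fl]] <- grepl(fl, df$flags %||% "")
  }
  out
}
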