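#' Build a true track from waypoints
#'
#' Interpolates positions along great-circle segments between consecutive
#' waypoints at a uniform time step, producing the ground-truth track a
#' simulated tag is carried along. Used both to drive the light simulator
#' and as the truth against which estimated positions are scored.
#'
#' @param waypoints a data.frame with columns `time` (coercible to POSIXct
#'   UTC), `lat`, `lon`; at least two rows, times strictly increasing.
#' @param colony `c(lat, lon)` of the breeding colony.
#' @param resolution samples per day along the track (default 144, i.e. a
#'   10-minute step, matching the light sampling interval).
#' @param bird_id,sex identifiers carried through to downstream outputs.
#' @return an object of class `puffin_track`: a list with `bird_id`, `sex`,
#'   `colony`, and `positions` (data.frame `time`, `lat`, `lon`).
#' @examples
#' wp <- data.frame(time = as.POSIXct(c("2014-01-01", "2014-01-10"), tz = "UTC"),
#'                  lat = c(60, 55), lon = c(-50, -45))
#' tr <- make_track(wp, colony = c(76.47, -70.22), resolution = 24)
#' @export
make_track <- function(waypoints, colony, resolution = 144,
                       bird_id = "sim", sex = c("M", "F")) {
  sex <- match.arg(sex)
  stopifnot(is.data.frame(waypoints), nrow(waypoints) >= 2,
            all(c("time", "lat", "lon") %in% names(waypoints)))
  wt <- .as_utc(waypoints$time)
  if (any(diff(as.numeric(wt)) <= 0)) {
    stop("make_track: waypoint times must be strictly increasing")
  }
  if (any(!is.finite(waypoints$lat)) || any(!is.finite(waypoints$lon))) {
    stop("make_track: non-finite waypoint coordinates")
  }
  step <- 86400 / resolution
  times <- seq(wt[1], wt[length(wt)], by = step)
  seg <- findInterval(as.numeric(times), as.numeric(wt),
                      rightmost.closed = TRUE)
  seg <- pmin(seg, length(wt) - 1)
  out <- matrix(NA_real_, nrow = length(times), ncol = 2)
  for (s in unique(seg)) {
    idx <- which(seg == s)
    f <- (as.numeric(times[idx]) - as.numeric(wt[s])) /
      (as.numeric(wt[s + 1]) - as.numeric(wt[s]))
    out[idx, ] <- gc_interpolate(
      c(waypoints$lat[s], waypoints$lon[s]),
      c(waypoints$lat[s + 1], waypoints$lon[s + 1]), f)
  }
  structure(list(bird_id = bird_id, sex = sex,
                 colony = colony,
                 positions = data.frame(time = times,
                                        lat = out[, 1], lon = out[, 2])),
            class = "puffin_track")
}

#' True position along a track at arbitrary times
#'
#' Great-circle interpolation between the bracketing track samples; times
#' outside the track span clamp to its endpoints.
#' @param track a `puffin_track`.
#' @param time POSIXct vector.
#' @return data.frame with `lat`, `lon`.
#' @export
track_position_at <- function(track, time) {
  time <- .as_utc(time)
  pos <- track$positions
  tn <- as.numeric(pos$time)
  qn <- pmin(pmax(as.numeric(time), tn[1]), tn[length(tn)])
  i <- findInterval(qn, tn, rightmost.closed = TRUE)
  i <- pmin(i, length(tn) - 1)
  out <- matrix(NA_real_, nrow = length(qn), ncol = 2)
  for (k in seq_along(qn)) {
    dt <- tn[i[k] + 1] - tn[i[k]]
    f <- if (dt > 0) (qn[k] - tn[i[k]]) / dt else 0
    out[k, ] <- gc_interpolate(c(pos$lat[i[k]], pos$lon[i[k]]),
                               c(pos$lat[i[k] + 1], pos$lon[i[k] + 1]), f)
  }
  data.frame(lat = out[, 1], lon = out[, 2])
}

#' Shading (sensor noise) model for simulated light
#'
#' Random attenuation of daytime light samples, emulating shading of the
#' leg-mounted tag by the bird's body or plumage. By default shading events
#' are independent per sample; `block_length > 1` draws geometric run
#' lengths instead, emulating sustained leg-tucking.
#'
#' @param shade_probability probability that a sample is shaded (default
#'   0.05, a moderate rate).
#' @param attenuation_factor multiplicative attenuation of shaded samples
#'   in \[0, 1\] (default 0.1).
#' @param sensor_max full-scale light value (default 64; the tag convention
#'   implied by a detection threshold of 10 on an integer scale).
#' @param block_length mean length (samples) of shading runs; 1 = i.i.d.
#' @export
shading_model <- function(shade_probability = 0.05,
                          attenuation_factor = 0.1,
                          sensor_max = 64, block_length = 1) {
  stopifnot(shade_probability >= 0, shade_probability <= 1,
            attenuation_factor >= 0, attenuation_factor <= 1,
            sensor_max > 0, block_length >= 1)
  structure(list(shade_probability = shade_probability,
                 attenuation_factor = attenuation_factor,
                 sensor_max = sensor_max,
                 block_length = block_length),
            class = "puffin_shading")
}

#' Simulate a tag light series along a track
#'
#' Ambient light is a clipped logistic function of solar elevation at the
#' true position: full scale well above the twilight zone, zero well below,
#' with a smooth ramp of width `transition_width` degrees of elevation. The
#' ramp is anchored so the light value equals `anchor_threshold` exactly
#' when the solar elevation equals `true_sun_angle` — the operational
#' definition of a tag's sun elevation angle, and what makes a calibration
#' grid search recover the generating angle. Shaded samples are multiplied
#' by the model's attenuation factor; all values are clipped to
#' `[0, sensor_max]` and rounded to integers.
#'
#' @param track a `puffin_track` from [make_track()].
#' @param interval_min sampling interval in minutes (default 10).
#' @param true_sun_angle solar elevation (degrees) at which light crosses
#'   the detection threshold (default -3.0).
#' @param noise a [shading_model()]; `NULL` for a noise-free series.
#' @param transition_width elevation span (degrees) of the 2--98% logistic
#'   ramp (default 3.5, roughly half an hour of twilight at mid-latitudes,
#'   comfortably wider than the sampling interval so that linear
#'   crossing-time interpolation stays unbiased).
#' @param anchor_threshold light value anchored at `true_sun_angle`
#'   (default 10, the standard detection threshold).
#' @param seed integer seed making the shading reproducible.
#' @return a `puffin_light` object: list with `bird_id`, `metadata`
#'   (colony, sex, sensor_max) and `samples` (data.frame `time`, `light`).
#' @export
simulate_light <- function(track, interval_min = 10, true_sun_angle = -3.0,
                           noise = shading_model(), transition_width = 3.5,
                           anchor_threshold = 10, seed = NULL) {
  if (interval_min <= 0) stop("simulate_light: interval_min must be > 0")
  sensor_max <- if (is.null(noise)) 64 else noise$sensor_max
  pos <- track$positions
  times <- seq(pos$time[1], pos$time[nrow(pos)], by = interval_min * 60)
  at <- track_position_at(track, times)
  elev <- solar_elevation(times, at$lat, at$lon)

  # logistic ramp: 2-98% over transition_width; anchored so that
  # light(true_sun_angle) == anchor_threshold
  s <- transition_width / (2 * stats::qlogis(0.98))
  centre <- true_sun_angle -
    s * stats::qlogis(anchor_threshold / sensor_max)
  light <- sensor_max * stats::plogis((elev - centre) / s)

  if (!is.null(noise) && noise$shade_probability > 0) {
    if (!is.null(seed)) set.seed(seed)
    shaded <- .draw_shading(length(light), noise)
    light[shaded] <- light[shaded] * noise$attenuation_factor
  }
  light <- pmin(sensor_max, pmax(0, round(light)))
  structure(list(bird_id = track$bird_id,
                 metadata = list(colony = track$colony, sex = track$sex,
                                 sensor_max = sensor_max),
                 samples = data.frame(time = times, light = as.integer(light))),
            class = "puffin_light")
}

.draw_shading <- function(n, noise) {
  if (noise$block_length <= 1) {
    return(stats::runif(n) < noise$shade_probability)
  }
  # geometric run lengths with the same marginal shading rate
  shaded <- logical(n)
  p_enter <- noise$shade_probability / noise$block_length /
    max(1e-12, 1 - noise$shade_probability)
  i <- 1
  while (i <= n) {
    if (stats::runif(1) < p_enter) {
      len <- stats::rgeom(1, 1 / noise$block_length) + 1
      shaded[i:min(n, i + len - 1)] <- TRUE
      i <- i + len
    } else {
      i <- i + 1
    }
  }
  shaded
}

#' Simulate a stationary calibration series
#'
#' Light series for a tag left at a fixed, known site — the control data
#' used to calibrate the sun elevation angle. Equivalent to
#' [simulate_light()] on a zero-length track.
#'
#' @param site `c(lat, lon)` of the calibration site.
#' @param start_date,end_date span of the series (coercible to POSIXct
#'   UTC); must cover at least 2 days.
#' @inheritParams simulate_light
#' @export
simulate_stationary <- function(site, start_date, end_date,
                                interval_min = 10, true_sun_angle = -3.0,
                                noise = shading_model(), seed = NULL,
                                bird_id = "calibration") {
  t0 <- .as_utc(start_date)
  t1 <- .as_utc(end_date)
  if (as.numeric(t1 - t0, units = "days") < 2) {
    stop("simulate_stationary: span must be at least 2 days")
  }
  wp <- data.frame(time = c(t0, t1),
                   lat = site[1] + c(0, 1e-9), lon = site[2])
  tr <- make_track(wp, colony = site, resolution = 24, bird_id = bird_id)
  simulate_light(tr, interval_min = interval_min,
                 true_sun_angle = true_sun_angle, noise = noise, seed = seed)
}

#' Write / read a light series as CSV
#'
#' Schema: header `timestamp,light`, ISO-8601 UTC timestamps, integer light.
#' @param x a `puffin_light` object.
#' @param path output file.
#' @export
write_light_csv <- function(x, path) {
  df <- data.frame(timestamp = format(x$samples$time, "%Y-%m-%dT%H:%M:%SZ"),
                   light = x$samples$light)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_light_csv
#' @param bird_id,metadata identifiers attached to the returned object.
#' @export
read_light_csv <- function(path, bird_id = NULL, metadata = list()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("timestamp", "light") %in% names(df)))
  time <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  if (anyNA(time)) time <- .as_utc(df$timestamp)
  structure(list(bird_id = bird_id %||% basename(path),
                 metadata = metadata,
                 samples = data.frame(time = time,
                                      light = as.integer(df$light))),
            class = "puffin_light")
}

#' Write a true track as GeoJSON
#'
#' LineString in lon/lat order with per-vertex ISO-8601 times in the
#' properties, so truth tracks can be inspected in standard GIS tools.
#' @export
write_track_geojson <- function(track, path) {
  pos <- track$positions
  gj <- list(
    type = "Feature",
    properties = list(bird_id = track$bird_id, sex = track$sex,
                      times = format(pos$time, "%Y-%m-%dT%H:%M:%SZ")),
    geometry = list(type = "LineString",
                    coordinates = unname(
                      lapply(seq_len(nrow(pos)),
                             function(i) c(pos$lon[i], pos$lat[i]))))
  )
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
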