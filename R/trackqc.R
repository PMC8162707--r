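#' Flag positions inside the equinox windows
#'
#' Latitude from day length is indeterminate near the equinoxes, when day
#' length is ~12 h everywhere. Positions dated within `window_days` days of
#' either equinox are flagged `equinox_removed`.
#'
#' @param positions a positions data.frame (see
#'   [positions_from_twilights()]).
#' @param window_days half-width of the exclusion window in days
#'   (default 15).
#' @param equinox_dates month-day strings for the spring and fall equinox
#'   (defaults `"03-20"`, `"09-22"`).
#' @return list with `positions` (flags updated) and `report` (one-stage
#'   filter report: input, removed, retained).
#' @export
remove_equinox <- function(positions, window_days = 15,
                           equinox_dates = c("03-20", "09-22")) {
  n <- nrow(positions)
  if (n == 0) {
    return(list(positions = positions,
                report = .stage_report("equinox", 0L, 0L)))
  }
  d <- as.Date(positions$midpoint_time, tz = "UTC")
  yrs <- unique(as.integer(format(d, "%Y")))
  yrs <- sort(unique(c(yrs - 1, yrs, yrs + 1)))
  eq <- as.Date(unlist(lapply(yrs, function(y) {
    paste0(y, "-", equinox_dates)
  })))
  mind <- vapply(as.numeric(d), function(x) {
    min(abs(x - as.numeric(eq)))
  }, numeric(1))
  hit <- mind <= window_days
  positions$equinox_removed <- positions$equinox_removed | hit
  list(positions = positions,
       report = .stage_report("equinox", n, sum(hit)))
}

#' Three-position spherical moving average
#'
#' Each interior position is replaced by the renormalised mean of the unit
#' 3-vectors of itself and its two temporal neighbours; endpoints are left
#' unchanged. Reduces the impact of single-twilight outliers on distance
#' sums.
#'
#' @param positions positions data.frame ordered by time (only rows with
#'   `valid == TRUE` are smoothed; others pass through untouched).
#' @return the data.frame with smoothed coordinates and `smoothed = TRUE`.
#' @export
smooth_track <- function(positions) {
  idx <- which(positions$valid)
  if (length(idx) < 3) {
    warning("smooth_track: fewer than 3 valid positions, returning unchanged")
    return(positions)
  }
  lat <- positions$lat[idx]; lon <- positions$lon[idx]
  v <- t(vapply(seq_along(idx),
                function(i) .to_unit(lat[i], lon[i]), numeric(3)))
  w <- v
  inner <- 2:(length(idx) - 1)
  w[inner, ] <- v[inner - 1, ] + v[inner, ] + v[inner + 1, ]
  ll <- .to_latlon(w)
  positions$lat[idx] <- ll[, 1]
  positions$lon[idx] <- ll[, 2]
  positions$smoothed[idx] <- TRUE
  positions
}

#' Speed filter for unrealistic movements
#'
#' Iteratively removes positions implying movement faster than `max_speed`
#' km/day. While any surviving consecutive pair implies a speed above the
#' limit, the member of a violating pair with the largest summed speed to
#' its surviving neighbours is removed (ties broken toward the later
#' position), and speeds are recomputed. This removes isolated spikes
#' first and guarantees that no surviving pair violates the limit.
#'
#' @param positions positions data.frame; only `valid` rows not already
#'   flagged by an earlier stage participate.
#' @param max_speed km/day (default 500).
#' @return list with `positions` (with `speed_removed` flags) and `report`.
#' @export
speed_filter <- function(positions, max_speed = 500) {
  active <- which(positions$valid & !positions$equinox_removed &
                    !positions$speed_removed)
  n_in <- length(active)
  repeat {
    if (length(active) < 2) break
    p <- cbind(positions$lat[active], positions$lon[active])
    tt <- as.numeric(positions$midpoint_time[active]) / 86400
    d <- gcd(p[-nrow(p), , drop = FALSE], p[-1, , drop = FALSE])
    dt <- pmax(diff(tt), 1e-6)
    sp <- d / dt
    viol <- which(sp > max_speed)
    if (length(viol) == 0) break
    cand <- sort(unique(c(viol, viol + 1)))
    score <- vapply(cand, function(i) {
      s <- 0
      if (i > 1) s <- s + sp[i - 1]
      if (i < length(active)) s <- s + sp[i]
      s
    }, numeric(1))
    # largest summed speed; tie -> later position
    worst <- cand[score >= max(score) - 1e-9]
    drop_i <- max(worst)
    positions$speed_removed[active[drop_i]] <- TRUE
    active <- active[-drop_i]
  }
  list(positions = positions,
       report = .stage_report("speed", n_in, n_in - length(active)))
}

#' Inland filter
#'
#' Removes positions that lie inside a land polygon *and* farther than
#' `max_inland_km` from the coastline. Points on land but within the
#' distance allowance are kept, so genuinely coastal (at-sea) use is not
#' biased offshore; points at sea are never removed.
#'
#' @param positions positions data.frame.
#' @param land a `puffin_landmask` (see [read_landmask()]); `NULL` or
#'   empty is an identity with a warning.
#' @param max_inland_km allowed distance from the sea in km (default 100).
#' @return list with `positions` (with `inland_removed` flags) and
#'   `report`.
#' @export
inland_filter <- function(positions, land, max_inland_km = 100) {
  active <- which(positions$valid & !positions$equinox_removed &
                    !positions$speed_removed & !positions$inland_removed)
  n_in <- length(active)
  if (is.null(land) || length(land$polygons) == 0) {
    warning("inland_filter: empty land mask, returning unchanged")
    return(list(positions = positions,
                report = .stage_report("inland", n_in, 0L)))
  }
  if (n_in > 0) {
    inside <- point_on_land(positions$lat[active], positions$lon[active],
                            land)
    hit <- logical(n_in)
    if (any(inside)) {
      dts <- dist_to_coast_km(positions$lat[active[inside]],
                              positions$lon[active[inside]], land)
      hit[inside] <- dts > max_inland_km
    }
    positions$inland_removed[active[hit]] <- TRUE
    n_rm <- sum(hit)
  } else {
    n_rm <- 0L
  }
  list(positions = positions, report = .stage_report("inland", n_in, n_rm))
}

#' Full quality-control pipeline
#'
#' Applies, in order: spherical smoothing, equinox-window removal, the
#' speed filter, and the inland filter. Returns the flagged positions and
#' a per-stage filter report whose counts are conserved
#' (input = removed + retained at every stage).
#'
#' @inheritParams remove_equinox
#' @inheritParams speed_filter
#' @inheritParams inland_filter
#' @export
qc_pipeline <- function(positions, land = NULL, window_days = 15,
                        equinox_dates = c("03-20", "09-22"),
                        max_speed = 500, max_inland_km = 100) {
  positions <- positions[order(positions$midpoint_time), , drop = FALSE]
  if (sum(positions$valid) >= 3) {
    positions <- smooth_track(positions)
  }
  st1 <- remove_equinox(positions, window_days, equinox_dates)
  st2 <- speed_filter(st1$positions, max_speed)
  st3 <- if (is.null(land)) {
    # no mask supplied: the inland stage is a no-op, not a warning
    n_act <- sum(st2$positions$valid & !st2$positions$equinox_removed &
                   !st2$positions$speed_removed)
    list(positions = st2$positions,
         report = .stage_report("inland", n_act, 0L))
  } else {
    inland_filter(st2$positions, land, max_inland_km)
  }
  pos <- st3$positions
  pos$retained <- pos$valid & !pos$equinox_removed & !pos$speed_removed &
    !pos$inland_removed
  list(positions = pos,
       report = rbind(st1$report, st2$report, st3$report))
}

.stage_report <- function(stage, input, removed) {
  data.frame(stage = stage, input = as.integer(input),
             removed = as.integer(removed),
             retained = as.integer(input - removed),
             stringsAsFactors = FALSE)
}
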