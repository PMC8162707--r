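#' Tri-monthly median locations
#'
#' Median position per 10-day third of each calendar month (days 1-10,
#' 11-20, 21-end), the summary unit used in place of kernel densities for
#' small geolocator samples. Medians are component-wise (median latitude,
#' median longitude); bins with no retained positions are absent.
#'
#' @param positions positions data.frame; rows with `retained == TRUE`
#'   (or, if that flag is absent, `valid == TRUE`) are used.
#' @return data.frame `bird_id`, `year`, `month`, `tercile`, `date`
#'   (bin-centre date), `lat`, `lon`, `n_positions`.
#' @export
tri_monthly_medians <- function(positions) {
  use <- if ("retained" %in% names(positions)) positions$retained
         else positions$valid
  pos <- positions[use, , drop = FALSE]
  if (nrow(pos) == 0) {
    return(data.frame(bird_id = character(0), year = integer(0),
                      month = integer(0), tercile = integer(0),
                      date = as.Date(character(0)), lat = numeric(0),
                      lon = numeric(0), n_positions = integer(0)))
  }
  d <- as.Date(pos$midpoint_time, tz = "UTC")
  day <- as.integer(format(d, "%d"))
  tercile <- ifelse(day <= 10, 1L, ifelse(day <= 20, 2L, 3L))
  key <- paste(format(d, "%Y"), format(d, "%m"), tercile, sep = "-")
  rows <- lapply(split(seq_len(nrow(pos)), key), function(idx) {
    lons <- pos$lon[idx]
    if (diff(range(lons)) > 180) {
      warning("tri_monthly_medians: bin spans > 180 degrees of longitude, dropped")
      return(NULL)
    }
    di <- d[idx]
    data.frame(bird_id = pos$bird_id[idx][1],
               year = as.integer(format(di[1], "%Y")),
               month = as.integer(format(di[1], "%m")),
               tercile = tercile[idx][1],
               date = as.Date(paste0(format(di[1], "%Y-%m-"),
                                     c("05", "15", "25")[tercile[idx][1]])),
               lat = stats::median(pos$lat[idx]),
               lon = stats::median(lons),
               n_positions = length(idx),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  out <- out[order(out$date), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Total migration distance
#'
#' Sum of (at-sea, land-avoiding) great-circle distances along the chain
#' colony -> first median -> ... -> last median -> colony.
#'
#' @param colony `c(lat, lon)`.
#' @param medians data.frame from [tri_monthly_medians()], chronological.
#' @param land optional `puffin_landmask` for rerouting.
#' @return distance in km.
#' @export
total_migration_distance <- function(colony, medians, land = NULL) {
  if (nrow(medians) == 0) stop("total_migration_distance: no median locations")
  pts <- rbind(colony,
               cbind(medians$lat, medians$lon),
               colony)
  sum(vapply(seq_len(nrow(pts) - 1), function(i) {
    at_sea_distance(pts[i, ], pts[i + 1, ], land)
  }, numeric(1)))
}

#' Farthest-distance statistics
#'
#' Mean at-sea distance of the `k` positions farthest from the colony,
#' with the mean coordinates of those positions and the date span over
#' which they occurred (not necessarily one month).
#'
#' @param colony `c(lat, lon)`.
#' @param positions validated positions data.frame.
#' @param land optional land mask (at-sea adjustment applies here too).
#' @param k number of farthest locations averaged (default 8).
#' @return list `farthest_km`, `farthest_location` (`c(lat, lon)`),
#'   `farthest_period` (`c(start, end)` as Dates), `k_used`.
#' @export
farthest_stats <- function(colony, positions, land = NULL, k = 8) {
  use <- if ("retained" %in% names(positions)) positions$retained
         else positions$valid
  pos <- positions[use, , drop = FALSE]
  if (nrow(pos) == 0) stop("farthest_stats: no validated positions")
  if (nrow(pos) < k) {
    warning(sprintf("farthest_stats: only %d positions (< k = %d), using all",
                    nrow(pos), k))
    k <- nrow(pos)
  }
  d <- vapply(seq_len(nrow(pos)), function(i) {
    at_sea_distance(colony, c(pos$lat[i], pos$lon[i]), land)
  }, numeric(1))
  top <- order(d, decreasing = TRUE)[seq_len(k)]
  dates <- as.Date(pos$midpoint_time[top], tz = "UTC")
  list(farthest_km = mean(d[top]),
       farthest_location = c(mean(pos$lat[top]), mean(pos$lon[top])),
       farthest_period = range(dates),
       k_used = k)
}

#' Monthly mean distance from the colony
#'
#' Arithmetic mean of at-sea distances to the colony over all validated
#' positions in each calendar month; months without positions are absent.
#'
#' @inheritParams farthest_stats
#' @return data.frame `year`, `month`, `mean_km`, `n`.
#' @export
monthly_mean_distance <- function(colony, positions, land = NULL) {
  use <- if ("retained" %in% names(positions)) positions$retained
         else positions$valid
  pos <- positions[use, , drop = FALSE]
  if (nrow(pos) == 0) {
    return(data.frame(year = integer(0), month = integer(0),
                      mean_km = numeric(0), n = integer(0)))
  }
  d <- vapply(seq_len(nrow(pos)), function(i) {
    at_sea_distance(colony, c(pos$lat[i], pos$lon[i]), land)
  }, numeric(1))
  ym <- format(as.Date(pos$midpoint_time, tz = "UTC"), "%Y-%m")
  rows <- lapply(split(seq_along(d), ym), function(idx) {
    data.frame(year = as.integer(substr(ym[idx][1], 1, 4)),
               month = as.integer(substr(ym[idx][1], 6, 7)),
               mean_km = mean(d[idx]), n = length(idx))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$year, out$month), , drop = FALSE]
}

#' Return-migration onset
#'
#' The start of return migration is taken as the first tri-monthly median,
#' strictly after the maximum-distance median, from which distance to the
#' colony declines over at least two consecutive steps while latitude
#' increases (movement northward in the general direction of the colony).
#' Returns `NULL` when no such bin exists (e.g. a tag that failed
#' mid-season on an outbound track).
#'
#' @param medians data.frame from [tri_monthly_medians()], chronological.
#' @param colony `c(lat, lon)`.
#' @param land optional land mask for the distance-to-colony series.
#' @return the onset `Date`, or `NULL`.
#' @export
return_migration_onset <- function(medians, colony, land = NULL) {
  if (nrow(medians) < 4) {
    warning("return_migration_onset: fewer than 4 medians")
    return(NULL)
  }
  d <- vapply(seq_len(nrow(medians)), function(i) {
    at_sea_distance(colony, c(medians$lat[i], medians$lon[i]), land)
  }, numeric(1))
  peak <- which.max(d)
  if (peak + 1 > nrow(medians) - 1) return(NULL)
  for (j in seq(peak + 1, nrow(medians) - 1)) {
    if (j < 2) next
    if (d[j] < d[j - 1] && d[j + 1] < d[j] &&
        medians$lat[j + 1] > medians$lat[j - 1]) {
      return(medians$date[j])
    }
  }
  NULL
}

#' Per-bird, per-season migration summary
#'
#' Assembles the per-deployment summary: total migration distance,
#' farthest-location statistics, monthly mean distances and return onset,
#' from validated positions.
#'
#' @param positions validated positions for one bird-season.
#' @param colony `c(lat, lon)`.
#' @param land optional land mask.
#' @param sex,season,mass_g,complete metadata carried into the summary.
#' @return list of class `puffin_summary`.
#' @export
migration_summary <- function(positions, colony, land = NULL,
                              sex = NA_character_, season = NA_character_,
                              mass_g = NA_real_, complete = TRUE) {
  med <- tri_monthly_medians(positions)
  fs <- farthest_stats(colony, positions, land)
  structure(list(
    bird_id = positions$bird_id[1],
    sex = sex, season = season, complete = complete, mass_g = mass_g,
    total_km = total_migration_distance(colony, med, land),
    farthest_km = fs$farthest_km,
    farthest_location = fs$farthest_location,
    farthest_period = fs$farthest_period,
    monthly_mean_km = monthly_mean_distance(colony, positions, land),
    return_onset = return_migration_onset(med, colony, land),
    medians = med), class = "puffin_summary")
}
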