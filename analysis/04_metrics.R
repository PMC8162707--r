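#!/usr/bin/env Rscript
# Per-bird migration metrics.
#
# From the validated positions: tri-monthly median locations, total
# migration distance along the colony-median chain with at-sea rerouting
# around Cape Farewell, mean distance/location/period of the eight
# farthest positions, monthly mean distances, and return-migration onset.
# Writes a per-bird summary table and the median locations.

source(file.path("analysis", "00_cohort_design.R"))

land <- greenland_landmask()
cohort <- utils::read.csv(file.path(results_dir(), "cohort.csv"),
                          stringsAsFactors = FALSE)
pos <- read_positions_csv(file.path(results_dir(), "positions.csv"))
pos$retained <- pos$valid & !pos$equinox_removed & !pos$speed_removed &
  !pos$inland_removed

summaries <- list()
medians <- list()
monthly <- list()
for (i in seq_len(nrow(cohort))) {
  id <- cohort$bird_id[i]
  p <- pos[pos$bird_id == id, ]
  s <- migration_summary(p, COLONY, land = land, sex = cohort$sex[i],
                         season = "2014/15", mass_g = cohort$mass_g[i])
  summaries[[id]] <- data.frame(
    bird_id = id, sex = s$sex, season = s$season,
    total_km = round_report(s$total_km),
    farthest_km = round_report(s$farthest_km),
    farthest_lat = round_report(s$farthest_location[1], 1),
    farthest_lon = round_report(s$farthest_location[2], 1),
    period_start = s$farthest_period[1], period_end = s$farthest_period[2],
    return_onset = if (is.null(s$return_onset)) NA else s$return_onset,
    mass_g = s$mass_g, stringsAsFactors = FALSE)
  medians[[id]] <- s$medians
  mm <- s$monthly_mean_km
  mm$bird_id <- id
  mm$sex <- s$sex
  monthly[[id]] <- mm
  cat(sprintf("%s (%s): total %5.0f km, farthest %4.0f km at %.1f N, %.1f W\n",
              id, s$sex, s$total_km, s$farthest_km,
              s$farthest_location[1], -s$farthest_location[2]))
}

utils::write.csv(do.call(rbind, summaries),
                 file.path(results_dir(), "bird_summaries.csv"),
                 row.names = FALSE)
utils::write.csv(do.call(rbind, medians),
                 file.path(results_dir(), "trimonthly_medians.csv"),
                 row.names = FALSE)
utils::write.csv(do.call(rbind, monthly),
                 file.path(results_dir(), "monthly_distances.csv"),
                 row.names = FALSE)
cat("per-bird summaries -> results/bird_summaries.csv\n")
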