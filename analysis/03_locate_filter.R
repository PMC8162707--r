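#!/usr/bin/env Rscript
# Threshold geolocation and track quality control for the cohort.
#
# For each bird: detect twilights (threshold 10, minimum dark period 4 h),
# estimate twice-daily positions with the calibrated sun angle, then apply
# the QC pipeline — spherical three-position smoothing, +/-15-day equinox
# window removal, the 500 km/day speed filter, and the 100-km inland
# filter against the coarse Greenland mask. Writes validated positions and
# the per-stage filter report.

source(file.path("analysis", "00_cohort_design.R"))

angle <- jsonlite::read_json(file.path(results_dir(),
                                       "calibration.json"))$best_angle
cat("using calibrated sun angle", angle, "deg\n")
land <- greenland_landmask()
cohort <- utils::read.csv(file.path(results_dir(), "cohort.csv"),
                          stringsAsFactors = FALSE)

all_pos <- list()
all_rep <- list()
for (i in seq_len(nrow(cohort))) {
  id <- cohort$bird_id[i]
  s <- read_light_csv(file.path(results_dir(), "lights",
                                paste0(id, "_light.csv")), bird_id = id)
  ev <- detect_twilights(s, threshold = 10, min_dark = 4)
  pos <- positions_from_twilights(ev, sun_angle = angle,
                                  lat_guess = 60, bird_id = id)
  qc <- qc_pipeline(pos, land = land)
  qc$report$bird_id <- id
  all_pos[[id]] <- qc$positions
  all_rep[[id]] <- qc$report
  cat(sprintf("%s: %d twilights -> %d positions, %d retained\n", id,
              nrow(ev), nrow(pos), sum(qc$positions$retained)))
}

pos <- do.call(rbind, all_pos)
write_positions_csv(pos, file.path(results_dir(), "positions.csv"))
utils::write.csv(do.call(rbind, all_rep),
                 file.path(results_dir(), "filter_report.csv"),
                 row.names = FALSE)
cat("validated positions -> results/positions.csv\n")
cat("filter report -> results/filter_report.csv\n")
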