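#!/usr/bin/env Rscript
# Calibrate the sun elevation angle from the colony control series.
#
# Grid search -6.0 to 0.0 deg in 0.5-deg steps over the stationary series
# simulated in 01_simulate.R; the angle minimising the median location
# bias at the known site is adopted for the cohort analysis. Writes the
# calibration grid to results/calibration.csv.

source(file.path("analysis", "00_cohort_design.R"))

cal_series <- read_light_csv(file.path(results_dir(), "lights",
                                       "colony_control_light.csv"),
                             bird_id = "colony_control")
cal <- calibrate_sun_angle(cal_series, COLONY,
                           angle_grid = seq(-6, 0, by = 0.5))

cat(sprintf("best sun elevation angle: %.1f deg (median bias %.1f km over %d twilight pairs)\n",
            cal$best_angle,
            min(cal$grid$median_bias_km, na.rm = TRUE), cal$n_pairs))
utils::write.csv(cal$grid, file.path(results_dir(), "calibration.csv"),
                 row.names = FALSE)
jsonlite::write_json(list(best_angle = cal$best_angle, site = cal$site),
                     file.path(results_dir(), "calibration.json"),
                     auto_unbox = TRUE)
cat("calibration grid -> results/calibration.csv\n")
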