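# Shared design for the synthetic cohort used by the numbered analysis
# scripts: nine birds (six males, three females) tagged at a high-Arctic
# colony (76.47 N, 70.22 W), emulating the two movement syndromes the
# study describes — males wintering between the Davis Strait and southeast
# Greenland (chain-like, synchronous), females overflying them to the
# central/southern North Atlantic (leap-frog, dispersive). Waypoints are
# jittered per bird so individuals differ while keeping the syndrome.
#
# Sourced by the other scripts; not run directly.

library(puffinGLS)

COLONY <- c(76.47, -70.22)
SEED <- 20140901

male_waypoints <- function() {
  data.frame(
    time = as.POSIXct(c("2014-09-25", "2014-10-15", "2014-11-01",
                        "2015-01-25", "2015-02-20", "2015-04-15",
                        "2015-05-15", "2015-05-24"), tz = "UTC"),
    lat = c(75.0, 68.0, 63.0, 60.0, 61.5, 56.0, 63.0, 68.0),
    lon = c(-68.0, -60.0, -56.0, -54.0, -40.0, -38.0, -40.0, -52.0))
}

female_waypoints <- function() {
  data.frame(
    time = as.POSIXct(c("2014-09-25", "2014-10-10", "2014-11-01",
                        "2014-12-01", "2015-02-01", "2015-04-15",
                        "2015-05-10", "2015-05-24"), tz = "UTC"),
    lat = c(75.0, 66.0, 58.5, 50.0, 42.0, 38.0, 50.0, 62.0),
    lon = c(-68.0, -57.0, -44.5, -35.0, -30.0, -28.0, -35.0, -42.0))
}

jitter_waypoints <- function(wp, sd_deg = 0.7, sd_days = 2) {
  n <- nrow(wp)
  wp$lat <- wp$lat + stats::rnorm(n, 0, sd_deg)
  wp$lon <- wp$lon + stats::rnorm(n, 0, sd_deg)
  shift <- round(stats::rnorm(n, 0, sd_days)) * 86400
  shift[c(1, n)] <- 0
  wp$time <- wp$time + shift
  wp <- wp[order(wp$time), ]
  wp
}

make_cohort <- function(seed = SEED) {
  set.seed(seed)
  birds <- data.frame(
    bird_id = c(paste0("M", 1:6), paste0("F", 1:3)),
    sex = c(rep("M", 6), rep("F", 3)),
    mass_g = c(round(stats::rnorm(6, 598, 36)), round(stats::rnorm(3, 460, 30))),
    stringsAsFactors = FALSE)
  tracks <- lapply(seq_len(nrow(birds)), function(i) {
    wp <- if (birds$sex[i] == "M") male_waypoints() else female_waypoints()
    make_track(jitter_waypoints(wp), colony = COLONY,
               bird_id = birds$bird_id[i], sex = birds$sex[i])
  })
  list(birds = birds, tracks = tracks)
}

results_dir <- function() {
  d <- file.path("results")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}
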