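make_valid_positions <- function(time, lat, lon, bird_id = "t") {
  data.frame(bird_id = bird_id, midpoint_time = as.POSIXct(time, tz = "UTC"),
             lat = lat, lon = lon, source = "midnight", valid = TRUE,
             reason = "", retained = TRUE, stringsAsFactors = FALSE)
}

test_that("at-sea distance equals gcd on open ocean and reroutes over land", {
  land <- greenland_landmask()
  p <- c(50, -40); q <- c(45, -30)
  expect_equal(at_sea_distance(p, q, land), gcd(p, q))
  # across southern Greenland: strictly longer than the direct line
  a <- c(64, -52); b <- c(64, -40)
  direct <- gcd(a, b)
  routed <- at_sea_distance(a, b, land)
  expect_gt(routed, direct)
  # and exactly the waypoint-sum for the configured waypoint
  w <- land$waypoints[["Cape Farewell"]]
  expect_equal(routed, gcd(a, w) + gcd(w, b))
  expect_gte(routed, direct)
})

test_that("at-sea distance rejects two on-land endpoints", {
  land <- greenland_landmask()
  expect_error(at_sea_distance(c(72, -41), c(70, -38), land), "on land")
})

test_that("tri-monthly medians bin by 10-day terciles", {
  p <- make_valid_positions(
    c("2014-12-02 12:00", "2014-12-05 12:00", "2014-12-09 12:00"),
    lat = c(50, 52, 58), lon = c(-40, -42, -44))
  m <- tri_monthly_medians(p)
  expect_equal(nrow(m), 1)
  expect_equal(m$tercile, 1L)
  expect_equal(m$lat, 52)
  expect_equal(m$lon, -42)
  expect_equal(m$n_positions, 3L)

  # even count: mean of the central pair
  p2 <- make_valid_positions(c("2014-12-12 12:00", "2014-12-19 12:00"),
                             lat = c(50, 54), lon = c(-40, -44))
  m2 <- tri_monthly_medians(p2)
  expect_equal(m2$lat, 52)
  expect_equal(m2$lon, -42)

  # positions only late in the month fall in tercile 3 alone
  p3 <- make_valid_positions(paste0("2014-12-", 25:28, " 12:00"),
                             lat = 50:53, lon = rep(-40, 4))
  m3 <- tri_monthly_medians(p3)
  expect_equal(m3$tercile, 3L)
  expect_equal(nrow(m3), 1)
})

test_that("total migration distance sums the colony-median chain", {
  colony <- c(76.47, -70.22)
  # all medians at the colony: zero
  m0 <- data.frame(lat = rep(colony[1], 3), lon = rep(colony[2], 3),
                   date = as.Date("2014-12-05") + 0:2)
  expect_equal(total_migration_distance(colony, m0), 0)
  # out-and-back to one median
  one <- data.frame(lat = 67.5, lon = colony[2], date = as.Date("2014-12-05"))
  d <- gcd(colony, c(67.5, colony[2]))
  expect_equal(total_migration_distance(colony, one), 2 * d, tolerance = 1e-9)
  # rerouting makes a land-crossing chain strictly longer
  land <- greenland_landmask()
  chain <- data.frame(lat = c(64, 64), lon = c(-52, -40),
                      date = as.Date("2014-12-05") + 0:1)
  unrerouted <- gcd(colony, c(64, -52)) + gcd(c(64, -52), c(64, -40)) +
    gcd(c(64, -40), colony)
  expect_gt(total_migration_distance(colony, chain, land), unrerouted)
  expect_error(total_migration_distance(colony, chain[0, ]), "no median")
})

test_that("chain distance is bounded below by the end legs", {
  colony <- c(76.47, -70.22)
  set.seed(11)
  for (i in 1:20) {
    k <- sample(3:8, 1)
    m <- data.frame(lat = runif(k, 40, 70), lon = runif(k, -60, -20),
                    date = as.Date("2014-12-01") + seq_len(k))
    tot <- total_migration_distance(colony, m)
    expect_gte(tot + 1e-9, gcd(colony, c(m$lat[1], m$lon[1])) +
                 gcd(c(m$lat[k], m$lon[k]), colony))
  }
})

test_that("farthest statistics average the k most distant locations", {
  colony <- c(76.47, -70.22)
  # identical points: stats collapse onto that point
  p <- make_valid_positions(paste0("2014-12-0", 1:8, " 12:00"),
                            lat = rep(60, 8), lon = rep(-40, 8))
  fs <- farthest_stats(colony, p)
  expect_equal(fs$farthest_km, gcd(colony, c(60, -40)))
  expect_equal(fs$farthest_location, c(60, -40))
  expect_equal(as.character(fs$farthest_period),
               c("2014-12-01", "2014-12-08"))

  # ten points at known distances vs a sort-and-average oracle
  set.seed(9)
  lat <- runif(10, 45, 70); lon <- runif(10, -60, -20)
  p2 <- make_valid_positions(as.POSIXct("2014-12-01", tz = "UTC") +
                               (0:9) * 86400, lat, lon)
  fs2 <- farthest_stats(colony, p2)
  d <- oracle_gcd(matrix(rep(colony, 10), ncol = 2, byrow = TRUE),
                  cbind(lat, lon))
  expect_equal(fs2$farthest_km, mean(sort(d, decreasing = TRUE)[1:8]),
               tolerance = 1e-6)

  # k = 1 degenerates to the maximum
  fs3 <- farthest_stats(colony, p2, k = 1)
  expect_equal(fs3$farthest_km, max(d), tolerance = 1e-6)

  # fewer than k positions: warn and use all
  expect_warning(fs4 <- farthest_stats(colony, p2[1:5, ]), "using all")
  expect_equal(fs4$k_used, 5)
})

test_that("monthly mean distance groups by calendar month", {
  colony <- c(76.47, -70.22)
  p <- make_valid_positions(c("2014-11-05 12:00", "2014-12-05 12:00",
                              "2014-12-20 12:00"),
                            lat = c(70, 65, 60), lon = rep(-60, 3))
  mm <- monthly_mean_distance(colony, p)
  expect_equal(nrow(mm), 2)
  d <- vapply(1:3, function(i) gcd(colony, c(p$lat[i], p$lon[i])),
              numeric(1))
  expect_equal(mm$mean_km[mm$month == 11], d[1])
  expect_equal(mm$mean_km[mm$month == 12], mean(d[2:3]), tolerance = 1e-9)
  expect_equal(mm$n, c(1L, 2L))
})

test_that("return onset is the first sustained decline after the peak", {
  colony <- c(76.47, -70.22)
  # colony-southward distances 1,2,3,2,1 (x1000 km) down a meridian
  lat <- colony[1] - c(1, 2, 3, 2, 1) * 1000 / 111.19
  m <- data.frame(lat = lat, lon = rep(colony[2], 5),
                  date = as.Date("2014-12-05") + (0:4) * 10)
  expect_equal(return_migration_onset(m, colony), m$date[4])

  # monotone outbound: no onset
  m2 <- data.frame(lat = colony[1] - (1:5) * 5, lon = rep(colony[2], 5),
                   date = as.Date("2014-12-05") + (0:4) * 10)
  expect_null(return_migration_onset(m2, colony))

  # plateau at the maximum, then decline: first declining bin
  lat3 <- colony[1] - c(1, 3, 3, 2, 1) * 1000 / 111.19
  m3 <- data.frame(lat = lat3, lon = rep(colony[2], 5),
                   date = as.Date("2014-12-05") + (0:4) * 10)
  expect_equal(return_migration_onset(m3, colony), m3$date[4])

  expect_warning(out <- return_migration_onset(m3[1:3, ], colony), "fewer")
  expect_null(out)
})

test_that("estimated-median totals track truth-median totals within 15%", {
  tr <- winter_track()
  colony <- tr$colony
  # truth medians from the true positions at twilight times
  rel_err <- vapply(1:20, function(seed) {
    run <- run_pipeline(tr, seed = seed)
    est <- tri_monthly_medians(run$positions)
    tru_pos <- run$positions
    tru_pos$lat <- tru_pos$true_lat
    tru_pos$lon <- tru_pos$true_lon
    tru <- tri_monthly_medians(tru_pos)
    abs(total_migration_distance(colony, est) -
          total_migration_distance(colony, tru)) /
      total_migration_distance(colony, tru)
  }, numeric(1))
  expect_lt(max(rel_err), 0.15)
})

test_that("migration_summary assembles a coherent per-bird record", {
  run <- run_pipeline(winter_track("b9"), seed = 2)
  colony <- c(76.47, -70.22)
  s <- migration_summary(run$positions, colony, sex = "M",
                         season = "2014/15", mass_g = 600)
  expect_s3_class(s, "puffin_summary")
  expect_equal(s$bird_id, "b9")
  expect_gte(s$total_km,
             gcd(colony, unlist(s$medians[1, c("lat", "lon")])) +
               gcd(unlist(s$medians[nrow(s$medians), c("lat", "lon")]),
                   colony) - 1e-9)
  expect_lte(s$farthest_km,
             max(vapply(seq_len(nrow(run$positions)), function(i) {
               gcd(colony, c(run$positions$lat[i], run$positions$lon[i]))
             }, numeric(1))) + 1e-9)
})
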