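# bare positions table builder for filter tests
pos_df <- function(time, lat, lon, bird_id = "t") {
  data.frame(bird_id = bird_id, midpoint_time = as.POSIXct(time, tz = "UTC"),
             lat = lat, lon = lon, source = "midnight", valid = TRUE,
             reason = "", smoothed = FALSE, equinox_removed = FALSE,
             speed_removed = FALSE, inland_removed = FALSE,
             stringsAsFactors = FALSE)
}

test_that("equinox windows flag exactly the configured dates", {
  p <- pos_df(c("2014-03-20 12:00", "2014-04-05 12:00", "2014-09-22 12:00",
                "2014-06-01 12:00"),
              lat = rep(50, 4), lon = rep(-40, 4))
  out <- remove_equinox(p)
  expect_equal(out$positions$equinox_removed, c(TRUE, FALSE, TRUE, FALSE))
  # window centre; Apr 5 is 16 days past Mar 20 and survives
  expect_equal(out$report$removed, 2L)
  expect_equal(out$report$input, out$report$removed + out$report$retained)
  # zero-width window: only the equinox dates themselves
  out0 <- remove_equinox(p, window_days = 0)
  expect_equal(out0$positions$equinox_removed, c(TRUE, FALSE, TRUE, FALSE))
  p2 <- pos_df("2014-03-21 12:00", 50, -40)
  expect_false(remove_equinox(p2, window_days = 0)$positions$equinox_removed)
})

test_that("spherical smoothing fixes identical points and averages meridians", {
  t3 <- c("2014-01-01", "2014-01-02", "2014-01-03")
  same <- smooth_track(pos_df(t3, rep(20, 3), rep(10, 3)))
  expect_equal(same$lat, rep(20, 3), tolerance = 1e-9)
  expect_equal(same$lon, rep(10, 3), tolerance = 1e-9)

  merid <- smooth_track(pos_df(t3, c(10, 20, 30), rep(0, 3)))
  # endpoints unchanged, middle at the renormalised vector mean
  expect_equal(merid$lat[c(1, 3)], c(10, 30))
  mid_expected <- atan2(sum(sin(c(10, 20, 30) * pi / 180)),
                        sum(cos(c(10, 20, 30) * pi / 180))) * 180 / pi
  expect_equal(merid$lat[2], mid_expected, tolerance = 1e-6)
  expect_equal(merid$lon[2], 0, tolerance = 1e-9)
})

test_that("smoothing keeps symmetric neighbours on their great circle", {
  # neighbours symmetric about a point on the equator
  p <- smooth_track(pos_df(c("2014-01-01", "2014-01-02", "2014-01-03"),
                           lat = c(0, 0, 0), lon = c(-10, 0, 10)))
  expect_equal(p$lat[2], 0, tolerance = 1e-9)
  expect_equal(p$lon[2], 0, tolerance = 1e-9)
})

test_that("smoothing fewer than 3 positions warns and is the identity", {
  p <- pos_df(c("2014-01-01", "2014-01-02"), c(10, 20), c(0, 0))
  expect_warning(out <- smooth_track(p), "fewer than 3")
  expect_equal(out$lat, p$lat)
})

test_that("speed filter removes unrealistic movements", {
  # 600 km in 24 h: the later position goes
  t0 <- as.POSIXct("2014-01-01 00:00", tz = "UTC")
  p <- pos_df(c(t0, t0 + 86400), lat = c(50, 50), lon = c(-40, -40 + 600 / 71.7))
  d <- gcd(c(50, -40), c(50, -40 + 600 / 71.7))
  stopifnot(abs(d - 600) < 15)
  out <- speed_filter(p)
  expect_equal(out$positions$speed_removed, c(FALSE, TRUE))

  # 300 km in 12 h is 600 km/day: removed too
  p2 <- pos_df(c(t0, t0 + 43200), lat = c(50, 50), lon = c(-40, -40 + 300 / 71.7))
  expect_equal(speed_filter(p2)$positions$speed_removed, c(FALSE, TRUE))

  # compliant track untouched
  p3 <- pos_df(c(t0, t0 + 86400, t0 + 2 * 86400),
               lat = c(50, 51, 52), lon = rep(-40, 3))
  out3 <- speed_filter(p3)
  expect_false(any(out3$positions$speed_removed))
  expect_equal(out3$report$removed, 0L)
})

test_that("speed filter prefers the spike over its neighbours and leaves no violating pair", {
  t0 <- as.POSIXct("2014-01-01 00:00", tz = "UTC")
  # middle point is a 800-km spike off an otherwise slow track
  p <- pos_df(c(t0, t0 + 86400, t0 + 2 * 86400),
              lat = c(50, 57.2, 50.5), lon = rep(-40, 3))
  out <- speed_filter(p)
  expect_equal(out$positions$speed_removed, c(FALSE, TRUE, FALSE))
  kept <- out$positions[!out$positions$speed_removed, ]
  sp <- gcd(cbind(kept$lat[-nrow(kept)], kept$lon[-nrow(kept)]),
            cbind(kept$lat[-1], kept$lon[-1])) /
    (diff(as.numeric(kept$midpoint_time)) / 86400)
  expect_true(all(sp <= 500))
})

test_that("random tracks never retain a > 500 km/day pair after filtering", {
  set.seed(77)
  t0 <- as.POSIXct("2014-01-01 00:00", tz = "UTC")
  for (rep in 1:20) {
    n <- 30
    lat <- cumsum(c(50, rnorm(n - 1, 0, 3)))
    lon <- cumsum(c(-40, rnorm(n - 1, 0, 4)))
    p <- pos_df(t0 + (0:(n - 1)) * 86400, pmin(pmax(lat, -80), 80),
                puffinGLS:::wrap_lon(lon))
    out <- speed_filter(p)
    kept <- out$positions[!out$positions$speed_removed, ]
    if (nrow(kept) >= 2) {
      sp <- gcd(cbind(kept$lat[-nrow(kept)], kept$lon[-nrow(kept)]),
                cbind(kept$lat[-1], kept$lon[-1])) /
        pmax(diff(as.numeric(kept$midpoint_time)) / 86400, 1e-9)
      expect_true(all(sp <= 500 + 1e-6))
    }
    expect_equal(out$report$input,
                 out$report$removed + out$report$retained)
  }
})

test_that("inland filter removes only deep-inland points", {
  island <- circle_island(50, -40, 400)
  t0 <- as.POSIXct("2014-01-01 00:00", tz = "UTC")
  # centre (400 km from coast), 150 km inside, 50 km inside, at sea
  pts <- rbind(c(50, -40),
               geosphere::destPoint(c(-40, 50), 90, 250e3, r = 6371000)[, 2:1],
               geosphere::destPoint(c(-40, 50), 90, 350e3, r = 6371000)[, 2:1],
               geosphere::destPoint(c(-40, 50), 90, 600e3, r = 6371000)[, 2:1])
  p <- pos_df(t0 + (0:3) * 86400, pts[, 1], pts[, 2])
  out <- inland_filter(p, island)
  expect_equal(out$positions$inland_removed, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(out$report$removed, 2L)
})

test_that("an empty land mask is an identity with a warning", {
  p <- pos_df("2014-01-01", 50, -40)
  expect_warning(out <- inland_filter(p, landmask(list())), "empty")
  expect_false(any(out$positions$inland_removed))
})

test_that("filter reports conserve counts and ignore bird relabelling", {
  run <- run_pipeline(winter_track("a"), seed = 5)
  run2 <- run_pipeline(winter_track("zzz"), seed = 5)
  expect_equal(run$report$input, run$report$removed + run$report$retained)
  expect_equal(run$report[-1], run2$report[-1])
  expect_equal(run$positions$lat, run2$positions$lat)
})

test_that("the pipeline keeps nearly all noise-free non-equinox positions", {
  tr <- winter_track()
  s <- simulate_light(tr, noise = NULL)
  pos <- positions_from_twilights(detect_twilights(s), sun_angle = -3,
                                  lat_guess = 55)
  qc <- qc_pipeline(pos, land = greenland_landmask())
  non_eq <- qc$positions[!qc$positions$equinox_removed & qc$positions$valid, ]
  removed <- sum(non_eq$speed_removed | non_eq$inland_removed)
  expect_lt(removed / nrow(non_eq), 0.05)
})

test_that("smoothing reduces mean positional error on noisy tracks", {
  tr <- winter_track()
  diffs <- vapply(1:20, function(seed) {
    s <- simulate_light(tr, seed = seed)
    pos <- positions_from_twilights(detect_twilights(s), sun_angle = -3,
                                    lat_guess = 55)
    pos <- pos[pos$valid, ]
    tru <- track_position_at(tr, pos$midpoint_time)
    raw <- mean(gcd(cbind(pos$lat, pos$lon), cbind(tru$lat, tru$lon)))
    sm <- smooth_track(pos)
    smo <- mean(gcd(cbind(sm$lat, sm$lon), cbind(tru$lat, tru$lon)))
    raw - smo
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})
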