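test_that("nearest centroid is exact at centroids and breaks ties low", {
  fld <- uniform_field(day1)
  cen <- fld$centroids
  idx <- nearest_centroid(cen$lat, cen$lon, fld)
  expect_equal(unname(idx), seq_len(nrow(cen)))
  # exactly equidistant centroids (co-located): the lower id wins, whatever
  # the input order
  twins <- tibble::tibble(centroid_id = c("c09", "c02"),
                          lat = c(36, 36), lon = c(11, 11))
  expect_equal(names(nearest_centroid(35.5, 11, dplyr::arrange(
    twins, centroid_id))), "c02")
})

test_that("nearest centroid agrees with a brute-force haversine scan", {
  set.seed(21)
  cen <- tibble::tibble(centroid_id = sprintf("c%03d", 1:40),
                        lat = runif(40, 35.8, 36.1),
                        lon = runif(40, -79.1, -78.75))
  qlat <- runif(1000, 35.8, 36.1)
  qlon <- runif(1000, -79.1, -78.75)
  got <- unname(nearest_centroid(qlat, qlon, cen))
  want <- vapply(seq_len(1000),
                 function(i) haversine_scan(qlat[i], qlon[i], cen), 1L)
  expect_equal(got, want)
  # and with the field-scale geodesic library as a second, independent check
  d <- geosphere::distm(cbind(qlon[1:50], qlat[1:50]),
                        cbind(cen$lon, cen$lat),
                        fun = geosphere::distHaversine)
  expect_equal(got[1:50], max.col(-d, ties.method = "first"))
})

test_that("a stationary home day reproduces the home-centroid hourly series", {
  fld <- uniform_field(day1)
  # make the field vary by hour at centroid 1 to exercise the time matching
  fld$values[1, , 1, 1] <- seq(2, 25, length.out = 24) * 0.6
  fld$values[1, , 1, 2] <- seq(2, 25, length.out = 24) * 0.4
  fld$values[1, , 1, 3] <- seq(2, 25, length.out = 24)
  track <- stationary_track(lat = 35.90, lon = -79.05)
  res <- personal_outdoor_series(track, fld, "pm25", "total")
  expect_equal(nrow(res), 17280L)
  expect_equal(res$value, rep(seq(2, 25, length.out = 24), each = 720))
  expect_equal(mean(res$value), mean(seq(2, 25, length.out = 24)))
})

test_that("uniform fields yield constant series regardless of movement", {
  fld <- uniform_field(day1)
  track <- stationary_track()
  track$lat <- track$lat + cumsum(rnorm(nrow(track), 0, 1e-4))
  res <- personal_outdoor_series(track, fld, "nox", "total")
  expect_equal(res$value, rep(20, 17280))
})

test_that("time splits between centroids average time-weighted", {
  fld <- uniform_field(day1)
  fld$values[1, , 1, ] <- rep(c(6, 4, 10), each = 24)   # bg, onroad, total
  fld$values[2, , 1, ] <- rep(c(12, 8, 20), each = 24)
  track <- stationary_track(lat = 35.90, lon = -79.05)
  half <- 8640L
  track$lon[(half + 1L):17280L] <- -79.00   # second half at centroid 2
  res <- personal_outdoor_series(track, fld, "pm25", "total")
  expect_equal(mean(res$value), 15)
})

test_that("missing fixes carry the previous geolocation forward", {
  fld <- uniform_field(day1)
  fld$values[1, , 1, 3] <- 10; fld$values[1, , 1, 1] <- 6; fld$values[1, , 1, 2] <- 4
  fld$values[2, , 1, 3] <- 20; fld$values[2, , 1, 1] <- 12; fld$values[2, , 1, 2] <- 8
  track <- stationary_track(lat = 35.90, lon = -79.05)
  track$valid[1000:17280] <- FALSE
  track$lon[1000:17280] <- -79.00   # position noise while invalid: ignored
  res <- personal_outdoor_series(track, fld, "pm25", "total")
  expect_equal(res$value, rep(10, 17280))
  # a leading gap back-fills from the first valid fix
  track2 <- stationary_track(lat = 35.90, lon = -79.05)
  track2 <- track2[-(1:100), ]
  res2 <- personal_outdoor_series(track2, fld, "pm25", "total", date = day1)
  expect_equal(nrow(res2), 17280L)
  expect_equal(res2$value, rep(10, 17280))
})

test_that("background and on-road personal series add to the total", {
  sc <- study_scenario(seed = 31, n_participants = 1, n_clinic_days = 2,
                       n_weeks = 2)
  fld <- generate_field(sc, day1)
  person <- generate_cohort(sc)$cohort[1, ]
  gd <- generate_participant_day(sc, person, day1)
  bg <- personal_outdoor_series(gd$track, fld, "ec", "background")$value
  onr <- personal_outdoor_series(gd$track, fld, "ec", "onroad")$value
  tot <- personal_outdoor_series(gd$track, fld, "ec", "total")$value
  expect_equal(bg + onr, tot, tolerance = 1e-12)
  expect_true(all(tot >= 0))
})

test_that("lag-day tracks copy geolocations, relocating weekend work time", {
  places <- place_geometry(35.90, -79.05, work_lat = 35.95, work_lon = -79.00)
  track <- stationary_track(lat = 35.95, lon = -79.00)   # at work all day
  track$lat[1:2000] <- 35.90
  track$lon[1:2000] <- -79.05                            # morning at home
  lag_wd <- lag_day_track(track, day1 - 1, places)       # Monday
  expect_equal(lag_wd$lat, track$lat)
  expect_equal(lag_wd$time, track$time - 86400)
  lag_we <- lag_day_track(track, day1 - 2, places)       # Sunday
  expect_equal(lag_we$lat[2001:17280], rep(35.90, 15280))
  expect_equal(lag_we$lon[2001:17280], rep(-79.05, 15280))
  expect_equal(lag_we$lat[1:2000], track$lat[1:2000])
  # no workplace: nothing relocates
  places0 <- place_geometry(35.90, -79.05)
  lag0 <- lag_day_track(track, day1 - 2, places0)
  expect_equal(lag0$lat, track$lat)
})
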