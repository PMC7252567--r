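home_pl <- place_geometry(35.90, -79.05, work_lat = 35.95, work_lon = -79.00)

test_that("stationary indoor day at home classifies as in_home throughout", {
  track <- stationary_track(pdop = 9, valid = TRUE)
  me <- classify_microenv(track, home_pl)
  expect_equal(nrow(me), 17280L)
  expect_true(all(me$me == "in_home"))
  # invalid fixes also mean indoors
  track2 <- stationary_track(pdop = 2, valid = FALSE)
  track2$valid[1] <- TRUE   # need one valid position to anchor the place
  me2 <- classify_microenv(track2, home_pl)
  expect_true(all(me2$me == "in_home"))
})

test_that("sustained high speed marks in-vehicle travel", {
  track <- stationary_track(speed = 60, pdop = 2)
  # drift the positions so the place is irrelevant
  track$lon <- track$lon + seq(0, 0.5, length.out = nrow(track))
  me <- classify_microenv(track, home_pl)
  expect_true(all(me$me == "in_vehicle"))
  # a short burst below the sustained window is not vehicle travel
  track2 <- stationary_track(speed = 0, pdop = 2)
  track2$speed_kmh[100:102] <- 50   # 15 s < 30 s window
  me2 <- classify_microenv(track2, home_pl)
  expect_false(any(me2$me == "in_vehicle"))
})

test_that("fix quality separates indoors from outdoors at a place", {
  track <- stationary_track(pdop = 1.5, valid = TRUE)
  me <- classify_microenv(track, home_pl)
  expect_true(all(me$me == "out_home"))
  # away from both places: other
  track3 <- stationary_track(lat = 35.925, lon = -79.025, pdop = 1.5)
  expect_true(all(classify_microenv(track3, home_pl)$me == "out_other"))
  track4 <- stationary_track(lat = 35.925, lon = -79.025, pdop = 9)
  expect_true(all(classify_microenv(track4, home_pl)$me == "in_other"))
})

test_that("gaps inherit the previous label and classification is deterministic", {
  track <- stationary_track(pdop = 9)
  keep <- rep(TRUE, nrow(track))
  keep[5000:8000] <- FALSE   # a long dropout while indoors at home
  me <- classify_microenv(track[keep, ], home_pl)
  expect_equal(nrow(me), 17280L)
  expect_true(all(me$me == "in_home"))
  me2 <- classify_microenv(track[keep, ], home_pl)
  expect_identical(me$me, me2$me)
})

test_that("collapsing to five classes merges outdoor labels one-hot", {
  me7 <- factor(c("out_home", "out_work", "out_other", "in_vehicle",
                  "in_home", "in_work", "in_other"),
                levels = microenv_levels(7))
  me5 <- collapse_microenv(me7)
  expect_equal(as.character(me5[1:3]), rep("outdoors", 3))
  expect_equal(as.character(me5[4:7]),
               c("in_vehicle", "in_home", "in_work", "in_other"))
  expect_false(anyNA(me5))
})

test_that("lag-day imputation copies labels and relabels weekend work time", {
  me_day <- me_series("in_home")
  me_day$me[1:1000] <- "in_work"
  me_day$me[1001:1500] <- "out_work"
  # weekday lag: identical sequence, re-stamped
  lag_wd <- lag_day_microenv(me_day, day1 - 1)   # Monday
  expect_identical(as.character(lag_wd$me), as.character(me_day$me))
  expect_equal(lag_wd$time, fivetiers:::day_ticks(day1 - 1))
  # weekend lag: work time becomes home time
  lag_we <- lag_day_microenv(me_day, day1 - 2)   # Sunday
  expect_true(all(lag_we$me[1:1000] == "in_home"))
  expect_true(all(lag_we$me[1001:1500] == "out_home"))
  expect_identical(as.character(lag_we$me[1501:17280]),
                   as.character(me_day$me[1501:17280]))
  # weekend lag with no work time: unchanged
  all_home <- me_series("in_home")
  expect_identical(as.character(lag_day_microenv(all_home, day1 - 2)$me),
                   as.character(all_home$me))
})

test_that("every tick carries exactly one label covering 24 h", {
  sc <- study_scenario(seed = 5, n_participants = 1, n_clinic_days = 2,
                       n_weeks = 2)
  person <- generate_cohort(sc)$cohort[1, ]
  gd <- generate_participant_day(sc, person, day1)
  pl <- place_geometry(person$home_lat, person$home_lon,
                       person$work_lat, person$work_lon)
  me <- classify_microenv(gd$track, pl)
  expect_equal(nrow(me), 17280L)
  expect_false(anyNA(me$me))
  frac <- table(me$me) / 17280
  expect_equal(sum(frac), 1)
})
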