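test_that("generated fields are additive, nonnegative and reproducible", {
  sc <- study_scenario(seed = 19, n_participants = 1, n_clinic_days = 2,
                       n_weeks = 2)
  fld <- generate_field(sc, c(day1, day1 + 1))
  expect_s3_class(fld, "concentration_field")
  expect_equal(length(fld$hours), 48L)
  v <- fld$values
  expect_true(all(v >= 0))
  expect_equal(v[, , , 3], v[, , , 1] + v[, , , 2], tolerance = 1e-12)
  # bit-identical regeneration from the same seed
  fld2 <- generate_field(sc, c(day1, day1 + 1))
  expect_identical(fld$values, fld2$values)
  # a different seed moves the surfaces
  sc2 <- study_scenario(seed = 20, n_participants = 1, n_clinic_days = 2,
                        n_weeks = 2)
  expect_false(identical(generate_field(sc2, day1)$values,
                         generate_field(sc, day1)$values))
})

test_that("on-road contributions decay with distance from the roads", {
  sc <- study_scenario(seed = 19, n_participants = 1, n_clinic_days = 2,
                       n_weeks = 2)
  fld <- generate_field(sc, day1)
  cen <- fld$centroids
  d <- fivetiers:::road_distance_m(cen, fivetiers:::scenario_roads(sc))
  onroad <- rowMeans(fld$values[, , 2, 2])   # ec, on-road
  ord <- order(d)
  expect_true(all(diff(onroad[ord]) <= 1e-12))
  # near-road ordering: on-road share dominates background for EC close to
  # the road, background dominates for PM2.5 everywhere
  near <- which.min(d)
  expect_gt(mean(fld$values[near, , 2, 2]), mean(fld$values[near, , 2, 1]))
  expect_lt(mean(fld$values[near, , 1, 2]), mean(fld$values[near, , 1, 1]))
})

test_that("scheduling expands clinic days with their lag days", {
  expect_equal(nrow(schedule_study(120)), 720L)
  one <- schedule_study(tibble::tibble(participant = "a", date = day1))
  expect_equal(nrow(one), 6L)
  expect_equal(sum(one$is_clinic), 1L)
  expect_equal(one$date, seq(day1 - 5, day1, by = 1))
  expect_equal(unique(one$clinic_date), day1)
  expect_equal(nrow(schedule_study(0)), 0L)
  # overlapping visits keep multiplicity
  two <- schedule_study(tibble::tibble(participant = "a",
                                       date = c(day1, day1 + 1)))
  expect_equal(nrow(two), 12L)
  expect_equal(nrow(dplyr::distinct(two, participant, date)), 7L)
})

test_that("generated participant-days honour their ground-truth plan", {
  sc <- study_scenario(seed = 23, n_participants = 2, n_clinic_days = 2,
                       n_weeks = 2)
  person <- generate_cohort(sc)$cohort[1, ]
  gd <- generate_participant_day(sc, person, day1)
  expect_equal(nrow(gd$truth), 17280L)
  expect_false(anyNA(gd$truth$me))
  expect_true(all(gd$accel$counts >= 0))
  expect_true(is.integer(gd$accel$counts))
  expect_equal(nrow(gd$accel), 86400L)
  # home ticks lie near home (allow GPS noise beyond the 40 m radius)
  at_home <- gd$truth$me %in% c("in_home", "out_home")
  d_home <- fivetiers:::haversine_m(gd$track$lat, gd$track$lon,
                                    person$home_lat, person$home_lon)
  slot <- match(round(as.numeric(gd$track$time)),
                round(as.numeric(gd$truth$time)))
  expect_gt(mean(d_home[at_home[slot]] < 60), 0.95)
  # planned vehicle spans move faster than the classifier threshold
  veh <- gd$truth$me[slot] == "in_vehicle"
  expect_gt(mean(gd$track$speed_kmh[veh] > 10), 0.9)
  # reproducible from the seed
  gd2 <- generate_participant_day(sc, person, day1)
  expect_identical(gd$track, gd2$track)
  expect_identical(gd$accel$counts, gd2$accel$counts)
})

test_that("a generated study bundle runs end to end without violations", {
  sc <- study_scenario(seed = 27, n_participants = 2, n_clinic_days = 2,
                       n_weeks = 3)
  st <- generate_study(sc)
  expect_s3_class(st, "exposure_study")
  expect_equal(nrow(st$cohort), 2L)
  expect_equal(sum(st$schedule$is_clinic), 2L)
  rec <- run_study(st)
  expect_equal(nrow(rec), nrow(st$schedule) * 12L)
  expect_equal(nrow(check_tier_records(rec)), 0L)
})
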