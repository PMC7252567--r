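p_all <- pollutant_params()

test_that("tick exposure weights concentrations by microenvironment", {
  me5 <- function(x) factor(x, levels = microenv_levels(5))
  expect_equal(exposure_tick(me5("outdoors"), 0, 10, p_all, "pm25"), 10)
  expect_equal(exposure_tick(me5("in_vehicle"), 0, 1, p_all, "pm25"), 0.44)
  expect_equal(exposure_tick(me5("in_work"), 0, 1, p_all, "ec"), 0.59)
  expect_equal(exposure_tick(me5("in_other"), 0, 1, p_all, "ec"), 0.59)
  expect_equal(exposure_tick(me5("in_home"), 7.3, 99, p_all, "nox"), 7.3)
  # CO: unattenuated everywhere
  for (m in microenv_levels(5)[-1]) {
    expect_equal(exposure_tick(me5(m), 0, 5, p_all, "co"), 5)
  }
  # 7-level input collapses transparently
  me7 <- factor("out_work", levels = microenv_levels(7))
  expect_equal(exposure_tick(me7, 0, 3, p_all, "pm25"), 3)
})

test_that("per-microenvironment exposure split sums to the total", {
  set.seed(41)
  me <- factor(sample(microenv_levels(7), 500, replace = TRUE),
               levels = microenv_levels(7))
  c_in <- runif(500, 0, 20)
  c_out <- runif(500, 0, 30)
  em <- exposure_by_me(me, c_in, c_out, p_all, "ec")
  expect_equal(rowSums(em),
               exposure_tick(me, c_in, c_out, p_all, "ec"))
  # only the occupied microenvironment is non-zero
  expect_true(all(rowSums(em != 0) <= 1))
})

test_that("dose increments follow E * MV * AT / BSA", {
  e <- c(10, 0, 0, 0, 0, 0, 0)
  expect_equal(sum(dose_tick(e, mv = 0.012, bsa = 2)), 0.005)
  expect_equal(dose_tick(e, mv = 0, bsa = 2), e * 0)
  expect_equal(dose_tick(e, mv = 0.012, bsa = 4),
               dose_tick(e, mv = 0.012, bsa = 2) / 2)
  expect_error(dose_tick(e, mv = 0.01, bsa = 0), "> 0")
})

test_that("a constant all-home day collapses tier 4 to tier 2 and 3 to 1", {
  hours <- fivetiers:::day_hours(day1)
  hourly <- tibble::tibble(time = hours, c_out_home = 10,
                           c_in_home = 6.2)
  ticks <- tibble::tibble(
    time = fivetiers:::day_ticks(day1),
    me = factor("in_home", levels = microenv_levels(7)),
    c_out_personal = 10, mv = 0.008)
  rec <- daily_metrics(ticks, hourly, test_participant(), "pm25", "total",
                       p_all)
  expect_equal(rec$tier1_out_home, 10)
  expect_equal(rec$tier3_out_personal, rec$tier1_out_home)
  expect_equal(rec$tier4_exposure, rec$tier2_in_home)
  expect_equal(rec$tier2_in_home, 6.2)
  # dose and time conservation
  expect_equal(sum(as.numeric(rec[paste0("dose_", microenv_levels(7))])),
               rec$tier5_dose)
  expect_equal(sum(as.numeric(rec[paste0("time_", microenv_levels(7))])),
               1440)
  expect_equal(rec$time_in_home, 1440)
  # tier5 = E * MV * 1440 / BSA for a constant day
  bsa <- body_surface_area(180, 75)
  expect_equal(rec$tier5_dose, 6.2 * 0.008 * 1440 / bsa)
})

test_that("run_study emits 12 records per scheduled participant-day", {
  sc <- study_scenario(seed = 9, n_participants = 1, n_clinic_days = 2,
                       n_weeks = 2)
  st <- generate_study(sc)
  rec <- run_study(st)
  expect_s3_class(rec, "tier_records")
  expect_equal(nrow(rec), nrow(st$schedule) * 12L)
  expect_equal(nrow(st$schedule), 2L * 6L)
  # every pollutant x component present for every scheduled day
  cnt <- dplyr::count(tibble::as_tibble(rec), participant, date, clinic_date)
  expect_true(all(cnt$n == 12L))
  # lag days flagged imputed, clinic days not
  expect_equal(sort(unique(rec$date[!rec$imputed])),
               sort(unique(st$schedule$date[st$schedule$is_clinic])))
  # audit is clean
  expect_equal(nrow(check_tier_records(rec)), 0L)
  # glance summarises the run
  g <- glance(rec)
  expect_equal(g$n_records, nrow(rec))
  expect_equal(g$n_participant_days, 12L)
  expect_equal(g$n_pollutants, 4L)
  # tidy returns a plain tibble, long form splits metrics
  expect_false(inherits(tidy(rec), "tier_records"))
  expect_true(all(c("metric", "value") %in% names(tidy(rec, long = TRUE))))
})

test_that("an empty schedule produces an empty record table", {
  sc <- study_scenario(seed = 9, n_participants = 1, n_clinic_days = 2,
                       n_weeks = 2)
  st <- generate_study(sc)
  st$schedule <- st$schedule[0, ]
  rec <- run_study(st)
  expect_equal(nrow(rec), 0L)
})

test_that("run_study agrees with the per-day assembly of daily_metrics", {
  sc <- study_scenario(seed = 13, n_participants = 1, n_clinic_days = 2,
                       n_weeks = 2)
  st <- generate_study(sc)
  # keep one clinic day only
  st$schedule <- st$schedule[st$schedule$is_clinic, ][1, ]
  cdate <- st$schedule$date[1]
  rec <- run_study(st)
  # independent reassembly through the exported per-stage functions
  person <- st$cohort[1, ]
  home <- st$homes[1, ]
  obs <- st$observations(person$participant, cdate)
  places <- place_geometry(person$home_lat, person$home_lon,
                           person$work_lat, person$work_lon)
  me <- classify_microenv(obs$track, places, cdate)
  pal <- vehicle_override(classify_pal(rolling_cpm(obs$accel)$cpm), me$me)
  mv <- minute_ventilation(pal, person$age, person$sex, person$weight_kg,
                           default_nmv_table())
  fld <- generate_field(sc, cdate)
  quest <- st$questionnaires[1, ]
  aer <- hourly_aer(st$weather, home, quest)
  hcid <- nearest_centroid(person$home_lat, person$home_lon, fld)
  for (comp in c("background", "total")) {
    cop <- personal_outdoor_series(obs$track, fld, "ec", comp, date = cdate)
    tier1 <- tibble::tibble(
      time = fivetiers:::day_hours(cdate),
      value = fld$values[unname(hcid), , match("ec", pollutants()),
                         match(comp, components())])
    c_in <- indoor_series(tier1, dplyr::select(aer, time, aer),
                          pollutant_params(), "ec")
    ticks <- tibble::tibble(time = me$time, me = me$me,
                            c_out_personal = cop$value, mv = mv)
    hourly <- tibble::tibble(time = tier1$time, c_out_home = tier1$value,
                             c_in_home = c_in$value)
    want <- daily_metrics(ticks, hourly,
                          dplyr::rename(person, participant = participant),
                          "ec", comp)
    got <- tibble::as_tibble(rec)[rec$pollutant == "ec" &
                                    rec$component == comp, ]
    expect_equal(got$tier1_out_home, want$tier1_out_home, tolerance = 1e-12)
    expect_equal(got$tier2_in_home, want$tier2_in_home, tolerance = 1e-12)
    expect_equal(got$tier3_out_personal, want$tier3_out_personal,
                 tolerance = 1e-12)
    expect_equal(got$tier4_exposure, want$tier4_exposure, tolerance = 1e-12)
    expect_equal(got$tier5_dose, want$tier5_dose, tolerance = 1e-12)
    expect_equal(as.numeric(got[paste0("dose_", microenv_levels(7))]),
                 as.numeric(want[paste0("dose_", microenv_levels(7))]),
                 tolerance = 1e-12)
  }
})
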