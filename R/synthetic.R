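#' Define a synthetic study scenario
#'
#' A scenario fixes everything the synthetic-study generator needs: the
#' random seed, cohort size and clinic-day schedule, the spatial domain
#' (bounding box and centroid grid emulating census-block centroids), road
#' polylines with per-pollutant emission strengths, background-field and
#' weather parameters, and the GPS/accelerometer noise model. Defaults are
#' the conditions of the panel-study design the package models: 15 adult
#' participants with coronary artery disease, 120 clinic participant-days in
#' consecutive-weekday pairs spread over roughly two years, five lag days
#' per clinic day (720 scheduled participant-days), a county-scale domain in
#' central North Carolina, 5-s GPS and 1-s accelerometer logging, and
#' 8 am - 8 am participant-days.
#'
#' Everything generated from a scenario is reproducible from `seed`;
#' per-day data use seeds derived from (seed, stream, date) so any
#' participant-day can be regenerated in isolation.
#'
#' @param seed Integer master seed.
#' @param n_participants Cohort size.
#' @param n_clinic_days Total clinic participant-days (even; visits are
#'   pairs of consecutive weekdays).
#' @param n_lags Lag days preceding each clinic day.
#' @param start_date First possible clinic date.
#' @param n_weeks Weeks the visit schedule is spread across.
#' @param bbox Domain bounding box `c(lon_min, lat_min, lon_max, lat_max)`.
#' @param grid_n Centroid grid is `grid_n` x `grid_n`.
#' @param background Per-pollutant background means, ug/m^3.
#' @param onroad_peak Per-pollutant on-road contribution at the road, ug/m^3.
#' @param road_decay_m E-folding distance of the near-road gradient, m.
#' @param work_fraction Fraction of participants with a workplace.
#' @return A list of class `study_scenario`.
#' @export
study_scenario <- function(seed = 1L, n_participants = 15L,
                           n_clinic_days = 120L, n_lags = 5L,
                           start_date = "2012-05-01", n_weeks = 104L,
                           bbox = c(-79.10, 35.80, -78.75, 36.10),
                           grid_n = 10L,
                           background = c(pm25 = 11, ec = 0.6, nox = 18,
                                          co = 350),
                           onroad_peak = c(pm25 = 2.5, ec = 4.5, nox = 130,
                                           co = 220),
                           road_decay_m = 250,
                           work_fraction = 0.6) {
  if (n_clinic_days %% 2L != 0L) abort("`n_clinic_days` must be even")
  stopifnot(all(background > 0), all(onroad_peak >= 0), road_decay_m > 0)
  structure(
    list(seed = as.integer(seed), n_participants = as.integer(n_participants),
         n_clinic_days = as.integer(n_clinic_days), n_lags = as.integer(n_lags),
         start_date = as.Date(start_date), n_weeks = as.integer(n_weeks),
         bbox = bbox, grid_n = as.integer(grid_n),
         background = background[POLLUTANTS],
         onroad_peak = onroad_peak[POLLUTANTS],
         road_decay_m = road_decay_m, work_fraction = work_fraction),
    class = "study_scenario")
}

# centroid grid over the bounding box, ids sorted ascending
scenario_centroids <- function(scenario) {
  b <- scenario$bbox
  n <- scenario$grid_n
  lons <- seq(b[1], b[3], length.out = n)
  lats <- seq(b[2], b[4], length.out = n)
  g <- tidyr::expand_grid(lat = lats, lon = lons)
  tibble::tibble(centroid_id = sprintf("c%04d", seq_len(nrow(g))),
                 lat = g$lat, lon = g$lon)
}

# two roads (a diagonal highway, a N-S arterial) as dense vertex lists
scenario_roads <- function(scenario) {
  b <- scenario$bbox
  t <- seq(0, 1, length.out = 150)
  rbind(
    cbind(lat = b[2] + t * (b[4] - b[2]), lon = b[1] + t * (b[3] - b[1])),
    cbind(lat = b[2] + t * (b[4] - b[2]),
          lon = (b[1] + b[3]) / 2 + 0.02 * sin(3 * pi * t))
  )
}

# distance (m) from each centroid to the nearest road vertex
road_distance_m <- function(centroids, roads) {
  d <- geosphere::distm(cbind(centroids$lon, centroids$lat),
                        cbind(roads[, "lon"], roads[, "lat"]),
                        fun = geosphere::distHaversine)
  apply(d, 1L, min)
}

# fixed per-pollutant spatial loading surfaces (smooth random bumps),
# deterministic in the scenario seed alone
background_surface <- function(scenario, centroids) {
  withr::with_seed(derive_seed(scenario$seed, 11L), {
    b <- scenario$bbox
    n_bump <- 6L
    surf <- sapply(POLLUTANTS, function(p) {
      cl <- runif(n_bump, b[1], b[3])
      ct <- runif(n_bump, b[2], b[4])
      amp <- runif(n_bump, -0.15, 0.25)
      sig <- runif(n_bump, 0.06, 0.15)
      s <- rep(1, nrow(centroids))
      for (k in seq_len(n_bump)) {
        s <- s + amp[k] * exp(-((centroids$lon - cl[k])^2 +
                                  (centroids$lat - ct[k])^2) / (2 * sig[k]^2))
      }
      pmax(s, 0.3)
    })
    colnames(surf) <- POLLUTANTS
    surf
  })
}

traffic_profile <- function(hour_of_day) {
  0.35 + 0.85 * exp(-((hour_of_day - 8) / 2)^2) +
    0.75 * exp(-((hour_of_day - 17.5) / 2.5)^2)
}

#' Generate the synthetic hourly concentration field
#'
#' Builds the hourly background / on-road / total concentration surfaces for
#' the participant-day windows of `dates`. The background is a smooth
#' positive surface (fixed random spatial loadings per pollutant) modulated
#' by a diurnal cycle and a lognormal day factor; the on-road component
#' decays exponentially with distance from the road polylines, scaled by a
#' rush-hour traffic profile, and is strongest (relative to background) for
#' EC and NOx; the total is exactly background + on-road. Deterministic per
#' (scenario seed, date).
#'
#' @param scenario A [study_scenario()].
#' @param dates Dates of the participant-days to cover.
#' @param day_start_hour Hour each window starts (default 8).
#' @return A [concentration_field()].
#' @export
generate_field <- function(scenario, dates, day_start_hour = DAY_START_HOUR) {
  stopifnot(inherits(scenario, "study_scenario"))
  dates <- sort(unique(as.Date(dates)))
  centroids <- scenario_centroids(scenario)
  surf <- background_surface(scenario, centroids)
  d_road <- road_distance_m(centroids, scenario_roads(scenario))
  # diffuse urban traffic share everywhere plus the sharp near-road gradient
  decay <- 0.25 + 0.75 * exp(-d_road / scenario$road_decay_m)
  nc <- nrow(centroids)
  hours <- do.call(c, lapply(dates, day_hours, day_start_hour = day_start_hour))
  nh <- length(hours)
  values <- array(0, dim = c(nc, nh, length(POLLUTANTS), length(COMPONENTS)))
  hod <- as.numeric(format(hours, "%H"))
  diurn_bg <- 1 + 0.15 * sin(2 * pi * (hod - 3) / 24)
  traffic <- traffic_profile(hod)
  for (di in seq_along(dates)) {
    hsel <- (di - 1L) * 24L + 1:24
    withr::with_seed(derive_seed(scenario$seed, 13L,
                                 as.integer(dates[di])), {
      day_bg <- exp(rnorm(length(POLLUTANTS), 0, 0.25))
      day_on <- exp(rnorm(length(POLLUTANTS), 0, 0.30))
    })
    for (pi in seq_along(POLLUTANTS)) {
      bg <- outer(surf[, pi], diurn_bg[hsel]) *
        scenario$background[pi] * day_bg[pi]
      onr <- outer(decay, traffic[hsel]) * scenario$onroad_peak[pi] *
        day_on[pi]
      values[, hsel, pi, 1] <- bg
      values[, hsel, pi, 2] <- onr
      values[, hsel, pi, 3] <- bg + onr
    }
  }
  concentration_field(centroids, hours, values)
}

#' Generate the synthetic cohort and their homes
#'
#' Participants are adults (45-80 y) placed at random locations in the
#' domain; a `work_fraction` share have a workplace 3-15 km from home.
#' Homes get leakage areas, volumes, stories, shielding classes, openable
#' areas and (for some) window fans spanning realistic single-family ranges.
#'
#' @param scenario A [study_scenario()].
#' @return List with tibbles `cohort` and `homes` (see [exposure_study()]).
#' @export
generate_cohort <- function(scenario) {
  n <- scenario$n_participants
  b <- scenario$bbox
  withr::with_seed(derive_seed(scenario$seed, 17L), {
    sex <- sample(c("male", "female"), n, replace = TRUE)
    height <- ifelse(sex == "male", rnorm(n, 176, 7), rnorm(n, 163, 6))
    weight <- ifelse(sex == "male", rnorm(n, 88, 14), rnorm(n, 75, 13))
    home_lat <- runif(n, b[2] + 0.02, b[4] - 0.02)
    home_lon <- runif(n, b[1] + 0.02, b[3] - 0.02)
    has_work <- runif(n) < scenario$work_fraction
    ang <- runif(n, 0, 2 * pi)
    dist_km <- runif(n, 3, 15)
    work_lat <- ifelse(has_work, home_lat + dist_km / 111 * sin(ang), NA)
    work_lon <- ifelse(
      has_work,
      home_lon + dist_km / (111 * cos(home_lat * pi / 180)) * cos(ang), NA)
    work_lat <- pmin(pmax(work_lat, b[2]), b[4])
    work_lon <- pmin(pmax(work_lon, b[1]), b[3])
    cohort <- tibble::tibble(
      participant = sprintf("p%02d", seq_len(n)),
      age = sample(45:80, n, replace = TRUE), sex = sex,
      height_cm = round(height, 1), weight_kg = round(pmax(weight, 45), 1),
      home_id = sprintf("h%02d", seq_len(n)),
      home_lat = home_lat, home_lon = home_lon,
      work_lat = work_lat, work_lon = work_lon)
    fan <- runif(n) < 0.3
    homes <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
      home_model(cohort$home_id[i],
                 a_leak = runif(1, 0.03, 0.12),
                 volume = runif(1, 250, 650),
                 stories = sample(1:2, 1),
                 shielding_class = sample(2:4, 1),
                 openable_area = runif(1, 0.4, 1.5),
                 fan_flow = if (fan[i]) runif(1, 300, 600) else 0)
    }))
    list(cohort = cohort, homes = homes)
  })
}

#' Expand clinic days into the modeled participant-day schedule
#'
#' Each clinic day contributes itself plus its `n_lags` preceding days, each
#' tagged with the clinic day it belongs to. Days shared by overlapping
#' visits appear once per visit (multiplicity), so `n` clinic days always
#' yield `n * (1 + n_lags)` scheduled participant-days; unique days can be
#' counted separately.
#'
#' @param clinic_days Tibble `participant`, `date` of clinic visits, or a
#'   single integer n: n clinic days for one participant on consecutive
#'   weekday pairs starting 2012-05-01.
#' @param n_lags Number of preceding lag days per clinic day (default 5).
#' @return Tibble `participant`, `date`, `is_clinic`, `clinic_date` with
#'   `nrow(clinic_days) * (1 + n_lags)` rows.
#' @export
#' @examples
#' nrow(schedule_study(120))   # 720
schedule_study <- function(clinic_days, n_lags = 5L) {
  if (is.numeric(clinic_days) && length(clinic_days) == 1L) {
    n <- as.integer(clinic_days)
    if (n < 0L) abort("number of clinic days must be >= 0")
    first_tue <- as.Date("2012-05-01")
    pair <- seq_len(max(n %/% 2L + n %% 2L, 0L)) - 1L
    dates <- as.Date(rbind(first_tue + pair * 7L, first_tue + pair * 7L + 1L))
    clinic_days <- tibble::tibble(participant = "p01",
                                  date = sort(dates)[seq_len(n)])
  }
  stopifnot(is.data.frame(clinic_days))
  if (nrow(clinic_days) == 0L) {
    return(tibble::tibble(participant = character(), date = as.Date(character()),
                          is_clinic = logical(),
                          clinic_date = as.Date(character())))
  }
  lags <- seq_len(n_lags)
  dplyr::bind_rows(lapply(seq_len(nrow(clinic_days)), function(i) {
    cd <- as.Date(clinic_days$date[i])
    tibble::tibble(participant = clinic_days$participant[i],
                   date = c(cd - rev(lags), cd),
                   is_clinic = c(rep(FALSE, n_lags), TRUE),
                   clinic_date = cd)
  }))
}

# assign clinic visits (pairs of consecutive weekdays) to participants,
# spread over the scenario's weeks
scenario_clinic_days <- function(scenario) {
  n_pairs <- scenario$n_clinic_days %/% 2L
  # first Tuesday on/after start_date
  d0 <- scenario$start_date
  d0 <- d0 + (match("2", format(d0 + 0:6, "%u")) - 1L)
  weeks <- floor(seq(0, scenario$n_weeks - 1L, length.out = n_pairs))
  pid <- sprintf("p%02d", (seq_len(n_pairs) - 1L) %% scenario$n_participants + 1L)
  dplyr::bind_rows(lapply(seq_len(n_pairs), function(k) {
    tue <- d0 + weeks[k] * 7L
    tibble::tibble(participant = pid[k], date = c(tue, tue + 1L))
  }))
}

#' Generate synthetic hourly weather
#'
#' Seasonal plus diurnal outdoor temperature with autocorrelated noise, and
#' wind speeds with a persistent daily mean — hourly, covering the
#' participant-day windows of `dates`.
#'
#' @param scenario A [study_scenario()].
#' @param dates Dates whose windows must be covered.
#' @param day_start_hour Window start hour.
#' @return Tibble `time`, `t_out` (deg C), `wind` (m/s).
#' @export
generate_weather <- function(scenario, dates,
                             day_start_hour = DAY_START_HOUR) {
  dates <- sort(unique(as.Date(dates)))
  hours <- do.call(c, lapply(dates, day_hours, day_start_hour = day_start_hour))
  hours <- sort(unique(hours))
  doy <- as.numeric(format(hours, "%j"))
  hod <- as.numeric(format(hours, "%H"))
  withr::with_seed(derive_seed(scenario$seed, 19L), {
    seasonal <- 15 - 9.5 * cos(2 * pi * (doy - 15) / 365)
    diurnal <- 4.5 * sin(2 * pi * (hod - 9) / 24)
    noise <- as.numeric(stats::filter(rnorm(length(hours), 0, 1.2), 0.8,
                                      method = "recursive"))
    day_wind <- exp(rnorm(length(hours) / 24, log(2.2), 0.45))
    wind <- pmax(rep(day_wind, each = 24L) +
                   rnorm(length(hours), 0, 0.5), 0)
    tibble::tibble(time = hours, t_out = seasonal + diurnal + noise,
                   wind = wind)
  })
}

# seasonal questionnaire flags for one clinic visit
generate_questionnaire <- function(scenario, participant, date) {
  withr::with_seed(derive_seed(scenario$seed, 23L,
                               as.integer(as.Date(date)),
                               sum(utf8ToInt(participant))),
  {
    mon <- as.integer(format(as.Date(date), "%m"))
    p_open <- c(0.08, 0.08, 0.25, 0.5, 0.5, 0.25, 0.2, 0.2, 0.45, 0.5,
                0.25, 0.08)[mon]
    windows <- runif(1) < p_open
    tibble::tibble(participant = participant, date = as.Date(date),
                   t_in = round(rnorm(1, 21.5, 1.2), 1),
                   windows_open = windows,
                   doors_open = runif(1) < 0.15,
                   fan_on = runif(1) < if (windows) 0.25 else 0.05)
  })
}

#' Generate one participant-day of synthetic logger data
#'
#' Realises a ground-truth day plan (home, commute, work, errands, outdoor
#' episodes) as a 5-s GPS track and 1-s accelerometer counts, together with
#' the true microenvironment label of every tick. GPS positions get
#' location noise; indoors the fix quality degrades (inflated position
#' dilution of precision, invalid fixes, dropped samples), emulating how
#' receivers behave under a roof. Activity counts are drawn per planned
#' physical-activity level with level-dependent means. Deterministic per
#' (scenario seed, participant, date).
#'
#' @param scenario A [study_scenario()].
#' @param person One cohort row (see [generate_cohort()]).
#' @param date The participant-day date.
#' @param day_start_hour Window start hour.
#' @return List with `track` (GPS tibble), `accel` (1-s counts tibble),
#'   `questionnaire`, and `truth` (tibble `time`, `me` of true labels).
#' @export
generate_participant_day <- function(scenario, person, date,
                                     day_start_hour = DAY_START_HOUR) {
  stopifnot(inherits(scenario, "study_scenario"), nrow(person) == 1L)
  date <- as.Date(date)
  seed <- derive_seed(scenario$seed, 29L, as.integer(date),
                      sum(utf8ToInt(person$participant)))
  withr::with_seed(seed, {
    plan <- build_day_plan(person, date)
    truth_me <- factor(rep(plan$me, plan$ticks), levels = ME7_LEVELS)
    ticks <- day_ticks(date, day_start_hour)
    track <- realize_track(plan, person, ticks)
    accel <- realize_accel(plan, date, day_start_hour)
    quest <- generate_questionnaire(scenario, person$participant, date)
    list(track = track, accel = accel, questionnaire = quest,
         truth = tibble::tibble(time = ticks, me = truth_me))
  })
}

# a day plan: segments of (me, ticks, lat, lon, speed profile), 17,280 ticks
build_day_plan <- function(person, date) {
  has_work <- !is.na(person$work_lat)
  worker_day <- has_work && !is_weekend(date)
  home <- c(person$home_lat, person$home_lon)
  seg <- function(me, mins, lat, lon, pal, speed = 0) {
    tibble::tibble(me = me, ticks = as.integer(round(mins * 12)), lat = lat,
                   lon = lon, pal = pal, speed = speed)
  }
  offset_deg <- function(m) m / 111000
  if (worker_day) {
    work <- c(person$work_lat, person$work_lon)
    commute_min <- max(5, round(
      haversine_m(home[1], home[2], work[1], work[2]) / 1000 / 45 * 60))
    plan <- dplyr::bind_rows(
      seg("in_home", 40, home[1], home[2], "sedentary"),
      seg("in_vehicle", commute_min, NA, NA, "light", speed = 45),
      seg("in_work", 195, work[1], work[2], "sedentary"),
      seg("out_other", 30, work[1] + offset_deg(90), work[2], "light"),
      seg("in_work", 200, work[1], work[2], "light"),
      seg("in_vehicle", commute_min, NA, NA, "light", speed = 45),
      seg("in_home", 120, home[1], home[2], "sedentary"),
      seg("out_home", 25, home[1] + offset_deg(12), home[2], "moderate"),
      seg("in_home", 9999, home[1], home[2], "sedentary"))
  } else {
    errand <- home + c(offset_deg(runif(1, 2000, 6000)) * sin(runif(1, 0, 6.28)),
                       offset_deg(runif(1, 2000, 6000)))
    plan <- dplyr::bind_rows(
      seg("in_home", 95, home[1], home[2], "sedentary"),
      seg("out_home", 30, home[1] + offset_deg(12), home[2], "light"),
      seg("in_home", 90, home[1], home[2], "sedentary"),
      seg("in_vehicle", 14, NA, NA, "light", speed = 40),
      seg("in_other", 90, errand[1], errand[2], "light"),
      seg("in_vehicle", 14, NA, NA, "light", speed = 40),
      seg("in_home", 150, home[1], home[2], "sedentary"),
      seg("out_home", 35, home[1] + offset_deg(12), home[2], "moderate"),
      seg("in_home", 9999, home[1], home[2], "sedentary"))
  }
  used <- cumsum(plan$ticks)
  over <- which(used >= TICKS_PER_DAY)[1]
  plan <- plan[seq_len(over), ]
  plan$ticks[over] <- TICKS_PER_DAY - (if (over > 1) used[over - 1L] else 0L)
  # vehicle segments interpolate between the neighbouring anchors
  for (i in which(plan$me == "in_vehicle")) {
    plan$lat[i] <- plan$lat[i - 1L]
    plan$lon[i] <- plan$lon[i - 1L]
  }
  plan$to_lat <- c(plan$lat[-1L], plan$lat[nrow(plan)])
  plan$to_lon <- c(plan$lon[-1L], plan$lon[nrow(plan)])
  plan
}

realize_track <- function(plan, person, ticks) {
  n <- TICKS_PER_DAY
  seg_id <- rep(seq_len(nrow(plan)), plan$ticks)
  me <- rep(plan$me, plan$ticks)
  lat <- rep(plan$lat, plan$ticks)
  lon <- rep(plan$lon, plan$ticks)
  speed <- rep(plan$speed, plan$ticks)
  # vehicle segments: move linearly from the previous to the next anchor
  for (i in which(plan$me == "in_vehicle")) {
    sel <- which(seg_id == i)
    f <- seq_along(sel) / length(sel)
    lat[sel] <- plan$lat[i] + f * (plan$to_lat[i] - plan$lat[i])
    lon[sel] <- plan$lon[i] + f * (plan$to_lon[i] - plan$lon[i])
    ramp <- pmin(1, pmin(seq_along(sel), rev(seq_along(sel))) / 4)
    d_m <- haversine_m(plan$lat[i], plan$lon[i], plan$to_lat[i], plan$to_lon[i])
    v <- d_m / (length(sel) * 5) * 3.6          # km/h to traverse on time
    speed[sel] <- pmax(v, 15) * ramp + rnorm(length(sel), 0, 1.5)
  }
  indoor <- me %in% c("in_home", "in_work", "in_other")
  outdoor <- me %in% c("out_home", "out_work", "out_other")
  vehicle <- me == "in_vehicle"
  noise_sd <- ifelse(indoor, 9, ifelse(vehicle, 8, 5)) / 111000
  lat <- lat + rnorm(n, 0, noise_sd)
  lon <- lon + rnorm(n, 0, noise_sd)
  speed[!vehicle] <- pmax(
    speed[!vehicle] + ifelse(outdoor[!vehicle], runif(sum(!vehicle), 1, 5),
                             runif(sum(!vehicle), 0, 1.5)), 0)
  pdop <- numeric(n)
  good_leak <- runif(n)
  pdop[indoor] <- ifelse(good_leak[indoor] < 0.05, runif(sum(indoor), 1.5, 3.5),
                         runif(sum(indoor), 4.5, 12))[seq_len(sum(indoor))]
  pdop[!indoor] <- ifelse(good_leak[!indoor] < 0.03,
                          runif(sum(!indoor), 4.5, 8),
                          runif(sum(!indoor), 1, 3))[seq_len(sum(!indoor))]
  valid <- runif(n) > ifelse(indoor, 0.15, 0.02)
  n_sat <- ifelse(indoor, sample(3:6, n, replace = TRUE),
                  sample(7:12, n, replace = TRUE))
  keep <- runif(n) > ifelse(indoor, 0.35, ifelse(vehicle, 0.05, 0.02))
  keep[1] <- TRUE
  tibble::tibble(time = ticks, lat = lat, lon = lon,
                 speed_kmh = pmax(speed, 0), n_sat = as.integer(n_sat),
                 pdop = round(pmax(pdop, 1), 2), valid = valid)[keep, ]
}

realize_accel <- function(plan, date, day_start_hour) {
  pal_per_tick <- rep(plan$pal, plan$ticks)
  pal_per_sec <- rep(pal_per_tick, each = 5L)
  mu <- c(sedentary = 0.7, light = 10, moderate = 42, vigorous = 80)
  counts <- rpois(SECS_PER_DAY, mu[pal_per_sec])
  start <- day_start(date, day_start_hour)
  tibble::tibble(time = start + (0:(SECS_PER_DAY - 1L)),
                 counts = as.integer(counts))
}

#' Generate a complete synthetic study
#'
#' Assembles a full study input bundle from a scenario: cohort and homes,
#' the clinic/lag-day schedule, hourly weather, per-visit questionnaires,
#' lazily generated GPS/accelerometer observations (cached, deterministic
#' per participant-day) and a lazily generated per-day concentration field.
#' The result feeds straight into [run_study()].
#'
#' @param scenario A [study_scenario()].
#' @return An [exposure_study()] bundle.
#' @export
#' @examples
#' \donttest{
#' sc <- study_scenario(seed = 42, n_participants = 2, n_clinic_days = 2,
#'                      n_weeks = 4)
#' study <- generate_study(sc)
#' }
generate_study <- function(scenario) {
  stopifnot(inherits(scenario, "study_scenario"))
  ch <- generate_cohort(scenario)
  clinic <- scenario_clinic_days(scenario)
  schedule <- schedule_study(clinic, scenario$n_lags)
  all_dates <- sort(unique(schedule$date))
  weather <- generate_weather(scenario, all_dates)
  questionnaires <- dplyr::bind_rows(lapply(seq_len(nrow(clinic)), function(i) {
    generate_questionnaire(scenario, clinic$participant[i], clinic$date[i])
  }))
  cohort <- ch$cohort
  obs_cache <- new.env(parent = emptyenv())
  observations <- function(pid, date) {
    key <- obs_key(pid, date)
    if (!exists(key, envir = obs_cache, inherits = FALSE)) {
      person <- cohort[cohort$participant == pid, ]
      obs_cache[[key]] <- generate_participant_day(scenario, person, date)
    }
    obs_cache[[key]]
  }
  field <- function(date) generate_field(scenario, date)
  study <- exposure_study(cohort, ch$homes, schedule, weather,
                          questionnaires, observations, field)
  study$scenario <- scenario
  study
}
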