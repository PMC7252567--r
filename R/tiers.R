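#' Microenvironment-weighted exposure at one tick
#'
#' The 5-s exposure combines the home-indoor and personal-outdoor
#' concentrations according to the occupied microenvironment:
#' indoors at home reads the home indoor concentration; indoors at work or
#' other buildings applies the non-residential building infiltration factor
#' to the personal outdoor concentration; in vehicles applies the vehicle
#' infiltration factor; outdoors reads the personal outdoor concentration
#' unattenuated:
#' `E = ME_in_home * C_in_home + [(ME_in_work + ME_in_other) * F_inf_other_bldg
#'  + ME_in_vehicle * F_inf_vehicle + ME_out] * C_out_personal`.
#'
#' @param me Microenvironment labels (5-level factor; a 7-level factor is
#'   collapsed first), vectorised.
#' @param c_in_home Home indoor concentration at each tick, ug/m^3.
#' @param c_out_personal Personal outdoor concentration at each tick, ug/m^3.
#' @param params One row of [pollutant_params()] (or the table plus
#'   `pollutant`).
#' @param pollutant Pollutant name when `params` is the full table.
#' @return Exposure at each tick, ug/m^3.
#' @export
#' @examples
#' p <- pollutant_params()
#' exposure_tick(factor("in_vehicle", levels = microenv_levels(5)),
#'               c_in_home = 0, c_out_personal = 1, p, "pm25")   # 0.44
exposure_tick <- function(me, c_in_home, c_out_personal,
                          params = pollutant_params(), pollutant = NULL) {
  pr <- resolve_params(params, pollutant)
  stopifnot(is.factor(me))
  if (identical(levels(me), ME7_LEVELS)) me <- collapse_microenv(me)
  if (!identical(levels(me), ME5_LEVELS)) {
    abort("`me` must use the 5- or 7-level microenvironment labels")
  }
  if (anyNA(me)) abort("`me` contains unlabelled ticks (one-hot violated)")
  if (any(c_in_home < 0) || any(c_out_personal < 0)) {
    abort("concentrations must be >= 0")
  }
  mult <- c(NA, pr$f_inf_other_bldg, pr$f_inf_other_bldg,
            pr$f_inf_vehicle, 1)[unclass(me)]
  out <- mult * c_out_personal
  at_home <- unclass(me) == 1L
  out[at_home] <- rep_len(c_in_home, length(me))[at_home]
  out
}

#' Per-microenvironment exposure split at one tick
#'
#' Splits the tick exposure of [exposure_tick()] over the seven
#' microenvironments: for each tick only the occupied microenvironment's
#' column is non-zero, and the row sum equals the total exposure.
#'
#' @param me 7-level microenvironment factor.
#' @inheritParams exposure_tick
#' @return Numeric matrix `length(me)` x 7 with columns named by
#'   `microenv_levels()`.
#' @export
exposure_by_me <- function(me, c_in_home, c_out_personal,
                           params = pollutant_params(), pollutant = NULL) {
  stopifnot(is.factor(me), identical(levels(me), ME7_LEVELS))
  e <- exposure_tick(me, c_in_home, c_out_personal, params, pollutant)
  out <- matrix(0, length(me), length(ME7_LEVELS),
                dimnames = list(NULL, ME7_LEVELS))
  out[cbind(seq_along(me), unclass(me))] <- e
  out
}

#' Inhaled dose increment at one tick
#'
#' The 5-s inhaled dose in microenvironment i is
#' `D_i = E_i * MV * AT / BSA`, mass inhaled over the timestep normalised by
#' body surface area; `AT` is exactly 5/60 min.
#'
#' @param e_by_me Per-microenvironment exposures: a vector of length 7 or a
#'   matrix with 7 columns (ug/m^3), as from [exposure_by_me()].
#' @param mv Minute ventilation, m^3/min (>= 0).
#' @param bsa Body surface area, m^2 (> 0).
#' @param at Timestep in minutes; default 5/60.
#' @return Dose increments, same shape as `e_by_me`, ug/m^2.
#' @export
#' @examples
#' dose_tick(c(10, 0, 0, 0, 0, 0, 0), mv = 0.012, bsa = 2)
dose_tick <- function(e_by_me, mv, bsa, at = 5 / 60) {
  if (any(bsa <= 0)) abort("`bsa` must be > 0")
  if (any(mv < 0)) abort("`mv` must be >= 0")
  e_by_me * (mv * at / bsa)
}

#' Assemble the five tier metrics for one participant-day
#'
#' Reduces the aligned series of one participant-day, pollutant and
#' component to a one-row tier record: 24-h mean home outdoor concentration
#' (tier 1) and home indoor concentration (tier 2) from the hourly series;
#' 24-h mean personal outdoor concentration (tier 3) and exposure (tier 4)
#' from the 17,280 5-s ticks; and the 24-h accumulated inhaled dose
#' (tier 5) with its per-microenvironment breakdown, plus minutes spent in
#' each of the seven microenvironments.
#'
#' @param ticks Tibble with 17,280 rows: `time`, `me` (7-level factor),
#'   `c_out_personal` (ug/m^3), `mv` (m^3/min).
#' @param hourly Tibble with 24 rows: `time`, `c_out_home`, `c_in_home`.
#' @param participant One-row tibble: `participant`, `height_cm`,
#'   `weight_kg`.
#' @param pollutant,component Which pollutant / source component the
#'   concentration series describe.
#' @param params [pollutant_params()] table.
#' @param imputed Were the day's inputs lag-day copies?
#' @param date Participant-day date; default inferred from `ticks`.
#' @return One-row tibble (a tier record): identifiers, `tier1_out_home`,
#'   `tier2_in_home`, `tier3_out_personal`, `tier4_exposure` (ug/m^3),
#'   `tier5_dose` (ug/m^2), `dose_<me>` and `time_<me>` for the seven
#'   microenvironments, and `imputed`.
#' @export
daily_metrics <- function(ticks, hourly, participant, pollutant, component,
                          params = pollutant_params(), imputed = FALSE,
                          date = NULL) {
  pollutant <- match.arg(pollutant, POLLUTANTS)
  component <- match.arg(component, COMPONENTS)
  stopifnot(is.data.frame(ticks), is.data.frame(hourly))
  date <- date %||% window_date(ticks$time[1])
  want_ticks <- day_ticks(date)
  if (nrow(ticks) != TICKS_PER_DAY || !isTRUE(all(ticks$time == want_ticks))) {
    abort(paste0("tick series must cover ",
                 format(want_ticks[1], "%Y-%m-%d %H:%M"), " to ",
                 format(want_ticks[TICKS_PER_DAY] + 5, "%Y-%m-%d %H:%M"),
                 " at 5-s cadence"))
  }
  want_hours <- day_hours(date)
  if (nrow(hourly) != 24L || !isTRUE(all(hourly$time == want_hours))) {
    abort("hourly series must cover the same 24-h window")
  }
  pr <- params_for(params, pollutant)
  c_in_tick <- rep(hourly$c_in_home, each = 720L)
  e_me <- exposure_by_me(ticks$me, c_in_tick, ticks$c_out_personal, pr)
  bsa <- body_surface_area(participant$height_cm, participant$weight_kg)
  d_me <- dose_tick(e_me, ticks$mv, bsa)
  dose_by_me <- colSums(d_me)
  time_by_me <- tabulate(unclass(ticks$me), length(ME7_LEVELS)) * 5 / 60
  out <- tibble::tibble(
    participant = as.character(participant$participant),
    date = as.Date(date), pollutant = pollutant, component = component,
    tier1_out_home = mean(hourly$c_out_home),
    tier2_in_home = mean(hourly$c_in_home),
    tier3_out_personal = mean(ticks$c_out_personal),
    tier4_exposure = mean(rowSums(e_me)),
    tier5_dose = sum(dose_by_me),
    imputed = isTRUE(imputed)
  )
  out[paste0("dose_", ME7_LEVELS)] <- as.list(dose_by_me)
  out[paste0("time_", ME7_LEVELS)] <- as.list(time_by_me)
  out
}

#' Run the full tiered exposure pipeline over a study
#'
#' Produces one tier record per scheduled participant-day, pollutant and
#' component. For each clinic visit the observed day's GPS track is
#' classified into microenvironments, activity counts are converted to
#' physical-activity levels (with the in-vehicle override) and minute
#' ventilation, and the track is matched to the concentration field; each
#' of the visit's lag days reuses the observed day's locations, labels and
#' counts (with the weekend work-to-home replacement) against that day's
#' own concentrations, weather and air exchange rate. A clinic day with
#' `n_lags = 5` therefore contributes six participant-days; days shared by
#' several visits are counted with multiplicity.
#'
#' @param study A study input bundle from [exposure_study()] or
#'   [generate_study()].
#' @param params [pollutant_params()] table.
#' @param nmv NMV lookup table, see [default_nmv_table()].
#' @param day_start_hour Hour each participant-day starts (default 8).
#' @param verbose Print per-visit progress.
#' @return A tibble of class `tier_records`, one row per participant-day x
#'   pollutant x component (see [daily_metrics()] for columns).
#' @export
run_study <- function(study, params = pollutant_params(),
                      nmv = default_nmv_table(), day_start_hour = DAY_START_HOUR,
                      verbose = FALSE) {
  stopifnot(inherits(study, "exposure_study"))
  validate_pollutant_params(params)
  validate_nmv_table(nmv)
  sched <- study$schedule
  visits <- dplyr::distinct(sched, .data$participant, .data$clinic_date)
  get_field <- field_accessor(study$field)
  out <- vector("list", nrow(visits))
  for (v in seq_len(nrow(visits))) {
    pid <- visits$participant[v]
    cdate <- visits$clinic_date[v]
    out[[v]] <- tryCatch(
      run_visit(study, pid, cdate,
                sched[sched$participant == pid & sched$clinic_date == cdate, ],
                get_field, params, nmv, day_start_hour),
      error = function(e) {
        abort(paste0("participant ", pid, ", clinic day ",
                     as.character(cdate), ": ", conditionMessage(e)))
      })
    if (verbose) {
      message("visit ", v, "/", nrow(visits), ": ", pid, " ",
              as.character(cdate))
    }
  }
  records <- dplyr::bind_rows(out)
  records <- new_tier_records(records,
                              n_participant_days = nrow(sched),
                              n_unique_days = nrow(dplyr::distinct(
                                sched, .data$participant, .data$date)))
  records
}

# one clinic visit: observed day + its lag days
run_visit <- function(study, pid, cdate, days, get_field, params, nmv,
                      day_start_hour) {
  person <- study$cohort[study$cohort$participant == pid, ]
  if (nrow(person) != 1L) abort("participant not in cohort")
  home <- study$homes[study$homes$home_id == person$home_id, ]
  if (nrow(home) != 1L) abort("home not in homes table")
  obs <- get_observation(study, pid, cdate)
  places <- place_geometry(person$home_lat, person$home_lon,
                           person$work_lat, person$work_lon)
  me_obs <- classify_microenv(obs$track, places, cdate, day_start_hour)
  pos <- track_tick_positions(obs$track, cdate, day_start_hour)
  cpm <- rolling_cpm(obs$accel, date = cdate, day_start_hour = day_start_hour)
  pal <- vehicle_override(classify_pal(cpm$cpm), me_obs$me)
  mv <- minute_ventilation(pal, person$age, person$sex, person$weight_kg, nmv)
  bsa <- body_surface_area(person$height_cm, person$weight_kg)

  fld0 <- get_field(cdate)
  centroids <- fld0$centroids
  cidx_obs <- unname(nearest_centroid(pos$lat, pos$lon, centroids))
  home_cidx <- unname(nearest_centroid(person$home_lat, person$home_lon,
                                       centroids))
  at_work <- if (!is.null(places$work)) {
    haversine_m(pos$lat, pos$lon, places$work["lat"], places$work["lon"]) <=
      places$place_radius
  } else {
    rep(FALSE, TICKS_PER_DAY)
  }
  quest <- study$questionnaires[
    study$questionnaires$participant == pid &
      study$questionnaires$date == cdate, ]
  if (nrow(quest) != 1L) abort("no questionnaire for the clinic day")

  me7_idx_obs <- unclass(me_obs$me)
  hour_slot <- (seq_len(TICKS_PER_DAY) - 1L) %/% 720L + 1L
  combos <- tidyr::expand_grid(pollutant = POLLUTANTS, component = COMPONENTS)
  day_frames <- vector("list", nrow(days))
  for (di in seq_len(nrow(days))) {
    d <- days$date[di]
    imputed <- !days$is_clinic[di]
    weekend <- is_weekend(d)
    me7_idx <- me7_idx_obs
    cidx <- cidx_obs
    if (imputed && weekend) {
      me7_idx[me7_idx == 2L] <- 1L        # in_work  -> in_home
      me7_idx[me7_idx == 6L] <- 5L        # out_work -> out_home
      cidx[at_work] <- home_cidx
    }
    fld <- get_field(d)
    hidx24 <- match(day_hours(d, day_start_hour), fld$hours)
    if (anyNA(hidx24)) {
      abort(paste0("field does not cover day ", as.character(d)))
    }
    quest_d <- quest
    quest_d$date <- d
    aer <- hourly_aer(study$weather, home, quest_d, day_start_hour)$aer

    frame <- day_records_fast(
      fld, cidx, hidx24, hour_slot, me7_idx, mv, bsa, aer,
      home_cidx, combos, params,
      participant = pid, date = d, imputed = imputed)
    frame$clinic_date <- as.Date(cdate)
    day_frames[[di]] <- frame
  }
  dplyr::bind_rows(day_frames)
}

# vectorised assembly of the 12 pollutant x component records for one day
day_records_fast <- function(fld, cidx, hidx24, hour_slot, me7_idx, mv, bsa,
                             aer, home_cidx, combos, params,
                             participant, date, imputed) {
  nc <- nrow(fld$centroids)
  nh <- length(fld$hours)
  np <- length(POLLUTANTS)
  me5_idx <- c(1L, 2L, 3L, 4L, 5L, 5L, 5L)[me7_idx]
  time_by_me <- tabulate(me7_idx, 7L) * 5 / 60
  hidx_tick <- hidx24[hour_slot]
  n_combo <- nrow(combos)
  rows <- vector("list", n_combo)
  mv_at_bsa <- mv * (5 / 60) / bsa
  for (ci in seq_len(n_combo)) {
    p <- combos$pollutant[ci]
    cc <- combos$component[ci]
    pi <- match(p, POLLUTANTS)
    cci <- match(cc, COMPONENTS)
    pr <- params[params$pollutant == p, ]
    base <- (cci - 1L) * nc * nh * np + (pi - 1L) * nc * nh
    tier1_h <- fld$values[base + (hidx24 - 1L) * nc + home_cidx]
    c_in_h <- indoor_series(
      tibble::tibble(time = seq_len(24L), value = tier1_h),
      tibble::tibble(time = seq_len(24L), aer = aer), pr)$value
    cop <- fld$values[base + (hidx_tick - 1L) * nc + cidx]
    mult <- c(NA, pr$f_inf_other_bldg, pr$f_inf_other_bldg,
              pr$f_inf_vehicle, 1)[me5_idx]
    e <- mult * cop
    at_home <- me5_idx == 1L
    e[at_home] <- c_in_h[hour_slot[at_home]]
    d_inc <- e * mv_at_bsa
    rs <- rowsum(d_inc, me7_idx)
    dose_by_me <- numeric(7L)
    dose_by_me[as.integer(rownames(rs))] <- rs[, 1]
    row <- tibble::tibble(
      participant = participant, date = as.Date(date),
      pollutant = p, component = cc,
      tier1_out_home = mean(tier1_h), tier2_in_home = mean(c_in_h),
      tier3_out_personal = mean(cop), tier4_exposure = mean(e),
      tier5_dose = sum(d_inc), imputed = imputed)
    row[paste0("dose_", ME7_LEVELS)] <- as.list(dose_by_me)
    row[paste0("time_", ME7_LEVELS)] <- as.list(time_by_me)
    rows[[ci]] <- row
  }
  dplyr::bind_rows(rows)
}

get_observation <- function(study, pid, cdate) {
  obs <- study$observations
  o <- if (is.function(obs)) {
    obs(pid, cdate)
  } else {
    obs[[obs_key(pid, cdate)]]
  }
  if (is.null(o)) abort("no GPS/accelerometer observation for the clinic day")
  o
}

obs_key <- function(pid, date) paste(pid, as.character(as.Date(date)), sep = "|")

field_accessor <- function(field) {
  if (inherits(field, "concentration_field")) {
    function(date) field
  } else if (is.function(field)) {
    cache <- new.env(parent = emptyenv())
    function(date) {
      key <- as.character(as.Date(date))
      if (!exists(key, envir = cache, inherits = FALSE)) {
        cache[[key]] <- field(date)
      }
      cache[[key]]
    }
  } else {
    abort("`study$field` must be a concentration_field or a function(date)")
  }
}

#' Bundle study inputs for the pipeline
#'
#' Collects the tables and per-visit observations [run_study()] consumes.
#' `observations` maps a clinic visit to its logger data: either a named
#' list keyed `"<participant>|<date>"` with elements `track` and `accel`,
#' or a function `(participant, date)` returning such a list. `field` is a
#' [concentration_field()] covering every scheduled day, or a function
#' `(date)` returning the day's field (centroids must be identical across
#' days).
#'
#' @param cohort Tibble: `participant`, `age`, `sex`, `height_cm`,
#'   `weight_kg`, `home_id`, `home_lat`, `home_lon`, `work_lat`, `work_lon`
#'   (NA when the participant has no workplace).
#' @param homes Tibble of [home_model()] rows.
#' @param schedule Tibble: `participant`, `date`, `is_clinic`,
#'   `clinic_date` (see [schedule_study()]).
#' @param weather Tibble: `time`, `t_out`, `wind` covering all scheduled
#'   windows.
#' @param questionnaires Tibble: `participant`, `date` (clinic date),
#'   `t_in`, `windows_open`, `doors_open`, `fan_on`.
#' @param observations See description.
#' @param field See description.
#' @return A list of class `exposure_study`.
#' @export
exposure_study <- function(cohort, homes, schedule, weather, questionnaires,
                           observations, field) {
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      abort(paste0(what, " lacks column(s): ", paste(miss, collapse = ", ")))
    }
  }
  need(cohort, c("participant", "age", "sex", "height_cm", "weight_kg",
                 "home_id", "home_lat", "home_lon"), "cohort")
  need(homes, c("home_id", "a_leak", "volume", "k_s", "k_w",
                "openable_area", "fan_flow"), "homes")
  need(schedule, c("participant", "date", "is_clinic", "clinic_date"),
       "schedule")
  need(weather, c("time", "t_out", "wind"), "weather")
  need(questionnaires, c("participant", "date", "t_in", "windows_open",
                         "doors_open", "fan_on"), "questionnaires")
  if (any(cohort$age < 18)) abort("participants must be adults (age >= 18)")
  structure(list(cohort = cohort, homes = homes, schedule = schedule,
                 weather = weather, questionnaires = questionnaires,
                 observations = observations, field = field),
            class = "exposure_study")
}

new_tier_records <- function(df, n_participant_days, n_unique_days) {
  structure(df, class = c("tier_records", class(df)),
            n_participant_days = n_participant_days,
            n_unique_days = n_unique_days)
}
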