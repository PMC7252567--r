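# Readers and writers for the package's CSV dialects. All timestamps are
# serialised ISO-8601 with explicit UTC offset; all files are comma-separated
# UTF-8 with a header row and '.' decimals.

fmt_time <- function(x) format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

read_csv_quiet <- function(path, col_types) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  readr::read_csv(path, col_types = col_types, progress = FALSE)
}

#' Read and write GPS logger tracks
#'
#' The GPS dialect has columns `time` (ISO-8601), `lat`, `lon`, `speed_kmh`,
#' `n_sat`, `pdop`, `valid`. On read, rows are time-sorted and malformed
#' rows — unparseable fields, PDOP below 1 on a valid fix, negative speed —
#' are dropped with a warning giving the count. Writers and readers
#' round-trip exactly.
#'
#' @param path File path.
#' @return `read_gps()`: a validated GPS tibble.
#' @export
read_gps <- function(path) {
  df <- read_csv_quiet(path, readr::cols(
    time = readr::col_datetime(), lat = readr::col_double(),
    lon = readr::col_double(), speed_kmh = readr::col_double(),
    n_sat = readr::col_integer(), pdop = readr::col_double(),
    valid = readr::col_logical()))
  n0 <- nrow(df)
  bad <- is.na(df$time) | is.na(df$valid) |
    (df$valid & (is.na(df$pdop) | df$pdop < 1)) |
    (!is.na(df$speed_kmh) & df$speed_kmh < 0)
  df <- df[!bad, ]
  if (sum(bad) > 0) {
    warn(paste0("dropped ", sum(bad), " malformed row(s) of ", n0,
                " in ", path))
  }
  if (nrow(df) == 0L) abort(paste0("no valid GPS rows in ", path))
  df$time <- study_time(df$time)
  dplyr::arrange(df, .data$time)
}

#' @rdname read_gps
#' @param track GPS tibble to write.
#' @export
write_gps <- function(track, path) {
  out <- track
  out$time <- fmt_time(out$time)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read and write the remaining study tables
#'
#' Plain CSV dialects for hourly weather (`time`, `t_out_c`, `wind_mps`),
#' daily questionnaires (`participant`, `date`, `t_in_c`, `windows_open`,
#' `doors_open`, `fan_on` as 0/1), 1-s accelerometer counts (`time`,
#' `counts`), the NMV lookup (`pal`, `age_lo`, `age_hi`, `sex`,
#' `nmv_lpm_per_kg`) and the long-format concentration field
#' (`centroid_id`, `lat`, `lon`, `time`, `pollutant`, `component`,
#' `conc_ugm3`).
#'
#' @param path File path.
#' @name study_io
#' @return The corresponding tibble (or, for the field, a
#'   [concentration_field()]).
NULL

#' @rdname study_io
#' @export
read_weather <- function(path) {
  df <- read_csv_quiet(path, readr::cols(
    time = readr::col_datetime(), t_out_c = readr::col_double(),
    wind_mps = readr::col_double()))
  tibble::tibble(time = study_time(df$time), t_out = df$t_out_c,
                 wind = df$wind_mps)
}

#' @rdname study_io
#' @param weather Weather tibble (`time`, `t_out`, `wind`).
#' @export
write_weather <- function(weather, path) {
  readr::write_csv(tibble::tibble(time = fmt_time(weather$time),
                                  t_out_c = weather$t_out,
                                  wind_mps = weather$wind),
                   path, progress = FALSE)
  invisible(path)
}

#' @rdname study_io
#' @export
read_questionnaires <- function(path) {
  df <- read_csv_quiet(path, readr::cols(
    participant = readr::col_character(), date = readr::col_date(),
    t_in_c = readr::col_double(), windows_open = readr::col_integer(),
    doors_open = readr::col_integer(), fan_on = readr::col_integer()))
  tibble::tibble(participant = df$participant, date = df$date,
                 t_in = df$t_in_c,
                 windows_open = df$windows_open == 1L,
                 doors_open = df$doors_open == 1L, fan_on = df$fan_on == 1L)
}

#' @rdname study_io
#' @param quests Questionnaire tibble.
#' @export
write_questionnaires <- function(quests, path) {
  readr::write_csv(tibble::tibble(
    participant = quests$participant, date = as.character(quests$date),
    t_in_c = quests$t_in,
    windows_open = as.integer(quests$windows_open),
    doors_open = as.integer(quests$doors_open),
    fan_on = as.integer(quests$fan_on)), path, progress = FALSE)
  invisible(path)
}

#' @rdname study_io
#' @export
read_accel <- function(path) {
  df <- read_csv_quiet(path, readr::cols(time = readr::col_datetime(),
                                         counts = readr::col_integer()))
  if (any(df$counts < 0, na.rm = TRUE)) abort("negative activity counts")
  tibble::tibble(time = study_time(df$time), counts = df$counts)
}

#' @rdname study_io
#' @param accel Accelerometer tibble.
#' @export
write_accel <- function(accel, path) {
  readr::write_csv(tibble::tibble(time = fmt_time(accel$time),
                                  counts = accel$counts),
                   path, progress = FALSE)
  invisible(path)
}

#' @rdname study_io
#' @export
read_nmv_table <- function(path) {
  df <- read_csv_quiet(path, readr::cols(
    pal = readr::col_character(), age_lo = readr::col_double(),
    age_hi = readr::col_double(), sex = readr::col_character(),
    nmv_lpm_per_kg = readr::col_double()))
  validate_nmv_table(df)
  df
}

#' @rdname study_io
#' @param field A [concentration_field()].
#' @export
write_field <- function(field, path) {
  df <- as_tibble(field)
  df$time <- fmt_time(df$time)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname study_io
#' @export
read_field <- function(path) {
  df <- read_csv_quiet(path, readr::cols(
    centroid_id = readr::col_character(), lat = readr::col_double(),
    lon = readr::col_double(), time = readr::col_datetime(),
    pollutant = readr::col_character(), component = readr::col_character(),
    conc_ugm3 = readr::col_double()))
  centroids <- dplyr::distinct(df, .data$centroid_id, .data$lat, .data$lon)
  centroids <- dplyr::arrange(centroids, .data$centroid_id)
  hours <- sort(unique(study_time(df$time)))
  values <- array(NA_real_, dim = c(nrow(centroids), length(hours),
                                    length(POLLUTANTS), length(COMPONENTS)))
  idx <- cbind(match(df$centroid_id, centroids$centroid_id),
               match(study_time(df$time), hours),
               match(df$pollutant, POLLUTANTS),
               match(df$component, COMPONENTS))
  if (anyNA(idx)) abort("field file has unknown pollutant/component labels")
  values[idx] <- df$conc_ugm3
  if (anyNA(values)) abort("field file does not cover the full grid")
  concentration_field(centroids, hours, values)
}

#' Read and write tier-record tables
#'
#' One row per participant-day, pollutant and component with the five tier
#' metrics, the per-microenvironment dose and time breakdowns and the
#' imputation flag, as produced by [run_study()].
#'
#' @param path File path.
#' @param records A `tier_records` tibble.
#' @export
write_tier_records <- function(records, path) {
  out <- records
  out$date <- as.character(out$date)
  if ("clinic_date" %in% names(out)) {
    out$clinic_date <- as.character(out$clinic_date)
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_tier_records
#' @export
read_tier_records <- function(path) {
  df <- read_csv_quiet(path, readr::cols(
    participant = readr::col_character(), date = readr::col_date(),
    clinic_date = readr::col_date(),
    pollutant = readr::col_character(), component = readr::col_character(),
    imputed = readr::col_logical(), .default = readr::col_double()))
  new_tier_records(df,
                   n_participant_days = nrow(dplyr::distinct(
                     df, .data$participant, .data$date)),
                   n_unique_days = nrow(dplyr::distinct(
                     df, .data$participant, .data$date)))
}

#' Audit the invariants of a tier-record table
#'
#' Checks every record for: non-negative metrics; the per-microenvironment
#' doses summing to the total dose (1e-9 relative); the per-microenvironment
#' minutes summing to 1440; and, per participant-day and pollutant,
#' background + on-road equalling total for every tier metric (1e-6
#' relative).
#'
#' @param records A `tier_records` tibble (e.g. from [read_tier_records()]).
#' @return A tibble of violations (zero rows when the table is clean) with
#'   columns `participant`, `date`, `pollutant`, `component`, `check`,
#'   `detail`.
#' @export
check_tier_records <- function(records) {
  dose_cols <- paste0("dose_", ME7_LEVELS)
  time_cols <- paste0("time_", ME7_LEVELS)
  probs <- list()
  flag <- function(rows, check, detail) {
    if (!any(rows)) return(NULL)
    tibble::tibble(participant = records$participant[rows],
                   date = records$date[rows],
                   pollutant = records$pollutant[rows],
                   component = records$component[rows],
                   check = check, detail = detail)
  }
  num_cols <- c("tier1_out_home", "tier2_in_home", "tier3_out_personal",
                "tier4_exposure", "tier5_dose", dose_cols, time_cols)
  neg <- rowSums(as.matrix(records[num_cols]) < -1e-12) > 0
  probs$neg <- flag(neg, "nonnegative", "negative metric value")
  dsum <- rowSums(as.matrix(records[dose_cols]))
  derr <- abs(dsum - records$tier5_dose) >
    1e-9 * abs(records$tier5_dose) + 1e-12
  probs$dose <- flag(derr, "dose_conservation",
                     "per-microenvironment doses do not sum to the total")
  tsum <- rowSums(as.matrix(records[time_cols]))
  terr <- abs(tsum - 1440) > 1e-9
  probs$time <- flag(terr, "time_total", "minutes do not sum to 1440")
  keys <- intersect(c("participant", "date", "clinic_date"), names(records))
  conc_cols <- setdiff(num_cols, time_cols)   # time is shared, not additive
  wide <- records %>%
    dplyr::select(dplyr::all_of(keys), "pollutant", "component",
                  dplyr::all_of(num_cols)) %>%
    tidyr::pivot_longer(dplyr::all_of(num_cols), names_to = "metric") %>%
    tidyr::pivot_wider(names_from = "component", values_from = "value")
  if (all(c("background", "onroad", "total") %in% names(wide))) {
    is_time <- wide$metric %in% time_cols
    bad <- !is_time &
      abs(wide$background + wide$onroad - wide$total) >
        1e-6 * abs(wide$total) + 1e-9
    bad_time <- is_time & (wide$background != wide$total |
                             wide$onroad != wide$total)
    if (any(bad | bad_time)) {
      sel <- bad | bad_time
      probs$add <- tibble::tibble(
        participant = wide$participant[sel], date = wide$date[sel],
        pollutant = wide$pollutant[sel], component = "total",
        check = ifelse(bad_time[sel], "time_consistency",
                       "component_additivity"),
        detail = paste0(ifelse(bad_time[sel],
                               "time differs across components for ",
                               "background + onroad != total for "),
                        wide$metric[sel]))
    }
  }
  empty <- tibble::tibble(participant = character(),
                          date = as.Date(character()),
                          pollutant = character(), component = character(),
                          check = character(), detail = character())
  dplyr::bind_rows(c(list(empty), probs))
}

#' Read a run configuration file
#'
#' YAML run configuration: a `pollutants:` section with per-pollutant
#' parameter overrides (`penetration`, `removal_rate`, `f_inf_other_bldg`,
#' `f_inf_vehicle`), a `microtrac:` section of classifier thresholds, and
#' scalar options (`day_start_hour`). Unknown top-level keys are rejected.
#'
#' @param path YAML file path.
#' @return A list with elements `params` (a [pollutant_params()] table),
#'   `microtrac` (threshold list) and `day_start_hour`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  cfg <- yaml::read_yaml(path)
  known <- c("pollutants", "microtrac", "day_start_hour")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    abort(paste0("unknown config key(s): ", paste(bad, collapse = ", ")))
  }
  list(params = pollutant_params(overrides = cfg$pollutants),
       microtrac = cfg$microtrac %||% list(),
       day_start_hour = cfg$day_start_hour %||% DAY_START_HOUR)
}
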