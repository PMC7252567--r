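#' Residential air-exchange-rate model inputs
#'
#' `home_model()` describes one residence for the extended
#' Lawrence-Berkeley-Laboratory (LBL) air-exchange-rate model: effective
#' leakage area, interior volume, stack and wind coefficients (defaulted
#' from the number of stories and a 1--5 shielding class), the openable
#' window/door area used for natural ventilation, and the rated window-fan
#' flow used for mechanical ventilation.
#'
#' The stack coefficient `k_s` (units (m/s)^2/K) scales the indoor-outdoor
#' temperature difference and grows with building height; the wind
#' coefficient `k_w` (dimensionless, applied to U^2) shrinks as the home is
#' more sheltered from wind. The built-in lookups are configurable
#' stand-ins in the classic LBL convention, not fitted values.
#'
#' @param home_id Identifier.
#' @param a_leak Effective air leakage area, m^2 (> 0).
#' @param volume Interior volume, m^3 (> 0).
#' @param stories Number of stories (1, 2 or 3); sets `k_s` when `k_s` is NULL.
#' @param shielding_class Wind shielding class 1 (exposed) .. 5 (heavily
#'   shielded); sets `k_w` when `k_w` is NULL.
#' @param k_s,k_w Optional explicit coefficients overriding the lookups.
#' @param openable_area Total openable window/door area, m^2 (>= 0).
#' @param fan_flow Rated window-fan airflow, m^3/h (>= 0).
#' @return A one-row tibble of class `home_model`.
#' @export
#' @examples
#' home_model("h1", a_leak = 0.05, volume = 350)
home_model <- function(home_id, a_leak, volume, stories = 1L,
                       shielding_class = 3L, k_s = NULL, k_w = NULL,
                       openable_area = 0.5, fan_flow = 0) {
  k_s <- k_s %||% stack_coefficient(stories)
  k_w <- k_w %||% wind_coefficient(shielding_class)
  home <- tibble::tibble(
    home_id = as.character(home_id), a_leak = a_leak, volume = volume,
    stories = as.integer(stories),
    shielding_class = as.integer(shielding_class),
    k_s = k_s, k_w = k_w,
    openable_area = openable_area, fan_flow = fan_flow
  )
  if (any(home$a_leak <= 0) || any(home$volume <= 0)) {
    abort("`a_leak` and `volume` must be > 0")
  }
  if (any(home$k_s < 0) || any(home$k_w < 0) ||
      any(home$openable_area < 0) || any(home$fan_flow < 0)) {
    abort("`k_s`, `k_w`, `openable_area`, `fan_flow` must be >= 0")
  }
  class(home) <- c("home_model", class(home))
  home
}

#' @rdname home_model
#' @export
stack_coefficient <- function(stories) {
  ks <- c(`1` = 0.0145, `2` = 0.0290, `3` = 0.0435)
  out <- ks[as.character(as.integer(stories))]
  if (any(is.na(out))) abort("`stories` must be 1, 2 or 3")
  unname(out)
}

#' @rdname home_model
#' @export
wind_coefficient <- function(shielding_class) {
  # squared terrain/shielding factors in the LBL lineage: class 1 = exposed
  kw <- c(0.1156, 0.0900, 0.0625, 0.0361, 0.0121)
  cls <- as.integer(shielding_class)
  if (any(is.na(cls)) || any(cls < 1L) || any(cls > 5L)) {
    abort("`shielding_class` must be an integer in 1..5")
  }
  kw[cls]
}

#' Airflow components of the air-exchange-rate model
#'
#' `leakage_flow()` is the LBL leakage airflow through unintentional
#' envelope openings, `Q_leak = A_leak * sqrt(k_s * |T_in - T_out| +
#' k_w * U^2)` (computed in m^3/s and returned in m^3/h). `natural_flow()`
#' is the natural-ventilation airflow through reported open windows/doors,
#' modeled as orifice flow through the openable area with discharge
#' coefficient `discharge_coef`, driven by the same stack and wind pressure
#' terms. `total_flow()` combines leakage, natural and mechanical airflows
#' in quadrature: `Q_total = sqrt(Q_leak^2 + Q_nat^2 + Q_mech^2)`.
#'
#' @param a_leak Effective leakage area, m^2.
#' @param k_s Stack coefficient, (m/s)^2/K.
#' @param k_w Wind coefficient, dimensionless.
#' @param t_in,t_out Indoor / outdoor temperature, degrees C.
#' @param wind Wind speed U, m/s.
#' @return Airflow in m^3/h (vectorised).
#' @export
#' @examples
#' leakage_flow(0.05, k_s = 1.5e-4, k_w = 1.0e-4, t_in = 20, t_out = 0, wind = 4)
#' total_flow(3, 4, 0)
leakage_flow <- function(a_leak, k_s, k_w, t_in, t_out, wind) {
  if (any(wind < 0)) abort("`wind` must be >= 0")
  q_ms <- a_leak * sqrt(k_s * abs(t_in - t_out) + k_w * wind^2)
  3600 * q_ms
}

#' @rdname leakage_flow
#' @param openable_area Openable window/door area, m^2.
#' @param discharge_coef Orifice discharge coefficient (default 0.6).
#' @export
natural_flow <- function(openable_area, k_s, k_w, t_in, t_out, wind,
                         discharge_coef = 0.6) {
  leakage_flow(discharge_coef * openable_area, k_s, k_w, t_in, t_out, wind)
}

#' @rdname leakage_flow
#' @param q_leak,q_nat,q_mech Leakage, natural and mechanical airflows, m^3/h.
#' @export
total_flow <- function(q_leak, q_nat, q_mech) {
  if (any(q_leak < 0) || any(q_nat < 0) || any(q_mech < 0)) {
    abort("airflows must be >= 0")
  }
  sqrt(q_leak^2 + q_nat^2 + q_mech^2)
}

#' Hourly residential air exchange rate
#'
#' Computes the hourly air exchange rate (AER, h^-1) for one home-day from
#' hourly weather and the day's occupant-behaviour questionnaire. Per hour:
#' leakage flow always applies; natural ventilation applies when windows or
#' doors were reported open; mechanical ventilation (the rated fan flow)
#' applies when a window fan was reported operating. The three flows combine
#' in quadrature and AER = Q_total / volume. The indoor temperature is held
#' at the questionnaire value for the whole day; the weather row stamped `h`
#' represents the hour `[h, h + 1)`.
#'
#' @param weather Tibble with columns `time` (hourly POSIXct), `t_out`
#'   (deg C), `wind` (m/s), covering the 24-h window of `quest$date`
#'   starting at `day_start_hour`.
#' @param home A [home_model()].
#' @param quest One questionnaire row: `date`, `t_in`, `windows_open`,
#'   `doors_open`, `fan_on`.
#' @param day_start_hour Hour the participant-day starts (default 8).
#' @return Tibble with columns `time`, `q_leak`, `q_nat`, `q_mech` (m^3/h)
#'   and `aer` (h^-1), 24 rows.
#' @export
hourly_aer <- function(weather, home, quest, day_start_hour = DAY_START_HOUR) {
  stopifnot(is.data.frame(weather), nrow(quest) == 1L)
  hours <- day_hours(quest$date, day_start_hour)
  idx <- match(hours, weather$time)
  if (anyNA(idx)) {
    abort(paste0("weather is missing hour(s): ",
                 paste(format(hours[is.na(idx)], "%Y-%m-%d %H:%M"),
                       collapse = ", ")))
  }
  wx <- weather[idx, ]
  if (any(!is.finite(wx$t_out)) || any(!is.finite(wx$wind))) {
    abort("weather values must be finite")
  }
  q_leak <- leakage_flow(home$a_leak, home$k_s, home$k_w,
                         quest$t_in, wx$t_out, wx$wind)
  open_house <- isTRUE(as.logical(quest$windows_open)) ||
    isTRUE(as.logical(quest$doors_open))
  q_nat <- if (open_house) {
    natural_flow(home$openable_area, home$k_s, home$k_w,
                 quest$t_in, wx$t_out, wx$wind)
  } else {
    rep(0, 24L)
  }
  q_mech <- if (isTRUE(as.logical(quest$fan_on))) {
    rep(home$fan_flow, 24L)
  } else {
    rep(0, 24L)
  }
  tibble::tibble(
    time = hours, q_leak = q_leak, q_nat = q_nat, q_mech = q_mech,
    aer = total_flow(q_leak, q_nat, q_mech) / home$volume
  )
}
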