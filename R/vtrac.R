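#' Rolling activity counts per minute
#'
#' For each evaluation time t (by default every 5-s tick of the day), sums
#' the 1-s accelerometer activity counts over the trailing minute (t - 60 s,
#' t], giving counts per minute (cpm). History before the start of the day
#' is padded with zeros, so the first minute is biased toward sedentary
#' only at day start.
#'
#' @param accel Tibble `time` (POSIXct, 1-s epochs), `counts` (non-negative).
#' @param at Optional POSIXct evaluation times; default the day's 5-s ticks.
#' @param date Participant-day date; default inferred from the first epoch.
#' @param day_start_hour Hour the day window starts.
#' @return Tibble `time`, `cpm`.
#' @export
rolling_cpm <- function(accel, at = NULL, date = NULL,
                        day_start_hour = DAY_START_HOUR) {
  stopifnot(is.data.frame(accel))
  if (nrow(accel) == 0L) abort("empty accelerometer series")
  if (any(accel$counts < 0) || any(!is.finite(accel$counts))) {
    abort("`counts` must be finite and >= 0")
  }
  date <- date %||% window_date(accel$time[1], day_start_hour)
  start <- day_start(date, day_start_hour)
  off <- round(as.numeric(accel$time) - as.numeric(start))
  if (any(off < 0) || any(off >= SECS_PER_DAY)) {
    abort("accelerometer samples outside the participant-day window")
  }
  sec <- numeric(SECS_PER_DAY)
  sec[off + 1L] <- accel$counts        # second s covers (s, s+1]
  cs <- c(0, cumsum(sec))
  at <- at %||% day_ticks(date, day_start_hour)
  s <- round(as.numeric(at) - as.numeric(start))
  if (any(s < 0) || any(s > SECS_PER_DAY)) {
    abort("evaluation times outside the participant-day window")
  }
  cpm <- cs[pmin(s, SECS_PER_DAY) + 1L] - cs[pmax(s - 60L, 0L) + 1L]
  tibble::tibble(time = at, cpm = cpm)
}

#' Classify physical activity intensity from counts per minute
#'
#' Maps Actical-style counts per minute to the four physical-activity
#' intensity levels with the standard cut-points: sedentary below 100 cpm,
#' light 100-1534, moderate 1535-3961, vigorous 3962 and above. Boundary
#' values belong to the upper class.
#'
#' @param cpm Counts per minute (>= 0, vectorised).
#' @return Ordered factor with levels sedentary < light < moderate <
#'   vigorous.
#' @export
#' @examples
#' classify_pal(c(99, 100, 1535, 3962))
classify_pal <- function(cpm) {
  if (any(cpm < 0) || any(!is.finite(cpm))) {
    abort("`cpm` must be finite and >= 0")
  }
  cut(cpm, breaks = c(-Inf, 100, 1535, 3962, Inf), labels = PAL_LEVELS,
      right = FALSE, ordered_result = TRUE)
}

#' In-vehicle override of the activity level
#'
#' Accelerometers pick up vehicle vibration while the rider sits still, so
#' any tick whose time-matched microenvironment is `in_vehicle` is forced to
#' sedentary; all other ticks are unchanged.
#'
#' @param pal Ordered PAL factor (from [classify_pal()]).
#' @param me Microenvironment labels (5- or 7-level factor), same length.
#' @return PAL factor with the override applied.
#' @export
vehicle_override <- function(pal, me) {
  stopifnot(length(pal) == length(me))
  pal[as.character(me) == "in_vehicle"] <- "sedentary"
  pal
}

#' Normalised minute ventilation table
#'
#' Inhaled minute ventilation per kilogram of body weight (NMV, L/min/kg) by
#' physical-activity level, age band and sex. The shipped default covers the
#' 4 PAL x 14 age bands x 2 sexes grid with synthetic placeholder medians
#' (plausible magnitudes, monotone in PAL, higher per-kg for children,
#' slightly declining in old age); studies should substitute their preferred
#' literature table via this same format, and all package tests inject their
#' own table.
#'
#' @return Tibble `pal`, `age_lo`, `age_hi`, `sex`, `nmv_lpm_per_kg`
#'   (112 rows). Age bands are half-open `[age_lo, age_hi)`.
#' @export
default_nmv_table <- function() {
  edges <- c(0, 1, 2, 3, 6, 11, 16, 21, 31, 41, 51, 61, 71, 81, Inf)
  base <- c(sedentary = 0.10, light = 0.16, moderate = 0.30, vigorous = 0.55)
  # per-kg ventilation is highest in early childhood, ~1 for adults
  age_mult <- c(2.6, 2.3, 2.1, 1.8, 1.5, 1.2, 1.05, 1.0, 0.98, 0.96,
                0.94, 0.92, 0.88, 0.84)
  sex_mult <- c(male = 0.97, female = 1.03)
  grid <- tidyr::expand_grid(
    pal = PAL_LEVELS, band = seq_len(14L), sex = c("male", "female"))
  tibble::tibble(
    pal = grid$pal,
    age_lo = edges[grid$band],
    age_hi = edges[grid$band + 1L],
    sex = grid$sex,
    nmv_lpm_per_kg = round(unname(
      base[grid$pal] * age_mult[grid$band] * sex_mult[grid$sex]), 4)
  )
}

validate_nmv_table <- function(nmv) {
  need <- c("pal", "age_lo", "age_hi", "sex", "nmv_lpm_per_kg")
  miss <- setdiff(need, names(nmv))
  if (length(miss)) {
    abort(paste0("NMV table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (any(nmv$nmv_lpm_per_kg <= 0)) abort("NMV values must be > 0")
  invisible(nmv)
}

#' Inhaled minute ventilation
#'
#' Looks up the normalised minute ventilation for the participant's activity
#' level, age band and sex and scales it by body weight:
#' `MV = NMV * BW / 1000` (L/min to m^3/min).
#'
#' @param pal PAL level(s) (character or factor).
#' @param age Age in years.
#' @param sex `"male"` or `"female"`.
#' @param weight_kg Body weight, kg.
#' @param nmv NMV table in the format of [default_nmv_table()].
#' @return Minute ventilation in m^3/min (vectorised over `pal`).
#' @export
#' @examples
#' minute_ventilation("light", age = 55, sex = "male", weight_kg = 70)
minute_ventilation <- function(pal, age, sex, weight_kg,
                               nmv = default_nmv_table()) {
  validate_nmv_table(nmv)
  sex <- match.arg(sex, c("male", "female"))
  band <- nmv[nmv$sex == sex & nmv$age_lo <= age & age < nmv$age_hi, ]
  if (nrow(band) == 0L) {
    abort(paste0("NMV table has no rows for sex=", sex, ", age=", age))
  }
  val <- band$nmv_lpm_per_kg[match(as.character(pal), band$pal)]
  if (anyNA(val)) {
    abort(paste0("NMV table lacks PAL cell(s): ",
                 paste(unique(as.character(pal)[is.na(val)]), collapse = ", "),
                 " for sex=", sex, ", age=", age))
  }
  unname(val) * weight_kg / 1000
}
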