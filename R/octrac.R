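#' Hourly concentration field at spatial centroids
#'
#' Container for the hourly outdoor concentration surfaces the personal
#' matching runs against: a table of geolocated centroids (e.g. census-block
#' centroids) and an array of hourly concentrations per centroid, pollutant
#' and component. `total` must equal `background + onroad` at every
#' centroid-hour.
#'
#' @param centroids Tibble `centroid_id`, `lat`, `lon` (unique ids).
#' @param hours POSIXct vector of hour stamps (strictly increasing).
#' @param values Numeric array `[centroid, hour, pollutant, component]`
#'   (ug/m^3, >= 0), dimensions matching `centroids`, `hours`,
#'   `pollutants()`, `components()`.
#' @return An object of class `concentration_field`.
#' @export
concentration_field <- function(centroids, hours, values) {
  stopifnot(is.data.frame(centroids), is.array(values))
  centroids <- dplyr::arrange(tibble::as_tibble(centroids), .data$centroid_id)
  if (anyDuplicated(centroids$centroid_id)) {
    abort("`centroid_id` must be unique")
  }
  dm <- dim(values)
  if (length(dm) != 4L || dm[1] != nrow(centroids) || dm[2] != length(hours) ||
      dm[3] != length(POLLUTANTS) || dm[4] != length(COMPONENTS)) {
    abort("`values` must be [centroid, hour, pollutant, component]")
  }
  if (any(values < 0) || any(!is.finite(values))) {
    abort("field values must be finite and >= 0")
  }
  dimnames(values) <- list(centroids$centroid_id, NULL, POLLUTANTS, COMPONENTS)
  err <- values[, , , "total", drop = FALSE] -
    values[, , , "background", drop = FALSE] -
    values[, , , "onroad", drop = FALSE]
  denom <- pmax(values[, , , "total", drop = FALSE], 1e-12)
  if (max(abs(err) / denom) > 1e-9) {
    abort("total must equal background + onroad at every centroid-hour")
  }
  structure(list(centroids = centroids, hours = hours, values = values),
            class = "concentration_field")
}

#' @export
print.concentration_field <- function(x, ...) {
  cat("<concentration_field> ", nrow(x$centroids), " centroids x ",
      length(x$hours), " hours x ", length(POLLUTANTS), " pollutants x ",
      length(COMPONENTS), " components\n", sep = "")
  cat("  hours: ", format(min(x$hours)), " .. ", format(max(x$hours)), "\n",
      sep = "")
  invisible(x)
}

#' @export
as_tibble.concentration_field <- function(x, ...) {
  grid <- tidyr::expand_grid(
    component = COMPONENTS, pollutant = POLLUTANTS,
    time = x$hours, centroid_id = x$centroids$centroid_id
  )
  grid$conc_ugm3 <- as.vector(x$values)
  dplyr::left_join(grid, x$centroids, by = "centroid_id") %>%
    dplyr::select("centroid_id", "lat", "lon", "time", "pollutant",
                  "component", "conc_ugm3") %>%
    dplyr::arrange(.data$centroid_id, .data$time, .data$pollutant,
                   .data$component)
}

#' Nearest field centroid to a point
#'
#' Finds, for each query point, the centroid minimising great-circle
#' (haversine) distance; ties break deterministically to the lowest
#' `centroid_id` (centroids are kept sorted by id).
#'
#' @param lat,lon Query coordinates, WGS84 decimal degrees (vectorised).
#' @param field A [concentration_field()] or its `centroids` tibble.
#' @return Integer vector of row indices into the centroid table, with the
#'   matching `centroid_id` as names.
#' @export
nearest_centroid <- function(lat, lon, field) {
  centroids <- if (inherits(field, "concentration_field")) {
    field$centroids
  } else {
    field
  }
  if (nrow(centroids) == 0L) abort("field has no centroids")
  # minimise the haversine half-angle term; monotone in great-circle distance
  p <- pi / 180
  qla <- lat * p
  qlo <- lon * p
  cla <- centroids$lat * p
  clo <- centroids$lon * p
  a <- outer(qla, cla, function(x, y) sin((y - x) / 2)^2) +
    (cos(qla) %o% cos(cla)) *
      outer(qlo, clo, function(x, y) sin((y - x) / 2)^2)
  idx <- max.col(-a, ties.method = "first")
  setNames(idx, centroids$centroid_id[idx])
}

#' Personal outdoor concentration series along a GPS track
#'
#' Matches each 5-s GPS sample temporally and spatially to the hourly
#' concentration field: the sample at time t reads the field hour containing
#' t (piecewise-constant hour binning) at the centroid nearest the sample's
#' position. Ticks with a missing or invalid fix reuse the previous sample's
#' geolocation (a leading gap back-fills from the first valid fix). The
#' 24-h average of the returned series is the personal outdoor metric.
#'
#' @param track GPS tibble as in [classify_microenv()].
#' @param field A [concentration_field()] covering the day.
#' @param pollutant One of `pollutants()`.
#' @param component One of `components()`.
#' @param date Participant-day date; default inferred from the track.
#' @param day_start_hour Hour the day window starts.
#' @return Tibble `time`, `value` (ug/m^3) with 17,280 rows.
#' @export
personal_outdoor_series <- function(track, field, pollutant, component,
                                    date = NULL,
                                    day_start_hour = DAY_START_HOUR) {
  pollutant <- match.arg(pollutant, POLLUTANTS)
  component <- match.arg(component, COMPONENTS)
  pos <- track_tick_positions(track, date, day_start_hour)
  cidx <- nearest_centroid(pos$lat, pos$lon, field)
  hidx <- match(pos$hour, field$hours)
  if (anyNA(hidx)) {
    abort(paste0("field does not cover hour(s): ",
                 paste(format(unique(pos$hour[is.na(hidx)]), "%Y-%m-%d %H:%M"),
                       collapse = ", ")))
  }
  value <- field$values[cbind(unname(cidx), hidx,
                              match(pollutant, POLLUTANTS),
                              match(component, COMPONENTS))]
  tibble::tibble(time = pos$time, value = value)
}

# Resolve a (possibly gappy) track to one geolocation per 5-s tick, with the
# enclosing field hour. Shared by the personal matching and the study runner.
track_tick_positions <- function(track, date = NULL,
                                 day_start_hour = DAY_START_HOUR) {
  stopifnot(is.data.frame(track))
  if (nrow(track) == 0L) abort("empty GPS track")
  date <- date %||% window_date(track$time[1], day_start_hour)
  ticks <- day_ticks(date, day_start_hour)
  off <- round(as.numeric(track$time) - as.numeric(ticks[1]))
  if (any(off < 0) || any(off >= SECS_PER_DAY)) {
    abort("track has samples outside the participant-day window")
  }
  slot <- as.integer(off %/% 5L) + 1L
  lat <- lon <- rep(NA_real_, TICKS_PER_DAY)
  ok <- as.logical(track$valid) & is.finite(track$lat) & is.finite(track$lon)
  lat[slot[ok]] <- track$lat[ok]
  lon[slot[ok]] <- track$lon[ok]
  if (all(is.na(lat))) abort("track contains no valid positions")
  hour_of <- ticks[1] + 3600 * ((seq_len(TICKS_PER_DAY) - 1L) %/% 720L)
  tibble::tibble(time = ticks, lat = locf_fill(lat), lon = locf_fill(lon),
                 hour = hour_of)
}

#' Impute a lag day's geolocations
#'
#' Copies the observed day's track to a lag day, re-stamping the times. On
#' weekend lag days, samples located at the participant's work place (within
#' the place radius of the work centre) are relocated to the home centre,
#' mirroring the weekend relabelling of the microenvironment series.
#'
#' @param track_day Observed-day GPS tibble.
#' @param lag_date Date to re-stamp to.
#' @param places A [place_geometry()]; needed for the weekend relocation.
#' @param weekend Is the lag day a weekend day? Default from `lag_date`.
#' @param day_start_hour Hour the day window starts.
#' @return GPS tibble for the lag day.
#' @export
lag_day_track <- function(track_day, lag_date, places,
                          weekend = is_weekend(lag_date),
                          day_start_hour = DAY_START_HOUR) {
  stopifnot(is.data.frame(track_day))
  date0 <- window_date(track_day$time[1], day_start_hour)
  shift <- as.numeric(day_start(lag_date, day_start_hour)) -
    as.numeric(day_start(date0, day_start_hour))
  out <- track_day
  out$time <- track_day$time + shift
  if (weekend && !is.null(places$work)) {
    d_work <- haversine_m(out$lat, out$lon,
                          places$work["lat"], places$work["lon"])
    at_work <- !is.na(d_work) & d_work <= places$place_radius
    out$lat[at_work] <- places$home["lat"]
    out$lon[at_work] <- places$home["lon"]
  }
  out
}
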