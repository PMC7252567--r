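#' Place geometry and classification thresholds for microenvironment
#' classification
#'
#' Describes the participant's known places (home, optionally work) as
#' radius-buffered points, plus the thresholds of the GPS classifier:
#' sustained speed above `speed_threshold` for at least `sustained_window`
#' seconds marks in-vehicle travel; a fix within `place_radius` metres of a
#' place centre belongs to that place (nearest wins); an invalid fix or a
#' position dilution of precision above `pdop_threshold` marks indoors;
#' labels are smoothed by majority vote over a centred `dwell_window`.
#'
#' @param home_lat,home_lon Home centre, WGS84 decimal degrees.
#' @param work_lat,work_lon Optional work centre.
#' @param place_radius Building-buffer radius, m.
#' @param speed_threshold In-vehicle speed threshold, km/h.
#' @param sustained_window Seconds the speed must stay above threshold.
#' @param pdop_threshold PDOP above which a fix counts as indoors.
#' @param dwell_window Label-smoothing window, seconds.
#' @return A list of class `place_geometry`.
#' @export
place_geometry <- function(home_lat, home_lon, work_lat = NULL,
                           work_lon = NULL, place_radius = 40,
                           speed_threshold = 10, sustained_window = 30,
                           pdop_threshold = 4, dwell_window = 60) {
  if (place_radius <= 0 || speed_threshold <= 0 || sustained_window <= 0 ||
      pdop_threshold <= 0 || dwell_window <= 0) {
    abort("all radii and thresholds must be > 0")
  }
  has_work <- !is.null(work_lat) && !is.null(work_lon) &&
    !is.na(work_lat) && !is.na(work_lon)
  structure(
    list(home = c(lat = home_lat, lon = home_lon),
         work = if (has_work) c(lat = work_lat, lon = work_lon),
         place_radius = place_radius, speed_threshold = speed_threshold,
         sustained_window = sustained_window,
         pdop_threshold = pdop_threshold, dwell_window = dwell_window),
    class = "place_geometry"
  )
}

#' Classify a GPS track into seven microenvironments
#'
#' Assigns every 5-s tick of a participant-day to one of seven
#' microenvironments (indoors/outdoors at home, work, other; in vehicle)
#' from the GPS logger track and the participant's place geometry. The
#' decision tree per tick: (1) sustained speed above the threshold marks
#' in-vehicle travel; (2) otherwise the place is home, work or other by
#' radius membership (nearest place wins); (3) indoors versus outdoors at
#' that place follows fix quality — an invalid fix or high PDOP indicates
#' the receiver is under a roof; (4) ticks with no GPS sample inherit the
#' previous tick's label (a leading gap back-fills from the first sample);
#' (5) the label sequence is smoothed by majority vote over the dwell
#' window, ties keeping the centre label. The result is one-hot by
#' construction: exactly one label per tick, 17,280 ticks covering the
#' 8 am - 8 am window.
#'
#' @param track Tibble of GPS samples: `time` (POSIXct, 5-s cadence),
#'   `lat`, `lon`, `speed_kmh`, `n_sat`, `pdop`, `valid` (logical). Gaps
#'   allowed; must be non-empty and lie within one participant-day.
#' @param places A [place_geometry()].
#' @param date Date of the participant-day; default inferred from the first
#'   sample.
#' @param day_start_hour Hour the day window starts (default 8).
#' @return Tibble `time`, `me` (factor with the seven levels of
#'   `microenv_levels()`), 17,280 rows.
#' @export
classify_microenv <- function(track, places, date = NULL,
                              day_start_hour = DAY_START_HOUR) {
  stopifnot(is.data.frame(track), inherits(places, "place_geometry"))
  if (nrow(track) == 0L) abort("empty GPS track")
  date <- date %||% window_date(track$time[1], day_start_hour)
  ticks <- day_ticks(date, day_start_hour)
  off <- round(as.numeric(track$time) - as.numeric(ticks[1]))
  if (any(off < 0) || any(off >= SECS_PER_DAY)) {
    abort("track has samples outside the participant-day window")
  }
  slot <- as.integer(off %/% 5L) + 1L

  lat <- lon <- speed <- pdop <- rep(NA_real_, TICKS_PER_DAY)
  valid <- rep(NA, TICKS_PER_DAY)
  lat[slot] <- track$lat; lon[slot] <- track$lon
  speed[slot] <- track$speed_kmh; pdop[slot] <- track$pdop
  valid[slot] <- as.logical(track$valid)
  present <- !is.na(valid)

  # carry positions/speed/fix quality forward over gaps and invalid fixes
  pos_ok <- present & valid & is.finite(lat) & is.finite(lon)
  if (!any(pos_ok)) abort("track contains no valid positions")
  lat_f <- locf_fill(ifelse(pos_ok, lat, NA_real_))
  lon_f <- locf_fill(ifelse(pos_ok, lon, NA_real_))
  speed_f <- locf_fill(ifelse(present, ifelse(is.finite(speed), speed, 0), NA))
  pdop_f <- locf_fill(ifelse(present, pdop, NA_real_))
  valid_f <- as.logical(locf_fill(ifelse(present, valid, NA)))

  # (1) in-vehicle: speed above threshold sustained >= sustained_window
  fast <- speed_f > places$speed_threshold
  need <- max(1L, as.integer(ceiling(places$sustained_window / 5)))
  r <- rle(fast)
  vehicle <- inverse.rle(list(
    lengths = r$lengths, values = r$values & r$lengths >= need))

  # (2) place by radius membership, nearest wins
  d_home <- haversine_m(lat_f, lon_f, places$home["lat"], places$home["lon"])
  if (!is.null(places$work)) {
    d_work <- haversine_m(lat_f, lon_f, places$work["lat"], places$work["lon"])
  } else {
    d_work <- rep(Inf, TICKS_PER_DAY)
  }
  place <- rep("other", TICKS_PER_DAY)
  in_home_r <- d_home <= places$place_radius
  in_work_r <- d_work <= places$place_radius
  place[in_work_r] <- "work"
  place[in_home_r & (!in_work_r | d_home <= d_work)] <- "home"

  # (3) indoors by fix quality
  indoor <- !valid_f | pdop_f > places$pdop_threshold

  lab <- ifelse(vehicle, "in_vehicle",
                paste0(ifelse(indoor, "in_", "out_"), place))
  me <- factor(lab, levels = ME7_LEVELS)

  # (5) dwell smoothing: centred majority vote, ties keep the centre label
  me <- smooth_majority(me, max(1L, as.integer(places$dwell_window / 5)))

  tibble::tibble(time = ticks, me = me)
}

# rolling majority vote over +/- half-window ticks; the incumbent label gets
# a half-vote bonus so ties are kept deterministically
smooth_majority <- function(me, window_ticks) {
  half <- window_ticks %/% 2L
  if (half < 1L) return(me)
  n <- length(me)
  lev <- levels(me)
  counts <- matrix(0, n, length(lev))
  idx <- unclass(me)
  onehot <- matrix(0L, n, length(lev))
  onehot[cbind(seq_len(n), idx)] <- 1L
  for (j in seq_along(lev)) {
    cs <- cumsum(c(rep(0L, half + 1L), onehot[, j], rep(0L, half)))
    counts[, j] <- cs[(half * 2L + 2L):(n + 2L * half + 1L)] - cs[seq_len(n)]
  }
  counts[cbind(seq_len(n), idx)] <- counts[cbind(seq_len(n), idx)] + 0.5
  factor(lev[max.col(counts, ties.method = "first")], levels = lev)
}

# plain haversine distance in metres (vectorised); geosphere backs the
# exported nearest-centroid lookup, this kernel keeps the classifier light
haversine_m <- function(lat1, lon1, lat2, lon2, r = 6378137) {
  p <- pi / 180
  dlat <- (lat2 - lat1) * p
  dlon <- (lon2 - lon1) * p
  a <- sin(dlat / 2)^2 + cos(lat1 * p) * cos(lat2 * p) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

#' Collapse seven microenvironments to five
#'
#' The three outdoor classes (outdoors at home, work, other) merge into a
#' single `outdoors` class; the indoor classes and `in_vehicle` are
#' unchanged. One-hot labelling is preserved.
#'
#' @param me A factor with the 7 levels of `microenv_levels()`, or a tibble
#'   with a `me` column.
#' @return Same shape as the input with 5-level labels.
#' @export
collapse_microenv <- function(me) {
  if (is.data.frame(me)) {
    me$me <- collapse_microenv(me$me)
    return(me)
  }
  stopifnot(is.factor(me))
  map <- c(in_home = "in_home", in_work = "in_work", in_other = "in_other",
           in_vehicle = "in_vehicle", out_home = "outdoors",
           out_work = "outdoors", out_other = "outdoors")
  factor(unname(map[as.character(me)]), levels = ME5_LEVELS)
}

#' Impute a lag day's microenvironment series
#'
#' Lag days (the five days preceding a clinic visit) have no GPS data; the
#' observed day's label sequence is copied and re-stamped. On weekend lag
#' days, time at work is re-assigned to home (indoors at work becomes
#' indoors at home, outdoors at work becomes outdoors at home), since the
#' observed day is a weekday.
#'
#' @param me_day Tibble `time`, `me` for the observed day (7-level labels).
#' @param lag_date Date to re-stamp to.
#' @param weekend Is the lag day a weekend day? Default from `lag_date`.
#' @param day_start_hour Hour the day window starts.
#' @return Tibble `time`, `me` for the lag day.
#' @export
lag_day_microenv <- function(me_day, lag_date, weekend = is_weekend(lag_date),
                             day_start_hour = DAY_START_HOUR) {
  stopifnot(is.data.frame(me_day), nrow(me_day) == TICKS_PER_DAY)
  me <- me_day$me
  if (weekend) {
    lab <- as.character(me)
    lab[lab == "in_work"] <- "in_home"
    lab[lab == "out_work"] <- "out_home"
    me <- factor(lab, levels = ME7_LEVELS)
  }
  tibble::tibble(time = day_ticks(lag_date, day_start_hour), me = me)
}
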