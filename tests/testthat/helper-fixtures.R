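# shared fixture builders; everything is generated in code at test time

day1 <- as.Date("2013-06-04")   # a Tuesday

# a small concentration field, constant in space and time per pollutant:
# total = value, split bg_frac / (1 - bg_frac) into background / on-road
uniform_field <- function(dates, value = c(pm25 = 10, ec = 1, nox = 20,
                                           co = 300),
                          bg_frac = 0.6,
                          centroids = tibble::tibble(
                            centroid_id = sprintf("c%02d", 1:4),
                            lat = c(35.90, 35.90, 35.95, 35.95),
                            lon = c(-79.05, -79.00, -79.05, -79.00))) {
  hours <- do.call(c, lapply(sort(unique(as.Date(dates))), fivetiers:::day_hours))
  nc <- nrow(centroids)
  nh <- length(hours)
  values <- array(0, dim = c(nc, nh, 4, 3))
  for (p in seq_along(pollutants())) {
    values[, , p, 1] <- value[pollutants()[p]] * bg_frac
    values[, , p, 2] <- value[pollutants()[p]] * (1 - bg_frac)
    values[, , p, 3] <- value[pollutants()[p]]
  }
  concentration_field(centroids, hours, values)
}

# stationary GPS track at a fixed point, 5-s cadence over a full day
stationary_track <- function(date = day1, lat = 35.90, lon = -79.05,
                             speed = 0, pdop = 2, valid = TRUE,
                             n_sat = 9L) {
  ticks <- fivetiers:::day_ticks(date)
  tibble::tibble(time = ticks, lat = lat, lon = lon, speed_kmh = speed,
                 n_sat = n_sat, pdop = pdop, valid = valid)
}

const_accel <- function(date = day1, counts = 0L) {
  start <- fivetiers:::day_start(date)
  tibble::tibble(time = start + 0:(86400L - 1L), counts = as.integer(counts))
}

me_series <- function(label, date = day1) {
  tibble::tibble(time = fivetiers:::day_ticks(date),
                 me = factor(label, levels = microenv_levels(7)))
}

# flat NMV table injected by tests (independent of the shipped defaults)
test_nmv <- function() {
  tidyr::expand_grid(pal = c("sedentary", "light", "moderate", "vigorous"),
                     sex = c("male", "female")) |>
    dplyr::mutate(age_lo = 0, age_hi = Inf,
                  nmv_lpm_per_kg = c(sedentary = 0.1, light = 0.2,
                                     moderate = 0.4, vigorous = 0.6)[pal])
}

test_participant <- function() {
  tibble::tibble(participant = "tp1", age = 60, sex = "male",
                 height_cm = 180, weight_kg = 75)
}

const_weather <- function(dates, t_out = 10, wind = 2) {
  hours <- do.call(c, lapply(sort(unique(as.Date(dates))), fivetiers:::day_hours))
  tibble::tibble(time = hours, t_out = t_out, wind = wind)
}
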