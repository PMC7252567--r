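# independent oracles used by the tests; these never call the code paths
# they check

# brute-force 1-s forward-Euler integration of the indoor mass balance,
# piecewise-constant outdoor concentration and AER per hour; returns the
# end-of-hour indoor concentrations
euler_indoor <- function(c_out, aer, penetration, removal_rate, init,
                         dt_s = 1) {
  n_steps <- as.integer(3600 / dt_s)
  dt_h <- dt_s / 3600
  vals <- numeric(length(c_out))
  cur <- init
  for (h in seq_along(c_out)) {
    gain <- aer[h] * penetration * c_out[h]
    loss <- aer[h] + removal_rate
    for (s in seq_len(n_steps)) cur <- cur + dt_h * (gain - loss * cur)
    vals[h] <- cur
  }
  vals
}

# plain scalar haversine scan for the nearest-centroid oracle
haversine_scan <- function(lat, lon, centroids, r = 6378137) {
  best <- 1L
  best_d <- Inf
  for (i in seq_len(nrow(centroids))) {
    p <- pi / 180
    a <- sin((centroids$lat[i] - lat) * p / 2)^2 +
      cos(lat * p) * cos(centroids$lat[i] * p) *
        sin((centroids$lon[i] - lon) * p / 2)^2
    d <- 2 * r * asin(min(1, sqrt(a)))
    if (d < best_d - 1e-9) {
      best_d <- d
      best <- i
    }
  }
  best
}
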