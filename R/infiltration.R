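#' Dynamic mass-balance infiltration model
#'
#' Hourly indoor concentrations of an ambient pollutant are modeled from the
#' home-outdoor series and the hourly air exchange rate (AER) with the
#' single-compartment mass balance
#' `dC_in/dt = AER * P * C_out - (AER + k_r) * C_in`,
#' where `P` is the envelope penetration coefficient and `k_r` the
#' first-order indoor removal rate (see [pollutant_params()]).
#'
#' `steady_state_ratio()` is the equilibrium indoor/outdoor ratio
#' `AER * P / (AER + k_r)`, which lies in (0, P]. `step_indoor()` advances
#' the balance over one step of `dt` hours with outdoor concentration and
#' AER held constant, using the exact exponential update
#' `C_ss + (C_in - C_ss) * exp(-(AER + k_r) * dt)` (unconditionally stable;
#' when `AER + k_r = 0` the indoor concentration is unchanged).
#' `indoor_series()` applies the step hour by hour along aligned outdoor and
#' AER series, initialising at the first hour's steady state so an arbitrary
#' start-up transient does not contaminate the first daily average.
#'
#' @param aer Air exchange rate, h^-1 (vectorised).
#' @param params One row of [pollutant_params()] (or the full table plus
#'   `pollutant`).
#' @param pollutant Pollutant name, required when `params` has four rows.
#' @return `steady_state_ratio()`: dimensionless ratio in (0, P].
#' @export
#' @examples
#' p <- pollutant_params()
#' steady_state_ratio(0.21, p, "pm25")   # 0.42
#' steady_state_ratio(1, p, "co")        # 1: ambient CO is not attenuated
steady_state_ratio <- function(aer, params = pollutant_params(),
                               pollutant = NULL) {
  pr <- resolve_params(params, pollutant)
  if (any(aer < 0)) abort("`aer` must be >= 0")
  if (any(aer + pr$removal_rate == 0)) {
    abort(paste0("steady-state ratio is undefined when aer = 0 and ",
                 "removal_rate = 0 (indoor tracks its initial condition)"))
  }
  aer * pr$penetration / (aer + pr$removal_rate)
}

#' @rdname steady_state_ratio
#' @param c_in,c_out Indoor / outdoor concentration, ug/m^3.
#' @param dt Step length in hours (> 0).
#' @export
step_indoor <- function(c_in, c_out, aer, params = pollutant_params(),
                        pollutant = NULL, dt = 1) {
  pr <- resolve_params(params, pollutant)
  if (any(dt <= 0)) abort("`dt` must be > 0")
  if (any(!is.finite(c_in)) || any(!is.finite(c_out)) || any(!is.finite(aer)) ||
      any(c_in < 0) || any(c_out < 0) || any(aer < 0)) {
    abort("`c_in`, `c_out`, `aer` must be finite and >= 0")
  }
  k <- aer + pr$removal_rate
  c_ss <- ifelse(k > 0, aer * pr$penetration * c_out / k, 0)
  ifelse(k > 0, c_ss + (c_in - c_ss) * exp(-k * dt), c_in)
}

#' @rdname steady_state_ratio
#' @param outdoor Tibble `time`, `value`: hourly outdoor concentrations,
#'   ug/m^3.
#' @param aer_series Tibble `time`, `aer`: hourly AER, h^-1, aligned with
#'   `outdoor`.
#' @param init Optional initial indoor concentration; default is the first
#'   hour's steady state times the first outdoor value (spin-up convention).
#' @return `indoor_series()`: tibble `time`, `value` of hourly indoor
#'   concentrations.
#' @export
indoor_series <- function(outdoor, aer_series, params = pollutant_params(),
                          pollutant = NULL, init = NULL) {
  pr <- resolve_params(params, pollutant)
  stopifnot(is.data.frame(outdoor), is.data.frame(aer_series))
  if (nrow(outdoor) != nrow(aer_series) ||
      !isTRUE(all(outdoor$time == aer_series$time))) {
    abort("`outdoor` and `aer_series` must share identical timestamps")
  }
  n <- nrow(outdoor)
  if (n == 0L) abort("empty series")
  c_out <- outdoor$value
  aer <- aer_series$aer
  if (any(!is.finite(c_out)) || any(c_out < 0) ||
      any(!is.finite(aer)) || any(aer < 0)) {
    abort("concentrations and AER must be finite and >= 0")
  }
  k <- aer + pr$removal_rate
  c_ss <- ifelse(k > 0, aer * pr$penetration * c_out / k, 0)
  if (is.null(init)) {
    init <- if (k[1] > 0) c_ss[1] else c_out[1] * pr$penetration
  }
  decay <- exp(-k)                     # dt = 1 h
  value <- numeric(n)
  cur <- init
  for (i in seq_len(n)) {
    cur <- if (k[i] > 0) c_ss[i] + (cur - c_ss[i]) * decay[i] else cur
    value[i] <- cur
  }
  tibble::tibble(time = outdoor$time, value = value)
}

resolve_params <- function(params, pollutant) {
  if (!is.null(pollutant)) return(params_for(params, pollutant))
  if (nrow(params) != 1L) {
    abort("supply a one-row parameter table or name a `pollutant`")
  }
  params
}
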