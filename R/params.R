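#' Per-pollutant infiltration parameters
#'
#' Returns the registry of pollutant-specific constants used throughout the
#' tiers: the building-envelope penetration coefficient `penetration` (P,
#' dimensionless), the first-order indoor removal rate `removal_rate`
#' (k_r, h^-1), and the equilibrium infiltration factors applied in
#' non-residential buildings (`f_inf_other_bldg`) and inside vehicles
#' (`f_inf_vehicle`).
#'
#' Defaults are the literature-reported values adopted by the model:
#' PM2.5 (P = 0.84, k_r = 0.21 h^-1), EC (0.98, 0.29), NOx (1.00, 0.5),
#' CO (1.00, 0 — ambient CO is not attenuated indoors), with
#' `f_inf_other_bldg` = 0.64, 0.59, 1.00, 1.00 and `f_inf_vehicle` = 0.44,
#' 0.44, 0.80, 1.00 respectively. They can be overridden per pollutant via
#' `overrides`, but are otherwise fixed: they are adopted constants, not
#' quantities the model estimates.
#'
#' @param overrides Optional named list (names in `pollutants()`), each a
#'   named list of the fields to replace, e.g.
#'   `list(pm25 = list(penetration = 0.9))`. Unknown pollutants or fields
#'   are an error.
#' @return A tibble with one row per pollutant and columns `pollutant`,
#'   `penetration`, `removal_rate`, `f_inf_other_bldg`, `f_inf_vehicle`.
#' @export
#' @examples
#' pollutant_params()
#' pollutant_params(overrides = list(pm25 = list(removal_rate = 0.3)))
pollutant_params <- function(overrides = NULL) {
  params <- tibble::tibble(
    pollutant        = POLLUTANTS,
    penetration      = c(0.84, 0.98, 1.00, 1.00),
    removal_rate     = c(0.21, 0.29, 0.50, 0.00),
    f_inf_other_bldg = c(0.64, 0.59, 1.00, 1.00),
    f_inf_vehicle    = c(0.44, 0.44, 0.80, 1.00)
  )
  if (!is.null(overrides)) {
    if (!is.list(overrides) || is.null(names(overrides))) {
      abort("`overrides` must be a named list of per-pollutant lists")
    }
    bad <- setdiff(names(overrides), POLLUTANTS)
    if (length(bad)) {
      abort(paste0("unknown pollutant(s) in overrides: ",
                   paste(bad, collapse = ", ")))
    }
    for (p in names(overrides)) {
      ov <- overrides[[p]]
      bad <- setdiff(names(ov), names(params)[-1])
      if (length(bad)) {
        abort(paste0("unknown parameter field(s) for ", p, ": ",
                     paste(bad, collapse = ", ")))
      }
      for (f in names(ov)) params[params$pollutant == p, f] <- ov[[f]]
    }
  }
  validate_pollutant_params(params)
  params
}

validate_pollutant_params <- function(params) {
  stopifnot(is.data.frame(params))
  need <- c("pollutant", "penetration", "removal_rate",
            "f_inf_other_bldg", "f_inf_vehicle")
  miss <- setdiff(need, names(params))
  if (length(miss)) {
    abort(paste0("pollutant parameter table lacks column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (!setequal(params$pollutant, POLLUTANTS) ||
      anyDuplicated(params$pollutant)) {
    abort("parameter table must have exactly one row per pollutant")
  }
  num <- as.matrix(params[need[-1]])
  if (any(!is.finite(num))) abort("pollutant parameters must be finite")
  if (any(params$penetration <= 0 | params$penetration > 1)) {
    abort("`penetration` must lie in (0, 1]")
  }
  if (any(params$removal_rate < 0)) abort("`removal_rate` must be >= 0")
  if (any(params$f_inf_other_bldg <= 0 | params$f_inf_other_bldg > 1 |
          params$f_inf_vehicle <= 0 | params$f_inf_vehicle > 1)) {
    abort("infiltration factors must lie in (0, 1]")
  }
  invisible(params)
}

# One-row parameter lookup used by the infiltration / exposure kernels.
params_for <- function(params, pollutant) {
  pollutant <- match.arg(pollutant, POLLUTANTS)
  row <- params[params$pollutant == pollutant, ]
  if (nrow(row) != 1L) abort(paste0("no parameters for pollutant ", pollutant))
  row
}

#' Body surface area (DuBois formula)
#'
#' `BSA = 0.007184 * BH^0.725 * BW^0.425`, with body height `BH` in cm and
#' body weight `BW` in kg; the result is in m^2. Used to normalise inhaled
#' dose across participants.
#'
#' @param height_cm Body height in centimetres (> 0).
#' @param weight_kg Body weight in kilograms (> 0).
#' @return Body surface area in m^2 (vectorised).
#' @export
#' @examples
#' body_surface_area(180, 75)
body_surface_area <- function(height_cm, weight_kg) {
  if (any(!is.finite(height_cm)) || any(!is.finite(weight_kg)) ||
      any(height_cm <= 0) || any(weight_kg <= 0)) {
    abort("`height_cm` and `weight_kg` must be finite and > 0")
  }
  0.007184 * height_cm^0.725 * weight_kg^0.425
}
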