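#' @export
print.tier_records <- function(x, ...) {
  cat("# Tier records: ", nrow(x), " rows (",
      attr(x, "n_participant_days") %||% NA, " participant-days, ",
      attr(x, "n_unique_days") %||% NA, " unique participant-days)\n",
      sep = "")
  NextMethod()
}

#' Tidy and summarise tier records
#'
#' `tidy()` returns the record table as a plain tibble, optionally pivoted
#' to one row per metric; `glance()` returns a one-row summary of a run:
#' record and participant-day counts (scheduled, i.e. with multiplicity
#' across overlapping visits, and unique), participants, date range and the
#' share of imputed (lag-day) records.
#'
#' @param x A `tier_records` object from [run_study()].
#' @param long Pivot the five tier metrics into `metric`/`value` columns?
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.tier_records <- function(x, long = FALSE, ...) {
  out <- tibble::as_tibble(x)
  if (long) {
    out <- tidyr::pivot_longer(
      out, dplyr::starts_with("tier"),
      names_to = "metric", values_to = "value")
  }
  out
}

#' @rdname tidy.tier_records
#' @export
glance.tier_records <- function(x, ...) {
  tibble::tibble(
    n_records = nrow(x),
    n_participant_days = attr(x, "n_participant_days") %||%
      nrow(dplyr::distinct(x, .data$participant, .data$date)),
    n_unique_participant_days = attr(x, "n_unique_days") %||%
      nrow(dplyr::distinct(x, .data$participant, .data$date)),
    n_participants = dplyr::n_distinct(x$participant),
    n_pollutants = dplyr::n_distinct(x$pollutant),
    n_components = dplyr::n_distinct(x$component),
    date_min = min(x$date), date_max = max(x$date),
    frac_imputed = mean(x$imputed)
  )
}

tier_metric_labels <- c(
  tier1_out_home = "Tier 1: home outdoor",
  tier2_in_home = "Tier 2: home indoor",
  tier3_out_personal = "Tier 3: personal outdoor",
  tier4_exposure = "Tier 4: exposure",
  tier5_dose = "Tier 5: inhaled dose")

#' Plot tier-metric distributions
#'
#' Boxplots of the daily 24-h metrics for each tier, faceted by pollutant,
#' coloured by source component — the at-a-glance picture of how much each
#' tier of individual information (infiltration, time-location, activity)
#' reshapes the exposure distribution. Note tier 5 is a dose (ug/m^2 body
#' surface area), not a concentration.
#'
#' @param records A `tier_records` tibble.
#' @param pollutants Which pollutants to show (default all).
#' @return A ggplot object.
#' @export
plot_tier_distributions <- function(records, pollutants = NULL) {
  df <- tidy.tier_records(records, long = TRUE)
  if (!is.null(pollutants)) df <- df[df$pollutant %in% pollutants, ]
  df$metric <- factor(tier_metric_labels[df$metric],
                      levels = tier_metric_labels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value,
                                   fill = .data$component)) +
    ggplot2::geom_boxplot(outlier.size = 0.4, linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$pollutant), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "daily metric (ug/m3; tier 5: ug/m2)",
                  fill = "component") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot time and dose shares by microenvironment
#'
#' For each participant, the distribution of daily time spent (minutes) and
#' daily inhaled dose accumulated in each of the seven microenvironments,
#' for one pollutant's total component.
#'
#' @param records A `tier_records` tibble.
#' @param pollutant Pollutant for the dose panel (default `"pm25"`).
#' @return A ggplot object.
#' @export
plot_me_breakdown <- function(records, pollutant = "pm25") {
  df <- tibble::as_tibble(records)
  df <- df[df$pollutant == pollutant & df$component == "total", ]
  long <- tidyr::pivot_longer(
    df, dplyr::matches("^(dose|time)_"),
    names_to = c("what", "me"), names_pattern = "(dose|time)_(.*)",
    values_to = "value")
  long$me <- factor(long$me, levels = ME7_LEVELS)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$me, y = .data$value,
                                     fill = .data$what)) +
    ggplot2::geom_boxplot(outlier.size = 0.4, linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$what), ncol = 1,
                        scales = "free_y") +
    ggplot2::labs(x = "microenvironment",
                  y = "daily minutes / daily dose (ug/m2)") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @export
autoplot.tier_records <- function(object, ...) {
  plot_tier_distributions(object, ...)
}
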