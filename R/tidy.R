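#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a simulation run
#'
#' @param x A `bombus_sim` object.
#' @param ... Unused.
#' @return The daily-metrics tibble with the scenario name prepended.
#' @export
tidy.bombus_sim <- function(x, ...) {
  dplyr::mutate(x$daily, scenario = x$scenario$name, .before = 1)
}

#' One-row summary of a simulation run
#'
#' @param x A `bombus_sim` object.
#' @param ... Unused.
#' @return A one-row tibble with the run's headline statistics: trip counts,
#'   trip-count-weighted mean durations, end-of-run queens and the mean
#'   colony count over the last three years.
#' @export
glance.bombus_sim <- function(x, ...) {
  d <- x$daily
  tibble::tibble(
    scenario = x$scenario$name,
    seed = x$seed,
    years = x$years,
    n_nectar_trips = sum(d$n_nectar_trips),
    n_pollen_trips = sum(d$n_pollen_trips),
    mean_nectar_trip_s = if (sum(d$n_nectar_trips) > 0) {
      weighted_mean_trip_duration(d)
    } else {
      NA_real_
    },
    mean_pollen_trip_s = if (sum(d$n_pollen_trips) > 0) {
      weighted_mean_trip_duration(d, .data$mean_pollen_trip_s,
                                  .data$n_pollen_trips)
    } else {
      NA_real_
    },
    end_queens = hibernating_queens_at_end(d),
    mean_colonies_last3y = mean_colonies_last3y(d)
  )
}

#' Tidy an experiment
#'
#' @param x A `bombus_experiment` object.
#' @param ... Unused.
#' @return The per-run summary tibble.
#' @export
tidy.bombus_experiment <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row-per-scenario summary of an experiment
#'
#' @param x A `bombus_experiment` object.
#' @param ... Unused.
#' @return The per-scenario summary from [summarise_experiment()].
#' @export
glance.bombus_experiment <- function(x, ...) {
  summarise_experiment(x)
}
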