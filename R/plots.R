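#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the handling-time curve of the mechanistic engine
#'
#' Total handling time for one nectar load against corolla depth, at fixed
#' glossa lengths, showing the vertical asymptote (pole) as the corolla
#' depth approaches the glossa length and the cap at `Tmax`.
#'
#' @param glossa_mm Glossa lengths to draw (one line each).
#' @param weight_g Bee weight.
#' @param nectar_volume_ul Per-flower nectar volume.
#' @param interflower_s Inter-flower travel time.
#' @param corolla_range_mm Corolla-depth range (default 0 to 19 mm).
#' @param gamma Filling level.
#' @param config A [handling_config()] for crop capacity and `Tmax`.
#' @return A ggplot.
#' @export
plot_handling_curve <- function(glossa_mm = c(6.9, 11.1), weight_g = 0.195,
                                nectar_volume_ul = 2,
                                interflower_s = 2,
                                corolla_range_mm = c(0, 19), gamma = 1,
                                config = handling_config()) {
  cd <- seq(corolla_range_mm[1], corolla_range_mm[2], length.out = 400)
  df <- purrr::map(glossa_mm, function(g) {
    traits <- forager_traits(g, weight_g)
    ta <- access_time(cd)
    ti <- ingestion_time(nectar_volume_ul, traits, cd, ta)
    nf <- n_flowers_per_load(config$crop_capacity_ul, nectar_volume_ul)
    th <- harder_handling_time(interflower_s, ta, ti, gamma, nf,
                               config$t_max_s)
    tibble::tibble(corolla_depth_mm = cd, glossa_mm = g,
                   handling_s = th$total_handling_s)
  }) |> purrr::list_rbind()
  ggplot2::ggplot(df, ggplot2::aes(.data$corolla_depth_mm, .data$handling_s,
                                   colour = factor(.data$glossa_mm))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "corolla depth C (mm)",
                  y = "handling time Th (s)",
                  colour = "glossa G (mm)") +
    ggplot2::theme_minimal()
}

#' Plot daily metrics of a run
#'
#' @param object A `bombus_sim`.
#' @param ... Unused.
#' @return A ggplot of daily queen and colony counts and trip counts.
#' @export
autoplot.bombus_sim <- function(object, ...) {
  d <- object$daily |>
    dplyr::select(.data$day, queens = .data$n_queens,
                  colonies = .data$n_colonies,
                  `nectar trips` = .data$n_nectar_trips,
                  `pollen trips` = .data$n_pollen_trips) |>
    tidyr::pivot_longer(-.data$day)
  ggplot2::ggplot(d, ggplot2::aes(.data$day, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~name, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "simulation day", y = NULL,
                  title = object$scenario$name) +
    ggplot2::theme_minimal()
}

#' Plot an experiment summary
#'
#' Boxplots by scenario of either the end-of-run hibernating-queen count or
#' the weighted mean nectar-trip duration, coloured by mortality model.
#'
#' @param object A `bombus_experiment`.
#' @param metric `"end_queens"` or `"mean_nectar_trip_s"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bombus_experiment <- function(object,
                                       metric = c("end_queens",
                                                  "mean_nectar_trip_s"),
                                       ...) {
  metric <- match.arg(metric)
  grid <- attr(object, "grid")
  df <- tibble::as_tibble(object) |>
    dplyr::left_join(grid, by = c(scenario = "name")) |>
    dplyr::mutate(scenario = factor(.data$scenario,
                                    levels = unique(grid$name)))
  ggplot2::ggplot(df, ggplot2::aes(.data$scenario, .data[[metric]],
                                   fill = .data$mortality_model)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = metric, fill = "mortality") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}
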