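#' The 19-scenario experiment grid
#'
#' `ORG` (mechanistic Harder engine, high mortality — the default) plus the
#' full cross of the three mortality models with the six fixed handling
#' times 112.5, 225, 450, 900, 1800 and 3600 s, named
#' `mortalitymodel_handlingtime` (`LOW_112` ... `HIGH_3600`).
#'
#' @return A tibble with columns `name`, `fixed_handling_enabled`,
#'   `fixed_handling_time_s` (`NA` for `ORG`) and `mortality_model`.
#' @examples
#' build_scenario_grid()
#' @export
build_scenario_grid <- function() {
  fixed <- c(112.5, 225, 450, 900, 1800, 3600)
  labels <- c("112", "225", "450", "900", "1800", "3600")
  mort <- c(LOW = "low", MED = "intermediate", HIGH = "high")
  grid <- tidyr::expand_grid(
    prefix = names(mort),
    level = seq_along(fixed)
  )
  dplyr::bind_rows(
    tibble::tibble(
      name = "ORG",
      fixed_handling_enabled = FALSE,
      fixed_handling_time_s = NA_real_,
      mortality_model = "high"
    ),
    tibble::tibble(
      name = paste0(grid$prefix, "_", labels[grid$level]),
      fixed_handling_enabled = TRUE,
      fixed_handling_time_s = fixed[grid$level],
      mortality_model = unname(mort[grid$prefix])
    )
  )
}

#' Trip-count-weighted mean trip duration
#'
#' Multiplies each day's mean trip duration by that day's trip count, sums
#' the products and divides by the total number of trips — i.e. the grand
#' mean over all individual trips, recoverable from daily summaries alone.
#'
#' @param daily A tibble of daily metrics.
#' @param mean_col,n_col Columns holding the daily mean duration and the
#'   daily trip count (tidy-eval). Defaults are the nectar columns of
#'   [run_simulation()] output.
#' @return The weighted mean duration in seconds.
#' @examples
#' d <- tibble::tibble(mean_s = c(300, 600), n = c(10, 30))
#' weighted_mean_trip_duration(d, mean_s, n)  # 525
#' @export
weighted_mean_trip_duration <- function(daily,
                                        mean_col = mean_nectar_trip_s,
                                        n_col = n_nectar_trips) {
  m <- dplyr::pull(daily, {{ mean_col }})
  n <- dplyr::pull(daily, {{ n_col }})
  keep <- !is.na(m) & n > 0
  if (sum(n[keep]) == 0) {
    rlang::abort("No trips recorded: weighted mean duration is undefined.")
  }
  sum(m[keep] * n[keep]) / sum(n[keep])
}

#' Queens on the final simulation day
#'
#' The number of (hibernating) queens on the last timestep — December 31 of
#' the final year — used as the population-size proxy.
#'
#' @param daily A tibble of daily metrics with columns `day` and `n_queens`.
#' @return Integer count.
#' @export
hibernating_queens_at_end <- function(daily) {
  stopifnot(nrow(daily) > 0)
  daily$n_queens[which.max(daily$day)]
}

#' Mean number of colonies over the last three years
#'
#' Mean of the daily colony count over timesteps 731 onwards of a 5-year
#' run (or the last `3 * 365` steps of longer/shorter runs).
#'
#' @param daily A tibble of daily metrics.
#' @return Mean daily colony count.
#' @export
mean_colonies_last3y <- function(daily) {
  from <- max(1L, nrow(daily) - 3L * 365L + 1L)
  mean(daily$n_colonies[from:nrow(daily)])
}

#' Run a scenario grid experiment
#'
#' Runs every scenario for the given number of replicates, with replicate
#' seeds derived deterministically from the master seed, the scenario name
#' and the replicate index (recorded in the output for audit). Emits one
#' summary row per run.
#'
#' @param grid A scenario tibble as from [build_scenario_grid()] (subset
#'   rows for smaller experiments).
#' @param landscape A [generate_landscape()] result shared by all runs.
#' @param replicates Replicates per scenario.
#' @param master_seed Master seed from which all replicate seeds derive.
#' @param years,initial_queens,params,bees,config Passed to
#'   [run_simulation()].
#' @return An object of class `bombus_experiment`: a tibble with columns
#'   `scenario`, `replicate`, `seed`, `mean_nectar_trip_s`,
#'   `mean_pollen_trip_s`, `n_nectar_trips`, `n_pollen_trips`, `end_queens`,
#'   `mean_colonies_last3y`, carrying the grid and settings as attributes.
#' @examples
#' land <- generate_landscape(landscape_spec(n_patches = 12, seed = 5))
#' grid <- dplyr::filter(build_scenario_grid(), name == "HIGH_3600")
#' run_experiment(grid, land, replicates = 1, master_seed = 1, years = 1,
#'                initial_queens = 10)
#' @export
run_experiment <- function(grid, landscape, replicates = 20,
                           master_seed = 1L, years = 5,
                           initial_queens = 100, params = sim_params(),
                           bees = bee_species_defaults(), config = NULL) {
  stopifnot(replicates >= 1, nrow(grid) >= 1)
  rows <- purrr::map(seq_len(nrow(grid)), function(i) {
    sc <- as.list(grid[i, ])
    purrr::map(seq_len(replicates), function(r) {
      seed <- .derive_seed(master_seed, sc$name, r)
      sim <- run_simulation(sc, landscape, years = years,
                            initial_queens = initial_queens, seed = seed,
                            params = params, bees = bees, config = config)
      d <- sim$daily
      has_n <- any(d$n_nectar_trips > 0)
      has_p <- any(d$n_pollen_trips > 0)
      tibble::tibble(
        scenario = sc$name,
        replicate = r,
        seed = seed,
        mean_nectar_trip_s = if (has_n) {
          weighted_mean_trip_duration(d)
        } else {
          NA_real_
        },
        mean_pollen_trip_s = if (has_p) {
          weighted_mean_trip_duration(d, .data$mean_pollen_trip_s,
                                      .data$n_pollen_trips)
        } else {
          NA_real_
        },
        n_nectar_trips = sum(d$n_nectar_trips),
        n_pollen_trips = sum(d$n_pollen_trips),
        end_queens = hibernating_queens_at_end(d),
        mean_colonies_last3y = mean_colonies_last3y(d)
      )
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  structure(rows,
            grid = grid, master_seed = master_seed, years = years,
            initial_queens = initial_queens,
            class = c("bombus_experiment", class(rows)))
}

#' Per-scenario experiment summary
#'
#' Replicate means (and trip-count-pooled duration means) per scenario.
#'
#' @param experiment A [run_experiment()] result.
#' @return A tibble, one row per scenario.
#' @export
summarise_experiment <- function(experiment) {
  experiment |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$scenario) |>
    dplyr::summarise(
      replicates = dplyr::n(),
      mean_nectar_trip_s = if (sum(.data$n_nectar_trips) > 0) {
        stats::weighted.mean(.data$mean_nectar_trip_s, .data$n_nectar_trips,
                             na.rm = TRUE)
      } else {
        NA_real_
      },
      mean_pollen_trip_s = if (sum(.data$n_pollen_trips) > 0) {
        stats::weighted.mean(.data$mean_pollen_trip_s, .data$n_pollen_trips,
                             na.rm = TRUE)
      } else {
        NA_real_
      },
      mean_end_queens = mean(.data$end_queens),
      mean_colonies_last3y = mean(.data$mean_colonies_last3y),
      .groups = "drop"
    )
}
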