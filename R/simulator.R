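.resolve_scenario <- function(scenario) {
  if (is.character(scenario) && length(scenario) == 1L) {
    grid <- build_scenario_grid()
    i <- match(scenario, grid$name)
    if (is.na(i)) {
      rlang::abort(sprintf(
        "Unknown scenario %s. Valid names: %s.",
        sQuote(scenario), paste(grid$name, collapse = ", ")
      ))
    }
    scenario <- as.list(grid[i, ])
  }
  if (is.data.frame(scenario)) scenario <- as.list(scenario[1, ])
  needed <- c("fixed_handling_enabled", "mortality_model")
  if (!all(needed %in% names(scenario))) {
    rlang::abort("scenario needs fixed_handling_enabled and mortality_model.")
  }
  mortality_rate(scenario$mortality_model)  # validates the name
  if (isTRUE(scenario$fixed_handling_enabled) &&
      (is.null(scenario$fixed_handling_time_s) ||
         is.na(scenario$fixed_handling_time_s))) {
    rlang::abort("fixed engine scenarios need fixed_handling_time_s.")
  }
  scenario$name <- scenario$name %||% "custom"
  scenario
}

#' Run one colony/population simulation
#'
#' Executes `years * 365` daily steps on the given landscape: patch
#' replenishment, queen emergence/search/founding, colony foraging and
#' development, and daily metric recording. The initial queen population is
#' placed at simulation start; each queen draws her emergence day uniformly
#' in the bee species' emergence window. Fully reproducible under a fixed
#' seed.
#'
#' @param scenario A scenario name from [build_scenario_grid()] (e.g.
#'   `"ORG"`, `"HIGH_900"`), or a list with `fixed_handling_enabled`,
#'   `fixed_handling_time_s` and `mortality_model`.
#' @param landscape A [generate_landscape()] result, or a list with
#'   `patches`, `species` and `nest_capacity`.
#' @param years Number of 365-day years (no leap days).
#' @param initial_queens Hibernating queens present on January 1 of year 1.
#' @param seed Integer seed for the run's RNG stream.
#' @param params A [sim_params()].
#' @param bees One row of a bee-species table (see
#'   [bee_species_defaults()]).
#' @param config A [handling_config()] supplying `Tmax`, flight speed and
#'   crop capacity; its engine fields are overridden by the scenario.
#' @param record_trips Keep a per-trip log (off by default: the daily
#'   counters suffice for the summary statistics and full logs are large).
#' @return An object of class `bombus_sim`: list with `daily` (tibble of
#'   per-day metrics), `trips` (tibble or `NULL`), `totals`, `scenario`,
#'   `seed`, `years`.
#' @examples
#' land <- generate_landscape(landscape_spec(n_patches = 15, seed = 2))
#' sim <- run_simulation("HIGH_3600", land, years = 1, initial_queens = 20,
#'                       seed = 1)
#' sim$daily
#' @export
run_simulation <- function(scenario, landscape, years = 5,
                           initial_queens = 100, seed = 1L,
                           params = sim_params(),
                           bees = bee_species_defaults(),
                           config = NULL, record_trips = FALSE) {
  stopifnot(years >= 1, initial_queens >= 0)
  sc <- .resolve_scenario(scenario)
  bees <- bees[1, ]
  if (is.null(config)) {
    config <- handling_config(crop_capacity_ul = bees$crop_capacity_ul)
  }
  config$fixed_handling_enabled <- isTRUE(sc$fixed_handling_enabled)
  if (config$fixed_handling_enabled) {
    config$fixed_handling_time_s <- sc$fixed_handling_time_s
  }
  eng <- .engine_cfg(config, sc$mortality_model)

  patches <- if (inherits(landscape, "bombus_landscape") ||
                 is.list(landscape) && !is.data.frame(landscape)) {
    landscape$patches
  } else {
    rlang::abort("`landscape` must be a bombus_landscape-like list.")
  }
  if (nrow(patches) == 0) rlang::abort("landscape has no patches.")
  species <- landscape$species %||% flower_species_defaults()
  nest_capacity <- landscape$nest_capacity %||% 0L

  n_days <- years * 365L
  out_nq <- integer(n_days); out_nc <- integer(n_days)
  out_nn <- integer(n_days); out_np <- integer(n_days)
  out_nd <- rep(NA_real_, n_days); out_pd <- rep(NA_real_, n_days)

  .with_seed(seed, {
    pt <- .patch_state(patches, species)
    nest_pool <- which(pt$nest)
    ct <- .counters(record = record_trips)
    delivered_inflow <- 0

    emerg <- if (initial_queens > 0) {
      sample(bees$emergence_start_doy:bees$emergence_end_doy,
             initial_queens, replace = TRUE)
    } else {
      integer(0)
    }
    searching <- 0L
    hib_new <- 0L
    cols <- list()
    next_id <- 1L

    for (day in seq_len(n_days)) {
      doy <- ((day - 1L) %% 365L) + 1L
      alive_idx <- which(vapply(cols, function(c) c$alive, logical(1)))
      pop_gone <- length(emerg) == 0L && searching == 0L &&
        hib_new == 0L && length(alive_idx) == 0L
      if (pop_gone) {
        # extinction is absorbing: all remaining metrics are zero
        next
      }

      flowering <- pt$spstart <= doy & doy <= pt$spend
      pt$nstock <- ifelse(flowering, pt$ncap, 0)
      pt$pstock <- ifelse(flowering, pt$pcap, 0)

      # queen emergence
      if (length(emerg) > 0L) {
        em <- emerg <= doy
        if (any(em)) {
          searching <- searching + sum(em)
          emerg <- emerg[!em]
        }
      }

      # nest searching
      if (searching > 0L) {
        if (doy > params$search_deadline_doy) {
          searching <- 0L
        } else {
          free <- nest_capacity - length(alive_idx)
          if (free > 0L && length(nest_pool) > 0L) {
            p <- params$p_nest * free / nest_capacity
            founds <- min(stats::rbinom(1, searching, p), free, searching)
            if (founds > 0L) {
              for (k in seq_len(founds)) {
                np_i <- .sample1(nest_pool)
                glossa <- stats::runif(1, bees$glossa_min_mm,
                                       bees$glossa_max_mm)
                col <- .colony_new(
                  next_id,
                  pt$x[np_i] + stats::runif(1, -200, 200),
                  pt$y[np_i] + stats::runif(1, -200, 200),
                  pt, eng, glossa, bees$weight_g, params
                )
                cols[[length(cols) + 1L]] <- col
                next_id <- next_id + 1L
              }
              searching <- searching - founds
              alive_idx <- which(vapply(cols, function(c) c$alive,
                                        logical(1)))
            }
          }
          if (searching > 0L) {
            searching <- searching -
              stats::rbinom(1, searching, params$search_mortality)
          }
        }
      }

      # colony steps, randomised order
      nn0 <- ct$nn; np0 <- ct$np; nd0 <- ct$ndur; pd0 <- ct$pdur
      if (length(alive_idx) > 0L && doy < params$season_end_doy) {
        ord <- alive_idx[sample.int(length(alive_idx))]
        for (ci in ord) {
          col <- .colony_day(cols[[ci]], pt, eng, params, day, doy, ct)
          hib_new <- hib_new + col$new_queens
          cols[[ci]] <- col
        }
      } else if (doy >= params$season_end_doy && length(alive_idx) > 0L) {
        for (ci in alive_idx) {
          cols[[ci]]$alive <- FALSE
          cols[[ci]]$queen <- FALSE
        }
      }

      alive_idx <- which(vapply(cols, function(c) c$alive, logical(1)))
      nqueens_col <- sum(vapply(cols[alive_idx],
                                function(c) isTRUE(c$queen), logical(1)))
      out_nq[day] <- length(emerg) + searching + nqueens_col + hib_new
      out_nc[day] <- length(alive_idx)
      out_nn[day] <- ct$nn - nn0
      out_np[day] <- ct$np - np0
      if (out_nn[day] > 0L) out_nd[day] <- (ct$ndur - nd0) / out_nn[day]
      if (out_np[day] > 0L) out_pd[day] <- (ct$pdur - pd0) / out_np[day]

      # year boundary: overwinter the produced queens
      if (doy == 365L) {
        surv <- if (hib_new > 0L) {
          stats::rbinom(1, hib_new, params$p_overwinter)
        } else {
          0L
        }
        emerg <- if (surv > 0L) {
          sample(bees$emergence_start_doy:bees$emergence_end_doy,
                 surv, replace = TRUE)
        } else {
          integer(0)
        }
        searching <- 0L
        hib_new <- 0L
        cols <- list()  # colonies dissolved at season end; drop the dead
      }
    }

    delivered_inflow <- ct$delivered
    trips <- .trips_tbl(ct)
  })

  daily <- tibble::tibble(
    day = seq_len(n_days),
    n_queens = out_nq,
    n_colonies = out_nc,
    n_nectar_trips = out_nn,
    n_pollen_trips = out_np,
    mean_nectar_trip_s = out_nd,
    mean_pollen_trip_s = out_pd
  )
  structure(
    list(
      daily = daily,
      trips = trips,
      totals = list(nectar_delivered_ul = delivered_inflow),
      scenario = sc,
      seed = as.integer(seed),
      years = years
    ),
    class = "bombus_sim"
  )
}

#' @export
print.bombus_sim <- function(x, ...) {
  cat("<bombus_sim>", x$scenario$name, "| seed", x$seed, "|",
      x$years, "years (", nrow(x$daily), "days )\n")
  cat("  end-of-run queens:", hibernating_queens_at_end(x$daily), "\n")
  nd <- x$daily
  ok <- nd$n_nectar_trips > 0
  if (any(ok)) {
    cat("  weighted mean nectar trip:",
        round(weighted_mean_trip_duration(
          nd, mean_nectar_trip_s, n_nectar_trips), 2), "s over",
        sum(nd$n_nectar_trips), "trips\n")
  } else {
    cat("  no nectar trips recorded\n")
  }
  invisible(x)
}
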