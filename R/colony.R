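#' Create a colony state
#'
#' Builds the colony record used by the per-day operations: nest location,
#' worker-line traits, per-patch distances, empty memory and founding-stage
#' stores. Mainly useful for composing and testing the trip-level
#' operations; [run_simulation()] creates colonies internally.
#'
#' @param x,y Nest coordinates in metres.
#' @param patches A patch tibble (see [generate_landscape()]).
#' @param species A flower-species tibble.
#' @param config A [handling_config()].
#' @param params A [sim_params()].
#' @param glossa_mm,weight_g Worker-line traits; defaults from the default
#'   bee species (midpoint glossa).
#' @param id Colony identifier.
#' @return A list of class `bombus_colony`.
#' @examples
#' land <- generate_landscape(landscape_spec(n_patches = 10, seed = 1))
#' col <- colony_state(2000, 2000, land$patches, land$species, handling_config())
#' @export
colony_state <- function(x, y, patches, species, config = handling_config(),
                         params = sim_params(), glossa_mm = 9, weight_g = 0.195,
                         id = 1L) {
  stopifnot(inherits(config, "bombus_handling_config"),
            inherits(params, "bombus_sim_params"))
  pt <- .patch_state(patches, .validate_species(species))
  eng <- .engine_cfg(config, "high")
  col <- .colony_new(id, x, y, pt, eng, glossa_mm, weight_g, params)
  col$pt_tt <- pt$tt
  class(col) <- "bombus_colony"
  col
}

#' Select a foraging patch
#'
#' The colony's patch choice: among memorised patches with remaining stock
#' (plus, with exploration probability `epsilon`, one random unmemorised
#' patch; always explored when the memory is empty), pick the patch
#' maximising the expected intake rate — expected collected load divided by
#' the expected trip duration at the patch's current filling level. Ties
#' break to the lowest `patch_id`.
#'
#' @param colony A [colony_state()].
#' @param patches A patch tibble with current stocks.
#' @param config A [handling_config()].
#' @param params A [sim_params()].
#' @param type `"nectar"` or `"pollen"`.
#' @return The chosen `patch_id`, or `NA` if no patch has stock.
#' @export
select_patch <- function(colony, patches, config = handling_config(),
                         params = sim_params(), type = "nectar") {
  type_i <- match(match.arg(type, c("nectar", "pollen")),
                  c("nectar", "pollen"))
  pt <- .colony_pt(colony, patches)
  eng <- .engine_cfg(config, "high")
  sel <- .select_patch_idx(colony, pt, eng, params, type_i)
  if (sel[1] == 0) NA_integer_ else pt$id[sel[1]]
}

# Rebuild the engine patch view consistent with the colony's precomputed
# per-patch vectors (same patch order assumed).
.colony_pt <- function(colony, patches) {
  if (nrow(patches) != length(colony$dist)) {
    rlang::abort("`patches` must have the rows the colony was built against.")
  }
  e <- new.env(parent = emptyenv())
  e$id <- patches$patch_id
  e$x <- patches$x_m; e$y <- patches$y_m
  e$ncap <- patches$nectar_capacity_ul
  e$nstock <- patches$nectar_stock_ul
  e$pcap <- patches$pollen_capacity_g
  e$pstock <- patches$pollen_stock_g
  e$tt <- colony$pt_tt %||% rep(0, nrow(patches))
  e$n <- nrow(patches)
  e
}

#' Perform one nectar or pollen foraging trip
#'
#' Composes the trip machinery once: select a patch (unless `patch_id` is
#' given), compute the handling time with the configured engine at the
#' patch's current filling level and the trip duration from the nest-patch
#' distance, deplete the patch, draw trip mortality, and on survival deliver
#' the load to the colony store, pay the trip's metabolic cost and memorise
#' the patch.
#'
#' @param colony A [colony_state()].
#' @param patches A patch tibble with current stocks.
#' @param config A [handling_config()].
#' @param mortality_model `"high"`, `"intermediate"` or `"low"`.
#' @param params A [sim_params()].
#' @param patch_id Optional patch to force; default selects by intake rate.
#' @param force_survival `NULL` to draw mortality, or `TRUE`/`FALSE` to force
#'   the outcome (for deterministic composition tests).
#' @param day Day stamp recorded on the trip.
#' @return A list with `trip` (one-row tibble: `day`, `type`, `duration_s`,
#'   `patch_id`, `collected`, `forager_died`), `colony`, and `patches`; or
#'   `NULL` if no patch has stock.
#' @export
nectar_trip <- function(colony, patches, config = handling_config(),
                        mortality_model = "high", params = sim_params(),
                        patch_id = NULL, force_survival = NULL, day = 1L) {
  .do_trip(colony, patches, config, mortality_model, params, patch_id,
           force_survival, day, type_i = 1L)
}

#' @rdname nectar_trip
#' @export
pollen_trip <- function(colony, patches, config = handling_config(),
                        mortality_model = "high", params = sim_params(),
                        patch_id = NULL, force_survival = NULL, day = 1L) {
  .do_trip(colony, patches, config, mortality_model, params, patch_id,
           force_survival, day, type_i = 2L)
}

# Trips read per-patch vectors directly, so the engine state is built from
# the patch tibble alone (species data is baked into the colony record).
.do_trip <- function(colony, patches, config, mortality_model, params,
                     patch_id, force_survival, day, type_i) {
  pt <- new.env(parent = emptyenv())
  pt$id <- patches$patch_id
  pt$x <- patches$x_m; pt$y <- patches$y_m
  pt$ncap <- patches$nectar_capacity_ul
  pt$nstock <- patches$nectar_stock_ul
  pt$pcap <- patches$pollen_capacity_g
  pt$pstock <- patches$pollen_stock_g
  pt$tt <- colony$pt_tt %||% rep(0, nrow(patches))
  eng <- .engine_cfg(config, mortality_model)
  ct <- .counters(record = TRUE)
  if (is.null(patch_id)) {
    sel <- .select_patch_idx(colony, pt, eng, params, type_i)
    if (sel[1] == 0) return(NULL)
  } else {
    idx <- match(patch_id, pt$id)
    if (is.na(idx)) rlang::abort(sprintf("Unknown patch_id %s.", patch_id))
    stock <- if (type_i == 1L) pt$nstock[idx] else pt$pstock[idx]
    cap <- if (type_i == 1L) pt$ncap[idx] else pt$pcap[idx]
    if (stock <= 0) return(NULL)
    gamma <- stock / cap
    th <- if (type_i == 1L) {
      .th_nectar_at(colony, pt, eng, idx, gamma)
    } else {
      min(params$pollen_handling_base_s / gamma, eng$tmax)
    }
    sel <- c(idx, colony$flight[idx] + th, th)
  }
  res <- .exec_trip(colony, pt, eng, params, sel, type_i, ct, day,
                    force_survival = force_survival)
  trips <- .trips_tbl(ct)
  names(trips)[names(trips) == "died"] <- "forager_died"
  list(
    trip = trips,
    colony = res$col,
    patches = .patch_tbl(patches, pt)
  )
}

#' Run one colony-day
#'
#' Foragers take sequential nectar or pollen trips (whichever store has the
#' larger relative deficit) until the colony's store targets are met, no
#' stocked patch remains, or each forager's daily time budget is exhausted.
#' Afterwards brood develops, eggs are laid, sexuals are produced in season,
#' consumption is deducted and starvation is tracked.
#'
#' @inheritParams nectar_trip
#' @param day Absolute simulation day (1-based).
#' @param doy Day of year in `1:365`; defaults to `((day - 1) %% 365) + 1`.
#' @return A list with `colony`, `patches`, `trips` (tibble of the day's
#'   trips) and `new_queens`.
#' @export
colony_daily_step <- function(colony, patches, config = handling_config(),
                              mortality_model = "high", params = sim_params(),
                              day = 1L, doy = ((day - 1L) %% 365L) + 1L) {
  if (!isTRUE(colony$alive)) rlang::abort("colony must be alive.")
  pt <- new.env(parent = emptyenv())
  pt$id <- patches$patch_id
  pt$x <- patches$x_m; pt$y <- patches$y_m
  pt$ncap <- patches$nectar_capacity_ul
  pt$nstock <- patches$nectar_stock_ul
  pt$pcap <- patches$pollen_capacity_g
  pt$pstock <- patches$pollen_stock_g
  pt$tt <- colony$pt_tt %||% rep(0, nrow(patches))
  eng <- .engine_cfg(config, mortality_model)
  ct <- .counters(record = TRUE)
  col <- .colony_day(colony, pt, eng, params, day, doy, ct)
  list(
    colony = col,
    patches = .patch_tbl(patches, pt),
    trips = .trips_tbl(ct),
    new_queens = col$new_queens
  )
}

#' Produce new queens from colony surplus
#'
#' From the switch day onwards, surplus stores above a reserve are converted
#' into hibernating queens: `floor(surplus / cost_per_queen)`, additionally
#' limited by the pollen store and by the worker population.
#'
#' @param colony A colony record.
#' @param doy Day of year.
#' @param params A [sim_params()].
#' @param n_need Daily nectar consumption used to size the reserve;
#'   recomputed from the colony when `NULL`.
#' @return A list with `colony` (stores reduced) and `n_new`.
#' @export
produce_sexuals <- function(colony, doy, params = sim_params(),
                            n_need = NULL) {
  if (doy < params$switch_doy) return(list(colony = colony, n_new = 0L))
  wtot <- sum(colony$workers)
  if (is.null(n_need)) {
    n_need <- wtot * params$worker_consumption_ul +
      sum(colony$brood) * params$brood_consumption_ul +
      if (isTRUE(colony$queen)) params$queen_consumption_ul else 0
  }
  reserve <- params$queen_reserve_days * n_need
  q <- min(
    floor(max(0, colony$nectar - reserve) / params$cost_per_queen_ul),
    floor(colony$pollen / params$cost_per_queen_pollen_g),
    wtot
  )
  q <- max(0L, as.integer(q))
  if (q > 0L) {
    colony$nectar <- colony$nectar - q * params$cost_per_queen_ul
    colony$pollen <- colony$pollen - q * params$cost_per_queen_pollen_g
    colony$qprod <- (colony$qprod %||% 0L) + q
  }
  list(colony = colony, n_new = q)
}

#' Run one queen-day
#'
#' Before her emergence day a queen does nothing. A searching queen founds a
#' colony with probability `p_nest` scaled by nest-site availability
#' (`free_sites / nest_capacity`), cannot found when the cap is reached, and
#' risks daily search mortality; searching past the deadline is fatal.
#'
#' @param queen A list with `state` (`"hibernating"`, `"searching"`,
#'   `"founding"` or `"dead"`) and `emergence_doy`.
#' @param doy Day of year.
#' @param free_sites,nest_capacity Current free nest sites and the
#'   landscape's total nest-site capacity.
#' @param params A [sim_params()].
#' @return The updated queen list; `state` becomes `"searching"`,
#'   `"founding"` or `"dead"`, and `founded` is `TRUE` on the day a colony
#'   is founded.
#' @export
queen_daily_step <- function(queen, doy, free_sites, nest_capacity,
                             params = sim_params()) {
  queen$founded <- FALSE
  if (queen$state == "dead") return(queen)
  if (queen$state == "hibernating") {
    if (doy >= queen$emergence_doy) queen$state <- "searching" else
      return(queen)
  }
  if (queen$state == "searching") {
    if (doy > params$search_deadline_doy) {
      queen$state <- "dead"
      return(queen)
    }
    if (free_sites > 0 && nest_capacity > 0) {
      p <- params$p_nest * free_sites / nest_capacity
      if (stats::runif(1) < p) {
        queen$state <- "founding"
        queen$founded <- TRUE
        return(queen)
      }
    }
    if (stats::runif(1) < params$search_mortality) queen$state <- "dead"
  }
  queen
}
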