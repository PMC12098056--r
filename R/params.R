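#' Colony and life-cycle parameters
#'
#' Tunable constants of the simplified colony model. Every value is
#' config-exposed; defaults are the package's resource-poor calibration
#' (see the methods vignette for rationale and units).
#'
#' @param daily_budget_s Daily foraging time budget per worker (s).
#' @param founding_budget_s Daily foraging budget of a founding queen (s);
#'   half a worker's budget, the remainder spent incubating.
#' @param switch_doy Day of year when colonies switch to producing sexuals.
#' @param season_end_doy Day of year when all colony activity stops; colony
#'   queens die and colonies dissolve.
#' @param dev_time_d Egg-to-worker development time (days, aggregate).
#' @param worker_lifespan_d Worker lifespan (days).
#' @param max_eggs_per_day Maximum eggs laid per queen per day.
#' @param worker_consumption_ul,queen_consumption_ul,brood_consumption_ul
#'   Daily nectar consumption (microlitres) per worker, queen, brood item.
#' @param brood_pollen_g Daily pollen consumption per brood item (g).
#' @param forage_cost_ul_per_s Metabolic cost of foraging, in microlitres of
#'   nectar-equivalent per second of trip time, paid from the colony store
#'   on each completed trip.
#' @param pollen_load_g Pollen carried per trip (g).
#' @param pollen_handling_base_s Base pollen handling time (s), divided by
#'   the pollen filling level and capped at `Tmax`.
#' @param target_days Days of consumption the colony aims to hold in store.
#' @param egg_nectar_threshold_ul,egg_pollen_threshold_g Minimum stores
#'   required to lay eggs.
#' @param cost_per_queen_ul,cost_per_queen_pollen_g Resources to produce one
#'   new queen.
#' @param queen_reserve_days Days of consumption held back before surplus is
#'   turned into queens.
#' @param queen_quota_per_day Daily appetite (queens' worth of resources) the
#'   store target adds during the sexual season.
#' @param p_nest Daily nest-founding probability at full site availability.
#' @param search_deadline_doy Last day of year a queen may keep searching.
#' @param search_mortality Daily mortality of searching queens.
#' @param p_overwinter Overwinter survival probability of hibernating queens.
#' @param starvation_days Consecutive zero-nectar days before colony death.
#' @param epsilon Per-trip probability of exploring an unmemorised patch.
#' @param forager_share Fraction of workers foraging on a given day.
#' @param founding_nectar_ul,founding_pollen_g Body reserves a founding
#'   queen seeds her nest with.
#' @param founding_eggs_per_day Eggs laid per day during the founding stage.
#' @return A list of class `bombus_sim_params`.
#' @export
sim_params <- function(daily_budget_s = 28800,
                       founding_budget_s = 14400,
                       switch_doy = 196,
                       season_end_doy = 304,
                       dev_time_d = 28,
                       worker_lifespan_d = 30,
                       max_eggs_per_day = 4,
                       worker_consumption_ul = 12,
                       queen_consumption_ul = 20,
                       brood_consumption_ul = 8,
                       brood_pollen_g = 8e-4,
                       forage_cost_ul_per_s = 0.07,
                       pollen_load_g = 0.015,
                       pollen_handling_base_s = 300,
                       target_days = 2,
                       egg_nectar_threshold_ul = 200,
                       egg_pollen_threshold_g = 0.005,
                       cost_per_queen_ul = 1200,
                       cost_per_queen_pollen_g = 0.05,
                       queen_reserve_days = 5,
                       queen_quota_per_day = 1,
                       p_nest = 0.2,
                       search_deadline_doy = 181,
                       search_mortality = 0.03,
                       p_overwinter = 0.3,
                       starvation_days = 2,
                       epsilon = 0.1,
                       forager_share = 0.3,
                       founding_nectar_ul = 300,
                       founding_pollen_g = 0.01,
                       founding_eggs_per_day = 3) {
  p <- as.list(environment())
  stopifnot(
    p$daily_budget_s > 0, p$founding_budget_s > 0,
    p$switch_doy > 1, p$season_end_doy <= 365,
    p$dev_time_d >= 1, p$worker_lifespan_d >= 1,
    p$forage_cost_ul_per_s >= 0, p$starvation_days >= 1,
    p$epsilon >= 0, p$epsilon <= 1,
    p$p_overwinter >= 0, p$p_overwinter <= 1,
    p$forager_share > 0, p$forager_share <= 1
  )
  structure(p, class = "bombus_sim_params")
}

#' Default bee-species table
#'
#' One *Bombus terrestris*-like species. Glossa length is drawn uniformly in
#' `[glossa_min_mm, glossa_max_mm]` per colony line; weight 0.195 g.
#'
#' @return A tibble with columns `name`, `glossa_min_mm`, `glossa_max_mm`,
#'   `weight_g`, `crop_capacity_ul`, `emergence_start_doy`,
#'   `emergence_end_doy`.
#' @export
bee_species_defaults <- function() {
  tibble::tibble(
    name = "terrestris",
    glossa_min_mm = 6.9,
    glossa_max_mm = 11.1,
    weight_g = 0.195,
    crop_capacity_ul = 120,
    emergence_start_doy = 60L,
    emergence_end_doy = 105L
  )
}

.bee_cols <- c("name", "glossa_min_mm", "glossa_max_mm", "weight_g",
               "crop_capacity_ul", "emergence_start_doy", "emergence_end_doy")

#' Read or write a bee-species table
#'
#' CSV with header `name,glossa_min_mm,glossa_max_mm,weight_g,
#' crop_capacity_ul,emergence_start_doy,emergence_end_doy`.
#'
#' @param path File path.
#' @return `read_bee_species()` returns a validated tibble.
#' @export
read_bee_species <- function(path) {
  b <- readr::read_csv(path, show_col_types = FALSE)
  b <- .check_columns(b, .bee_cols, "Bee-species table")
  if (any(b$glossa_min_mm <= 0) || any(b$glossa_max_mm < b$glossa_min_mm) ||
      any(b$weight_g <= 0) || any(b$crop_capacity_ul <= 0)) {
    rlang::abort("Bee-species table has out-of-range values.")
  }
  tibble::as_tibble(b)
}

#' @rdname read_bee_species
#' @param bees A bee-species tibble.
#' @export
write_bee_species <- function(bees, path) {
  readr::write_csv(bees[.bee_cols], path)
  invisible(path)
}
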