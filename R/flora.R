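#' Default flower-species table
#'
#' Six species matched to the habitats of the default resource-poor
#' landscape: two pasture forbs, a hedgerow shrub, a scrub forb, a sown
#' wildflower mix, and maize (wind-pollinated: pollen only, during a brief
#' pulse). Corolla depths are kept within the reach of short-tongued workers
#' so the mechanistic engine produces trips of a few hundred seconds on full
#' patches.
#'
#' @return A tibble, one row per species, with the columns documented in
#'   [read_flower_species()].
#' @examples
#' flower_species_defaults()
#' @export
flower_species_defaults <- function() {
  tibble::tibble(
    name = c("pasture_forb", "clover", "bramble", "willowherb",
             "wildflower_mix", "maize"),
    corolla_depth_mm = c(4, 2, 3, 5, 6, 0),
    nectar_volume_ul = c(1.5, 1.0, 2.5, 2.0, 2.0, 1.0),
    interflower_travel_s = c(2.0, 1.5, 2.5, 2.0, 1.5, 2.0),
    pollen_per_flower_g = c(2e-5, 1e-5, 3e-5, 2e-5, 4e-5, 8e-5),
    flowering_start_doy = c(75L, 110L, 70L, 65L, 90L, 190L),
    flowering_end_doy = c(280L, 270L, 250L, 250L, 280L, 210L),
    sugar_energy_kj_per_ul = c(5.8, 5.2, 6.1, 5.5, 5.9, 0)
  )
}

.species_cols <- c(
  "name", "corolla_depth_mm", "nectar_volume_ul", "interflower_travel_s",
  "pollen_per_flower_g", "flowering_start_doy", "flowering_end_doy",
  "sugar_energy_kj_per_ul"
)

.patch_cols <- c(
  "patch_id", "x_m", "y_m", "habitat", "species", "n_flowers",
  "nectar_capacity_ul", "pollen_capacity_g"
)

.check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    rlang::abort(sprintf(
      "%s is missing required column(s): %s.",
      what, paste(missing, collapse = ", ")
    ))
  }
  extra <- setdiff(names(df), required)
  if (length(extra) > 0) {
    rlang::warn(sprintf(
      "%s has unknown column(s) %s; ignoring them.",
      what, paste(extra, collapse = ", ")
    ))
  }
  df[required]
}

.validate_species <- function(sp) {
  sp <- .check_columns(sp, .species_cols, "Flower-species table")
  bad <- function(cond, msg) if (any(cond)) rlang::abort(msg)
  bad(sp$corolla_depth_mm < 0, "corolla_depth_mm must be >= 0.")
  bad(sp$nectar_volume_ul <= 0, "nectar_volume_ul must be > 0.")
  bad(sp$interflower_travel_s < 0, "interflower_travel_s must be >= 0.")
  bad(sp$flowering_start_doy < 1 | sp$flowering_end_doy > 365 |
        sp$flowering_start_doy > sp$flowering_end_doy,
      "flowering window must satisfy 1 <= start <= end <= 365.")
  bad(duplicated(sp$name), "species names must be unique.")
  tibble::as_tibble(sp)
}

#' Read or write a flower-species table
#'
#' CSV with header `name,corolla_depth_mm,nectar_volume_ul,
#' interflower_travel_s,pollen_per_flower_g,flowering_start_doy,
#' flowering_end_doy,sugar_energy_kj_per_ul` (UTF-8, comma-separated,
#' `.` decimal). Missing columns are an error naming the column; unknown
#' extra columns are ignored with a warning.
#'
#' @param path File path.
#' @return `read_flower_species()` returns a validated tibble.
#' @export
read_flower_species <- function(path) {
  sp <- readr::read_csv(path, show_col_types = FALSE)
  .validate_species(sp)
}

#' @rdname read_flower_species
#' @param species A flower-species tibble.
#' @export
write_flower_species <- function(species, path) {
  readr::write_csv(.validate_species(species), path)
  invisible(path)
}

#' Patch filling level
#'
#' The fraction of a patch's daily nectar capacity still in stock, the
#' volume-based proxy for the percentage of flowers still filled. Degenerate
#' patches with zero capacity have filling level 0.
#'
#' @param patches A patch tibble (columns `nectar_stock_ul`,
#'   `nectar_capacity_ul`; see [generate_landscape()]).
#' @return Numeric vector in `[0, 1]`, one value per patch.
#' @examples
#' p <- tibble::tibble(nectar_stock_ul = c(250, 0), nectar_capacity_ul = c(500, 0))
#' filling_level(p)  # 0.5 0
#' @export
filling_level <- function(patches) {
  ifelse(patches$nectar_capacity_ul > 0,
         patches$nectar_stock_ul / patches$nectar_capacity_ul, 0)
}

#' Pollen filling level
#'
#' @param patches A patch tibble.
#' @return Numeric vector in `[0, 1]`.
#' @export
pollen_filling_level <- function(patches) {
  ifelse(patches$pollen_capacity_g > 0,
         patches$pollen_stock_g / patches$pollen_capacity_g, 0)
}

#' Deplete a patch
#'
#' Removes up to `requested_ul` nectar (or `requested_g` pollen with
#' `resource = "pollen"`) from one patch; the collected amount is clamped to
#' the current stock and the stock never goes negative.
#'
#' @param patches A patch tibble.
#' @param patch_id Identifier of the patch to deplete.
#' @param requested Requested amount (microlitres of nectar or grams of
#'   pollen); must be >= 0.
#' @param resource `"nectar"` or `"pollen"`.
#' @return A list with `collected` (amount actually removed) and `patches`
#'   (the updated tibble).
#' @examples
#' land <- generate_landscape(landscape_spec(n_patches = 5, seed = 1))
#' deplete(land$patches, land$patches$patch_id[1], 50)$collected
#' @export
deplete <- function(patches, patch_id, requested, resource = "nectar") {
  if (!is.numeric(requested) || length(requested) != 1 || requested < 0) {
    rlang::abort("`requested` must be a single number >= 0.")
  }
  resource <- match.arg(resource, c("nectar", "pollen"))
  i <- match(patch_id, patches$patch_id)
  if (is.na(i)) rlang::abort(sprintf("Unknown patch_id %s.", patch_id))
  col <- if (resource == "nectar") "nectar_stock_ul" else "pollen_stock_g"
  stock <- patches[[col]][i]
  collected <- min(requested, stock)
  patches[[col]][i] <- stock - collected
  list(collected = collected, patches = patches)
}

#' Daily replenishment of patch stocks
#'
#' Resets each patch's nectar and pollen stocks to its daily capacity when
#' the day of year falls inside the flowering window of the patch's species
#' (inclusive bounds), and to zero outside it. The model replenishes by a
#' full daily reset: the time step is one day and no sub-daily secretion
#' kinetics are modelled.
#'
#' @param patches A patch tibble.
#' @param species A flower-species tibble supplying flowering windows.
#' @param day_of_year Integer in `1:365`.
#' @return The updated patch tibble.
#' @export
replenish_daily <- function(patches, species, day_of_year) {
  stopifnot(day_of_year >= 1, day_of_year <= 365)
  i <- match(patches$species, species$name)
  if (any(is.na(i))) {
    rlang::abort(sprintf(
      "Patch species not in species table: %s.",
      paste(unique(patches$species[is.na(i)]), collapse = ", ")
    ))
  }
  flowering <- species$flowering_start_doy[i] <= day_of_year &
    day_of_year <= species$flowering_end_doy[i]
  patches$nectar_stock_ul <- ifelse(flowering, patches$nectar_capacity_ul, 0)
  patches$pollen_stock_g <- ifelse(flowering, patches$pollen_capacity_g, 0)
  patches
}
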