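# Shared fixtures, all built in code.

# Small landscape for fast unit tests.
small_landscape <- function(seed = 3, n_patches = 12) {
  generate_landscape(landscape_spec(n_patches = n_patches, seed = seed))
}

# A hand-built two-patch table with equal nest distances, for selection and
# trip tests (patch 1 full, patch 2 partly depleted by default).
two_patches <- function(stock = c(1000, 200), capacity = c(1000, 1000),
                        pollen = c(0.5, 0.5)) {
  tibble::tibble(
    patch_id = 1:2,
    x_m = c(1000, 3000), y_m = c(2000, 2000),
    habitat = "semi_improved_pasture",
    species = "pasture_forb",
    n_flowers = 1000L,
    nectar_capacity_ul = capacity,
    nectar_stock_ul = stock,
    pollen_capacity_g = 0.5,
    pollen_stock_g = pollen
  )
}

# Colony sitting exactly between the two patches (1000 m to each), with
# both patches memorised and exploration disabled via params.
midpoint_colony <- function(patches = two_patches(),
                            config = handling_config()) {
  col <- colony_state(2000, 2000, patches, flower_species_defaults(),
                      config = config)
  col$mem <- c(1L, 2L)
  col
}

no_explore <- function(...) sim_params(epsilon = 0, ...)
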