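#' Specification for the synthetic resource-poor landscape
#'
#' Parameterises the fixture generator: a square landscape of point patches
#' whose habitat mix emulates a resource-poor mixed farm (semi-improved
#' pasture, maize, hedgerow, scrub, permanent pasture and a small
#' flower-rich plot). Patch centroids are placed uniformly at random;
#' habitats are drawn from the area-fraction multinomial; nectar and pollen
#' capacities come from the per-habitat table scaled by `richness`.
#'
#' @param extent_m Side length of the square landscape in metres.
#' @param n_patches Number of food-source patches.
#' @param habitat_mix Named numeric vector of area fractions over the six
#'   habitat types; must sum to 1.
#' @param habitat_table Per-habitat tibble assigning a flower species and
#'   daily nectar (microlitres) and pollen (grams) capacities per patch.
#' @param richness Multiplier applied to all floral capacities; 1 is the
#'   default resource-poor calibration.
#' @param sites_per_nest_patch Nest sites contributed by each hedgerow or
#'   scrub patch; sets the landscape's nest-site capacity.
#' @param seed Integer seed making generation deterministic.
#' @return A list of class `bombus_landscape_spec`.
#' @examples
#' landscape_spec(n_patches = 20, seed = 7)
#' @export
landscape_spec <- function(extent_m = 4000,
                           n_patches = 60,
                           habitat_mix = c(
                             semi_improved_pasture = 0.32,
                             permanent_pasture = 0.27,
                             maize = 0.20,
                             hedgerow = 0.08,
                             scrub = 0.08,
                             flower_rich_plot = 0.05
                           ),
                           habitat_table = default_habitat_table(),
                           richness = 1,
                           sites_per_nest_patch = 1,
                           seed = 1L) {
  stopifnot(
    extent_m > 0, n_patches >= 1, richness > 0, sites_per_nest_patch >= 0
  )
  if (length(habitat_mix) == 0) rlang::abort("`habitat_mix` must be non-empty.")
  if (abs(sum(habitat_mix) - 1) > 1e-8) {
    rlang::abort("`habitat_mix` fractions must sum to 1.")
  }
  if (!all(names(habitat_mix) %in% habitat_table$habitat)) {
    rlang::abort("every habitat in `habitat_mix` needs a `habitat_table` row.")
  }
  structure(
    list(
      extent_m = extent_m, n_patches = as.integer(n_patches),
      habitat_mix = habitat_mix, habitat_table = habitat_table,
      richness = richness, sites_per_nest_patch = sites_per_nest_patch,
      seed = as.integer(seed)
    ),
    class = "bombus_landscape_spec"
  )
}

#' Per-habitat floral assignment and capacities
#'
#' Daily per-patch nectar and pollen capacities for the default resource-poor
#' calibration. Maize provides no nectar: only a pollen pulse during its
#' brief flowering window.
#'
#' @return A tibble with columns `habitat`, `species`, `nectar_capacity_ul`,
#'   `pollen_capacity_g`.
#' @export
default_habitat_table <- function() {
  tibble::tibble(
    habitat = c("semi_improved_pasture", "permanent_pasture", "maize",
                "hedgerow", "scrub", "flower_rich_plot"),
    species = c("pasture_forb", "clover", "maize",
                "bramble", "willowherb", "wildflower_mix"),
    nectar_capacity_ul = c(11000, 9000, 0, 18000, 14000, 50000),
    pollen_capacity_g = c(0.7, 0.6, 2.2, 1.0, 0.8, 2.0)
  )
}

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic landscape
#'
#' Places `n_patches` point patches uniformly in the square extent, assigns
#' habitats from the area-fraction multinomial and capacities from the
#' per-habitat table (scaled by `richness`), and derives the nest-site
#' capacity from the number of hedgerow and scrub patches. Deterministic
#' given the spec's seed.
#'
#' @param spec A [landscape_spec()].
#' @param species A flower-species tibble; defaults to
#'   [flower_species_defaults()].
#' @return A list of class `bombus_landscape` with elements `patches`
#'   (tibble with runtime stock columns initialised to 0), `nest_capacity`,
#'   `species`, and `spec`.
#' @examples
#' land <- generate_landscape(landscape_spec(n_patches = 10, seed = 3))
#' land$patches
#' @export
generate_landscape <- function(spec = landscape_spec(),
                               species = flower_species_defaults()) {
  stopifnot(inherits(spec, "bombus_landscape_spec"))
  species <- .validate_species(species)
  missing_sp <- setdiff(spec$habitat_table$species, species$name)
  if (length(missing_sp) > 0) {
    rlang::abort(sprintf("habitat_table species not in species table: %s.",
                         paste(missing_sp, collapse = ", ")))
  }
  n <- spec$n_patches
  patches <- .with_seed(spec$seed, {
    habitat <- sample(names(spec$habitat_mix), n, replace = TRUE,
                      prob = spec$habitat_mix)
    tibble::tibble(
      patch_id = seq_len(n),
      x_m = stats::runif(n, 0, spec$extent_m),
      y_m = stats::runif(n, 0, spec$extent_m),
      habitat = habitat
    )
  })
  ht <- spec$habitat_table
  j <- match(patches$habitat, ht$habitat)
  patches$species <- ht$species[j]
  patches$nectar_capacity_ul <- ht$nectar_capacity_ul[j] * spec$richness
  patches$pollen_capacity_g <- ht$pollen_capacity_g[j] * spec$richness
  k <- match(patches$species, species$name)
  patches$n_flowers <- as.integer(ifelse(
    species$nectar_volume_ul[k] > 0,
    round(patches$nectar_capacity_ul / species$nectar_volume_ul[k]), 0
  ))
  patches$nectar_stock_ul <- 0
  patches$pollen_stock_g <- 0
  patches <- patches[, c(.patch_cols, "nectar_stock_ul", "pollen_stock_g")]

  nest_capacity <- spec$sites_per_nest_patch *
    sum(patches$habitat %in% c("hedgerow", "scrub"))
  structure(
    list(patches = patches, nest_capacity = as.integer(nest_capacity),
         species = species, spec = spec),
    class = "bombus_landscape"
  )
}

#' @export
print.bombus_landscape <- function(x, ...) {
  cat("<bombus landscape>", nrow(x$patches), "patches |",
      "nest capacity", x$nest_capacity, "|",
      "total daily nectar", sum(x$patches$nectar_capacity_ul), "ul\n")
  print(dplyr::count(x$patches, .data$habitat))
  invisible(x)
}

#' Read or write a landscape patch table
#'
#' CSV with header `patch_id,x_m,y_m,habitat,species,n_flowers,
#' nectar_capacity_ul,pollen_capacity_g`. Runtime stock columns are not
#' persisted; on reading they are initialised to zero. Missing columns are
#' an error naming the column; unknown extra columns are ignored with a
#' warning.
#'
#' @param path File path.
#' @return `read_landscape()` returns a patch tibble.
#' @export
read_landscape <- function(path) {
  p <- readr::read_csv(path, show_col_types = FALSE)
  p <- .check_columns(p, .patch_cols, "Landscape table")
  if (any(p$n_flowers < 0) || any(p$nectar_capacity_ul < 0) ||
      any(p$pollen_capacity_g < 0)) {
    rlang::abort("n_flowers and capacities must be >= 0.")
  }
  if (any(duplicated(p$patch_id))) rlang::abort("patch_id must be unique.")
  p$nectar_stock_ul <- 0
  p$pollen_stock_g <- 0
  tibble::as_tibble(p)
}

#' @rdname read_landscape
#' @param patches A patch tibble (or a `bombus_landscape`, whose patches are
#'   written).
#' @export
write_landscape <- function(patches, path) {
  if (inherits(patches, "bombus_landscape")) patches <- patches$patches
  readr::write_csv(patches[.patch_cols], path)
  invisible(path)
}
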