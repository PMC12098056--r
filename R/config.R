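#' Default general configuration
#'
#' Every key of the general parameter file with its documented default.
#' The engine switch `FixedHandlingTime?` and its companion
#' `FixedHandlingTime_s`, and the `ForagingMortalityModel` label, follow the
#' general-parameter-file naming convention; the remaining keys configure
#' the handling machinery and the experiment design.
#'
#' @return A named list of class `bombus_config`.
#' @export
default_config <- function() {
  structure(
    list(
      `FixedHandlingTime?` = FALSE,
      FixedHandlingTime_s = 900,
      ForagingMortalityModel = "high",
      t_max_s = 3600,
      flight_speed_m_s = 5,
      crop_capacity_ul = 120,
      years = 5,
      initial_queens = 100,
      replicates = 20,
      master_seed = 1,
      landscape = NULL,
      species_file = NULL,
      bee_species_file = NULL
    ),
    class = "bombus_config"
  )
}

.parse_bool <- function(x, key) {
  if (is.logical(x) && length(x) == 1 && !is.na(x)) return(x)
  if (is.character(x) && length(x) == 1 &&
      toupper(x) %in% c("TRUE", "FALSE")) {
    return(toupper(x) == "TRUE")
  }
  rlang::abort(sprintf("Key `%s` must be TRUE or FALSE.", key))
}

.parse_num <- function(x, key, min = -Inf, max = Inf) {
  if (is.character(x)) x <- suppressWarnings(as.numeric(x))
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x > max) {
    rlang::abort(sprintf(
      "Key `%s` must be a number in [%s, %s].", key, min, max
    ))
  }
  x
}

#' Parse and validate a general configuration
#'
#' Accepts a YAML file path or a named list. Unknown keys are rejected;
#' booleans accept `TRUE`/`FALSE` in either logical or upper-case string
#' form; out-of-range or mistyped values raise an error naming the key.
#'
#' @param x YAML file path or named list of overrides.
#' @return A validated `bombus_config` list (defaults filled in).
#' @examples
#' cfg <- parse_config(list(`FixedHandlingTime?` = "TRUE",
#'                          FixedHandlingTime_s = 900))
#' cfg$`FixedHandlingTime?`
#' @export
parse_config <- function(x = list()) {
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) rlang::abort(sprintf("Config file not found: %s", x))
    x <- yaml::read_yaml(x)
    if (is.null(x)) x <- list()
  }
  if (!is.list(x)) rlang::abort("Config must be a file path or a named list.")
  cfg <- default_config()
  unknown <- setdiff(names(x), names(cfg))
  if (length(unknown) > 0) {
    rlang::abort(sprintf("Unknown config key(s): %s.",
                         paste(unknown, collapse = ", ")))
  }
  cfg[names(x)] <- x

  cfg$`FixedHandlingTime?` <- .parse_bool(cfg$`FixedHandlingTime?`,
                                          "FixedHandlingTime?")
  cfg$FixedHandlingTime_s <- .parse_num(cfg$FixedHandlingTime_s,
                                        "FixedHandlingTime_s", min = 1e-9)
  if (!is.character(cfg$ForagingMortalityModel) ||
      !(cfg$ForagingMortalityModel %in% mortality_models()$name)) {
    rlang::abort(sprintf(
      "Key `ForagingMortalityModel` must be one of: %s.",
      paste(mortality_models()$name, collapse = ", ")
    ))
  }
  cfg$t_max_s <- .parse_num(cfg$t_max_s, "t_max_s", min = 1e-9)
  cfg$flight_speed_m_s <- .parse_num(cfg$flight_speed_m_s,
                                     "flight_speed_m_s", min = 1e-9)
  cfg$crop_capacity_ul <- .parse_num(cfg$crop_capacity_ul,
                                     "crop_capacity_ul", min = 1e-9)
  cfg$years <- .parse_num(cfg$years, "years", min = 1)
  cfg$initial_queens <- .parse_num(cfg$initial_queens, "initial_queens",
                                   min = 0)
  cfg$replicates <- .parse_num(cfg$replicates, "replicates", min = 1)
  cfg$master_seed <- .parse_num(cfg$master_seed, "master_seed")
  cfg
}

#' Handling configuration from a general configuration
#'
#' @param cfg A [parse_config()] result.
#' @return A [handling_config()].
#' @export
as_handling_config <- function(cfg) {
  handling_config(
    fixed_handling_enabled = cfg$`FixedHandlingTime?`,
    fixed_handling_time_s = cfg$FixedHandlingTime_s,
    t_max_s = cfg$t_max_s,
    flight_speed_m_s = cfg$flight_speed_m_s,
    crop_capacity_ul = cfg$crop_capacity_ul
  )
}

#' Scenario implied by a general configuration
#'
#' @param cfg A [parse_config()] result.
#' @return A scenario list usable by [run_simulation()].
#' @export
as_scenario <- function(cfg) {
  list(
    name = "config",
    fixed_handling_enabled = cfg$`FixedHandlingTime?`,
    fixed_handling_time_s = if (cfg$`FixedHandlingTime?`) {
      cfg$FixedHandlingTime_s
    } else {
      NA_real_
    },
    mortality_model = cfg$ForagingMortalityModel
  )
}
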