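#' Handling-time engine configuration
#'
#' Collects the constants that the trip-duration machinery needs: which
#' handling-time engine is active, the fixed handling time used by the
#' simplified engine, the handling-time cap `Tmax`, the flight speed and the
#' nectar crop capacity of a forager.
#'
#' @param fixed_handling_enabled Logical. `TRUE` selects the fixed
#'   handling-time engine; `FALSE` the mechanistic Harder engine.
#' @param fixed_handling_time_s Constant handling time in seconds used when
#'   the fixed engine is active. Divided by the patch filling level and
#'   capped at `t_max_s`.
#' @param t_max_s Maximum handling time `Tmax` in seconds. Handling times are
#'   capped here so that almost-empty patches cannot produce unbounded trips.
#' @param flight_speed_m_s Flight speed `v` in metres per second.
#' @param crop_capacity_ul Nectar crop capacity of a forager in microlitres;
#'   sets the number of flowers needed per load.
#' @return A list of class `bombus_handling_config`.
#' @examples
#' handling_config(fixed_handling_enabled = TRUE, fixed_handling_time_s = 900)
#' @export
handling_config <- function(fixed_handling_enabled = FALSE,
                            fixed_handling_time_s = 900,
                            t_max_s = 3600,
                            flight_speed_m_s = 5,
                            crop_capacity_ul = 120) {
  stopifnot(
    is.logical(fixed_handling_enabled), length(fixed_handling_enabled) == 1L,
    !is.na(fixed_handling_enabled),
    is.numeric(fixed_handling_time_s), fixed_handling_time_s > 0,
    is.numeric(t_max_s), t_max_s > 0,
    is.numeric(flight_speed_m_s), flight_speed_m_s > 0,
    is.numeric(crop_capacity_ul), crop_capacity_ul > 0
  )
  structure(
    list(
      fixed_handling_enabled = fixed_handling_enabled,
      fixed_handling_time_s = as.numeric(fixed_handling_time_s),
      t_max_s = as.numeric(t_max_s),
      flight_speed_m_s = as.numeric(flight_speed_m_s),
      crop_capacity_ul = as.numeric(crop_capacity_ul)
    ),
    class = "bombus_handling_config"
  )
}

#' Forager traits used by the Harder engine
#'
#' @param glossa_mm Glossa (tongue) length `G` in millimetres.
#' @param weight_g Body weight `W` in grams.
#' @return A list of class `bombus_forager_traits`.
#' @examples
#' forager_traits(glossa_mm = 11.1, weight_g = 0.195)
#' @export
forager_traits <- function(glossa_mm, weight_g) {
  stopifnot(
    is.numeric(glossa_mm), all(is.finite(glossa_mm)), all(glossa_mm > 0),
    is.numeric(weight_g), all(is.finite(weight_g)), all(weight_g > 0)
  )
  structure(list(glossa_mm = glossa_mm, weight_g = weight_g),
            class = "bombus_forager_traits")
}

#' Per-flower access time
#'
#' Time to access one flower, a linear function of corolla depth:
#' `Ta = 0.3 + 0.04 * C` seconds.
#'
#' @param corolla_depth_mm Corolla depth `C` in millimetres (vectorised).
#' @return Access time in seconds.
#' @examples
#' access_time(0)   # 0.3
#' access_time(19)  # 1.06
#' @export
access_time <- function(corolla_depth_mm) {
  if (!is.numeric(corolla_depth_mm) || any(!is.finite(corolla_depth_mm)) ||
      any(corolla_depth_mm < 0)) {
    rlang::abort("`corolla_depth_mm` must be finite and >= 0.")
  }
  0.3 + 0.04 * corolla_depth_mm
}

#' Per-flower ingestion time (Harder regression)
#'
#' Time to ingest the nectar of one flower, from Harder's lab regressions:
#' `Ti = log10(V + 1) / log10(0.3 * W^(1/3) * G^1.41 * (1 - C/G)^0.4)
#'       - 0.3 * Ta + 1`.
#'
#' The function has a vertical asymptote where the argument of the
#' denominator's logarithm crosses 1, which for realistic weights sits at a
#' corolla depth slightly below the glossa length. At or beyond the pole
#' (including `C >= G`, where the nectar is physically unreachable) the
#' ingestion time is unbounded and `Inf` is returned; downstream capping maps
#' it to `Tmax`.
#'
#' @param nectar_volume_ul Per-flower nectar volume `V` in microlitres
#'   (vectorised).
#' @param traits A [forager_traits()] object (`G`, `W`).
#' @param corolla_depth_mm Corolla depth `C` in millimetres (vectorised).
#' @param access_s Per-flower access time `Ta`; defaults to
#'   [access_time()] of `corolla_depth_mm`.
#' @return Ingestion time in seconds, or `Inf` at/beyond the pole.
#' @examples
#' ingestion_time(0.5, forager_traits(11.1, 0.195), corolla_depth_mm = 0)
#' @export
ingestion_time <- function(nectar_volume_ul, traits, corolla_depth_mm,
                           access_s = access_time(corolla_depth_mm)) {
  stopifnot(inherits(traits, "bombus_forager_traits"))
  if (!is.numeric(nectar_volume_ul) || any(!is.finite(nectar_volume_ul)) ||
      any(nectar_volume_ul < 0)) {
    rlang::abort("`nectar_volume_ul` must be finite and >= 0.")
  }
  if (!is.numeric(corolla_depth_mm) || any(!is.finite(corolla_depth_mm)) ||
      any(corolla_depth_mm < 0)) {
    rlang::abort("`corolla_depth_mm` must be finite and >= 0.")
  }
  G <- traits$glossa_mm
  W <- traits$weight_g
  n <- max(length(nectar_volume_ul), length(corolla_depth_mm), length(G))
  V <- rep_len(nectar_volume_ul, n)
  C <- rep_len(corolla_depth_mm, n)
  G <- rep_len(G, n)
  W <- rep_len(W, n)
  Ta <- rep_len(access_s, n)

  reach <- 1 - C / G
  arg <- ifelse(reach > 0, 0.3 * W^(1 / 3) * G^1.41 * reach^0.4, NA_real_)
  denom <- log10(arg)
  ti <- log10(V + 1) / denom - 0.3 * Ta + 1
  # Past the pole the denominator is <= 0 and the parse yields nonsense
  # (negative or undefined): treat as unbounded, to be capped at Tmax.
  unbounded <- is.na(denom) | denom <= 0 | !is.finite(ti) | ti < 0
  ti[unbounded] <- Inf
  ti
}

#' Flowers needed to fill one crop load
#'
#' @param crop_capacity_ul Crop capacity in microlitres.
#' @param nectar_volume_ul Per-flower nectar volume in microlitres.
#' @return Integer count `Nflowers = ceiling(crop / V)`, at least 1.
#' @examples
#' n_flowers_per_load(120, 0.5)  # 240
#' @export
n_flowers_per_load <- function(crop_capacity_ul, nectar_volume_ul) {
  if (!is.numeric(crop_capacity_ul) || any(crop_capacity_ul <= 0)) {
    rlang::abort("`crop_capacity_ul` must be > 0.")
  }
  if (!is.numeric(nectar_volume_ul) || any(nectar_volume_ul <= 0)) {
    rlang::abort("`nectar_volume_ul` must be > 0.")
  }
  pmax(1L, as.integer(ceiling(crop_capacity_ul / nectar_volume_ul)))
}

#' Harder-engine handling time for one nectar load
#'
#' Total handling time
#' `Th = ((Tt + Ta) / gamma + Ti) * Nflowers`, capped at `t_max_s`. Both the
#' inter-flower travel time and the access time are inflated by the patch
#' filling level `gamma`, representing the longer search for still-filled
#' flowers on a depleted patch. A filling level of 0 or an unbounded
#' ingestion time returns the cap.
#'
#' @param interflower_s Inter-flower travel time `Tt` in seconds (vectorised).
#' @param access_s Per-flower access time `Ta` in seconds.
#' @param ingest_s Per-flower ingestion time `Ti` in seconds; may be `Inf`.
#' @param gamma Patch filling level in `[0, 1]`.
#' @param n_flowers Flowers per load `Nflowers` (>= 1).
#' @param t_max_s Handling-time cap `Tmax` in seconds.
#' @return A tibble with columns `per_flower_access_s`, `per_flower_ingest_s`,
#'   `n_flowers`, `total_handling_s`, `capped`.
#' @examples
#' harder_handling_time(1, 0.5, 1.5, gamma = 1, n_flowers = 100)
#' @export
harder_handling_time <- function(interflower_s, access_s, ingest_s, gamma,
                                 n_flowers, t_max_s = 3600) {
  stopifnot(
    is.numeric(gamma), all(gamma >= 0 & gamma <= 1),
    is.numeric(n_flowers), all(n_flowers >= 1),
    is.numeric(t_max_s), t_max_s > 0
  )
  n <- max(length(interflower_s), length(access_s), length(ingest_s),
           length(gamma), length(n_flowers))
  Tt <- rep_len(interflower_s, n)
  Ta <- rep_len(access_s, n)
  Ti <- rep_len(ingest_s, n)
  g <- rep_len(gamma, n)
  Nf <- rep_len(n_flowers, n)

  raw <- ifelse(g > 0, ((Tt + Ta) / g + Ti) * Nf, Inf)
  capped <- !is.finite(raw) | raw >= t_max_s
  tibble::tibble(
    per_flower_access_s = Ta,
    per_flower_ingest_s = Ti,
    n_flowers = as.integer(Nf),
    total_handling_s = ifelse(capped, t_max_s, raw),
    capped = capped
  )
}

#' Fixed-engine handling time for one nectar load
#'
#' The simplified engine: a constant handling time divided by the patch
#' filling level, `Th = fixed_s / gamma`, capped at `t_max_s`. Independent of
#' corolla depth, glossa length, bee weight and nectar volume.
#'
#' @param fixed_s Configured constant handling time in seconds.
#' @param gamma Patch filling level in `[0, 1]` (vectorised).
#' @param t_max_s Handling-time cap `Tmax` in seconds.
#' @return A tibble with columns `total_handling_s` and `capped`.
#' @examples
#' fixed_handling_time(900, gamma = c(1, 0.5, 0.1))
#' @export
fixed_handling_time <- function(fixed_s, gamma, t_max_s = 3600) {
  stopifnot(
    is.numeric(fixed_s), all(fixed_s > 0),
    is.numeric(gamma), all(gamma >= 0 & gamma <= 1),
    is.numeric(t_max_s), t_max_s > 0
  )
  n <- max(length(fixed_s), length(gamma))
  f <- rep_len(fixed_s, n)
  g <- rep_len(gamma, n)
  raw <- ifelse(g > 0, f / g, Inf)
  capped <- raw >= t_max_s
  tibble::tibble(
    total_handling_s = ifelse(capped, t_max_s, raw),
    capped = capped
  )
}

#' Foraging-trip duration
#'
#' `F = 2 * distance / speed + Th`: round-trip flight to the patch plus the
#' handling time on it.
#'
#' @param distance_m One-way nest-to-patch distance in metres (vectorised).
#' @param flight_speed_m_s Flight speed in metres per second.
#' @param handling_s Handling time `Th` in seconds.
#' @return Trip duration in seconds.
#' @examples
#' trip_duration(500, 5, 900)  # 1100
#' @export
trip_duration <- function(distance_m, flight_speed_m_s, handling_s) {
  if (!is.numeric(flight_speed_m_s) || any(flight_speed_m_s <= 0)) {
    rlang::abort("`flight_speed_m_s` must be > 0.")
  }
  stopifnot(all(distance_m >= 0), all(handling_s >= 0))
  2 * distance_m / flight_speed_m_s + handling_s
}

#' @export
print.bombus_handling_config <- function(x, ...) {
  engine <- if (x$fixed_handling_enabled) {
    sprintf("fixed (%g s)", x$fixed_handling_time_s)
  } else {
    "Harder"
  }
  cat("<handling config> engine:", engine,
      "| Tmax:", x$t_max_s, "s",
      "| v:", x$flight_speed_m_s, "m/s",
      "| crop:", x$crop_capacity_ul, "ul\n")
  invisible(x)
}
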