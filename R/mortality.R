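#' The three foraging-mortality models
#'
#' Per-second mortality hazards experienced while on a foraging trip.
#' `"high"` (1e-5 s^-1) is the default, adapted from honeybee work;
#' `"intermediate"` (2.14e-6 s^-1) comes from field estimates for
#' *Bombus lucorum*; `"low"` (2.75e-7 s^-1) from multi-site estimates
#' covering *Bombus terrestris*.
#'
#' @return A tibble with columns `name` and `rate_per_s`.
#' @examples
#' mortality_models()
#' @export
mortality_models <- function() {
  tibble::tibble(
    name = c("high", "intermediate", "low"),
    rate_per_s = c(1e-5, 2.14e-6, 2.75e-7)
  )
}

#' Look up a foraging-mortality rate
#'
#' @param name One of `"high"`, `"intermediate"`, `"low"`.
#' @return The per-second hazard.
#' @examples
#' mortality_rate("high")  # 1e-5
#' @export
mortality_rate <- function(name) {
  reg <- mortality_models()
  i <- match(name, reg$name)
  if (any(is.na(i))) {
    rlang::abort(sprintf(
      "Unknown mortality model %s. Valid names: %s.",
      paste(sQuote(name[is.na(i)]), collapse = ", "),
      paste(reg$name, collapse = ", ")
    ))
  }
  reg$rate_per_s[i]
}

#' Per-trip survival probability
#'
#' Survival of one trip of duration `trip_s` under a constant hazard:
#' `exp(-rate * trip_s)`. The exponential form is additive in exposure, so
#' doubling the trip duration squares the survival probability.
#'
#' @param rate_per_s Hazard in s^-1 (>= 0, vectorised).
#' @param trip_s Trip duration in seconds (>= 0, vectorised).
#' @return Survival probability in `[0, 1]`.
#' @examples
#' trip_survival(1e-5, 3600)  # exp(-0.036)
#' @export
trip_survival <- function(rate_per_s, trip_s) {
  stopifnot(all(rate_per_s >= 0), all(trip_s >= 0))
  exp(-rate_per_s * trip_s)
}

#' Draw forager deaths
#'
#' Bernoulli draws of death with probability `1 - survival_p`, using R's
#' global RNG stream (seed it for reproducibility).
#'
#' @param survival_p Survival probabilities in `[0, 1]` (vectorised).
#' @param n Number of draws; defaults to `length(survival_p)`.
#' @return Logical vector, `TRUE` where the forager died.
#' @examples
#' set.seed(1)
#' sample_death(rep(0.5, 5))
#' @export
sample_death <- function(survival_p, n = length(survival_p)) {
  stopifnot(all(survival_p >= 0 & survival_p <= 1))
  stats::runif(n) > rep_len(survival_p, n)
}
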