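# Internal simulation engine. Patch state lives in an environment of
# parallel vectors so per-trip updates do not copy tibbles; colonies are
# plain lists with per-patch quantities precomputed at founding.

.derive_seed <- function(master_seed, scenario, replicate) {
  h <- as.numeric(master_seed) %% 2147483647
  for (ch in utf8ToInt(paste0(scenario, ":", replicate))) {
    h <- (h * 131 + ch) %% 2147483647
  }
  as.integer(h)
}

.sample1 <- function(x) if (length(x) == 1L) x else x[sample.int(length(x), 1L)]

# Engine view of the landscape: parallel vectors + species params per patch.
.patch_state <- function(patches, species) {
  i <- match(patches$species, species$name)
  if (any(is.na(i))) {
    rlang::abort("Landscape contains species absent from the species table.")
  }
  e <- new.env(parent = emptyenv())
  e$id <- patches$patch_id
  e$x <- patches$x_m
  e$y <- patches$y_m
  e$ncap <- patches$nectar_capacity_ul
  e$nstock <- patches$nectar_stock_ul
  e$pcap <- patches$pollen_capacity_g
  e$pstock <- patches$pollen_stock_g
  e$spstart <- species$flowering_start_doy[i]
  e$spend <- species$flowering_end_doy[i]
  e$tt <- species$interflower_travel_s[i]
  e$corolla <- species$corolla_depth_mm[i]
  e$vol <- species$nectar_volume_ul[i]
  e$nest <- patches$habitat %in% c("hedgerow", "scrub")
  e$n <- nrow(patches)
  e
}

.patch_tbl <- function(patches, pt) {
  patches$nectar_stock_ul <- pt$nstock
  patches$pollen_stock_g <- pt$pstock
  patches
}

.engine_cfg <- function(config, mortality_model) {
  list(
    fixed = config$fixed_handling_enabled,
    fixed_s = config$fixed_handling_time_s,
    tmax = config$t_max_s,
    v = config$flight_speed_m_s,
    crop = config$crop_capacity_ul,
    rate_mort = mortality_rate(mortality_model)
  )
}

.counters <- function(record = FALSE) {
  e <- new.env(parent = emptyenv())
  e$nn <- 0L; e$np <- 0L; e$ndur <- 0; e$pdur <- 0
  e$delivered <- 0
  e$record <- record
  if (record) {
    e$cap <- 1024L; e$len <- 0L
    e$day <- integer(e$cap); e$type <- integer(e$cap)
    e$dur <- numeric(e$cap); e$pid <- integer(e$cap)
    e$coll <- numeric(e$cap); e$died <- logical(e$cap)
  }
  e
}

.log_trip <- function(ct, day, type, dur, pid, coll, died) {
  if (ct$len == ct$cap) {
    ct$cap <- ct$cap * 2L
    for (f in c("day", "type", "pid")) length(ct[[f]]) <- ct$cap
    for (f in c("dur", "coll")) length(ct[[f]]) <- ct$cap
    length(ct$died) <- ct$cap
  }
  k <- ct$len + 1L
  ct$day[k] <- day; ct$type[k] <- type; ct$dur[k] <- dur
  ct$pid[k] <- pid; ct$coll[k] <- coll; ct$died[k] <- died
  ct$len <- k
}

.trips_tbl <- function(ct) {
  if (!ct$record) return(NULL)
  k <- seq_len(ct$len)
  tibble::tibble(
    day = ct$day[k],
    type = c("nectar", "pollen")[ct$type[k]],
    duration_s = ct$dur[k],
    patch_id = ct$pid[k],
    collected = ct$coll[k],
    died = ct$died[k]
  )
}

# New colony founded at a nest site; precomputes distances and, for the
# Harder engine, per-patch access/ingestion times and flowers-per-load for
# this colony's worker line.
.colony_new <- function(id, x, y, pt, eng, glossa, weight, params) {
  dist <- sqrt((pt$x - x)^2 + (pt$y - y)^2)
  col <- list(
    id = id, x = x, y = y,
    glossa = glossa, weight = weight,
    dist = dist, flight = 2 * dist / eng$v,
    workers = integer(params$worker_lifespan_d),
    brood = integer(params$dev_time_d),
    nectar = params$founding_nectar_ul,
    pollen = params$founding_pollen_g,
    mem = integer(0),
    starve = 0L, stage = 1L, queen = TRUE, alive = TRUE,
    qprod = 0L, new_queens = 0L
  )
  if (!eng$fixed) {
    traits <- forager_traits(glossa, weight)
    col$ta <- access_time(pt$corolla)
    col$ti <- ingestion_time(pt$vol, traits, pt$corolla, col$ta)
    col$nf <- n_flowers_per_load(eng$crop, pt$vol)
  }
  col
}

# Handling time (vector over patch indices) at the given filling levels.
.th_nectar_at <- function(col, pt, eng, idx, gamma) {
  if (eng$fixed) {
    th <- eng$fixed_s / gamma
  } else {
    th <- ((pt$tt[idx] + col$ta[idx]) / gamma + col$ti[idx]) * col$nf[idx]
  }
  th[th > eng$tmax] <- eng$tmax
  th
}

# Best patch by expected intake rate among memorised patches plus an
# epsilon-exploration candidate (always explore when memory is empty).
# Returns c(idx, trip duration, handling time); idx 0 when nothing has stock.
.select_patch_idx <- function(col, pt, eng, params, type) {
  if (type == 1L) { stock <- pt$nstock; cap <- pt$ncap } else {
    stock <- pt$pstock; cap <- pt$pcap
  }
  mem <- col$mem
  mc <- mem[stock[mem] > 0]
  cand <- mc
  if (length(mc) == 0L || stats::runif(1) < params$epsilon) {
    pool <- which(stock > 0)
    pool <- pool[match(pool, mem, 0L) == 0L]
    if (length(pool) > 0L) cand <- c(cand, .sample1(pool))
  }
  if (length(cand) == 0L) return(c(0, 0, 0))
  sc <- stock[cand]
  gamma <- sc / cap[cand]
  if (type == 1L) {
    th <- .th_nectar_at(col, pt, eng, cand, gamma)
    load <- sc
    load[load > eng$crop] <- eng$crop
  } else {
    th <- params$pollen_handling_base_s / gamma
    th[th > eng$tmax] <- eng$tmax
    load <- sc
    load[load > params$pollen_load_g] <- params$pollen_load_g
  }
  f <- col$flight[cand] + th
  rate <- load / f
  m <- max(rate)
  j <- which(rate >= m - 1e-12)
  k <- if (length(j) == 1L) j else j[which.min(pt$id[cand[j]])]
  c(cand[k], f[k], th[k])
}

# Execute one trip on a selected patch: deplete, draw mortality, deliver on
# survival, pay the trip's metabolic cost, memorise, log.
.exec_trip <- function(col, pt, eng, params, sel, type, ct, day,
                       force_survival = NULL) {
  idx <- sel[1]
  dur <- sel[2]
  if (type == 1L) {
    amt <- min(eng$crop, pt$nstock[idx])
    pt$nstock[idx] <- pt$nstock[idx] - amt
  } else {
    amt <- min(params$pollen_load_g, pt$pstock[idx])
    pt$pstock[idx] <- pt$pstock[idx] - amt
  }
  died <- if (is.null(force_survival)) {
    stats::runif(1) > exp(-eng$rate_mort * dur)
  } else {
    !force_survival
  }
  if (!died) {
    if (type == 1L) {
      col$nectar <- col$nectar + amt
      ct$delivered <- ct$delivered + amt
    } else {
      col$pollen <- col$pollen + amt
    }
    col$nectar <- max(0, col$nectar - params$forage_cost_ul_per_s * dur)
    if (match(idx, col$mem, 0L) == 0L) col$mem <- c(col$mem, as.integer(idx))
  }
  if (type == 1L) {
    ct$nn <- ct$nn + 1L; ct$ndur <- ct$ndur + dur
  } else {
    ct$np <- ct$np + 1L; ct$pdur <- ct$pdur + dur
  }
  if (ct$record) .log_trip(ct, day, type, dur, pt$id[idx], amt, died)
  list(col = col, died = died)
}

# One colony-day: foraging under the daily budget, brood development,
# egg laying, sexual production, consumption and starvation.
.colony_day <- function(col, pt, eng, params, day, doy, ct) {
  col$new_queens <- 0L
  wtot <- sum(col$workers)
  btot <- sum(col$brood)
  n_need <- wtot * params$worker_consumption_ul +
    btot * params$brood_consumption_ul +
    if (col$queen) params$queen_consumption_ul else 0
  p_need <- btot * params$brood_pollen_g
  sexual <- doy >= params$switch_doy
  # In the sexual season the store target covers the production reserve plus
  # the daily queen quota, so surplus above the reserve is actually reachable.
  n_target <- params$target_days * n_need +
    if (sexual) {
      params$queen_reserve_days * n_need +
        params$queen_quota_per_day * params$cost_per_queen_ul
    } else {
      params$egg_nectar_threshold_ul
    }
  p_target <- params$target_days * p_need +
    if (sexual) {
      params$queen_quota_per_day * params$cost_per_queen_pollen_g
    } else {
      params$egg_pollen_threshold_g
    }

  founding <- col$stage == 1L
  nf <- if (founding) 1L else {
    if (wtot == 0L) 0L else max(1L, min(wtot, floor(params$forager_share * wtot)))
  }
  budget <- if (founding) params$founding_budget_s else params$daily_budget_s

  done <- FALSE
  for (f in seq_len(nf)) {
    if (done) break
    left <- budget
    repeat {
      nd <- n_target - col$nectar
      pd <- p_target - col$pollen
      if (nd <= 0 && pd <= 0) { done <- TRUE; break }
      type <- if (pd > 0 && (nd <= 0 || pd / p_target > nd / n_target)) 2L else 1L
      sel <- .select_patch_idx(col, pt, eng, params, type)
      if (sel[1] == 0) {
        other <- 3L - type
        od <- if (other == 1L) nd else pd
        if (od > 0) sel <- .select_patch_idx(col, pt, eng, params, other)
        if (sel[1] == 0) { done <- TRUE; break }
        type <- other
      }
      if (sel[2] > left) break
      res <- .exec_trip(col, pt, eng, params, sel, type, ct, day)
      col <- res$col
      left <- left - sel[2]
      if (res$died) {
        if (founding) {
          col$queen <- FALSE
          col$alive <- FALSE
          return(col)
        }
        k <- max(which(col$workers > 0))
        col$workers[k] <- col$workers[k] - 1L
        break
      }
    }
  }

  # brood development and egg laying
  dev <- params$dev_time_d
  life <- params$worker_lifespan_d
  eggs <- 0L
  if (col$queen && !sexual &&
      col$nectar > params$egg_nectar_threshold_ul &&
      col$pollen > params$egg_pollen_threshold_g) {
    eggs <- if (founding) params$founding_eggs_per_day else
      params$max_eggs_per_day
  }
  emerge <- col$brood[dev]
  col$brood <- c(eggs, col$brood[-dev])
  col$workers <- c(emerge, col$workers[-life])
  if (founding && emerge > 0L) col$stage <- 2L

  # sexuals
  if (sexual && col$queen && col$stage == 2L) {
    ps <- produce_sexuals(col, doy, params, n_need = n_need)
    col <- ps$colony
    col$new_queens <- ps$n_new
  }

  # consumption and starvation
  col$nectar <- col$nectar - n_need
  col$pollen <- max(0, col$pollen - p_need)
  if (col$nectar <= 0) {
    col$nectar <- 0
    col$starve <- col$starve + 1L
    col$brood <- col$brood - (col$brood + 1L) %/% 2L  # half the brood starves
  } else {
    col$starve <- 0L
  }
  if (col$starve >= params$starvation_days) col$alive <- FALSE
  if (col$stage == 2L && sum(col$workers) == 0L && sum(col$brood) == 0L) {
    col$alive <- FALSE
  }
  col
}
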