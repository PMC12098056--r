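test_that("patch selection maximises intake rate and breaks ties by id", {
  cfg <- handling_config(fixed_handling_enabled = TRUE,
                         fixed_handling_time_s = 450)
  p <- two_patches(stock = c(1000, 200))  # gamma 1 vs 0.2, equal distance
  col <- midpoint_colony(p, cfg)
  expect_identical(select_patch(col, p, cfg, no_explore()), 1L)

  # identical patches: lowest patch id wins
  p2 <- two_patches(stock = c(600, 600))
  col2 <- midpoint_colony(p2, cfg)
  expect_identical(select_patch(col2, p2, cfg, no_explore()), 1L)

  # nothing in stock anywhere: no trip
  p3 <- two_patches(stock = c(0, 0))
  col3 <- midpoint_colony(p3, cfg)
  expect_identical(select_patch(col3, p3, cfg, no_explore()), NA_integer_)
})

test_that("a nectar trip composes engine, flight and depletion exactly", {
  cfg <- handling_config(fixed_handling_enabled = TRUE,
                         fixed_handling_time_s = 900)
  p <- two_patches(stock = c(800, 1000))
  col <- midpoint_colony(p, cfg)
  res <- nectar_trip(col, p, cfg, "low", no_explore(), patch_id = 1L,
                     force_survival = TRUE)
  th <- fixed_handling_time(900, 800 / 1000, cfg$t_max_s)$total_handling_s
  expect_equal(res$trip$duration_s, trip_duration(1000, 5, th))
  expect_equal(res$trip$collected, 120)
  expect_equal(res$patches$nectar_stock_ul[1], 680)
  expect_equal(res$colony$nectar,
               col$nectar + 120 - sim_params()$forage_cost_ul_per_s *
                 res$trip$duration_s)
  expect_true(1L %in% res$colony$mem)
})

test_that("trips clamp to stock and deaths forfeit the load", {
  cfg <- handling_config(fixed_handling_enabled = TRUE,
                         fixed_handling_time_s = 450)
  p <- two_patches(stock = c(50, 0))
  col <- midpoint_colony(p, cfg)
  res <- nectar_trip(col, p, cfg, "low", no_explore(), patch_id = 1L,
                     force_survival = TRUE)
  expect_equal(res$trip$collected, 50)
  expect_equal(res$patches$nectar_stock_ul[1], 0)

  # forced death: patch still depleted, store untouched, nothing memorised
  col2 <- colony_state(2000, 2000, p, flower_species_defaults(), cfg)
  res2 <- nectar_trip(col2, p, cfg, "low", no_explore(), patch_id = 1L,
                      force_survival = FALSE)
  expect_true(res2$trip$forager_died)
  expect_equal(res2$colony$nectar, col2$nectar)
  expect_false(1L %in% res2$colony$mem)
  expect_equal(res2$patches$nectar_stock_ul[1], 0)
})

test_that("pollen trips use the pollen stand-in handling rule", {
  cfg <- handling_config()
  p <- two_patches()
  p$x_m <- c(2250, 3000)  # 250 m to patch 1
  col <- colony_state(2000, 2000, p, flower_species_defaults(), cfg)
  res <- pollen_trip(col, p, cfg, "low", no_explore(), patch_id = 1L,
                     force_survival = TRUE)
  expect_equal(res$trip$duration_s, 2 * 250 / 5 + 300)  # gamma_pollen = 1
  expect_equal(res$trip$collected, sim_params()$pollen_load_g)

  # depleted pollen: handling capped at Tmax
  p2 <- two_patches(pollen = c(0.5 * 0.05, 0.5))
  p2$x_m <- c(2250, 3000)
  col2 <- colony_state(2000, 2000, p2, flower_species_defaults(), cfg)
  res2 <- pollen_trip(col2, p2, cfg, "low", no_explore(), patch_id = 1L,
                      force_survival = TRUE)
  expect_equal(res2$trip$duration_s, 100 + 3600)

  # no pollen anywhere: no trip
  p3 <- two_patches(pollen = c(0, 0))
  col3 <- midpoint_colony(p3, cfg)
  expect_null(pollen_trip(col3, p3, cfg, "low", no_explore()))
})

test_that("a colony-day respects store targets and the time budget", {
  cfg <- handling_config(fixed_handling_enabled = TRUE,
                         fixed_handling_time_s = 900)
  p <- two_patches(stock = c(1e6, 1e6), capacity = c(1e6, 1e6))
  col <- midpoint_colony(p, cfg)

  # founding colony, single forager with the founding budget: total trip
  # time is bounded by it
  col$nectar <- 0
  res <- colony_daily_step(col, p, cfg, "low", no_explore(), day = 130)
  expect_lte(sum(res$trips$duration_s), sim_params()$founding_budget_s)
  expect_gte(nrow(res$trips), 1)

  # stores above all targets at dawn: no trips at all
  col2 <- midpoint_colony(p, cfg)
  col2$nectar <- 1e6
  col2$pollen <- 1e3
  res2 <- colony_daily_step(col2, p, cfg, "low", no_explore(), day = 130)
  expect_equal(nrow(res2$trips), 0)

  # dead colonies may not step
  col3 <- midpoint_colony(p, cfg)
  col3$alive <- FALSE
  expect_error(colony_daily_step(col3, p, cfg), "alive")
})

test_that("sexual production converts surplus into queens by the floor rule", {
  params <- sim_params()
  col <- midpoint_colony(two_patches())
  col$stage <- 2L
  col$workers <- rep(2L, length(col$workers))  # 60 workers
  wtot <- sum(col$workers)
  need <- wtot * params$worker_consumption_ul +
    params$queen_consumption_ul
  reserve <- params$queen_reserve_days * need

  # before the switch day: nothing, regardless of surplus
  col$nectar <- reserve + 10 * params$cost_per_queen_ul
  col$pollen <- 1
  expect_equal(produce_sexuals(col, params$switch_doy - 1, params)$n_new, 0L)

  # no surplus: no queens
  col$nectar <- reserve
  expect_equal(produce_sexuals(col, 200, params)$n_new, 0L)

  # exactly three queens' worth of surplus
  col$nectar <- reserve + 3 * params$cost_per_queen_ul
  col$pollen <- 1
  out <- produce_sexuals(col, 200, params)
  expect_equal(out$n_new, 3L)
  expect_equal(out$colony$nectar, reserve)

  # bounded by the worker population
  col$workers <- c(2L, rep(0L, length(col$workers) - 1L))
  col$nectar <- 1e6
  col$pollen <- 1e3
  expect_equal(produce_sexuals(col, 200, params)$n_new, 2L)
})

test_that("queen daily transitions follow emergence, founding and the cap", {
  q <- list(state = "hibernating", emergence_doy = 100)
  expect_equal(queen_daily_step(q, 90, 5, 10)$state, "hibernating")

  set.seed(1)
  p1 <- sim_params(p_nest = 1)
  out <- queen_daily_step(q, 100, free_sites = 10, nest_capacity = 10,
                          params = p1)
  expect_equal(out$state, "founding")
  expect_true(out$founded)

  # cap reached: cannot found
  p0 <- sim_params(p_nest = 1, search_mortality = 0)
  out2 <- queen_daily_step(q, 100, free_sites = 0, nest_capacity = 10,
                           params = p0)
  expect_equal(out2$state, "searching")

  # past the deadline searching is fatal
  out3 <- queen_daily_step(q, sim_params()$search_deadline_doy + 1, 5, 10)
  expect_equal(out3$state, "dead")
})
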