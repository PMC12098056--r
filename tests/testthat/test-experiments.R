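test_that("the scenario grid matches the published design", {
  grid <- build_scenario_grid()
  expect_equal(nrow(grid), 19)
  expect_equal(grid$name[1], "ORG")
  expect_setequal(
    grid$name,
    c("ORG", paste0(rep(c("LOW", "MED", "HIGH"), each = 6), "_",
                    c("112", "225", "450", "900", "1800", "3600")))
  )
  med450 <- grid[grid$name == "MED_450", ]
  expect_true(med450$fixed_handling_enabled)
  expect_equal(med450$fixed_handling_time_s, 450)
  expect_equal(med450$mortality_model, "intermediate")

  org <- grid[grid$name == "ORG", ]
  expect_false(org$fixed_handling_enabled)
  expect_equal(org$mortality_model, "high")
  expect_true(is.na(org$fixed_handling_time_s))

  fixed <- grid$fixed_handling_time_s[grid$fixed_handling_enabled]
  expect_setequal(unique(fixed), c(112.5, 225, 450, 900, 1800, 3600))
})

test_that("the weighted mean equals the per-trip grand mean", {
  d <- tibble::tibble(mean_s = c(300, 600), n = c(10, 30))
  expect_equal(weighted_mean_trip_duration(d, mean_s, n), 525)
  expect_equal(weighted_mean_trip_duration(
    tibble::tibble(mean_s = 420, n = 7), mean_s, n), 420)

  # daily summaries of a synthetic trip log reproduce the grand mean
  set.seed(3)
  trips <- tibble::tibble(
    day = sample(1:30, 500, replace = TRUE),
    duration_s = rlnorm(500, log(600), 0.5)
  )
  daily <- dplyr::summarise(dplyr::group_by(trips, .data$day),
                            n = dplyr::n(), m = mean(.data$duration_s))
  expect_equal(weighted_mean_trip_duration(daily, m, n),
               mean(trips$duration_s))

  expect_error(weighted_mean_trip_duration(
    tibble::tibble(mean_s = NA_real_, n = 0), mean_s, n), "undefined")
})

test_that("the end-of-run census reads the final timestep", {
  d <- tibble::tibble(day = 1:1825,
                      n_queens = c(rep(50L, 1824), 123L),
                      n_colonies = 1L)
  expect_equal(hibernating_queens_at_end(d), 123L)
  d$n_queens[1825] <- 0L
  expect_equal(hibernating_queens_at_end(d), 0L)
})

test_that("experiments enumerate scenario x replicate deterministically", {
  land <- small_landscape()
  grid <- build_scenario_grid()[c(1, 19), ]  # ORG and HIGH_3600
  ex <- run_experiment(grid, land, replicates = 2, master_seed = 7,
                       years = 1, initial_queens = 10)
  expect_equal(nrow(ex), 4)
  expect_equal(ex$scenario, rep(grid$name, each = 2))
  expect_equal(anyDuplicated(ex$seed), 0L)

  ex2 <- run_experiment(grid, land, replicates = 2, master_seed = 7,
                        years = 1, initial_queens = 10)
  expect_identical(tidy(ex), tidy(ex2))

  one <- run_experiment(grid[1, ], land, replicates = 1, master_seed = 7,
                        years = 1, initial_queens = 10)
  expect_equal(nrow(one), 1)
  # the replicate seed derivation is recorded and reproducible
  expect_equal(one$seed, ex$seed[1])
})
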