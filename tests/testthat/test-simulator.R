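test_that("runs produce exactly years x 365 daily records", {
  land <- small_landscape()
  s1 <- run_simulation("HIGH_3600", land, years = 1, initial_queens = 10,
                       seed = 2)
  expect_equal(nrow(s1$daily), 365)
  s2 <- run_simulation("HIGH_3600", land, years = 2, initial_queens = 10,
                       seed = 2)
  expect_equal(nrow(s2$daily), 730)
})

test_that("the same seed reproduces a run exactly", {
  land <- small_landscape()
  a <- run_simulation("LOW_450", land, years = 1, initial_queens = 15,
                      seed = 31, record_trips = TRUE)
  b <- run_simulation("LOW_450", land, years = 1, initial_queens = 15,
                      seed = 31, record_trips = TRUE)
  expect_identical(a$daily, b$daily)
  expect_identical(a$trips, b$trips)
  c <- run_simulation("LOW_450", land, years = 1, initial_queens = 15,
                      seed = 32)
  expect_false(identical(a$daily, c$daily))
})

test_that("extinction is absorbing", {
  land <- small_landscape()
  sim <- run_simulation("HIGH_3600", land, years = 3, initial_queens = 15,
                        seed = 5)
  d <- sim$daily
  gone <- which(d$n_queens == 0 & d$n_colonies == 0)
  first <- min(gone)
  # the extinction day itself may still carry that day's trips
  after <- d[d$day > first, ]
  expect_true(all(after$n_queens == 0))
  expect_true(all(after$n_colonies == 0))
  expect_true(all(after$n_nectar_trips == 0))

  # no population at all: every record zero
  empty <- run_simulation("ORG", land, years = 1, initial_queens = 0,
                          seed = 1)
  expect_true(all(empty$daily$n_queens == 0))
  expect_true(all(empty$daily$n_nectar_trips == 0))
})

test_that("the per-trip log aggregates exactly to the daily metrics", {
  land <- small_landscape()
  sim <- run_simulation("MED_450", land, years = 1, initial_queens = 20,
                        seed = 17, record_trips = TRUE)
  d <- sim$daily
  tr <- sim$trips
  by_day <- dplyr::summarise(
    dplyr::group_by(tr[tr$type == "nectar", ], .data$day),
    n = dplyr::n(), m = mean(.data$duration_s)
  )
  expect_equal(sum(d$n_nectar_trips), nrow(tr[tr$type == "nectar", ]))
  expect_equal(d$n_nectar_trips[by_day$day], by_day$n)
  expect_equal(d$mean_nectar_trip_s[by_day$day], by_day$m)
  # days without trips have no mean
  none <- setdiff(d$day[d$n_nectar_trips == 0], by_day$day)
  expect_true(all(is.na(d$mean_nectar_trip_s[d$day %in% none])))
})

test_that("nectar is conserved from patches to colony stores", {
  land <- small_landscape()
  sim <- run_simulation("LOW_225", land, years = 1, initial_queens = 20,
                        seed = 23, record_trips = TRUE)
  tr <- sim$trips
  delivered <- sum(tr$collected[tr$type == "nectar" & !tr$died])
  expect_identical(delivered, sim$totals$nectar_delivered_ul)
})

test_that("invalid scenarios are rejected before stepping", {
  land <- small_landscape()
  expect_error(run_simulation("BOGUS_42", land), "Unknown scenario")
  expect_error(
    run_simulation(list(fixed_handling_enabled = TRUE,
                        mortality_model = "high"), land),
    "fixed_handling_time_s"
  )
  expect_error(
    run_simulation(list(fixed_handling_enabled = FALSE,
                        mortality_model = "nope"), land),
    "Unknown mortality"
  )
})
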