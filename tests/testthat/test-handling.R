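test_that("access time is linear in corolla depth", {
  expect_equal(access_time(0), 0.3)
  expect_equal(access_time(10), 0.7)
  expect_equal(access_time(19), 1.06)
  expect_equal(access_time(c(0, 10, 19)), c(0.3, 0.7, 1.06))
  expect_error(access_time(-1), "corolla")
})

test_that("ingestion time matches the independently computed regression value", {
  traits <- forager_traits(glossa_mm = 11.1, weight_g = 0.195)
  # frozen from an independent evaluation of the adopted parse
  expect_equal(ingestion_time(0.5, traits, corolla_depth_mm = 0),
               1.1564981495319915, tolerance = 1e-12)
  traits2 <- forager_traits(6.9, 0.195)
  expect_equal(ingestion_time(2, traits2, corolla_depth_mm = 5),
               3.245125133195521, tolerance = 1e-12)
})

test_that("ingestion time grows without bound towards the pole", {
  traits <- forager_traits(11.1, 0.195)
  # pole sits near C = 10.918 for these traits
  cd <- c(9, 10, 10.5, 10.8, 10.9)
  ti <- ingestion_time(2, traits, cd)
  expect_true(all(diff(ti) > 0))
  expect_gt(ti[5], 10)
  expect_gt(ingestion_time(2, traits, 10.917), 100)
  # at/past the pole and beyond the glossa the sentinel is returned
  expect_equal(ingestion_time(2, traits, 10.95), Inf)
  expect_equal(ingestion_time(2, traits, 11.1), Inf)
  expect_equal(ingestion_time(2, traits, 15), Inf)
})

test_that("flowers per load is a guarded ceiling", {
  expect_identical(n_flowers_per_load(120, 0.5), 240L)
  expect_identical(n_flowers_per_load(120, 7), 18L)
  expect_identical(n_flowers_per_load(120, 240), 1L)
  expect_error(n_flowers_per_load(120, 0), "nectar_volume_ul")
})

test_that("Harder-engine handling time scales with filling level and caps", {
  h1 <- harder_handling_time(1, 0.5, 1.5, gamma = 1, n_flowers = 100)
  expect_equal(h1$total_handling_s, 300)
  expect_false(h1$capped)

  h2 <- harder_handling_time(1, 0.5, 1.5, gamma = 0.5, n_flowers = 100)
  expect_equal(h2$total_handling_s, 450)

  h3 <- harder_handling_time(1, 0.5, 1.5, gamma = 0.02, n_flowers = 100)
  expect_equal(h3$total_handling_s, 3600)
  expect_true(h3$capped)

  # degenerate guards: empty patch and unreachable nectar both cap
  expect_equal(harder_handling_time(1, 0.5, 1.5, 0, 100)$total_handling_s,
               3600)
  expect_equal(harder_handling_time(1, 0.5, Inf, 1, 100)$total_handling_s,
               3600)
})

test_that("fixed-engine handling time is fixed_s over gamma, capped", {
  expect_equal(fixed_handling_time(900, 1)$total_handling_s, 900)
  expect_equal(fixed_handling_time(900, 0.5)$total_handling_s, 1800)
  f <- fixed_handling_time(3600, 0.25)
  expect_equal(f$total_handling_s, 3600)
  expect_true(f$capped)
  expect_equal(fixed_handling_time(900, 0)$total_handling_s, 3600)
})

test_that("trip duration composes flight and handling", {
  expect_equal(trip_duration(500, 5, 900), 1100)
  expect_equal(trip_duration(0, 3, 900), 900)
  expect_error(trip_duration(10, 0, 10), "flight_speed")

  set.seed(42)
  for (i in 1:50) {
    d <- runif(1, 0, 3000); v <- runif(1, 1, 10); th <- runif(1, 0, 4000)
    expect_equal(trip_duration(d, v, th), 2 * d / v + th)
  }
})

test_that("every handling time respects the cap (property)", {
  set.seed(7)
  for (i in 1:200) {
    tmax <- runif(1, 100, 5000)
    g <- runif(1, 0, 1)
    tt <- runif(1, 0, 5); ta <- runif(1, 0.3, 2); ti <- runif(1, 0, 50)
    nf <- sample(1:300, 1)
    hh <- harder_handling_time(tt, ta, ti, g, nf, t_max_s = tmax)
    expect_lte(hh$total_handling_s, tmax)
    raw <- if (g > 0) ((tt + ta) / g + ti) * nf else Inf
    expect_identical(hh$capped, raw >= tmax)
    fh <- fixed_handling_time(runif(1, 1, 5000), g, t_max_s = tmax)
    expect_lte(fh$total_handling_s, tmax)
  }
})

test_that("below the cap the fixed engine is linear in fixed_s with slope 1/gamma", {
  for (g in c(1, 0.8, 0.5, 0.25)) {
    fs <- c(50, 100, 200, 400)
    th <- fixed_handling_time(fs, g, t_max_s = 1e7)$total_handling_s
    expect_equal(th, fs / g)
    expect_equal(diff(th) / diff(fs), rep(1 / g, 3))
  }
})

test_that("Harder engine is strictly decreasing in gamma and non-decreasing in corolla depth", {
  g <- seq(0.1, 1, by = 0.1)
  th <- harder_handling_time(1, 0.5, 1.5, g, 100, t_max_s = 1e7)$total_handling_s
  expect_true(all(diff(th) < 0))

  traits <- forager_traits(11.1, 0.195)
  cd <- seq(0, 11.1, by = 0.1)
  ta <- access_time(cd)
  ti <- ingestion_time(2, traits, cd, ta)
  th <- harder_handling_time(1.5, ta, ti, 1, 60)$total_handling_s
  expect_true(all(diff(th) >= -1e-9))
  expect_equal(th[length(th)], 3600)  # capped at the pole and beyond
})

test_that("fixed-engine trips are invariant to flora and bee traits", {
  cfg <- handling_config(fixed_handling_enabled = TRUE,
                         fixed_handling_time_s = 900)
  base <- two_patches()
  durations <- sapply(1:5, function(i) {
    p <- base
    p$species <- "wildflower_mix"
    sp <- flower_species_defaults()
    col <- colony_state(2000, 2000, p, sp, config = cfg,
                        glossa_mm = runif(1, 5, 12),
                        weight_g = runif(1, 0.1, 0.4))
    res <- nectar_trip(col, p, cfg, "low", sim_params(), patch_id = 1L,
                       force_survival = TRUE)
    res$trip$duration_s
  })
  expect_equal(durations, rep(durations[1], 5))
  expect_equal(durations[1], 2 * 1000 / 5 + 900)
})
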