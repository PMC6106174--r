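test_that("generators are pure functions of the configuration seed", {
  cfg <- sim_config(grid_size = 9, n_species = 12, seed = 7,
                    homog_strength = 0.5)
  p1 <- simulate_atlas_pair(cfg)
  p2 <- simulate_atlas_pair(cfg)
  expect_identical(p1$atlas1$presence, p2$atlas1$presence)
  expect_identical(p1$atlas2$presence, p2$atlas2$presence)
  expect_identical(simulate_traits(cfg)$data, simulate_traits(cfg)$data)
  expect_identical(simulate_climate(cfg), simulate_climate(cfg))
  # a different seed changes the draw
  cfg2 <- sim_config(grid_size = 9, n_species = 12, seed = 8)
  expect_false(identical(simulate_atlas_pair(cfg2)$atlas1$presence,
                         p1$atlas1$presence))
  # the caller's RNG stream is not consumed
  set.seed(1); a <- rnorm(1)
  set.seed(1); invisible(simulate_atlas_pair(cfg)); b <- rnorm(1)
  expect_identical(a, b)
})

test_that("simulated atlases survive the exclusion/read round trip", {
  cfg <- sim_config(grid_size = 9, n_species = 10, seed = 2)
  pair <- simulate_atlas_pair(cfg)
  ex <- apply_exclusions(pair$atlas1)
  expect_identical(ex$grid, pair$atlas1$grid)
  expect_identical(ex$presence, pair$atlas1$presence)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_atlas(pair$atlas1, tmp)
  back <- read_atlas(tmp, "period1")
  expect_equal(back$presence, pair$atlas1$presence)
})

test_that("homogenization forcing drives taxonomic turnover down", {
  # no forcing: period 2 identical in law, mean change near 0
  deltas0 <- vapply(1:6, function(s) {
    cfg <- sim_config(grid_size = 12, n_species = 30, seed = s,
                      homog_strength = 0)
    pair <- simulate_atlas_pair(cfg)
    t1 <- neighborhood_turnover(pair$atlas1, measure = "sim")
    t2 <- neighborhood_turnover(pair$atlas2, measure = "sim")
    mean(t2$value - t1$value, na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(deltas0)), 0.01)
  # full forcing over the whole grid: neighbourhoods converge
  cfg1 <- sim_config(grid_size = 12, n_species = 30, seed = 1,
                     homog_strength = 1)
  pair1 <- simulate_atlas_pair(cfg1)
  t1 <- neighborhood_turnover(pair1$atlas1, measure = "sim")
  t2 <- neighborhood_turnover(pair1$atlas2, measure = "sim")
  expect_lt(mean(t2$value - t1$value, na.rm = TRUE), -0.02)
  # region outside the grid is rejected
  expect_error(simulate_atlas_pair(
    sim_config(grid_size = 9, n_species = 5, seed = 1,
               homog_region = c(1000, 2000, 1000, 2000))),
    "outside the grid")
})

test_that("trait coupling links trait values to range position", {
  cfg <- sim_config(grid_size = 9, n_species = 200, seed = 3,
                    trait_coupling = 0.8)
  tr <- simulate_traits(cfg)
  lat <- betadrift:::sim_latent(cfg)
  expect_gt(cor(log(tr$data$body_mass), lat$optima), 0.5)
  cfg0 <- sim_config(grid_size = 9, n_species = 200, seed = 3,
                     trait_coupling = 0)
  tr0 <- simulate_traits(cfg0)
  lat0 <- betadrift:::sim_latent(cfg0)
  expect_lt(abs(cor(log(tr0$data$body_mass), lat0$optima)), 0.25)
  # the default trait set mixes the four kinds
  expect_setequal(unique(unname(tr$types)),
                  c("continuous", "ordinal", "categorical", "binary_set"))
})

test_that("climate generator recovers its imposed trend, memory and tails", {
  # long-term trend: OLS slope of the annual minimum-temperature series
  # recovers the imposed 0.05 degC/yr across cells and replicate draws
  slopes <- unlist(lapply(1:3, function(s) {
    cfg <- sim_config(grid_size = 9, n_species = 5, seed = s,
                      climate_spec = list(
                        tmin = list(trend = 0.05, phi = 0.3, sd = 0.8,
                                    df = Inf)))
    cl <- simulate_climate(cfg)
    vapply(unique(cl$cell_id), function(cell)
      ts_trend(annualize(cl[cl$cell_id == cell, ])$min_temp), numeric(1))
  }))
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 0.05), 4 * se + 0.005)

  # AR(1) memory: monthly anomalies carry the imposed phi = 0.6
  cfg <- sim_config(grid_size = 9, n_species = 5, seed = 11,
                    climate_spec = list(
                      tmean = list(trend = 0, phi = 0.6, sd = 1, df = Inf)))
  cl <- simulate_climate(cfg)
  acs <- vapply(unique(cl$cell_id), function(cell) {
    x <- cl$tmean_c[cl$cell_id == cell]
    anom <- x - ave(x, cl$month[cl$cell_id == cell])
    ts_lag1(anom)
  }, numeric(1))
  expect_equal(mean(acs), 0.6, tolerance = 0.05)

  # heavy-tailed innovations raise the fat-tail statistic on average
  ft_for <- function(df, seed) {
    cfg <- sim_config(grid_size = 9, n_species = 5, seed = seed,
                      climate_spec = list(
                        tmean = list(trend = 0, phi = 0, sd = 1, df = df)))
    cl <- simulate_climate(cfg)
    mean(vapply(unique(cl$cell_id), function(cell) {
      x <- cl$tmean_c[cl$cell_id == cell]
      ts_fat_tail(x - ave(x, cl$month[cl$cell_id == cell]))
    }, numeric(1)))
  }
  expect_gt(ft_for(3, 13), ft_for(Inf, 13))
  expect_error(simulate_climate(sim_config(grid_size = 9, n_species = 5,
                                           seed = 1, n_years = 3)),
               "n_years")
})
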