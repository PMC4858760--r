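test_that("landscape generation is a pure function of the seed", {
  a <- make_landscape(8, 6, seed = 42)
  b <- make_landscape(8, 6, seed = 42)
  expect_identical(a$layers, b$layers)
  c <- make_landscape(8, 6, seed = 43)
  expect_false(identical(a$layers$temp_mean, c$layers$temp_mean))
})

test_that("temperature band means decrease northwards; heterogeneity layers are non-negative", {
  env <- make_landscape(12, 10, noise_scale = 0, seed = 1)
  means <- band_environment(env, 100)
  tm <- means$mean[means$layer == "temp_mean"] # band 1 = northernmost
  expect_true(all(diff(tm) > 0)) # strictly warmer southwards
  for (nm in c("temp_sd", "precip_sd", "alt_sd", "pet_sd", "dist_coast")) {
    expect_true(all(env$layers[[nm]] >= 0), info = nm)
  }
  # with noise, band means remain monotone in expectation; the generator's
  # summary statistics are reproducible from the seed alone
  env2 <- make_landscape(20, 20, seed = 9)
  env3 <- make_landscape(20, 20, seed = 9)
  expect_equal(vapply(env2$layers, mean, numeric(1)),
               vapply(env3$layers, mean, numeric(1)))
})

test_that("pure architectures have the stated range structure", {
  env <- make_landscape(10, 8, noise_scale = 0, seed = 2)
  # theta = 1: ranges strictly nested by cold rank
  pool <- simulate_pool(sim_config(8, theta = 1, noise = 0), env)
  expect_true(all(pool$archetype == "nested"))
  expect_true(all(diff(pool$cold_limit) > 0))
  s <- suitability(pool, env) > 0
  for (k in seq_len(7)) {
    expect_true(all(!s[, k + 1] | s[, k]), # range k+1 subset of range k
                info = paste("rank", k))
  }
  # theta = 0: evenly spaced optima at the stated spacing
  pool0 <- simulate_pool(sim_config(8, theta = 0, noise = 0), env)
  expect_true(all(pool0$archetype == "turnover"))
  spac <- diff(pool0$optimum)
  expect_equal(spac, rep(spac[1], 7))
  tr <- range(env$layers$temp_mean)
  expect_equal(spac[1], diff(tr) / 7)
  # theta = 0.5: union of the two archetypes in proportion
  pool5 <- simulate_pool(sim_config(10, theta = 0.5, noise = 0), env)
  expect_equal(unname(table(pool5$archetype)["nested"]), 5L)
  expect_equal(unname(table(pool5$archetype)["turnover"]), 5L)
})

test_that("truth draws respect suitability extremes and the seed", {
  env <- make_landscape(6, 6, seed = 3)
  pool <- simulate_pool(sim_config(4, theta = 1, noise = 0), env)
  t1 <- simulate_truth(pool, env, seed = 5)
  t2 <- simulate_truth(pool, env, seed = 5)
  expect_identical(t1$occupancy, t2$occupancy)
  # noise 0: presence deterministic, exactly where suitability is 1
  expect_equal(unname(t1$occupancy), unname(suitability(pool, env) == 1))
  # the most cold-tolerant zero-noise species covers every land pixel
  expect_true(all(t1$occupancy[, 1]))
})

test_that("nested zero-noise truth has zero multisite turnover", {
  env <- make_landscape(10, 10, seed = 4)
  pool <- simulate_pool(sim_config(12, theta = 1, noise = 0), env)
  truth <- simulate_truth(pool, env, seed = 4)
  p <- multisite_partition(truth)
  expect_equal(p$beta_sim, 0)
  expect_gt(p$beta_sne, 0)
})

test_that("record sampling emits only true presences and honours effort weighting", {
  env <- make_landscape(8, 8, seed = 6)
  pool <- simulate_pool(sim_config(10, theta = 0.5, noise = 0.1), env)
  truth <- simulate_truth(pool, env, seed = 6)
  effort <- rep(1, 64)
  n_pairs <- sum(truth$occupancy)

  # exhaustive uniform sampling recovers the truth exactly after rasterize
  occ <- sample_records(truth, effort, n_pairs, seed = 1)
  sg <- suppressMessages(rasterize(occ, env$grid))
  expect_equal(sg$occupancy[, truth$species_ids[truth$species_ids %in% sg$species_ids]],
               truth$occupancy[, truth$species_ids %in% sg$species_ids])

  # no (species, pixel) pair absent from the truth, over several seeds
  for (s in 1:5) {
    rec <- sample_records(truth, effort, 50, seed = s)
    sgr <- suppressMessages(rasterize(rec, env$grid))
    for (sp in sgr$species_ids) {
      expect_true(all(!sgr$occupancy[, sp] | truth$occupancy[, sp]))
    }
  }

  # zero effort in the south yields no southern records
  regions <- split_regions(env$grid, mean(env$grid$lat_range))
  eff_n <- ifelse(regions$labels == "north", 1, 0)
  rec_n <- sample_records(truth, eff_n, 30, seed = 2)
  sg_n <- suppressMessages(rasterize(rec_n, env$grid))
  south_rows <- which(regions$labels == "south")
  expect_equal(sum(sg_n$occupancy[south_rows, ]), 0)

  # 2:1 effort ratio: record share close to the presence-weighted expectation
  eff_b <- ifelse(regions$labels == "north", 2, 1)
  pairs_north <- sum(truth$occupancy[regions$labels == "north", ])
  pairs_south <- sum(truth$occupancy[regions$labels == "south", ])
  expected_share <- 2 * pairs_north / (2 * pairs_north + pairs_south)
  n_draw <- 400
  rec_b <- sample_records(truth, eff_b, n_draw, seed = 3, replace = TRUE)
  north_share <- mean(rec_b$y > (env$grid$n_rows / 2) * 100)
  expect_lt(abs(north_share - expected_share),
            4 * sqrt(expected_share * (1 - expected_share) / n_draw))

  # refusing to over-sample without replacement
  expect_error(sample_records(truth, effort, n_pairs + 1),
               class = "mossgrad_sim_error")
})

test_that("nestedness component rises and turnover falls as theta increases", {
  thetas <- c(0, 0.5, 1)
  med <- sapply(thetas, function(th) {
    vals <- sapply(1:20, function(s) {
      env <- make_landscape(10, 10, seed = s)
      pool <- simulate_pool(sim_config(20, theta = th, noise = 0.05,
                                       seed = s), env)
      truth <- simulate_truth(pool, env, seed = s)
      p <- multisite_partition(truth)
      c(sim = p$beta_sim, sne = p$beta_sne)
    })
    apply(vals, 1, median)
  })
  expect_true(all(diff(med["sne", ]) >= 0))
  expect_true(all(diff(med["sim", ]) <= 0))
})
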