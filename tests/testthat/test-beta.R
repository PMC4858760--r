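test_that("pairwise components are plain set arithmetic", {
  m <- rbind(c(1, 1, 1, 0), # {s1,s2,s3}
             c(0, 1, 1, 1)) # {s2,s3,s4}
  expect_equal(pairwise_components(m, 1, 2),
               c(a = 2, b_ij = 1, b_ji = 1))
  expect_equal(pairwise_components(m, 1, 1), c(a = 3, b_ij = 0, b_ji = 0))
  set.seed(21)
  for (k in 1:20) {
    mm <- random_incidence(2, 30)
    pc <- pairwise_components(mm, 1, 2)
    s1 <- which(mm[1, ] > 0); s2 <- which(mm[2, ] > 0)
    expect_equal(unname(pc), c(length(intersect(s1, s2)),
                               length(setdiff(s1, s2)),
                               length(setdiff(s2, s1))))
    expect_equal(unname(pc["a"] + pc["b_ij"]), length(s1))
  }
})

test_that("multisite partition reproduces worked examples", {
  # perfectly nested chain {s1..s4} > {s1,s2,s3} > {s1,s2}
  nested <- rbind(c(1, 1, 1, 1), c(1, 1, 0, 0), c(1, 1, 1, 0))
  p <- multisite_partition(nested)
  expect_equal(p$beta_sim, 0)
  expect_equal(p$beta_sor, 4 / 14)
  expect_equal(p$beta_sne, 4 / 14)
  # two disjoint sites: complete turnover, no nestedness
  disj <- rbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  pd <- multisite_partition(disj)
  expect_equal(pd$beta_sim, 1)
  expect_equal(pd$beta_sor, 1)
  expect_equal(pd$beta_sne, 0)
  # n = 2 equals the pairwise Sorensen / Simpson closed forms
  two <- rbind(c(1, 1, 1, 0), c(0, 1, 1, 1))
  pt <- multisite_partition(two)
  expect_equal(pt$beta_sor, 1 / 3)
  expect_equal(pt$beta_sim, 1 / 3)
  expect_equal(pt$beta_sne, 0)
  # degenerate inputs
  expect_error(multisite_partition(matrix(1, 1, 3)),
               class = "mossgrad_beta_error")
  expect_error(multisite_partition(matrix(0, 3, 3)),
               class = "mossgrad_beta_error")
})

test_that("multisite partition agrees with brute-force and library oracles", {
  skip_if_not_installed("vegan")
  set.seed(31)
  for (k in 1:40) {
    m <- random_incidence(sample(3:10, 1), 30)
    p <- multisite_partition(m)
    o <- oracle_multisite(m)
    expect_equal(p$beta_sim, unname(o["sim"]))
    expect_equal(p$beta_sne, unname(o["sne"]))
    v <- vegan::nestedbetasor(m)
    expect_equal(p$beta_sim, unname(v["turnover"]))
    expect_equal(p$beta_sne, unname(v["nestedness"]))
    expect_equal(p$beta_sor, unname(v["sorensen"]))
  }
})

test_that("partition is additive, bounded, and order-invariant", {
  set.seed(41)
  for (k in 1:200) {
    m <- random_incidence(sample(2:10, 1), sample(5:30, 1),
                          p = runif(1, 0.2, 0.8))
    if (ncol(m) == 0) next
    p <- multisite_partition(m)
    expect_equal(p$beta_sor, p$beta_sim + p$beta_sne, tolerance = 1e-14)
    expect_true(p$beta_sim >= 0 && p$beta_sor <= 1 &&
                  p$beta_sim <= p$beta_sor)
    ps <- multisite_partition(m[sample(nrow(m)), sample(ncol(m))])
    expect_equal(ps$beta_sor, p$beta_sor)
    expect_equal(ps$beta_sim, p$beta_sim)
  }
})

test_that("regional resampling draws only from the requested side and is seeded", {
  env <- make_landscape(10, 10, seed = 7)
  pool <- simulate_pool(sim_config(20, theta = 0.3, seed = 7), env)
  truth <- simulate_truth(pool, env, seed = 7)
  mask <- split_regions(env$grid, mean(env$grid$lat_range))
  d1 <- beta_sample(truth, mask, "north", 10, 50, seed = 1)
  d2 <- beta_sample(truth, mask, "north", 10, 50, seed = 1)
  expect_identical(d1$samples, d2$samples)
  expect_equal(nrow(d1$samples), 50)
  expect_error(beta_sample(truth, mask, "north", 51, 10, seed = 1),
               "smaller", class = "mossgrad_beta_error")
  # region of exactly the subset size: zero-variance distribution
  dall <- beta_sample(truth, mask, "north", sum(mask$labels == "north"),
                      20, seed = 3)
  expect_equal(var(dall$samples$beta_sim), 0)
  # nested zero-noise truth: every sampled subset has zero turnover
  pooln <- simulate_pool(sim_config(12, theta = 1, noise = 0), env)
  truthn <- simulate_truth(pooln, env, seed = 2)
  dn <- beta_sample(truthn, mask, "south", 20, 100, seed = 4)
  expect_true(all(dn$samples$beta_sim == 0))
  # two seeds give distributions that agree within Monte Carlo error
  da <- beta_sample(truth, mask, "south", 20, 300, seed = 5)
  db <- beta_sample(truth, mask, "south", 20, 300, seed = 6)
  se <- sqrt(var(da$samples$beta_sim) / 300 + var(db$samples$beta_sim) / 300)
  expect_lt(abs(mean(da$samples$beta_sim) - mean(db$samples$beta_sim)),
            5 * se)
})

test_that("distribution comparison handles identity, separation and known offsets", {
  mk <- function(v, group = "g", region = "r") {
    structure(list(samples = data.frame(sample = seq_along(v),
                                        beta_sor = v, beta_sim = v,
                                        beta_sne = v),
                   group = group, region = region,
                   n_samples = length(v)),
              class = "beta_sample_distribution")
  }
  a <- mk(runif(200))
  id <- compare_distributions(a, a, "beta_sim")
  expect_equal(id$p, 1)
  expect_equal(id$direction, "=")

  hi <- mk(runif(1000) + 2); lo <- mk(runif(1000))
  sep <- compare_distributions(hi, lo, "beta_sim")
  expect_equal(sep$p, 1 / 1000)
  expect_equal(sep$direction, ">")

  set.seed(51)
  va <- rnorm(500, 0.1); vb <- rnorm(500)
  cmp <- compare_distributions(mk(va), mk(vb), "beta_sne")
  m <- sum(va > vb) + 0.5 * sum(va == vb) # direct recount of the pairs
  expect_equal(cmp$p, max(min(2 * min(m / 500, 1 - m / 500), 1), 1 / 500))
  expect_equal(cmp$direction, if (median(va - vb) > 0) ">" else "<")
})
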