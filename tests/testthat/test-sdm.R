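make_sep_env <- function(n_rows = 12, n_cols = 12, seed = 5) {
  make_landscape(n_rows, n_cols, seed = seed)
}

# species grid with one species present exactly where temp exceeds its median
separable_species <- function(env) {
  pres <- env$layers$temp_mean > median(env$layers$temp_mean)
  species_grid(env$grid, "warm_lover", matrix(pres, ncol = 1))
}

test_that("collinearity screening drops one of each offending pair", {
  grid <- toy_grid(10, 10)
  set.seed(101)
  base <- rnorm(100)
  env <- env_stack(grid, list(
    a = base,
    b = base + rnorm(100, 0, 0.3), # r ~ 0.95 with a
    c = rnorm(100),
    d = rep(2, 100)))               # constant
  expect_warning(screen_predictors(env, r_max = 0.8), "constant layer")
  ps <- suppressWarnings(screen_predictors(env, r_max = 0.8))
  expect_false("d" %in% ps$retained)
  expect_equal(sum(c("a", "b") %in% ps$retained), 1)
  expect_true("c" %in% ps$retained)
  expect_equal(nrow(ps$log), 1)
  # orthogonal layers all retained
  env2 <- env_stack(grid, list(u = rnorm(100), v = rnorm(100),
                               w = rnorm(100)))
  expect_equal(screen_predictors(env2, 0.8)$retained, c("u", "v", "w"))
  # chain A~B, B~C strong, A~C weak: final set has no pair over the ceiling
  b2 <- base + rnorm(100, 0, 0.25)
  env3 <- env_stack(grid, list(A = base, B = b2,
                               C = b2 + rnorm(100, 0, 0.25)))
  ps3 <- screen_predictors(env3, 0.8)
  cm <- abs(cor(do.call(cbind, env3$layers[ps3$retained])))
  diag(cm) <- 0
  expect_true(all(cm <= 0.8)) # exhaustive recheck of every retained pair
})

test_that("evaluation scores match brute-force AUC and exhaustive TSS oracles", {
  set.seed(111)
  for (k in 1:15) {
    n <- 30
    labels <- c(rep(1, 10), rep(0, 20))
    pred <- round(runif(n), 2) # ties likely
    ev <- evaluate_predictions(pred, labels)
    expect_equal(ev$auc, oracle_auc(pred, labels))
    o <- oracle_max_tss(pred, labels)
    expect_equal(ev$tss, o$tss)
    expect_equal(ev$threshold_max_tss, o$threshold)
  }
  # perfect and uninformative classifiers
  lab <- c(1, 1, 1, 0, 0, 0, 0)
  expect_equal(evaluate_predictions(lab, lab)$auc, 1)
  expect_equal(evaluate_predictions(lab, lab)$tss, 1)
  flat <- evaluate_predictions(rep(0.4, 7), lab)
  expect_equal(flat$auc, 0.5)
  expect_equal(flat$tss, 0)
  expect_error(evaluate_predictions(runif(5), rep(1, 5)),
               class = "mossgrad_eval_error")
})

test_that("binarization and consensus follow the stated vote rules", {
  expect_equal(binarize(c(0.4, 0.6), 0.5), c(0L, 1L))
  expect_warning(binarize(c(0.1, 0.2), 0.5), "below threshold")
  members <- matrix(0L, 1, 12)
  members[1, 1:7] <- 1L # 7 of 12 vote present
  expect_equal(consensus(members), 1L)
  members[1, 7] <- 0L # exactly 6 of 12: tie resolves to absence
  expect_equal(consensus(members), 0L)
  allsame <- matrix(1L, 5, 3)
  expect_equal(consensus(allsame), rep(1L, 5))
  # weighted vote: a heavy member can carry the pixel
  m2 <- cbind(c(1L), c(0L), c(0L))
  expect_equal(consensus(m2, weights = c(10, 1, 1)), 1L)
})

test_that("a separable species is modelled perfectly by every replicate", {
  env <- make_sep_env()
  sg <- separable_species(env)
  cfg <- sdm_config(replicates = 5, techniques = c("glm", "maxlike"),
                    seed = 2)
  for (tech in cfg$techniques) {
    fit <- fit_species(sg, "warm_lover", env, tech, cfg,
                       predictors = "temp_mean")
    for (rep in fit$replicates) {
      expect_false(rep$skipped)
      expect_equal(rep$auc, 1.0)
      expect_equal(rep$tss, 1.0)
    }
  }
})

test_that("labels independent of the predictors give chance-level AUC", {
  env <- make_sep_env(15, 15, seed = 6)
  set.seed(121)
  pres <- runif(225) < 0.4
  sg <- species_grid(env$grid, "random_sp", matrix(pres, ncol = 1))
  cfg <- sdm_config(replicates = 10, techniques = "glm", seed = 3)
  fit <- fit_species(sg, "random_sp", env, "glm", cfg,
                     predictors = c("temp_mean", "precip_mean"))
  aucs <- vapply(fit$replicates, `[[`, numeric(1), "auc")
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("ensembles are reproducible and stack into bounded richness", {
  env <- make_sep_env(10, 10, seed = 8)
  pool <- simulate_pool(sim_config(6, theta = 0.5, noise = 0.05, seed = 8),
                        env)
  truth <- simulate_truth(pool, env, seed = 8)
  sg <- suppressMessages(filter_min_presence(truth, 10))
  cfg <- sdm_config(replicates = 2, techniques = c("glm", "rf"), seed = 4)
  ps <- screen_predictors(env, 0.8)
  e1 <- suppressMessages(ensemble_species(sg, sg$species_ids[1], env, cfg,
                                          ps$retained))
  e2 <- suppressMessages(ensemble_species(sg, sg$species_ids[1], env, cfg,
                                          ps$retained))
  expect_identical(e1$consensus, e2$consensus)
  expect_identical(e1$evaluation, e2$evaluation)
  # member count = techniques x replicates x threshold rules
  expect_equal(ncol(e1$members), 2 * 2 * 2)
  expect_true(all(e1$consensus %in% 0:1))

  ens <- suppressMessages(lapply(sg$species_ids, function(sp) {
    ensemble_species(sg, sp, env, cfg, ps$retained)
  }))
  st <- stack_sdm(ens, env$grid)
  # stacking is an elementwise sum of the consensus maps
  hand <- Reduce(`+`, lapply(ens, `[[`, "consensus"))
  expect_equal(st$values, as.numeric(hand))
  expect_true(all(st$values <= length(ens)))
  # permutation invariance and monotonicity of stacking
  st2 <- stack_sdm(rev(ens), env$grid)
  expect_equal(st2$values, st$values)
  st_fewer <- stack_sdm(ens[-1], env$grid)
  expect_true(all(st_fewer$values <= st$values))
  # empty stack: all-zero map
  expect_equal(stack_sdm(list(), env$grid)$values, rep(0, 100))
})
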