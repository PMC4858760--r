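# Per-species ensemble distribution modelling: collinearity screening,
# replicated 70/30 split-sample evaluation, threshold-consensus
# binarization and stacking into potential richness maps.

#' SDM configuration
#'
#' @param replicates Split-sampling replicates per technique (default 10).
#' @param train_frac Training fraction of the 70/30 split (default 0.7).
#' @param techniques Subset of `"glm"` (logistic regression with linear and
#'   quadratic terms), `"rf"` (random forest), `"maxlike"`
#'   (presence/background weighted logistic model).
#' @param threshold_rules Subset of `"max_tss"` (threshold maximizing the
#'   true skill statistic) and `"sens_spec"` (sensitivity = specificity).
#' @param background_cap Background sample size is
#'   `min(max(n_presences, background_cap), available absences)`.
#' @param ntree Trees per random forest (default 100).
#' @param weighted_consensus Weight each member's vote by its replicate TSS
#'   (default `TRUE`); otherwise equal weights.
#' @param seed Master seed; per-species/technique/replicate sub-seeds are
#'   derived from it, so every fit is individually reproducible.
#' @return List of class `sdm_config`.
#' @export
sdm_config <- function(replicates = 10, train_frac = 0.7,
                       techniques = c("glm", "rf", "maxlike"),
                       threshold_rules = c("max_tss", "sens_spec"),
                       background_cap = 1000, ntree = 100,
                       weighted_consensus = TRUE, seed = 1) {
  techniques <- match.arg(techniques, several.ok = TRUE)
  threshold_rules <- match.arg(threshold_rules, several.ok = TRUE)
  stopifnot(replicates >= 1, train_frac > 0, train_frac < 1,
            background_cap >= 1, ntree >= 1)
  structure(list(replicates = as.integer(replicates),
                 train_frac = train_frac, techniques = techniques,
                 threshold_rules = threshold_rules,
                 background_cap = as.integer(background_cap),
                 ntree = as.integer(ntree),
                 weighted_consensus = weighted_consensus,
                 seed = as.integer(seed)),
            class = "sdm_config")
}

#' Screen predictors for collinearity
#'
#' Pearson-correlation screening: while any retained pair has `|r| >
#' r_max`, the worst-offending pair is found and the member with the larger
#' mean absolute correlation to all other remaining candidates is dropped.
#' Constant layers are excluded up front with a warning (their correlation
#' is undefined). The full elimination log is returned.
#'
#' @param env An [env_stack()].
#' @param r_max Absolute-correlation ceiling for retained pairs
#'   (default 0.8).
#' @param candidates Layer names to consider (default all).
#' @return Object of class `predictor_set`: `candidates`, `retained`,
#'   `cor_matrix` (over non-constant candidates), `log` data frame of
#'   eliminations.
#' @export
screen_predictors <- function(env, r_max = 0.8,
                              candidates = names(env$layers)) {
  stopifnot(length(candidates) >= 2, r_max > 0)
  x <- do.call(cbind, env$layers[candidates])
  if (nrow(x) < 3) {
    stop_mossgrad("need >= 3 valid pixels to screen predictors",
                  "mossgrad_stat_error")
  }
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("screen_predictors: excluding constant layer(s): %s",
                    paste(candidates[sds == 0], collapse = ", ")))
  }
  keep <- candidates[sds > 0]
  cm <- stats::cor(x[, keep, drop = FALSE])
  retained <- keep
  log <- data.frame(dropped = character(), against = character(),
                    r = numeric(), mean_abs_r = numeric())
  repeat {
    sub <- abs(cm[retained, retained, drop = FALSE])
    diag(sub) <- 0
    if (length(retained) < 2 || max(sub) <= r_max) break
    worst <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    pair <- retained[worst]
    mean_r <- vapply(pair, function(v) {
      others <- setdiff(retained, v)
      mean(abs(cm[v, others]))
    }, numeric(1))
    drop <- pair[which.max(mean_r)] # ties: which.max takes the first
    log <- rbind(log, data.frame(
      dropped = drop, against = setdiff(pair, drop)[1],
      r = cm[pair[1], pair[2]], mean_abs_r = max(mean_r)))
    retained <- setdiff(retained, drop)
  }
  structure(list(candidates = candidates, retained = retained,
                 cor_matrix = cm, log = log),
            class = "predictor_set")
}

#' Threshold-free and threshold-dependent evaluation scores
#'
#' AUC is computed by the rank-sum (Mann-Whitney) identity; the true skill
#' statistic `TSS = sensitivity + specificity - 1` is maximized by an
#' exhaustive scan over all observed prediction values (prediction >=
#' threshold classifies as presence; ties in the maximum break to the
#' smallest threshold). The sensitivity = specificity threshold minimizes
#' `|sens - spec|`.
#'
#' @param pred Numeric predictions in `[0, 1]`.
#' @param labels 0/1 (or logical) observed classes; both classes required.
#' @return List: `auc`, `tss` (maximum), `threshold_max_tss`,
#'   `threshold_sens_spec`.
#' @export
evaluate_predictions <- function(pred, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(pred) == length(labels))
  np <- sum(labels == 1); nn <- sum(labels == 0)
  if (np == 0 || nn == 0) {
    stop_mossgrad("evaluation undefined: test set contains one class only",
                  "mossgrad_eval_error")
  }
  r <- rank(pred, ties.method = "average")
  auc <- (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
  thr <- sort(unique(pred))
  sens <- vapply(thr, function(t) sum(pred >= t & labels == 1) / np,
                 numeric(1))
  spec <- vapply(thr, function(t) sum(pred < t & labels == 0) / nn,
                 numeric(1))
  tss <- sens + spec - 1
  best <- which(tss == max(tss))[1]
  eq <- which.min(abs(sens - spec))
  list(auc = auc, tss = tss[best], threshold_max_tss = thr[best],
       threshold_sens_spec = thr[eq])
}

#' Binarize a continuous prediction map
#'
#' @param pred Numeric predictions.
#' @param threshold Classification threshold: `pred >= threshold` is 1.
#' @return Integer 0/1 vector; warns if everything falls below threshold.
#' @export
binarize <- function(pred, threshold) {
  out <- as.integer(pred >= threshold)
  if (all(out == 0)) warning("binarize: all predictions below threshold")
  out
}

#' Weighted-vote consensus of binary member maps
#'
#' A pixel is predicted present iff the weighted fraction of member maps
#' voting present exceeds 0.5; exact ties are resolved to absence, the
#' conservative choice for stacked richness.
#'
#' @param members Matrix of 0/1 member maps (pixels x members), or a list
#'   of vectors.
#' @param weights Non-negative member weights; if all zero, equal weights.
#' @return Integer 0/1 consensus vector.
#' @export
consensus <- function(members, weights = NULL) {
  if (is.list(members)) members <- do.call(cbind, members)
  m <- ncol(members)
  stopifnot(m >= 1)
  if (is.null(weights)) weights <- rep(1, m)
  stopifnot(length(weights) == m, all(weights >= 0))
  if (sum(weights) == 0) weights <- rep(1, m)
  vote <- as.numeric(members %*% weights) / sum(weights)
  as.integer(vote > 0.5)
}

sdm_design <- function(sg, species, env, predictors, cfg) {
  sp <- match(species, sg$species_ids)
  if (is.na(sp)) {
    stop_mossgrad(paste("unknown species:", species), "mossgrad_sdm_error")
  }
  pres <- which(sg$occupancy[, sp])
  pool <- which(!sg$occupancy[, sp])
  n_bg <- min(max(length(pres), cfg$background_cap), length(pool))
  bg <- with_seed(derive_seed(cfg$seed, paste0("bg/", species)), {
    sort(sample(pool, n_bg))
  })
  x_all <- do.call(cbind, env$layers[predictors])
  list(pres = pres, bg = bg, rows = c(pres, bg),
       y = c(rep(1L, length(pres)), rep(0L, length(bg))),
       x = x_all[c(pres, bg), , drop = FALSE], x_all = x_all)
}

quad_formula <- function(predictors) {
  stats::as.formula(paste(
    "y ~", paste(sprintf("%s + I(%s^2)", predictors, predictors),
                 collapse = " + ")))
}

# Logistic fit with a single AIC pass over the quadratic terms: an
# unpenalized quadratic under complete separation diverges with spurious
# curvature that can invert the ranking at the range extremes, so
# curvature is kept only where it improves AIC.
pruned_logistic <- function(df_tr, predictors, weights = NULL) {
  df_tr$.w <- if (is.null(weights)) rep(1, nrow(df_tr)) else weights
  full <- suppressWarnings(
    stats::glm(quad_formula(predictors), data = df_tr,
               family = stats::binomial(), weights = .w))
  qterms <- sprintf("I(%s^2)", predictors)
  keep_q <- tryCatch({
    d1 <- suppressWarnings(stats::drop1(
      full, scope = stats::as.formula(paste("~", paste(qterms, collapse = "+")))))
    qterms[d1$AIC[-1] > d1$AIC[1]]
  }, error = function(e) qterms)
  if (length(keep_q) == length(qterms)) return(full)
  terms <- c(predictors, keep_q)
  suppressWarnings(
    stats::glm(stats::as.formula(paste("y ~", paste(terms, collapse = " + "))),
               data = df_tr, family = stats::binomial(), weights = .w))
}

fit_one <- function(technique, xtr, ytr, x_all, predictors, cfg, sub_seed) {
  df_tr <- data.frame(y = ytr, xtr)
  df_all <- data.frame(x_all)
  if (technique == "glm") {
    fit <- pruned_logistic(df_tr, predictors)
    suppressWarnings(
      as.numeric(stats::predict(fit, newdata = df_all, type = "response")))
  } else if (technique == "rf") {
    fit <- with_seed(sub_seed, {
      randomForest::randomForest(x = xtr, y = factor(ytr, levels = 0:1),
                                 ntree = cfg$ntree)
    })
    as.numeric(stats::predict(fit, newdata = x_all, type = "prob")[, "1"])
  } else if (technique == "maxlike") {
    # presence/background weighted logistic: background re-weighted so both
    # classes carry equal total weight, the usual infinitely-weighted
    # pseudo-absence approximation
    w <- ifelse(ytr == 1, 1, sum(ytr == 1) / max(sum(ytr == 0), 1))
    fit <- pruned_logistic(df_tr, predictors, weights = w)
    suppressWarnings(
      as.numeric(stats::predict(fit, newdata = df_all, type = "response")))
  } else {
    stop_mossgrad(paste("unknown technique:", technique),
                  "mossgrad_sdm_error")
  }
}

#' Fit one species with one technique under replicated split-sampling
#'
#' Presences and a seeded uniform background sample from land pixels
#' without a presence are split 70/30 (stratified by class) `replicates`
#' times; each replicate is trained on its 70% and evaluated (AUC, TSS,
#' thresholds) on the held-out 30%, and predicts a continuous suitability
#' map over all land pixels. Replicates whose training split has fewer than
#' 2 presences, or whose test split has one class, are skipped and logged.
#'
#' @param sg A [species_grid()] (species should already have passed
#'   [filter_min_presence()]).
#' @param species Species id.
#' @param env An [env_stack()].
#' @param technique `"glm"`, `"rf"` or `"maxlike"`.
#' @param cfg An [sdm_config()].
#' @param predictors Retained predictor names (default: screen with
#'   defaults).
#' @return Object of class `sdm_fit`: per-replicate predictions, train/test
#'   row indices, scores and thresholds.
#' @export
fit_species <- function(sg, species, env, technique, cfg = sdm_config(),
                        predictors = NULL) {
  if (is.null(predictors)) predictors <- screen_predictors(env)$retained
  d <- sdm_design(sg, species, env, predictors, cfg)
  reps <- vector("list", cfg$replicates)
  for (r in seq_len(cfg$replicates)) {
    key <- paste0("sdm/", species, "/", technique, "/rep", r)
    sub_seed <- derive_seed(cfg$seed, key)
    split <- with_seed(derive_seed(cfg$seed, paste0("split/", species,
                                                    "/rep", r)), {
      # the split is shared across techniques so members differ only by
      # algorithm, not by data
      n1 <- sum(d$y == 1); n0 <- sum(d$y == 0)
      tr <- c(sample(which(d$y == 1), round(cfg$train_frac * n1)),
              sample(which(d$y == 0), round(cfg$train_frac * n0)))
      sort(tr)
    })
    test <- setdiff(seq_along(d$y), split)
    if (sum(d$y[split] == 1) < 2 || length(unique(d$y[test])) < 2) {
      reps[[r]] <- list(skipped = TRUE, reason = "degenerate split")
      next
    }
    pred_all <- fit_one(technique, d$x[split, , drop = FALSE], d$y[split],
                        d$x_all, predictors, cfg, sub_seed)
    ev <- evaluate_predictions(pred_all[d$rows[test]], d$y[test])
    reps[[r]] <- list(skipped = FALSE, train = split, test = test,
                      pred = pred_all, auc = ev$auc, tss = ev$tss,
                      threshold_max_tss = ev$threshold_max_tss,
                      threshold_sens_spec = ev$threshold_sens_spec)
  }
  n_skip <- sum(vapply(reps, `[[`, logical(1), "skipped"))
  if (n_skip > 0) {
    message(sprintf("fit_species(%s, %s): skipped %d degenerate replicate(s)",
                    species, technique, n_skip))
  }
  structure(list(species = species, technique = technique,
                 predictors = predictors, replicates = reps,
                 design = d[c("pres", "bg", "rows", "y")]),
            class = "sdm_fit")
}

#' Ensemble one species across techniques, replicates and threshold rules
#'
#' Every non-skipped replicate of every technique contributes one binary
#' member map per threshold rule; the consensus is their weighted vote
#' (weights = replicate TSS clamped at 0 when `weighted_consensus`).
#'
#' @inheritParams fit_species
#' @return Object of class `ensemble_result`: `species`, `fits` (one
#'   `sdm_fit` per technique), `members` (pixels x members 0/1 matrix),
#'   `weights`, `consensus` (0/1 per land pixel), `evaluation` data frame
#'   (species, technique, replicate, auc, tss, thresholds).
#' @export
ensemble_species <- function(sg, species, env, cfg = sdm_config(),
                             predictors = NULL) {
  if (is.null(predictors)) predictors <- screen_predictors(env)$retained
  fits <- lapply(cfg$techniques, function(tech) {
    fit_species(sg, species, env, tech, cfg, predictors)
  })
  members <- list(); weights <- numeric(0); eval_rows <- list()
  for (f in fits) {
    for (r in seq_along(f$replicates)) {
      rep <- f$replicates[[r]]
      if (rep$skipped) next
      eval_rows[[length(eval_rows) + 1]] <- data.frame(
        species = species, technique = f$technique, replicate = r,
        auc = rep$auc, tss = rep$tss,
        threshold_max_tss = rep$threshold_max_tss,
        threshold_sens_spec = rep$threshold_sens_spec)
      for (rule in cfg$threshold_rules) {
        thr <- if (rule == "max_tss") rep$threshold_max_tss else {
          rep$threshold_sens_spec
        }
        members[[length(members) + 1]] <-
          suppressWarnings(binarize(rep$pred, thr))
        weights <- c(weights,
                     if (cfg$weighted_consensus) max(rep$tss, 0) else 1)
      }
    }
  }
  if (length(members) == 0) {
    stop_mossgrad(paste("no usable ensemble member for species", species),
                  "mossgrad_sdm_error")
  }
  members <- do.call(cbind, members)
  structure(list(species = species, fits = fits, members = members,
                 weights = weights,
                 consensus = consensus(members, weights),
                 evaluation = do.call(rbind, eval_rows)),
            class = "ensemble_result")
}

#' Stack consensus maps into a potential richness map
#'
#' Per-pixel potential richness is the sum of the per-species binary
#' consensus maps; it is bounded by the number of stacked species and
#' monotone in the species set.
#'
#' @param ensembles List of `ensemble_result` objects (or bare 0/1
#'   vectors/matrix) on a shared grid.
#' @param grid The shared [lattice_grid()].
#' @return A [richness_map()].
#' @export
stack_sdm <- function(ensembles, grid) {
  mats <- lapply(ensembles, function(e) {
    if (inherits(e, "ensemble_result")) e$consensus else as.numeric(e)
  })
  n_land <- sum(grid$land_mask)
  if (length(mats) == 0) return(richness_map(grid, rep(0, n_land)))
  richness_map(grid, Reduce(`+`, mats))
}

#' Run the full per-group ensemble and stack
#'
#' Convenience wrapper: screens predictors once, ensembles every species in
#' the grid and stacks the consensus maps.
#'
#' @param sg A filtered [species_grid()].
#' @param env An [env_stack()].
#' @param cfg An [sdm_config()].
#' @param r_max Collinearity ceiling passed to [screen_predictors()].
#' @return List: `predictor_set`, `ensembles`, `evaluation` (all species),
#'   `stack` ([richness_map()]).
#' @export
sdm_ensemble <- function(sg, env, cfg = sdm_config(), r_max = 0.8) {
  ps <- screen_predictors(env, r_max = r_max)
  ensembles <- lapply(sg$species_ids, function(sp) {
    ensemble_species(sg, sp, env, cfg, predictors = ps$retained)
  })
  list(predictor_set = ps, ensembles = ensembles,
       evaluation = do.call(rbind, lapply(ensembles, `[[`, "evaluation")),
       stack = stack_sdm(ensembles, sg$grid))
}
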