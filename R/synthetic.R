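#' Environmental layer stack
#'
#' Named per-pixel environmental layers on a shared grid. Layer values are
#' stored over land pixels in [land_index()] order, like every per-pixel
#' vector in the package.
#'
#' @param grid A [lattice_grid()].
#' @param layers Named list of numeric vectors, one value per land pixel.
#' @return An object of class `env_stack`.
#' @export
env_stack <- function(grid, layers) {
  stopifnot(is.list(layers), !is.null(names(layers)),
            !anyDuplicated(names(layers)))
  n_land <- sum(grid$land_mask)
  for (nm in names(layers)) {
    if (length(layers[[nm]]) != n_land) {
      stop_mossgrad(sprintf("layer '%s' length != number of land pixels", nm),
                    "mossgrad_grid_error")
    }
    layers[[nm]] <- as.numeric(layers[[nm]])
  }
  structure(list(grid = grid, layers = layers), class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("env_stack: %d layers on %d land pixels\n  %s\n",
              length(x$layers), sum(x$grid$land_mask),
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' Generate a synthetic gridded landscape
#'
#' Builds an equal-area lattice with the driver layers used in the band
#' analyses: mean annual temperature (decreasing with latitude), mean
#' precipitation (longitudinal gradient), potential evapotranspiration
#' (strongly collinear with temperature, so the predictor screen has work
#' to do), the corresponding heterogeneity layers (per-pixel standard
#' deviations, non-negative), distance to coast (grid edge) and distance
#' to refugia (the southern corners). All stochastic texture is a pure
#' function of `seed`.
#'
#' @param n_rows,n_cols Lattice dimensions (>= 2).
#' @param lat_range Latitude span in degrees, bottom/top edge.
#' @param seed Integer seed.
#' @param noise_scale Multiplier on the stochastic texture of each layer;
#'   0 gives smooth deterministic gradients.
#' @param pixel_size Pixel edge in km (default 100).
#' @param land_mask Optional logical mask, default all land.
#' @return An [env_stack()].
#' @export
make_landscape <- function(n_rows, n_cols, lat_range = c(38, 54), seed = 1,
                           noise_scale = 1, pixel_size = 100,
                           land_mask = NULL) {
  stopifnot(n_rows >= 2, n_cols >= 2, noise_scale >= 0)
  grid <- lattice_grid(n_rows, n_cols, pixel_size = pixel_size,
                       lat_range = lat_range, land_mask = land_mask)
  li <- land_index(grid)
  cc <- pixel_centroids(grid)[li, ]
  n <- length(li)
  with_seed(derive_seed(seed, "landscape"), {
    lat <- cc$lat
    # lapse of ~0.9 degC per degree latitude, like mid-latitude Europe
    temp <- 18 - 0.9 * (lat - lat_range[1]) + noise_scale * stats::rnorm(n, 0, 0.6)
    precip <- 500 + 400 * (cc$col - 1) / max(grid$n_cols - 1, 1) +
      noise_scale * stats::rnorm(n, 0, 40)
    pet <- 320 + 28 * temp + noise_scale * stats::rnorm(n, 0, 15)
    dist_edge <- pmin(cc$row - 0.5, grid$n_rows - cc$row + 0.5,
                      cc$col - 0.5, grid$n_cols - cc$col + 0.5) * pixel_size
    refugia <- rbind(c(1, grid$n_rows), c(grid$n_cols, grid$n_rows))
    d_ref <- sqrt(pmin(
      (cc$col - refugia[1, 1])^2 + (grid$n_rows - cc$row + 1 - 1)^2,
      (cc$col - refugia[2, 1])^2 + (grid$n_rows - cc$row + 1 - 1)^2)) *
      pixel_size
    layers <- list(
      temp_mean   = temp,
      temp_sd     = 0.4 + noise_scale * abs(stats::rnorm(n, 0, 0.5)),
      precip_mean = pmax(precip, 0),
      precip_sd   = 25 + noise_scale * abs(stats::rnorm(n, 0, 20)),
      alt_sd      = 80 + noise_scale * abs(stats::rnorm(n, 0, 120)),
      pet_mean    = pmax(pet, 0),
      pet_sd      = 12 + noise_scale * abs(stats::rnorm(n, 0, 8)),
      dist_coast  = dist_edge,
      dist_refugia = d_ref)
    env_stack(grid, layers)
  })
}

#' Simulation configuration
#'
#' @param n_species Number of species in the pool.
#' @param theta Community architecture mix in `[0, 1]`: 1 = pure ordered
#'   species loss along the thermal gradient (nested ranges), 0 = pure
#'   species replacement (evenly spaced narrow optima), intermediate values
#'   mix the two archetypes in proportion.
#' @param noise Class-noise level in `[0, 1)`: maximum occupancy
#'   probability is `1 - noise`, so 0 gives deterministic incidence.
#' @param seed Integer master seed, recorded in all outputs.
#' @param domain_lat Optional latitude interval `c(lo, hi)` outside which
#'   the pool's species never occur (used to give northern and southern
#'   communities different architectures).
#' @param opt_window Quantile window of the thermal gradient over which
#'   turnover optima / nested cold limits are spread (default the full
#'   gradient).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_species = 60, theta = 0.5, noise = 0.05, seed = 1,
                       domain_lat = NULL, opt_window = c(0, 1)) {
  stopifnot(n_species >= 1, theta >= 0, theta <= 1, noise >= 0, noise < 1,
            length(opt_window) == 2, opt_window[1] < opt_window[2])
  structure(list(n_species = as.integer(n_species), theta = theta,
                 noise = noise, seed = as.integer(seed),
                 domain_lat = domain_lat, opt_window = opt_window),
            class = "sim_config")
}

#' Simulate a species pool with controlled beta-diversity architecture
#'
#' Two archetypes along the temperature gradient:
#' * **nested** (ordered loss): species `k` occupies every pixel warmer
#'   than its cold-tolerance limit, and limits are evenly spaced, so each
#'   species' range is a subset of the range of the next more cold-tolerant
#'   species — incidence is perfectly nested and multisite turnover is zero
#'   by construction.
#' * **turnover** (replacement): evenly spaced narrow Gaussian optima, so
#'   assemblages are replaced along the gradient.
#'
#' `round(theta * n_species)` species follow the nested archetype, the rest
#' the turnover archetype.
#'
#' @param cfg A [sim_config()].
#' @param env An [env_stack()] with a `temp_mean` layer.
#' @return A data frame of class `niche_table`: per species the archetype,
#'   cold limit and cold rank (nested), optimum and breadth (turnover),
#'   maximum occupancy probability and latitude domain.
#' @export
simulate_pool <- function(cfg, env) {
  stopifnot(inherits(cfg, "sim_config"), "temp_mean" %in% names(env$layers))
  lat <- env$grid$centroid_lat[land_index(env$grid)]
  in_dom <- if (is.null(cfg$domain_lat)) rep(TRUE, length(lat)) else {
    lat >= cfg$domain_lat[1] & lat <= cfg$domain_lat[2]
  }
  if (!any(in_dom)) {
    stop_mossgrad("domain_lat excludes every land pixel", "mossgrad_sim_error")
  }
  tr <- range(env$layers$temp_mean[in_dom])
  t_lo <- tr[1] + cfg$opt_window[1] * diff(tr)
  t_hi <- tr[1] + cfg$opt_window[2] * diff(tr)
  n_nested <- round(cfg$theta * cfg$n_species)
  n_turn <- cfg$n_species - n_nested
  p_max <- 1 - cfg$noise
  rows <- list()
  if (n_nested > 0) {
    # limit of the k-th species at (k-1)/n of the gradient: species 1 (rank 1,
    # most cold-tolerant) spans the whole domain, later ranks only its warm end
    lim <- t_lo + (seq_len(n_nested) - 1) / n_nested * (t_hi - t_lo)
    rows$nested <- data.frame(
      species = sprintf("nested_%03d", seq_len(n_nested)),
      archetype = "nested", cold_limit = lim, cold_rank = seq_len(n_nested),
      optimum = NA_real_, breadth = NA_real_, p_max = p_max)
  }
  if (n_turn > 0) {
    opt <- if (n_turn == 1) (t_lo + t_hi) / 2 else {
      seq(t_lo, t_hi, length.out = n_turn)
    }
    spacing <- if (n_turn == 1) (t_hi - t_lo) / 2 else diff(opt[1:2])
    rows$turnover <- data.frame(
      species = sprintf("turnover_%03d", seq_len(n_turn)),
      archetype = "turnover", cold_limit = NA_real_, cold_rank = NA_integer_,
      optimum = opt, breadth = pmax(2 * spacing, 1e-6), p_max = p_max)
  }
  nt <- do.call(rbind, rows)
  rownames(nt) <- NULL
  nt$domain_lo <- if (is.null(cfg$domain_lat)) -Inf else cfg$domain_lat[1]
  nt$domain_hi <- if (is.null(cfg$domain_lat)) Inf else cfg$domain_lat[2]
  class(nt) <- c("niche_table", "data.frame")
  nt
}

#' Per-pixel occupancy probability implied by a niche table
#'
#' Nested species: `p_max` wherever temperature is at or above the cold
#' limit, 0 elsewhere. Turnover species: `p_max * exp(-z^2/2)` with
#' `z = (temp - optimum)/breadth`, truncated to 0 beyond `|z| > 3` so
#' ranges are genuinely bounded. Species never occur outside their latitude
#' domain.
#'
#' @param niches A `niche_table`.
#' @param env An [env_stack()].
#' @return Matrix, land pixels x species, values in `[0, 1]`.
#' @export
suitability <- function(niches, env) {
  temp <- env$layers$temp_mean
  lat <- env$grid$centroid_lat[land_index(env$grid)]
  out <- matrix(0, length(temp), nrow(niches))
  colnames(out) <- niches$species
  for (k in seq_len(nrow(niches))) {
    r <- niches[k, ]
    p <- if (r$archetype == "nested") {
      r$p_max * as.numeric(temp >= r$cold_limit)
    } else {
      z <- (temp - r$optimum) / r$breadth
      ifelse(abs(z) > 3, 0, r$p_max * exp(-0.5 * z^2))
    }
    p[lat < r$domain_lo | lat > r$domain_hi] <- 0
    out[, k] <- p
  }
  out
}

#' Draw a true presence/absence grid from a species pool
#'
#' Presence is Bernoulli in the per-pixel suitability, giving the modelling
#' stage genuine class noise; pixels with suitability exactly 1 are always
#' present and suitability 0 never, so a zero-noise pool yields
#' deterministic incidence.
#'
#' @param niches A `niche_table`.
#' @param env An [env_stack()].
#' @param seed Integer seed.
#' @return A [species_grid()] — the ground truth.
#' @export
simulate_truth <- function(niches, env, seed = 1) {
  p <- suitability(niches, env)
  occ <- with_seed(derive_seed(seed, "truth"), {
    matrix(stats::runif(length(p)), nrow(p), ncol(p)) < p
  })
  species_grid(env$grid, niches$species, occ)
}

#' Spatially biased sampling-effort surface
#'
#' Constant within each side of a latitude split; the north:south ratio of
#' the two constants sets the bias the distribution-modelling stage must
#' cope with.
#'
#' @param grid A [lattice_grid()].
#' @param north_weight,south_weight Non-negative relative effort.
#' @param split_latitude Split in degrees (default 46).
#' @return Numeric effort per land pixel.
#' @export
make_effort <- function(grid, north_weight = 1, south_weight = 1,
                        split_latitude = 46.0) {
  stopifnot(north_weight >= 0, south_weight >= 0,
            north_weight + south_weight > 0)
  lat <- grid$centroid_lat[land_index(grid)]
  ifelse(lat > split_latitude, north_weight, south_weight)
}

#' Sample occurrence records from a true grid under biased effort
#'
#' Records are drawn from the (pixel, species) pairs that are truly present,
#' with probability proportional to the effort at the pixel; no false
#' presence is ever emitted. Record coordinates are the pixel centroids, so
#' rasterizing the records reproduces a subset of the truth exactly.
#'
#' @param truth A [species_grid()].
#' @param effort Numeric effort per land pixel (>= 0, not all zero).
#' @param n_records Number of records to draw.
#' @param seed Integer seed.
#' @param replace Draw with replacement? Without replacement (default),
#'   `n_records` may not exceed the number of available true pairs.
#' @return An `occurrence_table` with columns `species`, `x`, `y`.
#' @export
sample_records <- function(truth, effort, n_records, seed = 1,
                           replace = FALSE) {
  stopifnot(all(effort >= 0), any(effort > 0),
            length(effort) == nrow(truth$occupancy))
  pairs <- which(truth$occupancy, arr.ind = TRUE)
  if (nrow(pairs) == 0) {
    stop_mossgrad("truth grid has no presences to sample",
                  "mossgrad_sim_error")
  }
  w <- effort[pairs[, 1]]
  avail <- sum(w > 0)
  if (!replace && n_records > avail) {
    stop_mossgrad(sprintf(
      "n_records (%d) exceeds the %d sampleable true presences; reduce n_records or set replace = TRUE",
      n_records, avail), "mossgrad_sim_error")
  }
  idx <- with_seed(derive_seed(seed, "records"), {
    sample.int(nrow(pairs), n_records, replace = replace, prob = w)
  })
  cc <- pixel_centroids(truth$grid)[land_index(truth$grid), ]
  out <- data.frame(
    species = truth$species_ids[pairs[idx, 2]],
    x = cc$x[pairs[idx, 1]],
    y = cc$y[pairs[idx, 1]])
  class(out) <- c("occurrence_table", "data.frame")
  out
}

#' Assemble the two-region study scenario
#'
#' The landscape's northern and southern halves (split at `split_latitude`)
#' receive separate species pools with their own architecture parameter, so
#' e.g. `theta_north = 1, theta_south = 0` yields ordered species loss in
#' the north and species replacement in the south — the configuration whose
#' regional beta-diversity contrast the pipeline is designed to recover.
#'
#' @param n_rows,n_cols Grid size (default 20 x 20).
#' @param lat_range Latitude span; the default 38-54 puts the midline at 46.
#' @param n_species Total species, split evenly between regions.
#' @param theta_north,theta_south Architecture mix per region.
#' @param noise Class-noise level (see [sim_config()]).
#' @param split_latitude Regional split in degrees.
#' @param seed Master seed.
#' @return List with `env`, `niches`, `truth`, `regions` and the arguments
#'   as `config`.
#' @export
simulate_scenario <- function(n_rows = 20, n_cols = 20,
                              lat_range = c(38, 54), n_species = 60,
                              theta_north = 1, theta_south = 0,
                              noise = 0.05, split_latitude = 46.0,
                              seed = 1) {
  env <- make_landscape(n_rows, n_cols, lat_range = lat_range, seed = seed)
  n_n <- floor(n_species / 2)
  pool_n <- simulate_pool(
    sim_config(n_n, theta = theta_north, noise = noise, seed = seed,
               domain_lat = c(split_latitude, lat_range[2])), env)
  pool_s <- simulate_pool(
    sim_config(n_species - n_n, theta = theta_south, noise = noise,
               seed = seed, domain_lat = c(lat_range[1], split_latitude)),
    env)
  pool_n$species <- paste0("N_", pool_n$species)
  pool_s$species <- paste0("S_", pool_s$species)
  niches <- rbind(pool_n, pool_s)
  class(niches) <- c("niche_table", "data.frame")
  truth <- simulate_truth(niches, env, seed = seed)
  list(env = env, niches = niches, truth = truth,
       regions = split_regions(env$grid, split_latitude),
       config = list(n_rows = n_rows, n_cols = n_cols,
                     lat_range = lat_range, n_species = n_species,
                     theta_north = theta_north, theta_south = theta_south,
                     noise = noise, split_latitude = split_latitude,
                     seed = seed))
}
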