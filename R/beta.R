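# Multiple-site Sorensen dissimilarity partitioned into its turnover
# (Simpson-based) and nestedness-resultant components, plus the resampling
# machinery used to compare regions and groups.

as_incidence <- function(x) {
  m <- if (inherits(x, "species_grid")) x$occupancy else as.matrix(x)
  storage.mode(m) <- "integer"
  m
}

#' Pairwise incidence components of two sites
#'
#' The building blocks of the Sorensen family: `a` = species shared,
#' `b_ij` = species of site `i` absent from `j`, `b_ji` the reverse.
#'
#' @param sg A [species_grid()] or a sites-by-species 0/1 matrix.
#' @param i,j Site (row) indices.
#' @return Named numeric vector `c(a, b_ij, b_ji)`.
#' @export
pairwise_components <- function(sg, i, j) {
  m <- as_incidence(sg)
  stopifnot(i >= 1, i <= nrow(m), j >= 1, j <= nrow(m))
  a <- sum(m[i, ] & m[j, ])
  c(a = a, b_ij = sum(m[i, ]) - a, b_ji = sum(m[j, ]) - a)
}

#' Multiple-site Sorensen dissimilarity and its partition
#'
#' For `n` sites with richness `S_i`, pooled richness `S_T`, and pairwise
#' unique-species counts `b_ij`:
#' \deqn{\beta_{SIM} = \frac{\sum_{i<j}\min(b_{ij},b_{ji})}
#'   {(\sum_i S_i - S_T) + \sum_{i<j}\min(b_{ij},b_{ji})}}
#' \deqn{\beta_{SOR} = \frac{\sum_{i<j}\min + \sum_{i<j}\max}
#'   {2(\sum_i S_i - S_T) + \sum_{i<j}\min + \sum_{i<j}\max}}
#' and \eqn{\beta_{SNE} = \beta_{SOR} - \beta_{SIM}}, the additive
#' decomposition into species replacement (turnover) and richness-driven
#' nested dissimilarity. Species present at none of the sites are dropped
#' before computing `S_T`: the measure is defined on the realized pool.
#'
#' @param sg A [species_grid()] or a sites-by-species 0/1 matrix with at
#'   least 2 sites and 1 non-empty species.
#' @return An object of class `beta_partition` with fields `beta_sor`,
#'   `beta_sim`, `beta_sne`, `n_sites` and the raw `components`
#'   (`sum_min`, `sum_max`, `rich_diff` = \eqn{\sum S_i - S_T}).
#' @export
multisite_partition <- function(sg) {
  m <- as_incidence(sg)
  if (nrow(m) < 2) {
    stop_mossgrad("multisite dissimilarity needs >= 2 sites",
                  "mossgrad_beta_error")
  }
  m <- m[, colSums(m) > 0, drop = FALSE]
  if (ncol(m) == 0) {
    stop_mossgrad("incidence matrix is empty (no species present anywhere)",
                  "mossgrad_beta_error")
  }
  s_i <- rowSums(m)
  s_t <- ncol(m)
  shared <- tcrossprod(m)          # a_ij = shared species of sites i, j
  b <- matrix(s_i, nrow(m), nrow(m)) - shared # b_ij = unique to site i vs j
  ut <- upper.tri(b)
  sum_min <- sum(pmin(b[ut], t(b)[ut]))
  sum_max <- sum(pmax(b[ut], t(b)[ut]))
  rich_diff <- sum(s_i) - s_t
  beta_sim <- if (sum_min == 0) 0 else sum_min / (rich_diff + sum_min)
  denom_sor <- 2 * rich_diff + sum_min + sum_max
  beta_sor <- if (denom_sor == 0) 0 else (sum_min + sum_max) / denom_sor
  structure(list(beta_sor = beta_sor, beta_sim = beta_sim,
                 beta_sne = beta_sor - beta_sim,
                 n_sites = nrow(m),
                 components = c(sum_min = sum_min, sum_max = sum_max,
                                rich_diff = rich_diff)),
            class = "beta_partition")
}

#' @export
print.beta_partition <- function(x, ...) {
  cat(sprintf("multisite beta (n = %d sites): SOR = %.4f = SIM %.4f + SNE %.4f\n",
              x$n_sites, x$beta_sor, x$beta_sim, x$beta_sne))
  invisible(x)
}

#' Resampled distribution of multisite dissimilarity within a region
#'
#' Draws `n_samples` independent without-replacement subsets of
#' `sites_per_sample` pixels from one region of the grid and computes the
#' multisite partition on each, giving an empirical distribution of
#' (beta_sim, beta_sne) comparable across regions and species groups.
#'
#' @param sg A [species_grid()].
#' @param mask A `region_mask` from [split_regions()], or `NULL` to sample
#'   from all land pixels.
#' @param side `"north"`, `"south"`, or `"all"`.
#' @param sites_per_sample Pixels per subset (default 50).
#' @param n_samples Number of subsets (default 1000).
#' @param seed Integer seed.
#' @param group Optional label recorded in the result.
#' @return Object of class `beta_sample_distribution`: a data frame
#'   `samples` (`sample`, `beta_sor`, `beta_sim`, `beta_sne`) plus the
#'   sampling metadata.
#' @export
beta_sample <- function(sg, mask = NULL, side = "all",
                        sites_per_sample = 50, n_samples = 1000, seed = 1,
                        group = NA_character_) {
  stopifnot(sites_per_sample >= 2, n_samples >= 1)
  pool <- if (is.null(mask) || identical(side, "all")) {
    seq_len(nrow(sg$occupancy))
  } else {
    which(mask$labels == side)
  }
  if (length(pool) < sites_per_sample) {
    stop_mossgrad(sprintf(
      "region '%s' has %d pixels, fewer than sites_per_sample = %d; use a smaller subset size",
      side, length(pool), sites_per_sample), "mossgrad_beta_error")
  }
  res <- with_seed(derive_seed(seed, paste("beta_sample", side, group)), {
    vapply(seq_len(n_samples), function(r) {
      sites <- pool[sample.int(length(pool), sites_per_sample)]
      p <- multisite_partition(sg$occupancy[sites, , drop = FALSE])
      c(p$beta_sor, p$beta_sim, p$beta_sne)
    }, numeric(3))
  })
  structure(list(
    samples = data.frame(sample = seq_len(n_samples),
                         beta_sor = res[1, ], beta_sim = res[2, ],
                         beta_sne = res[3, ]),
    group = group, region = side, sites_per_sample = sites_per_sample,
    n_samples = n_samples, seed = seed),
    class = "beta_sample_distribution")
}

#' Compare two resampled dissimilarity distributions
#'
#' Samples are paired by index (after truncation to the shorter run) and
#' the two-sided Monte Carlo p-value is computed from the exceedance count
#' `m = #\{r : a_r > b_r\}` with ties counted half, `p = 2 min(m/R, 1 -
#' m/R)` floored at `1/R`. Identical distributions therefore give `p = 1`
#' and complete separation the floor `1/R`. The reported direction follows
#' the sign of the median difference.
#'
#' @param a,b `beta_sample_distribution` objects.
#' @param component `"beta_sim"` or `"beta_sne"`.
#' @return Object of class `beta_comparison`: `component`, labels of the
#'   sides, `direction` (`">"`, `"<"`, `"="`), `p`, `n_resamples`.
#' @export
compare_distributions <- function(a, b, component = c("beta_sim", "beta_sne")) {
  component <- match.arg(component)
  va <- a$samples[[component]]
  vb <- b$samples[[component]]
  r <- min(length(va), length(vb))
  if (r < 1) stop_mossgrad("empty distribution", "mossgrad_beta_error")
  va <- va[seq_len(r)]; vb <- vb[seq_len(r)]
  m <- sum(va > vb) + 0.5 * sum(va == vb)
  p <- max(2 * min(m / r, 1 - m / r), 1 / r)
  p <- min(p, 1)
  med <- stats::median(va - vb)
  direction <- if (med > 0) ">" else if (med < 0) "<" else "="
  structure(list(component = component,
                 side_a = paste(a$group, a$region),
                 side_b = paste(b$group, b$region),
                 direction = direction, p = p, n_resamples = r),
            class = "beta_comparison")
}

#' @export
print.beta_comparison <- function(x, ...) {
  cat(sprintf("%s: %s %s %s (p = %.4g, R = %d)\n", x$component,
              x$side_a, x$direction, x$side_b, x$p, x$n_resamples))
  invisible(x)
}
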