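# Global and local Lee's L bivariate spatial association between two
# per-pixel maps, with Monte Carlo significance classification.

#' Spatial weights matrix on the lattice
#'
#' Contiguity weights over land pixels. `rook` links the 4 edge neighbours,
#' `queen` additionally the 4 diagonal neighbours; `identity` gives each
#' pixel itself as sole neighbour (under which Lee's L collapses to the
#' Pearson correlation — useful as a check). Neighbour links to ocean
#' pixels are removed; land pixels with no land neighbour are flagged.
#'
#' @param grid A [lattice_grid()].
#' @param scheme `"queen"` (default), `"rook"` or `"identity"`.
#' @param row_standardize Scale each pixel's weights to sum to 1 (default
#'   `TRUE`; ignored for `identity`, whose rows already sum to 1).
#' @return Object of class `weights_matrix`: sparse `W` (land x land),
#'   `scheme`, `row_standardized`, and `isolated` (indices of land pixels
#'   with no neighbour).
#' @export
build_weights <- function(grid, scheme = c("queen", "rook", "identity"),
                          row_standardize = TRUE) {
  scheme <- match.arg(scheme)
  li <- land_index(grid)
  n <- length(li)
  if (n < 1) stop_mossgrad("grid has no land pixels", "mossgrad_grid_error")
  if (scheme == "identity") {
    w <- Matrix::Diagonal(n)
    return(structure(list(W = w, scheme = scheme, row_standardized = TRUE,
                          isolated = integer(0)),
                     class = "weights_matrix"))
  }
  offsets <- if (scheme == "rook") {
    cbind(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  } else {
    cbind(dr = rep(-1:1, each = 3), dc = rep(-1:1, 3))[-5, ]
  }
  pos_of <- match(seq_len(grid$n_rows * grid$n_cols), li) # full -> land
  row <- (li - 1L) %/% grid$n_cols + 1L
  col <- (li - 1L) %% grid$n_cols + 1L
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(offsets))) {
    r2 <- row + offsets[k, "dr"]
    c2 <- col + offsets[k, "dc"]
    ok <- r2 >= 1 & r2 <= grid$n_rows & c2 >= 1 & c2 <= grid$n_cols
    nb <- pos_of[(r2[ok] - 1L) * grid$n_cols + c2[ok]]
    keep <- !is.na(nb)
    from <- c(from, which(ok)[keep])
    to <- c(to, nb[keep])
  }
  w <- Matrix::sparseMatrix(i = from, j = to, x = 1, dims = c(n, n))
  isolated <- which(Matrix::rowSums(w) == 0)
  if (row_standardize) {
    rs <- Matrix::rowSums(w)
    rs[rs == 0] <- 1
    w <- Matrix::Diagonal(x = 1 / rs) %*% w
  }
  structure(list(W = w, scheme = scheme, row_standardized = row_standardize,
                 isolated = isolated),
            class = "weights_matrix")
}

as_map_values <- function(x) {
  if (inherits(x, "richness_map")) x$values else as.numeric(x)
}

lee_prepare <- function(x, y, weights) {
  x <- as_map_values(x); y <- as_map_values(y)
  w <- weights$W
  n <- length(x)
  stopifnot(length(y) == n, nrow(w) == n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_mossgrad("Lee's L undefined: a map has zero variance",
                  "mossgrad_stat_error")
  }
  list(xc = x - mean(x), yc = y - mean(y), w = w, n = n,
       denom = sqrt(sum((x - mean(x))^2)) * sqrt(sum((y - mean(y))^2)),
       wsum2 = sum(Matrix::rowSums(w)^2))
}

#' Global Lee's L
#'
#' The bivariate spatial association statistic
#' \deqn{L = \frac{n}{\sum_i (\sum_j w_{ij})^2}
#'   \frac{\sum_i (\sum_j w_{ij}(x_j-\bar x))(\sum_j w_{ij}(y_j-\bar y))}
#'        {\sqrt{\sum_i (x_i-\bar x)^2}\sqrt{\sum_i (y_i-\bar y)^2}}}
#' which blends the Pearson correlation of `x` and `y` with the spatial
#' smoothing induced by `W`; with identity weights it equals Pearson's r
#' exactly.
#'
#' @param x,y [richness_map()] objects or numeric vectors over land pixels.
#' @param weights A `weights_matrix` from [build_weights()].
#' @return Numeric scalar `L`.
#' @export
lee_global <- function(x, y, weights) {
  p <- lee_prepare(x, y, weights)
  wx <- as.numeric(p$w %*% p$xc)
  wy <- as.numeric(p$w %*% p$yc)
  (p$n / p$wsum2) * sum(wx * wy) / p$denom
}

#' Local Lee's L
#'
#' Per-pixel decomposition
#' \deqn{L_i = n \frac{(\sum_j w_{ij}(x_j-\bar x))(\sum_j w_{ij}(y_j-\bar y))}
#'        {\sqrt{\sum(x-\bar x)^2}\sqrt{\sum(y-\bar y)^2}}}
#' so that \eqn{\sum_i L_i / \sum_i(\sum_j w_{ij})^2} recovers the global
#' statistic. The `rescaled` output divides by the maximum absolute local
#' value; significance classification (see [lee_mc()]) is rank-based and
#' thus unaffected by any monotone rescaling.
#'
#' @inheritParams lee_global
#' @return List with `local` and `rescaled` numeric vectors per land pixel.
#' @export
lee_local <- function(x, y, weights) {
  p <- lee_prepare(x, y, weights)
  wx <- as.numeric(p$w %*% p$xc)
  wy <- as.numeric(p$w %*% p$yc)
  li <- p$n * wx * wy / p$denom
  list(local = li, rescaled = li / max(abs(li)))
}

#' Monte Carlo test on local Lee's L
#'
#' The null retains the paired values `(x_i, y_i)` and jointly permutes
#' them across pixels: the aspatial correlation between the maps is
#' preserved while the spatial arrangement is destroyed. Each pixel's
#' observed local L is ranked within its permutation distribution (the
#' observed value included, rank among `n_permutations + 1`): `Positive`
#' if it lies above the 97.5th percentile, `Negative` if below the 2.5th,
#' otherwise `not-significant` — a two-tailed test at the 95% level. The
#' global L is ranked the same way for a two-sided global p.
#'
#' @inheritParams lee_global
#' @param n_permutations Number of joint permutations (default 999).
#' @param seed Integer seed.
#' @return Object of class `lee_result`: `global`, `global_p`, `local`,
#'   `rescaled`, `classification` (factor `Positive` / `Negative` /
#'   `not-significant` per land pixel), `p_upper`, `p_lower`,
#'   `n_permutations`, `seed`.
#' @export
lee_mc <- function(x, y, weights, n_permutations = 999, seed = 1) {
  stopifnot(n_permutations >= 19)
  p <- lee_prepare(x, y, weights)
  wx <- as.numeric(p$w %*% p$xc)
  wy <- as.numeric(p$w %*% p$yc)
  obs_local <- p$n * wx * wy / p$denom
  obs_global <- sum(obs_local) / p$wsum2
  perm <- with_seed(derive_seed(seed, "lee_mc"), {
    vapply(seq_len(n_permutations), function(r) sample.int(p$n),
           integer(p$n))
  })
  # centring and the variance denominator are invariant under permutation
  xp <- matrix(p$xc[perm], p$n, n_permutations)
  yp <- matrix(p$yc[perm], p$n, n_permutations)
  lp <- p$n * as.matrix(p$w %*% xp) * as.matrix(p$w %*% yp) / p$denom
  ge <- rowSums(lp >= obs_local)
  le <- rowSums(lp <= obs_local)
  p_upper <- (ge + 1) / (n_permutations + 1)
  p_lower <- (le + 1) / (n_permutations + 1)
  classification <- factor(
    ifelse(p_upper <= 0.025, "Positive",
           ifelse(p_lower <= 0.025, "Negative", "not-significant")),
    levels = c("Positive", "Negative", "not-significant"))
  gp <- colSums(lp) / p$wsum2
  g_up <- (sum(gp >= obs_global) + 1) / (n_permutations + 1)
  g_lo <- (sum(gp <= obs_global) + 1) / (n_permutations + 1)
  structure(list(global = obs_global,
                 global_p = min(1, 2 * min(g_up, g_lo)),
                 local = obs_local,
                 rescaled = obs_local / max(abs(obs_local)),
                 classification = classification,
                 p_upper = p_upper, p_lower = p_lower,
                 n_permutations = n_permutations, seed = seed),
            class = "lee_result")
}

#' @export
print.lee_result <- function(x, ...) {
  tab <- table(x$classification)
  cat(sprintf("Lee's L = %.4f (MC p = %.4g, %d permutations)\n",
              x$global, x$global_p, x$n_permutations))
  cat(sprintf("  local classification: %d Positive, %d Negative, %d n.s.\n",
              tab[["Positive"]], tab[["Negative"]], tab[["not-significant"]]))
  invisible(x)
}
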