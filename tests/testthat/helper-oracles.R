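# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package implementations they check.

# Multisite Sorensen partition by explicit pairwise set operations.
oracle_multisite <- function(m) {
  m <- m[, colSums(m) > 0, drop = FALSE]
  n <- nrow(m)
  sum_min <- 0; sum_max <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      si <- which(m[i, ] > 0); sj <- which(m[j, ] > 0)
      b_ij <- length(setdiff(si, sj))
      b_ji <- length(setdiff(sj, si))
      sum_min <- sum_min + min(b_ij, b_ji)
      sum_max <- sum_max + max(b_ij, b_ji)
    }
  }
  rich_diff <- sum(rowSums(m > 0)) - ncol(m)
  sim <- if (sum_min == 0) 0 else sum_min / (rich_diff + sum_min)
  sor <- if (sum_min + sum_max == 0) 0 else {
    (sum_min + sum_max) / (2 * rich_diff + sum_min + sum_max)
  }
  c(sim = sim, sne = sor - sim, sor = sor)
}

# Pairwise Sorensen / Simpson dissimilarity from first principles.
oracle_pairwise_sorensen <- function(s1, s2) {
  a <- length(intersect(s1, s2))
  b <- length(setdiff(s1, s2)); c_ <- length(setdiff(s2, s1))
  (b + c_) / (2 * a + b + c_)
}
oracle_pairwise_simpson <- function(s1, s2) {
  a <- length(intersect(s1, s2))
  b <- length(setdiff(s1, s2)); c_ <- length(setdiff(s2, s1))
  min(b, c_) / (a + min(b, c_))
}

# Straight-line transcription of Lee's L: double loops, no linear algebra.
oracle_lee <- function(x, y, w) {
  n <- length(x)
  xc <- x - mean(x); yc <- y - mean(y)
  num <- 0; wsum2 <- 0
  local <- numeric(n)
  for (i in seq_len(n)) {
    wx <- 0; wy <- 0; wsum <- 0
    for (j in seq_len(n)) {
      wx <- wx + w[i, j] * xc[j]
      wy <- wy + w[i, j] * yc[j]
      wsum <- wsum + w[i, j]
    }
    local[i] <- n * wx * wy /
      (sqrt(sum(xc^2)) * sqrt(sum(yc^2)))
    num <- num + wx * wy
    wsum2 <- wsum2 + wsum^2
  }
  list(global = (n / wsum2) * num / (sqrt(sum(xc^2)) * sqrt(sum(yc^2))),
       local = local)
}

# AUC by brute-force pair counting (ties count half).
oracle_auc <- function(pred, labels) {
  pos <- pred[labels == 1]; neg <- pred[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Exhaustive max-TSS threshold scan, independent loop formulation.
oracle_max_tss <- function(pred, labels) {
  best <- -Inf; best_thr <- NA
  for (t in sort(unique(pred))) {
    sens <- mean(pred[labels == 1] >= t)
    spec <- mean(pred[labels == 0] < t)
    if (sens + spec - 1 > best) {
      best <- sens + spec - 1
      best_thr <- t
    }
  }
  list(tss = best, threshold = best_thr)
}

# Queen/rook adjacency by exhaustive pairwise offset check over land pixels.
oracle_neighbours <- function(grid, scheme) {
  li <- land_index(grid)
  rc <- cbind(row = (li - 1) %/% grid$n_cols + 1,
              col = (li - 1) %% grid$n_cols + 1)
  n <- length(li)
  adj <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    dr <- abs(rc[i, 1] - rc[j, 1]); dc <- abs(rc[i, 2] - rc[j, 2])
    touch <- if (scheme == "rook") dr + dc == 1 else {
      max(dr, dc) == 1
    }
    if (touch) adj[i, j] <- 1
  }
  adj
}

# Random incidence matrix with no all-empty species column.
random_incidence <- function(n_sites, n_species, p = 0.4) {
  m <- matrix(rbinom(n_sites * n_species, 1, p), n_sites, n_species)
  m[, colSums(m) > 0, drop = FALSE]
}

# Tiny all-land grid helper.
toy_grid <- function(n_rows = 4, n_cols = 4, lat_range = c(40, 52)) {
  lattice_grid(n_rows, n_cols, pixel_size = 100, lat_range = lat_range)
}
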