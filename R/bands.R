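# Latitudinal band aggregation and species-area normalization.

band_ids <- function(grid, band_width) {
  rows_per_band <- band_width / grid$pixel_size
  if (band_width <= 0 || rows_per_band != round(rows_per_band)) {
    stop_mossgrad("band_width must be a positive multiple of pixel_size",
                  "mossgrad_band_error")
  }
  row <- (seq_len(grid$n_rows * grid$n_cols) - 1L) %/% grid$n_cols + 1L
  ((row - 1L) %/% as.integer(rows_per_band)) + 1L # band 1 = northernmost
}

#' Aggregate a richness map into latitudinal bands
#'
#' Bands are equal-width strips of projected northing (default 100 km,
#' i.e. one pixel row), numbered from the north. Both the band total
#' (summed over land pixels, the area-dependent quantity the species-area
#' normalization applies to) and the per-pixel mean are reported. Bands
#' with no land pixels are flagged empty.
#'
#' @param r A [richness_map()].
#' @param band_width Band width in the grid's projected units (km).
#' @return Object of class `band_profile`: data frame `bands` with
#'   `band`, `lat_top`, `lat_bottom`, `n_land`, `richness_sum`,
#'   `richness_mean`, `empty`; plus `band_width` and the grid.
#' @export
band_aggregate <- function(r, band_width = 100) {
  grid <- r$grid
  ids <- band_ids(grid, band_width)
  li <- land_index(grid)
  n_bands <- max(ids)
  lat_all <- grid$centroid_lat
  agg <- lapply(seq_len(n_bands), function(b) {
    in_band <- which(ids == b)
    land <- intersect(in_band, li)
    vals <- r$values[match(land, li)]
    data.frame(band = b,
               lat_top = max(lat_all[in_band]),
               lat_bottom = min(lat_all[in_band]),
               n_land = length(land),
               richness_sum = if (length(land)) sum(vals) else NA_real_,
               richness_mean = if (length(land)) mean(vals) else NA_real_,
               empty = length(land) == 0)
  })
  structure(list(bands = do.call(rbind, agg), band_width = band_width,
                 grid = grid),
            class = "band_profile")
}

#' Species-area normalization of band richness
#'
#' Bands differ in land area; under the Arrhenius species-area relationship
#' `S = c A^z`, richness observed on area `A` scales to the reference area
#' `A_ref` (the largest band's land area) as
#' `S_norm = S (A_ref / A)^z`. With equal-area bands the profile is
#' unchanged for any `z`.
#'
#' @param p A `band_profile` from [band_aggregate()].
#' @param z Species-area exponent (>= 0, default 0.25, the canonical
#'   island-biogeography value).
#' @return The profile with a `richness_normalized` column (NA for empty
#'   bands).
#' @export
normalize_species_area <- function(p, z = 0.25) {
  if (z < 0) stop_mossgrad("z must be non-negative", "mossgrad_band_error")
  b <- p$bands
  if (all(b$empty)) {
    stop_mossgrad("no non-empty band to normalize", "mossgrad_band_error")
  }
  area <- b$n_land * p$grid$pixel_size^2
  a_ref <- max(area[!b$empty])
  b$richness_normalized <- ifelse(b$empty, NA_real_,
                                  b$richness_sum * (a_ref / area)^z)
  p$bands <- b
  p
}

#' Per-band environmental summaries
#'
#' Mean and standard deviation of every layer of the stack within each
#' latitudinal band (land pixels only).
#'
#' @param env An [env_stack()].
#' @param band_width Band width in projected units (km).
#' @return Data frame: `band`, `layer`, `mean`, `sd`, `n_land`.
#' @export
band_environment <- function(env, band_width = 100) {
  grid <- env$grid
  ids_land <- band_ids(grid, band_width)[land_index(grid)]
  out <- list()
  for (nm in names(env$layers)) {
    v <- env$layers[[nm]]
    for (b in sort(unique(ids_land))) {
      vals <- v[ids_land == b]
      out[[length(out) + 1]] <- data.frame(
        band = b, layer = nm, mean = mean(vals),
        sd = if (length(vals) > 1) stats::sd(vals) else 0,
        n_land = length(vals))
    }
  }
  do.call(rbind, out)
}
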