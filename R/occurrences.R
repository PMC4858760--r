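#' Read occurrence records from CSV
#'
#' Expects a UTF-8 CSV with a header naming at least `species`, `x`, `y`
#' (an optional `group` column assigns taxon-group membership; any merging
#' of groups is thereby a configuration choice of the input, not of the
#' code). Coordinates must be in the projected equal-area system of the
#' analysis grid.
#'
#' @param path File path.
#' @return A data frame of class `occurrence_table` with columns `species`,
#'   `x`, `y` and, when present in the file, `group`.
#' @export
read_occurrences <- function(path) {
  if (!file.exists(path)) {
    stop_mossgrad(paste("file not found:", path), "mossgrad_io_error")
  }
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, strip.white = TRUE)
  need <- c("species", "x", "y")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop_mossgrad(paste("occurrence file missing column(s):",
                        paste(missing_cols, collapse = ", ")),
                  "mossgrad_format_error")
  }
  if (nrow(df) == 0) {
    out <- data.frame(species = character(), x = numeric(), y = numeric())
    class(out) <- c("occurrence_table", "data.frame")
    return(out)
  }
  x <- suppressWarnings(as.numeric(df$x))
  y <- suppressWarnings(as.numeric(df$y))
  bad <- which(!is.finite(x) | !is.finite(y) | !nzchar(df$species))
  if (length(bad) > 0) {
    # +1 for the header: report file line numbers, not data-row indices
    stop_mossgrad(
      paste0("malformed occurrence row(s) at file line(s): ",
             paste(bad + 1L, collapse = ", "),
             " (non-numeric coordinates or empty species)"),
      "mossgrad_format_error")
  }
  out <- data.frame(species = df$species, x = x, y = y)
  if ("group" %in% names(df)) out$group <- df$group
  class(out) <- c("occurrence_table", "data.frame")
  out
}

#' Write occurrence records to CSV
#'
#' @param occ An `occurrence_table` (or compatible data frame).
#' @param path Output path.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(as.data.frame(occ), path, row.names = FALSE)
  invisible(path)
}

#' Rasterize occurrence records onto the lattice
#'
#' A pixel-species cell is present iff at least one record falls inside the
#' pixel. Pixels are half-open intervals `[x0, x0 + size) x [y0, y0 + size)`
#' so boundary points belong to the pixel on their lower-left; the
#' assignment is deterministic and record-order invariant. Records falling
#' outside the grid or on non-land pixels are counted and reported in the
#' `dropped` attribute (and a message), never silently discarded.
#'
#' @param occ An `occurrence_table`.
#' @param grid A [lattice_grid()].
#' @return A [species_grid()] with attribute `dropped` =
#'   `c(out_of_grid = , ocean = )`.
#' @export
rasterize <- function(occ, grid) {
  species_ids <- sort(unique(occ$species))
  n_land <- sum(grid$land_mask)
  occmat <- matrix(FALSE, n_land, max(length(species_ids), 0))
  dropped <- c(out_of_grid = 0L, ocean = 0L)
  if (nrow(occ) > 0) {
    col <- floor((occ$x - grid$origin[1]) / grid$pixel_size) + 1L
    row_from_bottom <- floor((occ$y - grid$origin[2]) / grid$pixel_size) + 1L
    row <- grid$n_rows - row_from_bottom + 1L
    inside <- col >= 1L & col <= grid$n_cols &
      row >= 1L & row <= grid$n_rows
    dropped["out_of_grid"] <- sum(!inside)
    pix <- (row[inside] - 1L) * grid$n_cols + col[inside]
    on_land <- grid$land_mask[pix]
    dropped["ocean"] <- sum(!on_land)
    pix <- pix[on_land]
    sp <- match(occ$species[inside][on_land], species_ids)
    land_pos <- match(pix, land_index(grid))
    occmat[cbind(land_pos, sp)] <- TRUE
  }
  if (sum(dropped) > 0) {
    message(sprintf(
      "rasterize: dropped %d record(s) outside the grid, %d on ocean pixels",
      dropped["out_of_grid"], dropped["ocean"]))
  }
  sg <- species_grid(grid, species_ids, occmat)
  attr(sg, "dropped") <- dropped
  sg
}

#' Remove rarely recorded species
#'
#' Retains exactly the species present in at least `min_presences` pixels.
#' Rare species carry too little information for split-sample distribution
#' modelling; the conventional cut, applied here by default, is 15 pixels.
#'
#' @param sg A [species_grid()].
#' @param min_presences Minimum pixel count to retain a species (>= 1).
#' @return A filtered [species_grid()]; removed species are messaged and
#'   kept in the `removed` attribute.
#' @export
filter_min_presence <- function(sg, min_presences = 15) {
  stopifnot(min_presences >= 1)
  counts <- presence_counts(sg)
  keep <- counts >= min_presences
  removed <- sg$species_ids[!keep]
  if (length(removed) > 0) {
    message(sprintf("filter_min_presence: removed %d of %d species (< %d presences)",
                    length(removed), length(keep), min_presences))
  }
  out <- species_grid(sg$grid, sg$species_ids[keep],
                      sg$occupancy[, keep, drop = FALSE])
  attr(out, "removed") <- removed
  out
}

#' Split land pixels into northern and southern regions
#'
#' @param grid A [lattice_grid()].
#' @param split_latitude Boundary latitude in degrees (default 46): pixels
#'   with centroid latitude strictly above it are `north`.
#' @return An object of class `region_mask`: factor `labels` over land
#'   pixels (levels `north`, `south`) and the `split_latitude`.
#' @export
split_regions <- function(grid, split_latitude = 46.0) {
  lat <- grid$centroid_lat[land_index(grid)]
  labels <- factor(ifelse(lat > split_latitude, "north", "south"),
                   levels = c("north", "south"))
  tab <- table(labels)
  if (any(tab == 0)) {
    warning(sprintf("split_regions: all land pixels are %s of %.2f deg; regional comparisons will be impossible",
                    names(tab)[tab > 0], split_latitude))
  }
  structure(list(labels = labels, split_latitude = split_latitude),
            class = "region_mask")
}

#' Correlation between two richness maps
#'
#' Computed over jointly non-missing land pixels of a shared grid; ocean
#' pixels never enter (zero-filling them would fabricate absences).
#'
#' @param a,b [richness_map()] objects on the same grid.
#' @param method `"pearson"` or `"spearman"`.
#' @return List with `estimate`, `n` (pixels used) and `method`.
#' @export
map_correlation <- function(a, b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!same_grid(a$grid, b$grid)) {
    stop_mossgrad("maps are not on the same grid", "mossgrad_grid_error")
  }
  ok <- is.finite(a$values) & is.finite(b$values)
  if (sum(ok) < 3) {
    stop_mossgrad("fewer than 3 jointly valid pixels", "mossgrad_stat_error")
  }
  x <- a$values[ok]; y <- b$values[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_mossgrad("correlation undefined: a map has zero variance",
                  "mossgrad_stat_error")
  }
  list(estimate = unname(stats::cor(x, y, method = method)),
       n = sum(ok), method = method)
}
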