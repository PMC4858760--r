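#' Equal-area lattice grid
#'
#' Constructs the spatial frame used by every stage of the pipeline: a
#' regular lattice of square pixels in a projected equal-area coordinate
#' system, with a land mask and a centroid latitude per pixel. Pixels are
#' stored row-major from the north-west corner (row 1 = northernmost row),
#' and every per-pixel vector in the package shares this order.
#'
#' Latitude is carried as an attribute of northing: the centroid latitude of
#' a row is obtained by linear interpolation of `lat_range` across the
#' grid's vertical extent, so `lat_range[2]` is the latitude of the grid's
#' top edge. This is adequate for equal-area grids where bands of constant
#' northing are the analysis unit; the package performs no reprojection.
#'
#' @param n_rows,n_cols Lattice dimensions (>= 1).
#' @param pixel_size Pixel edge length in projected units (km; default 100).
#' @param origin Numeric length-2, `(x, y)` of the lower-left corner of the
#'   lower-left pixel in projected units.
#' @param lat_range Numeric length-2, latitudes (degrees) of the grid's
#'   bottom and top edges.
#' @param land_mask Logical vector of length `n_rows * n_cols` in row-major
#'   order from the north-west corner; `TRUE` = land. Default: all land.
#' @return An object of class `lattice_grid`.
#' @export
lattice_grid <- function(n_rows, n_cols, pixel_size = 100, origin = c(0, 0),
                         lat_range = c(35, 71), land_mask = NULL) {
  stopifnot(n_rows >= 1, n_cols >= 1, pixel_size > 0,
            length(origin) == 2, is.finite(origin),
            length(lat_range) == 2, lat_range[2] > lat_range[1])
  n_pix <- n_rows * n_cols
  if (is.null(land_mask)) land_mask <- rep(TRUE, n_pix)
  if (length(land_mask) != n_pix) {
    stop_mossgrad("land_mask must have n_rows * n_cols entries",
                  "mossgrad_grid_error")
  }
  row_of <- rep(seq_len(n_rows), each = n_cols)
  northing <- origin[2] + (n_rows - row_of + 0.5) * pixel_size
  centroid_lat <- lat_range[1] +
    (northing - origin[2]) / (n_rows * pixel_size) * diff(lat_range)
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         pixel_size = pixel_size, origin = as.numeric(origin),
         lat_range = as.numeric(lat_range),
         land_mask = as.logical(land_mask),
         centroid_lat = centroid_lat),
    class = "lattice_grid")
}

#' @export
print.lattice_grid <- function(x, ...) {
  cat(sprintf("lattice_grid: %d x %d pixels of %g km, %d land (%.0f%%)\n",
              x$n_rows, x$n_cols, x$pixel_size, sum(x$land_mask),
              100 * mean(x$land_mask)))
  cat(sprintf("  latitude span %.2f-%.2f deg\n",
              x$lat_range[1], x$lat_range[2]))
  invisible(x)
}

#' Indices of land pixels
#'
#' @param grid A [lattice_grid()].
#' @return Integer vector of row-major pixel indices that are land, in
#'   row-major (north-west first) order. All per-land-pixel vectors in the
#'   package (occupancy rows, richness values, region labels) follow it.
#' @export
land_index <- function(grid) which(grid$land_mask)

#' Pixel centroid coordinates
#'
#' @param grid A [lattice_grid()].
#' @return Data frame with one row per pixel (row-major from the NW corner):
#'   `row`, `col`, `x`, `y` (projected centroids), `lat`, `land`.
#' @export
pixel_centroids <- function(grid) {
  row <- rep(seq_len(grid$n_rows), each = grid$n_cols)
  col <- rep(seq_len(grid$n_cols), times = grid$n_rows)
  data.frame(
    row = row, col = col,
    x = grid$origin[1] + (col - 0.5) * grid$pixel_size,
    y = grid$origin[2] + (grid$n_rows - row + 0.5) * grid$pixel_size,
    lat = grid$centroid_lat,
    land = grid$land_mask)
}

same_grid <- function(a, b) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    isTRUE(all.equal(a$pixel_size, b$pixel_size)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

#' Site-by-species presence/absence grid
#'
#' @param grid A [lattice_grid()].
#' @param species_ids Character vector of species labels.
#' @param occupancy Logical matrix, land pixels (rows, in [land_index()]
#'   order) by species (columns).
#' @return An object of class `species_grid`.
#' @export
species_grid <- function(grid, species_ids, occupancy) {
  occupancy <- as.matrix(occupancy)
  storage.mode(occupancy) <- "logical"
  if (nrow(occupancy) != sum(grid$land_mask) ||
      ncol(occupancy) != length(species_ids)) {
    stop_mossgrad("occupancy must be land pixels x species",
                  "mossgrad_grid_error")
  }
  colnames(occupancy) <- species_ids
  structure(list(grid = grid, species_ids = as.character(species_ids),
                 occupancy = occupancy),
            class = "species_grid")
}

#' @export
print.species_grid <- function(x, ...) {
  cat(sprintf("species_grid: %d land pixels x %d species, %d presences\n",
              nrow(x$occupancy), ncol(x$occupancy), sum(x$occupancy)))
  invisible(x)
}

#' Per-species presence counts
#'
#' @param sg A [species_grid()].
#' @return Named integer vector of pixel counts per species.
#' @export
presence_counts <- function(sg) colSums(sg$occupancy)

#' Per-pixel richness map
#'
#' @param grid A [lattice_grid()].
#' @param values Numeric vector over land pixels (in [land_index()] order);
#'   integer counts for stacked binary maps, real for averaged maps.
#' @return An object of class `richness_map`.
#' @export
richness_map <- function(grid, values) {
  if (length(values) != sum(grid$land_mask)) {
    stop_mossgrad("values must have one entry per land pixel",
                  "mossgrad_grid_error")
  }
  if (any(values < 0, na.rm = TRUE)) {
    stop_mossgrad("richness must be non-negative", "mossgrad_grid_error")
  }
  structure(list(grid = grid, values = as.numeric(values)),
            class = "richness_map")
}

#' Observed richness from a species grid
#'
#' Row sums of the occupancy matrix: the number of species present per
#' land pixel.
#'
#' @param sg A [species_grid()].
#' @return A [richness_map()].
#' @export
richness_from_grid <- function(sg) {
  richness_map(sg$grid, rowSums(sg$occupancy))
}

# ---- ESRI ASCII grid I/O ----------------------------------------------
# The six-line header + row-major (north first) numeric matrix format.
# NODATA cells are honoured as the mask.

#' Write a per-pixel map as an ESRI ASCII grid
#'
#' Ocean (non-land) pixels and `NA` values are written as the NODATA value.
#'
#' @param map A [richness_map()] or a numeric vector over land pixels.
#' @param path Output file path.
#' @param grid Required when `map` is a bare vector.
#' @param nodata NODATA sentinel (default -9999).
#' @export
write_asc <- function(map, path, grid = NULL, nodata = -9999) {
  if (inherits(map, "richness_map")) {
    grid <- map$grid
    values <- map$values
  } else {
    if (is.null(grid)) stop_mossgrad("grid required", "mossgrad_io_error")
    values <- as.numeric(map)
  }
  full <- rep(NA_real_, grid$n_rows * grid$n_cols)
  full[land_index(grid)] <- values
  full[is.na(full)] <- nodata
  hdr <- c(
    sprintf("NCOLS %d", grid$n_cols),
    sprintf("NROWS %d", grid$n_rows),
    sprintf("XLLCORNER %.10g", grid$origin[1]),
    sprintf("YLLCORNER %.10g", grid$origin[2]),
    sprintf("CELLSIZE %.10g", grid$pixel_size),
    sprintf("NODATA_VALUE %.10g", nodata))
  m <- matrix(full, nrow = grid$n_rows, ncol = grid$n_cols, byrow = TRUE)
  body <- apply(m, 1L, function(r) paste(format(r, trim = TRUE,
                                                scientific = FALSE),
                                         collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' NODATA cells become the grid's ocean mask. Latitude is not stored in the
#' format, so `lat_range` must be supplied if downstream latitudinal
#' operations are intended.
#'
#' @param path File path.
#' @param lat_range Latitudes of the grid's bottom/top edges (degrees).
#' @return A [richness_map()] whose grid carries the mask.
#' @export
read_asc <- function(path, lat_range = c(35, 71)) {
  if (!file.exists(path)) {
    stop_mossgrad(paste("file not found:", path), "mossgrad_io_error")
  }
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop_mossgrad("malformed ESRI ASCII header", "mossgrad_io_error")
  }
  nodata <- hdr[["nodata_value"]] %||% -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop_mossgrad("ESRI ASCII body does not match header dimensions",
                  "mossgrad_io_error")
  }
  full <- as.numeric(vals) # already row-major from the top row
  full[full == nodata] <- NA_real_
  grid <- lattice_grid(hdr$nrows, hdr$ncols, hdr$cellsize,
                       origin = c(hdr$xllcorner, hdr$yllcorner),
                       lat_range = lat_range,
                       land_mask = !is.na(full))
  richness_map(grid, full[!is.na(full)])
}

#' Serialize a species grid as wide CSV
#'
#' One row per land pixel (`pixel_id` = row-major full-grid index), one 0/1
#' column per species. Round-trips with [read_species_grid()].
#'
#' @param sg A [species_grid()].
#' @param path Output path.
#' @export
write_species_grid <- function(sg, path) {
  df <- data.frame(pixel_id = land_index(sg$grid),
                   sg$occupancy * 1L, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_species_grid
#' @param grid The [lattice_grid()] the file was written against.
#' @export
read_species_grid <- function(path, grid) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!identical(df$pixel_id, land_index(grid))) {
    stop_mossgrad("pixel_id column does not match the grid's land pixels",
                  "mossgrad_io_error")
  }
  occ <- as.matrix(df[, setdiff(names(df), "pixel_id"), drop = FALSE]) > 0
  species_grid(grid, colnames(occ), occ)
}
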