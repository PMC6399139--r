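#' Lattice world container
#'
#' A `cell_grid` holds the hectometric raster world the analysis runs on:
#' residential and road flags, per-cell human counts, veterinary-practice
#' markers and the unit-membership map. Matrices are `rows x cols`; row 1 is
#' the bottom of the map so that cell-centre coordinates have their origin in
#' the lower-left corner.
#'
#' @param rows,cols grid dimensions.
#' @param cell_size_m edge length of a cell in metres (100 m for an
#'   hectometric grid).
#' @param residential,road,vets logical matrices flagging residential land,
#'   road cells and veterinary-practice cells.
#' @param humans numeric matrix of per-cell human counts (positive only on
#'   residential cells).
#' @param unit integer matrix mapping every cell to its enumeration unit.
#' @return an object of class `cell_grid`.
#' @export
cell_grid <- function(rows, cols, cell_size_m = 100,
                      residential = NULL, road = NULL, humans = NULL,
                      vets = NULL, unit = NULL) {
  stopifnot(rows >= 1, cols >= 1, cell_size_m > 0)
  blank <- function(x, fill) if (is.null(x)) matrix(fill, rows, cols) else x
  g <- structure(list(
    rows = as.integer(rows), cols = as.integer(cols),
    cell_size_m = cell_size_m,
    cell_km = cell_size_m / 1000,
    residential = blank(residential, FALSE),
    road        = blank(road, FALSE),
    humans      = blank(humans, 0),
    vets        = blank(vets, FALSE),
    unit        = blank(unit, NA_integer_)
  ), class = "cell_grid")
  validate_cell_grid(g)
  g
}

validate_cell_grid <- function(g) {
  dims <- vapply(g[c("residential", "road", "humans", "vets", "unit")],
                 function(m) identical(dim(m), c(g$rows, g$cols)), logical(1))
  if (!all(dims)) stop("cell_grid layers have mismatched dimensions")
  if (any(g$humans > 0 & !g$residential))
    stop("human counts found on non-residential cells")
  if (any(g$vets & !g$road))
    stop("veterinary practices must lie on road cells")
  invisible(g)
}

#' @export
print.cell_grid <- function(x, ...) {
  cat(sprintf(
    "<cell_grid> %d x %d cells (%g m), %d residential, %d road, %d vets, %s humans\n",
    x$rows, x$cols, x$cell_size_m, sum(x$residential), sum(x$road),
    sum(x$vets), format(sum(x$humans), big.mark = ",")))
  invisible(x)
}

# Cell centre coordinates in km, origin lower-left. `cell` is a linear index
# in R's column-major order (cell = (col-1)*rows + row).
cell_xy <- function(grid, cell) {
  row <- (cell - 1L) %% grid$rows + 1L
  col <- (cell - 1L) %/% grid$rows + 1L
  cbind(x = (col - 0.5) * grid$cell_km, y = (row - 0.5) * grid$cell_km)
}

cell_index <- function(grid, row, col) (col - 1L) * grid$rows + row

cells_of_unit <- function(grid, unit_id) which(grid$unit == unit_id)

# Mean of cell centres, in km.
cells_centroid <- function(grid, cells) {
  xy <- cell_xy(grid, cells)
  c(x = mean(xy[, "x"]), y = mean(xy[, "y"]))
}

cells_area_km2 <- function(grid, n_cells) n_cells * grid$cell_km^2

#' Write a grid layer as an ASCII raster
#'
#' Writes one layer of a [cell_grid] (or any matrix on the same lattice) in
#' ESRI ASCII grid format: row-major from the top row, origin at the
#' lower-left corner, cell-centre registration implied by `xllcorner = 0`.
#'
#' @param m matrix to write (rows x cols, row 1 = bottom).
#' @param path output file.
#' @param cell_size_m cell edge in metres.
#' @param na_value value used for missing cells.
#' @export
write_ascii_grid <- function(m, path, cell_size_m = 100, na_value = -9999) {
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    "xllcorner 0", "yllcorner 0",
    sprintf("cellsize %g", cell_size_m),
    sprintf("NODATA_value %g", na_value))
  body <- apply(m[rev(seq_len(nrow(m))), , drop = FALSE], 1, function(r) {
    r[is.na(r)] <- na_value
    paste(format(r, trim = TRUE, scientific = FALSE), collapse = " ")
  })
  writeLines(c(hdr, body), path)
  invisible(path)
}
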