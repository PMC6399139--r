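#' Allocate grid cells to enumeration units
#'
#' Every cell is assigned to the unit containing its centre. On the lattice
#' world the membership is carried by the grid itself; this operation
#' validates it (no orphan cells, ids within range) and returns the explicit
#' cell-to-unit mapping. When a cell centre would lie on a shared boundary,
#' the generator's nearest-centre rule already breaks the tie toward the
#' lowest unit id, and that convention is preserved here.
#'
#' @param grid a [cell_grid].
#' @param units unit table (used to validate the id set).
#' @return integer vector of length `rows * cols` mapping each cell (linear,
#'   column-major index) to a unit id.
#' @export
allocate_cells <- function(grid, units) {
  map <- as.vector(grid$unit)
  orphans <- which(is.na(map))
  if (length(orphans))
    stop("cells with centroid in no unit: ",
         paste(utils::head(orphans, 10), collapse = ", "),
         if (length(orphans) > 10) " ..." else "")
  bad <- setdiff(unique(map), units$unit_id)
  if (length(bad))
    stop("cells mapped to unknown unit ids: ", paste(bad, collapse = ", "))
  map
}

#' Dasymetrically refine enumeration units to their residential land
#'
#' The residential cells allocated to each unit are dissolved into its
#' refined counterpart; area, centroid and residential fraction are
#' recomputed from those cells only. Units without any residential cell are
#' returned flagged `empty` (and are excluded from refined-support analyses
#' downstream, with a warning). A refined unit may consist of several
#' disjoint residential patches; it is still one logical unit.
#'
#' @param units unit table from [generate_region()].
#' @param grid a [cell_grid].
#' @return a data frame with one row per parent unit: `unit_id`,
#'   `n_res_cells`, `area_km2`, `centroid_x`, `centroid_y`,
#'   `residential_fraction`, `empty`.
#' @export
refine_units <- function(units, grid) {
  map <- allocate_cells(grid, units)
  res_cells <- which(as.vector(grid$residential))
  by_unit <- split(res_cells, factor(map[res_cells], levels = units$unit_id))
  n_res <- lengths(by_unit)
  cent <- t(vapply(by_unit, function(cells) {
    if (length(cells) == 0) c(x = NA_real_, y = NA_real_)
    else cells_centroid(grid, cells)
  }, numeric(2)))
  out <- data.frame(
    unit_id = units$unit_id,
    n_res_cells = as.integer(n_res),
    area_km2 = cells_area_km2(grid, as.integer(n_res)),
    centroid_x = cent[, 1],
    centroid_y = cent[, 2],
    residential_fraction = as.integer(n_res) / units$n_cells,
    empty = n_res == 0,
    row.names = NULL)
  if (any(out$empty))
    warning(sum(out$empty), " unit(s) have no residential cells; ",
            "their refined geometry is empty")
  out
}

#' Check the pycnophylactic (mass-preserving) property
#'
#' Binary dasymetric refinement reallocates counts in space but must never
#' rescale them: every per-unit total has to be identical before and after
#' refinement.
#'
#' @param original_counts,refined_counts numeric vectors named by unit id.
#' @return a list with `ok` (logical) and `deltas`, a data frame of the
#'   units whose counts changed.
#' @export
check_pycnophylactic <- function(original_counts, refined_counts) {
  if (is.null(names(original_counts)) || is.null(names(refined_counts)))
    stop("counts must be named by unit id")
  if (!setequal(names(original_counts), names(refined_counts)))
    stop("unit id sets differ between original and refined counts")
  refined_counts <- refined_counts[names(original_counts)]
  delta <- refined_counts - original_counts
  bad <- which(delta != 0)
  list(ok = length(bad) == 0,
       deltas = data.frame(unit_id = names(original_counts)[bad],
                           original = unname(original_counts[bad]),
                           refined = unname(refined_counts[bad]),
                           delta = unname(delta[bad]),
                           row.names = NULL))
}

#' Centroid displacement due to dasymetric refinement
#'
#' Euclidean distance (km) and compass bearing (degrees clockwise from
#' north) from each parent-unit centroid to its refined centroid — the data
#' behind displacement-arrow maps.
#'
#' @param units parent unit table.
#' @param refined output of [refine_units()].
#' @return data frame `unit_id`, `magnitude_km`, `bearing_deg`; empty
#'   refined units raise an error.
#' @export
centroid_displacement <- function(units, refined) {
  stopifnot(identical(units$unit_id, refined$unit_id))
  if (any(refined$empty))
    stop("cannot compute displacement for empty refined units: ",
         paste(refined$unit_id[refined$empty], collapse = ", "))
  dx <- refined$centroid_x - units$centroid_x
  dy <- refined$centroid_y - units$centroid_y
  mag <- sqrt(dx^2 + dy^2)
  bearing <- (90 - atan2(dy, dx) * 180 / pi) %% 360
  bearing[mag == 0] <- 0
  data.frame(unit_id = units$unit_id, magnitude_km = mag,
             bearing_deg = bearing, row.names = NULL)
}
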