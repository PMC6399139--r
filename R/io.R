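#' Write enumeration units as GeoJSON
#'
#' Emits each unit as a MultiPolygon of its cells' squares (cell-level
#' geometry, planar km coordinates, origin lower-left). Attribute fields
#' carry the unit id and any extra columns supplied.
#'
#' @param grid a [cell_grid].
#' @param cells_by_unit named list mapping unit id to integer cell indices.
#' @param attrs data frame of per-unit attributes (must contain `unit_id`).
#' @param path output file.
#' @export
write_units_geojson <- function(grid, cells_by_unit, attrs, path) {
  half <- grid$cell_km / 2
  feat <- lapply(names(cells_by_unit), function(uid) {
    cells <- cells_by_unit[[uid]]
    xy <- cell_xy(grid, cells)
    polys <- lapply(seq_len(nrow(xy)), function(i) {
      x <- xy[i, 1]; y <- xy[i, 2]
      list(list(
        c(x - half, y - half), c(x + half, y - half),
        c(x + half, y + half), c(x - half, y + half), c(x - half, y - half)))
    })
    props <- as.list(attrs[attrs$unit_id == uid, , drop = FALSE])
    list(type = "Feature",
         properties = lapply(props, function(v) unname(v)[1]),
         geometry = list(type = "MultiPolygon", coordinates = polys))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feat),
                       path, auto_unbox = TRUE, digits = 6)
  invisible(path)
}

# All CSV/GeoJSON/raster artifacts of one pipeline run.
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- result$region$grid
  units <- result$region$units
  p <- function(...) file.path(out_dir, ...)

  utils::write.csv(units[setdiff(names(units), "center_cell")],
                   p("units.csv"), row.names = FALSE)
  utils::write.csv(merge(result$refined, result$displacement,
                         by = "unit_id", all.x = TRUE),
                   p("refined_units.csv"), row.names = FALSE)
  utils::write.csv(result$table_municipal, p("unit_table_municipal.csv"),
                   row.names = FALSE)
  utils::write.csv(result$table_refined, p("unit_table_refined.csv"),
                   row.names = FALSE)
  utils::write.csv(result$incidence, p("incidence_rates.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, lapply(names(result$sqvif), function(s)
    cbind(support = s, result$sqvif[[s]]))), p("sqvif.csv"), row.names = FALSE)

  for (sup in c("municipal", "refined")) {
    fits <- result[[paste0("fits_", sup)]]
    tabs <- do.call(rbind, lapply(names(fits), function(fam)
      cbind(family = fam, support = sup, coefficient_table(fits[[fam]]))))
    utils::write.csv(tabs, p(sprintf("fit_coefficients_%s.csv", sup)),
                     row.names = FALSE)
  }
  utils::write.csv(result$report$aic_table, p("comparison_aic.csv"),
                   row.names = FALSE)
  utils::write.csv(result$report$pairwise_lrt, p("comparison_lrt.csv"),
                   row.names = FALSE)
  utils::write.csv(result$report$cross_support, p("comparison_cross_support.csv"),
                   row.names = FALSE)

  write_ascii_grid(grid$residential * 1L, p("residential.asc"), grid$cell_size_m)
  write_ascii_grid(round(result$dgrid, 4), p("distance_to_vet_km.asc"),
                   grid$cell_size_m)

  map <- allocate_cells(grid, units)
  res <- as.vector(grid$residential)
  all_cells <- split(seq_along(map), map)
  names(all_cells) <- as.character(units$unit_id[as.integer(names(all_cells))])
  write_units_geojson(grid, all_cells,
                      units[c("unit_id", "terrain", "area_km2", "human_pop")],
                      p("units.geojson"))
  res_cells <- split(which(res), map[res])
  names(res_cells) <- as.character(units$unit_id[as.integer(names(res_cells))])
  keep <- !result$refined$empty
  write_units_geojson(grid, res_cells[as.character(units$unit_id[keep])],
                      result$refined[keep, c("unit_id", "area_km2",
                                             "residential_fraction")],
                      p("refined_units.geojson"))

  jsonlite::write_json(result$summary, p("summary.json"), auto_unbox = TRUE,
                       digits = 10, pretty = TRUE)
  invisible(out_dir)
}
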