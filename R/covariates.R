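#' Demographic covariates and offset from dog records
#'
#' Aggregates individual dog records to the unit level: the at-risk dog
#' population `e` (the model offset), mean dog age in years, and the female
#' and mixed-breed percentages. Units without dogs are flagged and are
#' dropped from model rows downstream.
#'
#' @param dogs data frame from [generate_dogs()] (columns `unit_id`, `age`,
#'   `sex`, `breed`).
#' @param units unit table.
#' @return data frame `unit_id`, `e`, `DogAverageAge`, `FemaleDogRatio`,
#'   `MixedBreedRatio`, `flagged` (TRUE where `e == 0`).
#' @export
demographic_covariates <- function(dogs, units) {
  bad <- setdiff(unique(dogs$unit_id), units$unit_id)
  if (length(bad)) stop("dogs reference unknown units: ", paste(bad, collapse = ", "))
  f <- factor(dogs$unit_id, levels = units$unit_id)
  e <- as.integer(tabulate(f, nbins = nrow(units)))
  agg <- function(x) as.numeric(tapply(x, f, mean))
  out <- data.frame(
    unit_id = units$unit_id,
    e = e,
    DogAverageAge = agg(dogs$age),
    FemaleDogRatio = 100 * agg(dogs$sex == "female"),
    MixedBreedRatio = 100 * agg(dogs$breed == "mixed"),
    flagged = e == 0,
    row.names = NULL)
  out
}

#' Human population density on a given support
#'
#' Density in 1,000 people per square kilometre. The support determines the
#' area: the full unit for the municipal support, the residential portion
#' for the dasymetrically refined support — so for fixed counts the refined
#' density is always at least the municipal one.
#'
#' @param human_pop person count(s).
#' @param area_km2 area(s) in km^2, must be positive.
#' @return density in 1,000 people per km^2.
#' @export
population_density <- function(human_pop, area_km2) {
  if (any(area_km2 <= 0)) stop("area must be positive")
  (human_pop / 1000) / area_km2
}

#' Travel-distance grid to the nearest veterinary practice
#'
#' Multi-source shortest-path distances along the road network, in km, from
#' every veterinary practice. Road cells form an 8-connected graph with
#' centre-to-centre step costs (0.1 km orthogonal, 0.1*sqrt(2) km diagonal
#' on an hectometric grid); distances are computed with Dijkstra's algorithm
#' from all vet cells at once. Off-road cells are snapped to their nearest
#' road cell in the straight-line sense (ties broken toward the smallest
#' cell index) and receive that cell's network distance plus the snap
#' length. Road cells disconnected from every practice get the same
#' snap-based fallback, with a warning.
#'
#' @param grid a [cell_grid] with road and vet layers.
#' @return numeric `rows x cols` matrix of distances in km.
#' @export
distance_grid <- function(grid) {
  if (!any(grid$vets)) stop("no veterinary practice cells in grid")
  rows <- grid$rows; cols <- grid$cols
  step <- grid$cell_km
  road_cells <- which(as.vector(grid$road))
  vet_cells <- which(as.vector(grid$vets))

  ## 8-connected road graph; vertices are road cells
  idx <- integer(rows * cols)
  idx[road_cells] <- seq_along(road_cells)
  r <- (road_cells - 1L) %% rows + 1L
  co <- (road_cells - 1L) %/% rows + 1L
  offs <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L)) # half of 8-nbhd
  edges <- NULL; weights <- NULL
  for (o in offs) {
    r2 <- r + o[1]; c2 <- co + o[2]
    ok <- r2 >= 1L & r2 <= rows & c2 >= 1L & c2 <= cols
    nb <- (c2[ok] - 1L) * rows + r2[ok]
    has <- idx[nb] > 0L
    from <- idx[road_cells[ok]][has]
    to <- idx[nb][has]
    edges <- c(edges, rbind(from, to))
    weights <- c(weights, rep(step * sqrt(sum(o^2)), length(from)))
  }
  n_road <- length(road_cells)
  src <- n_road + 1L # virtual super-source joined to every vet cell
  g <- igraph::make_empty_graph(n = src, directed = FALSE)
  g <- igraph::add_edges(g, c(edges, rbind(src, idx[vet_cells])))
  d_road <- igraph::distances(
    g, v = src, weights = c(weights, rep(0, length(vet_cells))),
    algorithm = "dijkstra")[1, seq_len(n_road)]

  connected <- is.finite(d_road)
  if (!any(connected)) stop("no road cell is connected to a veterinary practice")
  if (!all(connected))
    warning(sum(!connected), " road cell(s) disconnected from every practice; ",
            "using straight-line snap fallback")

  dist <- matrix(NA_real_, rows, cols)
  dist[road_cells[connected]] <- d_road[connected]

  need <- which(is.na(as.vector(dist)))
  if (length(need)) {
    ref <- road_cells[connected]
    nn <- nearest_ref_cell((need - 1L) %% rows + 1L, (need - 1L) %/% rows + 1L,
                           (ref - 1L) %% rows + 1L, (ref - 1L) %/% rows + 1L)
    snap <- step * sqrt(((need - 1L) %% rows - (ref[nn] - 1L) %% rows)^2 +
                        ((need - 1L) %/% rows - (ref[nn] - 1L) %/% rows)^2)
    dist[need] <- d_road[connected][nn] + snap
  }
  dist
}

#' Zonal mean distance over a unit's cells
#'
#' Arithmetic mean of the distance-grid values over the cells of a unit on
#' the requested support: all allocated cells for the municipal support,
#' residential cells only for the refined support.
#'
#' @param dgrid matrix from [distance_grid()].
#' @param unit_cells integer cell indices; must be non-empty.
#' @return mean distance in km.
#' @export
zonal_mean_distance <- function(dgrid, unit_cells) {
  if (length(unit_cells) == 0) stop("empty cell set")
  mean(dgrid[unit_cells])
}

#' Assemble the per-unit analysis table on a chosen support
#'
#' One row per unit with at-risk dogs, holding the outcome placeholder,
#' offset and all six explanatory variables. Only `HumanPopulationDensity`
#' and `DistanceToVetCare` differ between supports: on the refined support
#' the density uses the residential area and the zonal distance averages
#' residential cells only, while all demographic columns and the income
#' surrogate are carried over unchanged. On the refined support, units with
#' an empty refined geometry are dropped (with the `e = 0` units) and noted.
#'
#' @param grid a [cell_grid].
#' @param units parent unit table.
#' @param refined output of [refine_units()].
#' @param demog output of [demographic_covariates()].
#' @param dgrid output of [distance_grid()].
#' @param support `"municipal"` or `"refined"`.
#' @param y optional count vector aligned with `units` (named by unit id or
#'   positional); attached as column `y` after row filtering.
#' @return a `data.frame` unit table with columns `unit_id`, `support`,
#'   `y` (if given), `e`, `DogAverageAge`, `FemaleDogRatio`,
#'   `MixedBreedRatio`, `AverageIncomeTax`, `HumanPopulationDensity`,
#'   `DistanceToVetCare`.
#' @export
build_unit_table <- function(grid, units, refined, demog, dgrid,
                             support = c("municipal", "refined"), y = NULL) {
  support <- match.arg(support)
  stopifnot(identical(units$unit_id, demog$unit_id),
            identical(units$unit_id, refined$unit_id))
  map <- allocate_cells(grid, units)
  res <- as.vector(grid$residential)

  if (support == "municipal") {
    area <- units$area_km2
    mean_dist <- vapply(units$unit_id, function(u)
      zonal_mean_distance(dgrid, which(map == u)), numeric(1))
    keep <- demog$e > 0
  } else {
    area <- refined$area_km2
    mean_dist <- vapply(seq_along(units$unit_id), function(i) {
      if (refined$empty[i]) return(NA_real_)
      zonal_mean_distance(dgrid, which(map == units$unit_id[i] & res))
    }, numeric(1))
    keep <- demog$e > 0 & !refined$empty
  }

  dropped <- units$unit_id[!keep]
  if (length(dropped))
    message(length(dropped), " unit(s) excluded from the ", support,
            " table (no dogs or empty refined geometry)")

  tab <- data.frame(
    unit_id = units$unit_id,
    support = support,
    e = demog$e,
    DogAverageAge = demog$DogAverageAge,
    FemaleDogRatio = demog$FemaleDogRatio,
    MixedBreedRatio = demog$MixedBreedRatio,
    AverageIncomeTax = units$income_tax,
    HumanPopulationDensity = ifelse(keep,
      population_density(units$human_pop, pmax(area, .Machine$double.eps)),
      NA_real_),
    DistanceToVetCare = mean_dist,
    row.names = NULL)
  if (!is.null(y)) {
    if (!is.null(names(y))) y <- y[as.character(units$unit_id)]
    stopifnot(length(y) == nrow(units))
    tab$y <- as.integer(y)
    tab <- tab[c("unit_id", "support", "y",
                 setdiff(names(tab), c("unit_id", "support", "y")))]
  }
  tab <- tab[keep, , drop = FALSE]
  row.names(tab) <- NULL
  req <- c("e", "DogAverageAge", "FemaleDogRatio", "MixedBreedRatio",
           "AverageIncomeTax", "HumanPopulationDensity", "DistanceToVetCare")
  miss <- req[vapply(req, function(v) anyNA(tab[[v]]), logical(1))]
  if (length(miss)) stop("missing covariate values in: ", paste(miss, collapse = ", "))
  tab
}
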