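#' Generate a synthetic study region
#'
#' Builds a seeded raster-lattice world emulating the Swiss study setting:
#' enumeration units grown by Voronoi assignment from seeded unit centres,
#' sparse "mountain" vs dense "plateau" residential-land fractions, a
#' connected road network (spanning tree over unit centres plus a spur into
#' each unit's residential patch), veterinary practices on residential road
#' cells biased toward populous units, and human counts allocated to
#' residential cells only. Mountain units are drawn from a larger southern
#' band of the lattice so they are on average about twice the area of plateau
#' units, mirroring large sparsely-populated alpine municipalities.
#'
#' The same `(config, seed)` pair always returns an identical region; the
#' global RNG state is left untouched.
#'
#' @param config a [region_config()].
#' @param seed integer seed.
#' @return a list with elements `grid` (a [cell_grid]) and `units`
#'   (a data frame with one row per enumeration unit: id, terrain, cell
#'   count, area, centroid, human population, income tax).
#' @export
generate_region <- function(config, seed = 1L) {
  validate_region_config(config)
  withr::with_seed(seed, generate_region_impl(config))
}

generate_region_impl <- function(cfg) {
  rows <- cfg$grid_rows; cols <- cfg$grid_cols
  n_cells <- rows * cols

  ## --- unit centres: mountain band at the bottom of the map, sized so
  ## mountain units are ~2x the area of plateau units
  n_mountain <- round(cfg$frac_mountain_units * cfg$n_units)
  n_plateau <- cfg$n_units - n_mountain
  f <- cfg$frac_mountain_units
  band <- if (n_mountain == 0) 0 else if (n_plateau == 0) 1 else 2 * f / (1 + f)
  band_rows <- max(min(round(band * rows), rows - (n_plateau > 0)),
                   (n_mountain > 0))

  sample_band <- function(r_lo, r_hi, n) {
    if (n == 0) return(integer(0))
    avail <- as.vector(outer(r_lo:r_hi, seq_len(cols),
                             function(r, co) (co - 1L) * rows + r))
    sample(avail, n)
  }
  centers <- c(sample_band(1L, max(band_rows, 1L), n_mountain),
               sample_band(band_rows + 1L, rows, n_plateau))
  terrain <- rep(c("mountain", "plateau"), c(n_mountain, n_plateau))

  ## --- Voronoi growth: each cell joins the nearest centre (ties -> lowest id)
  unit_of <- voronoi_assign(centers, rows, cols)
  unit_mat <- matrix(unit_of, rows, cols)

  units <- data.frame(unit_id = seq_len(cfg$n_units), terrain = terrain,
                      center_cell = centers, stringsAsFactors = FALSE)
  units$n_cells <- tabulate(unit_of, cfg$n_units)

  ## --- clustered residential land per unit
  res_range <- function(tr)
    if (tr == "mountain") cfg$residential_frac_range_mountain
    else cfg$residential_frac_range_plateau
  residential <- matrix(FALSE, rows, cols)
  res_seed <- integer(cfg$n_units)
  for (u in seq_len(cfg$n_units)) {
    cells_u <- which(unit_of == u)
    rng <- res_range(units$terrain[u])
    frac <- stats::runif(1, rng[1], rng[2])
    n_res <- round(frac * length(cells_u))
    res_seed[u] <- if (length(cells_u) == 1) cells_u else sample(cells_u, 1)
    if (n_res >= 1) {
      patch <- grow_patch(cells_u, res_seed[u], n_res, rows)
      residential[patch] <- TRUE
    }
  }

  ## --- roads: Euclidean MST over unit centres, rasterised as L-paths,
  ## plus a spur from each centre into the unit's residential seed
  road <- matrix(FALSE, rows, cols)
  xy <- cbind((centers - 1L) %/% rows, (centers - 1L) %% rows)
  g <- igraph::graph_from_adjacency_matrix(as.matrix(stats::dist(xy)),
                                           mode = "undirected", weighted = TRUE)
  mst <- igraph::mst(g)
  for (e in seq_len(igraph::ecount(mst))) {
    ends <- igraph::ends(mst, e)
    road[l_path(centers[as.integer(ends[1])], centers[as.integer(ends[2])], rows)] <- TRUE
  }
  for (u in seq_len(cfg$n_units))
    road[l_path(units$center_cell[u], res_seed[u], rows)] <- TRUE

  ## --- human population, allocated to residential cells
  n_res_cells <- tabulate(unit_of[residential], cfg$n_units)
  meanlog <- ifelse(units$terrain == "mountain",
                    log(cfg$human_pop_mean_mountain),
                    log(cfg$human_pop_mean_plateau)) - cfg$human_pop_sdlog^2 / 2
  pop <- round(stats::rlnorm(cfg$n_units, meanlog, cfg$human_pop_sdlog))
  # residential land has finite capacity: truncate to plausible occupancy
  pop <- pmin(pop, cfg$people_per_cell_cap * n_res_cells)
  pop[n_res_cells == 0] <- 0
  humans <- matrix(0, rows, cols)
  for (u in seq_len(cfg$n_units)) {
    if (pop[u] == 0) next
    cells_r <- which(residential & unit_mat == u)
    w <- stats::rgamma(length(cells_r), 1)
    humans[cells_r] <- as.vector(stats::rmultinom(1, pop[u], w / sum(w)))
  }
  if (any(pop == 0))
    warning(sum(pop == 0), " unit(s) have no residential land / population; ",
            "they will be excluded from refined-support analyses")

  ## --- veterinary practices on residential road cells, population-biased
  eligible <- which(road & residential)
  if (cfg$n_vet_practices > length(eligible))
    stop("infeasible config: ", cfg$n_vet_practices, " veterinary practices ",
         "but only ", length(eligible), " residential road cells")
  w <- pop[unit_of[eligible]] + 1
  vet_cells <- if (length(eligible) == 1) eligible else
    sample(eligible, cfg$n_vet_practices, prob = w)
  vets <- matrix(FALSE, rows, cols)
  vets[vet_cells] <- TRUE

  grid <- cell_grid(rows, cols, cfg$cell_size_m,
                    residential = residential, road = road, humans = humans,
                    vets = vets, unit = unit_mat)

  cent <- t(vapply(seq_len(cfg$n_units),
                   function(u) cells_centroid(grid, which(unit_of == u)),
                   numeric(2)))
  units$area_km2 <- cells_area_km2(grid, units$n_cells)
  units$centroid_x <- cent[, 1]
  units$centroid_y <- cent[, 2]
  units$human_pop <- pop
  units$income_tax <- pmax(0.2, stats::rnorm(cfg$n_units, cfg$income_mean_sd[1],
                                             cfg$income_mean_sd[2]))
  units$n_res_cells <- n_res_cells

  list(grid = grid, units = units)
}

# Nearest-centre assignment on the lattice; ties go to the lowest unit id.
voronoi_assign <- function(centers, rows, cols) {
  cell <- seq_len(rows * cols)
  r <- (cell - 1L) %% rows
  co <- (cell - 1L) %/% rows
  cr <- (centers - 1L) %% rows
  cc <- (centers - 1L) %/% rows
  d2 <- outer(r, cr, function(a, b) (a - b)^2) +
        outer(co, cc, function(a, b) (a - b)^2)
  max.col(-d2, ties.method = "first")
}

# Random 4-connected growth of a patch of `n_target` cells inside `cells`,
# starting from `start`.
grow_patch <- function(cells, start, n_target, rows) {
  allowed <- rep(FALSE, max(cells))
  allowed[cells] <- TRUE
  in_patch <- rep(FALSE, length(allowed))
  patch <- integer(n_target)
  patch[1] <- start
  in_patch[start] <- TRUE
  frontier <- integer(0)
  push_nbrs <- function(cell, frontier) {
    nb <- cell_neighbours4(cell, rows, length(allowed))
    nb <- nb[nb <= length(allowed) & allowed[nb] & !in_patch[nb]]
    union(frontier, nb)
  }
  frontier <- push_nbrs(start, frontier)
  k <- 1L
  while (k < n_target && length(frontier) > 0) {
    nxt <- if (length(frontier) == 1) frontier else sample(frontier, 1)
    frontier <- setdiff(frontier, nxt)
    k <- k + 1L
    patch[k] <- nxt
    in_patch[nxt] <- TRUE
    frontier <- push_nbrs(nxt, frontier)
  }
  patch[seq_len(k)]
}

cell_neighbours4 <- function(cell, rows, n_cells) {
  r <- (cell - 1L) %% rows + 1L
  nb <- c(if (r > 1L) cell - 1L,
          if (r < rows) cell + 1L,
          cell - rows, cell + rows)
  nb[nb >= 1L & nb <= n_cells]
}

# Cells of an axis-aligned L-shaped path (horizontal leg then vertical leg).
l_path <- function(from, to, rows) {
  r1 <- (from - 1L) %% rows + 1L; c1 <- (from - 1L) %/% rows + 1L
  r2 <- (to - 1L) %% rows + 1L;   c2 <- (to - 1L) %/% rows + 1L
  horiz <- (seq(c1, c2) - 1L) * rows + r1
  vert <- (c2 - 1L) * rows + seq(r1, r2)
  c(horiz, vert)
}

#' Generate dog records for a region
#'
#' Per-unit dog counts are Poisson with mean `human_pop *
#' dog_per_100_humans / 100`; ages are Gamma-distributed (default mean 5
#' years), sex is Bernoulli(0.5), and breed is Bernoulli with a per-unit
#' mixed-breed probability drawn from a Beta distribution (default mean 0.3).
#'
#' @param grid a [cell_grid] (unused beyond validation; dogs live in units).
#' @param units unit table from [generate_region()].
#' @param config the [region_config()].
#' @param seed integer seed.
#' @return a data frame with one row per dog: `unit_id`, `age` (years),
#'   `sex` (`"female"`/`"male"`), `breed` (`"mixed"`/`"pure"`).
#' @export
generate_dogs <- function(grid, units, config, seed = 1L) {
  withr::with_seed(seed, {
    n_dogs <- stats::rpois(nrow(units),
                           units$human_pop * config$dog_per_100_humans / 100)
    p_mixed <- stats::rbeta(nrow(units), config$mixed_breed_beta[1],
                            config$mixed_breed_beta[2])
    total <- sum(n_dogs)
    dogs <- data.frame(
      unit_id = rep(units$unit_id, n_dogs),
      age = stats::rgamma(total, config$dog_age_shape,
                          scale = config$dog_age_scale),
      sex = ifelse(stats::rbinom(total, 1, 0.5) == 1, "female", "male"),
      breed = ifelse(stats::rbinom(total, 1, rep(p_mixed, n_dogs)) == 1,
                     "mixed", "pure"),
      stringsAsFactors = FALSE)
    dogs
  })
}

#' Generate zero-inflated cancer counts for a unit table
#'
#' The generative mirror of the fitted incidence model: each unit is a
#' structural zero with probability `plogis(gamma . z)`; otherwise its count
#' is negative binomial with mean `e * exp(alpha + sum(beta * x))` and
#' dispersion `theta` (`theta = Inf` gives Poisson counts).
#'
#' @param unit_table a unit table (see [build_unit_table()]) containing the
#'   offset column `e` and every covariate named in `truth`.
#' @param truth a [truth_params()].
#' @param seed integer seed.
#' @return integer vector of counts, one per row of `unit_table`; rows with
#'   nonpositive offset get `NA` with a warning.
#' @export
generate_cancer_counts <- function(unit_table, truth, seed = 1L) {
  stopifnot(inherits(truth, "truth_params"))
  miss <- setdiff(names(truth$beta), names(unit_table))
  if (length(miss)) stop("unit_table lacks covariates: ", paste(miss, collapse = ", "))
  withr::with_seed(seed, {
    n <- nrow(unit_table)
    ok <- unit_table$e > 0
    if (!all(ok))
      warning(sum(!ok), " unit(s) with nonpositive offset excluded (NA counts)")
    x <- as.matrix(unit_table[names(truth$beta)])
    eta <- truth$alpha + drop(x %*% truth$beta) + log(pmax(unit_table$e, 1e-12))
    mu <- exp(eta)
    zn <- setdiff(names(truth$gamma), "(Intercept)")
    lin <- truth$gamma[["(Intercept)"]] +
      if (length(zn)) drop(as.matrix(unit_table[zn]) %*% truth$gamma[zn]) else 0
    pi_zero <- stats::plogis(lin)
    structural <- stats::rbinom(n, 1, pi_zero) == 1
    y <- if (is.finite(truth$theta))
      stats::rnbinom(n, mu = mu, size = truth$theta)
    else stats::rpois(n, mu)
    y[structural] <- 0L
    y[!ok] <- NA_integer_
    as.integer(y)
  })
}
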