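# Independent oracles and fixture builders used across the suite.

# Brute-force multi-source shortest paths on the road lattice, by repeated
# relaxation over 8-neighbourhoods (Bellman-Ford style), followed by the
# straight-line snap rule for cells without a finite road distance. Written
# independently of distance_grid() on purpose.
bf_distance_grid <- function(grid) {
  rows <- grid$rows; cols <- grid$cols; step <- grid$cell_km
  d <- matrix(Inf, rows, cols)
  d[grid$vets] <- 0
  road <- grid$road
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  repeat {
    changed <- FALSE
    for (r in seq_len(rows)) for (co in seq_len(cols)) {
      if (!road[r, co]) next
      for (k in seq_len(nrow(offs))) {
        r2 <- r + offs$dr[k]; c2 <- co + offs$dc[k]
        if (r2 < 1 || r2 > rows || c2 < 1 || c2 > cols || !road[r2, c2]) next
        cand <- d[r2, c2] + step * sqrt(offs$dr[k]^2 + offs$dc[k]^2)
        if (cand < d[r, co] - 1e-12) { d[r, co] <- cand; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  finite_road <- which(road & is.finite(d))
  out <- d
  for (cell in seq_len(rows * cols)) {
    if (cell %in% finite_road) next
    r <- (cell - 1L) %% rows + 1L; co <- (cell - 1L) %/% rows + 1L
    best <- Inf; best_cell <- NA_integer_
    for (fc in finite_road) {
      fr <- (fc - 1L) %% rows + 1L; fcc <- (fc - 1L) %/% rows + 1L
      dd <- sqrt((r - fr)^2 + (co - fcc)^2)
      if (dd < best - 1e-12) { best <- dd; best_cell <- fc }
    }
    out[cell] <- d[best_cell] + step * best
  }
  out
}

# Random road/vet grid for the distance oracle suite: a few random-walk
# roads plus vets on road cells. Always has >= 1 vet.
random_test_grid <- function(rows, cols, seed, p_disconnect = 0) {
  withr::with_seed(seed, {
    road <- matrix(FALSE, rows, cols)
    for (w in seq_len(2 + rpois(1, 1))) {
      r <- sample(rows, 1); co <- sample(cols, 1)
      for (s in seq_len(rows + cols)) {
        road[r, co] <- TRUE
        mv <- sample(4, 1)
        r <- min(max(r + c(-1, 1, 0, 0)[mv], 1), rows)
        co <- min(max(co + c(0, 0, -1, 1)[mv], 1), cols)
      }
    }
    if (p_disconnect > 0 && runif(1) < p_disconnect) {
      r0 <- sample(rows, 1)
      road[r0, ] <- FALSE # cut a horizontal swath to maybe disconnect
      road[sample(rows, 1), sample(cols, 1)] <- TRUE
    }
    road_cells <- which(road)
    vets <- matrix(FALSE, rows, cols)
    vets[sample(road_cells, min(length(road_cells), 1 + rpois(1, 1)))] <- TRUE
    cell_grid(rows, cols, 100, road = road, vets = vets)
  })
}

# Covariate table for model tests: positive offset, two standardized-scale
# covariates; counts appended by the caller.
sim_model_table <- function(n, seed, theta = 1, alpha = -4,
                            beta = c(x1 = 0.3, x2 = -0.2),
                            gamma = NULL) {
  withr::with_seed(seed, {
    tab <- data.frame(e = rpois(n, 150) + 50,
                      x1 = rnorm(n, 5, 1), x2 = rnorm(n, 3, 1))
    mu <- tab$e * exp(alpha + as.matrix(tab[names(beta)]) %*% beta)
    y <- if (is.finite(theta)) rnbinom(n, mu = mu, size = theta)
         else rpois(n, mu)
    if (!is.null(gamma)) {
      z <- gamma[["(Intercept)"]] +
        if (length(gamma) > 1)
          as.matrix(tab[setdiff(names(gamma), "(Intercept)")]) %*%
            gamma[setdiff(names(gamma), "(Intercept)")]
        else 0
      y[rbinom(n, 1, plogis(z)) == 1] <- 0
    }
    tab$y <- as.integer(y)
    tab
  })
}

# Small, fast region for property tests.
small_region_config <- function(...) {
  region_config(n_units = 12, grid_rows = 26, grid_cols = 26,
                n_vet_practices = 5, ...)
}

# One fully assembled pair of unit tables (+ counts) from a small region.
small_pipeline_tables <- function(seed, cfg = small_region_config(),
                                  truth = truth_params()) {
  reg <- suppressWarnings(generate_region(cfg, seed))
  dogs <- generate_dogs(reg$grid, reg$units, cfg, seed + 1L)
  refined <- suppressWarnings(refine_units(reg$units, reg$grid))
  demog <- demographic_covariates(dogs, reg$units)
  dgrid <- suppressWarnings(distance_grid(reg$grid))
  tm <- suppressMessages(build_unit_table(reg$grid, reg$units, refined,
                                          demog, dgrid, "municipal"))
  tr <- suppressMessages(build_unit_table(reg$grid, reg$units, refined,
                                          demog, dgrid, "refined"))
  shared <- intersect(tm$unit_id, tr$unit_id)
  tm <- tm[match(shared, tm$unit_id), ]
  tr <- tr[match(shared, tr$unit_id), ]
  y <- suppressWarnings(generate_cancer_counts(tr, truth, seed + 2L))
  tm$y <- tr$y <- y
  list(region = reg, refined = refined, demog = demog, dgrid = dgrid,
       municipal = tm, refined_tab = tr)
}
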