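# Shared fixtures, memoised so expensive geography is built once per run.

.gw_fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.gw_fixtures[[key]])) .gw_fixtures[[key]] <- force(expr)
  .gw_fixtures[[key]]
}

# Small city for unit tests (fast to generate, still has all layers).
small_city_config <- function(...) {
  defaults <- list(extent = 1600, street_spacing = 160, n_blocks = 24,
                   veg_grid_res = 20, parcel_size = 200, n_shops = 60,
                   n_recreation = 30, n_bus_stops = 50, n_rail_stations = 4,
                   dwelling_margin = 400)
  do.call(city_config, utils::modifyList(defaults, list(...)))
}

small_city <- function() memo("small_city", generate_city(small_city_config(), seed = 42))

small_style <- function() render_config(tile_size = 64)

# Full-scale study base used by the acceptance checks: default city,
# 24,773 dwellings, 400/800 m buffers, field-scored exposures.
acceptance_base <- function() {
  memo("acceptance_base", build_study_design(run_config(seed = 20260921L)))
}

# Walker-scale base: 1,994 dwellings restricted to 150 of the 200 blocks.
walker_base <- function() {
  memo("walker_base", {
    ab <- acceptance_base()
    blocks <- with_seed_helper(77L, sample(ab$city$blocks$id, 150L))
    b <- list(city = ab$city,
              dwellings = place_dwellings(ab$city, 1994L, seed = 20260921L,
                                          blocks = blocks),
              radii = c(400, 800))
    b$exposures <- compute_exposures(b$city, b$dwellings, radii = b$radii)
    b$covariates <- lapply(b$radii, function(r)
      buffer_covariates(b$dwellings, b$city, r))
    names(b$covariates) <- as.character(b$radii)
    b
  })
}

with_seed_helper <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Build a gw_tile by hand from a pixel array and truth mask.
make_tile <- function(pixels, truth, heading = 0L, point_id = 1L) {
  structure(list(point_id = point_id, heading = heading, pixels = pixels,
                 truth_mask = truth), class = "gw_tile")
}

# A hand-built tileset with given per-tile truth masks (pixels gray).
make_tileset <- function(masks, point_id = 1L) {
  headings <- c(0L, 90L, 180L, 270L)
  tiles <- lapply(seq_len(4L), function(i) {
    m <- masks[[i]]
    px <- array(0.5, dim = c(nrow(m), ncol(m), 3))
    make_tile(px, m, heading = headings[i], point_id = point_id)
  })
  structure(list(point_id = point_id, point = c(0, 0), tiles = tiles),
            class = "gw_tileset")
}

# A synthetic vegetation-textured tile (whole frame is foliage).
veg_texture_tile <- function(H = 64, seed = 1) {
  with_seed_helper(seed, {
    n <- H * H
    hsv <- list(h = runif(n, 0.26, 0.40), s = runif(n, 0.55, 0.95),
                v = pmin(pmax(0.30 + 0.35 * runif(n) + rnorm(n, 0, 0.12), 0.05), 1))
    cc <- greenwalk:::.hsv2rgb(hsv$h, hsv$s, hsv$v)
    px <- array(0, dim = c(H, H, 3))
    px[, , 1] <- cc$r; px[, , 2] <- cc$g; px[, , 3] <- cc$b
    make_tile(px, matrix(1L, H, H))
  })
}

# A gray tile with a single smooth green rectangle (man-made confounder).
confounder_tile <- function(H = 64) {
  px <- array(0.5, dim = c(H, H, 3))
  rows <- 30:45; cols <- 10:40
  cc <- greenwalk:::.hsv2rgb(0.33, 0.6, 0.55)
  px[rows, cols, 1] <- cc$r; px[rows, cols, 2] <- cc$g; px[rows, cols, 3] <- cc$b
  make_tile(px, matrix(0L, H, H))
}

# Minimal hand-built street scene: one straight horizontal street.
line_city <- function(length_m = 200) {
  structure(list(
    extent = c(0, 0, 1000, 1000),
    nodes = data.frame(id = 1:2, x = c(100, 100 + length_m), y = c(500, 500),
                       degree = c(1L, 1L)),
    edges = data.frame(id = 1L, from = 1L, to = 2L, length = length_m),
    blocks = data.frame(id = 1L, x = 500, y = 500),
    parcels = list(n = 2L, cell = 500,
                   centers = c(250, 750),
                   type = matrix(c(1L, 2L, 3L, 3L), 2, 2),
                   pop = matrix(100, 2, 2),
                   type_levels = c("commercial", "office", "residential")),
    amenities = list(shops = data.frame(x = numeric(), y = numeric()),
                     recreation_facilities = data.frame(x = numeric(), y = numeric()),
                     bus_stops = data.frame(x = numeric(), y = numeric()),
                     rail_stations = data.frame(x = 500, y = 500)),
    veg = list(x = c(0, 1000), y = c(0, 1000), z = matrix(0.4, 2, 2)),
    config = small_city_config(), seed = 1L), class = "gw_city")
}

# Independent IRLS logistic oracle (explicit weighted least squares).
irls_logistic <- function(X, y, iter = 60) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    beta <- drop(solve(crossprod(X, X * w), crossprod(X, w * z)))
  }
  beta
}

# Brute-force marginal log-likelihood of the random-intercept logistic
# model by trapezoidal integration on a fine grid.
grid_marginal_loglik <- function(X, y, g, beta, sigma, lim = 8, m = 40001) {
  bs <- seq(-lim, lim, length.out = m)
  h <- bs[2] - bs[1]
  total <- 0
  for (j in sort(unique(g))) {
    eta <- drop(X[g == j, , drop = FALSE] %*% beta)
    yj <- y[g == j]
    lf <- vapply(bs, function(bb) {
      sum(yj * stats::plogis(eta + bb, log.p = TRUE) +
            (1 - yj) * stats::plogis(-(eta + bb), log.p = TRUE)) +
        stats::dnorm(bb, 0, sigma, log = TRUE)
    }, numeric(1))
    mx <- max(lf)
    total <- total + mx + log(sum(exp(lf - mx)) * h)
  }
  total
}
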