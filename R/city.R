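# Synthetic planar city: street network, land-use parcels, amenities,
# street blocks and a spatially autocorrelated vegetation field. All
# geometry is planar, in meters; neighbourhood buffers are Euclidean disks.

#' City generator configuration
#'
#' @param extent side length of the square city extent, meters.
#' @param street_spacing nominal grid spacing of the street network, meters.
#'   Node positions are jittered and a fraction of edges is dropped or
#'   replaced by diagonal connectors, so intersection density varies.
#' @param n_blocks number of street blocks (Voronoi regions of random seed
#'   points); the clustering unit of the multilevel models.
#' @param veg_corr_length correlation length of the vegetation field, meters.
#' @param veg_grid_res resolution of the vegetation-field raster, meters.
#' @param parcel_size side length of square land-use parcels, meters.
#' @param n_shops,n_recreation,n_bus_stops,n_rail_stations amenity counts.
#' @param total_population total residential population spread over parcels.
#' @param edge_drop_prob probability a grid street segment is removed
#'   (connectivity is repaired afterwards).
#' @param diag_prob probability a diagonal connector is added in a grid cell.
#' @param dwelling_margin dwellings are placed at least this far from the
#'   extent boundary so their buffers are never truncated, meters.
#' @return a `gw_city_config` list.
#' @export
city_config <- function(extent = 12000, street_spacing = 160, n_blocks = 200,
                        veg_corr_length = 300, veg_grid_res = 20,
                        parcel_size = 250, n_shops = 2700, n_recreation = 1125,
                        n_bus_stops = 2250, n_rail_stations = 68,
                        total_population = 2160000,
                        edge_drop_prob = 0.04, diag_prob = 0.08,
                        dwelling_margin = 800) {
  cfg <- list(extent = extent, street_spacing = street_spacing,
              n_blocks = n_blocks, veg_corr_length = veg_corr_length,
              veg_grid_res = veg_grid_res, parcel_size = parcel_size,
              n_shops = n_shops, n_recreation = n_recreation,
              n_bus_stops = n_bus_stops, n_rail_stations = n_rail_stations,
              total_population = total_population,
              edge_drop_prob = edge_drop_prob, diag_prob = diag_prob,
              dwelling_margin = dwelling_margin)
  class(cfg) <- "gw_city_config"
  cfg
}

# Union-find over node ids, used to repair street-network connectivity.
.uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

# Gaussian random field on a grid via FFT convolution of white noise with a
# Gaussian kernel (torus topology), standardized, then squashed to [0, 1].
.veg_field <- function(extent, res, corr_length) {
  nx <- max(8L, round(extent / res))
  z <- matrix(stats::rnorm(nx * nx), nx, nx)
  s <- (corr_length / 2) / res           # kernel sd in cells
  d <- c(0:(nx %/% 2), -((nx - nx %/% 2 - 1):1)) # torus distances
  k1 <- exp(-d^2 / (2 * s^2))
  kern <- outer(k1, k1)
  sm <- Re(stats::fft(stats::fft(z) * stats::fft(kern / sum(kern)), inverse = TRUE)) / (nx * nx)
  sm <- (sm - mean(sm)) / stats::sd(as.vector(sm))
  centers <- (seq_len(nx) - 0.5) * (extent / nx)
  # logistic squash: mean greenery around 0.27, realistic street-level range
  list(x = centers, y = centers, z = stats::plogis(1.1 * sm - 1.0))
}

#' Generate a synthetic city scene
#'
#' Builds a reproducible planar city: a jittered-grid street network (single
#' connected component), square land-use parcels labelled
#' commercial/office/residential with population weights, amenity point sets
#' (shops, recreation facilities, bus stops, rail stations), a Voronoi
#' street-block partition, and a spatially autocorrelated vegetation field
#' with values in `[0, 1]`.
#'
#' @param config a [city_config()].
#' @param seed integer seed; the scene is a pure function of
#'   `(config, seed)`.
#' @return an object of class `gw_city`.
#' @examples
#' city <- generate_city(city_config(extent = 1500, n_blocks = 20), seed = 1)
#' city
#' @export
generate_city <- function(config = city_config(), seed = 1L) {
  if (!inherits(config, "gw_city_config")) stop("`config` must come from city_config()")
  if (config$extent <= 0) stop("configuration error: non-positive extent")
  ngrid <- floor(config$extent / config$street_spacing) + 1L
  if (ngrid < 2L) stop("configuration error: extent too small for any street")
  with_seed(child_seed(seed, "city"), {
    ext <- config$extent
    s <- config$street_spacing
    # --- street network: jittered grid + diagonals, with connectivity repair
    gx <- seq(0, by = s, length.out = ngrid)
    jit <- 0.22 * s
    xs <- outer(gx, rep(1, ngrid)) + matrix(stats::runif(ngrid^2, -jit, jit), ngrid)
    ys <- outer(rep(1, ngrid), gx) + matrix(stats::runif(ngrid^2, -jit, jit), ngrid)
    xs <- pmin(pmax(xs, 0), ext); ys <- pmin(pmax(ys, 0), ext)
    nid <- matrix(seq_len(ngrid^2), ngrid, ngrid)
    h_from <- as.vector(nid[-ngrid, ]); h_to <- as.vector(nid[-1L, ])
    v_from <- as.vector(nid[, -ngrid]); v_to <- as.vector(nid[, -1L])
    efrom <- c(h_from, v_from); eto <- c(h_to, v_to)
    keep <- stats::runif(length(efrom)) > config$edge_drop_prob
    d_from <- as.vector(nid[-ngrid, -ngrid]); d_to <- as.vector(nid[-1L, -1L])
    dkeep <- stats::runif(length(d_from)) < config$diag_prob
    all_from <- c(efrom[keep], d_from[dkeep])
    all_to <- c(eto[keep], d_to[dkeep])
    # repair: re-add dropped grid edges joining distinct components
    parent <- seq_len(ngrid^2)
    for (i in seq_along(all_from)) {
      a <- .uf_find(parent, all_from[i]); b <- .uf_find(parent, all_to[i])
      if (a != b) parent[a] <- b
    }
    dropped <- which(!keep)
    for (i in dropped) {
      a <- .uf_find(parent, efrom[i]); b <- .uf_find(parent, eto[i])
      if (a != b) {
        parent[a] <- b
        all_from <- c(all_from, efrom[i]); all_to <- c(all_to, eto[i])
      }
    }
    nodes <- data.frame(id = seq_len(ngrid^2), x = as.vector(xs), y = as.vector(ys))
    elen <- sqrt((nodes$x[all_from] - nodes$x[all_to])^2 +
                 (nodes$y[all_from] - nodes$y[all_to])^2)
    edges <- data.frame(id = seq_along(all_from), from = all_from, to = all_to,
                        length = elen)
    deg <- tabulate(c(edges$from, edges$to), nbins = nrow(nodes))
    nodes$degree <- deg
    # --- street blocks: Voronoi seeds, drawn in the dwelling core so housing
    # estates occupy (essentially) every block
    bm <- min(config$dwelling_margin, ext / 4)
    blocks <- data.frame(id = seq_len(config$n_blocks),
                         x = stats::runif(config$n_blocks, bm, ext - bm),
                         y = stats::runif(config$n_blocks, bm, ext - bm))
    # --- land-use parcels on a square grid
    npar <- max(2L, round(ext / config$parcel_size))
    ptype <- matrix(sample.int(3L, npar^2, replace = TRUE,
                               prob = c(0.27, 0.18, 0.55)), npar, npar)
    # population loads all types (mixed-use towers over podia), residential
    # most heavily, so density is not a deterministic function of use mix
    wmult <- c(0.5, 0.35, 1)[ptype]            # commercial, office, residential
    wraw <- matrix(stats::rlnorm(npar^2, 0, 0.6) * wmult, npar, npar)
    pop <- wraw / sum(wraw) * config$total_population
    parcels <- list(n = npar, cell = ext / npar,
                    centers = (seq_len(npar) - 0.5) * (ext / npar),
                    type = ptype, pop = pop,
                    type_levels = c("commercial", "office", "residential"))
    # --- amenities: shops favour commercial parcels, the rest uniform
    rand_pts <- function(n) data.frame(x = stats::runif(n, 0, ext),
                                       y = stats::runif(n, 0, ext))
    shop_w <- c(5, 2, 1)[ptype]
    cell_ix <- sample.int(npar^2, config$n_shops, replace = TRUE, prob = shop_w)
    ci <- (cell_ix - 1L) %% npar + 1L; cj <- (cell_ix - 1L) %/% npar + 1L
    cs <- ext / npar
    shops <- data.frame(x = (ci - 1L) * cs + stats::runif(config$n_shops, 0, cs),
                        y = (cj - 1L) * cs + stats::runif(config$n_shops, 0, cs))
    amenities <- list(shops = shops,
                      recreation_facilities = rand_pts(config$n_recreation),
                      bus_stops = rand_pts(config$n_bus_stops),
                      rail_stations = rand_pts(config$n_rail_stations))
    veg <- .veg_field(ext, config$veg_grid_res, config$veg_corr_length)
    structure(list(extent = c(0, 0, ext, ext), nodes = nodes, edges = edges,
                   blocks = blocks, parcels = parcels, amenities = amenities,
                   veg = veg, config = config, seed = as.integer(seed)),
              class = "gw_city")
  })
}

#' @export
print.gw_city <- function(x, ...) {
  cat(sprintf("<gw_city> %g x %g m | %d nodes, %d edges | %d blocks | seed %d\n",
              x$extent[3], x$extent[4], nrow(x$nodes), nrow(x$edges),
              nrow(x$blocks), x$seed))
  cat(sprintf("  vegetation field: %d x %d grid, mean %.3f\n",
              length(x$veg$x), length(x$veg$y), mean(x$veg$z)))
  invisible(x)
}

#' Vegetation field value at points
#'
#' Bilinear interpolation of the city's vegetation field; values in `[0, 1]`.
#'
#' @param city a `gw_city`.
#' @param x,y point coordinates in meters.
#' @return numeric vector of expected local greenery density.
#' @export
vegetation_at <- function(city, x, y) {
  stopifnot(inherits(city, "gw_city"))
  bilinear(city$veg, x, y)
}

#' Street block containing each point
#'
#' Blocks are the Voronoi regions of the city's block seed points, so every
#' point of the extent belongs to exactly one block (nearest-seed rule).
#'
#' @param city a `gw_city`.
#' @param x,y coordinates in meters.
#' @return integer block ids.
#' @export
block_of <- function(city, x, y) {
  stopifnot(inherits(city, "gw_city"))
  bs <- city$blocks
  n <- length(x)
  out <- integer(n)
  chunk <- 4000L
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    d2 <- outer(x[idx], bs$x, "-")^2 + outer(y[idx], bs$y, "-")^2
    out[idx] <- bs$id[max.col(-d2, ties.method = "first")]
  }
  out
}

#' Place dwellings clustered into housing estates
#'
#' Each street block hosts an "estate" anchor; dwellings pick a block with
#' block-specific weights and scatter around its anchor, emulating housing
#' estates (many dwellings per block). Dwellings are kept at least
#' `dwelling_margin` from the extent boundary so circular buffers are whole.
#'
#' @param city a `gw_city`.
#' @param n number of dwellings (`n = 0` gives an empty frame).
#' @param seed integer seed.
#' @param blocks optional integer vector of block ids; when given, estates
#'   are restricted to those blocks (e.g. a subsample of the city's blocks).
#' @return data.frame with columns `id`, `x`, `y`, `block_id`.
#' @export
place_dwellings <- function(city, n, seed = 1L, blocks = NULL) {
  stopifnot(inherits(city, "gw_city"), n >= 0)
  empty <- data.frame(id = integer(), x = numeric(), y = numeric(),
                      block_id = integer())
  if (n == 0L) return(empty)
  with_seed(child_seed(seed, "dwellings"), {
    m <- city$config$dwelling_margin
    ext <- city$extent[3]
    lo <- m; hi <- ext - m
    if (hi <= lo) stop("dwelling margin leaves no interior core")
    anchors <- city$blocks
    if (!is.null(blocks)) {
      anchors <- anchors[anchors$id %in% blocks, , drop = FALSE]
      if (nrow(anchors) == 0L) stop("no matching blocks")
    }
    anchors$x <- pmin(pmax(anchors$x, lo), hi)
    anchors$y <- pmin(pmax(anchors$y, lo), hi)
    w <- stats::rgamma(nrow(anchors), shape = 1.2)
    pick <- sample.int(nrow(anchors), n, replace = TRUE, prob = w)
    x <- pmin(pmax(anchors$x[pick] + stats::rnorm(n, 0, 60), lo), hi)
    y <- pmin(pmax(anchors$y[pick] + stats::rnorm(n, 0, 60), lo), hi)
    data.frame(id = seq_len(n), x = x, y = y, block_id = block_of(city, x, y))
  })
}

#' Export a city scene to GeoJSON layers
#'
#' Writes one GeoJSON FeatureCollection per layer (`streets`, `blocks`,
#' `parcels`, amenity point sets) plus a JSON sidecar with the seed and
#' configuration, into `dir`.
#'
#' @param city a `gw_city`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_city_geojson <- function(city, dir) {
  stopifnot(inherits(city, "gw_city"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fc <- function(features) list(type = "FeatureCollection", features = features)
  pt_feature <- function(x, y, props = NULL) {
    list(type = "Feature", geometry = list(type = "Point", coordinates = c(x, y)),
         properties = if (is.null(props)) stats::setNames(list(), character()) else props)
  }
  files <- character()
  streets <- lapply(seq_len(nrow(city$edges)), function(i) {
    e <- city$edges[i, ]
    list(type = "Feature",
         geometry = list(type = "LineString",
                         coordinates = list(c(city$nodes$x[e$from], city$nodes$y[e$from]),
                                            c(city$nodes$x[e$to], city$nodes$y[e$to]))),
         properties = list(id = e$id, length_m = e$length))
  })
  f <- file.path(dir, "streets.geojson")
  jsonlite::write_json(fc(streets), f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)
  blocks <- lapply(seq_len(nrow(city$blocks)), function(i) {
    pt_feature(city$blocks$x[i], city$blocks$y[i], list(block_id = city$blocks$id[i]))
  })
  f <- file.path(dir, "blocks.geojson")
  jsonlite::write_json(fc(blocks), f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)
  p <- city$parcels
  parcels <- list()
  for (i in seq_len(p$n)) for (j in seq_len(p$n)) {
    x0 <- (i - 1) * p$cell; y0 <- (j - 1) * p$cell
    parcels[[length(parcels) + 1L]] <- list(
      type = "Feature",
      geometry = list(type = "Polygon", coordinates = list(list(
        c(x0, y0), c(x0 + p$cell, y0), c(x0 + p$cell, y0 + p$cell),
        c(x0, y0 + p$cell), c(x0, y0)))),
      properties = list(landuse = p$type_levels[p$type[i, j]],
                        population = p$pop[i, j]))
  }
  f <- file.path(dir, "parcels.geojson")
  jsonlite::write_json(fc(parcels), f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)
  for (nm in names(city$amenities)) {
    a <- city$amenities[[nm]]
    feats <- lapply(seq_len(nrow(a)), function(i) pt_feature(a$x[i], a$y[i]))
    f <- file.path(dir, paste0(nm, ".geojson"))
    jsonlite::write_json(fc(feats), f, auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
  }
  f <- file.path(dir, "city_meta.json")
  jsonlite::write_json(list(seed = city$seed, config = unclass(city$config)),
                       f, auto_unbox = TRUE, digits = NA)
  invisible(c(files, f))
}

#' Write dwellings to CSV
#'
#' @param dwellings data.frame from [place_dwellings()].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_dwellings_csv <- function(dwellings, path) {
  utils::write.csv(dwellings, path, row.names = FALSE)
  invisible(path)
}
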