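# Synthetic street-level image tiles with exact ground-truth vegetation
# masks. Each sampling point gets four 90-degree field-of-view tiles at
# compass headings 0/90/180/270; the expected vegetation fraction of a tile
# tracks the city's vegetation field at the point. Tiles deliberately include
# green-coloured man-made confounders (smooth rectilinear patches) whose
# pixels are 0 in the truth mask, so colour-only vegetation detection
# overcounts while a shape-aware segmenter does not.

#' Render configuration for streetscape tiles
#'
#' @param tile_size tile side length in pixels (square tiles).
#' @param veg_weight multiplier mapping local vegetation-field density to the
#'   expected tile vegetation fraction; `0` renders vegetation-free tiles.
#' @param confounder_prob per-tile probability of adding at least one green
#'   man-made rectangle (truck/wall patch) that is *not* vegetation.
#' @param veg_value_noise pixel-value noise of the vegetation texture; the
#'   segmenter's texture filter relies on vegetation being rougher than
#'   painted surfaces.
#' @return a `gw_render_config` list.
#' @export
render_config <- function(tile_size = 256, veg_weight = 0.85,
                          confounder_prob = 0.35, veg_value_noise = 0.12) {
  structure(list(tile_size = as.integer(tile_size), veg_weight = veg_weight,
                 confounder_prob = confounder_prob,
                 veg_value_noise = veg_value_noise),
            class = "gw_render_config")
}

# Vectorized HSV -> RGB (h, s, v in [0, 1]).
.hsv2rgb <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6) %% 6
  f <- h6 - floor(h6)
  p <- v * (1 - s); q <- v * (1 - s * f); tt <- v * (1 - s * (1 - f))
  r <- v; g <- v; b <- v
  r[i == 1] <- q[i == 1]; r[i == 2 | i == 3] <- p[i == 2 | i == 3]; r[i == 4] <- tt[i == 4]
  g[i == 0] <- tt[i == 0]; g[i == 3] <- q[i == 3]; g[i == 4 | i == 5] <- p[i == 4 | i == 5]
  b[i == 0 | i == 1] <- p[i == 0 | i == 1]; b[i == 2] <- tt[i == 2]; b[i == 5] <- q[i == 5]
  list(r = r, g = g, b = b)
}

# Vectorized RGB -> HSV on flat vectors in [0, 1].
.rgb2hsv_flat <- function(r, g, b) {
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  d <- mx - mn
  h <- numeric(length(r))
  nz <- d > 0
  im <- nz & (mx == r)
  h[im] <- ((g[im] - b[im]) / d[im]) %% 6
  im <- nz & (mx == g) & (mx != r)
  h[im] <- (b[im] - r[im]) / d[im] + 2
  im <- nz & (mx == b) & (mx != r) & (mx != g)
  h[im] <- (r[im] - g[im]) / d[im] + 4
  h <- h / 6
  s <- ifelse(mx > 0, d / mx, 0)
  list(h = h, s = s, v = mx)
}

# Smooth 2-D noise in [0, 1]^2 pixel space: bilinear upsampling of coarse
# Gaussian grids at two octaves.
.smooth_noise <- function(H, W, cells = 10L) {
  oct <- function(nc) {
    grid <- list(x = seq(0, 1, length.out = nc),
                 y = seq(0, 1, length.out = nc),
                 z = matrix(stats::rnorm(nc * nc), nc, nc))
    px <- (col(matrix(0, H, W)) - 0.5) / W
    py <- (row(matrix(0, H, W)) - 0.5) / H
    matrix(bilinear(grid, as.vector(px), as.vector(py)), H, W)
  }
  oct(cells) + 0.45 * oct(3L * cells)
}

# Render one tile; assumes the RNG is already seeded by the caller.
.render_tile <- function(veg_level, style) {
  H <- style$tile_size; W <- H
  yfrac <- (row(matrix(0, H, W)) - 0.5) / H   # 0 top -> 1 bottom
  horizon <- 0.40 + stats::runif(1, -0.05, 0.05)
  road_top <- 0.72 + stats::runif(1, -0.03, 0.03)
  r <- matrix(0, H, W); g <- matrix(0, H, W); b <- matrix(0, H, W)
  # sky with vertical gradient
  sky <- yfrac < horizon
  grad <- 1 - 0.35 * (yfrac / horizon)
  r[sky] <- (0.55 * grad[sky]); g[sky] <- (0.72 * grad[sky]); b[sky] <- (0.97 * grad[sky])
  # building band: facade colour + window grid texture
  band <- !sky & yfrac < road_top
  base <- stats::runif(1, 0.5, 0.75)
  tint <- stats::runif(2, 0.88, 1.0)
  win <- (sin(col(r) * stats::runif(1, 0.25, 0.5)) > 0.6) &
         (sin(row(r) * stats::runif(1, 0.35, 0.7)) > 0.55)
  fac <- base * ifelse(win, 0.55, 1) + matrix(stats::rnorm(H * W, 0, 0.02), H, W)
  r[band] <- fac[band]; g[band] <- (fac * tint[1])[band]; b[band] <- (fac * tint[2])[band]
  # a couple of extra facades for variety
  for (k in seq_len(1L + stats::rpois(1, 1))) {
    x0 <- stats::runif(1, 0, 0.8); wdt <- stats::runif(1, 0.12, 0.35)
    top <- stats::runif(1, 0.12, horizon)
    sel <- band & (col(r) / W) >= x0 & (col(r) / W) <= x0 + wdt & yfrac >= top
    shade <- stats::runif(1, 0.4, 0.8)
    r[sel] <- shade; g[sel] <- shade * stats::runif(1, 0.9, 1)
    b[sel] <- shade * stats::runif(1, 0.8, 1)
  }
  # road
  road <- yfrac >= road_top
  rg <- 0.33 + matrix(stats::rnorm(H * W, 0, 0.03), H, W)
  r[road] <- rg[road]; g[road] <- rg[road]; b[road] <- (rg * 1.03)[road]
  # vegetation canopy/bushes: thresholded smooth noise, exact target coverage
  f <- min(max(veg_level * style$veg_weight + stats::runif(1, -0.02, 0.02), 0), 0.85)
  if (style$veg_weight <= 0) f <- 0
  truth <- matrix(0L, H, W)
  if (f > 0) {
    S <- .smooth_noise(H, W)
    thr <- stats::quantile(S, 1 - f, names = FALSE)
    vm <- S >= thr
    nveg <- sum(vm)
    if (nveg > 0) {
      hue <- stats::runif(nveg, 0.26, 0.40)
      sat <- stats::runif(nveg, 0.55, 0.95)
      val <- pmin(pmax(0.30 + 0.35 * stats::runif(nveg) +
                         stats::rnorm(nveg, 0, style$veg_value_noise), 0.05), 1)
      cc <- .hsv2rgb(hue, sat, val)
      r[vm] <- cc$r; g[vm] <- cc$g; b[vm] <- cc$b
      truth[vm] <- 1L
    }
  }
  # man-made green confounders: smooth rectilinear patches, truth = 0
  if (stats::runif(1) < style$confounder_prob) {
    for (k in seq_len(1L + (stats::runif(1) < 0.3))) {
      wdt <- round(stats::runif(1, 0.10, 0.28) * W)
      hgt <- round(stats::runif(1, 0.08, 0.22) * H)
      x0 <- sample.int(W - wdt, 1L)
      y0 <- sample.int(H - hgt, 1L) + round(0.25 * H)
      y0 <- min(y0, H - hgt)
      rows <- y0:(y0 + hgt - 1L); cols <- x0:(x0 + wdt - 1L)
      cc <- .hsv2rgb(stats::runif(1, 0.28, 0.38), stats::runif(1, 0.5, 0.8),
                     stats::runif(1, 0.45, 0.7))
      np <- length(rows) * length(cols)
      r[rows, cols] <- cc$r + stats::rnorm(np, 0, 0.006)
      g[rows, cols] <- cc$g + stats::rnorm(np, 0, 0.006)
      b[rows, cols] <- cc$b + stats::rnorm(np, 0, 0.006)
      truth[rows, cols] <- 0L
    }
  }
  clamp <- function(m) pmin(pmax(m, 0), 1)
  pixels <- array(0, dim = c(H, W, 3))
  pixels[, , 1] <- clamp(r); pixels[, , 2] <- clamp(g); pixels[, , 3] <- clamp(b)
  list(pixels = pixels, truth_mask = truth)
}

#' Render the four-tile streetscape set at a sampling point
#'
#' Produces exactly four tiles at compass headings 0, 90, 180 and 270 degrees
#' (each a 90-degree field of view, together covering the full panorama),
#' with pixel rasters and exact ground-truth vegetation masks. The expected
#' vegetation fraction increases with the city's vegetation field at the
#' point; rendering is a pure function of `(point, city, style, seed)`.
#'
#' @param point numeric `c(x, y)` in meters, inside the city extent.
#' @param city a `gw_city`.
#' @param style a [render_config()].
#' @param seed integer seed.
#' @param point_id identifier stored on the tiles.
#' @return an object of class `gw_tileset` with elements `point_id`, `point`
#'   and `tiles` (list of four `gw_tile`).
#' @export
render_tileset <- function(point, city, style = render_config(), seed = 1L,
                           point_id = 1L) {
  stopifnot(inherits(city, "gw_city"), length(point) == 2L)
  ext <- city$extent
  if (point[1] < ext[1] || point[1] > ext[3] || point[2] < ext[2] || point[2] > ext[4]) {
    stop("point outside city extent")
  }
  v <- vegetation_at(city, point[1], point[2])
  headings <- c(0L, 90L, 180L, 270L)
  tiles <- lapply(headings, function(h) {
    tl <- with_seed(child_seed(seed, sprintf("tile_%d_%.2f_%.2f", h, point[1], point[2])),
                    .render_tile(v, style))
    structure(list(point_id = point_id, heading = h, pixels = tl$pixels,
                   truth_mask = tl$truth_mask), class = "gw_tile")
  })
  structure(list(point_id = point_id, point = as.numeric(point), tiles = tiles),
            class = "gw_tileset")
}

#' Pooled ground-truth green fraction of a tileset
#'
#' The green view index of the point computed from the truth masks: the sum
#' of vegetation pixels over the four tiles divided by the sum of all pixels
#' (pooled ratio, not a mean of per-tile ratios).
#'
#' @param ts a `gw_tileset`.
#' @return a value in `[0, 1]`.
#' @export
truth_green_fraction <- function(ts) {
  stopifnot(inherits(ts, "gw_tileset"))
  green <- sum(vapply(ts$tiles, function(t) sum(t$truth_mask), numeric(1)))
  total <- sum(vapply(ts$tiles, function(t) length(t$truth_mask), numeric(1)))
  green / total
}

#' Render a validation corpus of single tiles
#'
#' Renders `n` independent tiles whose vegetation levels span the field's
#' realistic range, for segmenter validation against the ground truth
#' (mirroring expert relabelling of a sample of images).
#'
#' @param n number of images.
#' @param style a [render_config()].
#' @param seed integer seed.
#' @param veg_range range of vegetation-field levels spanned.
#' @return list of `gw_tile`.
#' @export
render_corpus <- function(n = 50L, style = render_config(), seed = 1L,
                          veg_range = c(0.03, 0.8)) {
  stopifnot(n >= 1)
  levels <- seq(veg_range[1], veg_range[2], length.out = n)
  lapply(seq_len(n), function(i) {
    tl <- with_seed(child_seed(seed, paste0("corpus", i)),
                    .render_tile(levels[i], style))
    structure(list(point_id = i, heading = 0L, pixels = tl$pixels,
                   truth_mask = tl$truth_mask), class = "gw_tile")
  })
}

#' Interface stub for live street-level imagery retrieval
#'
#' Documents where a real street-imagery backend (e.g. a Street View API
#' client) would plug in: it must return the same four-heading tileset
#' contract as [render_tileset()]. Retrieval itself is out of scope and this
#' stub always errors.
#'
#' @param point numeric `c(x, y)`.
#' @param ... backend options (unused).
#' @export
fetch_gsv_tileset <- function(point, ...) {
  stop("live street-imagery retrieval is not implemented; ",
       "use render_tileset() for the synthetic backend", call. = FALSE)
}

#' Write a tileset as PNG files plus a manifest row set
#'
#' Writes each tile's pixels and truth mask as PNG (requires the `png`
#' package) and returns the manifest (point_id, heading, file paths).
#'
#' @param ts a `gw_tileset`.
#' @param dir output directory.
#' @return data.frame manifest, invisibly.
#' @export
write_tileset_png <- function(ts, dir) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the `png` package is required to write tiles")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(ts$tiles, function(t) {
    f1 <- file.path(dir, sprintf("p%s_h%03d.png", ts$point_id, t$heading))
    f2 <- file.path(dir, sprintf("p%s_h%03d_mask.png", ts$point_id, t$heading))
    png::writePNG(t$pixels, f1)
    png::writePNG(t$truth_mask * 1.0, f2)
    data.frame(point_id = ts$point_id, heading = t$heading,
               tile = f1, mask = f2)
  })
  invisible(do.call(rbind, rows))
}
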