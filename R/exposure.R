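# Buffer exposure assessment: sampling points every 50 m along street
# centerlines inside Euclidean-disk buffers around dwellings, a green view
# index per point (pooled vegetation-pixel fraction over the point's four
# tiles), and the unweighted mean over a buffer's points as the dwelling's
# neighbourhood exposure.

#' All street-centerline sampling points of a city
#'
#' Points are generated per edge at arc-length multiples of `spacing` from
#' the edge's start node (both endpoints included when the length divides
#' evenly); coincident points at shared nodes are deduplicated by rounding
#' coordinates to 0.01 m. Per-buffer sampling is the subset of these points
#' inside the buffer disk, so scoring each unique point once serves every
#' overlapping buffer.
#'
#' @param city a `gw_city`.
#' @param spacing arc-length spacing in meters (default 50).
#' @return data.frame `id`, `x`, `y`, `edge_id`.
#' @export
network_sampling_points <- function(city, spacing = 50) {
  stopifnot(inherits(city, "gw_city"), spacing > 0)
  e <- city$edges; nd <- city$nodes
  x1 <- nd$x[e$from]; y1 <- nd$y[e$from]
  x2 <- nd$x[e$to]; y2 <- nd$y[e$to]
  k <- floor(e$length / spacing)
  reps <- k + 1L
  eid <- rep.int(e$id, reps)
  tt <- unlist(lapply(seq_len(nrow(e)), function(i) seq(0, k[i]) * spacing), use.names = FALSE)
  frac <- tt / rep.int(e$length, reps)
  px <- rep.int(x1, reps) + frac * rep.int(x2 - x1, reps)
  py <- rep.int(y1, reps) + frac * rep.int(y2 - y1, reps)
  key <- paste(round(px, 2), round(py, 2))
  keep <- !duplicated(key)
  data.frame(id = seq_len(sum(keep)), x = px[keep], y = py[keep],
             edge_id = eid[keep])
}

#' Sampling points inside a circular buffer
#'
#' Street-centerline points at `spacing` intervals whose Euclidean distance
#' to `center` is at most `radius` (closed disk). Returns an empty frame when
#' no street point falls inside the buffer; the caller decides the policy for
#' such dwellings.
#'
#' @param city a `gw_city`.
#' @param center numeric `c(x, y)`.
#' @param radius buffer radius, meters (> 0).
#' @param spacing sampling spacing, meters (default 50).
#' @param points optional precomputed [network_sampling_points()] table.
#' @return data.frame `id`, `x`, `y`, `edge_id`, `dist`.
#' @export
sample_points <- function(city, center, radius, spacing = 50, points = NULL) {
  stopifnot(radius > 0, spacing > 0, length(center) == 2L)
  if (is.null(points)) points <- network_sampling_points(city, spacing)
  d <- sqrt((points$x - center[1])^2 + (points$y - center[2])^2)
  out <- points[d <= radius, , drop = FALSE]
  out$dist <- d[d <= radius]
  rownames(out) <- NULL
  out
}

#' Green view index of a point from predicted vegetation masks
#'
#' The pooled integer ratio over a point's four tiles: total predicted
#' vegetation pixels divided by total pixels. No per-tile averaging — when
#' tile sizes differ, the pooled ratio (not the mean of per-tile ratios) is
#' the index.
#'
#' @param ts a `gw_tileset`.
#' @param masks list of four `gw_mask` objects matching the tileset's tiles.
#' @return object of class `gw_gvi`: `point_id`, `value`, `greenery_pixels`,
#'   `total_pixels`.
#' @export
green_view_index <- function(ts, masks) {
  stopifnot(inherits(ts, "gw_tileset"), length(masks) == 4L)
  greenery <- 0; total <- 0
  for (i in seq_len(4L)) {
    tm <- ts$tiles[[i]]; mk <- masks[[i]]
    if (!identical(dim(tm$truth_mask), dim(mk$mask))) {
      stop("mask dimensions do not match tile dimensions")
    }
    greenery <- greenery + sum(mk$mask)
    total <- total + length(mk$mask)
  }
  structure(list(point_id = ts$point_id, value = greenery / total,
                 greenery_pixels = as.integer(greenery),
                 total_pixels = as.integer(total)),
            class = "gw_gvi")
}

#' Mean green view index over a buffer's sampling points
#'
#' The unweighted arithmetic mean of the point values. An empty input is the
#' missing-exposure signal: `NA` is returned and the participant should be
#' excluded downstream (the pipeline logs such exclusions).
#'
#' @param values numeric vector of per-point green view index values (or a
#'   list of `gw_gvi` objects).
#' @return mean value, or `NA_real_` for empty input.
#' @export
buffer_mean_gvi <- function(values) {
  if (is.list(values)) values <- vapply(values, function(v) v$value, numeric(1))
  if (length(values) == 0L) return(NA_real_)
  mean(values)
}

# Score unique sampling points by one of three methods:
#  - "field": ground-truth expected green fraction (vegetation field value);
#  - "truth": render the tileset and pool the truth masks (Eq-style ratio);
#  - "segmented": render, segment each tile, and pool the predicted masks.
.score_points <- function(city, pts, method, style, seg_params, seed) {
  if (method == "field") return(vegetation_at(city, pts$x, pts$y))
  vapply(seq_len(nrow(pts)), function(i) {
    ts <- render_tileset(c(pts$x[i], pts$y[i]), city, style,
                         seed = child_seed(seed, paste0("pt", pts$id[i])),
                         point_id = pts$id[i])
    if (method == "truth") {
      truth_green_fraction(ts)
    } else {
      masks <- lapply(ts$tiles, segment_vegetation, params = seg_params)
      green_view_index(ts, masks)$value
    }
  }, numeric(1))
}

#' Per-dwelling buffer-mean green view index
#'
#' Computes, for every dwelling and every buffer radius, the mean green view
#' index over the street sampling points inside the buffer. Each unique
#' network point is scored once and reused across overlapping buffers.
#'
#' @param city a `gw_city`.
#' @param dwellings data.frame with `id`, `x`, `y` (e.g. from
#'   [place_dwellings()]).
#' @param radii buffer radii in meters (default `c(400, 800)`).
#' @param method how points are scored: `"field"` (ground-truth vegetation
#'   field; fast, used for large cohorts), `"truth"` (rendered tiles, truth
#'   masks) or `"segmented"` (rendered tiles through the segmenter).
#' @param style,seg_params render and segmenter configurations (used by the
#'   rendering methods).
#' @param spacing sampling spacing, meters.
#' @param seed seed for the rendering methods.
#' @return data.frame `participant_id`, `radius`, `n_points`, `mean_gvi`
#'   (`NA` with `n_points = 0` marks missing exposure).
#' @export
compute_exposures <- function(city, dwellings, radii = c(400, 800),
                              method = c("field", "truth", "segmented"),
                              style = render_config(),
                              seg_params = segmenter_config(),
                              spacing = 50, seed = 1L) {
  method <- match.arg(method)
  stopifnot(all(radii > 0))
  pts <- network_sampling_points(city, spacing)
  rmax <- max(radii)
  # restrict scoring to points any buffer can reach
  if (method != "field" && nrow(dwellings) > 0) {
    nd <- nearest_dist(pts$x, pts$y, dwellings$x, dwellings$y)
    pts <- pts[nd <= rmax, , drop = FALSE]
  }
  score <- .score_points(city, pts, method, style, seg_params, seed)
  n <- nrow(dwellings)
  npt <- matrix(0L, n, length(radii))
  mg <- matrix(NA_real_, n, length(radii))
  chunk <- 500L
  for (s in seq(1L, max(n, 1L), by = chunk)) {
    if (n == 0L) break
    idx <- s:min(s + chunk - 1L, n)
    d2 <- outer(dwellings$x[idx], pts$x, "-")^2 +
          outer(dwellings$y[idx], pts$y, "-")^2
    for (ri in seq_along(radii)) {
      inb <- d2 <= radii[ri]^2
      cnt <- rowSums(inb)
      npt[idx, ri] <- cnt
      sums <- inb %*% score
      mg[idx, ri] <- ifelse(cnt > 0, sums / cnt, NA_real_)
    }
  }
  out <- lapply(seq_along(radii), function(ri) {
    data.frame(participant_id = dwellings$id, radius = radii[ri],
               n_points = npt[, ri], mean_gvi = mg[, ri])
  })
  do.call(rbind, out)
}

#' Export sampling points to GeoJSON
#'
#' @param points data.frame from [network_sampling_points()] or
#'   [sample_points()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_points_geojson <- function(points, path) {
  feats <- lapply(seq_len(nrow(points)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(points$x[i], points$y[i])),
         properties = list(id = points$id[i], edge_id = points$edge_id[i]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
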