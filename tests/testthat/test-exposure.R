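test_that("sampling points sit at 50 m arc-length multiples on each edge", {
  lc <- line_city(200)
  pts <- sample_points(lc, center = c(200, 500), radius = 400)
  expect_equal(nrow(pts), 5L)
  expect_equal(sort(pts$x), c(100, 150, 200, 250, 300))
  expect_true(all(pts$y == 500))
  # spacing honoured for a non-multiple length: 0..170 -> 0, 50, 100, 150
  lc2 <- line_city(170)
  pts2 <- sample_points(lc2, center = c(200, 500), radius = 400)
  expect_equal(sort(pts2$x - 100), c(0, 50, 100, 150))
})

test_that("a buffer that misses every street yields an empty set", {
  lc <- line_city(200)
  pts <- sample_points(lc, center = c(200, 100), radius = 300)
  expect_equal(nrow(pts), 0L)
})

test_that("growing the radius never loses sampling points", {
  city <- small_city()
  all_pts <- network_sampling_points(city)
  n_prev <- -1L
  for (r in c(100, 200, 400, 800)) {
    n_r <- nrow(sample_points(city, c(800, 800), r, points = all_pts))
    expect_gte(n_r, n_prev)
    n_prev <- n_r
  }
})

test_that("duplicate points at shared nodes are removed", {
  city <- small_city()
  pts <- network_sampling_points(city)
  key <- paste(round(pts$x, 2), round(pts$y, 2))
  expect_false(any(duplicated(key)))
})

test_that("the green view index is the pooled integer ratio", {
  mk <- function(nveg, H = 100) {
    m <- matrix(0L, H, H); if (nveg > 0) m[seq_len(nveg)] <- 1L
    structure(list(point_id = 1L, heading = 0L, mask = m), class = "gw_mask")
  }
  ts <- make_tileset(replicate(4, matrix(0L, 100, 100), simplify = FALSE))
  gvi <- green_view_index(ts, list(mk(1000), mk(2000), mk(0), mk(1000)))
  expect_identical(gvi$value, 4000 / 40000)
  expect_identical(gvi$greenery_pixels, 4000L)
  expect_identical(green_view_index(ts, list(mk(0), mk(0), mk(0), mk(0)))$value, 0)
  # mismatched mask dimensions are a domain error
  bad <- mk(10, H = 50)
  expect_error(green_view_index(ts, list(bad, mk(0), mk(0), mk(0))),
               "dimensions")
})

test_that("pooling differs from averaging per-tile ratios for unequal tiles", {
  m_small <- matrix(1L, 10, 10)                  # 100/100
  m_large <- matrix(0L, 20, 20); m_large[1] <- 1L  # 1/400
  ts <- make_tileset(list(m_small, m_large, matrix(0L, 20, 20), matrix(0L, 20, 20)))
  masks <- lapply(ts$tiles, function(t)
    structure(list(point_id = 1L, heading = t$heading, mask = t$truth_mask),
              class = "gw_mask"))
  pooled <- green_view_index(ts, masks)$value
  per_tile_mean <- mean(c(1, 1 / 400, 0, 0))
  expect_equal(pooled, 101 / 1300)
  expect_false(isTRUE(all.equal(pooled, per_tile_mean)))
})

test_that("buffer means are unweighted and flag empty buffers as missing", {
  expect_equal(buffer_mean_gvi(c(0.2, 0.4)), 0.3)
  expect_equal(buffer_mean_gvi(0.7), 0.7)
  expect_equal(buffer_mean_gvi(rep(0.123, 9)), 0.123)
  expect_true(is.na(buffer_mean_gvi(numeric(0))))
  vals <- c(0.1, 0.5, 0.2)
  expect_true(buffer_mean_gvi(vals) >= min(vals) && buffer_mean_gvi(vals) <= max(vals))
})

test_that("truth-mask pipeline equals the mean ground-truth fraction exactly", {
  city <- small_city()
  dw <- place_dwellings(city, 3, seed = 4)
  style <- render_config(tile_size = 32)
  ex <- compute_exposures(city, dw, radii = 250, method = "truth",
                          style = style, seed = 99)
  pts <- network_sampling_points(city)
  for (i in seq_len(3)) {
    inb <- sample_points(city, c(dw$x[i], dw$y[i]), 250, points = pts)
    fr <- vapply(seq_len(nrow(inb)), function(k) {
      ts <- render_tileset(c(inb$x[k], inb$y[k]), city, style,
                           seed = greenwalk:::child_seed(99, paste0("pt", inb$id[k])),
                           point_id = inb$id[k])
      truth_green_fraction(ts)
    }, numeric(1))
    expect_equal(ex$mean_gvi[i], mean(fr), tolerance = 1e-12)
    expect_equal(ex$n_points[i], nrow(inb))
  }
})

test_that("exposure means at two radii are positively correlated", {
  city <- small_city()
  dw <- place_dwellings(city, 80, seed = 6)
  ex <- compute_exposures(city, dw, radii = c(200, 400), method = "field")
  wide <- merge(ex[ex$radius == 200, c("participant_id", "mean_gvi")],
                ex[ex$radius == 400, c("participant_id", "mean_gvi")],
                by = "participant_id")
  expect_gt(cor(wide$mean_gvi.x, wide$mean_gvi.y), 0.5)
})
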