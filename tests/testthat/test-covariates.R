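test_that("entropy land-use mix matches its closed form and bounds", {
  expect_equal(entropy_landuse_mix(c(1, 1, 1) / 3), 1.0)
  expect_equal(entropy_landuse_mix(c(1, 0, 0)), 0.0)
  expect_equal(entropy_landuse_mix(c(0.5, 0.5, 0)), log(2) / log(3))
  expect_error(entropy_landuse_mix(c(-0.1, 0.6, 0.5)), "negative")
  expect_error(entropy_landuse_mix(c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("vif matches the explicit least-squares oracle and flags collinearity", {
  with_seed_helper(3, {
    # orthogonal columns: both VIFs 1
    X0 <- cbind(a = rep(c(-1, 1), 50), b = rep(c(-1, -1, 1, 1), 25))
    expect_equal(unname(vif(X0)), c(1, 1), tolerance = 1e-12)
    # correlated columns vs brute-force 1 / (1 - R^2) via normal equations
    n <- 500
    z <- rnorm(n)
    X <- cbind(x1 = z + rnorm(n, 0, 0.8), x2 = z + rnorm(n, 0, 0.8),
               x3 = rnorm(n))
    v <- vif(X)
    for (k in 1:3) {
      A <- cbind(1, X[, -k])
      bhat <- solve(crossprod(A), crossprod(A, X[, k]))
      res <- X[, k] - A %*% bhat
      r2 <- 1 - sum(res^2) / sum((X[, k] - mean(X[, k]))^2)
      expect_equal(unname(v[k]), 1 / (1 - r2), tolerance = 1e-10)
    }
    # duplicated column -> infinite, with a diagnostic naming it
    Xd <- cbind(X, x1_copy = X[, "x1"])
    expect_warning(vd <- vif(Xd), "x1")
    expect_true(is.infinite(vd["x1_copy"]))
  })
})

test_that("z-scoring uses the sample sd and is idempotent and shift-invariant", {
  d <- data.frame(a = c(1, 2, 3), b = c(10, 30, 20))
  z <- standardize(d)
  expect_equal(z$a, c(-1, 0, 1))
  expect_equal(mean(z$b), 0, tolerance = 1e-12)
  expect_equal(sd(z$b), 1, tolerance = 1e-12)
  expect_equal(attr(z, "gw_center")[["a"]], 2)
  # shift invariance
  z2 <- standardize(data.frame(a = d$a + 100))
  expect_equal(z2$a, z$a)
  # z of z = z
  zz <- standardize(data.frame(a = z$a))
  expect_equal(zz$a, z$a)
  expect_error(standardize(data.frame(const = rep(4, 5))), "const")
})

test_that("buffer covariates honour limiting cases", {
  city <- small_city()
  # dwelling exactly at a rail station
  st <- city$amenities$rail_stations[1, ]
  dw <- data.frame(id = 1L, x = st$x, y = st$y)
  cv <- buffer_covariates(dw, city, 300)
  expect_equal(cv$dist_mtr, 0)
  # a city with no shops reports zero everywhere
  city0 <- generate_city(small_city_config(n_shops = 0), seed = 2)
  dw0 <- place_dwellings(city0, 5, seed = 1)
  expect_true(all(buffer_covariates(dw0, city0, 400)$n_shops == 0))
  # a disk covering the whole extent recovers the citywide land-use entropy
  center <- data.frame(id = 1L, x = 800, y = 800)
  cv_all <- buffer_covariates(center, city, radius = 2600)
  shares <- tabulate(city$parcels$type, 3L) / city$parcels$n^2
  expect_equal(cv_all$landuse_mix, entropy_landuse_mix(shares), tolerance = 1e-9)
})

test_that("counts and area-based covariates are monotone in the radius", {
  city <- small_city()
  dw <- place_dwellings(city, 20, seed = 7)
  prev <- NULL
  for (r in c(150, 300, 600)) {
    cv <- buffer_covariates(dw, city, r)
    if (!is.null(prev)) {
      for (col in c("n_shops", "n_recreation", "n_bus_stops")) {
        expect_true(all(cv[[col]] >= prev[[col]]))
      }
      expect_equal(cv$dist_mtr, prev$dist_mtr)  # not capped at the radius
    }
    expect_true(all(cv$landuse_mix >= 0 & cv$landuse_mix <= 1))
    expect_true(all(cv$pop_density >= 0))
    prev <- cv
  }
})

test_that("covariates are deterministic functions of city and dwelling", {
  city <- small_city()
  dw <- place_dwellings(city, 10, seed = 8)
  expect_identical(buffer_covariates(dw, city, 400),
                   buffer_covariates(dw, city, 400))
})
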