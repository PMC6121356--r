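test_that("cohort composition reproduces the survey margins", {
  city <- small_city()
  n <- 20000
  dw <- place_dwellings(city, n, seed = 1)
  coh <- simulate_cohort(city, n, cohort_margins(1L), seed = 2, dwellings = dw)
  expect_equal(mean(coh$age_band == "5-17"), 0.152, tolerance = 0.05)
  expect_equal(mean(coh$gender == "female"), 0.519, tolerance = 0.02)
  expect_equal(mean(coh$income_band == "medium_low"), 0.423, tolerance = 0.03)
  m2 <- cohort_margins(2L)
  expect_equal(sum(m2$income), 1)
  expect_equal(unname(m2$gender["female"]), 0.565)
})

test_that("invalid and degenerate margins behave as specified", {
  city <- small_city()
  bad <- cohort_margins(1L); bad$age <- bad$age * 2
  expect_error(simulate_cohort(city, 10, bad, seed = 1), "probability")
  degen <- list(age = c(`5-17` = 0, `18-44` = 1, `45-64` = 0, `65+` = 0),
                gender = c(male = 1, female = 0),
                income = c(low = 1, medium_low = 0, medium_high = 0, high = 0))
  coh <- simulate_cohort(city, 50, degen, seed = 3)
  expect_true(all(coh$age_band == "18-44"))
  expect_true(all(coh$gender == "male"))
})

test_that("a null generating model walks half the cohort", {
  with_seed_helper(4, {
    n <- 20000
    X <- matrix(rnorm(n * 16), n, 16, dimnames = list(NULL, greenwalk:::.gw_terms))
    gm <- gm_walk("400", icc = 1e-9, intercept = 0,
                  coefficients = setNames(rep(0, 16), greenwalk:::.gw_terms))
    walked <- simulate_walk_decision(X, rep(1:20, each = n / 20), gm, seed = 5)
    expect_equal(mean(walked), 0.5, tolerance = 0.02)
  })
})

test_that("with no block variance, block rates show only binomial noise", {
  with_seed_helper(6, {
    n <- 24000; J <- 40
    X <- matrix(0, n, 16, dimnames = list(NULL, greenwalk:::.gw_terms))
    gm <- gm_walk("400", icc = 1e-12, intercept = -0.4,
                  coefficients = setNames(rep(0, 16), greenwalk:::.gw_terms))
    g <- rep(seq_len(J), each = n / J)
    walked <- simulate_walk_decision(X, g, gm, seed = 7)
    rates <- tapply(walked, g, mean)
    p <- mean(walked)
    ratio <- var(rates) / (p * (1 - p) / (n / J))   # binomial oracle
    expect_gt(ratio, 0.5)
    expect_lt(ratio, 1.8)
  })
})

test_that("the generating green-view effect is the stated odds ratio", {
  with_seed_helper(8, {
    n <- 60000
    X <- matrix(0, n, 16, dimnames = list(NULL, greenwalk:::.gw_terms))
    X[, "gvi"] <- rnorm(n)
    cf <- setNames(rep(0, 16), greenwalk:::.gw_terms)
    cf["gvi"] <- log(1.149)
    gm <- gm_walk("400", icc = 1e-12, intercept = 0, coefficients = cf)
    walked <- simulate_walk_decision(X, rep(1:2, n / 2), gm, seed = 9)
    est <- glm(walked ~ X[, "gvi"], family = binomial())$coefficients[2]
    expect_equal(unname(exp(est)), 1.149, tolerance = 0.03)
  })
})

test_that("missing predictors are reported with the offending row", {
  X <- matrix(0, 4, 16, dimnames = list(NULL, greenwalk:::.gw_terms))
  X[3, "gvi"] <- NA
  gm <- gm_walk("400")
  expect_error(simulate_walk_decision(X, rep(1:2, 2), gm, seed = 1), "row 3")
  expect_error(simulate_walk_decision(X[, 1:10], rep(1:2, 2), gm, seed = 1),
               "missing terms")
})

test_that("walking-time simulation has the specified variance structure", {
  n <- 4000
  X <- matrix(0, n, 16, dimnames = list(NULL, greenwalk:::.gw_terms))
  g <- rep(1:40, each = 100)
  cf0 <- setNames(rep(0, 16), greenwalk:::.gw_terms)
  # no variance at all: constant minutes
  gm0 <- gm_walktime("400", icc = 0, intercept = 0.2, coefficients = cf0)
  gm0$sigma_b <- 0; gm0$sigma_e <- 0
  sim0 <- simulate_walk_time(X, g, gm0, seed = 2)
  expect_true(all(sim0$minutes == sim0$minutes[1]))
  expect_equal(sim0$n_floored, 0L)
  # doubling sigma_e doubles the residual sd of y given x
  gm1 <- gm_walktime("400", coefficients = cf0); gm1$sigma_b <- 0; gm1$sigma_e <- 0.5
  gm2 <- gm_walktime("400", coefficients = cf0); gm2$sigma_b <- 0; gm2$sigma_e <- 1.0
  s1 <- sd(simulate_walk_time(X, g, gm1, seed = 3)$y_std)
  s2 <- sd(simulate_walk_time(X, g, gm2, seed = 3)$y_std)
  expect_equal(s2 / s1, 2, tolerance = 0.05)
  # the 1-minute floor is logged
  gmf <- gm_walktime("400", coefficients = cf0, minutes_center = 1.5,
                     minutes_scale = 30)
  simf <- simulate_walk_time(X, g, gmf, seed = 4)
  expect_equal(simf$n_floored, sum(1.5 + 30 * simf$y_std < 1))
  expect_true(all(simf$minutes >= 1))
})

test_that("gender-specific generating slopes imply the effect-coded pair", {
  gm <- gm_walk("800", male_or = 1.181, female_or = 1.235)
  expect_equal(unname(gm$coefficients["gvi"] + 0.5 * gm$coefficients["gvi_x_gender"]),
               log(1.235))
  expect_equal(unname(gm$coefficients["gvi"] - 0.5 * gm$coefficients["gvi_x_gender"]),
               log(1.181))
})

test_that("simulation is reproducible and seeds give distinct replicates", {
  city <- small_city()
  coh1 <- simulate_cohort(city, 100, seed = 11)
  coh2 <- simulate_cohort(city, 100, seed = 11)
  expect_identical(coh1, coh2)
  X <- matrix(rnorm(1600), 100, 16, dimnames = list(NULL, greenwalk:::.gw_terms))
  gm <- gm_walk("400")
  w1 <- simulate_walk_decision(X, coh1$block_id, gm, seed = 1)
  expect_identical(w1, simulate_walk_decision(X, coh1$block_id, gm, seed = 1))
  expect_false(identical(w1, simulate_walk_decision(X, coh1$block_id, gm, seed = 2)))
})
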