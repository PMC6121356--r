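# Toy fixture shared across the quadrature checks: 2 groups x 3 observations.
toy_logistic <- function() {
  X <- cbind(`(Intercept)` = 1, x = c(-1, 0, 1, -0.5, 0.5, 1.5))
  list(X = X, y = c(0, 1, 1, 0, 0, 1), g = rep(1:2, each = 3))
}

test_that("adaptive GHQ reproduces brute-force integration to 1e-6", {
  toy <- toy_logistic()
  gh <- gauss_hermite(15)
  for (theta in list(c(0.2, 0.5, log(0.8)), c(-0.4, 1.2, log(0.3)),
                     c(0, 0, log(2)))) {
    ev <- greenwalk:::.ghq_eval(theta, toy$X, toy$y, toy$g, 2L, gh,
                                rep(0, 2), grad = FALSE)
    ref <- grid_marginal_loglik(toy$X, toy$y, toy$g, theta[1:2], exp(theta[3]))
    expect_equal(-ev$nll, ref, tolerance = 1e-6)
  }
})

test_that("quadrature order is converged: K = 15 vs K = 51 within 1e-6", {
  toy <- toy_logistic()
  theta <- c(0.3, 0.7, log(0.9))
  e15 <- greenwalk:::.ghq_eval(theta, toy$X, toy$y, toy$g, 2L,
                               gauss_hermite(15), rep(0, 2), grad = FALSE)
  e51 <- greenwalk:::.ghq_eval(theta, toy$X, toy$y, toy$g, 2L,
                               gauss_hermite(51), rep(0, 2), grad = FALSE)
  expect_equal(e15$nll, e51$nll, tolerance = 1e-6)
})

test_that("Gauss-Hermite rule integrates exp(-x^2) moments exactly", {
  gh <- gauss_hermite(7)
  expect_equal(sum(gh$weights), sqrt(pi), tolerance = 1e-12)
  expect_equal(sum(gh$weights * gh$nodes^2), sqrt(pi) / 2, tolerance = 1e-12)
  expect_equal(sum(gh$weights * gh$nodes^12),
               sqrt(pi) * prod(seq(11, 1, by = -2)) / 2^6, tolerance = 1e-8)
})

test_that("sigma_u = 0 reduces to plain logistic regression (IRLS oracle)", {
  with_seed_helper(12, {
    n <- 400
    X <- cbind(`(Intercept)` = 1, x1 = rnorm(n), x2 = rbinom(n, 1, 0.4))
    y <- rbinom(n, 1, plogis(-0.3 + 0.8 * X[, 2] - 0.5 * X[, 3]))
    fit <- fit_logistic_ri(X, y, rep(1:20, each = 20), sigma_fixed = 0)
    oracle <- irls_logistic(X, y)
    expect_equal(fit$coefficients$estimate, unname(oracle), tolerance = 1e-7)
    gfit <- glm.fit(X, y, family = binomial())
    expect_equal(fit$coefficients$estimate, unname(gfit$coefficients),
                 tolerance = 1e-7)
    expect_equal(fit$sigma_u, 0)
    expect_equal(fit$icc, 0)
  })
})

test_that("sigma_b = 0 reduces to ordinary least squares (normal equations)", {
  with_seed_helper(13, {
    n <- 300
    X <- cbind(`(Intercept)` = 1, x = rnorm(n))
    y <- 1 + 0.5 * X[, 2] + rnorm(n)
    fit <- fit_linear_ri(X, y, rep(1:10, each = 30), sigma_b_fixed = 0)
    bhat <- drop(solve(crossprod(X), crossprod(X, y)))
    expect_equal(fit$coefficients$estimate, unname(bhat), tolerance = 1e-10)
  })
})

test_that("balanced one-way design matches closed-form ML variance components", {
  with_seed_helper(14, {
    J <- 12; m <- 8; n <- J * m
    g <- rep(1:J, each = m)
    y <- 0.3 + rnorm(J, 0, 0.7)[g] + rnorm(n, 0, 1.1)
    fit <- fit_linear_ri(matrix(1, n, 1, dimnames = list(NULL, "mu")), y, g)
    ybar <- mean(y); ybj <- tapply(y, g, mean)
    SSW <- sum((y - ybj[g])^2); SSB <- m * sum((ybj - ybar)^2)
    s2e <- SSW / (n - J); s2b <- (SSB / J - s2e) / m
    expect_equal(fit$coefficients$estimate, ybar, tolerance = 1e-7)
    expect_equal(fit$sigma_e^2, s2e, tolerance = 1e-6)
    expect_equal(fit$sigma_b^2, s2b, tolerance = 1e-5)
  })
})

test_that("both fitters agree with lme4 maximum likelihood", {
  skip_if_not_installed("lme4")
  with_seed_helper(15, {
    n <- 1500; J <- 40
    g <- sample(1:J, n, TRUE)
    X <- cbind(`(Intercept)` = 1, x1 = rnorm(n), x2 = rnorm(n))
    b <- rnorm(J, 0, 0.6)
    y <- rbinom(n, 1, plogis(-0.2 + 0.5 * X[, 2] - 0.4 * X[, 3] + b[g]))
    fit <- fit_logistic_ri(X, y, g)
    ref <- lme4::glmer(y ~ X[, 2] + X[, 3] + (1 | g), family = binomial,
                       nAGQ = 15)
    expect_equal(fit$coefficients$estimate, unname(lme4::fixef(ref)),
                 tolerance = 1e-4)
    expect_equal(fit$sigma_u, sqrt(unname(unlist(lme4::VarCorr(ref)))),
                 tolerance = 1e-3)
    expect_equal(fit$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-6)
    yl <- 0.3 + 0.2 * X[, 2] + rnorm(J, 0, 0.5)[g] + rnorm(n)
    fl <- fit_linear_ri(X, yl, g)
    rl <- lme4::lmer(yl ~ X[, 2] + X[, 3] + (1 | g), REML = FALSE)
    expect_equal(fl$coefficients$estimate, unname(lme4::fixef(rl)),
                 tolerance = 1e-6)
    expect_equal(fl$coefficients$se, unname(sqrt(diag(as.matrix(stats::vcov(rl))))),
                 tolerance = 1e-4)
  })
})

test_that("information criteria identities hold exactly", {
  with_seed_helper(16, {
    n <- 200; g <- rep(1:10, each = 20)
    X <- cbind(`(Intercept)` = 1, x = rnorm(n))
    y <- rbinom(n, 1, plogis(0.3 * X[, 2] + rnorm(10, 0, 0.5)[g]))
    fit <- fit_logistic_ri(X, y, g, se = FALSE)
    expect_identical(fit$npar, 3L)
    expect_equal(fit$aic, 2 * fit$npar - 2 * fit$loglik)
    expect_equal(fit$bic, fit$npar * log(fit$n_obs) - 2 * fit$loglik)
    yl <- rnorm(n)
    fl <- fit_linear_ri(X, yl, g)
    expect_equal(fl$aic, 2 * fl$npar - 2 * fl$loglik)
    expect_equal(fl$bic, fl$npar * log(fl$n_obs) - 2 * fl$loglik)
  })
})

test_that("intraclass correlations follow the stated conventions", {
  fake_bin <- function(s) structure(list(family = "binomial", sigma_u = s),
                                    class = "gw_fit")
  fake_gau <- function(sb, se) structure(list(family = "gaussian", sigma_b = sb,
                                              sigma_e = se), class = "gw_fit")
  expect_equal(icc(fake_bin(0)), 0)
  expect_equal(icc(fake_bin(pi / sqrt(3))), 0.5)
  expect_equal(icc(fake_gau(1, 1)), 0.5)
  expect_equal(icc(fake_gau(0, 2)), 0)
})

test_that("larger generating block variance yields larger fitted ICC", {
  with_seed_helper(17, {
    n <- 1800; J <- 60
    g <- rep(1:J, each = n / J)
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
    mean_icc <- vapply(c(0.2, 0.55, 1.0), function(s) {
      mean(vapply(1:2, function(r) {
        b <- rnorm(J, 0, s)
        y <- rbinom(n, 1, plogis(-0.2 + b[g]))
        fit_logistic_ri(X, y, g, se = FALSE)$icc
      }, numeric(1)))
    }, numeric(1))
    expect_true(all(diff(mean_icc) > 0))
  })
})

test_that("simple slopes match a re-parameterized refit (delta-method oracle)", {
  with_seed_helper(18, {
    n <- 2500; J <- 50
    g <- sample(1:J, n, TRUE)
    gvi <- rnorm(n)
    genderF <- sample(c(-0.5, 0.5), n, TRUE)
    b <- rnorm(J, 0, 0.4)
    eta <- -0.2 + 0.25 * gvi + 0.3 * genderF + 0.15 * gvi * genderF + b[g]
    y <- rbinom(n, 1, plogis(eta))
    X <- cbind(`(Intercept)` = 1, gvi = gvi, genderF = genderF,
               gvi_x_gender = gvi * genderF)
    fit <- fit_logistic_ri(X, y, g)
    ss <- simple_slopes(fit)
    expect_equal(ss$estimate[ss$stratum == "female"],
                 fit$coefficients$estimate[2] + 0.5 * fit$coefficients$estimate[4])
    # recode so the female stratum is the reference: gvi main = female slope
    X2 <- cbind(`(Intercept)` = 1, gvi = gvi, genderF = genderF,
                gvi_x_gender = gvi * (genderF - 0.5))
    fit2 <- fit_logistic_ri(X2, y, g)
    expect_equal(ss$estimate[ss$stratum == "female"],
                 fit2$coefficients$estimate[2], tolerance = 1e-4)
    expect_equal(ss$se[ss$stratum == "female"],
                 fit2$coefficients$se[2], tolerance = 1e-3)
    # a model without the interaction cannot be stratified
    fit0 <- fit_linear_ri(X[, 1:2], rnorm(n), g)
    expect_error(simple_slopes(fit0), "interaction")
  })
})

test_that("zero interaction collapses both strata onto the main effect", {
  with_seed_helper(19, {
    n <- 800; g <- rep(1:20, each = 40)
    X <- cbind(`(Intercept)` = 1, gvi = rnorm(n),
               genderF = sample(c(-0.5, 0.5), n, TRUE))
    X <- cbind(X, gvi_x_gender = X[, "gvi"] * X[, "genderF"])
    y <- 0.4 * X[, "gvi"] + rnorm(20, 0, 0.3)[g] + rnorm(n)
    fit <- fit_linear_ri(X, y, g)
    fit$coefficients$estimate[4] <- 0  # null interaction by construction
    ss <- simple_slopes(fit)
    expect_equal(ss$estimate[1], ss$estimate[2])
    expect_equal(ss$estimate[1], fit$coefficients$estimate[2])
  })
})

test_that("fit results print and export coherently", {
  with_seed_helper(20, {
    n <- 300; g <- rep(1:15, each = 20)
    X <- cbind(`(Intercept)` = 1, x = rnorm(n))
    y <- rbinom(n, 1, plogis(0.4 * X[, 2]))
    fit <- fit_logistic_ri(X, y, g)
    expect_output(print(fit), "random-intercept")
    tab <- format_fit_table(fit)
    expect_true(any(grepl("AIC", tab)))
    expect_equal(sum(grepl("^x ", tab)), 1L)
    cf <- fit$coefficients
    expect_true(all(cf$ci_lo <= cf$estimate & cf$estimate <= cf$ci_hi))
    f <- withr::local_tempfile(fileext = ".json")
    write_fit_json(fit, f)
    expect_equal(jsonlite::read_json(f)$family, "binomial")
  })
})
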