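# Random-intercept regression implemented from scratch.
#
# Logistic: the marginal likelihood  prod_j int prod_i Bernoulli(y_ij |
# plogis(x_ij' beta + b)) phi(b; 0, sigma_u^2) db  is maximized by adaptive
# Gauss-Hermite quadrature: for each group the integrand is re-centered at
# its mode and re-scaled by the curvature there, so a modest number of nodes
# (default K = 15) is accurate even with hundreds of observations per group.
# The gradient uses the Fisher identity — the score of the marginal
# log-likelihood equals the posterior expectation of the complete-data score
# — evaluated with the same quadrature rule.
#
# Gaussian: profiled maximum likelihood over the variance ratio
# lambda = sigma_b^2 / sigma_e^2, with closed-form GLS for beta given lambda
# (Woodbury inverse per group) and closed-form sigma_e^2 given beta; the
# profile deviance is a smooth 1-D function of log(lambda).

.as_group_index <- function(groups) {
  f <- factor(groups)
  list(g = as.integer(f), J = nlevels(f), levels = levels(f))
}

.group_sum <- function(v, g, J) {
  out <- numeric(J)
  rs <- rowsum(v, g)
  out[as.integer(rownames(rs))] <- rs
  out
}

# One evaluation of the adaptive-GHQ marginal negative log-likelihood and
# its gradient at theta = c(beta, log sigma). Returns a list; warm starts
# the inner mode search from `b0`.
.ghq_eval <- function(theta, X, y, g, J, gh, b0, grad = TRUE) {
  p <- ncol(X)
  beta <- theta[seq_len(p)]
  sig <- exp(theta[p + 1L])
  sig2 <- sig^2
  eta0 <- drop(X %*% beta)
  b <- b0
  # inner Newton for the per-group posterior mode (log-concave: safe)
  for (it in seq_len(50L)) {
    pr <- stats::plogis(eta0 + b[g])
    gb <- .group_sum(y - pr, g, J) - b / sig2
    hb <- -(.group_sum(pr * (1 - pr), g, J) + 1 / sig2)
    step <- gb / hb
    step <- pmin(pmax(step, -4), 4)
    b <- b - step
    if (max(abs(gb)) < 1e-9) break
  }
  pr <- stats::plogis(eta0 + b[g])
  hb <- .group_sum(pr * (1 - pr), g, J) + 1 / sig2
  tau <- 1 / sqrt(hb)
  K <- length(gh$nodes)
  term <- matrix(0, J, K)
  P <- if (grad) matrix(0, length(y), K) else NULL
  BK <- matrix(0, J, K)
  s2t <- sqrt(2) * tau
  for (k in seq_len(K)) {
    bk <- b + s2t * gh$nodes[k]
    BK[, k] <- bk
    eta <- eta0 + bk[g]
    lp <- stats::plogis(eta, log.p = TRUE)
    lq <- stats::plogis(-eta, log.p = TRUE)
    llg <- .group_sum(y * lp + (1 - y) * lq, g, J)
    term[, k] <- llg + stats::dnorm(bk, 0, sig, log = TRUE) +
      log(gh$weights[k]) + gh$nodes[k]^2 + log(s2t)
    if (grad) P[, k] <- exp(lp)
  }
  logLg <- row_logsumexp(term)
  nll <- -sum(logLg)
  out <- list(nll = nll, b = b)
  if (grad) {
    om <- exp(term - logLg)            # posterior node weights per group
    r <- rowSums((y - P) * om[g, , drop = FALSE])
    gbeta <- -drop(crossprod(X, r))
    glsig <- -sum(om * (BK^2 / sig2 - 1))
    out$grad <- c(gbeta, glsig)
  }
  out
}

# Plain logistic regression by Newton-Raphson (the sigma_u = 0 reduction).
.logistic_newton <- function(X, y, tol = 1e-10, maxit = 50L) {
  p <- ncol(X)
  beta <- rep(0, p)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X, X * w)
    sc <- crossprod(X, y - mu)
    step <- solve(H, sc)
    beta <- beta + step
    if (max(abs(sc)) < tol) break
  }
  eta <- drop(X %*% beta)
  ll <- sum(y * stats::plogis(eta, log.p = TRUE) +
              (1 - y) * stats::plogis(-eta, log.p = TRUE))
  mu <- stats::plogis(eta)
  vc <- solve(crossprod(X, X * (mu * (1 - mu))))
  list(beta = beta, loglik = ll, vcov = vc, converged = it < maxit)
}

.fit_result <- function(family, terms, est, se, sigma, loglik, npar, n, J,
                        converged, vcov, extra = list()) {
  z <- est / se
  pval <- 2 * stats::pnorm(-abs(z))
  ci_lo <- est - stats::qnorm(0.975) * se
  ci_hi <- est + stats::qnorm(0.975) * se
  coefs <- data.frame(term = terms, estimate = est, se = se, z = z, p = pval,
                      ci_lo = ci_lo, ci_hi = ci_hi, row.names = NULL)
  if (family == "binomial") {
    coefs$or <- exp(est); coefs$or_lo <- exp(ci_lo); coefs$or_hi <- exp(ci_hi)
  }
  res <- c(list(family = family, coefficients = coefs, loglik = loglik,
                aic = 2 * npar - 2 * loglik, bic = npar * log(n) - 2 * loglik,
                npar = npar, n_obs = n, n_groups = J, converged = converged,
                vcov = vcov), sigma, extra)
  class(res) <- "gw_fit"
  res
}

#' Random-intercept logistic regression via adaptive Gauss-Hermite quadrature
#'
#' Maximizes the marginal likelihood of a logistic model with a Gaussian
#' random intercept per group, using mode-centered curvature-scaled
#' Gauss-Hermite quadrature with `K` nodes, a quasi-Newton optimizer on
#' `(beta, log sigma_u)` with the exact (Fisher-identity) score, and
#' standard errors from the observed information at the optimum. Odds ratios
#' and Wald 95% intervals are reported on the exponential scale.
#'
#' @param X design matrix including an intercept column.
#' @param y 0/1 response.
#' @param groups grouping factor (street block).
#' @param K number of quadrature nodes (default 15).
#' @param sigma_fixed optionally constrain `sigma_u`: `0` reduces the fit to
#'   plain logistic regression; a positive value fixes the SD.
#' @param se compute standard errors (finite differences of the analytic
#'   score; skip for speed inside replicate loops).
#' @param max_restarts quasi-Newton restarts from perturbed starts on
#'   non-convergence.
#' @return a `gw_fit` with coefficients, `sigma_u`, log-likelihood, AIC/BIC,
#'   latent-threshold ICC, convergence flag, `n_obs`, `n_groups`.
#' @export
fit_logistic_ri <- function(X, y, groups, K = 15L, sigma_fixed = NULL,
                            se = TRUE, max_restarts = 3L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(y)
  if (anyNA(X) || anyNA(y)) stop("missing values in design or response")
  if (!all(y %in% c(0, 1))) stop("y must be 0/1")
  p <- ncol(X)
  n <- length(y)
  gi <- .as_group_index(groups)
  if (!is.null(sigma_fixed) && sigma_fixed == 0) {
    fit <- .logistic_newton(X, y)
    sev <- sqrt(diag(fit$vcov))
    return(.fit_result("binomial", colnames(X), fit$beta, sev, list(sigma_u = 0),
                       fit$loglik, p, n, gi$J, fit$converged, fit$vcov,
                       extra = list(icc = 0, K = K)))
  }
  if (gi$J < 2L) stop("grouping factor must have >= 2 levels")
  degenerate <- all(y == 0) || all(y == 1)
  if (degenerate) {
    warning("degenerate response (all 0 or all 1): ",
            "maximum likelihood estimates are unbounded; fit flagged")
    max_restarts <- 0L
  }
  gh <- gauss_hermite(K)
  start_beta <- tryCatch(
    suppressWarnings(stats::glm.fit(X, y, family = stats::binomial())$coefficients),
    error = function(e) rep(0, p))
  start_beta[!is.finite(start_beta)] <- 0
  fixed_sig <- !is.null(sigma_fixed)
  cache <- new.env(parent = emptyenv())
  cache$b <- rep(0, gi$J)
  cache$theta <- NULL
  eval_at <- function(theta_full) {
    if (!is.null(cache$theta) && isTRUE(all.equal(cache$theta, theta_full,
                                                  tolerance = 0)) &&
        !is.null(cache$res)) return(cache$res)
    res <- .ghq_eval(theta_full, X, y, gi$g, gi$J, gh, cache$b)
    cache$b <- res$b
    cache$theta <- theta_full
    cache$res <- res
    res
  }
  if (fixed_sig) {
    lsig0 <- log(sigma_fixed)
    fn <- function(th) eval_at(c(th, lsig0))$nll
    gr <- function(th) eval_at(c(th, lsig0))$grad[seq_len(p)]
    par0 <- start_beta
  } else {
    fn <- function(th) eval_at(th)$nll
    gr <- function(th) eval_at(th)$grad
    par0 <- c(start_beta, log(0.4))
  }
  best <- NULL
  conv <- FALSE
  for (attempt in 0:max(max_restarts, 0L)) {
    par_try <- if (attempt == 0) par0 else
      par0 + stats::rnorm(length(par0), 0, 0.05 * attempt)
    opt <- stats::optim(par_try, fn, gr, method = "BFGS",
                        control = list(maxit = 400, reltol = 1e-12))
    if (is.null(best) || opt$value < best$value) best <- opt
    gnorm <- max(abs(gr(opt$par)))
    if (opt$convergence == 0 && gnorm < 1e-3 * max(1, abs(opt$value))) {
      best <- opt; conv <- TRUE; break
    }
  }
  if (degenerate) conv <- FALSE
  theta <- unname(if (fixed_sig) c(best$par, log(sigma_fixed)) else best$par)
  sig <- exp(theta[p + 1L])
  loglik <- -eval_at(theta)$nll
  npar <- p + if (fixed_sig) 0L else 1L
  vc <- matrix(NA_real_, p, p)
  sev <- rep(NA_real_, p)
  sigma_se <- NA_real_
  if (se) {
    free <- if (fixed_sig) seq_len(p) else seq_len(p + 1L)
    m <- length(free)
    Hn <- matrix(0, m, m)
    for (j in seq_len(m)) {
      h <- 1e-4 * max(1, abs(theta[free[j]]))
      tp <- theta; tp[free[j]] <- tp[free[j]] + h
      tm <- theta; tm[free[j]] <- tm[free[j]] - h
      gp <- .ghq_eval(tp, X, y, gi$g, gi$J, gh, cache$b)$grad[free]
      gm <- .ghq_eval(tm, X, y, gi$g, gi$J, gh, cache$b)$grad[free]
      Hn[, j] <- (gp - gm) / (2 * h)
    }
    Hn <- (Hn + t(Hn)) / 2
    vc_full <- tryCatch(solve(Hn), error = function(e) matrix(NA_real_, m, m))
    vc <- vc_full[seq_len(p), seq_len(p), drop = FALSE]
    sev <- sqrt(pmax(diag(vc), 0))
    if (!fixed_sig && all(is.finite(vc_full))) {
      # delta method: var(sigma) = sigma^2 var(log sigma)
      sigma_se <- sig * sqrt(max(vc_full[p + 1L, p + 1L], 0))
    }
  }
  dimnames(vc) <- list(colnames(X), colnames(X))
  .fit_result("binomial", colnames(X), theta[seq_len(p)], sev,
              list(sigma_u = sig, sigma_u_se = sigma_se), loglik, npar, n,
              gi$J, conv, vc,
              extra = list(icc = sig^2 / (sig^2 + pi^2 / 3), K = K))
}

#' Random-intercept linear regression by profiled maximum likelihood
#'
#' Fits `y = X beta + u_group + e` with `u ~ N(0, sigma_b^2)`,
#' `e ~ N(0, sigma_e^2)` by maximizing the profile (restricted, if
#' `reml = TRUE`) likelihood over the variance ratio
#' `lambda = sigma_b^2 / sigma_e^2`; `beta` is the closed-form GLS solution
#' given `lambda` and `sigma_e^2` is closed-form given `beta`. ML is the
#' default so AIC/BIC are comparable across fixed-effect specifications.
#'
#' @param X design matrix including an intercept column.
#' @param y continuous response.
#' @param groups grouping factor.
#' @param reml use REML instead of ML.
#' @param sigma_b_fixed optionally constrain `sigma_b`; `0` reduces to
#'   ordinary least squares.
#' @return a `gw_fit` with coefficients (standardized betas when `X` and `y`
#'   are standardized), `sigma_b`, `sigma_e`, log-likelihood, AIC/BIC,
#'   variance-ratio ICC and convergence flag.
#' @export
fit_linear_ri <- function(X, y, groups, reml = FALSE, sigma_b_fixed = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(y)
  if (anyNA(X) || anyNA(y)) stop("missing values in design or response")
  p <- ncol(X)
  n <- length(y)
  gi <- .as_group_index(groups)
  g <- gi$g; J <- gi$J
  nj <- tabulate(g, nbins = J)
  XtX <- crossprod(X)
  Sx <- rowsum(X, g)                      # J x p group sums (ordered 1..J)
  Sx_full <- matrix(0, J, p); Sx_full[as.integer(rownames(Sx)), ] <- Sx
  Sy <- .group_sum(y, g, J)
  Xty <- crossprod(X, y)
  prof <- function(llam) {
    lam <- exp(llam)
    cj <- lam / (1 + nj * lam)
    XtVX <- XtX - crossprod(Sx_full * sqrt(cj))
    XtVy <- Xty - crossprod(Sx_full, cj * Sy)
    beta <- solve(XtVX, XtVy)
    r <- y - drop(X %*% beta)
    Sr <- .group_sum(r, g, J)
    Q <- sum(r^2) - sum(cj * Sr^2)
    ldet <- sum(log1p(nj * lam))
    if (reml) {
      sig2 <- Q / (n - p)
      m2ll <- (n - p) * log(2 * pi * sig2) + ldet +
        determinant(XtVX, logarithm = TRUE)$modulus[1] + (n - p)
    } else {
      sig2 <- Q / n
      m2ll <- n * log(2 * pi * sig2) + ldet + n
    }
    list(m2ll = as.numeric(m2ll), beta = drop(beta), sig2 = sig2,
         XtVX = XtVX, lam = lam)
  }
  if (!is.null(sigma_b_fixed) && sigma_b_fixed == 0) {
    beta <- drop(solve(XtX, Xty))
    r <- y - drop(X %*% beta)
    sig2 <- sum(r^2) / n
    ll <- -0.5 * (n * log(2 * pi * sig2) + n)
    vc <- sig2 * solve(XtX)
    sev <- sqrt(diag(vc))
    return(.fit_result("gaussian", colnames(X), beta, sev,
                       list(sigma_b = 0, sigma_e = sqrt(sig2)), ll, p + 1L,
                       n, J, TRUE, vc, extra = list(icc = 0, reml = reml)))
  }
  if (J < 2L || all(nj <= 1L)) {
    stop("grouping is singular for a free random intercept ",
         "(need >= 2 groups and at least one group with > 1 observation)")
  }
  opt <- stats::optimize(function(l) prof(l)$m2ll, interval = c(-14, 10),
                         tol = 1e-10)
  llam <- opt$minimum
  # boundary check: OLS (lambda -> 0) may beat the interior point
  at0 <- prof(-40)
  sol <- if (at0$m2ll < opt$objective) at0 else prof(llam)
  lam <- if (at0$m2ll < opt$objective) 0 else sol$lam
  sig2e <- sol$sig2
  sig2b <- lam * sig2e
  vc <- sig2e * solve(sol$XtVX)
  sev <- sqrt(diag(vc))
  ll <- -sol$m2ll / 2
  dimnames(vc) <- list(colnames(X), colnames(X))
  .fit_result("gaussian", colnames(X), sol$beta, sev,
              list(sigma_b = sqrt(sig2b), sigma_e = sqrt(sig2e)), ll,
              p + 2L, n, J, TRUE, vc,
              extra = list(icc = lam / (1 + lam), reml = reml))
}

#' Intraclass correlation of a fitted model
#'
#' Gaussian: `sigma_b^2 / (sigma_b^2 + sigma_e^2)`. Binomial-logit:
#' latent-threshold convention `sigma_u^2 / (sigma_u^2 + pi^2 / 3)`.
#'
#' @param fit a `gw_fit`.
#' @return ICC in `[0, 1]`.
#' @export
icc <- function(fit) {
  stopifnot(inherits(fit, "gw_fit"))
  if (fit$family == "binomial") {
    fit$sigma_u^2 / (fit$sigma_u^2 + pi^2 / 3)
  } else {
    fit$sigma_b^2 / (fit$sigma_b^2 + fit$sigma_e^2)
  }
}

#' Simple-slopes post-hoc contrasts for an interaction model
#'
#' Stratum-specific slope of the focal predictor at each moderator level:
#' `slope = beta_main + w * beta_interaction` with the moderator's coding
#' weight `w`, standard errors by the delta method from the coefficient
#' covariance, and (for logistic fits) odds ratios with Wald intervals.
#'
#' @param fit a `gw_fit` whose model contains `main` and `interaction`.
#' @param main name of the focal predictor term.
#' @param interaction name of the interaction term.
#' @param weights named vector of moderator coding weights per stratum
#'   (default effect-coded gender: male -1/2, female +1/2).
#' @return data.frame with one row per stratum: estimate, se, Wald CI,
#'   p-value, and `or`/`or_lo`/`or_hi` for logistic fits.
#' @export
simple_slopes <- function(fit, main = "gvi", interaction = "gvi_x_gender",
                          weights = c(male = -0.5, female = 0.5)) {
  stopifnot(inherits(fit, "gw_fit"))
  terms <- fit$coefficients$term
  if (!(main %in% terms) || !(interaction %in% terms)) {
    stop("moderator interaction not in model: need terms `", main,
         "` and `", interaction, "`")
  }
  bm <- fit$coefficients$estimate[terms == main]
  bi <- fit$coefficients$estimate[terms == interaction]
  V <- fit$vcov
  vm <- V[main, main]; vi <- V[interaction, interaction]
  cmi <- V[main, interaction]
  out <- lapply(names(weights), function(s) {
    w <- weights[[s]]
    est <- bm + w * bi
    sev <- sqrt(vm + w^2 * vi + 2 * w * cmi)
    z <- est / sev
    data.frame(stratum = s, estimate = est, se = sev,
               ci_lo = est - 1.96 * sev, ci_hi = est + 1.96 * sev,
               p = 2 * stats::pnorm(-abs(z)))
  })
  out <- do.call(rbind, out)
  if (fit$family == "binomial") {
    out$or <- exp(out$estimate)
    out$or_lo <- exp(out$ci_lo); out$or_hi <- exp(out$ci_hi)
  }
  out
}

#' @export
print.gw_fit <- function(x, ...) {
  cat(sprintf("<gw_fit> %s random-intercept model | n = %d, groups = %d%s\n",
              x$family, x$n_obs, x$n_groups,
              if (isTRUE(x$converged)) "" else " [NOT CONVERGED]"))
  cf <- x$coefficients
  if (x$family == "binomial") {
    tab <- data.frame(term = cf$term, OR = round(cf$or, 3),
                      `2.5%` = round(cf$or_lo, 3), `97.5%` = round(cf$or_hi, 3),
                      p = signif(cf$p, 3), check.names = FALSE)
  } else {
    tab <- data.frame(term = cf$term, beta = round(cf$estimate, 3),
                      `2.5%` = round(cf$ci_lo, 3), `97.5%` = round(cf$ci_hi, 3),
                      p = signif(cf$p, 3), check.names = FALSE)
  }
  print(tab, row.names = FALSE)
  sig <- if (x$family == "binomial") sprintf("sigma_u = %.3f", x$sigma_u)
         else sprintf("sigma_b = %.3f, sigma_e = %.3f", x$sigma_b, x$sigma_e)
  cat(sprintf("%s | ICC = %.3f | logLik = %.1f | AIC = %.0f | BIC = %.0f\n",
              sig, x$icc, x$loglik, x$aic, x$bic))
  invisible(x)
}

#' Format a fit as a publication-style text table
#'
#' One row per fitted term with OR (or beta), 95% CI and p-value, plus a
#' footer with AIC, BIC and -2 log-likelihood.
#'
#' @param fit a `gw_fit`.
#' @return character vector of table lines.
#' @export
format_fit_table <- function(fit) {
  cf <- fit$coefficients
  if (fit$family == "binomial") {
    body <- sprintf("%-22s %6.3f (%.3f, %.3f)  p=%s", cf$term, cf$or,
                    cf$or_lo, cf$or_hi, format.pval(cf$p, digits = 3))
    head <- sprintf("%-22s %s", "Term", "OR (95% CI)")
  } else {
    body <- sprintf("%-22s %6.3f (%.3f, %.3f)  p=%s", cf$term, cf$estimate,
                    cf$ci_lo, cf$ci_hi, format.pval(cf$p, digits = 3))
    head <- sprintf("%-22s %s", "Term", "beta (95% CI)")
  }
  foot <- sprintf("AIC = %.0f  BIC = %.0f  -2LL = %.0f", fit$aic, fit$bic,
                  -2 * fit$loglik)
  c(head, body, foot)
}

#' Write a fit result to JSON
#'
#' @param fit a `gw_fit`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_fit_json <- function(fit, path) {
  out <- list(family = fit$family, coefficients = fit$coefficients,
              loglik = fit$loglik, aic = fit$aic, bic = fit$bic,
              icc = fit$icc, n_obs = fit$n_obs, n_groups = fit$n_groups,
              converged = fit$converged)
  if (fit$family == "binomial") out$sigma_u <- fit$sigma_u
  else { out$sigma_b <- fit$sigma_b; out$sigma_e <- fit$sigma_e }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
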