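# End-to-end orchestration: city -> exposures -> covariates -> standardized
# design -> simulated outcomes -> multilevel fits -> report, plus the
# replicate parameter-recovery loops used to check that the pipeline
# recovers the generating coefficients.

#' Run configuration
#'
#' @param seed top-level seed; fully determines every artifact of a run.
#' @param n cohort size for the walking-decision analysis.
#' @param n_walkers size of the walking-time subsample of walkers.
#' @param city a [city_config()].
#' @param radii buffer radii in meters (positive, distinct).
#' @param exposure_method see [compute_exposures()].
#' @param style,seg render / segmenter configurations.
#' @param icc_walk,icc_time generating null-model intraclass correlations.
#' @param spacing sampling-point spacing, meters.
#' @param K quadrature nodes for the logistic fits.
#' @param blocks optional block subset for dwelling placement.
#' @return a `gw_run_config` list.
#' @export
run_config <- function(seed = 1L, n = 24773L, n_walkers = 1994L,
                       city = city_config(), radii = c(400, 800),
                       exposure_method = "field", style = render_config(),
                       seg = segmenter_config(), icc_walk = 0.079,
                       icc_time = 0.160, spacing = 50, K = 15L,
                       blocks = NULL) {
  stopifnot(all(radii > 0), !anyDuplicated(radii), n >= 1)
  structure(list(seed = seed, n = n, n_walkers = n_walkers, city = city,
                 radii = radii, exposure_method = exposure_method,
                 style = style, seg = seg, icc_walk = icc_walk,
                 icc_time = icc_time, spacing = spacing, K = K,
                 blocks = blocks),
            class = "gw_run_config")
}

#' Build the dwelling-level study design base
#'
#' Generates the city, places dwellings, and computes exposures and buffer
#' covariates at every radius. This is the expensive, geography-level stage;
#' demographics and outcomes are drawn on top of it per replicate.
#'
#' @param cfg a [run_config()].
#' @return list with `city`, `dwellings`, `exposures`, `covariates` (list by
#'   radius), `radii`.
#' @export
build_study_design <- function(cfg) {
  stopifnot(inherits(cfg, "gw_run_config"))
  city <- generate_city(cfg$city, seed = cfg$seed)
  dwellings <- place_dwellings(city, cfg$n, seed = cfg$seed, blocks = cfg$blocks)
  exposures <- compute_exposures(city, dwellings, radii = cfg$radii,
                                 method = cfg$exposure_method,
                                 style = cfg$style, seg_params = cfg$seg,
                                 spacing = cfg$spacing, seed = cfg$seed)
  covariates <- lapply(cfg$radii, function(r) buffer_covariates(dwellings, city, r))
  names(covariates) <- as.character(cfg$radii)
  list(city = city, dwellings = dwellings, exposures = exposures,
       covariates = covariates, radii = cfg$radii, config = cfg)
}

# Continuous covariate columns, in model-term order.
.gw_cont_terms <- c("gvi", "pop_density", "landuse_mix", "intersection_density",
                    "n_shops", "n_recreation", "n_bus_stops", "dist_mtr")

#' Build the standardized fixed-effect design matrix
#'
#' Z-scores the continuous predictors (green view index and the seven
#' built-environment covariates) on the analysis sample, encodes age and
#' income bands as dummies against the youngest / lowest reference, gender
#' as effect-coded (-1/2 male, +1/2 female), and adds the green view index x
#' gender interaction. No intercept column is included.
#'
#' @param data data.frame with `mean_gvi`, the covariate columns of
#'   [buffer_covariates()], and factors `age_band`, `gender`, `income_band`.
#' @return numeric matrix with the model-term columns.
#' @export
build_design_matrix <- function(data) {
  raw <- data.frame(gvi = data$mean_gvi,
                    pop_density = data$pop_density,
                    landuse_mix = data$landuse_mix,
                    intersection_density = data$intersection_density,
                    n_shops = data$n_shops, n_recreation = data$n_recreation,
                    n_bus_stops = data$n_bus_stops, dist_mtr = data$dist_mtr)
  zd <- standardize(raw, cols = .gw_cont_terms)
  genderF <- ifelse(data$gender == "female", 0.5, -0.5)
  age <- as.character(data$age_band)
  inc <- as.character(data$income_band)
  X <- cbind(as.matrix(zd),
             age18_44 = as.numeric(age == "18-44"),
             age45_64 = as.numeric(age == "45-64"),
             age65p = as.numeric(age == "65+"),
             genderF = genderF,
             income_ml = as.numeric(inc == "medium_low"),
             income_mh = as.numeric(inc == "medium_high"),
             income_high = as.numeric(inc == "high"),
             gvi_x_gender = zd$gvi * genderF)
  X[, .gw_terms, drop = FALSE]
}

#' Assemble the analysis table for one radius
#'
#' Joins cohort demographics with the radius's exposures and covariates,
#' drops participants with missing exposure (empty buffers; the count is
#' reported), and builds the standardized design matrix on the retained
#' sample.
#'
#' @param base output of [build_study_design()].
#' @param radius one of the base's radii.
#' @param cohort demographics from [simulate_cohort()] on the base's
#'   dwellings.
#' @return list `X`, `block_id`, `data`, `n_excluded`.
#' @export
analysis_design <- function(base, radius, cohort) {
  ex <- base$exposures[base$exposures$radius == radius, ]
  cv <- base$covariates[[as.character(radius)]]
  df <- merge(cohort, ex[, c("participant_id", "n_points", "mean_gvi")],
              by.x = "dwelling_id", by.y = "participant_id")
  df <- merge(df, cv[, setdiff(names(cv), "radius")],
              by.x = "dwelling_id", by.y = "participant_id")
  df <- df[order(df$id), ]
  keep <- !is.na(df$mean_gvi)
  n_excluded <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  list(X = build_design_matrix(df), block_id = df$block_id, data = df,
       n_excluded = n_excluded)
}

#' Run the walking-decision analysis
#'
#' Full pipeline for the multilevel logistic analysis: simulate the cohort,
#' simulate walking decisions from the buffer-specific generating model, fit
#' the random-intercept logistic model per radius, and report odds ratios,
#' the null-model ICC, VIFs of the continuous predictors, and exclusions.
#'
#' @param cfg a [run_config()].
#' @param base optional precomputed [build_study_design()] output.
#' @param gms optional list of generating models by radius (defaults to the
#'   published per-buffer sets via [gm_walk()]).
#' @return object of class `gw_analysis1`.
#' @export
run_analysis1 <- function(cfg = run_config(), base = NULL, gms = NULL) {
  if (is.null(base)) base <- build_study_design(cfg)
  cohort <- simulate_cohort(base$city, cfg$n, cohort_margins(1L),
                            seed = cfg$seed, dwellings = base$dwellings)
  per_radius <- list()
  for (r in cfg$radii) {
    key <- as.character(r)
    buffer <- if (r <= 600) "400" else "800"
    gm <- if (!is.null(gms)) gms[[key]] else gm_walk(buffer, icc = cfg$icc_walk)
    d <- analysis_design(base, r, cohort)
    walked <- simulate_walk_decision(d$X, d$block_id, gm,
                                     seed = child_seed(cfg$seed, paste0("a1_", key)))
    Xi <- cbind(`(Intercept)` = 1, d$X)
    fit <- fit_logistic_ri(Xi, walked, d$block_id, K = cfg$K)
    null_fit <- fit_logistic_ri(matrix(1, length(walked), 1,
                                       dimnames = list(NULL, "(Intercept)")),
                                walked, d$block_id, K = cfg$K, se = FALSE)
    vifs <- vif(d$X[, .gw_cont_terms])
    per_radius[[key]] <- list(radius = r, gm = gm, design = d, walked = walked,
                              fit = fit, null_icc = icc(null_fit), vif = vifs,
                              n_excluded = d$n_excluded,
                              table = format_fit_table(fit))
  }
  structure(list(config = cfg, base = base, cohort = cohort,
                 per_radius = per_radius),
            class = "gw_analysis1")
}

#' Run the walking-time analysis
#'
#' Restricts to walkers from a walking-decision run, subsamples to the
#' target walker count, re-standardizes predictors on the walker subsample,
#' simulates standardized walking times from the buffer-specific generating
#' model, and fits the random-intercept linear model per radius.
#'
#' @param a1 a `gw_analysis1` result.
#' @param gms optional list of generating models by radius (defaults to
#'   [gm_walktime()] per buffer).
#' @return object of class `gw_analysis2`.
#' @export
run_analysis2 <- function(a1, gms = NULL) {
  stopifnot(inherits(a1, "gw_analysis1"))
  cfg <- a1$config
  per_radius <- list()
  for (key in names(a1$per_radius)) {
    pr <- a1$per_radius[[key]]
    buffer <- if (pr$radius <= 600) "400" else "800"
    walkers <- which(pr$walked == 1L)
    if (length(walkers) == 0L) {
      stop("no walkers in the ", key, " m analysis: walking-time model cannot be fit")
    }
    if (length(walkers) > cfg$n_walkers) {
      walkers <- with_seed(child_seed(cfg$seed, paste0("a2sub_", key)),
                           sort(sample(walkers, cfg$n_walkers)))
    }
    df <- pr$design$data[walkers, , drop = FALSE]
    if (length(unique(df$block_id)) < 2L) {
      stop("fewer than 2 blocks among walkers at ", key, " m")
    }
    X <- build_design_matrix(df)
    gm <- if (!is.null(gms)) gms[[key]] else gm_walktime(buffer, icc = cfg$icc_time)
    sim <- simulate_walk_time(X, df$block_id, gm,
                              seed = child_seed(cfg$seed, paste0("a2_", key)))
    Xi <- cbind(`(Intercept)` = 1, X)
    fit <- fit_linear_ri(Xi, sim$y_std, df$block_id)
    null_fit <- fit_linear_ri(matrix(1, nrow(df), 1,
                                     dimnames = list(NULL, "(Intercept)")),
                              sim$y_std, df$block_id)
    per_radius[[key]] <- list(radius = pr$radius, gm = gm, walkers = df,
                              X = X, y = sim$y_std, minutes = sim$minutes,
                              n_floored = sim$n_floored, fit = fit,
                              null_icc = icc(null_fit),
                              table = format_fit_table(fit))
  }
  structure(list(config = cfg, per_radius = per_radius),
            class = "gw_analysis2")
}

#' @export
print.gw_analysis1 <- function(x, ...) {
  for (key in names(x$per_radius)) {
    pr <- x$per_radius[[key]]
    cat(sprintf("== Walking decision, %s m buffer (n = %d, excluded %d, null ICC %.3f) ==\n",
                key, pr$fit$n_obs, pr$n_excluded, pr$null_icc))
    cat(pr$table, sep = "\n")
    cat(sprintf("max VIF (continuous predictors): %.2f\n\n", max(pr$vif)))
  }
  invisible(x)
}

#' @export
print.gw_analysis2 <- function(x, ...) {
  for (key in names(x$per_radius)) {
    pr <- x$per_radius[[key]]
    cat(sprintf("== Walking time, %s m buffer (n = %d walkers, null ICC %.3f) ==\n",
                key, pr$fit$n_obs, pr$null_icc))
    cat(pr$table, sep = "\n")
    cat("\n")
  }
  invisible(x)
}

#' Replicate parameter recovery for the walking-decision model
#'
#' For each replicate: redraw demographics on the fixed geography, simulate
#' walking decisions from `gm`, fit the random-intercept logistic model, and
#' record the green-view-index coefficient, its exponent (odds ratio), the
#' derived female-stratum simple slope, and the fitted ICC.
#'
#' @param base a [build_study_design()] output.
#' @param radius which radius to analyse.
#' @param gm generating model from [gm_walk()].
#' @param nrep number of replicates.
#' @param seed integer seed.
#' @param margins cohort composition (default analysis-1 margins).
#' @param K quadrature nodes.
#' @return data.frame with one row per replicate: `gvi_coef`, `gvi_or`,
#'   `female_or`, `male_or`, `icc`, `sigma_u`, `converged`.
#' @export
recover_walk <- function(base, radius, gm, nrep = 20L, seed = 1L,
                         margins = cohort_margins(1L), K = 15L) {
  out <- vector("list", nrep)
  for (r in seq_len(nrep)) {
    s <- child_seed(seed, paste0("rep", r))
    cohort <- simulate_cohort(base$city, nrow(base$dwellings), margins,
                              seed = s, dwellings = base$dwellings)
    d <- analysis_design(base, radius, cohort)
    walked <- simulate_walk_decision(d$X, d$block_id, gm,
                                     seed = child_seed(s, "y"))
    Xi <- cbind(`(Intercept)` = 1, d$X)
    fit <- fit_logistic_ri(Xi, walked, d$block_id, K = K, se = FALSE)
    cf <- fit$coefficients
    b_gvi <- cf$estimate[cf$term == "gvi"]
    b_int <- cf$estimate[cf$term == "gvi_x_gender"]
    out[[r]] <- data.frame(gvi_coef = b_gvi, gvi_or = exp(b_gvi),
                           female_or = exp(b_gvi + 0.5 * b_int),
                           male_or = exp(b_gvi - 0.5 * b_int),
                           icc = fit$icc, sigma_u = fit$sigma_u,
                           converged = fit$converged)
  }
  do.call(rbind, out)
}

#' Replicate parameter recovery for the walking-time model
#'
#' For each replicate: redraw walker demographics on the fixed geography,
#' simulate standardized walking times from `gm`, fit the random-intercept
#' linear model, and record the green-view-index coefficient and fitted ICC.
#'
#' @inheritParams recover_walk
#' @param gm generating model from [gm_walktime()].
#' @param margins cohort composition (default analysis-2 margins).
#' @return data.frame with one row per replicate: `gvi_beta`, `icc`,
#'   `sigma_b`, `sigma_e`.
#' @export
recover_walktime <- function(base, radius, gm, nrep = 20L, seed = 1L,
                             margins = cohort_margins(2L)) {
  out <- vector("list", nrep)
  for (r in seq_len(nrep)) {
    s <- child_seed(seed, paste0("trep", r))
    cohort <- simulate_cohort(base$city, nrow(base$dwellings), margins,
                              seed = s, dwellings = base$dwellings)
    d <- analysis_design(base, radius, cohort)
    sim <- simulate_walk_time(d$X, d$block_id, gm, seed = child_seed(s, "y"))
    Xi <- cbind(`(Intercept)` = 1, d$X)
    fit <- fit_linear_ri(Xi, sim$y_std, d$block_id)
    cf <- fit$coefficients
    out[[r]] <- data.frame(gvi_beta = cf$estimate[cf$term == "gvi"],
                           icc = fit$icc, sigma_b = fit$sigma_b,
                           sigma_e = fit$sigma_e)
  }
  do.call(rbind, out)
}

#' Write an exposure or covariate table to CSV
#'
#' @param table data.frame (e.g. from [compute_exposures()] or
#'   [buffer_covariates()]).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_exposure_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Null-model intraclass-correlation recovery
#'
#' Simulates intercept-only outcomes on a given block structure with the
#' block variance set by a target ICC (latent-threshold for binomial,
#' variance-ratio for gaussian), fits the null random-intercept model per
#' replicate, and returns the fitted ICCs.
#'
#' @param block_id integer block membership vector (defines n and groups).
#' @param icc_target generating intraclass correlation in `(0, 1)`.
#' @param family `"binomial"` or `"gaussian"`.
#' @param nrep number of replicates.
#' @param seed integer seed.
#' @param intercept fixed intercept of the null generating model (log-odds
#'   for binomial, standardized mean for gaussian).
#' @param K quadrature nodes for the binomial fits.
#' @return numeric vector of fitted ICCs, one per replicate.
#' @export
recover_null_icc <- function(block_id, icc_target,
                             family = c("binomial", "gaussian"), nrep = 20L,
                             seed = 1L, intercept = if (family == "binomial") -0.6 else 0,
                             K = 15L) {
  family <- match.arg(family)
  n <- length(block_id)
  blocks <- sort(unique(block_id))
  j <- match(block_id, blocks)
  Xi <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  vapply(seq_len(nrep), function(r) {
    with_seed(child_seed(seed, paste0("icc", family, r)), {
      if (family == "binomial") {
        sig_u <- sqrt(icc_target / (1 - icc_target) * pi^2 / 3)
        b <- stats::rnorm(length(blocks), 0, sig_u)
        y <- stats::rbinom(n, 1L, stats::plogis(intercept + b[j]))
        fit <- fit_logistic_ri(Xi, y, block_id, K = K, se = FALSE)
      } else {
        u <- stats::rnorm(length(blocks), 0, sqrt(icc_target))
        y <- intercept + u[j] + stats::rnorm(n, 0, sqrt(1 - icc_target))
        fit <- fit_linear_ri(Xi, y, block_id)
      }
      icc(fit)
    })
  }, numeric(1))
}
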