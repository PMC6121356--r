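# Simulated walking outcomes with the exact statistical structure of the two
# multilevel analyses: a random-intercept logistic model for the decision to
# walk and a random-intercept linear model for (standardized) total walking
# time among walkers. Generating fixed effects default to published
# coefficient sets so that model fitting becomes a parameter-recovery
# exercise.

# Fixed-effect term order shared by the design builder and the generators.
.gw_terms <- c("gvi", "pop_density", "landuse_mix", "intersection_density",
               "n_shops", "n_recreation", "n_bus_stops", "dist_mtr",
               "age18_44", "age45_64", "age65p", "genderF",
               "income_ml", "income_mh", "income_high", "gvi_x_gender")

# Published odds-ratio sets for the walking-decision model (per buffer).
.or_walk <- list(
  `400` = c(gvi = 1.149, pop_density = 1.050, landuse_mix = 1.039,
            intersection_density = 1.031, n_shops = 1.056,
            n_recreation = 1.008, n_bus_stops = 0.997, dist_mtr = 1.090,
            age18_44 = 0.354, age45_64 = 0.551, age65p = 1.763,
            genderF = 1.585, income_ml = 0.806, income_mh = 0.675,
            income_high = 0.555, gvi_x_gender = 1.070),
  `800` = c(gvi = 1.193, pop_density = 1.047, landuse_mix = 1.020,
            intersection_density = 1.003, n_shops = 1.191,
            n_recreation = 1.000, n_bus_stops = 0.948, dist_mtr = 1.095,
            age18_44 = 0.354, age45_64 = 0.551, age65p = 1.760,
            genderF = 1.585, income_ml = 0.806, income_mh = 0.675,
            income_high = 0.554, gvi_x_gender = 1.091))

# Published standardized-beta sets for the walking-time model (per buffer).
.beta_time <- list(
  `400` = c(gvi = 0.149, pop_density = 0.007, landuse_mix = 0.048,
            intersection_density = 0.055, n_shops = -0.017,
            n_recreation = 0.017, n_bus_stops = 0.061, dist_mtr = -0.004,
            age18_44 = -0.021, age45_64 = 0.097, age65p = 0.043,
            genderF = 0.057, income_ml = -0.110, income_mh = -0.245,
            income_high = -0.365, gvi_x_gender = 0.072),
  `800` = c(gvi = 0.233, pop_density = -0.042, landuse_mix = 0.006,
            intersection_density = 0.133, n_shops = 0.022,
            n_recreation = -0.100, n_bus_stops = 0.068, dist_mtr = 0.012,
            age18_44 = -0.022, age45_64 = 0.101, age65p = 0.057,
            genderF = 0.056, income_ml = -0.120, income_mh = -0.242,
            income_high = -0.376, gvi_x_gender = 0.075))

# Published gender-stratified green-view-index odds ratios (post-hoc).
.or_posthoc <- list(`400` = c(male = 1.127, female = 1.176),
                    `800` = c(male = 1.181, female = 1.235))

#' Cohort composition margins
#'
#' Marginal distributions of age band, gender and household income band for
#' the full walking-decision sample (`analysis = 1`, n = 24,773) or the
#' walking-time subsample of walkers (`analysis = 2`, n = 1,994). Income
#' shares are renormalized to sum exactly to 1.
#'
#' @param analysis 1 or 2.
#' @return list of named probability vectors `age`, `gender`, `income`.
#' @export
cohort_margins <- function(analysis = 1L) {
  m <- if (analysis == 1L) {
    list(age = c(`5-17` = 0.152, `18-44` = 0.382, `45-64` = 0.319, `65+` = 0.147),
         gender = c(male = 0.481, female = 0.519),
         income = c(low = 0.252, medium_low = 0.423, medium_high = 0.228,
                    high = 0.098))
  } else if (analysis == 2L) {
    list(age = c(`5-17` = 0.172, `18-44` = 0.298, `45-64` = 0.330, `65+` = 0.200),
         gender = c(male = 0.435, female = 0.565),
         income = c(low = 0.298, medium_low = 0.408, medium_high = 0.227,
                    high = 0.067))
  } else stop("analysis must be 1 or 2")
  lapply(m, function(v) v / sum(v))
}

.sigma_u_from_icc <- function(icc) sqrt(icc / (1 - icc) * pi^2 / 3)

#' Generating model for the walking-decision analysis
#'
#' Log-odds fixed effects on the standardized design (defaults: the
#' published per-buffer odds-ratio set, log-transformed), a street-block
#' random-intercept SD on the latent scale, and an intercept. Gender enters
#' the interaction effect-coded (-1/2 male, +1/2 female), so the main
#' green-view-index coefficient is the gender-averaged slope and
#' gender-specific slopes are `main +/- interaction / 2`.
#'
#' @param buffer `"400"` or `"800"` — selects the published coefficient set.
#' @param icc latent-threshold intraclass correlation that fixes the block
#'   SD via `sigma_u^2 = icc / (1 - icc) * pi^2 / 3` (default the published
#'   null-model value 0.079).
#' @param intercept baseline log-odds for the reference participant
#'   (child age band, low income, gender-averaged).
#' @param male_or,female_or optional gender-specific green-view-index odds
#'   ratios; when given they override the main and interaction coefficients
#'   (main = mean of the log odds, interaction = their difference). Defaults
#'   `NULL` (use the buffer's main/interaction set).
#' @param coefficients optional full replacement named coefficient vector.
#' @return object of class `gw_gm` (`family = "binomial"`).
#' @export
gm_walk <- function(buffer = c("400", "800"), icc = 0.079, intercept = -0.3,
                    male_or = NULL, female_or = NULL, coefficients = NULL) {
  buffer <- match.arg(buffer)
  cf <- if (is.null(coefficients)) log(.or_walk[[buffer]]) else coefficients
  if (!is.null(male_or) && !is.null(female_or)) {
    cf["gvi"] <- (log(male_or) + log(female_or)) / 2
    cf["gvi_x_gender"] <- log(female_or) - log(male_or)
  }
  stopifnot(setequal(names(cf), .gw_terms))
  structure(list(family = "binomial", coefficients = cf[.gw_terms],
                 intercept = intercept, sigma_u = .sigma_u_from_icc(icc),
                 icc = icc, buffer = buffer),
            class = "gw_gm")
}

#' Generating model for the walking-time analysis
#'
#' Fixed effects on the standardized outcome scale (defaults: the published
#' per-buffer standardized-beta set), with block and residual SDs chosen so
#' the variance-ratio intraclass correlation equals `icc` and the
#' conditional variance is `sigma_b^2 + sigma_e^2 = 1`. Minutes are a fixed
#' affine presentation transform of the standardized outcome.
#'
#' @param buffer `"400"` or `"800"`.
#' @param icc variance-ratio ICC (default the published null-model 0.160).
#' @param intercept mean standardized walking time at the reference levels.
#' @param minutes_center,minutes_scale affine back-transform to minutes,
#'   floored at 1 minute.
#' @param coefficients optional replacement named coefficient vector.
#' @return object of class `gw_gm` (`family = "gaussian"`).
#' @export
gm_walktime <- function(buffer = c("400", "800"), icc = 0.160, intercept = 0,
                        minutes_center = 60, minutes_scale = 25,
                        coefficients = NULL) {
  buffer <- match.arg(buffer)
  cf <- if (is.null(coefficients)) .beta_time[[buffer]] else coefficients
  stopifnot(setequal(names(cf), .gw_terms))
  structure(list(family = "gaussian", coefficients = cf[.gw_terms],
                 intercept = intercept, sigma_b = sqrt(icc),
                 sigma_e = sqrt(1 - icc), icc = icc, buffer = buffer,
                 minutes_center = minutes_center, minutes_scale = minutes_scale),
            class = "gw_gm")
}

#' Published gender-stratified green-view-index odds ratios
#'
#' @param buffer `"400"` or `"800"`.
#' @return named vector `male`, `female`.
#' @export
posthoc_gvi_or <- function(buffer = c("400", "800")) {
  .or_posthoc[[match.arg(buffer)]]
}

#' Write a generating model to JSON
#'
#' @param gm a `gw_gm`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gm_json <- function(gm, path) {
  jsonlite::write_json(unclass(gm), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Simulate cohort demographics on a city
#'
#' Places `n` dwellings (clustered into street blocks) and draws age band,
#' gender and income band independently from the given margins — one
#' participant per dwelling.
#'
#' @param city a `gw_city`.
#' @param n cohort size.
#' @param composition margins from [cohort_margins()] (or the same shape).
#' @param seed integer seed.
#' @param dwellings optional pre-placed dwellings to reuse (demographics are
#'   then re-drawn on the fixed geography).
#' @return data.frame `id`, `dwelling_id`, `block_id`, `x`, `y`, `age_band`,
#'   `gender`, `income_band` (factors with the reference level first).
#' @export
simulate_cohort <- function(city, n, composition = cohort_margins(1L),
                            seed = 1L, dwellings = NULL) {
  for (nm in c("age", "gender", "income")) {
    v <- composition[[nm]]
    if (is.null(v) || any(v < 0) || abs(sum(v) - 1) > 1e-6) {
      stop("composition margin `", nm, "` is not a probability vector summing to 1")
    }
  }
  if (is.null(dwellings)) dwellings <- place_dwellings(city, n, seed = seed)
  stopifnot(nrow(dwellings) == n)
  with_seed(child_seed(seed, "cohort"), {
    age <- sample(names(composition$age), n, replace = TRUE, prob = composition$age)
    gender <- sample(names(composition$gender), n, replace = TRUE,
                     prob = composition$gender)
    income <- sample(names(composition$income), n, replace = TRUE,
                     prob = composition$income)
    data.frame(id = seq_len(n), dwelling_id = dwellings$id,
               block_id = dwellings$block_id, x = dwellings$x, y = dwellings$y,
               age_band = factor(age, levels = names(composition$age)),
               gender = factor(gender, levels = names(composition$gender)),
               income_band = factor(income, levels = names(composition$income)))
  })
}

# Fixed-effect linear predictor of a generating model on a design matrix
# whose columns are the model terms.
.gm_eta <- function(X, gm) {
  miss <- setdiff(.gw_terms, colnames(X))
  if (length(miss)) stop("design is missing terms: ", paste(miss, collapse = ", "))
  if (anyNA(X)) {
    bad <- which(rowSums(is.na(X)) > 0)[1L]
    stop("missing predictor value for participant row ", bad)
  }
  gm$intercept + drop(X[, .gw_terms, drop = FALSE] %*% gm$coefficients[.gw_terms])
}

#' Simulate walking decisions
#'
#' Draws a street-block random intercept `b_j ~ N(0, sigma_u^2)` and then
#' `walked ~ Bernoulli(plogis(intercept + X beta + b_j))`.
#'
#' @param X standardized design matrix with named term columns (no intercept
#'   column; see [build_design_matrix()]).
#' @param block_id integer block id per row.
#' @param gm a binomial `gw_gm` from [gm_walk()].
#' @param seed integer seed.
#' @return integer 0/1 vector of walking flags.
#' @export
simulate_walk_decision <- function(X, block_id, gm, seed = 1L) {
  stopifnot(inherits(gm, "gw_gm"), gm$family == "binomial")
  eta_fix <- .gm_eta(X, gm)
  with_seed(child_seed(seed, "walkdec"), {
    blocks <- sort(unique(block_id))
    b <- stats::rnorm(length(blocks), 0, gm$sigma_u)
    eta <- eta_fix + b[match(block_id, blocks)]
    stats::rbinom(length(eta), 1L, stats::plogis(eta))
  })
}

#' Simulate walking time for walkers
#'
#' Standardized outcome `y = intercept + X gamma + u_block + e` with
#' `u ~ N(0, sigma_b^2)` and `e ~ N(0, sigma_e^2)`; minutes are obtained by
#' a fixed affine back-transform floored at 1 minute (the number of floored
#' observations is reported).
#'
#' @param X standardized design matrix (walkers only).
#' @param block_id integer block id per row.
#' @param gm a gaussian `gw_gm` from [gm_walktime()].
#' @param seed integer seed.
#' @return list with `y_std` (standardized outcome), `minutes`, and
#'   `n_floored`.
#' @export
simulate_walk_time <- function(X, block_id, gm, seed = 1L) {
  stopifnot(inherits(gm, "gw_gm"), gm$family == "gaussian")
  eta_fix <- .gm_eta(X, gm)
  with_seed(child_seed(seed, "walktime"), {
    blocks <- sort(unique(block_id))
    u <- stats::rnorm(length(blocks), 0, gm$sigma_b)
    y <- eta_fix + u[match(block_id, blocks)] +
      stats::rnorm(length(eta_fix), 0, gm$sigma_e)
    minutes_raw <- gm$minutes_center + gm$minutes_scale * y
    minutes <- pmax(minutes_raw, 1)
    list(y_std = y, minutes = minutes, n_floored = sum(minutes_raw < 1))
  })
}
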