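# Built-environment covariates per buffer: population density, land-use mix
# (normalized entropy over commercial/office/residential area shares),
# street intersection density, amenity counts, distance to the nearest rail
# station; plus z-score standardization and variance-inflation screening.

#' Normalized entropy land-use mix
#'
#' `-sum(p_j * log(p_j)) / log(3)` over the three land-use area shares
#' (commercial, office, residential), with `0 * log(0) == 0`; ranges from 0
#' (single use) to 1 (even mix).
#'
#' @param proportions three nonnegative values summing to 1.
#' @return entropy score in `[0, 1]`.
#' @export
entropy_landuse_mix <- function(proportions) {
  stopifnot(length(proportions) == 3L)
  if (any(proportions < 0)) stop("negative proportion")
  if (abs(sum(proportions) - 1) > 1e-9) stop("proportions must sum to 1")
  p <- proportions[proportions > 0]
  -sum(p * log(p)) / log(3)
}

# Disk offsets at raster resolution `res` for radius `r`: cell index offsets
# whose centre-to-centre distance is <= r.
.disk_offsets <- function(r, res) {
  m <- floor(r / res)
  g <- expand.grid(di = -m:m, dj = -m:m)
  g[g$di^2 + g$dj^2 <= (r / res)^2, , drop = FALSE]
}

# Count points (qx, qy) within the closed disk of radius r around each
# (px, py), chunked.
.count_in_disk <- function(px, py, qx, qy, r, chunk = 2000L) {
  n <- length(px)
  out <- integer(n)
  if (length(qx) == 0L) return(out)
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    d2 <- outer(px[idx], qx, "-")^2 + outer(py[idx], qy, "-")^2
    out[idx] <- rowSums(d2 <= r^2)
  }
  out
}

#' Buffer covariates for dwellings
#'
#' Computes, for each dwelling and the given radius, the built-environment
#' covariates inside the closed Euclidean disk: amenity counts, intersection
#' density (network nodes of degree >= 3 per km^2), population density
#' (parcel population apportioned by the share of parcel area inside the
#' disk, per km^2), land-use mix entropy of parcel-area shares, and the
#' distance to the nearest rail station (not capped at the radius). Area
#' integrals (parcel-disk overlap) are evaluated on a raster grid of
#' resolution `res` meters; dwellings are snapped to the nearest raster cell
#' centre for those integrals.
#'
#' @param dwellings data.frame with `id`, `x`, `y`.
#' @param city a `gw_city`.
#' @param radius buffer radius, meters.
#' @param res raster resolution for area integrals, meters (default 25).
#' @return data.frame with one row per dwelling: `participant_id`, `radius`,
#'   `pop_density` (persons/km^2), `landuse_mix`, `intersection_density`
#'   (per km^2), `n_shops`, `n_recreation`, `n_bus_stops`, `dist_mtr` (m).
#' @export
buffer_covariates <- function(dwellings, city, radius, res = 25) {
  stopifnot(inherits(city, "gw_city"), radius > 0)
  n <- nrow(dwellings)
  ext <- city$extent[3]
  p <- city$parcels
  # per-raster-cell population mass and land-use type
  nc <- max(1L, round(ext / res))
  res_eff <- ext / nc
  cell_area <- res_eff^2
  ci_all <- rep(seq_len(nc), nc)          # x index varies fastest
  cj_all <- rep(seq_len(nc), each = nc)
  cx <- (ci_all - 0.5) * res_eff
  cy <- (cj_all - 0.5) * res_eff
  pi_ix <- pmin(pmax(ceiling(cx / p$cell), 1L), p$n)
  pj_ix <- pmin(pmax(ceiling(cy / p$cell), 1L), p$n)
  ptype_cell <- p$type[cbind(pi_ix, pj_ix)]
  pop_cell <- p$pop[cbind(pi_ix, pj_ix)] * cell_area / (p$cell^2)
  # dwelling cell indices (snapped)
  di <- pmin(pmax(ceiling(dwellings$x / res_eff), 1L), nc)
  dj <- pmin(pmax(ceiling(dwellings$y / res_eff), 1L), nc)
  base_lin <- (dj - 1L) * nc + di
  offs <- .disk_offsets(radius, res_eff)
  pop_mass <- numeric(n)
  area_type <- matrix(0, n, 3L)
  for (k in seq_len(nrow(offs))) {
    ti <- di + offs$di[k]; tj <- dj + offs$dj[k]
    ok <- ti >= 1L & ti <= nc & tj >= 1L & tj <= nc
    lin <- (tj - 1L) * nc + ti
    lin_ok <- lin[ok]
    pop_mass[ok] <- pop_mass[ok] + pop_cell[lin_ok]
    tt <- ptype_cell[lin_ok]
    area_type[ok, 1L] <- area_type[ok, 1L] + (tt == 1L) * cell_area
    area_type[ok, 2L] <- area_type[ok, 2L] + (tt == 2L) * cell_area
    area_type[ok, 3L] <- area_type[ok, 3L] + (tt == 3L) * cell_area
  }
  disk_km2 <- pi * radius^2 / 1e6
  tot_area <- rowSums(area_type)
  shares <- area_type / ifelse(tot_area > 0, tot_area, 1)
  lum <- apply(shares, 1L, function(s) {
    s <- s / sum(s)
    entropy_landuse_mix(s)
  })
  inter <- city$nodes[city$nodes$degree >= 3L, , drop = FALSE]
  n_inter <- .count_in_disk(dwellings$x, dwellings$y, inter$x, inter$y, radius)
  am <- city$amenities
  n_shops <- .count_in_disk(dwellings$x, dwellings$y, am$shops$x, am$shops$y, radius)
  n_recr <- .count_in_disk(dwellings$x, dwellings$y,
                           am$recreation_facilities$x, am$recreation_facilities$y, radius)
  n_bus <- .count_in_disk(dwellings$x, dwellings$y, am$bus_stops$x, am$bus_stops$y, radius)
  dist_mtr <- nearest_dist(dwellings$x, dwellings$y,
                           am$rail_stations$x, am$rail_stations$y)
  data.frame(participant_id = dwellings$id, radius = radius,
             pop_density = pop_mass / disk_km2, landuse_mix = lum,
             intersection_density = n_inter / disk_km2,
             n_shops = n_shops, n_recreation = n_recr, n_bus_stops = n_bus,
             dist_mtr = dist_mtr)
}

#' Variance inflation factors
#'
#' `VIF_k = 1 / (1 - R^2_k)` where `R^2_k` comes from regressing predictor
#' `k` on all the others. Perfectly collinear columns are reported as `Inf`
#' with a warning naming them.
#'
#' @param design numeric matrix or data.frame of predictors (>= 2 columns,
#'   more rows than columns).
#' @return named numeric vector of VIFs.
#' @export
vif <- function(design) {
  X <- as.matrix(design)
  stopifnot(ncol(X) >= 2L, nrow(X) > ncol(X))
  out <- vapply(seq_len(ncol(X)), function(k) {
    fit <- stats::lm.fit(cbind(1, X[, -k, drop = FALSE]), X[, k])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, k] - mean(X[, k]))^2)
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(X)
  if (any(is.infinite(out))) {
    warning("perfectly collinear predictor(s): ",
            paste(names(out)[is.infinite(out)], collapse = ", "))
  }
  out
}

#' Z-score standardization with stored centers and scales
#'
#' Standardizes the given continuous columns to mean 0, sd 1 (sample sd,
#' n - 1 denominator), storing the per-column mean and sd as attributes so
#' the transform is invertible and coefficients read as per-SD effects.
#'
#' @param design data.frame.
#' @param cols names of columns to standardize; defaults to all numeric
#'   columns.
#' @return the data.frame with standardized columns and attributes
#'   `gw_center` / `gw_scale`; class `gw_standardized`.
#' @export
standardize <- function(design, cols = NULL) {
  if (is.null(cols)) cols <- names(design)[vapply(design, is.numeric, logical(1))]
  ctr <- numeric(0); scl <- numeric(0)
  for (cn in cols) {
    v <- design[[cn]]
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) stop("zero-variance column: ", cn)
    design[[cn]] <- (v - mean(v)) / s
    ctr[cn] <- mean(v); scl[cn] <- s
  }
  attr(design, "gw_center") <- ctr
  attr(design, "gw_scale") <- scl
  class(design) <- c("gw_standardized", class(design))
  design
}
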