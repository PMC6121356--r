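# Rule-based vegetation segmentation: a hue/saturation gate for green pixels
# combined with a shape/texture filter that rejects connected components that
# are too rectilinear and too smooth (man-made green confounders such as
# trucks or painted walls). Deterministic stand-in for a trained semantic
# segmentation network, behind the same mask contract so a neural model
# could be wired in instead.

#' Segmenter configuration
#'
#' @param hue_lo,hue_hi green hue window, in `[0, 1]` hue units
#'   (0.195-0.47 spans roughly 70-170 degrees).
#' @param sat_min,val_min minimum saturation and value for the colour gate.
#' @param min_frac minimum connected-component size as a fraction of the
#'   image (tiny speckles are dropped as noise).
#' @param fill_max bounding-box fill ratio above which a component counts as
#'   rectilinear; combined with the texture test below.
#' @param smooth_sd components whose within-component value-channel standard
#'   deviation is below this are "painted-smooth"; a component is rejected as
#'   man-made when it is both rectilinear (`fill > fill_max`) and smooth.
#' @param hard_smooth_sd components smoother than this are rejected outright
#'   regardless of shape (vegetation texture is never this flat).
#' @param shape_filter set `FALSE` for a colour-only gate (the baseline that
#'   man-made green objects fool).
#' @return a `gw_seg_config` list.
#' @export
segmenter_config <- function(hue_lo = 0.195, hue_hi = 0.47, sat_min = 0.15,
                             val_min = 0.08, min_frac = 1e-4, fill_max = 0.93,
                             smooth_sd = 0.05, hard_smooth_sd = 0.015,
                             shape_filter = TRUE) {
  structure(list(hue_lo = hue_lo, hue_hi = hue_hi, sat_min = sat_min,
                 val_min = val_min, min_frac = min_frac, fill_max = fill_max,
                 smooth_sd = smooth_sd, hard_smooth_sd = hard_smooth_sd,
                 shape_filter = shape_filter),
            class = "gw_seg_config")
}

#' Segment vegetation pixels in a tile
#'
#' Applies the green colour gate, labels connected components
#' (`EBImage::bwlabel`), and removes components whose geometry and texture
#' indicate man-made surfaces rather than foliage. Deterministic.
#'
#' @param tile a `gw_tile` (or any list with a `pixels` H x W x 3 array).
#' @param params a [segmenter_config()].
#' @return an object of class `gw_mask` with elements `point_id`, `heading`
#'   and `mask` (H x W integer matrix, 1 = predicted vegetation).
#' @export
segment_vegetation <- function(tile, params = segmenter_config()) {
  px <- tile$pixels
  if (is.null(px) || length(px) == 0L) stop("empty raster")
  stopifnot(length(dim(px)) == 3L, dim(px)[3] == 3L)
  H <- dim(px)[1]; W <- dim(px)[2]
  hsv <- .rgb2hsv_flat(as.vector(px[, , 1]), as.vector(px[, , 2]),
                       as.vector(px[, , 3]))
  gate <- hsv$h >= params$hue_lo & hsv$h <= params$hue_hi &
    hsv$s >= params$sat_min & hsv$v >= params$val_min
  gm <- matrix(as.integer(gate), H, W)
  if (params$shape_filter && any(gate)) {
    lab <- EBImage::bwlabel(gm)
    labv <- as.integer(lab)
    nlab <- max(labv)
    if (nlab > 0L) {
      rows <- rep.int(seq_len(H), W)
      cols <- rep(seq_len(W), each = H)
      on <- labv > 0L
      lv <- labv[on]
      npix <- tabulate(lv, nbins = nlab)
      rmin <- tapply(rows[on], lv, min); rmax <- tapply(rows[on], lv, max)
      cmin <- tapply(cols[on], lv, min); cmax <- tapply(cols[on], lv, max)
      bbox <- (rmax - rmin + 1) * (cmax - cmin + 1)
      fill <- npix / bbox
      vs <- hsv$v[on]
      vmean <- tapply(vs, lv, mean)
      vsd <- sqrt(pmax(tapply(vs * vs, lv, mean) - vmean^2, 0))
      min_px <- max(6, params$min_frac * H * W)
      drop <- npix < min_px |
        vsd < params$hard_smooth_sd |
        (fill > params$fill_max & vsd < params$smooth_sd)
      if (any(drop)) {
        keepmap <- c(0L, as.integer(!drop))
        gm <- matrix(keepmap[labv + 1L], H, W)
      }
    }
  }
  structure(list(point_id = tile$point_id, heading = tile$heading, mask = gm),
            class = "gw_mask")
}

#' Predicted green fraction of one tile
#'
#' @param tile a `gw_tile`.
#' @param params a [segmenter_config()].
#' @return proportion of predicted vegetation pixels.
#' @export
predicted_green_fraction <- function(tile, params = segmenter_config()) {
  mean(segment_vegetation(tile, params)$mask)
}

#' Per-image validation report from fraction series
#'
#' Computes the Pearson correlation between predicted and reference
#' per-image green fractions — the image-level statistic used to validate
#' automated extraction against reference (expert-style) masks.
#'
#' @param predicted,reference numeric vectors of per-image green fractions.
#' @return object of class `gw_validation` with `n_images`, `r` and a
#'   `per_image` data.frame.
#' @export
validation_report <- function(predicted, reference) {
  stopifnot(length(predicted) == length(reference), length(predicted) >= 3)
  if (stats::sd(predicted) == 0 || stats::sd(reference) == 0) {
    stop("correlation undefined: zero variance in a fraction series")
  }
  structure(list(n_images = length(predicted),
                 r = stats::cor(predicted, reference),
                 per_image = data.frame(predicted = predicted,
                                        reference = reference)),
            class = "gw_validation")
}

#' Validate the segmenter against ground-truth masks
#'
#' For every image in the corpus, computes the predicted green fraction from
#' the segmenter and the reference fraction from the truth mask, and reports
#' their Pearson correlation (image-level, as in validating automated
#' extraction against a sample of expert-labelled images).
#'
#' @param images a list of `gw_tile` and/or `gw_tileset` objects (tilesets
#'   are flattened into their tiles; at least 3 images in total).
#' @param params a [segmenter_config()].
#' @return a `gw_validation` object.
#' @export
validate_segmenter <- function(images, params = segmenter_config()) {
  tiles <- list()
  for (im in images) {
    if (inherits(im, "gw_tileset")) tiles <- c(tiles, im$tiles)
    else tiles <- c(tiles, list(im))
  }
  stopifnot(length(tiles) >= 3)
  pred <- vapply(tiles, predicted_green_fraction, numeric(1), params = params)
  ref <- vapply(tiles, function(t) mean(t$truth_mask), numeric(1))
  validation_report(pred, ref)
}

#' @export
print.gw_validation <- function(x, ...) {
  cat(sprintf("<gw_validation> %d images, Pearson r = %.3f\n", x$n_images, x$r))
  invisible(x)
}

#' Write a validation report to JSON and CSV
#'
#' @param report a `gw_validation`.
#' @param path_json,path_csv output paths (either may be `NULL`).
#' @return invisibly, the report.
#' @export
write_validation_report <- function(report, path_json = NULL, path_csv = NULL) {
  if (!is.null(path_json)) {
    jsonlite::write_json(list(n_images = report$n_images, r = report$r),
                         path_json, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(path_csv)) {
    utils::write.csv(report$per_image, path_csv, row.names = FALSE)
  }
  invisible(report)
}
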