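# Conversion of guiding images (IF channels, deep-learning probability
# maps) into per-spot Beta prior means: percentile capping, disk
# aggregation over spots, patch-overlap weighting, quantile mapping.

#' Cap image intensities at percentiles and rescale to [0, 1]
#'
#' Outlier control for raw fluorescence intensities: values above the
#' `high_pct` percentile are set to that percentile, values below the
#' `low_pct` percentile are set to zero, and everything is divided by the
#' maximum capped value so the result spans `[0, 1]` with maximum exactly 1
#' (an all-zero image is returned unchanged with a warning).
#'
#' @param image an [image_raster()].
#' @param low_pct,high_pct percentiles in `[0, 100]`, defaults 1 and 99.
#' @return An [image_raster()] on the `[0, 1]` scale.
#' @export
cap_and_rescale <- function(image, low_pct = 1, high_pct = 99) {
  .stop_if(!inherits(image, "image_raster"), "image must be an image_raster")
  .stop_if(low_pct < 0 || high_pct > 100 || low_pct >= high_pct,
           "need 0 <= low_pct < high_pct <= 100")
  px <- image$pixels
  .stop_if(length(px) == 0, "empty image")
  if (all(px == 0)) {
    warning("constant-zero image: returned unchanged")
    return(image)
  }
  hi <- quantile(px, high_pct / 100, names = FALSE)
  lo <- quantile(px, low_pct / 100, names = FALSE)
  px[px > hi] <- hi
  px[px < lo] <- 0
  image_raster(px / max(px), image$microns_per_pixel)
}

# pixel centers inside a disk: 0-based integer (row, col) with
# (r - cr)^2 + (c - cc)^2 <= radius^2
.disk_rows <- function(center, radius) {
  r0 <- ceiling(center[1] - radius)
  r1 <- floor(center[1] + radius)
  if (r1 < r0) integer(0) else r0:r1
}

#' Mean image intensity over each spot
#'
#' For each spot, averages the pixels whose (integer, 0-based) centers lie
#' within `radius_px` of the spot center (Euclidean disk). Disks are
#' clipped at the image border; a spot whose disk contains no in-bounds
#' pixel gets value 0 with a warning.
#'
#' @param image an [image_raster()], typically after [cap_and_rescale()].
#' @param geom a [spot_geometry()].
#' @return A [spot_prior_values()] with `source = "if_channel"`.
#' @export
spot_mean_intensity <- function(image, geom) {
  .stop_if(!inherits(image, "image_raster"), "image must be an image_raster")
  .stop_if(!inherits(geom, "spot_geometry"), "geom must be a spot_geometry")
  px <- image$pixels
  nr <- nrow(px); nc <- ncol(px)
  outside <- character(0)
  vals <- vapply(seq_along(geom$spot_ids), function(j) {
    ctr <- geom$centers[j, ]
    rad <- geom$radius_px[j]
    rows <- .disk_rows(ctr, rad)
    rows <- rows[rows >= 0 & rows <= nr - 1]
    tot <- 0; cnt <- 0L
    for (r in rows) {
      half <- sqrt(rad^2 - (r - ctr[1])^2)
      cols <- ceiling(ctr[2] - half):floor(ctr[2] + half)
      cols <- cols[cols >= 0 & cols <= nc - 1]
      if (length(cols)) {
        tot <- tot + sum(px[r + 1, cols + 1])
        cnt <- cnt + length(cols)
      }
    }
    if (cnt == 0L) {
      outside <<- c(outside, geom$spot_ids[j])
      0
    } else tot / cnt
  }, numeric(1))
  if (length(outside) > 0)
    warning("spot(s) without in-bounds pixels set to 0: ",
            paste(head(outside, 5), collapse = ", "))
  # mean of [0,1]-capped pixels stays in [0,1]; raw-scale images are
  # rescaled by their max only for the container contract
  if (length(vals) && max(vals) > 1) vals <- vals / max(vals)
  spot_prior_values(geom$spot_ids, vals, source = "if_channel")
}

#' Convert a patch probability map to per-spot values
#'
#' Each spot receives the overlap-weighted mean of the patch probabilities:
#' `sum_patch p * overlap(patch, disk) / sum_patch overlap(patch, disk)`,
#' where overlap counts the integer pixel centers lying inside both the
#' patch rectangle and the spot disk. Normalizing by the total overlapping
#' pixels keeps the result on the probability scale regardless of how much
#' of the disk the patches tile. Spots overlapping no patch get 0 with a
#' warning.
#'
#' @param map a [patch_probability_map()].
#' @param geom a [spot_geometry()].
#' @return A [spot_prior_values()] with `source = "dl_map"`.
#' @export
patch_map_to_spots <- function(map, geom) {
  .stop_if(!inherits(map, "patch_probability_map"),
           "map must be a patch_probability_map")
  .stop_if(!inherits(geom, "spot_geometry"), "geom must be a spot_geometry")
  pt <- map$patches
  uncovered <- character(0)
  vals <- vapply(seq_along(geom$spot_ids), function(j) {
    ctr <- geom$centers[j, ]
    rad <- geom$radius_px[j]
    rows <- .disk_rows(ctr, rad)
    wsum <- 0; psum <- 0
    for (r in rows) {
      half <- sqrt(rad^2 - (r - ctr[1])^2)
      c0 <- ceiling(ctr[2] - half); c1 <- floor(ctr[2] + half)
      if (c1 < c0) next
      in_row <- pt$row0_px <= r & r < pt$row0_px + pt$height_px
      if (!any(in_row)) next
      lo <- pmax(ceiling(pt$col0_px[in_row]), c0)
      hi <- pmin(ceiling(pt$col0_px[in_row] + pt$width_px[in_row]) - 1, c1)
      npx <- pmax(hi - lo + 1, 0)
      wsum <- wsum + sum(npx)
      psum <- psum + sum(npx * pt$probability[in_row])
    }
    if (wsum == 0) {
      uncovered <<- c(uncovered, geom$spot_ids[j])
      0
    } else psum / wsum
  }, numeric(1))
  if (length(uncovered) > 0)
    warning("spot(s) with zero patch overlap set to 0: ",
            paste(head(uncovered, 5), collapse = ", "))
  spot_prior_values(geom$spot_ids, vals, source = "dl_map")
}

#' Map values onto the quantiles of a reference distribution
#'
#' Image-derived intensities are not proportions; before they can serve as
#' Beta prior means they are mapped onto the empirical distribution of the
#' cell-type proportion estimates from a first, prior-free round of model
#' fitting. `output[j]` is the empirical quantile of `target` at the
#' fractional rank of `source[j]` (average ranks for ties, linear
#' interpolation between order statistics). The mapping is monotone and
#' the output's empirical distribution equals the target's (exactly, up to
#' interpolation at ties).
#'
#' @param source a [spot_prior_values()] or numeric vector.
#' @param target numeric vector of reference values (e.g. one row of a
#'   base-model [posterior_proportions()]), same length as `source`.
#' @return A [spot_prior_values()] with `source = "mapped"` when spot ids
#'   are available, otherwise a numeric vector.
#' @export
quantile_map <- function(source, target) {
  ids <- NULL
  if (inherits(source, "spot_prior_values")) {
    ids <- source$spot_ids
    source <- source$values
  }
  source <- as.numeric(source)
  target <- as.numeric(target)
  .stop_if(length(source) != length(target),
           "source and target must have the same length")
  .stop_if(any(!is.finite(source)) || any(!is.finite(target)),
           "values must be finite")
  n <- length(source)
  out <- if (n == 1) target else {
    fr <- (rank(source, ties.method = "average") - 1) / (n - 1)
    quantile(target, probs = fr, names = FALSE, type = 7)
  }
  if (is.null(ids)) out
  else spot_prior_values(ids, pmin(pmax(out, 0), 1), source = "mapped")
}

#' Beta shape parameters from mean and total count
#'
#' The image prior is a Beta distribution parameterised by its mean `tau`
#' (the per-spot image-derived estimate) and total-count/concentration
#' `lam` (the weight placed on the image relative to the transcriptome):
#' shapes are `(tau * lam, (1 - tau) * lam)`.
#'
#' @param tau mean(s) in `(0, 1)`.
#' @param lam positive total count.
#' @return List with numeric fields `alpha_shape` and `beta_shape`.
#' @export
beta_shapes <- function(tau, lam) {
  .stop_if(any(!is.finite(tau)) || any(tau <= 0) || any(tau >= 1),
           "tau must lie strictly inside (0, 1)")
  .stop_if(!is.finite(lam) || lam <= 0, "lam must be positive")
  list(alpha_shape = tau * lam, beta_shape = (1 - tau) * lam)
}

#' Assemble a Beta prior specification from mapped spot values
#'
#' Clamps the mapped values to `[1e-4, 1 - 1e-4]` (a Beta mean must be
#' interior) and bundles them with the target cell type(s) and
#' concentration.
#'
#' @param values a [spot_prior_values()] (typically from [quantile_map()]).
#' @param target_cell_type cell type id(s) the prior applies to; several
#'   ids denote a grouped prior on the sum of their proportions.
#' @param lam concentration, default 50 (the sweep-derived operating
#'   value, see [sweep_lambda()]).
#' @param clamp interior clamping margin, default 1e-4.
#' @return A [prior_spec()].
#' @export
make_prior <- function(values, target_cell_type, lam = 50, clamp = 1e-4) {
  .stop_if(!inherits(values, "spot_prior_values"),
           "values must be a spot_prior_values")
  tau <- pmin(pmax(values$values, clamp), 1 - clamp)
  prior_spec(target_cell_type, tau, lam, spot_ids = values$spot_ids)
}
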