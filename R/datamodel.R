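#' @useDynLib spotgist, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor dist mad median pnorm prcomp quantile rgamma rlnorm
#'   rnbinom rnorm rt runif sd setNames var
#' @importFrom utils head read.table write.table
NULL

.stop_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)

.check_ids <- function(ids, what) {
  .stop_if(anyNA(ids) || any(!nzchar(ids)), what, " contains missing/empty ids")
  .stop_if(anyDuplicated(ids) > 0, what, " contains duplicated ids: ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
  as.character(ids)
}

#' Genes-by-spots expression matrix
#'
#' Container for the spot expression matrix `Y` (rows = genes, columns =
#' spots). The `layer` field records where the values sit in the processing
#' chain: raw `counts`, neighborhood-aggregated `smoothed` counts, or
#' `normalized` values on the scale the decomposition model is fitted on.
#'
#' @param values numeric matrix of non-negative values, genes x spots.
#' @param gene_ids,spot_ids unique character ids; default to dimnames.
#' @param layer one of `"counts"`, `"smoothed"`, `"normalized"`.
#' @return An object of class `expression_matrix` with fields `values`,
#'   `gene_ids`, `spot_ids` and `layer`.
#' @export
expression_matrix <- function(values,
                              gene_ids = rownames(values),
                              spot_ids = colnames(values),
                              layer = c("counts", "smoothed", "normalized")) {
  layer <- match.arg(layer)
  values <- as.matrix(values)
  .stop_if(is.null(gene_ids) || is.null(spot_ids),
           "gene_ids and spot_ids are required (or provide dimnames)")
  gene_ids <- .check_ids(gene_ids, "gene_ids")
  spot_ids <- .check_ids(spot_ids, "spot_ids")
  .stop_if(nrow(values) != length(gene_ids) || ncol(values) != length(spot_ids),
           "value dimensions do not match gene/spot id counts")
  .stop_if(any(!is.finite(values)), "expression values must be finite")
  .stop_if(any(values < 0), "expression values must be non-negative")
  dimnames(values) <- list(gene_ids, spot_ids)
  structure(list(values = values, gene_ids = gene_ids, spot_ids = spot_ids,
                 layer = layer),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d spots, layer = %s\n",
              length(x$gene_ids), length(x$spot_ids), x$layer))
  invisible(x)
}

#' Single-cell reference counts with cell-type labels
#'
#' @param values non-negative integer matrix, genes x cells.
#' @param cell_type_labels one label per cell (character or factor); factor
#'   levels declare the cell-type universe and its order.
#' @param gene_ids unique gene ids; defaults to rownames.
#' @return An object of class `single_cell_reference`.
#' @export
single_cell_reference <- function(values, cell_type_labels,
                                  gene_ids = rownames(values)) {
  values <- as.matrix(values)
  gene_ids <- .check_ids(gene_ids, "gene_ids")
  .stop_if(nrow(values) != length(gene_ids), "gene_ids do not match rows")
  .stop_if(ncol(values) != length(cell_type_labels),
           "one cell_type_label is required per cell")
  .stop_if(any(!is.finite(values)) || any(values < 0),
           "reference counts must be finite and non-negative")
  if (!is.factor(cell_type_labels))
    cell_type_labels <- factor(cell_type_labels,
                               levels = unique(cell_type_labels))
  empty <- levels(cell_type_labels)[table(cell_type_labels) == 0L]
  .stop_if(length(empty) > 0,
           "no cells for type ", paste(empty, collapse = ", "))
  rownames(values) <- gene_ids
  structure(list(values = values, cell_type_labels = cell_type_labels,
                 gene_ids = gene_ids,
                 cell_types = levels(cell_type_labels)),
            class = "single_cell_reference")
}

#' @export
print.single_cell_reference <- function(x, ...) {
  cat(sprintf("<single_cell_reference> %d genes x %d cells, %d cell types\n",
              length(x$gene_ids), ncol(x$values), length(x$cell_types)))
  invisible(x)
}

#' Genes-by-cell-types signature matrix
#'
#' The reference matrix `W`: mean normalized expression of each gene in each
#' cell type, typically built with [build_signature()].
#'
#' @param values non-negative numeric matrix, genes x cell types.
#' @param gene_ids,cell_type_ids unique ids; default to dimnames.
#' @return An object of class `signature_matrix`.
#' @export
signature_matrix <- function(values, gene_ids = rownames(values),
                             cell_type_ids = colnames(values)) {
  values <- as.matrix(values)
  gene_ids <- .check_ids(gene_ids, "gene_ids")
  cell_type_ids <- .check_ids(cell_type_ids, "cell_type_ids")
  .stop_if(nrow(values) != length(gene_ids) ||
             ncol(values) != length(cell_type_ids),
           "value dimensions do not match id counts")
  .stop_if(any(!is.finite(values)) || any(values < 0),
           "signature values must be finite and non-negative")
  zero <- cell_type_ids[colSums(values) == 0]
  .stop_if(length(zero) > 0,
           "all-zero signature column for type ", paste(zero, collapse = ", "))
  dimnames(values) <- list(gene_ids, cell_type_ids)
  structure(list(values = values, gene_ids = gene_ids,
                 cell_type_ids = cell_type_ids),
            class = "signature_matrix")
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat(sprintf("<signature_matrix> %d genes x %d cell types\n",
              length(x$gene_ids), length(x$cell_type_ids)))
  invisible(x)
}

# strictly positive simplex columns: floor then renormalize
.simplexify <- function(values, floor = 1e-12) {
  values <- pmax(values, floor)
  sweep(values, 2, colSums(values), "/")
}

#' Cell-types-by-spots proportions matrix
#'
#' Columns live on the open simplex: strictly positive, summing to one
#' (within 1e-6).
#'
#' @param values numeric matrix, cell types x spots.
#' @param cell_type_ids,spot_ids unique ids; default to dimnames.
#' @return An object of class `proportions_matrix`.
#' @export
proportions_matrix <- function(values, cell_type_ids = rownames(values),
                               spot_ids = colnames(values)) {
  values <- as.matrix(values)
  cell_type_ids <- .check_ids(cell_type_ids, "cell_type_ids")
  spot_ids <- .check_ids(spot_ids, "spot_ids")
  .stop_if(nrow(values) != length(cell_type_ids) ||
             ncol(values) != length(spot_ids),
           "value dimensions do not match id counts")
  .stop_if(any(!is.finite(values)), "proportions must be finite")
  .stop_if(any(values <= 0), "proportions must be strictly positive")
  if (ncol(values) > 0)
    .stop_if(any(abs(colSums(values) - 1) > 1e-6),
             "proportion columns must sum to 1 within 1e-6")
  dimnames(values) <- list(cell_type_ids, spot_ids)
  structure(list(values = values, cell_type_ids = cell_type_ids,
                 spot_ids = spot_ids),
            class = "proportions_matrix")
}

#' @export
print.proportions_matrix <- function(x, ...) {
  cat(sprintf("<proportions_matrix> %d cell types x %d spots\n",
              length(x$cell_type_ids), length(x$spot_ids)))
  invisible(x)
}

#' Spot centers and radii in image pixel coordinates
#'
#' Pixel coordinates are 0-based `(row, col)` with the origin at the
#' top-left, the shared convention across all image-facing functions. The
#' default radius of 70 px matches the mRNA-capture spot footprint of the
#' slides the model was developed on; it does not automatically generalize
#' across magnifications, so it is exposed as data rather than hard-coded.
#'
#' @param spot_ids unique character ids.
#' @param centers numeric matrix/data frame with columns `(row_px, col_px)`.
#' @param radius_px positive radius, recycled per spot. Default 70.
#' @return An object of class `spot_geometry`.
#' @export
spot_geometry <- function(spot_ids, centers, radius_px = 70) {
  spot_ids <- .check_ids(spot_ids, "spot_ids")
  centers <- as.matrix(centers)
  .stop_if(ncol(centers) != 2, "centers must have two columns (row_px, col_px)")
  .stop_if(nrow(centers) != length(spot_ids),
           "centers must have one row per spot")
  .stop_if(any(!is.finite(centers)), "spot centers must be finite")
  radius_px <- rep_len(as.numeric(radius_px), length(spot_ids))
  .stop_if(any(!is.finite(radius_px)) || any(radius_px <= 0),
           "radius_px must be positive")
  dimnames(centers) <- list(spot_ids, c("row_px", "col_px"))
  structure(list(spot_ids = spot_ids, centers = centers,
                 radius_px = radius_px),
            class = "spot_geometry")
}

#' Grayscale image raster
#'
#' @param pixels numeric matrix of non-negative finite intensities,
#'   indexed `[row, col]`.
#' @param microns_per_pixel optional positive scalar.
#' @return An object of class `image_raster`.
#' @export
image_raster <- function(pixels, microns_per_pixel = NULL) {
  pixels <- as.matrix(pixels)
  .stop_if(any(!is.finite(pixels)), "pixel values must be finite")
  .stop_if(any(pixels < 0), "pixel values must be non-negative")
  if (!is.null(microns_per_pixel))
    .stop_if(!is.finite(microns_per_pixel) || microns_per_pixel <= 0,
             "microns_per_pixel must be positive")
  structure(list(pixels = pixels, microns_per_pixel = microns_per_pixel),
            class = "image_raster")
}

#' Patch-level probability map
#'
#' Rectangular patches (e.g. 50 x 50 micron tiles scored by a
#' tumor-infiltrating-lymphocyte classifier) carrying a probability each,
#' in pixel coordinates. Patches may overlap.
#'
#' @param patches data frame with columns `row0_px`, `col0_px`, `height_px`,
#'   `width_px`, `probability`.
#' @return An object of class `patch_probability_map`.
#' @export
patch_probability_map <- function(patches) {
  patches <- as.data.frame(patches)
  need <- c("row0_px", "col0_px", "height_px", "width_px", "probability")
  .stop_if(!all(need %in% names(patches)),
           "patches must have columns ", paste(need, collapse = ", "))
  patches <- patches[need]
  .stop_if(any(!is.finite(as.matrix(patches))), "patch fields must be finite")
  .stop_if(any(patches$height_px <= 0) || any(patches$width_px <= 0),
           "patch height/width must be positive")
  .stop_if(any(patches$probability < 0 | patches$probability > 1),
           "patch probabilities must lie in [0, 1]")
  structure(list(patches = patches), class = "patch_probability_map")
}

#' Per-spot prior values derived from a guiding image
#'
#' @param spot_ids unique character ids.
#' @param values numeric in `[0, 1]`, one per spot.
#' @param source provenance tag, e.g. `"if_channel"`, `"dl_map"`,
#'   `"synthetic"` or `"mapped"`.
#' @return An object of class `spot_prior_values`.
#' @export
spot_prior_values <- function(spot_ids, values,
                              source = c("if_channel", "dl_map", "synthetic",
                                         "mapped")) {
  source <- match.arg(source)
  spot_ids <- .check_ids(spot_ids, "spot_ids")
  values <- as.numeric(values)
  .stop_if(length(values) != length(spot_ids), "one value per spot required")
  .stop_if(any(!is.finite(values)), "prior values must be finite")
  .stop_if(any(values < 0 | values > 1), "prior values must lie in [0, 1]")
  structure(list(spot_ids = spot_ids, values = setNames(values, spot_ids),
                 source = source),
            class = "spot_prior_values")
}

#' Beta prior specification for one (group of) cell type(s)
#'
#' Per-spot prior means `tau` and a single concentration `lam` for the
#' image-informed cell type `a`. The Beta distribution is parameterised by
#' mean and total count: shapes `(tau * lam, (1 - tau) * lam)`, see
#' [beta_shapes()]. `target_cell_type` may name several types; the prior
#' then applies to the *sum* of their proportions (e.g. total lymphocyte
#' content), leaving the within-group split to the expression data.
#'
#' @param target_cell_type character vector of cell-type ids.
#' @param tau per-spot prior means, strictly inside `(0, 1)`.
#' @param lam positive concentration (total count) hyperparameter.
#' @param spot_ids optional spot ids matching `tau` (defaults to names).
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(target_cell_type, tau, lam, spot_ids = names(tau)) {
  force(spot_ids)
  target_cell_type <- .check_ids(target_cell_type, "target_cell_type")
  tau <- as.numeric(tau)
  .stop_if(any(!is.finite(tau)) || any(tau <= 0) || any(tau >= 1),
           "tau must lie strictly inside (0, 1)")
  .stop_if(!is.finite(lam) || lam <= 0, "lam must be positive")
  if (!is.null(spot_ids)) {
    spot_ids <- .check_ids(spot_ids, "spot_ids")
    .stop_if(length(spot_ids) != length(tau), "spot_ids must match tau")
    names(tau) <- spot_ids
  }
  structure(list(target_cell_type = target_cell_type, tau = tau, lam = lam,
                 spot_ids = spot_ids),
            class = "prior_spec")
}

#' Binary spot annotation mask
#'
#' E.g. pathologist-labelled immune-infiltrated spots. Ratio statistics
#' ([q_statistic()]) additionally require at least one annotated and one
#' unannotated spot.
#'
#' @param spot_ids unique character ids.
#' @param mask logical vector, `TRUE` = annotated/positive.
#' @return An object of class `spot_annotation`.
#' @export
spot_annotation <- function(spot_ids, mask) {
  spot_ids <- .check_ids(spot_ids, "spot_ids")
  .stop_if(!is.logical(mask) || anyNA(mask), "mask must be logical without NA")
  .stop_if(length(mask) != length(spot_ids), "one mask value per spot required")
  structure(list(spot_ids = spot_ids, mask = setNames(mask, spot_ids)),
            class = "spot_annotation")
}

#' MCMC configuration
#'
#' Defaults follow the published fitting protocol: 2000 iterations with the
#' first 1000 discarded as burn-in, one chain, posterior means as point
#' estimates.
#'
#' @param iterations total iterations per chain.
#' @param burn_in iterations discarded, `burn_in < iterations`.
#' @param chains number of chains (pooled after burn-in).
#' @param seed integer master seed; per-spot/per-chain streams are derived
#'   from it so that spots can be fitted independently with identical
#'   results.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(iterations = 2000, burn_in = 1000, chains = 1,
                        seed = 1) {
  .stop_if(iterations < 2 || burn_in < 0, "invalid iteration counts")
  .stop_if(burn_in >= iterations, "burn_in must be smaller than iterations")
  .stop_if(chains < 1, "chains must be >= 1")
  structure(list(iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in),
                 chains = as.integer(chains), seed = as.integer(seed)),
            class = "mcmc_config")
}
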