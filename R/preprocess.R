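# Reference signature construction, kNN smoothing of spot counts,
# normalization, and shared highly-variable-gene selection.

#' Smoothing configuration
#'
#' @param k_neighbors number of nearest neighbors aggregated per spot
#'   (default 5, the value used for fine-resolution spot arrays; coarser or
#'   sparser slides pooled together benefit from k = 10). `k_neighbors = 0`
#'   is an identity passthrough.
#' @param n_components dimensionality of the PCA space in which neighbors
#'   are searched (default 10).
#' @return An object of class `smoothing_config`.
#' @export
smoothing_config <- function(k_neighbors = 5, n_components = 10) {
  .stop_if(k_neighbors < 0, "k_neighbors must be >= 0")
  .stop_if(n_components < 1, "n_components must be >= 1")
  structure(list(k_neighbors = as.integer(k_neighbors),
                 n_components = as.integer(n_components)),
            class = "smoothing_config")
}

# library-size scale + Freeman-Tukey variance stabilization, used only to
# define the neighbor-search space during smoothing
.ft_transform <- function(x) {
  depth <- colSums(x)
  target <- median(depth)
  xs <- sweep(x, 2, pmax(depth, 1), "/") * target
  sqrt(xs) + sqrt(xs + 1)
}

#' Impute spot counts by k-nearest-neighbor aggregation
#'
#' Non-parametric smoothing that counteracts the lower transcript capture
#' of spot arrays relative to single-cell references. Follows the stepwise
#' doubling schedule of the published kNN-smoothing algorithm: in step `t`
#' each spot's raw counts are replaced by the sum over itself and its
#' `min(2^t - 1, k)` nearest neighbors, with neighbors found by Euclidean
#' distance in a `n_components`-dimensional PCA of variance-stabilized
#' (library-size-scaled, Freeman-Tukey-transformed) values, and the reduced
#' space recomputed from the current aggregate at every step.
#'
#' @param counts an [expression_matrix()] with `layer = "counts"`.
#' @param cfg a [smoothing_config()].
#' @param seed integer; the procedure is deterministic, the seed only fixes
#'   tie-breaking in degenerate distance ties.
#' @return An [expression_matrix()] with `layer = "smoothed"`. Each smoothed
#'   spot equals the sum of the raw counts of the spots aggregated into it.
#' @export
knn_smooth <- function(counts, cfg = smoothing_config(), seed = 1L) {
  .stop_if(!inherits(counts, "expression_matrix"),
           "counts must be an expression_matrix")
  .stop_if(counts$layer != "counts", "knn_smooth expects layer = 'counts'")
  x <- counts$values
  n <- ncol(x)
  k <- cfg$k_neighbors
  if (k == 0)
    return(expression_matrix(x, counts$gene_ids, counts$spot_ids,
                             layer = "smoothed"))
  .stop_if(k >= n, "k_neighbors must be smaller than the number of spots")
  set.seed(seed)
  s <- x
  steps <- ceiling(log2(k + 1))
  for (t in seq_len(steps)) {
    kt <- min(2^t - 1, k)
    ft <- .ft_transform(s)
    d <- min(cfg$n_components, n - 1, nrow(ft))
    pcs <- prcomp(t(ft), center = TRUE, scale. = FALSE, rank. = d)$x
    dd <- as.matrix(dist(pcs))
    s <- vapply(seq_len(n), function(j) {
      nb <- order(dd[j, ])            # self first (distance 0)
      rowSums(x[, nb[seq_len(kt + 1)], drop = FALSE])
    }, numeric(nrow(x)))
  }
  expression_matrix(s, counts$gene_ids, counts$spot_ids, layer = "smoothed")
}

# internal: log1p of depth-scaled values, the default variance-stabilizing
# normalization (see normalize_counts)
.lognorm <- function(x, scale_factor = 1e4) {
  depth <- colSums(x)
  log1p(sweep(x, 2, depth, "/") * scale_factor)
}

#' Normalize counts for model fitting
#'
#' Contract: the library-size effect is removed (spots with proportional
#' count profiles map to identical normalized profiles) and a monotone
#' per-gene variance-stabilizing transform is applied; output is
#' deterministic given the input. The default, `"lognorm"`, is `log1p` of
#' counts scaled to a common library size of `scale_factor`. A
#' Pearson-residual option (`"pearson"`, Poisson-NB residuals against a
#' depth-by-gene-abundance expectation, clipped at `sqrt(n)`) is provided
#' for workflows that prefer residual-type normalization; any consistent
#' variance-stabilizing hook can stand in because the decomposition model
#' only requires `Y` and `W` to share one normalized scale.
#'
#' @param counts an [expression_matrix()] (layer `"counts"` or
#'   `"smoothed"`).
#' @param method `"lognorm"` (default) or `"pearson"`.
#' @param scale_factor target library size for `"lognorm"`, default 10000.
#' @param theta NB dispersion used by `"pearson"`, default 100.
#' @return An [expression_matrix()] with `layer = "normalized"`. Note the
#'   Pearson variant recenters residuals to be non-negative by subtracting
#'   the per-gene minimum, keeping the container's non-negativity contract.
#' @export
normalize_counts <- function(counts, method = c("lognorm", "pearson"),
                             scale_factor = 1e4, theta = 100) {
  method <- match.arg(method)
  .stop_if(!inherits(counts, "expression_matrix"),
           "counts must be an expression_matrix")
  .stop_if(counts$layer == "normalized", "counts are already normalized")
  x <- counts$values
  zero <- counts$spot_ids[colSums(x) == 0]
  .stop_if(length(zero) > 0,
           "all-zero spot(s): ", paste(head(zero, 5), collapse = ", "))
  values <- if (method == "lognorm") {
    .lognorm(x, scale_factor)
  } else {
    depth <- colSums(x)
    pi_g <- rowSums(x) / sum(x)
    mu <- outer(pi_g, depth)
    res <- (x - mu) / sqrt(mu + mu^2 / theta)
    res[mu == 0] <- 0
    clip <- sqrt(ncol(x))
    res <- pmin(pmax(res, -clip), clip)
    res - apply(res, 1, min)
  }
  expression_matrix(values, counts$gene_ids, counts$spot_ids,
                    layer = "normalized")
}

#' Build the cell-type signature matrix from a single-cell reference
#'
#' `W[i, k]` is the mean normalized expression of gene `i` over the
#' reference cells of type `k`; collapsing the reference to per-type means
#' avoids carrying the full single-cell matrix through model fitting.
#'
#' @param ref a [single_cell_reference()].
#' @param normalizer function mapping a genes-by-cells count matrix to
#'   normalized values on the same scale as the spot normalization; the
#'   default applies the `"lognorm"` transform of [normalize_counts()].
#' @return A [signature_matrix()] whose column order is the reference's
#'   declared cell-type order.
#' @export
build_signature <- function(ref, normalizer = NULL) {
  .stop_if(!inherits(ref, "single_cell_reference"),
           "ref must be a single_cell_reference")
  if (is.null(normalizer)) normalizer <- .lognorm
  keep <- colSums(ref$values) > 0
  .stop_if(!any(keep), "reference has no cells with nonzero counts")
  norm <- normalizer(ref$values[, keep, drop = FALSE])
  labels <- ref$cell_type_labels[keep]
  empty <- ref$cell_types[!(ref$cell_types %in% labels)]
  .stop_if(length(empty) > 0,
           "no cells for type ", paste(empty, collapse = ", "))
  w <- vapply(ref$cell_types, function(k) {
    rowMeans(norm[, labels == k, drop = FALSE])
  }, numeric(nrow(norm)))
  signature_matrix(w, ref$gene_ids, ref$cell_types)
}

# per-gene dispersion statistic: variance of variance-stabilized values
.gene_dispersion <- function(x) apply(.lognorm(x), 1, var)

#' Select the shared most highly variable genes
#'
#' Ranks genes in each dataset by the variance of their
#' variance-stabilized (depth-scaled log1p) values, takes the `top_n` most
#' variable genes of each, and returns the intersection in the spot
#' dataset's gene order. Restricting model fitting to this shared set
#' mirrors the standard two-way HVG intersection (2000 per dataset for
#' full-size data).
#'
#' @param st an [expression_matrix()] of spot counts.
#' @param ref a [single_cell_reference()] (or second expression matrix).
#' @param top_n how many top genes to rank per dataset, default 2000.
#' @return Character vector of shared highly variable gene ids.
#' @export
select_shared_hvgs <- function(st, ref, top_n = 2000) {
  .stop_if(!inherits(st, "expression_matrix"),
           "st must be an expression_matrix")
  ref_vals <- if (inherits(ref, "single_cell_reference")) ref$values
              else if (inherits(ref, "expression_matrix")) ref$values
              else stop("ref must be a single_cell_reference or ",
                        "expression_matrix", call. = FALSE)
  shared <- intersect(st$gene_ids, rownames(ref_vals))
  .stop_if(length(shared) == 0, "datasets share no gene ids")
  top <- function(disp) names(sort(disp, decreasing = TRUE))[
    seq_len(min(top_n, length(disp)))]
  hv_st <- top(.gene_dispersion(st$values))
  hv_ref <- top(.gene_dispersion(ref_vals))
  out <- st$gene_ids[st$gene_ids %in% intersect(hv_st, hv_ref)]
  .stop_if(length(out) == 0, "no overlap between the top variable gene sets")
  out
}

# align Y (expression_matrix, normalized) and W (signature_matrix) on their
# shared genes by id; unmatched ids are dropped with a message
.align_genes <- function(Y, W) {
  shared <- intersect(Y$gene_ids, W$gene_ids)
  dropped <- (length(Y$gene_ids) - length(shared)) +
             (length(W$gene_ids) - length(shared))
  .stop_if(length(shared) < 2,
           "fewer than 2 genes shared between Y and W after alignment")
  if (dropped > 0)
    message(dropped, " unmatched gene id(s) dropped during Y/W alignment")
  list(Y = Y$values[shared, , drop = FALSE],
       W = W$values[shared, , drop = FALSE])
}
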