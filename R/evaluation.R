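# Performance statistics: the Q ratio against a binary annotation, the
# improvement Delta of the image-guided model over the base model, its
# permutation null with a normal-approximation fallback, MAE against
# simulated ground truth, and Spearman rank agreement.

.as_mask <- function(mask, n = NULL) {
  if (inherits(mask, "spot_annotation")) mask <- mask$mask
  .stop_if(!is.logical(mask) || anyNA(mask), "mask must be logical, no NA")
  if (!is.null(n)) .stop_if(length(mask) != n,
                            "mask length does not match the value vectors")
  .stop_if(!any(mask) || all(mask),
           "mask needs at least one annotated and one unannotated spot")
  mask
}

# run code with a private RNG stream, restoring the caller's afterwards
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", globalenv())
  on.exit(if (has) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Ratio of median proportions inside vs outside an annotation
#'
#' `Q = median(h[annotated]) / median(h[other])`: how much more of the
#' evaluated cell type a model places in annotated (e.g.
#' pathologist-labelled immune-infiltrated) spots than elsewhere. Larger is
#' better when the annotation is treated as ground truth. Invariant to
#' rescaling `h` by a positive constant and to spot order.
#'
#' @param h per-spot proportions of the evaluated cell type (group),
#'   strictly positive.
#' @param mask a [spot_annotation()] or logical vector.
#' @return A positive scalar.
#' @export
q_statistic <- function(h, mask) {
  h <- as.numeric(h)
  mask <- .as_mask(mask, length(h))
  .stop_if(any(!is.finite(h)) || any(h <= 0), "h must be strictly positive")
  denom <- median(h[!mask])
  .stop_if(denom == 0, "median of unannotated spots is zero")
  median(h[mask]) / denom
}

#' Improvement of the image-guided over the base model
#'
#' `Delta = Q_guided - Q_base`; antisymmetric in its arguments.
#'
#' @param q_gist,q_base finite `Q` statistics.
#' @return A scalar.
#' @export
delta_improvement <- function(q_gist, q_base) {
  .stop_if(!is.finite(q_gist) || !is.finite(q_base),
           "both Q values must be finite")
  q_gist - q_base
}

#' Permutation test for the improvement statistic
#'
#' Builds a null distribution for `Delta` by re-drawing the annotation
#' mask uniformly at random among spot subsets of the same size as the
#' observed annotation, recomputing `Delta` for each permuted mask. The
#' one-sided p-value is the proportion of permuted values at least as
#' extreme as the observed `Delta` (`>=` for the improvement claim;
#' `alternative = "two.sided"` compares `|Delta|`). When no permuted value
#' reaches the observed statistic the null is approximated by a normal
#' distribution with the mean and standard deviation of the permuted
#' values, and `used_normal_approx` is set.
#'
#' @param h_gist,h_base per-spot proportions of the evaluated cell type
#'   under the two models, aligned to `mask`.
#' @param mask a [spot_annotation()] or logical vector.
#' @param n_perm number of permutations, default 100000.
#' @param seed integer seed; results are bit-reproducible given it.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return An object of class `permutation_result` with fields
#'   `observed_delta`, `null_deltas`, `p_value`, `used_normal_approx`,
#'   `n_perm`, `seed`.
#' @export
permutation_test <- function(h_gist, h_base, mask, n_perm = 100000,
                             seed = 1L,
                             alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  h_gist <- as.numeric(h_gist); h_base <- as.numeric(h_base)
  .stop_if(length(h_gist) != length(h_base),
           "h_gist and h_base must have the same length")
  mask <- .as_mask(mask, length(h_gist))
  .stop_if(n_perm < 1, "n_perm must be >= 1")
  observed <- delta_improvement(q_statistic(h_gist, mask),
                                q_statistic(h_base, mask))
  n <- length(mask); npos <- sum(mask)
  null_deltas <- .with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      pm <- logical(n)
      pm[sample.int(n, npos)] <- TRUE
      delta_improvement(q_statistic(h_gist, pm), q_statistic(h_base, pm))
    }, numeric(1))
  })
  extreme <- if (alternative == "greater") sum(null_deltas >= observed)
             else sum(abs(null_deltas) >= abs(observed))
  if (extreme == 0) {
    mu <- mean(null_deltas); s <- sd(null_deltas)
    p <- if (alternative == "greater")
      pnorm(observed, mu, s, lower.tail = FALSE)
    else 2 * pnorm(abs(observed), mu, s, lower.tail = FALSE)
    used_normal <- TRUE
  } else {
    p <- extreme / n_perm
    used_normal <- FALSE
  }
  structure(list(observed_delta = observed, null_deltas = null_deltas,
                 p_value = min(p, 1), used_normal_approx = used_normal,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 alternative = alternative),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> Delta = %.4g, p = %.3g (%s, %d permutations%s)\n",
    x$observed_delta, x$p_value, x$alternative, x$n_perm,
    if (x$used_normal_approx) ", normal approximation" else ""))
  invisible(x)
}

#' Mean absolute error against ground-truth proportions
#'
#' Mean over all cell-type-by-spot entries of the absolute difference
#' between prediction and truth.
#'
#' @param pred,truth [proportions_matrix()] objects (or plain matrices) of
#'   matching shape and ordering.
#' @return A non-negative scalar.
#' @export
mean_absolute_error <- function(pred, truth) {
  pv <- if (inherits(pred, "proportions_matrix")) pred$values
        else as.matrix(pred)
  tv <- if (inherits(truth, "proportions_matrix")) truth$values
        else as.matrix(truth)
  .stop_if(!all(dim(pv) == dim(tv)), "pred and truth shapes differ")
  if (!is.null(rownames(pv)) && !is.null(rownames(tv)))
    .stop_if(!identical(rownames(pv), rownames(tv)) ||
               !identical(colnames(pv), colnames(tv)),
             "pred and truth orderings differ")
  mean(abs(pv - tv))
}

#' Spearman rank agreement
#'
#' Spearman correlation (average ranks at ties) between per-spot estimates
#' and a rank-comparable reference, the agreement metric used throughout
#' the hyperparameter sweep and image-ground-truth comparisons.
#'
#' @param pred,reference numeric vectors of equal length >= 3; constant
#'   input is an error (the correlation is undefined).
#' @return A scalar in `[-1, 1]`.
#' @export
rank_agreement <- function(pred, reference) {
  pred <- as.numeric(pred); reference <- as.numeric(reference)
  .stop_if(length(pred) != length(reference), "lengths differ")
  .stop_if(length(pred) < 3, "need at least 3 paired values")
  .stop_if(sd(pred) == 0 || sd(reference) == 0,
           "rank correlation undefined for constant input")
  cor(pred, reference, method = "spearman")
}

#' Encode ordinal infiltration grades
#'
#' Maps grade labels (default `low`/`middle`/`high`) onto `1/2/3` for
#' rank-based comparisons such as one-sided `wilcox.test` between spot
#' groups.
#'
#' @param grades character vector of grade labels.
#' @param levels ordered grade levels, lowest first.
#' @return Integer vector on the ordinal scale.
#' @export
encode_grades <- function(grades, levels = c("low", "middle", "high")) {
  out <- match(grades, levels)
  .stop_if(anyNA(out), "unknown grade label(s): ",
           paste(unique(grades[is.na(out)]), collapse = ", "))
  out
}
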