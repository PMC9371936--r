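# Synthetic-data generators matching the statistical structure the model
# assumes: a negative-binomial single-cell reference with truncated-t
# log-fold-changes between cell types, Dirichlet-weighted mixtures of
# independently drawn cells, and a synthetic guiding-image channel whose
# fidelity to one cell type's true proportions is tunable. Plus the two
# non-Bayesian baselines used for benchmarking.

#' Simulation configuration
#'
#' Defaults encode the benchmark design: 6 cell types, 100 mixture spots
#' with flat-Dirichlet ground truth, mixtures averaging 100 independently
#' drawn cells per type, and a paired reference of 100 cells per type.
#' Per-type mean profiles are a shared log-normal baseline times
#' `exp(lfc)` with `lfc` drawn from a scaled, truncated Student-t; counts
#' are negative binomial with mean `w` and dispersion `phi` (variance
#' `w + w^2/phi`). The log-fold-change scale defaults to 0.08 with heavy
#' t(3) tails: the benchmark emulates *closely related* cell types (the
#' regime where decomposition is genuinely hard and where the
#' log-fold-change distribution between two related immune populations
#' concentrates near zero with rare large values), with UMI-typical
#' gene-level overdispersion (`phi = 0.3`) and shallow spot-level depth
#' (2000 counts over 1000 genes). See the methods vignette for the full
#' rationale.
#'
#' @param n_genes number of genes, default 1000.
#' @param n_cell_types number of cell types, default 6.
#' @param cells_per_type reference cells per type, default 100.
#' @param n_spots number of mixture spots, default 100.
#' @param cells_per_spot cells drawn per type per spot, default 100.
#' @param dirichlet_alpha Dirichlet concentration (scalar or length-p),
#'   default 1 (flat).
#' @param nb_dispersion NB dispersion `phi` (scalar or per-gene),
#'   default 0.3.
#' @param lfc_df,lfc_scale,lfc_truncation truncated-t log-fold-change
#'   parameters, defaults 3, 0.08, 5.
#' @param baseline_meanlog,baseline_sdlog log-normal baseline mean profile
#'   parameters, defaults 0 and 1.
#' @param library_size expected per-cell depth the baseline is rescaled
#'   to, default 2000.
#' @param seed integer master seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000, n_cell_types = 6, cells_per_type = 100,
                       n_spots = 100, cells_per_spot = 100,
                       dirichlet_alpha = 1, nb_dispersion = 0.3,
                       lfc_df = 3, lfc_scale = 0.08, lfc_truncation = 5,
                       baseline_meanlog = 0, baseline_sdlog = 1,
                       library_size = 2000, seed = 1L) {
  .stop_if(n_genes < 1 || n_cell_types < 1 || cells_per_type < 1 ||
             n_spots < 1 || cells_per_spot < 1, "counts must be positive")
  .stop_if(any(dirichlet_alpha <= 0), "dirichlet_alpha must be positive")
  .stop_if(any(nb_dispersion <= 0), "nb_dispersion must be positive")
  .stop_if(lfc_df <= 0 || lfc_scale < 0 || lfc_truncation <= 0,
           "invalid log-fold-change parameters")
  structure(list(n_genes = as.integer(n_genes),
                 n_cell_types = as.integer(n_cell_types),
                 cells_per_type = as.integer(cells_per_type),
                 n_spots = as.integer(n_spots),
                 cells_per_spot = as.integer(cells_per_spot),
                 dirichlet_alpha = dirichlet_alpha,
                 nb_dispersion = nb_dispersion,
                 lfc_df = lfc_df, lfc_scale = lfc_scale,
                 lfc_truncation = lfc_truncation,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 library_size = library_size, seed = as.integer(seed)),
            class = "sim_config")
}

.rtrunc_t <- function(n, df, scale, trunc) {
  if (scale == 0) return(numeric(n))
  out <- numeric(0)
  while (length(out) < n) {
    d <- rt(n, df) * scale
    out <- c(out, d[abs(d) <= trunc])
  }
  out[seq_len(n)]
}

.rdirichlet <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = alpha, rate = 1),
              nrow = length(alpha))
  sweep(g, 2, colSums(g), "/")
}

.sim_ids <- function(cfg) {
  list(genes = sprintf("g%04d", seq_len(cfg$n_genes)),
       types = sprintf("ct%d", seq_len(cfg$n_cell_types)),
       spots = sprintf("spot%03d", seq_len(cfg$n_spots)))
}

# generative per-type mean profiles: shared log-normal baseline rescaled
# to the target library size, times exp(truncated-t lfc)
.sim_means <- function(cfg) {
  ids <- .sim_ids(cfg)
  baseline <- rlnorm(cfg$n_genes, cfg$baseline_meanlog, cfg$baseline_sdlog)
  baseline <- baseline / sum(baseline) * cfg$library_size
  lfc <- matrix(.rtrunc_t(cfg$n_genes * cfg$n_cell_types, cfg$lfc_df,
                          cfg$lfc_scale, cfg$lfc_truncation),
                cfg$n_genes, cfg$n_cell_types)
  w <- baseline * exp(lfc)
  dimnames(w) <- list(ids$genes, ids$types)
  w
}

#' Simulate a single-cell reference dataset
#'
#' Draws the generative per-type mean profiles, then `cells_per_type`
#' independent NB cells per type.
#'
#' @param cfg a [sim_config()].
#' @param seed seed for this draw, default `cfg$seed`.
#' @return List with `reference` (a [single_cell_reference()]) and `truth`
#'   (list with the generative mean matrix `W_true`).
#' @export
simulate_reference <- function(cfg = sim_config(), seed = cfg$seed) {
  set.seed(seed)
  w <- .sim_means(cfg)
  phi <- rep_len(cfg$nb_dispersion, cfg$n_genes)
  cells <- do.call(cbind, lapply(seq_len(cfg$n_cell_types), function(k) {
    matrix(rnbinom(cfg$n_genes * cfg$cells_per_type, mu = w[, k], size = phi),
           cfg$n_genes, cfg$cells_per_type)
  }))
  labels <- factor(rep(colnames(w), each = cfg$cells_per_type),
                   levels = colnames(w))
  list(reference = single_cell_reference(cells, labels, rownames(w)),
       truth = list(W_true = w))
}

#' Simulate mixture spots with Dirichlet ground truth
#'
#' For every spot a ground-truth proportion vector is drawn from
#' `Dirichlet(alpha)`; the spot's expression is the proportion-weighted
#' average, over cell types, of the mean of `cells_per_spot` freshly drawn
#' NB cells per type (independent of any reference draw).
#'
#' @param means generative per-type mean matrix (`truth$W_true` from
#'   [simulate_reference()]).
#' @param cfg a [sim_config()].
#' @param seed seed for this draw; defaults to an offset of `cfg$seed` so
#'   that mixtures are independent of the reference drawn at `cfg$seed`.
#' @return List with `counts` (an [expression_matrix()], layer `"counts"`)
#'   and `truth` (list with `H_true`, a [proportions_matrix()], and
#'   `W_true`).
#' @export
simulate_mixtures <- function(means, cfg = sim_config(),
                              seed = (cfg$seed + 500009) %% 2147483647) {
  .stop_if(nrow(means) != cfg$n_genes || ncol(means) != cfg$n_cell_types,
           "means shape does not match cfg")
  set.seed(seed)
  ids <- .sim_ids(cfg)
  alpha <- rep_len(cfg$dirichlet_alpha, cfg$n_cell_types)
  phi <- rep_len(cfg$nb_dispersion, cfg$n_genes)
  H <- .rdirichlet(cfg$n_spots, alpha)
  dimnames(H) <- list(ids$types, ids$spots)
  y <- vapply(seq_len(cfg$n_spots), function(j) {
    mix <- numeric(cfg$n_genes)
    for (k in seq_len(cfg$n_cell_types)) {
      cells <- matrix(
        rnbinom(cfg$n_genes * cfg$cells_per_spot, mu = means[, k],
                size = phi),
        cfg$n_genes, cfg$cells_per_spot)
      mix <- mix + H[k, j] * rowMeans(cells)
    }
    mix
  }, numeric(cfg$n_genes))
  dimnames(y) <- list(ids$genes, ids$spots)
  list(counts = expression_matrix(y, layer = "counts"),
       truth = list(H_true = proportions_matrix(.simplexify(H)),
                    W_true = means))
}

#' Simulate a guiding-image prior channel of tunable fidelity
#'
#' Emulates what a capped/aggregated/mapped image channel provides: values
#' that track one cell type's true proportions to a controllable degree.
#' Computed as the logit-space convex combination
#' `rho * logit(h_true) + (1 - rho) * noise` mapped back through the
#' logistic, where the noise is Gaussian with the location/scale of
#' `logit(h_true)`. `rho = 1` gives a monotone transform of the truth
#' (rank-perfect prior); `rho = 0` gives truth-independent noise (a
#' misleading prior).
#'
#' @param h_true per-spot true proportions of the target type, in (0, 1);
#'   a named vector or one row of `H_true`.
#' @param fidelity `rho` in `[0, 1]`.
#' @param seed integer seed.
#' @return A [spot_prior_values()] with `source = "synthetic"`.
#' @export
simulate_image_prior <- function(h_true, fidelity, seed = 1L) {
  .stop_if(fidelity < 0 || fidelity > 1, "fidelity must lie in [0, 1]")
  h <- pmin(pmax(as.numeric(h_true), 1e-6), 1 - 1e-6)
  ids <- names(h_true)
  .stop_if(is.null(ids), "h_true must be named by spot id")
  lg <- qlogis(h)
  set.seed(seed)
  noise <- rnorm(length(h), mean(lg), max(sd(lg), 1e-8))
  v <- plogis(fidelity * lg + (1 - fidelity) * noise)
  spot_prior_values(ids, pmin(pmax(v, 1e-4), 1 - 1e-4), source = "synthetic")
}

#' Per-spot linear regression baseline
#'
#' The simplest conceivable decomposition: ordinary least squares of each
#' spot's normalized expression on the signature columns, with negative
#' coefficients clipped to zero and the rest renormalized onto the
#' simplex. No intercept is used by default (the regression is on the
#' signature columns alone); set `intercept = TRUE` to absorb additive
#' scale offsets.
#'
#' @param Y an [expression_matrix()] with `layer = "normalized"`.
#' @param W a [signature_matrix()] (genes aligned by id).
#' @param intercept include an intercept, default FALSE.
#' @return A [proportions_matrix()].
#' @export
baseline_linear_regression <- function(Y, W, intercept = FALSE) {
  al <- .align_genes(Y, W)
  X <- if (intercept) cbind(`(intercept)` = 1, al$W) else al$W
  qx <- qr(X)
  .stop_if(qx$rank < ncol(X), "signature matrix is rank-deficient")
  cf <- qr.coef(qx, al$Y)
  h <- cf[if (intercept) -1 else TRUE, , drop = FALSE]
  proportions_matrix(.simplexify(pmax(h, 0)), colnames(al$W),
                     colnames(al$Y))
}

#' Per-spot constrained least-squares baseline
#'
#' Non-negative, sum-to-one least squares:
#' `argmin ||y - W h||^2  s.t.  h >= 0, sum(h) = 1`, solved as a quadratic
#' program per spot.
#'
#' @inheritParams baseline_linear_regression
#' @return A [proportions_matrix()].
#' @export
baseline_constrained_ls <- function(Y, W) {
  al <- .align_genes(Y, W)
  p <- ncol(al$W)
  D <- crossprod(al$W)
  .stop_if(qr(al$W)$rank < p, "signature matrix is rank-deficient")
  A <- cbind(rep(1, p), diag(p))  # first column: equality sum(h) = 1
  h <- apply(al$Y, 2, function(y) {
    sol <- tryCatch(
      quadprog::solve.QP(D, crossprod(al$W, y), A,
                         bvec = c(1, rep(0, p)), meq = 1),
      error = function(e) stop("constrained solver failed: ",
                               conditionMessage(e), call. = FALSE))
    sol$solution
  })
  proportions_matrix(.simplexify(pmax(h, 0)), colnames(al$W),
                     colnames(al$Y))
}

#' Run the simulation benchmark end to end
#'
#' Generates a paired reference and mixture dataset, pushes both through
#' the preprocessing path (log-normalization, shared-HVG restriction,
#' signature collapse), fits the requested estimators and reports each
#' one's mean absolute error against the Dirichlet ground truth.
#' Optionally fits the image-guided model with a synthetic prior of given
#' fidelity on the first cell type.
#'
#' @param cfg a [sim_config()].
#' @param methods subset of `c("base", "linear", "constrained", "gist")`.
#' @param top_n_hvg per-dataset HVG count before intersection, default 500.
#' @param mcmc an [mcmc_config()] for the Bayesian fits.
#' @param prior_fidelity synthetic image-prior fidelity for `"gist"`.
#' @param lambda prior concentration for `"gist"`, default 50.
#' @param target_cell_type prior target for `"gist"`, default the first
#'   simulated type.
#' @return List with `mae` (named numeric), `H` (list of
#'   [proportions_matrix()] per method), `truth`, `fits`, and the prepared
#'   `Y`/`W` inputs.
#' @export
run_decomposition_benchmark <- function(cfg = sim_config(),
                                        methods = c("base", "linear"),
                                        top_n_hvg = 500,
                                        mcmc = mcmc_config(1000, 500,
                                                           seed = cfg$seed),
                                        prior_fidelity = 0.9, lambda = 50,
                                        target_cell_type = "ct1") {
  methods <- match.arg(methods,
                       c("base", "linear", "constrained", "gist"),
                       several.ok = TRUE)
  ref <- simulate_reference(cfg)
  mix <- simulate_mixtures(ref$truth$W_true, cfg)
  hvgs <- select_shared_hvgs(mix$counts, ref$reference, top_n = top_n_hvg)
  Yn <- normalize_counts(mix$counts)
  Y <- expression_matrix(Yn$values[hvgs, , drop = FALSE],
                         layer = "normalized")
  Wfull <- build_signature(ref$reference)
  W <- signature_matrix(Wfull$values[hvgs, , drop = FALSE])

  H <- list(); fits <- list()
  truth <- mix$truth$H_true
  if ("base" %in% methods || "gist" %in% methods) {
    fits$base <- fit_base_model(Y, W, mcmc)
    H$base <- posterior_proportions(fits$base)
  }
  if ("linear" %in% methods) H$linear <- baseline_linear_regression(Y, W)
  if ("constrained" %in% methods) H$constrained <- baseline_constrained_ls(Y, W)
  if ("gist" %in% methods) {
    h_true_a <- truth$values[target_cell_type, ]
    raw <- simulate_image_prior(h_true_a, prior_fidelity,
                                seed = (cfg$seed + 99991) %% 2147483647)
    mapped <- quantile_map(raw, H$base$values[target_cell_type, ])
    pr <- make_prior(mapped, target_cell_type, lam = lambda)
    fits$gist <- fit_gist_model(Y, W, pr, mcmc)
    H$gist <- posterior_proportions(fits$gist)
  }
  mae <- vapply(H, function(hh) mean_absolute_error(hh, truth), numeric(1))
  if (!("base" %in% methods)) {
    H$base <- NULL
    mae <- mae[names(mae) != "base" | "base" %in% methods]
  }
  list(mae = mae, H = H, truth = mix$truth, fits = fits, Y = Y, W = W,
       hvgs = hvgs, cfg = cfg)
}
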