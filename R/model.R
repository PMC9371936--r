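# The Bayesian decomposition model. Per spot j the normalized expression
# y_j is modelled as
#
#   y_ij ~ t(nu_j, beta0_j + W_i H^(j), sigma_j)
#
# with H^(j) on the open simplex under a flat Dirichlet prior,
# nu_j = 3 + nu', nu' ~ Gamma(2, 0.1), beta0_j flat and sigma_j
# half-Cauchy. The image-guided variant multiplies the prior by a
# Beta(tau_j * lambda, (1 - tau_j) * lambda) density on the proportion of
# the image-informed cell type (or on the summed proportion of a group of
# types). Spots share no parameters and are fitted independently with
# per-spot RNG streams, so joint and single-spot fits agree exactly.

# derived per-spot / per-chain seed, kept below 2^31; keyed on the spot ID
# (not its column position) so that fitting any subset of spots reproduces
# the jointly-fitted results bit for bit
.spot_seed <- function(seed, spot_id, chain = 1L) {
  h <- 7
  for (cc in utf8ToInt(spot_id)) h <- (h * 131 + cc) %% 1048573
  ((as.double(seed) %% 97777L) * 1000003 + h * 1009 +
     (chain - 1) * 104729) %% 2147483647 + 1
}

.fit_spots <- function(Y, W, prior, cfg) {
  .stop_if(!inherits(cfg, "mcmc_config"), "cfg must be an mcmc_config")
  .stop_if(!inherits(Y, "expression_matrix"),
           "Y must be an expression_matrix")
  .stop_if(Y$layer != "normalized",
           "Y must be normalized (see normalize_counts)")
  .stop_if(!inherits(W, "signature_matrix"), "W must be a signature_matrix")
  al <- .align_genes(Y, W)
  p <- ncol(al$W)
  n <- ncol(al$Y)
  types <- colnames(al$W)
  spots <- colnames(al$Y)

  group <- integer(0); tau <- NULL; lam <- 0
  if (!is.null(prior)) {
    .stop_if(!inherits(prior, "prior_spec"), "prior must be a prior_spec")
    missing_t <- setdiff(prior$target_cell_type, types)
    .stop_if(length(missing_t) > 0, "prior target cell type(s) not in W: ",
             paste(missing_t, collapse = ", "))
    .stop_if(length(prior$target_cell_type) >= p,
             "the prior cannot target every cell type (1 - h_a must stay ",
             "positive)")
    group <- match(prior$target_cell_type, types) - 1L  # 0-based for C++
    tau <- prior$tau
    if (!is.null(prior$spot_ids)) {
      missing_s <- setdiff(spots, prior$spot_ids)
      .stop_if(length(missing_s) > 0, "prior tau missing for spot(s): ",
               paste(head(missing_s, 5), collapse = ", "))
      tau <- tau[spots]
    } else {
      .stop_if(length(tau) != n, "prior$tau must have one value per spot")
    }
    lam <- prior$lam
  }

  keep <- cfg$iterations - cfg$burn_in
  h_mean <- matrix(NA_real_, p, n, dimnames = list(types, spots))
  h_draws <- array(NA_real_, c(keep * cfg$chains, p, n))
  nu_mean <- beta0_mean <- sigma_mean <- ess_min <- setNames(numeric(n), spots)

  for (j in seq_len(n)) {
    y <- al$Y[, j]
    sdy <- max(sd(y), 1e-3)
    hj <- matrix(NA_real_, keep * cfg$chains, p)
    nuj <- b0j <- sgj <- numeric(0)
    for (ch in seq_len(cfg$chains)) {
      set.seed(.spot_seed(cfg$seed, spots[j], ch))
      sm <- .gist_spot_mcmc(y, al$W, rep(1, p), group,
                            if (length(group)) tau[j] else 0.5, lam,
                            cfg$iterations, cfg$burn_in,
                            sigma_scale = 5 * sdy, init_sigma = sdy / 2)
      rows <- (ch - 1) * keep + seq_len(keep)
      hj[rows, ] <- sm$h
      nuj <- c(nuj, sm$nu); b0j <- c(b0j, sm$beta0); sgj <- c(sgj, sm$sigma)
    }
    h_draws[, , j] <- hj
    h_mean[, j] <- colMeans(hj)
    nu_mean[j] <- mean(nuj)
    beta0_mean[j] <- mean(b0j)
    sigma_mean[j] <- mean(sgj)
    ess_min[j] <- if (p > 1)
      min(coda::effectiveSize(coda::mcmc(hj))) else keep * cfg$chains
  }

  low <- ess_min < 0.02 * keep * cfg$chains
  if (any(low))
    warning(sum(low), " spot(s) with low effective sample size; consider ",
            "more iterations or chains")

  structure(list(
    H_mean = proportions_matrix(.simplexify(h_mean), types, spots),
    nu_mean = nu_mean, beta0_mean = beta0_mean, sigma_mean = sigma_mean,
    h_draws = h_draws, cell_type_ids = types, spot_ids = spots,
    diagnostics = data.frame(spot_id = spots, ess_min = ess_min,
                             row.names = NULL),
    prior = prior, mcmc_config = cfg), class = "posterior_fit")
}

#' Fit the expression-only base model
#'
#' Per-spot Bayesian simplex regression with non-informative priors on all
#' cell-type proportions: the Student-t likelihood on normalized
#' expression, a flat Dirichlet on the simplex, Gamma(2, 0.1) on the
#' shifted degrees of freedom (support `nu > 3`), flat intercept and
#' half-Cauchy scale. Point estimates are posterior means over post-burn-in
#' draws.
#'
#' @param Y an [expression_matrix()] with `layer = "normalized"`, on the
#'   same normalized scale as `W`.
#' @param W a [signature_matrix()]; genes are aligned to `Y` by id and
#'   unmatched ids dropped.
#' @param cfg an [mcmc_config()].
#' @return An object of class `posterior_fit` with fields `H_mean` (a
#'   [proportions_matrix()]), `nu_mean`, `beta0_mean`, `sigma_mean`,
#'   per-spot draws `h_draws`, `diagnostics` and `mcmc_config`.
#' @export
fit_base_model <- function(Y, W, cfg = mcmc_config()) {
  .fit_spots(Y, W, prior = NULL, cfg = cfg)
}

#' Fit the image-guided model
#'
#' Identical to [fit_base_model()] except that each spot's log-prior gains
#' the Beta(`tau_j * lam`, `(1 - tau_j) * lam`) log-density evaluated at
#' the proportion of the image-informed cell type (for a grouped target,
#' at the summed proportion of the group). As `lam` tends to 0 the fit
#' approaches the base model; as `lam` grows the posterior mean of the
#' targeted proportion is pinned to `tau_j`.
#'
#' @inheritParams fit_base_model
#' @param prior a [prior_spec()]; `tau` must provide one value per spot of
#'   `Y` (matched by spot id when ids are present).
#' @return An object of class `posterior_fit`; see [fit_base_model()].
#' @export
fit_gist_model <- function(Y, W, prior, cfg = mcmc_config()) {
  .stop_if(is.null(prior), "prior is required (use fit_base_model otherwise)")
  .fit_spots(Y, W, prior = prior, cfg = cfg)
}

#' @export
print.posterior_fit <- function(x, ...) {
  cat(sprintf(
    "<posterior_fit> %d cell types x %d spots (%s), %d draws/spot\n",
    length(x$cell_type_ids), length(x$spot_ids),
    if (is.null(x$prior)) "base model" else "image-guided",
    dim(x$h_draws)[1]))
  invisible(x)
}

#' Posterior-mean proportions from a fit
#'
#' Returns the posterior-mean cell-type proportions with columns
#' renormalized to sum to exactly one (the mean of simplex samples can
#' drift from 1 by floating-point accumulation; the correction is
#' cosmetic, below 1e-6).
#'
#' @param fit a `posterior_fit`.
#' @return A [proportions_matrix()].
#' @export
posterior_proportions <- function(fit) {
  .stop_if(!inherits(fit, "posterior_fit"), "fit must be a posterior_fit")
  fit$H_mean
}

# drop-off onset rule: the selected lambda is the grid point at which the
# holdout metric first enters a sustained (monotone to the end of the
# grid) decrease; without one, max(grid) with a warning
.select_lambda <- function(holdout_metric, lambda_grid) {
  dec <- diff(holdout_metric) < 0
  sustained <- rev(cumprod(rev(dec))) > 0  # dec[t..end] all TRUE
  if (any(sustained)) {
    lambda_grid[which(sustained)[1] + 1L]
  } else {
    warning("no sustained drop-off detected; returning max(lambda_grid)")
    max(lambda_grid)
  }
}

# summed proportions over a (group of) cell type(s)
.group_proportions <- function(H, cell_types) {
  .stop_if(!all(cell_types %in% H$cell_type_ids),
           "unknown cell type(s): ",
           paste(setdiff(cell_types, H$cell_type_ids), collapse = ", "))
  colSums(H$values[cell_types, , drop = FALSE])
}

#' Sweep the prior concentration and locate the drop-off point
#'
#' Fits the image-guided model across an increasing grid of `lambda`
#' values and tracks two rank-agreement (Spearman) metrics: the
#' prior-targeted cell type against its reference values (expected to rise
#' with `lambda`, since the posterior is pulled towards the prior), and a
#' held-out cell type -- which receives no prior -- against independent
#' reference values. Overweighting the image eventually degrades the
#' held-out agreement; the selected `lambda` is the grid point at which a
#' sustained monotone decrease of the held-out metric begins (every later
#' grid step also decreases). If no sustained decrease occurs the maximum
#' grid value is returned with a warning.
#'
#' @inheritParams fit_gist_model
#' @param lambda_grid strictly increasing positive values, length >= 3.
#' @param target_reference per-spot reference values for the prior-targeted
#'   type (e.g. image-derived intensities).
#' @param holdout_reference per-spot reference values for `holdout_type`.
#' @param holdout_type cell type id held out of the prior.
#' @return An object of class `lambda_sweep_result` with fields
#'   `lambda_grid`, `target_metric`, `holdout_metric`, `selected_lambda`.
#' @export
sweep_lambda <- function(Y, W, prior, lambda_grid, target_reference,
                         holdout_reference, holdout_type,
                         cfg = mcmc_config()) {
  .stop_if(length(lambda_grid) < 3, "lambda_grid must have length >= 3")
  .stop_if(any(diff(lambda_grid) <= 0) || any(lambda_grid <= 0),
           "lambda_grid must be strictly increasing and positive")
  .stop_if(holdout_type %in% prior$target_cell_type,
           "holdout type must differ from the prior target")
  target_metric <- holdout_metric <- numeric(length(lambda_grid))
  for (i in seq_along(lambda_grid)) {
    pr_i <- prior_spec(prior$target_cell_type, prior$tau, lambda_grid[i],
                       spot_ids = prior$spot_ids)
    fit <- fit_gist_model(Y, W, pr_i, cfg)
    H <- posterior_proportions(fit)
    target_metric[i] <- rank_agreement(
      .group_proportions(H, prior$target_cell_type), target_reference)
    holdout_metric[i] <- rank_agreement(
      .group_proportions(H, holdout_type), holdout_reference)
  }
  if (any(diff(target_metric) < -0.05))
    warning("target metric not non-decreasing across the grid (MCMC noise ",
            "or a prior in conflict with the expression data)")
  selected <- .select_lambda(holdout_metric, lambda_grid)
  structure(list(lambda_grid = lambda_grid, target_metric = target_metric,
                 holdout_metric = holdout_metric, selected_lambda = selected),
            class = "lambda_sweep_result")
}

#' @export
print.lambda_sweep_result <- function(x, ...) {
  cat("<lambda_sweep_result>\n")
  print(data.frame(lambda = x$lambda_grid, target = round(x$target_metric, 3),
                   holdout = round(x$holdout_metric, 3)))
  cat("selected lambda:", x$selected_lambda, "\n")
  invisible(x)
}
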