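# Bayesian core: recovery, prior limits behaviour, invariants, and an
# independent MCMC oracle (JAGS) on the same posterior.

test_that("a single cell type forces h = 1 regardless of the data", {
  set.seed(2)
  Y <- expression_matrix(matrix(rexp(30), 15, 2,
                                dimnames = list(sprintf("g%d", 1:15),
                                                c("s1", "s2"))),
                         layer = "normalized")
  W <- signature_matrix(matrix(rexp(15), 15, 1,
                               dimnames = list(sprintf("g%d", 1:15), "only")))
  fit <- suppressWarnings(fit_base_model(Y, W, mcmc_config(300, 150, seed = 1)))
  expect_equal(unname(posterior_proportions(fit)$values), matrix(1, 1, 2))
})

test_that("noiseless orthogonal toy is recovered within 0.05, and matches
           the constrained least-squares optimum", {
  toy <- toy_noiseless(c(0.2, 0.3, 0.5), n = 2)
  fit <- suppressWarnings(fit_base_model(toy$Y, toy$W,
                                         mcmc_config(2000, 1000, seed = 7)))
  H <- posterior_proportions(fit)$values
  expect_true(all(abs(H - toy$h) < 0.05))
  # independent check that the truth is the sum-to-one least-squares
  # optimum: exhaustive support enumeration
  h_star <- enum_cls(toy$Y$values[, 1], toy$W$values)
  expect_equal(h_star, toy$h, tolerance = 1e-9)
  expect_true(all(abs(H[, 1] - h_star) < 0.05))
  # degrees-of-freedom support: all draws above 3
  expect_true(all(fit$nu_mean > 3))
})

test_that("joint and single-spot fits agree bit for bit (spot independence)", {
  toy <- toy_noiseless(c(0.25, 0.35, 0.4), n = 3, m = 21)
  cfg <- mcmc_config(400, 200, seed = 11)
  joint <- suppressWarnings(fit_base_model(toy$Y, toy$W, cfg))
  alone <- suppressWarnings(fit_base_model(
    expression_matrix(toy$Y$values[, 2, drop = FALSE], layer = "normalized"),
    toy$W, cfg))
  expect_identical(joint$H_mean$values[, 2], alone$H_mean$values[, 1])
  expect_identical(joint$nu_mean[[2]], alone$nu_mean[[1]])
})

test_that("permuting cell-type order permutes the posterior means", {
  toy <- toy_noiseless(c(0.2, 0.3, 0.5), n = 1)
  cfg <- mcmc_config(1500, 750, seed = 5)
  f1 <- suppressWarnings(fit_base_model(toy$Y, toy$W, cfg))
  perm <- c(3, 1, 2)
  Wp <- signature_matrix(toy$W$values[, perm])
  f2 <- suppressWarnings(fit_base_model(toy$Y, Wp, cfg))
  # exchangeable in distribution; deterministic-scan MCMC makes this an
  # approximate (tolerance 0.02), not bit-exact, identity
  expect_equal(f2$H_mean$values[colnames(toy$W$values), 1],
               f1$H_mean$values[, 1], tolerance = 0.02)
})

test_that("vanishing and dominating prior limits behave as stated", {
  toy <- toy_noiseless(c(0.2, 0.3, 0.5), n = 1)
  cfg <- mcmc_config(2000, 1000, seed = 13)
  base <- suppressWarnings(fit_base_model(toy$Y, toy$W, cfg))
  tau <- setNames(0.7, colnames(toy$Y$values))
  tiny <- suppressWarnings(
    fit_gist_model(toy$Y, toy$W, prior_spec("A", tau, 1e-6), cfg))
  expect_true(all(abs(tiny$H_mean$values - base$H_mean$values) < 0.02))
  huge <- suppressWarnings(
    fit_gist_model(toy$Y, toy$W, prior_spec("A", tau, 1e6), cfg))
  expect_gt(huge$H_mean$values["A", 1], 0.68)
  expect_lt(huge$H_mean$values["A", 1], 0.72)
})

test_that("a grouped prior pins the summed proportion of the group", {
  toy <- toy_noiseless(c(0.2, 0.3, 0.5), n = 1)
  tau <- setNames(0.8, "s1")
  fit <- suppressWarnings(fit_gist_model(
    toy$Y, toy$W, prior_spec(c("A", "B"), tau, 1e6),
    mcmc_config(2000, 1000, seed = 3)))
  expect_equal(sum(fit$H_mean$values[c("A", "B"), 1]), 0.8, tolerance = 0.02)
  # prior may not target every type
  expect_error(fit_gist_model(toy$Y, toy$W,
                              prior_spec(c("A", "B", "C"), tau, 10)),
               "every cell type")
})

test_that("posterior matches an independent JAGS fit of the same model", {
  set.seed(19)
  m <- 60; p <- 3
  W <- matrix(rexp(m * p), m, p,
              dimnames = list(sprintf("g%02d", 1:m), c("A", "B", "C")))
  h_true <- c(0.5, 0.3, 0.2)
  y <- as.vector(W %*% h_true) + rnorm(m, 0, 0.4)
  Y <- expression_matrix(matrix(pmax(y, 0), m, 1,
                                dimnames = list(rownames(W), "s1")),
                         layer = "normalized")
  fit <- fit_base_model(Y, signature_matrix(W),
                        mcmc_config(4000, 1000, seed = 2))

  library(rjags)
  mod <- "model {
    for (i in 1:m) { mu[i] <- beta0 + inprod(W[i,], h)
                     y[i] ~ dt(mu[i], prec, nu) }
    for (k in 1:p) { g[k] ~ dgamma(1, 1) }
    h <- g / sum(g)
    nup ~ dgamma(2, 0.1); nu <- 3 + nup
    beta0 ~ dnorm(0, 1.0E-6)
    sigma ~ dt(0, sig_prec, 1) T(0,)
    prec <- pow(sigma, -2)
  }"
  jm <- jags.model(textConnection(mod),
                   data = list(y = Y$values[, 1], W = W, m = m, p = p,
                               sig_prec = (5 * sd(Y$values[, 1]))^-2),
                   inits = list(.RNG.name = "base::Mersenne-Twister",
                                .RNG.seed = 42),
                   n.chains = 1, n.adapt = 300, quiet = TRUE)
  update(jm, 1000, progress.bar = "none")
  sm <- coda.samples(jm, c("h", "sigma"), n.iter = 3000,
                     progress.bar = "none")
  jh <- colMeans(sm[[1]])[paste0("h[", 1:p, "]")]
  expect_equal(unname(fit$H_mean$values[, 1]), unname(jh), tolerance = 0.03)
  expect_equal(fit$sigma_mean[[1]], unname(colMeans(sm[[1]])["sigma"]),
               tolerance = 0.1)
})

test_that("lambda sweep selects the stated drop-off point on a fixed
           metric sequence and warns without one", {
  # holdout {0.6,0.62,0.61,0.55,0.4} on {1,10,50,100,500} selects 50
  expect_equal(spotgist:::.select_lambda(c(0.6, 0.62, 0.61, 0.55, 0.4),
                                         c(1, 10, 50, 100, 500)), 50)
  # monotonically rising holdout: max(grid) with a warning
  expect_warning(
    sel <- spotgist:::.select_lambda(c(0.1, 0.2, 0.3, 0.4, 0.5),
                                     c(1, 10, 50, 100, 500)),
    "no sustained drop-off")
  expect_equal(sel, 500)
  expect_error(sweep_lambda(NULL, NULL, prior_spec("A", c(s1 = .5), 1),
                            c(1, 10), 1, 1, "B"),
               "length >= 3")
})
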