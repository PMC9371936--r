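# Generators: seed determinism, stated moments, degenerate limits; and the
# two baseline estimators against independent oracles.

test_that("generators are seed-deterministic and labelled consistently", {
  cfg <- sim_config(n_genes = 80, n_cell_types = 3, cells_per_type = 10,
                    n_spots = 6, cells_per_spot = 10, seed = 5)
  r1 <- simulate_reference(cfg)
  r2 <- simulate_reference(cfg)
  expect_identical(r1$reference$values, r2$reference$values)
  m1 <- simulate_mixtures(r1$truth$W_true, cfg)
  m2 <- simulate_mixtures(r2$truth$W_true, cfg)
  expect_identical(m1$counts$values, m2$counts$values)
  expect_identical(m1$truth$H_true$values, m2$truth$H_true$values)
  # mixtures use a different stream than the reference
  expect_false(identical(r1$reference$values[, 1], m1$counts$values[, 1]))
})

test_that("zero log-fold-change scale collapses all types to one profile", {
  cfg <- sim_config(n_genes = 50, n_cell_types = 4, cells_per_type = 5,
                    lfc_scale = 0, seed = 3)
  r <- simulate_reference(cfg)
  expect_equal(r$truth$W_true[, 1], r$truth$W_true[, 4],
               ignore_attr = TRUE)
})

test_that("large dispersion approaches Poisson variance", {
  cfg <- sim_config(n_genes = 4, n_cell_types = 1, cells_per_type = 10000,
                    nb_dispersion = 1e8, lfc_scale = 0, seed = 9,
                    library_size = 40)
  r <- simulate_reference(cfg)
  vm <- apply(r$reference$values, 1, var) / rowMeans(r$reference$values)
  expect_true(all(abs(vm - 1) < 0.1))
})

test_that("mixture expectation matches W %*% H within CLT error", {
  cfg <- sim_config(n_genes = 30, n_cell_types = 3, cells_per_type = 5,
                    n_spots = 500, cells_per_spot = 20,
                    dirichlet_alpha = c(1e6, 1e6, 1e6),  # pins H ~ 1/3 each
                    lfc_scale = 0.5, seed = 21)
  r <- simulate_reference(cfg)
  mx <- simulate_mixtures(r$truth$W_true, cfg)
  H <- mx$truth$H_true$values
  expect_true(all(abs(H - 1 / 3) < 0.01))
  expected <- r$truth$W_true %*% H
  got <- mx$counts$values
  # per-gene standard error of the mean over 500 replicate spots
  se <- apply(got, 1, sd) / sqrt(ncol(got))
  dev <- abs(rowMeans(got) - rowMeans(expected))
  expect_true(mean(dev <= 3 * se + 1e-8) > 0.95)
})

test_that("flat Dirichlet ground truth has mean 1/p", {
  cfg <- sim_config(n_genes = 10, n_cell_types = 5, cells_per_type = 2,
                    n_spots = 2, seed = 30)
  set.seed(30)
  draws <- spotgist:::.rdirichlet(10000, rep(1, 5))
  expect_true(all(abs(rowMeans(draws) - 0.2) < 0.01))
  expect_equal(colSums(draws), rep(1, 10000), tolerance = 1e-9)
})

test_that("synthetic image prior spans the fidelity range", {
  set.seed(12)
  h <- setNames(runif(100, 0.02, 0.6), sprintf("s%03d", 1:100))
  perfect <- simulate_image_prior(h, 1, seed = 4)
  expect_equal(rank_agreement(perfect$values, h), 1)
  noise <- simulate_image_prior(h, 0, seed = 4)
  expect_lt(abs(rank_agreement(noise$values, h)), 0.2)
  mid1 <- simulate_image_prior(h, 0.8, seed = 4)
  mid2 <- simulate_image_prior(h, 0.8, seed = 4)
  expect_identical(mid1$values, mid2$values)
  expect_gt(rank_agreement(mid1$values, h), 0.5)
})

test_that("linear-regression baseline recovers noiseless data and rejects
           rank deficiency", {
  toy <- toy_noiseless(c(0.1, 0.5, 0.4), n = 3)
  H <- baseline_linear_regression(toy$Y, toy$W)
  expect_true(all(abs(H$values - toy$h) < 1e-6))
  W_dup <- toy$W$values[, c(1, 1, 2)]
  colnames(W_dup) <- c("A", "Adup", "B")
  expect_error(baseline_linear_regression(toy$Y, signature_matrix(W_dup)),
               "rank-deficient")
})

test_that("constrained least squares matches grid and enumeration oracles", {
  set.seed(33)
  # p = 2 toys against a 1-D grid search
  for (i in 1:5) {
    W <- matrix(rexp(40), 20, 2,
                dimnames = list(sprintf("g%d", 1:20), c("A", "B")))
    y <- pmax(as.vector(W %*% c(0.8, 0.2)) + rnorm(20, 0, 1.5), 0)
    Y <- expression_matrix(matrix(y, dimnames = list(rownames(W), "s1")),
                           layer = "normalized")
    h <- baseline_constrained_ls(Y, signature_matrix(W))$values[, 1]
    h_grid <- grid_cls_p2(y, W)
    expect_equal(unname(h), h_grid, tolerance = 1e-3)
  }
  # p = 5 against exhaustive support enumeration (KKT on every face)
  for (i in 1:5) {
    W <- matrix(rexp(150), 30, 5,
                dimnames = list(sprintf("g%d", 1:30), LETTERS[1:5]))
    y <- pmax(as.vector(W %*% c(0.5, 0.3, 0.2, 0, 0)) + rnorm(30, 0, 2), 0)
    Y <- expression_matrix(matrix(y, dimnames = list(rownames(W), "s1")),
                           layer = "normalized")
    h <- baseline_constrained_ls(Y, signature_matrix(W))$values[, 1]
    h_enum <- enum_cls(y, W)
    expect_equal(unname(h), h_enum, tolerance = 1e-6)
  }
  # output always on the simplex
  expect_equal(sum(h), 1, tolerance = 1e-9)
  # exact recovery on noiseless data
  toy <- toy_noiseless(c(0.3, 0.3, 0.4), n = 1)
  expect_true(all(abs(baseline_constrained_ls(toy$Y, toy$W)$values -
                        toy$h) < 1e-6))
})

test_that("base model beats the linear baseline on replicate simulations", {
  # scaled-down replicates of the mixture benchmark; paired comparison
  wins <- 0L
  for (s in 1:3) {
    b <- suppressWarnings(suppressMessages(run_decomposition_benchmark(
      sim_config(seed = s, n_genes = 300, n_spots = 25, cells_per_type = 50,
                 cells_per_spot = 50),
      methods = c("base", "linear"), top_n_hvg = 200,
      mcmc = mcmc_config(600, 300, seed = s))))
    wins <- wins + (b$mae["base"] < b$mae["linear"])
  }
  expect_gte(wins, 2L)
})
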