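# Prior construction: capping, disk aggregation, patch overlap, quantile
# mapping, Beta parameterisation. Oracles are brute-force per-pixel loops.

test_that("cap_and_rescale matches direct percentile computation on 0..100", {
  img <- image_raster(matrix(0:100, nrow = 101))
  out <- cap_and_rescale(img)$pixels
  x <- 0:100
  hi <- quantile(x, 0.99, names = FALSE)   # 99
  lo <- quantile(x, 0.01, names = FALSE)   # 1
  expected <- pmin(x, hi); expected[expected < lo] <- 0
  expected <- expected / max(expected)
  expect_equal(as.numeric(out), expected)
  expect_equal(max(out), 1)

  expect_equal(cap_and_rescale(image_raster(matrix(7, 5, 5)))$pixels,
               matrix(1, 5, 5))
  expect_warning(z <- cap_and_rescale(image_raster(matrix(0, 4, 4))),
                 "constant-zero")
  expect_true(all(z$pixels == 0))
})

test_that("cap_and_rescale is idempotent on its own output", {
  set.seed(3)
  # 3 x 67 = 201 pixels: percentile positions land on order statistics
  img <- image_raster(matrix(rexp(201, 1 / 50), 3, 67))
  once <- cap_and_rescale(img)
  twice <- cap_and_rescale(once)
  expect_equal(twice$pixels, once$pixels, tolerance = 1e-9)
})

test_that("spot mean intensity equals the brute-force pixel loop", {
  set.seed(21)
  for (rep in 1:4) {
    nr <- sample(20:64, 1); nc <- sample(20:64, 1)
    px <- matrix(runif(nr * nc), nr, nc)
    ns <- sample(2:5, 1)
    centers <- cbind(runif(ns, -5, nr + 5), runif(ns, -5, nc + 5))
    radius <- runif(ns, 0.5, 12)
    geom <- spot_geometry(sprintf("s%d", seq_len(ns)), centers, radius)
    got <- suppressWarnings(spot_mean_intensity(image_raster(px), geom))
    expect_equal(unname(got$values), brute_spot_mean(px, centers, radius),
                 tolerance = 1e-9)
  }
})

test_that("spot mean intensity handles uniform images and edge cases", {
  geom <- spot_geometry(c("a", "b"), rbind(c(10, 10), c(30, 30)), c(5, 3))
  u <- spot_mean_intensity(image_raster(matrix(0.37, 50, 50)), geom)
  expect_equal(unname(u$values), c(0.37, 0.37))

  # disk exactly over a painted region reads ~1; a distant spot reads 0
  px <- matrix(0, 60, 60)
  for (r in 0:59) for (cc in 0:59)
    if ((r - 20)^2 + (cc - 20)^2 <= 64) px[r + 1, cc + 1] <- 1
  g2 <- spot_geometry(c("in", "out"), rbind(c(20, 20), c(50, 50)), c(8, 4))
  v <- spot_mean_intensity(image_raster(px), g2)
  expect_equal(unname(v$values), c(1, 0))

  # sub-pixel radius: single-pixel value
  g3 <- spot_geometry("p", rbind(c(4, 7)), 0.5)
  px2 <- matrix(runif(100), 10, 10)
  expect_equal(unname(spot_mean_intensity(image_raster(px2), g3)$values),
               px2[5, 8])

  # fully outside the image: 0 with a warning
  g4 <- spot_geometry("far", rbind(c(500, 500)), 3)
  expect_warning(o <- spot_mean_intensity(image_raster(px2), g4), "in-bounds")
  expect_equal(unname(o$values), 0)
})

test_that("patch map aggregation matches brute force and stays bounded", {
  # one patch covering the spot entirely
  m1 <- patch_probability_map(data.frame(row0_px = 0, col0_px = 0,
                                         height_px = 100, width_px = 100,
                                         probability = 0.8))
  g <- spot_geometry("s", rbind(c(40, 40)), 10)
  expect_equal(unname(patch_map_to_spots(m1, g)$values), 0.8)

  # two probability-0/1 patches with equal overlap average to 0.5
  m2 <- patch_probability_map(data.frame(
    row0_px = c(0, 40), col0_px = c(0, 0), height_px = c(40, 40),
    width_px = c(100, 100), probability = c(0, 1)))
  g2 <- spot_geometry("s", rbind(c(39.5, 50)), 8)
  expect_equal(unname(patch_map_to_spots(m2, g2)$values), 0.5)

  # no overlap: 0 with warning
  g3 <- spot_geometry("s", rbind(c(500, 500)), 5)
  expect_warning(z <- patch_map_to_spots(m2, g3), "zero patch overlap")
  expect_equal(unname(z$values), 0)

  set.seed(8)
  for (rep in 1:3) {
    np <- sample(2:5, 1)
    patches <- data.frame(row0_px = runif(np, 0, 50),
                          col0_px = runif(np, 0, 50),
                          height_px = runif(np, 5, 30),
                          width_px = runif(np, 5, 30),
                          probability = runif(np))
    ns <- sample(2:3, 1)
    centers <- cbind(runif(ns, 0, 60), runif(ns, 0, 60))
    radius <- runif(ns, 2, 15)
    geom <- spot_geometry(sprintf("s%d", seq_len(ns)), centers, radius)
    got <- suppressWarnings(
      patch_map_to_spots(patch_probability_map(patches), geom))
    want <- brute_patch_map(patches, centers, radius, extent = 90)
    expect_equal(unname(got$values), want, tolerance = 1e-9)
    nz <- want > 0
    expect_true(all(got$values[nz] >= min(patches$probability) - 1e-12))
    expect_true(all(got$values[nz] <= max(patches$probability) + 1e-12))
  }
})

test_that("quantile mapping preserves ranks and the target distribution", {
  expect_equal(quantile_map(c(0.1, 0.2, 0.3), c(0.5, 0.7, 0.9)),
               c(0.5, 0.7, 0.9))
  # idempotence: mapping a vector onto itself returns it
  set.seed(9)
  x <- runif(25)
  expect_equal(quantile_map(x, x), x)
  # all-tied source maps every spot to the target median
  tgt <- runif(11)
  expect_equal(quantile_map(rep(0.4, 11), tgt), rep(median(tgt), 11))
  # output distribution equals the target distribution (KS distance 0)
  src <- rnorm(40); tgt2 <- rexp(40)
  out <- quantile_map(src, tgt2)
  expect_equal(sort(out), sort(tgt2), tolerance = 1e-12)
  # monotone in the source
  expect_true(all(diff(out[order(src)]) >= 0))
  # average-rank convention, against brute-force rank computation
  src3 <- c(2, 2, 5)
  fr <- (rank(src3) - 1) / 2                   # 1.5 1.5 3 -> 0.25 0.25 1
  expect_equal(quantile_map(src3, c(0, 1, 10)),
               quantile(c(0, 1, 10), fr, names = FALSE))
  expect_error(quantile_map(1:3, 1:4), "length")
})

test_that("beta shapes reproduce mean/total-count parameterisation", {
  expect_equal(beta_shapes(0.5, 50), list(alpha_shape = 25, beta_shape = 25))
  expect_equal(beta_shapes(0.1, 10), list(alpha_shape = 1, beta_shape = 9))
  set.seed(14)
  for (i in 1:100) {
    tau <- runif(1, 0.01, 0.99); lam <- runif(1, 0.1, 500)
    sh <- beta_shapes(tau, lam)
    expect_equal(sh$alpha_shape / (sh$alpha_shape + sh$beta_shape), tau,
                 tolerance = 1e-12)
    expect_equal(sh$alpha_shape + sh$beta_shape, lam, tolerance = 1e-12)
  }
  expect_error(beta_shapes(1, 10), "inside")
})
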