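# Shared fixtures and independent brute-force oracles. Everything is built
# in code; no stored data.

# noiseless toy: orthogonal block signature, exact mixture Y = W %*% H
toy_signature <- function(m = 40, p = 3) {
  stopifnot(m %% p == 0 || m > p)
  W <- matrix(0, m, p,
              dimnames = list(sprintf("g%02d", seq_len(m)), LETTERS[seq_len(p)]))
  cuts <- round(seq(0, m, length.out = p + 1))
  for (k in seq_len(p)) W[(cuts[k] + 1):cuts[k + 1], k] <- 1
  W
}

toy_noiseless <- function(h = c(0.2, 0.3, 0.5), n = 1, m = 40) {
  W <- toy_signature(m, length(h))
  Y <- W %*% h %*% t(rep(1, n))
  colnames(Y) <- sprintf("s%d", seq_len(n))
  list(Y = expression_matrix(Y, layer = "normalized"),
       W = signature_matrix(W), h = h)
}

# brute-force per-pixel oracle for spot_mean_intensity
brute_spot_mean <- function(px, centers, radius) {
  vapply(seq_len(nrow(centers)), function(j) {
    tot <- 0; cnt <- 0
    for (r in 0:(nrow(px) - 1)) for (cc in 0:(ncol(px) - 1)) {
      if ((r - centers[j, 1])^2 + (cc - centers[j, 2])^2 <= radius[j]^2) {
        tot <- tot + px[r + 1, cc + 1]; cnt <- cnt + 1
      }
    }
    if (cnt == 0) 0 else tot / cnt
  }, numeric(1))
}

# brute-force pixel-overlap oracle for patch_map_to_spots
brute_patch_map <- function(patches, centers, radius, extent = 200) {
  vapply(seq_len(nrow(centers)), function(j) {
    wsum <- 0; psum <- 0
    for (t in seq_len(nrow(patches))) {
      n_in <- 0
      for (r in 0:extent) for (cc in 0:extent) {
        in_disk <- (r - centers[j, 1])^2 + (cc - centers[j, 2])^2 <=
          radius[j]^2
        in_patch <- r >= patches$row0_px[t] &&
          r < patches$row0_px[t] + patches$height_px[t] &&
          cc >= patches$col0_px[t] &&
          cc < patches$col0_px[t] + patches$width_px[t]
        if (in_disk && in_patch) n_in <- n_in + 1
      }
      wsum <- wsum + n_in
      psum <- psum + n_in * patches$probability[t]
    }
    if (wsum == 0) 0 else psum / wsum
  }, numeric(1))
}

# 1-D grid-search oracle for sum-to-one NNLS at p = 2
grid_cls_p2 <- function(y, W, step = 1e-4) {
  h1 <- seq(0, 1, by = step)
  obj <- vapply(h1, function(a) sum((y - W %*% c(a, 1 - a))^2), numeric(1))
  a <- h1[which.min(obj)]
  c(a, 1 - a)
}

# exhaustive support-enumeration oracle for sum-to-one NNLS (small p):
# for every support S solve the equality-constrained least squares
# restricted to S and keep the best feasible solution
enum_cls <- function(y, W) {
  p <- ncol(W)
  best <- NULL; best_obj <- Inf
  for (mask in 1:(2^p - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
    Ws <- W[, S, drop = FALSE]
    k <- length(S)
    kkt <- rbind(cbind(2 * crossprod(Ws), rep(1, k)), c(rep(1, k), 0))
    rhs <- c(2 * crossprod(Ws, y), 1)
    sol <- tryCatch(solve(kkt, rhs), error = function(e) NULL)
    if (is.null(sol)) next
    hs <- sol[seq_len(k)]
    if (any(hs < -1e-9)) next
    h <- numeric(p); h[S] <- pmax(hs, 0); h <- h / sum(h)
    obj <- sum((y - W %*% h)^2)
    if (obj < best_obj) { best_obj <- obj; best <- h }
  }
  best
}

# small expression fixture with ids
small_counts <- function(values, genes = NULL, spots = NULL) {
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(values)))
  if (is.null(spots)) spots <- sprintf("s%d", seq_len(ncol(values)))
  expression_matrix(values, genes, spots, layer = "counts")
}
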