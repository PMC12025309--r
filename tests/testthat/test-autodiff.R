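# Finite-difference validation of the reverse-mode core, op by op.
# Each check wraps an input as a parameter, takes a scalar loss (weighted
# sum), and compares analytic against central-difference gradients.

ns <- asNamespace("swindaf3d")

check_grad <- function(make_loss, x, n_checks = 6, tol = 1e-5) {
  ns$ad_tape_begin()
  px <- ns$ad_param(x)
  loss <- make_loss(px)
  ns$ad_backward(loss)
  g <- px$g
  ns$ad_tape_end()
  set.seed(42)
  idx <- sample(length(x), min(n_checks, length(x)))
  num <- num_grad(function(xx) ns$adt_val(make_loss(xx)), x, idx)
  expect_equal(as.numeric(g[idx]), num, tolerance = tol)
}

test_that("elementwise, matmul and normalization ops backpropagate correctly", {
  set.seed(1)
  x <- matrix(rnorm(6 * 4), 6, 4)
  w <- matrix(rnorm(24), 6, 4)
  check_grad(function(p) ns$op_sum(ns$op_mul(ns$op_sigmoid(p), w)), x)
  check_grad(function(p) ns$op_sum(ns$op_mul(ns$op_gelu(p), w)), x)
  B <- matrix(rnorm(4 * 3), 4, 3)
  wB <- matrix(rnorm(18), 6, 3)
  check_grad(function(p) ns$op_sum(ns$op_mul(ns$op_matmul(p, B), wB)), x)
  g <- rnorm(4); b <- rnorm(4)
  check_grad(function(p) ns$op_sum(ns$op_mul(ns$op_layernorm(p, g, b), w)),
             x, tol = 1e-4)
  check_grad(function(p) ns$op_sum(ns$op_mul(
    ns$op_groupnorm(p, g, b, groups = 2L), w)), x, tol = 1e-4)
  al <- runif(4, 0.1, 0.5)
  check_grad(function(p) ns$op_sum(ns$op_mul(ns$op_prelu(p, al), w)), x)
})

test_that("conv3d gradients match finite differences (incl. dilation)", {
  set.seed(2)
  dims <- c(4L, 3L, 3L)
  x <- matrix(rnorm(prod(dims) * 2), prod(dims), 2)
  W <- array(rnorm(2 * 3 * 27), c(2, 3, 27))
  bias <- rnorm(3)
  wt <- matrix(rnorm(prod(dims) * 3), prod(dims), 3)
  for (dil in c(1L, 2L)) {
    check_grad(function(p) ns$op_sum(ns$op_mul(
      ns$op_conv3d(p, W, bias, dims, 3L, dil), wt)), x)
    # and for the weights
    ns$ad_tape_begin()
    pw <- ns$ad_param(W)
    loss <- ns$op_sum(ns$op_mul(ns$op_conv3d(x, pw, bias, dims, 3L, dil), wt))
    ns$ad_backward(loss)
    gw <- pw$g
    ns$ad_tape_end()
    idx <- sample(length(W), 6)
    num <- num_grad(function(ww) ns$adt_val(ns$op_sum(ns$op_mul(
      ns$op_conv3d(x, ww, bias, dims, 3L, dil), wt))), W, idx)
    expect_equal(as.numeric(gw[idx]), num, tolerance = 1e-5)
  }
})

test_that("pooling, transposed conv and resize backpropagate correctly", {
  set.seed(3)
  dims <- c(4L, 4L, 2L)
  x <- matrix(rnorm(prod(dims) * 2), prod(dims), 2)
  wt <- matrix(rnorm(4 * 2), 4, 2)   # pooled extents (2, 2, 1)
  check_grad(function(p) ns$op_sum(ns$op_mul(ns$op_maxpool2(p, dims), wt)), x)
  Wt <- array(rnorm(2 * 2 * 8), c(2, 2, 8))
  bt <- rnorm(2)
  wt2 <- matrix(rnorm(prod(dims * 2L) * 2), prod(dims * 2L), 2)
  check_grad(function(p) ns$op_sum(ns$op_mul(
    ns$op_convtrans2(p, Wt, bt, dims), wt2)), x)
  wt3 <- matrix(rnorm(6 * 5 * 3 * 2), 6 * 5 * 3, 2)
  check_grad(function(p) ns$op_sum(ns$op_mul(
    ns$op_resize3(p, dims, c(6L, 5L, 3L)), wt3)), x)
})

test_that("gather/scatter and attention backpropagate correctly", {
  set.seed(4)
  x <- matrix(rnorm(5 * 3), 5, 3)
  idx <- c(2L, 0L, 5L, 1L, 1L, 3L)
  wt <- matrix(rnorm(length(idx) * 3), length(idx), 3)
  check_grad(function(p) ns$op_sum(ns$op_mul(ns$op_gather(p, idx), wt)), x)
  # fused window attention: 2 windows x 2 heads, t = 3, dh = 2
  t <- 3L; nb <- 4L; dh <- 2L
  Q <- array(rnorm(t * dh * nb), c(t, dh, nb))
  K <- array(rnorm(t * dh * nb), c(t, dh, nb))
  V <- array(rnorm(t * dh * nb), c(t, dh, nb))
  B <- array(rnorm(t * t * 2), c(t, t, 2))
  region <- matrix(c(0L, 0L, 1L, 0L, 0L, -1L), t, 2)  # mixed + padding
  wt4 <- array(rnorm(t * dh * nb), c(t, dh, nb))
  lossQ <- function(p) ns$op_sum(ns$op_mul(
    ns$op_attention(p, K, V, B, region, 2L), wt4))
  check_grad(lossQ, Q, tol = 1e-5)
  lossK <- function(p) ns$op_sum(ns$op_mul(
    ns$op_attention(Q, p, V, B, region, 2L), wt4))
  check_grad(lossK, K, tol = 1e-5)
  lossB <- function(p) ns$op_sum(ns$op_mul(
    ns$op_attention(Q, K, V, p, region, 2L), wt4))
  check_grad(lossB, B, tol = 1e-5)
})

test_that("gradients accumulate over parameter reuse", {
  x <- matrix(rnorm(4), 2, 2)
  ns$ad_tape_begin()
  p <- ns$ad_param(x)
  loss <- ns$op_sum(ns$op_add(ns$op_mul(p, p), p))  # d/dx = 2x + 1
  ns$ad_backward(loss)
  g <- p$g
  ns$ad_tape_end()
  expect_equal(as.numeric(g), as.numeric(2 * x + 1), tolerance = 1e-12)
})
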