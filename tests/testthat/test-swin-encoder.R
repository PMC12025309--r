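ns <- asNamespace("swindaf3d")

test_that("patch embedding follows the ceil shape rule", {
  ec <- tiny_ec()
  p <- ns$init_encoder_params(ec, 0)
  g <- embed_patches(array(runif(64 * 64 * 32), c(64, 64, 32)), ec, p)
  expect_identical(g$dims, c(32L, 32L, 16L))
  expect_identical(dim(ns$adt_val(g$feat)), c(32L * 32L * 16L, 12L))
  g2 <- embed_patches(array(runif(9 * 8 * 8), c(9, 8, 8)), ec, p)
  expect_identical(g2$dims, c(5L, 4L, 4L))
  # linearity: zero volume with zero projection gives a zero grid
  p0 <- p
  p0$patch_embed$W[] <- 0
  gz <- embed_patches(array(0, c(8, 8, 8)), ec, p0)
  expect_true(all(ns$adt_val(gz$feat) == 0))
  expect_error(embed_patches(array(0, c(1, 8, 8)), ec, p), ">= 2")
})

test_that("window partition covers every token exactly once (both shifts)", {
  for (dims in list(c(14L, 14L, 14L), c(8L, 8L, 8L), c(9L, 6L, 5L))) {
    V <- as.integer(prod(dims))
    grid <- list(feat = matrix(as.numeric(seq_len(V)), V, 1), dims = dims,
                 channels = 1L)
    for (shift in c(0L, 3L)) {
      wb <- partition_windows(grid, 7L, shift)
      got <- wb$idx[wb$idx > 0L]
      expect_identical(sort(got), seq_len(V))          # exact partition
      expect_identical(sum(wb$region >= 0L), V)        # valid flags agree
      back <- reverse_windows(wb)
      expect_identical(ns$adt_val(back$feat), grid$feat)  # inverse pair
    }
  }
  g14 <- list(feat = matrix(0, 14^3, 1), dims = rep(14L, 3), channels = 1L)
  expect_identical(partition_windows(g14, 7L, 0L)$nW, 8L)
  g8 <- list(feat = matrix(0, 8^3, 1), dims = rep(8L, 3), channels = 1L)
  wb8 <- partition_windows(g8, 7L, 0L)
  expect_identical(wb8$nW, 8L)
  expect_identical(sum(wb8$region >= 0L), 512L)
  expect_error(partition_windows(g8, 7L, 2L), "shift")
})

test_that("attention rows are normalized and masked pairs get zero weight", {
  set.seed(5)
  t <- 8L; nb <- 6L; dh <- 3L
  Q <- array(rnorm(t * dh * nb), c(t, dh, nb))
  K <- array(rnorm(t * dh * nb), c(t, dh, nb))
  V <- array(rnorm(t * dh * nb), c(t, dh, nb))
  B <- array(0, c(t, t, 2))
  region <- matrix(c(rep(0L, 5), 1L, 1L, -1L), t, 3)
  f <- ns$cpp_attn_fwd(Q, K, V, B, region, 2L)
  for (b in seq_len(nb)) {
    w <- (b - 1) %/% 2 + 1
    for (i in seq_len(t)) {
      ri <- region[i, w]
      if (ri < 0) {
        expect_true(all(f$P[i, , b] == 0))
        expect_true(all(f$out[i, , b] == 0))
      } else {
        expect_equal(sum(f$P[i, , b]), 1, tolerance = 1e-6)
        expect_true(all(f$P[i, region[, w] != ri, b] == 0))
      }
    }
  }
})

test_that("windowed attention equals dense attention when one window covers the grid", {
  set.seed(6)
  ec <- encoder_config(embed_dim = 8L, window = 5L, depths = c(1, 1, 1, 1),
                       heads = c(2, 2, 2, 2), use_relative_bias = FALSE)
  dims <- c(3L, 4L, 2L)                      # 24 tokens < 5^3, one window
  V <- prod(dims)
  X <- matrix(rnorm(V * 8), V, 8)
  p <- ns$init_encoder_params(ec, 1)$stage1$block1
  p$qkv$b <- rnorm(24)
  wb <- partition_windows(list(feat = X, dims = dims, channels = 8L), 5L, 0L)
  wb <- window_attention(wb, 2L, p, use_relative_bias = FALSE)
  got <- ns$adt_val(reverse_windows(wb)$feat)
  ref <- oracle_dense_attention(X, p$qkv$W, p$qkv$b, 2L)
  ref <- sweep(ref %*% p$proj$W, 2, p$proj$b, "+")
  expect_equal(got, ref, tolerance = 1e-5)
})

test_that("swin block with zero output projections is the identity", {
  ec <- tiny_ec(C = 8L)
  p <- ns$init_encoder_params(ec, 2)$stage1$block1
  p$proj$W[] <- 0; p$proj$b[] <- 0
  p$mlp$W2[] <- 0; p$mlp$b2[] <- 0
  dims <- c(5L, 4L, 4L)
  X <- matrix(rnorm(prod(dims) * 8), prod(dims), 8)
  grid <- list(feat = X, dims = dims, channels = 8L)
  for (parity in c("even", "odd")) {
    out <- swin_block(grid, p, parity, ec, heads = 2L)
    expect_equal(ns$adt_val(out$feat), X, tolerance = 1e-12)
    expect_identical(out$dims, dims)
  }
})

test_that("patch merging halves extents (ceil) and doubles channels", {
  ec <- tiny_ec(C = 12L)
  mp <- ns$init_encoder_params(ec, 0)$stage1$merge
  g <- list(feat = matrix(rnorm(32 * 32 * 16 * 12), 32 * 32 * 16, 12),
            dims = c(32L, 32L, 16L), channels = 12L)
  out <- merge_patches(g, mp)
  expect_identical(out$dims, c(16L, 16L, 8L))
  expect_identical(out$channels, 24L)
  g2 <- list(feat = matrix(rnorm(5 * 4 * 4 * 12), 80, 12),
             dims = c(5L, 4L, 4L), channels = 12L)
  out2 <- merge_patches(g2, mp)
  expect_identical(out2$dims, c(3L, 2L, 2L))
  mp0 <- mp; mp0$W[] <- 0
  out3 <- merge_patches(g2, mp0)
  expect_true(all(ns$adt_val(out3$feat) == 0))
})

test_that("the pyramid obeys the shape law for C in {12, 48}", {
  ec12 <- tiny_ec(C = 12L)
  pyr <- encode_volume(array(runif(64 * 64 * 32), c(64, 64, 32)), ec12,
                       ns$init_encoder_params(ec12, 0))
  dims_exp <- list(c(32L, 32L, 16L), c(16L, 16L, 8L), c(8L, 8L, 4L),
                   c(4L, 4L, 2L))
  for (l in 1:4) {
    expect_identical(pyr[[l]]$dims, dims_exp[[l]])
    expect_identical(pyr[[l]]$channels, as.integer(12 * 2^(l - 1)))
    expect_identical(dim(ns$adt_val(pyr[[l]]$feat)),
                     as.integer(c(prod(dims_exp[[l]]), 12 * 2^(l - 1))))
  }
  ec48 <- encoder_config(embed_dim = 48L, window = 7L)
  pyr48 <- encode_volume(array(runif(32 * 32 * 16), c(32, 32, 16)), ec48,
                         ns$init_encoder_params(ec48, 0))
  for (l in 1:4) {
    expect_identical(pyr48[[l]]$dims,
                     as.integer(ceiling(c(32, 32, 16) / 2^l)))
    expect_identical(pyr48[[l]]$channels, as.integer(48 * 2^(l - 1)))
  }
})

test_that("encoding is deterministic given fixed parameters", {
  ec <- tiny_ec(C = 8L)
  p <- ns$init_encoder_params(ec, 3)
  v <- array(runif(16 * 16 * 8), c(16, 16, 8))
  a <- encode_volume(v, ec, p)
  b <- encode_volume(v, ec, p)
  for (l in 1:4)
    expect_identical(ns$adt_val(a[[l]]$feat), ns$adt_val(b[[l]]$feat))
})
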