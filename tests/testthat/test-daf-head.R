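ns <- asNamespace("swindaf3d")

make_tiny <- function(seed = 0L) {
  ec <- tiny_ec()
  hc <- tiny_hc()
  list(ec = ec, hc = hc, model = build_swindaf3d(ec, hc, seed))
}

test_that("lateral projections align all levels at the fusion scale", {
  tm <- make_tiny()
  v <- array(runif(64 * 64 * 32), c(64, 64, 32))
  pyr <- encode_volume(v, tm$ec, tm$model$params$encoder)
  slfs <- project_laterals(pyr, tm$hc, tm$model$params$head)
  for (s in slfs) {
    expect_identical(s$dims, c(32L, 32L, 16L))
    expect_identical(dim(ns$adt_val(s$feat)), c(32L * 32L * 16L, 16L))
  }
  expect_error(project_laterals(pyr[1:3], tm$hc, tm$model$params$head),
               "4-level")
  # zero pyramid + zero projections -> zero SLFs
  hp <- tm$model$params$head
  for (i in 1:4) hp[[paste0("lat", i)]]$W[] <- 0
  zpyr <- lapply(pyr, function(l) {
    l$feat <- ns$adt_val(l$feat) * 0; l
  })
  z <- project_laterals(zpyr, tm$hc, hp)
  for (s in z) expect_true(all(ns$adt_val(s$feat) == 0))
})

test_that("MLF fusion concatenates in level order and is order-sensitive", {
  tm <- make_tiny(1)
  dims <- c(6L, 6L, 4L)
  slfs <- lapply(1:4, function(i)
    list(feat = matrix(rnorm(prod(dims) * 16), prod(dims), 16),
         dims = dims, channels = 16L, level = i))
  mlf <- fuse_mlf(slfs, tm$hc, tm$model$params$head)
  expect_identical(mlf$channels, 64L)
  expect_identical(dim(ns$adt_val(mlf$feat)), c(as.integer(prod(dims)), 64L))
  perm <- fuse_mlf(slfs[c(2, 1, 3, 4)], tm$hc, tm$model$params$head)
  expect_gt(max(abs(ns$adt_val(perm$feat) - ns$adt_val(mlf$feat))), 0)
  bad <- slfs; bad[[2]]$dims <- c(5L, 6L, 4L)
  bad[[2]]$feat <- bad[[2]]$feat[1:120, ]
  expect_error(fuse_mlf(bad, tm$hc, tm$model$params$head), "misaligned")
})

test_that("zero-parameter attention module outputs 0.5 everywhere", {
  tm <- make_tiny(2)
  dims <- c(6L, 6L, 4L)
  slf <- list(feat = matrix(rnorm(prod(dims) * 16), prod(dims), 16),
              dims = dims, channels = 16L, level = 1L)
  mlf <- list(feat = matrix(rnorm(prod(dims) * 64), prod(dims), 64),
              dims = dims, channels = 64L)
  ap <- tm$model$params$head$attn1
  ap <- rapply(ap, function(x) x * 0, how = "replace")
  am <- attention_weights(slf, mlf, tm$hc, ap)
  expect_true(all(ns$adt_val(am$feat) == 0.5))
  # contract: extents/channels match MLF, strictly inside (0,1)
  ap2 <- tm$model$params$head$attn2
  am2 <- attention_weights(slf, mlf, tm$hc, ap2)
  a2 <- ns$adt_val(am2$feat)
  expect_identical(dim(a2), c(as.integer(prod(dims)), 64L))
  expect_true(all(a2 > 0 & a2 < 1))
})

test_that("gating identities hold exactly", {
  tm <- make_tiny(3)
  dims <- c(4L, 4L, 2L)
  V <- prod(dims)
  slf <- list(feat = matrix(rnorm(V * 16), V, 16), dims = dims,
              channels = 16L, level = 1L)
  mlf <- list(feat = matrix(rnorm(V * 64), V, 64), dims = dims,
              channels = 64L)
  ones <- list(feat = matrix(1, V, 64), dims = dims, channels = 64L, level = 1L)
  zeros <- list(feat = matrix(0, V, 64), dims = dims, channels = 64L, level = 1L)
  # A == 1 passes the MLF through unchanged; A == 0 annihilates it
  expect_identical(ns$adt_val(ns$op_mul(ones$feat, mlf$feat)), mlf$feat)
  expect_true(all(ns$adt_val(ns$op_mul(zeros$feat, mlf$feat)) == 0))
  # elementwise gating agrees with a scalar loop on a 2x2x2 toy grid
  a <- array(runif(8), c(8, 1)); m <- array(rnorm(8), c(8, 1))
  got <- ns$adt_val(ns$op_mul(a, m))
  for (i in 1:8) expect_identical(got[i, 1], a[i, 1] * m[i, 1])
  # with A == 0 the refined output is independent of the MLF
  rp <- tm$model$params$head$refine1
  r1 <- refine_features(slf, mlf, zeros, tm$hc, rp)
  mlf2 <- list(feat = matrix(rnorm(V * 64), V, 64), dims = dims,
               channels = 64L)
  r2 <- refine_features(slf, mlf2, zeros, tm$hc, rp)
  expect_equal(ns$adt_val(r1$feat), ns$adt_val(r2$feat), tolerance = 1e-12)
  expect_identical(dim(ns$adt_val(r1$feat)), c(as.integer(V), 16L))
})

test_that("ASPP preserves extents and zero parameters give zero output", {
  hc <- head_config(16L)
  ec <- tiny_ec()
  hp <- ns$init_head_params(hc, ec, 4)
  dims <- c(12L, 10L, 9L)    # min extent 9 admits rates up to 4 unclamped
  fused <- list(feat = matrix(rnorm(prod(dims) * 64), prod(dims), 64),
                dims = dims, channels = 64L)
  out <- aspp_pool(fused, hc, hp$aspp)
  expect_identical(out$dims, dims)
  expect_identical(dim(ns$adt_val(out$feat)), c(as.integer(prod(dims)), 16L))
  z <- rapply(hp$aspp, function(x) x * 0, how = "replace")
  expect_true(all(ns$adt_val(aspp_pool(fused, hc, z)$feat) == 0))
  # oversized rates are clamped with a warning, not fatal
  small <- list(feat = matrix(rnorm(4 * 4 * 2 * 64), 32, 64),
                dims = c(4L, 4L, 2L), channels = 64L)
  w <- capture_warnings(aspp_pool(small, hc, hp$aspp))
  expect_true(all(grepl("clamped", w)) && length(w) >= 1L)
})

test_that("prediction sets have 4+4 auxiliary maps at input resolution in [0,1]", {
  tm <- make_tiny(5)
  v <- array(runif(32 * 32 * 16), c(32, 32, 16))
  ps <- suppressWarnings(predict_volume(tm$model, v))  # ASPP clamp at toy extents
  expect_identical(dim(ps$main), c(32L, 32L, 16L))
  expect_length(ps$aux_slf, 4L)
  expect_length(ps$aux_attn, 4L)
  for (m in c(list(ps$main), ps$aux_slf, ps$aux_attn)) {
    expect_identical(dim(m), c(32L, 32L, 16L))
    expect_true(min(m) >= 0 && max(m) <= 1)
  }
  bm <- binarize_prediction(ps$main)
  expect_true(all(bm$data %in% c(0, 1)))
})

test_that("every encoder and head parameter receives a finite, non-zero gradient", {
  ec <- tiny_ec()
  hc <- tiny_hc()
  model <- build_swindaf3d(ec, hc, seed = 6)
  v <- array(runif(24 * 24 * 16), c(24, 24, 16))
  G <- random_mask(c(24, 24, 16))
  ns$ad_tape_begin()
  pt <- ns$wrap_params(model$params)
  out <- suppressWarnings(ns$forward_swindaf3d(v, ec, hc, pt)) # ASPP clamp
  lb <- total_loss(out, G)
  ns$ad_backward(lb$tensor)
  gt <- ns$grad_tree(pt)
  ns$ad_tape_end()
  norms <- rapply(gt, function(g) {
    expect_true(all(is.finite(g)))
    sqrt(sum(g^2))
  }, how = "unlist")
  expect_true(all(norms > 0))
})
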