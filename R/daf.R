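# Deep attentive feature fusion head: lateral projections to a common
# fusion scale (level 1, half the input resolution), multi-layer feature
# (MLF) formation, per-level attention gating, refinement, 3D ASPP pooling,
# and the main + 8 auxiliary deep-supervision outputs.

#' Fusion head configuration
#'
#' @param lateral_channels width of the single-layer features (SLF) after
#'   lateral 1x1x1 projection; the MLF width is `4 * lateral_channels`.
#' @param aspp_rates dilation rates of the atrous spatial pyramid pooling
#'   branches (a 1x1x1 branch is always added).
#' @param groupnorm_groups groups for group normalization; must divide all
#'   head channel counts.
#' @param attn_hidden hidden width of the two inner attention convolutions.
#' @return A `head_config` list.
#' @export
head_config <- function(lateral_channels = 64L, aspp_rates = c(1L, 2L, 3L, 4L),
                        groupnorm_groups = 8L,
                        attn_hidden = lateral_channels) {
  lateral_channels <- as.integer(lateral_channels)
  attn_hidden <- as.integer(attn_hidden)
  g <- as.integer(groupnorm_groups)
  mlf <- 4L * lateral_channels
  if (lateral_channels < 1L || any(aspp_rates < 1L))
    stop("channels and rates must be positive")
  for (cc in c(lateral_channels, mlf, attn_hidden))
    if (cc %% g != 0L) stop("groupnorm_groups must divide all head widths")
  structure(list(lateral_channels = lateral_channels, mlf_channels = mlf,
                 aspp_rates = as.integer(aspp_rates), groupnorm_groups = g,
                 attn_hidden = attn_hidden),
            class = "head_config")
}

conv_unit <- function(cin, cout, k) {
  list(W = array(trunc_normal(cin * cout * k^3), c(cin, cout, k^3)),
       b = numeric(cout))
}

gn_unit <- function(c) list(g = rep(1, c), b = numeric(c))

cgp_unit <- function(cin, cout, k)   # conv + group norm + PReLU
  list(conv = conv_unit(cin, cout, k), gn = gn_unit(cout),
       alpha = rep(0.25, cout))

init_head_params <- function(hc, ec, seed = 0L) {
  with_seed(seed, {
    L <- hc$lateral_channels; M <- hc$mlf_channels; A <- hc$attn_hidden
    C <- ec$embed_dim
    p <- list()
    for (i in 1:4) {
      Ci <- C * 2L^(i - 1L)
      p[[paste0("lat", i)]] <- list(W = init_linear(Ci, L), b = numeric(L),
                                    gn = gn_unit(L), alpha = rep(0.25, L))
    }
    p$fuse <- cgp_unit(4L * L, M, 3L)
    for (i in 1:4) {
      p[[paste0("attn", i)]] <- list(c1 = cgp_unit(L + M, A, 3L),
                                     c2 = cgp_unit(A, A, 3L),
                                     c3 = conv_unit(A, M, 3L))
      p[[paste0("refine", i)]] <- list(c1 = cgp_unit(M + L, L, 3L),
                                       c2 = cgp_unit(L, L, 3L),
                                       c3 = list(W = init_linear(L, L),
                                                 b = numeric(L)))
    }
    nr <- length(hc$aspp_rates)
    p$aspp <- c(list(b0 = list(W = init_linear(4L * L, L), b = numeric(L))),
                stats::setNames(lapply(hc$aspp_rates, function(r)
                  conv_unit(4L * L, L, 3L)),
                  paste0("b", seq_len(nr))),
                list(proj = cgp_unit((nr + 1L) * L, L, 1L)))
    p$head_main <- list(W = init_linear(L, 1L), b = numeric(1))
    for (i in 1:4) {
      p[[paste0("head_slf", i)]] <- list(W = init_linear(L, 1L), b = numeric(1))
      p[[paste0("head_attn", i)]] <- list(W = init_linear(L, 1L), b = numeric(1))
    }
    p
  })
}

# conv3d + group norm + PReLU on a token grid
apply_cgp <- function(x, dims, p, k, groups, dil = 1L) {
  y <- op_conv3d(x, p$conv$W, p$conv$b, dims, k, dil)
  y <- op_groupnorm(y, p$gn$g, p$gn$b, groups)
  op_prelu(y, p$alpha)
}

#' Project pyramid levels to aligned single-layer features (SLF)
#'
#' Each level goes through a 1x1x1 projection to `lateral_channels`, group
#' norm and PReLU, then trilinear upsampling to the level-1 extents.
#'
#' @param pyramid 4-level list from [encode_volume()].
#' @param hc a [head_config()].
#' @param params head parameter list.
#' @return List of 4 aligned token grids.
#' @export
project_laterals <- function(pyramid, hc, params) {
  if (length(pyramid) != 4L) stop("expected a 4-level pyramid")
  d1 <- pyramid[[1]]$dims
  lapply(1:4, function(i) {
    p <- params[[paste0("lat", i)]]
    x <- op_addbias(op_matmul(pyramid[[i]]$feat, p$W), p$b)
    x <- op_groupnorm(x, p$gn$g, p$gn$b, hc$groupnorm_groups)
    x <- op_prelu(x, p$alpha)
    if (!identical(as.integer(pyramid[[i]]$dims), as.integer(d1)))
      x <- op_resize3(x, pyramid[[i]]$dims, d1)
    list(feat = x, dims = d1, channels = hc$lateral_channels, level = i)
  })
}

#' Fuse SLFs into the multi-layer feature block (MLF)
#'
#' Channel concatenation in level order 1..4 followed by a 3x3x3 convolution
#' (+ GN + PReLU) keeping `mlf_channels`.
#'
#' @param slfs list of 4 aligned SLFs.
#' @param hc a [head_config()].
#' @param params head parameter list.
#' @return MLF token grid.
#' @export
fuse_mlf <- function(slfs, hc, params) {
  d1 <- slfs[[1]]$dims
  for (s in slfs)
    if (!identical(as.integer(s$dims), as.integer(d1)))
      stop("SLF extents are misaligned")
  x <- op_cbind(lapply(slfs, `[[`, "feat"))
  x <- apply_cgp(x, d1, params$fuse, 3L, hc$groupnorm_groups)
  list(feat = x, dims = d1, channels = hc$mlf_channels)
}

#' Per-level attention weights over the MLF
#'
#' Concatenates (SLF_i, MLF) and applies three 3x3x3 convolutions (GN +
#' PReLU after the first two); a sigmoid maps the last, `mlf_channels`-wide
#' output into (0, 1).
#'
#' @param slf_i one SLF.
#' @param mlf the MLF grid.
#' @param hc a [head_config()].
#' @param params this level's attention parameters (`c1`, `c2`, `c3`).
#' @return Attention-map token grid, values strictly in (0, 1).
#' @export
attention_weights <- function(slf_i, mlf, hc, params) {
  if (!identical(as.integer(slf_i$dims), as.integer(mlf$dims)))
    stop("SLF/MLF extent mismatch")
  d <- mlf$dims
  x <- op_cbind(list(slf_i$feat, mlf$feat))
  x <- apply_cgp(x, d, params$c1, 3L, hc$groupnorm_groups)
  x <- apply_cgp(x, d, params$c2, 3L, hc$groupnorm_groups)
  x <- op_conv3d(x, params$c3$W, params$c3$b, d, 3L)
  list(feat = op_sigmoid(x), dims = d, channels = mlf$channels,
       level = slf_i$level)
}

#' Refine a level: gate the MLF and merge with the SLF
#'
#' `F' = A_i (elementwise) MLF`; (F', F_i) are concatenated and passed
#' through two 3x3x3 conv + GN + PReLU units and one 1x1x1 convolution to
#' `lateral_channels`.
#'
#' @param slf_i one SLF.
#' @param mlf the MLF grid.
#' @param attention_map output of [attention_weights()].
#' @param hc a [head_config()].
#' @param params this level's refinement parameters.
#' @return Attentive-feature token grid (SLF-shaped).
#' @export
refine_features <- function(slf_i, mlf, attention_map, hc, params) {
  d <- mlf$dims
  gated <- op_mul(attention_map$feat, mlf$feat)
  x <- op_cbind(list(gated, slf_i$feat))
  x <- apply_cgp(x, d, params$c1, 3L, hc$groupnorm_groups)
  x <- apply_cgp(x, d, params$c2, 3L, hc$groupnorm_groups)
  x <- op_addbias(op_matmul(x, params$c3$W), params$c3$b)
  list(feat = x, dims = d, channels = hc$lateral_channels,
       level = slf_i$level)
}

#' 3D atrous spatial pyramid pooling
#'
#' Parallel 3x3x3 dilated convolutions at each rate plus a 1x1x1 branch;
#' outputs are concatenated and projected back to `lateral_channels`.
#' Rates whose effective kernel exceeds the grid extent are clamped with a
#' warning.
#'
#' @param fused token grid (concatenated attentive features,
#'   `4 * lateral_channels`).
#' @param hc a [head_config()].
#' @param params ASPP parameter list.
#' @return Token grid with `lateral_channels` channels, extents preserved.
#' @export
aspp_pool <- function(fused, hc, params) {
  d <- fused$dims
  branches <- list(op_addbias(op_matmul(fused$feat, params$b0$W),
                              params$b0$b))
  max_rate <- max(1L, (min(d) - 1L) %/% 2L)
  for (j in seq_along(hc$aspp_rates)) {
    r <- hc$aspp_rates[j]
    if (r > max_rate) {
      warning("ASPP rate ", r, " clamped to ", max_rate,
              " for extents ", paste(d, collapse = "x"))
      r <- max_rate
    }
    p <- params[[paste0("b", j)]]
    branches[[j + 1L]] <- op_conv3d(fused$feat, p$W, p$b, d, 3L, dil = r)
  }
  x <- op_cbind(branches)
  x <- apply_cgp(x, d, params$proj, 1L, hc$groupnorm_groups)
  list(feat = x, dims = d, channels = hc$lateral_channels)
}

# sigmoid 1x1x1 head upsampled to the input extents (probability grid)
prob_head <- function(grid, hp, input_dims) {
  x <- op_addbias(op_matmul(grid$feat, hp$W), hp$b)
  x <- op_sigmoid(x)
  if (!identical(as.integer(grid$dims), as.integer(input_dims)))
    x <- op_resize3(x, grid$dims, input_dims)
  x
}

# full forward pass; params = list(encoder, head); returns tensors
forward_swindaf3d <- function(volume, ec, hc, params) {
  a <- if (inherits(volume, "us_volume")) volume$data else volume
  input_dims <- if (is_adt(a)) dim(a$v) else dim(a)
  pyr <- encode_volume(a, ec, params$encoder)
  slfs <- project_laterals(pyr, hc, params$head)
  mlf <- fuse_mlf(slfs, hc, params$head)
  attns <- lapply(1:4, function(i)
    attention_weights(slfs[[i]], mlf, hc, params$head[[paste0("attn", i)]]))
  refs <- lapply(1:4, function(i)
    refine_features(slfs[[i]], mlf, attns[[i]], hc,
                    params$head[[paste0("refine", i)]]))
  fused <- list(feat = op_cbind(lapply(refs, `[[`, "feat")),
                dims = mlf$dims, channels = 4L * hc$lateral_channels)
  pooled <- aspp_pool(fused, hc, params$head$aspp)
  list(
    main = prob_head(pooled, params$head$head_main, input_dims),
    aux_slf = lapply(1:4, function(i)
      prob_head(slfs[[i]], params$head[[paste0("head_slf", i)]], input_dims)),
    aux_attn = lapply(1:4, function(i)
      prob_head(refs[[i]], params$head[[paste0("head_attn", i)]], input_dims)),
    input_dims = input_dims)
}
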