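# Hierarchical shifted-window transformer encoder (3D Swin feature pyramid).
#
# A token grid is a list(feat, dims, channels): feat is a V x C matrix (or
# autodiff tensor) with V = prod(dims), h fastest. Four stages of
# window-attention blocks, separated by patch merging, yield levels at
# scales 1/2, 1/4, 1/8, 1/16 of the input with channels C, 2C, 4C, 8C.

#' Encoder configuration
#'
#' Defaults follow the standard Swin-UNETR encoder configuration used for
#' the 256 x 256 x 64 ultrasound volumes: embedding dim 48, window 7x7x7,
#' depths (2,2,2,2), heads (3,6,12,24), patch edge 2.
#'
#' @param embed_dim channels after patch embedding (C).
#' @param window odd positive window edge per axis.
#' @param depths transformer blocks per stage (length 4).
#' @param heads attention heads per stage (length 4); each stage's channel
#'   count `C * 2^(i-1)` must be divisible by its head count.
#' @param patch patch edge for embedding (fixed at 2).
#' @param use_relative_bias include learned relative-position bias.
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(embed_dim = 48L, window = 7L,
                           depths = c(2L, 2L, 2L, 2L),
                           heads = c(3L, 6L, 12L, 24L),
                           patch = 2L, use_relative_bias = TRUE) {
  embed_dim <- as.integer(embed_dim); window <- as.integer(window)
  depths <- as.integer(depths); heads <- as.integer(heads)
  if (length(depths) != 4L || length(heads) != 4L)
    stop("depths and heads must have length 4")
  if (window < 1L || window %% 2L == 0L) stop("window must be odd and >= 1")
  if (patch != 2L) stop("patch edge is fixed at 2")
  ch <- embed_dim * 2L^(0:3)
  if (any(ch %% heads != 0L))
    stop("stage channels (C, 2C, 4C, 8C) must be divisible by stage heads")
  structure(list(embed_dim = embed_dim, window = window, depths = depths,
                 heads = heads, patch = patch,
                 use_relative_bias = isTRUE(use_relative_bias)),
            class = "encoder_config")
}

# truncated normal (+/- 2 sd) initializer, sd = 0.02
trunc_normal <- function(n, sd = 0.02) {
  u <- stats::runif(n, stats::pnorm(-2), stats::pnorm(2))
  stats::qnorm(u) * sd
}

init_linear <- function(nin, nout, sd = 0.02)
  matrix(trunc_normal(nin * nout, sd), nin, nout)

# initialize all encoder parameters (nested named list of arrays)
init_encoder_params <- function(config, seed = 0L) {
  with_seed(seed, {
    C <- config$embed_dim
    w <- config$window
    nb <- (2L * w - 1L)^3
    p <- list()
    p$patch_embed <- list(W = init_linear(config$patch^3, C), b = numeric(C))
    for (s in 1:4) {
      Cs <- C * 2L^(s - 1L)
      st <- list()
      for (b in seq_len(config$depths[s])) {
        st[[paste0("block", b)]] <- list(
          ln1 = list(g = rep(1, Cs), b = numeric(Cs)),
          qkv = list(W = init_linear(Cs, 3L * Cs), b = numeric(3L * Cs)),
          bias_table = matrix(trunc_normal(nb * config$heads[s]), nb,
                              config$heads[s]),
          proj = list(W = init_linear(Cs, Cs), b = numeric(Cs)),
          ln2 = list(g = rep(1, Cs), b = numeric(Cs)),
          mlp = list(W1 = init_linear(Cs, 4L * Cs), b1 = numeric(4L * Cs),
                     W2 = init_linear(4L * Cs, Cs), b2 = numeric(Cs)))
      }
      if (s < 4L)
        st$merge <- list(ln = list(g = rep(1, 8L * Cs), b = numeric(8L * Cs)),
                         W = init_linear(8L * Cs, 2L * Cs))
      p[[paste0("stage", s)]] <- st
    }
    p
  })
}

# ---- patch embedding -------------------------------------------------------

#' Embed a volume into non-overlapping 2x2x2 patch tokens
#'
#' Odd extents are zero-padded; each patch's 8 intensities are flattened and
#' linearly projected to `embed_dim` channels (plus bias).
#'
#' @param volume [us_volume()], plain 3D array, or autodiff tensor thereof.
#' @param config an [encoder_config()].
#' @param params encoder parameter list (default: fresh seed-0 init).
#' @return Token grid list(feat, dims, channels) at half the input extents.
#' @export
embed_patches <- function(volume, config,
                          params = init_encoder_params(config)) {
  a <- if (inherits(volume, "us_volume")) volume$data else volume
  dm <- if (is_adt(a)) dim(a$v) else dim(a)
  if (length(dm) != 3L || any(dm < 2L))
    stop("volume must be 3D with every extent >= 2")
  gd <- as.integer(ceiling(dm / 2))
  Tn <- prod(gd)
  # voxel index for token (i,j,k) offset (o = a + 2b + 4c), 0-based coords
  ti <- seq_len(Tn) - 1L
  ih <- ti %% gd[1]; iw <- (ti %/% gd[1]) %% gd[2]; id_ <- ti %/% (gd[1] * gd[2])
  idx <- integer(Tn * 8L)
  for (o in 0:7) {
    vh <- 2L * ih + (o %% 2L); vw <- 2L * iw + ((o %/% 2L) %% 2L)
    vd <- 2L * id_ + (o %/% 4L)
    ok <- vh < dm[1] & vw < dm[2] & vd < dm[3]
    lin <- vh + dm[1] * (vw + dm[2] * vd) + 1L
    lin[!ok] <- 0L
    idx[o * Tn + seq_len(Tn)] <- lin
  }
  X8 <- op_gather_elems(a, idx, c(Tn, 8L))
  pe <- params$patch_embed
  feat <- op_addbias(op_matmul(X8, pe$W), pe$b)
  list(feat = feat, dims = gd, channels = config$embed_dim)
}

# ---- window partitioning ---------------------------------------------------

# effective per-axis shift: no shift along axes fully covered by one window
effective_shift <- function(dims, window, shift)
  ifelse(dims > window, shift, 0L)

#' Partition a token grid into (optionally shifted) attention windows
#'
#' The grid is cyclically shifted by `-shift` per axis (where the extent
#' exceeds the window), zero-padded to window multiples and tiled into
#' non-overlapping `window^3` blocks. Padding tokens and, under shifting,
#' tokens from non-adjacent wrapped regions are excluded from attention via
#' per-token region ids.
#'
#' @param grid token grid from [embed_patches()] (or any stage).
#' @param window window edge.
#' @param shift 0 or `floor(window/2)`.
#' @return A window batch: list(feat (nW*t x C), t, nW, window, idx, region,
#'   grid_dims, shift).
#' @export
partition_windows <- function(grid, window, shift = 0L) {
  window <- as.integer(window); shift <- as.integer(shift)
  if (window < 1L) stop("window must be >= 1")
  if (!shift %in% c(0L, window %/% 2L))
    stop("shift must be 0 or floor(window/2)")
  dm <- as.integer(grid$dims)
  s <- effective_shift(dm, window, shift)
  pd <- as.integer(ceiling(dm / window) * window)
  nw3 <- pd %/% window
  nW <- as.integer(prod(nw3))
  t <- as.integer(window^3)
  # enumerate rows: window index (wh fastest), then local (lh fastest)
  wi <- seq_len(nW) - 1L
  wh <- wi %% nw3[1]; ww <- (wi %/% nw3[1]) %% nw3[2]; wd <- wi %/% (nw3[1] * nw3[2])
  li <- seq_len(t) - 1L
  lh <- li %% window; lw <- (li %/% window) %% window; ld <- li %/% (window^2)
  # padded coords for all (window, local) pairs; local varies fastest
  ph <- rep(wh, each = t) * window + rep(lh, nW)
  pw <- rep(ww, each = t) * window + rep(lw, nW)
  pdp <- rep(wd, each = t) * window + rep(ld, nW)
  valid <- ph < dm[1] & pw < dm[2] & pdp < dm[3]
  oh <- (ph + s[1]) %% dm[1]; ow <- (pw + s[2]) %% dm[2]; od <- (pdp + s[3]) %% dm[3]
  idx <- oh + dm[1] * (ow + dm[2] * od) + 1L
  idx[!valid] <- 0L
  # region id: per-axis wrap flags; -1 marks padding
  region <- (ph + s[1] >= dm[1]) + 2L * (pw + s[2] >= dm[2]) +
    4L * (pdp + s[3] >= dm[3])
  region[!valid] <- -1L
  feat <- op_gather(grid$feat, idx)
  list(feat = feat, t = t, nW = nW, window = window,
       idx = as.integer(idx), region = matrix(as.integer(region), t, nW),
       grid_dims = dm, shift = s, channels = grid$channels)
}

#' Reverse a window partition back to the token grid
#'
#' Exact inverse of [partition_windows()] including un-shift and pad removal.
#'
#' @param batch a window batch.
#' @param original_dims grid extents (default: recorded in the batch).
#' @return Token grid.
#' @export
reverse_windows <- function(batch, original_dims = batch$grid_dims) {
  V <- prod(original_dims)
  inv <- integer(V)
  pos <- which(batch$idx > 0L)
  inv[batch$idx[pos]] <- pos
  if (any(inv == 0L)) stop("inconsistent index map: not a partition")
  list(feat = op_gather(batch$feat, inv), dims = as.integer(original_dims),
       channels = batch$channels)
}

# relative-position index matrix (t x t), values in 1..(2w-1)^3
rel_pos_index <- function(window) {
  t <- window^3
  li <- seq_len(t) - 1L
  lh <- li %% window; lw <- (li %/% window) %% window; ld <- li %/% (window^2)
  dh <- outer(lh, lh, "-") + window - 1L
  dw <- outer(lw, lw, "-") + window - 1L
  dd <- outer(ld, ld, "-") + window - 1L
  dh + (2L * window - 1L) * dw + (2L * window - 1L)^2 * dd + 1L
}

# permutation indices between the (N x 3C) qkv matrix and (t, dh, nb) cubes
qkv_cube_idx <- function(t, nW, heads, C, which) {
  dh <- C %/% heads
  N <- nW * t
  off <- (which - 1L) * C
  # cube linear order: i (token), then d (dim), then b = w*heads + h
  b <- seq_len(nW * heads) - 1L
  wv <- b %/% heads; hv <- b %% heads
  i <- rep(seq_len(t) - 1L, times = dh * nW * heads)
  d <- rep(rep(seq_len(dh) - 1L, each = t), times = nW * heads)
  wq <- rep(wv, each = t * dh); hq <- rep(hv, each = t * dh)
  row <- wq * t + i
  col <- off + hq * dh + d
  as.integer(row + N * col + 1L)
}

cube_back_idx <- function(t, nW, heads, C) {
  dh <- C %/% heads
  # matrix (N x C) column-major order: rows r = w*t + i, cols c = h*dh + d
  r <- seq_len(nW * t) - 1L
  wv <- r %/% t; iv <- r %% t
  cseq <- seq_len(C) - 1L
  hv <- cseq %/% dh; dv <- cseq %% dh
  i <- rep(iv, times = C)
  w <- rep(wv, times = C)
  h <- rep(hv, each = nW * t)
  d <- rep(dv, each = nW * t)
  as.integer(i + t * (d + dh * (w * heads + h)) + 1L)
}

#' Multi-head self-attention within windows
#'
#' Per window and head: scores `Q K' / sqrt(d)` plus relative-position bias
#' (if enabled), masked softmax over valid keys of the same region, output
#' re-projected. Padding query rows pass through as zeros.
#'
#' @param batch a window batch (features already layer-normalized upstream).
#' @param heads number of heads (channels must be divisible).
#' @param params block parameter list (`qkv`, `bias_table`, `proj`).
#' @param use_relative_bias include the bias term.
#' @return The window batch with attended features.
#' @export
window_attention <- function(batch, heads, params, use_relative_bias = TRUE) {
  C <- batch$channels
  if (C %% heads != 0L) stop("channels not divisible by heads")
  t <- batch$t; nW <- batch$nW
  dh <- C %/% heads
  qkv <- op_addbias(op_matmul(batch$feat, params$qkv$W), params$qkv$b)
  cd <- c(t, dh, nW * heads)
  Q <- op_gather_elems(qkv, qkv_cube_idx(t, nW, heads, C, 1L), cd)
  K <- op_gather_elems(qkv, qkv_cube_idx(t, nW, heads, C, 2L), cd)
  V <- op_gather_elems(qkv, qkv_cube_idx(t, nW, heads, C, 3L), cd)
  B <- if (use_relative_bias) {
    ri <- rel_pos_index(batch$window)
    nb <- nrow(adt_val(params$bias_table))
    bidx <- as.integer(rep(as.vector(ri), heads) +
                         nb * rep(seq_len(heads) - 1L, each = t * t))
    op_gather_elems(params$bias_table, bidx, c(t, t, heads))
  } else array(0, c(t, t, heads))
  att <- op_attention(Q, K, V, B, batch$region, heads)
  merged <- op_gather_elems(att, cube_back_idx(t, nW, heads, C), c(nW * t, C))
  out <- op_addbias(op_matmul(merged, params$proj$W), params$proj$b)
  validrow <- matrix(as.numeric(batch$region >= 0L), nW * t, C)  # t x nW stacked
  dim(validrow) <- c(nW * t, C)
  out <- op_mul(out, validrow)
  batch$feat <- out
  batch
}

#' One Swin transformer block
#'
#' Pre-norm window attention with residual, then a pre-norm 2-layer MLP
#' (hidden 4x, GELU) with residual. Even parity uses unshifted windows
#' (W-MSA), odd parity shifted windows (SW-MSA, shift `floor(window/2)`).
#'
#' @param grid token grid.
#' @param block_params one block's parameter list.
#' @param parity "even" or "odd".
#' @param config an [encoder_config()].
#' @param heads heads for this stage.
#' @return Token grid of identical shape.
#' @export
swin_block <- function(grid, block_params, parity, config, heads) {
  shift <- if (identical(parity, "odd")) config$window %/% 2L else 0L
  h1 <- op_layernorm(grid$feat, block_params$ln1$g, block_params$ln1$b)
  wb <- partition_windows(list(feat = h1, dims = grid$dims,
                               channels = grid$channels),
                          config$window, shift)
  wb <- window_attention(wb, heads, block_params, config$use_relative_bias)
  att <- reverse_windows(wb, grid$dims)
  x <- op_add(grid$feat, att$feat)
  h2 <- op_layernorm(x, block_params$ln2$g, block_params$ln2$b)
  m <- op_addbias(op_matmul(h2, block_params$mlp$W1), block_params$mlp$b1)
  m <- op_gelu(m)
  m <- op_addbias(op_matmul(m, block_params$mlp$W2), block_params$mlp$b2)
  list(feat = op_add(x, m), dims = grid$dims, channels = grid$channels)
}

#' Patch merging (downsample by 2, double channels)
#'
#' Concatenates each 2x2x2 token neighborhood (8C channels, zero-padded on
#' odd extents), layer-normalizes and projects to 2C.
#'
#' @param grid token grid.
#' @param params merge parameter list (`ln`, `W`).
#' @return Token grid with ceil-halved extents and doubled channels.
#' @export
merge_patches <- function(grid, params) {
  dm <- as.integer(grid$dims)
  gd <- as.integer(ceiling(dm / 2))
  Tn <- prod(gd)
  ti <- seq_len(Tn) - 1L
  ih <- ti %% gd[1]; iw <- (ti %/% gd[1]) %% gd[2]; id_ <- ti %/% (gd[1] * gd[2])
  parts <- vector("list", 8L)
  for (o in 0:7) {
    vh <- 2L * ih + (o %% 2L); vw <- 2L * iw + ((o %/% 2L) %% 2L)
    vd <- 2L * id_ + (o %/% 4L)
    ok <- vh < dm[1] & vw < dm[2] & vd < dm[3]
    lin <- vh + dm[1] * (vw + dm[2] * vd) + 1L
    lin[!ok] <- 0L
    parts[[o + 1L]] <- op_gather(grid$feat, as.integer(lin))
  }
  x <- op_cbind(parts)
  x <- op_layernorm(x, params$ln$g, params$ln$b)
  list(feat = op_matmul(x, params$W), dims = gd,
       channels = 2L * grid$channels)
}

#' Encode a volume into the four-level feature pyramid
#'
#' Stage i output is pyramid level i (scales 1/2, 1/4, 1/8, 1/16; channels
#' C, 2C, 4C, 8C); patch merging runs between stages 1-3 and 4.
#'
#' @param volume [us_volume()], 3D array, or autodiff tensor.
#' @param config an [encoder_config()].
#' @param params encoder parameters from `init_encoder_params`.
#' @return List of 4 token grids (the feature pyramid).
#' @export
encode_volume <- function(volume, config,
                          params = init_encoder_params(config)) {
  g <- embed_patches(volume, config, params)
  pyramid <- vector("list", 4L)
  for (s in 1:4) {
    st <- params[[paste0("stage", s)]]
    for (b in seq_len(config$depths[s])) {
      parity <- if (b %% 2L == 1L) "even" else "odd"
      g <- swin_block(g, st[[paste0("block", b)]], parity, config,
                      config$heads[s])
    }
    pyramid[[s]] <- g
    if (s < 4L) g <- merge_patches(g, st$merge)
  }
  pyramid
}
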