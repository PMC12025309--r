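# Reverse-mode automatic differentiation core.
#
# A tensor ("adt") is an environment holding a numeric value (scalar, matrix
# or array), an optional gradient, its parent tensors and a backward closure.
# During a recorded forward pass every tensor requiring gradients is pushed
# onto a tape; ad_backward() walks the tape in reverse creation order, which
# is a valid topological order for any forward computation.
#
# Feature grids live as V x C matrices (V = h*w*d, h fastest), matching an R
# array of dim c(h, w, d, C) reshaped to c(V, C); spatial dims are passed
# alongside. Heavy kernels (3D conv, attention, resize, pooling, gather) are
# compiled (src/kernels.cpp).

.ad <- new.env(parent = emptyenv())
.ad$tape <- NULL

ad_tape_begin <- function() {
  .ad$tape <- new.env(parent = emptyenv())
  .ad$tape$nodes <- vector("list", 256L)
  .ad$tape$n <- 0L
  invisible(NULL)
}

ad_tape_end <- function() {
  .ad$tape <- NULL
  invisible(NULL)
}

is_adt <- function(x) inherits(x, "adt")

adt_val <- function(x) if (is_adt(x)) x$v else x

adt_new <- function(v, parents = NULL, bw = NULL, req = FALSE) {
  e <- new.env(parent = emptyenv())
  e$v <- v
  e$g <- NULL
  e$req <- req
  e$parents <- parents
  e$bw <- bw
  class(e) <- "adt"
  tp <- .ad$tape
  if (req && !is.null(bw) && !is.null(tp)) {
    n <- tp$n + 1L
    if (n > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
    tp$nodes[[n]] <- e
    tp$n <- n
  }
  e
}

# Leaf tensor whose gradient is wanted (a learnable parameter).
ad_param <- function(v) adt_new(v, req = TRUE, bw = NULL)

ad_op <- function(inputs, value, bw, cache = NULL) {
  req <- !is.null(.ad$tape) &&
    any(vapply(inputs, function(i) is_adt(i) && i$req, logical(1)))
  if (!req) return(adt_new(value, req = FALSE))
  nd <- adt_new(value, parents = inputs, bw = bw, req = TRUE)
  nd$cache <- cache
  nd
}

ad_backward <- function(loss) {
  stopifnot(is_adt(loss), length(loss$v) == 1L, !is.null(.ad$tape))
  tp <- .ad$tape
  loss$g <- 1
  if (tp$n == 0L) return(invisible(NULL))
  for (k in rev(seq_len(tp$n))) {
    nd <- tp$nodes[[k]]
    if (is.null(nd$g) || is.null(nd$bw)) next
    gs <- nd$bw(nd)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      gj <- gs[[j]]
      if (is.null(gj) || !is_adt(p) || !p$req) next
      p$g <- if (is.null(p$g)) gj else p$g + gj
    }
  }
  invisible(NULL)
}

# ---- elementwise and linear-algebra ops ------------------------------------

op_add <- function(a, b) {
  ad_op(list(a, b), adt_val(a) + adt_val(b),
        function(nd) list(nd$g, nd$g))
}

op_sub <- function(a, b) {
  ad_op(list(a, b), adt_val(a) - adt_val(b),
        function(nd) list(nd$g, -nd$g))
}

op_mul <- function(a, b) {
  av <- adt_val(a); bv <- adt_val(b)
  ad_op(list(a, b), av * bv,
        function(nd) list(nd$g * bv, nd$g * av))
}

# multiply / add by a plain scalar constant
op_smul <- function(a, s) {
  ad_op(list(a), adt_val(a) * s, function(nd) list(nd$g * s))
}

op_sadd <- function(a, s) {
  ad_op(list(a), adt_val(a) + s, function(nd) list(nd$g))
}

# scalar tensor division a / b
op_sdiv <- function(a, b) {
  av <- adt_val(a); bv <- adt_val(b)
  ad_op(list(a, b), av / bv,
        function(nd) list(nd$g / bv, -nd$g * av / (bv * bv)))
}

op_matmul <- function(a, b) {
  av <- adt_val(a); bv <- adt_val(b)
  ad_op(list(a, b), av %*% bv,
        function(nd) list(nd$g %*% t(bv), crossprod(av, nd$g)))
}

# x: N x C, bias: length C
op_addbias <- function(x, b) {
  xv <- adt_val(x); bv <- adt_val(b)
  ad_op(list(x, b), sweep(xv, 2L, bv, "+"),
        function(nd) list(nd$g, colSums(nd$g)))
}

op_cbind <- function(lst) {
  vals <- lapply(lst, adt_val)
  ncols <- vapply(vals, ncol, integer(1))
  ends <- cumsum(ncols)
  starts <- c(1L, head(ends, -1L) + 1L)
  ad_op(lst, do.call(cbind, vals),
        function(nd) lapply(seq_along(lst), function(j)
          nd$g[, starts[j]:ends[j], drop = FALSE]))
}

op_reshape <- function(x, dm) {
  xv <- adt_val(x)
  odm <- dim(xv)
  v <- xv
  dim(v) <- dm
  ad_op(list(x), v, function(nd) {
    g <- nd$g
    dim(g) <- odm
    list(g)
  })
}

# ---- nonlinearities --------------------------------------------------------

op_sigmoid <- function(x) {
  v <- 1 / (1 + exp(-adt_val(x)))
  ad_op(list(x), v, function(nd) list(nd$g * v * (1 - v)))
}

op_gelu <- function(x) {
  xv <- adt_val(x)
  ad_op(list(x), xv * stats::pnorm(xv),
        function(nd) list(nd$g * (stats::pnorm(xv) + xv * stats::dnorm(xv))))
}

op_relu <- function(x) {
  xv <- adt_val(x)
  pos <- xv > 0
  ad_op(list(x), xv * pos, function(nd) list(nd$g * pos))
}

# PReLU with one learnable slope per channel; x: N x C, alpha: length C
op_prelu <- function(x, alpha) {
  xv <- adt_val(x); av <- adt_val(alpha)
  pos <- xv > 0
  A <- matrix(av, nrow(xv), ncol(xv), byrow = TRUE)
  v <- ifelse(pos, xv, A * xv)
  ad_op(list(x, alpha), v, function(nd) {
    list(nd$g * ifelse(pos, 1, A),
         colSums(nd$g * xv * !pos))
  })
}

op_log <- function(x) {
  xv <- adt_val(x)
  ad_op(list(x), log(xv), function(nd) list(nd$g / xv))
}

op_clip <- function(x, lo, hi) {
  xv <- adt_val(x)
  inside <- xv >= lo & xv <= hi
  ad_op(list(x), pmin(pmax(xv, lo), hi),
        function(nd) list(nd$g * inside))
}

# ---- normalization ---------------------------------------------------------

# Layer norm over the channel (last) dim of an N x C matrix.
op_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- adt_val(x)
  gv <- adt_val(gamma); bv <- adt_val(beta)
  mu <- rowMeans(xv)
  xc <- xv - mu
  va <- rowMeans(xc * xc)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  Gm <- matrix(gv, nrow(xv), ncol(xv), byrow = TRUE)
  v <- xhat * Gm + matrix(bv, nrow(xv), ncol(xv), byrow = TRUE)
  ad_op(list(x, gamma, beta), v, function(nd) {
    dxhat <- nd$g * Gm
    dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * inv
    list(dx, colSums(nd$g * xhat), colSums(nd$g))
  })
}

# Group norm for a single volume: normalizes over all voxels and the channels
# of each group (with batch size one this is also exactly what training-mode
# batch norm computes when groups == C).
op_groupnorm <- function(x, gamma, beta, groups, eps = 1e-5) {
  xv <- adt_val(x)
  gv <- adt_val(gamma); bv <- adt_val(beta)
  C <- ncol(xv)
  stopifnot(C %% groups == 0L)
  cg <- C %/% groups
  xhat <- xv
  inv <- numeric(groups)
  cols_of <- function(g) ((g - 1L) * cg + 1L):(g * cg)
  for (g in seq_len(groups)) {
    cs <- cols_of(g)
    m <- mean(xv[, cs])
    va <- mean((xv[, cs] - m)^2)
    inv[g] <- 1 / sqrt(va + eps)
    xhat[, cs] <- (xv[, cs] - m) * inv[g]
  }
  Gm <- matrix(gv, nrow(xv), C, byrow = TRUE)
  v <- xhat * Gm + matrix(bv, nrow(xv), C, byrow = TRUE)
  ad_op(list(x, gamma, beta), v, function(nd) {
    dx <- xhat  # reuse shape
    for (g in seq_len(groups)) {
      cs <- cols_of(g)
      dxhat <- nd$g[, cs, drop = FALSE] * Gm[, cs, drop = FALSE]
      xh <- xhat[, cs, drop = FALSE]
      dx[, cs] <- (dxhat - mean(dxhat) - xh * mean(dxhat * xh)) * inv[g]
    }
    list(dx, colSums(nd$g * xhat), colSums(nd$g))
  })
}

# ---- structural ops --------------------------------------------------------

# Row gather with zero-padding (idx 0 -> zero row); backward scatter-adds.
op_gather <- function(x, idx) {
  xv <- adt_val(x)
  n <- nrow(xv)
  ad_op(list(x), cpp_gather_rows(xv, as.integer(idx)),
        function(nd) list(cpp_scatter_rows(nd$g, as.integer(idx), n)))
}

# Element-level gather on the flattened value; out_dim gives the output shape.
op_gather_elems <- function(x, idx, out_dim) {
  xv <- adt_val(x)
  n <- length(xv)
  v <- cpp_gather_elems(as.numeric(xv), as.integer(idx))
  dim(v) <- out_dim
  odm <- dim(xv)
  ad_op(list(x), v, function(nd) {
    g <- cpp_scatter_elems(as.numeric(nd$g), as.integer(idx), n)
    dim(g) <- odm
    list(g)
  })
}

# ---- compiled spatial ops --------------------------------------------------

op_conv3d <- function(x, w, b, dims, k, dil = 1L) {
  xv <- adt_val(x); wv <- adt_val(w); bv <- adt_val(b)
  v <- cpp_conv3d_fwd(xv, as.integer(dims), wv, bv, as.integer(k),
                      as.integer(dil))
  ad_op(list(x, w, b), v, function(nd) {
    gr <- cpp_conv3d_bwd(xv, as.integer(dims), wv, nd$g, as.integer(k),
                         as.integer(dil))
    list(gr$dX, gr$dW, as.numeric(gr$db))
  })
}

op_convtrans2 <- function(x, w, b, dims) {
  xv <- adt_val(x); wv <- adt_val(w); bv <- adt_val(b)
  v <- cpp_convtrans2_fwd(xv, as.integer(dims), wv, bv)
  ad_op(list(x, w, b), v, function(nd) {
    gr <- cpp_convtrans2_bwd(xv, as.integer(dims), wv, nd$g)
    list(gr$dX, gr$dW, as.numeric(gr$db))
  })
}

op_maxpool2 <- function(x, dims) {
  xv <- adt_val(x)
  f <- cpp_maxpool2_fwd(xv, as.integer(dims))
  ad_op(list(x), f$out, function(nd)
    list(cpp_maxpool2_bwd(f$idx, nd$g, nrow(xv))))
}

# Trilinear resize of a V x C grid (differentiable); nearest is grad-free.
op_resize3 <- function(x, din, dout, nearest = FALSE) {
  xv <- adt_val(x)
  v <- cpp_resize3_fwd(xv, as.integer(din), as.integer(dout), nearest)
  if (nearest) return(ad_op(list(x), v, function(nd) list(NULL)))
  ad_op(list(x), v, function(nd)
    list(cpp_resize3_bwd(nd$g, as.integer(din), as.integer(dout))))
}

# Batched masked window attention over Q,K,V cubes (t, dh, nWin*heads),
# additive relative-position bias cube (t, t, heads), region imat (t, nWin).
op_attention <- function(q, k, v, bias, region, heads) {
  qv <- adt_val(q); kv <- adt_val(k); vv <- adt_val(v); bv <- adt_val(bias)
  f <- cpp_attn_fwd(qv, kv, vv, bv, region, as.integer(heads))
  ad_op(list(q, k, v, bias), f$out, function(nd) {
    gr <- cpp_attn_bwd(qv, kv, vv, f$P, nd$g, as.integer(heads))
    list(gr$dQ, gr$dK, gr$dV, gr$dB)
  })
}

# ---- reductions ------------------------------------------------------------

op_sum <- function(x) {
  xv <- adt_val(x)
  dm <- dim(xv)
  n <- length(xv)
  ad_op(list(x), sum(xv), function(nd) {
    g <- rep(as.numeric(nd$g), n)
    if (!is.null(dm)) dim(g) <- dm
    list(g)
  })
}

op_mean <- function(x) op_smul(op_sum(x), 1 / length(adt_val(x)))
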