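# Shared fixtures: tiny configurations and independent brute-force oracles.

tiny_ec <- function(C = 12L, window = 3L, depths = c(1L, 1L, 1L, 1L),
                    heads = if (C %% 3L == 0L) c(3L, 6L, 12L, 24L)
                            else c(2L, 2L, 2L, 2L))
  encoder_config(embed_dim = C, window = window, depths = depths,
                 heads = heads)

tiny_hc <- function(width = 16L) head_config(width)

# random smooth-ish binary mask (union of a few random boxes)
random_mask <- function(dims, n_boxes = 3, p_empty = 0) {
  a <- array(0, dims)
  if (runif(1) < p_empty) return(a)
  for (i in seq_len(n_boxes)) {
    lo <- pmax(1, floor(runif(3) * dims))
    hi <- pmin(dims, lo + floor(runif(3) * dims / 2))
    a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 1
  }
  a
}

# brute-force voxel-count overlap metrics (independent of the implementation)
oracle_dice <- function(A, B) {
  inter <- 0; na <- 0; nb <- 0
  for (i in seq_along(A)) {
    if (A[i] == 1 && B[i] == 1) inter <- inter + 1
    na <- na + (A[i] == 1); nb <- nb + (B[i] == 1)
  }
  if (na + nb == 0) 1 else 2 * inter / (na + nb)
}

oracle_iou <- function(A, B) {
  inter <- 0; uni <- 0
  for (i in seq_along(A)) {
    if (A[i] == 1 && B[i] == 1) inter <- inter + 1
    if (A[i] == 1 || B[i] == 1) uni <- uni + 1
  }
  if (uni == 0) 1 else inter / uni
}

# brute-force surface: voxels with any 6-neighbour outside the mask
# (grid border counts as outside); returns n x 3 coordinates
oracle_surface <- function(M) {
  dm <- dim(M)
  out <- vector("list", sum(M == 1))
  n <- 0L
  for (d in seq_len(dm[3])) for (w in seq_len(dm[2])) for (h in seq_len(dm[1])) {
    if (M[h, w, d] != 1) next
    nb <- c(
      if (h > 1) M[h - 1, w, d] else 0, if (h < dm[1]) M[h + 1, w, d] else 0,
      if (w > 1) M[h, w - 1, d] else 0, if (w < dm[2]) M[h, w + 1, d] else 0,
      if (d > 1) M[h, w, d - 1] else 0, if (d < dm[3]) M[h, w, d + 1] else 0)
    if (any(nb == 0)) { n <- n + 1L; out[[n]] <- c(h, w, d) }
  }
  if (n == 0L) matrix(integer(0), 0, 3) else do.call(rbind, out[seq_len(n)])
}

# all-pairs Euclidean surface Dice oracle
oracle_surface_dice <- function(A, B, d) {
  sa <- oracle_surface(A); sb <- oracle_surface(B)
  if (nrow(sa) + nrow(sb) == 0) return(1)
  if (nrow(sa) == 0 || nrow(sb) == 0) return(0)
  dist2 <- function(P, Q) {
    outer(P[, 1], Q[, 1], "-")^2 + outer(P[, 2], Q[, 2], "-")^2 +
      outer(P[, 3], Q[, 3], "-")^2
  }
  na <- sum(apply(dist2(sa, sb), 1, min) <= d^2)
  nb <- sum(apply(dist2(sb, sa), 1, min) <= d^2)
  (na + nb) / (nrow(sa) + nrow(sb))
}

# dense full-grid multi-head attention oracle (no windows, no bias)
oracle_dense_attention <- function(X, Wqkv, bqkv, heads) {
  N <- nrow(X); C <- ncol(X); dh <- C %/% heads
  qkv <- sweep(X %*% Wqkv, 2, bqkv, "+")
  out <- matrix(0, N, C)
  for (h in seq_len(heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    Q <- qkv[, cols, drop = FALSE]
    K <- qkv[, C + cols, drop = FALSE]
    V <- qkv[, 2 * C + cols, drop = FALSE]
    S <- Q %*% t(K) / sqrt(dh)
    P <- exp(S - apply(S, 1, max))
    P <- P / rowSums(P)
    out[, cols] <- P %*% V
  }
  out
}

# numeric gradient of f at x (array), central differences at chosen indices
num_grad <- function(f, x, idx, eps = 1e-6) {
  vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, 0)
}
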