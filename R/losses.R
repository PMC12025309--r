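# Hybrid Dice + binary cross-entropy objective with deep supervision.
#
# All losses accept plain numeric grids (returning a number) or autodiff
# tensors (returning a differentiable scalar tensor); prediction and ground
# truth must share extents. BCE is averaged over voxels so magnitudes are
# resolution-independent; the Dice term is scale-free already.

loss_input <- function(P, G) {
  pv <- adt_val(P); gv <- adt_val(G)
  if (length(pv) != length(gv))
    stop("prediction/ground-truth extent mismatch: ",
         length(pv), " vs ", length(gv), " voxels")
  gv <- as.numeric(gv)
  dim(gv) <- dim(pv)
  gv
}

finish_loss <- function(x, P) if (is_adt(P)) x else adt_val(x)

#' Soft Dice loss
#'
#' `1 - (2 sum(P G) + eps) / (sum(P^2) + sum(G^2) + eps)`. The smoothing
#' term defines the doubly-empty case as a perfect prediction (loss 0).
#'
#' @param P predicted probabilities in `[0, 1]` (array or tensor).
#' @param G binary ground truth of the same extents.
#' @param eps smoothing constant.
#' @return Loss in `[0, 1]` (up to eps effects).
#' @export
dice_loss <- function(P, G, eps = 1e-5) {
  gv <- loss_input(P, G)
  inter <- op_sum(op_mul(P, gv))
  den <- op_sadd(op_sum(op_mul(P, P)), sum(gv * gv) + eps)
  ratio <- op_sdiv(op_sadd(op_smul(inter, 2), eps), den)
  finish_loss(op_sadd(op_smul(ratio, -1), 1), P)
}

#' Binary cross-entropy loss (voxel-averaged)
#'
#' `-(1/N) sum(G log P + (1-G) log(1-P))` with probabilities clipped to
#' `[clip, 1-clip]` for stability.
#'
#' @inheritParams dice_loss
#' @param clip probability clipping bound.
#' @return Non-negative loss.
#' @export
bce_loss <- function(P, G, clip = 1e-7) {
  gv <- loss_input(P, G)
  Pc <- op_clip(P, clip, 1 - clip)
  pos <- op_mul(op_log(Pc), gv)
  neg <- op_mul(op_log(op_sadd(op_smul(Pc, -1), 1)), 1 - gv)
  finish_loss(op_smul(op_mean(op_add(pos, neg)), -1), P)
}

#' Hybrid output loss: Dice + BCE
#'
#' @inheritParams dice_loss
#' @return The sum of [dice_loss()] and [bce_loss()].
#' @export
output_loss <- function(P, G) {
  d <- dice_loss(P, G)
  b <- bce_loss(P, G)
  if (is_adt(P)) op_add(d, b) else d + b
}

#' Deep-supervision layer weights
#'
#' Defaults are the empirical weights (0.4, 0.5, 0.7, 0.8) for the four SLF
#' layers and again for the four attentive layers.
#'
#' @param w_slf,w_attn non-negative numeric length-4 weights.
#' @return A `loss_weights` list.
#' @export
loss_weights <- function(w_slf = c(0.4, 0.5, 0.7, 0.8),
                         w_attn = c(0.4, 0.5, 0.7, 0.8)) {
  stopifnot(length(w_slf) == 4L, length(w_attn) == 4L,
            all(w_slf >= 0), all(w_attn >= 0))
  structure(list(w_slf = as.numeric(w_slf), w_attn = as.numeric(w_attn)),
            class = "loss_weights")
}

#' Total deep-supervision loss over a prediction set
#'
#' `sum_i w_i (Dice+BCE)(aux_slf_i, G) + sum_j w_j (Dice+BCE)(aux_attn_j, G)
#'  + (Dice+BCE)(main, G)`.
#'
#' @param prediction_set output of [predict_volume()] or the internal
#'   forward pass (must carry 4 + 4 auxiliary maps).
#' @param G binary ground truth.
#' @param weights a [loss_weights()].
#' @return A `loss_breakdown` list: `per_slf`, `per_attn` (length-4
#'   numerics), `out`, `total`, and `tensor` (the differentiable total when
#'   the prediction set holds tensors, else NULL).
#' @export
total_loss <- function(prediction_set, G, weights = loss_weights()) {
  if (length(prediction_set$aux_slf) != 4L ||
      length(prediction_set$aux_attn) != 4L)
    stop("prediction set must carry 4 SLF + 4 attentive auxiliary maps")
  tensor_mode <- is_adt(prediction_set$main)
  ls <- lapply(prediction_set$aux_slf, output_loss, G = G)
  la <- lapply(prediction_set$aux_attn, output_loss, G = G)
  lo <- output_loss(prediction_set$main, G)
  if (tensor_mode) {
    tot <- lo
    for (i in 1:4) tot <- op_add(tot, op_smul(ls[[i]], weights$w_slf[i]))
    for (j in 1:4) tot <- op_add(tot, op_smul(la[[j]], weights$w_attn[j]))
    structure(list(per_slf = vapply(ls, adt_val, 0),
                   per_attn = vapply(la, adt_val, 0),
                   out = adt_val(lo), total = adt_val(tot), tensor = tot),
              class = "loss_breakdown")
  } else {
    per_slf <- unlist(ls); per_attn <- unlist(la)
    structure(list(per_slf = per_slf, per_attn = per_attn, out = lo,
                   total = sum(weights$w_slf * per_slf) +
                     sum(weights$w_attn * per_attn) + lo,
                   tensor = NULL),
              class = "loss_breakdown")
  }
}
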