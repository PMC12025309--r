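# Model containers and inference.

#' Build a SwinDAF3D model
#'
#' Combines the shifted-window transformer feature pyramid with the deep
#' attentive fusion head. Parameters are initialized deterministically from
#' `seed` (truncated normal, sd 0.02, zero biases).
#'
#' @param encoder an [encoder_config()].
#' @param head a [head_config()].
#' @param seed initialization seed.
#' @return A `seg_model` object (type `"swindaf3d"`).
#' @export
build_swindaf3d <- function(encoder = encoder_config(), head = head_config(),
                            seed = 0L) {
  structure(list(type = "swindaf3d", encoder_config = encoder,
                 head_config = head,
                 params = list(encoder = init_encoder_params(encoder, seed),
                               head = init_head_params(head, encoder,
                                                       seed + 1L))),
            class = "seg_model")
}

#' @export
print.seg_model <- function(x, ...) {
  cat(sprintf("<seg_model %s> %s parameters\n", x$type,
              format(model_param_count(x), big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters of a model
#'
#' @param model a `seg_model`.
#' @return Integer parameter count.
#' @export
model_param_count <- function(model) {
  sum(rapply(model$params, length, how = "unlist"))
}

# forward dispatch; params may be numeric (inference) or adt-wrapped (training)
model_forward <- function(model, volume, params = model$params) {
  switch(model$type,
         swindaf3d = forward_swindaf3d(volume, model$encoder_config,
                                       model$head_config, params),
         unet3d = forward_unet3d(volume, model$unet_config, params),
         stop("unknown model type: ", model$type))
}

#' Predict segmentation probability maps for a volume
#'
#' Runs the network forward and returns the prediction set: the main
#' probability grid at input resolution plus, for SwinDAF3D, the 4 SLF and
#' 4 attentive auxiliary probability grids (all in `[0, 1]`).
#'
#' @param model a `seg_model`.
#' @param volume a [us_volume()] or 3D array (preprocessed, `[0, 1]`).
#' @return List with `main` (3D array), `aux_slf`, `aux_attn` (lists of 3D
#'   arrays; empty for the U-Net baseline).
#' @export
predict_volume <- function(model, volume) {
  out <- model_forward(model, volume)
  dm <- out$input_dims
  to_arr <- function(x) { a <- adt_val(x); dim(a) <- dm; a }
  list(main = to_arr(out$main),
       aux_slf = lapply(out$aux_slf, to_arr),
       aux_attn = lapply(out$aux_attn, to_arr))
}

#' Binarize a probability grid into a label mask
#'
#' @param prob 3D array of probabilities.
#' @param threshold decision threshold (default 0.5).
#' @return A [us_mask()].
#' @export
binarize_prediction <- function(prob, threshold = 0.5) {
  us_mask((prob > threshold) * 1)
}

#' Save a model checkpoint
#'
#' Single-file archive holding the full parameter set, the configs and a
#' manifest (package version, timestamp).
#'
#' @param model a `seg_model`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(model = model,
               manifest = list(package = "swindaf3d",
                               version = as.character(utils::packageVersion("swindaf3d")),
                               saved = format(Sys.time()))),
          path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path checkpoint file from [save_checkpoint()].
#' @return The `seg_model`.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  obj <- readRDS(path)
  if (is.null(obj$model$type)) stop("not a valid checkpoint: ", path)
  obj$model
}

# tree utilities over nested parameter lists -------------------------------

tree_map <- function(f, a) {
  if (is.list(a)) lapply(a, function(x) tree_map(f, x)) else f(a)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else f(a, b)
}

wrap_params <- function(p) tree_map(ad_param, p)

grad_tree <- function(pt) tree_map(function(t) {
  if (is.null(t$g)) t$v * 0 else t$g
}, pt)
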