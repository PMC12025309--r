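# Reference 3D U-Net baseline: four encoder blocks (two 3x3x3 convs with
# batch norm + ReLU each), 2x2x2 max pooling, a bottleneck, and four decoder
# blocks with transposed-convolution upsampling and skip connections.
# With batch size one, training-mode batch normalization equals per-channel
# spatial normalization, which is how it is computed here.

#' Reference 3D U-Net configuration
#'
#' @param base_width channels of the first encoder block; doubled before
#'   each downsampling (so the bottleneck has `16 * base_width`).
#' @return A `unet_config` list.
#' @export
unet_config <- function(base_width = 8L) {
  base_width <- as.integer(base_width)
  if (base_width < 1L) stop("base_width must be positive")
  structure(list(base_width = base_width), class = "unet_config")
}

he_conv <- function(cin, cout, k) {
  sd <- sqrt(2 / (cin * k^3))
  list(W = array(stats::rnorm(cin * cout * k^3, 0, sd), c(cin, cout, k^3)),
       b = numeric(cout))
}

# conv(3) + BN + ReLU twice
unet_block_params <- function(cin, cout) {
  list(c1 = he_conv(cin, cout, 3L), n1 = gn_unit(cout),
       c2 = he_conv(cout, cout, 3L), n2 = gn_unit(cout))
}

init_unet_params <- function(config, seed = 0L) {
  w <- config$base_width
  with_seed(seed, {
    p <- list()
    widths <- w * c(1L, 2L, 4L, 8L)
    cin <- 1L
    for (i in 1:4) {
      p[[paste0("enc", i)]] <- unet_block_params(cin, widths[i])
      cin <- widths[i]
    }
    p$bottleneck <- unet_block_params(8L * w, 16L * w)
    for (i in 4:1) {
      ci <- w * 2L^i          # channels entering the up-convolution
      co <- w * 2L^(i - 1L)
      p[[paste0("up", i)]] <- list(
        W = array(stats::rnorm(ci * co * 8L, 0, sqrt(2 / ci)), c(ci, co, 8L)),
        b = numeric(co))
      p[[paste0("dec", i)]] <- unet_block_params(2L * co, co)
    }
    p$out <- list(W = init_linear(w, 1L), b = numeric(1))
    p
  })
}

#' Build the reference 3D U-Net baseline model
#'
#' @param config a [unet_config()].
#' @param seed initialization seed.
#' @return A `seg_model` object (type `"unet3d"`).
#' @export
build_reference_unet3d <- function(config = unet_config(), seed = 0L) {
  structure(list(type = "unet3d", unet_config = config,
                 params = init_unet_params(config, seed)),
            class = "seg_model")
}

unet_block <- function(x, dims, p) {
  x <- op_conv3d(x, p$c1$W, p$c1$b, dims, 3L)
  x <- op_groupnorm(x, p$n1$g, p$n1$b, groups = ncol(adt_val(x)))
  x <- op_relu(x)
  x <- op_conv3d(x, p$c2$W, p$c2$b, dims, 3L)
  x <- op_groupnorm(x, p$n2$g, p$n2$b, groups = ncol(adt_val(x)))
  op_relu(x)
}

forward_unet3d <- function(volume, config, params) {
  a <- if (inherits(volume, "us_volume")) volume$data else volume
  stopifnot(!is_adt(a))
  dm <- dim(a)
  pd <- as.integer(ceiling(dm / 16) * 16)   # pad so 4 halvings are exact
  if (!identical(pd, as.integer(dm))) {
    ap <- array(0, pd)
    ap[seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3])] <- a
    a <- ap
  }
  x <- a; dim(x) <- c(prod(pd), 1L)
  dims <- pd
  skips <- list(); sdims <- list()
  for (i in 1:4) {
    x <- unet_block(x, dims, params[[paste0("enc", i)]])
    skips[[i]] <- x; sdims[[i]] <- dims
    x <- op_maxpool2(x, dims)
    dims <- as.integer((dims + 1L) %/% 2L)
  }
  x <- unet_block(x, dims, params$bottleneck)
  for (i in 4:1) {
    up <- params[[paste0("up", i)]]
    x <- op_convtrans2(x, up$W, up$b, dims)
    dims <- 2L * dims
    x <- op_cbind(list(x, skips[[i]]))
    x <- unet_block(x, dims, params[[paste0("dec", i)]])
  }
  x <- op_addbias(op_matmul(x, params$out$W), params$out$b)
  x <- op_sigmoid(x)
  if (!identical(as.integer(pd), as.integer(dm))) {
    ti <- seq_len(prod(dm)) - 1L
    ih <- ti %% dm[1]; iw <- (ti %/% dm[1]) %% dm[2]; id_ <- ti %/% (dm[1] * dm[2])
    idx <- ih + pd[1] * (iw + pd[2] * id_) + 1L
    x <- op_gather(x, as.integer(idx))
  }
  list(main = x, aux_slf = list(), aux_attn = list(), input_dims = dm)
}
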