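# Training loop, k-fold cross-validation, model selection and the
# feature-size / window-size sensitivity sweep.

#' Training configuration
#'
#' Defaults follow the study protocol: Adam, learning rate 1e-4, weight
#' decay 1e-4, 50 epochs, batch size one, best model selected by highest
#' validation Dice.
#'
#' @param lr learning rate.
#' @param weight_decay L2 coefficient added to gradients (Adam-coupled).
#' @param epochs training epochs.
#' @param batch_size fixed at 1 (one volume per optimizer step).
#' @param seed seed driving initialization, data order and augmentation.
#' @param max_steps optional cap on total optimizer steps.
#' @param weights deep-supervision [loss_weights()] (SwinDAF3D only).
#' @param augmentation optional [augmentation_config()] applied online to
#'   training cases (seeded per step).
#' @param val_every evaluate validation DSC every this many epochs (the
#'   final epoch is always evaluated).
#' @return A `train_config` list.
#' @export
train_config <- function(lr = 1e-4, weight_decay = 1e-4, epochs = 50L,
                         batch_size = 1L, seed = 0L, max_steps = Inf,
                         weights = loss_weights(), augmentation = NULL,
                         val_every = 1L) {
  stopifnot(lr > 0, weight_decay >= 0, epochs >= 1, batch_size == 1L,
            max_steps >= 1, val_every >= 1)
  structure(list(lr = lr, weight_decay = weight_decay,
                 epochs = as.integer(epochs), batch_size = 1L,
                 seed = as.integer(seed), max_steps = max_steps,
                 weights = weights, augmentation = augmentation,
                 val_every = as.integer(val_every)),
            class = "train_config")
}

#' Assign cases to cross-validation folds
#'
#' Seeded shuffle followed by round-robin assignment, so fold sizes differ
#' by at most one. With `groups` (e.g. patient ids) the groups are shuffled
#' and assigned round-robin instead, keeping each group in a single fold.
#'
#' @param case_ids character vector of case ids.
#' @param k number of folds (default 6).
#' @param seed shuffle seed.
#' @param groups optional grouping vector aligned with `case_ids`.
#' @return A `cv_plan`: list(k, assignments named integer vector, seed).
#' @export
make_folds <- function(case_ids, k = 6L, seed = 0L, groups = NULL) {
  k <- as.integer(k)
  n <- length(case_ids)
  if (k > n) stop("k = ", k, " exceeds the number of cases (", n, ")")
  if (anyDuplicated(case_ids)) stop("case ids must be unique")
  assignments <- with_seed(seed, {
    if (is.null(groups)) {
      ord <- sample.int(n)
      f <- integer(n)
      f[ord] <- rep_len(seq_len(k), n)
      f
    } else {
      stopifnot(length(groups) == n)
      gu <- unique(groups)
      if (k > length(gu)) stop("k exceeds the number of groups")
      gord <- sample(gu)
      gf <- stats::setNames(rep_len(seq_len(k), length(gu)), gord)
      as.integer(gf[as.character(groups)])
    }
  })
  names(assignments) <- case_ids
  structure(list(k = k, assignments = assignments, seed = as.integer(seed)),
            class = "cv_plan")
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = tree_map(function(x) x * 0, params),
       v = tree_map(function(x) x * 0, params),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  if (weight_decay > 0)
    grads <- tree_map2(function(g, p) g + weight_decay * p, grads, params)
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g * g,
                       state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) (m / c1) / (sqrt(v / c2) + eps),
                   state$m, state$v)
  list(params = tree_map2(function(p, u) p - lr * u, params, upd),
       state = state)
}

# one forward/backward/update step; returns new params, state, diagnostics
train_step <- function(model, params, case, tc, adam) {
  ad_tape_begin()
  on.exit(ad_tape_end(), add = TRUE)
  pt <- wrap_params(params)
  out <- model_forward(model, case$volume, pt)
  G <- case$mask$data
  if (model$type == "swindaf3d") {
    lb <- total_loss(out, G, tc$weights)
    lt <- lb$tensor
  } else {
    lt <- output_loss(out$main, G)
    lb <- list(total = adt_val(lt))
  }
  if (!is.finite(adt_val(lt)))
    stop("non-finite loss at Adam step ", adam$t + 1L,
         " (case ", case$id, ")")
  ad_backward(lt)
  grads <- grad_tree(pt)
  res <- adam_step(params, grads, adam, tc$lr, tc$weight_decay)
  pred <- adt_val(out$main)
  dim(pred) <- dim(G)
  list(params = res$params, adam = res$state, loss = lb$total,
       train_dsc = dice_score((pred > 0.5) * 1, G))
}

# mean validation DSC of binarized main predictions
validation_dsc <- function(model, params, cases) {
  mean(vapply(cases, function(cs) {
    out <- model_forward(model, cs$volume, params)
    pred <- adt_val(out$main)
    dim(pred) <- dim(cs$mask$data)
    dice_score((pred > 0.5) * 1, cs$mask$data)
  }, 0))
}

#' Train a segmentation model
#'
#' Runs the configured epochs (batch size one), evaluates validation DSC on
#' binarized main predictions after every epoch, and keeps the parameters
#' of the best validation epoch. Fully seeded: initialization, data order
#' and augmentation derive from `tc$seed`.
#'
#' @param model a `seg_model` from [build_swindaf3d()] or
#'   [build_reference_unet3d()].
#' @param tc a [train_config()].
#' @param train_cases,val_cases non-empty lists of [us_case()].
#' @param checkpoint_path optional path; the best model is saved there.
#' @param verbose print per-epoch progress.
#' @return A `run_record`: list(history data frame, best_epoch,
#'   best_val_dsc, model (best parameters), checkpoint_path, steps).
#' @export
train_model <- function(model, tc, train_cases, val_cases,
                        checkpoint_path = NULL, verbose = FALSE) {
  stopifnot(inherits(tc, "train_config"),
            length(train_cases) >= 1L, length(val_cases) >= 1L)
  params <- model$params
  adam <- adam_init(params)
  best <- list(epoch = 0L, val_dsc = -Inf, params = params)
  hist <- vector("list", tc$epochs)
  step <- 0L
  for (ep in seq_len(tc$epochs)) {
    ord <- with_seed(derive_seed(tc$seed, ep), sample.int(length(train_cases)))
    losses <- c(); dscs <- c()
    for (ci in ord) {
      if (step >= tc$max_steps) break
      step <- step + 1L
      cs <- train_cases[[ci]]
      if (!is.null(tc$augmentation))
        cs <- augment_case(cs, tc$augmentation,
                           seed = derive_seed(tc$seed, 1000L + step))
      st <- train_step(model, params, cs, tc, adam)
      params <- st$params; adam <- st$adam
      losses <- c(losses, st$loss); dscs <- c(dscs, st$train_dsc)
    }
    last <- ep == tc$epochs || step >= tc$max_steps
    vd <- if (ep %% tc$val_every == 0L || last)
      validation_dsc(model, params, val_cases) else NA_real_
    hist[[ep]] <- data.frame(epoch = ep, steps = step,
                             train_loss = mean(losses),
                             train_dsc = mean(dscs), val_dsc = vd)
    if (verbose)
      message(sprintf("epoch %d: loss %.4f train DSC %.3f val DSC %.3f",
                      ep, mean(losses), mean(dscs), vd))
    if (!is.na(vd) && vd > best$val_dsc)
      best <- list(epoch = ep, val_dsc = vd, params = params)
    if (step >= tc$max_steps) break
  }
  best_model <- model
  best_model$params <- best$params
  if (!is.null(checkpoint_path)) save_checkpoint(best_model, checkpoint_path)
  structure(list(history = do.call(rbind, hist[!vapply(hist, is.null, TRUE)]),
                 best_epoch = best$epoch, best_val_dsc = best$val_dsc,
                 model = best_model, checkpoint_path = checkpoint_path,
                 steps = step),
            class = "run_record")
}

#' Evaluate a model (or checkpoint) on a set of cases
#'
#' Full-resolution metrics after 0.5 binarization of the main prediction.
#'
#' @param model a `seg_model` or a checkpoint path.
#' @param cases list of [us_case()].
#' @param d surface-Dice tolerance.
#' @return Data frame (case, dsc, iou, sdsc) plus a final `mean` row.
#' @export
evaluate_model <- function(model, cases, d = 1) {
  if (is.character(model)) model <- load_checkpoint(model)
  rows <- lapply(cases, function(cs) {
    out <- model_forward(model, cs$volume)
    pred <- adt_val(out$main)
    dim(pred) <- dim(cs$mask$data)
    m <- seg_metrics((pred > 0.5) * 1, cs$mask$data, d)
    data.frame(case = cs$id, dsc = m$dsc, iou = m$iou, sdsc = m$sdsc)
  })
  tab <- do.call(rbind, rows)
  rbind(tab, data.frame(case = "mean", dsc = mean(tab$dsc),
                        iou = mean(tab$iou), sdsc = mean(tab$sdsc)))
}

#' Run k-fold cross-validation
#'
#' Trains one model per fold (validation = the held-out fold), selects the
#' best-validation-DSC checkpoint per fold, and records that checkpoint's
#' DSC/IoU/SDSC on its validation fold. Summary rows use the population-std
#' convention.
#'
#' @param cases list of [us_case()].
#' @param model_builder zero-argument function returning a fresh
#'   `seg_model` (e.g. `function() build_swindaf3d(ec, hc)`).
#' @param tc a [train_config()].
#' @param k folds (default 6).
#' @param groups optional grouping (e.g. patient ids) for leakage-free
#'   splits.
#' @param model_name label used in the fold table.
#' @return List: `fold_table` (long data frame model/fold/metric/value),
#'   `summary` ([fold_summary_table()] output), `plan`, `records`.
#' @export
run_cross_validation <- function(cases, model_builder, tc, k = 6L,
                                 groups = NULL, model_name = "model") {
  ids <- vapply(cases, `[[`, "", "id")
  plan <- make_folds(ids, k, seed = tc$seed, groups = groups)
  records <- vector("list", k)
  rows <- list()
  for (f in seq_len(k)) {
    val_idx <- which(plan$assignments == f)
    tr <- cases[-val_idx]; va <- cases[val_idx]
    rec <- train_model(model_builder(), tc, tr, va)
    records[[f]] <- rec
    ev <- evaluate_model(rec$model, va)
    mrow <- ev[ev$case == "mean", ]
    rows[[f]] <- data.frame(model = model_name, fold = f,
                            metric = c("dsc", "iou", "sdsc"),
                            value = c(mrow$dsc, mrow$iou, mrow$sdsc))
  }
  fold_table <- do.call(rbind, rows)
  list(fold_table = fold_table, summary = fold_summary_table(fold_table),
       plan = plan, records = records)
}

#' Feature-size / window-size sensitivity sweep
#'
#' Instantiates each encoder variant (feature sizes at fixed window 7, then
#' window sizes at fixed feature size 48 by default). In `"shape"` mode it
#' records parameter counts and a forward-pass success flag on a small
#' volume; in `"train"` mode it additionally runs the training protocol per
#' variant.
#'
#' @param feature_sizes embedding dims swept at `windows[match]` fixed 7.
#' @param window_sizes window edges swept at feature size 48.
#' @param mode "shape" or "train".
#' @param input_shape volume extents for the forward smoke test.
#' @param head a [head_config()] shared by all variants.
#' @param tc,train_cases,val_cases used only in `"train"` mode.
#' @param fixed_feature,fixed_window the held-constant values.
#' @return Data frame: sweep, feature_size, window, params, forward_ok (and
#'   val_dsc in train mode).
#' @export
sensitivity_sweep <- function(feature_sizes = c(24L, 36L, 48L, 60L),
                              window_sizes = c(3L, 5L, 7L, 9L),
                              mode = c("shape", "train"),
                              input_shape = c(64L, 64L, 32L),
                              head = head_config(16L),
                              tc = NULL, train_cases = NULL, val_cases = NULL,
                              fixed_feature = 48L, fixed_window = 7L) {
  mode <- match.arg(mode)
  stopifnot(length(feature_sizes) >= 1L, length(window_sizes) >= 1L)
  variants <- rbind(
    data.frame(sweep = "feature_size", feature_size = feature_sizes,
               window = fixed_window),
    data.frame(sweep = "window_size", feature_size = fixed_feature,
               window = window_sizes))
  vol <- array(0.5, input_shape)
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    row <- data.frame(sweep = v$sweep, feature_size = v$feature_size,
                      window = v$window, params = NA_real_,
                      forward_ok = FALSE)
    ok <- tryCatch({
      ec <- encoder_config(embed_dim = v$feature_size, window = v$window)
      model <- build_swindaf3d(ec, head)
      row$params <- model_param_count(model)
      invisible(predict_volume(model, vol))
      TRUE
    }, error = function(e) {
      message("variant ", v$feature_size, "/", v$window, " failed: ",
              conditionMessage(e))
      FALSE
    })
    row$forward_ok <- ok
    if (mode == "train" && ok) {
      ec <- encoder_config(embed_dim = v$feature_size, window = v$window)
      rec <- train_model(build_swindaf3d(ec, head), tc, train_cases,
                         val_cases)
      row$val_dsc <- rec$best_val_dsc
    }
    row
  })
  do.call(rbind, rows)
}
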