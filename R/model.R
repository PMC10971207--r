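#' Modality configuration
#'
#' Selects which stack channels feed the network: darkfield only (`"DF"`),
#' the two IR ratio channels only (`"IR"`), or their concatenation
#' (`"COMBINED"`).
#'
#' @param name one of `"DF"`, `"IR"`, `"COMBINED"`.
#' @return An object of class `modality_config` with the channel indices into
#'   the stack's fixed channel order (`r1238`, `r1546`, `df`).
#' @export
modality_config <- function(name = c("COMBINED", "IR", "DF")) {
  name <- match.arg(toupper(name), c("COMBINED", "IR", "DF"))
  channels <- switch(name, DF = 3L, IR = c(1L, 2L), COMBINED = 1:3)
  structure(list(name = name, channels = channels), class = "modality_config")
}

#' Training protocol configuration
#'
#' Defaults follow the acquisition-scale training protocol: Adam with learning
#' rate 2e-4 and weight decay 1e-5, a stepped learning-rate schedule halving
#' every 5 epochs, plain cross-entropy with the background class ignored,
#' early stopping on validation loss, random affine augmentation of every
#' patch in every iteration, and three replicate trainings with derived seeds.
#'
#' @param learning_rate Adam learning rate.
#' @param weight_decay L2 penalty folded into the gradient.
#' @param scheduler_step_epochs,scheduler_gamma the learning rate after epoch
#'   `e` (0-based) is `learning_rate * scheduler_gamma^floor(e / step)`.
#' @param max_epochs epoch budget.
#' @param batch_size minibatch size.
#' @param early_stopping_patience epochs without validation improvement before
#'   stopping; `min_delta` is the smallest improvement that counts.
#' @param min_delta see above.
#' @param augment apply random affine augmentation during training.
#' @param aug_rotation_deg,aug_translation_frac,aug_scale,aug_shear_deg
#'   augmentation ranges: rotation (+/- deg), translation (+/- fraction of the
#'   patch), isotropic scale interval, shear (+/- deg).
#' @param n_replicates number of parallel replicate trainings (replicate `r`
#'   is seeded with `seed + r`).
#' @param seed base seed.
#' @param backbone `"resnet50"` (bottleneck stages 3-4-6-3, output stride 32)
#'   or `"reduced"` (two basic residual blocks, output stride 4) for CPU-scale
#'   runs.
#' @param class_weights optional per-class loss weights (classes 1..3);
#'   `NULL` for the plain unweighted loss.
#' @param verbose print per-epoch losses.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 2e-4,
                         weight_decay = 1e-5,
                         scheduler_step_epochs = 5L,
                         scheduler_gamma = 0.5,
                         max_epochs = 30L,
                         batch_size = 8L,
                         early_stopping_patience = 10L,
                         min_delta = 1e-4,
                         augment = TRUE,
                         aug_rotation_deg = 30,
                         aug_translation_frac = 0.1,
                         aug_scale = c(0.9, 1.1),
                         aug_shear_deg = 5,
                         n_replicates = 3L,
                         seed = 0L,
                         backbone = c("resnet50", "reduced"),
                         class_weights = NULL,
                         verbose = FALSE) {
  backbone <- match.arg(backbone)
  if (learning_rate <= 0 || weight_decay < 0)
    stop_param("rates must be positive")
  if (!(scheduler_gamma > 0 && scheduler_gamma < 1))
    stop_param("scheduler_gamma must be in (0, 1)")
  if (n_replicates < 1) stop_param("n_replicates must be >= 1")
  if (max_epochs < 0 || batch_size < 1) stop_param("invalid epoch/batch settings")
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 scheduler_step_epochs = as.integer(scheduler_step_epochs),
                 scheduler_gamma = scheduler_gamma,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 early_stopping_patience = as.integer(early_stopping_patience),
                 min_delta = min_delta, augment = augment,
                 aug_rotation_deg = aug_rotation_deg,
                 aug_translation_frac = aug_translation_frac,
                 aug_scale = aug_scale, aug_shear_deg = aug_shear_deg,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), backbone = backbone,
                 class_weights = class_weights, verbose = verbose),
            class = "train_config")
}

#' Learning-rate schedule
#'
#' @param config a [train_config()].
#' @param epochs number of epochs to tabulate.
#' @return Numeric vector: `learning_rate * gamma^floor(e / step)` for epochs
#'   `e = 0 .. epochs - 1`.
#' @export
lr_schedule <- function(config, epochs = config$max_epochs) {
  e <- seq_len(epochs) - 1L
  config$learning_rate * config$scheduler_gamma ^
    (e %/% config$scheduler_step_epochs)
}

#' Build the fully convolutional segmentation network
#'
#' Constructs the layer specification of an FCN over a residual backbone. The
#' first convolution is sized to the modality's channel count; the head is a
#' 1x1 convolution to per-pixel class scores followed by bilinear up-sampling
#' back to the input grid, so an input of shape `C x H x W` maps to scores
#' `n_classes x H x W` for any `H`, `W` divisible by the output stride.
#'
#' @param modality a [modality_config()] (or an integer channel count).
#' @param n_classes number of tissue classes (>= 2; background is not a
#'   predicted class, it is ignored by the loss and masked at inference).
#' @param backbone `"resnet50"` or `"reduced"`.
#' @return An object of class `fcn_spec`.
#' @export
build_fcn <- function(modality, n_classes = 3L, backbone = c("resnet50", "reduced")) {
  backbone <- match.arg(backbone)
  in_ch <- if (inherits(modality, "modality_config"))
    length(modality$channels) else as.integer(modality)
  if (n_classes < 2) stop_param("n_classes must be >= 2")
  if (backbone == "reduced") {
    layers <- list(
      list(type = "conv", out = 8L, k = 3L, stride = 2L, pad = 1L),
      list(type = "bn"), list(type = "relu"),
      list(type = "res_basic", out = 16L, stride = 2L),
      list(type = "res_basic", out = 16L, stride = 1L),
      list(type = "conv", out = as.integer(n_classes), k = 1L, stride = 1L,
           pad = 0L),
      list(type = "upsample", factor = 4L)
    )
    stride_product <- 4L
  } else {
    blocks <- function(mid, n, first_stride) {
      c(list(list(type = "res_bneck", mid = as.integer(mid),
                  stride = as.integer(first_stride))),
        rep(list(list(type = "res_bneck", mid = as.integer(mid), stride = 1L)),
            n - 1))
    }
    layers <- c(
      list(list(type = "conv", out = 64L, k = 7L, stride = 2L, pad = 3L),
           list(type = "bn"), list(type = "relu"), list(type = "maxpool")),
      blocks(64, 3, 1), blocks(128, 4, 2), blocks(256, 6, 2), blocks(512, 3, 2),
      list(list(type = "conv", out = as.integer(n_classes), k = 1L,
                stride = 1L, pad = 0L),
           list(type = "upsample", factor = 32L))
    )
    stride_product <- 32L
  }
  structure(list(spec = list(in_channels = as.integer(in_ch), layers = layers),
                 in_channels = as.integer(in_ch),
                 n_classes = as.integer(n_classes),
                 backbone = backbone, stride_product = stride_product),
            class = "fcn_spec")
}

check_input_dims <- function(fcn, h, w) {
  s <- fcn$stride_product
  if (h %% s != 0 || w %% s != 0)
    stop_param("input size %d x %d must be divisible by the network stride product %d",
               h, w, s)
}

#' Forward pass through an FCN
#'
#' @param fcn an `fcn_spec`.
#' @param params a parameter list from [init_fcn_params()] or training.
#' @param x array `H x W x C` or `H x W x C x B` of standardized inputs.
#' @param probs return softmax probabilities instead of raw scores.
#' @return Array `H x W x n_classes x B` of per-pixel scores/probabilities.
#' @export
fcn_forward <- function(fcn, params, x, probs = FALSE) {
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  d <- dim(x)
  if (d[3] != fcn$in_channels)
    stop_param("input has %d channels but the network expects %d", d[3],
               fcn$in_channels)
  check_input_dims(fcn, d[1], d[2])
  nn_forward(fcn$spec, params, x, FALSE, probs)
}

#' Initialize FCN parameters
#' @param fcn an `fcn_spec`.
#' @param seed integer seed (Kaiming-normal convolution weights).
#' @return Opaque parameter list consumed by [fcn_forward()] and training.
#' @export
init_fcn_params <- function(fcn, seed = 0L) {
  nn_init(fcn$spec, as.integer(seed))
}

#' Random affine augmentation of one patch
#'
#' Applies a random (or explicitly given) affine transform about the patch
#' centre: channels are interpolated bilinearly and labels nearest-neighbor
#' with the identical transform; regions mapped from outside the patch are
#' filled with 0 (background, ignored by the loss). Draws use R's RNG, so the
#' caller controls reproducibility with `set.seed()`.
#'
#' @param patch list with `channels` (`H x W x C`) and optional `labels`.
#' @param rotation_deg,translation_frac,scale,shear_deg ranges, as in
#'   [train_config()].
#' @param params optional explicit transform `list(rot, shear, scale, tr, tc)`
#'   bypassing the random draw.
#' @return The augmented patch (same spatial size, same fields).
#' @export
augment_affine <- function(patch, rotation_deg = 30, translation_frac = 0.1,
                           scale = c(0.9, 1.1), shear_deg = 5, params = NULL) {
  ch <- patch$channels
  if (length(dim(ch)) != 3L) stop_param("patch$channels must be H x W x C")
  H <- dim(ch)[1]; W <- dim(ch)[2]
  if (is.null(params)) {
    params <- list(rot = stats::runif(1, -rotation_deg, rotation_deg),
                   shear = stats::runif(1, -shear_deg, shear_deg),
                   scale = stats::runif(1, scale[1], scale[2]),
                   tr = stats::runif(1, -translation_frac, translation_frac) * H,
                   tc = stats::runif(1, -translation_frac, translation_frac) * W)
  }
  lab <- patch$labels
  res <- warp_affine_cpp(ch, if (is.null(lab)) NULL else lab,
                         params$rot, params$shear, params$scale,
                         params$tr, params$tc)
  out <- patch
  out$channels <- array(res$channels, dim(ch))
  if (!is.null(lab)) out$labels <- res$labels
  out
}

#' Train the segmentation model
#'
#' Fits the fully convolutional segmentation network on the training split of
#' a patch dataset, once per replicate. Replicate `r` is seeded with
#' `config$seed + r` (initialization, shuffling and augmentation), giving
#' bit-reproducible training histories. The learning rate follows the stepped
#' schedule, training stops early when the validation loss fails to improve by
#' `min_delta` for `early_stopping_patience` epochs, and the weights from the
#' best validation epoch are retained. The cross-entropy loss ignores
#' background (label 0) pixels.
#'
#' @param dataset a [patch_dataset()] with train (and ideally val) splits.
#' @param modality a [modality_config()] or its name.
#' @param config a [train_config()].
#' @return An object of class `dfir_fcn`: the fitted model ensemble, with
#'   `replicates` (each carrying `params`, a `history` data.frame, and the
#'   best/stopped epoch), the `fcn` spec, `modality`, `config`, and the
#'   training standardization `stats`.
#' @seealso [predict.dfir_fcn()], [predict_section()]
#' @export
train_segmenter <- function(dataset, modality = "COMBINED",
                            config = train_config()) {
  if (!inherits(dataset, "patch_dataset"))
    stop_param("dataset must be a patch_dataset")
  if (!inherits(modality, "modality_config"))
    modality <- modality_config(modality)
  train <- patch_arrays(dataset, "train", modality)
  if (is.null(train)) stop_param("the training split is empty")
  val <- patch_arrays(dataset, "val", modality)
  fcn <- build_fcn(modality, n_classes = 3L, backbone = config$backbone)
  check_input_dims(fcn, dim(train$X)[1], dim(train$X)[2])

  reps <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    seed_r <- config$seed + r
    hyper <- list(learning_rate = config$learning_rate,
                  weight_decay = config$weight_decay,
                  scheduler_step_epochs = config$scheduler_step_epochs,
                  scheduler_gamma = config$scheduler_gamma,
                  max_epochs = config$max_epochs,
                  batch_size = config$batch_size,
                  early_stopping_patience = config$early_stopping_patience,
                  min_delta = config$min_delta,
                  seed = as.integer(seed_r),
                  augment = isTRUE(config$augment),
                  aug_rotation_deg = config$aug_rotation_deg,
                  aug_translation_frac = config$aug_translation_frac,
                  aug_scale_lo = config$aug_scale[1],
                  aug_scale_hi = config$aug_scale[2],
                  aug_shear_deg = config$aug_shear_deg,
                  verbose = isTRUE(config$verbose),
                  n_classes = fcn$n_classes,
                  class_weights = config$class_weights)
    params0 <- init_fcn_params(fcn, seed = seed_r)
    fit <- nn_train(fcn$spec, params0, train$X, train$Y,
                    if (is.null(val)) NULL else val$X,
                    if (is.null(val)) NULL else val$Y, hyper)
    reps[[r]] <- list(params = fit$params,
                      history = as.data.frame(fit$history),
                      best_epoch = fit$best_epoch,
                      stopped_epoch = fit$stopped_epoch,
                      replicate = r, seed = seed_r)
  }
  structure(list(replicates = reps, fcn = fcn, modality = modality,
                 config = config, stats = dataset$stats),
            class = "dfir_fcn")
}

#' @export
print.dfir_fcn <- function(x, ...) {
  cat(sprintf("<dfir_fcn> %s backbone, modality %s (%d input channels), %d replicate(s)\n",
              x$fcn$backbone, x$modality$name, x$fcn$in_channels,
              length(x$replicates)))
  for (r in x$replicates) {
    h <- r$history
    if (nrow(h))
      cat(sprintf("  replicate %d: %d epochs (best %d), final train loss %.4f%s\n",
                  r$replicate, r$stopped_epoch, r$best_epoch,
                  h$train_loss[nrow(h)],
                  if (all(is.na(h$val_loss))) "" else
                    sprintf(", best val loss %.4f", min(h$val_loss, na.rm = TRUE))))
    else cat(sprintf("  replicate %d: untrained (0 epochs)\n", r$replicate))
  }
  invisible(x)
}

#' @export
summary.dfir_fcn <- function(object, ...) {
  print(object)
  n_par <- sum(vapply(object$replicates[[1]]$params, length, 0L))
  cat(sprintf("  parameters: %s\n", format(n_par, big.mark = ",")))
  cat(sprintf("  protocol: Adam lr %.1e, weight decay %.1e, step %d, gamma %.2f, batch %d\n",
              object$config$learning_rate, object$config$weight_decay,
              object$config$scheduler_step_epochs, object$config$scheduler_gamma,
              object$config$batch_size))
  invisible(object)
}

#' @export
plot.dfir_fcn <- function(x, ...) {
  hs <- lapply(x$replicates, `[[`, "history")
  if (!nrow(hs[[1]])) {
    warning("no training history to plot")
    return(invisible(x))
  }
  ylim <- range(unlist(lapply(hs, function(h) c(h$train_loss, h$val_loss))),
                na.rm = TRUE)
  graphics::plot(NULL, xlim = c(1, max(vapply(hs, nrow, 0L))), ylim = ylim,
                 xlab = "epoch", ylab = "cross-entropy loss",
                 main = sprintf("training history (%s)", x$modality$name))
  for (i in seq_along(hs)) {
    graphics::lines(hs[[i]]$epoch, hs[[i]]$train_loss, col = i, lty = 1)
    if (!all(is.na(hs[[i]]$val_loss)))
      graphics::lines(hs[[i]]$epoch, hs[[i]]$val_loss, col = i, lty = 2)
  }
  graphics::legend("topright", legend = c("train", "validation"), lty = 1:2,
                   bty = "n")
  invisible(x)
}

#' Whole-section prediction by tiling
#'
#' Tiles the section, runs the network on each tile, blends overlapping tile
#' softmax scores by averaging, takes the per-pixel argmax, and forces pixels
#' outside the tissue mask to class 0.
#'
#' @param model a fitted `dfir_fcn` (or any object honoring `model_fun`).
#' @param stack a `multimodal_stack` whose channels match the model modality.
#' @param tile tile side in px.
#' @param overlap overlap between neighboring tiles in px.
#' @param replicate which replicate's weights to use.
#' @param model_fun optional override: `function(x[H,W,C,B]) -> probs
#'   [H,W,K,B]`, used in place of the fitted network (e.g. a stub).
#' @return Integer label matrix on the stack grid (0 outside the mask).
#' @export
predict_section <- function(model, stack, tile = 256L, overlap = 32L,
                            replicate = 1L, model_fun = NULL) {
  H <- stack$grid_shape[1]; W <- stack$grid_shape[2]
  tile <- as.integer(tile); overlap <- as.integer(overlap)
  if (is.null(model_fun)) {
    if (tile %% model$fcn$stride_product != 0)
      stop_param("tile (%d) must be a multiple of the network stride product (%d)",
                 tile, model$fcn$stride_product)
    params <- model$replicates[[replicate]]$params
    model_fun <- function(x) nn_forward(model$fcn$spec, params, x, FALSE, TRUE)
    chans <- model$modality$channels
    stats <- model$stats
  } else {
    chans <- seq_len(dim(stack$channels)[3])
    stats <- stack$stats
  }
  if (tile > H || tile > W)
    stop_param("tile (%d) exceeds the section (%d x %d)", tile, H, W)
  if (overlap < 0 || overlap >= tile)
    stop_param("overlap must be in [0, tile)")
  x <- standardize_channels(stack$channels, stack$tissue_mask, stats,
                            select = chans)
  starts <- function(n) {
    s <- seq(0L, n - tile, by = tile - overlap)
    unique(c(s, n - tile))
  }
  acc <- NULL
  wt <- matrix(0, H, W)
  for (r0 in starts(H)) {
    for (c0 in starts(W)) {
      rs <- (r0 + 1L):(r0 + tile)
      cs <- (c0 + 1L):(c0 + tile)
      xt <- array(x[rs, cs, , drop = FALSE], c(tile, tile, length(chans), 1L))
      pr <- model_fun(xt)
      K <- dim(pr)[3]
      if (is.null(acc)) acc <- array(0, dim = c(H, W, K))
      acc[rs, cs, ] <- acc[rs, cs, , drop = FALSE] +
        array(pr[, , , 1], c(tile, tile, K))
      wt[rs, cs] <- wt[rs, cs] + 1
    }
  }
  for (k in seq_len(dim(acc)[3])) acc[, , k] <- acc[, , k] / wt
  pred <- matrix(max.col(matrix(acc, H * W, dim(acc)[3]),
                         ties.method = "first"), H, W)
  pred[!stack$tissue_mask] <- 0L
  storage.mode(pred) <- "integer"
  pred
}

#' Predict method for fitted segmentation models
#'
#' @param object a fitted `dfir_fcn`.
#' @param newdata a `multimodal_stack`.
#' @param tile,overlap,replicate passed to [predict_section()].
#' @param ... unused.
#' @return Integer label matrix (see [predict_section()]).
#' @export
predict.dfir_fcn <- function(object, newdata, tile = 256L, overlap = 32L,
                             replicate = 1L, ...) {
  predict_section(object, newdata, tile = tile, overlap = overlap,
                  replicate = replicate)
}
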