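#' Training configuration
#'
#' Optimization protocol: stochastic gradient descent with momentum on the
#' soft Dice loss, initial learning rate 0.01, and automatic reduction of
#' the learning rate by `lr_factor` whenever the validation loss has not
#' improved for `lr_patience` consecutive epochs. The weights from the epoch
#' with the highest validation Dice are kept.
#'
#' @param initial_lr Initial learning rate.
#' @param momentum SGD momentum coefficient.
#' @param lr_patience Non-improving validation epochs before a reduction.
#' @param lr_factor Multiplier applied to the learning rate at a reduction.
#' @param max_epochs Training epochs.
#' @param batch_size Slices per gradient step.
#' @param loss_smooth Dice-loss smoothing constant (epsilon). The default 1
#'   (the conventional smooth-Dice constant) keeps a usable gradient on
#'   tumor-free slices, penalizing false positives there; a tiny epsilon
#'   leaves such slices with loss near 1 but almost no gradient.
#' @param threshold Probability cutoff for the hard validation Dice.
#' @param augment Apply train-time geometric + grayscale augmentation?
#' @param seed RNG seed controlling shuffling and augmentation.
#' @return An object of class `train_config`.
#' @export
train_config <- function(initial_lr = 0.01, momentum = 0.9, lr_patience = 3L,
                         lr_factor = 0.1, max_epochs = 200L, batch_size = 16L,
                         loss_smooth = 1, threshold = 0.5, augment = TRUE,
                         seed = 1L) {
  if (lr_factor <= 0 || lr_factor >= 1) stopf("lr_factor must be in (0, 1)")
  if (lr_patience < 1) stopf("lr_patience must be >= 1")
  if (loss_smooth <= 0) stopf("loss_smooth must be > 0")
  structure(list(initial_lr = initial_lr, momentum = momentum,
                 lr_patience = as.integer(lr_patience), lr_factor = lr_factor,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 loss_smooth = loss_smooth, threshold = threshold,
                 augment = isTRUE(augment), seed = as.integer(seed)),
            class = "train_config")
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)`, computed per
#' sample and averaged over the batch. The epsilon keeps the loss defined
#' (and zero) when prediction and target are both empty.
#'
#' @param pred_probs Predicted probabilities in `[0, 1]`; an `H x W` matrix
#'   or an `H x W x 1 x N` batch.
#' @param target_mask Binary target of the same shape.
#' @param eps Smoothing constant.
#' @return Scalar loss in `[0, 1]`.
#' @export
dice_loss <- function(pred_probs, target_mask, eps = 1e-6) {
  if (!identical(dim(pred_probs), dim(target_mask)))
    stopf("prediction and target shapes differ")
  n <- if (length(dim(pred_probs)) == 4L) dim(pred_probs)[4] else 1L
  pm <- matrix(pred_probs, ncol = n)
  tm <- matrix(target_mask, ncol = n)
  inter <- colSums(pm * tm)
  denom <- colSums(pm) + colSums(tm)
  mean(1 - (2 * inter + eps) / (denom + eps))
}

# Gradient of dice_loss w.r.t. pred_probs (same shape as pred).
dice_loss_grad <- function(pred_probs, target_mask, eps = 1e-6) {
  d <- dim(pred_probs)
  n <- if (length(d) == 4L) d[4] else 1L
  pm <- matrix(pred_probs, ncol = n)
  tm <- matrix(target_mask, ncol = n)
  inter <- colSums(pm * tm)
  denom <- colSums(pm) + colSums(tm) + eps
  num <- 2 * inter + eps
  g <- -(2 * tm * rep(denom, each = nrow(pm)) -
           rep(num, each = nrow(pm))) / rep(denom^2, each = nrow(pm)) / n
  dim(g) <- d
  g
}

#' Hard Dice of a thresholded probability map (evaluation-time Dice)
#'
#' @param probs Probability array; @param target binary array;
#' @param threshold cutoff (`>=` is foreground).
#' @return Scalar Dice in `[0, 1]` (1 when both masks are empty).
#' @keywords internal
hard_dice <- function(probs, target, threshold = 0.5) {
  dice((probs >= threshold) * 1L, (target >= 0.5) * 1L)
}

# plateau learning-rate scheduler -------------------------------------------

plateau_state <- function(lr, patience, factor, min_delta = 1e-8) {
  list(lr = lr, patience = patience, factor = factor, min_delta = min_delta,
       best = Inf, wait = 0L)
}

# One scheduler step on a new validation loss. Reduces lr by `factor` after
# `patience` consecutive non-improving epochs, then resets the counter.
plateau_update <- function(state, val_loss) {
  if (val_loss < state$best - state$min_delta) {
    state$best <- val_loss
    state$wait <- 0L
  } else {
    state$wait <- state$wait + 1L
    if (state$wait >= state$patience) {
      state$lr <- state$lr * state$factor
      state$wait <- 0L
    }
  }
  state
}

# ---------------------------------------------------------------------------

prepare_training_arrays <- function(samples, preprocess, augment) {
  H <- nrow(samples[[1]]$image)
  W <- ncol(samples[[1]]$image)
  n <- length(samples)
  x <- array(0, c(H, W, 1L, n))
  y <- array(0, c(H, W, 1L, n))
  for (i in seq_len(n)) {
    s <- samples[[i]]
    img <- s$image
    masks <- list(liver = s$liver_mask, tumor = s$tumor_mask)
    if (augment) {
      ga <- geometric_augment(img, masks, preprocess)
      img <- ga$image
      masks <- ga$masks
    }
    inp <- prepare_input(img, masks$liver, preprocess)
    if (augment && preprocess$gray_float_enabled) inp <- grayscale_float(inp)
    x[, , 1L, i] <- inp
    y[, , 1L, i] <- masks$tumor
  }
  list(x = x, y = y)
}

sgd_update <- function(model, grads, vel, lr, momentum) {
  for (nm in names(model$params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    v <- vel$params[[nm]]
    if (is.null(v)) v <- g * 0
    v <- momentum * v - lr * g
    vel$params[[nm]] <- v
    model$params[[nm]] <- model$params[[nm]] + v
  }
  for (nm in names(grads$att)) {
    v <- vel$att[[nm]]
    if (is.null(v)) v <- grads$att[[nm]] * 0
    v <- momentum * v - lr * grads$att[[nm]]
    vel$att[[nm]] <- v
    model$att[[nm]] <- model$att[[nm]] + v
  }
  list(model = model, vel = vel)
}

#' Train a segmentation network on slice samples
#'
#' Runs SGD with momentum on the soft Dice loss over mini-batches of
#' preprocessed (and, per epoch, re-augmented) training slices. After each
#' epoch the validation slices are scored with the soft loss and the hard
#' Dice at the configured threshold; the learning rate is reduced by
#' `lr_factor` when the validation loss stalls for `lr_patience` epochs, and
#' the weights with the highest validation Dice are retained.
#'
#' @param model An `snet_model` from [build_snet()].
#' @param train_samples,val_samples Lists of [slice_sample()] with HU
#'   images; both nonempty. Run [contrast_filter()] on the training list
#'   beforehand if desired — never on validation.
#' @param config A [train_config()].
#' @param preprocess A [preprocess_config()]; stored in the returned
#'   checkpoint so inference can replay it.
#' @param verbose Print a line per epoch?
#' @return An object of class `snet_checkpoint`: the best model, the
#'   preprocess/train configs, `history` (per-epoch train loss, validation
#'   loss, validation Dice, learning rate) and `best_epoch`.
#' @export
train_snet <- function(model, train_samples, val_samples,
                       config = train_config(),
                       preprocess = preprocess_config(), verbose = FALSE) {
  if (!length(train_samples) || !length(val_samples))
    stopf("empty training or validation set")
  with_seed(config$seed, {
    sched <- plateau_state(config$initial_lr, config$lr_patience,
                           config$lr_factor)
    vel <- list(params = list(), att = list())
    best_dice <- -Inf
    best_model <- model
    best_epoch <- 0L
    hist <- data.frame(epoch = integer(), train_loss = numeric(),
                       val_loss = numeric(), val_dice = numeric(),
                       lr = numeric())
    val_arrays <- prepare_training_arrays(val_samples, preprocess,
                                          augment = FALSE)
    for (epoch in seq_len(config$max_epochs)) {
      tr <- prepare_training_arrays(train_samples, preprocess,
                                    augment = config$augment)
      ord <- sample(length(train_samples))
      losses <- numeric()
      for (start in seq(1, length(ord), by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, length(ord))]
        xb <- tr$x[, , , idx, drop = FALSE]
        yb <- tr$y[, , , idx, drop = FALSE]
        fw <- snet_forward(model, xb, training = TRUE)
        model <- fw$model
        loss <- dice_loss(fw$probs, yb, config$loss_smooth)
        if (!is.finite(loss))
          stopf("training diverged (non-finite loss) at epoch %d", epoch)
        losses <- c(losses, loss)
        dprobs <- dice_loss_grad(fw$probs, yb, config$loss_smooth)
        dlogits <- dprobs * fw$probs * (1 - fw$probs)
        grads <- snet_backward(model, fw, dlogits)
        upd <- sgd_update(model, grads, vel, sched$lr, config$momentum)
        model <- upd$model
        vel <- upd$vel
      }
      # validation: evaluation-mode forward in one batch
      vp <- snet_forward(model, val_arrays$x)
      val_loss <- dice_loss(vp, val_arrays$y, config$loss_smooth)
      vd <- vapply(seq_len(dim(vp)[4]), function(i)
        hard_dice(vp[, , 1L, i], val_arrays$y[, , 1L, i], config$threshold),
        numeric(1))
      val_dice <- mean(vd)
      hist <- rbind(hist, data.frame(epoch = epoch,
                                     train_loss = mean(losses),
                                     val_loss = val_loss,
                                     val_dice = val_dice, lr = sched$lr))
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  val loss %.4f  val dice %.4f  lr %g",
                        epoch, mean(losses), val_loss, val_dice, sched$lr))
      if (val_dice > best_dice) {
        best_dice <- val_dice
        best_model <- model
        best_epoch <- epoch
      }
      sched <- plateau_update(sched, val_loss)
    }
    structure(list(model = best_model, preprocess = preprocess,
                   train_config = config, history = hist,
                   best_epoch = best_epoch, best_val_dice = best_dice),
              class = "snet_checkpoint")
  })
}

#' @export
print.snet_checkpoint <- function(x, ...) {
  cat(sprintf("<snet_checkpoint> %d epochs, best epoch %d (val Dice %.3f)\n",
              nrow(x$history), x$best_epoch, x$best_val_dice))
  invisible(x)
}

#' Save / load a trained checkpoint
#'
#' The checkpoint embeds the model (weights + architecture config) and the
#' preprocessing and training configurations, so inference replays exactly
#' the training-time preprocessing.
#'
#' @param checkpoint An `snet_checkpoint` from [train_snet()].
#' @param path File path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the checkpoint.
#' @export
save_checkpoint <- function(checkpoint, path) {
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!inherits(ck, "snet_checkpoint")) stopf("not a checkpoint file: %s", path)
  ck
}

#' Segment a whole volume slice by slice
#'
#' Applies the training-time deterministic preprocessing to every axial
#' slice, runs the network, thresholds, restacks to 3D, applies
#' morphological closing per slice and finally re-intersects with the liver
#' mask (the network operates on liver-masked input, so predictions outside
#' the liver are artefacts of closing).
#'
#' @param checkpoint An `snet_checkpoint` (or an `snet_model`, in which case
#'   `preprocess` must be given).
#' @param case List with `volume` ([ct_volume()]) and `liver_mask` (3D
#'   binary array), e.g. a phantom case.
#' @param preprocess Optional [preprocess_config()]; must match the one
#'   stored in the checkpoint if both are present.
#' @param threshold Probability cutoff.
#' @param close_radius Structuring-element radius of the closing (0 to
#'   skip).
#' @return 3D integer 0/1 tumor mask, same shape as the volume.
#' @export
predict_volume <- function(checkpoint, case, preprocess = NULL,
                           threshold = 0.5, close_radius = 1) {
  if (inherits(checkpoint, "snet_checkpoint")) {
    model <- checkpoint$model
    stored <- checkpoint$preprocess
    if (!is.null(preprocess) && !identical(unclass(preprocess), unclass(stored)))
      stopf("preprocessing config mismatch between training and inference")
    preprocess <- stored
  } else {
    model <- checkpoint
    if (is.null(preprocess))
      stopf("a preprocess_config is required when passing a bare model")
  }
  vol <- case$volume$data
  d <- dim(vol)
  out <- array(0L, d)
  nonempty <- which(vapply(seq_len(d[3]),
                           function(z) sum(case$liver_mask[, , z]) > 0,
                           logical(1)))
  if (!length(nonempty)) return(out)
  x <- array(0, c(d[1], d[2], length(nonempty)))
  for (i in seq_along(nonempty)) {
    z <- nonempty[i]
    x[, , i] <- prepare_input(vol[, , z], case$liver_mask[, , z], preprocess)
  }
  probs <- snet_forward(model, x)
  for (i in seq_along(nonempty)) {
    z <- nonempty[i]
    m <- (probs[, , i] >= threshold) * 1L
    if (close_radius >= 1) m <- close_mask(m, close_radius)
    out[, , z] <- m * case$liver_mask[, , z]
  }
  out
}
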