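#' Network architecture configuration
#'
#' A compact U-shaped encoder-decoder. The contraction path has
#' `depth` resolution levels whose channel counts double per level starting
#' at `base_channels`; 2x2 max-pooling sits between levels. The deepest
#' level is the bottleneck, refined by the channel + spatial attention block.
#' The expansion path mirrors the encoder with 2x upsampling and halving
#' channels; each encoder level's output is concatenated onto the
#' same-resolution decoder level (long skip connection). A final 1x1
#' convolution with sigmoid yields the per-pixel tumor probability.
#'
#' @param depth Number of resolution levels (>= 2), bottleneck included.
#' @param base_channels Channels at the first level (>= 4).
#' @param kernel_size Odd spatial kernel size of the 2D convolutions.
#' @param convs_per_block Convolutions per level block.
#' @param upsample_mode `"nearest_conv"` (nearest-neighbour upsample followed
#'   by a conv) or `"transpose_conv"` (zero-insertion upsample followed by a
#'   conv, i.e. a fractionally-strided convolution).
#' @param attention_reduction Perceptron reduction ratio of the attention
#'   block; must divide the bottleneck channel count.
#' @param attention_activation `"softmax"` or `"sigmoid"` attention
#'   normalization.
#' @param in_channels,out_channels Input/output channel counts (1: one
#'   grayscale slice in, one tumor probability map out).
#' @return An object of class `snet_config`.
#' @export
snet_config <- function(depth = 4L, base_channels = 32L, kernel_size = 3L,
                        convs_per_block = 2L,
                        upsample_mode = c("nearest_conv", "transpose_conv"),
                        attention_reduction = 8L,
                        attention_activation = c("softmax", "sigmoid"),
                        in_channels = 1L, out_channels = 1L) {
  upsample_mode <- match.arg(upsample_mode)
  attention_activation <- match.arg(attention_activation)
  if (depth < 2L) stopf("depth must be >= 2")
  if (base_channels < 4L) stopf("base_channels must be >= 4")
  if (kernel_size %% 2 == 0) stopf("kernel_size must be odd")
  if (convs_per_block < 1L) stopf("convs_per_block must be >= 1")
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 kernel_size = as.integer(kernel_size),
                 convs_per_block = as.integer(convs_per_block),
                 upsample_mode = upsample_mode,
                 attention_reduction = as.integer(attention_reduction),
                 attention_activation = attention_activation,
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels)),
            class = "snet_config")
}

#' Encoder channel sequence of a configuration
#'
#' @param config An [snet_config()].
#' @return Integer vector: channels at levels 1..depth (doubling rule).
#' @export
snet_channels <- function(config) {
  as.integer(config$base_channels * 2^(seq_len(config$depth) - 1))
}

#' Build a segmentation network with freshly initialized weights
#'
#' Convolution weights use He-normal initialization; batch-norm scales start
#' at 1 and shifts at 0. The final-layer bias starts at -2 (a background
#' prior: tumor voxels are a small minority, and starting the probability
#' maps near background sidesteps the Dice-loss cold start). Identical
#' `(config, seed)` give bit-identical parameters.
#'
#' @param config An [snet_config()].
#' @param seed Integer seed for the initialization.
#' @return An object of class `snet_model` holding the config, a flat named
#'   parameter list, batch-norm running moments, and the attention
#'   parameters.
#' @export
build_snet <- function(config = snet_config(), seed = 1L) {
  ch <- snet_channels(config)
  d <- config$depth
  k <- config$kernel_size
  ncv <- config$convs_per_block
  params <- list()
  bn_state <- list()
  add_block <- function(prefix, cin, cout) {
    for (j in seq_len(ncv)) {
      ci <- if (j == 1) cin else cout
      params[[paste0(prefix, "_conv", j, "_w")]] <<- init_conv(k, ci, cout)
      params[[paste0(prefix, "_conv", j, "_b")]] <<- numeric(cout)
      params[[paste0(prefix, "_bn", j, "_g")]] <<- rep(1, cout)
      params[[paste0(prefix, "_bn", j, "_b")]] <<- numeric(cout)
      bn_state[[paste0(prefix, "_bn", j)]] <<- list(mean = numeric(cout),
                                                    var = rep(1, cout))
    }
  }
  att <- with_seed(seed, {
    for (i in seq_len(d)) {
      cin <- if (i == 1) config$in_channels else ch[i - 1]
      add_block(paste0("enc", i), cin, ch[i])
    }
    for (i in rev(seq_len(d - 1))) {
      params[[paste0("up", i, "_w")]] <- init_conv(k, ch[i + 1], ch[i])
      params[[paste0("up", i, "_b")]] <- numeric(ch[i])
      params[[paste0("up", i, "_bng")]] <- rep(1, ch[i])
      params[[paste0("up", i, "_bnb")]] <- numeric(ch[i])
      bn_state[[paste0("up", i, "_bn")]] <- list(mean = numeric(ch[i]),
                                                 var = rep(1, ch[i]))
      add_block(paste0("dec", i), 2L * ch[i], ch[i])
    }
    params[["out_w"]] <- init_conv(1L, ch[1], config$out_channels)
    # background prior: start the output bias negative so initial probability
    # maps are mostly background, avoiding the Dice-loss cold start on
    # heavily imbalanced masks
    params[["out_b"]] <- rep(-2, config$out_channels)
    attention_params(ch[d], config$attention_reduction,
                     config$attention_activation,
                     seed = derive_seed(seed, 999L))
  })
  structure(list(config = config, params = params, bn_state = bn_state,
                 att = att),
            class = "snet_model")
}

#' @export
print.snet_model <- function(x, ...) {
  ch <- snet_channels(x$config)
  cat(sprintf("<snet_model> depth %d, channels %s, %s attention, %s parameters\n",
              x$config$depth, paste(ch, collapse = "-"),
              x$att$activation, format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Total number of trainable parameters
#'
#' @param model An `snet_model`.
#' @return Integer count over convolution, batch-norm and attention weights.
#' @export
n_parameters <- function(model) {
  n <- sum(vapply(model$params, length, numeric(1)))
  n + length(model$att$mlp_w1) + length(model$att$mlp_b1) +
    length(model$att$mlp_w2) + length(model$att$mlp_b2) +
    length(model$att$sp_w) + 1L
}

# zero-insertion 2x upsample (used by the transpose_conv mode)
zeroins_fwd <- function(x) {
  d <- dim(x)
  y <- array(0, c(2 * d[1], 2 * d[2], d[3], d[4]))
  y[seq(1, 2 * d[1], 2), seq(1, 2 * d[2], 2), , ] <- x
  y
}
zeroins_bwd <- function(dy) {
  d <- dim(dy)
  dy[seq(1, d[1], 2), seq(1, d[2], 2), , , drop = FALSE]
}

block_fwd <- function(x, model, prefix, training) {
  p <- model$params
  ncv <- model$config$convs_per_block
  cache <- list(ins = vector("list", ncv), bns = vector("list", ncv),
                outs = vector("list", ncv))
  h <- x
  for (j in seq_len(ncv)) {
    cache$ins[[j]] <- h
    cj <- conv_fwd(h, p[[paste0(prefix, "_conv", j, "_w")]],
                   p[[paste0(prefix, "_conv", j, "_b")]])
    bn <- bn_fwd(cj, p[[paste0(prefix, "_bn", j, "_g")]],
                 p[[paste0(prefix, "_bn", j, "_b")]],
                 model$bn_state[[paste0(prefix, "_bn", j)]], training)
    model$bn_state[[paste0(prefix, "_bn", j)]] <- bn$state
    cache$bns[[j]] <- bn$cache
    h <- relu_fwd(bn$y)
    cache$outs[[j]] <- h
  }
  list(y = h, cache = cache, model = model)
}

block_bwd <- function(dy, model, prefix, cache, grads) {
  p <- model$params
  ncv <- model$config$convs_per_block
  for (j in rev(seq_len(ncv))) {
    dy <- relu_bwd(dy, cache$outs[[j]])
    bnb <- bn_bwd(dy, p[[paste0(prefix, "_bn", j, "_g")]], cache$bns[[j]])
    grads[[paste0(prefix, "_bn", j, "_g")]] <- bnb$dgamma
    grads[[paste0(prefix, "_bn", j, "_b")]] <- bnb$dbeta
    cvb <- conv_bwd(cache$ins[[j]], p[[paste0(prefix, "_conv", j, "_w")]],
                    bnb$dx)
    grads[[paste0(prefix, "_conv", j, "_w")]] <- cvb$dw
    grads[[paste0(prefix, "_conv", j, "_b")]] <- cvb$db
    dy <- cvb$dx
  }
  list(dx = dy, grads = grads)
}

as_batch <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) == 2L) {
    dim(x) <- c(dim(as.matrix(x)), 1L, 1L)
  } else if (length(d) == 3L) {
    dim(x) <- c(d[1], d[2], 1L, d[3])   # stack of single-channel slices
  } else if (length(d) != 4L) stopf("input must be H x W [x N]")
  x
}

#' Forward pass: tumor probability maps for a batch of slices
#'
#' @param model An `snet_model` from [build_snet()].
#' @param x Input in `[0, 1]`: an `H x W` matrix, an `H x W x N` stack, or
#'   an `H x W x 1 x N` array. H and W must be divisible by
#'   `2^(depth - 1)`.
#' @param training Use batch statistics and keep the backward cache?
#'   (Internal; inference callers leave this `FALSE`.)
#' @return For `training = FALSE`, an array shaped like the input with
#'   values in `[0, 1]`. For `training = TRUE`, a list with `probs`,
#'   `logits`, `cache` and the model with updated batch-norm moments.
#' @export
snet_forward <- function(model, x, training = FALSE) {
  in_dim <- dim(x)
  x <- as_batch(x)
  d <- dim(x)
  depth <- model$config$depth
  div <- 2^(depth - 1)
  if (d[1] %% div != 0 || d[2] %% div != 0)
    stopf("spatial size %dx%d not divisible by %d; pad to %dx%d",
          d[1], d[2], div, ceiling(d[1] / div) * div, ceiling(d[2] / div) * div)
  p <- model$params
  cache <- list(enc = vector("list", depth), pool = vector("list", depth - 1),
                up = vector("list", depth - 1), dec = vector("list", depth - 1),
                updims = vector("list", depth - 1))
  h <- x
  enc_out <- vector("list", depth)
  for (i in seq_len(depth - 1)) {
    bf <- block_fwd(h, model, paste0("enc", i), training)
    model <- bf$model
    enc_out[[i]] <- bf$y
    cache$enc[[i]] <- bf$cache
    mp <- maxpool_fwd(bf$y)
    cache$pool[[i]] <- list(idx = mp$idx, xdim = dim(bf$y))
    h <- mp$y
  }
  bf <- block_fwd(h, model, paste0("enc", depth), training)
  model <- bf$model
  cache$enc[[depth]] <- bf$cache
  cb <- cbam_fwd(bf$y, model$att)
  cache$cbam <- cb$cache
  u <- cb$y
  for (i in rev(seq_len(depth - 1))) {
    cache$updims[[i]] <- dim(u)
    up <- if (model$config$upsample_mode == "nearest_conv") upsample_fwd(u)
          else zeroins_fwd(u)
    cu <- conv_fwd(up, p[[paste0("up", i, "_w")]], p[[paste0("up", i, "_b")]])
    bn <- bn_fwd(cu, p[[paste0("up", i, "_bng")]], p[[paste0("up", i, "_bnb")]],
                 model$bn_state[[paste0("up", i, "_bn")]], training)
    model$bn_state[[paste0("up", i, "_bn")]] <- bn$state
    ru <- relu_fwd(bn$y)
    cache$up[[i]] <- list(upin = up, bncache = bn$cache, relout = ru)
    ci <- dim(enc_out[[i]])[3]
    cat_hwcn <- dim(ru)
    merged <- array(0, c(cat_hwcn[1], cat_hwcn[2], ci + cat_hwcn[3],
                         cat_hwcn[4]))
    merged[, , seq_len(ci), ] <- enc_out[[i]]
    merged[, , ci + seq_len(cat_hwcn[3]), ] <- ru
    bf <- block_fwd(merged, model, paste0("dec", i), training)
    model <- bf$model
    cache$dec[[i]] <- bf$cache
    u <- bf$y
  }
  logits <- conv_fwd(u, p$out_w, p$out_b)
  probs <- 1 / (1 + exp(-logits))
  if (!training) {
    if (!is.null(in_dim)) dim(probs) <- in_dim else dim(probs) <- dim(x)[1:2]
    return(probs)
  }
  cache$final_in <- u
  list(probs = probs, logits = logits, cache = cache, model = model)
}

# Backward pass from dL/dlogits; returns parameter gradients in the same
# (flat) naming scheme as model$params plus attention grads under $att.
snet_backward <- function(model, fw, dlogits) {
  p <- model$params
  depth <- model$config$depth
  cache <- fw$cache
  grads <- list()
  cvb <- conv_bwd(cache$final_in, p$out_w, dlogits)
  grads$out_w <- cvb$dw
  grads$out_b <- cvb$db
  du <- cvb$dx
  for (i in seq_len(depth - 1)) {
    bb <- block_bwd(du, model, paste0("dec", i), cache$dec[[i]], grads)
    grads <- bb$grads
    dmerged <- bb$dx
    ci <- dim(cache$enc[[i]]$outs[[model$config$convs_per_block]])[3]
    dskip <- dmerged[, , seq_len(ci), , drop = FALSE]
    dru <- dmerged[, , -seq_len(ci), , drop = FALSE]
    upc <- cache$up[[i]]
    dru <- relu_bwd(dru, upc$relout)
    bnb <- bn_bwd(dru, p[[paste0("up", i, "_bng")]], upc$bncache)
    grads[[paste0("up", i, "_bng")]] <- bnb$dgamma
    grads[[paste0("up", i, "_bnb")]] <- bnb$dbeta
    cvb <- conv_bwd(upc$upin, p[[paste0("up", i, "_w")]], bnb$dx)
    grads[[paste0("up", i, "_w")]] <- cvb$dw
    grads[[paste0("up", i, "_b")]] <- cvb$db
    du <- if (model$config$upsample_mode == "nearest_conv")
      upsample_bwd(cvb$dx, cache$updims[[i]])
    else zeroins_bwd(cvb$dx)
    # stash the skip gradient for the encoder sweep
    cache$enc[[i]]$dskip <- dskip
  }
  cbb <- cbam_bwd(du, cache$cbam, model$att)
  grads$att <- cbb$grads
  dy <- cbb$dx
  bb <- block_bwd(dy, model, paste0("enc", depth), cache$enc[[depth]], grads)
  grads <- bb$grads
  dh <- bb$dx
  for (i in rev(seq_len(depth - 1))) {
    dpool <- maxpool_bwd(dh, cache$pool[[i]]$idx, cache$pool[[i]]$xdim)
    dtot <- dpool + cache$enc[[i]]$dskip
    bb <- block_bwd(dtot, model, paste0("enc", i), cache$enc[[i]], grads)
    grads <- bb$grads
    dh <- bb$dx
  }
  grads
}

#' Threshold a probability map into a binary tumor mask
#'
#' @param model An `snet_model`.
#' @param slice `H x W` matrix in `[0, 1]` (a preprocessed slice).
#' @param threshold Probability cutoff in (0, 1); pixels with probability
#'   `>= threshold` become foreground.
#' @return `H x W` integer 0/1 matrix.
#' @export
predict_mask <- function(model, slice, threshold = 0.5) {
  if (threshold <= 0 || threshold > 1) stopf("threshold must be in (0, 1]")
  probs <- snet_forward(model, slice)
  (probs >= threshold) * 1L
}
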