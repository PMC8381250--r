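#' Parameters of the channel + spatial attention block
#'
#' The channel branch pools each channel's plane to its spatial average and
#' maximum, passes both descriptors through one shared two-layer perceptron
#' (hidden width `channels / reduction`, ReLU), sums the two outputs and
#' normalizes. The spatial branch pools across channels to per-position
#' average and maximum maps, combines them with a 1x1 convolution (a linear
#' combination of the two maps plus bias) and normalizes. Normalization is
#' softmax by default — weights are then a probability over channels or over
#' positions — with a sigmoid alternative; under softmax the refined features
#' scale as 1/C and 1/(H*W), so [apply_cbam()] can compensate by the element
#' count (`rescale`).
#'
#' @param channels Number of input channels C.
#' @param reduction Perceptron reduction ratio r; must divide C.
#' @param activation `"softmax"` (default) or `"sigmoid"`.
#' @param rescale Multiply refined features by the element count under
#'   softmax so expected magnitude is preserved. Ignored for sigmoid.
#' @param seed Seed for the He-normal weight initialization.
#' @return An object of class `attention_params`.
#' @export
attention_params <- function(channels, reduction = 8,
                             activation = c("softmax", "sigmoid"),
                             rescale = TRUE, seed = 1L) {
  activation <- match.arg(activation)
  if (channels < 1) stopf("channels must be >= 1")
  if (reduction < 1 || channels %% reduction != 0)
    stopf("reduction ratio (%d) must divide the channel count (%d)",
          reduction, channels)
  hidden <- channels %/% reduction
  with_seed(seed, {
    structure(list(
      channels = as.integer(channels), reduction = as.integer(reduction),
      activation = activation, rescale = isTRUE(rescale),
      mlp_w1 = matrix(rnorm(hidden * channels, 0, sqrt(2 / channels)),
                      hidden, channels),
      mlp_b1 = numeric(hidden),
      mlp_w2 = matrix(rnorm(channels * hidden, 0, sqrt(2 / max(1, hidden))),
                      channels, hidden),
      mlp_b2 = numeric(channels),
      sp_w = rnorm(2, 0, 1), sp_b = 0),
      class = "attention_params")
  })
}

act_forward <- function(z, activation) {
  if (activation == "softmax") {
    e <- exp(z - max(z))
    e / sum(e)
  } else 1 / (1 + exp(-z))
}

act_backward <- function(dw, w, activation) {
  if (activation == "softmax") w * (dw - sum(dw * w))
  else dw * w * (1 - w)
}

# ---- batched internals: x has dim (H, W, C, N) ----

channel_att_fwd <- function(x, params) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  xm <- x; dim(xm) <- c(H * W, C * N)
  s_avg <- matrix(colMeans(xm), C, N)
  am <- apply(xm, 2, which.max)
  s_max <- matrix(xm[cbind(am, seq_len(C * N))], C, N)
  pre_a <- params$mlp_w1 %*% s_avg + params$mlp_b1
  pre_m <- params$mlp_w1 %*% s_max + params$mlp_b1
  h_a <- pmax(pre_a, 0); h_m <- pmax(pre_m, 0)
  z <- params$mlp_w2 %*% (h_a + h_m) + 2 * params$mlp_b2
  w <- apply(z, 2, act_forward, activation = params$activation)
  w <- matrix(w, C, N)
  list(w = w,
       cache = list(dims = d, s_avg = s_avg, s_max = s_max, am = am,
                    pre_a = pre_a, pre_m = pre_m, h_a = h_a, h_m = h_m, w = w))
}

channel_att_bwd <- function(dw, cache, params) {
  d <- cache$dims; H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  dz <- matrix(0, C, N)
  for (n in seq_len(N))
    dz[, n] <- act_backward(dw[, n], cache$w[, n], params$activation)
  dh <- t(params$mlp_w2) %*% dz
  dh_a <- dh * (cache$pre_a > 0)
  dh_m <- dh * (cache$pre_m > 0)
  grads <- list(
    mlp_w2 = dz %*% t(cache$h_a + cache$h_m),
    mlp_b2 = 2 * rowSums(dz),
    mlp_w1 = dh_a %*% t(cache$s_avg) + dh_m %*% t(cache$s_max),
    mlp_b1 = rowSums(dh_a + dh_m))
  ds_avg <- t(params$mlp_w1) %*% dh_a
  ds_max <- t(params$mlp_w1) %*% dh_m
  dxm <- matrix(rep(as.vector(ds_avg) / (H * W), each = H * W), H * W, C * N)
  idx <- cbind(cache$am, seq_len(C * N))
  dxm[idx] <- dxm[idx] + as.vector(ds_max)
  dim(dxm) <- d
  list(dx = dxm, grads = grads)
}

spatial_att_fwd <- function(x, params) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  HW <- H * W
  w <- matrix(0, HW, N)
  avg <- matrix(0, HW, N); mx <- matrix(0, HW, N)
  am <- matrix(1L, HW, N)
  for (n in seq_len(N)) {
    A <- x[, , , n, drop = FALSE]
    dim(A) <- c(HW, C)
    avg[, n] <- rowMeans(A)
    m <- A[, 1]; a <- rep(1L, HW)
    if (C > 1) for (cc in 2:C) {
      upd <- which(A[, cc] > m)  # which() drops NAs: a non-finite
      m[upd] <- A[upd, cc]       # activation still reaches the loss via
      a[upd] <- cc               # the average map, without crashing here
    }
    mx[, n] <- m; am[, n] <- a
    z <- params$sp_w[1] * avg[, n] + params$sp_w[2] * m + params$sp_b
    w[, n] <- act_forward(z, params$activation)
  }
  list(w = w, cache = list(dims = d, avg = avg, mx = mx, am = am, w = w))
}

spatial_att_bwd <- function(dw, cache, params) {
  d <- cache$dims; H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  HW <- H * W
  dx <- array(0, d)
  g_wa <- 0; g_wm <- 0; g_b <- 0
  for (n in seq_len(N)) {
    dz <- act_backward(dw[, n], cache$w[, n], params$activation)
    g_wa <- g_wa + sum(dz * cache$avg[, n])
    g_wm <- g_wm + sum(dz * cache$mx[, n])
    g_b <- g_b + sum(dz)
    dA <- matrix(dz * params$sp_w[1] / C, HW, C)
    idx <- cbind(seq_len(HW), cache$am[, n])
    dA[idx] <- dA[idx] + dz * params$sp_w[2]
    dim(dA) <- c(H, W, C)
    dx[, , , n] <- dA
  }
  list(dx = dx, grads = list(sp_w = c(g_wa, g_wm), sp_b = g_b))
}

mul_channel <- function(x, wc, fac = 1) {
  d <- dim(x)
  xm <- x; dim(xm) <- c(d[1] * d[2], d[3] * d[4])
  xm <- xm * rep(as.vector(wc) * fac, each = d[1] * d[2])
  dim(xm) <- d
  xm
}

mul_spatial <- function(x, ws, fac = 1) {
  d <- dim(x)
  xm <- x; dim(xm) <- c(d[1] * d[2], d[3] * d[4])
  wmat <- ws[, rep(seq_len(d[4]), each = d[3]), drop = FALSE] * fac
  xm <- xm * wmat
  dim(xm) <- d
  xm
}

cbam_fwd <- function(x, params) {
  d <- dim(x)
  fc <- if (params$activation == "softmax" && params$rescale) d[3] else 1
  fs <- if (params$activation == "softmax" && params$rescale) d[1] * d[2] else 1
  ca <- channel_att_fwd(x, params)
  x1 <- mul_channel(x, ca$w, fc)
  sa <- spatial_att_fwd(x1, params)
  y <- mul_spatial(x1, sa$w, fs)
  list(y = y, cache = list(x = x, x1 = x1, ca = ca, sa = sa, fc = fc, fs = fs))
}

cbam_bwd <- function(dy, cache, params) {
  d <- dim(dy)
  HW <- d[1] * d[2]
  # through the spatial multiply
  dx1 <- mul_spatial(dy, cache$sa$w, cache$fs)
  prod_s <- dy * cache$x1
  dim(prod_s) <- c(HW, d[3], d[4])
  dws <- matrix(0, HW, d[4])
  for (n in seq_len(d[4]))
    dws[, n] <- rowSums(prod_s[, , n, drop = FALSE], dims = 1) * cache$fs
  sb <- spatial_att_bwd(dws, cache$sa$cache, params)
  dx1 <- dx1 + sb$dx
  # through the channel multiply
  dx <- mul_channel(dx1, cache$ca$w, cache$fc)
  prod_c <- dx1 * cache$x
  dim(prod_c) <- c(HW, d[3] * d[4])
  dwc <- matrix(colSums(prod_c), d[3], d[4]) * cache$fc
  cb <- channel_att_bwd(dwc, cache$ca$cache, params)
  dx <- dx + cb$dx
  grads <- c(cb$grads, sb$grads)
  list(dx = dx, grads = grads)
}

as_feature_map <- function(f) {
  if (length(dim(f)) == 3L) {
    dim(f) <- c(dim(f), 1L)
  } else if (length(dim(f)) != 4L) stopf("feature map must be H x W x C")
  if (!all(is.finite(f))) stopf("non-finite feature values")
  f
}

#' Channel attention weights of a feature map
#'
#' Computes per-channel importance weights from the spatially pooled average
#' and maximum descriptors through the shared perceptron; under the softmax
#' activation the weights are a probability over channels (sum to 1).
#'
#' @param f Feature map, an `H x W x C` numeric array.
#' @param params An [attention_params()] with matching channel count.
#' @return Numeric vector of length C.
#' @export
channel_attention <- function(f, params) {
  f <- as_feature_map(f)
  if (dim(f)[3] != params$channels)
    stopf("feature map has %d channels but params expect %d",
          dim(f)[3], params$channels)
  as.vector(channel_att_fwd(f, params)$w)
}

#' Spatial attention map of a feature map
#'
#' Pools the channels to per-position average and maximum maps, combines
#' them with the 1x1 convolution and normalizes; under softmax the map is a
#' probability over the H*W positions.
#'
#' @inheritParams channel_attention
#' @return `H x W` numeric matrix.
#' @export
spatial_attention <- function(f, params) {
  f <- as_feature_map(f)
  sa <- spatial_att_fwd(f, params)
  matrix(sa$w[, 1], dim(f)[1], dim(f)[2])
}

#' Refine a feature map by channel then spatial attention
#'
#' Sequential refinement: the map is broadcast-multiplied by its channel
#' weights, then the channel-refined map is broadcast-multiplied by its
#' spatial weights. With softmax activation and `rescale = TRUE` in the
#' params, each product is additionally scaled by the element count (C, then
#' H*W) so uniform attention is the identity.
#'
#' @inheritParams channel_attention
#' @return Array of the same shape as `f`.
#' @export
apply_cbam <- function(f, params) {
  drop3 <- length(dim(f)) == 3L
  f <- as_feature_map(f)
  if (dim(f)[3] != params$channels)
    stopf("feature map has %d channels but params expect %d",
          dim(f)[3], params$channels)
  y <- cbam_fwd(f, params)$y
  if (drop3) dim(y) <- dim(y)[1:3]
  y
}
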