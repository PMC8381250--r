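# Thin R wrappers around the C++ kernels plus batch-norm, ReLU and the
# parameter initializers. Feature batches are arrays with dim (H, W, C, N).

conv_fwd <- function(x, w, b) {
  y <- conv2d_forward_cpp(x, w, b, dim(x), dim(w))
  dim(y) <- c(dim(x)[1], dim(x)[2], dim(w)[4], dim(x)[4])
  y
}

conv_bwd <- function(x, w, dy) {
  g <- conv2d_backward_cpp(x, w, dy, dim(x), dim(w))
  dim(g$dx) <- dim(x)
  dim(g$dw) <- dim(w)
  g
}

maxpool_fwd <- function(x) {
  d <- dim(x)
  r <- maxpool2_forward_cpp(x, d)
  dim(r$y) <- c(d[1] / 2, d[2] / 2, d[3], d[4])
  r
}

maxpool_bwd <- function(dy, idx, xdim) {
  dx <- maxpool2_backward_cpp(dy, idx, as.integer(prod(xdim)))
  dim(dx) <- xdim
  dx
}

upsample_fwd <- function(x) {
  d <- dim(x)
  y <- upsample2_forward_cpp(x, d)
  dim(y) <- c(2 * d[1], 2 * d[2], d[3], d[4])
  y
}

upsample_bwd <- function(dy, xdim) {
  dx <- upsample2_backward_cpp(dy, as.integer(xdim))
  dim(dx) <- xdim
  dx
}

# He-normal conv weight init, shape (k, k, Cin, Cout).
init_conv <- function(k, cin, cout) {
  array(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
        c(k, k, cin, cout))
}

# Batch normalization over (H, W, N) per channel. `state` carries running
# moments for inference; `training` picks batch vs running statistics.
bn_fwd <- function(x, gamma, beta, state, training, momentum = 0.1,
                   eps = 1e-5) {
  d <- dim(x)
  if (training) {
    st <- bn_stats_cpp(x, d)
    mu <- st$mean
    var <- pmax(st$meansq - mu^2, 0)
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * var
  } else {
    mu <- state$mean
    var <- state$var
  }
  istd <- 1 / sqrt(var + eps)
  ap <- bn_apply_cpp(x, d, mu, istd, gamma, beta, training)
  y <- ap$y
  dim(y) <- d
  cache <- if (training) list(xhat = ap$xhat, istd = istd, dims = d) else NULL
  list(y = y, state = state, cache = cache)
}

bn_bwd <- function(dy, gamma, cache) {
  d <- cache$dims
  g <- bn_backward_cpp(dy, cache$xhat, d, gamma, cache$istd)
  dx <- g$dx
  dim(dx) <- d
  list(dx = dx, dgamma = g$dgamma, dbeta = g$dbeta)
}

relu_fwd <- function(x) pmax(x, 0)
relu_bwd <- function(dy, x) dy * (x > 0)
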