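test_that("encoder channels follow the doubling rule", {
  cfg <- snet_config(depth = 4, base_channels = 32)
  expect_equal(snet_channels(cfg), c(32L, 64L, 128L, 256L))
  m <- build_snet(snet_config(depth = 3, base_channels = 8,
                              attention_reduction = 4), seed = 1)
  expect_equal(dim(m$params$enc1_conv1_w)[4], 8)
  expect_equal(dim(m$params$enc2_conv1_w)[4], 16)
  expect_equal(dim(m$params$enc3_conv1_w)[4], 32)
  # decoder mirrors the encoder (halving rule)
  expect_equal(dim(m$params$up2_w)[3:4], c(32L, 16L))
  expect_equal(dim(m$params$up1_w)[3:4], c(16L, 8L))
  expect_equal(dim(m$params$dec1_conv1_w)[3], 16L)  # concat doubles input
})

test_that("builds are a deterministic function of (config, seed)", {
  cfg <- snet_config(depth = 2, base_channels = 4, attention_reduction = 2)
  a <- build_snet(cfg, seed = 9)
  b <- build_snet(cfg, seed = 9)
  expect_identical(a$params, b$params)
  expect_identical(a$att, b$att)
  expect_equal(n_parameters(a), n_parameters(b))
})

test_that("forward pass preserves shape and stays in [0, 1]", {
  m <- build_snet(snet_config(depth = 3, base_channels = 4,
                              attention_reduction = 2), seed = 2)
  x <- matrix(runif(32 * 32), 32, 32)
  p <- snet_forward(m, x)
  expect_equal(dim(p), c(32, 32))
  expect_true(all(p >= 0 & p <= 1))
  batch <- array(runif(32 * 32 * 3), c(32, 32, 3))
  pb <- snet_forward(m, batch)
  expect_equal(dim(pb), c(32, 32, 3))
  # deterministic with fixed weights
  expect_identical(snet_forward(m, x), p)
})

test_that("indivisible input sizes fail with the required padding named", {
  m <- build_snet(snet_config(depth = 3, base_channels = 4,
                              attention_reduction = 2), seed = 2)
  expect_error(snet_forward(m, matrix(0.5, 30, 30)), "divisible by 4")
})

test_that("a zero-initialized final layer yields constant 0.5 maps", {
  m <- build_snet(snet_config(depth = 2, base_channels = 4,
                              attention_reduction = 2), seed = 3)
  m$params$out_w[] <- 0
  m$params$out_b[] <- 0
  p <- snet_forward(m, matrix(0, 16, 16))
  expect_equal(as.vector(p), rep(0.5, 256))
})

test_that("loss gradients reach the first layer through the whole net", {
  set.seed(4)
  m <- build_snet(snet_config(depth = 2, base_channels = 4,
                              attention_reduction = 2), seed = 4)
  x <- array(runif(16 * 16 * 1 * 2), c(16, 16, 1, 2))
  y <- array(rbinom(16 * 16 * 2, 1, 0.3), c(16, 16, 1, 2))
  fw <- snet_forward(m, x, training = TRUE)
  dprobs <- snetseg:::dice_loss_grad(fw$probs, y, 1)
  gr <- snetseg:::snet_backward(m, fw, dprobs * fw$probs * (1 - fw$probs))
  expect_gt(max(abs(gr$enc1_conv1_w)), 0)
  expect_gt(max(abs(gr$att$mlp_w1)), 0)
})

test_that("analytic gradients match central finite differences", {
  set.seed(5)
  m <- build_snet(snet_config(depth = 2, base_channels = 4,
                              attention_reduction = 2), seed = 7)
  x <- array(runif(8 * 8 * 1 * 2), c(8, 8, 1, 2))
  y <- array(rbinom(8 * 8 * 2, 1, 0.3), c(8, 8, 1, 2))
  lossfn <- function(mm) {
    fw <- snet_forward(mm, x, training = TRUE)
    dice_loss(fw$probs, y, 1)
  }
  fw <- snet_forward(m, x, training = TRUE)
  dprobs <- snetseg:::dice_loss_grad(fw$probs, y, 1)
  gr <- snetseg:::snet_backward(m, fw, dprobs * fw$probs * (1 - fw$probs))
  eps <- 1e-5
  for (nm in c("enc1_conv1_w", "enc2_bn1_g", "up1_w", "dec1_conv2_w",
               "out_w", "out_b")) {
    for (i in sample(length(gr[[nm]]), min(2, length(gr[[nm]])))) {
      m1 <- m; m1$params[[nm]][i] <- m1$params[[nm]][i] + eps
      m2 <- m; m2$params[[nm]][i] <- m2$params[[nm]][i] - eps
      num <- (lossfn(m1) - lossfn(m2)) / (2 * eps)
      expect_equal(gr[[nm]][i], num, tolerance = 1e-4)
    }
  }
  for (nm in c("mlp_w1", "mlp_w2", "sp_w")) {
    for (i in sample(length(gr$att[[nm]]), min(2, length(gr$att[[nm]])))) {
      m1 <- m; m1$att[[nm]][i] <- m1$att[[nm]][i] + eps
      m2 <- m; m2$att[[nm]][i] <- m2$att[[nm]][i] - eps
      num <- (lossfn(m1) - lossfn(m2)) / (2 * eps)
      expect_equal(gr$att[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("both upsampling modes run forward and backward", {
  for (mode in c("nearest_conv", "transpose_conv")) {
    m <- build_snet(snet_config(depth = 2, base_channels = 4,
                                attention_reduction = 2,
                                upsample_mode = mode), seed = 6)
    x <- array(runif(8 * 8 * 2), c(8, 8, 1, 2))
    y <- array(rbinom(8 * 8 * 2, 1, 0.3), c(8, 8, 1, 2))
    fw <- snet_forward(m, x, training = TRUE)
    expect_equal(dim(fw$probs), dim(x))
    dprobs <- snetseg:::dice_loss_grad(fw$probs, y, 1)
    gr <- snetseg:::snet_backward(m, fw, dprobs * fw$probs * (1 - fw$probs))
    expect_gt(max(abs(gr$enc1_conv1_w)), 0)
  }
})

test_that("predicted masks respect the threshold with >= ties", {
  m <- build_snet(snet_config(depth = 2, base_channels = 4,
                              attention_reduction = 2), seed = 3)
  m$params$out_w[] <- 0
  m$params$out_b[] <- 0  # constant 0.5 probability
  expect_true(all(predict_mask(m, matrix(0.3, 16, 16), 0.5) == 1))
  expect_true(all(predict_mask(m, matrix(0.3, 16, 16), 1.0) == 0))
  # monotonicity: higher threshold never adds foreground
  m2 <- build_snet(snet_config(depth = 2, base_channels = 4,
                               attention_reduction = 2), seed = 8)
  sl <- matrix(runif(256), 16, 16)
  lo <- predict_mask(m2, sl, 0.3)
  hi <- predict_mask(m2, sl, 0.7)
  expect_true(all(hi <= lo))
})
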