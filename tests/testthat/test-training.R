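test_that("soft Dice loss has the right extremes and worked value", {
  t4 <- array(0, c(4, 4, 1, 1)); t4[1:2, 1, 1, 1] <- 1; t4[1:2, 2, 1, 1] <- 1
  expect_lt(dice_loss(t4, t4, 1e-9), 1e-6)                 # perfect overlap
  expect_gt(dice_loss(t4 * 0, t4, 1e-9), 1 - 1e-6)         # no overlap
  # half-confidence on a 4-pixel target: Dice = 2*2/(2+4), loss = 1/3
  expect_equal(dice_loss(t4 * 0.5, t4, 1e-12), 1 / 3, tolerance = 1e-9)
  expect_error(dice_loss(matrix(0.5, 2, 2), matrix(0, 3, 3)), "differ")
})

test_that("dice loss is batch-averaged per sample", {
  p <- array(0, c(2, 2, 1, 2)); y <- array(0, c(2, 2, 1, 2))
  y[, , 1, 1] <- 1; p[, , 1, 1] <- 1  # perfect
  y[1, 1, 1, 2] <- 1; p[2, 2, 1, 2] <- 1  # disjoint
  expect_equal(dice_loss(p, y, 1e-12), 0.5, tolerance = 1e-9)
})

test_that("loss gradient matches finite differences", {
  set.seed(6)
  p <- array(runif(16), c(2, 2, 1, 4))
  y <- array(rbinom(16, 1, 0.4), c(2, 2, 1, 4))
  g <- snetseg:::dice_loss_grad(p, y, 1)
  eps <- 1e-6
  for (i in sample(16, 5)) {
    p1 <- p; p1[i] <- p1[i] + eps
    p2 <- p; p2[i] <- p2[i] - eps
    num <- (dice_loss(p1, y, 1) - dice_loss(p2, y, 1)) / (2 * eps)
    expect_equal(g[i], num, tolerance = 1e-6)
  }
})

test_that("plateau schedule cuts the rate after exactly 3 stale epochs", {
  st <- snetseg:::plateau_state(0.01, patience = 3L, factor = 0.1)
  trace <- numeric()
  for (loss in c(0.9, 0.9, 0.9, 0.9)) {  # epoch 1 sets best, 3 stale follow
    st <- snetseg:::plateau_update(st, loss)
    trace <- c(trace, st$lr)
  }
  expect_equal(trace, c(0.01, 0.01, 0.01, 0.001))
  # improvement resets the counter
  st <- snetseg:::plateau_state(0.01, 3L, 0.1)
  for (loss in c(0.9, 0.9, 0.8, 0.8, 0.8, 0.8)) st <- snetseg:::plateau_update(st, loss)
  expect_equal(st$lr, 0.001)
  # rates only ever change by factor multiples and never increase
  st <- snetseg:::plateau_state(0.01, 2L, 0.5)
  lrs <- vapply(rep(1, 9), function(l) {
    st <<- snetseg:::plateau_update(st, l); st$lr
  }, numeric(1))
  expect_true(all(diff(lrs) <= 0))
  expect_true(all(abs(log(lrs / 0.01) / log(0.5) -
                        round(log(lrs / 0.01) / log(0.5))) < 1e-9))
})

test_that("loss decreases under gradient descent on one batch", {
  set.seed(12)
  cs <- generate_case(phantom_config(image_size = 32, n_slices = 4,
                                     contrast_gap = 40, noise_sd = 3), 5)
  sl <- Filter(function(s) sum(s$tumor_mask) > 0, extract_slices(cs))
  m <- build_snet(snet_config(depth = 2, base_channels = 8,
                              attention_reduction = 4), seed = 2)
  pc <- preprocess_config()
  arr <- snetseg:::prepare_training_arrays(sl, pc, augment = FALSE)
  vel <- list(params = list(), att = list())
  losses <- numeric(51)
  for (step in 0:50) {
    fw <- snet_forward(m, arr$x, training = TRUE)
    m <- fw$model
    losses[step + 1] <- dice_loss(fw$probs, arr$y, 1)
    if (step == 50) break
    dprobs <- snetseg:::dice_loss_grad(fw$probs, arr$y, 1)
    gr <- snetseg:::snet_backward(m, fw, dprobs * fw$probs * (1 - fw$probs))
    upd <- snetseg:::sgd_update(m, gr, vel, 0.01, 0.9)
    m <- upd$model
    vel <- upd$vel
  }
  expect_lt(losses[51], losses[1])
  # and the trend is real, not a single lucky step
  expect_lt(mean(tail(losses, 10)), mean(head(losses, 10)))
})

test_that("training returns the best-validation-Dice checkpoint, seeded", {
  set.seed(13)
  cs <- generate_case(phantom_config(image_size = 32, n_slices = 6,
                                     contrast_gap = 40), 6)
  sl <- extract_slices(cs)
  m <- build_snet(snet_config(depth = 2, base_channels = 4,
                              attention_reduction = 2), seed = 3)
  cfg <- train_config(max_epochs = 3, batch_size = 8, augment = FALSE,
                      seed = 5)
  ck1 <- train_snet(m, sl, sl, cfg)
  ck2 <- train_snet(m, sl, sl, cfg)
  expect_equal(ck1$history, ck2$history)
  expect_equal(nrow(ck1$history), 3)
  expect_equal(ck1$best_val_dice, max(ck1$history$val_dice))
  expect_equal(ck1$history$val_dice[ck1$best_epoch], ck1$best_val_dice)
  expect_true(all(diff(ck1$history$lr) <= 0))
})

test_that("checkpoints roundtrip through disk with their configs", {
  set.seed(14)
  cs <- generate_case(phantom_config(image_size = 32, n_slices = 4), 7)
  sl <- extract_slices(cs)
  m <- build_snet(snet_config(depth = 2, base_channels = 4,
                              attention_reduction = 2), seed = 1)
  ck <- train_snet(m, sl, sl, train_config(max_epochs = 1, augment = FALSE))
  path <- file.path(tempdir(), "ck.rds")
  save_checkpoint(ck, path)
  back <- load_checkpoint(path)
  expect_identical(back$model$params, ck$model$params)
  unlink(path)
})

test_that("volume prediction is shaped, liver-confined, empty on empty liver", {
  set.seed(15)
  cs <- generate_case(phantom_config(image_size = 32, n_slices = 4,
                                     contrast_gap = 40), 8)
  sl <- extract_slices(cs)
  m <- build_snet(snet_config(depth = 2, base_channels = 4,
                              attention_reduction = 2), seed = 2)
  ck <- train_snet(m, sl, sl, train_config(max_epochs = 1, augment = FALSE))
  pred <- predict_volume(ck, cs)
  expect_identical(dim(pred), dim(cs$volume$data))
  expect_equal(sum(pred == 1 & cs$liver_mask == 0), 0)
  empty <- cs
  empty$liver_mask[] <- 0L
  expect_equal(sum(predict_volume(ck, empty)), 0)
  # preprocessing mismatch is refused
  other <- preprocess_config(hu_window = c(-200, 250))
  expect_error(predict_volume(ck, cs, preprocess = other), "mismatch")
})

test_that("a diverging run aborts with a diagnostic", {
  set.seed(16)
  cs <- generate_case(phantom_config(image_size = 32, n_slices = 4), 9)
  sl <- extract_slices(cs)
  m <- build_snet(snet_config(depth = 2, base_channels = 4,
                              attention_reduction = 2), seed = 3)
  # poisoned weights propagate a non-finite loss; training must stop, not
  # keep stepping (note an absurd learning rate alone cannot trigger this:
  # the Dice loss is bounded and saturated sigmoids freeze the gradients)
  m$params$enc1_conv1_w[1] <- NaN
  expect_error(
    train_snet(m, sl, sl, train_config(max_epochs = 5, augment = FALSE)),
    "diverged")
})
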