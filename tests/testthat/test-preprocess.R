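test_that("HU windowing clips and maps linearly onto [0, 1]", {
  w <- c(-100, 300)
  expect_equal(window_and_normalize(-100, w), 0)
  expect_equal(window_and_normalize(300, w), 1)
  expect_equal(window_and_normalize(-500, w), 0)
  expect_equal(window_and_normalize(1000, w), 1)
  expect_equal(window_and_normalize(100, w), 0.5)
  expect_error(window_and_normalize(0, c(10, 10)), "degenerate")
})

test_that("point-to-point flip inverts the foreground and blanks outside", {
  img <- matrix(c(255, 0, 100, 200), 2, 2)
  fg <- matrix(c(1, 1, 1, 0), 2, 2)
  out <- flip_point_to_point(img, fg)
  expect_equal(out[1, 1], 0)    # 255 -> 0
  expect_equal(out[2, 1], 255)  # 0 -> 255
  expect_equal(out[1, 2], 155)  # 100 -> 255 - 100
  expect_equal(out[2, 2], 0)    # background forced to black
  expect_error(flip_point_to_point(matrix(300, 1, 1), matrix(1, 1, 1)),
               "\\[0, 255\\]")
})

test_that("flip is an involution on the foreground", {
  set.seed(42)
  for (i in 1:20) {
    img <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
    fg <- rand_mask(c(8, 8), 0.6)
    twice <- flip_point_to_point(flip_point_to_point(img, fg), fg)
    expect_equal(twice[fg == 1], img[fg == 1])
    expect_true(all(twice[fg == 0] == 0))
  }
})

test_that("grayscale float is a seeded clipped affine map", {
  img <- matrix(runif(36), 6, 6)
  expect_equal(grayscale_float(img, u = 1, v = 0), img)
  expect_equal(grayscale_float(matrix(0, 3, 3), u = 1, v = 0.2),
               matrix(0.2, 3, 3))
  set.seed(8); a <- grayscale_float(img)
  set.seed(8); b <- grayscale_float(img)
  expect_identical(a, b)
  expect_true(all(grayscale_float(img, u = 1.2, v = 0.2) <= 1))
})

test_that("geometric augmentation transforms image and masks together", {
  set.seed(3)
  img <- matrix(runif(256), 16, 16)
  masks <- list(liver = rand_mask(c(16, 16), 0.4))
  masks$tumor <- masks$liver * rand_mask(c(16, 16), 0.4)

  idt <- geometric_augment(img, masks, transform = list(
    angle = 0, dx = 0, dy = 0, mirror = FALSE, shear = 0))
  expect_identical(idt$image, img)

  mir <- list(angle = 0, dx = 0, dy = 0, mirror = TRUE, shear = 0)
  once <- geometric_augment(img, masks, transform = mir)
  twice <- geometric_augment(once$image, once$masks, transform = mir)
  expect_equal(twice$image, img, tolerance = 1e-12)
  expect_equal(twice$masks$liver, masks$liver)

  rot <- list(angle = 90, dx = 0, dy = 0, mirror = FALSE, shear = 0)
  r1 <- geometric_augment(img, masks, transform = rot)
  expect_equal(sum(r1$masks$liver), sum(masks$liver))
  expect_equal(sum(r1$masks$tumor), sum(masks$tumor))
  expect_true(all(r1$masks$liver %in% c(0, 1)))
})

test_that("random augmentations preserve tumor-inside-liver containment", {
  set.seed(9)
  cfg <- preprocess_config(rotation_max = 15, translation_max = 3,
                           shear_max = 0.1)
  liver <- matrix(0L, 16, 16); liver[5:12, 5:12] <- 1L
  tumor <- matrix(0L, 16, 16); tumor[7:9, 7:9] <- 1L
  img <- matrix(runif(256), 16, 16)
  for (i in 1:20) {
    out <- geometric_augment(img, list(liver = liver, tumor = tumor), cfg)
    expect_equal(sum(out$masks$tumor == 1 & out$masks$liver == 0), 0)
  }
})

test_that("contrast filter drops tumor slices strictly below threshold", {
  s_hi <- contrast_slice(60, 45)   # contrast 15
  s_lo <- contrast_slice(60, 58)   # contrast 2
  s_none <- contrast_slice(60, 60) # contrast 0 but see below
  s_free <- s_none
  s_free$tumor_mask[] <- 0L        # tumor-free: passes unconditionally

  expect_length(contrast_filter(list(s_hi, s_lo), 0), 2)
  kept <- contrast_filter(list(s_hi, s_lo, s_free), 10)
  expect_length(kept, 2)
  expect_identical(kept[[1]], s_hi)
  expect_identical(kept[[2]], s_free)
  expect_length(contrast_filter(list(s_hi), 20), 0)
  expect_error(contrast_filter(list(s_hi), -1), ">= 0")
})

test_that("contrast filter output is an order-preserving subsequence", {
  set.seed(4)
  samples <- lapply(1:12, function(i)
    contrast_slice(60, 60 - runif(1, 0, 30), idx = i))
  kept <- contrast_filter(samples, 12)
  pos <- match(vapply(kept, function(s) s$slice_index, integer(1)),
               vapply(samples, function(s) s$slice_index, integer(1)))
  expect_true(all(diff(pos) >= 0))
  for (k in kept) expect_true(any(vapply(samples, identical, logical(1), k)))
})

test_that("prepared network input is liver-masked and in [0, 1]", {
  cs <- manual_case()
  sl <- extract_slices(cs)[[2]]
  inp <- prepare_input(sl$image, sl$liver_mask, preprocess_config())
  expect_true(all(inp >= 0 & inp <= 1))
  expect_true(all(inp[sl$liver_mask == 0] == 0))
  # hypodense tumor turns bright under the flip
  expect_gt(mean(inp[sl$tumor_mask == 1]),
            mean(inp[sl$liver_mask == 1 & sl$tumor_mask == 0]))
})
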