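#' Preprocessing configuration
#'
#' Collects every knob of the slice preprocessing stack. The deterministic
#' part (HU windowing, point-to-point flip) is applied identically at train
#' and inference time; the stochastic part (grayscale float, geometric
#' augmentation) is train-time only and re-sampled per epoch.
#'
#' @param hu_window Length-2 numeric `(low, high)` HU clipping window.
#' @param flip_enabled Apply the foreground point-to-point intensity flip?
#' @param gray_float_enabled Apply random grayscale scale/shift at train time?
#' @param rotation_max Max augmentation rotation, degrees.
#' @param translation_max Max augmentation translation, pixels.
#' @param mirror Allow random horizontal mirroring?
#' @param shear_max Max affine shear coefficient.
#' @param contrast_filter_threshold Minimum |mean tumor HU - mean liver HU|
#'   for a tumor-bearing training slice to be kept, in HU.
#' @param seed RNG seed for the stochastic augmentations.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(hu_window = c(-100, 300), flip_enabled = TRUE,
                              gray_float_enabled = TRUE, rotation_max = 10,
                              translation_max = 4, mirror = TRUE,
                              shear_max = 0.05,
                              contrast_filter_threshold = 10, seed = 1L) {
  if (hu_window[1] >= hu_window[2]) stopf("degenerate HU window")
  if (rotation_max < 0 || translation_max < 0 || shear_max < 0)
    stopf("augmentation maxima must be >= 0")
  if (contrast_filter_threshold < 0) stopf("contrast threshold must be >= 0")
  structure(list(hu_window = as.numeric(hu_window),
                 flip_enabled = isTRUE(flip_enabled),
                 gray_float_enabled = isTRUE(gray_float_enabled),
                 rotation_max = rotation_max, translation_max = translation_max,
                 mirror = isTRUE(mirror), shear_max = shear_max,
                 contrast_filter_threshold = contrast_filter_threshold,
                 seed = as.integer(seed)),
            class = "preprocess_config")
}

#' Clip to an HU window and normalize to [0, 1]
#'
#' Values are clipped to `[low, high]` and mapped linearly so `low -> 0` and
#' `high -> 1`. The default window (-100, 300) HU brackets liver parenchyma
#' and hepatic lesions while discarding air and dense bone.
#'
#' @param image_hu Numeric array of HU values (any shape).
#' @param window Length-2 numeric `(low, high)`.
#' @return Array of the same shape with values in `[0, 1]`.
#' @export
window_and_normalize <- function(image_hu, window = c(-100, 300)) {
  if (window[1] >= window[2]) stopf("degenerate HU window")
  if (!all(is.finite(image_hu))) stopf("non-finite HU values")
  pmin(pmax((image_hu - window[1]) / (window[2] - window[1]), 0), 1)
}

#' Point-to-point intensity flip of the foreground
#'
#' Inverts 8-bit intensities inside the foreground: each foreground pixel p
#' is divided by 255, subtracted from 1 and rescaled, which reduces to
#' `255 - p`. Everything outside the foreground is set to 0 (black), so in a
#' liver-windowed rendering the liver turns gray, hypodense tumors turn
#' bright, and the surroundings vanish. The flip is an involution on the
#' foreground and is applied identically at train and inference time.
#'
#' @param image8 Array with values in `[0, 255]` (8-bit rendering).
#' @param foreground_mask Binary array of the same shape (1 = foreground,
#'   typically the liver mask).
#' @return Array of the same shape, `255 - p` inside the foreground, 0
#'   outside.
#' @export
flip_point_to_point <- function(image8, foreground_mask) {
  if (!identical(dim(image8), dim(foreground_mask)))
    stopf("image and mask shapes differ")
  if (any(image8 < 0 | image8 > 255))
    stopf("pixel values outside [0, 255]")
  out <- (255 - image8) * (foreground_mask == 1)
  out
}

#' Random grayscale scale-and-shift augmentation
#'
#' Draws one multiplicative factor u ~ Uniform(0.8, 1.2) and one additive
#' shift v ~ Uniform(-0.2, 0.2) per image from the current RNG and returns
#' `clip(I * u + v, 0, 1)`. `u` and `v` can be forced for testing.
#'
#' @param image01 Array with values in `[0, 1]`.
#' @param u,v Optional forced factor/shift.
#' @return Augmented array, clipped back to `[0, 1]`.
#' @export
grayscale_float <- function(image01, u = NULL, v = NULL) {
  if (any(image01 < 0 | image01 > 1)) stopf("image values outside [0, 1]")
  if (is.null(u)) u <- runif(1, 0.8, 1.2)
  if (is.null(v)) v <- runif(1, -0.2, 0.2)
  pmin(pmax(image01 * u + v, 0), 1)
}

# Inverse-mapped affine warp about the image center. Angle in degrees,
# translation in pixels, shear as an x-shear coefficient. `interp` is
# "bilinear" (images) or "nearest" (masks). Out-of-domain pixels get `fill`.
affine_warp <- function(img, angle = 0, dx = 0, dy = 0, mirror = FALSE,
                        shear = 0, interp = c("bilinear", "nearest"),
                        fill = 0) {
  interp <- match.arg(interp)
  H <- nrow(img); W <- ncol(img)
  ch <- (H + 1) / 2; cw <- (W + 1) / 2
  th <- angle * pi / 180
  # forward transform: mirror, shear, rotate, translate (about center)
  A <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  Sh <- matrix(c(1, 0, shear, 1), 2, 2)
  M <- A %*% Sh
  if (mirror) M <- M %*% matrix(c(1, 0, 0, -1), 2, 2)
  Minv <- solve(M)
  out_h <- matrix(seq_len(H) - ch, H, W)
  out_w <- matrix(seq_len(W) - cw, H, W, byrow = TRUE)
  src_h <- Minv[1, 1] * (out_h - dx) + Minv[1, 2] * (out_w - dy) + ch
  src_w <- Minv[2, 1] * (out_h - dx) + Minv[2, 2] * (out_w - dy) + cw
  if (interp == "nearest") {
    hi <- round(src_h); wi <- round(src_w)
    ok <- hi >= 1 & hi <= H & wi >= 1 & wi <= W
    out <- matrix(fill, H, W)
    out[ok] <- img[cbind(hi[ok], wi[ok])]
  } else {
    h0 <- floor(src_h); w0 <- floor(src_w)
    fh <- src_h - h0; fw <- src_w - w0
    out <- matrix(fill, H, W)
    gv <- function(hh, ww) {
      ok <- hh >= 1 & hh <= H & ww >= 1 & ww <= W
      v <- matrix(0, H, W)
      v[ok] <- img[cbind(hh[ok], ww[ok])]
      list(v = v, ok = ok)
    }
    g00 <- gv(h0, w0); g10 <- gv(h0 + 1, w0)
    g01 <- gv(h0, w0 + 1); g11 <- gv(h0 + 1, w0 + 1)
    val <- (1 - fh) * (1 - fw) * g00$v + fh * (1 - fw) * g10$v +
      (1 - fh) * fw * g01$v + fh * fw * g11$v
    any_ok <- g00$ok | g10$ok | g01$ok | g11$ok
    out[any_ok] <- val[any_ok]
  }
  out
}

#' Geometric augmentation of a slice and its masks
#'
#' Samples one affine transform (rotation, translation, optional mirror,
#' shear) from the current RNG and applies the same transform to the image
#' (bilinear interpolation) and to every mask (nearest neighbour, so masks
#' stay binary). A transform can be forced through `transform` for testing.
#'
#' @param image 2D numeric array.
#' @param masks Named list of 2D binary arrays aligned with `image`.
#' @param config A [preprocess_config()] providing the sampling maxima.
#' @param transform Optional forced list with elements `angle`, `dx`, `dy`,
#'   `mirror`, `shear`.
#' @return List with `image` and `masks` after the shared transform.
#' @export
geometric_augment <- function(image, masks, config = preprocess_config(),
                              transform = NULL) {
  for (m in masks)
    if (!identical(dim(image), dim(m))) stopf("image and mask shapes differ")
  if (is.null(transform)) {
    transform <- list(
      angle = runif(1, -config$rotation_max, config$rotation_max),
      dx = round(runif(1, -config$translation_max, config$translation_max)),
      dy = round(runif(1, -config$translation_max, config$translation_max)),
      mirror = config$mirror && runif(1) < 0.5,
      shear = runif(1, -config$shear_max, config$shear_max))
  }
  identity_tf <- transform$angle == 0 && transform$dx == 0 &&
    transform$dy == 0 && !isTRUE(transform$mirror) && transform$shear == 0
  if (identity_tf) return(list(image = image, masks = masks))
  wa <- function(img, interp) {
    affine_warp(img, transform$angle, transform$dx, transform$dy,
                isTRUE(transform$mirror), transform$shear, interp)
  }
  list(image = wa(image, "bilinear"),
       masks = lapply(masks, function(m) wa(m, "nearest")))
}

#' Filter out low-contrast tumor-bearing slices
#'
#' For each slice carrying tumor, computes the contrast
#' `c = |mean HU in tumor - mean HU in liver-minus-tumor|` and drops the
#' slice if `c < threshold`. Slices without tumor pass unconditionally (the
#' filter concerns liver/tumor contrast only). Intended for the training set
#' only — validation and test slices must never be filtered — and must run on
#' HU-valued images, before windowing.
#'
#' @param samples List of [slice_sample()] objects with HU images.
#' @param threshold Minimum contrast in HU (>= 0).
#' @return The surviving samples, in input order.
#' @export
contrast_filter <- function(samples, threshold = 10) {
  if (threshold < 0) stopf("threshold must be >= 0")
  keep <- vapply(samples, function(s) {
    if (sum(s$tumor_mask) == 0) return(TRUE)
    liver_only <- s$liver_mask == 1 & s$tumor_mask == 0
    if (!any(liver_only)) return(TRUE)
    ct <- abs(mean(s$image[s$tumor_mask == 1]) - mean(s$image[liver_only]))
    ct >= threshold
  }, logical(1))
  samples[keep]
}

#' Build the network input for one slice
#'
#' The deterministic preprocessing applied everywhere (train, validation,
#' test): HU windowing to `[0, 1]`, 8-bit rendering, foreground
#' point-to-point flip with the liver mask as foreground, then rescale to
#' `[0, 1]`. With flipping disabled, the windowed image is masked to the
#' liver instead.
#'
#' @param image_hu 2D HU array.
#' @param liver_mask 2D binary liver mask.
#' @param config A [preprocess_config()].
#' @return 2D array in `[0, 1]`, zero outside the liver.
#' @export
prepare_input <- function(image_hu, liver_mask, config = preprocess_config()) {
  img01 <- window_and_normalize(image_hu, config$hu_window)
  if (config$flip_enabled) {
    img8 <- round(img01 * 255)
    flip_point_to_point(img8, liver_mask) / 255
  } else {
    img01 * (liver_mask == 1)
  }
}
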