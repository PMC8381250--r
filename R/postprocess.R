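# Morphological closing of binary masks. Everything outside the array is
# treated as background, the standard convention for segmentation masks.

ball_offsets <- function(radius, ndim) {
  s <- -radius:radius
  g <- if (ndim == 2) expand.grid(dx = s, dy = s)
       else expand.grid(dx = s, dy = s, dz = s)
  g[rowSums(g^2) <= radius^2, , drop = FALSE]
}

shift_combine <- function(mask, offs, combine) {
  d <- dim(mask)
  r <- max(abs(as.matrix(offs)))
  nd <- length(d)
  pd <- d + 2 * r
  pad <- array(if (identical(combine, pmax)) 0 else 0, pd)
  core <- lapply(d, function(n) r + seq_len(n))
  if (nd == 2) pad[core[[1]], core[[2]]] <- mask
  else pad[core[[1]], core[[2]], core[[3]]] <- mask
  acc <- NULL
  for (i in seq_len(nrow(offs))) {
    o <- as.numeric(offs[i, ])
    ix <- lapply(seq_len(nd), function(k) r + seq_len(d[k]) + o[k])
    sub <- if (nd == 2) pad[ix[[1]], ix[[2]]] else pad[ix[[1]], ix[[2]], ix[[3]]]
    acc <- if (is.null(acc)) sub else combine(acc, sub)
  }
  acc
}

dilate_mask <- function(mask, radius) {
  shift_combine(mask, ball_offsets(radius, length(dim(mask))), pmax)
}

erode_mask <- function(mask, radius) {
  shift_combine(mask, ball_offsets(radius, length(dim(mask))), pmin)
}

#' Morphological closing of a binary mask
#'
#' Dilation followed by erosion with a disk (2D) or ball (3D) structuring
#' element of the given radius, with the outside of the array treated as
#' background. The dilate-erode sequence runs on a domain padded by the
#' radius so that dilated mass near the border is not cropped before the
#' erosion; closing therefore fills cavities and narrow interruptions
#' smaller than the element while never removing foreground (it is
#' extensive and idempotent, including at the array border). Applied to
#' predicted tumor masks as a noise-reduction step.
#'
#' @param mask Binary 2D or 3D array (values 0/1).
#' @param radius Structuring-element radius in pixels (>= 1).
#' @return Integer 0/1 array of the same shape.
#' @export
close_mask <- function(mask, radius = 1) {
  d <- dim(mask)
  if (is.null(d) || !(length(d) %in% c(2L, 3L)))
    stopf("mask must be a 2D or 3D array")
  if (!is_binary(mask)) stopf("mask must be binary (0/1)")
  if (radius < 1) stopf("radius must be >= 1")
  r <- as.integer(ceiling(radius))
  pd <- d + 2L * r
  padded <- array(0, pd)
  core <- lapply(seq_along(d), function(k) r + seq_len(d[k]))
  if (length(d) == 2L) padded[core[[1]], core[[2]]] <- mask
  else padded[core[[1]], core[[2]], core[[3]]] <- mask
  closed <- erode_mask(dilate_mask(padded, radius), radius)
  out <- if (length(d) == 2L) closed[core[[1]], core[[2]]]
         else closed[core[[1]], core[[2]], core[[3]]]
  storage.mode(out) <- "integer"
  dim(out) <- d
  out
}
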