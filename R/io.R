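#' CT volume container
#'
#' Bundles a 3D array of Hounsfield-unit values with its voxel spacing and a
#' case identifier. Axial slices are taken along the third array axis.
#'
#' @param data 3D numeric array of HU values.
#' @param spacing Numeric length-3 vector, voxel size in mm (x, y, z).
#' @param case_id Character scalar identifying the scan.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(data, spacing = c(1, 1, 1), case_id = "case") {
  if (length(dim(data)) != 3L) stopf("expected 3D volume, got %dD", length(dim(data)))
  if (length(spacing) != 3L || any(spacing <= 0))
    stopf("spacing must be 3 positive values")
  if (!all(is.finite(data))) stopf("volume contains non-finite values")
  structure(list(data = data, spacing = as.numeric(spacing),
                 case_id = as.character(case_id)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ct_volume '%s'> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              x$case_id, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Read a CT volume from a NIfTI file
#'
#' @param path Path to a `.nii` or `.nii.gz` file containing a 3D volume.
#' @param case_id Case identifier; defaults to the file name stem.
#' @return A [ct_volume()].
#' @export
read_volume <- function(path, case_id = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stopf("expected 3D volume, got %dD data in %s", length(dim(arr)), path)
  sp <- RNifti::pixdim(img)
  if (length(sp) < 3L || any(!is.finite(sp[1:3])) || any(sp[1:3] <= 0))
    stopf("missing or invalid voxel spacing in %s", path)
  if (is.null(case_id))
    case_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  ct_volume(arr, sp[1:3], case_id)
}

#' Write a CT volume (or label volume) to NIfTI
#'
#' @param vol A [ct_volume()] or a 3D array (spacing then defaults to 1 mm).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (is.array(vol)) vol <- ct_volume(vol)
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Decode a LiTS label volume into liver and tumor masks
#'
#' LiTS convention: 0 = background, 1 = liver, 2 = tumor. The liver mask is
#' label >= 1 (the tumor lies inside the liver); the tumor mask is label == 2.
#'
#' @param labels Integer array with values in `{0, 1, 2}`.
#' @return List with binary arrays `liver_mask` and `tumor_mask`.
#' @export
decode_labels <- function(labels) {
  bad <- setdiff(unique(as.vector(labels)), c(0, 1, 2))
  if (length(bad))
    stopf("invalid label value(s): %s (expected 0, 1, 2)",
          paste(bad, collapse = ", "))
  liver <- (labels >= 1) * 1L
  tumor <- (labels == 2) * 1L
  storage.mode(liver) <- "integer"
  storage.mode(tumor) <- "integer"
  list(liver_mask = liver, tumor_mask = tumor)
}

#' Encode liver and tumor masks as a LiTS label volume
#'
#' Inverse of [decode_labels()]: tumor voxels get 2, remaining liver voxels 1.
#'
#' @param liver_mask,tumor_mask Binary arrays of identical shape with
#'   `tumor_mask` contained in `liver_mask`.
#' @return Integer label array with values in `{0, 1, 2}`.
#' @export
encode_labels <- function(liver_mask, tumor_mask) {
  if (!identical(dim(liver_mask), dim(tumor_mask)))
    stopf("mask shapes differ")
  if (!is_binary(liver_mask) || !is_binary(tumor_mask))
    stopf("masks must be binary")
  if (any(tumor_mask == 1 & liver_mask == 0))
    stopf("tumor mask extends outside liver mask")
  lab <- array(0L, dim(liver_mask))
  lab[liver_mask == 1] <- 1L
  lab[tumor_mask == 1] <- 2L
  lab
}

#' One 2D slice with its masks
#'
#' @param image 2D numeric array (HU or normalized intensities).
#' @param liver_mask,tumor_mask 2D binary arrays aligned with `image`.
#' @param case_id Case identifier.
#' @param slice_index 1-based axial slice index within the case.
#' @return An object of class `slice_sample`.
#' @export
slice_sample <- function(image, liver_mask, tumor_mask, case_id, slice_index) {
  if (!identical(dim(image), dim(liver_mask)) ||
      !identical(dim(image), dim(tumor_mask)))
    stopf("image and mask shapes differ")
  if (any(tumor_mask == 1 & liver_mask == 0))
    stopf("tumor mask extends outside liver mask")
  structure(list(image = image, liver_mask = liver_mask,
                 tumor_mask = tumor_mask, case_id = as.character(case_id),
                 slice_index = as.integer(slice_index)),
            class = "slice_sample")
}

#' Extract axial slice samples from a case
#'
#' @param case A list with elements `volume` ([ct_volume()]), `liver_mask`
#'   and `tumor_mask` (3D binary arrays), e.g. a phantom case from
#'   [generate_case()].
#' @param keep_empty Keep slices whose liver mask is empty? Default `FALSE`:
#'   liver-free slices carry no signal for a tumor network operating inside
#'   the liver.
#' @return List of [slice_sample()] objects, slice indices strictly
#'   increasing.
#' @export
extract_slices <- function(case, keep_empty = FALSE) {
  vol <- case$volume
  if (!identical(dim(vol$data), dim(case$liver_mask)) ||
      !identical(dim(vol$data), dim(case$tumor_mask)))
    stopf("volume and mask shapes differ")
  nz <- dim(vol$data)[3]
  out <- vector("list", nz)
  keep <- logical(nz)
  for (z in seq_len(nz)) {
    lm <- case$liver_mask[, , z]
    if (!keep_empty && sum(lm) == 0) next
    out[[z]] <- slice_sample(vol$data[, , z], lm, case$tumor_mask[, , z],
                             vol$case_id, z)
    keep[z] <- TRUE
  }
  out[keep]
}

#' Split a cohort of case ids into train/validation/test sets
#'
#' The split is at the case level so no slice of one patient can appear in
#' two strata. Stratum sizes are `round(fraction * n)` for train and
#' validation, with the remainder as test; with 131 cases and fractions
#' 100/131, 10/131, 21/131 this reproduces the conventional 100/10/21
#' partition.
#'
#' @param case_ids Character vector of unique case identifiers (>= 3).
#' @param fractions Length-3 numeric summing to 1: train, validation, test.
#' @param seed Integer seed controlling the shuffle.
#' @return List with character vectors `train`, `val`, `test`.
#' @export
split_cohort <- function(case_ids, fractions = c(100, 10, 21) / 131,
                         seed = 1L) {
  n <- length(case_ids)
  if (n < 3L) stopf("need at least 3 cases to split, got %d", n)
  if (anyDuplicated(case_ids)) stopf("case ids must be unique")
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-6)
    stopf("fractions must be 3 values summing to 1")
  n_train <- round(fractions[1] * n)
  n_val <- round(fractions[2] * n)
  n_test <- n - n_train - n_val
  if (n_train < 1 || n_val < 1 || n_test < 1)
    stopf("empty stratum: sizes %d/%d/%d", n_train, n_val, n_test)
  perm <- with_seed(seed, sample(case_ids))
  list(train = perm[seq_len(n_train)],
       val = perm[n_train + seq_len(n_val)],
       test = perm[n_train + n_val + seq_len(n_test)])
}
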