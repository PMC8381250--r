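#' Configuration for the synthetic CT phantom generator
#'
#' The phantom emulates the intensity structure that makes liver-tumor
#' segmentation hard: an air background at -1000 HU, a soft-tissue body
#' ellipse, an elliptical liver with one Hounsfield-unit distribution, and
#' irregular blob-shaped tumors drawn from a second, overlapping HU
#' distribution. `contrast_gap` is the separation between the liver and
#' tumor mean HU; tumors are hypodense (darker) by default, as most hepatic
#' lesions are on portal-venous CT.
#'
#' @param image_size Pixels per side of each square slice (>= 32).
#' @param n_slices Axial slices per case.
#' @param liver_hu_mean,liver_hu_sd Liver parenchyma HU distribution.
#' @param contrast_gap HU separation between liver and tumor means.
#' @param tumor_hu_mean Tumor HU mean; default `liver_hu_mean - contrast_gap`.
#' @param tumor_hu_sd Tumor HU standard deviation.
#' @param body_hu_mean Mean HU of the surrounding soft-tissue body.
#' @param background_hu Background (air) HU.
#' @param tumor_count_range Integer interval: tumors per case.
#' @param tumor_radius_range Pixel interval: main tumor radius.
#' @param noise_sd Additive acquisition noise, HU.
#' @param seed Default RNG seed used when none is passed to the generator.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 64L, n_slices = 8L,
                           liver_hu_mean = 60, liver_hu_sd = 10,
                           contrast_gap = 30, tumor_hu_mean = NULL,
                           tumor_hu_sd = 10, body_hu_mean = 20,
                           background_hu = -1000,
                           tumor_count_range = c(1L, 3L),
                           tumor_radius_range = c(3, 8),
                           noise_sd = 5, seed = 1L) {
  if (is.null(tumor_hu_mean)) tumor_hu_mean <- liver_hu_mean - contrast_gap
  cfg <- list(image_size = as.integer(image_size),
              n_slices = as.integer(n_slices),
              liver_hu_mean = liver_hu_mean, liver_hu_sd = liver_hu_sd,
              contrast_gap = contrast_gap, tumor_hu_mean = tumor_hu_mean,
              tumor_hu_sd = tumor_hu_sd, body_hu_mean = body_hu_mean,
              background_hu = background_hu,
              tumor_count_range = as.integer(round(tumor_count_range)),
              tumor_radius_range = as.numeric(tumor_radius_range),
              noise_sd = noise_sd, seed = as.integer(seed))
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  if (cfg$image_size < 32L) stopf("image_size must be >= 32")
  if (cfg$n_slices < 1L) stopf("n_slices must be >= 1")
  if (cfg$noise_sd < 0) stopf("noise_sd must be >= 0")
  if (cfg$liver_hu_sd < 0 || cfg$tumor_hu_sd < 0) stopf("HU sd must be >= 0")
  rng <- cfg$tumor_radius_range
  cnt <- cfg$tumor_count_range
  if (length(rng) != 2L || rng[1] > rng[2] || rng[1] <= 0)
    stopf("tumor_radius_range must be a nonempty positive interval")
  if (length(cnt) != 2L || cnt[1] > cnt[2] || cnt[1] < 0)
    stopf("tumor_count_range must be a nonempty non-negative interval")
  semi_minor <- 0.26 * cfg$image_size
  if (rng[2] >= semi_minor)
    stopf("max tumor radius (%.1f) must be smaller than the liver semi-minor axis (%.1f)",
          rng[2], semi_minor)
  invisible(cfg)
}

# Rasterize a disk: pixels within radius r of (cx, cy) on an S x S grid.
disk_pixels <- function(S, cx, cy, r) {
  x <- matrix(seq_len(S), S, S)
  y <- matrix(seq_len(S), S, S, byrow = TRUE)
  (x - cx)^2 + (y - cy)^2 <= r^2
}

# Elliptical mask on an S x S grid.
ellipse_pixels <- function(S, cx, cy, a, b) {
  if (a < 1 || b < 1) return(matrix(FALSE, S, S))
  x <- matrix(seq_len(S), S, S)
  y <- matrix(seq_len(S), S, S, byrow = TRUE)
  ((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1
}

# An irregular tumor blob: a main disk plus 0-2 satellite disks whose centers
# and radii are bounded so the union stays within 1.1x the main radius.
# Returns a logical S x S mask. All random draws come from the current RNG.
tumor_blob <- function(S, cx, cy, r) {
  blob <- disk_pixels(S, cx, cy, r)
  n_sat <- sample(0:2, 1)
  if (n_sat > 0) {
    for (s in seq_len(n_sat)) {
      ang <- runif(1, 0, 2 * pi)
      d <- r * runif(1, 0.2, 0.5)
      rs <- r * runif(1, 0.4, 0.6)
      blob <- blob | disk_pixels(S, cx + d * cos(ang), cy + d * sin(ang), rs)
    }
  }
  blob
}

#' Generate one synthetic phantom case
#'
#' Deterministic function of `(config, seed)`. Each axial slice holds a body
#' ellipse over an air background and an elliptical liver whose semi-axes
#' follow a spherical-cap profile along z (so end slices may hold no liver).
#' Tumors are unions of perturbed disks placed entirely inside the liver,
#' spanning one to three consecutive slices with tapered radii. Voxel HU
#' values are drawn from the configured normal distributions plus additive
#' acquisition noise.
#'
#' @param config A [phantom_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A list of class `phantom_case` with elements `volume`
#'   ([ct_volume()]), `liver_mask`, `tumor_mask` (3D 0/1 integer arrays) and
#'   `provenance` (the config and seed used).
#' @export
generate_case <- function(config, seed = config$seed) {
  validate_phantom_config(config)
  with_seed(seed, generate_case_impl(config, seed))
}

generate_case_impl <- function(config, seed) {
  S <- config$image_size
  Z <- config$n_slices
  # per-case anatomy jitter
  cx <- S / 2 + runif(1, -0.03, 0.03) * S
  cy <- S / 2 + runif(1, -0.03, 0.03) * S
  a0 <- 0.33 * S * runif(1, 0.9, 1.05)
  b0 <- 0.26 * S * runif(1, 0.9, 1.05)
  zc <- (Z + 1) / 2
  zh <- max(0.75, 0.45 * Z)   # half-extent of the liver along z

  liver <- array(0L, c(S, S, Z))
  zscale <- numeric(Z)
  for (z in seq_len(Z)) {
    u <- (z - zc) / zh
    sc <- if (abs(u) < 1) sqrt(1 - u^2) else 0
    zscale[z] <- sc
    if (sc > 0) liver[, , z] <- ellipse_pixels(S, cx, cy, a0 * sc, b0 * sc) * 1L
  }

  tumor <- array(0L, c(S, S, Z))
  n_tum <- if (config$tumor_count_range[1] == config$tumor_count_range[2])
    config$tumor_count_range[1]
  else sample(config$tumor_count_range[1]:config$tumor_count_range[2], 1)
  eligible <- which(zscale >= 0.5)
  if (n_tum > 0 && length(eligible) == 0)
    stopf("no slice can host a tumor (liver too thin along z)")
  for (t in seq_len(n_tum)) {
    placed <- FALSE
    for (attempt in seq_len(100L)) {
      r <- runif(1, config$tumor_radius_range[1], config$tumor_radius_range[2])
      zt <- if (length(eligible) == 1) eligible else sample(eligible, 1)
      span <- sample(seq_len(min(3L, Z)), 1)
      zs <- zt:min(Z, zt + span - 1L)
      # candidate center inside the central part of the liver at zt
      ang <- runif(1, 0, 2 * pi)
      rad <- runif(1, 0, 0.55)
      tx <- cx + rad * a0 * zscale[zt] * cos(ang)
      ty <- cy + rad * b0 * zscale[zt] * sin(ang)
      blobs <- vector("list", length(zs))
      ok <- TRUE
      for (i in seq_along(zs)) {
        dz <- (i - 1) / max(1, length(zs))
        rz <- r * sqrt(max(0, 1 - dz^2))
        if (rz < 1) { blobs[[i]] <- matrix(FALSE, S, S); next }
        bl <- tumor_blob(S, tx, ty, rz)
        if (any(bl & liver[, , zs[i]] == 0L)) { ok <- FALSE; break }
        blobs[[i]] <- bl
      }
      if (!ok) next
      for (i in seq_along(zs))
        tumor[, , zs[i]] <- pmax(tumor[, , zs[i]], blobs[[i]] * 1L)
      placed <- TRUE
      break
    }
    if (!placed)
      stopf("could not place tumor %d inside the liver after 100 attempts; config too tight", t)
  }

  body_a <- 0.46 * S
  body_b <- 0.40 * S
  vol <- array(config$background_hu, c(S, S, Z))
  for (z in seq_len(Z)) {
    body <- ellipse_pixels(S, S / 2, S / 2, body_a, body_b)
    sl <- vol[, , z]
    nb <- sum(body)
    if (nb) sl[body] <- rnorm(nb, config$body_hu_mean, 15)
    lv <- liver[, , z] == 1L
    nl <- sum(lv)
    if (nl) sl[lv] <- rnorm(nl, config$liver_hu_mean, config$liver_hu_sd)
    tm <- tumor[, , z] == 1L
    nt <- sum(tm)
    if (nt) sl[tm] <- rnorm(nt, config$tumor_hu_mean, config$tumor_hu_sd)
    vol[, , z] <- sl
  }
  if (config$noise_sd > 0)
    vol <- vol + array(rnorm(length(vol), 0, config$noise_sd), dim(vol))

  structure(list(volume = ct_volume(vol, c(1, 1, 2.5),
                                    sprintf("phantom_%06d", seed %% 1000000L)),
                 liver_mask = liver, tumor_mask = tumor,
                 provenance = list(config = config, seed = seed)),
            class = "phantom_case")
}

#' Generate a cohort of phantom cases
#'
#' Per-case seeds are derived from the master seed with a counter-based
#' scheme, so case i is identical whether generated alone or within any
#' cohort. Tumor radii are additionally spread across the configured range
#' (case i draws from a narrow window centred at the i-th quantile of
#' `tumor_radius_range`), which guarantees both small and large tumors in a
#' cohort so size stratification is well-populated.
#'
#' @param config A [phantom_config()].
#' @param n_cases Number of cases (>= 1).
#' @param seed Master seed.
#' @return List of `phantom_case` objects with unique case ids.
#' @export
generate_cohort <- function(config, n_cases, seed = config$seed) {
  if (n_cases < 1) stopf("n_cases must be >= 1")
  rng <- config$tumor_radius_range
  w <- rng[2] - rng[1]
  lapply(seq_len(n_cases), function(i) {
    ti <- if (n_cases == 1) 0.5 else (i - 1) / (n_cases - 1)
    ctr <- rng[1] + ti * w
    sub <- c(max(rng[1], ctr - 0.15 * w), min(rng[2], ctr + 0.15 * w))
    cfg_i <- config
    cfg_i$tumor_radius_range <- sub
    cs <- generate_case(cfg_i, derive_seed(seed, i))
    cs$volume$case_id <- sprintf("phantom_%03d", i)
    cs
  })
}

#' Write a phantom case as NIfTI volume + LiTS label mask
#'
#' @param case A `phantom_case`.
#' @param dir Output directory (created if needed).
#' @return Paths of the two files written, invisibly.
#' @export
write_phantom_case <- function(case, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- case$volume$case_id
  vp <- file.path(dir, paste0(id, "_volume.nii.gz"))
  lp <- file.path(dir, paste0(id, "_labels.nii.gz"))
  write_volume(case$volume, vp)
  lab <- encode_labels(case$liver_mask, case$tumor_mask)
  write_volume(ct_volume(lab, case$volume$spacing, id), lp)
  invisible(c(volume = vp, labels = lp))
}

#' Write a cohort to disk with a CSV manifest
#'
#' @param cohort List of `phantom_case` objects.
#' @param dir Output directory.
#' @return The manifest as a data frame (case id, tumor voxel count, seed),
#'   invisibly; written to `manifest.csv` in `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cs in cohort) write_phantom_case(cs, dir)
  man <- data.frame(
    case_id = vapply(cohort, function(cs) cs$volume$case_id, character(1)),
    n_tumor_voxels = vapply(cohort, function(cs) sum(cs$tumor_mask), numeric(1)),
    seed = vapply(cohort, function(cs) cs$provenance$seed, numeric(1)))
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}
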