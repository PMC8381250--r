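# Independent brute-force oracles and small fixture builders. These are
# deliberately written as naive loops so they share no code path with the
# package implementation they check.

# naive morphology: per-pixel loops over all structuring-element offsets,
# outside the array treated as background
oracle_dilate <- function(mask, radius) {
  d <- dim(mask)
  nd <- length(d)
  offs <- as.matrix(do.call(expand.grid, rep(list(-radius:radius), nd)))
  offs <- offs[rowSums(offs^2) <= radius^2, , drop = FALSE]
  out <- array(0L, d)
  it <- as.matrix(do.call(expand.grid, lapply(d, seq_len)))
  for (r in seq_len(nrow(it))) {
    p <- it[r, ]
    hit <- FALSE
    for (o in seq_len(nrow(offs))) {
      q <- p + offs[o, ]
      if (all(q >= 1) && all(q <= d)) {
        v <- if (nd == 2) mask[q[1], q[2]] else mask[q[1], q[2], q[3]]
        if (v == 1) { hit <- TRUE; break }
      }
    }
    if (hit) {
      if (nd == 2) out[p[1], p[2]] <- 1L else out[p[1], p[2], p[3]] <- 1L
    }
  }
  out
}

oracle_erode <- function(mask, radius) {
  d <- dim(mask)
  nd <- length(d)
  offs <- as.matrix(do.call(expand.grid, rep(list(-radius:radius), nd)))
  offs <- offs[rowSums(offs^2) <= radius^2, , drop = FALSE]
  out <- array(0L, d)
  it <- as.matrix(do.call(expand.grid, lapply(d, seq_len)))
  for (r in seq_len(nrow(it))) {
    p <- it[r, ]
    all_fg <- TRUE
    for (o in seq_len(nrow(offs))) {
      q <- p + offs[o, ]
      v <- if (any(q < 1) || any(q > d)) 0
      else if (nd == 2) mask[q[1], q[2]] else mask[q[1], q[2], q[3]]
      if (v != 1) { all_fg <- FALSE; break }
    }
    if (all_fg) {
      if (nd == 2) out[p[1], p[2]] <- 1L else out[p[1], p[2], p[3]] <- 1L
    }
  }
  out
}

# closing on the background-extended domain: embed in a padded array so the
# dilation is not cropped before the erosion, then crop back
oracle_close <- function(mask, radius) {
  d <- dim(mask)
  r <- as.integer(ceiling(radius))
  pd <- d + 2L * r
  padded <- array(0L, pd)
  core <- lapply(seq_along(d), function(k) r + seq_len(d[k]))
  if (length(d) == 2L) padded[core[[1]], core[[2]]] <- mask
  else padded[core[[1]], core[[2]], core[[3]]] <- mask
  closed <- oracle_erode(oracle_dilate(padded, radius), radius)
  out <- if (length(d) == 2L) closed[core[[1]], core[[2]]]
         else closed[core[[1]], core[[2]], core[[3]]]
  storage.mode(out) <- "integer"
  dim(out) <- d
  out
}

# naive symmetric surface distances: boundary by explicit neighbour checks,
# then all-pairs minimum distances
oracle_surface <- function(a, b, spacing = rep(1, length(dim(a)))) {
  bound <- function(m) {
    d <- dim(m)
    nd <- length(d)
    it <- as.matrix(do.call(expand.grid, lapply(d, seq_len)))
    keep <- logical(nrow(it))
    for (r in seq_len(nrow(it))) {
      p <- it[r, ]
      v <- if (nd == 2) m[p[1], p[2]] else m[p[1], p[2], p[3]]
      if (v != 1) next
      for (k in seq_len(nd)) for (s in c(-1L, 1L)) {
        q <- p; q[k] <- q[k] + s
        nb <- if (any(q < 1) || any(q > d)) 0
        else if (nd == 2) m[q[1], q[2]] else m[q[1], q[2], q[3]]
        if (nb == 0) keep[r] <- TRUE
      }
    }
    it[keep, , drop = FALSE]
  }
  pa <- bound(a); pb <- bound(b)
  mind <- function(p, q) {
    vapply(seq_len(nrow(p)), function(i) {
      best <- Inf
      for (j in seq_len(nrow(q))) {
        dd <- sqrt(sum(((p[i, ] - q[j, ]) * spacing)^2))
        if (dd < best) best <- dd
      }
      best
    }, numeric(1))
  }
  pooled <- c(mind(pa, pb), mind(pb, pa))
  list(assd = mean(pooled), rmsd = sqrt(mean(pooled^2)))
}

# random binary array with roughly the given foreground fraction, never all-0
rand_mask <- function(dims, p = 0.3) {
  m <- array(as.integer(runif(prod(dims)) < p), dims)
  if (sum(m) == 0) m[1] <- 1L
  m
}

# a hand-built 3D case: liver on some slices, a small tumor block inside
manual_case <- function(nx = 12, ny = 12, nz = 10, liver_slices = 4:7) {
  liver <- array(0L, c(nx, ny, nz))
  tumor <- array(0L, c(nx, ny, nz))
  for (z in liver_slices) liver[3:10, 3:10, z] <- 1L
  tumor[5:6, 5:6, liver_slices[2]] <- 1L
  vol <- array(-1000, c(nx, ny, nz))
  vol[liver == 1] <- 60
  vol[tumor == 1] <- 30
  list(volume = ct_volume(vol, c(1, 1, 2.5), "manual"),
       liver_mask = liver, tumor_mask = tumor)
}

# slice with prescribed liver/tumor mean HU for contrast-filter tests
contrast_slice <- function(liver_hu, tumor_hu, idx = 1L) {
  img <- matrix(-1000, 16, 16)
  liver <- matrix(0L, 16, 16); liver[4:13, 4:13] <- 1L
  tumor <- matrix(0L, 16, 16); tumor[7:9, 7:9] <- 1L
  img[liver == 1] <- liver_hu
  img[tumor == 1] <- tumor_hu
  slice_sample(img, liver, tumor, "c", idx)
}

# permute attention parameters consistently with a channel permutation
permute_att <- function(params, perm) {
  params$mlp_w1 <- params$mlp_w1[, perm, drop = FALSE]
  params$mlp_w2 <- params$mlp_w2[perm, , drop = FALSE]
  params$mlp_b2 <- params$mlp_b2[perm]
  params
}
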