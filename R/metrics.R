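# LiTS-style evaluation metrics: volumetric overlap (Dice, VOE) and
# symmetric surface distances (ASSD, RMSD), per case and cohort-pooled,
# with tumor-size stratification.

check_pair <- function(a, b) {
  if (!identical(dim(a), dim(b))) stopf("mask shapes differ")
  if (!is_binary(a) || !is_binary(b)) stopf("masks must be binary (0/1)")
}

#' Dice overlap of two binary masks
#'
#' `2|A n B| / (|A| + |B|)`. Convention: two empty masks have Dice 1
#' (perfect agreement on absence); exactly one empty mask gives 0.
#'
#' @param a,b Binary arrays of identical shape.
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(a, b) {
  check_pair(a, b)
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a * b) / (sa + sb)
}

#' Volumetric overlap error
#'
#' `1 - |A n B| / |A u B|` (one minus the Jaccard index). Two empty masks
#' give 0 (no error).
#'
#' @inheritParams dice
#' @return Scalar in `[0, 1]`.
#' @export
voe <- function(a, b) {
  check_pair(a, b)
  uni <- sum(a | b)
  if (uni == 0) return(0)
  1 - sum(a * b) / uni
}

#' Dice per case: unweighted mean of per-case Dice scores
#'
#' @param predictions,references Aligned lists of binary masks, one pair per
#'   case.
#' @return Scalar in `[0, 1]`.
#' @export
dice_per_case <- function(predictions, references) {
  if (!length(predictions) || length(predictions) != length(references))
    stopf("need equal-length nonempty prediction and reference lists")
  mean(mapply(dice, predictions, references))
}

#' Dice global: Dice over all cases pooled into one volume
#'
#' Intersections and mask sizes are summed over the cohort before the Dice
#' ratio is taken, so large tumors dominate (unlike [dice_per_case()]).
#'
#' @inheritParams dice_per_case
#' @return Scalar in `[0, 1]`.
#' @export
dice_global <- function(predictions, references) {
  if (!length(predictions) || length(predictions) != length(references))
    stopf("need equal-length nonempty prediction and reference lists")
  inter <- 0; tot <- 0
  for (i in seq_along(predictions)) {
    check_pair(predictions[[i]], references[[i]])
    inter <- inter + sum(predictions[[i]] * references[[i]])
    tot <- tot + sum(predictions[[i]]) + sum(references[[i]])
  }
  if (tot == 0) return(1)
  2 * inter / tot
}

# Boundary voxels: foreground with at least one background face-neighbour
# (4-connectivity in 2D, 6 in 3D); the outside counts as background.
# Returns an n x ndim matrix of 1-based coordinates.
boundary_coords <- function(mask) {
  d <- dim(mask)
  nd <- length(d)
  pd <- d + 2L
  pad <- array(0, pd)
  if (nd == 2) pad[1 + seq_len(d[1]), 1 + seq_len(d[2])] <- mask
  else pad[1 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] <- mask
  core <- lapply(d, function(n) 1 + seq_len(n))
  sub <- function(off) {
    ix <- lapply(seq_len(nd), function(k) core[[k]] + off[k])
    if (nd == 2) pad[ix[[1]], ix[[2]]] else pad[ix[[1]], ix[[2]], ix[[3]]]
  }
  has_bg <- array(FALSE, d)
  for (k in seq_len(nd)) for (s in c(-1L, 1L)) {
    off <- integer(nd); off[k] <- s
    has_bg <- has_bg | (sub(off) == 0)
  }
  which(mask == 1 & has_bg, arr.ind = TRUE)
}

#' Symmetric surface distances between two masks
#'
#' Boundary voxels (foreground voxels with a background face-neighbour) are
#' extracted from both masks; directed Euclidean distances from every
#' boundary voxel of A to the boundary of B and vice versa are pooled.
#' ASSD is the mean of the pooled distances and RMSD the root of the mean of
#' their squares, both in mm via the voxel spacing.
#'
#' @param a,b Binary arrays of identical shape (2D or 3D).
#' @param spacing Voxel size in mm, one value per array dimension.
#' @return List with `assd` and `rmsd` (mm). If either mask is empty the
#'   distances are undefined: both are `NA` with a warning.
#' @export
surface_distances <- function(a, b, spacing = rep(1, length(dim(a)))) {
  check_pair(a, b)
  nd <- length(dim(a))
  if (length(spacing) != nd) stopf("spacing must have %d components", nd)
  if (sum(a) == 0 || sum(b) == 0) {
    warning("surface distance undefined for an empty mask; returning NA")
    return(list(assd = NA_real_, rmsd = NA_real_))
  }
  pa <- boundary_coords(a)
  pb <- boundary_coords(b)
  sa <- sweep(pa, 2, spacing, `*`)
  sb <- sweep(pb, 2, spacing, `*`)
  d_ab <- min_dists_cpp(sa, sb)
  d_ba <- min_dists_cpp(sb, sa)
  pooled <- c(d_ab, d_ba)
  list(assd = mean(pooled), rmsd = sqrt(mean(pooled^2)))
}

#' Tumor voxel count of a case
#'
#' @param case A list with a `tumor_mask` element, or a bare binary array.
#' @return Integer voxel count.
#' @export
tumor_voxel_count <- function(case) {
  m <- if (is.list(case)) case$tumor_mask else case
  as.integer(sum(m))
}

#' Stratify cases into small and large tumor groups
#'
#' With `mode = "fraction"` the cutoff is `threshold` times the cohort's
#' maximum per-case tumor voxel count; with `mode = "absolute"` the cutoff
#' is `threshold` voxels. A case is labelled `"large"` when its count is
#' `>=` the cutoff (ties go to large), `"small"` otherwise.
#'
#' @param counts Integer vector of per-case tumor voxel counts (or a list of
#'   cases accepted by [tumor_voxel_count()]).
#' @param threshold Cutoff, fractional (default 0.2) or absolute.
#' @param mode `"fraction"` or `"absolute"`.
#' @return Character vector of `"small"` / `"large"` labels.
#' @export
stratify_by_size <- function(counts, threshold = 0.2,
                             mode = c("fraction", "absolute")) {
  mode <- match.arg(mode)
  if (is.list(counts)) counts <- vapply(counts, tumor_voxel_count, integer(1))
  if (all(counts == 0)) stopf("all cases have empty tumor masks")
  cutoff <- if (mode == "fraction") threshold * max(counts) else threshold
  ifelse(counts >= cutoff, "large", "small")
}

#' Evaluate a cohort of predictions against references
#'
#' Computes the per-case Dice, VOE, ASSD and RMSD, the cohort summary
#' (Dice per case, Dice global, mean VOE, mean ASSD, mean RMSD), and the
#' size-stratified Dice (per case and global within each stratum). Cases
#' with an empty prediction or reference have undefined surface distances;
#' these appear as `NA` and are excluded from the cohort distance means with
#' a warning.
#'
#' @param predictions,references Aligned lists of binary tumor masks
#'   (stratification uses the reference counts).
#' @param spacing Voxel size in mm.
#' @param strat_threshold Fractional size-stratification cutoff.
#' @param case_ids Optional case identifiers; defaults to list names or
#'   `case_1, ...`.
#' @return An object of class `eval_report`: `per_case` data frame, `cohort`
#'   list, `strata` data frame, and the stratification cutoff used.
#' @export
evaluate_cohort <- function(predictions, references,
                            spacing = rep(1, length(dim(references[[1]]))),
                            strat_threshold = 0.2, case_ids = NULL) {
  n <- length(predictions)
  if (n == 0 || n != length(references))
    stopf("prediction/reference case lists differ in length")
  if (is.null(case_ids)) {
    case_ids <- names(predictions)
    if (is.null(case_ids)) case_ids <- sprintf("case_%d", seq_len(n))
  }
  if (!is.null(names(references)) && !is.null(names(predictions)) &&
      !identical(names(predictions), names(references)))
    stopf("prediction and reference case ids do not match")
  counts <- vapply(references, tumor_voxel_count, integer(1))
  strat <- stratify_by_size(counts, strat_threshold)
  dc <- numeric(n); ve <- numeric(n); as_ <- numeric(n); rm_ <- numeric(n)
  for (i in seq_len(n)) {
    dc[i] <- dice(predictions[[i]], references[[i]])
    ve[i] <- voe(predictions[[i]], references[[i]])
    sd_ <- if (sum(predictions[[i]]) == 0 || sum(references[[i]]) == 0) {
      list(assd = NA_real_, rmsd = NA_real_)
    } else surface_distances(predictions[[i]], references[[i]], spacing)
    as_[i] <- sd_$assd
    rm_[i] <- sd_$rmsd
  }
  if (anyNA(as_))
    warning(sprintf("%d case(s) with an empty mask excluded from distance means",
                    sum(is.na(as_))))
  per_case <- data.frame(case_id = case_ids, n_tumor_voxels = counts,
                         dice = dc, voe = ve, assd = as_, rmsd = rm_,
                         stratum = strat, row.names = NULL)
  cohort <- list(dice_per_case = mean(dc),
                 dice_global = dice_global(predictions, references),
                 voe_mean = mean(ve),
                 assd_mean = mean(as_, na.rm = TRUE),
                 rmsd_mean = mean(rm_, na.rm = TRUE))
  strata <- do.call(rbind, lapply(c("small", "large"), function(s) {
    idx <- which(strat == s)
    if (!length(idx)) return(NULL)
    data.frame(stratum = s, n_cases = length(idx),
               dice_per_case = mean(dc[idx]),
               dice_global = dice_global(predictions[idx], references[idx]))
  }))
  structure(list(per_case = per_case, cohort = cohort, strata = strata,
                 strat_threshold = strat_threshold),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d cases\n", nrow(x$per_case)))
  cat(sprintf("  Dice per case %.4f | Dice global %.4f | VOE %.4f | ASSD %.3f | RMSD %.3f\n",
              x$cohort$dice_per_case, x$cohort$dice_global, x$cohort$voe_mean,
              x$cohort$assd_mean, x$cohort$rmsd_mean))
  if (!is.null(x$strata)) {
    for (i in seq_len(nrow(x$strata)))
      cat(sprintf("  %s tumors (n=%d): DC %.4f, DG %.4f\n",
                  x$strata$stratum[i], x$strata$n_cases[i],
                  x$strata$dice_per_case[i], x$strata$dice_global[i]))
  }
  invisible(x)
}

#' Write an evaluation report to CSV
#'
#' @param report An `eval_report`.
#' @param path Output CSV path (per-case rows; cohort summary rows appended
#'   with case_id `"_cohort"`).
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  pc <- report$per_case
  co <- data.frame(case_id = "_cohort", n_tumor_voxels = sum(pc$n_tumor_voxels),
                   dice = report$cohort$dice_per_case,
                   voe = report$cohort$voe_mean,
                   assd = report$cohort$assd_mean,
                   rmsd = report$cohort$rmsd_mean, stratum = "all")
  write.csv(rbind(pc, co), path, row.names = FALSE)
  invisible(path)
}
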