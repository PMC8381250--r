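test_that("Dice handles identity, disjointness and partial overlap", {
  a <- array(0L, c(3, 3, 1)); a[1:2, 1:2, 1] <- 1L  # |A| = 4
  b <- array(0L, c(3, 3, 1)); b[1:2, 1, 1] <- 1L    # |B| = 2, overlap 2
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, b), 2 * 2 / 6)
  d <- array(0L, c(3, 3, 1)); d[3, 3, 1] <- 1L
  expect_equal(dice(b, d), 0)
  expect_equal(dice(a * 0L, a * 0L), 1)  # both empty: perfect agreement
  expect_equal(dice(a, a * 0L), 0)
  expect_equal(dice(a, b), dice(b, a))
  expect_error(dice(a, array(0L, c(2, 2, 1))), "differ")
})

test_that("VOE is one minus Jaccard with sane conventions", {
  a <- array(0L, c(3, 3, 1)); a[1:2, 1:2, 1] <- 1L
  b <- array(0L, c(3, 3, 1)); b[1:2, 1, 1] <- 1L
  expect_equal(voe(a, a), 0)
  expect_equal(voe(a, b), 1 - 2 / 4)
  d <- array(0L, c(3, 3, 1)); d[3, 3, 1] <- 1L
  expect_equal(voe(b, d), 1)
  expect_equal(voe(a * 0L, a * 0L), 0)
  expect_equal(voe(a, b), voe(b, a))
})

test_that("Dice per case and Dice global separate as designed", {
  # case 1: perfect 10-voxel masks; case 2: disjoint 2-voxel masks
  p1 <- array(0L, c(5, 5, 1)); p1[1:2, 1:5, 1] <- 1L
  r1 <- p1
  p2 <- array(0L, c(5, 5, 1)); p2[5, 4:5, 1] <- 1L
  r2 <- array(0L, c(5, 5, 1)); r2[1, 1:2, 1] <- 1L
  preds <- list(p1, p2); refs <- list(r1, r2)
  expect_equal(dice_per_case(preds, refs), 0.5)
  expect_equal(dice_global(preds, refs), 2 * 10 / 24)
  expect_equal(dice_per_case(list(p1), list(r1)),
               dice_global(list(p1), list(r1)))
  expect_equal(dice_per_case(refs, refs), 1)
  expect_equal(dice_global(refs, refs), 1)
})

test_that("surface distances reproduce hand-computed cases", {
  a <- array(0L, c(3, 3, 2)); a[2, 2, 1] <- 1L
  expect_equal(surface_distances(a, a, c(1, 1, 1)),
               list(assd = 0, rmsd = 0))
  # two single voxels 3 mm apart along z (spacing 1,1,3)
  b <- array(0L, c(3, 3, 2)); b[2, 2, 2] <- 1L
  sd1 <- surface_distances(a, b, c(1, 1, 3))
  expect_equal(sd1$assd, 3)
  expect_equal(sd1$rmsd, 3)
  # pooled distances {0, 0, 4}
  p <- matrix(0L, 1, 5); p[1, 1] <- 1L
  q <- matrix(0L, 1, 5); q[1, 1] <- 1L; q[1, 5] <- 1L
  sd2 <- surface_distances(p, q, c(1, 1))
  expect_equal(sd2$assd, 4 / 3, tolerance = 1e-12)
  expect_equal(sd2$rmsd, sqrt(16 / 3), tolerance = 1e-12)
  expect_warning(surface_distances(a, a * 0L), "empty")
})

test_that("surface distances match the all-pairs oracle on random masks", {
  set.seed(31)
  for (i in 1:8) {
    a <- rand_mask(c(8, 8, 3), 0.3)
    b <- rand_mask(c(8, 8, 3), 0.3)
    got <- surface_distances(a, b, c(1, 1, 2.5))
    want <- oracle_surface(a, b, c(1, 1, 2.5))
    expect_equal(got$assd, want$assd, tolerance = 1e-9)
    expect_equal(got$rmsd, want$rmsd, tolerance = 1e-9)
    # symmetry in the argument order
    rev <- surface_distances(b, a, c(1, 1, 2.5))
    expect_equal(rev$assd, got$assd, tolerance = 1e-12)
  }
})

test_that("VOE relates to Dice as 1 - D/(2 - D) on random masks", {
  set.seed(32)
  for (i in 1:20) {
    a <- rand_mask(c(6, 6, 2), 0.4)
    b <- rand_mask(c(6, 6, 2), 0.4)
    d <- dice(a, b)
    expect_equal(voe(a, b), 1 - d / (2 - d), tolerance = 1e-12)
  }
})

test_that("size stratification cuts at the configured threshold", {
  expect_equal(stratify_by_size(c(100L, 1000L), 0.2),
               c("small", "large"))
  expect_equal(stratify_by_size(c(5L, 10L, 200L), 0), rep("large", 3))
  # a count exactly at the cutoff goes to large
  expect_equal(stratify_by_size(c(200L, 1000L), 0.2)[1], "large")
  expect_equal(stratify_by_size(c(30L, 600L), 100, mode = "absolute"),
               c("small", "large"))
  expect_error(stratify_by_size(c(0L, 0L)), "empty")
})

test_that("cohort evaluation aggregates per-case rows correctly", {
  set.seed(33)
  refs <- lapply(1:4, function(i) {
    m <- array(0L, c(8, 8, 2))
    n <- c(2, 3, 10, 12)[i]
    m[seq_len(n)] <- 1L
    m
  })
  preds <- lapply(refs, function(m) m)  # perfect predictions
  rep1 <- evaluate_cohort(preds, refs, c(1, 1, 1), 0.2)
  expect_equal(nrow(rep1$per_case), 4)
  expect_equal(rep1$cohort$dice_per_case, 1)
  expect_equal(rep1$cohort$dice_global, 1)
  expect_equal(rep1$cohort$voe_mean, 0)
  expect_equal(rep1$cohort$assd_mean, 0)
  expect_equal(rep1$cohort$rmsd_mean, 0)

  # perturbed predictions: cohort means equal hand-computed column means
  preds2 <- lapply(refs, function(m) {
    p <- m; p[1] <- 1L - p[1]; p
  })
  rep2 <- evaluate_cohort(preds2, refs, c(1, 1, 1), 0.2)
  expect_equal(rep2$cohort$dice_per_case, mean(rep2$per_case$dice))
  expect_equal(rep2$cohort$voe_mean, mean(rep2$per_case$voe))
  expect_equal(rep2$cohort$dice_global,
               dice_global(preds2, refs))
  # strata are exhaustive and disjoint
  expect_equal(sum(rep2$strata$n_cases), 4)
  expect_setequal(rep2$per_case$stratum, c("small", "large"))
})

test_that("eval reports serialize to CSV", {
  refs <- list(array(c(1L, rep(0L, 7)), c(2, 2, 2)),
               array(c(1L, 1L, rep(0L, 6)), c(2, 2, 2)))
  rep1 <- evaluate_cohort(refs, refs, c(1, 1, 1))
  path <- file.path(tempdir(), "report.csv")
  write_eval_report(rep1, path)
  back <- read.csv(path)
  expect_equal(nrow(back), 3)
  expect_equal(back$dice[3], 1)
  unlink(path)
})
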