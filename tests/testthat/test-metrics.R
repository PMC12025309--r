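test_that("dice and IoU match hand counts", {
  A <- array(0, c(4, 4, 4)); B <- array(0, c(4, 4, 4))
  A[1:2, 1:2, 1:2] <- 1                      # |A| = 8
  B[2:3, 1:2, 1:2] <- 1                      # |B| = 8, overlap 4
  expect_equal(dice_score(A, B), 0.5)
  expect_equal(iou_score(A, B), 4 / 12)
  expect_equal(dice_score(A, A), 1)
  expect_equal(iou_score(A, A), 1)
  D <- array(0, c(4, 4, 4)); D[4, 4, 4] <- 1
  expect_equal(dice_score(A, D), 0)
  Z <- array(0, c(4, 4, 4))
  expect_equal(dice_score(Z, Z), 1)
  expect_equal(iou_score(Z, Z), 1)
  expect_error(dice_score(A, array(0, c(4, 4, 2))), "mismatch")
})

test_that("surface extraction matches 6-connected erosion", {
  cube <- array(0, c(5, 5, 5)); cube[2:4, 2:4, 2:4] <- 1
  expect_identical(nrow(extract_surface(cube)), 26L)   # center survives
  single <- array(0, c(3, 3, 3)); single[2, 2, 2] <- 1
  expect_identical(unname(extract_surface(single)[1, ]), c(2L, 2L, 2L))
  expect_identical(nrow(extract_surface(array(0, c(3, 3, 3)))), 0L)
  # voxels on the grid border are surface (erosion with zero padding)
  full <- array(1, c(3, 3, 3))
  expect_identical(nrow(extract_surface(full)), 26L)   # all but the center
})

test_that("surface Dice follows the tolerance-distance definition", {
  A <- array(0, c(7, 7, 7)); A[2, 2, 2] <- 1
  B <- array(0, c(7, 7, 7)); B[5, 2, 2] <- 1           # distance 3
  expect_equal(surface_dice(A, B, 1), 0)
  expect_equal(surface_dice(A, B, 3), 1)
  cube <- array(0, c(8, 8, 8)); cube[2:4, 2:4, 2:4] <- 1
  shifted <- array(0, c(8, 8, 8)); shifted[3:5, 2:4, 2:4] <- 1
  expect_equal(surface_dice(cube, shifted, 1),
               oracle_surface_dice(cube, shifted, 1))
  expect_equal(surface_dice(cube, shifted, 1), 1)
  expect_equal(surface_dice(cube, cube, 1), 1)
  expect_equal(surface_dice(array(0, c(4, 4, 4)), array(0, c(4, 4, 4)), 1), 1)
  expect_equal(surface_dice(cube, array(0, c(8, 8, 8)), 1), 0)
  expect_equal(surface_dice(cube, shifted, Inf), 1)
})

test_that("metrics agree with brute-force oracles on random pairs", {
  set.seed(11)
  for (i in 1:25) {
    A <- random_mask(c(8, 8, 8), p_empty = 0.1)
    B <- random_mask(c(8, 8, 8), p_empty = 0.1)
    expect_equal(dice_score(A, B), oracle_dice(A, B), tolerance = 1e-12)
    expect_equal(iou_score(A, B), oracle_iou(A, B), tolerance = 1e-12)
    expect_equal(surface_dice(A, B, 1), oracle_surface_dice(A, B, 1),
                 tolerance = 1e-12)
    # symmetry and the DSC/IoU identity
    expect_equal(dice_score(A, B), dice_score(B, A))
    expect_equal(surface_dice(A, B, 1.5), surface_dice(B, A, 1.5))
    expect_equal(dice_score(A, B),
                 2 * iou_score(A, B) / (1 + iou_score(A, B)),
                 tolerance = 1e-12)
  }
})

test_that("growing the intersection never decreases DSC or IoU", {
  set.seed(12)
  A <- array(0, c(6, 6, 6)); A[2:5, 2:5, 2:5] <- 1
  B <- array(0, c(6, 6, 6)); B[1:4, 1:4, 1:4] <- 1
  base_d <- dice_score(A, B); base_i <- iou_score(A, B)
  # move one B-only voxel onto an A-only voxel: |A|,|B| fixed, overlap +1
  bonly <- which(B == 1 & A == 0); aonly <- which(A == 1 & B == 0)
  B2 <- B; B2[bonly[1]] <- 0; B2[aonly[1]] <- 1
  expect_gte(dice_score(A, B2), base_d)
  expect_gte(iou_score(A, B2), base_i)
})

test_that("fold summaries use the population-std convention", {
  s <- summarize_folds(c(0.854, 0.815, 0.841, 0.832, 0.849, 0.835))
  expect_equal(round(s$mean, 3), 0.838)
  expect_equal(round(s$std, 3), 0.013)
  expect_equal(summarize_folds(c(0.5, 0.5, 0.5))$std, 0)
  s01 <- summarize_folds(c(0, 1))
  expect_equal(s01$mean, 0.5)
  expect_equal(s01$std, 0.5)
  expect_error(summarize_folds(0.5), "at least 2")
})

test_that("exact Wilcoxon signed-rank matches enumeration and wilcox.test", {
  r0 <- wilcoxon_compare(c(1, 2, 3, 4, 5, 6), c(1, 2, 3, 4, 5, 6))
  expect_equal(r0$p_raw, 1)
  a <- c(0.85, 0.82, 0.84, 0.83, 0.85, 0.84)
  b <- a - c(0.02, 0.01, 0.04, 0.03, 0.02, 0.01)
  r <- wilcoxon_compare(a, b)
  expect_equal(r$p_raw, 2 / 64)
  expect_equal(r$statistic, 21)
  r1 <- wilcoxon_compare(a, b, sided = "one")
  expect_equal(r1$p_raw, 1 / 64)
  # Bonferroni arithmetic
  r5 <- wilcoxon_compare(a, b, m = 5)
  expect_equal(r5$p_adjusted, min(1, 5 * r5$p_raw))
  expect_equal(wilcoxon_compare(a, b, m = 40)$p_adjusted, 1)
  # agreement with the exact base-R test on tie-free data
  set.seed(13)
  for (i in 1:10) {
    x <- rnorm(8); y <- rnorm(8)
    ours <- wilcoxon_compare(x, y)$p_raw
    ref <- wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value
    expect_equal(ours, ref, tolerance = 1e-12)
  }
  expect_error(wilcoxon_compare(1:4, 2:5), "at least 5")
  expect_error(wilcoxon_compare(1:6, 1:5), "equal length")
})

test_that("benchmark summary rows reproduce the published values", {
  sm <- fold_summary_table(benchmark_fold_table())
  pick <- function(mo, me, col)
    sm[sm$model == mo & sm$metric == me, col]
  # agreement to the printed 3-decimal precision (half an ulp of print)
  expect_lt(abs(pick("swindaf3d", "dsc", "mean") - 0.838), 5.01e-4)
  expect_lt(abs(pick("swindaf3d", "dsc", "std") - 0.013), 5.01e-4)
  expect_lt(abs(pick("unet3d", "dsc", "std") - 0.025), 5.01e-4)
  expect_lt(abs(pick("unet3d", "sdsc", "mean") - 0.661), 5.01e-4)
})
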