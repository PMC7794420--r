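test_that("voxel classification follows the two-threshold rule", {
  th <- prm_thresholds()
  # the three canonical quadrants
  expect_identical(classify_voxel(-970, -900, th), 64L)
  expect_identical(classify_voxel(-940, -900, th), 32L)
  expect_identical(classify_voxel(-940, -800, th), 8L)
  # both cuts are inclusive
  expect_identical(classify_voxel(-950, -856, th), 64L)
  expect_identical(classify_voxel(-950 + 1e-9, -856, th), 32L)
  expect_identical(classify_voxel(-950, -856 + 1e-9, th), 8L)
  # low-inspiratory / high-expiratory quadrant folds into normal
  expect_identical(classify_voxel(-970, -800, th), 8L)
  expect_error(classify_voxel(NaN, -900, th), "finite")
  expect_error(classify_voxel(-900, Inf, th), "finite")
  expect_error(prm_thresholds(-856, -950), "below")
})

test_that("volume classification equals a voxel-by-voxel loop", {
  set.seed(42)
  for (rep in 1:3) {
    pair <- random_pair(8L)
    prm <- classify_volume(pair)
    m <- pair$mask$voxels
    oracle <- array(0L, dim(m))
    for (i in which(m))
      oracle[i] <- classify_voxel(pair$insp$voxels[i], pair$exp_reg$voxels[i])
    expect_identical(prm$codes, oracle)
    expect_true(all(prm$codes[!m] == 0))
    expect_true(all(prm$codes %in% c(0L, 8L, 32L, 64L)))
  }
})

test_that("hand-built 3x3x3 pair quantifies by exact counting", {
  n <- 3L
  hu_in <- array(-870, c(n, n, n)); hu_ex <- array(-780, c(n, n, n))
  hu_in[1:5] <- -970; hu_ex[1:5] <- -900       # 5 emphysema voxels
  hu_in[6:9] <- -940; hu_ex[6:9] <- -900       # 4 fSAD voxels
  # as_volume: the lenient container (grids smaller than a CT volume)
  pair <- paired_scan(as_volume(hu_in, c(10, 10, 10)),
                      as_volume(hu_ex, c(10, 10, 10)),
                      lung_mask(array(TRUE, c(n, n, n)), c(10, 10, 10)))
  qs <- prm_summary(classify_volume(pair), pair)
  expect_equal(round(qs$emph_pct, 2), 18.52)    # 5/27
  expect_equal(round(qs$fsad_pct, 2), 14.81)    # 4/27
  expect_equal(round(qs$normal_pct, 2), 66.67)  # 18/27
  expect_identical(qs$emph_pct + qs$fsad_pct + qs$normal_pct, 100)
})

test_that("percentages always sum to exactly 100 over the mask", {
  set.seed(7)
  for (rep in 1:5) {
    pair <- random_pair(8L)
    qs <- prm_summary(classify_volume(pair), pair)
    expect_identical(qs$emph_pct + qs$fsad_pct + qs$normal_pct, 100)
  }
})

test_that("threshold monotonicity holds", {
  set.seed(8)
  pair <- random_pair(10L)
  emph_at <- function(cut) prm_summary(
    classify_volume(pair, prm_thresholds(insp_cut = cut)), pair)$emph_pct
  cuts <- c(-990, -970, -950, -930, -910)
  expect_true(all(diff(vapply(cuts, emph_at, 0)) >= 0))
  trapped_at <- function(cut) {
    qs <- prm_summary(classify_volume(pair, prm_thresholds(exp_cut = cut)),
                      pair)
    qs$emph_pct + qs$fsad_pct
  }
  expect_true(all(diff(vapply(c(-900, -880, -856, -830, -800),
                              trapped_at, 0)) >= 0))
})

test_that("summary is invariant to a shared spatial permutation", {
  set.seed(9)
  pair <- random_pair(8L)
  perm <- sample(8^3)
  shuffle <- function(a) array(a[perm], dim(a))
  pair2 <- paired_scan(
    ct_volume(shuffle(pair$insp$voxels)),
    ct_volume(shuffle(pair$exp_reg$voxels)),
    lung_mask(shuffle(pair$mask$voxels)))
  q1 <- prm_summary(classify_volume(pair), pair)
  q2 <- prm_summary(classify_volume(pair2), pair2)
  expect_equal(unclass(q1), unclass(q2))
})

test_that("air volumes integrate the linear air-fraction model", {
  pair <- tiny_pair(8L, hu_in = -789, hu_ex = -472.5, spacing = c(2, 2, 2))
  qs <- prm_summary(classify_volume(pair), pair)
  # beta(-789) = 0.8, beta(-472.5) = 0.5; 512 voxels of 8 mm^3
  expect_equal(qs$tlc_l, 512 * 8 * 0.8 / 1e6, tolerance = 1e-12)
  expect_equal(qs$frc_l, 512 * 8 * 0.5 / 1e6, tolerance = 1e-12)
  expect_gt(qs$tlc_l, qs$frc_l)
})

test_that("degenerate masks are rejected", {
  expect_error(lung_mask(array(FALSE, c(4, 4, 4))), "empty")
  pair <- tiny_pair(8L)
  pair$mask$voxels[] <- FALSE
  expect_error(classify_volume(pair), "empty")
})
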