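test_that("group draws honour the calibrated means (sd forced to zero)", {
  p0 <- phantom_params(groups = list(
    COPD = list(emph = c(8.5, 0), fsad = c(23.7, 0), j = c(1.5, 0)),
    `non-COPD` = list(emph = c(1.7, 0), fsad = c(11.2, 0), j = c(1.7, 0))))
  tn <- sample_subject("non-COPD", p0)
  expect_equal(tn$emph_pct, 1.7)
  expect_equal(tn$fsad_pct, 11.2)
  tc <- sample_subject("COPD", p0)
  expect_equal(tc$fsad_pct, 23.7)
  expect_equal(tc$mean_j, 1.5)
  expect_error(sample_subject("asthma", p0), "unknown group")
})

test_that("calibrated truncated normals match the target mean exactly", {
  for (tgt in list(c(8.5, 7.5), c(23.7, 13.6), c(11.2, 13.4))) {
    cal <- calibrate_truncnorm(tgt[1], tgt[2], 0, 60)
    expect_equal(unname(cal$realized["mean"]), tgt[1], tolerance = 1e-6)
  }
  # feasible coefficient of variation: sd matches too
  cal <- calibrate_truncnorm(23.7, 13.6, 0, 60)
  expect_equal(unname(cal$realized["sd"]), 13.6, tolerance = 1e-4)
  # draws reproduce the calibrated moments
  set.seed(1)
  x <- prm3d:::rtrunc(4e4, cal, 0, 60)
  expect_true(all(x >= 0 & x <= 60))
  expect_equal(mean(x), 23.7, tolerance = 0.2)
})

test_that("subject draws are reproducible and seeds matter", {
  p <- fast_params()
  set.seed(33); t1 <- sample_subject("COPD", p)
  set.seed(33); t2 <- sample_subject("COPD", p)
  expect_identical(t1, t2)
  co1 <- generate_cohort(1, 1, p, seed = 5, with_field = FALSE)
  co2 <- generate_cohort(1, 1, p, seed = 5, with_field = FALSE)
  expect_identical(co1$manifest, co2$manifest)
  expect_identical(co1$subjects[[1]]$pair$insp$voxels,
                   co2$subjects[[1]]$pair$insp$voxels)
  expect_setequal(co1$manifest$group, c("COPD", "non-COPD"))
  co3 <- generate_cohort(1, 1, p, seed = 6, with_field = FALSE)
  expect_false(identical(co1$manifest$emph_pct, co3$manifest$emph_pct))
})

test_that("planted burdens are recovered by PRM within quantization noise", {
  p <- phantom_params()
  truth <- structure(list(group = "COPD", emph_pct = 10, fsad_pct = 20,
                          mean_j = 1.5, lesion_centroids = NULL),
                     class = "subject_truth")
  set.seed(10)
  s <- generate_paired_scan(truth, p, with_field = FALSE)
  qs <- prm_summary(classify_volume(s$pair), s$pair)
  expect_lt(abs(qs$emph_pct - 10), 1.5)
  expect_lt(abs(qs$fsad_pct - 20), 1.5)
  # nothing planted -> nothing measured beyond the attenuation tails
  truth0 <- structure(list(group = "non-COPD", emph_pct = 0, fsad_pct = 0,
                           mean_j = 1.6, lesion_centroids = NULL),
                      class = "subject_truth")
  s0 <- generate_paired_scan(truth0, p, with_field = FALSE)
  q0 <- prm_summary(classify_volume(s0$pair), s0$pair)
  expect_lt(q0$emph_pct, 0.5)
  expect_lt(q0$fsad_pct, 0.5)
})

test_that("lesion burdens beyond the mask capacity are refused", {
  p <- phantom_params()
  truth <- structure(list(group = "COPD", emph_pct = 55, fsad_pct = 42,
                          mean_j = 1.2, lesion_centroids = NULL),
                     class = "subject_truth")
  expect_error(generate_paired_scan(truth, p, with_field = FALSE),
               "capacity")
})

test_that("the displacement field hits the target median Jacobian", {
  p <- phantom_params()
  truth <- structure(list(group = "COPD", emph_pct = 8, fsad_pct = 20,
                          mean_j = 1.5, lesion_centroids = NULL),
                     class = "subject_truth")
  set.seed(11)
  s <- generate_paired_scan(truth, p)
  m <- s$pair$mask$voxels
  # package route
  J <- jacobian_map(deformation_gradient(s$field))
  expect_lt(abs(median(J[m]) - 1.5), 0.05)
  # independent finite-difference oracle at sampled interior voxels
  set.seed(12)
  idx <- which(m, arr.ind = TRUE)
  idx <- idx[idx[, 1] > 1 & idx[, 1] < 64 & idx[, 2] > 1 & idx[, 2] < 64 &
               idx[, 3] > 1 & idx[, 3] < 64, ]
  idx <- idx[sample(nrow(idx), 400), ]
  u <- s$field$vectors; h <- s$field$spacing
  jo <- apply(idx, 1, function(v) {
    Fm <- diag(3)
    for (i in 1:3) for (j in 1:3) {
      e <- c(0L, 0L, 0L); e[j] <- 1L
      up <- u[v[1] + e[1], v[2] + e[2], v[3] + e[3], i]
      um <- u[v[1] - e[1], v[2] - e[2], v[3] - e[3], i]
      Fm[i, j] <- Fm[i, j] + (up - um) / (2 * h[j])
    }
    det(Fm)
  })
  expect_lt(abs(median(jo) - 1.5), 0.06)
  # lesions reduce local expansion (air trapping)
  lesion <- array(FALSE, dim(m))
  cen <- s$truth$lesion_centroids
  lesion[cen[, 1:3]] <- TRUE
  expect_lt(mean(J[lesion]), mean(J[m & !lesion]))
})

test_that("upper-third bias places COPD lesions high in the lung", {
  p <- phantom_params(upper_bias = c(COPD = Inf, `non-COPD` = 1))
  truth <- structure(list(group = "COPD", emph_pct = 8, fsad_pct = 15,
                          mean_j = 1.5, lesion_centroids = NULL),
                     class = "subject_truth")
  set.seed(13)
  s <- generate_paired_scan(truth, p, with_field = FALSE)
  m <- s$pair$mask$voxels
  zr <- range(slice.index(m, 3)[m])
  cut <- zr[1] + 2 / 3 * diff(zr)
  expect_true(all(s$truth$lesion_centroids[, 3] >= cut))
})

test_that("cohort generation writes a complete manifest and files", {
  d <- withr::local_tempdir()
  p <- fast_params()
  co <- generate_cohort(2, 1, p, seed = 3, with_field = TRUE, dir = d)
  expect_equal(nrow(co$manifest), 3L)
  expect_true(all(file.exists(co$manifest$insp)))
  expect_true(all(file.exists(co$manifest$field)))
  expect_true(file.exists(file.path(d, "manifest.csv")))
  back <- read_volume(co$manifest$insp[1])
  expect_equal(back$voxels, round(co$subjects[[1]]$pair$insp$voxels),
               tolerance = 1e-9)
})
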