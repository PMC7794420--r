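test_that("NIfTI volumes round-trip bit-exactly with geometry", {
  vol <- ct_volume(array(-900, c(16, 16, 16)), spacing = c(0.6, 0.6, 1.0),
                   origin = c(-100, -80.5, 40))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(vol, f)
  back <- read_volume(f)
  expect_identical(as.numeric(back$voxels), as.numeric(vol$voxels))
  expect_equal(back$spacing, c(0.6, 0.6, 1.0), tolerance = 1e-6)
  expect_equal(back$origin, c(-100, -80.5, 40), tolerance = 1e-6)
})

test_that("PRM label maps round-trip losslessly as unsigned 8-bit", {
  set.seed(1)
  codes <- array(sample(c(0L, 8L, 32L, 64L), 16^3, TRUE), c(16, 16, 16))
  for (ext in c(".nii.gz", ".mha")) {
    f <- withr::local_tempfile(fileext = ext)
    write_volume(as_volume(codes), f)
    back <- read_volume(f)
    expect_identical(as.integer(back$voxels), as.integer(codes))
    expect_setequal(unique(as.vector(back$voxels)), c(0, 8, 32, 64))
  }
})

test_that("float heatmaps round-trip within single precision", {
  set.seed(2)
  hm <- array(runif(32^3), c(32, 32, 32))
  for (ext in c(".nii", ".mha", ".mhd")) {
    f <- withr::local_tempfile(fileext = ext)
    write_volume(as_volume(hm), f, datatype = "float")
    expect_lt(max(abs(read_volume(f)$voxels - hm)), 1e-6)
  }
})

test_that("MetaImage .mhd writes a companion raster and reads back", {
  d <- withr::local_tempdir()
  f <- file.path(d, "vol.mhd")
  vol <- ct_volume(array(round(rnorm(10^3, -800, 50)), c(10, 10, 10)),
                   spacing = c(1.2, 1.2, 2.5))
  write_volume(vol, f, datatype = "int16")
  expect_true(file.exists(file.path(d, "vol.raw")))
  back <- read_volume(f)
  expect_identical(as.numeric(back$voxels), as.numeric(vol$voxels))
  expect_equal(back$spacing, vol$spacing)
})

test_that("dimensionality and format contracts are enforced", {
  f4 <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(5, 5, 5, 3))), f4)
  expect_error(read_volume(f4), "3D")
  expect_error(read_volume(withr::local_tempfile(fileext = ".txt")),
               "unsupported|not found")
  expect_error(read_field(f4), NA)  # 3-component 4D is a valid field
  f5 <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(5, 5, 5, 4))), f5)
  expect_error(read_field(f5), "3 components")
  suppressWarnings(
    expect_error(write_volume(as_volume(array(0, c(8, 8, 8))),
                              file.path(tempdir(), "no_such_dir", "x.nii.gz")),
                 "failed to write"))
})

test_that("displacement fields round-trip and keep the mapping convention", {
  zero <- displacement_field(array(0, c(8, 8, 8, 3)), spacing = c(2, 2, 2))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_field(zero, f)
  back <- read_field(f)
  expect_true(all(back$vectors == 0))
  expect_identical(back$reference, "expiration")

  u <- array(0, c(8, 8, 8, 3))
  u[, , , 1] <- 1; u[, , , 2] <- 2; u[, , , 3] <- 3
  write_field(displacement_field(u), f)
  expect_equal(read_field(f)$vectors, u, tolerance = 1e-7)
})

test_that("run configuration validates keys and study defaults", {
  cfg <- read_run_config()
  expect_equal(cfg$prm$insp_cut, -950)
  expect_equal(cfg$prm$exp_cut, -856)
  expect_equal(cfg$train$folds, 5L)
  expect_equal(cfg$train$lr, 1e-4)

  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("prm:\n  insp_cut: -800\n  exp_cut: -856", f)
  expect_error(read_run_config(f), "insp_cut")
  writeLines("nonsense: 1", f)
  expect_error(read_run_config(f), "unknown config")
  writeLines("train:\n  iterations: 10\n  batch: 4", f)
  expect_equal(read_run_config(f)$train$iterations, 10)
})
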