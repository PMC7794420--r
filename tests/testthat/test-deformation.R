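test_that("zero field gives the identity deformation gradient", {
  Fg <- deformation_gradient(
    displacement_field(array(0, c(8, 8, 8, 3)), spacing = c(2, 1, 0.5)))
  for (i in 1:3) for (j in 1:3)
    expect_true(all(Fg$F[, , , i, j] == (i == j)))
  expect_true(all(jacobian_map(Fg) == 1))
})

test_that("affine fields reproduce closed forms everywhere, faces included", {
  A <- diag(c(1.2, 1.1, 1.0))
  Fg <- deformation_gradient(affine_field(A))
  for (i in 1:3) for (j in 1:3)
    expect_equal(max(abs(Fg$F[, , , i, j] - A[i, j])), 0, tolerance = 1e-12)
  expect_equal(range(jacobian_map(Fg)), c(1.32, 1.32), tolerance = 1e-12)
  # uniform scaling: J = s^3
  Fs <- deformation_gradient(affine_field(diag(rep(1.2, 3))))
  expect_equal(range(jacobian_map(Fs)), rep(1.2^3, 2), tolerance = 1e-12)
})

test_that("central differences converge at second order on a smooth field", {
  exact_grad <- function(x, y, z) 0.3 * cos(x) * sin(0.5 * y)  # du1/dx
  make_field <- function(n) {
    h <- 2 * pi / n
    ax <- (seq_len(n) - 1) * h
    X <- array(ax, c(n, n, n))
    Y <- array(rep(ax, each = n), c(n, n, n))
    u <- array(0, c(n, n, n, 3))
    u[, , , 1] <- 0.3 * sin(X) * sin(0.5 * Y)
    displacement_field(u, spacing = c(h, h, h))
  }
  err <- vapply(c(16L, 32L), function(n) {
    h <- 2 * pi / n
    ax <- (seq_len(n) - 1) * h
    Fg <- deformation_gradient(make_field(n))
    interior <- 2:(n - 1)
    truth <- outer(0.3 * cos(ax[interior]),
                   sin(0.5 * ax[interior]))  # du1/dx over (x, y)
    got <- Fg$F[interior, interior, 5, 1, 1] - 1
    max(abs(got - truth))
  }, 0)
  expect_gt(err[1] / err[2], 3)  # halving h cuts the error ~4x
})

test_that("principal stretches match the SVD oracle and sort correctly", {
  F0 <- diag(c(1.5, 1.2, 0.9))
  lam <- principal_stretches(deformation_gradient(affine_field(F0)))
  expect_equal(lam$lam1[3, 3, 3], 1.5, tolerance = 1e-9)
  expect_equal(lam$lam2[3, 3, 3], 1.2, tolerance = 1e-9)
  expect_equal(lam$lam3[3, 3, 3], 0.9, tolerance = 1e-9)
  set.seed(5)
  for (rep in 1:10) {
    A <- diag(3) + matrix(rnorm(9, 0, 0.15), 3)
    if (det(A) <= 0.1) next
    lam <- principal_stretches(deformation_gradient(affine_field(A, n = 6L)))
    sv <- svd(A)$d
    expect_equal(c(lam$lam1[3, 3, 3], lam$lam2[3, 3, 3], lam$lam3[3, 3, 3]),
                 sv, tolerance = 1e-8)
  }
})

test_that("J, ADI and SRI are invariant to rigid rotation", {
  set.seed(6)
  S <- diag(c(1.4, 1.15, 0.95))
  base <- deformation_gradient(affine_field(S, n = 6L))
  lam0 <- principal_stretches(base)
  pick <- function(x) x[3, 3, 3]
  for (rep in 1:5) {
    R <- random_rotation()
    Fg <- deformation_gradient(affine_field(R %*% S, n = 6L))
    lam <- principal_stretches(Fg)
    expect_equal(pick(jacobian_map(Fg)), pick(jacobian_map(base)),
                 tolerance = 1e-8)
    expect_equal(pick(adi(lam$lam1, lam$lam2, lam$lam3)),
                 pick(adi(lam0$lam1, lam0$lam2, lam0$lam3)),
                 tolerance = 1e-7)
    expect_equal(pick(sri(lam$lam1, lam$lam2, lam$lam3)),
                 pick(sri(lam0$lam1, lam0$lam2, lam0$lam3)),
                 tolerance = 1e-7)
  }
})

test_that("ADI and SRI evaluate their closed forms", {
  expect_equal(adi(1.3, 1.3, 1.3), 0)
  expect_equal(adi(1.5, 1.0, 1.0), 0.5)
  expect_equal(sri(1.2, 1.2, 0.8), 0)         # slab-like
  expect_equal(sri(1.5, 1.0, 1.0), 1)         # rod-like
  expect_equal(adi(2, 1.6, 1.2),
               sqrt((0.4 / 1.6)^2 + (0.4 / 1.2)^2), tolerance = 1e-12)
  expect_equal(sri(2, 1.6, 1.2),
               (2 / pi) * atan2(1.6 * 0.4, 1.2 * 0.4), tolerance = 1e-12)
  expect_error(adi(1.5, 1.2, -0.1), "positive")
  expect_error(sri(1.0, 1.2, 0.9), "ordered")
})

test_that("air fraction is the clamped linear attenuation mixture", {
  expect_equal(air_fraction(-1000), 1)
  expect_equal(air_fraction(55), 0)
  expect_equal(air_fraction(-472.5), 0.5)
  expect_equal(air_fraction(c(-1100, 100)), c(1, 0))  # clamped
  expect_error(air_fraction(NA), "finite")
})

test_that("air-volume change combines J and the two air fractions", {
  n <- 12L
  pair0 <- tiny_pair(n, hu_in = -800, hu_ex = -800)
  zero <- displacement_field(array(0, c(n, n, n, 3)))
  expect_true(all(abs(delta_vair_f(pair0, zero)) < 1e-12))
  # beta_ex = 0.5, beta_in = 0.8, uniform J = 1.5 -> 1.5*0.8 - 0.5 = 0.7
  pair <- tiny_pair(n, hu_in = -789, hu_ex = -472.5, spacing = c(1, 1, 1))
  s <- 1.5^(1 / 3)
  fld <- affine_field(diag(rep(s, 3)), n = n, spacing = c(1, 1, 1))
  dv <- delta_vair_f(pair, fld)
  expect_equal(max(abs(dv - 0.7)), 0, tolerance = 1e-9)
})

test_that("functional maps carry plausible per-subject medians on phantoms", {
  set.seed(21)
  p <- phantom_params()
  s <- generate_paired_scan(sample_subject("COPD", p), p)
  fm <- functional_maps(s$pair, s$field)
  m <- s$pair$mask$voxels
  expect_true(all(fm$j_map[m] > 0))
  expect_true(all(fm$adi_map[m] >= 0, na.rm = TRUE))
  expect_true(all(fm$sri_map[m] >= 0 & fm$sri_map[m] <= 1, na.rm = TRUE))
  expect_equal(unname(fm$scalars["j"]), s$truth$mean_j, tolerance = 0.01)
  # IN is more aerated than EX and J > 1, so air volume rises on average
  expect_gt(mean(fm$dvair_map[m]), 0)
})
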