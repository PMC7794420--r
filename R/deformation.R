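# Registration-derived functional variables: deformation gradient F = I + grad(u),
# Jacobian determinant J, principal stretches, anisotropic deformation index
# (ADI), slab-rod index (SRI) and air-volume change. All maps live on the
# expiration reference grid (the field maps EX -> IN, so J > 1 means local
# expansion toward inspiration).

# Partial derivative of a 3D array along one axis in physical units (mm):
# central differences in the interior, second-order one-sided at the faces.
diff_axis <- function(a, axis, h) {
  d <- dim(a)
  n <- d[axis]
  if (n < 3L) stop("need at least 3 voxels along axis ", axis, call. = FALSE)
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(a, perm), nrow = n)
  out <- m
  out[2:(n - 1L), ] <- (m[3:n, ] - m[1:(n - 2L), ]) / 2
  out[1L, ] <- (-3 * m[1L, ] + 4 * m[2L, ] - m[3L, ]) / 2
  out[n, ]  <- (3 * m[n, ] - 4 * m[n - 1L, ] + m[n - 2L, ]) / 2
  aperm(array(out, d[perm]), order(perm)) / h
}

#' Deformation gradient F = I + grad(u) of a displacement field
#'
#' Derivatives are taken in physical units (mm) by central differences, with
#' second-order one-sided stencils at the grid faces (exact for affine
#' fields everywhere, including faces).
#'
#' @param field a [displacement_field()].
#' @return object of class `deformation_gradient`: a 5D array
#'   (nx, ny, nz, 3, 3) where `[,,,i,j]` holds dphi_i/dx_j, plus geometry.
#' @export
deformation_gradient <- function(field) {
  stopifnot(inherits(field, "displacement_field"))
  if (any(field$spacing <= 0) || any(!is.finite(field$spacing)))
    stop("degenerate spacing", call. = FALSE)
  d <- dim(field$vectors)[1:3]
  if (any(d < 3L)) stop("need at least 3 voxels per axis", call. = FALSE)
  F <- array(field_gradient_cpp(as.vector(field$vectors), d, field$spacing),
             c(d, 3, 3))
  structure(list(F = F, spacing = field$spacing, origin = field$origin),
            class = "deformation_gradient")
}

f_component <- function(Fg, i, j) Fg$F[, , , i, j]

#' Jacobian determinant map det(F)
#'
#' @param Fg a [deformation_gradient()].
#' @return 3D array of per-voxel determinants (J > 1: local expansion).
#' @export
jacobian_map <- function(Fg) {
  stopifnot(inherits(Fg, "deformation_gradient"))
  F <- Fg$F
  F[, , , 1, 1] * (F[, , , 2, 2] * F[, , , 3, 3] - F[, , , 2, 3] * F[, , , 3, 2]) -
  F[, , , 1, 2] * (F[, , , 2, 1] * F[, , , 3, 3] - F[, , , 2, 3] * F[, , , 3, 1]) +
  F[, , , 1, 3] * (F[, , , 2, 1] * F[, , , 3, 2] - F[, , , 2, 2] * F[, , , 3, 1])
}

#' Principal stretches (sorted square roots of eigenvalues of F'F)
#'
#' Uses the closed-form trigonometric eigenvalue solution for symmetric 3x3
#' matrices, vectorised over voxels. Voxels where F'F is not positive
#' definite are flagged `NA` (attribute `n_degenerate` counts them).
#'
#' @param Fg a [deformation_gradient()].
#' @return list of 3D arrays `lam1 >= lam2 >= lam3` (> 0 where valid).
#' @export
principal_stretches <- function(Fg) {
  stopifnot(inherits(Fg, "deformation_gradient"))
  F <- Fg$F
  # C = F'F, symmetric: entries c11, c22, c33, c12, c13, c23
  col <- function(j) list(F[, , , 1, j], F[, , , 2, j], F[, , , 3, j])
  f1 <- col(1); f2 <- col(2); f3 <- col(3)
  dot <- function(a, b) a[[1]] * b[[1]] + a[[2]] * b[[2]] + a[[3]] * b[[3]]
  c11 <- dot(f1, f1); c22 <- dot(f2, f2); c33 <- dot(f3, f3)
  c12 <- dot(f1, f2); c13 <- dot(f1, f3); c23 <- dot(f2, f3)
  q <- (c11 + c22 + c33) / 3
  p2 <- (c11 - q)^2 + (c22 - q)^2 + (c33 - q)^2 + 2 * (c12^2 + c13^2 + c23^2)
  p <- sqrt(pmax(p2, 0) / 6)
  iso <- p < 1e-14
  ps <- ifelse(iso, 1, p)  # avoid 0/0; isotropic handled below
  b11 <- (c11 - q) / ps; b22 <- (c22 - q) / ps; b33 <- (c33 - q) / ps
  b12 <- c12 / ps; b13 <- c13 / ps; b23 <- c23 / ps
  detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
    b13 * (b12 * b23 - b22 * b13)
  r <- pmin(pmax(detB / 2, -1), 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  e1[iso] <- q[iso]; e2[iso] <- q[iso]; e3[iso] <- q[iso]
  bad <- e3 <= 0
  n_bad <- sum(bad)
  if (n_bad > 0) {
    prm3d_log("principal_stretches: %d voxels with non-PD F'F flagged NA",
              n_bad)
    e1[bad] <- NA_real_; e2[bad] <- NA_real_; e3[bad] <- NA_real_
  }
  out <- list(lam1 = sqrt(e1), lam2 = sqrt(e2), lam3 = sqrt(e3))
  attr(out, "n_degenerate") <- n_bad
  out
}

#' Anisotropic deformation index
#'
#' `ADI = sqrt(((lam1 - lam2)/lam2)^2 + ((lam2 - lam3)/lam3)^2)`: zero for
#' isotropic deformation, growing with directional preference.
#'
#' @param lam1,lam2,lam3 principal stretches with `lam1 >= lam2 >= lam3 > 0`
#'   (arrays or scalars), e.g. from [principal_stretches()].
#' @return array/scalar of ADI values (>= 0).
#' @export
adi <- function(lam1, lam2, lam3) {
  check_stretches(lam1, lam2, lam3)
  sqrt(((lam1 - lam2) / lam2)^2 + ((lam2 - lam3) / lam3)^2)
}

#' Slab-rod index
#'
#' `SRI = (2/pi) * atan2(lam2 * (lam1 - lam2), lam3 * (lam2 - lam3))`,
#' clamped to \[0, 1\]: 0 for slab-like deformation (lam1 = lam2 > lam3),
#' 1 for rod-like (lam1 > lam2 = lam3).
#'
#' @inheritParams adi
#' @return array/scalar of SRI values in \[0, 1\].
#' @export
sri <- function(lam1, lam2, lam3) {
  check_stretches(lam1, lam2, lam3)
  val <- (2 / pi) * atan2(lam2 * (lam1 - lam2), lam3 * (lam2 - lam3))
  pmin(pmax(val, 0), 1)
}

check_stretches <- function(lam1, lam2, lam3) {
  ok <- stats::complete.cases(cbind(as.vector(lam3)))
  if (any(as.vector(lam3)[ok] <= 0))
    stop("principal stretches must be positive (lam3 <= 0)", call. = FALSE)
  tol <- 1e-9
  if (any(as.vector(lam1)[ok] < as.vector(lam2)[ok] - tol) ||
      any(as.vector(lam2)[ok] < as.vector(lam3)[ok] - tol))
    stop("principal stretches must be ordered lam1 >= lam2 >= lam3",
         call. = FALSE)
  invisible(TRUE)
}

#' Air fraction of a voxel from its attenuation
#'
#' Linear mixture model on the attenuation scale between pure tissue
#' (55 HU, fraction 0) and pure air (-1000 HU, fraction 1), clamped to
#' \[0, 1\].
#'
#' @param hu attenuation in HU (vectorised).
#' @return air fraction in \[0, 1\].
#' @export
air_fraction <- function(hu) {
  if (anyNA(hu) || any(!is.finite(hu)))
    stop("non-finite attenuation value", call. = FALSE)
  pmin(pmax((55 - hu) / (55 - (-1000)), 0), 1)
}

#' Per-voxel air-volume change between breath holds
#'
#' On each expiration-grid voxel x: `J(x) * beta_in(x + u(x)) - beta_ex(x)`,
#' where beta is the air fraction and the inspiratory air fraction is
#' evaluated at the corresponding inspiration-space location by trilinear
#' interpolation (out-of-grid correspondences clamp to the nearest edge and
#' are counted in attribute `n_clamped`).
#'
#' @param pair a [paired_scan()].
#' @param field the [displacement_field()] (EX -> IN).
#' @param Fg optional precomputed [deformation_gradient()].
#' @return 3D array of air-volume change per voxel volume.
#' @export
delta_vair_f <- function(pair, field, Fg = NULL) {
  stopifnot(inherits(pair, "paired_scan"), inherits(field, "displacement_field"))
  if (!same_geometry(pair$insp, field))
    stop("pair and field do not share geometry", call. = FALSE)
  if (is.null(Fg)) Fg <- deformation_gradient(field)
  J <- jacobian_map(Fg)
  d <- dim(field$vectors)[1:3]
  beta_in <- air_fraction(pair$insp$voxels)
  beta_ex <- air_fraction(pair$exp_reg$voxels)
  # continuous voxel coordinates of x + u(x) on the inspiration grid
  ax <- lapply(1:3, function(k) {
    (seq_len(d[k]) - 1) + 0  # 0-based index coordinate
  })
  coord <- array(0, c(d, 3))
  coord[, , , 1] <- ax[[1]]
  coord[, , , 2] <- rep(ax[[2]], each = d[1])
  coord[, , , 3] <- rep(ax[[3]], each = d[1] * d[2])
  for (k in 1:3)
    coord[, , , k] <- coord[, , , k] + field$vectors[, , , k] / field$spacing[k]
  res <- interp3(beta_in, coord[, , , 1], coord[, , , 2], coord[, , , 3])
  if (attr(res, "n_clamped") > 0)
    prm3d_log("delta_vair_f: %d correspondences clamped to grid edge",
              attr(res, "n_clamped"))
  out <- J * res$value - beta_ex
  attr(out, "n_clamped") <- attr(res, "n_clamped")
  out
}

# Trilinear interpolation of a 3D array at 0-based continuous voxel
# coordinates; coordinates outside the grid clamp to the nearest edge.
interp3 <- function(a, x, y, z) {
  res <- interp3_cpp(as.vector(a), dim(a), as.vector(x), as.vector(y),
                     as.vector(z))
  out <- list(value = res$value)
  attr(out, "n_clamped") <- res$n_clamped
  out
}

#' All functional maps and per-subject scalars for one subject
#'
#' Computes the Jacobian, ADI, SRI and air-volume-change maps from a
#' displacement field and paired scan, plus the per-subject scalars
#' (voxel-median over the lung mask, robust to lesion outliers).
#'
#' @param pair a [paired_scan()].
#' @param field a [displacement_field()] on the same grid.
#' @return object of class `functional_maps`: list with 3D arrays `j_map`,
#'   `adi_map`, `sri_map`, `dvair_map` and a named numeric `scalars`
#'   (`j`, `adi`, `sri`, `dvair`).
#' @export
functional_maps <- function(pair, field) {
  Fg <- deformation_gradient(field)
  j_map <- jacobian_map(Fg)
  lam <- principal_stretches(Fg)
  adi_map <- adi(lam$lam1, lam$lam2, lam$lam3)
  sri_map <- sri(lam$lam1, lam$lam2, lam$lam3)
  dvair_map <- delta_vair_f(pair, field, Fg)
  m <- pair$mask$voxels
  med <- function(x) stats::median(x[m], na.rm = TRUE)
  structure(list(j_map = j_map, adi_map = adi_map, sri_map = sri_map,
                 dvair_map = dvair_map,
                 scalars = c(j = med(j_map), adi = med(adi_map),
                             sri = med(sri_map), dvair = med(dvair_map))),
            class = "functional_maps")
}
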