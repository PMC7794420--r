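# Synthetic paired inspiration/expiration CT phantoms with planted
# emphysema/fSAD burdens, ground-truth displacement fields and cohort
# statistics calibrated to the study's group means (COPD: Emph% 8.5,
# fSAD% 23.7, median J 1.5; non-COPD: 1.7, 11.2, 1.7).

#' Phantom generator parameters
#'
#' Defaults encode the study conditions: burden and Jacobian distributions
#' calibrated per group, lesion attenuation levels placed on the correct
#' side of the -950/-856 HU cuts with a misclassification tail, and a 2:1
#' upper-lung placement bias for COPD lesions.
#'
#' @param shape grid shape (voxels per axis).
#' @param spacing voxel size in mm.
#' @param lung_axes_frac ellipsoid semi-axes as fractions of the half-extent.
#' @param groups per-group mean/sd of planted Emph%, fSAD% and median
#'   Jacobian (truncated to valid ranges, see [calibrate_truncnorm()]).
#' @param burden_max per-class burden cap (%); joint cap is `pair_max`.
#' @param pair_max cap on Emph% + fSAD%.
#' @param j_max upper truncation of the Jacobian draw.
#' @param hu list of `c(mean, sd)` attenuation models (HU) for normal
#'   parenchyma, emphysema and fSAD lesions at IN and EX.
#' @param hu_noise_sd additional global attenuation noise sd (HU).
#' @param background_hu soft-tissue background level (HU).
#' @param lesion_radius mean and sd of blob radius (voxels).
#' @param upper_bias named per-group sampling weight of lesion centres in
#'   the upper lung third relative to the rest (`Inf` restricts lesions to
#'   the upper third).
#' @param pert_sigma_mm Gaussian correlation length of the random
#'   displacement perturbation (mm).
#' @param pert_j_sd target voxel sd of the Jacobian fluctuation contributed
#'   by the perturbation.
#' @param aniso base anisotropy of the affine expansion (relative axis
#'   scales; normalised to determinant one, then scaled to hit the target
#'   median Jacobian).
#' @return object of class `phantom_params`.
#' @export
phantom_params <- function(
    shape = c(64L, 64L, 64L),
    spacing = c(4, 4, 4),
    lung_axes_frac = c(0.75, 0.85, 0.9),
    groups = list(
      COPD = list(emph = c(8.5, 7.5), fsad = c(23.7, 13.6), j = c(1.5, 0.3)),
      `non-COPD` = list(emph = c(1.7, 2.5), fsad = c(11.2, 13.4),
                        j = c(1.7, 0.4))),
    burden_max = 60, pair_max = 80, j_max = 3,
    hu = list(normal_in = c(-870, 30), normal_ex = c(-780, 25),
              emph_in = c(-975, 10), emph_ex = c(-920, 15),
              fsad_in = c(-900, 15), fsad_ex = c(-900, 15)),
    hu_noise_sd = 5, background_hu = 40,
    lesion_radius = c(3, 1),
    upper_bias = c(COPD = 2, `non-COPD` = 1),
    pert_sigma_mm = 20, pert_j_sd = 0.03,
    aniso = c(1, 1.05, 1.15)) {
  p <- list(shape = as.integer(shape), spacing = as.numeric(spacing),
            lung_axes_frac = lung_axes_frac, groups = groups,
            burden_max = burden_max, pair_max = pair_max, j_max = j_max,
            hu = hu, hu_noise_sd = hu_noise_sd, background_hu = background_hu,
            lesion_radius = lesion_radius, upper_bias = upper_bias,
            pert_sigma_mm = pert_sigma_mm, pert_j_sd = pert_j_sd,
            aniso = aniso)
  stopifnot(length(p$shape) == 3L, all(p$shape >= 16L),
            all(p$spacing > 0), all(p$lung_axes_frac > 0 & p$lung_axes_frac < 1))
  for (g in p$groups) {
    if (g$emph[1] < 0 || g$emph[1] > burden_max ||
        g$fsad[1] < 0 || g$fsad[1] > burden_max)
      stop("group burden means must lie in [0, burden_max]", call. = FALSE)
    if (g$emph[1] + g$fsad[1] > pair_max)
      stop("group burden means exceed pair_max", call. = FALSE)
    if (g$j[1] < 1) stop("mean Jacobian must be >= 1", call. = FALSE)
    if (any(c(g$emph[2], g$fsad[2], g$j[2]) < 0))
      stop("sds must be >= 0", call. = FALSE)
  }
  class(p) <- "phantom_params"
  p
}

# ---- calibrated truncated-normal draws --------------------------------------

tn_moments <- function(mu, sigma, a, b) {
  if (sigma <= 0) return(c(mean = mu, sd = 0))
  al <- (a - mu) / sigma; be <- (b - mu) / sigma
  sl <- stats::pnorm(al, lower.tail = FALSE)
  su <- stats::pnorm(be, lower.tail = FALSE)
  Z <- sl - su
  if (Z <= 0) return(c(mean = NA_real_, sd = NA_real_))
  dal <- stats::dnorm(al); dbe <- stats::dnorm(be)
  m <- mu + sigma * (dal - dbe) / Z
  v <- sigma^2 * (1 + (al * dal - be * dbe) / Z - ((dal - dbe) / Z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

#' Calibrate a truncated normal to target post-truncation moments
#'
#' Finds underlying `(mu, sigma)` such that the \[a, b\]-truncated normal
#' has mean exactly `target_mean` and sd as close as attainable to
#' `target_sd`. (A normal truncated at zero cannot exceed a coefficient of
#' variation of about one, so for targets beyond that the realised sd is
#' capped while the mean is still matched exactly.)
#'
#' @param target_mean,target_sd desired post-truncation moments.
#' @param a,b truncation bounds.
#' @return list with `mu`, `sigma`, and the `realized` mean/sd.
#' @export
calibrate_truncnorm <- function(target_mean, target_sd, a, b) {
  stopifnot(target_mean > a, target_mean < b, target_sd >= 0)
  if (target_sd == 0)
    return(list(mu = target_mean, sigma = 0,
                realized = c(mean = target_mean, sd = 0)))
  mu_for_mean <- function(sigma) {
    # post-truncation mean is increasing in mu; keep |z-score| <= 6 for
    # numerically safe quantile draws
    lo <- max(a - 6 * sigma, a - 1e6); hi <- b + 6 * sigma
    f <- function(mu) tn_moments(mu, sigma, a, b)["mean"] - target_mean
    if (f(lo) > 0) return(lo)
    stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  }
  sd_gap <- function(log_sigma) {
    sigma <- exp(log_sigma)
    mu <- mu_for_mean(sigma)
    mom <- tn_moments(mu, sigma, a, b)
    # the mean must match exactly; the sd is matched as well as attainable
    abs(mom["sd"] - target_sd) + 1e4 * abs(mom["mean"] - target_mean)
  }
  opt <- stats::optimize(sd_gap, log(c(target_sd / 20, target_sd * 20)),
                         tol = 1e-8)
  sigma <- exp(opt$minimum)
  mu <- mu_for_mean(sigma)
  list(mu = mu, sigma = sigma, realized = tn_moments(mu, sigma, a, b))
}

# cache of calibrations (keyed by the four numbers)
.prm3d_cache <- new.env(parent = emptyenv())

calibrated_tn <- function(target_mean, target_sd, a, b) {
  key <- paste0("tn:", paste(signif(c(target_mean, target_sd, a, b), 12),
                             collapse = ","))
  if (is.null(.prm3d_cache[[key]]))
    .prm3d_cache[[key]] <- calibrate_truncnorm(target_mean, target_sd, a, b)
  .prm3d_cache[[key]]
}

# quantile-based truncated-normal draw (stable for heavy one-sided truncation)
rtrunc <- function(n, cal, a, b) {
  if (cal$sigma == 0) return(rep(cal$mu, n))
  sl <- stats::pnorm((a - cal$mu) / cal$sigma, lower.tail = FALSE)
  su <- stats::pnorm((b - cal$mu) / cal$sigma, lower.tail = FALSE)
  s <- sl + stats::runif(n) * (su - sl)
  cal$mu + cal$sigma * stats::qnorm(s, lower.tail = FALSE)
}

# ---- subject truth ----------------------------------------------------------

#' Draw one subject's ground-truth planted parameters
#'
#' Burdens come from the group's calibrated truncated normals (see
#' [calibrate_truncnorm()]); draws violating the joint burden cap are
#' redrawn. Uses R's RNG stream (seed with [set.seed()] for
#' reproducibility).
#'
#' @param group "COPD" or "non-COPD".
#' @param params a [phantom_params()].
#' @return object of class `subject_truth` with `group`, `emph_pct`,
#'   `fsad_pct`, `mean_j` (lesion centroids are filled in by
#'   [generate_paired_scan()]).
#' @export
sample_subject <- function(group, params = phantom_params()) {
  if (!group %in% names(params$groups))
    stop("unknown group: ", group, " (expected ",
         paste(names(params$groups), collapse = " or "), ")", call. = FALSE)
  g <- params$groups[[group]]
  cal_e <- calibrated_tn(g$emph[1], g$emph[2], 0, params$burden_max)
  cal_f <- calibrated_tn(g$fsad[1], g$fsad[2], 0, params$burden_max)
  cal_j <- calibrated_tn(g$j[1], g$j[2], 1, params$j_max)
  for (try in 1:100) {
    e <- rtrunc(1L, cal_e, 0, params$burden_max)
    f <- rtrunc(1L, cal_f, 0, params$burden_max)
    if (e + f <= params$pair_max) break
  }
  if (e + f > params$pair_max) {  # pathological calibration; scale back
    sc <- params$pair_max / (e + f)
    e <- e * sc; f <- f * sc
  }
  structure(list(group = group, emph_pct = e, fsad_pct = f,
                 mean_j = rtrunc(1L, cal_j, 1, params$j_max),
                 lesion_centroids = NULL),
            class = "subject_truth")
}

# ---- geometry helpers -------------------------------------------------------

phantom_mask <- function(params) {
  key <- paste0("mask:", paste(c(params$shape, params$lung_axes_frac),
                               collapse = ","))
  if (!is.null(.prm3d_cache[[key]])) return(.prm3d_cache[[key]])
  d <- params$shape
  semi <- params$lung_axes_frac * d / 2
  ctr <- (d - 1) / 2
  x <- ((seq_len(d[1]) - 1) - ctr[1]) / semi[1]
  y <- ((seq_len(d[2]) - 1) - ctr[2]) / semi[2]
  z <- ((seq_len(d[3]) - 1) - ctr[3]) / semi[3]
  r2 <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  m <- r2 <= 1
  .prm3d_cache[[key]] <- m
  m
}

# per-voxel misclassification model: P(measured class | planted class)
class_probs <- function(params) {
  cuts <- c(insp = -950, exp = -856)
  ptail <- function(model, cut) {
    sd_tot <- sqrt(model[2]^2 + params$hu_noise_sd^2)
    unname(stats::pnorm(cut, model[1], sd_tot))
  }
  pin <- c(e = ptail(params$hu$emph_in, cuts["insp"]),
           f = ptail(params$hu$fsad_in, cuts["insp"]),
           n = ptail(params$hu$normal_in, cuts["insp"]))
  pex <- c(e = ptail(params$hu$emph_ex, cuts["exp"]),
           f = ptail(params$hu$fsad_ex, cuts["exp"]),
           n = ptail(params$hu$normal_ex, cuts["exp"]))
  list(PE = pin * pex, PF = (1 - pin) * pex)  # P(meas Emph | k), P(meas fSAD | k)
}

# planted fractions (0..1) such that the expected PRM-measured fractions
# equal the truth burdens, given the attenuation misclassification model
planted_fractions <- function(truth, params) {
  pr <- class_probs(params)
  te <- truth$emph_pct / 100; tf <- truth$fsad_pct / 100
  A <- rbind(c(pr$PE[["e"]] - pr$PE[["n"]], pr$PE[["f"]] - pr$PE[["n"]]),
             c(pr$PF[["e"]] - pr$PF[["n"]], pr$PF[["f"]] - pr$PF[["n"]]))
  bvec <- c(te - pr$PE[["n"]], tf - pr$PF[["n"]])
  p <- solve(A, bvec)
  pmax(p, 0)
}

# paint spherical blobs into `free` voxels until `target` voxels are set;
# returns voxel indices painted and the centre list
paint_blobs <- function(target, free, mask, params, upper_w) {
  d <- dim(mask)
  painted <- logical(length(free)); dim(painted) <- d
  centres <- NULL
  if (target <= 0)
    return(list(sel = painted, centres = centres, n = 0L, shortfall = 0L))
  zidx <- slice.index(mask, 3)
  zs <- range(zidx[mask])
  upper_cut <- zs[1] + 2 / 3 * (zs[2] - zs[1])
  # candidate centres with upper-third weighting, drawn in bulk; an
  # infinite bias restricts centres to the upper third outright
  cand <- which(free)
  zc <- zidx[cand]
  if (is.infinite(upper_w) && any(zc >= upper_cut)) {
    cand <- cand[zc >= upper_cut]
    w <- rep(1, length(cand))
  } else {
    w <- rep(1, length(cand))
    w[zc >= upper_cut] <- min(upper_w, 1e6)
  }
  centre_pool <- cand[sample.int(length(cand), min(length(cand), 5000L),
                                 replace = TRUE, prob = w)]
  pool_pos <- 0L
  n_painted <- 0L
  guard <- 0L
  exhausted <- FALSE
  while (n_painted < target && guard < 20000L && !exhausted) {
    guard <- guard + 1L
    miss <- 0L
    repeat {
      pool_pos <- pool_pos + 1L
      if (pool_pos > length(centre_pool)) {
        centre_pool <- cand[sample.int(length(cand), 5000L, replace = TRUE,
                                       prob = w)]
        pool_pos <- 1L
      }
      centre_flat <- centre_pool[pool_pos]
      if (!painted[centre_flat]) break
      miss <- miss + 1L
      if (miss %% 2000L == 0L && !any(!painted[cand])) {
        # every eligible centre is painted: region is full, stop planting
        exhausted <- TRUE
        break
      }
    }
    if (exhausted) break
    ci <- arrayInd(centre_flat, d)
    r <- max(1.2, stats::rnorm(1, params$lesion_radius[1],
                               params$lesion_radius[2]))
    rr <- ceiling(r)
    rng <- lapply(1:3, function(k) max(1, ci[k] - rr):min(d[k], ci[k] + rr))
    dx2 <- (rng[[1]] - ci[1])^2
    dy2 <- (rng[[2]] - ci[2])^2
    dz2 <- (rng[[3]] - ci[3])^2
    ball <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= r^2
    sub <- free[rng[[1]], rng[[2]], rng[[3]], drop = FALSE] &
      !painted[rng[[1]], rng[[2]], rng[[3]], drop = FALSE] & ball
    new_flat <- which(sub)
    if (!length(new_flat)) next
    # translate sub-box indices to full-grid flat indices
    si <- arrayInd(new_flat, dim(sub))
    flat <- (rng[[1]][si[, 1]]) +
      d[1] * ((rng[[2]][si[, 2]] - 1) + d[2] * (rng[[3]][si[, 3]] - 1))
    excess <- (n_painted + length(flat)) - target
    if (excess > 0) {  # trim farthest-first so counts are exact
      dist2 <- (rng[[1]][si[, 1]] - ci[1])^2 + (rng[[2]][si[, 2]] - ci[2])^2 +
        (rng[[3]][si[, 3]] - ci[3])^2
      keep <- order(dist2)[seq_len(length(flat) - excess)]
      flat <- flat[keep]
    }
    painted[flat] <- TRUE
    n_painted <- n_painted + length(flat)
    centres <- rbind(centres, c(ci, r))
  }
  list(sel = painted, centres = centres, n = n_painted,
       shortfall = target - n_painted)
}

# Gaussian smoothing by FFT with a cached transfer function
fft_smooth <- function(a, sigma_vox) {
  d <- dim(a)
  key <- paste0("kern:", paste(c(d, signif(sigma_vox, 8)), collapse = ","))
  K <- .prm3d_cache[[key]]
  if (is.null(K)) {
    g1 <- function(n, s) {
      f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
      exp(-2 * pi^2 * s^2 * f^2)  # Fourier transform of the Gaussian
    }
    kx <- g1(d[1], sigma_vox[1]); ky <- g1(d[2], sigma_vox[2])
    kz <- g1(d[3], sigma_vox[3])
    K <- outer(outer(kx, ky), kz)
    .prm3d_cache[[key]] <- K
  }
  Re(stats::fft(stats::fft(a) * K, inverse = TRUE)) / prod(d)
}

# ---- scan-pair generation ---------------------------------------------------

#' Generate one phantom: paired scans, lung mask, displacement field
#'
#' Builds an ellipsoidal lung in a soft-tissue background, plants emphysema
#' blobs (low attenuation at IN and EX) and fSAD blobs (normal at IN,
#' air-trapped at EX) covering the truth burdens, and constructs a smooth
#' ground-truth displacement field: a global anisotropic expansion tuned so
#' the voxel-median Jacobian over the mask matches `truth$mean_j`, plus a
#' band-limited random perturbation, with local expansion pulled toward 1
#' inside lesions (air trapping). Planted voxel counts are chosen so the
#' expected PRM-measured burden equals the planted truth under the
#' attenuation noise model.
#'
#' @param truth a [sample_subject()] draw.
#' @param params a [phantom_params()].
#' @param with_field generate the displacement field (disable when only the
#'   attenuation pair is needed; saves most of the runtime).
#' @return list with `pair` (a [paired_scan()]), `field` (a
#'   [displacement_field()] or `NULL`), and `truth` updated with lesion
#'   centroids and realised planted voxel counts.
#' @export
generate_paired_scan <- function(truth, params = phantom_params(),
                                 with_field = TRUE) {
  stopifnot(inherits(truth, "subject_truth"))
  d <- params$shape
  mask <- phantom_mask(params)
  n_mask <- sum(mask)
  pf <- planted_fractions(truth, params)
  n_e <- round(pf[1] * n_mask); n_f <- round(pf[2] * n_mask)
  if (n_e + n_f > 0.9 * n_mask)
    stop("lesion burden exceeds mask capacity", call. = FALSE)
  ub <- params$upper_bias[[truth$group]] %||% 1
  eb <- paint_blobs(n_e, mask, mask, params, ub)
  fb <- paint_blobs(n_f, mask & !eb$sel, mask, params, ub)
  n_e <- eb$n; n_f <- fb$n
  if (eb$shortfall > 0 || fb$shortfall > 0) {
    # placement region filled up (e.g. lesions restricted to the upper
    # lung): burden truncates at the regional capacity; update the truth
    # to the expected PRM measurement of what was actually planted
    prm3d_log("lesion burden truncated at regional capacity (%d + %d voxels short)",
              eb$shortfall, fb$shortfall)
    pr <- class_probs(params)
    pv <- c(n_e, n_f, n_mask - n_e - n_f) / n_mask
    truth$emph_pct <- 100 * sum(pr$PE * pv)
    truth$fsad_pct <- 100 * sum(pr$PF * pv)
  }
  # attenuation volumes
  hu_draw <- function(model, n) stats::rnorm(n, model[1], model[2])
  noise <- function(n) if (params$hu_noise_sd > 0)
    stats::rnorm(n, 0, params$hu_noise_sd) else 0
  hu_in <- array(params$background_hu, d)
  hu_ex <- array(params$background_hu, d)
  hu_in[mask] <- hu_draw(params$hu$normal_in, n_mask)
  hu_ex[mask] <- hu_draw(params$hu$normal_ex, n_mask)
  if (n_e > 0) {
    hu_in[eb$sel] <- hu_draw(params$hu$emph_in, n_e)
    hu_ex[eb$sel] <- hu_draw(params$hu$emph_ex, n_e)
  }
  if (n_f > 0) {
    hu_in[fb$sel] <- hu_draw(params$hu$fsad_in, n_f)
    hu_ex[fb$sel] <- hu_draw(params$hu$fsad_ex, n_f)
  }
  hu_in[mask] <- hu_in[mask] + noise(n_mask)
  hu_ex[mask] <- hu_ex[mask] + noise(n_mask)
  hu_in <- pmin(pmax(hu_in, -1090), 3090)
  hu_ex <- pmin(pmax(hu_ex, -1090), 3090)
  insp <- ct_volume(hu_in, params$spacing)
  exp_reg <- ct_volume(hu_ex, params$spacing)
  lm <- lung_mask(mask, params$spacing)
  pair <- paired_scan(insp, exp_reg, lm)
  centres <- rbind(if (!is.null(eb$centres)) cbind(eb$centres, 1),
                   if (!is.null(fb$centres)) cbind(fb$centres, 2))
  truth$lesion_centroids <- centres  # columns: i, j, k, radius, class(1=E,2=F)
  truth$planted <- c(emph_vox = n_e, fsad_vox = n_f, mask_vox = n_mask)
  field <- if (with_field)
    phantom_field(truth, params, mask, eb$sel | fb$sel, centres) else NULL
  list(pair = pair, field = field, truth = truth)
}

phantom_field <- function(truth, params, mask, lesion_sel, centres) {
  d <- params$shape; h <- params$spacing
  # random band-limited perturbation: white noise smoothed on a half-
  # resolution grid (the correlation length far exceeds the coarse voxel
  # size) then upsampled, scaled to a target Jacobian sd
  dc <- pmax(d %/% 2L, 8L)
  sigma_coarse <- params$pert_sigma_mm / (h * d / dc)
  u <- lapply(1:3, function(k)
    resample_grid(fft_smooth(array(stats::rnorm(prod(dc)), dc), sigma_coarse),
                  d))
  div_terms <- vapply(1:3, function(k) stats::sd(diff_axis(u[[k]], k, h[k])), 0)
  sc <- params$pert_j_sd / sqrt(sum(div_terms^2))
  for (k in 1:3) u[[k]] <- u[[k]] * sc
  # local contraction at lesions (reduced expansion / air trapping)
  if (!is.null(centres) && nrow(centres) > 0) {
    gamma <- (truth$mean_j - 1) / 6
    ules <- blob_contraction_cpp(d, h, centres[, 1:4, drop = FALSE], gamma)
    nv <- prod(d)
    for (k in 1:3)
      u[[k]] <- u[[k]] + array(ules[((k - 1) * nv + 1):(k * nv)], d)
  }
  # gradient of the non-affine part, restricted to mask voxels (only the
  # mask median enters the tuning; the affine part is added analytically)
  Gfull <- field_gradient_cpp(c(u[[1]], u[[2]], u[[3]]), d, h)
  G <- Gfull[as.vector(mask), , drop = FALSE]
  G[, c(1, 5, 9)] <- G[, c(1, 5, 9)] - 1  # gradient of u, not of x + u
  S0 <- params$aniso / prod(params$aniso)^(1 / 3)  # det = 1
  med_j <- function(cs) {
    F11 <- G[, 1] + cs * S0[1]; F22 <- G[, 5] + cs * S0[2]
    F33 <- G[, 9] + cs * S0[3]
    J <- F11 * (F22 * F33 - G[, 8] * G[, 6]) -
      G[, 4] * (G[, 2] * F33 - G[, 8] * G[, 3]) +
      G[, 7] * (G[, 2] * G[, 6] - F22 * G[, 3])
    stats::median(J)
  }
  # secant iteration on the global scale factor
  c0 <- truth$mean_j^(1 / 3); f0 <- med_j(c0) - truth$mean_j
  c1 <- (truth$mean_j - f0)^(1 / 3); f1 <- med_j(c1) - truth$mean_j
  for (it in 1:6) {
    if (abs(f1) < 5e-4 || abs(f1 - f0) < 1e-12) break
    c2 <- c1 - f1 * (c1 - c0) / (f1 - f0)
    c0 <- c1; f0 <- f1
    c1 <- c2; f1 <- med_j(c1) - truth$mean_j
  }
  ctr <- (d - 1) / 2 * h
  ax <- lapply(1:3, function(k) ((seq_len(d[k]) - 1) * h[k]) - ctr[k])
  scale3 <- c1 * S0 - 1
  uu <- array(0, c(d, 3))
  uu[, , , 1] <- u[[1]] + scale3[1] * ax[[1]]
  uu[, , , 2] <- u[[2]] + scale3[2] * rep(ax[[2]], each = d[1])
  uu[, , , 3] <- u[[3]] + scale3[3] * rep(ax[[3]], each = d[1] * d[2])
  displacement_field(uu, spacing = h)
}

# ---- cohort generation ------------------------------------------------------

#' Generate a labelled phantom cohort
#'
#' Subjects are drawn sequentially from one RNG stream, so a given
#' `(params, seed)` reproduces the cohort bit-identically.
#'
#' @param n_copd,n_noncopd subjects per group (>= 1; the source study had
#'   204 COPD and 392 non-COPD).
#' @param params a [phantom_params()].
#' @param seed integer seed.
#' @param with_field generate displacement fields (see
#'   [generate_paired_scan()]).
#' @param dir optional directory; when given, per-subject volumes, masks and
#'   fields are written as NIfTI and the manifest as `manifest.csv`.
#' @return object of class `phantom_cohort`: list of `subjects` (each as
#'   returned by [generate_paired_scan()], plus `id`/`label`) and a
#'   `manifest` data.frame (id, group, planted burdens, file paths).
#' @export
generate_cohort <- function(n_copd, n_noncopd, params = phantom_params(),
                            seed = 1L, with_field = TRUE, dir = NULL) {
  stopifnot(n_copd >= 1L, n_noncopd >= 1L)
  set.seed(seed)
  groups <- rep(c("COPD", "non-COPD"), c(n_copd, n_noncopd))
  if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  subjects <- vector("list", length(groups))
  rows <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    id <- sprintf("S%04d", i)
    truth <- sample_subject(groups[i], params)
    s <- generate_paired_scan(truth, params, with_field = with_field)
    s$id <- id; s$label <- groups[i]
    paths <- c(insp = NA_character_, exp = NA_character_,
               mask = NA_character_, field = NA_character_)
    if (!is.null(dir)) {
      paths <- c(insp = file.path(dir, paste0(id, "_in.nii.gz")),
                 exp = file.path(dir, paste0(id, "_ex.nii.gz")),
                 mask = file.path(dir, paste0(id, "_mask.nii.gz")),
                 field = if (with_field)
                   file.path(dir, paste0(id, "_field.nii.gz")) else
                     NA_character_)
      write_volume(as_volume(round(s$pair$insp$voxels), params$spacing),
                   paths["insp"], datatype = "int16")
      write_volume(as_volume(round(s$pair$exp_reg$voxels), params$spacing),
                   paths["exp"], datatype = "int16")
      write_volume(as_volume(array(as.integer(s$pair$mask$voxels),
                                   dim(s$pair$mask$voxels)),
                             params$spacing), paths["mask"],
                   datatype = "uint8")
      if (with_field) write_field(s$field, paths["field"])
    }
    subjects[[i]] <- s
    rows[[i]] <- data.frame(id = id, group = groups[i],
                            emph_pct = s$truth$emph_pct,
                            fsad_pct = s$truth$fsad_pct,
                            mean_j = s$truth$mean_j,
                            insp = paths[["insp"]], exp = paths[["exp"]],
                            mask = paths[["mask"]], field = paths[["field"]],
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir))
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  structure(list(subjects = subjects, manifest = manifest, params = params,
                 seed = seed),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d subjects (%d COPD / %d non-COPD)\n",
              nrow(x$manifest), sum(x$manifest$group == "COPD"),
              sum(x$manifest$group == "non-COPD")))
  invisible(x)
}
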