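# Parametric response mapping: joint thresholding of registered
# inspiration/expiration attenuation into normal (8), fSAD (32) and
# emphysema (64) classes, plus mask-level quantification.

PRM_BG <- 0L; PRM_NORMAL <- 8L; PRM_FSAD <- 32L; PRM_EMPH <- 64L

#' PRM attenuation thresholds
#'
#' Defaults are the standard lung cuts: -950 HU on the inspiratory scan
#' (emphysema) and -856 HU on the expiratory scan (air trapping). Both cuts
#' are inclusive (`<=`).
#'
#' @param insp_cut inspiratory threshold in HU.
#' @param exp_cut expiratory threshold in HU; must exceed `insp_cut`.
#' @return object of class `prm_thresholds`.
#' @export
prm_thresholds <- function(insp_cut = -950, exp_cut = -856) {
  stopifnot(is.finite(insp_cut), is.finite(exp_cut))
  if (insp_cut >= exp_cut)
    stop("insp_cut must be below exp_cut", call. = FALSE)
  structure(list(insp_cut = insp_cut, exp_cut = exp_cut),
            class = "prm_thresholds")
}

#' Classify voxels by paired attenuation
#'
#' Vectorised over voxels. Codes: 64 = emphysema (at or below both cuts),
#' 32 = fSAD (above the inspiratory cut, at or below the expiratory cut),
#' 8 = normal, which also absorbs the "unclassified" quadrant (at or below
#' the inspiratory cut but above the expiratory cut).
#'
#' @param hu_in,hu_ex inspiratory/expiratory attenuation (HU), equal length.
#' @param th a [prm_thresholds()].
#' @return integer vector of class codes in \{8, 32, 64\}.
#' @export
classify_voxel <- function(hu_in, hu_ex, th = prm_thresholds()) {
  if (length(hu_in) != length(hu_ex))
    stop("hu_in and hu_ex must have equal length", call. = FALSE)
  if (anyNA(hu_in) || anyNA(hu_ex) ||
      any(!is.finite(hu_in)) || any(!is.finite(hu_ex)))
    stop("non-finite attenuation value", call. = FALSE)
  low_in <- hu_in <= th$insp_cut
  low_ex <- hu_ex <= th$exp_cut
  code <- rep.int(PRM_NORMAL, length(hu_in))
  code[!low_in & low_ex] <- PRM_FSAD
  code[low_in & low_ex]  <- PRM_EMPH
  code
}

#' Voxel-wise PRM classification of a registered pair
#'
#' Applies [classify_voxel()] inside the lung mask; voxels outside the mask
#' receive code 0 (background). The count of "unclassified" voxels (low
#' inspiratory, high expiratory attenuation, folded into code 8) is logged
#' and attached as attribute `n_unclassified`.
#'
#' @param pair a [paired_scan()].
#' @param th a [prm_thresholds()].
#' @return object of class `prm_volume`: integer code grid plus geometry and
#'   the thresholds used.
#' @export
classify_volume <- function(pair, th = prm_thresholds()) {
  stopifnot(inherits(pair, "paired_scan"))
  m <- pair$mask$voxels
  if (!any(m)) stop("empty lung mask", call. = FALSE)
  codes <- array(PRM_BG, dim(m))
  hu_in <- pair$insp$voxels[m]
  hu_ex <- pair$exp_reg$voxels[m]
  codes[m] <- classify_voxel(hu_in, hu_ex, th)
  n_uncl <- sum(hu_in <= th$insp_cut & hu_ex > th$exp_cut)
  prm3d_log("PRM: %d mask voxels, %d unclassified folded into normal",
            sum(m), n_uncl)
  structure(list(codes = codes, thresholds = th, spacing = pair$insp$spacing,
                 origin = pair$insp$origin),
            class = "prm_volume", n_unclassified = n_uncl)
}

#' Summarise a PRM volume into quantitative CT measures
#'
#' Percentages are computed over mask voxel counts (exact rational
#' arithmetic, so they sum to 100). Air volumes integrate the linear
#' air-fraction model over the mask: TLC from the inspiratory volume, FRC
#' from the registered expiratory volume, both in litres.
#'
#' @param prm a `prm_volume` from [classify_volume()].
#' @param pair the [paired_scan()] the PRM was derived from.
#' @return object of class `qct_summary` with fields `emph_pct`, `fsad_pct`,
#'   `normal_pct`, `tlc_l`, `frc_l`, `n_mask`.
#' @export
prm_summary <- function(prm, pair) {
  stopifnot(inherits(prm, "prm_volume"), inherits(pair, "paired_scan"))
  if (!identical(dim(prm$codes), dim(pair$mask$voxels)))
    stop("PRM volume and pair do not share geometry", call. = FALSE)
  m <- pair$mask$voxels
  n <- sum(m)
  codes <- prm$codes[m]
  n_emph <- sum(codes == PRM_EMPH)
  n_fsad <- sum(codes == PRM_FSAD)
  n_norm <- n - n_emph - n_fsad
  voxvol <- prod(pair$insp$spacing)  # mm^3
  tlc_l <- sum(air_fraction(pair$insp$voxels[m])) * voxvol / 1e6
  frc_l <- sum(air_fraction(pair$exp_reg$voxels[m])) * voxvol / 1e6
  emph_pct <- 100 * n_emph / n
  fsad_pct <- 100 * n_fsad / n
  structure(list(emph_pct = emph_pct, fsad_pct = fsad_pct,
                 normal_pct = 100 - emph_pct - fsad_pct,  # sums exactly
                 tlc_l = tlc_l, frc_l = frc_l, n_mask = n),
            class = "qct_summary")
}

#' @export
print.qct_summary <- function(x, ...) {
  cat(sprintf(
    "<qct_summary> Emph%% %.2f | fSAD%% %.2f | Normal%% %.2f | TLC %.2f L | FRC %.2f L\n",
    x$emph_pct, x$fsad_pct, x$normal_pct, x$tlc_l, x$frc_l))
  invisible(x)
}
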