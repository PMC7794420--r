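# Volumetric Grad-CAM: gradients of a class logit with respect to the third
# conv block's post-activation feature volume (8^3, pre-pool) are globally
# average-pooled into channel weights; the ReLU'd weighted channel sum is
# upsampled trilinearly to the 32^3 network grid and max-normalised.

#' 3D Grad-CAM heatmap for one input
#'
#' @param model a trained `cnn3d_model`.
#' @param input a [assemble_input()] object matching the model's channels.
#' @param target_class "COPD" or "non-COPD" (the logit whose saliency is
#'   mapped).
#' @return object of class `heatmap_volume`: `values` (32^3 array in
#'   \[0, 1\], max 1 unless identically zero) plus the class tag.
#' @export
grad_cam <- function(model, input, target_class = "COPD") {
  stopifnot(inherits(model, "cnn3d_model"), inherits(input, "network_input"))
  target_class <- match.arg(target_class, c("COPD", "non-COPD"))
  cam8 <- cnn_gradcam_cpp(model$params, as.vector(input$values),
                          as.integer(target_class == "COPD"))
  cam8 <- array(cam8, c(8L, 8L, 8L))
  target <- dim(input$values)[2:4]
  cam <- resample_grid(cam8, target)
  cam[cam < 0] <- 0
  mx <- max(cam)
  if (mx > 0) cam <- cam / mx
  structure(list(values = cam, target_class = target_class),
            class = "heatmap_volume")
}

# map a [0,1] heat value to an RGB triple on a blue->red "hot" ramp
heat_rgb <- function(v) {
  r <- pmin(1, 2 * v)
  g <- pmin(1, pmax(0, 2 * v - 0.5)) * 0.8
  b <- pmax(0, 1 - 2 * v)
  cbind(r, g, b)
}

#' Export a Grad-CAM overlay: heatmap volume plus mid-plane PNG triptych
#'
#' Writes the heatmap as NIfTI next to three PNG slices (axial, sagittal,
#' coronal mid-planes, index `floor(shape/2)` on the sliced axis in 0-based
#' convention) with the heat alpha-blended over the grayscale background.
#' The background is resampled to the heatmap grid when shapes differ.
#'
#' @param heatmap a [grad_cam()] result.
#' @param background a [ct_volume()] or `prm_volume` to draw under the heat.
#' @param prefix output path prefix; writes `<prefix>_cam.nii.gz` and
#'   `<prefix>_{axial,sagittal,coronal}.png`.
#' @return invisibly, the written file paths.
#' @export
export_overlay <- function(heatmap, background, prefix) {
  stopifnot(inherits(heatmap, "heatmap_volume"))
  bg <- if (inherits(background, "prm_volume")) background$codes
  else if (inherits(background, "ct_volume")) background$voxels
  else stop("background must be a ct_volume or prm_volume", call. = FALSE)
  hv <- heatmap$values
  if (!identical(dim(bg), dim(hv))) bg <- resample_grid(bg, dim(hv))
  rng <- range(bg)
  bgn <- if (diff(rng) > 0) (bg - rng[1]) / diff(rng) else bg * 0
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  nii <- paste0(prefix, "_cam.nii.gz")
  write_volume(as_volume(hv), nii, datatype = "float")
  d <- dim(hv)
  mid <- floor(d / 2) + 1L  # R index of the 0-based floor(shape/2) plane
  slices <- list(
    axial    = list(bg = bgn[, , mid[3]], heat = hv[, , mid[3]]),
    sagittal = list(bg = bgn[mid[1], , ], heat = hv[mid[1], , ]),
    coronal  = list(bg = bgn[, mid[2], ], heat = hv[, mid[2], ]))
  paths <- nii
  for (nm in names(slices)) {
    s <- slices[[nm]]
    alpha <- pmin(1, pmax(0, s$heat)) * 0.7
    rgbh <- heat_rgb(as.vector(s$heat))
    img <- array(0, c(dim(s$bg), 3))
    for (ch in 1:3)
      img[, , ch] <- (1 - alpha) * s$bg + alpha * array(rgbh[, ch], dim(s$bg))
    p <- paste0(prefix, "_", nm, ".png")
    # PNG rows run top to bottom; flip the second image axis for display
    png::writePNG(aperm(img, c(2, 1, 3))[rev(seq_len(dim(img)[2])), , ], p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
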