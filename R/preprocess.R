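# Conversion of any supported map kind into the fixed-size normalized
# network input: trilinear resampling to 32^3 followed by a fixed affine
# intensity window into [0, 1].

#' Supported network input kinds
#'
#' @return named integer vector mapping kind to channel count: raw
#'   attenuation (`in`, `ex`), their two-channel concatenation (`inex`),
#'   the PRM code map (`prm`), and the functional maps (`dvair`, `j`,
#'   `adi`, `sri`).
#' @export
input_kinds <- function() {
  c(prm = 1L, "in" = 1L, ex = 1L, dvair = 1L, j = 1L, adi = 1L, sri = 1L,
    inex = 2L)
}

#' Trilinear resampling of a 3D grid
#'
#' Voxel-centred lattice convention: target index i maps to source
#' coordinate `(i + 0.5) * n_src / n_tgt - 0.5` per axis; coordinates are
#' clamped to the grid. A source already at the target shape is returned
#' unchanged. Label grids (e.g. PRM codes) are interpolated like any other
#' scalar grid, so class borders blend.
#'
#' @param a 3D numeric array (>= 2 voxels per axis).
#' @param target integer length-3 target shape (default 32^3).
#' @return 3D array with dimensions `target`.
#' @export
resample_grid <- function(a, target = c(32L, 32L, 32L)) {
  d <- dim(a)
  if (length(d) != 3L) stop("resample_grid: source must be 3D", call. = FALSE)
  if (any(d < 2L)) stop("resample_grid: source needs >= 2 voxels per axis",
                        call. = FALSE)
  target <- as.integer(target)
  if (length(target) != 3L || any(target < 1L))
    stop("resample_grid: invalid target shape", call. = FALSE)
  if (identical(d, target)) return(a)
  array(resample3d_cpp(as.vector(a), d, target), target)
}

# fixed normalization windows per kind (affine clamp -> [0,1])
norm_windows <- list(
  "in"  = c(-1024, 0),
  ex    = c(-1024, 0),
  j     = c(0.5, 3),
  adi   = c(0, 2),
  sri   = c(0, 1),
  dvair = c(-0.5, 1.5)
)

#' Normalize a grid into \[0, 1\] for network input
#'
#' Attenuation kinds (`in`, `ex`) clamp to \[-1024, 0\] HU and map
#' affinely; PRM codes divide by 64 so severity is monotone
#' (background 0, normal 0.125, fSAD 0.5, emphysema 1); `j` clamps to
#' \[0.5, 3\], `adi` to \[0, 2\], `dvair` to \[-0.5, 1.5\]; `sri` is already
#' native \[0, 1\].
#'
#' @param a numeric array/vector of map values (finite).
#' @param kind one of `names(input_kinds())` except `inex` (normalize the
#'   two channels separately as `in` and `ex`).
#' @return values in \[0, 1\], same shape as `a`.
#' @export
normalize_input <- function(a, kind) {
  if (anyNA(a) || any(!is.finite(a)))
    stop("normalize_input: non-finite values", call. = FALSE)
  if (kind == "prm") return(a / 64)
  w <- norm_windows[[kind]]
  if (is.null(w)) stop("unknown input kind: ", kind, call. = FALSE)
  pmin(pmax((a - w[1]) / (w[2] - w[1]), 0), 1)
}

#' Assemble one subject's network input
#'
#' Resamples the requested map(s) to 32^3, normalizes into \[0, 1\] and
#' stacks channels. `inex` stacks the inspiratory and registered expiratory
#' attenuation volumes as two channels; all other kinds are single-channel.
#'
#' @param subject named list holding whatever the kind needs: `pair`
#'   (a [paired_scan()]; for `in`, `ex`, `inex`), `prm` (a `prm_volume`;
#'   for `prm`), `fmaps` (a [functional_maps()]; for `dvair`, `j`, `adi`,
#'   `sri`). Optional `id` and `label` are carried through.
#' @param kind one of `names(input_kinds())`.
#' @param target spatial shape of the network input.
#' @return object of class `network_input`: array (C, 32, 32, 32) in
#'   \[0, 1\] plus `kind`, `id`, `label`.
#' @export
assemble_input <- function(subject, kind, target = c(32L, 32L, 32L)) {
  if (!kind %in% names(input_kinds()))
    stop("unknown input kind: ", kind, call. = FALSE)
  need <- function(what, field) {
    x <- subject[[field]]
    if (is.null(x))
      stop("input kind '", kind, "' requires missing component '", field,
           "'", call. = FALSE)
    x
  }
  grids <- switch(kind,
    "in"  = list("in" = need(kind, "pair")$insp$voxels),
    ex    = list(ex = need(kind, "pair")$exp_reg$voxels),
    inex  = {
      p <- need(kind, "pair")
      list("in" = p$insp$voxels, ex = p$exp_reg$voxels)
    },
    prm   = list(prm = need(kind, "prm")$codes),
    j     = list(j = need(kind, "fmaps")$j_map),
    adi   = list(adi = need(kind, "fmaps")$adi_map),
    sri   = list(sri = need(kind, "fmaps")$sri_map),
    dvair = list(dvair = need(kind, "fmaps")$dvair_map)
  )
  ch <- lapply(names(grids), function(nm) {
    g <- grids[[nm]]
    if (anyNA(g)) g[is.na(g)] <- 0  # degenerate-voxel flags carry no signal
    normalize_input(resample_grid(g, target), nm)
  })
  values <- array(0, c(length(ch), target))
  for (i in seq_along(ch)) values[i, , , ] <- ch[[i]]
  structure(list(values = values, kind = kind,
                 id = subject$id %||% NA_character_,
                 label = subject$label %||% NA_character_),
            class = "network_input")
}
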