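#' @useDynLib prm3d, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- domain containers ------------------------------------------------------

#' CT volume container
#'
#' A 3D scalar grid of attenuation values in Hounsfield units (HU) together
#' with its voxel geometry. All in-memory grids in this package use (x, y, z)
#' index order, 0-based voxel-centred coordinates, and the convention
#' physical position = `origin + index * spacing`.
#'
#' @param voxels 3D numeric array of HU values (finite, within \[-1100, 3100\]
#'   for CT volumes; label maps and derived maps use [as_volume()] instead).
#' @param spacing numeric length-3, per-axis voxel size in mm (> 0).
#' @param origin numeric length-3, physical offset in mm of voxel (0,0,0).
#' @return object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  v <- as_volume(voxels, spacing, origin)
  if (any(dim(v$voxels) < 8L))
    stop("ct_volume: each axis must have at least 8 voxels", call. = FALSE)
  if (!all(is.finite(v$voxels)))
    stop("ct_volume: all HU values must be finite", call. = FALSE)
  rng <- range(v$voxels)
  if (rng[1] < -1100 || rng[2] > 3100)
    stop("ct_volume: HU outside [-1100, 3100]", call. = FALSE)
  v
}

#' Generic volume container (label maps, heatmaps, derived scalar maps)
#'
#' Like [ct_volume()] but without the HU range/shape invariants; used for PRM
#' code maps, Grad-CAM heatmaps and functional maps.
#'
#' @inheritParams ct_volume
#' @return object of class `ct_volume`.
#' @export
as_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (inherits(voxels, "ct_volume")) return(voxels)
  if (length(dim(voxels)) != 3L)
    stop("volume payload must be 3D, got ", length(dim(voxels)), "D",
         call. = FALSE)
  spacing <- as.numeric(spacing)
  origin  <- as.numeric(origin)
  stopifnot(length(spacing) == 3L, length(origin) == 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be positive and finite", call. = FALSE)
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "ct_volume")
}

#' Binary lung mask sharing the geometry of its CT volume
#'
#' @param voxels 3D logical (or 0/1) array.
#' @inheritParams ct_volume
#' @return object of class `lung_mask`.
#' @export
lung_mask <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(voxels)) != 3L)
    stop("mask payload must be 3D", call. = FALSE)
  m <- array(as.logical(voxels), dim(voxels))
  if (anyNA(m)) stop("mask contains NA", call. = FALSE)
  if (!any(m)) stop("mask is empty", call. = FALSE)
  structure(list(voxels = m, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "lung_mask")
}

#' Voxel displacement field from the expiration grid into inspiration space
#'
#' Stores u(x) in mm on the expiration reference grid, with the mapping
#' convention `x_insp = x_exp + u(x_exp)`.
#'
#' @param vectors 4D numeric array (nx, ny, nz, 3) of displacements in mm.
#' @inheritParams ct_volume
#' @return object of class `displacement_field` with `reference = "expiration"`.
#' @export
displacement_field <- function(vectors, spacing = c(1, 1, 1),
                               origin = c(0, 0, 0)) {
  d <- dim(vectors)
  if (length(d) != 4L || d[4] != 3L)
    stop("displacement field must be (nx, ny, nz, 3), got last axis ",
         if (length(d) >= 4) d[4] else "none", call. = FALSE)
  if (!all(is.finite(vectors)))
    stop("displacement field contains non-finite values", call. = FALSE)
  structure(list(vectors = vectors, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), reference = "expiration"),
            class = "displacement_field")
}

#' A registered inspiration/expiration pair with a shared lung mask
#'
#' @param insp inspiration [ct_volume()] (reference grid).
#' @param exp_reg expiration volume resampled onto the inspiration grid.
#' @param mask shared [lung_mask()].
#' @return object of class `paired_scan`.
#' @export
paired_scan <- function(insp, exp_reg, mask) {
  stopifnot(inherits(insp, "ct_volume"), inherits(exp_reg, "ct_volume"),
            inherits(mask, "lung_mask"))
  if (!same_geometry(insp, exp_reg) || !same_geometry(insp, mask))
    stop("paired_scan: insp, exp_reg and mask must share geometry",
         call. = FALSE)
  structure(list(insp = insp, exp_reg = exp_reg, mask = mask),
            class = "paired_scan")
}

grid_dim <- function(x) {
  if (inherits(x, "displacement_field")) dim(x$vectors)[1:3] else dim(x$voxels)
}

#' Do two grid objects share shape, spacing and origin?
#' @param a,b volume, mask or field objects.
#' @param tol numeric tolerance on spacing/origin (mm).
#' @return logical scalar.
#' @export
same_geometry <- function(a, b, tol = 1e-6) {
  identical(grid_dim(a), grid_dim(b)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %s voxels, spacing %s mm, range [%.1f, %.1f]\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
print.paired_scan <- function(x, ...) {
  cat(sprintf("<paired_scan> %s voxels, %d mask voxels\n",
              paste(dim(x$insp$voxels), collapse = "x"),
              sum(x$mask$voxels)))
  invisible(x)
}

# ---- on-disk formats --------------------------------------------------------

volume_format <- function(path) {
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) "nifti"
  else if (grepl("\\.(mha|mhd)$", lp)) "metaimage"
  else stop("unsupported volume format: ", basename(path),
            " (use .nii, .nii.gz, .mha or .mhd)", call. = FALSE)
}

#' Read a 3D volume from NIfTI or MetaImage
#'
#' Integer payloads (label maps such as PRM codes) round-trip bit-exactly;
#' float payloads round-trip within single-precision tolerance.
#'
#' @param path file path ending in `.nii`, `.nii.gz`, `.mha` or `.mhd`.
#' @return a [ct_volume()] (HU/label/heatmap payload with geometry).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (volume_format(path) == "nifti") {
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) != 3L)
      stop("expected a 3D volume, got ", length(d), "D: ", basename(path),
           call. = FALSE)
    sp <- abs(RNifti::pixdim(img))[1:3]
    xf <- RNifti::xform(img)
    as_volume(array(as.vector(img), d), spacing = sp, origin = xf[1:3, 4])
  } else {
    mi <- read_metaimage(path)
    if (length(mi$dim) != 3L)
      stop("expected a 3D volume, got ", length(mi$dim), "D: ",
           basename(path), call. = FALSE)
    as_volume(array(mi$data, mi$dim), spacing = mi$spacing, origin = mi$origin)
  }
}

#' Write a 3D volume (HU, label map or heatmap) to NIfTI or MetaImage
#'
#' Storage type is chosen from the payload: integer-valued grids in
#' \[0, 255\] are written as unsigned 8-bit (PRM codes), other integer grids
#' as signed 16-bit (HU), and anything else as 32-bit float.
#'
#' @param vol a [ct_volume()] or bare 3D array.
#' @param path destination path (`.nii`, `.nii.gz`, `.mha` or `.mhd`).
#' @param datatype override: one of "uint8", "int16", "float".
#' @return invisibly, `path`.
#' @export
write_volume <- function(vol, path, datatype = NULL) {
  vol <- as_volume(vol)
  if (is.null(datatype)) datatype <- guess_datatype(vol$voxels)
  fmt <- volume_format(path)
  ok <- tryCatch({
    if (fmt == "nifti") {
      img <- RNifti::asNifti(vol$voxels)
      RNifti::pixdim(img) <- vol$spacing
      m <- diag(c(vol$spacing, 1)); m[1:3, 4] <- vol$origin
      RNifti::qform(img) <- structure(m, code = 2L)
      RNifti::writeNifti(img, path, datatype = datatype)
    } else {
      write_metaimage(vol$voxels, path, vol$spacing, vol$origin, datatype)
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("failed to write ", path, ": ", conditionMessage(ok), call. = FALSE)
  if (!file.exists(path))
    stop("failed to write ", path, call. = FALSE)
  invisible(path)
}

guess_datatype <- function(x) {
  if (max(abs(x - round(x))) < 1e-9) {
    if (min(x) >= 0 && max(x) <= 255) "uint8"
    else if (min(x) >= -32768 && max(x) <= 32767) "int16"
    else "float"
  } else "float"
}

#' Read a displacement field from 4D NIfTI
#'
#' @param path 4D NIfTI file whose last axis holds the 3 vector components.
#' @return a [displacement_field()].
#' @export
read_field <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L || d[4] != 3L)
    stop("displacement field must be 4D with 3 components on the last axis,",
         " got [", paste(d, collapse = ", "), "]: ", basename(path),
         call. = FALSE)
  sp <- abs(RNifti::pixdim(img))[1:3]
  xf <- RNifti::xform(img)
  displacement_field(array(as.vector(img), d), spacing = sp,
                     origin = xf[1:3, 4])
}

#' Write a displacement field as 4D NIfTI (32-bit float)
#'
#' The mapping convention (`x_insp = x_exp + u(x_exp)`, components in mm) is
#' recorded in the NIfTI `descrip` header field.
#'
#' @param field a [displacement_field()].
#' @param path destination `.nii`/`.nii.gz` path.
#' @return invisibly, `path`.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "displacement_field"))
  img <- RNifti::asNifti(field$vectors)
  RNifti::pixdim(img) <- c(field$spacing, 1)
  m <- diag(c(field$spacing, 1)); m[1:3, 4] <- field$origin
  RNifti::qform(img) <- structure(m, code = 2L)
  img <- RNifti::asNifti(img, list(descrip = "disp mm: x_insp = x_exp + u"))
  ok <- tryCatch({ RNifti::writeNifti(img, path, datatype = "float"); TRUE },
                 error = function(e) e)
  if (!isTRUE(ok))
    stop("failed to write ", path, ": ", conditionMessage(ok), call. = FALSE)
  invisible(path)
}

# ---- MetaImage (.mha/.mhd) --------------------------------------------------
# Minimal MetaImage codec: uncompressed raster, ASCII header. .mha embeds the
# raster after the header (ElementDataFile = LOCAL); .mhd points to a .raw
# companion. Little-endian on disk.

met_types <- list(
  MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
  MET_CHAR   = list(what = "integer", size = 1L, signed = TRUE),
  MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_INT    = list(what = "integer", size = 4L, signed = TRUE),
  MET_FLOAT  = list(what = "numeric", size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "numeric", size = 8L, signed = TRUE)
)

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list(); nbytes <- 0L
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("truncated MetaImage header", call. = FALSE)
    nbytes <- nbytes + nchar(line, type = "bytes") + 1L
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("bad MetaImage header line: ", line,
                               call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  ndims <- as.integer(hdr$NDims %||% "3")
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  if (length(dims) != ndims) stop("DimSize does not match NDims", call. = FALSE)
  type <- hdr$ElementType %||% "MET_FLOAT"
  tt <- met_types[[type]]
  if (is.null(tt)) stop("unsupported MetaImage ElementType: ", type,
                        call. = FALSE)
  n <- prod(dims)
  endian <- if (identical(hdr$BinaryDataByteOrderMSB, "True") ||
                identical(hdr$ElementByteOrderMSB, "True")) "big" else "little"
  if (identical(hdr$CompressedData, "True"))
    stop("compressed MetaImage not supported", call. = FALSE)
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    data <- readBin(con, tt$what, n = n, size = tt$size, signed = tt$signed,
                    endian = endian)
  } else {
    raw_path <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(raw_path))
      stop("MetaImage raster file not found: ", raw_path, call. = FALSE)
    rcon <- file(raw_path, "rb")
    on.exit(close(rcon), add = TRUE)
    data <- readBin(rcon, tt$what, n = n, size = tt$size, signed = tt$signed,
                    endian = endian)
  }
  if (length(data) != n) stop("truncated MetaImage raster", call. = FALSE)
  spacing <- as.numeric(strsplit(hdr$ElementSpacing %||%
                                   paste(rep("1", ndims), collapse = " "),
                                 "\\s+")[[1]])
  origin <- as.numeric(strsplit(hdr$Offset %||%
                                  paste(rep("0", ndims), collapse = " "),
                                "\\s+")[[1]])
  list(data = data, dim = dims, spacing = spacing, origin = origin)
}

write_metaimage <- function(arr, path, spacing, origin, datatype = "float") {
  type <- switch(datatype, uint8 = "MET_UCHAR", int16 = "MET_SHORT",
                 float = "MET_FLOAT", double = "MET_DOUBLE",
                 stop("unsupported datatype: ", datatype, call. = FALSE))
  tt <- met_types[[type]]
  local_data <- grepl("\\.mha$", tolower(path))
  raw_name <- paste0(sub("\\.mhd$", "", basename(path), ignore.case = TRUE),
                     ".raw")
  hdr <- c(
    "ObjectType = Image",
    paste0("NDims = ", length(dim(arr))),
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    paste0("DimSize = ", paste(dim(arr), collapse = " ")),
    paste0("ElementSpacing = ", paste(spacing, collapse = " ")),
    paste0("Offset = ", paste(origin, collapse = " ")),
    paste0("ElementType = ", type),
    paste0("ElementDataFile = ", if (local_data) "LOCAL" else raw_name)
  )
  payload <- if (tt$what == "integer") as.integer(round(arr)) else
    as.numeric(arr)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  if (local_data) {
    writeBin(payload, con, size = tt$size, endian = "little")
  } else {
    rcon <- file(file.path(dirname(path), raw_name), "wb")
    on.exit(close(rcon), add = TRUE)
    writeBin(payload, rcon, size = tt$size, endian = "little")
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- config and logging -----------------------------------------------------

#' Read and validate a YAML run configuration
#'
#' Unknown keys are rejected; missing keys take package defaults, which equal
#' the study values (PRM cuts -950/-856 HU, 32^3 network input, filters
#' 32/64/128, Adam learning rate 1e-4, five folds).
#'
#' @param path YAML file; `NULL` for pure defaults.
#' @return validated named list of class `run_config`.
#' @export
read_run_config <- function(path = NULL) {
  defaults <- list(
    seed = 1L,
    phantom = list(n_copd = 40L, n_noncopd = 40L),
    prm = list(insp_cut = -950, exp_cut = -856),
    prep = list(input_kind = "prm"),
    train = list(folds = 5L, iterations = 300L, batch = 8L, lr = 1e-4),
    out_dir = "prm3d_run"
  )
  cfg <- defaults
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    bad <- setdiff(names(user), names(defaults))
    if (length(bad)) stop("unknown config keys: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    for (k in names(user)) {
      if (is.list(defaults[[k]])) {
        badk <- setdiff(names(user[[k]]), names(defaults[[k]]))
        if (length(badk)) stop("unknown config keys in '", k, "': ",
                               paste(badk, collapse = ", "), call. = FALSE)
        cfg[[k]][names(user[[k]])] <- user[[k]]
      } else cfg[[k]] <- user[[k]]
    }
  }
  if (cfg$prm$insp_cut >= cfg$prm$exp_cut)
    stop("config: insp_cut must be below exp_cut", call. = FALSE)
  if (cfg$train$folds < 2L) stop("config: folds must be >= 2", call. = FALSE)
  if (cfg$train$lr <= 0 || cfg$train$batch < 1L || cfg$train$iterations < 1L)
    stop("config: invalid training parameters", call. = FALSE)
  if (!cfg$prep$input_kind %in% names(input_kinds()))
    stop("config: unknown input_kind '", cfg$prep$input_kind, "'",
         call. = FALSE)
  class(cfg) <- "run_config"
  cfg
}

#' Timestamped log line (quiet unless `options(prm3d.verbose = TRUE)`)
#' @param ... passed to [sprintf()].
#' @return invisibly, the formatted line.
#' @keywords internal
prm3d_log <- function(...) {
  line <- sprintf("[prm3d %s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  sprintf(...))
  if (isTRUE(getOption("prm3d.verbose", FALSE))) message(line)
  invisible(line)
}
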