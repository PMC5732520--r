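#' Construct a CT volume
#'
#' A `ct_volume` is a 3-D array of CT attenuation values (Hounsfield units)
#' together with the voxel spacing, the world position of the centre of voxel
#' `[1,1,1]`, and the mapping of array axes to world axes. All geometry in the
#' pipeline is expressed in world millimetres; array axis `i` runs along world
#' x, `j` along y, `k` along z (the identity orientation) unless stated
#' otherwise.
#'
#' @param values 3-D numeric array of attenuation values (HU).
#' @param spacing Numeric length-3, per-axis voxel size in mm; all `> 0`.
#' @param origin Numeric length-3, world coordinate (mm) of the centre of the
#'   first voxel. Default `c(0, 0, 0)`.
#' @param axes Character length-3 naming the world axis of each array axis.
#'   Only the identity `c("x", "y", "z")` is produced by the readers.
#'
#' @return An object of class `ct_volume`.
#' @export
#' @examples
#' vol <- ct_volume(array(100, c(4, 4, 4)), spacing = c(0.3, 0.3, 0.5))
#' dim(vol$values)
ct_volume <- function(values, spacing, origin = c(0, 0, 0),
                      axes = c("x", "y", "z")) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be a 3-D array", call. = FALSE)
  }
  if (any(dim(values) < 1L)) stop("`values` must be non-empty", call. = FALSE)
  if (!all(is.finite(values))) {
    stop("attenuation values must all be finite", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 positive finite values (mm)", call. = FALSE)
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("`origin` must be 3 finite values (mm)", call. = FALSE)
  }
  structure(
    list(values = values, spacing = spacing, origin = origin, axes = axes),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<ct_volume> %d x %d x %d voxels, spacing (%.3g, %.3g, %.3g) mm\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]
  ))
  cat(sprintf(
    "  origin (%.3g, %.3g, %.3g) mm; HU range [%.4g, %.4g]\n",
    x$origin[1], x$origin[2], x$origin[3],
    min(x$values), max(x$values)
  ))
  invisible(x)
}

#' World coordinates of voxel centres
#'
#' @param volume A [ct_volume()].
#' @param axis Integer 1..3; which axis.
#' @return Numeric vector of world coordinates (mm) of voxel centres along
#'   `axis`.
#' @keywords internal
voxel_centers <- function(volume, axis) {
  n <- dim(volume$values)[axis]
  volume$origin[axis] + (seq_len(n) - 1) * volume$spacing[axis]
}

#' Load a CT volume from disk
#'
#' Reads a CT volume into world coordinates (mm). Three on-disk forms are
#' supported: NIfTI (`.nii` / `.nii.gz`), a directory of single-frame DICOM
#' files (one slice per file; the `RescaleSlope`/`RescaleIntercept` tags are
#' honoured so returned values are HU), and a raw binary array with a JSON
#' sidecar describing `shape`, `spacing`, `origin` and `dtype`.
#'
#' @param path File (NIfTI, raw) or directory (DICOM) path.
#' @param format One of `"nifti"`, `"dicom_dir"`, `"raw"`. Default guesses
#'   from the path: directories are DICOM, `.nii`/`.nii.gz` NIfTI, `.bin`
#'   raw (expecting `<path>.json` alongside).
#' @return A [ct_volume()].
#' @export
load_volume <- function(path, format = c("auto", "nifti", "dicom_dir", "raw")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) {
      "dicom_dir"
    } else if (grepl("\\.nii(\\.gz)?$", path)) {
      "nifti"
    } else {
      "raw"
    }
  }
  if (format == "dicom_dir") {
    if (!dir.exists(path)) {
      stop("DICOM directory not found: ", path, call. = FALSE)
    }
    return(read_dicom_series(path))
  }
  if (!file.exists(path)) {
    stop("volume file not found: ", path, call. = FALSE)
  }
  switch(format,
    nifti = read_nifti_volume(path),
    raw = read_raw_volume(path)
  )
}

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vals <- as.array(img)
  if (length(dim(vals)) != 3L) {
    stop("expected a 3-D NIfTI volume: ", path, call. = FALSE)
  }
  spacing <- RNifti::pixdim(img)[1:3]
  # world position of voxel (1,1,1) centre from the qform/sform translation
  xf <- tryCatch(RNifti::xform(img), error = function(e) NULL)
  origin <- if (!is.null(xf)) as.numeric(xf[1:3, 4]) else c(0, 0, 0)
  ct_volume(vals, spacing = spacing, origin = origin)
}

#' Save a CT volume
#'
#' Writes NIfTI (`.nii`/`.nii.gz`) or raw-binary + JSON sidecar, matching
#' [load_volume()].
#'
#' @param volume A [ct_volume()].
#' @param path Output path; format chosen from the extension.
#' @return `path`, invisibly.
#' @export
save_volume <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::asNifti(volume$values)
    mat <- diag(4)
    diag(mat)[1:3] <- volume$spacing
    mat[1:3, 4] <- volume$origin
    img <- RNifti::`sform<-`(img, structure(mat, code = 2L))
    img <- RNifti::`qform<-`(img, structure(mat, code = 2L))
    RNifti::pixdim(img) <- volume$spacing
    RNifti::writeNifti(img, path)
  } else {
    writeBin(as.vector(volume$values), path, size = 8, endian = "little")
    jsonlite::write_json(
      list(
        shape = dim(volume$values), spacing = volume$spacing,
        origin = volume$origin, dtype = "float64"
      ),
      paste0(path, ".json"),
      auto_unbox = FALSE, digits = NA
    )
  }
  invisible(path)
}

read_raw_volume <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop("raw volume sidecar not found: ", sidecar, call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  shape <- as.integer(meta$shape)
  n <- prod(shape)
  size <- switch(meta$dtype,
    float64 = 8L, float32 = 4L, int16 = 2L,
    stop("unsupported raw dtype: ", meta$dtype, call. = FALSE)
  )
  what <- if (meta$dtype == "int16") integer() else numeric()
  vals <- readBin(path, what, n = n, size = size, endian = "little")
  if (length(vals) != n) {
    stop("raw volume truncated: ", path, call. = FALSE)
  }
  ct_volume(array(as.numeric(vals), shape),
    spacing = meta$spacing, origin = meta$origin
  )
}
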