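# Minimal DICOM support: uncompressed single-frame files, little-endian
# explicit-VR transfer syntax, one slice per file. Covers the tags a CT
# series needs (geometry + rescale); anything fancier should be converted
# to NIfTI upstream.

DCM_TAGS <- list(
  rows = c(0x0028L, 0x0010L),
  cols = c(0x0028L, 0x0011L),
  bits_allocated = c(0x0028L, 0x0100L),
  pixel_representation = c(0x0028L, 0x0103L),
  pixel_spacing = c(0x0028L, 0x0030L),
  slice_thickness = c(0x0018L, 0x0050L),
  image_position = c(0x0020L, 0x0032L),
  instance_number = c(0x0020L, 0x0013L),
  rescale_intercept = c(0x0028L, 0x1052L),
  rescale_slope = c(0x0028L, 0x1053L),
  pixel_data = c(0x7FE0L, 0x0010L)
)

read_uint16 <- function(con) {
  b <- readBin(con, "integer", n = 1L, size = 2L, signed = FALSE,
               endian = "little")
  if (length(b) == 0L) NA_integer_ else b
}

#' Read one DICOM file (minimal subset)
#' @param path File path.
#' @return List of parsed elements keyed by the names in `DCM_TAGS`.
#' @keywords internal
read_dicom_file <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  preamble <- readBin(con, "raw", n = 132L)
  if (length(preamble) < 132L ||
      rawToChar(preamble[129:132]) != "DICM") {
    stop("not a DICOM file (missing DICM magic): ", path, call. = FALSE)
  }
  out <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  repeat {
    group <- read_uint16(con)
    if (is.na(group)) break
    element <- read_uint16(con)
    vr <- rawToChar(readBin(con, "raw", n = 2L))
    if (vr %in% long_vrs) {
      readBin(con, "raw", n = 2L) # reserved
      len <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    } else if (grepl("^[A-Z]{2}$", vr)) {
      len <- read_uint16(con)
    } else {
      stop("unsupported (implicit-VR?) DICOM encoding in ", path,
           call. = FALSE)
    }
    key <- NULL
    for (nm in names(DCM_TAGS)) {
      tg <- DCM_TAGS[[nm]]
      if (group == tg[1] && element == tg[2]) key <- nm
    }
    if (is.null(key)) {
      seek(con, len, origin = "current")
      next
    }
    if (key == "pixel_data") {
      nr <- out$rows
      nc <- out$cols
      if (is.null(nr) || is.null(nc)) {
        stop("PixelData before Rows/Columns in ", path, call. = FALSE)
      }
      signed <- isTRUE(out$pixel_representation == 1L)
      px <- readBin(con, "integer", n = nr * nc, size = 2L,
                    signed = signed, endian = "little")
      # row-major on disk -> [col, row] then transpose to [row, col]
      out$pixel_data <- t(matrix(px, nrow = nc, ncol = nr))
    } else {
      bytes <- readBin(con, "raw", n = len)
      val <- rawToChar(bytes)
      out[[key]] <- switch(vr,
        US = readBin(bytes, "integer", n = len / 2L, size = 2L,
                     signed = FALSE, endian = "little"),
        DS = as.numeric(strsplit(trimws(val), "\\\\")[[1]]),
        IS = as.integer(strsplit(trimws(val), "\\\\")[[1]]),
        val
      )
    }
  }
  for (k in c("rows", "cols", "pixel_data")) {
    if (is.null(out[[k]])) {
      stop("DICOM file missing required element ", k, ": ", path,
           call. = FALSE)
    }
  }
  out
}

#' Read a DICOM series directory as a CT volume
#'
#' Slices are ordered by `ImagePositionPatient` z; the rescale tags are
#' applied so values are HU. Array axes follow (column, row, slice) so that
#' axis 1 is world x for an axial identity-orientation series.
#'
#' @param path Directory containing one `.dcm` file per slice.
#' @return A [ct_volume()].
#' @keywords internal
read_dicom_series <- function(path) {
  files <- list.files(path, pattern = "\\.dcm$", full.names = TRUE)
  if (length(files) == 0L) {
    stop("no .dcm files in directory: ", path, call. = FALSE)
  }
  slices <- lapply(files, read_dicom_file)
  z <- vapply(slices, function(s) {
    if (!is.null(s$image_position)) s$image_position[3] else NA_real_
  }, numeric(1))
  if (anyNA(z)) {
    ord <- order(vapply(slices, function(s) {
      if (!is.null(s$instance_number)) s$instance_number[1] else NA_integer_
    }, integer(1)))
  } else {
    ord <- order(z)
  }
  slices <- slices[ord]
  z <- z[ord]
  first <- slices[[1]]
  ps <- first$pixel_spacing %||% c(1, 1)
  if (length(slices) > 1L && !anyNA(z)) {
    dz <- diff(z)
    if (max(dz) - min(dz) > 1e-4 * max(abs(dz))) {
      stop("inconsistent slice spacing in DICOM series: ", path,
           call. = FALSE)
    }
    slice_gap <- dz[1]
  } else {
    slice_gap <- first$slice_thickness %||% 1
  }
  slope <- (first$rescale_slope %||% 1)[1]
  intercept <- (first$rescale_intercept %||% 0)[1]
  nr <- first$rows[1]
  nc <- first$cols[1]
  vals <- array(0, c(nc, nr, length(slices)))
  for (i in seq_along(slices)) {
    s <- slices[[i]]
    if (s$rows[1] != nr || s$cols[1] != nc) {
      stop("inconsistent slice dimensions in DICOM series: ", path,
           call. = FALSE)
    }
    vals[, , i] <- t(s$pixel_data) * slope + intercept
  }
  origin <- if (!is.null(first$image_position)) {
    first$image_position
  } else {
    c(0, 0, 0)
  }
  # PixelSpacing is (row gap, column gap); array axis 1 is columns (world x)
  ct_volume(vals, spacing = c(ps[2], ps[1], slice_gap), origin = origin)
}

dcm_element <- function(group, element, vr, bytes) {
  if (length(bytes) %% 2L == 1L) bytes <- c(bytes, as.raw(0L))
  header <- c(
    writeBin(c(group, element), raw(), size = 2L, endian = "little"),
    charToRaw(vr)
  )
  if (vr %in% c("OB", "OW")) {
    c(header, as.raw(c(0, 0)),
      writeBin(length(bytes), raw(), size = 4L, endian = "little"), bytes)
  } else {
    c(header,
      writeBin(as.integer(length(bytes)), raw(), size = 2L,
               endian = "little")[1:2], bytes)
  }
}

dcm_ds <- function(x) charToRaw(paste(format(x, trim = TRUE), collapse = "\\"))

#' Write a CT volume as a minimal DICOM series
#'
#' One explicit-VR little-endian file per slice, with geometry and rescale
#' tags. Intended for building test fixtures and interchange with DICOM
#' viewers; stored values are `(HU - intercept) / slope` as signed 16-bit.
#'
#' @param volume A [ct_volume()].
#' @param dir Output directory (created if needed).
#' @param rescale_slope,rescale_intercept Rescale tags to encode.
#' @return `dir`, invisibly.
#' @export
write_dicom_series <- function(volume, dir, rescale_slope = 1,
                               rescale_intercept = -1024) {
  stopifnot(inherits(volume, "ct_volume"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(volume$values)
  for (k in seq_len(d[3])) {
    stored <- round((volume$values[, , k] - rescale_intercept) / rescale_slope)
    if (any(stored < -32768 | stored > 32767)) {
      stop("stored values overflow int16; adjust rescale", call. = FALSE)
    }
    # disk layout row-major (x fastest); stored is [x, y], so R's
    # column-major vectorisation is already the disk order
    px <- writeBin(as.integer(stored), raw(), size = 2L, endian = "little")
    ipp <- c(volume$origin[1], volume$origin[2],
             volume$origin[3] + (k - 1) * volume$spacing[3])
    body <- c(
      dcm_element(0x0018L, 0x0050L, "DS", dcm_ds(volume$spacing[3])),
      dcm_element(0x0020L, 0x0013L, "IS", charToRaw(as.character(k))),
      dcm_element(0x0020L, 0x0032L, "DS", dcm_ds(ipp)),
      dcm_element(0x0028L, 0x0010L, "US",
                  writeBin(as.integer(d[2]), raw(), size = 2L,
                           endian = "little")),
      dcm_element(0x0028L, 0x0011L, "US",
                  writeBin(as.integer(d[1]), raw(), size = 2L,
                           endian = "little")),
      dcm_element(0x0028L, 0x0030L, "DS",
                  dcm_ds(c(volume$spacing[2], volume$spacing[1]))),
      dcm_element(0x0028L, 0x0100L, "US",
                  writeBin(16L, raw(), size = 2L, endian = "little")),
      dcm_element(0x0028L, 0x0103L, "US",
                  writeBin(1L, raw(), size = 2L, endian = "little")),
      dcm_element(0x0028L, 0x1052L, "DS", dcm_ds(rescale_intercept)),
      dcm_element(0x0028L, 0x1053L, "DS", dcm_ds(rescale_slope)),
      dcm_element(0x7FE0L, 0x0010L, "OW", px)
    )
    con <- file(file.path(dir, sprintf("slice%04d.dcm", k)), "wb")
    writeBin(raw(128L), con)
    writeBin(charToRaw("DICM"), con)
    writeBin(body, con)
    close(con)
  }
  invisible(dir)
}
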