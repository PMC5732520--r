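#' Describe a density calibration phantom
#'
#' A calibration phantom holds rods of known hydroxyapatite-equivalent
#' mineral density that are scanned alongside the specimen; averaging the HU
#' inside each rod and regressing density on HU gives the scanner's
#' HU-to-density line. Rod locations are supplied explicitly (world-space
#' cylinders or voxel masks) — the phantom is never auto-detected.
#'
#' @param rod_density Numeric, nominal mineral density of each rod in
#'   mg/cm^3, strictly increasing; at least 2 rods. The reference phantom
#'   carries rods at 0, 100 and 200 mg/cm^3.
#' @param rod_regions List, one entry per rod: either a list
#'   `list(p0=, p1=, radius=)` describing a world-space cylinder from `p0`
#'   to `p1` (mm), or a logical array matching the volume to be sampled.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(rod_density = c(0, 100, 200), rod_regions) {
  rod_density <- as.numeric(rod_density)
  if (length(rod_density) < 2L) stop("need at least 2 rods", call. = FALSE)
  if (any(diff(rod_density) <= 0)) {
    stop("rod densities must be strictly increasing", call. = FALSE)
  }
  if (length(rod_regions) != length(rod_density)) {
    stop("one region per rod required", call. = FALSE)
  }
  structure(list(rod_density = rod_density, rod_regions = rod_regions),
            class = "phantom_spec")
}

rod_region_mask <- function(volume, region) {
  if (is.array(region) && is.logical(region)) {
    if (!identical(dim(region), dim(volume$values))) {
      stop("rod mask dimensions do not match the volume", call. = FALSE)
    }
    return(region)
  }
  # cylinder: voxel centre within `radius` of segment p0-p1
  cx <- voxel_centers(volume, 1)
  cy <- voxel_centers(volume, 2)
  cz <- voxel_centers(volume, 3)
  g <- expand.grid(x = cx, y = cy, z = cz, KEEP.OUT.ATTRS = FALSE)
  p0 <- as.numeric(region$p0)
  p1 <- as.numeric(region$p1)
  ax <- p1 - p0
  len2 <- sum(ax^2)
  if (len2 <= 0) stop("degenerate rod cylinder", call. = FALSE)
  dx <- g$x - p0[1]; dy <- g$y - p0[2]; dz <- g$z - p0[3]
  t <- (dx * ax[1] + dy * ax[2] + dz * ax[3]) / len2
  inside_t <- t >= 0 & t <= 1
  rx <- dx - t * ax[1]; ry <- dy - t * ax[2]; rz <- dz - t * ax[3]
  inside <- inside_t & (rx^2 + ry^2 + rz^2 <= region$radius^2)
  array(inside, dim(volume$values))
}

#' Mean HU inside each phantom rod
#'
#' A voxel belongs to a rod iff its centre lies inside the rod region.
#'
#' @param volume A [ct_volume()].
#' @param spec A [phantom_spec()].
#' @return Numeric vector of per-rod mean HU, in rod order.
#' @export
rod_mean_hu <- function(volume, spec) {
  stopifnot(inherits(volume, "ct_volume"), inherits(spec, "phantom_spec"))
  vapply(seq_along(spec$rod_regions), function(i) {
    m <- rod_region_mask(volume, spec$rod_regions[[i]])
    if (!any(m)) {
      stop("rod region ", i, " contains no voxel centres", call. = FALSE)
    }
    mean(volume$values[m])
  }, numeric(1))
}

#' Fit the HU-to-density calibration line
#'
#' Ordinary least squares of rod density (mg/cm^3) on rod mean HU:
#' `density = slope * HU + intercept`.
#'
#' @param rod_hu Numeric, per-rod mean HU.
#' @param rod_density Numeric, per-rod nominal density (mg/cm^3).
#' @return Object of class `density_calibration` with fields `slope`
#'   ((mg/cm^3)/HU), `intercept` (mg/cm^3), `fit_r2`, the inputs, and a
#'   `warnings` character vector (non-empty if the fitted slope is
#'   negative).
#' @export
#' @examples
#' fit_calibration(c(10, 110, 210), c(0, 100, 200))
fit_calibration <- function(rod_hu, rod_density) {
  rod_hu <- as.numeric(rod_hu)
  rod_density <- as.numeric(rod_density)
  if (length(rod_hu) != length(rod_density) || length(rod_hu) < 2L) {
    stop("need matching HU/density vectors of length >= 2", call. = FALSE)
  }
  if (diff(range(rod_hu)) == 0) {
    stop("degenerate calibration: all rod HU equal", call. = FALSE)
  }
  fit <- stats::lm(rod_density ~ rod_hu)
  co <- stats::coef(fit)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((rod_density - mean(rod_density))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  warnings <- character()
  if (co[["rod_hu"]] <= 0) {
    warnings <- "calibration slope is not positive; check rod regions"
  }
  structure(
    list(
      slope = unname(co[["rod_hu"]]), intercept = unname(co[["(Intercept)"]]),
      fit_r2 = r2, rod_hu = rod_hu, rod_density = rod_density,
      warnings = warnings
    ),
    class = "density_calibration"
  )
}

#' @export
print.density_calibration <- function(x, ...) {
  cat(sprintf(
    "<density_calibration> density = %.6g * HU + %.6g mg/cm^3 (R^2 = %.4f)\n",
    x$slope, x$intercept, x$fit_r2
  ))
  if (length(x$warnings)) cat("  warning:", x$warnings, "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.density_calibration <- function(x, ...) {
  tibble::tibble(
    rod = seq_along(x$rod_hu),
    hu = x$rod_hu,
    density = x$rod_density,
    fitted = x$slope * x$rod_hu + x$intercept
  )
}

#' @exportS3Method generics::glance
glance.density_calibration <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, intercept = x$intercept, fit_r2 = x$fit_r2,
    n_rods = length(x$rod_hu)
  )
}

#' Convert HU to equivalent mineral density
#'
#' Applies the calibration line and converts mg/cm^3 to g/cm^3. The result
#' may be negative for very low HU; the material laws clamp downstream.
#'
#' @param cal A [fit_calibration()] result.
#' @param hu Numeric HU values.
#' @return Equivalent mineral density in g/cm^3.
#' @export
hu_to_density <- function(cal, hu) {
  stopifnot(inherits(cal, "density_calibration"))
  (cal$slope * hu + cal$intercept) / 1000
}

#' Write / read a calibration record as JSON
#' @param cal A [fit_calibration()] result.
#' @param path JSON file path.
#' @return `path` (write) or a `density_calibration` (read).
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "density_calibration"))
  jsonlite::write_json(
    cal[c("slope", "intercept", "fit_r2", "rod_hu", "rod_density")],
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      slope = x$slope, intercept = x$intercept, fit_r2 = x$fit_r2,
      rod_hu = x$rod_hu, rod_density = x$rod_density, warnings = character()
    ),
    class = "density_calibration"
  )
}
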