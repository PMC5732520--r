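#' Density-to-modulus power law (vertebral form), pre-clamp
#'
#' `E = 1890 * rho^1.92` MPa for `rho > 0` and `E = 0.001` MPa at
#' `rho <= 0` (the zero-density floor of the published pilot equations;
#' the pipeline's 0.01 MPa modulus clamp is applied later by
#' [clamp_modulus()], so the raw value here can be below the clamp).
#'
#' @param rho Equivalent mineral density (g/cm^3).
#' @return Young's modulus in MPa, before clamping.
#' @export
#' @examples
#' keller_modulus(1.0) # 1890
keller_modulus <- function(rho) {
  ifelse(rho > 0, 1890 * rho^1.92, 0.001)
}

#' Density-to-compressive-yield power law (vertebral form)
#'
#' `sigma_c = 284 * rho^2.27` MPa for `rho > 0.2`; below that the yield is
#' the sentinel `1e20` MPa, i.e. low-density elements never yield.
#'
#' @param rho Equivalent mineral density (g/cm^3).
#' @return Compressive yield stress in MPa.
#' @export
#' @examples
#' keller_yield(1.0) # 284
keller_yield <- function(rho) {
  ifelse(rho > 0.2, 284 * rho^2.27, 1e20)
}

#' Clamp a raw modulus to the admissible range
#'
#' Moduli below 0.01 MPa become 0.01 MPa; above 20 GPa become 20 GPa.
#' @param E_raw Raw modulus (MPa).
#' @return Clamped modulus (MPa).
#' @export
clamp_modulus <- function(E_raw) {
  pmin(pmax(E_raw, 0.01), 20000)
}

#' Define a density-property law
#'
#' The vertebral power law above is the normative default (its coefficients
#' are printed); other literature laws (femoral forms) can be registered by
#' supplying their functions and a citation.
#'
#' @param name Identifier.
#' @param modulus_fn Function rho (g/cm^3) -> E (MPa), pre-clamp.
#' @param yield_fn Function rho (g/cm^3) -> compressive yield (MPa).
#' @param citation Reference string.
#' @return Object of class `material_law`.
#' @export
material_law <- function(name = "keller_vertebra",
                         modulus_fn = keller_modulus,
                         yield_fn = keller_yield,
                         citation = "vertebral power law (pilot-adopted)") {
  stopifnot(is.function(modulus_fn), is.function(yield_fn))
  structure(list(name = name, modulus_fn = modulus_fn, yield_fn = yield_fn,
                 citation = citation),
            class = "material_law")
}

#' @export
print.material_law <- function(x, ...) {
  cat(sprintf("<material_law> %s (%s)\n", x$name, x$citation))
  invisible(x)
}

#' Per-element mean HU
#'
#' Each tet's HU is the mean over CT voxels whose centres lie inside it;
#' tets too small to contain a voxel centre fall back to trilinear
#' interpolation at the tet centroid.
#'
#' @param volume A [ct_volume()].
#' @param mesh A [tet_mesh()].
#' @return Numeric vector, one HU value per tet.
#' @export
element_average_hu <- function(volume, mesh) {
  stopifnot(inherits(volume, "ct_volume"), inherits(mesh, "tet_mesh"))
  if (!is.null(mesh$ct_transform)) {
    # map model coordinates back into the CT frame before sampling
    tr <- mesh$ct_transform
    mesh$nodes <- sweep(mesh$nodes, 2, tr$offset, "+") %*% tr$rotation
    mesh$ct_transform <- NULL
  }
  cx <- voxel_centers(volume, 1)
  cy <- voxel_centers(volume, 2)
  cz <- voxel_centers(volume, 3)
  d <- dim(volume$values)
  out <- numeric(nrow(mesh$tets))
  for (e in seq_len(nrow(mesh$tets))) {
    vts <- mesh$nodes[mesh$tets[e, ], , drop = FALSE]
    lo <- apply(vts, 2, min)
    hi <- apply(vts, 2, max)
    ix <- which(cx >= lo[1] & cx <= hi[1])
    iy <- which(cy >= lo[2] & cy <= hi[2])
    iz <- which(cz >= lo[3] & cz <= hi[3])
    hu <- NA_real_
    if (length(ix) && length(iy) && length(iz)) {
      g <- as.matrix(expand.grid(x = cx[ix], y = cy[iy], z = cz[iz],
                                 KEEP.OUT.ATTRS = FALSE))
      bc <- barycentric_coords(vts, g)
      inside <- rowSums(bc >= -1e-9) == 4L
      if (any(inside)) {
        gi <- expand.grid(i = ix, j = iy, k = iz, KEEP.OUT.ATTRS = FALSE)
        lin <- gi$i + (gi$j - 1L) * d[1] + (gi$k - 1L) * d[1] * d[2]
        hu <- mean(volume$values[lin[inside]])
      }
    }
    if (is.na(hu)) {
      hu <- trilinear_at(volume, colMeans(vts))
      if (is.na(hu)) {
        stop("element ", e, " lies outside the CT volume", call. = FALSE)
      }
    }
    out[e] <- hu
  }
  out
}

# barycentric coordinates of points (n x 3) in tet vts (4 x 3)
barycentric_coords <- function(vts, p) {
  t_ <- t(vts[1:3, , drop = FALSE]) - vts[4, ]
  rel <- sweep(p, 2, vts[4, ], "-")
  lam <- t(solve(t_, t(rel)))
  cbind(lam, 1 - rowSums(lam))
}

trilinear_at <- function(volume, p) {
  d <- dim(volume$values)
  fr <- (p - volume$origin) / volume$spacing + 1
  # clamp to the valid interpolation box (half-voxel edge effects)
  fr <- pmin(pmax(fr, 1), d)
  if (any((p - volume$origin) / volume$spacing + 1 < 0.5) ||
      any((p - volume$origin) / volume$spacing + 1 > d + 0.5)) {
    return(NA_real_)
  }
  i0 <- pmin(floor(fr), d - 1e-9)
  i0 <- pmax(floor(i0), 1)
  i1 <- pmin(i0 + 1, d)
  w <- fr - i0
  v <- volume$values
  val <- 0
  for (bx in 0:1) for (by in 0:1) for (bz in 0:1) {
    wx <- if (bx) w[1] else 1 - w[1]
    wy <- if (by) w[2] else 1 - w[2]
    wz <- if (bz) w[3] else 1 - w[3]
    ii <- if (bx) i1[1] else i0[1]
    jj <- if (by) i1[2] else i0[2]
    kk <- if (bz) i1[3] else i0[3]
    val <- val + wx * wy * wz * v[ii, jj, kk]
  }
  val
}

#' Assign element materials from CT
#'
#' Runs the full per-element chain: element-average HU, calibration to
#' equivalent density, power-law modulus with the clamp, power-law
#' compressive yield, tensile yield at `tensile_ratio` times compressive,
#' Poisson ratio 0.3. Shell elements run through the same chain with their
#' HU fixed at `shell_hu` (cortical bone analog).
#'
#' @param mesh A [tet_mesh()].
#' @param volume A [ct_volume()].
#' @param cal A [fit_calibration()] result.
#' @param law A [material_law()] (default the vertebral power law).
#' @param shell_hu Assumed HU of the cortical shell (default 1000).
#' @param tensile_ratio Tensile/compressive yield ratio (default 0.8).
#' @return Object of class `element_materials`: a list with tibbles `tets`
#'   and `shell`, each with columns `element`, `hu`, `rho`, `E`, `nu`,
#'   `sigma_c`, `sigma_t`.
#' @export
assign_materials <- function(mesh, volume, cal, law = material_law(),
                             shell_hu = 1000, tensile_ratio = 0.8) {
  stopifnot(inherits(law, "material_law"))
  hu <- element_average_hu(volume, mesh)
  mat_chain <- function(hu, idx) {
    rho <- hu_to_density(cal, hu)
    sigma_c <- law$yield_fn(rho)
    tibble::tibble(
      element = idx, hu = hu, rho = rho,
      E = clamp_modulus(law$modulus_fn(rho)),
      nu = 0.3,
      sigma_c = sigma_c,
      sigma_t = tensile_ratio * sigma_c
    )
  }
  shell_tbl <- if (nrow(mesh$shell) > 0L) {
    mat_chain(rep(shell_hu, nrow(mesh$shell)), seq_len(nrow(mesh$shell)))
  } else {
    mat_chain(numeric(0), integer(0))
  }
  structure(
    list(tets = mat_chain(hu, seq_along(hu)), shell = shell_tbl,
         law = law$name, tensile_ratio = tensile_ratio,
         shell_hu = shell_hu),
    class = "element_materials"
  )
}

#' @export
print.element_materials <- function(x, ...) {
  cat(sprintf(
    "<element_materials> %d tets, %d shells (law %s)\n  E range [%.4g, %.4g] MPa\n",
    nrow(x$tets), nrow(x$shell), x$law, min(x$tets$E), max(x$tets$E)
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.element_materials <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$tets, part = "tet", .before = 1),
    dplyr::mutate(x$shell, part = "shell", .before = 1)
  )
}

#' Write per-element materials as CSV
#' @param materials An [assign_materials()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_materials_csv <- function(materials, path) {
  utils::write.csv(tidy(materials), path, row.names = FALSE)
  invisible(path)
}

#' Calibrate the Drucker-Prager surface from uniaxial strengths
#'
#' Finds `alpha` and `k` of the pressure-sensitive yield function
#' `f(sigma) = alpha * I1 + sqrt(J2) - k` such that the surface passes
#' through uniaxial compression at `sigma_c` and uniaxial tension at
#' `tensile_ratio * sigma_c`:
#' `alpha = (1 - r) / (sqrt(3) * (1 + r))`, `k = r * sigma_c *
#' (alpha + 1/sqrt(3))`. `tensile_ratio = 1` recovers the von Mises
#' cylinder (`alpha = 0`, `k = sigma_c / sqrt(3)`).
#'
#' @param sigma_c Compressive yield stress (MPa), `> 0`.
#' @param tensile_ratio Tensile/compressive ratio in `(0, 1]` (default
#'   0.8).
#' @return Object of class `dp_params`: list with `alpha`, `k` (MPa).
#' @export
#' @examples
#' dp_params(100, 0.8)
dp_params <- function(sigma_c, tensile_ratio = 0.8) {
  stopifnot(all(sigma_c > 0), tensile_ratio > 0, tensile_ratio <= 1)
  r <- tensile_ratio
  alpha <- (1 - r) / (sqrt(3) * (1 + r))
  k <- r * sigma_c * (alpha + 1 / sqrt(3))
  structure(list(alpha = alpha, k = k), class = "dp_params")
}

#' Evaluate the Drucker-Prager yield function
#'
#' `f = alpha * I1 + sqrt(J2) - k`, negative inside the elastic domain.
#'
#' @param stress Symmetric 3x3 stress (MPa), or a length-6 Voigt vector
#'   `(s11, s22, s33, s12, s23, s31)`.
#' @param params A [dp_params()].
#' @return `f` in MPa.
#' @export
dp_yield_value <- function(stress, params) {
  if (is.matrix(stress) && all(dim(stress) == c(3, 3))) {
    sv <- c(stress[1, 1], stress[2, 2], stress[3, 3],
            stress[1, 2], stress[2, 3], stress[3, 1])
  } else {
    sv <- as.numeric(stress)
  }
  i1 <- sv[1] + sv[2] + sv[3]
  m <- i1 / 3
  j2 <- 0.5 * ((sv[1] - m)^2 + (sv[2] - m)^2 + (sv[3] - m)^2) +
    sv[4]^2 + sv[5]^2 + sv[6]^2
  params$alpha * i1 + sqrt(j2) - params$k
}
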