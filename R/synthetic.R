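# Synthetic specimens: calibrated CT phantoms of femur-like primitives,
# bilinear force-displacement recordings, and cohorts with the age /
# laterality / instrument-noise structure the validation statistics
# assume.

#' Design a synthetic CT phantom
#'
#' The phantom emulates a calibrated CT acquisition: a specimen (bar,
#' cylinder, or a femur-like union of a shaft, an angled neck and a
#' spherical head) with a cortical rim and a trabecular interior, plus
#' three calibration rods, voxelised at the scanner spacing with
#' partial-volume emulation (supersampled averaging) and optional Gaussian
#' HU noise.
#'
#' @param geometry `"bar"`, `"cylinder"` or `"sphere_capped_cylinder"`.
#' @param dimensions Named numeric: for `bar`, `c(x=, y=, z=)` mm; for
#'   `cylinder`, `c(radius=, length=)`; for `sphere_capped_cylinder`,
#'   `c(shaft_radius=, shaft_length=, neck_radius=, neck_length=,
#'   head_radius=, neck_angle_deg=)`.
#' @param cortical_thickness Cortical rim thickness (mm, default 3).
#' @param cortical_density Cortical equivalent density (g/cm^3, default
#'   1.1).
#' @param trabecular_density Interior equivalent density: a constant
#'   (g/cm^3, default 0.3) or a function `(x, y, z) -> rho`.
#' @param rod_hu Noise-free HU means of the three rods (default
#'   `c(0, 100, 200)`, matching rod densities 0/100/200 mg/cm^3 under the
#'   identity calibration).
#' @param rod_density Nominal rod densities (mg/cm^3).
#' @param noise_sigma Additive Gaussian HU noise SD (default 0).
#' @param spacing Voxel spacing mm (default `c(0.3, 0.3, 0.5)`, the
#'   scanner acquisition values).
#' @param supersample Sub-voxel samples per axis for partial-volume
#'   emulation (default 8).
#' @param cal_slope,cal_intercept The generator's inverse calibration:
#'   specimen HU = `(rho * 1000 - cal_intercept) / cal_slope` (defaults 1
#'   and 0, so HU = 1000 rho).
#' @param seed Integer seed; fixed seed gives bit-identical volumes.
#' @return Object of class `phantom_design`.
#' @export
phantom_design <- function(geometry = c("bar", "cylinder",
                                        "sphere_capped_cylinder"),
                           dimensions = NULL,
                           cortical_thickness = 3,
                           cortical_density = 1.1,
                           trabecular_density = 0.3,
                           rod_hu = c(0, 100, 200),
                           rod_density = c(0, 100, 200),
                           noise_sigma = 0,
                           spacing = c(0.3, 0.3, 0.5),
                           supersample = 8L,
                           cal_slope = 1, cal_intercept = 0,
                           seed = 1L) {
  geometry <- match.arg(geometry)
  if (is.null(dimensions)) {
    dimensions <- switch(geometry,
      bar = c(x = 10, y = 10, z = 40),
      cylinder = c(radius = 8, length = 60),
      sphere_capped_cylinder = c(shaft_radius = 8, shaft_length = 40,
                                 neck_radius = 6, neck_length = 15,
                                 head_radius = 10, neck_angle_deg = 20)
    )
  }
  if (any(dimensions <= 0)) stop("dimensions must be positive", call. = FALSE)
  structure(
    list(geometry = geometry, dimensions = dimensions,
         cortical_thickness = cortical_thickness,
         cortical_density = cortical_density,
         trabecular_density = trabecular_density,
         rod_hu = rod_hu, rod_density = rod_density,
         noise_sigma = noise_sigma, spacing = as.numeric(spacing),
         supersample = as.integer(supersample),
         cal_slope = cal_slope, cal_intercept = cal_intercept,
         seed = as.integer(seed)),
    class = "phantom_design"
  )
}

# approximate SDF of the specimen (exact sign; magnitude exact near the
# boundary for the band test the generator needs)
phantom_sdf <- function(design) {
  dm <- design$dimensions
  switch(design$geometry,
    bar = function(x, y, z) {
      pmax(pmax(abs(x - dm["x"] / 2) - dm["x"] / 2,
                abs(y - dm["y"] / 2) - dm["y"] / 2),
           abs(z - dm["z"] / 2) - dm["z"] / 2)
    },
    cylinder = function(x, y, z) {
      pmax(sqrt(x^2 + y^2) - dm["radius"],
           abs(z - dm["length"] / 2) - dm["length"] / 2)
    },
    sphere_capped_cylinder = function(x, y, z) {
      a <- dm["neck_angle_deg"] * pi / 180
      shaft <- pmax(sqrt(x^2 + y^2) - dm["shaft_radius"],
                    abs(z - dm["shaft_length"] / 2) - dm["shaft_length"] / 2)
      # neck from the shaft top, tilted `a` from the shaft axis in x-z
      nx <- x * cos(a) - (z - dm["shaft_length"]) * sin(a)
      nz <- x * sin(a) + (z - dm["shaft_length"]) * cos(a)
      neck <- pmax(sqrt(nx^2 + y^2) - dm["neck_radius"],
                   abs(nz - dm["neck_length"] / 2) - dm["neck_length"] / 2)
      hc <- c(sin(a), 0, cos(a)) * dm["neck_length"]
      hx <- hc[1]; hz <- dm["shaft_length"] + hc[3]
      head <- sqrt((x - hx)^2 + y^2 + (z - hz)^2) - dm["head_radius"]
      pmin(pmin(shaft, neck), head)
    }
  )
}

phantom_landmark <- function(design) {
  dm <- design$dimensions
  switch(design$geometry,
    bar = list(landmark = c(dm[["x"]] / 2, dm[["y"]] / 2, dm[["z"]]),
               shaft_axis = c(0, 0, -1)),
    cylinder = list(landmark = c(0, 0, dm[["length"]]),
                    shaft_axis = c(0, 0, -1)),
    sphere_capped_cylinder = list(
      landmark = c(-dm[["shaft_radius"]], 0, dm[["shaft_length"]]),
      shaft_axis = c(0, 0, -1)
    )
  )
}

#' Generate a calibrated CT phantom
#'
#' Voxelises the design at the requested spacing. Inside the specimen the
#' equivalent density is `cortical_density` within `cortical_thickness` of
#' the boundary and the trabecular field elsewhere; rods carry their
#' designed HU; the background is water (0 HU). Each voxel averages
#' `supersample^3` sub-voxel evaluations; seeded Gaussian HU noise is
#' added last.
#'
#' @param design A [phantom_design()].
#' @return Object of class `ct_phantom`: list with `volume` (a
#'   [ct_volume()]), `phantom` (a [phantom_spec()] locating the rods), and
#'   `truth` (surface, density function, landmark, shaft axis, calibration
#'   constants, design).
#' @export
make_phantom <- function(design) {
  stopifnot(inherits(design, "phantom_design"))
  set.seed(design$seed)
  sdf <- phantom_sdf(design)
  dm <- design$dimensions
  bb <- switch(design$geometry,
    bar = rbind(c(0, 0, 0), c(dm[["x"]], dm[["y"]], dm[["z"]])),
    cylinder = rbind(c(-dm[["radius"]], -dm[["radius"]], 0),
                     c(dm[["radius"]], dm[["radius"]], dm[["length"]])),
    sphere_capped_cylinder = {
      a <- dm[["neck_angle_deg"]] * pi / 180
      hx <- sin(a) * dm[["neck_length"]]
      hz <- dm[["shaft_length"]] + cos(a) * dm[["neck_length"]]
      rbind(
        c(min(-dm[["shaft_radius"]], hx - dm[["head_radius"]]),
          -max(dm[["shaft_radius"]], dm[["head_radius"]]), 0),
        c(max(dm[["shaft_radius"]], hx + dm[["head_radius"]]),
          max(dm[["shaft_radius"]], dm[["head_radius"]]),
          hz + dm[["head_radius"]])
      )
    }
  )
  sp <- design$spacing
  rod_r <- max(2, 2 * max(sp[1:2])) # rods at least 2 mm radius
  rod_gap <- 4 * rod_r
  y_rod <- bb[1, 2] - 3 * rod_r
  margin <- 2 * max(sp)
  lo <- c(bb[1, 1] - margin - rod_gap, y_rod - 2 * rod_r - margin,
          bb[1, 3] - margin)
  hi <- c(bb[2, 1] + margin + rod_gap, bb[2, 2] + margin,
          bb[2, 3] + margin)
  lo <- floor(lo / sp) * sp # snap to the voxel grid
  nvox <- pmax(2L, as.integer(ceiling((hi - lo) / sp)))
  origin <- lo + sp / 2

  rho_tr <- design$trabecular_density
  rho_at <- function(x, y, z) {
    phi <- sdf(x, y, z)
    inside <- phi <= 0
    rho <- numeric(length(x))
    tr <- if (is.function(rho_tr)) rho_tr(x, y, z) else rho_tr
    rho[inside] <- ifelse(phi[inside] > -design$cortical_thickness,
                          design$cortical_density,
                          if (length(tr) > 1) tr[inside] else tr)
    rho
  }

  # rod geometry: three z-parallel cylinders below the specimen; the
  # sampling ROI is eroded by a voxel footprint so every ROI voxel is
  # pure rod (no partial-volume dilution of the rod means)
  xc <- (lo[1] + hi[1]) / 2
  rod_x <- xc + c(-rod_gap, 0, rod_gap)
  roi_erode <- 0.5 * sqrt(sum(sp[1:2]^2)) + 1e-9
  rod_z <- c(lo[3] + margin / 2, hi[3] - margin / 2)
  rod_regions <- lapply(rod_x, function(rx) {
    list(p0 = c(rx, y_rod, rod_z[1] + sp[3]),
         p1 = c(rx, y_rod, rod_z[2] - sp[3]),
         radius = rod_r - roi_erode)
  })

  hu_at <- function(x, y, z) {
    rho <- rho_at(x, y, z)
    hu <- (rho * 1000 - design$cal_intercept) / design$cal_slope
    # water background where outside the specimen
    for (ri in seq_along(rod_x)) {
      inrod <- (x - rod_x[ri])^2 + (y - y_rod)^2 <= rod_r^2 &
        z >= lo[3] + margin / 2 & z <= hi[3] - margin / 2
      hu[inrod] <- design$rod_hu[ri]
    }
    hu
  }

  s <- design$supersample
  offs <- ((seq_len(s) - 0.5) / s - 0.5)
  cx <- origin[1] + (seq_len(nvox[1]) - 1) * sp[1]
  cy <- origin[2] + (seq_len(nvox[2]) - 1) * sp[2]
  vals <- array(0, nvox)
  for (k in seq_len(nvox[3])) {
    zc <- origin[3] + (k - 1) * sp[3]
    acc <- matrix(0, nvox[1], nvox[2])
    for (oz in offs) {
      z <- zc + oz * sp[3]
      for (oy in offs) {
        yv <- cy + oy * sp[2]
        g <- expand.grid(x = cx, y = yv, KEEP.OUT.ATTRS = FALSE)
        slab <- 0
        for (ox in offs) {
          slab <- slab + hu_at(g$x + ox * sp[1], g$y, rep(z, nrow(g)))
        }
        acc <- acc + matrix(slab, nvox[1], nvox[2])
      }
    }
    vals[, , k] <- acc / s^3
  }
  if (design$noise_sigma > 0) {
    vals <- vals + stats::rnorm(length(vals), 0, design$noise_sigma)
  }
  vol <- ct_volume(vals, spacing = sp, origin = origin)

  truth_surface <- switch(design$geometry,
    bar = surface_box(c(0, 0, 0), c(dm[["x"]], dm[["y"]], dm[["z"]])),
    cylinder = surface_cylinder(base = c(0, 0, 0), radius = dm[["radius"]],
                                length = dm[["length"]], top = "flat"),
    sphere_capped_cylinder = {
      mask_grid <- expand.grid(
        x = cx, y = origin[2] + (seq_len(nvox[2]) - 1) * sp[2],
        KEEP.OUT.ATTRS = FALSE
      )
      mask <- array(FALSE, nvox)
      for (k in seq_len(nvox[3])) {
        z <- origin[3] + (k - 1) * sp[3]
        mask[, , k] <- matrix(
          sdf(mask_grid$x, mask_grid$y, rep(z, nrow(mask_grid))) <= 0,
          nvox[1], nvox[2]
        )
      }
      mask_to_surface(mask, sp, origin)
    }
  )
  lm <- phantom_landmark(design)
  structure(
    list(
      volume = vol,
      phantom = phantom_spec(design$rod_density, rod_regions),
      truth = list(
        surface = truth_surface, sdf = sdf, rho_at = rho_at,
        landmark = lm$landmark, shaft_axis = lm$shaft_axis,
        cal_slope = design$cal_slope, cal_intercept = design$cal_intercept,
        rod_hu = design$rod_hu, design = design
      )
    ),
    class = "ct_phantom"
  )
}

#' @export
print.ct_phantom <- function(x, ...) {
  cat(sprintf("<ct_phantom> %s specimen\n", x$truth$design$geometry))
  print(x$volume)
  invisible(x)
}

#' Generate a bilinear force-displacement recording
#'
#' Linear loading at `stiffness` up to the programmed knee at
#' `fracture_load`, then a reduced post-knee slope; the knee point itself
#' is always a sample. Seeded Gaussian force noise emulates load-cell
#' scatter.
#'
#' @param stiffness Pre-knee slope (N/mm), > 0.
#' @param fracture_load Programmed knee load (N), > 0.
#' @param post_knee_stiffness_fraction Post-knee slope as a fraction of
#'   `stiffness` in `[0, 1]`; 1 gives a straight (fracture-free) curve.
#' @param increment Displacement sampling step (mm, default 0.01).
#' @param max_displacement Recording end (mm; default twice the knee
#'   displacement).
#' @param noise_sigma Force noise SD (N, default 0).
#' @param seed Integer seed.
#' @param source Curve source tag (default `"mechanical"`).
#' @return An [fd_curve()].
#' @export
make_curve <- function(stiffness, fracture_load,
                       post_knee_stiffness_fraction = 0.5,
                       increment = 0.01, max_displacement = NULL,
                       noise_sigma = 0, seed = 1L,
                       source = "mechanical") {
  stopifnot(stiffness > 0, fracture_load > 0,
            post_knee_stiffness_fraction >= 0,
            post_knee_stiffness_fraction <= 1)
  set.seed(seed)
  dk <- fracture_load / stiffness
  if (is.null(max_displacement)) max_displacement <- 2 * dk
  d <- seq(0, max_displacement, by = increment)
  if (post_knee_stiffness_fraction < 1 && !any(abs(d - dk) < 1e-12)) {
    d <- sort(c(d, dk))
  }
  f <- ifelse(
    d <= dk, stiffness * d,
    fracture_load + post_knee_stiffness_fraction * stiffness * (d - dk)
  )
  if (noise_sigma > 0) f <- f + stats::rnorm(length(f), 0, noise_sigma)
  fd_curve(d, f, source = source)
}

#' Design a validation cohort
#'
#' Paired left/right femora from `n_specimens / 2` cadavers. Each femur's
#' latent strength follows the age model
#' `fracture_load = b0 + b1 * age + eps` (N) with a laterality offset of
#' `+/- laterality_effect / 2`; mechanical and FE measurements share the
#' latent strength with independent instrument noise, and structural
#' stiffness is `fracture_load / stiffness_divisor + eta`.
#'
#' @param n_specimens Even specimen count (default 20).
#' @param age_range Cadaver age range in years (default `c(74, 101)`).
#' @param b0,b1 Age-model intercept and slope (defaults 15856 N and
#'   -142.6 N/yr, the reported cohort fit).
#' @param strength_sd SD of the latent strength residual `eps` (N, default
#'   1000: with the default age spread this puts the age-model R^2 near
#'   the reported 0.49).
#' @param mech_sd,fea_sd Instrument noise SDs on the measured fracture
#'   loads (N, default 700 each, giving a mech-vs-FE fracture-load R^2
#'   near the reported 0.62).
#' @param fea_scale,fea_offset Affine bias of the FE prediction relative
#'   to the latent strength (defaults 0.8201 and 1702.6 N, the reported
#'   fitted line relating the two measurements; with these the weakest
#'   specimens keep positive predicted loads).
#' @param stiffness_divisor Load-to-stiffness divisor `c` (mm, default
#'   2.7, the reported mean load / mean stiffness).
#' @param stiffness_sd SD of the stiffness residual `eta` (N/mm, default
#'   150, keeping the mech-vs-FE stiffness R^2 near the reported 0.55).
#' @param laterality_effect Right-minus-left strength difference (N,
#'   default 0).
#' @param seed Integer seed.
#' @return Object of class `cohort_design`.
#' @export
cohort_design <- function(n_specimens = 20L, age_range = c(74, 101),
                          b0 = 15856, b1 = -142.6,
                          strength_sd = 1000,
                          mech_sd = 700, fea_sd = 700,
                          fea_scale = 0.8201, fea_offset = 1702.6,
                          stiffness_divisor = 2.7, stiffness_sd = 150,
                          laterality_effect = 0, seed = 1L) {
  n_specimens <- as.integer(n_specimens)
  if (n_specimens < 2L || n_specimens %% 2L != 0L) {
    stop("n_specimens must be an even count >= 2", call. = FALSE)
  }
  if (strength_sd < 0 || mech_sd < 0 || fea_sd < 0 || stiffness_sd < 0) {
    stop("noise SDs must be >= 0", call. = FALSE)
  }
  structure(
    list(n_specimens = n_specimens, age_range = as.numeric(age_range),
         b0 = b0, b1 = b1, strength_sd = strength_sd,
         mech_sd = mech_sd, fea_sd = fea_sd,
         fea_scale = fea_scale, fea_offset = fea_offset,
         stiffness_divisor = stiffness_divisor, stiffness_sd = stiffness_sd,
         laterality_effect = laterality_effect, seed = as.integer(seed)),
    class = "cohort_design"
  )
}

#' Generate a synthetic specimen cohort
#'
#' @param design A [cohort_design()].
#' @param curves Also attach bilinear mech/FE curves per specimen
#'   (list-columns `mech_curve`, `fea_curve`; default `TRUE`).
#' @return A tibble with one row per femur: `specimen`, `cadaver`, `age`,
#'   `sex`, `side`, the latent and measured strengths and stiffnesses, and
#'   optionally the curves.
#' @export
make_cohort <- function(design, curves = TRUE) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(design$seed)
  n_cad <- design$n_specimens %/% 2L
  ages <- stats::runif(n_cad, design$age_range[1], design$age_range[2])
  sexes <- rep(c("M", "F"), length.out = n_cad)
  rec <- tidyr::expand_grid(
    cadaver = seq_len(n_cad), side = c("right", "left")
  )
  rec$age <- ages[rec$cadaver]
  rec$sex <- sexes[rec$cadaver]
  rec$specimen <- sprintf("S%02d%s", rec$cadaver,
                          ifelse(rec$side == "right", "R", "L"))
  n <- nrow(rec)
  side_off <- ifelse(rec$side == "right", 0.5, -0.5) * design$laterality_effect
  latent <- design$b0 + design$b1 * rec$age + side_off +
    stats::rnorm(n, 0, design$strength_sd)
  latent <- pmax(latent, 500) # keep strengths physical
  mech_fl <- pmax(latent + stats::rnorm(n, 0, design$mech_sd), 200)
  fea_fl <- pmax(design$fea_scale * latent + design$fea_offset +
                   stats::rnorm(n, 0, design$fea_sd), 200)
  mech_st <- pmax(mech_fl / design$stiffness_divisor +
                    stats::rnorm(n, 0, design$stiffness_sd), 50)
  fea_st <- pmax(fea_fl / design$stiffness_divisor +
                   stats::rnorm(n, 0, design$stiffness_sd), 50)
  out <- tibble::tibble(
    specimen = rec$specimen, cadaver = rec$cadaver, age = rec$age,
    sex = rec$sex, side = rec$side,
    latent_strength = latent,
    mech_fracture_load = mech_fl, mech_stiffness = mech_st,
    fea_fracture_load = fea_fl, fea_stiffness = fea_st
  )
  if (curves) {
    curve_seeds <- sample.int(2^30, 2 * n)
    out$mech_curve <- purrr::map(seq_len(n), function(i) {
      dk <- mech_fl[i] / mech_st[i]
      make_curve(mech_st[i], mech_fl[i], post_knee_stiffness_fraction = 0.5,
                 increment = dk / 100, max_displacement = 1.5 * dk,
                 seed = curve_seeds[i], source = "mechanical")
    })
    out$fea_curve <- purrr::map(seq_len(n), function(i) {
      dk <- fea_fl[i] / fea_st[i]
      make_curve(fea_st[i], fea_fl[i], post_knee_stiffness_fraction = 0.5,
                 increment = dk / 100, max_displacement = 1.5 * dk,
                 seed = curve_seeds[n + i], source = "fea")
    })
  }
  out
}

#' Extract fracture metrics from a cohort's curves
#'
#' Applies the mechanical and FE fracture detectors to every specimen's
#' curves, returning the records table [cohort_report()] expects.
#'
#' @param cohort A [make_cohort()] tibble with curve list-columns.
#' @return A tibble with the detector-derived `mech_fracture_load`,
#'   `mech_stiffness`, `fea_fracture_load`, `fea_stiffness` replacing the
#'   generator's measured values.
#' @export
cohort_metrics <- function(cohort) {
  stopifnot(all(c("mech_curve", "fea_curve") %in% names(cohort)))
  mech <- purrr::map(cohort$mech_curve, fracture_load_mechanical)
  fea <- purrr::map(cohort$fea_curve, fracture_load_fea)
  dplyr::mutate(
    dplyr::select(cohort, -dplyr::any_of(c(
      "mech_fracture_load", "mech_stiffness",
      "fea_fracture_load", "fea_stiffness", "mech_curve", "fea_curve"
    ))),
    mech_fracture_load = purrr::map_dbl(mech, "fracture_load"),
    mech_stiffness = purrr::map_dbl(mech, "stiffness"),
    fea_fracture_load = purrr::map_dbl(fea, "fracture_load"),
    fea_stiffness = purrr::map_dbl(fea, "stiffness")
  )
}
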