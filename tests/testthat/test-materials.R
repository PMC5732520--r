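test_that("power-law modulus and yield match their printed coefficients", {
  expect_equal(keller_modulus(1.0), 1890)
  expect_equal(keller_modulus(0), 0.001)
  expect_equal(keller_modulus(-0.3), 0.001)
  expect_equal(keller_modulus(0.5), 1890 * 0.5^1.92)
  expect_equal(keller_modulus(0.5), 499.4, tolerance = 1e-3)

  expect_equal(keller_yield(1.0), 284)
  expect_equal(keller_yield(0.1), 1e20)
  expect_equal(keller_yield(0.2), 1e20)
  expect_equal(keller_yield(0.5), 284 * 0.5^2.27)
  expect_equal(keller_yield(0.5), 58.9, tolerance = 1e-3)
})

test_that("modulus clamp enforces the 0.01 MPa - 20 GPa range", {
  expect_equal(clamp_modulus(keller_modulus(4.0)), 20000)
  expect_gt(keller_modulus(4.0), 20000)
  expect_equal(clamp_modulus(keller_modulus(0.001)), 0.01)
  expect_equal(clamp_modulus(5000), 5000)
  # idempotent and order-preserving
  x <- c(-5, 0.001, 0.5, 19999, 2e5)
  expect_identical(clamp_modulus(clamp_modulus(x)), clamp_modulus(x))
  expect_true(all(diff(clamp_modulus(sort(x))) >= 0))
})

test_that("laws are monotone non-decreasing above their thresholds", {
  set.seed(1)
  r <- sort(runif(200, 0, 4))
  expect_true(all(diff(keller_modulus(r)) >= 0))
  r2 <- sort(runif(200, 0.2001, 4))
  expect_true(all(diff(keller_yield(r2)) >= 0))
})

test_that("element HU averaging matches voxel membership and ramps", {
  # constant field: every element inherits the constant
  vol <- ct_volume(array(700, c(20, 20, 20)), spacing = c(1, 1, 1),
                   origin = c(0.5, 0.5, 0.5))
  m <- tetrahedralize(surface_box(c(1, 1, 1), c(19, 19, 19)), 4)
  expect_true(all(abs(element_average_hu(vol, m) - 700) < 1e-12))

  # explicit two-voxel membership: tet holding centres with HU 100 and 200
  vals <- array(0, c(4, 4, 4))
  vals[2, 2, 2] <- 100
  vals[3, 2, 2] <- 200
  vol2 <- ct_volume(vals, spacing = c(1, 1, 1))
  nodes <- rbind(c(0.5, 0.5, 0.5), c(2.5, 0.5, 0.5), c(1.5, 2, 0.8),
                 c(1.5, 1, 2.2))
  mesh1 <- tet_mesh(nodes, matrix(1:4, 1), rbind(c(2, 3, 4), c(1, 4, 3), c(1, 2, 4), c(1, 3, 2)))
  hu <- element_average_hu(vol2, mesh1)
  expect_equal(hu, 150)

  # linear ramp: element averages sit near the centroid value
  d <- c(24, 10, 10)
  ramp <- array(rep(seq_len(d[1]) * 10, times = d[2] * d[3]), d)
  vol3 <- ct_volume(ramp, spacing = c(1, 1, 1), origin = c(0.5, 0.5, 0.5))
  m3 <- tetrahedralize(surface_box(c(1, 1, 1), c(23, 9, 9)), 3)
  hu3 <- element_average_hu(vol3, m3)
  centroids <- (m3$nodes[m3$tets[, 1], 1] + m3$nodes[m3$tets[, 2], 1] +
                  m3$nodes[m3$tets[, 3], 1] + m3$nodes[m3$tets[, 4], 1]) / 4
  expected <- centroids * 10 + 5 # ramp value at centroid x
  expect_lt(max(abs(hu3 - expected)), 10) # within one ramp-per-voxel step

  # element fully outside the volume errors with its index
  far <- tet_mesh(nodes + 100, matrix(1:4, 1),
                  rbind(c(2, 3, 4), c(1, 4, 3), c(1, 2, 4), c(1, 3, 2)))
  expect_error(element_average_hu(vol2, far), "element 1")
})

test_that("material assignment runs HU through the full chain", {
  d <- phantom_design("bar", dimensions = c(x = 8, y = 8, z = 16),
                      cortical_thickness = 0, trabecular_density = 1.0,
                      spacing = c(0.5, 0.5, 0.5), supersample = 2, seed = 5)
  ph <- make_phantom(d)
  cal <- fit_calibration(rod_mean_hu(ph$volume, ph$phantom),
                         ph$phantom$rod_density)
  m <- tetrahedralize(segment_bone(ph$volume, 500), 2.5)
  m <- overlay_shell(m, 0.2)
  mats <- assign_materials(m, ph$volume, cal)

  # uniform 1000-HU specimen: every tet material equals the shell material
  expect_true(all(abs(mats$tets$hu - 1000) < 1e-9))
  expect_equal(unique(round(mats$tets$E, 9)),
               round(mats$shell$E[1], 9))
  expect_equal(mats$shell$E[1], clamp_modulus(keller_modulus(1.0)))
  expect_equal(mats$shell$sigma_c[1], keller_yield(1.0))

  # exact constructed ratio and Poisson
  expect_true(all(mats$tets$sigma_t == 0.8 * mats$tets$sigma_c))
  expect_true(all(mats$tets$nu == 0.3))
  expect_true(all(mats$tets$E >= 0.01 & mats$tets$E <= 20000))

  # per-element E matches the hand-evaluated law from the known rho field
  rho <- hu_to_density(cal, mats$tets$hu)
  expect_equal(mats$tets$E, clamp_modulus(1890 * rho^1.92),
               tolerance = 1e-9)

  # materials CSV export
  csv <- withr::local_tempfile(fileext = ".csv")
  write_materials_csv(mats, csv)
  tab <- read.csv(csv)
  expect_equal(nrow(tab), nrow(mats$tets) + nrow(mats$shell))
  expect_true(all(c("hu", "rho", "E", "nu", "sigma_c", "sigma_t")
                  %in% names(tab)))
})

test_that("pressure-sensitive yield surface is calibrated by both uniaxial states", {
  p <- dp_params(100, 0.8)
  expect_equal(p$alpha, (1 - 0.8) / (sqrt(3) * 1.8), tolerance = 1e-12)
  expect_equal(p$alpha, 0.06415, tolerance = 1e-4)
  expect_equal(p$k, 0.8 * 100 * (p$alpha + 1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(p$k, 51.32, tolerance = 1e-3)

  # von Mises limit
  pv <- dp_params(100, 1)
  expect_equal(pv$alpha, 0)
  expect_equal(pv$k, 100 / sqrt(3))

  # surface passes through both uniaxial strengths for random sigma_c
  set.seed(7)
  for (sc in runif(20, 1, 500)) {
    pp <- dp_params(sc, 0.8)
    comp <- diag(c(-sc, 0, 0))
    tens <- diag(c(0.8 * sc, 0, 0))
    expect_lt(abs(dp_yield_value(comp, pp)), 1e-9 * sc)
    expect_lt(abs(dp_yield_value(tens, pp)), 1e-9 * sc)
  }

  # hydrostatic tension p*I: f = 3 alpha p - k
  pp <- dp_params(50, 0.8)
  expect_equal(dp_yield_value(diag(c(7, 7, 7)), pp),
               3 * pp$alpha * 7 - pp$k, tolerance = 1e-12)
  expect_equal(dp_yield_value(matrix(0, 3, 3), pp), -pp$k)
})
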