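test_that("segmentation extracts the largest component at the threshold", {
  # sphere of 800 HU in 0 background
  n <- 31
  sp <- c(1, 1, 1)
  cc <- (n + 1) / 2
  g <- expand.grid(i = 1:n, j = 1:n, k = 1:n)
  r <- sqrt((g$i - cc)^2 + (g$j - cc)^2 + (g$k - cc)^2)
  vals <- array(ifelse(r <= 10, 800, 0), c(n, n, n))
  vol <- ct_volume(vals, spacing = sp)
  s <- segment_bone(vol, 400)
  expect_true(surface_is_closed(s))
  ctr <- colMeans(s$vertices)
  rad <- sqrt(rowSums(sweep(s$vertices, 2, ctr, "-")^2))
  expect_true(all(abs(rad - 10) <= max(sp))) # within one voxel

  expect_error(segment_bone(vol, 1e4), "threshold")

  # two disjoint blobs: only the larger survives
  vals2 <- array(0, c(20, 10, 10))
  vals2[2:8, 2:8, 2:8] <- 500    # 343 voxels
  vals2[12:15, 2:5, 2:5] <- 500  # 64 voxels
  s2 <- segment_bone(ct_volume(vals2, spacing = c(1, 1, 1)), 400)
  expect_lt(max(s2$vertices[, 1]), 10) # second blob excluded
  expect_equal(surface_volume(s2), 343)
})

test_that("specimen cut clips at the right distance and slope", {
  cy <- surface_cylinder(c(0, 0, 0), radius = 10, length = 200, n_seg = 48)
  cut <- cut_and_orient(cy, landmark_gt_tip = c(0, 0, 200),
                        shaft_axis = c(0, 0, -1),
                        cut_distance = 120, coronal_slope_deg = 0)
  expect_true(surface_is_closed(cut))
  zr <- range(cut$vertices[, 3])
  expect_equal(zr[1], 0, tolerance = 1e-9)
  expect_equal(diff(zr), 120, tolerance = 1e-9)

  cut20 <- cut_and_orient(cy, c(0, 0, 200), c(0, 0, -1), 120, 20)
  ax <- attr(cut20, "shaft_axis")
  # cut-face normal is -z after orientation; shaft axis 20 deg off vertical
  expect_equal(acos(abs(ax[3])) * 180 / pi, 20, tolerance = 1e-9)
  expect_true(surface_is_closed(cut20))

  expect_error(cut_and_orient(cy, c(0, 0, 200), c(0, 0, -1), 300, 0),
               "does not intersect")
})

test_that("cut commutes with a rigid transform of the input", {
  cy <- surface_cylinder(c(0, 0, 0), radius = 8, length = 120, n_seg = 24)
  rot <- rotation_about_axis(c(0.3, 0.2, 0.93), 33)
  tr <- c(5, -7, 11)
  cy_moved <- transform_surface(cy, rot, tr)
  a <- cut_and_orient(cy, c(0, 0, 120), c(0, 0, -1), 80, 20)
  b <- cut_and_orient(cy_moved, as.vector(rot %*% c(0, 0, 120)) + tr,
                      as.vector(rot %*% c(0, 0, -1)), 80, 20,
                      anterior_axis = as.vector(rot %*% c(0, 1, 0)))
  # the oriented frame is canonical: outputs coincide vertex-for-vertex
  expect_equal(surface_volume(b), surface_volume(a), tolerance = 1e-8)
  expect_equal(b$vertices, a$vertices, tolerance = 1e-7)
  expect_equal(attr(b, "shaft_axis"), attr(a, "shaft_axis"),
               tolerance = 1e-9)
})

test_that("tet meshing reproduces analytic volumes at target edge length", {
  box <- surface_box(c(0, 0, 0), c(20, 20, 20))
  m <- tetrahedralize(box, 1.5)
  expect_equal(mesh_volume(m), 8000, tolerance = 0.005)
  expect_gt(min(tet_volumes(m)), 0)
  med <- stats::median(mesh_edge_lengths(m))
  expect_lt(abs(med - 1.5) / 1.5, 0.25)

  sph <- surface_sphere(c(0, 0, 0), 10, 3)
  ms <- tetrahedralize(sph, 1.5)
  expect_equal(mesh_volume(ms), 4 / 3 * pi * 1000, tolerance = 0.02)
  expect_gt(min(tet_volumes(ms)), 0)
})

test_that("mesh volume error decreases under refinement", {
  sph <- surface_sphere(c(0, 0, 0), 10, 3)
  vtrue <- 4 / 3 * pi * 1000
  errs <- vapply(c(3, 1.5, 1), function(e) {
    abs(mesh_volume(tetrahedralize(sph, e)) - vtrue) / vtrue
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("shell overlay covers non-cut boundary triangles and is idempotent", {
  box <- surface_box(c(0, 0, 0), c(15, 15, 15))
  m <- tetrahedralize(box, 3)
  m1 <- overlay_shell(m, 0.2)
  expect_equal(nrow(m1$shell), nrow(m1$boundary_tris)) # no cut face tagged
  expect_true(all(m1$shell$thickness == 0.2))
  m2 <- overlay_shell(m1, 0.2)
  expect_identical(m2$shell, m1$shell)

  # with a cut plane, cut-face triangles carry no shell
  cy <- surface_cylinder(c(0, 0, 0), radius = 8, length = 80, n_seg = 24,
                         top = "hemisphere")
  cut <- cut_and_orient(cy, c(0, 0, 88), c(0, 0, -1), 60, 0)
  mc <- overlay_shell(tetrahedralize(cut, 4), 0.2)
  expect_lt(nrow(mc$shell), nrow(mc$boundary_tris))

  # zero thickness contributes no stiffness
  k0 <- membrane_stiffness(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), 0,
                           1000, 0.3)
  expect_true(all(k0 == 0))
})

test_that("boundary sets tag the resin band and the loaded spherical cap", {
  cy <- surface_cylinder(c(0, 0, 0), radius = 8, length = 60, n_seg = 32,
                         top = "hemisphere")
  cut <- cut_and_orient(cy, c(0, 0, 68), c(0, 0, -1), 50, 0)
  m <- tetrahedralize(cut, 3)
  m <- tag_boundary_sets(m, distal_depth = 15, cap_angle_deg = 60,
                         head_center = c(0, 0, 42), head_radius = 8)
  z <- m$nodes[, 3]
  expect_true(all(z[m$node_sets$fixed_distal] <= 15 + 1e-6))
  band <- which(z <= 15 + 1e-9)
  expect_setequal(m$node_sets$fixed_distal, band)
  expect_length(intersect(m$node_sets$fixed_distal,
                          m$node_sets$cap_contact), 0)

  # brute-force point-in-cone membership on boundary nodes
  bn <- unique(as.vector(m$boundary_tris))
  rel <- sweep(m$nodes[bn, , drop = FALSE], 2, c(0, 0, 42), "-")
  rr <- sqrt(rowSums(rel^2))
  oracle <- bn[abs(rr - 8) < 2 & rel[, 3] / pmax(rr, 1e-12) >= cos(pi / 3) &
                 rel[, 3] > 0]
  oracle <- setdiff(oracle, band)
  expect_setequal(m$node_sets$cap_contact, oracle)

  expect_error(tag_boundary_sets(m, 15, cap_angle_deg = 0,
                                 head_center = c(0, 0, 42), head_radius = 8),
               "cap_contact")
})

test_that("surface and mesh files round-trip / export well-formed text", {
  s <- surface_sphere(c(1, 2, 3), 5, 1)
  stl <- withr::local_tempfile(fileext = ".stl")
  write_surface(s, stl)
  s2 <- read_surface(stl)
  expect_equal(surface_volume(s2), surface_volume(s), tolerance = 1e-6)
  expect_true(surface_is_closed(s2))

  ply <- withr::local_tempfile(fileext = ".ply")
  write_surface(s, ply)
  s3 <- read_surface(ply)
  expect_equal(s3$triangles, s$triangles)
  expect_equal(s3$vertices, s$vertices, tolerance = 1e-6)

  m <- tetrahedralize(surface_box(c(0, 0, 0), c(10, 10, 10)), 4)
  m <- overlay_shell(m, 0.2)
  vtu <- withr::local_tempfile(fileext = ".vtu")
  write_mesh_vtu(m, vtu, cell_data = list(E = rep(1, nrow(m$tets))))
  x <- readLines(vtu)
  expect_true(any(grepl("UnstructuredGrid", x)))
  expect_equal(sum(grepl("DataArray", x)) %% 2, 0)

  inp <- withr::local_tempfile(fileext = ".inp")
  m$node_sets$fixed_distal <- 1:5
  write_mesh_inp(m, inp)
  y <- readLines(inp)
  expect_true(any(grepl("C3D4", y)))
  expect_true(any(grepl("SHELL SECTION", y)))
  expect_true(any(grepl("NSET=FIXED_DISTAL", y)))
})
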