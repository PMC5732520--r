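test_that("tet stiffness obeys mechanics identities and the B'DB oracle", {
  set.seed(3)
  coords <- rbind(c(0, 0, 0), c(2, 0.1, 0), c(0.3, 1.8, 0.2),
                  c(0.1, 0.4, 2.2))
  K <- tet4_stiffness(coords, E = 1200, nu = 0.3)
  expect_equal(K, t(K), tolerance = 1e-10)
  # rigid translations are zero-energy
  for (dir in 1:3) {
    u <- rep(0, 12)
    u[seq(dir, 12, by = 3)] <- 1
    expect_lt(max(abs(K %*% u)), 1e-8 * max(abs(K)))
  }
  # rigid rotation about z: u = omega x r
  u_rot <- as.vector(t(cbind(-coords[, 2], coords[, 1], 0)))
  expect_lt(max(abs(K %*% u_rot)), 1e-7 * max(abs(K)))
  # exactly 6 (near-)zero eigenvalues
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-6 * max(ev)), 6)
  expect_true(all(ev > -1e-8 * max(ev)))

  # unit reference tet against the independent oracle
  ref <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(tet4_stiffness(ref, 1, 0), tet4_oracle(ref, 1, 0),
               tolerance = 1e-12)
  expect_equal(tet4_stiffness(coords, 1200, 0.3),
               tet4_oracle(coords, 1200, 0.3), tolerance = 1e-9)

  # scaling coordinates by s scales K by s (constant-strain dimension count)
  expect_equal(tet4_stiffness(coords * 3, 1200, 0.3), 3 * K,
               tolerance = 1e-9)

  expect_error(tet4_stiffness(rbind(coords[1:3, ], coords[1, ]), 1, 0.3),
               "degenerate")
})

test_that("membrane stiffness is linear in thickness and passes the stretch patch", {
  tri <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 3, 0))
  K1 <- membrane_stiffness(tri, 0.2, 1000, 0.3)
  K2 <- membrane_stiffness(tri, 0.4, 1000, 0.3)
  expect_equal(K2, 2 * K1, tolerance = 1e-12)
  expect_equal(K1, t(K1), tolerance = 1e-12)
  ev <- eigen(K1, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-9 * max(ev)))

  # uniform biaxial stretch of an in-plane triangle: energy from the
  # plane-stress closed form E t A eps^2 (1 + nu) / (1 - nu^2)
  E <- 1000; nu <- 0.3; t <- 0.2; eps <- 0.01
  A <- 3
  u <- as.vector(t(cbind(eps * tri[, 1], eps * tri[, 2], 0)))
  energy <- 0.5 * sum(u * (K1 %*% u))
  closed <- 0.5 * E * t * A * (2 * eps^2 * (1 + nu)) / (1 - nu^2)
  expect_equal(energy, closed, tolerance = 1e-9)

  # out-of-plane translation costs nothing (membrane only)
  uz <- as.vector(t(cbind(0, 0, c(1, 1, 1))))
  expect_lt(max(abs(K1 %*% uz)), 1e-12)

  expect_error(membrane_stiffness(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                                  0.2, 1000, 0.3), "zero-area")
})

test_that("assembly is order-independent and energy-consistent", {
  m <- bar_mesh(w = 6, L = 12, edge = 4)
  mats <- uniform_materials(m, E = 500, nu = 0.25)
  asm <- assemble(m, mats)
  expect_equal(dim(asm$K), rep(3 * nrow(m$nodes), 2))
  expect_lt(max(abs(asm$K - Matrix::t(asm$K))), 1e-10)

  # permuting the elements leaves the matrix unchanged
  perm <- sample(nrow(m$tets))
  m2 <- m
  m2$tets <- m$tets[perm, , drop = FALSE]
  asm2 <- assemble(m2, mats)
  expect_lt(max(abs(asm$K - asm2$K)), 1e-9)

  # single-tet mesh: global equals the element matrix
  one <- tet_mesh(m$nodes[m$tets[1, ], ], matrix(1:4, 1),
                  rbind(c(2, 3, 4), c(1, 4, 3), c(1, 2, 4), c(1, 3, 2)))
  asm1 <- assemble(one, uniform_materials(one, 500, 0.25))
  expect_equal(as.matrix(asm1$K),
               unname(tet4_stiffness(one$nodes, 500, 0.25)),
               tolerance = 1e-10)

  # energy of a linear field equals the sum of element energies
  u <- as.vector(t(cbind(0.001 * m$nodes[, 1], 0, 0.002 * m$nodes[, 3])))
  e_global <- 0.5 * sum(u * as.vector(asm$K %*% u))
  e_sum <- sum(vapply(seq_len(nrow(m$tets)), function(e) {
    dofs <- as.vector(t(cbind(3 * m$tets[e, ] - 2, 3 * m$tets[e, ] - 1,
                              3 * m$tets[e, ])))
    Ke <- tet4_stiffness(m$nodes[m$tets[e, ], ], 500, 0.25)
    0.5 * sum(u[dofs] * (Ke %*% u[dofs]))
  }, numeric(1)))
  expect_equal(e_global, e_sum, tolerance = 1e-9)

  # missing material errors with the element count
  short <- mats
  short$tets <- short$tets[-1, ]
  expect_error(assemble(m, short), "do not cover")
})

test_that("uniaxial bar reproduces EA/L, zero load and superposition", {
  m <- bar_mesh(w = 10, L = 100, edge = 4)
  mats <- uniform_materials(m, E = 1000, nu = 0)
  bc <- boundary_conditions(m$node_sets$base, m$node_sets$top,
                            load_axis = c(0, 0, -1), increment = 0.1,
                            n_steps = 3)
  asm <- assemble(m, mats)
  sol <- solve_linear(asm, bc, 0.5)
  expect_equal(sol$force / 0.5, 1000 * 100 / 100, tolerance = 0.005)
  # equilibrium: fixed reactions balance driven reactions
  expect_equal(sol$reactions_fixed, -sol$force, tolerance = 1e-6)

  expect_equal(solve_linear(asm, bc, 0)$force, 0, tolerance = 1e-10)
  expect_equal(solve_linear(asm, bc, 1)$force, 2 * sol$force,
               tolerance = 1e-8)

  # under-constrained (floating) system errors
  expect_error(solve_displacement(asm$K, 3L, 0.5), "singular")
})

test_that("patch test: affine boundary displacement is reproduced exactly", {
  m <- tetrahedralize(surface_box(c(0, 0, 0), c(6, 6, 6)), 2.5)
  A <- rbind(c(0.002, 0.0005, 0), c(0, -0.001, 0.0008),
             c(0.0002, 0, 0.0015))
  b <- c(0.01, -0.02, 0.005)
  u_affine <- m$nodes %*% t(A) + rep(b, each = nrow(m$nodes))
  bnodes <- sort(unique(as.vector(m$boundary_tris)))
  bdofs <- as.vector(t(cbind(3 * bnodes - 2, 3 * bnodes - 1, 3 * bnodes)))
  vals <- as.vector(t(u_affine[bnodes, ]))
  for (nu in c(0, 0.3, 0.45)) {
    asm <- assemble(m, uniform_materials(m, E = 750, nu = nu))
    sol <- solve_displacement(asm$K, bdofs, vals)
    expect_lt(max(abs(sol$u - as.vector(t(u_affine)))), 1e-8)
  }
})

test_that("bar stiffness error decreases monotonically under mesh refinement", {
  # with nu = 0.3 and a clamped base the discrete bar is stiffer than
  # EA/L; the excess must shrink as the target edge decreases
  errs <- vapply(c(6, 3, 2), function(edge) {
    m <- bar_mesh(w = 10, L = 40, edge = edge)
    mats <- uniform_materials(m, E = 1000, nu = 0.3)
    bc <- boundary_conditions(m$node_sets$base, m$node_sets$top,
                              c(0, 0, -1), 0.1, 3L)
    sol <- solve_linear(assemble(m, mats), bc, 0.1)
    abs(sol$force / 0.1 - 1000 * 100 / 40)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})
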