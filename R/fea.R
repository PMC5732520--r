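# Linear-tetrahedron + membrane-triangle finite elements, sparse assembly
# and the displacement-driven linear solve. Constant-strain elements with
# one integration point (exact for linear tets).

# isotropic 6x6 constitutive matrix, engineering shear Voigt order
# (xx, yy, zz, xy, yz, zx)
iso_d_matrix <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- diag(c(rep(2 * mu, 3), rep(mu, 3)))
  D[1:3, 1:3] <- D[1:3, 1:3] + lam
  D
}

# gradients of the 4 linear shape functions; rows = nodes, cols = x,y,z
tet_shape_gradients <- function(coords) {
  Dm <- rbind(coords[2, ] - coords[1, ],
              coords[3, ] - coords[1, ],
              coords[4, ] - coords[1, ])
  detd <- det(Dm)
  if (abs(detd) < 1e-12) {
    stop("degenerate tetrahedron (zero volume)", call. = FALSE)
  }
  ginv <- solve(Dm) # columns are grad(lambda_2..4)
  g234 <- t(ginv)
  rbind(-colSums(g234), g234)
}

tet_b_matrix <- function(coords) {
  g <- tet_shape_gradients(coords)
  B <- matrix(0, 6, 12)
  for (a in 1:4) {
    c0 <- 3 * (a - 1)
    bx <- g[a, 1]; by <- g[a, 2]; bz <- g[a, 3]
    B[1, c0 + 1] <- bx
    B[2, c0 + 2] <- by
    B[3, c0 + 3] <- bz
    B[4, c0 + 1] <- by; B[4, c0 + 2] <- bx
    B[5, c0 + 2] <- bz; B[5, c0 + 3] <- by
    B[6, c0 + 1] <- bz; B[6, c0 + 3] <- bx
  }
  B
}

#' Stiffness matrix of a 4-node linear tetrahedron
#'
#' Constant-strain formulation `K = V * B' D B`; symmetric positive
#' semi-definite with the six rigid-body zero-energy modes.
#'
#' @param coords 4x3 node coordinates (mm), positively oriented.
#' @param E Young's modulus (MPa).
#' @param nu Poisson ratio.
#' @return 12x12 stiffness matrix (N/mm with mm/MPa inputs).
#' @export
tet4_stiffness <- function(coords, E, nu) {
  coords <- as.matrix(coords)
  V <- signed_tet_volume(coords, matrix(1:4, 1))
  if (V <= 1e-12) {
    stop("degenerate or negatively oriented tetrahedron", call. = FALSE)
  }
  B <- tet_b_matrix(coords)
  V * t(B) %*% iso_d_matrix(E, nu) %*% B
}

#' Stiffness matrix of a 3-node membrane triangle
#'
#' Constant-strain plane-stress membrane (in-plane stiffness only, no
#' bending), lifted to the three global displacement components per node.
#'
#' @param coords 3x3 node coordinates (mm).
#' @param thickness Membrane thickness (mm).
#' @param E Young's modulus (MPa).
#' @param nu Poisson ratio.
#' @return 9x9 symmetric PSD stiffness matrix.
#' @export
membrane_stiffness <- function(coords, thickness, E, nu) {
  coords <- as.matrix(coords)
  e1 <- coords[2, ] - coords[1, ]
  v2 <- coords[3, ] - coords[1, ]
  nrm <- c(e1[2] * v2[3] - e1[3] * v2[2],
           e1[3] * v2[1] - e1[1] * v2[3],
           e1[1] * v2[2] - e1[2] * v2[1])
  a2 <- sqrt(sum(nrm^2)) # 2 * area
  if (a2 < 1e-12) stop("zero-area shell triangle", call. = FALSE)
  if (thickness == 0) return(matrix(0, 9, 9))
  e1 <- e1 / sqrt(sum(e1^2))
  nrm <- nrm / a2
  e2 <- c(nrm[2] * e1[3] - nrm[3] * e1[2],
          nrm[3] * e1[1] - nrm[1] * e1[3],
          nrm[1] * e1[2] - nrm[2] * e1[1])
  # local 2-D coordinates
  p <- cbind(as.vector((coords - rep(coords[1, ], each = 3)) %*% e1),
             as.vector((coords - rep(coords[1, ], each = 3)) %*% e2))
  area <- a2 / 2
  # CST shape gradients in 2-D
  b <- c(p[2, 2] - p[3, 2], p[3, 2] - p[1, 2], p[1, 2] - p[2, 2]) / (2 * area)
  cxy <- c(p[3, 1] - p[2, 1], p[1, 1] - p[3, 1], p[2, 1] - p[1, 1]) / (2 * area)
  B2 <- matrix(0, 3, 6)
  for (a in 1:3) {
    B2[1, 2 * a - 1] <- b[a]
    B2[2, 2 * a] <- cxy[a]
    B2[3, 2 * a - 1] <- cxy[a]
    B2[3, 2 * a] <- b[a]
  }
  Dps <- E / (1 - nu^2) *
    matrix(c(1, nu, 0, nu, 1, 0, 0, 0, (1 - nu) / 2), 3, 3)
  K2 <- thickness * area * t(B2) %*% Dps %*% B2
  # lift: local (u1,u2) per node from global (x,y,z)
  T_ <- matrix(0, 6, 9)
  for (a in 1:3) {
    T_[2 * a - 1, (3 * a - 2):(3 * a)] <- e1
    T_[2 * a, (3 * a - 2):(3 * a)] <- e2
  }
  t(T_) %*% K2 %*% T_
}

## ---- assembly -------------------------------------------------------------

# Global sparse strain-displacement operator: a (6*ntet) x ndof sparse
# matrix mapping nodal displacements to per-element engineering strains.
# Reassembling a tangent is then a block-diagonal product, so the nonlinear
# solver never rebuilds element topology.
assemble_b_operator <- function(mesh) {
  nt <- nrow(mesh$tets)
  ndof <- 3L * nrow(mesh$nodes)
  ii <- vector("list", nt)
  jj <- vector("list", nt)
  xx <- vector("list", nt)
  vols <- numeric(nt)
  for (e in seq_len(nt)) {
    coords <- mesh$nodes[mesh$tets[e, ], , drop = FALSE]
    B <- tet_b_matrix(coords)
    vols[e] <- signed_tet_volume(coords, matrix(1:4, 1))
    dofs <- as.vector(t(cbind(3 * mesh$tets[e, ] - 2,
                              3 * mesh$tets[e, ] - 1,
                              3 * mesh$tets[e, ])))
    nzero <- which(B != 0)
    ii[[e]] <- 6L * (e - 1L) + ((nzero - 1L) %% 6L) + 1L
    jj[[e]] <- dofs[((nzero - 1L) %/% 6L) + 1L]
    xx[[e]] <- B[nzero]
  }
  list(
    B = Matrix::sparseMatrix(
      i = unlist(ii), j = unlist(jj), x = unlist(xx),
      dims = c(6L * nt, ndof)
    ),
    volumes = vols
  )
}

# block-diagonal sparse matrix from an array of 6x6 blocks (6 x 6 x n)
block_diag6 <- function(blocks) {
  n <- dim(blocks)[3]
  base <- rep(6L * (seq_len(n) - 1L), each = 36L)
  i <- base + rep(rep(1:6, times = 6), times = n)
  j <- base + rep(rep(1:6, each = 6), times = n)
  Matrix::sparseMatrix(i = i, j = j, x = as.vector(blocks),
                       dims = c(6L * n, 6L * n))
}

# elastic constitutive blocks scaled by element volume
elastic_blocks <- function(E, nu, volumes) {
  n <- length(E)
  blocks <- array(0, c(6, 6, n))
  for (e in seq_len(n)) {
    blocks[, , e] <- volumes[e] * iso_d_matrix(E[e], nu[e])
  }
  blocks
}

# shell global stiffness (elastic, assembled once)
assemble_shell_stiffness <- function(mesh, shell_materials) {
  ndof <- 3L * nrow(mesh$nodes)
  ns <- nrow(mesh$shell)
  if (ns == 0L) {
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(ndof, ndof)))
  }
  ii <- jj <- xx <- vector("list", ns)
  for (e in seq_len(ns)) {
    nd <- c(mesh$shell$n1[e], mesh$shell$n2[e], mesh$shell$n3[e])
    K <- membrane_stiffness(mesh$nodes[nd, , drop = FALSE],
                            mesh$shell$thickness[e],
                            shell_materials$E[e], shell_materials$nu[e])
    dofs <- as.vector(t(cbind(3 * nd - 2, 3 * nd - 1, 3 * nd)))
    ii[[e]] <- rep(dofs, times = 9)
    jj[[e]] <- rep(dofs, each = 9)
    xx[[e]] <- as.vector(K)
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(ndof, ndof))
}

#' Assemble the global elastic stiffness matrix
#'
#' Sum of tet and shell element stiffness; symmetric, order-independent.
#'
#' @param mesh A [tet_mesh()].
#' @param materials An [assign_materials()] result covering every tet (and
#'   shell, if present).
#' @return List with `K` (sparse `ndof x ndof`), `ndof`, and the internal
#'   strain operator reused by the nonlinear solver.
#' @export
assemble <- function(mesh, materials) {
  stopifnot(inherits(mesh, "tet_mesh"), inherits(materials, "element_materials"))
  if (nrow(materials$tets) != nrow(mesh$tets)) {
    stop("materials do not cover all ", nrow(mesh$tets), " tets (got ",
         nrow(materials$tets), ")", call. = FALSE)
  }
  if (nrow(mesh$shell) > 0L && nrow(materials$shell) != nrow(mesh$shell)) {
    stop("materials do not cover all shell elements", call. = FALSE)
  }
  op <- assemble_b_operator(mesh)
  blocks <- elastic_blocks(materials$tets$E, materials$tets$nu, op$volumes)
  Dblk <- block_diag6(blocks)
  Kshell <- assemble_shell_stiffness(mesh, materials$shell)
  K <- Matrix::t(op$B) %*% Dblk %*% op$B + Kshell
  list(K = Matrix::forceSymmetric((K + Matrix::t(K)) / 2),
       ndof = 3L * nrow(mesh$nodes),
       B = op$B, volumes = op$volumes, Kshell = Kshell)
}

#' Displacement boundary conditions for the stance-configuration solve
#'
#' @param fixed_nodes Node ids with all translations fixed (resin box).
#' @param driven_nodes Node ids sharing the prescribed displacement along
#'   the load axis (resin cap analog); transverse components left free.
#' @param load_axis Unit vector along which displacement is driven; must be
#'   a signed coordinate axis (default `c(0, 0, -1)`, vertical).
#' @param increment Prescribed displacement per step (mm, default 0.1).
#' @param n_steps Number of displacement steps (default 20).
#' @return Object of class `boundary_conditions`.
#' @export
boundary_conditions <- function(fixed_nodes, driven_nodes,
                                load_axis = c(0, 0, -1),
                                increment = 0.1, n_steps = 20L) {
  fixed_nodes <- as.integer(fixed_nodes)
  driven_nodes <- as.integer(driven_nodes)
  if (length(fixed_nodes) == 0L || length(driven_nodes) == 0L) {
    stop("fixed and driven node sets must be non-empty", call. = FALSE)
  }
  if (length(intersect(fixed_nodes, driven_nodes)) > 0L) {
    stop("fixed and driven node sets overlap", call. = FALSE)
  }
  load_axis <- as.numeric(load_axis)
  if (abs(sqrt(sum(load_axis^2)) - 1) > 1e-9) {
    stop("load_axis must be a unit vector", call. = FALSE)
  }
  comp <- which(abs(abs(load_axis) - 1) < 1e-12)
  if (length(comp) != 1L) {
    stop("load_axis must be a signed coordinate axis", call. = FALSE)
  }
  if (increment <= 0 || n_steps < 1L) {
    stop("increment must be > 0 and n_steps >= 1", call. = FALSE)
  }
  structure(
    list(fixed_nodes = fixed_nodes, driven_nodes = driven_nodes,
         load_axis = load_axis, axis_comp = comp,
         axis_sign = sign(load_axis[comp]),
         increment = increment, n_steps = as.integer(n_steps)),
    class = "boundary_conditions"
  )
}

# constrained dofs and values for prescribed magnitude u along the axis
bc_constraints <- function(bc, prescribed_u) {
  fixed_dofs <- as.vector(rbind(3 * bc$fixed_nodes - 2,
                                3 * bc$fixed_nodes - 1,
                                3 * bc$fixed_nodes))
  driven_dofs <- 3 * bc$driven_nodes - 3 + bc$axis_comp
  list(
    dofs = c(fixed_dofs, driven_dofs),
    values = c(rep(0, length(fixed_dofs)),
               rep(prescribed_u * bc$axis_sign, length(driven_dofs))),
    driven_dofs = driven_dofs
  )
}

#' Solve a linear system under Dirichlet constraints
#'
#' @param K Sparse symmetric stiffness.
#' @param constrained_dofs Integer dof ids with prescribed values.
#' @param constrained_values Prescribed displacements (mm).
#' @return List `u` (full displacement vector) and `reactions` (forces at
#'   the constrained dofs, in constraint order).
#' @export
solve_displacement <- function(K, constrained_dofs, constrained_values) {
  ndof <- nrow(K)
  free <- setdiff(seq_len(ndof), constrained_dofs)
  u <- numeric(ndof)
  u[constrained_dofs] <- constrained_values
  rhs <- -K[free, constrained_dofs, drop = FALSE] %*% constrained_values
  Kff <- K[free, free, drop = FALSE]
  # sparse Cholesky: fails (rather than returning a spurious particular
  # solution) when the constrained system still has rigid-body modes
  ch <- tryCatch(
    Matrix::Cholesky(Matrix::forceSymmetric(Kff), LDL = FALSE, perm = TRUE),
    error = function(e) {
      stop("singular stiffness system: insufficient constraints? (",
           conditionMessage(e), ")", call. = FALSE)
    }
  )
  # second line of defence: a singular factorisation cannot reproduce a
  # generic probe right-hand side (it only solves rhs lying in the range)
  probe <- sin(seq_along(free))
  xp <- Matrix::solve(ch, probe)
  if (!all(is.finite(xp)) ||
      max(abs(Kff %*% xp - probe)) > 1e-6 * max(abs(probe))) {
    stop("singular stiffness system: insufficient constraints?",
         call. = FALSE)
  }
  uf <- Matrix::solve(ch, rhs)
  u[free] <- as.vector(uf)
  f <- as.vector(K %*% u)
  list(u = u, reactions = f[constrained_dofs])
}

#' Linear elastic solve under the stance boundary conditions
#'
#' @param assembly An [assemble()] result (or a bare sparse matrix `K`).
#' @param bc A [boundary_conditions()].
#' @param prescribed_u Prescribed displacement magnitude along the load
#'   axis (mm).
#' @return List with `u` (displacements), `force` (total reaction of the
#'   driven nodes projected on the load axis, N; positive when pushing),
#'   and `reactions_fixed` (same projection summed over fixed nodes).
#' @export
solve_linear <- function(assembly, bc, prescribed_u) {
  K <- if (is.list(assembly)) assembly$K else assembly
  con <- bc_constraints(bc, prescribed_u)
  sol <- solve_displacement(K, con$dofs, con$values)
  f <- numeric(nrow(K))
  f[con$dofs] <- sol$reactions
  driven_force <- sum(f[con$driven_dofs]) * bc$axis_sign
  fixed_axis_dofs <- 3 * bc$fixed_nodes - 3 + bc$axis_comp
  list(
    u = sol$u,
    force = driven_force,
    reactions_fixed = sum(f[fixed_axis_dofs]) * bc$axis_sign
  )
}
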