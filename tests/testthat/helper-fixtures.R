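# Shared fixtures and independent oracles. Oracles are deliberately coded
# from first principles (normal equations, rank enumeration, B'DB products)
# so they never share a code path with the implementation they check.

# hand-specified uniform materials for a mesh (bypasses the CT chain)
uniform_materials <- function(mesh, E, nu = 0, sigma_c = 1e20,
                              tensile_ratio = 1) {
  nt <- nrow(mesh$tets)
  ns <- nrow(mesh$shell)
  row_tbl <- function(n) {
    tibble::tibble(
      element = seq_len(n), hu = 0, rho = 0,
      E = rep(E, length.out = n), nu = rep(nu, length.out = n),
      sigma_c = rep(sigma_c, length.out = n),
      sigma_t = tensile_ratio * rep(sigma_c, length.out = n)
    )
  }
  structure(
    list(tets = row_tbl(nt), shell = row_tbl(ns), law = "uniform",
         tensile_ratio = tensile_ratio, shell_hu = 1000),
    class = "element_materials"
  )
}

# axis-aligned bar mesh with node sets at z = 0 and z = L
bar_mesh <- function(w = 10, L = 100, edge = 4) {
  m <- tetrahedralize(surface_box(c(0, 0, 0), c(w, w, L)), edge)
  z <- m$nodes[, 3]
  m$node_sets$base <- which(abs(z) < 1e-9)
  m$node_sets$top <- which(abs(z - L) < 1e-9)
  m
}

# ordinary least squares through the normal equations (independent of lm)
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  yhat <- X %*% beta
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(intercept = beta[1], slope = beta[2], r2 = 1 - ss_res / ss_tot)
}

# Mann-Whitney U by direct pair counting, exact p by full enumeration of
# group assignments (small n only)
mwu_oracle <- function(a, b) {
  u_stat <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_stat(a, b)
  pool <- c(a, b)
  idx <- utils::combn(length(pool), length(a))
  us <- apply(idx, 2, function(i) u_stat(pool[i], pool[-i]))
  mean_u <- length(a) * length(b) / 2
  p <- mean(abs(us - mean_u) >= abs(u_obs - mean_u) - 1e-12)
  list(U = u_obs, p = p)
}

# tet4 stiffness straight from the B'DB product with independently derived
# shape-function gradients (solving the linear system for each basis fn)
tet4_oracle <- function(coords, E, nu) {
  A <- cbind(1, coords)
  V <- abs(det(A)) / 6
  grads <- matrix(0, 4, 3)
  for (a in 1:4) {
    rhs <- numeric(4)
    rhs[a] <- 1
    cf <- solve(A, rhs)
    grads[a, ] <- cf[2:4]
  }
  B <- matrix(0, 6, 12)
  for (a in 1:4) {
    gx <- grads[a, 1]; gy <- grads[a, 2]; gz <- grads[a, 3]
    c0 <- 3 * (a - 1)
    B[1, c0 + 1] <- gx; B[2, c0 + 2] <- gy; B[3, c0 + 3] <- gz
    B[4, c0 + 1] <- gy; B[4, c0 + 2] <- gx
    B[5, c0 + 2] <- gz; B[5, c0 + 3] <- gy
    B[6, c0 + 1] <- gz; B[6, c0 + 3] <- gx
  }
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- diag(c(rep(2 * mu, 3), rep(mu, 3)))
  D[1:3, 1:3] <- D[1:3, 1:3] + lam
  V * t(B) %*% D %*% B
}
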