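#' Solver configuration
#'
#' @param newton_tol Relative residual tolerance per step (default 1e-6):
#'   the out-of-balance force norm at free dofs relative to the reaction
#'   norm.
#' @param max_iters Equilibrium iteration cap per step (default 25); after
#'   10 iterations the solver falls back to modified Newton on the elastic
#'   stiffness.
#' @param linear_solver `"direct"` (sparse Cholesky/LU) — the only backend.
#' @return Object of class `solver_config`.
#' @export
solver_config <- function(newton_tol = 1e-6, max_iters = 25L,
                          linear_solver = "direct") {
  stopifnot(newton_tol > 0, max_iters >= 1)
  structure(list(newton_tol = newton_tol, max_iters = as.integer(max_iters),
                 linear_solver = linear_solver),
            class = "solver_config")
}

# per-element stress from strain and plastic strain (vectorised)
elastic_stress <- function(eps, epsp, lam, mu) {
  e <- eps - epsp
  tr <- e[, 1] + e[, 2] + e[, 3]
  cbind(
    lam * tr + 2 * mu * e[, 1],
    lam * tr + 2 * mu * e[, 2],
    lam * tr + 2 * mu * e[, 3],
    mu * e[, 4], mu * e[, 5], mu * e[, 6]
  )
}

#' Displacement-controlled nonlinear solve
#'
#' Advances the prescribed cap displacement in `bc$n_steps` increments of
#' `bc$increment` mm. Each step runs Newton iteration on the out-of-balance
#' force with the elastoplastic tangent (elastic stiffness after 10
#' iterations, or when the tangent factorisation fails), with the
#' Drucker-Prager radial return applied element-wise. Shell membranes stay
#' elastic. The force-displacement curve collects the total driven-node
#' reaction along the load axis at every converged step.
#'
#' @param mesh A [tet_mesh()] (shells optional).
#' @param materials An [assign_materials()] result.
#' @param bc A [boundary_conditions()].
#' @param cfg A [solver_config()].
#' @return Object of class `fem_result`: `curve` (an [fd_curve()] of
#'   completed steps), `yielded_fraction_per_step` (cumulative fraction of
#'   tets that have yielded), `convergence` (per-step tibble including the
#'   fixed/driven reaction balance), `converged` flag, the final
#'   displacement field `u`, per-tet final `stress` (Voigt),
#'   `element_volumes`, and the `ever_yielded` flags.
#' @export
solve_nonlinear <- function(mesh, materials, bc, cfg = solver_config()) {
  stopifnot(inherits(bc, "boundary_conditions"),
            inherits(cfg, "solver_config"))
  asm <- assemble(mesh, materials)
  B <- asm$B
  vols <- asm$volumes
  Kshell <- asm$Kshell
  nt <- nrow(mesh$tets)
  ndof <- asm$ndof

  E <- materials$tets$E
  nu <- materials$tets$nu
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  G <- mu
  Kb <- E / (3 * (1 - 2 * nu))
  dp <- dp_params(materials$tets$sigma_c, materials$tensile_ratio)
  alpha <- rep(dp$alpha, length.out = nt)
  kdp <- dp$k

  blocks0 <- elastic_blocks(E, nu, vols)
  K_elastic <- asm$K

  u <- numeric(ndof)
  epsp <- matrix(0, nt, 6)
  ever_yielded <- logical(nt)
  final_sigma <- matrix(0, nt, 6)

  curve_d <- numeric(0)
  curve_f <- numeric(0)
  yfrac <- numeric(0)
  log_rows <- list()
  converged_all <- TRUE

  for (step in seq_len(bc$n_steps)) {
    target <- step * bc$increment
    con <- bc_constraints(bc, target)
    free <- setdiff(seq_len(ndof), con$dofs)
    # elastic predictor lift: distribute the constraint increment through
    # the elastic stiffness so the Newton start state is smooth
    dcon <- con$values - u[con$dofs]
    u[con$dofs] <- con$values
    if (any(dcon != 0)) {
      rhs <- -K_elastic[free, con$dofs, drop = FALSE] %*% dcon
      u[free] <- u[free] +
        as.vector(Matrix::solve(K_elastic[free, free, drop = FALSE], rhs))
    }

    step_converged <- FALSE
    res_norm <- NA_real_
    state <- NULL
    for (iter in seq_len(cfg$max_iters)) {
      eps <- matrix(as.vector(B %*% u), ncol = 6, byrow = TRUE)
      trial <- elastic_stress(eps, epsp, lam, mu)
      state <- dp_return_map_vec(trial, alpha, kdp, G, Kb)
      sigma <- state$sigma
      f_int <- as.vector(Matrix::t(B) %*% as.vector(t(sigma * vols))) +
        as.vector(Kshell %*% u)
      r <- -f_int[free]
      res_norm <- sqrt(sum(r^2))
      ref_norm <- max(sqrt(sum(f_int[con$dofs]^2)), 1e-8)
      if (res_norm <= cfg$newton_tol * ref_norm) {
        step_converged <- TRUE
        break
      }
      use_elastic <- iter > 10L
      Kt <- if (use_elastic) K_elastic else {
        blocks <- blocks0
        pl <- which(state$plastic & !state$apex)
        if (length(pl)) {
          # continuum tangent: D - (Dn)(Dn)' / (G + 9 K alpha^2)
          i1 <- trial[pl, 1] + trial[pl, 2] + trial[pl, 3]
          mhyd <- i1 / 3
          s <- trial[pl, , drop = FALSE]
          s[, 1] <- s[, 1] - mhyd; s[, 2] <- s[, 2] - mhyd
          s[, 3] <- s[, 3] - mhyd
          sj2 <- sqrt(0.5 * (s[, 1]^2 + s[, 2]^2 + s[, 3]^2) +
                        s[, 4]^2 + s[, 5]^2 + s[, 6]^2)
          for (idx in seq_along(pl)) {
            e_ <- pl[idx]
            dn <- c(rep(3 * Kb[e_] * alpha[e_], 3), 0, 0, 0) +
              G[e_] * s[idx, ] / max(sj2[idx], 1e-12)
            denom <- G[e_] + 9 * Kb[e_] * alpha[e_]^2
            blocks[, , e_] <- blocks[, , e_] -
              vols[e_] * (dn %o% dn) / denom
          }
        }
        ap <- which(state$apex)
        if (length(ap)) {
          for (e_ in ap) blocks[, , e_] <- 1e-6 * blocks0[, , e_]
        }
        Kt_ <- Matrix::t(B) %*% block_diag6(blocks) %*% B + Kshell
        Matrix::forceSymmetric((Kt_ + Matrix::t(Kt_)) / 2)
      }
      du <- tryCatch(
        as.vector(Matrix::solve(Kt[free, free, drop = FALSE], r)),
        error = function(e) NULL
      )
      if (is.null(du)) {
        du <- as.vector(Matrix::solve(K_elastic[free, free, drop = FALSE], r))
      }
      u[free] <- u[free] + du
    }

    log_rows[[step]] <- tibble::tibble(
      step = step, displacement = target, iterations = iter,
      residual = res_norm, converged = step_converged
    )
    if (!step_converged) {
      if (step == 1L) {
        stop(sprintf(
          "nonlinear solve failed to converge at step 1 (residual %.3g after %d iterations)",
          res_norm, cfg$max_iters
        ), call. = FALSE)
      }
      converged_all <- FALSE
      warning(sprintf(
        "step %d did not converge; returning partial curve of %d steps",
        step, step - 1L
      ), call. = FALSE)
      break
    }

    # commit plastic state
    epsp <- epsp + state$dlambda * state$nflow
    ever_yielded <- ever_yielded | state$plastic
    eps <- matrix(as.vector(B %*% u), ncol = 6, byrow = TRUE)
    sigma <- dp_return_map_vec(elastic_stress(eps, epsp, lam, mu),
                               alpha, kdp, G, Kb)$sigma
    f_int <- as.vector(Matrix::t(B) %*% as.vector(t(sigma * vols))) +
      as.vector(Kshell %*% u)
    force <- sum(f_int[con$driven_dofs]) * bc$axis_sign
    fixed_axis_dofs <- 3 * bc$fixed_nodes - 3 + bc$axis_comp
    log_rows[[step]]$reaction_balance <-
      abs(sum(f_int[fixed_axis_dofs]) + sum(f_int[con$driven_dofs])) /
      max(abs(force), 1e-8)
    curve_d <- c(curve_d, target)
    curve_f <- c(curve_f, force)
    yfrac <- c(yfrac, mean(ever_yielded))
    final_sigma <- sigma
  }

  curve <- if (length(curve_d) >= 3L) {
    fd_curve(curve_d, curve_f, source = "fea")
  } else {
    out <- tibble::tibble(displacement = curve_d, force = curve_f)
    attr(out, "source") <- "fea"
    out
  }
  structure(
    list(curve = curve, yielded_fraction_per_step = yfrac,
         convergence = dplyr::bind_rows(log_rows),
         converged = converged_all, u = u,
         stress = final_sigma, element_volumes = vols,
         ever_yielded = ever_yielded),
    class = "fem_result"
  )
}

#' @export
print.fem_result <- function(x, ...) {
  n <- nrow(x$curve)
  cat(sprintf(
    "<fem_result> %d steps%s; final force %.4g N at %.3g mm; yielded fraction %.3f\n",
    n, if (x$converged) "" else " (partial)",
    if (n) x$curve$force[n] else NA, if (n) x$curve$displacement[n] else NA,
    if (length(x$yielded_fraction_per_step)) {
      utils::tail(x$yielded_fraction_per_step, 1)
    } else 0
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.fem_result <- function(x, ...) {
  dplyr::mutate(tibble::as_tibble(x$curve),
                yielded_fraction = x$yielded_fraction_per_step)
}

#' @exportS3Method generics::glance
glance.fem_result <- function(x, ...) {
  tibble::tibble(
    n_steps = nrow(x$curve),
    converged = x$converged,
    max_force = if (nrow(x$curve)) max(x$curve$force) else NA_real_,
    final_yielded_fraction = if (length(x$yielded_fraction_per_step)) {
      utils::tail(x$yielded_fraction_per_step, 1)
    } else 0,
    total_iterations = sum(x$convergence$iterations)
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.fem_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$displacement)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$force), colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$force,
                                     colour = .data$yielded_fraction)) +
    ggplot2::scale_colour_viridis_c(name = "yielded") +
    ggplot2::labs(x = "Displacement (mm)", y = "Force (N)",
                  title = "FE force-displacement")
}
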