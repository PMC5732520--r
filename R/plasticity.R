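# Elastic-perfectly-plastic Drucker-Prager with associated flow:
# closed-form radial return with apex projection, vectorised over
# elements. Voigt order (xx, yy, zz, xy, yz, zx); strains engineering.

# vectorised return map
# trial: n x 6 trial stress; alpha, k: length-n surface constants;
# G, Kb: shear / bulk moduli per element.
# Returns corrected stress, plastic multiplier dlambda, flags, and the
# flow vector n (strain-like Voigt) for tangent/plastic-strain updates.
dp_return_map_vec <- function(trial, alpha, k, G, Kb) {
  i1 <- trial[, 1] + trial[, 2] + trial[, 3]
  m <- i1 / 3
  s <- trial
  s[, 1] <- s[, 1] - m; s[, 2] <- s[, 2] - m; s[, 3] <- s[, 3] - m
  j2 <- 0.5 * (s[, 1]^2 + s[, 2]^2 + s[, 3]^2) +
    s[, 4]^2 + s[, 5]^2 + s[, 6]^2
  sj2 <- sqrt(j2)
  f <- alpha * i1 + sj2 - k
  plastic <- f > 0
  apex <- logical(length(f))
  sigma <- trial
  dlam <- numeric(length(f))
  nflow <- matrix(0, length(f), 6)
  if (any(plastic)) {
    p <- which(plastic)
    dl <- f[p] / (G[p] + 9 * Kb[p] * alpha[p]^2)
    sj2_new <- sj2[p] - G[p] * dl
    reg <- sj2_new >= 0
    # regular radial return
    pr <- p[reg]
    if (length(pr)) {
      dlr <- dl[reg]
      scale_dev <- ifelse(sj2[pr] > 0, 1 - G[pr] * dlr / sj2[pr], 0)
      m_new <- m[pr] - 3 * Kb[pr] * alpha[pr] * dlr
      for (cdx in 1:6) {
        sigma[pr, cdx] <- s[pr, cdx] * scale_dev +
          if (cdx <= 3) m_new else 0
      }
      dlam[pr] <- dlr
      # flow vector from the trial deviator direction
      inv2sj <- ifelse(sj2[pr] > 0, 1 / (2 * sj2[pr]), 0)
      nflow[pr, 1] <- alpha[pr] + s[pr, 1] * inv2sj
      nflow[pr, 2] <- alpha[pr] + s[pr, 2] * inv2sj
      nflow[pr, 3] <- alpha[pr] + s[pr, 3] * inv2sj
      nflow[pr, 4] <- 2 * s[pr, 4] * inv2sj
      nflow[pr, 5] <- 2 * s[pr, 5] * inv2sj
      nflow[pr, 6] <- 2 * s[pr, 6] * inv2sj
    }
    # apex return: deviator vanishes, hydrostat on the cone tip
    pa <- p[!reg]
    if (length(pa)) {
      apex[pa] <- TRUE
      m_apex <- k[pa] / (3 * alpha[pa])
      sigma[pa, 1:3] <- m_apex
      sigma[pa, 4:6] <- 0
      # volumetric-only effective flow; dlambda from the pressure change
      dlam[pa] <- (m[pa] - m_apex) / (3 * Kb[pa] * alpha[pa])
      nflow[pa, 1:3] <- alpha[pa]
    }
  }
  list(sigma = sigma, dlambda = dlam, plastic = plastic, apex = apex,
       nflow = nflow)
}

#' Return-map a trial stress to the Drucker-Prager surface
#'
#' Closest-point (radial) return under associated elastic-perfectly-plastic
#' flow; trial states inside the surface are returned unchanged; states
#' beyond the cone apex are projected to the apex and flagged.
#'
#' @param trial_stress Symmetric 3x3 trial stress (MPa) or length-6 Voigt
#'   vector `(s11, s22, s33, s12, s23, s31)`.
#' @param params A [dp_params()].
#' @param E,nu Elastic constants used for the predictor.
#' @return List with `stress` (corrected, same shape as Voigt vector),
#'   `plastic` and `apex` logical flags.
#' @export
return_map <- function(trial_stress, params, E, nu) {
  if (is.matrix(trial_stress) && all(dim(trial_stress) == c(3, 3))) {
    sv <- c(trial_stress[1, 1], trial_stress[2, 2], trial_stress[3, 3],
            trial_stress[1, 2], trial_stress[2, 3], trial_stress[3, 1])
  } else {
    sv <- as.numeric(trial_stress)
  }
  G <- E / (2 * (1 + nu))
  Kb <- E / (3 * (1 - 2 * nu))
  r <- dp_return_map_vec(matrix(sv, 1), params$alpha, params$k, G, Kb)
  list(stress = as.vector(r$sigma), plastic = r$plastic[1], apex = r$apex[1])
}
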