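test_that("phantom volumes are deterministic and honour the design", {
  d <- phantom_design("bar", dimensions = c(x = 8, y = 8, z = 16),
                      cortical_thickness = 0, trabecular_density = 1.0,
                      spacing = c(0.5, 0.5, 0.5), supersample = 2,
                      noise_sigma = 3, seed = 21)
  a <- make_phantom(d)
  b <- make_phantom(d)
  expect_identical(a$volume$values, b$volume$values)

  # constant-density bar, no noise: interior voxels at the inverse-cal HU
  d0 <- phantom_design("bar", dimensions = c(x = 8, y = 8, z = 16),
                       cortical_thickness = 0, trabecular_density = 1.0,
                       spacing = c(0.5, 0.5, 0.5), supersample = 2,
                       seed = 21)
  ph <- make_phantom(d0)
  ctr <- vapply(1:3, function(ax) {
    which.min(abs(
      ph$volume$origin[ax] +
        (seq_len(dim(ph$volume$values)[ax]) - 1) * ph$volume$spacing[ax] -
        4
    ))
  }, integer(1))
  expect_equal(ph$volume$values[ctr[1], ctr[2], ctr[3]], 1000)
  expect_true(surface_is_closed(ph$truth$surface))
  expect_equal(surface_volume(ph$truth$surface), 8 * 8 * 16)
})

test_that("voxelised boundary misclassification shrinks as spacing halves", {
  frac_err <- vapply(c(1, 0.5), function(h) {
    d <- phantom_design("cylinder", dimensions = c(radius = 6, length = 20),
                        cortical_thickness = 0, trabecular_density = 1.0,
                        spacing = c(h, h, h), supersample = 2, seed = 2)
    ph <- make_phantom(d)
    v <- ph$volume
    g <- expand.grid(
      x = v$origin[1] + (seq_len(dim(v$values)[1]) - 1) * h,
      y = v$origin[2] + (seq_len(dim(v$values)[2]) - 1) * h,
      z = v$origin[3] + (seq_len(dim(v$values)[3]) - 1) * h,
      KEEP.OUT.ATTRS = FALSE
    )
    sd_ <- ph$truth$sdf(g$x, g$y, g$z)
    truly_in <- sd_ <= 0
    # a 750-HU cut classifies voxels by 75% coverage, so the partial-volume
    # skin (coverage between 50% and 75%) is misclassified: its volume
    # shrinks linearly with the voxel size
    seg_in <- as.vector(v$values) > 750
    near <- abs(sd_) < 3 # rod-free specimen neighbourhood
    sum(seg_in[near] != truly_in[near]) * h^3
  }, numeric(1))
  expect_lt(frac_err[2], frac_err[1])
})

test_that("bilinear curve generator matches its programmed parameters", {
  cv <- make_curve(stiffness = 1000, fracture_load = 1000,
                   post_knee_stiffness_fraction = 0.5, increment = 0.01)
  fm <- fracture_load_fea(
    fd_curve(cv$displacement, cv$force, source = "fea")
  )
  expect_lt(abs(fm$fracture_load - 1000), 1000 * 0.01 + 1e-9)
  expect_equal(fm$stiffness, 1000, tolerance = 1e-9)

  # knee fraction 1: straight line, no fracture
  lin <- make_curve(1000, 1000, post_knee_stiffness_fraction = 1,
                    increment = 0.01)
  expect_error(fracture_load_fea(fd_curve(lin$displacement, lin$force,
                                          source = "fea")),
               "no fracture")

  # determinism under the seed
  c1 <- make_curve(800, 500, 0.5, noise_sigma = 5, seed = 33)
  c2 <- make_curve(800, 500, 0.5, noise_sigma = 5, seed = 33)
  expect_identical(c1$force, c2$force)
})

test_that("zero-noise cohorts recover the age slope exactly", {
  dsg <- cohort_design(n_specimens = 20, strength_sd = 0, mech_sd = 0,
                       fea_sd = 0, stiffness_sd = 0, seed = 4)
  rep_ <- cohort_report(cohort_metrics(make_cohort(dsg)))
  age_slope <- rep_$regressions$slope[
    rep_$regressions$analysis == "load_vs_age" &
      rep_$regressions$source == "mechanical"]
  expect_equal(age_slope, -142.6, tolerance = 1e-9)
  r2 <- rep_$regressions$r2[
    rep_$regressions$analysis == "fracture_load_mech_vs_fea"]
  expect_equal(r2, 1, tolerance = 1e-9)
})

test_that("noisy cohorts cover the true age slope at the nominal CI rate", {
  hits <- vapply(1:50, function(s) {
    coh <- make_cohort(cohort_design(n_specimens = 20, seed = 1000 + s),
                       curves = FALSE)
    fit <- lm(mech_fracture_load ~ age, data = coh)
    ci <- confint(fit)["age", ]
    ci[1] <= -142.6 && -142.6 <= ci[2]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("null laterality gives uniform Mann-Whitney p-values", {
  # a single-age design removes the paired-cadaver age structure, so the
  # two sides are genuinely independent samples under the null
  ps <- vapply(1:80, function(s) {
    coh <- make_cohort(
      cohort_design(n_specimens = 16, age_range = c(87, 87),
                    laterality_effect = 0, seed = 3000 + s),
      curves = FALSE
    )
    mann_whitney_u(
      coh$mech_fracture_load[coh$side == "right"],
      coh$mech_fracture_load[coh$side == "left"]
    )$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("cohort sample moments match the documented model at large n", {
  dsg <- cohort_design(n_specimens = 10000, seed = 77)
  coh <- make_cohort(dsg, curves = FALSE)
  mean_age <- mean(dsg$age_range)
  # expected latent mean and the 3-standard-error band
  mu <- dsg$b0 + dsg$b1 * mean_age
  age_var <- diff(dsg$age_range)^2 / 12
  tot_sd <- sqrt(dsg$b1^2 * age_var + dsg$strength_sd^2 + dsg$mech_sd^2)
  se <- tot_sd / sqrt(nrow(coh))
  expect_lt(abs(mean(coh$mech_fracture_load) - mu), 3 * se)
  expect_lt(abs(sd(coh$mech_fracture_load) - tot_sd), 3 * tot_sd / sqrt(nrow(coh)))
  # stiffness divisor
  expect_equal(mean(coh$mech_stiffness),
               mean(coh$mech_fracture_load) / dsg$stiffness_divisor,
               tolerance = 0.01)
})

test_that("laterality effect shifts the right side by its design value", {
  coh <- make_cohort(
    cohort_design(n_specimens = 5000, laterality_effect = 800,
                  strength_sd = 0, mech_sd = 0, fea_sd = 0,
                  stiffness_sd = 0, seed = 9),
    curves = FALSE
  )
  diffs <- coh$mech_fracture_load[coh$side == "right"] -
    coh$mech_fracture_load[coh$side == "left"]
  expect_equal(mean(diffs), 800, tolerance = 1e-9)
})
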