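test_that("window stiffness recovers programmed slopes", {
  d <- seq(0, 1, by = 0.05)
  lin <- fd_curve(d, 1000 * d)
  expect_equal(stiffness_20_80(lin, 1000), 1000, tolerance = 1e-9)

  # bilinear with the knee at 800 N: the 20-80% window avoids the knee
  bl <- make_curve(stiffness = 1000, fracture_load = 800,
                   post_knee_stiffness_fraction = 0.3, increment = 0.01)
  expect_equal(stiffness_20_80(bl, 800), 1000, tolerance = 1e-9)

  # matches the normal-equations oracle on the windowed samples
  set.seed(5)
  f <- 1000 * d + rnorm(length(d), 0, 20)
  noisy <- fd_curve(d, f)
  w <- which(f >= 0.2 * 900 & f <= 0.8 * 900)
  o <- ols_oracle(d[w], f[w])
  expect_equal(stiffness_20_80(noisy, 900), o$slope, tolerance = 1e-10)

  # scale equivariance
  scaled <- fd_curve(d, 3 * f)
  expect_equal(stiffness_20_80(scaled, 3 * 900),
               3 * stiffness_20_80(noisy, 900), tolerance = 1e-9)

  expect_error(stiffness_20_80(fd_curve(c(0, 1, 2), c(0, 1000, 2000)), 1000),
               "denser")
})

test_that("tangent-drop detector fires at the programmed knee", {
  # 5 tangents of 1000 over 0.1 mm steps, then 700: fracture at 500 N
  d <- seq(0, 0.7, by = 0.1)
  f <- c(0, 100, 200, 300, 400, 500, 570, 640)
  fm <- fracture_load_fea(fd_curve(d, f, source = "fea"))
  expect_equal(fm$fracture_load, 500)
  expect_equal(fm$detection_index, 6)
  expect_equal(fm$reference_stiffness, 1000, tolerance = 1e-9)

  # purely linear: no fracture
  expect_error(fracture_load_fea(fd_curve(d, 1000 * d, source = "fea")),
               "no fracture",
               class = "femstrength_no_fracture")

  # generator curve with programmed knee: detected within one increment
  for (frac in c(0.2, 0.5, 0.7)) {
    cv <- make_curve(stiffness = 1200, fracture_load = 950,
                     post_knee_stiffness_fraction = frac,
                     increment = 0.01, source = "fea")
    fm2 <- fracture_load_fea(cv)
    expect_lt(abs(fm2$fracture_load - 950), 1200 * 0.01 + 1e-9)
  }
})

test_that("mechanical detector matches the FE rule and survives noise", {
  cv <- make_curve(stiffness = 1000, fracture_load = 1000,
                   post_knee_stiffness_fraction = 0.5, increment = 0.01)
  a <- fracture_load_fea(cv)
  b <- fracture_load_mechanical(cv, smooth_window = 1L)
  expect_equal(b$fracture_load, a$fracture_load)

  # concave-but-shallow curve: tangent never below 80% of reference
  d <- seq(0.01, 1, by = 0.01)
  f <- 1000 * d - 60 * d^2 # tangent 1000 -> 880
  expect_error(fracture_load_mechanical(fd_curve(d, f)), "no fracture")

  # 1% force noise: detected load within 3% of the noiseless result
  # across seeded replicates (smoothing spans ~10% of the loading stroke
  # at this sampling density)
  base <- fracture_load_mechanical(
    make_curve(1000, 1000, 0.2, increment = 0.01, noise_sigma = 0),
    smooth_window = 25L
  )$fracture_load
  loads <- vapply(1:100, function(s) {
    fracture_load_mechanical(
      make_curve(1000, 1000, 0.2, increment = 0.01, noise_sigma = 10,
                 seed = s),
      smooth_window = 25L
    )$fracture_load
  }, numeric(1))
  expect_true(all(abs(loads - base) / base < 0.03))
})

test_that("detectors are stable under uniform 2x resampling", {
  cv <- make_curve(stiffness = 900, fracture_load = 720,
                   post_knee_stiffness_fraction = 0.4, increment = 0.02,
                   source = "fea")
  fm <- fracture_load_fea(cv)
  d2 <- seq(min(cv$displacement), max(cv$displacement),
            length.out = 2 * nrow(cv))
  f2 <- approx(cv$displacement, cv$force, xout = d2)$y
  fm2 <- fracture_load_fea(fd_curve(d2, f2, source = "fea"))
  inc_force <- 900 * 0.02
  expect_lt(abs(fm2$fracture_load - fm$fracture_load), inc_force + 1e-9)
})

test_that("regression agrees with hand values and the normal equations", {
  r <- linreg(0:10, 2 * (0:10) + 1)
  expect_equal(r$slope, 2, tolerance = 1e-12)
  expect_equal(r$intercept, 1, tolerance = 1e-12)
  expect_equal(r$r2, 1)

  r2 <- linreg(c(0, 1, 2), c(0, 1, 4))
  expect_equal(r2$slope, 2, tolerance = 1e-12)
  expect_equal(r2$intercept, -1 / 3, tolerance = 1e-12)
  expect_equal(r2$r2, 12 / 13, tolerance = 1e-9)

  set.seed(31)
  for (i in 1:100) {
    n <- sample(3:12, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    if (stats::var(x) == 0) next
    o <- ols_oracle(x, y)
    got <- linreg(x, y)
    expect_equal(got$slope, o$slope, tolerance = 1e-10)
    expect_equal(got$intercept, o$intercept, tolerance = 1e-10)
    expect_equal(got$r2, o$r2, tolerance = 1e-10)
  }

  expect_error(linreg(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("rank-sum test agrees with exhaustive enumeration", {
  m <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(m$U, 0)
  o <- mwu_oracle(c(1, 2), c(3, 4))
  expect_equal(m$U, o$U)
  expect_equal(m$p_value, o$p, tolerance = 1e-10)

  # identity U(a,b) + U(b,a) = |a| |b|
  set.seed(8)
  for (i in 1:100) {
    a <- rnorm(sample(2:6, 1))
    b <- rnorm(sample(2:6, 1))
    u1 <- mann_whitney_u(a, b)
    u2 <- mann_whitney_u(b, a)
    expect_equal(u1$U + u2$U, length(a) * length(b))
    o <- mwu_oracle(a, b)
    expect_equal(u1$U, o$U)
    expect_equal(u1$p_value, o$p, tolerance = 1e-10)
  }

  # identical groups: symmetry gives p = 1
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p_value, 1,
               tolerance = 1e-12)
})

test_that("cohort report runs the five validation analyses", {
  set.seed(2)
  n <- 10
  age <- runif(2 * n, 70, 100)
  latent <- 15000 - 140 * age
  rec <- tibble::tibble(
    specimen = sprintf("S%02d", 1:(2 * n)),
    age = age, sex = rep(c("M", "F"), n),
    side = rep(c("right", "left"), each = n),
    mech_fracture_load = latent,
    mech_stiffness = latent / 2.7,
    fea_fracture_load = latent,     # perfectly correlated
    fea_stiffness = latent / 2.7
  )
  rep_ <- cohort_report(rec)
  regs <- rep_$regressions
  expect_equal(nrow(regs), 6)
  r2_load <- regs$r2[regs$analysis == "fracture_load_mech_vs_fea"]
  expect_equal(r2_load, 1, tolerance = 1e-12)
  age_slope <- regs$slope[regs$analysis == "load_vs_age" &
                            regs$source == "mechanical"]
  expect_equal(age_slope, -140, tolerance = 1e-9)

  # identical left/right values: laterality p = 1 under enumeration-free
  # symmetry (wilcox normal approx gives exactly 1 for equal ranks)
  rec2 <- rec
  rec2$mech_fracture_load <- rep(latent[1:n], 2)
  rec2$mech_stiffness <- rep(latent[1:n] / 2.7, 2)
  rec2$fea_fracture_load <- rep(latent[1:n], 2)
  rec2$fea_stiffness <- rep(latent[1:n] / 2.7, 2)
  rep2 <- cohort_report(rec2)
  expect_true(all(rep2$laterality$p_value == 1))

  expect_error(cohort_report(rec[, -2]), "missing columns")

  # multiple regression of load on age/sex/side reports all terms
  lp <- load_predictors(rec)
  expect_true("age" %in% lp$term)
  expect_equal(lp$estimate[lp$term == "age"], -140, tolerance = 1e-9)

  json <- withr::local_tempfile(fileext = ".json")
  write_cohort_report(rep_, json)
  back <- jsonlite::read_json(json, simplifyVector = TRUE)
  expect_equal(nrow(back$regressions), 6)
  expect_true(file.exists(sub("\\.json$", "_regressions.csv", json)))
})

test_that("curve CSV round-trips preserve samples", {
  cv <- make_curve(800, 640, 0.5, increment = 0.05)
  path <- withr::local_tempfile(fileext = ".csv")
  write_curve_csv(cv, path)
  rt <- read_curve_csv(path)
  expect_equal(rt$displacement, cv$displacement)
  expect_equal(rt$force, cv$force)
})
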