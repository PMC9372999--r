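# Reference flow fields and the equal-average-shear calibration

test_that("Poiseuille profile reproduces the printed channel values", {
  g <- slit_geometry(34)
  p <- poiseuille_profile(f = 0.0461, geometry = g, eta = 4.05)
  # v_max = f Lz^2 / (8 eta) at the strongest-flow force density
  expect_equal(p$v_max, 0.0461 * 34^2 / (8 * 4.05), tolerance = 1e-12)
  expect_equal(p$v_max, 1.644, tolerance = 1e-3)
  # mean over maximum is 2/3 for a parabola
  expect_equal(p$v_mean / p$v_max, 2 / 3, tolerance = 1e-5)
  # no-slip and symmetry
  expect_equal(p$v[1], 0)
  expect_equal(p$v, rev(p$v))
  # f = 0 is quiescent
  p0 <- poiseuille_profile(f = 0, geometry = g)
  expect_true(all(p0$v == 0))
})

test_that("dynamic viscosity composes from density and kinematic viscosity", {
  fl <- fluid_params(rho = 5, nu = 0.81)
  expect_equal(fl$eta, 4.05)
})

test_that("EO profile solves the Stokes balance against the charge density", {
  g <- slit_geometry(34)
  ch <- solve_pb_no_salt(g)
  eo <- eo_profile(ch, eE = 40, eta = 4.05)
  expect_equal(eo$v[1], 0)
  expect_equal(eo$v[length(eo$v)], 0)
  expect_equal(eo$v, rev(eo$v), tolerance = 1e-9)
  # analytic counterion-only solution: v proportional to
  # log(cos(K z) / cos(K Lz/2))
  gc <- gouy_chapman_profile(eo$z, g)
  vref <- log(cos(gc$K * eo$z) / cos(gc$K * g$Lz / 2))
  vref <- vref * eo$v_max / max(vref)
  expect_lt(max(abs(eo$v - vref)) / eo$v_max, 1e-4)
  # eE = 0 is quiescent
  expect_true(all(eo_profile(ch, eE = 0)$v == 0))
  # zero charge cannot drive a flow
  expect_error(match_amplitude("eo_no_salt", 1,
                               charge = solve_pb_no_salt(g, Sigma = 0)),
               "zero charge")
})

test_that("thin double layers produce plug flow", {
  # synthetic exponential double layer with kappa Lz = 200: the
  # Helmholtz-Smoluchowski limit has <v>/v_max -> 1
  Lz <- 34
  kap <- 200 / Lz
  z <- seq(-Lz / 2, Lz / 2, length.out = 4097)
  rho <- exp(-kap * (Lz / 2 - abs(z)))
  ch <- structure(list(z = z, rho_el = rho, Sigma = NA, l_B = NA,
                       kappa = kap, regime = "synthetic"),
                  class = "charge_profile")
  eo <- eo_profile(ch, eE = 1)
  expect_gt(eo$v_mean / eo$v_max, 0.98)
})

test_that("average shear telescopes to 2 v_max / Lz for no-slip profiles", {
  g <- slit_geometry(34)
  profiles <- list(
    poiseuille_profile(v_max = 1.644, geometry = g),
    eo_profile(solve_pb_no_salt(g), eE = 160),
    eo_profile(solve_pb_with_salt(g, kappa = KAPPA_SALT), eE = 307))
  for (p in profiles)
    expect_equal(average_shear(p), 2 * p$v_max / g$Lz, tolerance = 5e-3)
  # the printed strongest-flow value: 2 * 1.644 / 34
  expect_equal(average_shear(profiles[[1]]), 0.0967, tolerance = 1e-3)
  # a uniform profile has no shear
  flat <- profiles[[1]]
  flat$v <- rep(1, length(flat$v))
  flat <- slitflow:::velocity_profile_object(flat$z, flat$v, "flat", 0)
  expect_equal(average_shear(flat), 0)
})

test_that("matched amplitudes equalize the average shear across flow types", {
  g <- slit_geometry(34)
  vmax <- 1.644
  chn <- solve_pb_no_salt(g)
  chs <- solve_pb_with_salt(g, kappa = KAPPA_SALT)
  f <- match_amplitude("poiseuille", vmax, g)
  expect_equal(f, 0.0461, tolerance = 1e-3)
  een <- match_amplitude("eo_no_salt", vmax, g, charge = chn)
  ees <- match_amplitude("eo_salt", vmax, g, charge = chs)
  ps <- list(poiseuille_profile(f = f, geometry = g),
             eo_profile(chn, een), eo_profile(chs, ees))
  gd <- vapply(ps, average_shear, 1)
  expect_lt(max(gd) / min(gd) - 1, 1e-2)
  # linearity: doubling the target doubles the amplitude
  expect_equal(match_amplitude("poiseuille", 2 * vmax, g), 2 * f)
  expect_equal(match_amplitude("eo_no_salt", 2 * vmax, g, charge = chn),
               2 * een, tolerance = 1e-12)
  # the calibrated no-salt field for the weakest flow is near the printed
  # eE = 40 (the normalization convention is only pinned to ~15%)
  ee_weak <- match_amplitude("eo_no_salt", 0.411, g, charge = chn)
  expect_lt(abs(ee_weak - 40) / 40, 0.15)
})

test_that("profiles scale linearly with the driver amplitude", {
  g <- slit_geometry(17)
  ch <- solve_pb_no_salt(g)
  a <- eo_profile(ch, eE = 10)
  b <- eo_profile(ch, eE = 30)
  expect_equal(b$v, 3 * a$v, tolerance = 1e-10)
})

test_that("velocity profile TSV export records the calibration header", {
  g <- slit_geometry(17)
  p <- poiseuille_profile(v_max = 0.822, geometry = g)
  f <- tempfile(fileext = ".tsv")
  write_velocity_profile(p, f)
  lines <- readLines(f)
  expect_true(any(grepl("kind=poiseuille", lines)))
  expect_true(any(grepl("v_max=0.822", lines)))
  d <- read.table(f, sep = "\t")
  expect_equal(d[[2]], p$v, tolerance = 1e-9)
  unlink(f)
})

test_that("per-particle streaming force matches the Stokes force density", {
  g <- slit_geometry(17)
  # Poiseuille: force density f shared among rho particles per cell
  fp <- streaming_force_profile("poiseuille", 0.0922, g, rho = 5)
  expect_true(all(fp$fx == 0.0922 / 5))
  ch <- solve_pb_no_salt(g)
  fe <- streaming_force_profile("eo_no_salt", 40, g, rho = 5, charge = ch)
  expect_equal(fe$fx, approx(ch$z, ch$rho_el, xout = fe$z)$y * 40 / 5,
               tolerance = 1e-12)
})
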