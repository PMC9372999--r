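# Gyration tensor, profiles, velocity statistics, persistence length,
# Zimm time / Weissenberg number

test_that("gyration handles the exact reference shapes", {
  # two monomers separated by d: Rg = d/2 and a pure rod (b = 1)
  g2 <- gyration(rbind(c(0, 0, 0), c(3, 0, 0)))
  expect_equal(g2$Rg, 1.5)
  expect_equal(g2$asphericity, 1)
  # eight corners of a cube: isotropic, b = 0
  cube <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  g8 <- gyration(cube)
  expect_equal(g8$asphericity, 0, tolerance = 1e-12)
  expect_equal(g8$Rg, sqrt(3))
  # all monomers coincident: degenerate, flagged
  g0 <- gyration(matrix(1, 5, 3))
  expect_equal(g0$Rg, 0)
  expect_true(g0$degenerate)
})

test_that("eigenvalue sum equals the squared gyration radius on any frame", {
  set.seed(41)
  for (i in 1:25) {
    m <- random_frame(sample(3:60, 1), scale = runif(1, 0.5, 4))
    g <- gyration(m)
    expect_lt(abs(sum(g$eigenvalues) - g$Rg^2), 1e-10 * max(1, g$Rg^2))
    expect_true(g$asphericity >= 0 && g$asphericity <= 1)
    expect_true(all(g$eigenvalues >= -1e-12))
    # against R's eigen() on the same tensor
    expect_equal(g$eigenvalues,
                 sort(eigen(g$tensor, symmetric = TRUE)$values),
                 tolerance = 1e-10)
  }
})

test_that("a large isotropic cloud is spherical", {
  set.seed(42)
  g <- gyration(random_frame(10000))
  expect_lt(g$asphericity, 0.01)
})

test_that("monomer density normalizes to one and finds point masses", {
  g <- slit_geometry(17)
  frames <- lapply(1:5, function(i) matrix(c(rep(0, 20), rep(0, 20),
                                             rep(0, 20)), 20, 3))
  d <- monomer_density(frames, g)
  expect_equal(sum(d$value * d$bin_width), 1, tolerance = 1e-12)
  expect_equal(sum(d$value > 0), 1)  # single occupied bin at the center
  expect_gt(d$value[which.max(d$value)], 0)
  expect_error(monomer_density(list(list()), g), "at least one frame")
})

test_that("equilibrium monomer density is symmetric within error bars", {
  set.seed(43)
  g <- slit_geometry(17)
  trajs <- lapply(1:4, function(s) {
    mc <- chain_mc(polymer_spec(), n_sweeps = 15000, warmup_sweeps = 4000,
                   sample_stride = 10, geometry = g, frame_stride = 1)
    mc$frames
  })
  d <- monomer_density(trajs, g, bin_width = 1)
  nz <- length(d$z)
  asym <- abs(d$value - rev(d$value))
  err2 <- sqrt(d$stderr^2 + rev(d$stderr)^2)
  ok <- asym <= 2.5 * err2 | (d$value + rev(d$value)) < 0.01 * max(d$value)
  expect_gt(mean(ok), 0.9)
})

test_that("asphericity profile is consistent with the pooled average", {
  set.seed(44)
  g <- slit_geometry(17)
  mc <- chain_mc(polymer_spec(), n_sweeps = 20000, warmup_sweeps = 5000,
                 sample_stride = 10, geometry = g, frame_stride = 1)
  prof <- asphericity_profile(list(mc$frames), g, bin_width = 2,
                              min_count = 20)
  pooled <- mean(vapply(mc$frames, function(m) gyration(m)$asphericity, 1))
  # bins holding most of the samples must bracket the pooled value
  good <- which(prof$counts > 0.1 * sum(prof$counts))
  expect_true(any(abs(prof$value[good] - pooled) < 0.1))
  # identical frames in a bin give zero error
  same <- replicate(8, mc$frames[[1]], simplify = FALSE)
  p2 <- asphericity_profile(list(same, same), g, bin_width = 4)
  expect_true(all(p2$stderr[p2$counts > 0] == 0))
})

test_that("velocity statistics reduce correctly for trivial fields", {
  prof <- data.frame(z = seq(-8, 8, by = 0.5), vx = 0)
  vs <- velocity_stats(list(fluid_profile = prof, v_mono = 0))
  expect_equal(vs$v_fluid_mean, 0)
  # uniform translation: every average equals u
  prof$vx <- 0.7
  vs <- velocity_stats(list(fluid_profile = prof, v_mono = 0.7))
  expect_equal(vs$v_fluid_mean, 0.7)
  expect_equal(vs$v_mono, 0.7)
  expect_equal(vs$mono_ratio, 1, tolerance = 1e-9)
  # parabolic profile: fitted v_max matches the analytic peak
  g <- slit_geometry(17)
  p <- poiseuille_profile(v_max = 0.822, geometry = g)
  vs <- velocity_stats(list(fluid_profile = data.frame(z = p$z, vx = p$v),
                            v_mono = NULL))
  expect_equal(vs$v_max, 0.822, tolerance = 1e-6)
  # plain grid mean (matching binned data) carries an O(h) endpoint bias
  expect_equal(vs$fluid_ratio, 2 / 3, tolerance = 5e-3)
})

test_that("persistence length reproduces the freely jointed reference", {
  # uniform random bond directions: <theta^2> = (pi^2 - 4)/2 by direct
  # integration of theta^2 sin(theta)/2, so Lp = 4 sigma/(pi^2 - 4)
  set.seed(45)
  frames <- lapply(1:300, function(i) {
    b <- matrix(rnorm(3 * 30), 30, 3)
    b <- b / sqrt(rowSums(b^2))
    apply(rbind(0, b), 2, cumsum)
  })
  pl <- persistence_length(frames)
  expect_equal(pl$theta2_mean, (pi^2 - 4) / 2, tolerance = 0.01)
  expect_equal(pl$Lp, 4 / (pi^2 - 4), tolerance = 0.01)
  # straight chain: infinite persistence, flagged as Inf
  straight <- matrix(c(1:5, rep(0, 10)), 5, 3)
  expect_equal(persistence_length(list(straight))$Lp, Inf)
})

test_that("angle-fluctuation and bond-correlation estimates agree when stiff", {
  set.seed(46)
  mc <- chain_mc(polymer_spec(eps_bend = 10), n_sweeps = 20000,
                 warmup_sweeps = 5000, sample_stride = 10, frame_stride = 1,
                 max_pivot = 0.6)
  pl <- persistence_length(mc$frames)
  expect_equal(pl$Lp, pl$Lp_correlation, tolerance = 0.12)
})

test_that("Zimm time and Weissenberg number follow the closed form", {
  g <- slit_geometry(34)
  # direct formula evaluation as the oracle
  expect_equal(zimm_time(40), 4.05 * 40^(3 * 0.588) / (sqrt(6) * pi))
  # tau_Z scales as N^(3 nu): doubling N multiplies it by 2^1.764
  expect_equal(zimm_time(80) / zimm_time(40), 2^(3 * 0.588),
               tolerance = 1e-12)
  w <- weissenberg(geometry = g, v_max = 1.644)
  expect_equal(w$flow_time, 34 / 1.644)
  expect_equal(w$Wi, w$tau_Z * 1.644 / 34)
  # v_max -> 0 switches the flow off: Wi -> 0
  expect_equal(weissenberg(geometry = g, v_max = 0)$Wi, 0)
})

test_that("profile TSV export round-trips values and metadata", {
  g <- slit_geometry(17)
  frames <- lapply(1:3, function(i) random_frame(40))
  d <- monomer_density(frames, g, bin_width = 1)
  f <- tempfile(fileext = ".tsv")
  write_profile_table(d, f, "monomer density")
  lines <- readLines(f)
  expect_true(any(grepl("normalization=probability density", lines)))
  tab <- read.table(f, sep = "\t")
  expect_equal(tab[[2]], d$value, tolerance = 1e-9)
  unlink(f)
})
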