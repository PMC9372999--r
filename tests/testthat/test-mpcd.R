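# MPCD solvent engine: streaming, grid shift, SRD collision, thermostat,
# SRR walls, and the global conservation ledgers

make_state <- function(n, geometry, kT = 1, seed = 1) {
  set.seed(seed)
  pos <- cbind(runif(n, 0, geometry$Lx), runif(n, 0, geometry$Ly),
               runif(n, -geometry$Lz / 2 + 1e-6, geometry$Lz / 2 - 1e-6))
  vel <- matrix(rnorm(3 * n, sd = sqrt(kT)), n, 3)
  structure(list(pos = pos, vel = vel, mass = 1, geometry = geometry),
            class = "fluid_state")
}

test_that("streaming is ballistic without forces and walls in the way", {
  g <- tiny_geometry()
  st <- make_state(1, g)
  st$pos[1, ] <- c(1, 1, 0); st$vel[1, ] <- c(0, 0, 0)
  out <- stream(st, 0.1)
  expect_equal(out$pos[1, ], c(1, 1, 0))
  st$vel[1, ] <- c(1, 0, 0)
  out <- stream(st, 0.1)
  expect_equal(out$pos[1, ], c(1.1, 1, 0))
  expect_equal(attr(out, "n_reflections"), 0L)
})

test_that("constant force streaming follows exact kinematics", {
  g <- tiny_geometry()
  st <- make_state(1, g)
  st$pos[1, ] <- c(1, 1, 0); st$vel[1, ] <- c(0, 0, 0)
  force <- list(z = c(-4, 4), fx = c(1, 1))
  out <- stream(st, 0.1, force)
  # half-kick / drift / half-kick: dv = f dt, dx = f dt^2 / 2
  expect_equal(out$vel[1, 1], 0.1, tolerance = 1e-12)
  expect_equal(out$pos[1, 1] - 1, 0.005, tolerance = 1e-9)
  expect_equal(attr(out, "injected_px"), 0.1, tolerance = 1e-12)
})

test_that("grid shift components are uniform on [-1/2, 1/2)", {
  set.seed(42)
  draws <- t(replicate(100000, as.numeric(grid_shift())))
  expect_true(all(draws >= -0.5 & draws < 0.5))
  expect_lt(max(abs(colMeans(draws))), 0.01)
  # variance of U(-1/2, 1/2) is 1/12
  expect_equal(apply(draws, 2, var), rep(1 / 12, 3), tolerance = 0.02)
})

test_that("cell assignment maps every particle to exactly one unit cell", {
  g <- tiny_geometry()
  st <- make_state(500, g)
  set.seed(3)
  sh <- grid_shift()
  ca <- cell_assign(st$pos, sh, g)
  expect_length(ca$cell, 500)
  expect_true(all(ca$cell >= 0 & ca$cell < ca$n_cells))
  # two particles closer than any cell diagonal but in the same shifted cell
  # must share the id; verify against a direct computation
  ix <- ((floor(st$pos[, 1] - sh[1]) %% 6) + 6) %% 6
  iy <- ((floor(st$pos[, 2] - sh[2]) %% 6) + 6) %% 6
  iz <- pmin(pmax(floor(st$pos[, 3] + 4 - sh[3]), -1), 8)
  expect_equal(ca$cell, as.integer((iz + 1) + 10 * (ix + 6 * iy)))
})

test_that("SRD collision conserves cell momentum and kinetic energy", {
  g <- tiny_geometry()
  st <- make_state(800, g, seed = 7)
  set.seed(8)
  ca <- cell_assign(st$pos, grid_shift(), g)
  mass <- rep(1, 800); mass[1:40] <- 5  # include heavy solute members
  v2 <- srd_collide(st$vel, mass, ca, thermostat = FALSE)
  # per-cell momentum identical to 1e-12 (direct summation oracle)
  for (k in 1:3) {
    p_before <- tapply(mass * st$vel[, k], ca$cell, sum)
    p_after <- tapply(mass * v2[, k], ca$cell, sum)
    expect_lt(max(abs(p_before - p_after)), 1e-12 * max(1, max(abs(p_before))))
  }
  # rotation alone conserves total kinetic energy
  expect_equal(sum(mass * v2^2), sum(mass * st$vel^2), tolerance = 1e-12)
  # a single-particle cell is left untouched
  st1 <- make_state(1, g)
  ca1 <- cell_assign(st1$pos, c(0, 0, 0), g)
  expect_equal(srd_collide(st1$vel, 1, ca1, thermostat = FALSE),
               st1$vel)
})

test_that("collision statistics are Galilean invariant under a boost", {
  g <- tiny_geometry()
  st <- make_state(600, g, seed = 9)
  boost <- c(1.3, -0.7, 0.2)
  set.seed(77)
  sh <- grid_shift()
  ca <- cell_assign(st$pos, sh, g)
  set.seed(123)
  v1 <- srd_collide(st$vel, 1, ca, thermostat = FALSE)
  set.seed(123)
  v2 <- srd_collide(sweep(st$vel, 2, -boost), 1, ca, thermostat = FALSE)
  # identical seeds: post-collision velocities differ by exactly the boost
  expect_equal(sweep(v2, 2, boost), v1, tolerance = 1e-12)
})

test_that("Maxwellian thermostat preserves cell momentum exactly", {
  g <- tiny_geometry()
  st <- make_state(800, g, seed = 10)
  st$vel <- st$vel * 1.4  # start hot
  set.seed(11)
  ca <- cell_assign(st$pos, grid_shift(), g)
  v2 <- mbs_thermostat(st$vel, 1, ca, kT = 1)
  for (k in 1:3) {
    p_before <- tapply(st$vel[, k], ca$cell, sum)
    p_after <- tapply(v2[, k], ca$cell, sum)
    expect_lt(max(abs(p_before - p_after)), 1e-12 * max(1, max(abs(p_before))))
  }
})

test_that("thermostatted relative energy satisfies cell-level equipartition", {
  # over many collisions the mean relative kinetic energy per cell must be
  # (3/2)(N_c - 1) kT
  g <- tiny_geometry()
  st <- make_state(round(5 * 6 * 6 * 8), g, seed = 12)
  set.seed(13)
  tot <- 0; dof <- 0
  for (rep in 1:150) {
    ca <- cell_assign(st$pos, grid_shift(), g)
    st$vel <- srd_collide(st$vel, 1, ca, thermostat = TRUE)
    cnt <- tabulate(ca$cell + 1L, nbins = ca$n_cells)
    for (k in 1:3) {
      vcm <- tapply(st$vel[, k], ca$cell, mean)
      vrel <- st$vel[, k] - vcm[as.character(ca$cell)]
      tot <- tot + sum(vrel^2) / 2
    }
    dof <- dof + sum(pmax(cnt - 1, 0)) * 1.5
  }
  expect_equal(tot / dof, 1, tolerance = 0.01)
})

test_that("SRR wall draws are flux-weighted Maxwellian into the fluid", {
  set.seed(14)
  d <- srr_reflect_draws(100000, kT = 1, mass = 1)
  expect_true(all(d[, 3] > 0))
  # tangential components: Maxwellian at kT
  expect_equal(mean(d[, 1]), 0, tolerance = 0.02)
  expect_equal(var(d[, 1]), 1, tolerance = 0.02)
  expect_equal(var(d[, 2]), 1, tolerance = 0.02)
  # flux-weighted normal: Rayleigh with <v> = sqrt(pi/2), <v^2> = 2
  expect_equal(mean(d[, 3]), sqrt(pi / 2), tolerance = 0.02)
  expect_equal(mean(d[, 3]^2), 2, tolerance = 0.03)
  # heavier particles are proportionally slower
  d5 <- srr_reflect_draws(50000, kT = 1, mass = 5)
  expect_equal(mean(d5[, 3]^2), 2 / 5, tolerance = 0.03)
})

test_that("wall-crossing segments are restored to the wall and re-emitted", {
  g <- tiny_geometry()
  st <- make_state(400, g, seed = 15)
  st$pos[, 3] <- 3.95          # all just below the upper wall at z = 4
  st$vel[, 3] <- 2             # heading out
  set.seed(16)
  out <- stream(st, 0.1)
  expect_equal(attr(out, "n_reflections"), 400L)
  expect_true(all(out$pos[, 3] <= 4))
  # with vz = 2 the impact happens at t* = 0.025; all remaining flight is
  # directed back into the fluid
  expect_true(all(out$vel[, 3] < 0))
  # wall momentum tally equals the total velocity change of the particles
  dp <- colSums(out$vel - st$vel)
  expect_equal(as.numeric(attr(out, "wall_dp")), dp, tolerance = 1e-10)
  # a segment not crossing any wall is unaffected
  st2 <- make_state(10, g, seed = 17)
  st2$vel[, 3] <- 0
  out2 <- stream(st2, 0.1)
  expect_equal(out2$pos[, 3], st2$pos[, 3])
})

test_that("global momentum ledger balances force input against the walls", {
  # injected body-force momentum = fluid momentum change + momentum absorbed
  # by the walls, to high precision over a driven run
  g <- slit_geometry(10, 8, 8)
  fl <- fluid_params()
  set.seed(18)
  st <- slitflow:::fluid_state(g, fl)
  fx <- rep(0.01, 9)
  out <- slitflow:::cpp_run_mpcd(st$pos, st$vel, NULL, NULL, g$Lx, g$Ly,
                                 g$Lz, fl$alpha, fl$dt_c, fl$kT, TRUE, fx,
                                 slitflow:::empty_pp(), slitflow:::empty_wp(),
                                 1, 1, fl$dt_c, 400L, 0L, 20L, 0L, fl$rho)
  dp_fluid <- sum(out$svel[, 1]) - sum(st$vel[, 1])
  balance <- out$injected_px + out$wall_dp[1] - dp_fluid
  expect_lt(abs(balance) / abs(out$injected_px), 1e-8)
})

test_that("equilibrium velocities are Maxwellian and the density is flat", {
  g <- slit_geometry(12, 10, 10)
  fl <- fluid_params()
  set.seed(19)
  st <- slitflow:::fluid_state(g, fl)
  out <- slitflow:::cpp_run_mpcd(st$pos, st$vel, NULL, NULL, g$Lx, g$Ly,
                                 g$Lz, fl$alpha, fl$dt_c, fl$kT, TRUE,
                                 numeric(0), slitflow:::empty_pp(),
                                 slitflow:::empty_wp(), 1, 1, fl$dt_c,
                                 1500L, 2L, 24L, 0L, fl$rho)
  # per-component variance k_BT/m_f, from the transverse accumulators
  kT_meas <- sum(out$bin_v2y + out$bin_v2z) / (2 * sum(out$bin_cnt))
  expect_equal(kT_meas, 1, tolerance = 0.01)
  # time-averaged density flat within 2% across the channel, walls included
  counts <- out$bin_cnt / mean(out$bin_cnt)
  expect_lt(max(abs(counts - 1)), 0.02)
  # x-velocity distribution is centered Gaussian: no spontaneous flow
  vx <- out$bin_vx / out$bin_cnt
  expect_lt(max(abs(vx)), 0.02)
})

test_that("fluid temperature stays on target under strong driving", {
  # strongest-flow conditions in a short channel; compare against a
  # thermostat-off control which heats up monotonically
  g <- slit_geometry(10, 8, 8)
  fl <- fluid_params()
  set.seed(20)
  st <- slitflow:::fluid_state(g, fl)
  fx <- rep(0.13, 9)  # v_max ~ 1.0 in this narrow channel
  run1 <- slitflow:::cpp_run_mpcd(st$pos, st$vel, NULL, NULL, g$Lx, g$Ly,
                                  g$Lz, fl$alpha, fl$dt_c, fl$kT, TRUE, fx,
                                  slitflow:::empty_pp(),
                                  slitflow:::empty_wp(), 1, 1, fl$dt_c,
                                  2000L, 2L, 20L, 0L, fl$rho)
  kT1 <- sum(run1$bin_v2y + run1$bin_v2z) / (2 * sum(run1$bin_cnt))
  expect_equal(kT1, 1, tolerance = 0.02)
  set.seed(20)
  run0 <- slitflow:::cpp_run_mpcd(st$pos, st$vel, NULL, NULL, g$Lx, g$Ly,
                                  g$Lz, fl$alpha, fl$dt_c, fl$kT, FALSE, fx,
                                  slitflow:::empty_pp(),
                                  slitflow:::empty_wp(), 1, 1, fl$dt_c,
                                  2000L, 2L, 20L, 0L, fl$rho)
  kT0 <- sum(run0$bin_v2y + run0$bin_v2z) / (2 * sum(run0$bin_cnt))
  expect_gt(kT0, kT1 + 0.05)  # the control heats up
})

test_that("measured viscosity matches kinetic theory within 5%", {
  v <- measure_viscosity(warmup = 1500, production = 2500, seeds = 1:2)
  expect_equal(v$nu, srd_viscosity_theory(), tolerance = 0.05)
})
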