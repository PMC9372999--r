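# Run orchestration, reproducibility and file formats

small_config <- function(seeds = 1, production = 200, warmup = 50,
                         polymer = polymer_spec(N = 10)) {
  run_config(slit_geometry(8, 6, 6), polymer = polymer,
             schedule = list(warmup = warmup, production = production,
                             sample_stride = 2, traj_stride = 10),
             seeds = seeds)
}

test_that("initial states hit the configured density with zero momentum", {
  cfg <- small_config()
  set.seed(71)
  init <- build_initial_state(cfg)
  expect_equal(nrow(init$fluid$pos), round(5 * 6 * 6 * 8))
  ptot <- colSums(init$fluid$vel) + 5 * colSums(init$chain$vel)
  expect_lt(max(abs(ptot)), 1e-10)
  expect_true(all(abs(init$fluid$pos[, 3]) <= 4))
})

test_that("identical seed and config give bit-identical trajectories", {
  cfg <- small_config()
  r1 <- run_simulation(cfg)
  r2 <- run_simulation(cfg)
  expect_identical(r1$per_seed[[1]]$frames_pos, r2$per_seed[[1]]$frames_pos)
  expect_identical(r1$fluid_profile$vx, r2$fluid_profile$vx)
  expect_identical(r1$manifest$config_hash, r2$manifest$config_hash)
})

test_that("checkpoint restart reproduces an uninterrupted run bit-exactly", {
  cfg <- small_config()
  sys <- mpcd_system(cfg, seed = 7)
  full <- advance(sys, 120, sample_stride = 0, traj_stride = 0)
  # split run: 60 steps, checkpoint to disk, restore, 60 more
  sys2 <- mpcd_system(cfg, seed = 7)
  half <- advance(sys2, 60)
  ckpt <- tempfile(fileext = ".rds")
  save_checkpoint(half$sys, ckpt)
  set.seed(999)  # scramble the session RNG to prove the restore matters
  restored <- load_checkpoint(ckpt)
  second <- advance(restored, 60)
  expect_identical(second$sys$spos, full$sys$spos)
  expect_identical(second$sys$svel, full$sys$svel)
  expect_identical(second$sys$mpos, full$sys$mpos)
  expect_identical(second$sys$step, full$sys$step)
  unlink(ckpt)
})

test_that("zero production steps still yield a valid manifest", {
  cfg <- small_config(production = 0, warmup = 10)
  run <- run_simulation(cfg)
  expect_null(run$per_seed[[1]]$frames_pos)
  expect_equal(run$per_seed[[1]]$n_samples, 0)
  expect_type(run$manifest$config_hash, "character")
  expect_equal(run$manifest$seeds_completed, 1L)
})

test_that("run configuration YAML round-trips to an identical object", {
  cfg <- run_config(slit_geometry(17, 30, 22),
                    polymer = polymer_spec(eps_bend = 9.5),
                    wall = wall_interaction(w = 1, kappa = 0.23, Lz = 17),
                    flow = list(kind = "eo_no_salt", v_max = 0.822),
                    schedule = list(warmup = 100, production = 200,
                                    sample_stride = 2, traj_stride = 10),
                    seeds = 4:7, chain_com_z = 2.5)
  f <- tempfile(fileext = ".yaml")
  write_run_config(cfg, f)
  cfg2 <- read_run_config(f)
  expect_equal(cfg2, cfg)
  # and parse(serialize(parse(x))) is the identity on the text level
  txt1 <- write_run_config(cfg)
  txt2 <- write_run_config(cfg2)
  expect_identical(txt1, txt2)
  unlink(f)
})

test_that("extended XYZ trajectories round-trip", {
  set.seed(72)
  g <- slit_geometry(8, 6, 6)
  pos <- array(rnorm(10 * 3 * 4), c(10, 3, 4))
  vel <- array(rnorm(10 * 3 * 4), c(10, 3, 4))
  f <- tempfile(fileext = ".xyz")
  write_xyz(pos, vel, f, g, times = c(1, 2, 3, 4) * 0.5)
  back <- read_xyz(f)
  expect_equal(back$pos, pos, tolerance = 1e-9)
  expect_equal(back$vel, vel, tolerance = 1e-9)
  expect_equal(back$times, c(0.5, 1, 1.5, 2))
  lines <- readLines(f)
  expect_equal(lines[1], "10")
  expect_true(grepl("Lattice=", lines[2]))
  unlink(f)
})

test_that("a failing seed is reported while the others continue", {
  # a polymer with an absurd MD step destabilizes immediately
  cfg <- small_config(seeds = c(1, 2),
                      polymer = polymer_spec(N = 10, dt_md = 0.1))
  cfg$polymer$dt_md <- 0.2  # force n_sub = 1 with a huge step
  expect_error(run_simulation(cfg))  # all seeds fail -> error
})

test_that("run outputs land on disk in the documented formats", {
  cfg <- small_config()
  outdir <- tempfile()
  run <- run_simulation(cfg, outdir = outdir)
  expect_true(file.exists(file.path(outdir, "chain_seed1.xyz")))
  expect_true(file.exists(file.path(outdir, "fluid_profile.tsv")))
  expect_true(file.exists(file.path(outdir, "monomer_density.tsv")))
  smry <- jsonlite::read_json(file.path(outdir, "summary.json"))
  expect_true(!is.null(smry$config_hash))
  expect_equal(smry$flow_kind, "none")
  unlink(outdir, recursive = TRUE)
})

test_that("equilibrium no-flow run reproduces the Monte Carlo density", {
  # hard-wall confined flexible chain: the MPCD run's monomer distribution
  # must match solvent-free Monte Carlo of the same Hamiltonian (coarse
  # 4-bin comparison within combined errors)
  set.seed(73)
  g <- slit_geometry(12, 10, 10)
  mc <- chain_mc(polymer_spec(N = 20), n_sweeps = 100000,
                 warmup_sweeps = 8000, sample_stride = 5, geometry = g,
                 frame_stride = 2)
  cfg <- run_config(g, polymer = polymer_spec(N = 20),
                    schedule = list(warmup = 1500, production = 8000,
                                    sample_stride = 8, traj_stride = 0),
                    seeds = 1:3)
  run <- run_simulation(cfg)
  dens_md <- run_monomer_density(run)
  # compare the folded (|z|) shape: center-vs-wall occupation and the mean
  # monomer |z|; folding removes the slow left/right wandering of the chain
  # that desk-length trajectories cannot average out
  fold2 <- function(z, v) {
    inner <- mean(v[abs(z) < 3]); outer <- mean(v[abs(z) >= 3])
    c(inner, outer) / mean(v)
  }
  md2 <- fold2(dens_md$z, dens_md$value)
  zs <- unlist(lapply(mc$frames, function(m) m[, 3]))
  h <- hist(zs, breaks = seq(-6, 6, by = 0.5), plot = FALSE)
  mc2 <- fold2(h$mids, h$density)
  expect_lt(max(abs(md2 - mc2)), 0.25)
  md_absz <- weighted.mean(abs(dens_md$z), dens_md$value)
  expect_equal(md_absz, mean(abs(zs)), tolerance = 0.10)
})
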