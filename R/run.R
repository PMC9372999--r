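# Run orchestration: initial states, the warmup/production loop over
# independent seeds, observable collection and standard outputs.

#' Build the initial state for a run
#'
#' Solvent placed uniformly at the configured density with Maxwellian
#' velocities, the chain grown as a self-avoiding walk inside the channel,
#' and the total momentum of solvent plus chain removed exactly.
#'
#' @param config a [run_config()].
#' @return list with `fluid` (a `fluid_state`) and `chain` (a
#'   `polymer_chain`, or NULL).
#' @export
build_initial_state <- function(config) {
  st <- fluid_state(config$geometry, config$fluid)
  chain <- NULL
  if (!is.null(config$polymer)) {
    chain <- grow_chain(config$polymer, config$geometry,
                        com_z = config$chain_com_z)
    M <- config$polymer$mass
    sd <- sqrt(config$fluid$kT / M)
    chain$vel <- matrix(rnorm(3 * config$polymer$N, sd = sd),
                        config$polymer$N, 3)
    # remove the net momentum of the composite system
    ptot <- colSums(st$vel) * st$mass + colSums(chain$vel) * M
    mtot <- nrow(st$pos) * st$mass + config$polymer$N * M
    st$vel <- sweep(st$vel, 2, ptot / mtot)
    chain$vel <- sweep(chain$vel, 2, ptot / mtot)
  } else {
    st$vel <- sweep(st$vel, 2, colMeans(st$vel))
  }
  list(fluid = st, chain = chain)
}

# Resolve the flow driver to (amplitude, per-particle force profile, v_max).
resolve_flow <- function(config) {
  flow <- config$flow
  g <- config$geometry
  eta <- config$fluid$eta
  if (flow$kind == "none")
    return(list(kind = "none", amplitude = 0, v_max = 0,
                force = streaming_force_profile("none", 0, g),
                profile = NULL))
  charge <- NULL
  if (flow$kind == "eo_no_salt")
    charge <- solve_pb_no_salt(g)
  if (flow$kind == "eo_salt")
    charge <- solve_pb_with_salt(g, kappa = KAPPA_SALT)
  amp <- flow$amplitude
  if (is.null(amp))
    amp <- match_amplitude(flow$kind, flow$v_max, g, eta, charge)
  prof <- if (flow$kind == "poiseuille")
    poiseuille_profile(f = amp, geometry = g, eta = eta) else
    eo_profile(charge, amp, eta)
  list(kind = flow$kind, amplitude = amp, v_max = prof$v_max,
       force = streaming_force_profile(flow$kind, amp, g,
                                       rho = config$fluid$rho, charge = charge),
       profile = prof, charge = charge)
}

#' Low-level simulation system
#'
#' Builds a ready-to-advance system (initial state plus resolved driver) for
#' one seed. [advance()] then runs MPCD steps and accumulates observables;
#' [run_simulation()] is the high-level multi-seed driver.
#'
#' @param config a [run_config()].
#' @param seed RNG seed for this trajectory.
#' @return an object of class `mpcd_system`.
#' @export
mpcd_system <- function(config, seed) {
  set.seed(seed)
  init <- build_initial_state(config)
  flow <- resolve_flow(config)
  structure(list(config = config, seed = seed, step = 0L,
                 spos = init$fluid$pos, svel = init$fluid$vel,
                 mpos = if (is.null(init$chain)) NULL else init$chain$pos,
                 mvel = if (is.null(init$chain)) NULL else init$chain$vel,
                 flow = flow),
            class = "mpcd_system")
}

#' @export
print.mpcd_system <- function(x, ...) {
  cat(sprintf("mpcd_system: seed %d, step %d, %d solvent particles%s\n",
              x$seed, x$step, nrow(x$spos),
              if (is.null(x$mpos)) "" else
                sprintf(", chain N = %d", nrow(x$mpos))))
  invisible(x)
}

#' Advance a simulation system
#'
#' Runs `nsteps` MPCD steps (stream + n_sub MD substeps + shifted-grid
#' collision with the thermostat), optionally accumulating observables.
#'
#' @param sys an [mpcd_system()].
#' @param nsteps MPCD steps to run.
#' @param sample_stride steps between observable samples (0 = no sampling,
#'   e.g. during warmup).
#' @param traj_stride steps between stored chain frames (0 = none).
#' @return list with the updated `sys` and `out` (raw engine accumulators).
#' @export
advance <- function(sys, nsteps, sample_stride = 0, traj_stride = 0) {
  cfg <- sys$config
  g <- cfg$geometry
  pol <- cfg$polymer
  pp <- if (is.null(pol)) empty_pp() else unclass(pol)
  wp <- if (!is.null(cfg$wall)) engine_wp(cfg$wall) else empty_wp(g$Lz)
  wp$Lz <- g$Lz
  n_sub <- if (is.null(pol)) 1L else max(1L, round(cfg$fluid$dt_c / pol$dt_md))
  dt_md <- if (is.null(pol)) cfg$fluid$dt_c else cfg$fluid$dt_c / n_sub
  nbins <- round(2 * g$Lz)
  out <- cpp_run_mpcd(sys$spos, sys$svel, sys$mpos, sys$mvel,
                      g$Lx, g$Ly, g$Lz, cfg$fluid$alpha, cfg$fluid$dt_c,
                      cfg$fluid$kT, TRUE, sys$flow$force$fx, pp, wp,
                      if (is.null(pol)) 1 else pol$mass, n_sub, dt_md,
                      as.integer(nsteps), as.integer(sample_stride),
                      as.integer(nbins), as.integer(traj_stride),
                      cfg$fluid$rho)
  sys$spos <- out$spos
  sys$svel <- out$svel
  if (!is.null(sys$mpos)) { sys$mpos <- out$mpos; sys$mvel <- out$mvel }
  sys$step <- sys$step + as.integer(nsteps)
  list(sys = sys, out = out)
}

# Convert raw engine accumulators into tidy per-seed observables.
collect_outputs <- function(out, config) {
  g <- config$geometry
  nbins <- length(out$bin_cnt)
  edges <- seq(-g$Lz / 2, g$Lz / 2, length.out = nbins + 1)
  zc <- (edges[-1] + edges[-length(edges)]) / 2
  fluid_profile <- data.frame(
    z = zc,
    vx = ifelse(out$bin_cnt > 0, out$bin_vx / pmax(out$bin_cnt, 1), NA),
    kT_transverse = ifelse(out$bin_cnt > 0,
                           (out$bin_v2y + out$bin_v2z) /
                             (2 * pmax(out$bin_cnt, 1)), NA),
    count = out$bin_cnt)
  nf <- out$n_frames
  frames_pos <- frames_vel <- NULL
  if (!is.null(out$frames_pos) && nf > 0) {
    N <- nrow(out$mpos)
    frames_pos <- array(out$frames_pos[seq_len(N * 3 * nf)], c(N, 3, nf))
    frames_vel <- array(out$frames_vel[seq_len(N * 3 * nf)], c(N, 3, nf))
  }
  list(fluid_profile = fluid_profile,
       mono_hist = out$mono_hist,
       v_mono = if (out$mono_vx_n > 0) out$mono_vx_sum / out$mono_vx_n else NA,
       com_z = out$com_z, rg = out$rg, b = out$b,
       frames_pos = frames_pos, frames_vel = frames_vel,
       wall_dp = out$wall_dp, injected_px = out$injected_px,
       n_samples = out$n_samples)
}

#' Run a full simulation over independent seeds
#'
#' For each seed: build the initial state, equilibrate for the warmup steps,
#' then accumulate observables over the production steps. Profiles and
#' transport statistics are averaged over seeds with independent-trajectory
#' standard errors; a manifest records the configuration hash, seeds and
#' package version. A seed whose trajectory becomes unstable (bond
#' overstretch) is reported in the manifest and skipped; the other seeds
#' continue.
#'
#' @param config a [run_config()].
#' @param outdir optional output directory: monomer trajectories (extended
#'   XYZ), profile TSVs, a JSON summary and the manifest are written there.
#' @return an object of class `mpcd_run`.
#' @export
run_simulation <- function(config, outdir = NULL) {
  sch <- config$schedule
  seeds <- config$seeds
  per_seed <- vector("list", length(seeds))
  failures <- list()
  one_seed <- function(cfg, seed) {
    sys <- mpcd_system(cfg, seed)
    if (sch$warmup > 0) sys <- advance(sys, sch$warmup)$sys
    adv <- advance(sys, sch$production, sch$sample_stride, sch$traj_stride)
    collect_outputs(adv$out, cfg)
  }
  for (i in seq_along(seeds)) {
    res <- tryCatch(one_seed(config, seeds[i]), error = function(e) e)
    if (inherits(res, "error") && !is.null(config$polymer) &&
        grepl("overstretch|overlap", conditionMessage(res))) {
      # instability at the configured MD substep: halve it once and retry
      cfg2 <- config
      cfg2$polymer$dt_md <- config$polymer$dt_md / 2
      res <- tryCatch(one_seed(cfg2, seeds[i]), error = function(e) e)
    }
    if (inherits(res, "error")) {
      failures[[as.character(seeds[i])]] <- conditionMessage(res)
    } else {
      per_seed[[i]] <- res
    }
  }
  ok <- !vapply(per_seed, is.null, TRUE)
  if (!any(ok)) stop("all seeds failed: ", paste(unlist(failures),
                                                 collapse = "; "))
  kept <- per_seed[ok]
  # combine fluid profiles and transport stats across seeds
  prof <- kept[[1]]$fluid_profile
  if (length(kept) > 1) {
    vxm <- sapply(kept, function(r) r$fluid_profile$vx)
    prof$vx <- rowMeans(vxm, na.rm = TRUE)
    prof$vx_se <- apply(vxm, 1, stats::sd) / sqrt(ncol(vxm))
  }
  v_mono <- vapply(kept, function(r) r$v_mono, 0)
  manifest <- list(
    config_hash = config_hash(write_run_config(config)),
    seeds = seeds, seeds_completed = seeds[ok],
    failures = failures,
    package_version = as.character(utils::packageVersion("slitflow")),
    r_version = R.version.string,
    steps = sch)
  run <- structure(list(
    config = config, per_seed = kept, fluid_profile = prof,
    v_mono = if (all(is.na(v_mono))) NULL else mean(v_mono, na.rm = TRUE),
    v_mono_seeds = v_mono,
    flow = resolve_flow(config), manifest = manifest), class = "mpcd_run")
  if (!is.null(outdir)) write_run_outputs(run, outdir)
  run
}

#' @export
print.mpcd_run <- function(x, ...) {
  cat(sprintf("mpcd_run: %s flow, Lz = %g, %d/%d seeds completed\n",
              x$config$flow$kind, x$config$geometry$Lz,
              length(x$manifest$seeds_completed), length(x$manifest$seeds)))
  if (!is.null(x$v_mono))
    cat(sprintf("  <v_mono> = %.4g, driver v_max = %.4g\n", x$v_mono,
                x$flow$v_max))
  invisible(x)
}

#' @export
summary.mpcd_run <- function(object, ...) {
  vs <- velocity_stats(object)
  g <- object$config$geometry
  rg_all <- unlist(lapply(object$per_seed, function(r) r$rg))
  b_all <- unlist(lapply(object$per_seed, function(r) r$b))
  out <- list(flow_kind = object$config$flow$kind,
              v_max = vs$v_max, v_fluid_mean = vs$v_fluid_mean,
              v_mono = vs$v_mono, mono_ratio = vs$mono_ratio,
              fluid_ratio = vs$fluid_ratio,
              Rg_mean = if (length(rg_all)) mean(rg_all) else NA,
              b_mean = if (length(b_all)) mean(b_all) else NA,
              mean_abs_com_z = mean(abs(unlist(lapply(object$per_seed,
                                                      function(r) r$com_z)))),
              Lz = g$Lz)
  class(out) <- "summary.mpcd_run"
  out
}

#' @export
print.summary.mpcd_run <- function(x, ...) {
  cat(sprintf("%s flow in Lz = %g channel\n", x$flow_kind, x$Lz))
  cat(sprintf("  v_max = %.4g, <v_fluid>/v_max = %.3f\n", x$v_max,
              x$fluid_ratio))
  if (is.finite(x$mono_ratio))
    cat(sprintf("  <v_mono>/v_max = %.3f\n", x$mono_ratio))
  if (is.finite(x$Rg_mean))
    cat(sprintf("  <Rg> = %.3f, <b> = %.3f, <|z_cm|> = %.3f\n",
                x$Rg_mean, x$b_mean, x$mean_abs_com_z))
  invisible(x)
}

#' Monomer density profile of a run
#'
#' Independent-trajectory average of the per-seed monomer histograms,
#' normalized as a probability density across the channel.
#'
#' @param run an `mpcd_run`.
#' @return a `profile_table`.
#' @export
run_monomer_density <- function(run) {
  g <- run$config$geometry
  hists <- lapply(run$per_seed, function(r) r$mono_hist)
  nb <- length(hists[[1]])
  edges <- seq(-g$Lz / 2, g$Lz / 2, length.out = nb + 1)
  zc <- (edges[-1] + edges[-length(edges)]) / 2
  width <- diff(edges)[1]
  dens <- sapply(hists, function(h) h / sum(h) / width)
  dens <- matrix(dens, nrow = nb)
  m <- rowMeans(dens)
  se <- if (ncol(dens) > 1) apply(dens, 1, stats::sd) / sqrt(ncol(dens)) else
    rep(NA_real_, nb)
  profile_table(zc, m, se, Reduce(`+`, hists), width,
                "probability density, integral 1 over the channel")
}

write_run_outputs <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  g <- run$config$geometry
  for (i in seq_along(run$per_seed)) {
    r <- run$per_seed[[i]]
    if (!is.null(r$frames_pos))
      write_xyz(r$frames_pos, r$frames_vel,
                file.path(outdir, sprintf("chain_seed%d.xyz", i)), g)
  }
  utils::write.table(run$fluid_profile,
                     file.path(outdir, "fluid_profile.tsv"),
                     sep = "\t", row.names = FALSE)
  if (!is.null(run$config$polymer))
    write_profile_table(run_monomer_density(run),
                        file.path(outdir, "monomer_density.tsv"),
                        "monomer density")
  s <- summary(run)
  write_summary_json(c(unclass(s), run$manifest),
                     file.path(outdir, "summary.json"))
  invisible(outdir)
}
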