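# Chain construction and solvent-free equilibrium sampling.

#' Grow a self-avoiding chain inside the channel
#'
#' Inserts a bead-spring chain as a self-avoiding random walk with bond
#' lengths near the FENE+WCA minimum (0.96 sigma): each new bead is placed at
#' a uniformly random direction from the last, rejected if it overlaps any
#' previous bead (center distance < sigma) or leaves the channel. The whole
#' attempt restarts after too many dead ends.
#'
#' @param spec a [polymer_spec()].
#' @param geometry a [slit_geometry()], or NULL for an unconfined (bulk)
#'   chain.
#' @param com_z target center-of-mass height for the inserted chain (a0). The
#'   default 0 starts the chain mid-channel.
#' @param bond insertion bond length (sigma units of spec).
#' @param max_restarts insertion attempts before giving up.
#' @return an object of class `polymer_chain`: `pos`, `vel` (zeros), `spec`.
#' @export
grow_chain <- function(spec = polymer_spec(), geometry = NULL, com_z = 0,
                       bond = 0.96, max_restarts = 200) {
  N <- spec$N
  b <- bond * spec$sigma
  half <- if (is.null(geometry)) Inf else geometry$Lz / 2
  margin <- 0.5 * spec$sigma
  for (attempt in seq_len(max_restarts)) {
    pos <- matrix(NA_real_, N, 3)
    pos[1, ] <- c(0, 0, min(max(com_z, -half + margin), half - margin))
    ok <- TRUE
    for (i in 2:N) {
      placed <- FALSE
      for (try in 1:50) {
        u <- rnorm(3)
        u <- u / sqrt(sum(u^2))
        cand <- pos[i - 1, ] + b * u
        if (abs(cand[3]) >= half - 1e-3) next
        if (i > 2) {
          d2 <- rowSums(sweep(pos[1:(i - 2), , drop = FALSE], 2, cand)^2)
          if (any(d2 < spec$sigma^2)) next
        }
        pos[i, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) {
      # recenter the chain's center of mass at the requested height when the
      # walk drifted, provided all beads stay inside
      dz <- com_z - mean(pos[, 3])
      if (all(abs(pos[, 3] + dz) < half - 1e-3)) pos[, 3] <- pos[, 3] + dz
      return(structure(list(pos = pos, vel = matrix(0, N, 3), spec = spec),
                       class = "polymer_chain"))
    }
  }
  stop("chain insertion failed after ", max_restarts, " restarts")
}

#' @export
print.polymer_chain <- function(x, ...) {
  g <- gyration(x$pos)
  cat(sprintf("bead-spring chain: N = %d, Rg = %.3f, eps_bend = %g\n",
              x$spec$N, g$Rg, x$spec$eps_bend))
  invisible(x)
}

#' Equilibrium Monte Carlo sampling of the chain
#'
#' Solvent-free Metropolis sampling of the full chain Hamiltonian (WCA +
#' FENE + bending, optionally confined between the channel walls with the
#' screened vdW attraction). Moves are single-bead displacements plus pivot
#' rotations of the chain tail, which decorrelate global quantities quickly.
#' Used for equilibrium reference statistics: the collisional-coupling MPCD
#' dynamics must reproduce exactly this ensemble.
#'
#' @param spec a [polymer_spec()].
#' @param n_sweeps production sweeps (one sweep = N displacement attempts + 2
#'   pivots).
#' @param warmup_sweeps discarded equilibration sweeps.
#' @param sample_stride sweeps between samples.
#' @param geometry optional [slit_geometry()] for confined sampling.
#' @param wall optional [wall_interaction()] (requires `geometry`).
#' @param max_disp displacement half-width (a0).
#' @param max_pivot pivot half-angle (radians).
#' @param frame_stride keep every `frame_stride`-th sampled conformation
#'   (0 = none).
#' @param kT temperature.
#' @return list with `rg` and `b` sample vectors, `Rg_mean`, `Rg_se`
#'   (autocorrelation-corrected), `b_mean`, `theta2_mean`, `Lp`
#'   (2 sigma/<theta^2>), `com_z` and `mono_absz` samples (chain center and
#'   mean monomer |z| per sample), `frames`, acceptance rates and `pos`.
#' @export
chain_mc <- function(spec = polymer_spec(), n_sweeps = 50000,
                     warmup_sweeps = 5000, sample_stride = 5,
                     geometry = NULL, wall = NULL, max_disp = 0.12,
                     max_pivot = if (spec$eps_bend > 0) 0.6 else pi,
                     frame_stride = 0, kT = 1) {
  chain <- grow_chain(spec, geometry)
  walls <- !is.null(geometry)
  wp <- if (walls && !is.null(wall)) engine_wp(wall) else
    empty_wp(if (walls) geometry$Lz else 1)
  if (walls) wp$Lz <- geometry$Lz
  out <- cpp_chain_mc(chain$pos, n_sweeps, warmup_sweeps, sample_stride,
                      unclass(spec), wp, walls, max_disp, max_pivot,
                      frame_stride, kT)
  rg <- out$rg
  ac <- acf_decorrelation(rg)
  out$Rg_mean <- mean(rg)
  out$Rg_se <- stats::sd(rg) / sqrt(length(rg) / ac)
  out$b_mean <- mean(out$b)
  out$Lp <- 2 * spec$sigma / out$theta2_mean
  out$spec <- spec
  out
}

# crude integrated autocorrelation (in units of samples), for honest errors
acf_decorrelation <- function(x, max_lag = min(200, length(x) %/% 3)) {
  if (length(x) < 10) return(1)
  a <- stats::acf(x, lag.max = max_lag, plot = FALSE)$acf[-1]
  pos <- which(a < 0.05)
  cut <- if (length(pos)) pos[1] else max_lag
  max(1, 1 + 2 * sum(a[seq_len(cut)]))
}

#' MD substep integration of the chain
#'
#' Velocity-Verlet integration of the full intrachain + wall force field for
#' `n_sub` substeps of length `dt_md`, with monomers crossing a wall plane
#' handled by the stochastic reflection rule (the same contract as the
#' solvent). With `geometry = NULL` the chain is integrated unconfined
#' (microcanonical when started with finite velocities).
#'
#' @param chain a `polymer_chain` (fields `pos`, `vel`, `spec`).
#' @param n_sub number of substeps.
#' @param dt_md substep length (t0).
#' @param geometry optional [slit_geometry()].
#' @param wall optional [wall_interaction()].
#' @param kT wall temperature for SRR re-emission.
#' @return the updated chain, with attributes `potential`, `kinetic`,
#'   `wall_dp`.
#' @export
md_substep_loop <- function(chain, n_sub, dt_md = chain$spec$dt_md,
                            geometry = NULL, wall = NULL, kT = 1) {
  walls <- !is.null(geometry)
  wp <- if (walls && !is.null(wall)) engine_wp(wall) else
    empty_wp(if (walls) geometry$Lz else 1)
  if (walls) wp$Lz <- geometry$Lz
  out <- cpp_md_substeps(chain$pos, chain$vel, n_sub, dt_md,
                         chain$spec$mass, unclass(chain$spec), wp, walls, kT)
  chain$pos <- out$pos
  chain$vel <- out$vel
  attr(chain, "potential") <- out$potential
  attr(chain, "kinetic") <- out$kinetic
  attr(chain, "wall_dp") <- out$wall_dp
  chain
}

#' Intrachain energy and forces
#'
#' Total potential energy and per-monomer forces of the chain Hamiltonian
#' (WCA + FENE + bending + optional wall attraction). Raises a
#' bond-overstretch error when any bond reaches R0.
#'
#' @inheritParams md_substep_loop
#' @param pos N x 3 monomer positions.
#' @param spec a [polymer_spec()].
#' @return list with `energy` and N x 3 `forces`.
#' @export
chain_energy <- function(pos, spec = polymer_spec(), geometry = NULL,
                         wall = NULL) {
  walls <- !is.null(geometry) && !is.null(wall)
  wp <- if (walls) engine_wp(wall) else empty_wp()
  if (walls) wp$Lz <- geometry$Lz
  cpp_chain_energy_forces(pos, unclass(spec), wp)
}
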