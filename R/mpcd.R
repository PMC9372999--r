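# R-level surface of the MPCD solvent engine: thin wrappers over the Rcpp
# core exposing the individual algorithm steps (streaming, grid shift, cell
# assignment, SRD collision, thermostat, SRR wall draws) plus the transport
# measurement used to verify the fluid viscosity.

#' Create an MPCD fluid state
#'
#' Solvent particles placed uniformly in the box at the requested density with
#' Maxwellian velocities at temperature kT and the net momentum removed.
#'
#' @param geometry a [slit_geometry()].
#' @param fluid a [fluid_params()].
#' @param m_f fluid particle mass.
#' @return an object of class `fluid_state` with `pos`, `vel` (n x 3), `mass`,
#'   `geometry`.
#' @export
fluid_state <- function(geometry, fluid = fluid_params(), m_f = 1) {
  n <- round(fluid$rho * geometry$Lx * geometry$Ly * geometry$Lz)
  pos <- cbind(runif(n, 0, geometry$Lx),
               runif(n, 0, geometry$Ly),
               runif(n, -geometry$Lz / 2, geometry$Lz / 2))
  sd <- sqrt(fluid$kT / m_f)
  vel <- matrix(rnorm(3 * n, sd = sd), n, 3)
  vel <- sweep(vel, 2, colMeans(vel))  # zero net momentum
  structure(list(pos = pos, vel = vel, mass = m_f, geometry = geometry),
            class = "fluid_state")
}

#' @export
print.fluid_state <- function(x, ...) {
  cat(sprintf("MPCD fluid state: %d particles in %g x %g x %g\n",
              nrow(x$pos), x$geometry$Lx, x$geometry$Ly, x$geometry$Lz))
  invisible(x)
}

#' Streaming step with body force and SRR walls
#'
#' Propagates all fluid particles for a time `dt` by velocity-Verlet free
#' flight under the (z-dependent, x-directed) body force: half kick, ballistic
#' drift, half kick. Trajectory segments crossing a wall plane are restored to
#' the impact point and re-emitted with a stochastic-reflection velocity;
#' x and y are wrapped periodically.
#'
#' @param state a [fluid_state()].
#' @param dt streaming time (t0).
#' @param force per-particle force profile from [streaming_force_profile()],
#'   or NULL for force-free streaming.
#' @param kT wall temperature for the SRR draws.
#' @return the updated `fluid_state`, with attributes `wall_dp` (momentum
#'   absorbed by the walls), `injected_px` and `n_reflections`.
#' @export
stream <- function(state, dt, force = NULL, kT = 1) {
  stopifnot(dt > 0)
  g <- state$geometry
  fx <- if (is.null(force)) numeric(0) else force$fx
  out <- cpp_stream(state$pos, state$vel, state$mass, dt, fx,
                    g$Lx, g$Ly, g$Lz, kT)
  st <- state
  st$pos <- out$pos
  st$vel <- out$vel
  attr(st, "wall_dp") <- out$wall_dp
  attr(st, "injected_px") <- out$injected_px
  attr(st, "n_reflections") <- out$n_reflections
  st
}

#' Random collision-grid shift
#'
#' Each component uniform on `[-a0/2, a0/2)`; applied to the cell binning
#' only, never to particle coordinates (Galilean invariance).
#' @return numeric length-3 offset.
#' @export
grid_shift <- function() cpp_grid_shift()

#' Assign particles to collision cells
#'
#' Cubic cells of unit edge on the shifted grid; periodic wrapping in x and y,
#' truncated cells at the walls (one extra slot per side holds the partial
#' cells created by the shift).
#'
#' @param pos n x 3 positions.
#' @param shift length-3 grid shift.
#' @param geometry a [slit_geometry()].
#' @return list with 0-based `cell` ids and the total `n_cells`.
#' @export
cell_assign <- function(pos, shift, geometry) {
  nx <- round(geometry$Lx); ny <- round(geometry$Ly); nz <- round(geometry$Lz)
  list(cell = cpp_cell_assign(pos, shift, nx, ny, nz, geometry$Lz),
       n_cells = (nz + 2) * nx * ny)
}

#' SRD collision step
#'
#' Per cell, velocities relative to the mass-weighted center-of-mass velocity
#' are rotated by the angle alpha around a random axis (one axis per cell),
#' conserving momentum and kinetic energy cell-wise; the cell-level Maxwellian
#' thermostat then rescales the relative velocities to a Gamma-distributed
#' kinetic energy at kT, preserving the center-of-mass velocity exactly.
#'
#' @param vel n x 3 velocities (solvent and any solute members together).
#' @param mass per-particle masses (length n or scalar).
#' @param cells result of [cell_assign()].
#' @param fluid a [fluid_params()] (rotation angle, kT).
#' @param thermostat apply the Maxwellian thermostat (default TRUE).
#' @param rotate apply the SRD rotation (set FALSE to exercise the thermostat
#'   alone).
#' @return the post-collision velocity matrix.
#' @export
srd_collide <- function(vel, mass, cells, fluid = fluid_params(),
                        thermostat = TRUE, rotate = TRUE) {
  if (length(mass) == 1) mass <- rep(mass, nrow(vel))
  cpp_collide(vel, mass, cells$cell, cells$n_cells, fluid$alpha, fluid$kT,
              thermostat, rotate)
}

#' Cell-level Maxwellian thermostat
#'
#' The thermostat applied on its own (no rotation): relative velocities in
#' each cell are rescaled so the relative kinetic energy follows the
#' Gamma(3(N_c - 1)/2, kT) distribution of a Maxwell-Boltzmann ensemble,
#' with the cell center-of-mass velocity preserved to machine precision.
#'
#' @inheritParams srd_collide
#' @param kT target temperature.
#' @return rescaled velocity matrix.
#' @export
mbs_thermostat <- function(vel, mass, cells, kT = 1) {
  if (length(mass) == 1) mass <- rep(mass, nrow(vel))
  cpp_collide(vel, mass, cells$cell, cells$n_cells, 0, kT,
              thermostat = TRUE, rotate_flag = FALSE)
}

#' Stochastic-reflection wall velocity draws
#'
#' Velocities handed to particles re-emitted from a wall: tangential
#' components Maxwellian at kT, wall-normal component flux-weighted (Rayleigh)
#' and directed into the fluid. Draws are for the lower wall (outgoing +z).
#'
#' @param n number of draws.
#' @param kT temperature.
#' @param mass particle mass.
#' @return n x 3 matrix of velocities with positive third component.
#' @export
srr_reflect_draws <- function(n, kT = 1, mass = 1) cpp_srr_draw(n, kT, mass)

#' Measure the MPCD fluid viscosity from a forced channel flow
#'
#' Drives a small slit channel with a weak constant body force, runs to the
#' stationary state, fits the time-averaged velocity profile to a no-slip
#' parabola and inverts \eqn{v(z) = \frac{f}{2\eta}\left[(L_z/2)^2 -
#' z^2\right]} for the dynamic viscosity; the kinematic viscosity is
#' \eqn{\nu = \eta / \rho}. Results from several seeds are averaged.
#'
#' @param fluid a [fluid_params()].
#' @param geometry a [slit_geometry()]; small boxes suffice.
#' @param f body force density (m_f a0^-2 t0^-2); weak enough for laminar
#'   Stokes-like flow. The default drives v_max about half the thermal speed,
#'   which keeps the per-seed scatter of the fitted curvature below 1%
#'   (weaker drives are noise-limited) while Mach-number corrections stay
#'   negligible.
#' @param warmup,production MPCD steps before / during profile accumulation.
#' @param seeds integer vector of RNG seeds (one run each).
#' @return list with `nu` (mean over seeds), `nu_seeds`, `eta`, `slip_ratio`
#'   (fitted wall velocity over v_max), `v_max`, `profile` (last seed).
#' @export
measure_viscosity <- function(fluid = fluid_params(),
                              geometry = slit_geometry(20, Lx = 10, Ly = 10),
                              f = 0.04, warmup = 2500, production = 2500,
                              seeds = 1:4) {
  nus <- numeric(length(seeds))
  slips <- numeric(length(seeds))
  vmaxs <- numeric(length(seeds))
  prof <- NULL
  for (si in seq_along(seeds)) {
    set.seed(seeds[si])
    st <- fluid_state(geometry, fluid)
    force <- streaming_force_profile("poiseuille", f, geometry,
                                     rho = fluid$rho)
    nbins <- round(2 * geometry$Lz)
    wu <- cpp_run_mpcd(st$pos, st$vel, NULL, NULL, geometry$Lx, geometry$Ly,
                       geometry$Lz, fluid$alpha, fluid$dt_c, fluid$kT, TRUE,
                       force$fx, empty_pp(), empty_wp(), 1, 1, fluid$dt_c,
                       warmup, 0L, nbins, 0L, fluid$rho)
    out <- cpp_run_mpcd(wu$spos, wu$svel, NULL, NULL, geometry$Lx,
                        geometry$Ly, geometry$Lz, fluid$alpha, fluid$dt_c,
                        fluid$kT, TRUE, force$fx, empty_pp(), empty_wp(), 1,
                        1, fluid$dt_c, production, 2L, nbins, 0L, fluid$rho)
    zc <- seq(-geometry$Lz / 2, geometry$Lz / 2,
              length.out = nbins + 1)
    zc <- (zc[-1] + zc[-length(zc)]) / 2
    vx <- out$bin_vx / pmax(out$bin_cnt, 1)
    fit <- stats::lm(vx ~ I(zc^2))
    curv <- stats::coef(fit)[[2]]          # = -f / (2 eta)
    eta <- -f / (2 * curv)
    nus[si] <- eta / fluid$rho
    v0 <- stats::coef(fit)[[1]]
    vwall <- v0 + curv * (geometry$Lz / 2)^2
    slips[si] <- vwall / v0
    vmaxs[si] <- v0
    prof <- data.frame(z = zc, vx = vx)
  }
  list(nu = mean(nus), nu_seeds = nus, eta = mean(nus) * fluid$rho,
       slip_ratio = mean(slips), v_max = mean(vmaxs), profile = prof)
}

# Placeholder chain/wall parameter lists for solvent-only engine calls.
empty_pp <- function() list(sigma = 1, eps = 1, k = 30, R0 = 1.5,
                            eps_bend = 0)
empty_wp <- function(Lz = 1) list(on = FALSE, Lz = Lz, w = 0, kappa = 1,
                                  cutoff = 1, etab = c(0, 0))

# Wall parameter list for the engine, with the tabulated closed-form energy.
# The engine computes the force analytically from `w`, so the site-density
# scaling is folded into the effective strength passed down.
engine_wp <- function(wall_int, sigma = 1, n_tab = 4096) {
  if (is.null(wall_int) || wall_int$w == 0) return(empty_wp(
    if (is.null(wall_int)) 1 else wall_int$Lz))
  weff <- wall_int$w * wall_int$site_density
  d <- seq(0, wall_int$cutoff, length.out = n_tab)
  shift <- vdw_single_wall(wall_int$cutoff, weff, wall_int$kappa, sigma)
  dd <- pmax(d, sigma)
  u <- vdw_single_wall(pmax(dd, 1e-8), weff, wall_int$kappa, sigma) - shift
  u[dd >= wall_int$cutoff] <- 0
  list(on = TRUE, Lz = wall_int$Lz, w = weff, kappa = wall_int$kappa,
       cutoff = wall_int$cutoff, etab = u)
}
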