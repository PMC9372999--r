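# Analytic / numerical reference flow fields in the slit: Poiseuille from a
# constant body force, electroosmotic from Stokes balance against the
# Poisson-Boltzmann charge density, plus the equal-average-shear calibration
# used to compare flow types.

velocity_profile_object <- function(z, v, kind, amplitude) {
  h <- z[2] - z[1]
  # centered differences for the shear rate, one-sided at the walls
  n <- length(z)
  g <- numeric(n)
  g[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * h)
  g[1] <- (v[2] - v[1]) / h
  g[n] <- (v[n] - v[n - 1]) / h
  vmean <- sum((v[-1] + v[-n]) / 2 * h) / (z[n] - z[1])  # trapezoid average
  ag <- abs(g)
  gdot <- sum((ag[-1] + ag[-n]) / 2 * h) / (z[n] - z[1])
  structure(list(z = z, v = v, shear = g, v_max = max(v),
                 v_mean = vmean, kind = kind, amplitude = amplitude,
                 Gamma_dot = gdot),
            class = "velocity_profile")
}

#' @export
print.velocity_profile <- function(x, ...) {
  cat(sprintf("stationary %s velocity profile\n", x$kind))
  cat(sprintf("  Lz = %g a0, amplitude = %.5g\n", diff(range(x$z)), x$amplitude))
  cat(sprintf("  v_max = %.5g a0/t0, <v> = %.5g, <v>/v_max = %.4f\n",
              x$v_max, x$v_mean, x$v_mean / x$v_max))
  cat(sprintf("  average shear Gamma_dot = %.5g /t0\n", x$Gamma_dot))
  invisible(x)
}

#' Poiseuille profile from a constant body force
#'
#' Stationary solution of the Stokes balance eta v'' = -f with no-slip walls:
#' a parabola with \eqn{v_{max} = f L_z^2 / (8 \eta)} and mean velocity
#' 2/3 of the maximum. `f` is the body force *density* (m_f a0^-2 t0^-2,
#' i.e. per unit volume); the per-particle force applied inside the simulator
#' is f / rho.
#'
#' @param f body force density (>= 0). Exactly one of `f`, `v_max` is given.
#' @param v_max target maximum velocity from which `f` is derived.
#' @param geometry a [slit_geometry()].
#' @param eta dynamic viscosity (m_f a0^-1 t0^-1).
#' @param n_grid grid points across the channel.
#' @return a `velocity_profile`; the `amplitude` field is the force density.
#' @export
poiseuille_profile <- function(f = NULL, v_max = NULL, geometry, eta = 4.05,
                               n_grid = 513) {
  stopifnot(inherits(geometry, "slit_geometry"), eta > 0)
  if (is.null(f) == is.null(v_max))
    stop("give exactly one of f and v_max")
  L <- geometry$Lz
  if (is.null(f)) f <- 8 * eta * v_max / L^2
  stopifnot(f >= 0)
  z <- seq(-L / 2, L / 2, length.out = n_grid)
  v <- f / (2 * eta) * ((L / 2)^2 - z^2)
  velocity_profile_object(z, v, "poiseuille", f)
}

#' Electroosmotic profile from a charge distribution
#'
#' Solves the stationary 1D Stokes balance
#' \eqn{\eta v''(z) = -\rho_{el}(z)\, eE} with no-slip walls by double
#' cumulative trapezoidal integration on the charge-profile grid: the external
#' field acting on the mobile double-layer charge is exactly compensated by
#' viscous stresses in the stationary state.
#'
#' @param charge a `charge_profile` (see [solve_pb_no_salt()]).
#' @param eE field amplitude (m_f a0 t0^-2 per unit charge e), >= 0.
#' @param eta dynamic viscosity.
#' @return a `velocity_profile`; the `amplitude` field is `eE`.
#' @export
eo_profile <- function(charge, eE, eta = 4.05) {
  if (!inherits(charge, "charge_profile")) stop("charge must be a charge_profile")
  stopifnot(eE >= 0, eta > 0)
  z <- charge$z
  h <- z[2] - z[1]
  src <- -charge$rho_el * eE / eta            # v'' on the grid
  dv <- cumtrapz_uniform(src, h)              # v' up to a constant
  dv <- dv - dv[(length(z) + 1) / 2]          # symmetry: v'(0) = 0
  v <- cumtrapz_uniform(dv, h)                # v up to a constant
  v <- v - v[1]                               # no-slip at the lower wall
  # trapezoid asymmetries leave a tiny residual at the upper wall; remove it
  # with a linear ramp so both boundaries are met exactly
  v <- v - (z - z[1]) / (z[length(z)] - z[1]) * v[length(v)]
  velocity_profile_object(z, v, paste0("eo_", charge$regime), eE)
}

cumtrapz_uniform <- function(y, h) {
  c(0, cumsum((y[-1] + y[-length(y)]) / 2 * h))
}

#' Spatially averaged shear rate of a profile
#'
#' The equal-shear calibration used to compare flow types averages the
#' magnitude of the local shear rate over the channel,
#' \eqn{\dot\Gamma = \frac{1}{L_z}\int |\partial v/\partial z|\, dz}.
#' For any no-slip profile rising monotonically to a single maximum this
#' telescopes to 2 v_max / Lz, which is why fixing the average shear across
#' flow types is the same as fixing v_max.
#'
#' @param profile a `velocity_profile` on a uniform grid (>= 3 points).
#' @return average shear rate (t0^-1).
#' @export
average_shear <- function(profile) {
  stopifnot(inherits(profile, "velocity_profile"), length(profile$z) >= 3)
  profile$Gamma_dot
}

#' Calibrate a driver amplitude to a target maximum velocity
#'
#' The Stokes problem is linear in the driving amplitude, so a single solve at
#' unit amplitude fixes the scale factor.
#'
#' @param kind one of "poiseuille", "eo_no_salt", "eo_salt".
#' @param v_max target maximum velocity (> 0).
#' @param geometry a [slit_geometry()] (used for Poiseuille).
#' @param eta dynamic viscosity.
#' @param charge a `charge_profile`, required for the EO kinds.
#' @return the driver amplitude: force density f for Poiseuille, field eE for
#'   electroosmosis.
#' @export
match_amplitude <- function(kind = c("poiseuille", "eo_no_salt", "eo_salt"),
                            v_max, geometry = NULL, eta = 4.05,
                            charge = NULL) {
  kind <- match.arg(kind)
  stopifnot(v_max > 0)
  if (kind == "poiseuille") {
    stopifnot(inherits(geometry, "slit_geometry"))
    return(8 * eta * v_max / geometry$Lz^2)
  }
  if (is.null(charge)) stop("EO amplitude matching needs a charge profile")
  if (max(abs(charge$rho_el)) == 0)
    stop("cannot drive an electroosmotic flow with a zero charge profile")
  ref <- eo_profile(charge, eE = 1, eta = eta)
  v_max / ref$v_max
}

#' Export a velocity profile as TSV
#'
#' Columns z, v_x, shear_rate; "#" header records kind, amplitude, v_max and
#' the average shear.
#' @param profile a `velocity_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_velocity_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# velocity profile kind=%s", profile$kind),
    sprintf("# amplitude=%.10g", profile$amplitude),
    sprintf("# v_max=%.10g", profile$v_max),
    sprintf("# Gamma_dot=%.10g", profile$Gamma_dot),
    "# z_a0\tv_x_a0_per_t0\tshear_per_t0"), con)
  write.table(data.frame(profile$z, profile$v, profile$shear),
              con, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Per-particle streaming force profile for the MPCD solvent
#'
#' Converts a flow driver into the per-particle body force f_x(z) applied to
#' solvent particles during streaming. For Poiseuille the force density f is
#' uniform, so each particle receives f / rho; for electroosmosis the force
#' density rho_el(z) eE is shared among the rho particles per unit volume,
#' giving rho_el(z) eE / rho per particle. Momentum input per unit volume then
#' equals the Stokes force density in both cases.
#'
#' @param kind flow kind ("none", "poiseuille", "eo_no_salt", "eo_salt").
#' @param amplitude driver amplitude (force density f, or field eE).
#' @param geometry a [slit_geometry()].
#' @param rho solvent number density.
#' @param charge `charge_profile` for the EO kinds.
#' @param n_grid lookup-table resolution.
#' @return list with `z` and per-particle `fx` suitable for the engine.
#' @export
streaming_force_profile <- function(kind, amplitude, geometry, rho = 5,
                                    charge = NULL, n_grid = 513) {
  z <- seq(-geometry$Lz / 2, geometry$Lz / 2, length.out = n_grid)
  fx <- switch(kind,
    none = rep(0, n_grid),
    poiseuille = rep(amplitude / rho, n_grid),
    eo_no_salt = ,
    eo_salt = {
      if (is.null(charge)) stop("EO force profile needs a charge profile")
      approx(charge$z, charge$rho_el, xout = z, rule = 2)$y * amplitude / rho
    },
    stop("unknown flow kind: ", kind))
  list(z = z, fx = fx)
}
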