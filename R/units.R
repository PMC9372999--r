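#' MPCD unit system
#'
#' The simulation works in the standard MPCD reduced units: the fluid particle
#' mass \eqn{m_f}, the collision cell edge \eqn{a_0} and the thermal energy
#' \eqn{k_B T} are the base units, and the derived time unit is
#' \deqn{t_0 = a_0 \sqrt{m_f / k_B T}.}
#'
#' @param m_f fluid particle mass (mass unit).
#' @param a0 collision cell edge length (length unit).
#' @param kT thermal energy (energy unit).
#' @return an object of class `mpcd_units` with fields `m_f`, `a0`, `kT`, `t0`.
#' @export
mpcd_units <- function(m_f = 1, a0 = 1, kT = 1) {
  stopifnot(m_f > 0, a0 > 0, kT > 0)
  structure(list(m_f = m_f, a0 = a0, kT = kT, t0 = a0 * sqrt(m_f / kT)),
            class = "mpcd_units")
}

#' Physical length of the collision cell
#'
#' The mapping between reduced and physical lengths used for ionic-strength
#' conversions: the two channel widths simulated, 17 a0 and 34 a0, correspond
#' to 2.5 nm and 5.0 nm, giving a0 = 0.147 nm. This single named constant is
#' the only place the physical scale enters.
#' @export
A0_NM <- 2.5 / 17

#' Bjerrum length of water at room temperature, in a0
#' @export
L_BJERRUM_A0 <- 0.718 / A0_NM

#' Surface charge of the channel walls (e per a0^2)
#'
#' The walls carry 0.5 e/nm^2; in reduced units that is 0.5 * A0_NM^2.
#' @export
SIGMA_WALL_A0 <- 0.5 * A0_NM^2

#' Convert a molar concentration to reduced number density
#'
#' @param c_molL concentration in mol/L.
#' @param a0_nm physical size of the cell edge in nm (default [A0_NM]).
#' @return number density in units of a0^-3.
#' @examples
#' conc_molL_to_a0(2) # the added-salt concentration used in the channel runs
#' @export
conc_molL_to_a0 <- function(c_molL, a0_nm = A0_NM) {
  stopifnot(c_molL >= 0)
  avogadro <- 6.02214076e23
  per_nm3 <- c_molL * avogadro / 1e24   # mol/L -> nm^-3
  per_nm3 * a0_nm^3
}

#' MPCD fluid parameters
#'
#' Solvent parameters of the SRD fluid. The defaults are the liquid-like
#' parameter set used throughout: rotation angle 130 degrees, number density
#' 5 a0^-3 and collision interval 0.1 t0, for which the kinematic viscosity is
#' 0.81 a0^2/t0 and the dynamic viscosity eta = rho * m_f * nu = 4.05.
#'
#' @param rho mean solvent number density (a0^-3).
#' @param alpha SRD rotation angle in degrees.
#' @param dt_c collision interval (t0).
#' @param kT target temperature (energy units).
#' @param nu kinematic viscosity (a0^2/t0). The default is the measured value
#'   for the default parameter set; [srd_viscosity_theory()] gives the
#'   kinetic-theory prediction.
#' @return an object of class `fluid_params`.
#' @export
fluid_params <- function(rho = 5, alpha = 130, dt_c = 0.1, kT = 1, nu = 0.81) {
  stopifnot(rho >= 1, alpha > 0, alpha < 180, dt_c > 0, kT > 0, nu > 0)
  structure(list(rho = rho, alpha = alpha, dt_c = dt_c, kT = kT,
                 nu = nu, eta = rho * nu),
            class = "fluid_params")
}

#' Kinetic-theory viscosity of the SRD fluid
#'
#' Analytic prediction for the kinematic viscosity of an SRD fluid with a
#' random grid shift, as the sum of the kinetic (streaming) and collisional
#' contributions. Used as an independent cross-check of the measured
#' viscosity, never as the measurement itself.
#'
#' @inheritParams fluid_params
#' @param m_f fluid particle mass.
#' @return kinematic viscosity in a0^2/t0.
#' @export
srd_viscosity_theory <- function(rho = 5, alpha = 130, dt_c = 0.1, kT = 1,
                                 m_f = 1) {
  a <- alpha * pi / 180
  nu_kin <- (kT * dt_c / (2 * m_f)) *
    (5 * rho / ((rho - 1 + exp(-rho)) * (2 - cos(a) - cos(2 * a))) - 1)
  nu_col <- (1 / (18 * dt_c)) * (1 - cos(a)) * (1 - (1 - exp(-rho)) / rho)
  nu_kin + nu_col
}

#' Slit channel geometry
#'
#' Two hard walls at z = -Lz/2 and z = +Lz/2; the box is periodic in x and y.
#'
#' @param Lz wall separation (a0). The channel-flow studies use 17 or 34.
#' @param Lx,Ly lateral box dimensions (a0).
#' @return an object of class `slit_geometry`.
#' @export
slit_geometry <- function(Lz, Lx = 60, Ly = 45) {
  stopifnot(Lz > 0, Lx > 0, Ly > 0)
  structure(list(Lz = Lz, Lx = Lx, Ly = Ly, z_wall = c(-Lz / 2, Lz / 2)),
            class = "slit_geometry")
}
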