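# Bead-spring chain model: WCA excluded volume between all monomer pairs,
# FENE bonds between successive monomers, optional harmonic bending for
# semiflexible chains, and the screened laterally-integrated van der Waals
# attraction to the channel walls.

#' Bead-spring polymer specification
#'
#' Kremer-Grest defaults: N = 40 monomers of size sigma = a0, WCA strength
#' eps = kT, bond constant k = 30 eps/sigma^2, maximum extension R0 = 1.5
#' sigma, monomer mass M = 5 m_f (the average solvent mass per collision
#' cell). `eps_bend = 0` gives the fully flexible chain; the semiflexible
#' model is calibrated so that L_p = 2 sigma / <theta^2> ~ 10 sigma
#' (see [calibrate_bending()]).
#'
#' @param N monomer count (>= 2).
#' @param sigma monomer size (a0).
#' @param eps WCA strength (kT).
#' @param k FENE spring constant (eps/sigma^2).
#' @param R0 maximum bond extension (sigma).
#' @param eps_bend bending strength (kT); 0 for the flexible chain.
#' @param mass monomer mass (m_f).
#' @param dt_md MD substep (t0); must not exceed 0.02 of the collision
#'   interval in coupled runs. Default 0.01 * 0.1 t0.
#' @return an object of class `polymer_spec`.
#' @export
polymer_spec <- function(N = 40, sigma = 1, eps = 1, k = 30, R0 = 1.5,
                         eps_bend = 0, mass = 5, dt_md = 0.001) {
  stopifnot(N >= 2, sigma > 0, eps >= 0, k > 0, R0 > 0, eps_bend >= 0,
            mass > 0, dt_md > 0)
  structure(list(N = as.integer(N), sigma = sigma, eps = eps, k = k, R0 = R0,
                 eps_bend = eps_bend, mass = mass, dt_md = dt_md),
            class = "polymer_spec")
}

#' Weeks-Chandler-Andersen potential
#'
#' Purely repulsive truncated-and-shifted Lennard-Jones,
#' \eqn{U(r) = 4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6] + \epsilon} for
#' \eqn{r < 2^{1/6}\sigma} and zero beyond (good-solvent excluded volume).
#'
#' @param r pairwise distance(s), > 0.
#' @param sigma monomer size.
#' @param eps interaction strength.
#' @return list with vectors `energy` and `force` (magnitude of the repulsive
#'   central force, positive = repulsive).
#' @export
wca_potential <- function(r, sigma = 1, eps = 1) {
  if (any(r <= 0)) stop("monomer overlap: r must be > 0")
  rc <- 2^(1 / 6) * sigma
  inside <- r < rc
  sr6 <- ifelse(inside, (sigma / r)^6, 0)
  e <- ifelse(inside, 4 * eps * (sr6^2 - sr6) + eps, 0)
  f <- ifelse(inside, 24 * eps * (2 * sr6^2 - sr6) / r, 0)
  list(energy = e, force = f)
}

#' FENE bond potential
#'
#' Finitely extensible nonlinear elastic bond,
#' \eqn{U(r) = -\tfrac{1}{2} k R_0^2 \ln(1 - r^2/R_0^2)}: harmonic with
#' stiffness k at small extension and diverging at r = R0.
#'
#' @param r bond length(s), 0 <= r < R0.
#' @param k spring constant.
#' @param R0 maximum extension.
#' @return list with `energy` and `force` (attractive restoring magnitude).
#' @export
fene_potential <- function(r, k = 30, R0 = 1.5) {
  if (any(r < 0)) stop("bond length must be >= 0")
  if (any(r >= R0))
    stop(sprintf("FENE bond overstretched: r = %.6g >= R0 = %.4g",
                 max(r), R0))
  x2 <- (r / R0)^2
  list(energy = -0.5 * k * R0^2 * log1p(-x2),
       force = k * r / (1 - x2))
}

#' Bending energy of a semiflexible chain
#'
#' Harmonic in the bond angles, \eqn{U = \tfrac{\epsilon_{bend}}{2}\sum_i
#' \theta_i^2}, where theta_i = 0 for a straight chain. Small-angle
#' equipartition (two transverse modes per joint) gives <theta^2> = 2 kT /
#' eps_bend and hence the worm-like-chain persistence length
#' L_p = 2 sigma / <theta^2> = sigma eps_bend / kT.
#'
#' @param theta bond angles in radians, in `[0, pi]`.
#' @param eps_bend bending strength (kT).
#' @return total bending energy.
#' @export
bending_energy <- function(theta, eps_bend) {
  stopifnot(all(theta >= 0 & theta <= pi), eps_bend >= 0)
  0.5 * eps_bend * sum(theta^2)
}

#' Wall van der Waals interaction parameters
#'
#' @param w attraction strength (kT); the channel studies use w = 1.
#' @param kappa inverse Debye screening length (a0^-1): vdW attractions are
#'   screened by the implicit ionic solution.
#' @param Lz wall separation (a0).
#' @param cutoff interaction cutoff measured from each wall (a0); beyond it
#'   the (energy-shifted) interaction is zero. Default 8/kappa, where the
#'   unshifted magnitude has decayed by more than e^-8.
#' @param site_density dimensionless surface density (n_s sigma^2) of the
#'   induced-dipole sites localized at the fluid-solid boundary, multiplying
#'   the laterally integrated kernel; 1 recovers the bare plane integral. The
#'   default 1/(2 pi) is calibrated so that w = kT leaves equilibrium
#'   flexible-chain statistics unchanged while still perturbing stiff chains
#'   (see the methods vignette).
#' @return an object of class `wall_interaction`.
#' @export
wall_interaction <- function(w = 1, kappa = KAPPA_NO_SALT, Lz,
                             cutoff = 8 / kappa,
                             site_density = 1 / (2 * pi)) {
  stopifnot(w >= 0, Lz > 0, site_density > 0)
  if (w > 0 && kappa <= 0) stop("screened wall attraction needs kappa > 0")
  structure(list(w = w, kappa = kappa, Lz = Lz, cutoff = min(cutoff, Lz),
                 site_density = site_density),
            class = "wall_interaction")
}

# E_n(x) = int_1^inf exp(-x t) / t^n dt by upward recursion from pracma's E1.
expint_en <- function(n, x) {
  e <- pracma::expint_E1(x)
  if (n == 1) return(e)
  for (m in 1:(n - 1)) e <- (exp(-x) - x * e) / m
  e
}

# Laterally integrated screened vdW attraction of a single wall at distance
# d > 0: U(d) = -2 pi w sigma^6 * E5(kappa d) / d^4, the exact integral of the
# kernel -w sigma^6 exp(-kappa r) / r^6 over the wall plane.
vdw_single_wall <- function(d, w, kappa, sigma = 1) {
  -2 * pi * w * sigma^6 * expint_en(5, kappa * d) / d^4
}

#' Screened van der Waals attraction of the channel walls
#'
#' Induced-dipole attraction \eqn{-w\sigma^6 e^{-\kappa r}/r^6} between a
#' monomer and wall sites localized at the two fluid-solid boundaries,
#' integrated exactly over each wall plane:
#' \deqn{U_{vdW}(z) = -2\pi w \sigma^6 \left[ \frac{E_5(\kappa z_+)}{z_+^4}
#'  + \frac{E_5(\kappa z_-)}{z_-^4} \right], \quad z_\pm = L_z/2 \pm z,}
#' with \eqn{E_5} the order-5 exponential integral. Each wall's contribution
#' is truncated at the cutoff distance and shifted to zero there so forces
#' stay continuous.
#'
#' The planar integral diverges at contact while the only wall repulsion in
#' the model is the stochastic reflection at the plane, so the attraction is
#' regularized inside one monomer size: for wall distances d < sigma the
#' energy is held at its d = sigma value (zero force). The exact closed form
#' applies for all d >= sigma, leaving a finite contact well of order w.
#'
#' @param z monomer z coordinate(s), strictly inside the walls.
#' @param wall a [wall_interaction()].
#' @param sigma monomer size.
#' @return list with `energy` (<= 0) and `force` (dU/dz with sign: positive
#'   force pushes toward +z, i.e. toward the nearer attracting wall at z > 0).
#' @export
vdw_wall <- function(z, wall, sigma = 1) {
  stopifnot(inherits(wall, "wall_interaction"))
  half <- wall$Lz / 2
  if (any(abs(z) >= half))
    stop("monomer at or beyond a wall plane")
  if (wall$w == 0)
    return(list(energy = rep(0, length(z)), force = rep(0, length(z))))
  weff <- wall$w * wall$site_density  # site density scales the plane integral
  shift <- vdw_single_wall(wall$cutoff, weff, wall$kappa, sigma)
  one <- function(d) { # energy and dU/dd from one wall at distance d
    dd <- pmax(d, sigma)   # contact plateau inside one monomer size
    u <- ifelse(dd < wall$cutoff,
                vdw_single_wall(dd, weff, wall$kappa, sigma) - shift, 0)
    # dU/dd = 2 pi w sigma^6 exp(-kappa d)/d^5 (from d/dd of the integral)
    dudd <- ifelse(d >= sigma & d < wall$cutoff,
                   2 * pi * weff * sigma^6 * exp(-wall$kappa * d) / d^5, 0)
    list(u = u, dudd = dudd)
  }
  lo <- one(half + z)   # wall at -Lz/2, distance z_+ = Lz/2 + z
  hi <- one(half - z)   # wall at +Lz/2, distance z_- = Lz/2 - z
  # force_z = -dU/dz; distance to lower wall grows with z, to upper shrinks
  list(energy = lo$u + hi$u,
       force = -lo$dudd + hi$dudd)
}

#' Calibrate the bending strength to a target persistence length
#'
#' Adjusts eps_bend so that equilibrium sampling of the full chain model
#' (WCA + FENE + bending) realizes \eqn{L_p = 2\sigma/\langle\theta^2\rangle}
#' at the target. Small-angle equipartition gives the starting point
#' eps_bend = target kT / sigma; a secant iteration on log(eps_bend) against
#' Monte Carlo estimates of <theta^2> then refines it (the sin(theta) measure
#' and excluded volume shift the realized value by a few percent).
#'
#' @param target_Lp target persistence length in sigma units (default 10).
#' @param spec base [polymer_spec()] (its eps_bend is ignored).
#' @param n_sweeps Monte Carlo sweeps per iteration.
#' @param tol relative tolerance on the realized L_p.
#' @param max_iter secant iterations.
#' @param seed RNG seed for the calibration runs.
#' @return the calibrated [polymer_spec()] with `eps_bend` set and attributes
#'   `Lp_realized` and `calibration` (iteration table).
#' @export
calibrate_bending <- function(target_Lp = 10, spec = polymer_spec(),
                              n_sweeps = 20000, tol = 0.02, max_iter = 8,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  measure <- function(eps_bend) {
    s <- spec; s$eps_bend <- eps_bend
    mc <- chain_mc(s, n_sweeps = n_sweeps, sample_stride = 5,
                   warmup_sweeps = max(2000, n_sweeps %/% 10))
    2 * spec$sigma / mc$theta2_mean
  }
  hist <- data.frame(eps_bend = numeric(), Lp = numeric())
  x1 <- target_Lp * 1  # equipartition estimate, kT units
  l1 <- measure(x1)
  hist[1, ] <- c(x1, l1)
  # L_p is monotone increasing and near-linear in eps_bend
  x2 <- x1 * target_Lp / l1
  for (it in seq_len(max_iter)) {
    l2 <- measure(x2)
    hist[nrow(hist) + 1, ] <- c(x2, l2)
    if (abs(l2 - target_Lp) / target_Lp < tol) break
    slope <- (l2 - l1) / (x2 - x1)
    x1 <- x2; l1 <- l2
    x2 <- max(0.1, x2 + (target_Lp - l2) / slope)
  }
  out <- spec
  out$eps_bend <- hist$eps_bend[nrow(hist)]
  attr(out, "Lp_realized") <- hist$Lp[nrow(hist)]
  attr(out, "calibration") <- hist
  out
}
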