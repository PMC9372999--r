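# Nonlinear Poisson-Boltzmann electrostatics between two charged plates.
#
# Reduced-unit conventions: lengths in a0, charge in units of the elementary
# charge e, potentials in kT/e (phi = e psi / kT). Poisson's equation in these
# units is phi'' = -4 pi l_B rho_el(z) with l_B the Bjerrum length in a0.
# Each wall carries a surface charge of magnitude Sigma; the mobile ions are
# taken positive (counterions), so rho_el(z) >= 0 and the electroneutrality
# condition is integral(rho_el) = 2 Sigma.

#' An ionic species
#'
#' @param valency signed integer valency Z.
#' @param conc number density in a0^-3 (see [conc_molL_to_a0()] to convert
#'   from mol/L).
#' @return an object of class `ionic_species`.
#' @export
ionic_species <- function(valency, conc) {
  if (!is.finite(conc) || conc < 0) stop("ionic concentration must be finite and >= 0")
  if (valency == 0) stop("ionic valency must be nonzero")
  structure(list(valency = as.integer(valency), conc = conc),
            class = "ionic_species")
}

#' Inverse Debye screening length
#'
#' Evaluates \eqn{\kappa = \sqrt{4\pi l_B \sum_\alpha Z_\alpha^2 c_\alpha}}
#' from a list of ionic species. Note that the two channel-run values
#' (kappa = 0.23 a0^-1 without added salt, kappa = 0.47 a0^-1 at 2 mol/L) are
#' adopted verbatim as canonical run constants ([KAPPA_NO_SALT],
#' [KAPPA_SALT]); they are not reproduced by the textbook sum for any obvious
#' bookkeeping of the counterions, so this function is a utility kept separate
#' from the pinned run parameters.
#'
#' @param species list of [ionic_species()] objects (may be empty: kappa = 0).
#' @param l_B Bjerrum length in a0.
#' @return inverse screening length in a0^-1.
#' @export
debye_kappa <- function(species, l_B) {
  stopifnot(l_B > 0)
  if (length(species) == 0) return(0)
  s <- 0
  for (sp in species) {
    if (!inherits(sp, "ionic_species")) sp <- do.call(ionic_species, sp)
    s <- s + sp$valency^2 * sp$conc
  }
  sqrt(4 * pi * l_B * s)
}

#' Canonical screening constants of the channel runs
#'
#' Inverse Debye lengths (a0^-1) used by the reference setups: no added salt
#' and c_salt = 2 mol/L. Pinned as run constants; see [debye_kappa()].
#' @export
KAPPA_NO_SALT <- 0.23

#' @rdname KAPPA_NO_SALT
#' @export
KAPPA_SALT <- 0.47

# Integrate the half-channel PB initial-value problem with classic RK4 and
# return phi, phi' and the running integral of the mobile charge on the grid.
# rho_fun(phi) must give the mobile charge density (>= 0 for counterions).
pb_integrate_half <- function(phi0, rho_fun, l_B, half, n) {
  h <- half / n
  z <- seq(0, half, length.out = n + 1)
  phi <- numeric(n + 1); dphi <- numeric(n + 1); qint <- numeric(n + 1)
  phi[1] <- phi0; dphi[1] <- 0; qint[1] <- 0
  # state y = (phi, phi', integral of rho_el)
  deriv <- function(y) c(y[2], -4 * pi * l_B * rho_fun(y[1]), rho_fun(y[1]))
  y <- c(phi0, 0, 0)
  for (i in seq_len(n)) {
    k1 <- deriv(y)
    k2 <- deriv(y + h / 2 * k1)
    k3 <- deriv(y + h / 2 * k2)
    k4 <- deriv(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    phi[i + 1] <- y[1]; dphi[i + 1] <- y[2]; qint[i + 1] <- y[3]
  }
  list(z = z, phi = phi, dphi = dphi, qint = qint)
}

pb_profile_object <- function(z_half, rho_half, Sigma, l_B, kappa, regime,
                              c_salt = 0, diagnostics = list()) {
  # mirror the half-channel solution onto the full symmetric grid
  z <- c(-rev(z_half[-1]), z_half)
  rho <- c(rev(rho_half[-1]), rho_half)
  structure(list(z = z, rho_el = rho, Sigma = Sigma, l_B = l_B,
                 kappa = kappa, regime = regime, c_salt = c_salt,
                 diagnostics = diagnostics),
            class = "charge_profile")
}

#' @export
print.charge_profile <- function(x, ...) {
  cat(sprintf("Poisson-Boltzmann charge profile (%s)\n", x$regime))
  cat(sprintf("  Lz = %g a0, %d grid points\n", diff(range(x$z)), length(x$z)))
  cat(sprintf("  Sigma = %.5g e/a0^2, l_B = %.4g a0, kappa = %.3g a0^-1\n",
              x$Sigma, x$l_B, x$kappa))
  cat(sprintf("  rho_el(wall) = %.4g, rho_el(0) = %.4g e/a0^3\n",
              x$rho_el[1], x$rho_el[(length(x$z) + 1) / 2]))
  cat(sprintf("  integrated mobile charge / 2 Sigma = %.8f\n",
              integrate_profile(x) / (2 * x$Sigma)))
  invisible(x)
}

#' Integrate a charge profile across the channel
#'
#' Simpson quadrature of rho_el(z) on the (uniform, odd-length) profile grid.
#' By electroneutrality this equals 2 Sigma.
#' @param profile a `charge_profile`.
#' @return integrated mobile charge per unit wall area (e/a0^2).
#' @export
integrate_profile <- function(profile) {
  simpson_uniform(profile$rho_el, profile$z[2] - profile$z[1])
}

simpson_uniform <- function(y, h) {
  n <- length(y)
  stopifnot(n %% 2 == 1, n >= 3)
  w <- rep(c(2, 4), length.out = n); w[1] <- 1; w[n] <- 1
  sum(w * y) * h / 3
}

#' Solve the counterion-only Poisson-Boltzmann problem in a slit
#'
#' Numerically solves the nonlinear PB boundary-value problem between two
#' plates carrying surface charge Sigma each, with only the neutralizing
#' counterions present (no added salt). The counterion density is
#' n(z) = n0 exp(-phi(z)) with phi(0) = 0 at the channel midplane; n0 is found
#' by shooting so that Gauss's law phi'(Lz/2) = -4 pi l_B Sigma holds at the
#' wall, which is equivalent to global electroneutrality.
#'
#' @param geometry a [slit_geometry()].
#' @param Sigma surface charge per wall (e/a0^2, >= 0).
#' @param l_B Bjerrum length (a0).
#' @param n_grid number of grid intervals across the channel (even, >= 64).
#' @param kappa optional inverse screening length to record on the profile
#'   (defaults to [KAPPA_NO_SALT] at the canonical wall charge); purely
#'   metadata for the no-salt regime.
#' @return a `charge_profile` with rho_el >= 0 on a symmetric grid.
#' @export
solve_pb_no_salt <- function(geometry, Sigma = SIGMA_WALL_A0,
                             l_B = L_BJERRUM_A0, n_grid = 512,
                             kappa = KAPPA_NO_SALT) {
  stopifnot(inherits(geometry, "slit_geometry"), Sigma >= 0, n_grid >= 64)
  half <- geometry$Lz / 2
  nh <- ceiling(n_grid / 2)
  if (Sigma == 0) {
    zs <- seq(0, half, length.out = nh + 1)
    return(pb_profile_object(zs, rep(0, nh + 1), Sigma, l_B, kappa, "no-salt"))
  }
  target <- -4 * pi * l_B * Sigma
  shoot <- function(log_n0) {
    n0 <- exp(log_n0)
    sol <- pb_integrate_half(0, function(p) n0 * exp(-p), l_B, half, nh)
    sol$dphi[nh + 1] - target
  }
  # bracket n0 around the mean counterion density 2 Sigma / Lz
  n_mean <- 2 * Sigma / geometry$Lz
  lo <- log(n_mean * 1e-4); hi <- log(n_mean)
  # phi'(wall) is monotone decreasing in n0; expand bracket if needed
  it <- 0
  while (shoot(lo) < 0 && it < 60) { lo <- lo - 1; it <- it + 1 }
  root <- uniroot(shoot, c(lo, hi), tol = 1e-14)
  n0 <- exp(root$root)
  sol <- pb_integrate_half(0, function(p) n0 * exp(-p), l_B, half, nh)
  resid <- abs(sol$dphi[nh + 1] - target) / abs(target)
  if (resid > 1e-6)
    stop(sprintf("PB no-salt solver did not converge: residual %.3g after %d evals",
                 resid, root$iter))
  pb_profile_object(sol$z, n0 * exp(-sol$phi), Sigma, l_B, kappa, "no-salt",
                    diagnostics = list(n0 = n0, residual = resid,
                                       iterations = root$iter))
}

#' Solve the added-salt Poisson-Boltzmann problem in a slit
#'
#' Symmetric 1:1 electrolyte between two charged plates. Ion densities follow
#' n_pm(z) = c_s exp(∓ phi(z)) against a neutral reference (phi -> 0 where the
#' solution is locally neutral), so the net mobile charge is
#' rho_el = -2 c_s sinh(phi) and PB reads phi'' = kappa^2 sinh(phi) with
#' kappa^2 = 8 pi l_B c_s. The midplane potential is found by shooting on
#' Gauss's law at the wall.
#'
#' Either `c_salt` (a0^-3, per species) or `kappa` may be given; when `kappa`
#' is supplied it takes precedence and fixes c_s = kappa^2 / (8 pi l_B). The
#' canonical channel runs pin kappa = 0.47 a0^-1 for c_salt = 2 mol/L.
#'
#' @inheritParams solve_pb_no_salt
#' @param c_salt salt number density per species (a0^-3).
#' @param kappa inverse Debye length (a0^-1) overriding `c_salt`.
#' @return a `charge_profile` (net mobile charge, >= 0 for positive Sigma).
#' @export
solve_pb_with_salt <- function(geometry, Sigma = SIGMA_WALL_A0,
                               l_B = L_BJERRUM_A0, c_salt = NULL,
                               kappa = NULL, n_grid = 512) {
  stopifnot(inherits(geometry, "slit_geometry"), Sigma >= 0, n_grid >= 64)
  if (is.null(kappa) && is.null(c_salt))
    stop("supply either c_salt or kappa")
  if (!is.null(kappa)) {
    stopifnot(kappa > 0)
    c_s <- kappa^2 / (8 * pi * l_B)
  } else {
    stopifnot(c_salt > 0)
    c_s <- c_salt
    kappa <- sqrt(8 * pi * l_B * c_s)
  }
  half <- geometry$Lz / 2
  nh <- ceiling(n_grid / 2)
  rho_fun <- function(p) -2 * c_s * sinh(p)
  if (Sigma == 0) {
    zs <- seq(0, half, length.out = nh + 1)
    return(pb_profile_object(zs, rep(0, nh + 1), Sigma, l_B, kappa,
                             "added-salt", c_salt = c_s))
  }
  target <- -4 * pi * l_B * Sigma
  shoot <- function(phi0) {
    sol <- pb_integrate_half(phi0, rho_fun, l_B, half, nh)
    sol$dphi[nh + 1] - target
  }
  # counterions positive, midplane potential phi0 < 0; shoot() decreases as
  # phi0 becomes more negative, so expand the bracket downward
  lo <- -1e-8; it <- 0
  while (shoot(lo) > 0 && it < 200) { lo <- lo * 2; it <- it + 1 }
  root <- uniroot(shoot, c(lo, 0), tol = 1e-14)
  sol <- pb_integrate_half(root$root, rho_fun, l_B, half, nh)
  resid <- abs(sol$dphi[nh + 1] - target) / abs(target)
  if (resid > 1e-6)
    stop(sprintf("PB added-salt solver did not converge: residual %.3g", resid))
  pb_profile_object(sol$z, rho_fun(sol$phi), Sigma, l_B, kappa, "added-salt",
                    c_salt = c_s,
                    diagnostics = list(phi0 = root$root, residual = resid,
                                       iterations = root$iter))
}

#' Closed-form counterion-only profile (Gouy-Chapman between plates)
#'
#' The analytic solution of the no-salt PB problem,
#' n(z) = K^2/(2 pi l_B) sec^2(K z), with K the root of
#' K tan(K Lz/2) = 2 pi l_B Sigma. Kept as an independent reference for
#' validating the numerical solver; not used by the solver itself.
#'
#' @inheritParams solve_pb_no_salt
#' @param z positions at which to evaluate (a0).
#' @return list with `K` and the counterion charge density `rho_el` at `z`.
#' @export
gouy_chapman_profile <- function(z, geometry, Sigma = SIGMA_WALL_A0,
                                 l_B = L_BJERRUM_A0) {
  half <- geometry$Lz / 2
  rhs <- 2 * pi * l_B * Sigma
  K <- uniroot(function(K) K * tan(K * half) - rhs,
               c(1e-12, (pi / 2 - 1e-9) / half), tol = 1e-15)$root
  list(K = K, rho_el = K^2 / (2 * pi * l_B) / cos(K * z)^2)
}

#' Export a charge profile as TSV
#'
#' Two columns (z in a0, rho_el in e/a0^3) with "#"-prefixed header lines
#' recording Sigma, l_B, kappa and the regime.
#'
#' @param profile a `charge_profile`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_charge_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# charge profile regime=%s", profile$regime),
    sprintf("# Sigma_e_per_a0sq=%.10g", profile$Sigma),
    sprintf("# l_B_a0=%.10g", profile$l_B),
    sprintf("# kappa_per_a0=%.10g", profile$kappa),
    "# z_a0\trho_el_e_per_a0cube"), con)
  write.table(data.frame(z = profile$z, rho_el = profile$rho_el),
              con, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read back a charge profile written by [write_charge_profile()]
#' @param path TSV path.
#' @return a `charge_profile`.
#' @export
read_charge_profile <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  getv <- function(key) {
    ln <- hdr[grepl(paste0("^# ", key, "="), hdr)]
    as.numeric(sub(paste0("# ", key, "="), "", ln))
  }
  regime <- sub("# charge profile regime=", "",
                hdr[grepl("regime=", hdr)])
  d <- read.table(text = lines[!startsWith(lines, "#")], sep = "\t")
  structure(list(z = d[[1]], rho_el = d[[2]], Sigma = getv("Sigma_e_per_a0sq"),
                 l_B = getv("l_B_a0"), kappa = getv("kappa_per_a0"),
                 regime = regime, c_salt = NA, diagnostics = list()),
            class = "charge_profile")
}
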