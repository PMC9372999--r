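# Shared test oracles and small utilities, independent of the package's own
# numerical paths wherever they stand in for one.

# Simpson quadrature on a uniform, odd-length grid
simpson_uniform_test <- function(y, h) {
  n <- length(y)
  w <- rep(c(2, 4), length.out = n); w[1] <- 1; w[n] <- 1
  sum(w * y) * h / 3
}

# trapezoid quadrature
trapz_test <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))

# direct 2D quadrature of the screened vdW kernel -w s^6 e^(-kr)/r^6 over a
# wall plane at perpendicular distance d: the oracle for the closed form
vdw_plane_quadrature <- function(d, w = 1, kappa = 0.23, sigma = 1) {
  f <- function(s) {
    r <- sqrt(d^2 + s^2)
    -w * sigma^6 * exp(-kappa * r) / r^6 * 2 * pi * s
  }
  stats::integrate(f, 0, Inf, rel.tol = 1e-10)$value
}

# Boltzmann average of theta^2 for a single harmonic bond angle with the
# spherical sin(theta) measure, by quadrature
theta2_single_angle <- function(eps_bend, kT = 1) {
  num <- stats::integrate(function(t) t^2 * sin(t) *
                            exp(-0.5 * eps_bend * t^2 / kT), 0, pi,
                          rel.tol = 1e-10)$value
  den <- stats::integrate(function(t) sin(t) *
                            exp(-0.5 * eps_bend * t^2 / kT), 0, pi,
                          rel.tol = 1e-10)$value
  num / den
}

# random chain-like coordinates for property checks
random_frame <- function(N, scale = 1) {
  matrix(rnorm(3 * N, sd = scale), N, 3)
}

# standard fluid/geometry fixtures for small engine runs
tiny_geometry <- function() slit_geometry(8, Lx = 6, Ly = 6)

# periodic wrap into [0, L)
wrap_test <- function(x, L) x - L * floor(x / L)
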