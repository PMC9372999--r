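# Structural and transport observables: gyration tensor and asphericity,
# binned monomer density and conditioned asphericity profiles, velocity
# statistics, persistence length, Zimm time and Weissenberg number.

#' Gyration tensor summary of a single conformation
#'
#' Computes the center of mass, the instantaneous gyration radius
#' \eqn{\hat R_g^2 = \frac{1}{N}\sum_i |r_i - r_{cm}|^2}, the gyration tensor
#' \eqn{G_{\alpha\beta} = \frac{1}{N}\sum_i (r_{i\alpha}-r_{cm,\alpha})
#' (r_{i\beta}-r_{cm,\beta})} with ordered eigenvalues
#' \eqn{\lambda_1 \le \lambda_2 \le \lambda_3}, and the dimensionless
#' asphericity
#' \deqn{b = \frac{(\lambda_3-\lambda_2)^2 + (\lambda_3-\lambda_1)^2 +
#'   (\lambda_2-\lambda_1)^2}{2(\lambda_1+\lambda_2+\lambda_3)^2}}
#' (0 for a sphere, 1 for a rod). For a degenerate conformation with all
#' monomers coincident, `Rg = 0`, `b` is NaN and `degenerate` is TRUE.
#'
#' @param pos N x 3 matrix of monomer positions.
#' @return an object of class `gyration_summary`: fields `Rg`, `rcm`,
#'   `tensor`, `eigenvalues` (ascending), `asphericity`, `degenerate`.
#' @export
gyration <- function(pos) {
  pos <- as.matrix(pos)
  stopifnot(ncol(pos) == 3, nrow(pos) >= 2)
  rcm <- colMeans(pos)
  d <- sweep(pos, 2, rcm)
  G <- crossprod(d) / nrow(pos)
  lam <- sort(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  lam[lam < 0 & lam > -1e-12] <- 0
  tr <- sum(lam)
  b <- if (tr > 0) {
    ((lam[3] - lam[2])^2 + (lam[3] - lam[1])^2 + (lam[2] - lam[1])^2) /
      (2 * tr^2)
  } else NaN
  structure(list(Rg = sqrt(max(tr, 0)), rcm = rcm, tensor = G,
                 eigenvalues = lam, asphericity = b,
                 degenerate = !is.finite(b)),
            class = "gyration_summary")
}

#' @export
print.gyration_summary <- function(x, ...) {
  cat(sprintf("Rg = %.4g, b = %.4g (eigenvalues %.4g %.4g %.4g)\n",
              x$Rg, x$asphericity, x$eigenvalues[1], x$eigenvalues[2],
              x$eigenvalues[3]))
  invisible(x)
}

# Shared constructor for binned profiles with independent-trajectory errors.
profile_table <- function(centers, value, stderr, counts, width,
                          normalization, min_count = 0) {
  structure(list(z = centers, value = value, stderr = stderr,
                 counts = counts, bin_width = width,
                 normalization = normalization,
                 flagged = counts < min_count),
            class = "profile_table")
}

#' @export
print.profile_table <- function(x, ...) {
  cat(sprintf("binned profile: %d bins of width %.3g (%s)\n",
              length(x$z), x$bin_width, x$normalization))
  invisible(x)
}

#' Export a binned profile as TSV
#' @param profile a `profile_table`.
#' @param path output path.
#' @param what short label recorded in the header.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(profile, path, what = "profile") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# %s", what),
               sprintf("# bin_width=%.10g", profile$bin_width),
               sprintf("# normalization=%s", profile$normalization),
               "# z\tvalue\tstderr\tcount"), con)
  write.table(data.frame(profile$z, profile$value, profile$stderr,
                         profile$counts),
              con, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# frames: list over trajectories, each an array N x 3 x nframes (or a list of
# N x 3 matrices). Coerce to a list of lists of matrices.
as_frame_list <- function(frames) {
  if (is.array(frames) && length(dim(frames)) == 3)
    frames <- list(frames)
  if (is.matrix(frames[[1]])) frames <- list(frames)
  lapply(frames, function(traj) {
    if (is.array(traj) && length(dim(traj)) == 3)
      lapply(seq_len(dim(traj)[3]), function(k) traj[, , k])
    else traj
  })
}

#' Monomer density profile across the channel
#'
#' Probability density of finding a monomer center at height z, normalized so
#' that the profile integrates to 1 over the channel. The standard error per
#' bin is computed across independent trajectories.
#'
#' @param frames monomer positions: one trajectory (N x 3 x nframes array or
#'   list of N x 3 matrices) or a list of such trajectories.
#' @param geometry a [slit_geometry()].
#' @param bin_width bin width in a0 (default 0.25).
#' @return a `profile_table` whose `value` integrates to 1.
#' @export
monomer_density <- function(frames, geometry, bin_width = 0.25) {
  trajs <- as_frame_list(frames)
  if (length(trajs) == 0 || length(trajs[[1]]) == 0)
    stop("monomer_density needs at least one frame")
  half <- geometry$Lz / 2
  breaks <- seq(-half, half, by = bin_width)
  if (breaks[length(breaks)] < half) breaks <- c(breaks, half)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  widths <- diff(breaks)
  per_traj <- vapply(trajs, function(traj) {
    zs <- unlist(lapply(traj, function(m) m[, 3]))
    counts <- tabulate(findInterval(zs, breaks, all.inside = TRUE),
                       nbins = length(centers))
    counts / sum(counts) / widths   # probability density
  }, numeric(length(centers)))
  per_traj <- matrix(per_traj, nrow = length(centers))
  m <- rowMeans(per_traj)
  se <- if (ncol(per_traj) > 1)
    apply(per_traj, 1, stats::sd) / sqrt(ncol(per_traj)) else
    rep(NA_real_, length(centers))
  total_counts <- length(trajs) * length(trajs[[1]]) *
    nrow(trajs[[1]][[1]]) * (widths / sum(widths))
  profile_table(centers, m, se, round(total_counts), bin_width,
                "probability density, integral 1 over the channel")
}

#' Asphericity conditioned on the chain position
#'
#' Mean asphericity of conformations whose center of mass falls in each z bin,
#' with independent-trajectory standard errors. Bins holding fewer than
#' `min_count` conformations (pooled) are flagged: near-wall bins are rarely
#' visited and their averages are noisy.
#'
#' @inheritParams monomer_density
#' @param bin_width conditioning bin width in a0 (a common choice is half the
#'   bulk gyration radius).
#' @param min_count minimum pooled samples per reported bin.
#' @return a `profile_table` (value = mean asphericity per bin).
#' @export
asphericity_profile <- function(frames, geometry, bin_width = 2,
                                min_count = 100) {
  trajs <- as_frame_list(frames)
  half <- geometry$Lz / 2
  breaks <- seq(-half, half, by = bin_width)
  if (breaks[length(breaks)] < half) breaks <- c(breaks, half)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  nb <- length(centers)
  per_traj_mean <- matrix(NA_real_, nb, length(trajs))
  pooled_n <- integer(nb)
  for (tix in seq_along(trajs)) {
    bsum <- numeric(nb); bn <- integer(nb)
    for (m in trajs[[tix]]) {
      g <- gyration(m)
      if (g$degenerate) next
      bin <- findInterval(g$rcm[3], breaks, all.inside = TRUE)
      bsum[bin] <- bsum[bin] + g$asphericity
      bn[bin] <- bn[bin] + 1L
    }
    per_traj_mean[, tix] <- ifelse(bn > 0, bsum / bn, NA)
    pooled_n <- pooled_n + bn
  }
  m <- rowMeans(per_traj_mean, na.rm = TRUE)
  se <- apply(per_traj_mean, 1, function(r) {
    r <- r[is.finite(r)]
    if (length(r) > 1) stats::sd(r) / sqrt(length(r)) else 0
  })
  m[pooled_n == 0] <- NA
  profile_table(centers, m, se, pooled_n, bin_width,
                "mean asphericity conditioned on chain center-of-mass bin",
                min_count = min_count)
}

#' Velocity statistics of fluid and chain
#'
#' Channel-averaged transport statistics from a simulation result: the binned
#' fluid velocity profile, its channel average and fitted maximum, the mean
#' monomer velocity along the flow, and the ratios used to compare transport
#' across flow types. `v_max` is obtained from a quadratic fit of the central
#' half of the fluid profile (exact for a parabola, and a robust estimate of
#' the plateau for plug-like profiles, where the fitted curvature is small).
#'
#' @param run an `mpcd_run` result (see [run_simulation()]), or a list with
#'   fields `fluid_profile` (data.frame z, vx) and `v_mono`.
#' @return list with `profile`, `v_fluid_mean`, `v_max`, `v_mono`, and the
#'   ratios `fluid_ratio` = <v_fluid>/v_max and `mono_ratio` = <v_mono>/v_max.
#' @export
velocity_stats <- function(run) {
  prof <- run$fluid_profile
  keep <- is.finite(prof$vx)
  z <- prof$z[keep]; vx <- prof$vx[keep]
  v_mean <- mean(vx)
  central <- abs(z) <= max(abs(z)) / 2
  fit <- stats::lm(vx ~ I(z^2), subset = central)
  v_max_fit <- unname(stats::coef(fit)[1])
  v_max <- max(v_max_fit, max(vx))
  list(profile = prof, v_fluid_mean = v_mean, v_max = v_max,
       v_mono = run$v_mono,
       fluid_ratio = v_mean / v_max,
       mono_ratio = if (is.null(run$v_mono)) NA_real_ else run$v_mono / v_max)
}

#' Bond angles of a conformation
#'
#' Angle at each interior monomer between successive bond vectors (0 =
#' straight).
#' @param pos N x 3 position matrix, N >= 3.
#' @return numeric vector of N - 2 angles in radians.
#' @export
bond_angles <- function(pos) {
  pos <- as.matrix(pos)
  stopifnot(nrow(pos) >= 3)
  b <- diff(pos)
  bn <- b / sqrt(rowSums(b^2))
  ct <- rowSums(bn[-nrow(bn), , drop = FALSE] * bn[-1, , drop = FALSE])
  acos(pmin(1, pmax(-1, ct)))
}

#' Persistence length from bond-angle fluctuations
#'
#' Pools all interior bond angles over the supplied conformations and
#' evaluates \eqn{L_p = 2\sigma / \langle\theta^2\rangle}. For perfectly
#' straight input (`<theta^2>` = 0) the result is +Inf. A cross-check from the
#' exponential decay of bond-vector correlations,
#' \eqn{\langle t_i \cdot t_{i+s}\rangle = e^{-s\,b/L_p}}, is returned
#' alongside.
#'
#' @param frames one trajectory or a list of trajectories of N x 3 matrices.
#' @param sigma monomer size (a0).
#' @return list with `Lp` (angle-fluctuation estimate), `theta2_mean`,
#'   `Lp_correlation` (bond-correlation estimate) and `n_angles`.
#' @export
persistence_length <- function(frames, sigma = 1) {
  trajs <- as_frame_list(frames)
  th2 <- 0; n <- 0L
  csum <- 0; cn <- 0L; bond_len <- 0
  for (traj in trajs) for (m in traj) {
    th <- bond_angles(m)
    th2 <- th2 + sum(th^2); n <- n + length(th)
    b <- diff(m); bl <- sqrt(rowSums(b^2))
    bn <- b / bl
    csum <- csum + sum(rowSums(bn[-nrow(bn), , drop = FALSE] *
                                 bn[-1, , drop = FALSE]))
    cn <- cn + nrow(bn) - 1L
    bond_len <- bond_len + mean(bl)
  }
  nframes <- sum(vapply(trajs, length, 1L))
  theta2 <- th2 / n
  g <- csum / cn
  bl <- bond_len / nframes
  list(Lp = if (theta2 > 0) 2 * sigma / theta2 else Inf,
       theta2_mean = theta2,
       Lp_correlation = if (g < 1 && g > 0) -bl / log(g) else Inf,
       n_angles = n)
}

#' Zimm relaxation time of the chain
#'
#' Longest relaxation time of a self-avoiding chain with unscreened
#' hydrodynamics, \deqn{\tau_Z = \frac{\eta \sigma^3 N^{3\nu}}{\sqrt{6}\,\pi\,
#' k_B T},} with Flory exponent nu = 0.588.
#'
#' @param N monomer count.
#' @param sigma monomer size (a0).
#' @param eta solvent dynamic viscosity.
#' @param kT thermal energy.
#' @param nu_flory Flory exponent.
#' @return Zimm time in t0.
#' @export
zimm_time <- function(N = 40, sigma = 1, eta = 4.05, kT = 1,
                      nu_flory = 0.588) {
  eta * sigma^3 * N^(3 * nu_flory) / (sqrt(6) * pi * kT)
}

#' Weissenberg number of a channel flow
#'
#' Ratio of the Zimm relaxation time to the flow time scale, the inverse of
#' the average shear rate, \eqn{L_z / v_{max}}:
#' \eqn{Wi = \tau_Z v_{max} / L_z}. Wi >> 1 means the chain cannot relax
#' between shear events.
#'
#' @param spec a [polymer_spec()].
#' @param fluid a [fluid_params()].
#' @param geometry a [slit_geometry()].
#' @param v_max maximum flow velocity (a0/t0, >= 0).
#' @param nu_flory Flory exponent.
#' @return an object of class `timescale_report` with `tau_Z`, `flow_time`,
#'   `Wi`.
#' @export
weissenberg <- function(spec = polymer_spec(), fluid = fluid_params(),
                        geometry, v_max, nu_flory = 0.588) {
  stopifnot(v_max >= 0)
  tz <- zimm_time(spec$N, spec$sigma, fluid$eta, fluid$kT, nu_flory)
  ft <- if (v_max > 0) geometry$Lz / v_max else Inf
  structure(list(tau_Z = tz, flow_time = ft, Wi = tz / ft),
            class = "timescale_report")
}

#' @export
print.timescale_report <- function(x, ...) {
  cat(sprintf("tau_Z = %.4g t0, flow time = %.4g t0, Wi = %.3g\n",
              x$tau_Z, x$flow_time, x$Wi))
  invisible(x)
}
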