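# File formats: extended XYZ trajectories, YAML run configuration,
# RDS checkpoints (exact round trip), JSON run summaries.

#' Write monomer frames as extended XYZ
#'
#' One block per frame: atom count, a comment line carrying the lattice,
#' per-column properties and the time stamp, then one line per monomer with
#' species label, position and velocity.
#'
#' @param frames_pos N x 3 x nframes array of positions.
#' @param frames_vel matching velocity array (optional; zeros if NULL).
#' @param path output file.
#' @param geometry a [slit_geometry()].
#' @param times frame times (t0); defaults to the frame index.
#' @param species species label (single string).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(frames_pos, frames_vel = NULL, path, geometry,
                      times = NULL, species = "M") {
  stopifnot(length(dim(frames_pos)) == 3)
  N <- dim(frames_pos)[1]
  nf <- dim(frames_pos)[3]
  if (is.null(frames_vel)) frames_vel <- array(0, dim(frames_pos))
  if (is.null(times)) times <- seq_len(nf)
  con <- file(path, "w")
  on.exit(close(con))
  lattice <- sprintf("%g 0 0 0 %g 0 0 0 %g",
                     geometry$Lx, geometry$Ly, geometry$Lz)
  for (f in seq_len(nf)) {
    writeLines(as.character(N), con)
    writeLines(sprintf(
      'Lattice="%s" Properties=species:S:1:pos:R:3:vel:R:3 Time=%.10g',
      lattice, times[f]), con)
    m <- cbind(frames_pos[, , f], frames_vel[, , f])
    writeLines(sprintf("%s %.10g %.10g %.10g %.10g %.10g %.10g", species,
                       m[, 1], m[, 2], m[, 3], m[, 4], m[, 5], m[, 6]), con)
  }
  invisible(path)
}

#' Read an extended XYZ trajectory written by [write_xyz()]
#' @param path file path.
#' @return list with `pos` and `vel` arrays (N x 3 x nframes) and `times`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  i <- 1
  pos <- list(); vel <- list(); times <- numeric()
  while (i <= length(lines)) {
    N <- as.integer(lines[i])
    tm <- as.numeric(sub('.*Time=([0-9eE+.-]+).*', "\\1", lines[i + 1]))
    block <- lines[(i + 2):(i + 1 + N)]
    m <- do.call(rbind, lapply(strsplit(block, " "), function(p)
      as.numeric(p[-1])))
    pos[[length(pos) + 1]] <- m[, 1:3, drop = FALSE]
    vel[[length(vel) + 1]] <- m[, 4:6, drop = FALSE]
    times <- c(times, tm)
    i <- i + 2 + N
  }
  nf <- length(pos)
  N <- nrow(pos[[1]])
  parr <- array(unlist(pos), c(N, 3, nf))
  varr <- array(unlist(vel), c(N, 3, nf))
  list(pos = parr, vel = varr, times = times)
}

#' Assemble a run configuration
#'
#' The single container tying together geometry, fluid, polymer, wall
#' interaction, flow driver and schedule; validated for cross-consistency
#' (shared Lz, kappa shared between the charge profile regime and the wall
#' screening).
#'
#' @param geometry a [slit_geometry()].
#' @param fluid a [fluid_params()].
#' @param polymer a [polymer_spec()] or NULL for a pure-solvent run.
#' @param wall a [wall_interaction()] or NULL for purely repulsive walls.
#' @param flow list with `kind` ("none", "poiseuille", "eo_no_salt",
#'   "eo_salt") and either `amplitude` or `v_max` (the other is derived).
#' @param schedule list with `warmup`, `production`, `sample_stride`,
#'   `traj_stride` (MPCD steps).
#' @param seeds integer seeds, one independent trajectory each (the channel
#'   studies use at least 4).
#' @param chain_com_z initial chain center-of-mass height (a0).
#' @return an object of class `run_config`.
#' @export
run_config <- function(geometry, fluid = fluid_params(),
                       polymer = polymer_spec(), wall = NULL,
                       flow = list(kind = "none", amplitude = 0),
                       schedule = list(warmup = 1000, production = 4000,
                                       sample_stride = 2, traj_stride = 20),
                       seeds = 1:4, chain_com_z = 0) {
  stopifnot(inherits(geometry, "slit_geometry"),
            inherits(fluid, "fluid_params"))
  if (!is.null(polymer)) stopifnot(inherits(polymer, "polymer_spec"))
  if (!is.null(wall)) {
    stopifnot(inherits(wall, "wall_interaction"))
    if (abs(wall$Lz - geometry$Lz) > 1e-9)
      stop("wall interaction and geometry disagree on Lz")
    if (flow$kind == "eo_no_salt" && abs(wall$kappa - KAPPA_NO_SALT) > 1e-9)
      warning("wall screening kappa differs from the no-salt run constant")
    if (flow$kind == "eo_salt" && abs(wall$kappa - KAPPA_SALT) > 1e-9)
      warning("wall screening kappa differs from the added-salt run constant")
  }
  if (is.null(flow$kind)) stop("flow$kind is required")
  if (is.null(flow$amplitude) && is.null(flow$v_max) && flow$kind != "none")
    stop("flow needs amplitude or v_max")
  sch <- utils::modifyList(list(warmup = 1000, production = 4000,
                                sample_stride = 2, traj_stride = 20),
                           schedule)
  structure(list(geometry = geometry, fluid = fluid, polymer = polymer,
                 wall = wall, flow = flow, schedule = sch,
                 seeds = as.integer(seeds), chain_com_z = chain_com_z),
            class = "run_config")
}

#' Serialize a run configuration to YAML
#' @param config a [run_config()].
#' @param path output path; NULL returns the YAML string.
#' @return `path` (or the YAML text), invisibly.
#' @export
write_run_config <- function(config, path = NULL) {
  plain <- rapply(unclass(config), identity, how = "replace")
  txt <- yaml::as.yaml(plain, precision = 15)
  if (is.null(path)) return(invisible(txt))
  writeLines(txt, path)
  invisible(path)
}

#' Parse a YAML run configuration
#' @param path file path (or a YAML string when `text = TRUE`).
#' @param text treat `path` as YAML text.
#' @return a [run_config()].
#' @export
read_run_config <- function(path, text = FALSE) {
  y <- if (text) yaml::yaml.load(path) else yaml::read_yaml(path)
  geom <- slit_geometry(y$geometry$Lz, y$geometry$Lx, y$geometry$Ly)
  fl <- fluid_params(y$fluid$rho, y$fluid$alpha, y$fluid$dt_c, y$fluid$kT,
                     y$fluid$nu)
  pol <- if (!is.null(y$polymer))
    polymer_spec(y$polymer$N, y$polymer$sigma, y$polymer$eps, y$polymer$k,
                 y$polymer$R0, y$polymer$eps_bend, y$polymer$mass,
                 y$polymer$dt_md) else NULL
  wl <- if (!is.null(y$wall))
    wall_interaction(y$wall$w, y$wall$kappa, y$wall$Lz, y$wall$cutoff,
                     y$wall$site_density) else NULL
  run_config(geom, fl, pol, wl, flow = y$flow, schedule = y$schedule,
             seeds = y$seeds,
             chain_com_z = if (is.null(y$chain_com_z)) 0 else y$chain_com_z)
}

#' Save / load a simulation checkpoint
#'
#' A single-container binary checkpoint holding the full particle state, step
#' counter and the R RNG state; loading restores the RNG so a continued run
#' is bit-identical to an uninterrupted one.
#'
#' @param sys an `mpcd_system` (see [mpcd_system()]).
#' @param path checkpoint path.
#' @return `path` / the restored `mpcd_system`.
#' @export
save_checkpoint <- function(sys, path) {
  sys$rng_state <- get(".Random.seed", envir = globalenv())
  saveRDS(sys, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  sys <- readRDS(path)
  assign(".Random.seed", sys$rng_state, envir = globalenv())
  sys$rng_state <- NULL
  sys
}

#' Write a JSON run summary
#' @param summary named list of scalar results.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# simple polynomial rolling hash of a string, as a hex id for manifests
config_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
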