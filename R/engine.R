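#' Random initial configuration on the membrane disk
#'
#' Places `n_molecules` anchors uniformly on the disk with rejection of
#' anchor-anchor overlaps (centers closer than `2*r1`), heads at the bond
#' rest length straight above the membrane plane. Deterministic for a given
#' `rng_seed` in the config.
#'
#' @param config a [SimulationConfig-class].
#' @param max_tries placement attempts per molecule before declaring the
#'   packing infeasible.
#' @return A [SystemState-class] at time 0.
#' @export
initRandom <- function(config, max_tries = 2000) {
  stopifnot(is(config, "SimulationConfig"))
  n <- config@n_molecules
  R <- config@domain_radius
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(config@rng_seed %% .Machine$integer.max)
  pos <- matrix(0, n, 3)
  min2 <- (2 * config@r1)^2
  placed <- 0L
  while (placed < n) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      r <- R * sqrt(runif(1))
      th <- runif(1, 0, 2 * pi)
      p <- c(r * cos(th), r * sin(th), 0)
      if (placed == 0L) { ok <- TRUE; break }
      d2 <- (pos[1:placed, 1] - p[1])^2 + (pos[1:placed, 2] - p[2])^2
      if (min(d2) >= min2) { ok <- TRUE; break }
    }
    if (!ok)
      stop("packing infeasible: could not place molecule ", placed + 1,
           " without overlap on a ", R, "-nm disk")
    placed <- placed + 1L
    pos[placed, ] <- p
  }
  heads <- pos
  heads[, 3] <- heads[, 3] + config@r1 + config@r2
  new("SystemState", time = 0, pos1 = pos, pos2 = heads,
      mobile = rep(TRUE, n), labels = rep(list(character()), n))
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Advance a system state by Euler-Maruyama integration
#'
#' Runs `n_steps` overdamped Brownian-dynamics steps without recording
#' intermediate frames. For each mobile particle the update is
#' \eqn{\Delta x = D_p F \Delta t + \sqrt{2 D_p \Delta t}\,\xi} with
#' standard-normal \eqn{\xi} per coordinate; static molecules do not move.
#' A warning is emitted if any single-step displacement exceeded `r1`
#' (timestep too large for the acting forces).
#'
#' @param state a [SystemState-class].
#' @param config a [SimulationConfig-class].
#' @param n_steps number of steps (default 1).
#' @param seed integer RNG seed for this stretch of dynamics; defaults to
#'   the config seed.
#' @param Dp per-particle diffusion coefficient (nm^2/ns); defaults to the
#'   analytic calibration [particleDiffusion()].
#' @return The advanced [SystemState-class].
#' @export
stepDynamics <- function(state, config, n_steps = 1,
                         seed = config@rng_seed, Dp = NULL) {
  stopifnot(is(state, "SystemState"))
  if (any(!is.finite(state@pos1)) || any(!is.finite(state@pos2)))
    stop("non-finite coordinates")
  res <- .cpp_run(state@pos1, state@pos2, state@mobile,
                  .molecule_ea(state, config),
                  .engine_params(config, Dp), as.numeric(n_steps), 1L,
                  as.numeric(seed), FALSE, .cluster_cutoff(config),
                  0, 0, -1L, 0L, 0L)
  if (res$n_big_steps > 0)
    warning(res$n_big_steps,
            " step(s) displaced a particle by more than r1; reduce dt")
  new("SystemState", time = state@time + n_steps * config@dt,
      pos1 = res$pos1, pos2 = res$pos2, mobile = state@mobile,
      labels = state@labels)
}

#' Run a Brownian-dynamics simulation
#'
#' Integrates `config@n_steps` steps from a random initial configuration
#' (or from `init`, supporting continuation from the endpoint of a previous
#' run), sampling every `config@sample_stride` steps. The recorded
#' trajectory has `floor(n_steps/sample_stride) + 1` frames including the
#' initial one.
#'
#' @param config a [SimulationConfig-class].
#' @param init optional [SystemState-class] to continue from; defaults to
#'   [initRandom()].
#' @param seed integer seed for the dynamics RNG (defaults to the config
#'   seed). Two runs with identical seeds and inputs are bit-identical.
#' @param Dp per-particle diffusion coefficient (nm^2/ns), defaulting to
#'   [particleDiffusion()].
#' @return A [Trajectory-class].
#' @examples
#' cfg <- simConfig(n_molecules = 20, domain_radius = 100, E_a = 4,
#'                  n_steps = 2e4, sample_stride = 1e4, rng_seed = 7)
#' traj <- runSimulation(cfg)
#' traj
#' @export
runSimulation <- function(config, init = NULL, seed = config@rng_seed,
                          Dp = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  if (is.null(init)) init <- initRandom(config)
  stopifnot(is(init, "SystemState"))
  if (nrow(init@pos1) != config@n_molecules)
    config@n_molecules <- nrow(init@pos1)
  res <- .cpp_run(init@pos1, init@pos2, init@mobile,
                  .molecule_ea(init, config),
                  .engine_params(config, Dp), config@n_steps,
                  as.integer(config@sample_stride), as.numeric(seed), TRUE,
                  .cluster_cutoff(config), 0, 0, -1L, 0L, 0L)
  if (res$n_big_steps > 0)
    warning(res$n_big_steps,
            " step(s) displaced a particle by more than r1; reduce dt")
  .as_trajectory(res, config, init, seed)
}

.as_trajectory <- function(res, config, init, seed) {
  nf <- as.integer(res$n_frames)
  new("Trajectory", config = config,
      times = init@time + res$times[seq_len(nf)],
      pos1 = res$traj1[, , seq_len(nf), drop = FALSE],
      pos2 = res$traj2[, , seq_len(nf), drop = FALSE],
      energies = res$energies[seq_len(nf)],
      mobile = init@mobile, labels = init@labels,
      provenance = list(seed = seed,
                        version = as.character(utils::packageVersion("SyxDynamics"))))
}

#' Final frame of a trajectory, for continuation runs
#'
#' @param traj a [Trajectory-class].
#' @return The last recorded [SystemState-class].
#' @export
finalState <- function(traj) {
  getFrame(traj, nFrames(traj))
}

#' Insert a static, highly attractive seed molecule
#'
#' Emulates a newly formed target site (e.g. a docked vesicle contact): one
#' immobile dimer, interacting through the clustering potential with a well
#' depth of `seed_ea` (default 8 \eqn{k_BT}), is added at a uniformly chosen
#' empty membrane site -- a position with no existing anchor within the
#' clustering interaction radius plus `clearance`. Fails if no empty site
#' can be found (densely covered membrane).
#'
#' @param state a [SystemState-class].
#' @param config a [SimulationConfig-class].
#' @param seed integer seed for the placement draw.
#' @param clearance extra empty margin around the site in nm (default 2).
#' @param seed_ea seed well depth in \eqn{k_BT} (informational; the engine
#'   applies 8 \eqn{k_BT} to molecules tagged "seed").
#' @param max_tries placement attempts before giving up.
#' @return A [SystemState-class] with one additional immobile molecule
#'   tagged `"seed"`.
#' @export
insertSeed <- function(state, config, seed = config@rng_seed,
                       clearance = 2, seed_ea = 8, max_tries = 5000) {
  stopifnot(is(state, "SystemState"))
  R <- config@domain_radius
  min_d <- 2 * config@r1 + config@i_offset + clearance
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed %% .Machine$integer.max)
  found <- NULL
  for (try in seq_len(max_tries)) {
    r <- R * sqrt(runif(1))
    th <- runif(1, 0, 2 * pi)
    p <- c(r * cos(th), r * sin(th), 0)
    d2 <- (state@pos1[, 1] - p[1])^2 + (state@pos1[, 2] - p[2])^2 +
      (state@pos1[, 3] - p[3])^2
    if (min(d2) >= min_d^2) { found <- p; break }
  }
  if (is.null(found))
    stop("no empty membrane site found for the seed molecule")
  head_p <- found + c(0, 0, config@r1 + config@r2)
  new("SystemState", time = state@time,
      pos1 = rbind(state@pos1, found), pos2 = rbind(state@pos2, head_p),
      mobile = c(state@mobile, FALSE),
      labels = c(state@labels, list("seed")))
}

#' Calibrate the per-particle diffusion coefficient
#'
#' Refines the analytic starting point \eqn{D_p = 2 D_{eff}} (the in-plane
#' center of mass of two equally mobile particles diffuses with
#' \eqn{(D_1 + D_2)/4}) by simulating isolated, non-interacting dimers and
#' fitting the anchor mean-squared displacement over lags of 10-100
#' \eqn{\mu s}, iterating until the measured dimer diffusion coefficient is
#' within `tol` of `config@D_eff`.
#'
#' @param config a [SimulationConfig-class].
#' @param n_steps steps per calibration run.
#' @param n_dimers independent dimers simulated jointly (spaced far apart,
#'   zero attraction) to reduce estimator variance.
#' @param tol relative tolerance on the measured dimer D (default 0.05).
#' @param max_iter maximum refinement iterations.
#' @param seed integer RNG seed.
#' @return `Dp` in nm^2/ns, with attributes `measured_D` (the dimer
#'   diffusion coefficient in \eqn{\mu m^2/s}) and `iterations`.
#' @export
calibrateParticleDiffusion <- function(config, n_steps = 4e6, n_dimers = 8,
                                       tol = 0.05, max_iter = 4,
                                       seed = config@rng_seed) {
  stopifnot(is(config, "SimulationConfig"))
  Dp <- particleDiffusion(config)
  measured <- NA_real_
  for (it in seq_len(max_iter)) {
    traj <- .free_dimer_run(config, Dp, n_steps, n_dimers,
                            seed = seed + 97 * (it - 1))
    measured <- msdDiffusion(traj, lag_range_us = c(10, 100))
    if (abs(measured - config@D_eff) <= tol * config@D_eff) break
    if (it == max_iter)
      stop("diffusion calibration did not converge: measured ",
           signif(measured, 4), " um2/s vs target ", config@D_eff)
    Dp <- Dp * config@D_eff / measured
  }
  structure(Dp, measured_D = measured, iterations = it)
}

# isolated non-interacting dimers on a quasi-infinite membrane; one engine
# call, dimers spaced 1000 nm apart so that no pair ever interacts
.free_dimer_run <- function(config, Dp, n_steps, n_dimers, seed) {
  spacing <- 1000
  side <- ceiling(sqrt(n_dimers))
  idx <- seq_len(n_dimers) - 1
  pos1 <- cbind((idx %% side) * spacing, (idx %/% side) * spacing, 0)
  pos2 <- pos1
  pos2[, 3] <- config@r1 + config@r2
  free_cfg <- config
  free_cfg@n_molecules <- n_dimers
  free_cfg@E_a <- 0
  free_cfg@domain_radius <- 1e7  # wall never reached
  free_cfg@n_steps <- n_steps
  state <- new("SystemState", time = 0, pos1 = pos1, pos2 = pos2,
               mobile = rep(TRUE, n_dimers),
               labels = rep(list(character()), n_dimers))
  runSimulation(free_cfg, init = state, seed = seed, Dp = Dp)
}

# ---------------------------------------------------------------------------
# Plain-text trajectory container: a directory holding the config as YAML,
# run metadata as YAML, and per-frame particle coordinates as CSV (one long
# table per particle type; anchors in pos1.csv as the canonical per-frame
# anchor export).

#' Persist / load a trajectory as a plain-text container
#'
#' The container is a directory holding `config.yaml`, `meta.yaml` (times,
#' energies, mobility, labels, provenance) and two long-format CSV tables
#' `pos1.csv` / `pos2.csv` with columns `frame, molecule, x, y, z` (nm);
#' `pos1.csv` doubles as the per-frame anchor-position export.
#'
#' @param traj a [Trajectory-class].
#' @param dir directory to create (must not exist for save).
#' @return `saveTrajectory` returns `dir` invisibly; `loadTrajectory`
#'   returns the reconstructed [Trajectory-class].
#' @export
saveTrajectory <- function(traj, dir) {
  stopifnot(is(traj, "Trajectory"))
  if (dir.exists(dir)) stop("directory already exists: ", dir)
  dir.create(dir, recursive = TRUE)
  writeSimConfig(traj@config, file.path(dir, "config.yaml"))
  yaml::write_yaml(list(
    times = traj@times, energies = traj@energies,
    mobile = traj@mobile,
    labels = lapply(traj@labels, as.character),
    provenance = traj@provenance), file.path(dir, "meta.yaml"))
  .write_pos_csv(traj@pos1, file.path(dir, "pos1.csv"))
  .write_pos_csv(traj@pos2, file.path(dir, "pos2.csv"))
  invisible(dir)
}

.write_pos_csv <- function(arr, path) {
  d <- dim(arr)
  df <- data.frame(
    frame = rep(seq_len(d[3]), each = d[2]),
    molecule = rep(seq_len(d[2]), times = d[3]),
    x = as.vector(arr[1, , ]), y = as.vector(arr[2, , ]),
    z = as.vector(arr[3, , ]))
  write.csv(df, path, row.names = FALSE)
}

.read_pos_csv <- function(path, n, nf) {
  df <- read.csv(path)
  arr <- array(0, dim = c(3, n, nf))
  arr[1, , ] <- df$x
  arr[2, , ] <- df$y
  arr[3, , ] <- df$z
  arr
}

#' @rdname saveTrajectory
#' @export
loadTrajectory <- function(dir) {
  config <- readSimConfig(file.path(dir, "config.yaml"))
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  nf <- length(meta$times)
  n <- length(meta$mobile)
  new("Trajectory", config = config, times = as.numeric(meta$times),
      pos1 = .read_pos_csv(file.path(dir, "pos1.csv"), n, nf),
      pos2 = .read_pos_csv(file.path(dir, "pos2.csv"), n, nf),
      energies = as.numeric(meta$energies),
      mobile = as.logical(meta$mobile),
      labels = lapply(meta$labels, as.character),
      provenance = meta$provenance)
}
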