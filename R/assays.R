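# Simulated experiments: FRAP, membrane exploration, seeded aggregation at
# a docking site, and the docking/priming candidate census.

#' Simulated FRAP experiment
#'
#' Starting from an (ideally equilibrated) configuration, molecules whose
#' anchors lie inside a disc covering `bleach_frac` of the membrane area
#' (concentric with the domain, radius \eqn{R\sqrt{bleach\_frac}}) are
#' tagged "bleached"; tags never affect the dynamics. The recovery curve
#' reports the number of fluorescent (untagged) molecules inside the disc,
#' normalized to the pre-bleach molecule count inside the disc. In a closed
#' system ideal mixing caps recovery at `1 - bleach_frac`.
#'
#' @param state a [SystemState-class], typically the endpoint of a
#'   converged run.
#' @param config a [SimulationConfig-class]; `n_steps`/`sample_stride`
#'   control duration and curve resolution.
#' @param bleach_frac bleached area fraction (default 0.1).
#' @param seed integer seed for the dynamics.
#' @param Dp per-particle diffusion coefficient (nm^2/ns).
#' @return list with `curve` (data.frame `time_s`, `recovered`),
#'   `bleach` (center/radius in nm), `n_bleached`, and the underlying
#'   [Trajectory-class] as `traj`.
#' @export
frapAssay <- function(state, config, bleach_frac = 0.1,
                      seed = config@rng_seed, Dp = NULL) {
  stopifnot(is(state, "SystemState"))
  radius <- config@domain_radius * sqrt(bleach_frac)
  inside0 <- sqrt(state@pos1[, 1]^2 + state@pos1[, 2]^2) <= radius
  labels <- state@labels
  for (m in which(inside0))
    labels[[m]] <- union(labels[[m]], "bleached")
  st <- new("SystemState", time = state@time, pos1 = state@pos1,
            pos2 = state@pos2, mobile = state@mobile, labels = labels)
  traj <- runSimulation(config, init = st, seed = seed, Dp = Dp)
  curve <- frapCurve(traj, radius = radius)
  list(curve = curve, bleach = list(center = c(0, 0), radius = radius),
       n_bleached = sum(inside0), traj = traj)
}

#' @rdname frapAssay
#' @param traj a [Trajectory-class] whose molecules carry "bleached" tags.
#' @param radius bleach-disc radius in nm.
#' @export
frapCurve <- function(traj, radius) {
  bleached <- vapply(traj@labels, function(l) "bleached" %in% l, logical(1))
  F <- nFrames(traj)
  rho2 <- traj@pos1[1, , , drop = FALSE]^2 + traj@pos1[2, , , drop = FALSE]^2
  inside <- matrix(rho2[1, , ] <= radius^2, nrow = nMolecules(traj))
  pre <- sum(inside[, 1])
  if (pre == 0) stop("no molecules inside the bleach disc at t = 0")
  fluor <- colSums(inside & !bleached)
  data.frame(time_s = (traj@times - traj@times[1]) * 1e-9,
             recovered = fluor / pre)
}

#' Membrane exploration by lattice coverage
#'
#' Divides the membrane into square cells of `cell_nm` (vesicle-sized,
#' default 40 nm) on a lattice centered on the domain axis, marks a cell
#' visited once any anchor center falls inside it (checked every
#' integration step), and reports the visited fraction of the cells
#' intersecting the disk over time. Cells occupied at t = 0 count as
#' visited from the start.
#'
#' @param state starting [SystemState-class].
#' @param config a [SimulationConfig-class]; `n_steps` caps the run.
#' @param cell_nm lattice cell edge (nm).
#' @param stop_frac optionally stop early once this visited fraction is
#'   reached (0 = run to `n_steps`).
#' @param seed integer dynamics seed.
#' @param Dp per-particle diffusion coefficient (nm^2/ns).
#' @return list with `curve` (data.frame `time_ms`, `fraction`),
#'   `t50_ms`/`t75_ms` (`NA` if not reached: right-censored),
#'   `initial_fraction`, `n_cells`, and `first_visit_ms` (matrix, `NA`
#'   for never-visited or out-of-disk cells).
#' @export
membraneCoverage <- function(state, config, cell_nm = 40, stop_frac = 0,
                             seed = config@rng_seed, Dp = NULL) {
  stopifnot(is(state, "SystemState"))
  res <- .cpp_run(state@pos1, state@pos2, state@mobile,
                  .molecule_ea(state, config),
                  .engine_params(config, Dp), config@n_steps,
                  as.integer(config@sample_stride), as.numeric(seed), FALSE,
                  .cluster_cutoff(config), cell_nm, stop_frac, -1L, 0L, 0L)
  fv <- res$first_visit_step
  in_disk <- res$cell_in_disk
  n_cells <- res$n_cells_in_disk
  steps <- sort(fv[in_disk & fv >= 0])
  dt_ms <- config@dt * 1e-6
  ts <- unique(steps)
  curve <- data.frame(time_ms = ts * dt_ms,
                      fraction = vapply(ts, function(s) sum(steps <= s), 0) /
                        n_cells)
  t_at <- function(fr) {
    k <- ceiling(fr * n_cells)
    if (length(steps) >= k) steps[k] * dt_ms else NA_real_
  }
  fv_ms <- fv * dt_ms
  fv_ms[fv < 0 | !in_disk] <- NA
  list(curve = curve, t50_ms = t_at(0.5), t75_ms = t_at(0.75),
       initial_fraction = sum(fv == 0 & in_disk) / n_cells,
       n_cells = n_cells, first_visit_ms = fv_ms)
}

#' Newly visited cells within a time window
#'
#' Counts lattice cells first visited in `(0, window_ms]`, i.e. excluding
#' the cells already occupied at the start: a scale-robust measure of
#' exploration speed.
#'
#' @param coverage result of [membraneCoverage()].
#' @param window_ms time window in ms.
#' @return number of newly visited cells.
#' @export
newlyVisited <- function(coverage, window_ms) {
  fv <- coverage$first_visit_ms
  sum(!is.na(fv) & fv > 0 & fv <= window_ms)
}

#' Aggregation kinetics at a seeded docking site
#'
#' Inserts a static, strongly attractive (8 \eqn{k_BT}) seed molecule into
#' an empty membrane site of the given configuration (fresh placement per
#' replica) and records the first time the seed's distance-cutoff cluster
#' reaches each size up to `target_size`. Replicas that never reach a size
#' within `config@n_steps` are right-censored (`NA` time).
#'
#' @param state equilibrated [SystemState-class] (without seed).
#' @param config a [SimulationConfig-class]; `n_steps` caps each replica.
#' @param target_size largest cluster size tracked.
#' @param n_replicas number of independent replicas.
#' @param seed base integer seed; replica r uses `seed + r` for placement
#'   and dynamics.
#' @param check_stride steps between seed-cluster size checks.
#' @param Dp per-particle diffusion coefficient (nm^2/ns).
#' @return data.frame with `replica`, `size`, `time_ms`, `censored`.
#' @export
seededAggregation <- function(state, config, target_size = 40,
                              n_replicas = 3, seed = config@rng_seed,
                              check_stride = 2000, Dp = NULL) {
  out <- vector("list", n_replicas)
  for (r in seq_len(n_replicas)) {
    st <- insertSeed(state, config, seed = seed + r)
    n <- nrow(st@pos1)
    res <- .cpp_run(st@pos1, st@pos2, st@mobile,
                    .molecule_ea(st, config),
                    .engine_params(config, Dp), config@n_steps,
                    as.integer(config@sample_stride),
                    as.numeric(seed + r), FALSE, .cluster_cutoff(config),
                    0, 0, n - 1L, as.integer(target_size),
                    as.integer(check_stride))
    hit <- res$seed_hit_step
    out[[r]] <- data.frame(replica = r, size = seq_len(target_size),
                           time_ms = ifelse(hit >= 0, hit * config@dt * 1e-6,
                                            NA_real_),
                           censored = hit < 0)
  }
  do.call(rbind, out)
}

#' Docking- and priming-candidate census on a vesicle-scale lattice
#'
#' Divides the membrane into square cells of `cell_nm` (default 30 nm, the
#' area accessible to a vesicle near the membrane; 20 x 20 cells for the
#' default 300-nm domain). Per cell it reports: the time-averaged anchor
#' count (docking candidates -- every Syntaxin-1A is docking competent),
#' and the number of molecules that are accessible (free, or on a cluster
#' boundary with at most `boundary_max_neighbors` anchors within the
#' clustering interaction radius) and remain within the cell plus a 1-cell
#' tolerance ring for at least `window_ms` (priming candidates). Both
#' readings of accessibility are reported: `priming` counts free-or-
#' boundary molecules, `priming_boundary` restricts to cluster-boundary
#' molecules.
#'
#' @param traj a [Trajectory-class] spanning at least `window_ms`.
#' @param window_ms persistence requirement in ms (default 100, the
#'   priming timescale).
#' @param cell_nm lattice cell edge (nm).
#' @param boundary_max_neighbors neighbor-count threshold separating
#'   boundary from interior anchors (default 3; interior anchors in
#'   near-hexagonal packing have 5 or more).
#' @param cutoff proximity cutoff for cluster identification (nm).
#' @return list with `grid` (data.frame `cell_x`, `cell_y`, `x_nm`,
#'   `y_nm`, `in_disk`, `docking`, `priming`, `priming_boundary`),
#'   `per_frame_total` (anchors inside the lattice per frame) and the
#'   parameters used.
#' @export
candidateCensus <- function(traj, window_ms = 100, cell_nm = 30,
                            boundary_max_neighbors = 3, cutoff = NULL) {
  config <- traj@config
  R <- config@domain_radius
  F <- nFrames(traj)
  n <- nMolecules(traj)
  dt_frame_ms <- diff(traj@times[1:2]) * 1e-6
  span_ms <- (traj@times[F] - traj@times[1]) * 1e-6
  if (span_ms < window_ms)
    stop("trajectory spans ", signif(span_ms, 3), " ms < window of ",
         window_ms, " ms")
  ncell <- ceiling(2 * R / cell_nm)
  org <- -ncell * cell_nm / 2

  cx <- floor((traj@pos1[1, , , drop = TRUE] - org) / cell_nm)
  cy <- floor((traj@pos1[2, , , drop = TRUE] - org) / cell_nm)
  cx <- matrix(cx, n, F)
  cy <- matrix(cy, n, F)
  in_grid <- cx >= 0 & cy >= 0 & cx < ncell & cy < ncell

  # docking: time-averaged anchor count per cell
  dock <- matrix(0, ncell, ncell)
  for (f in seq_len(F)) {
    ok <- which(in_grid[, f])
    for (m in ok)
      dock[cx[m, f] + 1, cy[m, f] + 1] <- dock[cx[m, f] + 1, cy[m, f] + 1] + 1
  }
  dock <- dock / F

  # accessibility per molecule and frame
  labs <- identifyClusters(traj, cutoff = cutoff)
  irad <- 2 * config@r1 + config@i_offset
  nbrs <- .cpp_neighbor_counts(traj@pos1, irad)
  sizes <- matrix(0L, n, F)
  for (f in seq_len(F)) {
    s <- tabulate(labs[, f])
    sizes[, f] <- s[labs[, f]]
  }
  free <- sizes == 1
  boundary <- sizes >= 2 & nbrs <= boundary_max_neighbors
  w <- ceiling(window_ms / dt_frame_ms)

  prim <- matrix(0, ncell, ncell)
  prim_b <- matrix(0, ncell, ncell)
  mark <- function(mat, qual_m) {
    # sliding windows of w frames within qualifying stretches; all visited
    # cells must fit a 3x3 box, whose center cell gets the candidate
    hits <- matrix(FALSE, ncell, ncell)
    runs <- rle(qual_m)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    for (k in which(runs$values & runs$lengths >= w)) {
      for (s in starts[k]:(ends[k] - w + 1)) {
        win <- s:(s + w - 1)
        rx <- range(cxm[win]); ry <- range(cym[win])
        if (rx[2] - rx[1] <= 2 && ry[2] - ry[1] <= 2) {
          ccx <- round(mean(rx)); ccy <- round(mean(ry))
          if (ccx >= 0 && ccy >= 0 && ccx < ncell && ccy < ncell)
            hits[ccx + 1, ccy + 1] <- TRUE
        }
      }
    }
    mat + hits
  }
  for (m in seq_len(n)) {
    cxm <- cx[m, ]; cym <- cy[m, ]
    prim <- mark(prim, free[m, ] | boundary[m, ])
    prim_b <- mark(prim_b, boundary[m, ])
  }

  centers <- org + (seq_len(ncell) - 0.5) * cell_nm
  # a cell is kept when its square intersects the disk
  nearest2 <- function(c0) pmax(abs(c0) - cell_nm / 2, 0)^2
  grid <- expand.grid(cell_x = seq_len(ncell) - 1, cell_y = seq_len(ncell) - 1)
  grid$x_nm <- centers[grid$cell_x + 1]
  grid$y_nm <- centers[grid$cell_y + 1]
  grid$in_disk <- nearest2(grid$x_nm) + nearest2(grid$y_nm) <= R^2
  grid$docking <- dock[cbind(grid$cell_x + 1, grid$cell_y + 1)]
  grid$priming <- prim[cbind(grid$cell_x + 1, grid$cell_y + 1)]
  grid$priming_boundary <- prim_b[cbind(grid$cell_x + 1, grid$cell_y + 1)]

  list(grid = grid, per_frame_total = colSums(in_grid),
       window_ms = window_ms, cell_nm = cell_nm,
       boundary_max_neighbors = boundary_max_neighbors)
}
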