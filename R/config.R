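#' Create a simulation configuration
#'
#' Constructs a validated [SimulationConfig-class]. All arguments are in
#' simulation units (nm, ns, \eqn{k_BT}) except `D_eff`
#' (\eqn{\mu m^2/s}). A head/anchor size ratio `r2/r1 <= 1` removes the
#' steric cluster-size limit and triggers a warning (unbounded growth).
#'
#' @param n_molecules number of Syntaxin-1A dimers.
#' @param domain_radius disk radius in nm.
#' @param r1,r2 anchor and head radii in nm.
#' @param D_eff effective dimer diffusion coefficient in \eqn{\mu m^2/s}.
#' @param k_m membrane restraint stiffness (\eqn{k_BT/nm^2}).
#' @param k_rep head repulsion stiffness (\eqn{k_BT/nm^2}).
#' @param E_a clustering well depth (\eqn{k_BT}).
#' @param i_offset clustering range offset (nm); interaction radius is
#'   `2*r1 + i_offset`.
#' @param dt timestep (ns).
#' @param n_steps steps to integrate.
#' @param sample_stride steps between recorded frames.
#' @param rng_seed integer seed (bit-reproducibility contract).
#' @param boundary_k disk wall stiffness (\eqn{k_BT/nm^2}).
#' @param bond_k anchor-head bond stiffness (\eqn{k_BT/nm^2}).
#' @return A [SimulationConfig-class] object.
#' @examples
#' cfg <- simConfig(n_molecules = 50, domain_radius = 120, E_a = 4,
#'                  n_steps = 1e4)
#' cfg
#' @export
simConfig <- function(n_molecules = 500, domain_radius = 300, r1 = 3.0,
                      r2 = 3.3, D_eff = 0.2, k_m = 20, k_rep = 2,
                      E_a = 4.0, i_offset = 2.25, dt = 5,
                      n_steps = 50e6, sample_stride = 2000,
                      rng_seed = 1, boundary_k = 20, bond_k = 10) {
  cfg <- new("SimulationConfig",
    n_molecules = as.numeric(n_molecules),
    domain_radius = as.numeric(domain_radius), r1 = as.numeric(r1),
    r2 = as.numeric(r2), D_eff = as.numeric(D_eff), k_m = as.numeric(k_m),
    k_rep = as.numeric(k_rep), E_a = as.numeric(E_a),
    i_offset = as.numeric(i_offset), dt = as.numeric(dt),
    n_steps = as.numeric(n_steps), sample_stride = as.numeric(sample_stride),
    rng_seed = as.numeric(rng_seed), boundary_k = as.numeric(boundary_k),
    bond_k = as.numeric(bond_k))
  validObject(cfg)
  if (cfg@r2 / cfg@r1 <= 1)
    warning("r2/r1 <= 1: no steric size limit, cluster growth is unbounded")
  cfg
}

.config_fields <- function() {
  c("n_molecules", "domain_radius", "r1", "r2", "D_eff", "k_m", "k_rep",
    "E_a", "i_offset", "dt", "n_steps", "sample_stride", "rng_seed",
    "boundary_k", "bond_k")
}

#' Read / write a simulation configuration as a flat YAML file
#'
#' Every [SimulationConfig-class] field is addressable by its slot name;
#' fields missing from the file keep their defaults, unknown keys are an
#' error.
#'
#' @param path file path.
#' @return `readSimConfig` returns a [SimulationConfig-class];
#'   `writeSimConfig` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeSimConfig(simConfig(n_molecules = 20, domain_radius = 100,
#'                          n_steps = 100), f)
#' readSimConfig(f)
#' @export
readSimConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals) || !is.list(vals)) stop("config file is empty or malformed")
  unknown <- setdiff(names(vals), .config_fields())
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(simConfig, lapply(vals, as.numeric))
}

#' @rdname readSimConfig
#' @param config a [SimulationConfig-class].
#' @export
writeSimConfig <- function(config, path) {
  stopifnot(is(config, "SimulationConfig"))
  vals <- lapply(setNames(.config_fields(), .config_fields()),
                 function(s) slot(config, s))
  yaml::write_yaml(vals, path)
  invisible(path)
}

# internal: parameter list handed to the C++ engine; Dp is the per-particle
# diffusion coefficient in nm^2/ns (both particles share it)
.engine_params <- function(config, Dp = NULL) {
  if (is.null(Dp)) Dp <- particleDiffusion(config)
  list(r1 = config@r1, r2 = config@r2, Dp = Dp, dt = config@dt,
       km = config@k_m, krep = config@k_rep, kbond = config@bond_k,
       kwall = config@boundary_k, R = config@domain_radius,
       ioff = config@i_offset)
}

#' Per-particle diffusion coefficient implied by the target dimer mobility
#'
#' The dimer's in-plane center of mass moves with \eqn{(D_1 + D_2)/4}
#' for two particles of equal mobility, so the analytic choice
#' \eqn{D_p = 2 D_{eff}} makes an isolated dimer diffuse at `D_eff`.
#' Returned in nm\eqn{^2}/ns (0.2 \eqn{\mu m^2/s} = 2e-4 nm\eqn{^2}/ns).
#'
#' @param config a [SimulationConfig-class].
#' @return per-particle diffusion coefficient in nm^2/ns.
#' @seealso [calibrateParticleDiffusion()] for the simulation-refined value.
#' @export
particleDiffusion <- function(config) {
  2 * config@D_eff * 1e-3
}

#' Accessors for simulation objects
#'
#' `nMolecules` and `nFrames` report problem sizes; `trajTimes` returns the
#' frame times in ns; `getFrame` extracts one frame of a [Trajectory-class]
#' as a [SystemState-class]; `anchorPositions` returns the n x 3 anchor
#' coordinate matrix of a frame; `configOf` returns the generating
#' [SimulationConfig-class].
#'
#' @param x a [Trajectory-class] or [SystemState-class].
#' @param frame frame index (1-based).
#' @name accessors
NULL

#' @rdname accessors
#' @export
nMolecules <- function(x) {
  if (is(x, "Trajectory")) return(dim(x@pos1)[2])
  if (is(x, "SystemState")) return(nrow(x@pos1))
  stop("no molecules in a ", class(x))
}

#' @rdname accessors
#' @export
nFrames <- function(x) {
  stopifnot(is(x, "Trajectory"))
  dim(x@pos1)[3]
}

#' @rdname accessors
#' @export
trajTimes <- function(x) {
  stopifnot(is(x, "Trajectory"))
  x@times
}

#' @rdname accessors
#' @export
configOf <- function(x) {
  stopifnot(is(x, "Trajectory"))
  x@config
}

#' @rdname accessors
#' @export
getFrame <- function(x, frame) {
  stopifnot(is(x, "Trajectory"), frame >= 1, frame <= nFrames(x))
  new("SystemState", time = x@times[frame],
      pos1 = t(x@pos1[, , frame, drop = TRUE]),
      pos2 = t(x@pos2[, , frame, drop = TRUE]),
      mobile = x@mobile, labels = x@labels)
}

#' @rdname accessors
#' @export
anchorPositions <- function(x, frame = NULL) {
  if (is(x, "SystemState")) return(x@pos1)
  stopifnot(is(x, "Trajectory"))
  if (is.null(frame)) stop("frame required for a Trajectory")
  t(x@pos1[, , frame, drop = TRUE])
}
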