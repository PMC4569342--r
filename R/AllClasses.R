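#' Simulation configuration for the Syntaxin-1A dimer model
#'
#' Holds every model and integration parameter in simulation units
#' (nm, ns, \eqn{k_BT}). Defaults reproduce the reference setup: 500
#' molecules on a disk of 300 nm radius, anchor radius \eqn{r_1 = 3} nm,
#' head radius \eqn{r_2 = 3.3} nm, effective dimer diffusion
#' \eqn{D = 0.2\,\mu m^2/s}, membrane force constant
#' \eqn{k_m = 20\,k_BT/nm^2}, head repulsion \eqn{k_{rep} = 2\,k_BT/nm^2},
#' clustering interaction range offset 2.25 nm and a 5 ns timestep.
#'
#' @slot n_molecules number of Syntaxin-1A dimers.
#' @slot domain_radius radius of the disk-shaped membrane patch (nm).
#' @slot r1,r2 anchor and head particle radii (nm). The size ratio
#'   \code{r2/r1} limits the maximal cluster size; ratios at or below 1
#'   give unbounded growth (a warning is issued).
#' @slot D_eff target effective diffusion coefficient of an isolated dimer
#'   (\eqn{\mu m^2/s}).
#' @slot k_m membrane restraint force constant (\eqn{k_BT/nm^2}).
#' @slot k_rep head-head / head-anchor repulsion force constant
#'   (\eqn{k_BT/nm^2}).
#' @slot E_a well depth of the anchor-anchor clustering potential
#'   (\eqn{k_BT}); its core repulsion stiffness equals \code{E_a}.
#' @slot i_offset range offset of the clustering potential: the interaction
#'   radius is \code{2*r1 + i_offset} (nm).
#' @slot dt integration timestep (ns).
#' @slot n_steps number of integration steps per run.
#' @slot sample_stride steps between recorded frames.
#' @slot rng_seed integer seed; runs with equal seeds are bit-identical.
#' @slot boundary_k stiffness of the half-harmonic wall confining anchors
#'   to the disk (\eqn{k_BT/nm^2}).
#' @slot bond_k stiffness of the intramolecular anchor-head bond
#'   (\eqn{k_BT/nm^2}); rest length is \code{r1 + r2}.
#'
#' @seealso [simConfig()], [readSimConfig()]
#' @export
setClass("SimulationConfig",
  representation(
    n_molecules = "numeric",
    domain_radius = "numeric",
    r1 = "numeric",
    r2 = "numeric",
    D_eff = "numeric",
    k_m = "numeric",
    k_rep = "numeric",
    E_a = "numeric",
    i_offset = "numeric",
    dt = "numeric",
    n_steps = "numeric",
    sample_stride = "numeric",
    rng_seed = "numeric",
    boundary_k = "numeric",
    bond_k = "numeric"
  )
)

setValidity("SimulationConfig", function(object) {
  msgs <- character()
  scalar <- function(x) length(x) == 1L && is.finite(x)
  for (s in slotNames(object)) {
    if (!scalar(slot(object, s))) msgs <- c(msgs, paste0(s, " must be a finite scalar"))
  }
  if (length(msgs)) return(msgs)
  if (object@E_a < 0) msgs <- c(msgs, "E_a must be >= 0")
  if (object@dt <= 0) msgs <- c(msgs, "dt must be > 0")
  if (object@r1 <= 0 || object@r2 <= 0) msgs <- c(msgs, "particle radii must be > 0")
  if (object@domain_radius <= 10 * object@r2)
    msgs <- c(msgs, "domain_radius must exceed 10 * r2")
  if (object@n_molecules < 1) msgs <- c(msgs, "n_molecules must be >= 1")
  if (object@sample_stride < 1) msgs <- c(msgs, "sample_stride must be >= 1")
  if (object@n_steps < 0) msgs <- c(msgs, "n_steps must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Instantaneous state of the simulated membrane patch
#'
#' Per-molecule 3D coordinates of both particles of each Syntaxin-1A dimer,
#' plus mobility flags (static seed particles are immobile) and free-form
#' per-molecule tag sets (used e.g. for "bleached" and "seed" marks, which
#' never affect the dynamics).
#'
#' @slot time simulation time (ns).
#' @slot pos1 n x 3 matrix, anchor (particle 1) coordinates in nm.
#' @slot pos2 n x 3 matrix, head (particle 2) coordinates in nm.
#' @slot mobile logical vector of length n.
#' @slot labels list of character vectors, one tag set per molecule.
#' @export
setClass("SystemState",
  representation(
    time = "numeric",
    pos1 = "matrix",
    pos2 = "matrix",
    mobile = "logical",
    labels = "list"
  )
)

setValidity("SystemState", function(object) {
  n <- nrow(object@pos1)
  msgs <- character()
  if (ncol(object@pos1) != 3L || ncol(object@pos2) != 3L)
    msgs <- c(msgs, "pos1/pos2 must have 3 columns")
  if (nrow(object@pos2) != n || length(object@mobile) != n ||
      length(object@labels) != n)
    msgs <- c(msgs, "pos1, pos2, mobile and labels must have equal length")
  if (any(!is.finite(object@pos1)) || any(!is.finite(object@pos2)))
    msgs <- c(msgs, "coordinates must be finite")
  if (length(msgs)) msgs else TRUE
})

#' A sampled Brownian-dynamics trajectory
#'
#' Frames are stored as 3 x n x F arrays (coordinate, molecule, frame) for
#' anchors and heads separately. `energies` holds the total potential energy
#' of each sampled frame. `provenance` records the RNG seed actually used
#' and the package version.
#'
#' @slot config the [SimulationConfig-class] that produced the run.
#' @slot times frame times in ns, strictly increasing.
#' @slot pos1,pos2 3 x n x F coordinate arrays (nm).
#' @slot energies total potential energy per frame (\eqn{k_BT}).
#' @slot mobile,labels as in [SystemState-class].
#' @slot provenance named list (seed, package version, ...).
#' @export
setClass("Trajectory",
  representation(
    config = "SimulationConfig",
    times = "numeric",
    pos1 = "array",
    pos2 = "array",
    energies = "numeric",
    mobile = "logical",
    labels = "list",
    provenance = "list"
  )
)

setValidity("Trajectory", function(object) {
  msgs <- character()
  d1 <- dim(object@pos1)
  d2 <- dim(object@pos2)
  if (length(d1) != 3L || d1[1] != 3L) msgs <- c(msgs, "pos1 must be 3 x n x F")
  if (!identical(d1, d2)) msgs <- c(msgs, "pos1 and pos2 dims must match")
  if (length(object@times) != d1[3]) msgs <- c(msgs, "times must have one entry per frame")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    msgs <- c(msgs, "frame times must be strictly increasing")
  if (length(object@mobile) != d1[2]) msgs <- c(msgs, "mobile must have one entry per molecule")
  if (length(msgs)) msgs else TRUE
})

#' A single-channel STED-style intensity image
#'
#' A non-negative 2D intensity array with its pixel size (nm per pixel,
#' default 10), a channel tag (`"syntaxin"` or `"brp"`) and an optional
#' logical membrane mask on the same pixel grid.
#'
#' @slot intensity numeric matrix, arbitrary units, non-negative.
#' @slot pixel_size nm per pixel.
#' @slot channel `"syntaxin"` or `"brp"`.
#' @slot mask logical matrix of the same dimension, or a 0 x 0 matrix if
#'   no membrane mask is available.
#' @export
setClass("StedImage",
  representation(
    intensity = "matrix",
    pixel_size = "numeric",
    channel = "character",
    mask = "matrix"
  )
)

setValidity("StedImage", function(object) {
  msgs <- character()
  if (object@pixel_size <= 0) msgs <- c(msgs, "pixel_size must be > 0")
  if (any(object@intensity < 0)) msgs <- c(msgs, "intensities must be non-negative")
  if (!object@channel %in% c("syntaxin", "brp"))
    msgs <- c(msgs, "channel must be 'syntaxin' or 'brp'")
  if (length(object@mask) > 0 && !identical(dim(object@mask), dim(object@intensity)))
    msgs <- c(msgs, "mask must match the intensity dimensions")
  if (length(msgs)) msgs else TRUE
})

#' Active zones derived from Bruchpilot rings
#'
#' Bruchpilot spots grouped into ring structures define active zones: per
#' ring, a filled circular mask of radius (mean spot-to-centroid distance +
#' padding). `zone_px` assigns each pixel its active-zone id (0 = none).
#'
#' @slot rings data.frame with one row per accepted ring: `az`, `cx_px`,
#'   `cy_px` (ring center, 0-based pixel coordinates), `ring_radius_nm`,
#'   `mask_radius_nm`, `n_spots`, `fit_residual_nm`.
#' @slot members list of integer vectors: indices (into the BRP center
#'   table) of the spots forming each ring.
#' @slot zone_px integer matrix on the image grid; entry k > 0 marks pixels
#'   of active zone k.
#' @slot pad_nm padding added inside/outside the ring (nm).
#' @slot pixel_size nm per pixel.
#' @export
setClass("ActiveZoneSet",
  representation(
    rings = "data.frame",
    members = "list",
    zone_px = "matrix",
    pad_nm = "numeric",
    pixel_size = "numeric"
  )
)

setValidity("ActiveZoneSet", function(object) {
  if (nrow(object@rings) != length(object@members))
    return("rings and members must agree in length")
  TRUE
})

# ---- show methods ----------------------------------------------------------

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:",
      sprintf("%d molecules on a %.0f-nm disk", object@n_molecules,
              object@domain_radius), "\n")
  cat(sprintf("  r1 = %.2f nm, r2 = %.2f nm (ratio %.3f), E_a = %.2f kBT\n",
              object@r1, object@r2, object@r2 / object@r1, object@E_a))
  cat(sprintf("  D_eff = %.3f um2/s, dt = %g ns, n_steps = %g (stride %g)\n",
              object@D_eff, object@dt, object@n_steps, object@sample_stride))
  cat(sprintf("  k_m = %g, k_rep = %g, bond_k = %g, boundary_k = %g kBT/nm2, seed = %g\n",
              object@k_m, object@k_rep, object@bond_k, object@boundary_k,
              object@rng_seed))
})

setMethod("show", "SystemState", function(object) {
  cat(sprintf("SystemState: %d molecules at t = %g ns (%d immobile)\n",
              nrow(object@pos1), object@time, sum(!object@mobile)))
})

setMethod("show", "Trajectory", function(object) {
  d <- dim(object@pos1)
  cat(sprintf("Trajectory: %d molecules, %d frames, t = %g .. %g ns\n",
              d[2], d[3], object@times[1], object@times[d[3]]))
  cat(sprintf("  E_a = %g kBT on a %.0f-nm disk; seed %s\n",
              object@config@E_a, object@config@domain_radius,
              as.character(object@provenance$seed %||% NA)))
})

setMethod("show", "StedImage", function(object) {
  cat(sprintf("StedImage [%s]: %d x %d px at %g nm/px%s\n", object@channel,
              nrow(object@intensity), ncol(object@intensity),
              object@pixel_size,
              if (length(object@mask) > 0) ", with membrane mask" else ""))
})

setMethod("show", "ActiveZoneSet", function(object) {
  cat(sprintf("ActiveZoneSet: %d ring(s), pad %g nm\n", nrow(object@rings),
              object@pad_nm))
  if (nrow(object@rings) > 0) print(object@rings)
})

`%||%` <- function(a, b) if (is.null(a)) b else a
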