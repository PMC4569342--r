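#' Interaction potentials of the Syntaxin-1A dimer model
#'
#' Analytic energies and radial force magnitudes of the three potential
#' types, vectorized over distance. Units: nm in, \eqn{k_BT} and
#' \eqn{k_BT}/nm out. The returned `force` is the signed magnitude along
#' the separation direction: positive values push the particles apart.
#'
#' `membranePotential` restrains the anchor to the membrane plane:
#' \eqn{U(d) = \frac{1}{2} k_m d^2} with `d` the (signed) distance to the
#' plane; the force acts along the plane normal.
#'
#' `repulsionPotential` is the soft-core overlap penalty acting between
#' head-head and head-anchor pairs:
#' \eqn{U(d) = \frac{1}{2} k (d - r_{sum})^2} for \eqn{d < r_{sum}}, zero
#' otherwise.
#'
#' `attractionPotential` is the piecewise-harmonic clustering potential
#' between anchors, with well depth `E_a` reached at contact
#' (\eqn{d = r_{sum}}), an attractive branch out to the interaction radius
#' `i_radius`, and a harmonic core whose stiffness `k_core` defaults to
#' `E_a`:
#' \deqn{U(d) = \frac{1}{2} k_{core} (d - r)^2 - E_a \quad (d < r)}
#' \deqn{U(d) = \frac{2 E_a}{(i - r)^2} (d - r)^2 - E_a \quad (r \le d < \frac{i+r}{2})}
#' \deqn{U(d) = -\frac{2 E_a}{(i - r)^2} (d - i)^2 \quad (\frac{i+r}{2} \le d < i)}
#' and zero beyond. The potential is continuous with continuous first
#' derivative at all three branch boundaries.
#'
#' @param d distance (nm); any sign for `membranePotential`, non-negative
#'   otherwise.
#' @param k_m,k,k_core,E_a force constants (\eqn{k_BT/nm^2}) and well depth
#'   (\eqn{k_BT}).
#' @param r_sum sum of the two particle radii (nm).
#' @param i_radius interaction radius (nm), must exceed `r_sum`.
#' @return A list with numeric vectors `energy` and `force`.
#' @examples
#' membranePotential(1, k_m = 20)$energy   # 10 kBT
#' attractionPotential(6, r_sum = 6, i_radius = 8.25, E_a = 4)$energy # -4
#' @export
membranePotential <- function(d, k_m = 20) {
  stopifnot(k_m > 0)
  list(energy = 0.5 * k_m * d^2, force = -k_m * d)
}

#' @rdname membranePotential
#' @export
repulsionPotential <- function(d, r_sum, k = 2) {
  stopifnot(r_sum > 0)
  if (any(d < 0)) stop("distances must be non-negative")
  inside <- d < r_sum
  e <- ifelse(inside, 0.5 * k * (d - r_sum)^2, 0)
  f <- ifelse(inside, -k * (d - r_sum), 0)
  list(energy = e, force = f)
}

#' @rdname membranePotential
#' @export
attractionPotential <- function(d, r_sum, i_radius, E_a, k_core = E_a) {
  if (i_radius <= r_sum) stop("i_radius must exceed r_sum")
  stopifnot(E_a >= 0)
  if (any(d < 0)) stop("distances must be non-negative")
  r <- r_sum; i <- i_radius
  mid <- (i + r) / 2
  cc <- 2 * E_a / (i - r)^2
  e <- numeric(length(d)); f <- numeric(length(d))
  b1 <- d < r
  e[b1] <- 0.5 * k_core * (d[b1] - r)^2 - E_a
  f[b1] <- -k_core * (d[b1] - r)
  b2 <- d >= r & d < mid
  e[b2] <- cc * (d[b2] - r)^2 - E_a
  f[b2] <- -2 * cc * (d[b2] - r)
  b3 <- d >= mid & d < i
  e[b3] <- -cc * (d[b3] - i)^2
  f[b3] <- 2 * cc * (d[b3] - i)
  list(energy = e, force = f)
}

#' Total energy and per-particle forces of a configuration
#'
#' Assembles all model potentials over a [SystemState-class]: anchor-anchor
#' clustering attraction, head-head and head-anchor repulsion between
#' different molecules, the intramolecular anchor-head bond, the membrane
#' restraint on anchors, and the disk wall. Forces are the exact negative
#' gradients of the summed potential energy.
#'
#' @param state a [SystemState-class].
#' @param config a [SimulationConfig-class].
#' @return list with `energy` (scalar, \eqn{k_BT}) and n x 3 force matrices
#'   `f1` (anchors) and `f2` (heads), in \eqn{k_BT}/nm.
#' @export
pairEnergyForces <- function(state, config) {
  stopifnot(is(state, "SystemState"), is(config, "SimulationConfig"))
  if (any(!is.finite(state@pos1)) || any(!is.finite(state@pos2)))
    stop("non-finite coordinates")
  .cpp_forces(state@pos1, state@pos2, .molecule_ea(state, config),
              .engine_params(config))
}

# per-molecule well depths: seed-tagged molecules interact with 8 kBT
.molecule_ea <- function(state, config, seed_ea = 8) {
  ea <- rep(config@E_a, nrow(state@pos1))
  is_seed <- vapply(state@labels, function(l) "seed" %in% l, logical(1))
  ea[is_seed] <- seed_ea
  ea
}
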