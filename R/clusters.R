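# Cluster identification and equilibrium cluster statistics.
#
# A cluster is a set of molecules whose anchors form a connected component
# of the proximity graph: two anchors are linked when their centers are at
# most 1 nm beyond contact, i.e. within 2*r1 + 1 nm.

.cluster_cutoff <- function(config) 2 * config@r1 + 1

#' Identify clusters by anchor proximity
#'
#' Connected components of the anchor-proximity graph (centers within
#' `cutoff`, transitively closed so chains merge). For a
#' [SystemState-class] the result is an integer label vector; for a
#' [Trajectory-class] an n x F label matrix (labels are per-frame, numbered
#' in order of first member).
#'
#' @param x a [SystemState-class] or [Trajectory-class].
#' @param cutoff proximity cutoff in nm; defaults to `2*r1 + 1` of the
#'   associated config (7 nm for the standard radii). Required for a bare
#'   [SystemState-class].
#' @return integer vector (state) or matrix (trajectory) of cluster labels.
#' @examples
#' cfg <- simConfig(n_molecules = 3, domain_radius = 100, n_steps = 0)
#' st <- initRandom(cfg)
#' identifyClusters(st, cutoff = 7)
#' @export
identifyClusters <- function(x, cutoff = NULL) {
  if (is(x, "Trajectory")) {
    if (is.null(cutoff)) cutoff <- .cluster_cutoff(x@config)
    return(.cpp_cluster_frames(x@pos1, cutoff))
  }
  stopifnot(is(x, "SystemState"))
  if (is.null(cutoff)) stop("cutoff required for a bare SystemState")
  arr <- array(t(x@pos1), dim = c(3, nrow(x@pos1), 1))
  as.vector(.cpp_cluster_frames(arr, cutoff))
}

#' Effective diameter of a simulated cluster
#'
#' Maps a member count to the diameter of the circle whose area equals the
#' summed anchor cross sections divided by the in-cluster packing fraction:
#' \eqn{d = 2 \sqrt{N \pi r_1^2 / (\pi \phi)} = 2 r_1 \sqrt{N/\phi}}.
#' The default packing fraction 0.65 is calibrated once from converged
#' large clusters (see [measurePackingFraction()]); with it, the mapping
#' reproduces the observed 120-140 nm ceiling for several hundred members
#' at a size ratio of 1.1 and the 40-45 nm ceiling at ratio 1.5.
#'
#' @param n member count(s).
#' @param r1 anchor radius (nm).
#' @param packing in-cluster area packing fraction.
#' @return effective diameter(s) in nm, monotone in `n`.
#' @export
effectiveDiameter <- function(n, r1 = 3.0, packing = 0.65) {
  2 * r1 * sqrt(n / packing)
}

#' Measure the anchor packing fraction of identified clusters
#'
#' For each cluster with at least `min_size` members, the packing fraction
#' is the summed anchor cross-section area divided by the area of the
#' convex hull of the anchor centers dilated by `r1`. Used once to
#' calibrate the count-to-diameter mapping of [effectiveDiameter()].
#'
#' @param state a [SystemState-class].
#' @param cutoff proximity cutoff (nm).
#' @param r1 anchor radius (nm).
#' @param min_size smallest cluster used.
#' @return named numeric vector of per-cluster packing fractions (possibly
#'   empty).
#' @export
measurePackingFraction <- function(state, cutoff = 7, r1 = 3.0,
                                   min_size = 20) {
  labs <- identifyClusters(state, cutoff = cutoff)
  sizes <- table(labs)
  big <- as.integer(names(sizes)[sizes >= min_size])
  out <- numeric(0)
  for (cl in big) {
    xy <- state@pos1[labs == cl, 1:2, drop = FALSE]
    h <- grDevices::chull(xy)
    hx <- xy[h, 1]; hy <- xy[h, 2]
    a_hull <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
    per <- sum(sqrt(diff(c(hx, hx[1]))^2 + diff(c(hy, hy[1]))^2))
    a_dil <- a_hull + per * r1 + pi * r1^2
    out <- c(out, setNames(nrow(xy) * pi * r1^2 / a_dil, cl))
  }
  out
}

#' Per-frame cluster table
#'
#' One row per cluster per frame: member count, in-plane centroid and
#' effective diameter.
#'
#' @param traj a [Trajectory-class].
#' @param cutoff proximity cutoff (nm), defaulting to `2*r1 + 1`.
#' @param burnin fraction of initial frames excluded (default 0: keep all;
#'   equilibrium statistics conventionally use 0.25).
#' @param packing packing fraction for [effectiveDiameter()].
#' @return data.frame with columns `frame`, `time_ns`, `cluster`, `size`,
#'   `cx`, `cy`, `diameter_nm`.
#' @export
clusterTable <- function(traj, cutoff = NULL, burnin = 0, packing = 0.65) {
  labs <- identifyClusters(traj, cutoff = cutoff)
  keep <- .frames_after_burnin(ncol(labs), burnin)
  out <- vector("list", length(keep))
  for (q in seq_along(keep)) {
    f <- keep[q]
    l <- labs[, f]
    sizes <- tabulate(l)
    cls <- which(sizes > 0)
    cx <- vapply(cls, function(c) mean(traj@pos1[1, l == c, f]), 0)
    cy <- vapply(cls, function(c) mean(traj@pos1[2, l == c, f]), 0)
    out[[q]] <- data.frame(frame = f, time_ns = traj@times[f], cluster = cls,
                           size = sizes[cls], cx = cx, cy = cy,
                           diameter_nm = effectiveDiameter(sizes[cls],
                                                           traj@config@r1,
                                                           packing))
  }
  do.call(rbind, out)
}

.frames_after_burnin <- function(nf, burnin) {
  first <- min(nf, floor(nf * burnin) + 1)
  first:nf
}

#' Time-averaged cluster size distribution
#'
#' Averages the per-frame distribution of cluster sizes over the frames
#' after a burn-in fraction. In `by = "count"` mode the support is the
#' member count; `by = "diameter"` bins the effective diameters.
#'
#' @param traj a [Trajectory-class].
#' @param by `"count"` or `"diameter"`.
#' @param burnin fraction of initial frames excluded (default 0.25).
#' @param cutoff proximity cutoff (nm).
#' @param breaks diameter bin breaks in nm (diameter mode).
#' @param packing packing fraction for the diameter mapping.
#' @return data.frame with the support (`size` or `diameter_nm` bin
#'   midpoints), `mean_count` (average clusters per frame) and `prob`
#'   (normalized frequency).
#' @export
clusterSizeDistribution <- function(traj, by = c("count", "diameter"),
                                    burnin = 0.25, cutoff = NULL,
                                    breaks = seq(0, 200, by = 10),
                                    packing = 0.65) {
  by <- match.arg(by)
  labs <- identifyClusters(traj, cutoff = cutoff)
  keep <- .frames_after_burnin(ncol(labs), burnin)
  n <- nrow(labs)
  if (by == "count") {
    acc <- numeric(n)
    for (f in keep) {
      sizes <- tabulate(labs[, f], nbins = n)
      counts <- tabulate(sizes[sizes > 0], nbins = n)
      acc <- acc + counts
    }
    acc <- acc / length(keep)
    sup <- which(acc > 0)
    return(data.frame(size = sup, mean_count = acc[sup],
                      prob = acc[sup] / sum(acc)))
  }
  mids <- (head(breaks, -1) + tail(breaks, -1)) / 2
  acc <- numeric(length(mids))
  for (f in keep) {
    sizes <- tabulate(labs[, f])
    d <- effectiveDiameter(sizes[sizes > 0], traj@config@r1, packing)
    h <- hist(pmin(d, max(breaks) - 1e-9), breaks = breaks, plot = FALSE)
    acc <- acc + h$counts
  }
  acc <- acc / length(keep)
  data.frame(diameter_nm = mids, mean_count = acc,
             prob = if (sum(acc) > 0) acc / sum(acc) else acc)
}

#' Mean cluster size and single-molecule fraction
#'
#' Both statistics are computed per frame (mean member count over clusters,
#' and the fraction of molecules that are singletons) and then averaged
#' over the frames after burn-in.
#'
#' @inheritParams clusterSizeDistribution
#' @return list with `mean_size`, `single_fraction`, and a `per_frame`
#'   data.frame (`frame`, `time_ns`, `mean_size`, `single_fraction`).
#' @export
clusteringSummary <- function(traj, burnin = 0.25, cutoff = NULL) {
  labs <- identifyClusters(traj, cutoff = cutoff)
  keep <- .frames_after_burnin(ncol(labs), burnin)
  n <- nrow(labs)
  ms <- sf <- numeric(length(keep))
  for (q in seq_along(keep)) {
    sizes <- tabulate(labs[, keep[q]])
    sizes <- sizes[sizes > 0]
    ms[q] <- mean(sizes)
    sf[q] <- sum(sizes == 1) / n
  }
  list(mean_size = mean(ms), single_fraction = mean(sf),
       per_frame = data.frame(frame = keep, time_ns = traj@times[keep],
                              mean_size = ms, single_fraction = sf))
}

#' Convergence check for equilibrium cluster statistics
#'
#' A run is considered converged when the mean cluster size averaged over
#' two consecutive halves of the trajectory differs by less than `tol`
#' (relative).
#'
#' @param traj a [Trajectory-class].
#' @param tol relative tolerance (default 0.05).
#' @param cutoff proximity cutoff (nm).
#' @return logical, with attribute `halves` holding the two means.
#' @export
isConverged <- function(traj, tol = 0.05, cutoff = NULL) {
  labs <- identifyClusters(traj, cutoff = cutoff)
  nf <- ncol(labs)
  half <- function(fr) {
    mean(vapply(fr, function(f) {
      s <- tabulate(labs[, f]); mean(s[s > 0])
    }, 0))
  }
  m1 <- half(seq_len(floor(nf / 2)))
  m2 <- half((floor(nf / 2) + 1):nf)
  structure(abs(m2 - m1) <= tol * max(m1, m2), halves = c(m1, m2))
}
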