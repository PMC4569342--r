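# Mobility and exchange kinetics of molecules and clusters.

#' Diffusion coefficient from the mean-squared displacement
#'
#' Fits a straight line to the in-plane anchor MSD over the requested lag
#' window, pooled over the selected molecules, and converts the slope to a
#' diffusion coefficient via \eqn{MSD = 4 D t}. Longer lags are noisier, so
#' the fit weights each lag by \eqn{1/lag^2} (proportional to the inverse
#' variance of an MSD estimate from overlapping windows).
#'
#' @param traj a [Trajectory-class].
#' @param lag_range_us lag window in \eqn{\mu s} (default 10-100).
#' @param molecules molecule indices to pool (default: all mobile).
#' @return diffusion coefficient in \eqn{\mu m^2/s}.
#' @export
msdDiffusion <- function(traj, lag_range_us = c(10, 100), molecules = NULL) {
  if (is.null(molecules)) molecules <- which(traj@mobile)
  dt_frame <- diff(traj@times[1:2])  # ns
  lags <- seq_len(nFrames(traj) - 1)
  lag_ns <- lags * dt_frame
  keep <- lag_ns >= lag_range_us[1] * 1e3 & lag_ns <= lag_range_us[2] * 1e3
  if (!any(keep))
    stop("no frame lags inside the requested window; adjust sample_stride")
  lags <- lags[keep]
  x <- traj@pos1[1, molecules, , drop = FALSE]
  y <- traj@pos1[2, molecules, , drop = FALSE]
  F <- nFrames(traj)
  msd <- vapply(lags, function(L) {
    dx <- x[, , (1 + L):F, drop = FALSE] - x[, , 1:(F - L), drop = FALSE]
    dy <- y[, , (1 + L):F, drop = FALSE] - y[, , 1:(F - L), drop = FALSE]
    mean(dx^2 + dy^2)
  }, 0)
  t_ns <- lags * dt_frame
  fit <- lm(msd ~ t_ns, weights = 1 / lags^2)
  D_nm2_ns <- unname(coef(fit)[2]) / 4
  D_nm2_ns * 1e3  # nm^2/ns -> um^2/s
}

#' Cluster diffusion coefficient by size
#'
#' Tracks centroids of clusters whose membership is unchanged between
#' consecutive frames and converts their squared centroid displacements to
#' a diffusion coefficient per size bin (\eqn{D = \langle \Delta r^2
#' \rangle / 4 \Delta t}). Intervals in which any molecule joins or leaves
#' are discarded, so the estimate is not contaminated by exchange events.
#'
#' @param traj a [Trajectory-class].
#' @param size_bins integer break points; bin i collects sizes in
#'   `[size_bins[i], size_bins[i+1])`.
#' @param cutoff proximity cutoff (nm).
#' @param min_obs bins with fewer observations are reported as `NA`.
#' @return data.frame with `size_lo`, `size_hi`, `mean_size`, `n_obs`,
#'   `D_um2_s`.
#' @export
clusterDiffusion <- function(traj, size_bins = c(1, 2, 3, 5, 9, 17, 33, 65),
                             cutoff = NULL, min_obs = 10) {
  labs <- identifyClusters(traj, cutoff = cutoff)
  F <- ncol(labs)
  dt_ms <- diff(traj@times[1:2]) * 1e-6
  nb <- length(size_bins)
  bins_hi <- c(size_bins[-1], Inf)
  sq <- vector("list", nb)
  szs <- vector("list", nb)
  for (f in seq_len(F - 1)) {
    l0 <- labs[, f]; l1 <- labs[, f + 1]
    sizes0 <- tabulate(l0)
    for (cl in which(sizes0 > 0)) {
      mem <- which(l0 == cl)
      cl1 <- l1[mem[1]]
      mem1 <- which(l1 == cl1)
      if (length(mem) != length(mem1) || !all(mem == mem1)) next
      b <- findInterval(length(mem), size_bins)
      if (b < 1 || b > nb) next
      dx <- mean(traj@pos1[1, mem, f + 1]) - mean(traj@pos1[1, mem, f])
      dy <- mean(traj@pos1[2, mem, f + 1]) - mean(traj@pos1[2, mem, f])
      sq[[b]] <- c(sq[[b]], dx^2 + dy^2)
      szs[[b]] <- c(szs[[b]], length(mem))
    }
  }
  n_obs <- vapply(sq, length, 0L)
  D <- vapply(seq_len(nb), function(b) {
    if (n_obs[b] < min_obs) return(NA_real_)
    mean(sq[[b]]) / (4 * dt_ms * 1e6) * 1e3  # nm^2/ns -> um^2/s
  }, 0)
  data.frame(size_lo = size_bins, size_hi = bins_hi,
             mean_size = vapply(szs, function(s)
               if (length(s)) mean(s) else NA_real_, 0),
             n_obs = n_obs, D_um2_s = D)
}

#' Single-molecule step lengths at a fixed lag
#'
#' In-plane displacement magnitudes of every mobile molecule over the
#' stated lag, pooled across the trajectory. For pure free diffusion the
#' lengths are Rayleigh distributed with scale \eqn{\sqrt{2 D t}}.
#'
#' @param traj a [Trajectory-class].
#' @param lag_us lag in \eqn{\mu s} (default 200); must be a multiple of
#'   the frame spacing. A zero lag returns all-zero lengths.
#' @param burnin fraction of initial frames excluded.
#' @return numeric vector of step lengths (nm) with attribute `lag_us`.
#' @export
stepLengths <- function(traj, lag_us = 200, burnin = 0) {
  dt_frame_us <- diff(traj@times[1:2]) * 1e-3
  if (lag_us == 0) {
    n <- sum(traj@mobile) * nFrames(traj)
    return(structure(numeric(n), lag_us = 0))
  }
  L <- lag_us / dt_frame_us
  if (abs(L - round(L)) > 1e-9)
    stop("lag (", lag_us, " us) is not a multiple of the frame spacing (",
         dt_frame_us, " us)")
  L <- as.integer(round(L))
  F <- nFrames(traj)
  if (L >= F) stop("lag exceeds the trajectory length")
  keep <- .frames_after_burnin(F, burnin)
  keep <- keep[keep <= F - L]
  mob <- which(traj@mobile)
  dx <- traj@pos1[1, mob, keep + L, drop = FALSE] -
    traj@pos1[1, mob, keep, drop = FALSE]
  dy <- traj@pos1[2, mob, keep + L, drop = FALSE] -
    traj@pos1[2, mob, keep, drop = FALSE]
  structure(as.vector(sqrt(dx^2 + dy^2)), lag_us = lag_us)
}

#' Dissociation rates and residence times
#'
#' A molecule dissociates between frames t and t+1 when it belongs to a
#' cluster (size >= 2) at t and at t+1 is in no cluster sharing another
#' member with its former cluster; the event is only counted if the
#' molecule stays detached from the former cluster's members for at least
#' `debounce` consecutive frames (suppresses boundary flicker). Rates are
#' events per particle per ms, binned by the source-cluster size and,
#' separately, by the molecule's anchor neighbor count (anchors within the
#' clustering interaction radius). Residence times are contiguous
#' cluster-membership durations, right-censored at the trajectory ends.
#'
#' @param traj a [Trajectory-class].
#' @param cutoff proximity cutoff (nm).
#' @param debounce frames a molecule must stay detached (default 2).
#' @param size_bins breaks for the source-cluster size.
#' @param burnin fraction of initial frames excluded.
#' @return list with data.frames `by_size` (`size_lo`, `size_hi`,
#'   `events`, `particle_ms`, `rate_per_ms`), `by_neighbors` (`neighbors`,
#'   `events`, `particle_ms`, `rate_per_ms`), and `residence`
#'   (`molecule`, `start_frame`, `frames`, `duration_ms`, `censored`).
#' @export
dissociationAndResidence <- function(traj, cutoff = NULL, debounce = 2,
                                     size_bins = c(2, 3, 5, 9, 17, 33, 65),
                                     burnin = 0) {
  labs <- identifyClusters(traj, cutoff = cutoff)
  F <- ncol(labs)
  n <- nrow(labs)
  keep <- .frames_after_burnin(F, burnin)
  dt_ms <- diff(traj@times[1:2]) * 1e-6
  irad <- 2 * traj@config@r1 + traj@config@i_offset
  nbrs <- .cpp_neighbor_counts(traj@pos1, irad)

  sizes_per_frame <- matrix(0L, n, F)  # size of the molecule's cluster
  for (f in seq_len(F)) {
    s <- tabulate(labs[, f])
    sizes_per_frame[, f] <- s[labs[, f]]
  }
  clustered <- sizes_per_frame >= 2

  # stay[m, f]: between frames f and f+1 the molecule remains attached,
  # i.e. it is clustered at f+1 and its new cluster shares at least one
  # other member with its cluster at f. Molecules that move together show
  # up as >= 2 occurrences of the same (old label, new label) transition.
  stay <- matrix(FALSE, n, F - 1)
  for (f in seq_len(F - 1)) {
    key <- paste(labs[, f], labs[, f + 1])
    cnt <- table(key)
    stay[, f] <- clustered[, f] & clustered[, f + 1] &
      as.vector(cnt[key]) >= 2
  }

  # detached for the full debounce window: not attached (by the shared-
  # member rule) to any former-cluster member at frames f+1 .. f+debounce
  detached_after <- function(m, f, mem_old) {
    if (f + debounce > F) return(FALSE)  # window not observable
    for (g in (f + 1):(f + debounce)) {
      if (clustered[m, g]) {
        mates <- which(labs[, g] == labs[m, g])
        if (any(mates %in% mem_old & mates != m)) return(FALSE)
      }
    }
    TRUE
  }

  nb_size <- length(size_bins)
  ev_size <- numeric(nb_size)
  occ_size <- numeric(nb_size)
  max_nb <- max(nbrs) + 1L
  ev_nb <- numeric(max_nb + 1L)   # index = neighbors + 1
  occ_nb <- numeric(max_nb + 1L)

  frames_tr <- keep[keep < F]
  for (f in frames_tr) {
    l0 <- labs[, f]
    in_cl <- which(clustered[, f])
    if (!length(in_cl)) next
    sz <- sizes_per_frame[in_cl, f]
    b <- findInterval(sz, size_bins)
    valid <- b >= 1 & b <= nb_size
    for (q in which(valid)) occ_size[b[q]] <- occ_size[b[q]] + dt_ms
    nbv <- nbrs[in_cl, f] + 1L
    for (q in seq_along(in_cl)) occ_nb[nbv[q]] <- occ_nb[nbv[q]] + dt_ms
    cand <- in_cl[!stay[in_cl, f]]
    for (m in cand) {
      mem_old <- which(l0 == l0[m])
      if (detached_after(m, f, mem_old)) {
        q <- match(m, in_cl)
        if (valid[q]) ev_size[b[q]] <- ev_size[b[q]] + 1
        ev_nb[nbv[q]] <- ev_nb[nbv[q]] + 1
      }
    }
  }

  by_size <- data.frame(size_lo = size_bins,
                        size_hi = c(size_bins[-1], Inf),
                        events = ev_size, particle_ms = occ_size,
                        rate_per_ms = ifelse(occ_size > 0,
                                             ev_size / occ_size, NA))
  nb_seq <- seq_len(max_nb + 1L) - 1L
  by_nb <- data.frame(neighbors = nb_seq, events = ev_nb,
                      particle_ms = occ_nb,
                      rate_per_ms = ifelse(occ_nb > 0, ev_nb / occ_nb, NA))
  by_nb <- by_nb[by_nb$particle_ms > 0, ]

  # residence: contiguous membership spells; continuity between frames is
  # the same shared-member rule as above (stay matrix)
  res <- list()
  for (m in seq_len(n)) {
    f <- 1L
    while (f <= F) {
      if (!clustered[m, f]) { f <- f + 1L; next }
      start <- f
      while (f < F && stay[m, f]) f <- f + 1L
      res[[length(res) + 1L]] <-
        c(m, start, f - start + 1L, start == 1L || f == F)
      f <- f + 1L
    }
  }
  residence <- if (length(res)) {
    rr <- do.call(rbind, res)
    data.frame(molecule = rr[, 1], start_frame = rr[, 2], frames = rr[, 3],
               duration_ms = rr[, 3] * dt_ms, censored = rr[, 4] == 1)
  } else {
    data.frame(molecule = integer(), start_frame = integer(),
               frames = integer(), duration_ms = numeric(),
               censored = logical())
  }
  list(by_size = by_size, by_neighbors = by_nb, residence = residence)
}
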