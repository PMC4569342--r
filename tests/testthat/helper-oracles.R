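# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# central finite difference of a scalar function
fd_derivative <- function(f, x, eps = 1e-5) {
  (f(x + eps) - f(x - eps)) / (2 * eps)
}

# finite-difference gradient of a configuration energy with respect to all
# particle coordinates; energy_fn(pos1, pos2) -> scalar
fd_config_gradient <- function(energy_fn, pos1, pos2, eps = 1e-5) {
  g1 <- pos1 * 0
  g2 <- pos2 * 0
  for (i in seq_len(nrow(pos1))) {
    for (k in 1:3) {
      pp <- pos1; pp[i, k] <- pp[i, k] + eps
      pm <- pos1; pm[i, k] <- pm[i, k] - eps
      g1[i, k] <- (energy_fn(pp, pos2) - energy_fn(pm, pos2)) / (2 * eps)
      pp <- pos2; pp[i, k] <- pp[i, k] + eps
      pm <- pos2; pm[i, k] <- pm[i, k] - eps
      g2[i, k] <- (energy_fn(pos1, pp) - energy_fn(pos1, pm)) / (2 * eps)
    }
  }
  list(g1 = g1, g2 = g2)
}

# brute-force O(n^2) union-find on anchor positions: returns the canonical
# partition (list of sorted member vectors, ordered by smallest member)
brute_partition <- function(pos, cutoff) {
  n <- nrow(pos)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      if (sqrt(sum((pos[i, ] - pos[j, ])^2)) < cutoff) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  canonical_partition(roots)
}

canonical_partition <- function(labels) {
  groups <- split(seq_along(labels), labels)
  groups <- lapply(groups, function(g) sort(as.integer(g)))
  unname(groups[order(vapply(groups, min, 0L))])
}

# FRAP recovery for pure diffusion in a closed disk (Neumann boundary):
# fluorophore concentration starts at 0 inside the bleach disc (radius a)
# and c0 outside; Bessel-series solution evaluated as the fluorescent
# fraction inside the disc normalized to the pre-bleach content.
frap_disk_theory <- function(t_s, R_nm, a_nm, D_um2_s, n_terms = 80) {
  D <- D_um2_s * 1e6        # nm^2/s
  R <- R_nm; a <- a_nm
  lam <- j1_zeros(n_terms)
  cbar <- (R^2 - a^2) / R^2  # relative to c0
  # A_k for c(r,0)/c0 = 1{r>a}
  Ak <- -(2 * a / (lam * R)) * besselJ(lam * a / R, 1) /
    besselJ(lam, 0)^2
  sapply(t_s, function(tt) {
    decay <- exp(-D * lam^2 * tt / R^2)
    inner <- 2 * pi * sum(Ak * decay * (a * R / lam) *
                            besselJ(lam * a / R, 1))
    (cbar * pi * a^2 + inner) / (pi * a^2)
  })
}

# positive zeros of J1 by sign-change bracketing
j1_zeros <- function(n) {
  xs <- seq(0.5, 4 * n + 10, by = 0.1)
  v <- besselJ(xs, 1)
  idx <- which(v[-1] * v[-length(v)] < 0)
  roots <- vapply(idx, function(i)
    uniroot(function(x) besselJ(x, 1), c(xs[i], xs[i + 1]),
            tol = 1e-12)$root, 0)
  roots[seq_len(n)]
}

# brute-force windowed local-maximum scan (reference for detectMaxima)
brute_maxima <- function(img, window, min_intensity) {
  rad <- window %/% 2
  nr <- nrow(img); nc <- ncol(img)
  hits <- NULL
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      v <- img[r, c]
      if (!(v > min_intensity)) next
      ismax <- TRUE; strict <- FALSE
      for (dr in -rad:rad) {
        for (dc in -rad:rad) {
          if (dr == 0 && dc == 0) next
          if (dr^2 + dc^2 > rad^2 + 1e-9) next
          rr <- r + dr; cc <- c + dc
          if (rr < 1 || cc < 1 || rr > nr || cc > nc) next
          if (img[rr, cc] > v) { ismax <- FALSE; break }
          if (img[rr, cc] < v) strict <- TRUE
        }
        if (!ismax) break
      }
      if (ismax && strict) hits <- rbind(hits, c(r - 1L, c - 1L))
    }
  }
  hits
}
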