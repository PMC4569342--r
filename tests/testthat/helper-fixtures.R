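# Small fixtures built in code.

tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_molecules = 10, domain_radius = 80, E_a = 4,
                   n_steps = 1000, sample_stride = 100, rng_seed = 1)
  defaults[names(args)] <- args
  do.call(simConfig, defaults)
}

# a bare state from explicit anchor positions (heads at rest length above)
state_from_anchors <- function(pos1, r1 = 3, r2 = 3.3) {
  n <- nrow(pos1)
  pos2 <- pos1
  pos2[, 3] <- pos2[, 3] + r1 + r2
  new("SystemState", time = 0, pos1 = pos1, pos2 = pos2,
      mobile = rep(TRUE, n), labels = rep(list(character()), n))
}

# random anchors on a disk with a minimal separation (rejection sampling)
random_anchors <- function(n, R, min_sep = 0) {
  pos <- matrix(0, n, 3)
  placed <- 0
  while (placed < n) {
    r <- R * sqrt(runif(1)); th <- runif(1, 0, 2 * pi)
    p <- c(r * cos(th), r * sin(th), 0)
    if (placed == 0 || min_sep == 0 ||
        min(sqrt(rowSums(sweep(pos[1:placed, , drop = FALSE], 2, p)^2))) >=
          min_sep) {
      placed <- placed + 1
      pos[placed, ] <- p
    }
  }
  pos
}

# single rendered spot as a StedImage (no noise)
single_spot_image <- function(fwhm, profile = "gaussian", n = 301,
                              peak = 150, bg = 0, ps = 10,
                              center_nm = ((n - 1) / 2) * ps) {
  img <- matrix(bg, n, n)
  img <- SyxDynamics:::.render_spot(img, ps, center_nm, center_nm, peak,
                                    fwhm, profile)
  stedImage(img, ps, "syntaxin")
}
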