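# Synthetic ground-truth generators: STED-like two-channel images and
# reference trajectories. Every rendered object is recorded in a ground
# truth table, so recovery by the analysis pipeline can be scored exactly.

#' Specification of a synthetic two-channel STED image
#'
#' Defaults emulate post-deconvolution two-color STED data of a Drosophila
#' NMJ bouton membrane: Bruchpilot rings of ~230 nm diameter built from 5
#' discrete spots of 25 nm FWHM (the deconvolution PSF scale), and
#' Syntaxin-1A clusters rendered as isotropic Lorentzian intensity
#' profiles whose FWHM diameters are drawn from truncated normal
#' distributions -- mean 80 nm inside active zones versus 64 nm outside,
#' SD 15 nm, truncated above 20 nm. Placement margins keep the AZ/outside
#' ground truth unambiguous: AZ clusters stay `margin_nm` inside the AZ
#' mask edge, outside clusters at least `margin_nm` beyond it.
#'
#' @param size_px image side length in pixels.
#' @param pixel_size nm per pixel (default 10).
#' @param n_az number of Bruchpilot rings (active zones).
#' @param ring_diameter_nm BRP ring diameter (default 230).
#' @param spots_per_ring discrete BRP spots per ring (default 5).
#' @param spot_fwhm_nm BRP spot FWHM (default 25).
#' @param n_syx_az,n_syx_out Syntaxin-1A cluster counts in the two groups.
#' @param mean_az,mean_out,sd_diam,min_diam diameter distribution (nm).
#' @param peak_range Syntaxin peak intensity range (a.u.).
#' @param brp_peak_range BRP peak intensity range (a.u.).
#' @param background constant background level (a.u.).
#' @param read_noise_sd Gaussian read noise SD (a.u.); Poisson shot noise
#'   is always applied first.
#' @param photons_per_au photon gain of the shot-noise model: intensities
#'   are Poisson-sampled at `I * photons_per_au` counts and rescaled, so
#'   larger values give the smoother texture of post-deconvolution data
#'   (relative shot noise \eqn{1/\sqrt{I \cdot gain}}).
#' @param profile `"gaussian"` (default; deconvolved spots are compact,
#'   and Gaussian profiles keep neighboring half-max areas independent) or
#'   `"lorentzian"` (the raw deconvolution PSF family; its wings inflate
#'   FWHM estimates of nearby clusters).
#' @param pad_nm active-zone mask padding used for placement (default 25).
#' @param margin_nm classification safety margin (default 15).
#' @param min_sep_nm minimal center separation of syntaxin clusters
#'   (default 130, keeping half-max areas and detection windows disjoint).
#' @return A validated list of class `"ImageSpec"`.
#' @export
imageSpec <- function(size_px = 1500, pixel_size = 10, n_az = 7,
                      ring_diameter_nm = 230, spots_per_ring = 5,
                      spot_fwhm_nm = 25, n_syx_az = 28, n_syx_out = 60,
                      mean_az = 80, mean_out = 64, sd_diam = 15,
                      min_diam = 20, peak_range = c(100, 200),
                      brp_peak_range = c(150, 250), background = 5,
                      read_noise_sd = 2, photons_per_au = 4,
                      profile = c("gaussian", "lorentzian"),
                      pad_nm = 25, margin_nm = 15, min_sep_nm = 130) {
  spec <- list(size_px = size_px, pixel_size = pixel_size, n_az = n_az,
               ring_diameter_nm = ring_diameter_nm,
               spots_per_ring = spots_per_ring,
               spot_fwhm_nm = spot_fwhm_nm, n_syx_az = n_syx_az,
               n_syx_out = n_syx_out, mean_az = mean_az,
               mean_out = mean_out, sd_diam = sd_diam, min_diam = min_diam,
               peak_range = peak_range, brp_peak_range = brp_peak_range,
               background = background, read_noise_sd = read_noise_sd,
               photons_per_au = photons_per_au,
               profile = match.arg(profile), pad_nm = pad_nm,
               margin_nm = margin_nm, min_sep_nm = min_sep_nm)
  stopifnot(size_px > 50, pixel_size > 0, ring_diameter_nm > 0,
            spot_fwhm_nm > 0, min_diam > 0, sd_diam >= 0,
            mean_az > 0, mean_out > 0)
  class(spec) <- "ImageSpec"
  spec
}

# truncated-normal diameters
.rdiam <- function(n, mean, sd, min_diam) {
  out <- numeric(0)
  while (length(out) < n) {
    d <- rnorm(n, mean, sd)
    out <- c(out, d[d > min_diam])
  }
  out[seq_len(n)]
}

# add an isotropic radial profile to an intensity matrix (nm coordinates,
# pixel centers at (i-1)*ps)
.render_spot <- function(img, ps, x_nm, y_nm, peak, fwhm, profile) {
  cut_nm <- 4 * fwhm
  n <- nrow(img)
  cols <- max(1, floor((x_nm - cut_nm) / ps) + 1):
    min(n, ceiling((x_nm + cut_nm) / ps) + 1)
  rows <- max(1, floor((y_nm - cut_nm) / ps) + 1):
    min(n, ceiling((y_nm + cut_nm) / ps) + 1)
  ry <- (rows - 1) * ps - y_nm
  cx <- (cols - 1) * ps - x_nm
  d2 <- outer(ry^2, cx^2, `+`)
  if (profile == "gaussian") {
    s2 <- (fwhm / 2.35482)^2
    add <- peak * exp(-d2 / (2 * s2))
  } else {
    g2 <- (fwhm / 2)^2
    add <- peak * g2 / (d2 + g2)
  }
  add[d2 > cut_nm^2] <- 0
  img[rows, cols] <- img[rows, cols] + add
  img
}

#' Generate a synthetic two-channel STED image with ground truth
#'
#' Renders BRP rings (discrete spots on circles) into the `brp` channel
#' and Syntaxin-1A clusters into the `syntaxin` channel, AZ-group clusters
#' inside the nominal active-zone masks and outside-group clusters well
#' beyond them, then applies Poisson shot noise and Gaussian read noise on
#' top of a constant background. Deterministic for a fixed seed.
#'
#' @param spec an [imageSpec()].
#' @param seed integer seed.
#' @return list with `syx` and `brp` ([StedImage-class], the syntaxin
#'   image carrying a full-frame membrane mask) and `truth` (data.frame:
#'   `channel`, `x_nm`, `y_nm`, `fwhm_nm`, `group`, `ring_id`).
#' @export
generateSyntheticImage <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "ImageSpec"))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  ps <- spec$pixel_size
  n <- spec$size_px
  side_nm <- (n - 1) * ps
  ring_r <- spec$ring_diameter_nm / 2
  mask_r <- ring_r + spec$pad_nm

  # ring centers: mutually >= 3.2 mask radii apart, away from the border
  border <- mask_r + 120
  centers <- matrix(0, 0, 2)
  tries <- 0
  while (nrow(centers) < spec$n_az) {
    p <- runif(2, border, side_nm - border)
    if (nrow(centers) == 0 ||
        min(sqrt((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2)) >=
          3.2 * mask_r) {
      centers <- rbind(centers, p)
    }
    tries <- tries + 1
    if (tries > 500 * max(1, spec$n_az))
      stop("requested active-zone density geometrically infeasible")
  }

  brp <- matrix(0, n, n)
  truth <- list()
  if (spec$n_az > 0) {
    for (k in seq_len(spec$n_az)) {
      phase <- runif(1, 0, 2 * pi)
      ang <- phase + 2 * pi * (seq_len(spec$spots_per_ring) - 1) /
        spec$spots_per_ring
      sx <- centers[k, 1] + ring_r * cos(ang)
      sy <- centers[k, 2] + ring_r * sin(ang)
      pk <- runif(spec$spots_per_ring, spec$brp_peak_range[1],
                  spec$brp_peak_range[2])
      for (q in seq_along(ang)) {
        brp <- .render_spot(brp, ps, sx[q], sy[q], pk[q],
                            spec$spot_fwhm_nm, spec$profile)
        truth[[length(truth) + 1]] <-
          data.frame(channel = "brp", x_nm = sx[q], y_nm = sy[q],
                     fwhm_nm = spec$spot_fwhm_nm, group = "brp",
                     ring_id = k)
      }
    }
  }

  # syntaxin clusters
  syx <- matrix(0, n, n)
  placed <- matrix(0, 0, 2)
  place <- function(candidate_fn, n_want, group_label) {
    diams <- .rdiam(n_want, if (group_label == "az") spec$mean_az else
      spec$mean_out, spec$sd_diam, spec$min_diam)
    got <- 0; tries <- 0
    recs <- list()
    while (got < n_want) {
      p <- candidate_fn()
      tries <- tries + 1
      if (tries > 2000 * max(1, n_want))
        stop("requested syntaxin cluster density geometrically infeasible")
      if (is.null(p)) next
      if (nrow(placed) > 0 &&
          min(sqrt((placed[, 1] - p[1])^2 + (placed[, 2] - p[2])^2)) <
            spec$min_sep_nm) next
      got <- got + 1
      placed <<- rbind(placed, p[1:2])
      pk <- runif(1, spec$peak_range[1], spec$peak_range[2])
      syx <<- .render_spot(syx, ps, p[1], p[2], pk, diams[got],
                           spec$profile)
      recs[[got]] <- data.frame(channel = "syntaxin", x_nm = p[1],
                                y_nm = p[2], fwhm_nm = diams[got],
                                group = group_label,
                                ring_id = if (length(p) > 2) p[3] else NA)
    }
    recs
  }
  if (spec$n_syx_az > 0) {
    if (spec$n_az == 0) stop("AZ-group clusters requested but n_az = 0")
    # AZ clusters sit on an annulus around the BRP ring (as observed:
    # syntaxin microdomains align with the ring), clipped to stay
    # margin_nm inside the AZ mask so the ground truth is unambiguous.
    # Jittered angular slots along the ring guarantee the separation.
    n_slots <- max(1, floor(2 * pi * ring_r / spec$min_sep_nm))
    if (spec$n_syx_az > spec$n_az * n_slots)
      stop("requested syntaxin cluster density geometrically infeasible: ",
           "at most ", n_slots, " AZ clusters fit per ring")
    idx <- seq_len(spec$n_syx_az) - 1
    ring_of <- (idx %% spec$n_az) + 1
    slot_of <- (idx %/% spec$n_az)
    diams <- .rdiam(spec$n_syx_az, spec$mean_az, spec$sd_diam,
                    spec$min_diam)
    slot_phase <- runif(spec$n_az, 0, 2 * pi)
    for (q in seq_len(spec$n_syx_az)) {
      k <- ring_of[q]
      th <- slot_phase[k] +
        (slot_of[q] + runif(1, -0.15, 0.15)) * 2 * pi / n_slots
      rr <- runif(1, max(ring_r - 15, 0),
                  min(ring_r + 15, mask_r - spec$margin_nm))
      p <- c(centers[k, 1] + rr * cos(th), centers[k, 2] + rr * sin(th))
      placed <- rbind(placed, p)
      pk <- runif(1, spec$peak_range[1], spec$peak_range[2])
      syx <- .render_spot(syx, ps, p[1], p[2], pk, diams[q], spec$profile)
      truth[[length(truth) + 1]] <-
        data.frame(channel = "syntaxin", x_nm = p[1], y_nm = p[2],
                   fwhm_nm = diams[q], group = "az", ring_id = k)
    }
  }
  if (spec$n_syx_out > 0) {
    truth <- c(truth, place(function() {
      p <- runif(2, 80, side_nm - 80)
      if (spec$n_az > 0) {
        d <- sqrt((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2)
        if (min(d) < mask_r + spec$margin_nm + 60) return(NULL)
      }
      p
    }, spec$n_syx_out, "outside"))
  }

  noisy <- function(img) {
    img <- img + spec$background
    gain <- spec$photons_per_au
    img <- rpois(length(img), lambda = as.vector(img) * gain) / gain +
      rnorm(length(img), 0, spec$read_noise_sd)
    matrix(pmax(img, 0), n, n)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(channel = character(), x_nm = numeric(), y_nm = numeric(),
               fwhm_nm = numeric(), group = character(), ring_id = integer())
  list(syx = stedImage(noisy(syx), ps, "syntaxin",
                       mask = matrix(TRUE, n, n)),
       brp = stedImage(noisy(brp), ps, "brp"),
       truth = truth)
}

#' Generate reference trajectories with known ground truth
#'
#' Three trajectory kinds with analytically known behavior, used to
#' validate the trajectory-analysis operations independently of the
#' dynamics engine:
#' \describe{
#'   \item{`"free-diffusers"`}{ideal 2D Brownian walkers at diffusion
#'     coefficient `D_um2_s`; with `reflect` the wall rejects outgoing
#'     steps (walkers stay put), which keeps the uniform distribution
#'     exactly stationary.}
#'   \item{`"frozen-clusters"`}{static configuration with a prescribed
#'     cluster-size `partition` (members packed within the proximity
#'     cutoff, clusters far apart).}
#'   \item{`"two-state-exchange"`}{molecules alternate between membership
#'     in a static core cluster and a private, well-separated parking
#'     position far from it, with exponential holding times (`k_on`,
#'     `k_off` per ms).}
#' }
#'
#' @param kind one of `"free-diffusers"`, `"frozen-clusters"`,
#'   `"two-state-exchange"`.
#' @param params named list; common: `n_frames`, `frame_ns` (frame
#'   spacing, default 1e4 ns), `domain_radius` (default 300).
#'   Free-diffusers: `n` (walkers, default 50), `D_um2_s` (default 0.2),
#'   `reflect` (default TRUE). Frozen-clusters: `partition` (integer
#'   vector of cluster sizes). Two-state-exchange: `n` (exchangers,
#'   default 20), `core` (static core size, default 6), `k_on`, `k_off`
#'   (switch rates per ms).
#' @param seed integer seed.
#' @return A [Trajectory-class] (provenance notes the generator kind).
#' @export
generateReferenceTrajectory <- function(kind = c("free-diffusers",
                                                 "frozen-clusters",
                                                 "two-state-exchange"),
                                        params = list(), seed = 1) {
  kind <- match.arg(kind)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  p <- params
  F <- p$n_frames %||% 200
  frame_ns <- p$frame_ns %||% 1e4
  R <- p$domain_radius %||% 300

  if (kind == "free-diffusers") {
    n <- p$n %||% 50
    D <- (p$D_um2_s %||% 0.2) * 1e-3  # nm^2/ns
    reflect <- p$reflect %||% TRUE
    sig <- sqrt(2 * D * frame_ns)
    rho <- R * sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
    x <- rho * cos(th); y <- rho * sin(th)
    arr <- array(0, dim = c(3, n, F))
    arr[1, , 1] <- x; arr[2, , 1] <- y
    for (f in 2:F) {
      xn <- x + rnorm(n, 0, sig)
      yn <- y + rnorm(n, 0, sig)
      if (reflect) {
        # reject-and-stay at the wall: symmetric proposals rejected at the
        # boundary leave the uniform distribution exactly stationary
        out <- xn^2 + yn^2 > R^2
        xn[out] <- x[out]
        yn[out] <- y[out]
      }
      x <- xn; y <- yn
      arr[1, , f] <- x; arr[2, , f] <- y
    }
    mobile <- rep(TRUE, n)
  } else if (kind == "frozen-clusters") {
    part <- p$partition %||% c(5, 3, 1)
    n <- sum(part)
    arr <- array(0, dim = c(3, n, F))
    # shell-packed member offsets: center, 6 at 6.5 nm, 12 at 13 nm; every
    # member is within the 7-nm proximity cutoff of an inner-shell member
    offs <- rbind(c(0, 0),
                  6.5 * cbind(cos(2 * pi * (0:5) / 6),
                              sin(2 * pi * (0:5) / 6)),
                  13 * cbind(cos(2 * pi * (0:11) / 12),
                             sin(2 * pi * (0:11) / 12)))
    if (any(part > nrow(offs)))
      stop("frozen-cluster partition sizes above ", nrow(offs),
           " are not supported")
    m <- 1
    for (k in seq_along(part)) {
      cx <- ((k - 1) %% 8) * 100 - R / 2
      cy <- ((k - 1) %/% 8) * 100 - R / 2
      for (q in seq_len(part[k])) {
        arr[1, m, ] <- cx + offs[q, 1]
        arr[2, m, ] <- cy + offs[q, 2]
        m <- m + 1
      }
    }
    mobile <- rep(FALSE, n)
  } else {
    n_ex <- p$n %||% 20
    core <- p$core %||% 6
    k_on <- p$k_on %||% 1    # per ms, free -> clustered
    k_off <- p$k_off %||% 1  # per ms, clustered -> free
    dt_ms <- frame_ns * 1e-6
    p_on <- 1 - exp(-k_on * dt_ms)
    p_off <- 1 - exp(-k_off * dt_ms)
    n <- core + n_ex
    arr <- array(0, dim = c(3, n, F))
    # static core ring at the origin (mutually within the 7-nm cutoff)
    core_ang <- 2 * pi * seq_len(core) / core
    arr[1, seq_len(core), ] <- 6.5 * cos(core_ang)
    arr[2, seq_len(core), ] <- 6.5 * sin(core_ang)
    # each exchanger docks 5.5 nm outside "its" core member (+ jitter)
    slot <- ((seq_len(n_ex) - 1) %% core) + 1
    jit <- runif(n_ex, -0.08, 0.08)
    in_x <- 12 * cos(core_ang[slot] + jit)
    in_y <- 12 * sin(core_ang[slot] + jit)
    state <- runif(n_ex) < k_on / (k_on + k_off)  # start near stationarity
    # each exchanger owns a fixed, well-separated parking position far
    # from the core, so detached molecules can never form spurious
    # clusters among themselves
    tier <- (seq_len(n_ex) - 1) %/% 36
    park_r <- 120 + 25 * tier
    if (max(park_r) > R)
      stop("domain_radius too small for ", n_ex, " exchangers")
    park_a <- 2 * pi * ((seq_len(n_ex) - 1) %% 36) / 36
    fx <- cbind(park_r * cos(park_a), park_r * sin(park_a))
    for (f in seq_len(F)) {
      if (f > 1) {
        flip_off <- state & runif(n_ex) < p_off
        flip_on <- !state & runif(n_ex) < p_on
        state[flip_off] <- FALSE
        state[flip_on] <- TRUE
      }
      arr[1, core + seq_len(n_ex), f] <- ifelse(state, in_x, fx[, 1])
      arr[2, core + seq_len(n_ex), f] <- ifelse(state, in_y, fx[, 2])
    }
    mobile <- c(rep(FALSE, core), rep(TRUE, n_ex))
  }

  cfg <- simConfig(n_molecules = n, domain_radius = max(R, 34),
                   E_a = 0, dt = frame_ns, n_steps = F - 1,
                   sample_stride = 1, rng_seed = seed)
  new("Trajectory", config = cfg, times = (seq_len(F) - 1) * frame_ns,
      pos1 = arr, pos2 = arr + rep(c(0, 0, 6.3), each = 1),
      energies = numeric(F), mobile = mobile,
      labels = rep(list(character()), n),
      provenance = list(seed = seed, kind = kind, synthetic = TRUE))
}
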