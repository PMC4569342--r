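# Mobility and exchange statistics on reference trajectories with known
# ground truth.

test_that("free-diffuser step lengths are Rayleigh distributed", {
  D <- 0.2
  lag_us <- 200
  tr <- generateReferenceTrajectory(
    "free-diffusers",
    list(n = 200, n_frames = 100, frame_ns = lag_us * 1e3,
         D_um2_s = D, reflect = FALSE, domain_radius = 1e5), seed = 21)
  sl <- stepLengths(tr, lag_us = lag_us)
  scale <- sqrt(2 * D * 1e-3 * lag_us * 1e3)  # nm
  ks <- suppressWarnings(
    ks.test(sl, function(q) 1 - exp(-q^2 / (2 * scale^2))))
  expect_gt(ks$p.value, 0.01)
  # zero lag gives all-zero lengths; incompatible lags fail loudly
  expect_true(all(stepLengths(tr, lag_us = 0) == 0))
  expect_error(stepLengths(tr, lag_us = 300), "not a multiple")
})

test_that("MSD regression recovers the generating diffusion coefficient", {
  tr <- generateReferenceTrajectory(
    "free-diffusers",
    list(n = 100, n_frames = 500, frame_ns = 1e4, D_um2_s = 0.2,
         reflect = FALSE, domain_radius = 1e5), seed = 22)
  expect_equal(msdDiffusion(tr), 0.2, tolerance = 0.1)
})

test_that("cluster diffusion: singletons at D_eff, frozen clusters at 0", {
  tr <- generateReferenceTrajectory(
    "free-diffusers",
    list(n = 60, n_frames = 300, frame_ns = 1e4, D_um2_s = 0.2,
         reflect = FALSE, domain_radius = 1e6), seed = 23)
  # walkers start far apart on a huge domain: all singletons
  cd <- clusterDiffusion(tr, size_bins = c(1, 2))
  expect_equal(cd$D_um2_s[1], 0.2, tolerance = 0.1)
  fz <- generateReferenceTrajectory("frozen-clusters",
                                    list(partition = c(12, 12, 12),
                                         n_frames = 30))
  cdf <- clusterDiffusion(fz, size_bins = c(1, 2, 16))
  expect_equal(cdf$D_um2_s[cdf$size_lo == 2], 0)
})

test_that("two-state exchange kinetics are recovered", {
  # k_off = 1/ms: mean residence 1 ms; ~3600 completed spells keep the
  # sampling error near 1.7% for a 5% check
  tr <- generateReferenceTrajectory(
    "two-state-exchange",
    list(n = 120, core = 6, k_on = 1, k_off = 1, n_frames = 6000,
         frame_ns = 1e4), seed = 24)
  dr <- dissociationAndResidence(tr, cutoff = 7, debounce = 2)
  res <- dr$residence
  ok <- !res$censored & res$molecule > 6
  expect_gt(sum(ok), 2000)
  expect_equal(mean(res$duration_ms[ok]), 1.0, tolerance = 0.05)
  # per-particle dissociation rate approximates k_off once the static
  # core molecules (which never dissociate) leave the denominator
  tot <- dr$by_size
  span_ms <- (max(trajTimes(tr)) - min(trajTimes(tr))) * 1e-6
  rate <- sum(tot$events) / (sum(tot$particle_ms) - 6 * span_ms)
  expect_equal(rate, 1.0, tolerance = 0.1)
})

test_that("frozen trajectories yield no events and censored residences", {
  fz <- generateReferenceTrajectory("frozen-clusters",
                                    list(partition = c(6, 4),
                                         n_frames = 50, frame_ns = 1e4))
  dr <- dissociationAndResidence(fz, cutoff = 7)
  expect_equal(sum(dr$by_size$events), 0)
  expect_true(all(dr$residence$censored))
  expect_equal(unique(dr$residence$frames), 50)
})

test_that("cluster mobility scales inversely with member count", {
  # centroid of an N-cluster averages N independent noise sources, so
  # D(N) ~ D_eff / N; checked on the 50-ms equilibrium run
  long <- shared_long_run()
  cd <- clusterDiffusion(long, size_bins = c(1, 2, 3, 5, 9, 17, 33))
  ok <- !is.na(cd$D_um2_s) & cd$n_obs >= 30
  expect_gte(sum(ok), 4)
  expect_equal(cd$D_um2_s[1], 0.2, tolerance = 0.2)
  fit <- lm(log(cd$D_um2_s[ok]) ~ log(cd$mean_size[ok]))
  slope <- unname(coef(fit)[2])
  expect_gt(slope, -1.25)
  expect_lt(slope, -0.75)
})

test_that("stronger clustering shifts step lengths shorter", {
  g <- shared_grid_runs()
  med <- vapply(c(1, 4), function(i) {
    median(unlist(lapply(1:3, function(r)
      stepLengths(g$prod[[i]][[r]], lag_us = 200))))
  }, 0)
  # E_a = 4.8 vs 3.6: the mobile fraction shrinks, the distribution
  # narrows towards the slow clustered component
  expect_lt(med[2], med[1])
})
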