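# Initialization, integrator contracts, seeding, persistence.

test_that("random initialization respects overlaps and is reproducible", {
  cfg <- simConfig(n_molecules = 500, domain_radius = 300, n_steps = 0,
                   rng_seed = 11)
  st <- initRandom(cfg)
  d <- dist(st@pos1[, 1:2])
  expect_true(all(d >= 6.0))
  expect_true(all(sqrt(st@pos1[, 1]^2 + st@pos1[, 2]^2) <= 300))
  expect_true(all(st@pos1[, 3] == 0))
  st2 <- initRandom(cfg)
  expect_identical(st@pos1, st2@pos1)
  # single molecule: head sits at the bond rest length above the anchor
  one <- initRandom(simConfig(n_molecules = 1, domain_radius = 50,
                              n_steps = 0))
  expect_equal(one@pos2[1, 3] - one@pos1[1, 3], 6.3)
  # infeasible packing fails explicitly
  expect_error(initRandom(simConfig(n_molecules = 500, domain_radius = 40,
                                    n_steps = 0)), "infeasible")
})

test_that("integrator honors degenerate and deterministic contracts", {
  cfg <- tiny_config(n_molecules = 4, domain_radius = 60, rng_seed = 2)
  st <- initRandom(cfg)
  # zero mobility: state unchanged even under forces
  frozen <- stepDynamics(st, cfg, n_steps = 100, Dp = 0)
  expect_identical(frozen@pos1, st@pos1)
  expect_identical(frozen@pos2, st@pos2)
  # fixed seed: two runs bit-identical
  a <- stepDynamics(st, cfg, n_steps = 500, seed = 99)
  b <- stepDynamics(st, cfg, n_steps = 500, seed = 99)
  expect_identical(a@pos1, b@pos1)
  expect_identical(a@pos2, b@pos2)
  c <- stepDynamics(st, cfg, n_steps = 500, seed = 100)
  expect_false(identical(c@pos1, a@pos1))
  # zero steps: single-frame trajectory equal to the input
  cfg0 <- tiny_config(n_molecules = 4, n_steps = 0)
  tr <- runSimulation(cfg0, init = st)
  expect_equal(nFrames(tr), 1)
  expect_equal(anchorPositions(tr, 1), st@pos1)
})

test_that("free-particle displacements have the Euler-Maruyama variance", {
  # single isolated dimer, no interactions: per-step anchor displacement
  # variance must be 2 Dp dt per coordinate (chi-square test)
  cfg <- simConfig(n_molecules = 1, domain_radius = 1e5, n_steps = 2000,
                   sample_stride = 1, boundary_k = 0, rng_seed = 4)
  tr <- runSimulation(cfg, init = state_from_anchors(matrix(0, 1, 3)))
  dx <- diff(tr@pos1[1, 1, ])
  n <- length(dx)
  s2 <- 2 * particleDiffusion(cfg) * cfg@dt
  stat <- sum(dx^2) / s2  # ~ chi-square with n dof
  expect_gt(pchisq(stat, df = n), 0.005)
  expect_lt(pchisq(stat, df = n), 0.995)
})

test_that("the wall keeps anchors on the disk", {
  cfg <- simConfig(n_molecules = 20, domain_radius = 50, E_a = 0,
                   n_steps = 2e5, sample_stride = 1e3, rng_seed = 6)
  tr <- runSimulation(cfg)
  rho <- sqrt(tr@pos1[1, , ]^2 + tr@pos1[2, , ]^2)
  # allowed penetration: 3 sigma of a step plus the harmonic equilibrium
  # spread sqrt(kT/k) inside the wall
  allow <- 3 * sqrt(2 * particleDiffusion(cfg) * cfg@dt) +
    3 * sqrt(1 / cfg@boundary_k)
  expect_lt(max(rho), 50 + allow)
})

test_that("potential energy is stationary in equilibrium (Mann-Kendall)", {
  cfg <- simConfig(n_molecules = 30, domain_radius = 100, E_a = 0,
                   n_steps = 2e5, sample_stride = 2e3, rng_seed = 8)
  tr <- runSimulation(cfg)
  e <- tr@energies
  # second half, thinned to decorrelate neighboring frames
  half <- e[seq(length(e) %/% 2, length(e), by = 3)]
  mk <- suppressWarnings(cor.test(seq_along(half), half,
                                  method = "kendall"))
  expect_gt(mk$p.value, 0.05)
})

test_that("an ideal-gas run forms no persistent clusters", {
  cfg <- simConfig(n_molecules = 100, domain_radius = 250, E_a = 0,
                   n_steps = 1e5, sample_stride = 1e3, rng_seed = 12)
  tr <- runSimulation(cfg)
  labs <- identifyClusters(tr)
  big <- vapply(seq_len(ncol(labs)), function(f)
    max(tabulate(labs[, f])), 0)
  expect_lt(mean(big > 3), 0.9)
})

test_that("diffusion calibration recovers the target dimer mobility", {
  cfg <- simConfig(n_molecules = 1, n_steps = 0, rng_seed = 3)
  Dp <- calibrateParticleDiffusion(cfg, n_steps = 1e6, n_dimers = 8)
  expect_lt(abs(attr(Dp, "measured_D") - 0.2) / 0.2, 0.05)
  # linearity: doubling Dp doubles the measured free-dimer D
  t1 <- SyxDynamics:::.free_dimer_run(cfg, 2e-4, 1e6, 8, seed = 5)
  t2 <- SyxDynamics:::.free_dimer_run(cfg, 4e-4, 1e6, 8, seed = 5)
  expect_equal(msdDiffusion(t2) / msdDiffusion(t1), 2, tolerance = 0.15)
})

test_that("seed insertion creates a static tagged molecule or fails", {
  cfg <- simConfig(n_molecules = 30, domain_radius = 100, n_steps = 2e4,
                   sample_stride = 2e3, rng_seed = 13)
  st <- initRandom(cfg)
  st2 <- insertSeed(st, cfg, seed = 21)
  n <- nMolecules(st2)
  expect_equal(n, 31)
  expect_false(st2@mobile[n])
  expect_true("seed" %in% st2@labels[[n]])
  expect_true(all(SyxDynamics:::.molecule_ea(st2, cfg)[-n] == cfg@E_a))
  expect_equal(SyxDynamics:::.molecule_ea(st2, cfg)[n], 8)
  # the seed does not move over a simulated stretch
  tr <- runSimulation(cfg, init = st2, seed = 22)
  expect_true(all(tr@pos1[, n, ] == tr@pos1[, n, 1]))
  # densely covered membrane: no empty site
  dense <- state_from_anchors(as.matrix(expand.grid(
    x = seq(-48, 48, by = 7), y = seq(-48, 48, by = 7), z = 0)))
  dense_cfg <- simConfig(n_molecules = nrow(dense@pos1),
                         domain_radius = 50, n_steps = 0)
  expect_error(insertSeed(dense, dense_cfg, max_tries = 300), "no empty")
})

test_that("trajectories survive the plain-text container round trip", {
  cfg <- tiny_config(n_molecules = 6, n_steps = 400, sample_stride = 100,
                     rng_seed = 14)
  tr <- runSimulation(cfg)
  d <- withr::local_tempdir()
  dir <- file.path(d, "traj")
  saveTrajectory(tr, dir)
  expect_true(file.exists(file.path(dir, "pos1.csv")))
  back <- loadTrajectory(dir)
  expect_equal(back@pos1, tr@pos1, tolerance = 1e-12)
  expect_equal(back@times, tr@times)
  expect_equal(back@mobile, tr@mobile)
  expect_equal(back@config@E_a, tr@config@E_a)
})

test_that("continuation runs extend a trajectory seamlessly", {
  cfg <- tiny_config(n_molecules = 8, n_steps = 1000, sample_stride = 500,
                     rng_seed = 15)
  tr <- runSimulation(cfg)
  tr2 <- runSimulation(cfg, init = finalState(tr), seed = 16)
  expect_equal(tr2@times[1], tr@times[nFrames(tr)])
  expect_equal(anchorPositions(tr2, 1),
               anchorPositions(tr, nFrames(tr)))
})
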