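# Simulated assays on cheap reference inputs (engine-based assay behavior
# at the study conditions is exercised in test-acceptance.R).

test_that("FRAP labels conserve molecules and recover to the mixing cap", {
  # ideal walkers in a closed disk; exactly 10% of them start inside the
  # bleach disc so the ideal-mixing plateau is 0.9
  R <- 200; a <- R * sqrt(0.1)
  n <- 400
  tr <- generateReferenceTrajectory(
    "free-diffusers",
    list(n = n, n_frames = 600, frame_ns = 2e5, D_um2_s = 0.2,
         reflect = TRUE, domain_radius = R), seed = 31)
  # relabel positions: move 10 walkers inside the disc, the rest outside
  rho <- sqrt(tr@pos1[1, , 1]^2 + tr@pos1[2, , 1]^2)
  inside <- order(rho)[1:40]
  for (m in inside) {
    sc <- (a * 0.8 * runif(1)) / max(rho[m], 1e-6)
    tr@pos1[1:2, m, 1] <- tr@pos1[1:2, m, 1] * sc
  }
  outside <- setdiff(seq_len(n), inside)
  for (m in outside[rho[outside] <= a]) {
    tr@pos1[1:2, m, 1] <- tr@pos1[1:2, m, 1] * (1.2 * a / rho[m])
  }
  tr@labels <- lapply(seq_len(n), function(m)
    if (m %in% inside) "bleached" else character())
  curve <- frapCurve(tr, radius = a)
  expect_equal(curve$recovered[1], 0)
  expect_true(all(diff(range(curve$time_s)) > 0))
  # plateau at 1 - bleached fraction under ideal mixing
  plateau <- mean(tail(curve$recovered, 400))
  expect_equal(plateau, 0.9, tolerance = 0.12)
  # conservation: bleached count never changes
  expect_equal(sum(vapply(tr@labels, function(l) "bleached" %in% l, TRUE)),
               40)
})

test_that("coverage tracking is deterministic and handles immobility", {
  cfg <- simConfig(n_molecules = 10, domain_radius = 80, E_a = 0,
                   n_steps = 5e4, sample_stride = 5e3, rng_seed = 32)
  st <- initRandom(cfg)
  cov1 <- membraneCoverage(st, cfg, cell_nm = 40, seed = 5)
  cov2 <- membraneCoverage(st, cfg, cell_nm = 40, seed = 5)
  expect_identical(cov1$curve, cov2$curve)
  expect_equal(cov1$initial_fraction,
               sum(!is.na(cov1$first_visit_ms) &
                     cov1$first_visit_ms == 0) / cov1$n_cells)
  # immobile molecules never visit new cells
  still <- st
  still@mobile <- rep(FALSE, 10)
  cov3 <- membraneCoverage(still, cfg, cell_nm = 40, seed = 5)
  expect_equal(newlyVisited(cov3, 1e9), 0)
  expect_true(all(cov3$curve$fraction == cov3$initial_fraction))
})

test_that("seeded aggregation reports monotone first-passage times", {
  cfg <- simConfig(n_molecules = 60, domain_radius = 120, E_a = 4.4,
                   n_steps = 4e5, sample_stride = 2e3, rng_seed = 33)
  st <- stepDynamics(initRandom(cfg), cfg, n_steps = 2e5, seed = 1)
  agg <- seededAggregation(st, cfg, target_size = 5, n_replicas = 2,
                           seed = 34, check_stride = 500)
  for (r in 1:2) {
    tt <- agg$time_ms[agg$replica == r]
    expect_equal(tt[1], 0)  # size 1: the seed itself
    reached <- tt[!is.na(tt)]
    expect_true(all(diff(reached) >= 0))
  }
})

test_that("census counts molecules exactly and finds boundary candidates", {
  fz <- generateReferenceTrajectory(
    "frozen-clusters", list(partition = c(7, 1), n_frames = 20,
                            frame_ns = 1e7, domain_radius = 300))
  cc <- candidateCensus(fz, window_ms = 100, cell_nm = 30)
  # docking: time-averaged counts sum to the molecules inside the grid
  expect_equal(sum(cc$grid$docking), mean(cc$per_frame_total))
  expect_equal(unique(cc$per_frame_total), 8)
  # hex-shell cluster: 6 boundary members + the free singleton qualify
  expect_equal(sum(cc$grid$priming), 7)
  expect_equal(sum(cc$grid$priming_boundary), 6)
  # persistence shorter than the window disqualifies everything
  expect_error(candidateCensus(fz, window_ms = 1e9), "spans")
})
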