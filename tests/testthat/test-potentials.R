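# The three interaction potentials and the assembled forces.

test_that("membrane potential is the printed harmonic restraint", {
  expect_equal(membranePotential(0)$energy, 0)
  expect_equal(membranePotential(1, k_m = 20)$energy, 10)
  # analytic force matches a central finite difference
  d <- 0.5
  fd <- fd_derivative(function(x) membranePotential(x, 20)$energy, d)
  expect_equal(membranePotential(d, 20)$force, -fd, tolerance = 1e-6)
})

test_that("repulsion potential is harmonic inside contact and zero outside", {
  r <- 6.6
  expect_equal(repulsionPotential(r, r)$energy, 0)
  expect_equal(repulsionPotential(r + 1, r)$energy, 0)
  expect_equal(repulsionPotential(r - 1, r, k = 2)$energy, 1)
  expect_true(repulsionPotential(r - 1, r)$force > 0)  # pushes apart
  expect_error(repulsionPotential(-0.1, r), "non-negative")
})

test_that("clustering potential branches agree with their printed forms", {
  r <- 6.0; i <- 8.25; Ea <- 4.0
  expect_equal(attractionPotential(r, r, i, Ea)$energy, -Ea)
  expect_equal(attractionPotential(i, r, i, Ea)$energy, 0)
  # midpoint value evaluated independently from both adjacent branches
  mid <- (i + r) / 2
  branch2 <- 2 * Ea / (i - r)^2 * (mid - r)^2 - Ea
  branch3 <- -2 * Ea / (i - r)^2 * (mid - i)^2
  expect_equal(branch2, branch3)
  expect_equal(branch2, -2.0)
  expect_equal(attractionPotential(mid, r, i, Ea)$energy, branch2)
  expect_error(attractionPotential(5, r_sum = 6, i_radius = 6, E_a = 4),
               "exceed")
})

test_that("clustering potential is C0/C1 continuous with compact support", {
  r <- 6.0; i <- 8.25; Ea <- 4.4
  for (b in c(r, (i + r) / 2, i)) {
    eps <- 1e-7
    lo <- attractionPotential(b - eps, r, i, Ea)
    hi <- attractionPotential(b + eps, r, i, Ea)
    expect_lt(abs(hi$energy - lo$energy), 1e-5)
    expect_lt(abs(hi$force - lo$force), 1e-4)
  }
  d <- seq(0.1, 12, by = 0.005)
  u <- attractionPotential(d, r, i, Ea)
  # no jumps on a dense grid: increments bounded by the local slope
  slope_bound <- max(abs(u$force)) * 0.005 * 1.5 + 1e-8
  expect_lt(max(abs(diff(u$energy))), slope_bound)
  expect_true(all(u$energy[d >= i] == 0))
  expect_true(all(u$force[d >= i] == 0))
  rep_u <- repulsionPotential(d, 6.6)
  expect_true(all(rep_u$energy[d >= 6.6] == 0))
  # force equals -dU/dd everywhere away from the kinks
  for (d0 in c(3, 6.5, 7.5, 9)) {
    fd <- fd_derivative(function(x) attractionPotential(x, r, i, Ea)$energy,
                        d0)
    expect_equal(attractionPotential(d0, r, i, Ea)$force, -fd,
                 tolerance = 1e-6)
  }
})

test_that("assembled forces are the exact negative energy gradient", {
  set.seed(42)
  cfg <- tiny_config(n_molecules = 5, domain_radius = 60)
  pos1 <- random_anchors(5, 25, min_sep = 5)
  pos1[, 3] <- rnorm(5, 0, 0.2)
  pos2 <- pos1 + cbind(rnorm(5, 0, 1), rnorm(5, 0, 1), 6 + rnorm(5, 0, 0.5))
  st <- new("SystemState", time = 0, pos1 = pos1, pos2 = pos2,
            mobile = rep(TRUE, 5), labels = rep(list(character()), 5))
  out <- pairEnergyForces(st, cfg)
  efn <- function(p1, p2) {
    s <- st; s@pos1 <- p1; s@pos2 <- p2
    pairEnergyForces(s, cfg)$energy
  }
  g <- fd_config_gradient(efn, pos1, pos2)
  scale <- max(abs(out$f1), abs(out$f2), 1)
  expect_lt(max(abs(out$f1 + g$g1)) / scale, 1e-5)
  expect_lt(max(abs(out$f2 + g$g2)) / scale, 1e-5)
})

test_that("pair forces obey symmetry and invariance properties", {
  cfg <- tiny_config(n_molecules = 2, domain_radius = 60)
  mk <- function(p1, p2) new("SystemState", time = 0, pos1 = p1, pos2 = p2,
                             mobile = c(TRUE, TRUE),
                             labels = list(character(), character()))
  p1 <- rbind(c(-3.2, 0, 0), c(3.2, 0, 0))
  p2 <- rbind(c(-3.2, 1.5, 6.1), c(3.2, -1.5, 6.1))
  st <- mk(p1, p2)
  out <- pairEnergyForces(st, cfg)
  # mirrored configuration gives mirrored forces
  mir <- function(m) { m[, 1] <- -m[, 1]; m }
  out_m <- pairEnergyForces(mk(mir(p1)[2:1, ], mir(p2)[2:1, ]), cfg)
  expect_equal(out_m$energy, out$energy)
  expect_equal(out_m$f1, mir(out$f1)[2:1, ])
  # in-plane rotation and translation leave the energy unchanged
  th <- 0.7
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  shift <- c(4, -7, 0)
  rot <- function(m) sweep(m %*% t(Rz), 2, -shift)
  out_r <- pairEnergyForces(mk(rot(p1), rot(p2)), cfg)
  expect_equal(out_r$energy, out$energy, tolerance = 1e-12)
  # far-separated molecules: zero interaction energy beyond the membrane
  far1 <- rbind(c(-30, 0, 0), c(30, 0, 0))
  far2 <- far1; far2[, 3] <- 6.3
  expect_equal(pairEnergyForces(mk(far1, far2), cfg)$energy, 0)
  # non-finite coordinates are rejected
  bad <- p1; bad[1, 1] <- NaN
  expect_error(pairEnergyForces(mk(bad, p2), cfg), "finite")
})

test_that("neighbor-list forces equal all-pairs forces exactly", {
  set.seed(7)
  cfg <- tiny_config(n_molecules = 40, domain_radius = 60)
  for (rep in 1:5) {
    pos1 <- random_anchors(40, 55, min_sep = 4)
    pos2 <- pos1 + cbind(rnorm(40, 0, 2), rnorm(40, 0, 2),
                         6 + rnorm(40, 0, 1))
    ea <- rep(4, 40)
    par <- SyxDynamics:::.engine_params(cfg)
    a <- SyxDynamics:::.cpp_forces(pos1, pos2, ea, par)
    b <- SyxDynamics:::.cpp_forces_verlet(pos1, pos2, ea, par, 2)
    expect_identical(a$energy, b$energy)
    expect_identical(a$f1, b$f1)
    expect_identical(a$f2, b$f2)
  }
})
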