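# Cluster identification and equilibrium statistics.

test_that("proximity rule and transitivity define cluster membership", {
  # two anchors just inside the cutoff (contact + 1 nm)
  st <- state_from_anchors(rbind(c(0, 0, 0), c(6.5, 0, 0)))
  expect_equal(max(identifyClusters(st, cutoff = 7)), 1)
  # just beyond the cutoff: two singletons
  st <- state_from_anchors(rbind(c(0, 0, 0), c(7.5, 0, 0)))
  expect_equal(max(identifyClusters(st, cutoff = 7)), 2)
  # chain of three: transitive closure merges the ends
  st <- state_from_anchors(rbind(c(0, 0, 0), c(6.5, 0, 0), c(13, 0, 0)))
  expect_equal(max(identifyClusters(st, cutoff = 7)), 1)
})

test_that("cluster labels match the brute-force union-find oracle", {
  set.seed(31)
  for (rep in 1:50) {
    n <- sample(2:50, 1)
    pos <- random_anchors(n, runif(1, 20, 60))
    st <- state_from_anchors(pos)
    got <- canonical_partition(identifyClusters(st, cutoff = 7))
    want <- brute_partition(pos, 7)
    expect_identical(got, want)
  }
})

test_that("size distributions conserve molecules and handle edge cases", {
  fz <- generateReferenceTrajectory("frozen-clusters",
                                    list(partition = rep(1, 10),
                                         n_frames = 3))
  csd <- clusterSizeDistribution(fz, burnin = 0)
  expect_equal(csd$size, 1)
  expect_equal(csd$prob, 1)
  fz2 <- generateReferenceTrajectory("frozen-clusters",
                                     list(partition = c(7, 5, 2, 1),
                                          n_frames = 4))
  csd2 <- clusterSizeDistribution(fz2, burnin = 0)
  expect_equal(sum(csd2$size * csd2$mean_count), 15)  # conservation
  cs <- clusteringSummary(fz2, burnin = 0)
  expect_equal(cs$mean_size, 15 / 4)
  expect_equal(cs$single_fraction, 1 / 15)
  # all molecules in one cluster
  one <- generateReferenceTrajectory("frozen-clusters",
                                     list(partition = 12, n_frames = 2))
  cs1 <- clusteringSummary(one, burnin = 0)
  expect_equal(cs1$mean_size, 12)
  expect_equal(cs1$single_fraction, 0)
  # diameter mode sums to the same number of clusters
  csd_d <- clusterSizeDistribution(fz2, by = "diameter", burnin = 0)
  expect_equal(sum(csd_d$mean_count), 4)
})

test_that("effective diameter is monotone and matches the area mapping", {
  d <- effectiveDiameter(1:200)
  expect_true(all(diff(d) > 0))
  # N from the circle-area mapping: d = 2 r1 sqrt(N / phi)
  expect_equal(effectiveDiameter(65, r1 = 3, packing = 0.65), 60)
  # packing fraction of a hex-packed fixture is physically plausible
  hexpos <- as.matrix(expand.grid(x = seq(0, 60, by = 6.2),
                                  y = seq(0, 60, by = 6.2)))
  hexpos[, 2] <- hexpos[, 2] + 3.1 * (hexpos[, 1] %/% 6.2 %% 2)
  st <- state_from_anchors(cbind(hexpos, 0))
  phi <- measurePackingFraction(st, cutoff = 7)
  expect_gt(phi[1], 0.5)
  expect_lt(phi[1], 1.0)
})

test_that("cluster tables report per-frame composition", {
  fz <- generateReferenceTrajectory("frozen-clusters",
                                    list(partition = c(5, 3, 1),
                                         n_frames = 4))
  ct <- clusterTable(fz)
  expect_equal(nrow(ct), 12)  # 3 clusters x 4 frames
  expect_setequal(ct$size[ct$frame == 1], c(5, 3, 1))
  expect_true(all(ct$diameter_nm > 0))
})
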