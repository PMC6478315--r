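test_that("symmetry-aware RMSD handles identity, flips and translations", {
  sys <- symmetric_complex()
  lg <- which(sys$atoms$ligand)
  expect_equal(symmetry_aware_rmsd(sys, sys$xyz, sys$xyz), 0)
  # 180-degree flip about the para axis is a graph automorphism: RMSD 0
  com <- colMeans(sys$xyz[lg, , drop = FALSE])
  flip <- diag(c(1, -1, -1))
  xyz <- sys$xyz
  xyz[lg, ] <- sweep(sweep(xyz[lg, , drop = FALSE], 2, com) %*% flip, 2,
                     com, `+`)
  expect_lt(symmetry_aware_rmsd(sys, xyz, sys$xyz), 1e-10)
  # without symmetry handling the flip is large: mapping min <= identity
  idmap <- list(seq_along(lg))
  attr(idmap, "heavy") <- seq_along(lg)
  rid <- symmetry_aware_rmsd(sys, xyz, sys$xyz, mappings = idmap)
  expect_gt(rid, 1)
  # rigid ligand translation by d after perfect backbone alignment: RMSD d
  xyz2 <- sys$xyz
  xyz2[lg, ] <- sweep(xyz2[lg, , drop = FALSE], 2, c(1.5, 0, 0), `+`)
  expect_equal(symmetry_aware_rmsd(sys, xyz2, sys$xyz), 1.5,
               tolerance = 1e-9)
})

test_that("symmetry-aware RMSD is invariant to global rigid motion of the pose", {
  sys <- symmetric_complex()
  lg <- which(sys$atoms$ligand)
  set.seed(6)
  xyz <- sys$xyz
  xyz[lg, ] <- sweep(xyz[lg, , drop = FALSE], 2, c(0.7, -0.4, 0.8), `+`)
  r0 <- symmetry_aware_rmsd(sys, xyz, sys$xyz)
  R <- mrmcdock:::rotation_matrix(c(2, -1, 0.5), 0.9)
  moved <- sweep(xyz %*% t(R), 2, c(3, 4, -5), `+`)
  expect_lt(abs(symmetry_aware_rmsd(sys, moved, sys$xyz) - r0), 1e-8)
})

test_that("complete-linkage clustering matches the brute-force oracle", {
  # two tight groups (intra well under 0.5) separated by about 10: with 21
  # of 45 off-diagonal distances intra, percentile 46 interpolates into the
  # gap, so the cutoff cleanly separates the groups
  set.seed(14)
  pts <- rbind(matrix(rnorm(12, 0, 0.1), 6), matrix(rnorm(8, 10, 0.1), 4))
  D <- as.matrix(dist(pts))
  cl <- cluster_poses(D, percentile = 46)
  expect_equal(length(unique(cl$assignment)), 2)
  expect_true(same_partition(cl$assignment, rep(c(1, 2), c(6, 4))))
  # seeded random suite, all sizes <= 8, against the naive oracle
  for (case in seq_len(20)) {
    set.seed(200 + case)
    n <- sample(2:8, 1)
    P <- matrix(stats::runif(n * 2, 0, 10), n, 2)
    D <- as.matrix(dist(P))
    cl <- cluster_poses(D, percentile = sample(c(10, 25, 50), 1))
    oracle <- oracle_complete_linkage(D, cl$cutoff)
    expect_true(same_partition(cl$assignment, oracle))
    # complete-linkage guarantee: intra-cluster distances under the cutoff
    for (k in unique(cl$assignment)) {
      memb <- which(cl$assignment == k)
      if (length(memb) > 1)
        expect_lte(max(D[memb, memb]), cl$cutoff)
    }
  }
  # degenerate inputs
  expect_equal(cluster_poses(matrix(0, 1, 1))$assignment, 1L)
  expect_error(cluster_poses(matrix(numeric(0), 0, 0)), "validation error")
  expect_error(cluster_poses(matrix(c(0, 1, 2, 0), 2, 2)),
               "validation error")
})

test_that("the percentile cutoff uses off-diagonal distances only", {
  D <- as.matrix(dist(c(0, 1, 2, 3)))
  cl <- cluster_poses(D, percentile = 50)
  off <- D[upper.tri(D)]
  expect_equal(cl$cutoff, as.numeric(stats::quantile(off, 0.5, type = 7)))
})

test_that("the three ranking rules select the documented poses", {
  records <- data.frame(interaction_energy = c(-10, -12, -5))
  expect_equal(rank_poses(records, method = 1), 2)
  # clusters: A = {1,2,3} mean -6, B = {4,5} mean -11
  records2 <- data.frame(interaction_energy = c(-4, -6, -8, -10, -12))
  clusters <- structure(list(assignment = c(1L, 1L, 1L, 2L, 2L)),
                        class = "pose_clusters")
  expect_equal(rank_poses(records2, clusters, method = 2), 3)  # best of A
  expect_equal(rank_poses(records2, clusters, method = 3), 5)  # best of B
  # size ties broken by lower mean energy
  records3 <- data.frame(interaction_energy = c(-4, -6, -20, -1, -2))
  clusters3 <- structure(list(assignment = c(1L, 1L, 2L, 2L, 3L)),
                         class = "pose_clusters")
  expect_equal(rank_poses(records3, clusters3, method = 2), 3)
  # a single cluster makes all three methods agree
  one <- structure(list(assignment = rep(1L, 3)), class = "pose_clusters")
  for (m in 1:3)
    expect_equal(rank_poses(records, one, method = m), 2)
  expect_error(rank_poses(records[0, , drop = FALSE]), "validation error")
  expect_error(rank_poses(records, method = 2), "validation error")
})

test_that("best-of-N curves follow the prefix-minimum rule", {
  records <- data.frame(drug = "d1", interaction_energy = c(1, 2, 3),
                        rmsd = c(4, 0.5, 2))
  perf <- summarize_performance(records)
  expect_equal(perf$best_of_n$avg_min_rmsd, c(4, 0.5, 0.5))
  # N_max = total runs recovers the overall best (the dashed baseline)
  expect_equal(perf$best_of_n$avg_min_rmsd[3], perf$baseline)
  # two drugs: averaging across drugs
  records2 <- rbind(records,
                    data.frame(drug = "d2", interaction_energy = c(5, 1),
                               rmsd = c(1, 3)))
  perf2 <- summarize_performance(records2, n_max = 2)
  expect_equal(perf2$best_of_n$avg_min_rmsd, c((4 + 3) / 2, (0.5 + 1) / 2))
  # the CDF of top-ranked RMSDs is a proper non-decreasing CDF
  cdf <- perf2$cdf
  xs <- seq(0, 6, by = 0.5)
  expect_true(all(diff(cdf(xs)) >= 0))
  expect_equal(cdf(max(perf2$top_rmsd)), 1)
})

test_that("effective move size decomposes rigid ligand displacements", {
  sys <- symmetric_complex()
  lg <- which(sys$atoms$ligand)
  ems0 <- effective_move_size(sys, sys$xyz, sys$xyz)
  expect_equal(ems0$translation, 0)
  expect_lt(ems0$rotation, 1e-4)   # acos precision near unit trace
  # pure 2 A translation
  xyz <- sys$xyz
  xyz[lg, ] <- sweep(xyz[lg, , drop = FALSE], 2, c(0, 2, 0), `+`)
  ems1 <- effective_move_size(sys, sys$xyz, xyz)
  expect_equal(ems1$translation, 2, tolerance = 1e-9)
  expect_lt(ems1$rotation, 1e-4)   # acos precision near unit trace
  # pure 30-degree rotation about the ligand centroid
  com <- colMeans(sys$xyz[lg, , drop = FALSE])
  R <- mrmcdock:::rotation_matrix(c(0, 0, 1), pi / 6)
  xyz2 <- sys$xyz
  xyz2[lg, ] <- sweep(sweep(xyz2[lg, , drop = FALSE], 2, com) %*% t(R), 2,
                      com, `+`)
  ems2 <- effective_move_size(sys, sys$xyz, xyz2)
  expect_lt(ems2$translation, 1e-9)
  expect_equal(ems2$rotation, 30, tolerance = 1e-6)
})

test_that("RMSD time series track trajectory snapshots", {
  sys <- symmetric_complex()
  model <- energy_model(sys)
  traj <- run_mc(model, 300, mix = move_mix("fixed_protein"), seed = 9,
                 stride = 50)
  ts <- rmsd_timeseries(traj, sys, sys$xyz)
  expect_equal(nrow(ts), length(traj$snapshots))
  expect_equal(ts$rmsd[1],
               symmetry_aware_rmsd(sys, traj$snapshots[[1]]$xyz, sys$xyz))
  # a frozen trajectory gives a constant series
  frozen <- move_mix("fixed_protein"); frozen$max_size[] <- 0
  tf <- run_mc(model, 100, mix = frozen, seed = 10, stride = 25)
  tsf <- rmsd_timeseries(tf, sys, sys$xyz)
  expect_true(all(abs(tsf$rmsd - tsf$rmsd[1]) < 1e-12))
})
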