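test_that("move mixes follow the production fractions and sizes", {
  ff <- move_mix("fully_flexible")
  expect_equal(sum(ff$fraction), 1)
  expect_equal(ff$max_size,
               c(2, 180, 2, 180, 1, 180)[match(ff$kind, c(
                 "backbone_rotation", "sidechain_rotation", "backrub",
                 "ligand_bond_rotation", "ligand_translation",
                 "ligand_rotation"))])
  fp <- move_mix("fixed_protein")
  expect_setequal(fp$kind, c("ligand_bond_rotation", "ligand_translation",
                             "ligand_rotation"))
  expect_equal(fp$fraction, rep(1 / 3, 3))
  so <- move_mix("sidechain_only")
  expect_setequal(so$kind, c("sidechain_rotation", "ligand_bond_rotation",
                             "ligand_translation", "ligand_rotation"))
  expect_equal(so$fraction, rep(1 / 4, 4))
})

test_that("ligand translations are uniform in the ball", {
  sys <- small_complex()
  lg <- which(sys$atoms$ligand)
  set.seed(41)
  tables <- mrmcdock:::build_move_tables(sys)
  d <- replicate(10000, {
    tr <- propose_move("ligand_translation", sys, sys$xyz, 1, tables)
    tr$size
  })
  expect_true(all(d <= 1))
  # uniform-in-ball mean radius is 3R/4; binomial-style 3 sigma window
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - 0.75), 3 * se + 0.01)
})

test_that("move proposals displace exactly the advertised atom sets", {
  sys <- small_complex()
  tables <- mrmcdock:::build_move_tables(sys)
  set.seed(42)
  first_res_core <- which(sys$atoms$residue == 1 &
                            sys$atoms$name %in% c("N", "H", "CA"))
  for (k in seq_len(30)) {
    tr <- propose_move("backbone_rotation", sys, sys$xyz, 10, tables)
    still <- setdiff(seq_len(nrow(sys$xyz)), tr$moved)
    expect_identical(tr$xyz[still, ], sys$xyz[still, ])
    # the chain start never moves under any phi/psi pivot
    expect_true(all(first_res_core %in% still))
    # the ligand never rides along with protein moves
    expect_false(any(which(sys$atoms$ligand) %in% tr$moved))
  }
  # backrub: the flanking alpha carbons sit on the rotation axis
  for (dof in seq_len(nrow(tables$backrub))) {
    pr <- tables$backrub[dof, ]
    moving <- tables$backrub_moving(pr[1], pr[2])
    expect_false(sys$residues$calpha[pr[1]] %in% moving)
    expect_false(sys$residues$calpha[pr[2]] %in% moving)
  }
  for (k in seq_len(20)) {
    tr <- propose_move("backrub", sys, sys$xyz, 10, tables)
    still <- setdiff(seq_len(nrow(sys$xyz)), tr$moved)
    expect_identical(tr$xyz[still, ], sys$xyz[still, ])
  }
  # sidechain rotations touch only atomistic-residue side chains
  atomistic <- which(sys$residues$region == "atomistic" &
                       !sys$residues$is_ligand)
  for (dof in tables$sidechain) {
    expect_true(all(sys$atoms$residue[dof$moving] %in% atomistic))
    expect_false(any(sys$atoms$backbone[dof$moving]))
  }
})

test_that("Metropolis acceptance has the exact Boltzmann probability", {
  beta <- simulation_settings()$beta
  expect_true(metropolis_accept(0, beta))
  expect_true(metropolis_accept(-5, beta))
  set.seed(7)
  kT <- 1 / beta
  acc <- mean(vapply(seq_len(1e5), function(i)
    metropolis_accept(kT, beta), logical(1)))
  p <- exp(-1)
  expect_lt(abs(acc - p), 3 * sqrt(p * (1 - p) / 1e5))
  expect_error(metropolis_accept(NaN, beta), "domain error")
})

test_that("the sampler obeys detailed balance on a discrete two-well chain", {
  # 9 lattice states, two wells; neighbour proposals; boundary moves
  # rejected by staying put, which preserves detailed balance
  u <- c(0.0, 1.2, 2.0, 1.2, 0.4, 1.2, 2.0, 1.2, 0.0)
  beta <- 1.6773
  p_exact <- exp(-beta * u) / sum(exp(-beta * u))
  set.seed(99)
  state <- 5L
  n_steps <- 1e6L; stride <- 1000L
  visits <- integer(9)
  samples <- integer(n_steps %/% stride)
  for (t in seq_len(n_steps)) {
    prop <- state + sample(c(-1L, 1L), 1)
    if (prop >= 1L && prop <= 9L &&
        metropolis_accept(u[prop] - u[state], beta)) state <- prop
    if (t %% stride == 0L) samples[t %/% stride] <- state
  }
  n <- length(samples)
  freq <- tabulate(samples, 9) / n
  for (k in 1:9) {
    se <- sqrt(p_exact[k] * (1 - p_exact[k]) / n)
    expect_lt(abs(freq[k] - p_exact[k]), 3 * se + 0.01)
  }
})

test_that("run_mc is deterministic, respects the mode, and keeps books", {
  sys <- small_complex()
  model <- energy_model(sys)
  a <- run_mc(model, 400, seed = 17)
  b <- run_mc(model, 400, seed = 17)
  expect_identical(a$final_xyz, b$final_xyz)
  expect_identical(a$log, b$log)
  # fixed protein: every protein coordinate bit-identical at every snapshot
  fp <- run_mc(model, 400, mix = move_mix("fixed_protein"), seed = 5)
  prot <- which(!sys$atoms$ligand)
  for (s in fp$snapshots)
    expect_identical(s$xyz[prot, ], sys$xyz[prot, ])
  # move-kind frequencies match the mix fractions within binomial 3 sigma
  counts <- table(a$log$kind)
  mix <- move_mix("fully_flexible")
  for (k in names(counts)) {
    p <- mix$fraction[mix$kind == k]
    expect_lt(abs(counts[[k]] / 400 - p), 3 * sqrt(p * (1 - p) / 400))
  }
  # accumulated deltas agree with a full recomputation at the end
  u_full <- mrmcdock:::scaled_total(total_energy(model, a$final_xyz),
                                    c(1, 1))
  expect_lt(abs(a$u_accum - u_full), 1e-6)
  expect_true(all(a$acceptance$accepted <= a$acceptance$attempted))
  # snapshots at the stride plus the final configuration
  expect_equal(vapply(a$snapshots, `[[`, numeric(1), "move"),
               seq(100, 400, by = 100))
  expect_identical(a$snapshots[[4]]$xyz, a$final_xyz)
})

test_that("acceptance-by-size histograms conserve attempt counts", {
  sys <- small_complex()
  model <- energy_model(sys)
  traj <- run_mc(model, 300, seed = 23)
  for (k in unique(traj$log$kind)) {
    h <- acceptance_by_size(traj, kind = k, breaks = 6)
    expect_equal(sum(h$attempted),
                 sum(traj$log$kind == k & !traj$log$noop))
    expect_true(all(h$accepted <= h$attempted))
  }
})
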