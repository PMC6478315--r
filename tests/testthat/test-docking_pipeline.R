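test_that("initial poses respect the placement ball and randomise torsions", {
  sys <- small_complex()
  site <- attr(sys, "site_center")
  lg <- which(sys$atoms$ligand)
  set.seed(12)
  poses <- generate_initial_poses(sys, site, n_poses = 400,
                                  placement_radius = 4)
  expect_length(poses, 400)
  disp <- vapply(poses, function(p)
    sqrt(sum((colMeans(p[lg, , drop = FALSE]) - site)^2)), numeric(1))
  expect_true(all(disp <= 4))
  # the protein is untouched by pose generation
  prot <- which(!sys$atoms$ligand)
  expect_identical(poses[[1]][prot, ], sys$xyz[prot, ])
  # with a rotatable bond, internal torsions vary between poses
  rb <- sys$rotatable_bonds[[1]]
  tor <- vapply(poses[1:50], function(p)
    mrmcdock:::dihedral_value(p[rb$moving[1], ], p[rb$atoms[1], ],
                              p[rb$atoms[2], ],
                              p[setdiff(which(sys$atoms$ligand),
                                        c(rb$atoms, rb$moving))[1], ]),
    numeric(1))
  expect_gt(stats::sd(tor), 0.3)
  # determinism under a fixed seed
  set.seed(12)
  poses2 <- generate_initial_poses(sys, site, n_poses = 400,
                                   placement_radius = 4)
  expect_identical(poses, poses2)
})

test_that("a rigid ligand yields poses differing only by rigid placement", {
  toy <- make_two_state_toy()        # single-atom ligand, no torsions
  set.seed(3)
  poses <- generate_initial_poses(toy$system, c(0, 0, 0), n_poses = 20,
                                  placement_radius = 4)
  lg <- which(toy$system$atoms$ligand)
  for (p in poses) expect_equal(dim(p), dim(toy$system$xyz))
  # rigid: intra-ligand distances preserved (trivially, one atom) and the
  # receptor rows identical
  rec <- which(!toy$system$atoms$ligand)
  for (p in poses[1:5]) expect_identical(p[rec, ], toy$system$xyz[rec, ])
})

test_that("seed-pose selection is an argmin with first-index tie-breaking", {
  poses <- list(matrix(1, 2, 3), matrix(2, 2, 3), matrix(3, 2, 3))
  fake_energy <- function(x) c(5, -2, 7)[round(x[1, 1])]
  sel <- select_seed_pose(poses, fake_energy)
  expect_equal(sel$index, 2)
  expect_equal(sel$energy, -2)
  sel2 <- select_seed_pose(poses, function(x) 1)
  expect_equal(sel2$index, 1)
  expect_error(select_seed_pose(list(), function(x) 0), "validation error")
  # large scan matches an explicit brute-force minimum
  set.seed(8)
  sys <- small_complex()
  model <- energy_model(sys)
  poses <- generate_initial_poses(sys, attr(sys, "site_center"), 200, 4)
  efn <- function(x) total_energy(model, x)$total
  sel3 <- select_seed_pose(poses, efn)
  all_e <- vapply(poses, efn, numeric(1))
  expect_equal(sel3$index, which.min(all_e))
  expect_equal(sel3$energy, min(all_e))
})

test_that("docking campaigns are reproducible and internally consistent", {
  sys <- small_complex()
  model <- energy_model(sys)
  spec <- docking_run_spec("mc", n_trial_moves = 200, n_initial_poses = 30,
                           site_center = attr(sys, "site_center"),
                           rng_seed = 77, stride = 100)
  camp <- run_campaign(list(neutral = model), spec, n_runs_per_variant = 2,
                       references = list(sys$xyz))
  expect_equal(nrow(camp$records), 2)
  expect_equal(length(camp$poses), 2)
  expect_false(camp$records$seed[1] == camp$records$seed[2])
  expect_true(all(is.finite(camp$records$interaction_energy)))
  expect_true(all(is.finite(camp$records$total_energy)))
  # report energies equal recomputed energies of the stored configurations
  for (r in seq_len(nrow(camp$records))) {
    xyz <- camp$poses[[camp$records$run[r]]]
    expect_lt(abs(camp$records$total_energy[r] -
                    total_energy(model, xyz)$total), 1e-6)
    expect_lt(abs(camp$records$interaction_energy[r] -
                    interaction_energy(model, xyz)), 1e-6)
  }
  # same master seed, same report
  camp2 <- run_campaign(list(neutral = model), spec, n_runs_per_variant = 2,
                        references = list(sys$xyz))
  expect_identical(camp$records, camp2$records)
  # tab-separated report round-trips
  path <- withr::local_tempfile(fileext = ".tsv")
  write_campaign_report(camp, path)
  back <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(back), nrow(camp$records))
  expect_equal(back$interaction_energy, camp$records$interaction_energy)
})

test_that("docking run specs default to the production protocol", {
  mc <- docking_run_spec("mc")
  expect_equal(mc$n_trial_moves, 40000)
  expect_equal(mc$n_initial_poses, 1000)
  expect_equal(mc$placement_radius, 4)
  nc <- docking_run_spec("ncmc_mixed")
  expect_equal(nc$n_trial_moves, 80000)
})

test_that("the ncmc_mixed protocol runs end to end in a docking run", {
  toy <- make_two_state_toy()
  model <- energy_model(toy$system, wall = toy$wall)
  spec <- docking_run_spec("ncmc_mixed", n_trial_moves = 1600,
                           n_initial_poses = 20,
                           site_center = c(0, 0, 0), mode = "fixed_protein",
                           rng_seed = 5)
  run <- run_docking(model, spec)
  expect_s3_class(run, "docking_run")
  expect_gte(nrow(run$trajectory$ncmc_log), 1)
  expect_true(is.finite(run$pose$interaction_energy))
})
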