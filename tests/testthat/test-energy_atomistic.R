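test_that("the SEDDD dielectric reproduces its closed form", {
  p <- seddd_parameters()
  expect_equal(p$eps0, 2); expect_equal(p$eps1, 8); expect_equal(p$c, 0.625)
  # fully exposed pair at 10 A: effective dielectric 80
  expect_equal(seddd_dielectric(10, 0, p), 80)
  # fully buried limit approaches eps0 * r
  expect_equal(seddd_dielectric(1, 1 - 1e-12, p), 2, tolerance = 1e-9)
  expect_equal(seddd_dielectric(5, 0.5, p), 5 * (2 + 0.5 * 6))
  expect_error(seddd_dielectric(-1, 0, p), "domain error")
  expect_error(seddd_dielectric(5, 1.2, p), "domain error")
  # linear in r, non-increasing in s
  r <- seq(0.5, 12, by = 0.25)
  expect_equal(seddd_dielectric(r, 0.3, p) / r,
               rep(seddd_dielectric(1, 0.3, p), length(r)))
  s <- seq(0, 0.999, by = 1e-3)
  expect_true(all(diff(seddd_dielectric(5, s, p)) <= 0))
})

test_that("pair overlap is symmetric, clamped and zero for exposed groups", {
  expect_equal(pair_overlap(0, 0), 0)
  expect_equal(pair_overlap(0.5, 0.3), 0.5)      # c (vk + vl) = 0.625 * 0.8
  expect_equal(pair_overlap(0.3, 0.5), pair_overlap(0.5, 0.3))
  s <- pair_overlap(1, 1)                        # c * 2 = 1.25, clamped
  expect_true(s >= 0 && s < 1)
  expect_equal(s, 1 - 1e-9)
  expect_error(pair_overlap(-0.1, 0), "domain error")
})

test_that("hydration occlusion is zero when isolated, max when coincident,
           and decays with neighbour distance", {
  mk_two <- function(d) {
    atoms <- rbind(
      data.frame(name = "C1", element = "C", charge = 0, rmin_half = 1.9,
                 epsilon = 0, residue = 1, group = 1, backbone = FALSE,
                 ligand = FALSE, solv_volume = 25, solv_sigma = 3.5),
      data.frame(name = "C2", element = "C", charge = 0, rmin_half = 1.9,
                 epsilon = 0, residue = 2, group = 2, backbone = FALSE,
                 ligand = TRUE, solv_volume = 25, solv_sigma = 3.5))
    residues <- data.frame(name = c("AAA", "LIG"), region = "atomistic",
                           calpha = NA_integer_,
                           is_ligand = c(FALSE, TRUE))
    molecular_system(atoms, rbind(c(0, 0, 0), c(d, 0, 0)), residues,
                     ligand_bonds = data.frame(i = integer(), j = integer(),
                                               order = numeric()))
  }
  iso <- energy_model(mk_two(50))
  expect_equal(compute_hydration_volumes(iso), c(0, 0))
  # coincident neighbour saturates the clamp (configured maximum 1)
  co <- energy_model(mk_two(0))
  expect_equal(compute_hydration_volumes(co), c(1, 1))
  # monotone decay over a neighbour-distance scan
  vs <- vapply(seq(1.5, 9.5, by = 0.5), function(d)
    compute_hydration_volumes(energy_model(mk_two(d)))[1], numeric(1))
  expect_true(all(diff(vs) < 0))
  expect_true(all(vs >= 0 & vs <= 1))
  # the intra-moiety variant sees no cross-moiety occluder
  expect_equal(compute_hydration_volumes(energy_model(mk_two(3)),
                                         occluders = "intra"), c(0, 0))
})

test_that("two unit charges fully exposed at 10 A give the closed-form energy", {
  atoms <- do.call(rbind, lapply(1:2, function(i)
    data.frame(name = paste0("Q", i), element = "C", charge = 1,
               rmin_half = 0.1, epsilon = 0, residue = i, group = i,
               backbone = FALSE, ligand = i == 2, solv_volume = 0,
               solv_sigma = 3.5)))
  residues <- data.frame(name = c("QQQ", "LIG"), region = "atomistic",
                         calpha = NA_integer_, is_ligand = c(FALSE, TRUE))
  sys <- molecular_system(atoms, rbind(c(0, 0, 0), c(10, 0, 0)), residues,
                          ligand_bonds = data.frame(i = integer(),
                                                    j = integer(),
                                                    order = numeric()))
  model <- energy_model(sys)
  e <- total_energy(model, sys$xyz)
  expect_equal(e$u_elec_int, 332.0636 / (80 * 10), tolerance = 1e-12)
  # past the cutoff the pair vanishes
  xyz <- sys$xyz; xyz[2, 1] <- 10.1
  expect_equal(total_energy(model, xyz)$u_elec_int, 0)
  # at s = 0 the pair energy scales as 1/r^2 (dielectric linear in r)
  rs <- seq(2, 9, by = 0.5)
  es <- vapply(rs, function(r) {
    xyz[2, 1] <- r; total_energy(model, xyz)$u_elec_int
  }, numeric(1))
  expect_equal(es, es[1] * (rs[1] / rs)^2, tolerance = 1e-9)
})

test_that("an LJ pair at its minimum distance has depth sqrt(eps_i eps_j)", {
  atoms <- do.call(rbind, lapply(1:2, function(i)
    data.frame(name = paste0("C", i), element = "C", charge = 0,
               rmin_half = 1.7, epsilon = c(0.2, 0.45)[i], residue = i,
               group = i, backbone = FALSE, ligand = i == 2,
               solv_volume = 0, solv_sigma = 3.5)))
  residues <- data.frame(name = c("CCC", "LIG"), region = "atomistic",
                         calpha = NA_integer_, is_ligand = c(FALSE, TRUE))
  sys <- molecular_system(atoms, rbind(c(0, 0, 0), c(3.4, 0, 0)), residues,
                          ligand_bonds = data.frame(i = integer(),
                                                    j = integer(),
                                                    order = numeric()))
  model <- energy_model(sys)
  expect_equal(total_energy(model, sys$xyz)$u_vdw_int, -sqrt(0.2 * 0.45),
               tolerance = 1e-12)
  # overlapping atoms are capped, finite, and flagged
  xyz <- sys$xyz; xyz[2, ] <- xyz[1, ]
  e <- total_energy(model, xyz)
  expect_true(is.finite(e$total))
  expect_true(e$clash)
})

test_that("the full potential equals the naive all-pairs oracle", {
  sys <- small_complex()   # 84 atoms, mixed regions, ligand
  model <- energy_model(sys)
  for (case in 1:3) {
    set.seed(100 + case)
    xyz <- sys$xyz + 0.15 * matrix(rnorm(length(sys$xyz)), ncol = 3)
    e <- total_energy(model, xyz)
    orc <- oracle_energy(sys, xyz)
    for (f in c("u_cg", "u_bb", "u_go", "u_protein", "u_ligand",
                "u_vdw_int", "u_elec_int", "total"))
      expect_lt(abs(e[[f]] - orc[[f]]), 1e-8)
  }
})

test_that("the coupling views of the total energy are consistent", {
  sys <- small_complex()
  model <- energy_model(sys)
  e <- total_energy(model, sys$xyz, lambda = c(1, 1))
  # Eq-1-style and coupling-style assemblies agree at full coupling
  expect_lt(abs(e$total - (e$u_cg + e$u_aa + e$u_cg_aa + e$u_restraint)),
            1e-8 * max(1, abs(e$total)))
  # interaction terms are exactly the lambda-scaled terms
  e0 <- total_energy(model, sys$xyz, lambda = c(0, 0))
  expect_equal(e$total - e0$total, e$u_vdw_int + e$u_elec_int,
               tolerance = 1e-10)
  expect_equal(interaction_energy(model, sys$xyz),
               e$u_vdw_int + e$u_elec_int)
  # at lambda = 0 the total ignores the ligand pose entirely
  lg <- which(sys$atoms$ligand)
  xyz2 <- sys$xyz
  xyz2[lg, ] <- sweep(xyz2[lg, , drop = FALSE], 2, c(5, 0, 0), `+`)
  expect_lt(abs(total_energy(model, xyz2, c(0, 0))$total - e0$total), 1e-8)
  # ligand far outside the cutoff: zero interaction
  xyz3 <- sys$xyz
  xyz3[lg, ] <- sweep(xyz3[lg, , drop = FALSE], 2, c(200, 0, 0), `+`)
  expect_equal(interaction_energy(model, xyz3), 0)
})

test_that("energy is invariant under global rigid transforms", {
  sys <- small_complex()
  model <- energy_model(sys)
  e0 <- total_energy(model, sys$xyz)$total
  R <- mrmcdock:::rotation_matrix(c(1, 2, 3), 1.1)
  xyz <- sweep(sys$xyz %*% t(R), 2, c(5, -3, 11), `+`)
  expect_lt(abs(total_energy(model, xyz)$total - e0), 1e-8)
})

test_that("nonbonded class sums partition the pair energies", {
  sys <- small_complex()
  model <- energy_model(sys)
  nb <- nonbonded_energy(model, sys$xyz)
  e <- total_energy(model, sys$xyz)
  expect_equal(sum(nb$u_vdw[nb$class %in% c("lig_prot_aa", "lig_prot_cg")]),
               e$u_vdw_int)
  expect_equal(sum(nb$u_elec[nb$class %in% c("lig_prot_aa", "lig_prot_cg")]),
               e$u_elec_int)
})
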