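# Synthetic, fully parameterised receptor-ligand fixtures.  Magnitudes are
# chosen so that ligand moves at 300 K have nontrivial acceptance and no
# built-in steric clash: small LJ radii (Rmin/2 1.0 A heavy, 0.5 A hydrogen),
# modest well depths, and bonded equilibria taken from the built geometry so
# the reference configuration is an exact minimum of every bonded term.

toy_lj <- function(element) {
  switch(element,
         H = c(rmin_half = 0.5, epsilon = 0.02),
         O = c(rmin_half = 1.0, epsilon = 0.15),
         N = c(rmin_half = 1.0, epsilon = 0.12),
         c(rmin_half = 1.0, epsilon = 0.10))
}

toy_solv <- function(element) {
  switch(element,
         H = c(volume = 0, sigma = 3.5),
         O = c(volume = 15, sigma = 3.5),
         N = c(volume = 15, sigma = 3.5),
         c(volume = 20, sigma = 3.5))
}

toy_atom_row <- function(name, element, charge, residue, backbone, ligand) {
  lj <- toy_lj(element); sv <- toy_solv(element)
  data.frame(name = name, element = element, charge = charge,
             rmin_half = lj[["rmin_half"]], epsilon = lj[["epsilon"]],
             residue = residue, group = NA_integer_, backbone = backbone,
             ligand = ligand, solv_volume = sv[["volume"]],
             solv_sigma = sv[["sigma"]], stringsAsFactors = FALSE)
}

# Enumerate bonded terms from a bond list and build-geometry equilibria.
build_bonded_terms <- function(xyz, bond_pairs, k_bond = 100, k_angle = 30,
                               v_dihedral = 0.5) {
  bonds <- data.frame(i = bond_pairs[, 1], j = bond_pairs[, 2],
                      k = k_bond,
                      r0 = sqrt(rowSums((xyz[bond_pairs[, 1], , drop = FALSE] -
                                         xyz[bond_pairs[, 2], , drop = FALSE])^2)))
  adj <- lapply(seq_len(nrow(xyz)), function(i)
    c(bond_pairs[bond_pairs[, 1] == i, 2], bond_pairs[bond_pairs[, 2] == i, 1]))
  ang <- list()
  for (j in seq_len(nrow(xyz))) {
    nb <- adj[[j]]
    if (length(nb) < 2) next
    for (x in seq_along(nb)) for (y in seq_along(nb)) {
      if (y <= x) next
      ang[[length(ang) + 1L]] <- c(nb[x], j, nb[y])
    }
  }
  angles <- if (length(ang)) {
    am <- do.call(rbind, ang)
    data.frame(i = am[, 1], j = am[, 2], k = am[, 3], kt = k_angle,
               theta0 = vapply(seq_len(nrow(am)), function(r)
                 angle_value(xyz[am[r, 1], ], xyz[am[r, 2], ],
                             xyz[am[r, 3], ]), numeric(1)))
  } else empty_angles()
  dih <- list()
  sin_ok <- function(p1, p2, p3) {
    # reject near-collinear triples whose torsion plane is ill-defined
    v1 <- p1 - p2; v2 <- p3 - p2
    cr <- c(v1[2] * v2[3] - v1[3] * v2[2],
            v1[3] * v2[1] - v1[1] * v2[3],
            v1[1] * v2[2] - v1[2] * v2[1])
    sqrt(sum(cr^2)) > 1e-3
  }
  for (b in seq_len(nrow(bond_pairs))) {
    j <- bond_pairs[b, 1]; k <- bond_pairs[b, 2]
    for (i in setdiff(adj[[j]], k)) for (l in setdiff(adj[[k]], j)) {
      if (i == l) next
      if (!sin_ok(xyz[i, ], xyz[j, ], xyz[k, ]) ||
          !sin_ok(xyz[j, ], xyz[k, ], xyz[l, ])) next
      dih[[length(dih) + 1L]] <- c(i, j, k, l)
    }
  }
  dihedrals <- if (length(dih)) {
    dm <- do.call(rbind, dih)
    phi0 <- vapply(seq_len(nrow(dm)), function(r)
      dihedral_value(xyz[dm[r, 1], ], xyz[dm[r, 2], ], xyz[dm[r, 3], ],
                     xyz[dm[r, 4], ]), numeric(1))
    # single Fourier term (n = 1) with its minimum at the built torsion
    data.frame(i = dm[, 1], j = dm[, 2], k = dm[, 3], l = dm[, 4],
               vn = v_dihedral, n = 1, gamma = phi0 + pi)
  } else empty_dihedrals()
  list(bonds = bonds, angles = angles, dihedrals = dihedrals)
}

#' Generate a synthetic helical receptor
#'
#' Builds a helix-like alpha-carbon trace with full backbone atoms
#' (N, H, CA, HA, C, O) and a two-bead side chain (CB, CG) per residue, all
#' bonded terms parameterised with equilibria at the built geometry.  A
#' binding-site centre is placed outside the helix surface at mid-height and
#' the `n_atomistic_residues` residues closest to it form the atomistic
#' region (a concave patch of the helix face); the rest are coarse.
#'
#' @param n_residues Number of residues (positive).
#' @param n_atomistic_residues Size of the atomistic patch (<= n_residues).
#' @param seed Integer; the construction is deterministic, the seed is
#'   recorded for provenance.
#' @return An `mrmc_system` (receptor only) with attribute `"site_center"`.
#' @export
make_toy_receptor <- function(n_residues = 16, n_atomistic_residues = 6,
                              seed = 1) {
  stopifnot(n_residues >= 4, n_atomistic_residues <= n_residues,
            n_atomistic_residues >= 1)
  rise <- 1.5; radius <- 2.3; turn <- deg2rad(100)
  ca <- t(vapply(seq_len(n_residues), function(r)
    c(radius * cos(r * turn), radius * sin(r * turn), rise * r),
    numeric(3)))
  out_v <- t(apply(ca, 1, function(p) {
    v <- c(p[1], p[2], 0); v / sqrt(sum(v^2))
  }))
  atoms <- list(); coords <- list()
  bond_pairs <- list()
  idx <- 0L
  at_idx <- function(res, k) (res - 1L) * 8L + k   # 8 atoms per residue
  for (r in seq_len(n_residues)) {
    d_prev <- if (r > 1) ca[r - 1, ] - ca[r, ] else ca[r, ] - ca[r + 1, ]
    d_next <- if (r < n_residues) ca[r + 1, ] - ca[r, ] else ca[r, ] - ca[r - 1, ]
    N <- ca[r, ] + 0.32 * d_prev
    hdir <- out_v[r, ] + c(0, 0, 0.6)
    H <- N + 1.0 * hdir / sqrt(sum(hdir^2))
    CA <- ca[r, ]
    hadir <- -out_v[r, ] + c(0, 0, -0.9)
    HA <- CA + 1.0 * hadir / sqrt(sum(hadir^2))
    C <- ca[r, ] + 0.36 * d_next
    O <- C + 1.23 * out_v[r, ]
    CB <- CA + 1.53 * out_v[r, ]
    sidedir <- out_v[r, ] + c(0, 0, 0.8)
    CG <- CB + 1.53 * sidedir / sqrt(sum(sidedir^2))
    coords[[r]] <- rbind(N, H, CA, HA, C, O, CB, CG)
    atoms[[r]] <- do.call(rbind, list(
      toy_atom_row("N", "N", -0.30, r, TRUE, FALSE),
      toy_atom_row("H", "H", 0.30, r, TRUE, FALSE),
      toy_atom_row("CA", "C", 0.00, r, TRUE, FALSE),
      toy_atom_row("HA", "H", 0.00, r, TRUE, FALSE),
      toy_atom_row("C", "C", 0.30, r, TRUE, FALSE),
      toy_atom_row("O", "O", -0.30, r, TRUE, FALSE),
      toy_atom_row("CB", "C", 0.05, r, FALSE, FALSE),
      toy_atom_row("CG", "C", -0.05, r, FALSE, FALSE)))
    # intra-residue bonds
    for (pr in list(c(1, 3), c(1, 2), c(3, 4), c(3, 5), c(5, 6), c(3, 7),
                    c(7, 8)))
      bond_pairs[[length(bond_pairs) + 1L]] <-
        c(at_idx(r, pr[1]), at_idx(r, pr[2]))
    if (r > 1)   # peptide bond C(r-1) - N(r)
      bond_pairs[[length(bond_pairs) + 1L]] <-
        c(at_idx(r - 1L, 5L), at_idx(r, 1L))
  }
  xyz <- do.call(rbind, coords)
  rownames(xyz) <- NULL
  atoms_df <- do.call(rbind, atoms)
  atoms_df$group <- default_groups(atoms_df)
  mid <- ceiling(n_residues / 2)
  site <- ca[mid, ] + 6.5 * out_v[mid, ]
  d_site <- sqrt(rowSums(sweep(ca, 2, site)^2))
  atomistic <- order(d_site)[seq_len(n_atomistic_residues)]
  residues <- data.frame(
    name = "ALA",
    region = ifelse(seq_len(n_residues) %in% atomistic, "atomistic",
                    "coarse"),
    calpha = vapply(seq_len(n_residues), at_idx, integer(1), k = 3L),
    is_ligand = FALSE, stringsAsFactors = FALSE)
  bt <- build_bonded_terms(xyz, do.call(rbind, bond_pairs))
  sys <- molecular_system(atoms_df, xyz, residues, bt$bonds, bt$angles,
                          bt$dihedrals)
  attr(sys, "site_center") <- site
  attr(sys, "seed") <- seed
  sys
}

#' Generate a synthetic ligand
#'
#' Chain ligands are heavy-atom carbon chains in a zigzag geometry with
#' `n_rotatable_bonds + 3` atoms, giving exactly the requested number of
#' rotatable bonds.  Symmetric ligands are a six-membered carbon ring with
#' two identical oxygen substituents in para positions, whose bond graph has
#' a nontrivial automorphism group (order 4).
#'
#' @param n_rotatable_bonds Number of rotatable bonds for chain ligands.
#' @param symmetric Build the para-disubstituted ring instead of a chain.
#' @param seed Recorded for provenance; the construction is deterministic.
#' @return An `"mrmc_ligand"` with elements, coordinates, bonds, rotatable
#'   bonds and per-atom toy parameters in `$params` (charge, LJ, solvation).
#' @export
make_toy_ligand <- function(n_rotatable_bonds = 1, symmetric = FALSE,
                            seed = 1) {
  if (symmetric) {
    th <- deg2rad(seq(0, 300, by = 60))
    ring <- cbind(1.4 * cos(th), 1.4 * sin(th), 0)
    o1 <- c((1.4 + 1.36), 0, 0)
    o2 <- c(-(1.4 + 1.36), 0, 0)
    xyz <- rbind(ring, o1, o2)
    elements <- c(rep("C", 6), "O", "O")
    bonds <- data.frame(
      i = c(1, 2, 3, 4, 5, 6, 1, 4),
      j = c(2, 3, 4, 5, 6, 1, 7, 8),
      order = 1)
    charge <- c(0.2, 0, 0, 0.2, 0, 0, -0.2, -0.2)
  } else {
    n <- n_rotatable_bonds + 3L
    xyz <- matrix(0, n, 3)
    for (i in seq_len(n)[-1]) {
      dir <- if (i %% 2 == 0) c(1, 0.55, 0) else c(1, -0.55, 0)
      xyz[i, ] <- xyz[i - 1, ] + 1.53 * dir / sqrt(sum(dir^2))
    }
    elements <- rep("C", n)
    bonds <- data.frame(i = seq_len(n - 1), j = 2:n, order = 1)
    charge <- rep_len(c(0.1, -0.1), n)
    if (n %% 2 == 1) charge[n] <- 0
  }
  params <- do.call(rbind, lapply(seq_along(elements), function(i)
    toy_atom_row(paste0(elements[i], i), elements[i], charge[i], 1L,
                 FALSE, TRUE)))
  lig <- list(elements = elements, xyz = xyz, bonds = bonds,
              rotatable_bonds = detect_rotatable_bonds(bonds, elements),
              params = params, seed = seed)
  class(lig) <- "mrmc_ligand"
  lig
}

#' Assemble a toy receptor-ligand complex
#'
#' Places the ligand centroid at the receptor's binding-site centre and
#' merges topologies into one parameterised `mrmc_system` ready for
#' [energy_model()].
#'
#' @param receptor From [make_toy_receptor()] (or equivalent).
#' @param ligand From [make_toy_ligand()].
#' @return An `mrmc_system` with attribute `"site_center"`.
#' @export
make_toy_complex <- function(receptor = make_toy_receptor(),
                             ligand = make_toy_ligand()) {
  site <- attr(receptor, "site_center")
  n_prot <- nrow(receptor$atoms)
  lxyz <- sweep(ligand$xyz, 2, colMeans(ligand$xyz))
  lxyz <- sweep(lxyz, 2, site, `+`)
  lp <- ligand$params
  lp$residue <- nrow(receptor$residues) + 1L
  lp$group <- NA_integer_
  atoms <- rbind(receptor$atoms, lp)
  atoms$group <- default_groups(atoms)
  residues <- rbind(receptor$residues,
                    data.frame(name = "LIG", region = "atomistic",
                               calpha = NA_integer_, is_ligand = TRUE,
                               stringsAsFactors = FALSE))
  xyz <- rbind(receptor$xyz, lxyz)
  lig_bonds_abs <- data.frame(i = ligand$bonds$i + n_prot,
                              j = ligand$bonds$j + n_prot,
                              order = ligand$bonds$order)
  lig_bt <- build_bonded_terms(xyz,
                               as.matrix(lig_bonds_abs[, c("i", "j")]),
                               k_bond = 100, k_angle = 30, v_dihedral = 0.3)
  sys <- molecular_system(
    atoms, xyz, residues,
    bonds = rbind(receptor$bonds, lig_bt$bonds),
    angles = rbind(receptor$angles, lig_bt$angles),
    dihedrals = rbind(receptor$dihedrals, lig_bt$dihedrals),
    ligand_bonds = lig_bonds_abs,
    rotatable_bonds = detect_rotatable_bonds(lig_bonds_abs, atoms$element))
  attr(sys, "site_center") <- site
  sys
}

#' Two-state binding toy with exact Boltzmann weights
#'
#' A rigid two-atom receptor whose atoms form two Lennard-Jones pockets of
#' different depth, with a single-atom apolar ligand confined to a
#' spherical wall.  The partition-function ratio of the two half-space pose
#' basins (ligand x < 0 vs x > 0) is computable by dense quadrature over
#' the ligand's translational coordinates via [two_state_weights()].
#'
#' @param eps_a,eps_b LJ well depths (kcal/mol) of the two pocket atoms;
#'   equal depths give weight ratio 1 by symmetry.
#' @param separation Distance between the pocket atoms, A.
#' @param wall_radius Confinement radius about the midpoint, A.
#' @return list of class `"two_state_toy"`: `system`, `wall`, the pocket
#'   positions `pos_a`/`pos_b`, and the ligand LJ parameters.
#' @export
make_two_state_toy <- function(eps_a = 2.0, eps_b = 0.5, separation = 7,
                               wall_radius = 9) {
  pos_a <- c(-separation / 2, 0, 0)
  pos_b <- c(separation / 2, 0, 0)
  mk <- function(nm, eps, res) {
    row <- toy_atom_row(nm, "C", 0, res, FALSE, FALSE)
    row$rmin_half <- 1.5; row$epsilon <- eps
    row
  }
  lig_row <- toy_atom_row("L1", "C", 0, 3L, FALSE, TRUE)
  lig_row$rmin_half <- 1.5; lig_row$epsilon <- 0.4
  atoms <- rbind(mk("PA", eps_a, 1L), mk("PB", eps_b, 2L), lig_row)
  atoms$group <- 1:3
  start <- pos_a - c(3.0, 0, 0)        # at the LJ minimum of pocket A
  xyz <- rbind(pos_a, pos_b, start)
  residues <- data.frame(name = c("PKA", "PKB", "LIG"),
                         region = "atomistic",
                         calpha = NA_integer_,
                         is_ligand = c(FALSE, FALSE, TRUE),
                         stringsAsFactors = FALSE)
  sys <- molecular_system(atoms, xyz, residues,
                          ligand_bonds = data.frame(i = integer(),
                                                    j = integer(),
                                                    order = numeric()))
  out <- list(system = sys,
              wall = list(center = c(0, 0, 0), radius = wall_radius),
              pos_a = pos_a, pos_b = pos_b,
              eps_pair_a = sqrt(eps_a * 0.4), eps_pair_b = sqrt(eps_b * 0.4),
              rmin_pair = 3.0)
  class(out) <- "two_state_toy"
  out
}

# Analytic potential of the two-state toy for a ligand at positions x
# (m x 3): sum of the two truncated LJ pocket terms.  Matches the package
# energy model because the toy has zero charges and no bonded terms.
two_state_potential <- function(toy, x, cutoff = 10) {
  lj <- function(d, eps) {
    xr <- (toy$rmin_pair / pmax(d, 1e-6))^6
    e <- eps * (xr^2 - 2 * xr)
    e[d > cutoff] <- 0
    pmin(e, PAIR_ENERGY_CAP)
  }
  da <- sqrt(rowSums(sweep(x, 2, toy$pos_a)^2))
  db <- sqrt(rowSums(sweep(x, 2, toy$pos_b)^2))
  lj(da, toy$eps_pair_a) + lj(db, toy$eps_pair_b)
}

#' Quadrature Boltzmann weights of the two-state toy
#'
#' Dense trapezoidal quadrature of `exp(-beta U)` over the ligand's
#' translational coordinates inside the confinement wall, split into the
#' two half-space basins (x < 0 belongs to pocket A).
#'
#' @param toy A [make_two_state_toy()] object.
#' @param settings A [simulation_settings()] (provides beta and cutoff).
#' @param spacing Grid spacing, A (default 0.25).
#' @return Named numeric `c(A = wA, B = wB)` with `wA + wB = 1`.
#' @export
two_state_weights <- function(toy, settings = simulation_settings(),
                              spacing = 0.25) {
  R <- toy$wall$radius
  g <- seq(-R, R, by = spacing)
  grid <- as.matrix(expand.grid(x = g, y = g, z = g))
  inside <- sqrt(rowSums(grid^2)) <= R
  grid <- grid[inside, , drop = FALSE]
  u <- two_state_potential(toy, grid, cutoff = settings$nonbonded_cutoff)
  bw <- exp(-settings$beta * u)
  wa <- sum(bw[grid[, 1] < 0]); wb <- sum(bw[grid[, 1] >= 0])
  c(A = wa / (wa + wb), B = wb / (wa + wb))
}

#' Single-particle harmonic-well calibration fixture
#'
#' One far-away receptor atom (outside the nonbonded cutoff) and a
#' single-atom ligand held by a centroid restraint `U = (k/2) |x - x0|^2`,
#' so each sampled coordinate has exact variance `kB T / k`.  Used to
#' calibrate the MC engine against the Boltzmann closed form.
#'
#' @param k Restraint force constant, kcal/mol/A^2.
#' @return list with `system` and `restraint` (pass both to
#'   [energy_model()]).
#' @export
make_harmonic_toy <- function(k = 1.0) {
  rec <- toy_atom_row("PX", "C", 0, 1L, FALSE, FALSE)
  rec$epsilon <- 0
  lig <- toy_atom_row("L1", "C", 0, 2L, FALSE, TRUE)
  lig$epsilon <- 0
  atoms <- rbind(rec, lig)
  atoms$group <- 1:2
  center <- c(25, 0, 0)
  xyz <- rbind(c(0, 0, 0), center)
  residues <- data.frame(name = c("PKX", "LIG"), region = "atomistic",
                         calpha = NA_integer_,
                         is_ligand = c(FALSE, TRUE), stringsAsFactors = FALSE)
  sys <- molecular_system(atoms, xyz, residues,
                          ligand_bonds = data.frame(i = integer(),
                                                    j = integer(),
                                                    order = numeric()))
  list(system = sys, restraint = list(center = center, k = k))
}

#' Write a toy fixture to structure + parameter files
#'
#' Emits the PDB structure, the native-schema parameter file and, when the
#' system has a ligand bond graph, the ligand connectivity, so any toy can
#' be round-tripped through the file interfaces.
#'
#' @param sys An `mrmc_system`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Named character vector of the written paths.
#' @export
write_fixture <- function(sys, dir, prefix = "toy") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pdb <- file.path(dir, paste0(prefix, ".pdb"))
  par <- file.path(dir, paste0(prefix, ".par"))
  write_structure(sys, pdb)
  write_parameters(sys, par)
  c(pdb = pdb, par = par)
}
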