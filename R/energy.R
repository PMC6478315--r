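#' SEDDD solvation parameters
#'
#' Parameters of the solvent-exposure-dependent distance-dependent
#' dielectric.  Defaults are the production values: low dielectric 2, high
#' dielectric 8, hydration-overlap constant 0.625.  Note a slope of 8 per
#' Angstrom corresponds to a constant dielectric of 80 at 10 A separation.
#'
#' @param eps0 Low (buried) dielectric constant, dimensionless.
#' @param eps1 High (exposed) dielectric constant, dimensionless.
#' @param c Constant converting summed hydration-shell occlusions into the
#'   pair overlap `s_kl = c (v_k + v_l)`.
#' @return An object of class `"seddd_parameters"`.
#' @export
seddd_parameters <- function(eps0 = 2, eps1 = 8, c = 0.625) {
  stopifnot(eps1 > eps0, eps0 > 0, c >= 0)
  structure(list(eps0 = eps0, eps1 = eps1, c = c),
            class = "seddd_parameters")
}

#' Hydration-shell pair overlap
#'
#' `s_kl = c (v_k + v_l)`, clamped to `[0, 1 - 1e-9]` so that the dielectric
#' interpolation stays inside its stated range `0 <= s_kl < 1`.  Symmetric
#' in its arguments; vectorised.
#'
#' @param v_k,v_l Hydration-shell occlusion fractions (>= 0).
#' @param c Overlap constant (default from [seddd_parameters()]).
#' @return `s_kl`, dimensionless.
#' @export
pair_overlap <- function(v_k, v_l, c = seddd_parameters()$c) {
  if (any(v_k < 0) || any(v_l < 0))
    stop("domain error: hydration volumes must be non-negative")
  pmin(c * (v_k + v_l), 1 - 1e-9)
}

#' SEDDD effective dielectric
#'
#' `eps_ij = r_ij * (eps0 + (1 - s_kl) * (eps1 - eps0))`: linear in distance,
#' non-increasing in burial.  Fully exposed pairs (`s = 0`) at 10 A with the
#' default constants give an effective dielectric of 80.
#'
#' @param r_ij Interatomic distance(s), A (> 0).
#' @param s_kl Hydration overlap(s) in `[0, 1)`.
#' @param params A [seddd_parameters()] object.
#' @return Effective dielectric, dimensionless; vectorised.
#' @export
seddd_dielectric <- function(r_ij, s_kl, params = seddd_parameters()) {
  if (any(r_ij <= 0)) stop("domain error: r_ij must be positive")
  if (any(s_kl < 0 | s_kl >= 1))
    stop("domain error: s_kl must lie in [0, 1)")
  r_ij * (params$eps0 + (1 - s_kl) * (params$eps1 - params$eps0))
}

# Pair energy cap (kcal/mol) keeping exp(-beta * dU) well-defined for clashes.
PAIR_ENERGY_CAP <- 1e6
WALL_ENERGY <- 1e6

# Row-wise cross product of 3-column matrices.
cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

bond_energy_vec <- function(xyz, tbl) {
  if (nrow(tbl) == 0) return(numeric(0))
  d <- sqrt(rowSums((xyz[tbl$i, , drop = FALSE] -
                     xyz[tbl$j, , drop = FALSE])^2))
  tbl$k * (d - tbl$r0)^2
}

angle_energy_vec <- function(xyz, tbl) {
  if (nrow(tbl) == 0) return(numeric(0))
  v1 <- xyz[tbl$i, , drop = FALSE] - xyz[tbl$j, , drop = FALSE]
  v2 <- xyz[tbl$k, , drop = FALSE] - xyz[tbl$j, , drop = FALSE]
  ct <- rowSums(v1 * v2) / sqrt(rowSums(v1^2) * rowSums(v2^2))
  th <- acos(pmin(1, pmax(-1, ct)))
  tbl$kt * (th - tbl$theta0)^2
}

dihedral_angle_vec <- function(xyz, i, j, k, l) {
  b1 <- xyz[j, , drop = FALSE] - xyz[i, , drop = FALSE]
  b2 <- xyz[k, , drop = FALSE] - xyz[j, , drop = FALSE]
  b3 <- xyz[l, , drop = FALSE] - xyz[k, , drop = FALSE]
  n1 <- cross_rows(b1, b2)
  n2 <- cross_rows(b2, b3)
  m1 <- cross_rows(n1, b2 / sqrt(rowSums(b2^2)))
  atan2(rowSums(m1 * n2), rowSums(n1 * n2))
}

dihedral_energy_vec <- function(xyz, tbl) {
  if (nrow(tbl) == 0) return(numeric(0))
  phi <- dihedral_angle_vec(xyz, tbl$i, tbl$j, tbl$k, tbl$l)
  (tbl$vn / 2) * (1 + cos(tbl$n * phi - tbl$gamma))
}

# Classify a bonded term by the atoms it touches.
classify_bonded <- function(sys, idx_mat) {
  if (nrow(idx_mat) == 0) return(character(0))
  a <- sys$atoms
  coarse_res <- sys$residues$region == "coarse"
  apply(idx_mat, 1, function(ix) {
    lig <- a$ligand[ix]
    if (all(lig)) return("lig")
    crs <- coarse_res[a$residue[ix]]
    if (all(crs & a$backbone[ix])) return("bb")
    if (!any(crs)) return("aa")
    "cgaa"
  })
}

#' Precompute an energy model for a parameterised system
#'
#' Builds the pair lists, exclusion/1-4 scalings, interaction-class labels,
#' hydration-group tables, Go contact lists and bonded-term classifications
#' needed to evaluate the mixed-resolution potential repeatedly.  Nonbonded
#' pairs with both atoms in coarse residues are excluded (their interactions
#' are carried by the Go and backbone terms); 1-2 and 1-3 pairs are excluded
#' and 1-4 pairs scaled by the AMBER conventions (vdW / 2.0,
#' electrostatics / 1.2).
#'
#' @param sys A fully parameterised `mrmc_system`.
#' @param settings A [simulation_settings()] object.
#' @param go A [go_parameters()] object.
#' @param seddd A [seddd_parameters()] object.
#' @param contacts Native-contact data.frame; built from `sys$xyz` via
#'   [build_native_contacts()] when `NULL`.
#' @param restraint Optional `list(center, k)`: flat harmonic restraint
#'   `U = (k/2) |x - center|^2` on the ligand heavy-atom centroid
#'   (kcal/mol/A^2); used by toy systems.
#' @param wall Optional `list(center, radius)`: spherical confinement of the
#'   ligand centroid; configurations outside add a large constant energy.
#' @return An object of class `"mrmc_energy_model"`.
#' @export
energy_model <- function(sys, settings = simulation_settings(),
                         go = go_parameters(), seddd = seddd_parameters(),
                         contacts = NULL, restraint = NULL, wall = NULL) {
  validate_system(sys)
  a <- sys$atoms
  n <- nrow(a)
  if (any(is.na(a$charge)) || any(is.na(a$rmin_half)) || any(is.na(a$epsilon)))
    stop("validation error: system is not fully parameterised")
  coarse_res <- sys$residues$region == "coarse"
  coarse_atom <- coarse_res[a$residue] & !a$ligand
  aa_prot <- !coarse_atom & !a$ligand

  # Bond-path exclusions from the union of harmonic and chemical bonds.
  A <- matrix(FALSE, n, n)
  bp <- rbind(as.matrix(sys$bonds[, c("i", "j")]),
              if (!is.null(sys$ligand_bonds))
                as.matrix(sys$ligand_bonds[, c("i", "j")]))
  if (!is.null(bp) && nrow(bp) > 0) {
    A[bp] <- TRUE; A[bp[, 2:1, drop = FALSE]] <- TRUE
  }
  An <- A * 1
  p2 <- (An %*% An) > 0
  p3 <- ((An %*% An) %*% An) > 0
  excl <- A | p2
  p14 <- p3 & !excl
  diag(excl) <- TRUE

  ut <- upper.tri(matrix(0, n, n))
  include <- ut & !excl & !(outer(coarse_atom, coarse_atom, `&`))
  idx <- which(include, arr.ind = TRUE)
  ii <- idx[, 1]; jj <- idx[, 2]
  is14 <- p14[idx]
  cls <- integer(length(ii))        # 1 lig-lig, 2 lig-AAprot, 3 lig-CG,
  li <- a$ligand[ii]; lj <- a$ligand[jj]  # 4 AA-AA, 5 CG-AA cross
  cls[li & lj] <- 1L
  cls[xor(li, lj)] <- ifelse(coarse_atom[ii] | coarse_atom[jj], 3L, 2L)[xor(li, lj)]
  cls[!li & !lj & !(coarse_atom[ii] | coarse_atom[jj])] <- 4L
  cls[!li & !lj & (coarse_atom[ii] | coarse_atom[jj])] <- 5L

  # Hydration groups: representative heavy atom, shell radius, width.
  gidx <- a$group
  groups <- sort(unique(gidx))
  rep_atom <- vapply(groups, function(g) {
    memb <- which(gidx == g)
    hv <- memb[a$element[memb] != "H"]
    if (length(hv)) hv[1] else memb[1]
  }, integer(1))
  gmap <- match(gidx, groups)

  if (is.null(contacts)) contacts <- build_native_contacts(sys, go)
  res <- sys$residues
  coarse_list <- which(coarse_res)
  nn_i <- integer(0); nn_j <- integer(0)
  if (length(coarse_list) >= 2) {
    prs <- utils::combn(coarse_list, 2)
    sep_ok <- abs(prs[2, ] - prs[1, ]) >= 3
    key <- paste(prs[1, ], prs[2, ])
    natkey <- paste(contacts$i, contacts$j)
    keep <- sep_ok & !(key %in% natkey)
    nn_i <- res$calpha[prs[1, keep]]
    nn_j <- res$calpha[prs[2, keep]]
  }

  b_cls <- classify_bonded(sys, as.matrix(sys$bonds[, c("i", "j")]))
  an_cls <- classify_bonded(sys, as.matrix(sys$angles[, c("i", "j", "k")]))
  di_cls <- classify_bonded(sys, as.matrix(sys$dihedrals[, c("i", "j", "k", "l")]))

  lig_heavy <- which(a$ligand & a$element != "H")

  model <- list(
    sys = sys, settings = settings, go = go, seddd = seddd,
    contacts = contacts,
    nat_ai = res$calpha[contacts$i], nat_aj = res$calpha[contacts$j],
    nat_r0 = contacts$r0, nn_i = nn_i, nn_j = nn_j,
    ii = ii, jj = jj, cls = cls,
    qq = K_COUL * a$charge[ii] * a$charge[jj],
    rmin = a$rmin_half[ii] + a$rmin_half[jj],
    epsv = sqrt(a$epsilon[ii] * a$epsilon[jj]),
    vdw_scale = ifelse(is14, 0.5, 1),
    elec_scale = ifelse(is14, 1 / 1.2, 1),
    gii = gmap[ii], gjj = gmap[jj],
    int_pair = cls %in% c(2L, 3L),
    gmap = gmap, rep_atom = rep_atom,
    same_moiety = outer(a$ligand[rep_atom], a$ligand, `==`),
    group_R = a$rmin_half[rep_atom], group_sigma = a$solv_sigma[rep_atom],
    atom_volume = a$solv_volume,
    b_cls = b_cls, an_cls = an_cls, di_cls = di_cls,
    lig_heavy = lig_heavy,
    restraint = restraint, wall = wall
  )
  class(model) <- "mrmc_energy_model"
  model
}

#' Hydration-shell occlusion fractions
#'
#' EEF1-style Gaussian solvent-exclusion sum: the occlusion `v_k` of group
#' `k`'s first hydration shell is the sum over all occluding atoms `m`
#' outside the group (within the nonbonded cutoff) of
#' `V_m * exp(-((r_mk - R_k)/sigma_k)^2) / (2 pi^{3/2} sigma_k r_mk^2)`,
#' where `R_k` is the group's shell radius (its heavy atom's Rmin/2),
#' `sigma_k` its Gaussian exclusion width and `V_m` the neighbour's
#' solvation volume; clamped to at most 1.  Isolated groups give 0 (fully
#' exposed); coincident neighbours saturate the clamp.
#'
#' With `occluders = "intra"` only atoms of the group's own moiety (protein
#' or ligand) occlude.  Intra-moiety electrostatic pairs use these values,
#' so the protein and ligand self-energies are exactly those of the
#' isolated moieties and the decoupled (`lambda = 0`) state is independent
#' of the ligand pose; protein-ligand interaction pairs use the full
#' (`"all"`) occlusion, which responds to ligand burial.
#'
#' @param model An [energy_model()].
#' @param xyz Coordinates (defaults to the system reference).
#' @param occluders `"all"` or `"intra"`.
#' @return Numeric vector of `v_k`, one per hydration group, in `[0, 1]`.
#' @export
compute_hydration_volumes <- function(model, xyz = model$sys$xyz,
                                      occluders = c("all", "intra")) {
  occluders <- match.arg(occluders)
  hydration_volumes(model, xyz)[[if (occluders == "all") "v_full"
                                 else "v_intra"]]
}

# Both occlusion variants from one distance evaluation.
hydration_volumes <- function(model, xyz) {
  if (any(is.na(model$group_sigma)) || any(is.na(model$atom_volume)))
    stop("validation error: missing group solvation parameters")
  D <- dist_cross(xyz[model$rep_atom, , drop = FALSE], xyz)
  # exclude own-group members: D[g, m] for atoms m belonging to group g
  D[cbind(model$gmap, seq_along(model$gmap))] <- NA
  D[D > model$settings$nonbonded_cutoff] <- NA
  Dc <- pmax(D, 1e-6)
  contrib <- sweep(exp(-((Dc - model$group_R) / model$group_sigma)^2) / Dc^2,
                   2, model$atom_volume, `*`) /
    (2 * pi^1.5 * model$group_sigma)
  v_full <- pmin(rowSums(contrib, na.rm = TRUE), 1)
  contrib[!model$same_moiety] <- NA
  v_intra <- pmin(rowSums(contrib, na.rm = TRUE), 1)
  list(v_full = v_full, v_intra = v_intra)
}

# Per-pair nonbonded energies (vdW, SEDDD electrostatics) at a configuration.
pair_nonbonded <- function(model, xyz) {
  cutoff <- model$settings$nonbonded_cutoff
  dx <- xyz[model$ii, , drop = FALSE] - xyz[model$jj, , drop = FALSE]
  d <- sqrt(rowSums(dx^2))
  clash <- any(d < 1e-6)
  d <- pmax(d, 1e-6)
  within <- d <= cutoff
  hv <- hydration_volumes(model, xyz)
  vsum <- ifelse(model$int_pair,
                 hv$v_full[model$gii] + hv$v_full[model$gjj],
                 hv$v_intra[model$gii] + hv$v_intra[model$gjj])
  s <- pmin(model$seddd$c * vsum, 1 - 1e-9)
  denom <- model$seddd$eps0 + (1 - s) * (model$seddd$eps1 - model$seddd$eps0)
  elec <- ifelse(within, model$qq * model$elec_scale / (d^2 * denom), 0)
  elec <- pmin(pmax(elec, -PAIR_ENERGY_CAP), PAIR_ENERGY_CAP)
  x6 <- (model$rmin / d)^6
  vdw <- ifelse(within, model$epsv * (x6^2 - 2 * x6) * model$vdw_scale, 0)
  clash <- clash || any(vdw > PAIR_ENERGY_CAP)
  vdw <- pmin(vdw, PAIR_ENERGY_CAP)
  list(vdw = vdw, elec = elec, clash = clash, d = d)
}

#' Evaluate the mixed-resolution potential
#'
#' Computes the full energy breakdown at the given coordinates and coupling
#' state.  The protein-ligand van der Waals and electrostatic terms are
#' scaled by `lambda` (coupling factors in `[0,1]`); at `lambda = c(1, 1)`
#' the breakdown satisfies both assemblies
#' `total = u_protein + u_ligand + u_vdw_int + u_elec_int (+ restraints)` and
#' `total = u_cg + u_aa + u_cg_aa (+ restraints)`.
#'
#' @param model An [energy_model()].
#' @param xyz n x 3 coordinates, A.
#' @param lambda Numeric length-2 vector `c(lambda_vdw, lambda_elec)`.
#' @return A list of class `"mrmc_energy"` with components `u_cg`, `u_bb`,
#'   `u_go`, `u_aa`, `u_cg_aa`, `u_protein`, `u_ligand`, `u_vdw_int`,
#'   `u_elec_int`, `u_restraint`, `total` (kcal/mol) and a logical `clash`
#'   flag set when any pair energy hit the cap.
#' @export
total_energy <- function(model, xyz, lambda = c(1, 1)) {
  stopifnot(length(lambda) == 2, all(lambda >= 0), all(lambda <= 1))
  sys <- model$sys
  cutoff <- model$settings$nonbonded_cutoff

  pe <- pair_nonbonded(model, xyz)
  vdw <- pe$vdw; elec <- pe$elec; clash <- pe$clash

  csum <- function(val, k) sum(val[model$cls == k])
  nb_lig <- csum(vdw, 1) + csum(elec, 1)
  int_aa_vdw <- csum(vdw, 2); int_aa_elec <- csum(elec, 2)
  int_cg_vdw <- csum(vdw, 3); int_cg_elec <- csum(elec, 3)
  nb_aa <- csum(vdw, 4) + csum(elec, 4)
  nb_cross <- csum(vdw, 5) + csum(elec, 5)

  be <- bond_energy_vec(xyz, sys$bonds)
  ae <- angle_energy_vec(xyz, sys$angles)
  de <- dihedral_energy_vec(xyz, sys$dihedrals)
  bnd <- function(kls) sum(be[model$b_cls == kls]) +
    sum(ae[model$an_cls == kls]) + sum(de[model$di_cls == kls])
  u_bb <- bnd("bb"); lig_bonded <- bnd("lig")
  aa_bonded <- bnd("aa"); cgaa_bonded <- bnd("cgaa")

  u_go <- 0
  if (length(model$nat_ai)) {
    dn <- sqrt(rowSums((xyz[model$nat_ai, , drop = FALSE] -
                        xyz[model$nat_aj, , drop = FALSE])^2))
    xr <- model$nat_r0 / dn
    u_go <- u_go + sum(model$go$epsilon * (5 * xr^12 - 6 * xr^10))
  }
  if (length(model$nn_i)) {
    dv <- sqrt(rowSums((xyz[model$nn_i, , drop = FALSE] -
                        xyz[model$nn_j, , drop = FALSE])^2))
    dv <- dv[dv <= cutoff]
    if (length(dv))
      u_go <- u_go + sum(5 * model$go$epsilon * (model$go$r_hc / dv)^12)
  }

  u_restraint <- 0
  if (!is.null(model$restraint) || !is.null(model$wall)) {
    cen <- colMeans(xyz[model$lig_heavy, , drop = FALSE])
    if (!is.null(model$restraint))
      u_restraint <- u_restraint + (model$restraint$k / 2) *
        sum((cen - model$restraint$center)^2)
    if (!is.null(model$wall) &&
        sqrt(sum((cen - model$wall$center)^2)) > model$wall$radius)
      u_restraint <- u_restraint + WALL_ENERGY
  }

  u_cg <- u_bb + u_go
  u_ligand <- lig_bonded + nb_lig
  u_vdw_int <- int_aa_vdw + int_cg_vdw
  u_elec_int <- int_aa_elec + int_cg_elec
  u_aa_prot <- aa_bonded + nb_aa
  u_cgaa_prot <- cgaa_bonded + nb_cross
  u_protein <- u_cg + u_aa_prot + u_cgaa_prot
  out <- list(
    u_cg = u_cg, u_bb = u_bb, u_go = u_go,
    u_aa = u_aa_prot + u_ligand + int_aa_vdw + int_aa_elec,
    u_cg_aa = u_cgaa_prot + int_cg_vdw + int_cg_elec,
    u_protein = u_protein, u_ligand = u_ligand,
    u_vdw_int = u_vdw_int, u_elec_int = u_elec_int,
    u_restraint = u_restraint,
    lambda = lambda,
    total = u_protein + u_ligand + lambda[1] * u_vdw_int +
      lambda[2] * u_elec_int + u_restraint,
    clash = clash
  )
  class(out) <- "mrmc_energy"
  out
}

#' @export
print.mrmc_energy <- function(x, ...) {
  cat("Energy breakdown (kcal/mol), lambda = (", x$lambda[1], ",",
      x$lambda[2], ")\n")
  for (f in c("u_cg", "u_bb", "u_go", "u_aa", "u_cg_aa", "u_protein",
              "u_ligand", "u_vdw_int", "u_elec_int", "u_restraint", "total"))
    cat(sprintf("  %-12s %14.6f\n", f, x[[f]]))
  invisible(x)
}

#' Format an energy breakdown as a one-row tabular record
#' @param x An `"mrmc_energy"` breakdown.
#' @return A one-row data.frame of the energy components.
#' @export
energy_record <- function(x) {
  as.data.frame(x[c("u_cg", "u_bb", "u_go", "u_aa", "u_cg_aa", "u_protein",
                    "u_ligand", "u_vdw_int", "u_elec_int", "u_restraint",
                    "total")])
}

#' Protein-ligand interaction energy (the pose-ranking score)
#'
#' Sum of the protein-ligand van der Waals and electrostatic terms at full
#' coupling.
#'
#' @param model An [energy_model()].
#' @param xyz Coordinates.
#' @return Scalar kcal/mol.
#' @export
interaction_energy <- function(model, xyz) {
  e <- total_energy(model, xyz)
  e$u_vdw_int + e$u_elec_int
}

#' Coarse-grained energy components
#'
#' @param model An [energy_model()].
#' @param xyz Coordinates.
#' @return A list `(u_bb, u_go, u_cg)` in kcal/mol with `u_cg = u_bb + u_go`
#'   exactly.
#' @export
cg_energy <- function(model, xyz) {
  e <- total_energy(model, xyz)
  list(u_bb = e$u_bb, u_go = e$u_go, u_cg = e$u_cg)
}

#' Backbone bonded energy of the coarse region
#'
#' Bond, angle and dihedral terms whose atoms are all backbone atoms of
#' coarse residues; no 1-4 nonbonded terms are included.
#'
#' @param model An [energy_model()].
#' @param xyz Coordinates.
#' @return Scalar kcal/mol.
#' @export
backbone_energy <- function(model, xyz) {
  sys <- model$sys
  sum(bond_energy_vec(xyz, sys$bonds)[model$b_cls == "bb"]) +
    sum(angle_energy_vec(xyz, sys$angles)[model$an_cls == "bb"]) +
    sum(dihedral_energy_vec(xyz, sys$dihedrals)[model$di_cls == "bb"])
}

#' Nonbonded energy sums by interaction class
#'
#' @param model An [energy_model()].
#' @param xyz Coordinates.
#' @return data.frame with rows per class (`lig_lig`, `lig_prot_aa`,
#'   `lig_prot_cg`, `aa_aa`, `cg_aa_cross`) and columns `u_vdw`, `u_elec`.
#' @export
nonbonded_energy <- function(model, xyz) {
  pe <- pair_nonbonded(model, xyz)
  vdw <- pe$vdw; elec <- pe$elec
  labs <- c("lig_lig", "lig_prot_aa", "lig_prot_cg", "aa_aa", "cg_aa_cross")
  data.frame(class = labs,
             u_vdw = vapply(1:5, function(k) sum(vdw[model$cls == k]),
                            numeric(1)),
             u_elec = vapply(1:5, function(k) sum(elec[model$cls == k]),
                             numeric(1)))
}
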