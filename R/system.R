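#' Construct a mixed-resolution molecular system
#'
#' A `mrmc_system` bundles the topology, force-field parameters, region
#' labels and reference coordinates of a receptor-ligand complex.  Atoms are
#' indexed 1-based; coordinates are in Angstrom, energies in kcal/mol, angle
#' equilibria stored in radians.
#'
#' @param atoms data.frame with one row per atom and columns `name`,
#'   `element`, `charge` (e), `rmin_half` (A), `epsilon` (kcal/mol, >= 0),
#'   `residue` (1-based residue index), `group` (SEDDD hydration-group id),
#'   `backbone` (logical), `ligand` (logical), `solv_volume` (A^3),
#'   `solv_sigma` (A, Gaussian exclusion width).
#' @param xyz n x 3 numeric matrix of reference coordinates (A).
#' @param residues data.frame with columns `name` (3-letter code), `region`
#'   (`"atomistic"` or `"coarse"`), `calpha` (atom index or NA), `is_ligand`.
#' @param bonds data.frame `i, j, k, r0`; harmonic `k (r - r0)^2` with `k`
#'   in kcal/mol/A^2 (AMBER convention).
#' @param angles data.frame `i, j, k, kt, theta0`; `kt (theta - theta0)^2`,
#'   `theta0` radians.
#' @param dihedrals data.frame `i, j, k, l, vn, n, gamma`; Fourier term
#'   `(vn/2) (1 + cos(n phi - gamma))`, `gamma` radians; multiple terms per
#'   torsion appear as multiple rows.
#' @param ligand_bonds data.frame `i, j, order` over absolute atom indices
#'   (the ligand's chemical bond graph, used for rotatable-bond detection and
#'   symmetry mappings).
#' @param rotatable_bonds list of `list(atoms = c(i, j), moving = <indices>)`
#'   describing ligand rotatable bonds; normally filled by
#'   [detect_rotatable_bonds()].
#' @return An object of class `"mrmc_system"`.
#' @export
molecular_system <- function(atoms, xyz, residues,
                             bonds = empty_bonds(),
                             angles = empty_angles(),
                             dihedrals = empty_dihedrals(),
                             ligand_bonds = NULL,
                             rotatable_bonds = list()) {
  xyz <- as.matrix(xyz)
  sys <- list(atoms = atoms, xyz = xyz, residues = residues,
              bonds = bonds, angles = angles, dihedrals = dihedrals,
              ligand_bonds = ligand_bonds,
              rotatable_bonds = rotatable_bonds)
  class(sys) <- "mrmc_system"
  validate_system(sys)
  sys
}

empty_bonds <- function() data.frame(i = integer(), j = integer(),
                                     k = numeric(), r0 = numeric())
empty_angles <- function() data.frame(i = integer(), j = integer(),
                                      k = integer(), kt = numeric(),
                                      theta0 = numeric())
empty_dihedrals <- function() data.frame(i = integer(), j = integer(),
                                         k = integer(), l = integer(),
                                         vn = numeric(), n = numeric(),
                                         gamma = numeric())

#' Validate a molecular system
#'
#' Checks the structural invariants: finite coordinates, non-negative LJ
#' well depths, every atom in exactly one residue and one hydration group,
#' valid bonded-term indices, coarse residues having a defined alpha carbon,
#' ligand residues atomistic, and rotatable-bond moving sets being proper
#' subsets excluding the pivot pair.
#'
#' @param sys An `mrmc_system`.
#' @return `sys`, invisibly; stops with a validation error otherwise.
#' @export
validate_system <- function(sys) {
  a <- sys$atoms
  n <- nrow(a)
  if (nrow(sys$xyz) != n || ncol(sys$xyz) != 3)
    stop("validation error: xyz must be ", n, " x 3")
  if (!all(is.finite(sys$xyz)))
    stop("validation error: non-finite coordinates")
  if (any(!is.na(a$epsilon) & a$epsilon < 0))
    stop("validation error: negative LJ epsilon")
  if (any(a$residue < 1 | a$residue > nrow(sys$residues)))
    stop("validation error: atom residue index out of range")
  if (any(is.na(a$group)))
    stop("validation error: every atom must belong to a hydration group")
  r <- sys$residues
  if (any(r$is_ligand & r$region != "atomistic"))
    stop("validation error: ligand residues must be atomistic")
  coarse <- which(r$region == "coarse")
  if (any(is.na(r$calpha[coarse])))
    stop("validation error: coarse residue without alpha carbon: residue ",
         coarse[which(is.na(r$calpha[coarse]))[1]])
  for (tbl in list(sys$bonds[c("i", "j")], sys$angles[c("i", "j", "k")],
                   sys$dihedrals[c("i", "j", "k", "l")])) {
    idx <- unlist(tbl, use.names = FALSE)
    if (length(idx) && (any(idx < 1) || any(idx > n)))
      stop("validation error: bonded term index out of range")
  }
  for (rb in sys$rotatable_bonds) {
    if (any(rb$atoms %in% rb$moving))
      stop("validation error: rotatable-bond moving set contains the pivot")
    if (length(rb$moving) == 0 || length(rb$moving) >= n)
      stop("validation error: rotatable-bond moving set must be a proper",
           " non-empty subset")
  }
  invisible(sys)
}

#' @export
print.mrmc_system <- function(x, ...) {
  r <- x$residues
  cat("Mixed-resolution molecular system\n")
  cat("  atoms:    ", nrow(x$atoms), " (", sum(x$atoms$ligand),
      " ligand)\n", sep = "")
  cat("  residues: ", nrow(r), " (", sum(r$region == "atomistic" & !r$is_ligand),
      " atomistic protein, ", sum(r$region == "coarse"), " coarse, ",
      sum(r$is_ligand), " ligand)\n", sep = "")
  cat("  bonded terms:", nrow(x$bonds), "bonds,", nrow(x$angles), "angles,",
      nrow(x$dihedrals), "dihedral terms\n")
  cat("  ligand rotatable bonds:", length(x$rotatable_bonds), "\n")
  invisible(x)
}

# Convenience accessors -------------------------------------------------------

ligand_atoms <- function(sys) which(sys$atoms$ligand)
protein_atoms <- function(sys) which(!sys$atoms$ligand)
heavy_atoms <- function(sys) which(sys$atoms$element != "H")
backbone_atoms <- function(sys) which(sys$atoms$backbone & !sys$atoms$ligand)

#' Read a receptor (or complex) structure from a PDB file
#'
#' Parses ATOM/HETATM records (other records ignored), groups atoms into
#' residues in file order and flags the ligand by residue name.  The result
#' carries no force-field parameters; attach them with [attach_parameters()].
#'
#' @param path Path to a PDB file.
#' @param ligand_resname Residue name(s) identifying the ligand (default
#'   `"LIG"`).
#' @return An `mrmc_system` with per-atom parameters unset (NA charge/LJ) and
#'   all residues initially atomistic; use [assign_regions()] to label the
#'   coarse region.
#' @export
read_structure <- function(path, ligand_resname = "LIG") {
  if (!file.exists(path)) stop("format error: file not found: ", path)
  check_pdb_records(path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  if (any(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z)))
    stop("format error: unparseable coordinates in ", path)
  rid <- paste(at$chain, at$resno, at$insert)
  resfac <- factor(rid, levels = unique(rid))
  residue_index <- as.integer(resfac)
  resnames <- tapply(at$resid, residue_index, function(z) z[1])
  is_lig_res <- unname(resnames %in% ligand_resname)
  elem <- at$elesy
  if (any(is.na(elem) | elem == ""))
    elem <- substr(trimws(at$elety), 1, 1)
  atoms <- data.frame(
    name = trimws(at$elety),
    element = trimws(elem),
    charge = NA_real_, rmin_half = NA_real_, epsilon = NA_real_,
    residue = residue_index,
    group = NA_integer_,
    backbone = trimws(at$elety) %in% backbone_atom_names(),
    ligand = is_lig_res[residue_index],
    solv_volume = NA_real_, solv_sigma = NA_real_,
    stringsAsFactors = FALSE
  )
  atoms$backbone[atoms$ligand] <- FALSE
  calpha <- rep(NA_integer_, length(resnames))
  ca <- which(atoms$name == "CA" & !atoms$ligand)
  calpha[atoms$residue[ca]] <- ca
  residues <- data.frame(
    name = unname(resnames),
    region = "atomistic",
    calpha = calpha,
    is_ligand = is_lig_res,
    stringsAsFactors = FALSE
  )
  atoms$group <- default_groups(atoms)
  molecular_system(atoms, cbind(at$x, at$y, at$z), residues)
}

# One hydration group per heavy atom together with its trailing hydrogens;
# hydrogens preceding any heavy atom join the first heavy group.
default_groups <- function(atoms) {
  g <- cumsum(atoms$element != "H")
  g[g == 0L] <- 1L
  g
}

backbone_atom_names <- function() {
  c("N", "H", "H1", "H2", "H3", "CA", "HA", "HA2", "HA3", "C", "O", "OXT")
}

check_pdb_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grep("^(ATOM|HETATM)", lines)
  for (li in rec) {
    ln <- lines[li]
    if (nchar(ln) < 54)
      stop("format error: truncated ATOM/HETATM record at line ", li)
    coords <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                            substr(ln, 39, 46),
                                            substr(ln, 47, 54))))
    if (any(is.na(coords)))
      stop("format error: unparseable coordinate field at line ", li)
  }
  invisible(TRUE)
}

#' Write a system's coordinates to a PDB file
#'
#' @param sys An `mrmc_system`.
#' @param path Output path.
#' @param xyz Optional coordinates to write (defaults to `sys$xyz`).
#' @return `path`, invisibly.
#' @export
write_structure <- function(sys, path, xyz = sys$xyz) {
  a <- sys$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(xyz)),
                   type = ifelse(a$ligand, "HETATM", "ATOM"),
                   resno = a$residue,
                   resid = sys$residues$name[a$residue],
                   eleno = seq_len(nrow(a)),
                   elety = a$name,
                   elesy = a$element,
                   chain = ifelse(a$ligand, "L", "A"))
  invisible(path)
}

#' Assign atomistic vs coarse regions
#'
#' A protein residue is atomistic iff it lies in `explicit_residues` or any
#' of its non-hydrogen atoms is within `contact_cutoff` of any ligand
#' non-hydrogen atom in at least one reference complex; all other protein
#' residues are coarse.  Ligand residues are always atomistic.
#'
#' @param sys An `mrmc_system`.
#' @param references List of `mrmc_system` reference complexes sharing
#'   `sys`'s residue numbering (each must contain a ligand).
#' @param contact_cutoff Heavy-atom contact distance in Angstrom (default 3).
#' @param explicit_residues Integer vector of residue indices forced
#'   atomistic regardless of contacts (e.g. a mobile helix).
#' @return `sys` with updated `residues$region`.
#' @export
assign_regions <- function(sys, references = list(), contact_cutoff = 3,
                           explicit_residues = integer()) {
  nres <- nrow(sys$residues)
  atomistic <- logical(nres)
  atomistic[explicit_residues] <- TRUE
  for (ref in references) {
    if (nrow(ref$residues) != nres ||
        !all(ref$residues$name[!ref$residues$is_ligand] ==
             sys$residues$name[!sys$residues$is_ligand]))
      stop("validation error: reference residue numbering does not match")
    lig <- which(ref$atoms$ligand & ref$atoms$element != "H")
    if (length(lig) == 0) next
    prot <- which(!ref$atoms$ligand & ref$atoms$element != "H")
    d <- dist_cross(ref$xyz[prot, , drop = FALSE],
                    ref$xyz[lig, , drop = FALSE])
    near <- prot[apply(d, 1, min) <= contact_cutoff]
    atomistic[unique(ref$atoms$residue[near])] <- TRUE
  }
  region <- ifelse(atomistic, "atomistic", "coarse")
  region[sys$residues$is_ligand] <- "atomistic"
  sys$residues$region <- region
  validate_system(sys)
  sys
}

# Bonded geometry helpers ------------------------------------------------------

angle_value <- function(p1, p2, p3) {
  v1 <- p1 - p2; v2 <- p3 - p2
  ct <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(1, pmax(-1, ct)))
}

dihedral_value <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}
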