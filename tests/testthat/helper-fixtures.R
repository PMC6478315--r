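# Shared text fixtures and small systems, built in code at test time.

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          het = FALSE, element = substr(name, 1, 1)) {
  sprintf("%-6s%5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (het) "HETATM" else "ATOM", serial, name, resname, chain,
          resno, x, y, z, 1.00, 0.00, element)
}

# Two alanine residues (5 heavy atoms each) plus a two-atom HETATM ligand.
write_two_residue_pdb <- function(path) {
  lines <- c(
    pdb_atom_line(1, "N", "ALA", "A", 1, 0.0, 0.0, 0.0),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 1.45, 0.0, 0.0),
    pdb_atom_line(3, "C", "ALA", "A", 1, 2.0, 1.4, 0.0),
    pdb_atom_line(4, "O", "ALA", "A", 1, 1.4, 2.4, 0.0),
    pdb_atom_line(5, "CB", "ALA", "A", 1, 2.0, -0.8, 1.2),
    pdb_atom_line(6, "N", "ALA", "A", 2, 3.3, 1.5, 0.0),
    pdb_atom_line(7, "CA", "ALA", "A", 2, 4.0, 2.8, 0.0),
    pdb_atom_line(8, "C", "ALA", "A", 2, 5.5, 2.6, 0.2),
    pdb_atom_line(9, "O", "ALA", "A", 2, 6.0, 1.5, 0.4),
    pdb_atom_line(10, "CB", "ALA", "A", 2, 3.6, 3.7, 1.2),
    pdb_atom_line(11, "C1", "LIG", "L", 3, 8.0, 2.0, 0.0, het = TRUE,
                  element = "C"),
    pdb_atom_line(12, "C2", "LIG", "L", 3, 9.5, 2.0, 0.0, het = TRUE,
                  element = "C"),
    "END")
  writeLines(lines, path)
  path
}

sdf_v2000 <- function(title, coords, elements, bonds) {
  n <- nrow(coords); m <- nrow(bonds)
  c(title, "  fixture", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m),
    vapply(seq_len(n), function(i)
      sprintf("%10.4f%10.4f%10.4f %-3s 0  0", coords[i, 1], coords[i, 2],
              coords[i, 3], elements[i]), character(1)),
    vapply(seq_len(m), function(b)
      sprintf("%3d%3d%3d  0", bonds[b, 1], bonds[b, 2], bonds[b, 3]),
      character(1)),
    "M  END", "$$$$")
}

write_ethane_sdf <- function(path) {
  writeLines(sdf_v2000("ethane", rbind(c(0, 0, 0), c(1.53, 0, 0)),
                       c("C", "C"), rbind(c(1, 2, 1))), path)
  path
}

write_butane_sdf <- function(path) {
  coords <- rbind(c(0, 0, 0), c(1.53, 0, 0), c(2.04, 1.44, 0),
                  c(3.57, 1.44, 0))
  writeLines(sdf_v2000("butane", coords, rep("C", 4),
                       rbind(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1))), path)
  path
}

write_benzene_sdf <- function(path) {
  th <- seq(0, 300, by = 60) * pi / 180
  coords <- cbind(1.4 * cos(th), 1.4 * sin(th), 0)
  bonds <- cbind(1:6, c(2:6, 1), rep(c(2, 1), 3))
  writeLines(sdf_v2000("benzene", coords, rep("C", 6), bonds), path)
  path
}

# N-methylacetamide heavy atoms: the C-N bond is an amide, nothing rotates.
write_amide_sdf <- function(path) {
  coords <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.1, 1.1, 0),
                  c(2.2, -1.2, 0), c(3.7, -1.3, 0))
  bonds <- rbind(c(1, 2, 1), c(2, 3, 2), c(2, 4, 1), c(4, 5, 1))
  writeLines(sdf_v2000("nma", coords, c("C", "C", "O", "N", "C"), bonds),
             path)
  path
}

write_butane_mol2 <- function(path) {
  writeLines(c("@<TRIPOS>MOLECULE", "butane", " 4 3 0 0 0", "SMALL",
               "NO_CHARGES", "",
               "@<TRIPOS>ATOM",
               "  1 C1  0.0000  0.0000  0.0000 C.3 1 BUT",
               "  2 C2  1.5300  0.0000  0.0000 C.3 1 BUT",
               "  3 C3  2.0400  1.4400  0.0000 C.3 1 BUT",
               "  4 C4  3.5700  1.4400  0.0000 C.3 1 BUT",
               "@<TRIPOS>BOND",
               "  1 1 2 1", "  2 2 3 1", "  3 3 4 1"), path)
  path
}

# A coarse-only system of alpha-carbon particles at prescribed positions,
# for exercising the Go term in isolation.
ca_only_system <- function(ca_xyz, region = "coarse") {
  n <- nrow(ca_xyz)
  atoms <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(name = "CA", element = "C", charge = 0, rmin_half = 1.0,
               epsilon = 0.0, residue = i, group = i, backbone = TRUE,
               ligand = FALSE, solv_volume = 20, solv_sigma = 3.5,
               stringsAsFactors = FALSE)
  }))
  residues <- data.frame(name = "GLY", region = region,
                         calpha = seq_len(n), is_ligand = FALSE,
                         stringsAsFactors = FALSE)
  molecular_system(atoms, ca_xyz, residues)
}

small_complex <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_toy_complex(make_toy_receptor(10, 4),
                                 make_toy_ligand(1))
    cache
  }
})

symmetric_complex <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_toy_complex(make_toy_receptor(8, 3),
                                 make_toy_ligand(symmetric = TRUE))
    cache
  }
})
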