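#' Read a ligand from an SDF (V2000) or MOL2 file
#'
#' Parses the atom block and connection table, builds the bond graph and
#' detects rotatable bonds.  The format is chosen from the file extension
#' (`.sdf`/`.mol` vs `.mol2`).
#'
#' @param path Path to an SDF V2000 or TRIPOS MOL2 file.
#' @return A list of class `"mrmc_ligand"` with elements `elements`
#'   (character), `xyz` (n x 3, A), `bonds` (data.frame `i, j, order`) and
#'   `rotatable_bonds` (list of `list(atoms, moving)`).
#' @export
read_ligand <- function(path) {
  if (!file.exists(path)) stop("format error: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  lig <- if (ext == "mol2") read_mol2(path) else read_sdf_v2000(path)
  g <- igraph::graph_from_edgelist(as.matrix(lig$bonds[, c("i", "j")]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(lig$elements) -
                                     igraph::vcount(g)))
  if (igraph::components(g)$no != 1L)
    stop("validation error: disconnected ligand bond graph")
  lig$rotatable_bonds <- detect_rotatable_bonds(lig$bonds, lig$elements)
  class(lig) <- "mrmc_ligand"
  lig
}

read_sdf_v2000 <- function(path) {
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(path))
  sdf <- sdfs[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- gsub("_.*$", "", rownames(ab))
  xyz <- unname(ab[, 1:3, drop = FALSE])
  bonds <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                      order = as.numeric(bb[, 3]))
  list(elements = elements, xyz = xyz, bonds = bonds)
}

# Minimal TRIPOS MOL2 reader: ATOM and BOND sections only.
read_mol2 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  sec <- function(name) {
    st <- grep(paste0("^@<TRIPOS>", name), lines)
    if (length(st) == 0) stop("format error: MOL2 missing @<TRIPOS>", name)
    st <- st[1] + 1L
    en <- grep("^@<TRIPOS>", lines)
    en <- en[en > st]
    lines[st:(if (length(en)) en[1] - 1L else length(lines))]
  }
  atom_lines <- trimws(sec("ATOM"))
  atom_lines <- atom_lines[nzchar(atom_lines)]
  tok <- strsplit(atom_lines, "\\s+")
  xyz <- t(vapply(tok, function(t) as.numeric(t[3:5]), numeric(3)))
  elements <- vapply(tok, function(t) sub("\\..*$", "", t[6]), character(1))
  bond_lines <- trimws(sec("BOND"))
  bond_lines <- bond_lines[nzchar(bond_lines)]
  bt <- strsplit(bond_lines, "\\s+")
  ord <- vapply(bt, function(t) t[4], character(1))
  ordn <- suppressWarnings(as.numeric(ord))
  ordn[ord == "ar"] <- 1.5
  ordn[ord == "am"] <- 1      # amide; excluded from rotation by the amide rule
  if (any(is.na(ordn))) stop("format error: unparseable MOL2 bond order")
  bonds <- data.frame(i = vapply(bt, function(t) as.integer(t[2]), integer(1)),
                      j = vapply(bt, function(t) as.integer(t[3]), integer(1)),
                      order = ordn)
  list(elements = elements, xyz = xyz, bonds = bonds)
}

#' Detect rotatable bonds in a ligand bond graph
#'
#' A bond is rotatable iff it is a single bond, acyclic (a bridge of the
#' graph), joins two non-terminal heavy atoms (each endpoint has at least one
#' further heavy-atom neighbour) and is not an amide C-N bond (carbon double-
#' bonded to oxygen, bonded to nitrogen).  For each rotatable bond the moving
#' set is the connected component on the `j` side after deleting the bond,
#' excluding the pivot atoms themselves.
#'
#' @param bonds data.frame `i, j, order`.
#' @param elements Character vector of element symbols, one per atom.
#' @return List of `list(atoms = c(i, j), moving = <atom indices>)`.
#' @export
detect_rotatable_bonds <- function(bonds, elements) {
  n <- length(elements)
  if (nrow(bonds) == 0) return(list())
  g <- igraph::add_vertices(
    igraph::graph_from_edgelist(as.matrix(bonds[, c("i", "j")]),
                                directed = FALSE),
    max(0L, n - max(bonds$i, bonds$j)))
  heavy <- elements != "H"
  adj <- igraph::as_adj_list(g)
  heavy_deg <- vapply(adj, function(nb) sum(heavy[as.integer(nb)]),
                      numeric(1))
  is_amide <- function(i, j) {
    for (pair in list(c(i, j), c(j, i))) {
      ci <- pair[1]; nj <- pair[2]
      if (elements[ci] == "C" && elements[nj] == "N") {
        nb_bonds <- bonds[(bonds$i == ci | bonds$j == ci), ]
        other <- ifelse(nb_bonds$i == ci, nb_bonds$j, nb_bonds$i)
        if (any(elements[other] == "O" & nb_bonds$order == 2)) return(TRUE)
      }
    }
    FALSE
  }
  out <- list()
  for (b in seq_len(nrow(bonds))) {
    i <- bonds$i[b]; j <- bonds$j[b]
    if (bonds$order[b] != 1) next
    if (!heavy[i] || !heavy[j]) next
    if (heavy_deg[i] < 2 || heavy_deg[j] < 2) next   # terminal heavy atom
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(i, j)))
    comp <- igraph::components(g2)$membership
    if (comp[i] == comp[j]) next                     # ring bond
    if (is_amide(i, j)) next
    moving <- setdiff(which(comp == comp[j]), c(i, j))
    if (length(moving) == 0) next
    out[[length(out) + 1L]] <- list(atoms = c(i, j), moving = moving)
  }
  out
}

#' Enumerate element-preserving automorphisms of the ligand heavy-atom graph
#'
#' Used for symmetry-aware RMSD: each automorphism is a permutation of the
#' ligand heavy atoms preserving both element labels and the bond graph.
#' The identity is always included.  Enumeration is refused above `cap`
#' mappings (pathological symmetry) rather than silently truncated.
#'
#' @param bonds data.frame `i, j, order` over ligand atom indices.
#' @param elements Element symbols per ligand atom.
#' @param cap Maximum number of mappings (default 10000).
#' @return A list of integer permutation vectors over the *heavy* atoms,
#'   expressed in heavy-atom subindices, with the heavy-atom index map in
#'   attribute `"heavy"`.
#' @export
ligand_automorphisms <- function(bonds, elements, cap = 10000) {
  heavy <- which(elements != "H")
  remap <- match(seq_along(elements), heavy)
  hb <- bonds[bonds$i %in% heavy & bonds$j %in% heavy, , drop = FALSE]
  g <- igraph::graph_from_edgelist(
    cbind(remap[hb$i], remap[hb$j]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(heavy) - igraph::vcount(g)))
  col <- as.integer(factor(elements[heavy]))
  n_maps <- igraph::count_isomorphisms(g, g, method = "vf2",
                                       vertex.color1 = col,
                                       vertex.color2 = col)
  if (n_maps > cap)
    stop("validation error: ligand symmetry too large (", n_maps,
         " automorphisms, cap ", cap, ")")
  maps <- igraph::isomorphisms(g, g, method = "vf2",
                               vertex.color1 = col, vertex.color2 = col)
  out <- lapply(maps, as.integer)
  attr(out, "heavy") <- heavy
  out
}
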