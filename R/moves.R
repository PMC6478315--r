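#' Monte Carlo move mix for a protein-flexibility mode
#'
#' The production move set: six move kinds with maximum sizes 2 deg
#' (backbone rotation), 180 deg (sidechain rotation), 2 deg (backrub),
#' 180 deg (ligand bond rotation), 1 A (ligand translation) and 180 deg
#' (ligand rotation about its centre of mass).  Three flexibility modes are
#' supported: `fully_flexible` uses all six kinds (fractions
#' 0.1/0.2/0.1/0.2/0.2/0.2), `fixed_protein` uses only the three ligand
#' moves at one third each, and `sidechain_only` adds sidechain rotation at
#' one quarter each.  Fractions are normalised to sum to 1.
#'
#' @param mode One of `"fully_flexible"`, `"fixed_protein"`,
#'   `"sidechain_only"`.
#' @return A data.frame of class `"mrmc_move_mix"` with columns `kind`,
#'   `max_size` (degrees or A) and `fraction`.
#' @export
move_mix <- function(mode = c("fully_flexible", "fixed_protein",
                              "sidechain_only")) {
  mode <- match.arg(mode)
  specs <- data.frame(
    kind = c("backbone_rotation", "sidechain_rotation", "backrub",
             "ligand_bond_rotation", "ligand_translation", "ligand_rotation"),
    max_size = c(2, 180, 2, 180, 1, 180),
    stringsAsFactors = FALSE
  )
  frac <- switch(mode,
    fully_flexible = c(0.1, 0.2, 0.1, 0.2, 0.2, 0.2),
    fixed_protein  = c(0, 0, 0, 1, 1, 1) / 3,
    sidechain_only = c(0, 0.25, 0, 0.25, 0.25, 0.25))
  specs$fraction <- frac / sum(frac)
  specs <- specs[specs$fraction > 0, ]
  rownames(specs) <- NULL
  attr(specs, "mode") <- mode
  class(specs) <- c("mrmc_move_mix", "data.frame")
  specs
}

# Precompute the degrees of freedom each protein move kind can act on.
build_move_tables <- function(sys) {
  a <- sys$atoms
  res <- sys$residues
  prot_res <- which(!res$is_ligand)
  find_atom <- function(r, names) {
    idx <- which(a$residue == r & a$name %in% names)
    if (length(idx)) idx[1] else NA_integer_
  }
  res_atoms <- split(seq_len(nrow(a)), a$residue)

  backbone <- list()
  for (pos in seq_along(prot_res)) {
    r <- prot_res[pos]
    later <- unlist(res_atoms[as.character(prot_res[seq_along(prot_res) > pos])],
                    use.names = FALSE)
    nN <- find_atom(r, "N"); nCA <- find_atom(r, "CA"); nC <- find_atom(r, "C")
    if (!is.na(nN) && !is.na(nCA)) {   # phi
      own <- setdiff(res_atoms[[as.character(r)]],
                     which(a$residue == r & a$name %in% c("N", "H", "H1",
                                                          "H2", "H3", "CA")))
      moving <- c(own, later)
      if (length(moving))
        backbone[[length(backbone) + 1L]] <-
          list(axis = c(nN, nCA), moving = moving)
    }
    if (!is.na(nCA) && !is.na(nC)) {   # psi
      own <- which(a$residue == r & a$name %in% c("O", "OXT"))
      moving <- c(own, later)
      if (length(moving))
        backbone[[length(backbone) + 1L]] <-
          list(axis = c(nCA, nC), moving = moving)
    }
  }

  # Sidechain rotatable bonds: intra-residue bonds of atomistic protein
  # residues whose distal side carries no backbone atoms.
  sidechain <- list()
  for (r in prot_res[res$region[prot_res] == "atomistic"]) {
    ratoms <- res_atoms[[as.character(r)]]
    rb <- sys$bonds[sys$bonds$i %in% ratoms & sys$bonds$j %in% ratoms, ,
                    drop = FALSE]
    if (nrow(rb) == 0) next
    g <- igraph::make_empty_graph(n = length(ratoms), directed = FALSE)
    g <- igraph::add_edges(g, as.vector(rbind(match(rb$i, ratoms),
                                              match(rb$j, ratoms))))
    for (b in seq_len(nrow(rb))) {
      gi <- match(rb$i[b], ratoms); gj <- match(rb$j[b], ratoms)
      g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(gi, gj)))
      comp <- igraph::components(g2)$membership
      if (comp[gi] == comp[gj]) next
      for (ordpair in list(c(gi, gj), c(gj, gi))) {
        pa <- ordpair[1]; pb <- ordpair[2]
        side_b <- ratoms[comp == comp[pb]]
        if (any(a$backbone[side_b])) next
        moving <- setdiff(side_b, ratoms[pb])
        if (length(moving) == 0) next
        sidechain[[length(sidechain) + 1L]] <-
          list(axis = c(ratoms[pa], ratoms[pb]), moving = moving)
        break
      }
    }
  }

  # Backrub candidate residue pairs: sequence separation 2-10, both with CA.
  with_ca <- prot_res[!is.na(res$calpha[prot_res])]
  pairs <- list()
  for (x in seq_along(with_ca)) {
    for (y in seq_along(with_ca)) {
      if (y <= x) next
      sep <- with_ca[y] - with_ca[x]
      if (sep >= 2 && sep <= 10)
        pairs[[length(pairs) + 1L]] <- c(with_ca[x], with_ca[y])
    }
  }
  backrub <- if (length(pairs)) do.call(rbind, pairs) else
    matrix(integer(0), ncol = 2)

  # Atoms moved by a backrub between residues ri and rj: the residues
  # strictly between plus the carbonyl of ri and amide of rj.
  backrub_moving <- function(ri, rj) {
    between <- which(a$residue > ri & a$residue < rj & !a$ligand)
    c(between,
      which(a$residue == ri & a$name %in% c("C", "O")),
      which(a$residue == rj & a$name %in% c("N", "H")))
  }

  list(backbone = backbone, sidechain = sidechain, backrub = backrub,
       backrub_moving = backrub_moving,
       ligand = which(a$ligand))
}

#' Propose a single Monte Carlo trial move
#'
#' Draws and applies one trial move of the given kind.  Rotation angles are
#' uniform in `(-max, +max)`; ligand translations are uniform in the ball of
#' radius `max_size`; ligand rotations use a uniformly distributed random
#' axis through the ligand centroid.  Coarse-residue side chains ride
#' rigidly with their residue.  When a kind has no applicable degrees of
#' freedom the move is a logged no-op.
#'
#' @param kind Move kind (see [move_mix()]).
#' @param sys An `mrmc_system`.
#' @param xyz Current coordinates.
#' @param max_size Maximum move size (degrees, or A for translations).
#' @param tables Move tables from the engine (internal; built on demand if
#'   `NULL`).
#' @return list `(xyz, moved, kind, size, noop)` where `size` is the drawn
#'   magnitude (degrees or A) and `moved` the atom indices displaced.
#' @export
propose_move <- function(kind, sys, xyz, max_size, tables = NULL) {
  if (is.null(tables)) tables <- build_move_tables(sys)
  noop <- function() list(xyz = xyz, moved = integer(0), kind = kind,
                          size = 0, noop = TRUE)
  ang <- function() deg2rad(stats::runif(1, -max_size, max_size))
  out <- switch(kind,
    backbone_rotation = {
      if (length(tables$backbone) == 0) return(noop())
      dof <- tables$backbone[[sample.int(length(tables$backbone), 1)]]
      th <- ang()
      list(xyz = rotate_about_axis(xyz, dof$moving, xyz[dof$axis[1], ],
                                   xyz[dof$axis[2], ], th),
           moved = dof$moving, size = abs(rad2deg(th)))
    },
    sidechain_rotation = {
      if (length(tables$sidechain) == 0) return(noop())
      dof <- tables$sidechain[[sample.int(length(tables$sidechain), 1)]]
      th <- ang()
      list(xyz = rotate_about_axis(xyz, dof$moving, xyz[dof$axis[1], ],
                                   xyz[dof$axis[2], ], th),
           moved = dof$moving, size = abs(rad2deg(th)))
    },
    backrub = {
      if (nrow(tables$backrub) == 0) return(noop())
      pr <- tables$backrub[sample.int(nrow(tables$backrub), 1), ]
      moving <- tables$backrub_moving(pr[1], pr[2])
      if (length(moving) == 0) return(noop())
      cai <- sys$residues$calpha[pr[1]]; caj <- sys$residues$calpha[pr[2]]
      th <- ang()
      list(xyz = rotate_about_axis(xyz, moving, xyz[cai, ], xyz[caj, ], th),
           moved = moving, size = abs(rad2deg(th)))
    },
    ligand_bond_rotation = {
      if (length(sys$rotatable_bonds) == 0) return(noop())
      rb <- sys$rotatable_bonds[[sample.int(length(sys$rotatable_bonds), 1)]]
      th <- ang()
      list(xyz = rotate_about_axis(xyz, rb$moving, xyz[rb$atoms[1], ],
                                   xyz[rb$atoms[2], ], th),
           moved = rb$moving, size = abs(rad2deg(th)))
    },
    ligand_translation = {
      v <- random_in_ball(max_size)
      xyz2 <- xyz
      xyz2[tables$ligand, ] <- sweep(xyz[tables$ligand, , drop = FALSE],
                                     2, v, `+`)
      list(xyz = xyz2, moved = tables$ligand, size = sqrt(sum(v^2)))
    },
    ligand_rotation = {
      com <- colMeans(xyz[tables$ligand, , drop = FALSE])
      axis <- random_unit_vector()
      th <- ang()
      list(xyz = rotate_about_axis(xyz, tables$ligand, com, com + axis, th),
           moved = tables$ligand, size = abs(rad2deg(th)))
    },
    stop("unknown move kind: ", kind))
  out$kind <- kind
  out$noop <- FALSE
  out
}

#' Metropolis acceptance test
#'
#' Accepts with probability `min(1, exp(-beta * delta_u))`.
#'
#' @param delta_u Energy change of the trial move, kcal/mol (finite).
#' @param beta Inverse temperature, mol/kcal.
#' @return Logical.
#' @export
metropolis_accept <- function(delta_u, beta) {
  if (!is.finite(delta_u)) stop("domain error: delta_u must be finite")
  if (delta_u <= 0) return(TRUE)
  stats::runif(1) < exp(-beta * delta_u)
}
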