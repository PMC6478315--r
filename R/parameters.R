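#' Read a native force-field parameter file
#'
#' The native parameter schema is plain tabular text with bracketed section
#' headers.  Lines starting with `#` are comments.  Sections and columns:
#'
#' * `[atoms]`: `index name charge rmin_half epsilon group solv_volume
#'   solv_sigma` -- per-atom partial charge (e), LJ Rmin/2 (A) and well depth
#'   (kcal/mol), hydration group id and EEF1-style solvation volume (A^3) and
#'   Gaussian exclusion width (A).
#' * `[bonds]`: `i j k r0` (kcal/mol/A^2, A).
#' * `[angles]`: `i j k kt theta0` (kcal/mol/rad^2, degrees in the file).
#' * `[dihedrals]`: `i j k l vn n gamma` (kcal/mol, periodicity, degrees).
#' * `[ligand_bonds]`: `i j order` -- the ligand chemical bond graph.
#'
#' Atom indices refer to atom order in the companion structure file.
#'
#' @param path Path to a parameter file.
#' @return A list with elements `atoms`, `bonds`, `angles`, `dihedrals`,
#'   `ligand_bonds` (angles/dihedral angles converted to radians).
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) stop("validation error: parameter file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  sec <- NULL
  out <- list()
  buf <- list()
  flush_buf <- function(out, sec, buf) {
    if (is.null(sec) || length(buf) == 0) return(out)
    mat <- do.call(rbind, buf)
    out[[sec]] <- mat
    out
  }
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      out <- flush_buf(out, sec, buf)
      sec <- gsub("\\[|\\]", "", ln)
      buf <- list()
    } else {
      buf[[length(buf) + 1L]] <- strsplit(ln, "\\s+")[[1]]
    }
  }
  out <- flush_buf(out, sec, buf)

  parse_num <- function(mat, cols, int_cols = character()) {
    df <- as.data.frame(mat, stringsAsFactors = FALSE)
    names(df) <- cols[seq_len(ncol(df))]
    for (cn in cols) {
      if (cn == "name") next
      df[[cn]] <- if (cn %in% int_cols) as.integer(df[[cn]]) else as.numeric(df[[cn]])
      if (any(is.na(df[[cn]])))
        stop("format error: non-numeric value in parameter column ", cn)
    }
    df
  }
  res <- list(atoms = NULL, bonds = empty_bonds(), angles = empty_angles(),
              dihedrals = empty_dihedrals(), ligand_bonds = NULL)
  if (!is.null(out$atoms))
    res$atoms <- parse_num(out$atoms,
                           c("index", "name", "charge", "rmin_half", "epsilon",
                             "group", "solv_volume", "solv_sigma"),
                           int_cols = c("index", "group"))
  if (!is.null(out$bonds))
    res$bonds <- parse_num(out$bonds, c("i", "j", "k", "r0"),
                           int_cols = c("i", "j"))
  if (!is.null(out$angles)) {
    res$angles <- parse_num(out$angles, c("i", "j", "k", "kt", "theta0"),
                            int_cols = c("i", "j", "k"))
    res$angles$theta0 <- deg2rad(res$angles$theta0)
  }
  if (!is.null(out$dihedrals)) {
    res$dihedrals <- parse_num(out$dihedrals,
                               c("i", "j", "k", "l", "vn", "n", "gamma"),
                               int_cols = c("i", "j", "k", "l"))
    res$dihedrals$gamma <- deg2rad(res$dihedrals$gamma)
  }
  if (!is.null(out$ligand_bonds))
    res$ligand_bonds <- parse_num(out$ligand_bonds, c("i", "j", "order"),
                                  int_cols = c("i", "j"))
  res
}

#' Write a system's parameters in the native schema
#'
#' @param sys An `mrmc_system` with complete parameters.
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_parameters()] for the format.
#' @export
write_parameters <- function(sys, path) {
  a <- sys$atoms
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste(...), con)
  wl("# mrmcdock native parameter file")
  wl("[atoms]")
  for (i in seq_len(nrow(a)))
    wl(i, a$name[i], a$charge[i], a$rmin_half[i], a$epsilon[i], a$group[i],
       a$solv_volume[i], a$solv_sigma[i])
  wl("[bonds]")
  b <- sys$bonds
  for (i in seq_len(nrow(b))) wl(b$i[i], b$j[i], b$k[i], b$r0[i])
  wl("[angles]")
  an <- sys$angles
  for (i in seq_len(nrow(an)))
    wl(an$i[i], an$j[i], an$k[i], an$kt[i], rad2deg(an$theta0[i]))
  wl("[dihedrals]")
  d <- sys$dihedrals
  for (i in seq_len(nrow(d)))
    wl(d$i[i], d$j[i], d$k[i], d$l[i], d$vn[i], d$n[i], rad2deg(d$gamma[i]))
  if (!is.null(sys$ligand_bonds)) {
    wl("[ligand_bonds]")
    lb <- sys$ligand_bonds
    for (i in seq_len(nrow(lb))) wl(lb$i[i], lb$j[i], lb$order[i])
  }
  invisible(path)
}

#' Attach parameters from the native schema to a structure
#'
#' @param sys An `mrmc_system` (typically from [read_structure()]).
#' @param params A parameter list from [read_parameters()].
#' @return `sys` with charges, LJ and solvation parameters, hydration groups
#'   and bonded-term tables populated; ligand rotatable bonds are re-detected
#'   from `params$ligand_bonds` when present.
#' @export
attach_parameters <- function(sys, params) {
  pa <- params$atoms
  if (is.null(pa)) stop("validation error: parameter file has no [atoms] section")
  if (nrow(pa) != nrow(sys$atoms))
    stop("validation error: parameter file describes ", nrow(pa),
         " atoms but structure has ", nrow(sys$atoms))
  ord <- order(pa$index)
  pa <- pa[ord, ]
  sys$atoms$charge <- pa$charge
  sys$atoms$rmin_half <- pa$rmin_half
  sys$atoms$epsilon <- pa$epsilon
  sys$atoms$group <- pa$group
  sys$atoms$solv_volume <- pa$solv_volume
  sys$atoms$solv_sigma <- pa$solv_sigma
  sys$bonds <- params$bonds
  sys$angles <- params$angles
  sys$dihedrals <- params$dihedrals
  if (!is.null(params$ligand_bonds)) {
    sys$ligand_bonds <- params$ligand_bonds
    sys$rotatable_bonds <- detect_rotatable_bonds(
      params$ligand_bonds, sys$atoms$element)
  }
  validate_system(sys)
  sys
}
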