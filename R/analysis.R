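ligand_local <- function(sys) {
  lig <- which(sys$atoms$ligand)
  heavy <- lig[sys$atoms$element[lig] != "H"]
  lb <- sys$ligand_bonds
  if (is.null(lb))
    stop("validation error: system has no ligand bond graph")
  data_bonds <- data.frame(i = match(lb$i, lig), j = match(lb$j, lig),
                           order = lb$order)
  list(lig = lig, heavy = heavy, bonds = data_bonds,
       elements = sys$atoms$element[lig])
}

#' Symmetry-aware ligand RMSD
#'
#' Superposes the pose onto the reference by a rigid-body least-squares fit
#' of the shared protein backbone atoms (no ligand atoms enter the fit),
#' then reports the minimum ligand heavy-atom RMSD over all
#' element-preserving automorphisms of the ligand bond graph (chemically
#' equivalent atom mappings).
#'
#' @param sys An `mrmc_system` (provides ligand topology and backbone).
#' @param xyz Pose coordinates.
#' @param ref_xyz Reference coordinates (same atom indexing).
#' @param backbone Atom indices used for the fit; defaults to all protein
#'   backbone atoms.  With fewer than 3 the fit is skipped and coordinates
#'   are compared in the given frame.
#' @param mappings Optional precomputed [ligand_automorphisms()] result.
#' @return RMSD in Angstrom.
#' @export
symmetry_aware_rmsd <- function(sys, xyz, ref_xyz, backbone = NULL,
                                mappings = NULL) {
  ll <- ligand_local(sys)
  if (is.null(backbone)) backbone <- backbone_atoms(sys)
  if (length(backbone) >= 3) {
    fit <- kabsch(xyz[backbone, , drop = FALSE],
                  ref_xyz[backbone, , drop = FALSE])
    xyz <- apply_superposition(xyz, fit)
  }
  if (is.null(mappings))
    mappings <- ligand_automorphisms(ll$bonds, ll$elements)
  heavy_local <- attr(mappings, "heavy")
  pose_h <- xyz[ll$lig[heavy_local], , drop = FALSE]
  ref_h <- ref_xyz[ll$lig[heavy_local], , drop = FALSE]
  if (nrow(pose_h) == 0 || length(mappings) == 0)
    stop("validation error: no valid ligand atom correspondence")
  min(vapply(mappings, function(pm) rmsd_plain(pose_h[pm, , drop = FALSE],
                                               ref_h), numeric(1)))
}

#' Complete-linkage pose clustering at a percentile cutoff
#'
#' Agglomerative complete-linkage clustering of a pose-pose distance matrix,
#' cut at the given percentile (linear-interpolation definition) of the
#' off-diagonal pairwise distances, so cluster diameters scale with the
#' spread of the ensemble.  Complete linkage guarantees every intra-cluster
#' distance is at most the cutoff.
#'
#' @param D Symmetric non-negative distance matrix with zero diagonal (or a
#'   `dist`).
#' @param percentile Cutoff percentile of off-diagonal distances
#'   (default 10).
#' @return list of class `"pose_clusters"`: `assignment` (integer cluster id
#'   per pose), `cutoff` (A), `tree` (the `hclust` object, `NULL` for n = 1)
#'   and `heights` (linkage distances).
#' @export
cluster_poses <- function(D, percentile = 10) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  n <- nrow(D)
  if (is.null(n) || n == 0) stop("validation error: empty distance matrix")
  if (any(D < 0) || any(abs(diag(D)) > 1e-12) || any(abs(D - t(D)) > 1e-8))
    stop("validation error: distance matrix must be symmetric,",
         " non-negative with zero diagonal")
  if (n == 1)
    return(structure(list(assignment = 1L, cutoff = NA_real_, tree = NULL,
                          heights = numeric(0)),
                     class = "pose_clusters"))
  off <- D[upper.tri(D)]
  cutoff <- as.numeric(stats::quantile(off, percentile / 100, type = 7))
  tree <- stats::hclust(stats::as.dist(D), method = "complete")
  assignment <- stats::cutree(tree, h = cutoff)
  structure(list(assignment = as.integer(assignment), cutoff = cutoff,
                 tree = tree, heights = tree$height),
            class = "pose_clusters")
}

#' @export
print.pose_clusters <- function(x, ...) {
  cat("Pose clustering:", length(unique(x$assignment)), "clusters of",
      length(x$assignment), "poses; cutoff",
      format(x$cutoff, digits = 4), "A\n")
  invisible(x)
}

#' Select the best pose by one of three ranking rules
#'
#' Method 1: the pose with the lowest protein-ligand interaction energy,
#' ignoring clusters.  Method 2: the lowest-interaction-energy pose within
#' the largest cluster (size ties broken by lower mean interaction energy).
#' Method 3: the lowest-interaction-energy pose within the cluster whose
#' mean interaction energy is lowest.
#'
#' @param records data.frame with an `interaction_energy` column.
#' @param clusters A [cluster_poses()] result (required for methods 2-3).
#' @param method 1, 2 or 3.
#' @return Row index of the selected pose in `records`.
#' @export
rank_poses <- function(records, clusters = NULL, method = 1) {
  if (is.null(records) || nrow(records) == 0)
    stop("validation error: empty pose records")
  en <- records$interaction_energy
  if (method == 1) return(which.min(en))
  if (is.null(clusters))
    stop("validation error: methods 2-3 require clusters")
  asg <- clusters$assignment
  if (length(asg) != nrow(records))
    stop("validation error: clusters inconsistent with records")
  ids <- sort(unique(asg))
  size <- vapply(ids, function(k) sum(asg == k), integer(1))
  meane <- vapply(ids, function(k) mean(en[asg == k]), numeric(1))
  target <- if (method == 2) {
    cand <- ids[size == max(size)]
    cand[which.min(meane[match(cand, ids)])]
  } else if (method == 3) {
    ids[which.min(meane)]
  } else stop("unknown ranking method: ", method)
  members <- which(asg == target)
  members[which.min(en[members])]
}

#' Summarise docking performance across drugs
#'
#' For each drug, the runs are sorted by interaction energy and the minimum
#' RMSD among the `N` lowest-energy runs is recorded; this best-of-N value
#' is averaged over drugs for `N = 1..n_max`.  Also returns the empirical
#' CDF of the `N = 1` (lowest-energy pose) RMSDs and the no-energy baseline
#' (mean over drugs of each drug's overall best RMSD).
#'
#' @param records data.frame with columns `drug`, `interaction_energy`,
#'   `rmsd`.
#' @param n_max Largest `N` (default: the largest per-drug run count).
#' @return list with `best_of_n` (data.frame `N`, `avg_min_rmsd`),
#'   `cdf` (an [stats::ecdf()] of the top-ranked RMSDs), `top_rmsd`
#'   (named per-drug vector) and `baseline`.
#' @export
summarize_performance <- function(records, n_max = NULL) {
  stopifnot(all(c("drug", "interaction_energy", "rmsd") %in% names(records)))
  by_drug <- split(records, records$drug)
  if (is.null(n_max)) n_max <- max(vapply(by_drug, nrow, integer(1)))
  prefix_min <- function(df, N) {
    ord <- order(df$interaction_energy)
    min(df$rmsd[ord[seq_len(min(N, nrow(df)))]])
  }
  best_of_n <- data.frame(
    N = seq_len(n_max),
    avg_min_rmsd = vapply(seq_len(n_max), function(N)
      mean(vapply(by_drug, prefix_min, numeric(1), N = N)), numeric(1)))
  top <- vapply(by_drug, prefix_min, numeric(1), N = 1)
  list(best_of_n = best_of_n, cdf = stats::ecdf(top), top_rmsd = top,
       baseline = mean(vapply(by_drug, function(df) min(df$rmsd),
                              numeric(1))))
}

#' Effective ligand translation and rotation between two configurations
#'
#' Aligns the post configuration to the pre configuration on the protein
#' backbone, then decomposes the rigid transform minimising the ligand
#' heavy-atom RMSD between the two into a translation magnitude (centroid
#' shift, A) and a rotation angle (from the trace of the optimal rotation,
#' reported in [0, 180] degrees).
#'
#' @param sys An `mrmc_system`.
#' @param pre,post Coordinate matrices with identical topology.
#' @return list `(translation, rotation)` in A and degrees.
#' @export
effective_move_size <- function(sys, pre, post) {
  bb <- backbone_atoms(sys)
  if (length(bb) >= 3) {
    fit <- kabsch(post[bb, , drop = FALSE], pre[bb, , drop = FALSE])
    post <- apply_superposition(post, fit)
  }
  lig <- which(sys$atoms$ligand & sys$atoms$element != "H")
  lp <- pre[lig, , drop = FALSE]; lq <- post[lig, , drop = FALSE]
  translation <- sqrt(sum((colMeans(lq) - colMeans(lp))^2))
  if (length(lig) >= 3) {
    fit2 <- kabsch(lp, lq)
    tr <- sum(diag(fit2$R))
    angle <- rad2deg(acos(pmin(1, pmax(-1, (tr - 1) / 2))))
  } else angle <- 0
  list(translation = translation, rotation = angle)
}

#' Ligand RMSD time series along a trajectory
#'
#' Symmetry-aware ligand RMSD of every stored snapshot relative to a
#' reference configuration.
#'
#' @param traj An `"mrmc_trajectory"`.
#' @param sys The `mrmc_system`.
#' @param ref_xyz Reference coordinates.
#' @param ... Passed to [symmetry_aware_rmsd()].
#' @return data.frame with columns `move` and `rmsd`.
#' @export
rmsd_timeseries <- function(traj, sys, ref_xyz, ...) {
  ll <- ligand_local(sys)
  maps <- ligand_automorphisms(ll$bonds, ll$elements)
  data.frame(
    move = vapply(traj$snapshots, `[[`, numeric(1), "move"),
    rmsd = vapply(traj$snapshots, function(s)
      symmetry_aware_rmsd(sys, s$xyz, ref_xyz, mappings = maps, ...),
      numeric(1)))
}

#' Plot a docking trajectory
#'
#' Total-energy trace over snapshots, optionally with the ligand RMSD
#' series on a second panel when a reference is supplied.
#'
#' @param x An `"mrmc_trajectory"`.
#' @param sys Optional `mrmc_system` (needed for the RMSD panel).
#' @param ref_xyz Optional reference coordinates.
#' @param ... Further graphical parameters.
#' @return Invisibly, the data plotted.
#' @export
plot.mrmc_trajectory <- function(x, sys = NULL, ref_xyz = NULL, ...) {
  moves <- vapply(x$snapshots, `[[`, numeric(1), "move")
  etot <- vapply(x$snapshots, function(s) s$energy$total, numeric(1))
  if (!is.null(sys) && !is.null(ref_xyz)) {
    op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
    on.exit(graphics::par(op))
  }
  graphics::plot(moves, etot, type = "l", xlab = "trial move",
                 ylab = "total energy (kcal/mol)", ...)
  out <- data.frame(move = moves, total = etot)
  if (!is.null(sys) && !is.null(ref_xyz)) {
    rs <- rmsd_timeseries(x, sys, ref_xyz)
    graphics::plot(rs$move, rs$rmsd, type = "l", xlab = "trial move",
                   ylab = "ligand RMSD (A)")
    out$rmsd <- rs$rmsd
  }
  invisible(out)
}
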