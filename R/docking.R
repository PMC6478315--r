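#' Docking run specification
#'
#' Bundles the protocol choices of a docking run.  Defaults follow the
#' production protocol: 1000 random initial poses placed within 4 A of the
#' site centre, refinement by 40000 trial moves of regular MC or 80000
#' elementary trial moves of the mixed NCMC/MC protocol, fully flexible
#' protein.
#'
#' @param protocol `"mc"` or `"ncmc_mixed"`.
#' @param n_trial_moves Total trial-move budget (default 40000 for MC,
#'   80000 for NCMC/MC; for the mixed protocol both interior NCMC and
#'   regular moves count toward the budget).
#' @param n_initial_poses Number of random initial poses (default 1000).
#' @param placement_radius Radius of the random-placement ball, A (default 4).
#' @param site_center 3-vector, A; default `NULL` means the reference
#'   ligand's heavy-atom centre of mass.
#' @param mode Protein-flexibility mode (see [move_mix()]).
#' @param rng_seed Integer seed for the run.
#' @param protonation_variant Free-text label carried into reports.
#' @param seed_by `"total"` (default) or `"interaction"`: which energy
#'   selects the starting pose.
#' @param stride Snapshot stride for the refinement trajectory.
#' @return A list of class `"docking_run_spec"`.
#' @export
docking_run_spec <- function(protocol = c("mc", "ncmc_mixed"),
                             n_trial_moves = NULL, n_initial_poses = 1000,
                             placement_radius = 4, site_center = NULL,
                             mode = "fully_flexible", rng_seed = 1,
                             protonation_variant = "default",
                             seed_by = c("total", "interaction"),
                             stride = 100) {
  protocol <- match.arg(protocol)
  if (is.null(n_trial_moves))
    n_trial_moves <- if (protocol == "mc") 40000 else 80000
  structure(list(protocol = protocol, n_trial_moves = n_trial_moves,
                 n_initial_poses = n_initial_poses,
                 placement_radius = placement_radius,
                 site_center = site_center, mode = mode,
                 rng_seed = rng_seed,
                 protonation_variant = protonation_variant,
                 seed_by = match.arg(seed_by), stride = stride),
            class = "docking_run_spec")
}

#' Generate random initial ligand poses
#'
#' Each pose places the ligand centroid uniformly within
#' `placement_radius` of the site centre, applies a uniform random
#' orientation (random axis, random angle in (-180, 180] degrees) and sets
#' every rotatable bond to an independent uniform random angle.
#'
#' @param sys An `mrmc_system` containing the ligand.
#' @param site_center 3-vector, A.
#' @param n_poses Number of poses.
#' @param placement_radius Ball radius, A.
#' @param xyz Base coordinates (default system reference).
#' @return List of `n_poses` coordinate matrices.
#' @export
generate_initial_poses <- function(sys, site_center, n_poses = 1000,
                                   placement_radius = 4, xyz = sys$xyz) {
  lig <- which(sys$atoms$ligand)
  poses <- vector("list", n_poses)
  for (p in seq_len(n_poses)) {
    pose <- xyz
    for (rb in sys$rotatable_bonds) {
      th <- stats::runif(1, -pi, pi)
      pose <- rotate_about_axis(pose, rb$moving, pose[rb$atoms[1], ],
                                pose[rb$atoms[2], ], th)
    }
    com <- colMeans(pose[lig, , drop = FALSE])
    axis <- random_unit_vector()
    th <- stats::runif(1, -pi, pi)
    pose <- rotate_about_axis(pose, lig, com, com + axis, th)
    target <- site_center + random_in_ball(placement_radius)
    shift <- target - colMeans(pose[lig, , drop = FALSE])
    pose[lig, ] <- sweep(pose[lig, , drop = FALSE], 2, shift, `+`)
    poses[[p]] <- pose
  }
  poses
}

#' Select the seed pose for refinement
#'
#' Returns the pose minimising the energy function; ties are broken by the
#' lowest pose index.
#'
#' @param poses List of coordinate matrices.
#' @param energy_fn Function mapping a coordinate matrix to a scalar energy.
#' @return list `(index, xyz, energy, energies)`.
#' @export
select_seed_pose <- function(poses, energy_fn) {
  if (length(poses) == 0) stop("validation error: empty pose list")
  energies <- vapply(poses, energy_fn, numeric(1))
  best <- which.min(energies)     # which.min returns the first minimum
  list(index = best, xyz = poses[[best]], energy = energies[best],
       energies = energies)
}

#' Run one docking run: random-pose search then MC refinement
#'
#' @param model An [energy_model()].
#' @param spec A [docking_run_spec()].
#' @param references Optional list of reference coordinate matrices for the
#'   ligand-RMSD columns of the pose record.
#' @return list of class `"docking_run"` with `pose` (a one-row PoseRecord
#'   data.frame), `trajectory`, `seed_pose` and `initial_energies`.
#' @export
run_docking <- function(model, spec = docking_run_spec("mc"),
                        references = list()) {
  set.seed(spec$rng_seed)
  sys <- model$sys
  site <- spec$site_center
  if (is.null(site)) {
    ligh <- which(sys$atoms$ligand & sys$atoms$element != "H")
    site <- colMeans(sys$xyz[ligh, , drop = FALSE])
  }
  poses <- generate_initial_poses(sys, site, spec$n_initial_poses,
                                  spec$placement_radius)
  energy_fn <- if (spec$seed_by == "total")
    function(x) total_energy(model, x)$total
  else function(x) interaction_energy(model, x)
  seedp <- select_seed_pose(poses, energy_fn)
  mix <- move_mix(spec$mode)
  if (spec$protocol == "mc") {
    traj <- run_mc(model, spec$n_trial_moves, mix = mix, xyz = seedp$xyz,
                   stride = spec$stride)
  } else {
    sched <- build_schedule()
    per_cycle <- 400 + nrow(sched$phases) * sched$moves_per_phase
    n_cycles <- max(1L, floor(spec$n_trial_moves / per_cycle))
    traj <- run_mixed_protocol(model, n_cycles, mix = mix,
                               schedule = sched, xyz = seedp$xyz,
                               stride = spec$stride)
  }
  e <- total_energy(model, traj$final_xyz)
  pose <- data.frame(
    variant = spec$protonation_variant, seed = spec$rng_seed,
    protocol = spec$protocol,
    interaction_energy = e$u_vdw_int + e$u_elec_int,
    total_energy = e$total, stringsAsFactors = FALSE)
  for (ri in seq_along(references))
    pose[[paste0("rmsd_ref", ri)]] <-
      symmetry_aware_rmsd(sys, traj$final_xyz, references[[ri]])
  out <- list(pose = pose, trajectory = traj, seed_pose = seedp,
              initial_energies = seedp$energies, final_xyz = traj$final_xyz)
  class(out) <- "docking_run"
  out
}

#' Run a docking campaign
#'
#' Fans out independent seeded docking runs over one or more prepared
#' protonation variants and aggregates the final-pose records.  Per-run
#' seeds are derived deterministically from the master seed by a counter
#' scheme, so campaigns are reproducible run-by-run.  A failed run is
#' recorded with `ok = FALSE` and skipped, not fatal.
#'
#' @param models Named list of [energy_model()] objects, one per variant
#'   (variants are inputs, not computed).
#' @param spec A [docking_run_spec()] template (its `rng_seed` acts as the
#'   master seed).
#' @param n_runs_per_variant Runs per variant.
#' @param references Optional list of reference coordinate matrices for
#'   RMSD columns.
#' @return list of class `"docking_campaign"`: `records` (one row per
#'   successful run: run id, variant, seed, energies, RMSDs) and `poses`
#'   (list of final coordinate matrices named by run id).
#' @export
run_campaign <- function(models, spec = docking_run_spec("mc"),
                         n_runs_per_variant = 2, references = list()) {
  if (is.null(names(models))) names(models) <- paste0("variant", seq_along(models))
  records <- list(); poses <- list()
  counter <- 0L
  for (vn in names(models)) {
    for (r in seq_len(n_runs_per_variant)) {
      counter <- counter + 1L
      run_spec <- spec
      run_spec$rng_seed <- (spec$rng_seed * 10007L + counter) %% .Machine$integer.max
      run_spec$protonation_variant <- vn
      run_id <- sprintf("%s_run%02d", vn, r)
      res <- tryCatch(run_docking(models[[vn]], run_spec, references),
                      error = function(e) e)
      if (inherits(res, "error")) {
        warning("docking run ", run_id, " failed: ", conditionMessage(res))
        next
      }
      rec <- cbind(run = run_id, res$pose, ok = TRUE,
                   stringsAsFactors = FALSE)
      records[[length(records) + 1L]] <- rec
      poses[[run_id]] <- res$final_xyz
    }
  }
  out <- list(records = do.call(rbind, records), poses = poses, spec = spec)
  class(out) <- "docking_campaign"
  out
}

#' @export
print.docking_campaign <- function(x, ...) {
  cat("Docking campaign:", nrow(x$records), "successful runs\n")
  print(utils::head(x$records, 10))
  invisible(x)
}

#' Write the campaign report as tab-separated text
#' @param campaign A `"docking_campaign"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_campaign_report <- function(campaign, path) {
  utils::write.table(campaign$records, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
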