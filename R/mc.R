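scaled_total <- function(e, lambda) {
  e$u_protein + e$u_ligand + lambda[1] * e$u_vdw_int +
    lambda[2] * e$u_elec_int + e$u_restraint
}

#' Run a Metropolis Monte Carlo simulation
#'
#' Trial moves are drawn from the move mix by their fractions, applied to
#' the current configuration, and accepted with the Metropolis criterion at
#' the model's temperature.  The running energy is tracked by accumulated
#' move deltas and checked against a full recomputation every
#' `recompute_interval` moves; drift beyond 1e-4 kcal/mol is a hard error
#' (bookkeeping bug guard).
#'
#' @param model An [energy_model()].
#' @param n_moves Number of trial moves.
#' @param mix A [move_mix()].
#' @param xyz Starting coordinates (default: system reference).
#' @param lambda Coupling factors held fixed over the run (default fully
#'   coupled).
#' @param stride Snapshot interval in moves (default 100); the final
#'   configuration is always recorded.
#' @param recompute_interval Full-recomputation interval (default 1000).
#' @param seed Optional integer; when given, `set.seed(seed)` is called so
#'   the trajectory is reproducible.
#' @return An object of class `"mrmc_trajectory"`: `log` (per-move
#'   data.frame: `move, kind, size, delta_u, accepted, noop`), `snapshots`
#'   (list of `list(move, xyz, energy)`), `final_xyz`, `acceptance`
#'   (per-kind attempted/accepted counts) and `lambda`.
#' @export
run_mc <- function(model, n_moves, mix = move_mix("fully_flexible"),
                   xyz = model$sys$xyz, lambda = c(1, 1), stride = 100,
                   recompute_interval = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tables <- build_move_tables(model$sys)
  e <- total_energy(model, xyz, lambda)
  u <- scaled_total(e, lambda)
  u_accum <- u
  kinds <- mix$kind
  log_kind <- character(n_moves); log_size <- numeric(n_moves)
  log_du <- numeric(n_moves); log_acc <- logical(n_moves)
  log_noop <- logical(n_moves)
  snapshots <- list()
  beta <- model$settings$beta
  for (m in seq_len(n_moves)) {
    kind <- kinds[sample.int(length(kinds), 1, prob = mix$fraction)]
    trial <- propose_move(kind, model$sys, xyz, mix$max_size[mix$kind == kind],
                          tables)
    log_kind[m] <- kind; log_size[m] <- trial$size; log_noop[m] <- trial$noop
    if (trial$noop) {
      log_du[m] <- 0; log_acc[m] <- TRUE
    } else {
      e_new <- total_energy(model, trial$xyz, lambda)
      u_new <- scaled_total(e_new, lambda)
      du <- u_new - u
      log_du[m] <- du
      if (metropolis_accept(du, beta)) {
        xyz <- trial$xyz; u <- u_new; e <- e_new
        u_accum <- u_accum + du
        log_acc[m] <- TRUE
      }
    }
    if (m %% recompute_interval == 0) {
      u_full <- scaled_total(total_energy(model, xyz, lambda), lambda)
      if (abs(u_full - u_accum) > 1e-4)
        stop("energy bookkeeping drift: ", abs(u_full - u_accum),
             " kcal/mol after ", m, " moves")
      u <- u_full
    }
    if (m %% stride == 0)
      snapshots[[length(snapshots) + 1L]] <-
        list(move = m, xyz = xyz, energy = total_energy(model, xyz, lambda))
  }
  if (n_moves %% stride != 0 || n_moves == 0)
    snapshots[[length(snapshots) + 1L]] <-
      list(move = n_moves, xyz = xyz,
           energy = total_energy(model, xyz, lambda))
  log <- data.frame(move = seq_len(n_moves), kind = log_kind,
                    size = log_size, delta_u = log_du, accepted = log_acc,
                    noop = log_noop, stringsAsFactors = FALSE)
  out <- list(log = log, snapshots = snapshots, final_xyz = xyz,
              acceptance = acceptance_table(log), lambda = lambda,
              u_accum = u_accum)
  class(out) <- "mrmc_trajectory"
  out
}

acceptance_table <- function(log) {
  if (nrow(log) == 0)
    return(data.frame(kind = character(), attempted = integer(),
                      accepted = integer()))
  agg <- aggregate(cbind(attempted = rep(1L, nrow(log)),
                         accepted = as.integer(log$accepted)) ~ kind,
                   data = log, FUN = sum)
  agg
}

#' @export
print.mrmc_trajectory <- function(x, ...) {
  cat("MC trajectory:", nrow(x$log), "trial moves,",
      length(x$snapshots), "snapshots\n")
  if (nrow(x$acceptance)) {
    for (i in seq_len(nrow(x$acceptance)))
      cat(sprintf("  %-22s %6d attempted  %6d accepted (%.3f)\n",
                  x$acceptance$kind[i], x$acceptance$attempted[i],
                  x$acceptance$accepted[i],
                  x$acceptance$accepted[i] / x$acceptance$attempted[i]))
  }
  if (!is.null(x$ncmc_log) && nrow(x$ncmc_log))
    cat("  NCMC moves:", nrow(x$ncmc_log), "attempted,",
        sum(x$ncmc_log$accepted), "accepted\n")
  invisible(x)
}

#' Acceptance rate binned by move size
#'
#' Supports the move-size diagnostics: histograms of attempted and accepted
#' move counts per size bin for one move kind.  Per-bin attempt counts sum
#' to the total number of attempts of that kind.
#'
#' @param traj An `"mrmc_trajectory"` (or its `log`/`ncmc_log` data.frame
#'   with columns `size` and `accepted`).
#' @param kind Move kind to select (ignored when `traj` is a data.frame).
#' @param breaks Bin edges for the move size (passed to [cut()]).
#' @return data.frame with `bin`, `attempted`, `accepted`, `rate`.
#' @export
acceptance_by_size <- function(traj, kind = NULL, breaks = 10) {
  log <- if (is.data.frame(traj)) traj else traj$log
  if (!is.null(kind) && "kind" %in% names(log))
    log <- log[log$kind == kind & !log$noop, , drop = FALSE]
  if (nrow(log) == 0)
    return(data.frame(bin = character(), attempted = integer(),
                      accepted = integer(), rate = numeric()))
  bins <- cut(log$size, breaks = breaks, include.lowest = TRUE)
  att <- tapply(rep(1L, nrow(log)), bins, sum, default = 0L)
  acc <- tapply(as.integer(log$accepted), bins, sum, default = 0L)
  data.frame(bin = names(att), attempted = as.integer(att),
             accepted = as.integer(acc),
             rate = ifelse(att > 0, acc / att, NA_real_))
}

#' Write a trajectory as a multi-model PDB plus a tabular energy log
#'
#' @param traj An `"mrmc_trajectory"`.
#' @param sys The `mrmc_system` the trajectory belongs to.
#' @param pdb_path Output multi-model PDB path.
#' @param log_path Optional path for the tab-separated energy/acceptance log.
#' @return `pdb_path`, invisibly.
#' @export
write_trajectory <- function(traj, sys, pdb_path, log_path = NULL) {
  con <- file(pdb_path, "w")
  on.exit(close(con))
  a <- sys$atoms
  for (si in seq_along(traj$snapshots)) {
    snap <- traj$snapshots[[si]]
    writeLines(sprintf("MODEL     %4d", si), con)
    for (i in seq_len(nrow(a))) {
      writeLines(sprintf("%-6s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f",
                         if (a$ligand[i]) "HETATM" else "ATOM", i,
                         substr(a$name[i], 1, 4),
                         substr(sys$residues$name[a$residue[i]], 1, 3),
                         if (a$ligand[i]) "L" else "A", a$residue[i],
                         snap$xyz[i, 1], snap$xyz[i, 2], snap$xyz[i, 3]), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  if (!is.null(log_path)) {
    recs <- do.call(rbind, lapply(traj$snapshots, function(s)
      cbind(move = s$move, energy_record(s$energy))))
    utils::write.table(recs, log_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(pdb_path)
}
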