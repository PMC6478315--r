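#' Build a nonequilibrium candidate Monte Carlo coupling schedule
#'
#' The default schedule has four phases of 100 interior moves each: the
#' ligand charges are first switched off (`lambda_elec` 1 -> 0), then the
#' van der Waals coupling (`lambda_vdw` 1 -> 0), after which both are
#' restored in reverse order (`vdw` 0 -> 1, then `elec` 0 -> 1).  Within a
#' phase the active coupling changes by `lambda_step` every `moves_per_step`
#' interior moves, so each phase traverses its parameter fully between 1 and
#' 0; both couplings are 1 at the start and end, and both are 0 at the end
#' of the second phase.
#'
#' @param moves_per_phase Interior MC moves per phase (default 100).
#' @param lambda_step Coupling increment per update (default 0.05; must
#'   divide 1 exactly).
#' @param moves_per_step Interior moves between updates (default 5).
#' @param phases data.frame with columns `param` (`"vdw"`/`"elec"`) and
#'   `direction` (`"down"`/`"up"`); defaults to the four-phase cycle.
#' @return An object of class `"ncmc_schedule"`.
#' @export
build_schedule <- function(moves_per_phase = 100, lambda_step = 0.05,
                           moves_per_step = 5,
                           phases = data.frame(
                             param = c("elec", "vdw", "vdw", "elec"),
                             direction = c("down", "down", "up", "up"),
                             stringsAsFactors = FALSE)) {
  n_updates <- moves_per_phase / moves_per_step
  if (moves_per_phase %% moves_per_step != 0)
    stop("validation error: moves_per_phase must be a multiple of",
         " moves_per_step")
  if (abs(n_updates * lambda_step - 1) > 1e-9)
    stop("validation error: schedule must traverse lambda fully: ",
         "updates-per-phase * lambda_step must equal 1")
  grid <- seq(0, n_updates) * lambda_step   # exact shared lambda grid
  grid[length(grid)] <- 1
  out <- list(phases = phases, moves_per_phase = moves_per_phase,
              lambda_step = lambda_step, moves_per_step = moves_per_step,
              n_updates = as.integer(n_updates), grid = grid)
  class(out) <- "ncmc_schedule"
  out
}

#' @export
print.ncmc_schedule <- function(x, ...) {
  cat("NCMC schedule:", nrow(x$phases), "phases x", x$moves_per_phase,
      "interior moves; lambda step", x$lambda_step, "every",
      x$moves_per_step, "moves\n")
  cat("  phase order:",
      paste(x$phases$param, x$phases$direction, collapse = ", "), "\n")
  invisible(x)
}

#' Coupling-state trajectory of a schedule
#'
#' @param schedule An [build_schedule()] object.
#' @return data.frame with one row per lambda update: `update`, `phase`,
#'   `param`, `lambda_vdw`, `lambda_elec` (the state *after* the update).
#' @export
schedule_states <- function(schedule) {
  lam <- c(vdw = 1, elec = 1)
  rows <- list()
  upd <- 0L
  for (p in seq_len(nrow(schedule$phases))) {
    param <- schedule$phases$param[p]
    down <- schedule$phases$direction[p] == "down"
    for (k in seq_len(schedule$n_updates)) {
      idx <- if (down) schedule$n_updates - k else k
      lam[param] <- schedule$grid[idx + 1L]
      upd <- upd + 1L
      rows[[upd]] <- data.frame(update = upd, phase = p, param = param,
                                lambda_vdw = lam[["vdw"]],
                                lambda_elec = lam[["elec"]])
    }
  }
  do.call(rbind, rows)
}

#' Perform one NCMC move
#'
#' Runs the scheduled driven simulation: interior Metropolis MC under the
#' coupling-scaled potential, with the active coupling stepped along the
#' schedule.  At each coupling update the nonequilibrium work accumulates
#' the coupling change times the corresponding unscaled interaction
#' component evaluated at the configuration current when the change is
#' applied.  The whole sequence is finally accepted with probability
#' `min(1, exp(-beta * w))`; on rejection the pre-move configuration is
#' restored exactly.
#'
#' Work is accounted per component as `lambda_step * (sum of component
#' values at up-updates - sum at down-updates)`, which is algebraically the
#' update-by-update sum and makes the zero-work cancellation of a frozen
#' configuration exact in floating point.
#'
#' @param model An [energy_model()].
#' @param xyz Current coordinates.
#' @param schedule An [build_schedule()] object.
#' @param mix A [move_mix()] used for the interior moves.
#' @param tables Optional precomputed move tables.
#' @return list of class `"ncmc_move"`: `work` (kcal/mol), `accepted`,
#'   `interior_accept_count`, `interior_moves`, `xyz` (post-move
#'   configuration, restored to `xyz_pre` on rejection), `xyz_pre`,
#'   `xyz_attempt` (the driven configuration before any restoration),
#'   `p_final`, and `work_log` (one row per coupling update: `param`,
#'   `dlambda`, `u_component`), from which the work can be replayed.
#' @export
ncmc_move <- function(model, xyz, schedule = build_schedule(),
                      mix = move_mix("fully_flexible"), tables = NULL) {
  if (is.null(tables)) tables <- build_move_tables(model$sys)
  xyz_pre <- xyz
  beta <- model$settings$beta
  lam <- c(1, 1)                      # (vdw, elec)
  e <- total_energy(model, xyz, lam)
  u <- scaled_total(e, lam)
  w_up <- c(vdw = 0, elec = 0)
  w_down <- c(vdw = 0, elec = 0)
  n_acc <- 0L; n_int <- 0L
  wl_param <- character(0); wl_dlam <- numeric(0); wl_u <- numeric(0)
  kinds <- mix$kind
  for (p in seq_len(nrow(schedule$phases))) {
    param <- schedule$phases$param[p]
    ci <- if (param == "vdw") 1L else 2L
    down <- schedule$phases$direction[p] == "down"
    for (k in seq_len(schedule$n_updates)) {
      for (mstep in seq_len(schedule$moves_per_step)) {
        kind <- kinds[sample.int(length(kinds), 1, prob = mix$fraction)]
        trial <- propose_move(kind, model$sys, xyz,
                              mix$max_size[mix$kind == kind], tables)
        n_int <- n_int + 1L
        if (trial$noop) { n_acc <- n_acc + 1L; next }
        e_new <- total_energy(model, trial$xyz, lam)
        u_new <- scaled_total(e_new, lam)
        if (metropolis_accept(u_new - u, beta)) {
          xyz <- trial$xyz; u <- u_new; e <- e_new
          n_acc <- n_acc + 1L
        }
      }
      comp <- if (param == "vdw") e$u_vdw_int else e$u_elec_int
      idx <- if (down) schedule$n_updates - k else k
      lam_old <- lam[ci]
      lam[ci] <- schedule$grid[idx + 1L]
      if (down) w_down[param] <- w_down[param] + comp
      else w_up[param] <- w_up[param] + comp
      wl_param <- c(wl_param, param)
      wl_dlam <- c(wl_dlam, lam[ci] - lam_old)
      wl_u <- c(wl_u, comp)
      u <- scaled_total(e, lam)       # energy of current config at new lambda
    }
  }
  w <- schedule$lambda_step * ((w_up[["vdw"]] - w_down[["vdw"]]) +
                               (w_up[["elec"]] - w_down[["elec"]]))
  p_final <- min(1, exp(-beta * w))
  accepted <- stats::runif(1) < p_final
  out <- list(work = w, accepted = accepted,
              interior_accept_count = n_acc, interior_moves = n_int,
              xyz = if (accepted) xyz else xyz_pre, xyz_pre = xyz_pre,
              xyz_attempt = xyz, p_final = p_final,
              work_log = data.frame(param = wl_param, dlambda = wl_dlam,
                                    u_component = wl_u))
  class(out) <- "ncmc_move"
  out
}

#' Run the mixed NCMC/MC protocol
#'
#' Alternates blocks of regular Metropolis MC with single NCMC moves: each
#' cycle performs `mc_moves_per_cycle` regular moves followed by one NCMC
#' move.  With the defaults (400 regular + 4 x 100 interior moves) each
#' cycle accounts for 800 elementary trial moves, so a 80000-move budget
#' corresponds to 100 cycles.
#'
#' @param model An [energy_model()].
#' @param n_cycles Number of NCMC/MC cycles.
#' @param mix A [move_mix()].
#' @param schedule An [build_schedule()] object.
#' @param mc_moves_per_cycle Regular MC moves per cycle (default 400).
#' @param xyz Starting coordinates.
#' @param stride Snapshot stride within the regular-MC blocks.
#' @param seed Optional integer seed.
#' @return An `"mrmc_trajectory"` whose `ncmc_log` data.frame records, per
#'   NCMC move: `work`, `accepted`, `interior_accept_count`, `p_final` and
#'   the effective ligand `translation` (A) and `rotation` (degrees).
#' @export
run_mixed_protocol <- function(model, n_cycles,
                               mix = move_mix("fully_flexible"),
                               schedule = build_schedule(),
                               mc_moves_per_cycle = 400,
                               xyz = model$sys$xyz, stride = 100,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tables <- build_move_tables(model$sys)
  logs <- list(); snaps <- list(); ncmc_rows <- list()
  move_offset <- 0L
  for (cyc in seq_len(n_cycles)) {
    seg <- run_mc(model, mc_moves_per_cycle, mix = mix, xyz = xyz,
                  stride = stride)
    seg$log$move <- seg$log$move + move_offset
    logs[[length(logs) + 1L]] <- seg$log
    for (s in seg$snapshots) {
      s$move <- s$move + move_offset
      snaps[[length(snaps) + 1L]] <- s
    }
    xyz <- seg$final_xyz
    move_offset <- move_offset + mc_moves_per_cycle
    nm <- ncmc_move(model, xyz, schedule, mix, tables)
    # generated (attempted) ligand displacement, whether or not accepted
    eff <- effective_move_size(model$sys, nm$xyz_pre, nm$xyz_attempt)
    ncmc_rows[[cyc]] <- data.frame(
      cycle = cyc, work = nm$work, accepted = nm$accepted,
      interior_accept_count = nm$interior_accept_count,
      p_final = nm$p_final,
      translation = eff$translation, rotation = eff$rotation)
    xyz <- nm$xyz
    move_offset <- move_offset + nm$interior_moves
    snaps[[length(snaps) + 1L]] <-
      list(move = move_offset, xyz = xyz, energy = total_energy(model, xyz))
  }
  log <- do.call(rbind, logs)
  out <- list(log = log, snapshots = snaps, final_xyz = xyz,
              acceptance = acceptance_table(log), lambda = c(1, 1),
              ncmc_log = do.call(rbind, ncmc_rows))
  class(out) <- "mrmc_trajectory"
  out
}
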