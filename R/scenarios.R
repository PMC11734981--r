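# Treatment-arm experiment grid: named therapy combinations sharing a common
# pre-treatment growth phase, plus cross-arm comparison tables.

.arm_names <- c("untreated", "rt", "bev", "doc", "chemo", "rt_doc", "rt_bev",
                "triple", "triple_half", "triple_late")

#' Define a treatment scenario
#'
#' Known arms combine the three agents: `untreated`, `rt` (radiotherapy
#' only), `bev`, `doc` (drug monotherapies), `chemo` (bevacizumab +
#' docetaxel), `rt_doc`, `rt_bev` (radiation + one drug), `triple` (all
#' three), `triple_half` (triple with half the radiation fractions) and
#' `triple_late` (triple with radiotherapy starting at t = 186, after the
#' chemotherapy sessions conclude).  All therapies otherwise start at t = 80.
#'
#' @param arm Arm name, one of the set above.
#' @param params Base parameter set (defaults loaded if `NULL`).
#' @param overrides Additional parameter overrides applied on top of the
#'   arm's own (list of group -> key -> value).
#' @param t_end Simulation horizon (default 650).
#' @return A list of class `crtsim_scenario` with resolved `params`,
#'   `protocol`, `arm` and `t_end`.
#' @export
scenario <- function(arm, params = NULL, overrides = NULL, t_end = 650) {
  arm <- match.arg(arm, .arm_names)
  over <- overrides %||% list()
  rt_arms <- c("rt", "rt_doc", "rt_bev", "triple", "triple_half", "triple_late")
  if (arm %in% rt_arms) {
    # the clinical course delivers 30 daily fractions on a 5-on/2-off
    # calendar (six calendar weeks, ending at t = 120 when starting at 80)
    over$radiotherapy <- utils::modifyList(list(weekend_breaks = TRUE),
                                           over$radiotherapy %||% list())
  }
  if (arm == "triple_half") {
    over$radiotherapy <- utils::modifyList(list(N_rad = 15L),
                                           over$radiotherapy %||% list())
  }
  if (arm == "triple_late") {
    over$radiotherapy <- utils::modifyList(list(t0_rad = 186),
                                           over$radiotherapy %||% list())
  }
  p <- if (is.null(params)) {
    load_parameters(if (length(over)) over else NULL)
  } else if (length(over)) {
    merged <- unclass(params)
    for (g in names(over)) {
      merged[[g]] <- utils::modifyList(merged[[g]], over[[g]])
    }
    out <- structure(merged, class = "crtsim_params")
    validate_parameters(out)
    out
  } else {
    params
  }
  flags <- switch(arm,
    untreated = c(FALSE, FALSE, FALSE),
    rt = c(TRUE, FALSE, FALSE),
    bev = c(FALSE, TRUE, FALSE),
    doc = c(FALSE, FALSE, TRUE),
    chemo = c(FALSE, TRUE, TRUE),
    rt_doc = c(TRUE, FALSE, TRUE),
    rt_bev = c(TRUE, TRUE, FALSE),
    c(TRUE, TRUE, TRUE)   # triple, triple_half, triple_late
  )
  structure(list(
    arm = arm, params = p,
    protocol = build_protocol(p, rt_on = flags[1], bev_on = flags[2],
                              doc_on = flags[3]),
    t_end = t_end
  ), class = "crtsim_scenario")
}

#' Run a treatment arm
#'
#' Executes a scenario on the given grid.  Because every arm shares the same
#' untreated growth phase before therapy starts, a pre-computed base state
#' (e.g. the state at t = 80 from an untreated run) can be supplied to avoid
#' re-simulating it; the reference oxygen field for oxygen-mode
#' sensitization must then be passed along (`c0_field`).
#'
#' @param sc A `crtsim_scenario`.
#' @param grid A `crtsim_grid`.
#' @param base_state Optional starting `crtsim_state`.
#' @param c0_field Optional t = 0 oxygen field (see [run_simulation()]).
#' @param ... Further arguments passed to [run_simulation()]
#'   (`dt_max`, `snapshot_times`, `control`, `verbose`, ...).
#' @return A `crtsim_trajectory` with the arm name attached.
#' @export
run_arm <- function(sc, grid, base_state = NULL, c0_field = NULL, ...) {
  stopifnot(inherits(sc, "crtsim_scenario"))
  traj <- run_simulation(sc$params, sc$protocol, grid, sc$t_end,
                         state0 = base_state, c0_field = c0_field, ...)
  traj$arm <- sc$arm
  traj
}

#' Align arm metrics at checkpoints
#'
#' Builds a comparison table of surface coverage, tumor radius and healthy
#' recession across arms at the requested checkpoint times (defaults follow
#' the narrative checkpoints t = 120, 350, 500).  All trajectories must
#' share the same grid and cover every checkpoint.
#'
#' @param trajs List of `crtsim_trajectory` objects (named, or carrying
#'   `$arm`).
#' @param checkpoints Times at which to compare.
#' @return Data frame with columns `arm`, `t`, `SC`, `R_t`, `phi`.
#' @export
compare_arms <- function(trajs, checkpoints = c(120, 350, 500)) {
  if (inherits(trajs, "crtsim_trajectory")) trajs <- list(trajs)
  n_ref <- trajs[[1]]$grid$n
  R_ref <- trajs[[1]]$grid$R_tissue
  rows <- list()
  for (k in seq_along(trajs)) {
    tr <- trajs[[k]]
    if (tr$grid$n != n_ref || tr$grid$R_tissue != R_ref) {
      stop("trajectories were computed on different grids", call. = FALSE)
    }
    nm <- tr$arm %||% names(trajs)[k] %||% paste0("arm", k)
    m <- tr$metrics
    for (tc in checkpoints) {
      j <- which.min(abs(m$t - tc))
      if (abs(m$t[j] - tc) > 0.5) {
        stop("trajectory '", nm, "' does not cover checkpoint t = ", tc,
             call. = FALSE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        arm = nm, t = m$t[j], SC = m$SC[j], R_t = m$R_t[j], phi = m$phi[j])
    }
  }
  do.call(rbind, rows)
}

#' Write trajectory outputs to disk
#'
#' Metrics as CSV (`t, SC, R_t, phi, mass_total, novoid_max_err`) and each
#' snapshot as a columnar CSV of all fields by radius.
#'
#' @param traj A `crtsim_trajectory`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trajectory <- function(traj, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- traj$metrics
  m$SC <- m$SC * 100   # percent in outputs
  utils::write.csv(m, file.path(dir, "metrics.csv"), row.names = FALSE)
  for (nm in names(traj$snapshots)) {
    s <- traj$snapshots[[nm]]
    df <- data.frame(r = traj$grid$cell_centers, s$theta, s$chem,
                     p_int = s$p_int, check.names = FALSE)
    utils::write.csv(df, file.path(dir, paste0("snapshot_", nm, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}
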