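# Shared fixtures and independent oracles for the test suite.
#
# The oracle functions re-state the model's printed algebra directly and are
# kept separate from the package implementation on purpose: property tests
# compare the two on randomly generated states.

default_params <- local({
  p <- NULL
  function() {
    if (is.null(p)) p <<- load_parameters()
    p
  }
})

# A parameter set with all kinetic processes switched off except what the
# caller re-enables; useful for isolating single mechanisms.
quiet_params <- function(overrides = list()) {
  off <- list(
    cell_kinetics = list(k_m_h = 0, k_m_c = 0, k_d_h = 0, k_d_c = 0),
    vascular = list(k_ang = 0, k_occ_yv = 1e-12, k_occ_mv = 1e-13,
                    k_mat_ves = 0),
    oxygen = list(k_rep = 0, k_c_h = 0, k_c_c = 0, k_cm_h = 0, k_cm_c = 0),
    vegf = list(k_sec = 0, k_cang = 0, k_dg = 0),
    chemotaxis = list(chi_g = 0)
  )
  for (g in names(overrides)) {
    off[[g]] <- utils::modifyList(off[[g]] %||% list(), overrides[[g]])
  }
  load_parameters(off)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random valid local states (vectorised): fractions from a Dirichlet-like
# draw, chemicals positive, pressures closed by the package.
random_local_states <- function(n, params, seed = 421L) {
  set.seed(seed)
  raw <- matrix(rexp(5 * n), n, 5)
  th <- raw / rowSums(raw) * runif(n, 0.9, 1.0)
  local_state(th[, 1], th[, 2], th[, 3] / 20, th[, 4] / 20,
              1 - th[, 1] - th[, 2] - th[, 3] / 20 - th[, 4] / 20,
              c = runif(n, 0, 1), g = runif(n, 0, 0.02),
              a = runif(n, 0, 1), w = runif(n, 0, 1),
              p_int = runif(n, -0.2, 0.5), params = params)
}

# ---- independent oracles (printed formulas re-stated) -----------------------

oracle_H <- function(x, h) (1 + tanh(x / h)) / 2

oracle_sources <- function(s, p) {
  ck <- p$cell_kinetics; va <- p$vascular
  th <- lapply(s$theta, pmax, 0)
  c <- s$chem$c; g <- s$chem$g
  mit <- function(km, t) km * t * th$int * c / (ck$c_p + c)
  die <- function(kd, t) kd * t * (ck$c_c1 + c) / (ck$c_c2 + c)
  q_h <- mit(ck$k_m_h, th$h) - die(ck$k_d_h, th$h)
  q_c <- mit(ck$k_m_c, th$c) - die(ck$k_d_c, th$c)
  press <- th$h * s$p_h + th$c * s$p_c
  mat <- va$k_mat_ves * va$k_g1 * g / (g + va$k_g2)^2 *
    th$yv * (th$yv + va$m)^va$nu
  q_yv <- va$k_ang * g * (th$yv + th$mv) * th$int / (va$eps + th$int) -
    va$k_occ_yv * th$yv * oracle_H(press - va$p_crit_yv, va$h_occ) - mat
  q_mv <- -va$k_occ_mv * th$mv * oracle_H(press - va$p_crit_mv, va$h_occ) + mat
  list(q_h = q_h, q_c = q_c, q_yv = q_yv, q_mv = q_mv,
       q_int = -(q_h + q_c + q_yv + q_mv))
}

oracle_oxygen <- function(s, p) {
  o <- p$oxygen; ck <- p$cell_kinetics
  th <- lapply(s$theta, pmax, 0)
  c <- s$chem$c
  o$k_rep * (th$yv + th$mv) * (o$c_v - c) -
    (o$k_c_h * th$h * c + o$k_c_c * th$c * c) -
    (o$k_cm_h * th$h + o$k_cm_c * th$c) * th$int * c / (ck$c_p + c)
}

oracle_vegf <- function(s, p) {
  v <- p$vegf
  th <- lapply(s$theta, pmax, 0)
  v$k_sec * (th$h + v$omega * th$c) * s$chem$c / (s$chem$c + v$c_a)^2 -
    v$k_cang * (th$yv + th$mv) * s$chem$g - v$k_dg * s$chem$g
}

# Brute-force 5-on/2-off calendar: walk days from t0, treating 5, skipping 2.
oracle_weekend_calendar <- function(n_frac, t0) {
  times <- numeric(0)
  day <- 0
  while (length(times) < n_frac) {
    if (day %% 7 < 5) times <- c(times, t0 + day)
    day <- day + 1
  }
  times
}

# ---- shared heavy runs (computed once, reused across test files) ------------
#
# Two experiment domains mirror the study layout: the default tissue of
# radius 30 for the radiotherapy-versus-untreated comparison and the
# quantitative checkpoints, and the larger radius-50 tissue for the
# combination-arm comparisons, whose tumors would otherwise fill the small
# domain well before the 650-unit horizon.

.run_cache <- new.env(parent = emptyenv())

acceptance_grid <- function(domain = c("r30", "r50")) {
  domain <- match.arg(domain)
  key <- paste0("grid_", domain)
  if (is.null(.run_cache[[key]])) {
    .run_cache[[key]] <- if (domain == "r30") build_grid(30, 48) else
      build_grid(50, 72)
  }
  .run_cache[[key]]
}

# Untreated growth to t = 80, shared by every treatment arm on its domain.
base_run <- function(domain = "r30") {
  key <- paste0("base_", domain)
  if (is.null(.run_cache[[key]])) {
    g <- acceptance_grid(domain)
    p <- load_parameters(list(scales = list(R_tissue = g$R_tissue)))
    .run_cache[[key]] <- run_simulation(
      p, build_protocol(p, FALSE, FALSE, FALSE), g, t_end = 80)
  }
  .run_cache[[key]]
}

arm_run <- function(name, domain = "r30", t_end = 650, overrides = NULL,
                    snapshot_times = numeric(0)) {
  key <- paste0(name, "_", domain, "_", t_end, "_", length(snapshot_times),
                "_", paste(deparse(overrides), collapse = ""))
  if (is.null(.run_cache[[key]])) {
    g <- acceptance_grid(domain)
    over <- overrides %||% list()
    over$scales <- utils::modifyList(list(R_tissue = g$R_tissue),
                                     over$scales %||% list())
    sc <- scenario(name, t_end = t_end, overrides = over)
    .run_cache[[key]] <- run_arm(
      sc, g, base_state = base_run(domain)$state,
      c0_field = rep(0.25, g$n), snapshot_times = snapshot_times)
  }
  .run_cache[[key]]
}

untreated_run <- function(domain = "r30", t_end = 350,
                          snapshot_times = numeric(0)) {
  arm_run("untreated", domain, t_end, snapshot_times = snapshot_times)
}

metric_at <- function(traj, t, col = "SC") {
  m <- traj$metrics
  m[[col]][match(t, m$t)]
}
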