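homeostatic_state <- function(grid, params) {
  s <- initial_state(grid, params)
  s$theta[, "h"] <- 0.6
  s$theta[, "c"] <- 0
  s
}

test_that("uniform tissue is stationary: zero flow and zero pressure", {
  p <- default_params()
  g <- build_grid(30, 40)
  s <- homeostatic_state(g, p)
  pint <- pressure_solve(s, g, p)
  u <- attr(pint, "u")
  expect_lt(max(abs(as.numeric(pint))), 1e-9)
  expect_lt(max(abs(u)), 1e-9)
  div <- crtsim:::mixture_divergence(s$theta, u, s$chem[, "g"], g, p)
  expect_lt(max(abs(div)), 1e-10)
  u2 <- momentum_solve(s, g, p)
  expect_lt(max(abs(u2)), 1e-9)
})

test_that("mixture flux balances a prescribed chemoattractant gradient", {
  p <- default_params()
  g <- build_grid(30, 60)
  s <- homeostatic_state(g, p)
  s$chem[, "g"] <- 0.01 * (1 + cos(pi * g$cell_centers / g$R_tissue))
  pint <- pressure_solve(s, g, p)
  u <- attr(pint, "u")
  expect_gt(max(abs(u[, "yv"])), 0)   # vessels migrate up-gradient
  div <- crtsim:::mixture_divergence(s$theta, u, s$chem[, "g"], g, p)
  expect_lt(max(abs(div)), 1e-10)
})

test_that("quasi-steady oxygen matches the uniform fixed point", {
  # uniform vasculature with a linear sink only:
  # k_rep th_v (c_v - c) = k_c_h th_h c
  p <- load_parameters(list(oxygen = list(k_cm_h = 0, k_cm_c = 0)))
  g <- build_grid(30, 50)
  s <- homeostatic_state(g, p)
  o <- p$oxygen
  th_v <- 0.017; th_h <- 0.6
  c_star <- o$k_rep * th_v * o$c_v / (o$k_rep * th_v + o$k_c_h * th_h)
  cs <- chemical_solve(s, g, p, "c")
  expect_lt(max(abs(cs - c_star)), 1e-10)
})

test_that("steady chemistry conserves mass under zero-flux boundaries", {
  # at steady state the volume integral of the source must vanish exactly,
  # which holds only if the discrete boundary flux is zero
  p <- default_params()
  g <- build_grid(30, 64)
  tr <- run_simulation(p, build_protocol(p, FALSE, FALSE, FALSE), g,
                       t_end = 15)
  s <- tr$state
  cs <- chemical_solve(s, g, p, "c")
  st2 <- s; st2$chem[, "c"] <- cs
  src <- oxygen_source(
    local_state(s$theta[, "h"], s$theta[, "c"], s$theta[, "yv"],
                s$theta[, "mv"], s$theta[, "int"], c = cs,
                g = s$chem[, "g"], params = p), p)
  expect_lt(abs(sum(src * g$cell_volumes)) / sum(g$cell_volumes), 1e-9)
})

test_that("chemistry solve converges at second order (manufactured field)", {
  kappa <- 1; D <- 0.5
  errs <- vapply(c(50, 100, 200), function(n) {
    g <- build_grid(30, n)
    R <- g$R_tissue
    r <- g$cell_centers
    c_star <- 1 + cos(pi * r / R)
    lap <- -(pi / R) * sin(pi * r / R) / r - (pi / R)^2 * cos(pi * r / R)
    extra <- -D * lap + kappa * c_star
    # oxygen reduced to a pure linear sink of strength kappa
    p <- load_parameters(list(oxygen = list(
      D_c = D, k_rep = 0, k_c_h = kappa / 0.5, k_c_c = 0,
      k_cm_h = 0, k_cm_c = 0)))
    s <- homeostatic_state(g, p)
    s$theta[, "h"] <- 0.5
    s$theta[, "int"] <- 0.483
    sol <- chemical_solve(s, g, p, "c", extra_source = extra)
    max(abs(sol - c_star))
  }, numeric(1))
  expect_gt(errs[1] / errs[2], 3.0)
  expect_gt(errs[2] / errs[3], 3.0)
  expect_lt(errs[3], 1e-3)
})

test_that("momentum solve converges at second order (manufactured field)", {
  zero_drag <- as.list(setNames(
    rep(0, 10), c("h_c", "h_yv", "h_mv", "h_int", "c_yv", "c_mv", "c_int",
                  "yv_mv", "yv_int", "mv_int")))
  p <- load_parameters(list(mechanics = list(d_ij = zero_drag)))
  mu <- p$mechanics$mu
  th <- 0.2
  errs <- vapply(c(40, 80, 160), function(n) {
    g <- build_grid(30, n)
    R <- g$R_tissue
    s <- initial_state(g, p)
    s$theta[] <- th   # uniform, all phases equal
    rf <- g$face_radii[2:n]
    u_star <- function(r) sin(pi * r / R)
    # residual force of the axisymmetric viscous operator for u_star
    f <- -2 * mu * th * (-(pi / R)^2 * sin(pi * rf / R) +
                           (pi / R) * cos(pi * rf / R) / rf -
                           sin(pi * rf / R) / rf^2)
    force <- matrix(0, n - 1, 5)
    force[, 1] <- f
    u <- momentum_solve(s, g, p, extra_force = force)
    max(abs(u[2:n, 1] - u_star(rf)))
  }, numeric(1))
  expect_gt(errs[1] / errs[2], 3.0)
  expect_gt(errs[2] / errs[3], 3.0)
})

test_that("the homeostatic state is a discrete fixed point of a step", {
  p <- default_params()
  g <- build_grid(30, 40)
  s <- homeostatic_state(g, p)
  new <- advance_step(s, 0.1, p, g)
  expect_s3_class(new, "crtsim_state")
  expect_lt(max(abs(new$theta - s$theta)), 1e-12)
  expect_lt(max(abs(new$u)), 1e-10)
  expect_equal(new$time, 0.1)
})

test_that("frozen-flow radiation decay matches the closed-form survival", {
  ov <- list(radiotherapy = list(N_rad = 1, t0_rad = 0.5,
                                 k_rad = 0.91, r_t = 0.5))
  p <- quiet_params(ov)
  g <- build_grid(30, 16)
  s <- initial_state(g, p)
  s$theta[, "c"] <- 0.1
  s$theta[, "h"] <- 0.5
  s$theta[, "int"] <- 1 - 0.1 - 0.5 - 0.017
  pr <- build_protocol(p, bev_on = FALSE, doc_on = FALSE)
  sf_exact <- decay_survival(2.5, 0.91, 0.5)
  err <- vapply(c(0.1, 0.05), function(dt) {
    tr <- run_simulation(p, pr, g, t_end = 3, state0 = s, dt_max = dt)
    abs(tr$state$theta[1, "c"] / 0.1 - sf_exact)
  }, numeric(1))
  expect_lt(err[1], 2e-3)
  # second-order step error: halving dt shrinks the defect about fourfold
  expect_gt(err[1] / err[2], 2.5)
  expect_lt(err[1] / err[2], 6)
})

test_that("implicit transport matches a dense ODE integration (frozen flow)", {
  skip_if_not_installed("deSolve")
  p <- default_params()
  g <- build_grid(30, 16)
  tr <- run_simulation(p, build_protocol(p, FALSE, FALSE, FALSE), g,
                       t_end = 20)
  s <- tr$state
  chi <- p$chemotaxis$chi_g
  n <- g$n
  dgrad <- (s$chem[-1, "g"] - s$chem[-n, "g"]) / g$dr
  rhs <- function(t, y, parms) {
    th <- matrix(y, n, 5, dimnames = list(NULL, crtsim:::PHASES))
    dth <- matrix(0, n, 5)
    loc <- local_state(th[, 1], th[, 2], th[, 3], th[, 4], th[, 5],
                       c = s$chem[, "c"], g = s$chem[, "g"],
                       p_int = s$p_int, params = p)
    q <- phase_rates(loc, p)
    qm <- cbind(q$q_h, q$q_c, q$q_yv, q$q_mv, q$q_int)
    rf <- g$face_radii; rc <- g$cell_centers
    for (i in 1:5) {
      v <- s$u[, i]
      if (i == 3) v[2:n] <- v[2:n] + chi * dgrad
      vin <- v[2:n]
      thup <- ifelse(vin >= 0, th[1:(n - 1), i], th[2:n, i])
      flux <- rf[2:n] * vin * thup          # interior faces
      divv <- (c(flux, 0) - c(0, flux)) / (rc * g$dr)
      dth[, i] <- -divv + qm[, i]
    }
    list(as.numeric(dth))
  }
  ode_out <- deSolve::ode(as.numeric(s$theta), times = c(0, 1), func = rhs,
                          atol = 1e-11, rtol = 1e-11)
  th_ode <- matrix(ode_out[2, -1], n, 5)

  st <- s; sp <- NULL
  ctl <- list(freeze_flow = TRUE, freeze_chem = TRUE)
  for (k in 1:50) {
    new <- advance_step(st, 0.02, p, g, state_prev = sp, control = ctl)
    sp <- st; st <- new
  }
  expect_lt(max(abs(st$theta - th_ode)), 2e-5)
})

test_that("short growth conserves mixture volume and the no-void identity", {
  p <- default_params()
  g <- build_grid(30, 32)
  tr <- run_simulation(p, build_protocol(p, FALSE, FALSE, FALSE), g,
                       t_end = 25)
  m <- tr$metrics
  expect_lt(max(m$novoid_max_err), 1e-6)
  expect_lt(max(abs(m$mass_err)) / m$mass_total[1], 1e-9)
  # surface coverage grows monotonically for the untreated seed
  expect_true(all(diff(m$SC) > 0))
})

test_that("trajectories self-converge as the step ceiling shrinks", {
  p <- default_params()
  g <- build_grid(30, 32)
  pr <- build_protocol(p, FALSE, FALSE, FALSE)
  t1 <- run_simulation(p, pr, g, t_end = 15, dt_max = 0.1)
  t2 <- run_simulation(p, pr, g, t_end = 15, dt_max = 0.05)
  sc1 <- t1$metrics$SC[t1$metrics$t == 15]
  sc2 <- t2$metrics$SC[t2$metrics$t == 15]
  expect_lt(abs(sc1 - sc2) / sc2, 2e-3)
})

test_that("step rejection reports negative fractions instead of continuing", {
  p <- default_params()
  g <- build_grid(30, 16)
  s <- initial_state(g, p)
  s$theta[, "c"] <- -1  # corrupted state
  s$theta[, "h"] <- 0.6
  out <- advance_step(s, 0.1, p, g)
  expect_s3_class(out, "crtsim_step_failure")
})
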