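# Spatial discretization and time integration of the coupled multiphase
# system on the radially symmetric finite-volume grid.
#
# Layout: volume fractions, pressures and concentrations live at cell
# centers; phase velocities live at cell faces (staggered / MAC
# arrangement), which keeps the mixture-incompressibility constraint free of
# pressure checkerboard modes.  The momentum balances of all five phases and
# the interstitial-pressure closure are assembled into one sparse linear
# system and solved monolithically; phase transport uses implicit upwind
# fluxes built from the same face velocities and the same upwinded face
# fractions as the continuity constraint, so the no-void identity is
# inherited by the discrete update.

# ---- small dense tridiagonal solver (Thomas algorithm) ----------------------
.thomas <- function(lower, diag, upper, rhs) {
  n <- length(diag)
  cp <- numeric(n); dp <- numeric(n)
  cp[1] <- upper[1] / diag[1]
  dp[1] <- rhs[1] / diag[1]
  for (k in 2:n) {
    m <- diag[k] - lower[k] * cp[k - 1]
    cp[k] <- upper[k] / m
    dp[k] <- (rhs[k] - lower[k] * dp[k - 1]) / m
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (k in (n - 1):1) x[k] <- dp[k] - cp[k] * x[k + 1]
  x
}

# ---- quasi-steady chemistry -------------------------------------------------

# Radial Laplacian with zero-flux boundaries applied to a cell field:
# coefficients for the tridiagonal operator D * (1/r) d/dr (r d/dr).
.laplacian_coefs <- function(D, grid) {
  n <- grid$n; dr <- grid$dr
  rf <- grid$face_radii
  rc <- grid$cell_centers
  wplus <- D * rf[2:(n + 1)] / (rc * dr^2)   # coupling to cell k+1
  wminus <- D * rf[1:n] / (rc * dr^2)        # coupling to cell k-1
  wplus[n] <- 0    # zero-flux outer boundary
  wminus[1] <- 0   # r = 0 face has zero area
  list(lower = wminus, upper = wplus, diag = -(wplus + wminus))
}

# Newton iteration for D lap(x) + s(x) + extra = 0 with s'(x) supplied.
.solve_quasi_steady <- function(x0, D, src, dsrc, grid, extra = 0,
                                tol = 1e-11, maxit = 30L) {
  lap <- .laplacian_coefs(D, grid)
  x <- x0
  n <- grid$n
  for (it in seq_len(maxit)) {
    Lx <- lap$diag * x + lap$upper * c(x[-1], 0) + lap$lower * c(0, x[-n])
    resid <- Lx + src(x) + extra
    if (max(abs(resid)) < tol) break
    dx <- .thomas(lap$lower, lap$diag + dsrc(x), lap$upper, -resid)
    x <- x + dx
    if (it == maxit) {
      stop("quasi-steady chemistry solve did not converge (max residual ",
           format(max(abs(resid))), ")", call. = FALSE)
    }
  }
  if (any(x < -1e-10)) {
    stop("negative concentration in quasi-steady solve", call. = FALSE)
  }
  pmax(x, 0)
}

#' Quasi-steady chemical field solve
#'
#' Solves `D_i lap(i) + s_i = 0` with zero-flux (Neumann) boundaries for one
#' chemical species, holding the volume fractions (and the other chemicals)
#' of `state` fixed: the chemical dynamics are minutes-to-hours while the
#' cellular dynamics are days, so each species equilibrates instantaneously.
#' The nonlinear saturating sinks are handled by Newton iteration with an
#' analytic Jacobian.
#'
#' @param state A `crtsim_state`.
#' @param grid A `crtsim_grid`.
#' @param params A `crtsim_params` object.
#' @param species One of `"c"`, `"g"`, `"a"`, `"w"`.
#' @param forcing Optional `crtsim_forcing`; required for the drugs (supplies
#'   the blood concentration at `state$time`) and used for the
#'   bevacizumab-modified VEGF sink when the drug is active.
#' @param extra_source Optional known source field added to `s_i` (used by
#'   manufactured-solution verification).
#' @return The concentration field (length `n` vector).
#' @export
chemical_solve <- function(state, grid, params, species, forcing = NULL,
                           extra_source = 0) {
  species <- match.arg(species, CHEMICALS)
  th <- pmax(state$theta, 0)
  tv <- th[, "yv"] + th[, "mv"]
  ck <- params$cell_kinetics
  t_now <- state$time
  if (species == "c") {
    o <- params$oxygen
    lin <- o$k_c_h * th[, "h"] + o$k_c_c * th[, "c"]
    mit <- (o$k_cm_h * th[, "h"] + o$k_cm_c * th[, "c"]) * th[, "int"]
    src <- function(x) o$k_rep * tv * (o$c_v - x) - lin * x -
      mit * x / (ck$c_p + x)
    dsrc <- function(x) -o$k_rep * tv - lin - mit * ck$c_p / (ck$c_p + x)^2
    return(.solve_quasi_steady(state$chem[, "c"], o$D_c, src, dsrc, grid,
                               extra = extra_source))
  }
  if (species == "g") {
    v <- params$vegf
    sec <- v$k_sec * (th[, "h"] + v$omega * th[, "c"]) *
      state$chem[, "c"] / (state$chem[, "c"] + v$c_a)^2
    sink <- v$k_cang * tv + v$k_dg
    bev_sink <- 0
    if (!is.null(forcing) && isTRUE(forcing$bev_on)) {
      a <- state$chem[, "a"]
      bev_sink <- params$bevacizumab$k_n_g * a / (params$bevacizumab$a_50 + a)
    }
    src <- function(x) sec - (sink + bev_sink) * x
    dsrc <- function(x) -(sink + bev_sink)
    return(.solve_quasi_steady(state$chem[, "g"], v$D_g, src, dsrc, grid,
                               extra = extra_source))
  }
  if (species == "a") {
    b <- params$bevacizumab
    a_c <- if (is.null(forcing)) 0 else
      b$a_inj * .pulse_train(t_now, forcing$bev_times, b$k_el_a,
                             inclusive = FALSE)
    src <- function(x) b$k_rep_a * tv * (a_c - x) - b$k_d_a * x -
      b$k_n_a * state$chem[, "g"] * x / (b$a_50 + x) -
      b$k_cap_yv * x * th[, "yv"]
    dsrc <- function(x) -b$k_rep_a * tv - b$k_d_a -
      b$k_n_a * state$chem[, "g"] * b$a_50 / (b$a_50 + x)^2 -
      b$k_cap_yv * th[, "yv"]
    return(.solve_quasi_steady(state$chem[, "a"], b$D_a, src, dsrc, grid,
                               extra = extra_source))
  }
  # docetaxel
  d <- params$docetaxel
  w_c <- if (is.null(forcing)) 0 else
    d$w_inj * .pulse_train(t_now, forcing$doc_times, d$k_el_w,
                           inclusive = FALSE)
  l_h <- proliferation_rate("h", state$theta[, "int"], state$chem[, "c"], params)
  l_c <- proliferation_rate("c", state$theta[, "int"], state$chem[, "c"], params)
  cons <- d$k_cn_h * th[, "h"] * smoothed_heaviside(l_h - d$l_cr, d$h_d) +
    d$k_cn_c * th[, "c"] * smoothed_heaviside(l_c - d$l_cr, d$h_d)
  src <- function(x) d$k_rep_w * tv * (w_c - x) - d$k_d_w * x -
    x / (d$w_m + x) * cons
  dsrc <- function(x) -d$k_rep_w * tv - d$k_d_w - cons * d$w_m / (d$w_m + x)^2
  .solve_quasi_steady(state$chem[, "w"], d$D_w, src, dsrc, grid,
                      extra = extra_source)
}

# ---- monolithic momentum + pressure solve -----------------------------------

# Face-averaged fractions (interior faces only).
.face_avg <- function(theta) {
  n <- nrow(theta)
  (theta[-n, , drop = FALSE] + theta[-1, , drop = FALSE]) / 2
}

# Upwinded face value of a cell field given face velocities (interior faces).
.face_upwind <- function(field, v_face) {
  n <- length(field)
  ifelse(v_face >= 0, field[-n], field[-1])
}

# Block-tridiagonal solve with 6x6 blocks (forward block elimination,
# backward substitution).  D, L, U are 6 x 6 x n arrays (L couples block k to
# k-1, U to k+1), rhs is 6 x n.
.block_thomas <- function(D, L, U, rhs) {
  n <- dim(D)[3]
  W <- array(0, c(6, 7, n))
  W[, 1:6, ] <- U
  W[, 7, ] <- rhs
  fac <- array(0, c(6, 7, n))
  fac[, , 1] <- solve(D[, , 1], W[, , 1])
  for (k in 2:n) {
    Lk <- L[, , k]
    Wk <- W[, , k]
    Wk[, 7] <- Wk[, 7] - Lk %*% fac[, 7, k - 1]
    fac[, , k] <- solve(D[, , k] - Lk %*% fac[, 1:6, k - 1], Wk)
  }
  x <- matrix(0, 6, n)
  x[, n] <- fac[, 7, n]
  for (k in (n - 1):1) {
    x[, k] <- fac[, 7, k] - fac[, 1:6, k] %*% x[, k + 1]
  }
  x
}

# Assemble and solve the coupled creeping-flow system: per-phase momentum
# balances at interior faces plus the mixture-incompressibility constraint at
# cells, with p_int pinned to zero in the outermost cell.  `upwind_v` gives
# the face velocities used to pick upwind fractions in the constraint (the
# previous iterate); `g_field` supplies the chemotactic flux of young
# vessels.  Unknowns are ordered by position (cell pressure + same-index
# face velocities), which renders the system block-tridiagonal with 6x6
# blocks.  Returns face velocities (with boundary zeros) and p_int.
.flow_solve <- function(theta, p_stress, g_field, grid, params,
                        upwind_v = NULL, extra_force = NULL,
                        drag_override = NULL) {
  n <- grid$n; nf <- n - 1L; dr <- grid$dr
  mu <- params$mechanics$mu
  dmat <- if (is.null(drag_override)) params$mechanics$d_ij else drag_override
  chi <- params$chemotaxis$chi_g
  rf <- grid$face_radii[2:n]          # interior face radii
  rc <- grid$cell_centers
  thc <- pmax(theta, 0)
  thf <- .face_avg(thc)               # nf x 5 face-averaged fractions
  if (is.null(upwind_v)) upwind_v <- matrix(0, n + 1, 5)

  # block layout: block k holds [p_k, u_{1..5, face k}]; block n has no face
  # and pads the velocity slots with identity rows.
  D <- array(0, c(6, 6, n)); L <- array(0, c(6, 6, n)); U <- array(0, c(6, 6, n))
  rhs <- matrix(0, 6, n)

  fidx <- seq_len(nf)
  dgrad <- (g_field[-1] - g_field[-n]) / dr    # dg/dr at interior faces

  for (i in 1:5) {
    ri <- i + 1L
    # viscous coupling to neighbouring faces through cell-centred strain
    vm <- 2 * mu * rc[fidx] * thc[fidx, i] / (rf * dr^2)       # u_{f-1}
    vp <- 2 * mu * rc[fidx + 1] * thc[fidx + 1, i] / (rf * dr^2)  # u_{f+1}
    hoop <- 2 * mu * thf[, i] / rf^2
    dragdiag <- rowSums(sweep(thf, 2, dmat[i, ], "*")) * thf[, i]
    D[ri, ri, fidx] <- -(vm + vp) - hoop - dragdiag - 1e-10
    if (nf > 1) {
      L[ri, ri, fidx[-1]] <- vm[-1]
      U[ri, ri, fidx[-nf]] <- vp[-nf]
    }
    for (j in setdiff(1:5, i)) {
      if (dmat[i, j] != 0) {
        D[ri, j + 1L, fidx] <- dmat[i, j] * thf[, i] * thf[, j]
      }
    }
    if (PHASES[i] %in% c("h", "c", "int")) {
      D[ri, 1L, fidx] <- thf[, i] / dr        # p_k
      U[ri, 1L, fidx] <- -thf[, i] / dr       # p_{k+1}
      if (PHASES[i] %in% c("h", "c")) {
        rhs[ri, fidx] <- rhs[ri, fidx] +
          thf[, i] * (p_stress[fidx + 1L] - p_stress[fidx]) / dr
      }
    }
    if (!is.null(extra_force)) {
      rhs[ri, fidx] <- rhs[ri, fidx] - extra_force[, i]
    }
    D[ri, ri, n] <- 1   # padding row for the absent face n
  }

  # mixture incompressibility at cells 1..n-1 (the volume-weighted sum of all
  # n constraints vanishes identically under zero boundary fluxes, so the
  # omitted cell is implied); cell n carries the pressure reference.
  vhint <- upwind_v[2:n, , drop = FALSE]
  vhint[, 3] <- vhint[, 3] + chi * dgrad     # effective young-vessel velocity
  kk <- seq_len(n - 1L)
  for (i in 1:5) {
    thup <- .face_upwind(thc[, i], vhint[, i])   # nf values
    # + flux through right face of cell k (face k, same block)
    D[1L, i + 1L, kk] <- rf[kk] * thup[kk] / (rc[kk] * dr)
    # - flux through left face of cell k (face k-1, previous block)
    L[1L, i + 1L, kk[-1]] <- -rf[kk[-1] - 1L] * thup[kk[-1] - 1L] /
      (rc[kk[-1]] * dr)
  }
  # chemotactic flux of young vessels (known, goes to the right-hand side)
  thup_yv <- .face_upwind(thc[, 3], vhint[, 3])
  chflux <- chi * rf * thup_yv * dgrad          # at interior faces
  # left-face flux is zero for cell 1; for cell k it is chflux[k-1]
  div_ch <- (chflux[kk] - c(0, chflux[seq_len(n - 2L)])) / (rc[kk] * dr)
  rhs[1L, kk] <- rhs[1L, kk] - div_ch
  D[1L, 1L, n] <- 1    # pressure reference p_n = 0

  sol <- .block_thomas(D, L, U, rhs)

  u <- matrix(0, n + 1, 5, dimnames = list(NULL, PHASES))
  u[2:n, ] <- t(sol[2:6, fidx, drop = FALSE])
  list(u = u, p_int = sol[1L, ])
}

#' Solve the multiphase momentum balances with pressures held fixed
#'
#' Computes the five phase velocity fields from the creeping-flow momentum
#' balances `div(theta_i sigma_i) + F_i = 0`, with the interstitial pressure
#' taken from `state` and the cell pressures closed through
#' [cell_pressure()].  The interphase drag couples all phases, so one
#' coupled linear system is solved.  Where a phase vanishes its momentum
#' equation degenerates; a tiny diagonal ridge keeps the system nonsingular
#' and returns a zero velocity there.
#'
#' @param state A `crtsim_state` (pressures read from `state$p_int`).
#' @param grid A `crtsim_grid`.
#' @param params A `crtsim_params` object.
#' @param extra_force Optional `(n-1) x 5` matrix of body forces at interior
#'   faces (manufactured-solution verification).
#' @return `(n+1) x 5` matrix of face velocities (boundary faces are 0 by
#'   symmetry and no-penetration).
#' @export
momentum_solve <- function(state, grid, params, extra_force = NULL) {
  n <- grid$n; nf <- n - 1L; dr <- grid$dr
  theta <- state$theta
  S <- membrane_stress(theta[, "h"] + theta[, "c"], params$mechanics$Lambda,
                       params$mechanics$theta_star)
  # pressures fixed: solve only the momentum block (p terms move to the rhs)
  mu <- params$mechanics$mu
  dmat <- params$mechanics$d_ij
  rf <- grid$face_radii[2:n]; rc <- grid$cell_centers
  thc <- pmax(theta, 0)
  thf <- .face_avg(thc)
  P <- state$p_int + S    # common pressure of h and c
  uidx <- function(i, f) (i - 1L) * nf + f
  N <- 5L * nf
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  rhs <- numeric(N)
  add <- function(r, c, v) { ii <<- c(ii, r); jj <<- c(jj, c); xx <<- c(xx, v) }
  fidx <- seq_len(nf)
  for (i in 1:5) {
    rows <- uidx(i, fidx)
    vm <- 2 * mu * rc[fidx] * thc[fidx, i] / (rf * dr^2)
    vp <- 2 * mu * rc[fidx + 1] * thc[fidx + 1, i] / (rf * dr^2)
    hoop <- 2 * mu * thf[, i] / rf^2
    dragdiag <- rowSums(sweep(thf, 2, dmat[i, ], "*")) * thf[, i]
    add(rows, rows, -(vm + vp) - hoop - dragdiag - 1e-10)
    if (nf > 1) {
      add(rows[-1], uidx(i, fidx[-nf]), vm[-1])
      add(rows[-nf], uidx(i, fidx[-1]), vp[-nf])
    }
    for (j in setdiff(1:5, i)) {
      if (dmat[i, j] != 0) {
        add(rows, uidx(j, fidx), dmat[i, j] * thf[, i] * thf[, j])
      }
    }
    p_i <- switch(PHASES[i], h = P, c = P, int = state$p_int, NULL)
    if (!is.null(p_i)) {
      rhs[rows] <- rhs[rows] + thf[, i] * (p_i[fidx + 1L] - p_i[fidx]) / dr
    }
    if (!is.null(extra_force)) rhs[rows] <- rhs[rows] - extra_force[, i]
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(N, N))
  sol <- as.numeric(Matrix::solve(A, rhs))
  u <- matrix(0, n + 1, 5, dimnames = list(NULL, PHASES))
  for (i in 1:5) u[2:n, i] <- sol[uidx(i, fidx)]
  u
}

#' Solve for the interstitial pressure enforcing mixture incompressibility
#'
#' Finds `p_int` such that the divergence of the total mixture flux
#' (including the chemotactic flux of young vessels) vanishes in every cell,
#' with the phase velocities satisfying their momentum balances under the
#' closed pressures `p_h = p_c = p_int + Sigma`, `p_yv = p_mv = 0`.  The
#' momentum and constraint equations are solved monolithically.
#'
#' @param state A `crtsim_state`.
#' @param grid A `crtsim_grid`.
#' @param params A `crtsim_params` object.
#' @return The `p_int` field (length `n`), with the consistent face
#'   velocities attached as attribute `u`.
#' @export
pressure_solve <- function(state, grid, params) {
  S <- membrane_stress(state$theta[, "h"] + state$theta[, "c"],
                       params$mechanics$Lambda, params$mechanics$theta_star)
  fl <- .flow_solve(state$theta, S, state$chem[, "g"], grid, params,
                    upwind_v = state$u)
  structure(fl$p_int, u = fl$u)
}

# Discrete mixture-divergence residual (per cell) for diagnostics/tests.
mixture_divergence <- function(theta, u, g_field, grid, params) {
  n <- grid$n
  chi <- params$chemotaxis$chi_g
  rf <- grid$face_radii[2:n]
  rc <- grid$cell_centers
  dr <- grid$dr
  dgrad <- (g_field[-1] - g_field[-n]) / dr
  thc <- pmax(theta, 0)
  flux <- numeric(n - 1)   # total mixture flux at interior faces
  for (i in 1:5) {
    v <- u[2:n, i]
    veff <- if (i == 3) v + chi * dgrad else v
    thup <- .face_upwind(thc[, i], veff)
    flux <- flux + rf * v * thup
    if (i == 3) flux <- flux + chi * rf * thup * dgrad
  }
  (c(flux, 0) - c(0, flux)) / (rc * dr)
}

# ---- phase transport --------------------------------------------------------

# Implicit upwind update of one phase: solves
#   c0 * th + div(v th) - G * th = rhs
# with zero-flux boundaries, where v is the face velocity (length n+1,
# boundary entries 0), G the implicit per-unit rate and rhs collects the
# BDF history and explicit production.
.transport_solve <- function(c0, v, G, rhs, grid) {
  n <- grid$n; dr <- grid$dr
  rf <- grid$face_radii
  rc <- grid$cell_centers
  lower <- numeric(n); upper <- numeric(n); diag <- c0 - G
  vin <- v[2:n]   # interior faces
  pos <- vin >= 0
  wr <- rf[2:n] * vin / (rc[1:(n - 1)] * dr)   # right-face factor, cell k
  wl <- rf[2:n] * vin / (rc[2:n] * dr)         # left-face factor, cell k+1
  # right face of cell k (k = 1..n-1)
  diag[1:(n - 1)] <- diag[1:(n - 1)] + ifelse(pos, wr, 0)
  upper[1:(n - 1)] <- upper[1:(n - 1)] + ifelse(pos, 0, wr)
  # left face of cell k+1
  diag[2:n] <- diag[2:n] - ifelse(pos, 0, wl)
  lower[2:n] <- lower[2:n] - ifelse(pos, wl, 0)
  .thomas(lower, diag, upper, rhs)
}

# Implicit per-unit-theta rates G_i and explicit productions for all phases
# at the current iterate, therapy included.  The interstitial production
# closes the mixture: at Picard convergence the realized rates sum to zero.
.rate_split <- function(theta, chem, p_int, grid, params, therapy, t) {
  ck <- params$cell_kinetics; va <- params$vascular
  th <- pmax(theta, 0)
  c <- chem[, "c"]; g <- chem[, "g"]; a <- chem[, "a"]; w <- chem[, "w"]
  cfac <- c / (ck$c_p + c)
  death <- (ck$c_c1 + c) / (ck$c_c2 + c)
  S <- membrane_stress(pmin(th[, "h"] + th[, "c"], 1 - 1e-9),
                       params$mechanics$Lambda, params$mechanics$theta_star)
  press <- (th[, "h"] + th[, "c"]) * (p_int + S)
  ang <- va$k_ang * g * th[, "int"] / (va$eps + th[, "int"])
  matc <- va$k_mat_ves * va$k_g1 * g / (g + va$k_g2)^2 * (th[, "yv"] + va$m)^va$nu

  G <- matrix(0, grid$n, 5, dimnames = list(NULL, PHASES))
  prod <- matrix(0, grid$n, 5, dimnames = list(NULL, PHASES))
  G[, "h"] <- ck$k_m_h * th[, "int"] * cfac - ck$k_d_h * death
  G[, "c"] <- ck$k_m_c * th[, "int"] * cfac - ck$k_d_c * death
  G[, "yv"] <- ang - va$k_occ_yv *
    smoothed_heaviside(press - va$p_crit_yv, va$h_occ) - matc
  prod[, "yv"] <- ang * th[, "mv"]
  G[, "mv"] <- -va$k_occ_mv * smoothed_heaviside(press - va$p_crit_mv, va$h_occ)
  prod[, "mv"] <- matc * th[, "yv"]

  if (!is.null(therapy)) {
    if (therapy$rt_on && length(therapy$schedule) > 0) {
      pulses <- .pulse_train(t, therapy$schedule, therapy$r_t,
                             inclusive = FALSE)
      if (pulses > 0) {
        mode <- therapy$sensitization_mode
        if (identical(mode, "oxygen")) {
          kcoef <- therapy$k_rad_ox * pulses *
            (1 + therapy$xi_ox * tanh(c / therapy$c_initial_field))
        } else {
          kcoef <- therapy$k_rad * pulses
          if (identical(mode, "docetaxel")) {
            l_c <- ck$k_m_c * th[, "int"] * cfac
            gate <- smoothed_heaviside(l_c - params$docetaxel$l_cr,
                                       params$docetaxel$h_d)
            kcoef <- kcoef * (1 + therapy$xi_doc * tanh(w / therapy$h_s) * gate)
          }
        }
        G[, "c"] <- G[, "c"] - kcoef
      }
    }
    if (therapy$doc_on) {
      d <- params$docetaxel
      l_h <- ck$k_m_h * th[, "int"] * cfac
      l_c <- ck$k_m_c * th[, "int"] * cfac
      wfac <- w / (d$w_m + w)
      G[, "h"] <- G[, "h"] -
        d$k_ap_h * wfac * smoothed_heaviside(l_h - d$l_cr, d$h_d)
      G[, "c"] <- G[, "c"] -
        d$k_ap_c * wfac * smoothed_heaviside(l_c - d$l_cr, d$h_d)
    }
    if (therapy$bev_on) {
      G[, "yv"] <- G[, "yv"] - params$bevacizumab$k_ap_yv * a
    }
  }
  # interstitial closure from the realized rates at the current iterate
  realized <- G[, 1:4] * theta[, 1:4] + prod[, 1:4]
  prod[, "int"] <- -rowSums(realized)
  list(G = G, prod = prod)
}

#' Advance the coupled system by one time step
#'
#' One segregated implicit step: (1) implicit upwind finite-volume update of
#' all five volume fractions with therapy-modified sources, (2) monolithic
#' momentum + pressure solve, (3) quasi-steady chemical solves; the three
#' stages are iterated to a coupled fixed point.  Time discretization is
#' BDF2 (variable step), falling back to BDF1 on the first step and after
#' schedule events, where the forcing is discontinuous.
#'
#' @param state Current `crtsim_state`.
#' @param dt Time step, positive.
#' @param params,grid,therapy Model configuration; `therapy` may be `NULL`
#'   (therapy-free) or a `crtsim_forcing`.
#' @param state_prev State one step earlier (for BDF2); `NULL` forces BDF1.
#' @param control List of solver controls: `picard_tol` (coupled residual
#'   tolerance on the volume fractions, default 1e-8), `picard_max` (default
#'   50), `neg_tol` (abort threshold for negative fractions, default 1e-8),
#'   `freeze_flow` / `freeze_chem` (keep the velocities / chemical fields of
#'   the incoming state fixed; used for semi-discrete verification).
#' @return The new `crtsim_state`, with the number of coupled iterations in
#'   attribute `iterations`.
#' @export
advance_step <- function(state, dt, params, grid, therapy = NULL,
                         state_prev = NULL, control = list()) {
  stopifnot(dt > 0)
  tol <- control$picard_tol %||% 1e-8
  maxit <- control$picard_max %||% 50L
  neg_tol <- control$neg_tol %||% 1e-8
  n <- grid$n
  t_new <- state$time + dt

  if (is.null(state_prev)) {
    c0 <- 1 / dt
    time_rhs <- state$theta / dt
    pred <- state$theta
    chem_pred <- state$chem
  } else {
    rho <- dt / (state$time - state_prev$time)
    c0 <- (1 + 2 * rho) / ((1 + rho) * dt)
    time_rhs <- ((1 + rho) * state$theta -
                   rho^2 / (1 + rho) * state_prev$theta) / dt
    pred <- state$theta + rho * (state$theta - state_prev$theta)
    chem_pred <- pmax(state$chem + rho * (state$chem - state_prev$chem), 0)
  }

  theta_it <- pred
  chem_it <- chem_pred
  u_it <- state$u
  p_it <- state$p_int

  freeze_flow <- isTRUE(control$freeze_flow)
  freeze_chem <- isTRUE(control$freeze_chem)
  for (it in seq_len(maxit)) {
    if (freeze_flow) {
      u_new <- state$u; p_new <- state$p_int
    } else {
      thsum <- pmin(pmax(theta_it[, "h"] + theta_it[, "c"], 0), 1 - 1e-9)
      S <- membrane_stress(thsum, params$mechanics$Lambda,
                           params$mechanics$theta_star)
      fl <- .flow_solve(theta_it, S, chem_it[, "g"], grid, params,
                        upwind_v = u_it)
      u_new <- fl$u; p_new <- fl$p_int
    }

    rs <- .rate_split(theta_it, chem_it, p_new, grid, params, therapy, t_new)
    chi <- params$chemotaxis$chi_g
    dgrad <- (chem_it[-1, "g"] - chem_it[-n, "g"]) / grid$dr
    theta_new <- matrix(0, n, 5, dimnames = list(NULL, PHASES))
    for (i in 1:5) {
      v <- u_new[, i]
      if (i == 3) v[2:n] <- v[2:n] + chi * dgrad
      theta_new[, i] <- .transport_solve(
        c0, v, rs$G[, i], time_rhs[, i] + rs$prod[, i], grid)
    }
    if (min(theta_new) < -neg_tol) {
      return(structure(list(failed = TRUE,
                            reason = "negative volume fraction"),
                       class = "crtsim_step_failure"))
    }

    chem_new <- chem_it
    if (!freeze_chem) {
      st_tmp <- list(theta = theta_new, chem = chem_it, u = u_new,
                     p_int = p_new, time = t_new)
      chem_new[, "c"] <- chemical_solve(st_tmp, grid, params, "c", therapy)
      st_tmp$chem <- chem_new
      chem_new[, "g"] <- chemical_solve(st_tmp, grid, params, "g", therapy)
      st_tmp$chem <- chem_new
      if (!is.null(therapy) && therapy$bev_on &&
          t_new >= min(therapy$bev_times)) {
        chem_new[, "a"] <- chemical_solve(st_tmp, grid, params, "a", therapy)
        st_tmp$chem <- chem_new
      }
      if (!is.null(therapy) && therapy$doc_on &&
          t_new >= min(therapy$doc_times)) {
        chem_new[, "w"] <- chemical_solve(st_tmp, grid, params, "w", therapy)
      }
    }

    res <- max(abs(theta_new - theta_it))
    # Anderson-style (depth-1 secant) mixing of the fixed-point iterates
    G_unmixed <- theta_new
    f_new <- theta_new - theta_it
    if (it > 1L && res > tol) {
      df <- f_new - f_prev
      dn <- sum(df * df)
      if (dn > 0) {
        gam <- sum(f_new * df) / dn
        if (is.finite(gam) && abs(gam) < 5) {
          theta_new <- theta_new - gam * (theta_new - G_prev)
        }
      }
    }
    f_prev <- f_new
    G_prev <- G_unmixed
    theta_it <- theta_new
    chem_it <- chem_new
    u_it <- u_new
    p_it <- p_new
    if (res < tol) {
      return(structure(
        list(theta = theta_it, chem = chem_it, u = u_it, p_int = p_it,
             time = t_new),
        class = "crtsim_state", iterations = it))
    }
  }
  structure(list(failed = TRUE, reason = "coupled iteration not converged"),
            class = "crtsim_step_failure")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a full simulation
#'
#' Integrates the coupled system from an initial state to `t_end`,
#' recording the tumor metrics (surface coverage, tumor radius,
#' healthy-tissue recession) and conservation diagnostics at unit time
#' intervals and optional full-state snapshots at requested times.  Steps
#' are clipped to land exactly on schedule events (radiation fractions, drug
#' injections) and recording times; after an event the integrator restarts
#' at first order.  The model has no stochastic component: repeated runs are
#' bit-reproducible.
#'
#' @param params A `crtsim_params` object.
#' @param protocol A `crtsim_protocol`; use flags in [build_protocol()] to
#'   disable agents.
#' @param grid A `crtsim_grid`.
#' @param t_end Final time.
#' @param state0 Optional starting state (defaults to [initial_state()]).
#' @param c0_field Reference oxygen field for oxygen-mode sensitization;
#'   defaults to the starting state's oxygen when that state is at `t = 0`.
#' @param dt_max Maximum time step (default 0.1).
#' @param record_dt Metric recording interval (default 1).
#' @param snapshot_times Times at which to store full states.
#' @param control Solver controls, see [advance_step()].
#' @param verbose Print one line per recorded time.
#' @return A `crtsim_trajectory`: list with `metrics` (data frame),
#'   `snapshots` (named list of states), `state` (final), `grid`, `params`,
#'   `protocol`.
#' @export
run_simulation <- function(params, protocol, grid, t_end,
                           state0 = NULL, c0_field = NULL,
                           dt_max = 0.1, record_dt = 1,
                           snapshot_times = numeric(0),
                           control = list(), verbose = FALSE) {
  if (is.null(state0)) state0 <- initial_state(grid, params)
  if (is.null(c0_field)) {
    if (identical(params$radiotherapy$sensitization_mode, "oxygen") &&
        state0$time > 0) {
      stop("oxygen sensitization from a restarted state requires the ",
           "t = 0 oxygen field via `c0_field`", call. = FALSE)
    }
    c0_field <- state0$chem[, "c"]
  }
  therapy <- if (protocol$rt_on || protocol$bev_on || protocol$doc_on) {
    therapy_forcing(params, protocol, c_initial_field = c0_field)
  } else NULL

  t0 <- state0$time
  events <- sort(unique(c(protocol$radiation_times, protocol$bev_times,
                          protocol$doc_times)))
  events <- events[events > t0 & events <= t_end]
  record_times <- seq(ceiling(t0 / record_dt) * record_dt, t_end,
                      by = record_dt)
  record_times <- record_times[record_times > t0 + 1e-12]
  stops <- sort(unique(c(events, record_times, snapshot_times, t_end)))
  stops <- stops[stops > t0 + 1e-12 & stops <= t_end + 1e-12]

  theta_h0 <- state0$theta[, "h"]
  mass0 <- sum(grid$cell_volumes * rowSums(state0$theta))
  metrics <- list(metrics_row(state0, grid, theta_h0, mass0))
  snapshots <- list()
  if (any(abs(snapshot_times - t0) < 1e-9)) {
    snapshots[[sprintf("t%g", t0)]] <- state0
  }

  state <- state0
  state_prev <- NULL     # NULL => first step is BDF1
  dt <- dt_max
  dt_floor <- 1e-5
  next_rec <- 1L

  while (state$time < t_end - 1e-12) {
    # do not step across the next stop (event/record/snapshot time)
    upcoming <- stops[stops > state$time + 1e-12]
    t_stop <- upcoming[1]
    dt_try <- min(dt, t_stop - state$time)
    new <- advance_step(state, dt_try, params, grid, therapy,
                        state_prev = state_prev, control = control)
    if (inherits(new, "crtsim_step_failure")) {
      dt <- dt_try / 2
      if (dt < dt_floor) {
        stop("time step underflow at t = ", format(state$time), ": ",
             new$reason, call. = FALSE)
      }
      next
    }
    state_prev <- state
    state <- new
    if (abs(state$time - t_stop) < 1e-9) state$time <- t_stop  # snap to stops
    dt <- min(dt_try * 1.3, dt_max)
    at_event <- length(events) > 0 && any(abs(events - state$time) < 1e-9)
    if (at_event) state_prev <- NULL   # restart at first order across jumps

    if (any(abs(record_times - state$time) < 1e-9)) {
      metrics[[length(metrics) + 1L]] <-
        metrics_row(state, grid, theta_h0, mass0)
      if (verbose) {
        m <- metrics[[length(metrics)]]
        message(sprintf("t=%7.2f  SC=%.5f  R_t=%6.3f  phi=%6.2f  novoid=%.2e",
                        m$t, m$SC, m$R_t, m$phi, m$novoid_max_err))
      }
    }
    if (any(abs(snapshot_times - state$time) < 1e-9)) {
      snapshots[[sprintf("t%g", state$time)]] <- state
    }
  }

  structure(list(
    metrics = do.call(rbind, metrics),
    snapshots = snapshots,
    state = state,
    grid = grid, params = params, protocol = protocol
  ), class = "crtsim_trajectory")
}
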