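# Treatment forcing: fractionated radiation kill kinetics with optional
# docetaxel- or oxygen-driven sensitization, pulsed intravenous
# pharmacokinetics, drug source terms and their modifications of the phase
# sources, and linear-quadratic calibration utilities.

# Sum of exponentially decaying pulses: sum_i 1[t >= t_i] exp(-rate (t - t_i)).
# The activating step is a sharp unit step, inclusive at the pulse instant.
# The time integrator evaluates sources at the end of each step, so it uses
# the exclusive form: a step that lands exactly on a pulse instant must not
# apply the new pulse retroactively over the step it closes.
.pulse_train <- function(t, times, rate, inclusive = TRUE) {
  if (length(times) == 0) return(0)
  dt <- t - times
  keep <- if (inclusive) dt >= 0 else dt > 0
  sum(exp(-rate * dt[keep]))
}

#' Radiation forcing object
#'
#' Bundles the fraction schedule and the radiosensitization configuration
#' for use by the kill-rate functions and the solver.  For oxygen-mode
#' sensitization the oxygen field at treatment start is frozen once
#' (`c_initial_field`) and used as the normalising reference thereafter.
#'
#' @param params A `crtsim_params` object.
#' @param protocol A `crtsim_protocol` from [build_protocol()].
#' @param c_initial_field Oxygen concentration field at `t = 0` (required
#'   when `sensitization_mode == "oxygen"`); must be strictly positive.
#' @return An object of class `crtsim_forcing`.
#' @export
therapy_forcing <- function(params, protocol, c_initial_field = NULL) {
  rt <- params$radiotherapy
  if (identical(rt$sensitization_mode, "oxygen")) {
    if (is.null(c_initial_field) || any(c_initial_field <= 0)) {
      stop("oxygen sensitization requires a strictly positive initial ",
           "oxygen field", call. = FALSE)
    }
  }
  if (length(protocol$radiation_times) > 0 && (rt$k_rad <= 0 || rt$r_t <= 0)) {
    stop("k_rad and r_t must be positive when radiation fractions are ",
         "scheduled", call. = FALSE)
  }
  structure(list(
    schedule = protocol$radiation_times,
    bev_times = protocol$bev_times,
    doc_times = protocol$doc_times,
    bev_on = protocol$bev_on, doc_on = protocol$doc_on,
    rt_on = protocol$rt_on,
    k_rad = rt$k_rad, r_t = rt$r_t,
    sensitization_mode = rt$sensitization_mode,
    xi_doc = rt$xi_doc, h_s = rt$h_s,
    k_rad_ox = rt$k_rad_ox, xi_ox = rt$xi_ox,
    c_initial_field = c_initial_field
  ), class = "crtsim_forcing")
}

#' Radiation kill rate
#'
#' The cancer-cell death rate induced by the fraction train:
#' `R = k_rad * theta_c * sum_i 1[t >= t_i] exp(-r_t (t - t_i))`.  Each
#' fraction switches on sharply at its start time and its effect decays
#' exponentially with rate `r_t`.  Subtracted from the cancer source term.
#'
#' @param t Time.
#' @param theta_c Cancer volume fraction (vectorised).
#' @param forcing A `crtsim_forcing` object.
#' @return Non-negative kill rate.
#' @export
radiation_kill_rate <- function(t, theta_c, forcing) {
  forcing$k_rad * pmax(theta_c, 0) *
    .pulse_train(t, forcing$schedule, forcing$r_t)
}

#' Docetaxel-sensitized radiation kill
#'
#' Amplifies a base kill rate `R` by
#' `1 + xi_doc * tanh(w / h_s) * H(l_c - l_cr, h_d)`: the taxane arrests the
#' cycle of rapidly proliferating cells in their radiosensitive phase, so
#' amplification requires both drug presence (`w`) and a proliferation rate
#' `l_c` above the critical value `l_cr`.
#'
#' @param R Base kill rate (from [radiation_kill_rate()]).
#' @param w Local docetaxel concentration.
#' @param l_c Cancer proliferation rate ([proliferation_rate()] with
#'   phase `"c"`).
#' @param forcing A `crtsim_forcing` object.
#' @param params A `crtsim_params` object (for the proliferation gate).
#' @return Amplified kill rate, `>= R`.
#' @export
docetaxel_sensitized_kill <- function(R, w, l_c, forcing, params) {
  gate <- smoothed_heaviside(l_c - params$docetaxel$l_cr, params$docetaxel$h_d)
  R * (1 + forcing$xi_doc * tanh(w / forcing$h_s) * gate)
}

#' Oxygen-sensitized radiation kill
#'
#' Replaces the base strength with `k_rad_ox` and multiplies the pulse train
#' by `1 + xi_ox * tanh(c / c0)`, where `c0` is the oxygen level frozen at
#' treatment start: well-oxygenated cells are killed more effectively,
#' hypoxic cells resist.  `k_rad_ox` is calibrated (see
#' [calibrate_krad_ox()]) so that standalone oxygen-sensitized radiotherapy
#' matches the unsensitized killing effect.
#'
#' @param t Time.
#' @param theta_c Cancer volume fraction.
#' @param c Current oxygen concentration.
#' @param c0 Reference (initial) oxygen concentration, strictly positive.
#' @param forcing A `crtsim_forcing` object.
#' @return Kill rate.
#' @export
oxygen_sensitized_kill <- function(t, theta_c, c, c0, forcing) {
  if (any(c0 <= 0)) {
    stop("reference oxygen concentration c0 must be positive", call. = FALSE)
  }
  base <- forcing$k_rad_ox * pmax(theta_c, 0) *
    .pulse_train(t, forcing$schedule, forcing$r_t)
  base * (1 + forcing$xi_ox * tanh(c / c0))
}

#' Bloodstream drug concentration under pulsed intravenous dosing
#'
#' `inj_level * sum_i 1[t >= t_i] exp(-k_el (t - t_i))`: each injection
#' raises the blood level by `inj_level` instantaneously and is eliminated
#' exponentially.  Used for both bevacizumab and docetaxel.
#'
#' @param t Time (vectorised).
#' @param inj_level Concentration added per injection.
#' @param k_el Elimination rate constant, positive.
#' @param times Injection times.
#' @return Blood concentration at `t`.
#' @export
blood_concentration <- function(t, inj_level, k_el, times) {
  if (k_el <= 0) stop("k_el must be positive", call. = FALSE)
  inj_level * vapply(t, .pulse_train, numeric(1), times = times, rate = k_el)
}

#' Bevacizumab tissue source term
#'
#' Replenishment from the vasculature towards the current blood level,
#' minus tissue decay, consumption while neutralizing VEGF (half-maximal at
#' the median effective dose `a_50`) and consumption during young-vessel
#' apoptosis.
#'
#' @param s A `crtsim_local` state.
#' @param a_c_now Current blood concentration ([blood_concentration()]).
#' @param params A `crtsim_params` object.
#' @return Net production rate of `a`.
#' @export
bevacizumab_source <- function(s, a_c_now, params) {
  b <- params$bevacizumab
  tv <- .clamp0(s$theta$yv) + .clamp0(s$theta$mv)
  a <- s$chem$a; g <- s$chem$g
  b$k_rep_a * tv * (a_c_now - a) - b$k_d_a * a -
    b$k_n_a * g * a / (b$a_50 + a) - b$k_cap_yv * a * .clamp0(s$theta$yv)
}

#' Docetaxel tissue source term
#'
#' Replenishment from the vasculature, minus tissue decay and consumption by
#' cells, the latter saturating at `w_m` and gated to rapidly proliferating
#' cells through the smooth switch on `l_i - l_cr`.
#'
#' @param s A `crtsim_local` state.
#' @param w_c_now Current blood concentration.
#' @param l_h,l_c Healthy and cancer proliferation rates.
#' @param params A `crtsim_params` object.
#' @return Net production rate of `w`.
#' @export
docetaxel_source <- function(s, w_c_now, l_h, l_c, params) {
  d <- params$docetaxel
  tv <- .clamp0(s$theta$yv) + .clamp0(s$theta$mv)
  w <- s$chem$w
  cons <- d$k_cn_h * .clamp0(s$theta$h) *
    smoothed_heaviside(l_h - d$l_cr, d$h_d) +
    d$k_cn_c * .clamp0(s$theta$c) * smoothed_heaviside(l_c - d$l_cr, d$h_d)
  d$k_rep_w * tv * (w_c_now - w) - d$k_d_w * w - w / (d$w_m + w) * cons
}

#' Bevacizumab effects on the young-vessel and VEGF sources
#'
#' Subtracts drug-induced endothelial apoptosis `k_ap_yv * a * theta_yv`
#' from the young-vessel source and VEGF neutralization
#' `k_n_g * g * a / (a_50 + a)` from the VEGF source.
#'
#' @param q_yv Young-vessel source before the drug.
#' @param s_g VEGF source before the drug.
#' @param s A `crtsim_local` state.
#' @param params A `crtsim_params` object.
#' @return List with modified `q_yv` and `s_g`.
#' @export
apply_bevacizumab_effects <- function(q_yv, s_g, s, params) {
  b <- params$bevacizumab
  a <- s$chem$a
  list(
    q_yv = q_yv - b$k_ap_yv * a * .clamp0(s$theta$yv),
    s_g = s_g - b$k_n_g * s$chem$g * a / (b$a_50 + a)
  )
}

#' Docetaxel cytotoxic effect on a phase source
#'
#' Subtracts `k_ap,i * theta_i * w / (w_m + w) * H(l_i - l_cr, h_d)` from the
#' phase source: saturating drug-induced apoptosis restricted to rapidly
#' proliferating cells.
#'
#' @param q_i Phase source before the drug.
#' @param phase `"h"` or `"c"`.
#' @param theta_i Phase volume fraction.
#' @param w Local docetaxel concentration.
#' @param l_i Proliferation rate of the phase.
#' @param params A `crtsim_params` object.
#' @return Modified source.
#' @export
apply_cytotoxic_effect <- function(q_i, phase, theta_i, w, l_i, params) {
  phase <- match.arg(phase, c("h", "c"))
  d <- params$docetaxel
  k_ap <- if (phase == "h") d$k_ap_h else d$k_ap_c
  q_i - k_ap * .clamp0(theta_i) * w / (d$w_m + w) *
    smoothed_heaviside(l_i - d$l_cr, d$h_d)
}

# All therapy modifications of the phase sources at a point, collected so
# the interstitial closure can include them (the mixture stays closed under
# treatment).  Returns increments dq_i (all <= 0: therapies only remove).
therapy_phase_modifications <- function(s, params, therapy, t) {
  n <- length(s$theta$c)
  dq_h <- rep(0, n); dq_c <- rep(0, n); dq_yv <- rep(0, n)
  if (therapy$rt_on && length(therapy$schedule) > 0) {
    mode <- therapy$sensitization_mode
    if (identical(mode, "oxygen")) {
      kill <- oxygen_sensitized_kill(t, s$theta$c, s$chem$c,
                                     therapy$c_initial_field, therapy)
    } else {
      kill <- radiation_kill_rate(t, s$theta$c, therapy)
      if (identical(mode, "docetaxel")) {
        l_c <- proliferation_rate("c", s$theta$int, s$chem$c, params)
        kill <- docetaxel_sensitized_kill(kill, s$chem$w, l_c, therapy, params)
      }
    }
    dq_c <- dq_c - kill
  }
  if (therapy$doc_on) {
    l_h <- proliferation_rate("h", s$theta$int, s$chem$c, params)
    l_c <- proliferation_rate("c", s$theta$int, s$chem$c, params)
    dq_h <- dq_h + (apply_cytotoxic_effect(0, "h", s$theta$h, s$chem$w, l_h,
                                           params))
    dq_c <- dq_c + (apply_cytotoxic_effect(0, "c", s$theta$c, s$chem$w, l_c,
                                           params))
  }
  if (therapy$bev_on) {
    eff <- apply_bevacizumab_effects(0, 0, s, params)
    dq_yv <- dq_yv + eff$q_yv
  }
  list(dq_h = dq_h, dq_c = dq_c, dq_yv = dq_yv)
}

#' Linear-quadratic cell survival
#'
#' `SF = exp(n (-alpha d - beta d^2))` for `n` fractions of dose `d` (Gy):
#' the standard clonogenic-survival model whose alpha/beta ratio encodes the
#' radiosensitivity of the tissue.
#'
#' @param alpha Linear coefficient (per Gy).
#' @param beta Quadratic coefficient (per Gy^2).
#' @param n Number of fractions.
#' @param d Dose per fraction (Gy).
#' @return Surviving fraction in (0, 1].
#' @export
lq_survival <- function(alpha, beta, n, d) {
  stopifnot(alpha >= 0, beta >= 0, n >= 0, d >= 0)
  exp(n * (-alpha * d - beta * d^2))
}

#' Calibrate the LQ coefficients from one survival observation
#'
#' Given an observed surviving fraction after `n` fractions of dose `d` and
#' a fixed `alpha/beta` ratio, solves
#' `n (alpha d + (alpha / ratio) d^2) = -log(SF_obs)` in closed form.
#'
#' @param SF_obs Observed surviving fraction in (0, 1].
#' @param d Dose per fraction (Gy), positive.
#' @param n Number of fractions, positive integer.
#' @param ratio The alpha/beta ratio (Gy), positive.
#' @return List with `alpha` and `beta = alpha / ratio`.
#' @export
calibrate_alpha_beta <- function(SF_obs, d, n, ratio) {
  if (!(SF_obs > 0 && SF_obs <= 1)) {
    stop("SF_obs must lie in (0, 1]", call. = FALSE)
  }
  stopifnot(d > 0, n >= 1, ratio > 0)
  alpha <- -log(SF_obs) / (n * (d + d^2 / ratio))
  list(alpha = alpha, beta = alpha / ratio)
}

#' Proliferation-free survival under single-fraction decay kill
#'
#' Integrating `d(theta_c)/dt = -k_rad theta_c exp(-r_t (t - t_rad))` from
#' the fraction time gives
#' `theta_c / theta_c(0) = exp(-(k_rad / r_t) (1 - exp(-r_t t)))`: the
#' surviving fraction of a non-proliferating population `t` time units after
#' one fraction.
#'
#' @param t_since Time since the fraction, `>= 0` (vectorised).
#' @param k_rad Kill strength.
#' @param r_t Decay rate of the kill effect, positive.
#' @return Surviving fraction in (0, 1].
#' @export
decay_survival <- function(t_since, k_rad, r_t) {
  if (r_t <= 0) stop("r_t must be positive", call. = FALSE)
  stopifnot(all(t_since >= 0))
  exp(-(k_rad / r_t) * (1 - exp(-r_t * t_since)))
}

#' Fit the kill strength to a survival target
#'
#' Closed-form inversion of [decay_survival()] at fixed `r_t`:
#' `k_rad = -r_t log(SF) / (1 - exp(-r_t t_window))`.  `r_t` is held fixed
#' (default 0.5) because a single survival observation cannot identify both
#' parameters.
#'
#' @param SF_target Target surviving fraction in (0, 1).
#' @param t_window Observation window, positive.
#' @param r_t_fixed Fixed decay rate.
#' @return The fitted `k_rad`.
#' @export
fit_krad <- function(SF_target, t_window, r_t_fixed = 0.5) {
  if (!(SF_target > 0 && SF_target < 1)) {
    stop("SF_target must lie in (0, 1)", call. = FALSE)
  }
  denom <- 1 - exp(-r_t_fixed * t_window)
  if (!(t_window > 0) || denom <= 0) {
    stop("degenerate observation window", call. = FALSE)
  }
  -r_t_fixed * log(SF_target) / denom
}

#' Calibrate the oxygen-mode radiotherapy strength
#'
#' The oxygen-sensitized kill replaces `k_rad` by
#' `k_rad_ox (1 + xi_ox tanh(c / c0))`; for standalone radiotherapy the two
#' forms must produce an equivalent killing effect.  This routine equates
#' the time-integrated kill over one course:
#' `k_rad_ox = k_rad * I0 / I_ox` with
#' `I0 = int sum_i pulses dt` and
#' `I_ox = int sum_i pulses * (1 + xi_ox tanh(ratio(t))) dt`, where
#' `ratio(t)` is the (possibly time-dependent) relative oxygenation `c/c0`.
#'
#' @param params A `crtsim_params` object (supplies `k_rad`, `r_t`, `xi_ox`).
#' @param protocol A `crtsim_protocol` with the fraction schedule.
#' @param c_over_c0 Either a single representative relative oxygenation or a
#'   function of time returning it.
#' @param horizon Integration end; defaults to 20 half-lives past the last
#'   fraction.
#' @return The calibrated `k_rad_ox`.
#' @export
calibrate_krad_ox <- function(params, protocol, c_over_c0,
                              horizon = NULL) {
  rt <- params$radiotherapy
  times <- protocol$radiation_times
  if (length(times) == 0) stop("protocol has no radiation fractions",
                               call. = FALSE)
  if (is.null(horizon)) horizon <- max(times) + 20 / rt$r_t
  ratio_fun <- if (is.function(c_over_c0)) c_over_c0 else
    function(t) rep(c_over_c0, length(t))
  pulses <- function(t) {
    vapply(t, .pulse_train, numeric(1), times = times, rate = rt$r_t)
  }
  # integrate piecewise between fraction times: the train is smooth inside
  # each segment and jumps at every fraction
  brk <- sort(unique(c(times, horizon)))
  brk <- brk[brk <= horizon]
  seg_int <- function(f) {
    tot <- 0
    for (s in seq_len(length(brk) - 1L)) {
      tot <- tot + stats::integrate(f, brk[s], brk[s + 1L],
                                    rel.tol = 1e-10)$value
    }
    tot
  }
  I0 <- seg_int(pulses)
  Iox <- seg_int(function(t) pulses(t) * (1 + rt$xi_ox * tanh(ratio_fun(t))))
  rt$k_rad * I0 / Iox
}
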