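# Pointwise algebraic kinetics of the therapy-free model: phase source
# terms, pressure closures and the chemical source terms for oxygen and
# VEGF.  All functions are pure and vectorised over grid cells.

#' Smoothed Heaviside step
#'
#' `H(x, h) = (1 + tanh(x / h)) / 2`, the smooth switch used by the vessel
#' occlusion terms and by the proliferation gating of docetaxel.  `h` sets
#' the steepness: the switch transitions over a width of order `h` around 0.
#'
#' @param x Argument (vectorised).
#' @param h Steepness parameter, must be positive.
#' @return Values in (0, 1), strictly increasing in `x`.
#' @export
smoothed_heaviside <- function(x, h) {
  if (!is.numeric(h) || any(h <= 0)) {
    stop("steepness parameter h must be > 0", call. = FALSE)
  }
  0.5 * (1 + tanh(x / h))
}

#' Membrane stress closure
#'
#' Cells behave as an isotropic fluid until their combined density exceeds
#' the natural density `theta_star`; beyond it their membranes deform and
#' carry the stress `Lambda * (theta - theta_star) / (1 - theta)^2`, which
#' grows without bound as the mixture packs towards 1.
#'
#' @param theta_sum Combined healthy + cancer volume fraction, in `[0, 1)`.
#' @param Lambda Tension constant.
#' @param theta_star Natural density, in (0, 1).
#' @return Non-negative stress, continuous at `theta_star`.
#' @export
membrane_stress <- function(theta_sum, Lambda, theta_star) {
  if (any(theta_sum >= 1)) {
    stop("membrane stress is singular at theta = 1", call. = FALSE)
  }
  if (any(theta_sum < 0)) {
    stop("theta_sum must be non-negative", call. = FALSE)
  }
  ifelse(theta_sum >= theta_star,
         Lambda * (theta_sum - theta_star) / (1 - theta_sum)^2,
         0)
}

#' Pressure closure for the cellular phases
#'
#' Healthy and cancer cells share a common pressure
#' `p_h = p_c = p_int + Sigma(theta_h + theta_c)`; the vascular phases are
#' held at the reference pressure (0), since intravascular flow is not
#' resolved.
#'
#' @param p_int Interstitial pressure (vectorised).
#' @param theta_h,theta_c Cell volume fractions.
#' @param params A `crtsim_params` object.
#' @return List with components `p_h` and `p_c` (always equal).
#' @export
cell_pressure <- function(p_int, theta_h, theta_c, params) {
  s <- membrane_stress(theta_h + theta_c, params$mechanics$Lambda,
                       params$mechanics$theta_star)
  p <- p_int + s
  list(p_h = p, p_c = p)
}

#' Proliferation rate of a cellular phase
#'
#' `l_i = k_m,i * theta_int * c / (c_p + c)`: mitosis requires interstitial
#' raw material and saturates in oxygen with half-maximum at `c_p`.  Used
#' both inside the phase sources and as the criterion for "rapidly
#' proliferating" cells targeted by docetaxel.
#'
#' @param phase `"h"` or `"c"`.
#' @param theta_int Interstitial volume fraction.
#' @param c Oxygen concentration.
#' @param params A `crtsim_params` object.
#' @return Non-negative rate (per time unit).
#' @export
proliferation_rate <- function(phase, theta_int, c, params) {
  phase <- match.arg(phase, c("h", "c"))
  k_m <- if (phase == "h") params$cell_kinetics$k_m_h else params$cell_kinetics$k_m_c
  k_m * pmax(theta_int, 0) * c / (params$cell_kinetics$c_p + c)
}

# Kinetics are evaluated on volume fractions clamped at zero; the transported
# fields themselves are never clamped (negativity beyond tolerance aborts the
# run in the solver).
.clamp0 <- function(x) pmax(x, 0)

#' Construct a local (pointwise) state
#'
#' Bundles volume fractions, chemical concentrations and closed pressures
#' for the pointwise kinetics functions.  All components may be vectors of a
#' common length (grid cells).
#'
#' @param theta_h,theta_c,theta_yv,theta_mv,theta_int Volume fractions.
#' @param c,g,a,w Chemical concentrations (oxygen, VEGF, bevacizumab,
#'   docetaxel).
#' @param p_int Interstitial pressure (default 0).
#' @param params Parameter set used to close `p_h`, `p_c`.
#' @return A list of class `crtsim_local` with `theta`, `chem`, `p_h`, `p_c`,
#'   `p_int` components.
#' @export
local_state <- function(theta_h, theta_c, theta_yv, theta_mv, theta_int,
                        c = 0, g = 0, a = 0, w = 0, p_int = 0, params) {
  pr <- cell_pressure(p_int, theta_h, theta_c, params)
  structure(list(
    theta = list(h = theta_h, c = theta_c, yv = theta_yv, mv = theta_mv,
                 int = theta_int),
    chem = list(c = c, g = g, a = a, w = w),
    p_h = pr$p_h, p_c = pr$p_c, p_int = p_int
  ), class = "crtsim_local")
}

#' Healthy-cell source term
#'
#' Mitosis (interstitial- and oxygen-limited) minus death, with the death
#' rate amplified under starvation through the factor
#' `(c_c1 + c) / (c_c2 + c)`.
#'
#' @param s A `crtsim_local` state.
#' @param params A `crtsim_params` object.
#' @return Net production rate of `theta_h`.
#' @export
source_healthy <- function(s, params) {
  ck <- params$cell_kinetics
  th <- .clamp0(s$theta$h); tint <- .clamp0(s$theta$int); c <- s$chem$c
  ck$k_m_h * th * tint * c / (ck$c_p + c) -
    ck$k_d_h * th * (ck$c_c1 + c) / (ck$c_c2 + c)
}

#' Cancer-cell source term
#'
#' Same functional form as [source_healthy()] with the cancer constants;
#' the model stipulates faster mitosis (`k_m_c > k_m_h`) and higher hypoxia
#' resilience (`k_d_c < k_d_h`).
#'
#' @inheritParams source_healthy
#' @export
source_cancer <- function(s, params) {
  ck <- params$cell_kinetics
  tc <- .clamp0(s$theta$c); tint <- .clamp0(s$theta$int); c <- s$chem$c
  ck$k_m_c * tc * tint * c / (ck$c_p + c) -
    ck$k_d_c * tc * (ck$c_c1 + c) / (ck$c_c2 + c)
}

# Vessel maturation rate, shared (with opposite signs) by the young- and
# mature-vessel sources.
.maturation_rate <- function(g, theta_yv, params) {
  v <- params$vascular
  v$k_mat_ves * v$k_g1 * g / (g + v$k_g2)^2 *
    .clamp0(theta_yv) * (.clamp0(theta_yv) + v$m)^v$nu
}

#' Young-vessel source term
#'
#' VEGF-driven angiogenesis (saturating in interstitial supply), minus
#' pressure-induced occlusion (smooth switch on the cellular partial
#' pressure `theta_h p_h + theta_c p_c` crossing `p_crit_yv`), minus
#' maturation into the established network.
#'
#' @inheritParams source_healthy
#' @export
source_young_vessels <- function(s, params) {
  v <- params$vascular
  tyv <- .clamp0(s$theta$yv); tmv <- .clamp0(s$theta$mv)
  tint <- .clamp0(s$theta$int)
  g <- s$chem$g
  press <- .clamp0(s$theta$h) * s$p_h + .clamp0(s$theta$c) * s$p_c
  v$k_ang * g * (tyv + tmv) * tint / (v$eps + tint) -
    v$k_occ_yv * tyv * smoothed_heaviside(press - v$p_crit_yv, v$h_occ) -
    .maturation_rate(g, s$theta$yv, params)
}

#' Mature-vessel source term
#'
#' Gains the maturation flux lost by the young vessels and loses volume to
#' occlusion, with a smaller rate constant and a higher pressure threshold
#' reflecting the tougher mechanics of the established network.
#'
#' @inheritParams source_healthy
#' @export
source_mature_vessels <- function(s, params) {
  v <- params$vascular
  tmv <- .clamp0(s$theta$mv)
  press <- .clamp0(s$theta$h) * s$p_h + .clamp0(s$theta$c) * s$p_c
  -v$k_occ_mv * tmv * smoothed_heaviside(press - v$p_crit_mv, v$h_occ) +
    .maturation_rate(s$chem$g, s$theta$yv, params)
}

#' Interstitial source closing the mixture
#'
#' The tissue is a closed system: whatever volume the cellular phases gain
#' is drawn from the interstitial fluid and vice versa, so
#' `q_int = -(q_h + q_c + q_yv + q_mv)` exactly.  When therapy is active the
#' therapy-modified phase sources must be passed in, so the closed-system
#' identity holds for the modified system too.
#'
#' @param q_h,q_c,q_yv,q_mv Phase production rates.
#' @return `q_int`.
#' @export
source_interstitial <- function(q_h, q_c, q_yv, q_mv) {
  -(q_h + q_c + q_yv + q_mv)
}

#' Oxygen source term
#'
#' Replenishment from the vasculature towards the intravascular level `c_v`,
#' minus sustenance consumption by both cell types and mitosis-linked
#' consumption saturating with half-maximum `c_p`.
#'
#' @inheritParams source_healthy
#' @export
oxygen_source <- function(s, params) {
  o <- params$oxygen
  th <- .clamp0(s$theta$h); tc <- .clamp0(s$theta$c)
  tv <- .clamp0(s$theta$yv) + .clamp0(s$theta$mv)
  tint <- .clamp0(s$theta$int)
  c <- s$chem$c
  o$k_rep * tv * (o$c_v - c) -
    (o$k_c_h * th * c + o$k_c_c * tc * c) -
    (o$k_cm_h * th + o$k_cm_c * tc) * tint * c / (params$cell_kinetics$c_p + c)
}

#' VEGF source term
#'
#' Hypoxia-tuned secretion by cells (maximal at oxygen level `c_a`, with
#' cancer cells secreting `omega`-fold more), minus binding by endothelial
#' receptors and natural decay.
#'
#' @inheritParams source_healthy
#' @export
vegf_source <- function(s, params) {
  v <- params$vegf
  th <- .clamp0(s$theta$h); tc <- .clamp0(s$theta$c)
  tv <- .clamp0(s$theta$yv) + .clamp0(s$theta$mv)
  c <- s$chem$c; g <- s$chem$g
  v$k_sec * (th + v$omega * tc) * c / (c + v$c_a)^2 -
    v$k_cang * tv * g - v$k_dg * g
}

#' All phase production rates at a point, therapy included
#'
#' Evaluates the five phase sources, applies any active therapy
#' modifications (radiation kill with optional sensitization, bevacizumab's
#' young-vessel apoptosis, docetaxel's proliferation-gated apoptosis), and
#' closes the mixture through [source_interstitial()], so the returned rates
#' sum to zero exactly whether or not therapy is active.
#'
#' @param s A `crtsim_local` state.
#' @param params A `crtsim_params` object.
#' @param therapy Optional therapy forcing built by [therapy_forcing()];
#'   `NULL` simulates the therapy-free model.
#' @param t Current time (needed when `therapy` is active).
#' @return List with components `q_h`, `q_c`, `q_yv`, `q_mv`, `q_int`.
#' @export
phase_rates <- function(s, params, therapy = NULL, t = 0) {
  q_h <- source_healthy(s, params)
  q_c <- source_cancer(s, params)
  q_yv <- source_young_vessels(s, params)
  q_mv <- source_mature_vessels(s, params)
  if (!is.null(therapy)) {
    mod <- therapy_phase_modifications(s, params, therapy, t)
    q_h <- q_h + mod$dq_h
    q_c <- q_c + mod$dq_c
    q_yv <- q_yv + mod$dq_yv
  }
  list(q_h = q_h, q_c = q_c, q_yv = q_yv, q_mv = q_mv,
       q_int = source_interstitial(q_h, q_c, q_yv, q_mv))
}
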