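make_forcing <- function(overrides = NULL, rt_on = TRUE, bev_on = FALSE,
                         doc_on = FALSE, c0 = 0.25) {
  p <- load_parameters(overrides)
  pr <- build_protocol(p, rt_on = rt_on, bev_on = bev_on, doc_on = doc_on)
  therapy_forcing(p, pr, c_initial_field = c0)
}

test_that("radiation kill is a decaying pulse train, inclusive at fractions", {
  f <- make_forcing()   # fractions at 80, 81, ..., 109; k_rad 0.23, r_t 0.5
  expect_equal(radiation_kill_rate(79.999, 0.1, f), 0)
  expect_equal(radiation_kill_rate(80, 0.1, f), 0.23 * 0.1)
  expect_equal(radiation_kill_rate(81, 0.1, f),
               0.023 * (1 + exp(-0.5)))
  # decays between fractions with rate r_t
  expect_equal(radiation_kill_rate(80.5, 0.1, f),
               0.023 * exp(-0.25))
})

test_that("kill-rate superposition is linear in the pulse train", {
  f_all <- make_forcing()
  single <- lapply(seq_along(f_all$schedule), function(i) {
    f1 <- f_all; f1$schedule <- f_all$schedule[i]; f1
  })
  for (t in c(85.3, 100, 109.9, 140)) {
    total <- radiation_kill_rate(t, 0.37, f_all)
    parts <- sum(vapply(single, function(f1)
      radiation_kill_rate(t, 0.37, f1), numeric(1)))
    expect_equal(total, parts, tolerance = 1e-14)
  }
})

test_that("docetaxel sensitization amplifies kill by the gated tanh factor", {
  p <- default_params()
  f <- make_forcing(list(radiotherapy = list(sensitization_mode = "docetaxel")))
  R <- 0.05
  expect_equal(docetaxel_sensitized_kill(R, 0, 1, f, p), R)
  # saturated drug and proliferation: 1 + xi_doc = 3-fold with xi_doc = 2
  expect_equal(docetaxel_sensitized_kill(R, 1e3 * f$h_s, 10, f, p), 3 * R,
               tolerance = 1e-6)
  # w = h_s with an open gate: 1 + 2 tanh(1)
  amp <- docetaxel_sensitized_kill(R, f$h_s, 10, f, p) / R
  expect_equal(amp, 1 + 2 * tanh(1), tolerance = 1e-6)
})

test_that("oxygen sensitization rescales the base strength by oxygenation", {
  f <- make_forcing(list(radiotherapy = list(sensitization_mode = "oxygen")))
  t <- 80
  base <- f$k_rad_ox * 0.1   # one fresh pulse
  expect_equal(oxygen_sensitized_kill(t, 0.1, 0, 0.25, f), base)
  expect_equal(oxygen_sensitized_kill(t, 0.1, 0.25, 0.25, f),
               base * (1 + 2 * tanh(1)))
  expect_error(oxygen_sensitized_kill(t, 0.1, 0.2, 0, f), "positive")
  # Table-4 configuration is accepted by the loader
  expect_equal(f$k_rad_ox, 0.11)
  expect_equal(f$xi_ox, 2)
})

test_that("oxygen-mode strength calibrates to an equivalent course kill", {
  p <- default_params()
  pr <- build_protocol(p, bev_on = FALSE, doc_on = FALSE)
  # at a constant relative oxygenation the closed form is exact
  ratio <- 0.6
  k_cal <- calibrate_krad_ox(p, pr, ratio)
  expect_equal(k_cal, p$radiotherapy$k_rad / (1 + 2 * tanh(ratio)),
               tolerance = 1e-6)
  # the integrated kill of the calibrated sensitized train matches the
  # unsensitized one by construction
  expect_equal(k_cal * (1 + p$radiotherapy$xi_ox * tanh(ratio)),
               p$radiotherapy$k_rad, tolerance = 1e-6)
  # the shipped strength corresponds to a moderate (hypoxic-leaning)
  # treatment-averaged oxygenation, between the anoxic and saturated limits
  k_anoxic <- p$radiotherapy$k_rad
  k_oxic <- p$radiotherapy$k_rad / (1 + 2 * tanh(1))
  expect_lt(p$radiotherapy$k_rad_ox, k_anoxic)
  expect_gt(p$radiotherapy$k_rad_ox, k_oxic)
})

test_that("blood concentration superposes decaying injection pulses", {
  times <- c(80, 101, 122)
  expect_equal(blood_concentration(79, 1.5, 0.05, times), 0)
  expect_equal(blood_concentration(80, 1.5, 0.05, times), 1.5)
  expect_equal(blood_concentration(101, 1.5, 0.05, times),
               1.5 * (1 + exp(-0.05 * 21)))
  expect_error(blood_concentration(80, 1, 0, times), "positive")
})

test_that("periodic dosing peaks converge to the geometric-series limit", {
  k_el <- 0.12; Tp <- 21; inj <- 2
  times <- (0:199) * Tp
  peak <- blood_concentration(times[200], inj, k_el, times)
  expect_equal(peak, inj / (1 - exp(-k_el * Tp)), tolerance = 1e-10)
  # k-th peak equals the fresh pulse plus all decayed predecessors
  k <- 7
  expect_equal(blood_concentration(times[k], inj, k_el, times),
               inj + inj * sum(exp(-k_el * (times[k] - times[1:(k - 1)]))))
})

test_that("drug tissue sources reproduce worked values and half-max points", {
  p <- load_parameters(list(bevacizumab = list(k_rep_a = 1, k_d_a = 0,
                                               k_n_a = 0, k_cap_yv = 0)))
  s <- local_state(0.5, 0.1, 0.005, 0.015, 0.38, a = 0.5, params = p)
  expect_equal(bevacizumab_source(s, a_c_now = 1, p), 0.02 * 0.5)
  # VEGF-neutralization consumption runs at half maximum when a = a_50
  p2 <- default_params()
  s2 <- local_state(0.5, 0.1, 0, 0, 0.4, g = 0.01,
                    a = p2$bevacizumab$a_50, params = p2)
  full <- bevacizumab_source(s2, 0, p2)
  no_n <- bevacizumab_source(
    s2, 0, load_parameters(list(bevacizumab = list(k_n_a = 0))))
  expect_equal(no_n - full, p2$bevacizumab$k_n_a * 0.01 / 2)

  pw <- load_parameters(list(docetaxel = list(k_rep_w = 1, k_d_w = 0,
                                              k_cn_h = 0, k_cn_c = 0)))
  sw <- local_state(0.5, 0.1, 0.005, 0.015, 0.38, w = 0, params = pw)
  expect_equal(docetaxel_source(sw, w_c_now = 1, l_h = 0, l_c = 0, pw), 0.02)
  expect_equal(docetaxel_source(sw, w_c_now = 0, l_h = 0, l_c = 0, pw), 0)
})

test_that("drug effects modify the phase and VEGF sources as prescribed", {
  p <- default_params()
  s <- local_state(0.5, 0.2, 0.01, 0.015, 0.27, g = 0.005,
                   a = 0.2, w = 0, params = p)
  eff <- apply_bevacizumab_effects(1, 2, s, p)
  expect_equal(eff$q_yv, 1 - p$bevacizumab$k_ap_yv * 0.2 * 0.01)
  expect_equal(eff$s_g, 2 - p$bevacizumab$k_n_g * 0.005 * 0.2 /
                 (p$bevacizumab$a_50 + 0.2))
  s0 <- local_state(0.5, 0.2, 0.01, 0.015, 0.27, g = 0.005, a = 0,
                    params = p)
  eff0 <- apply_bevacizumab_effects(1, 2, s0, p)
  expect_equal(eff0$q_yv, 1)
  expect_equal(eff0$s_g, 2)

  # cytotoxic kill saturates in drug and is gated on proliferation
  expect_equal(apply_cytotoxic_effect(0.4, "c", 0.3, 0, 10, p), 0.4)
  q_sat <- apply_cytotoxic_effect(0, "c", 0.3, 1e6, 1e3, p)
  expect_equal(q_sat, -p$docetaxel$k_ap_c * 0.3, tolerance = 1e-5)
  q_half <- apply_cytotoxic_effect(0, "c", 0.3, p$docetaxel$w_m, 1e3, p)
  expect_equal(q_half, -p$docetaxel$k_ap_c * 0.3 / 2, tolerance = 1e-5)
})

test_that("LQ survival matches the published calibration points", {
  expect_equal(lq_survival(0.015, 0.0015, 1, 0), 1)
  # single 30 Gy fraction: SF = exp(-1.8) ~ 16 %
  expect_equal(lq_survival(0.015, 0.0015, 1, 30), exp(-1.8))
  expect_equal(lq_survival(0.015, 0.0015, 1, 30), 0.16, tolerance = 0.04)
  # 30 fractions of 2 Gy: ~ 34 % survival
  expect_equal(lq_survival(0.015, 0.0015, 30, 2), exp(-1.08))
  expect_equal(round(lq_survival(0.015, 0.0015, 30, 2), 2), 0.34)
  # strictly decreasing in dose and fraction count
  expect_true(all(diff(lq_survival(0.015, 0.0015, 1, 0:30)) < 0))
  expect_true(all(diff(sapply(1:20, lq_survival,
                              alpha = 0.015, beta = 0.0015, d = 2)) < 0))
})

test_that("alpha/beta calibration inverts the LQ model", {
  cal <- calibrate_alpha_beta(0.16, d = 30, n = 1, ratio = 10)
  expect_equal(signif(cal$alpha, 2), 0.015)
  expect_equal(cal$beta, cal$alpha / 10)
  expect_equal(calibrate_alpha_beta(1, 30, 1, 10)$alpha, 0)
  expect_equal(calibrate_alpha_beta(exp(-1.2), 10, 1, 10)$alpha, 0.06)
  expect_error(calibrate_alpha_beta(0, 30, 1, 10), "SF_obs")
  # round trip at machine precision: survival of the calibrated pair
  for (SF in c(0.9, 0.5, 0.16, 0.01)) {
    cal <- calibrate_alpha_beta(SF, d = 2, n = 30, ratio = 10)
    expect_equal(lq_survival(cal$alpha, cal$beta, 30, 2), SF,
                 tolerance = 1e-12)
  }
})

test_that("decay survival follows the integrated single-fraction law", {
  expect_equal(decay_survival(0, 0.91, 0.5), 1)
  expect_equal(decay_survival(1e6, 0.91, 0.5), exp(-0.91 / 0.5))
  # fitted parameters give ~16 % survival 12 time units after one fraction
  expect_equal(round(decay_survival(12, 0.91, 0.5), 2), 0.16)
  expect_error(decay_survival(5, 0.9, 0), "positive")
})

test_that("kill-strength fitting inverts decay survival exactly", {
  for (SF in c(0.9, 0.5, 0.16, 0.02)) {
    k <- fit_krad(SF, t_window = 12, r_t_fixed = 0.5)
    expect_equal(decay_survival(12, k, 0.5), SF, tolerance = 1e-12)
  }
  # the published rounded pair: k_rad ~ 0.91 for SF = 0.16 over 12 units
  expect_equal(round(fit_krad(0.16, 12, 0.5), 2), 0.92)
  expect_equal(fit_krad(0.16, 12, 0.5), 0.9187, tolerance = 1e-3)
  expect_lt(fit_krad(1 - 1e-9, 12, 0.5), 1e-8)
  expect_error(fit_krad(0.16, 0, 0.5), "degenerate")
})
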