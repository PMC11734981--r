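# crtsim default dimensionless parameter set (one length unit = 400 um,
# one time unit = 24 h).
#
# Radiotherapy and radiosensitization blocks carry published calibration
# values.  The therapy-free, drag, diffusivity and drug constants are a
# SYNTHETIC package calibration: k_d_h, k_rep, k_sec and k_mat_ves are pinned
# so that the homeostatic state (theta_h=0.6, theta_yv=0.002, theta_mv=0.015,
# theta_int=0.383, c=0.25, g=6e-4) is a fixed point of the cell, oxygen,
# VEGF and young-vessel kinetics; the remaining values are order-of-magnitude
# physiological choices documented in the methods vignette.  Replace any
# value with the string "unresolved" to force the loader to demand an
# explicit number.
cell_kinetics:
  k_m_h: 1.0                      # healthy mitosis rate constant
  k_m_c: 1.2                      # cancer mitosis rate constant (> k_m_h)
  k_d_h: 0.149220779220779        # healthy death rate (homeostasis-pinned)
  k_d_c: 0.06                     # cancer death rate (< k_d_h)
  c_p: 0.1                        # oxygen at half-maximal mitosis
  c_c1: 0.3                       # death-modulation threshold (> c_c2)
  c_c2: 0.05                      # death-modulation threshold
vascular:
  k_ang: 5.0                      # angiogenesis rate constant
  eps: 0.1                        # interstitial fraction at half-max angiogenesis
  k_occ_yv: 0.946086459916978     # young-vessel occlusion rate (homeostasis-pinned)
  k_occ_mv: 0.172771289494939     # mature-vessel occlusion rate (homeostasis-pinned, < k_occ_yv)
  p_crit_yv: 0.2                  # young-vessel occlusion pressure threshold
  p_crit_mv: 0.3                  # mature-vessel threshold (> p_crit_yv)
  h_occ: 0.1                      # occlusion Heaviside steepness
  k_mat_ves: 0.05                 # maturation rate
  k_g1: 1.0                       # maturation shape factor
  k_g2: 0.01                      # maturation VEGF scale
  m: 0.01                         # maturation substrate offset
  nu: 1.0                         # maturation substrate exponent
mechanics:
  mu: 1.0                         # uniform dynamic viscosity of all phases
  Lambda: 1.0                     # membrane tension constant
  theta_star: 0.6                 # natural cell density
  p_ref: 0.0                      # vascular reference pressure
  d_ij:                           # symmetric interphase drag table
    h_c: 18.0
    h_yv: 18.0
    h_mv: 18.0
    h_int: 18.0
    c_yv: 18.0
    c_mv: 18.0
    c_int: 18.0
    yv_mv: 18.0
    yv_int: 18.0
    mv_int: 18.0
chemotaxis:
  chi_g: 20.0                     # young-vessel chemoattraction potency
oxygen:
  D_c: 0.5
  k_rep: 4.17310924369748         # vascular replenishment (homeostasis-pinned)
  c_v: 1.0                        # intravascular oxygen level
  k_c_h: 0.3                      # healthy sustenance consumption
  k_c_c: 0.45                     # cancer sustenance consumption
  k_cm_h: 0.05                    # healthy mitosis-linked consumption
  k_cm_c: 0.1                     # cancer mitosis-linked consumption
vegf:
  D_g: 1.0
  k_sec: 0.0004212                # secretion rate (homeostasis-pinned)
  omega: 10.0                     # cancer secretion multiplier
  c_a: 0.05                       # oxygen level of maximal secretion
  k_cang: 10.0                    # binding by endothelial receptors
  k_dg: 1.0                       # natural decay
bevacizumab:
  D_a: 0.25
  k_rep_a: 1.0                    # vascular replenishment
  k_d_a: 0.05                     # tissue decay
  k_n_a: 1.0                      # consumption while neutralizing VEGF
  a_50: 0.5                       # median effective dose
  k_cap_yv: 0.1                   # consumption inducing endothelial apoptosis
  k_ap_yv: 0.5                    # young-vessel apoptosis rate
  k_n_g: 10.0                     # VEGF neutralization rate
  a_inj: 1.0                      # bloodstream level at injection
  k_el_a: 0.05                    # bloodstream elimination rate
  N_bev: 6
  T_bev: 21.0
  t_inj1_bev: 80.0
docetaxel:
  D_w: 0.5
  k_rep_w: 2.0                    # vascular replenishment
  k_d_w: 0.05                     # tissue decay
  k_cn_h: 0.1                     # consumption by healthy cells
  k_cn_c: 0.2                     # consumption by cancer cells
  w_m: 0.5                        # half-maximal consumption concentration
  l_cr: 0.3                       # critical proliferation rate
  h_d: 0.02                       # proliferation Heaviside steepness
  k_ap_h: 0.3                     # healthy-cell apoptosis rate
  k_ap_c: 2.5                     # cancer-cell apoptosis rate
  w_inj: 1.0                      # bloodstream level at injection
  k_el_w: 0.25                    # bloodstream elimination rate
  N_doc: 6
  T_doc: 21.0
  t_inj1_doc: 80.0
radiotherapy:
  k_rad: 0.23                     # strength of radiotherapy
  r_t: 0.5                        # half-life parameter of radiation kill
  t0_rad: 80.0                    # first fraction time
  Tp_rad: 1.0                     # fraction period
  N_rad: 30
  weekend_breaks: no              # opt-in 5-on/2-off calendar
  sensitization_mode: none        # none | docetaxel | oxygen
  xi_doc: 2.0                     # docetaxel radiosensitization multiplier
  h_s: 0.003                      # taxane-concentration smoothing parameter
  k_rad_ox: 0.11                  # oxygen-mode radiotherapy strength
  xi_ox: 2.0                      # oxygen radiosensitization multiplier
scales:
  L_ref: 400.0                    # micrometres per length unit
  T_ref: 24.0                     # hours per time unit
  R_tissue: 30.0                  # domain radius
  R_seed: 1.0                     # cancer seed radius
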