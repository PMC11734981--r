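---
title: "A multiphase continuum model of vascular tumor growth under chemo-radiotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multiphase continuum model of vascular tumor growth under chemo-radiotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`crtsim` treats a growing tumor and its host tissue as a mixture of five
interpenetrating incompressible fluid phases: healthy cells
($\theta_h$), cancer cells ($\theta_c$), young angiogenic vessels
($\theta_{yv}$), mature vessels ($\theta_{mv}$) and interstitial fluid
($\theta_{int}$).  Volume fractions obey advection–reaction balances

$$\partial_t \theta_i + \nabla\cdot(\mathbf{u}_i\theta_i) = q_i,$$

with an extra chemotactic flux $\chi_g\nabla\cdot(\theta_{yv}\nabla g)$
for the young vessels, which migrate up gradients of vascular endothelial
growth factor (VEGF).  Two structural identities close the mixture: the
no-void condition $\sum_i\theta_i = 1$ and the closed-system condition
$\sum_i q_i = 0$ — volume gained by any cellular phase is drawn from the
interstitial fluid and vice versa.  The package enforces the second
identity *exactly* by construction (the interstitial source is defined as
the negated sum of the others, including every therapy modification), and
the first one discretely through the pressure closure described below.

Phase kinetics follow saturating laws: mitosis needs interstitial raw
material and oxygen ($k_{m,i}\,\theta_i\theta_{int}\,c/(c_p+c)$), death
accelerates under starvation through the factor $(c_{c1}+c)/(c_{c2}+c)$
with $c_{c1}>c_{c2}$, angiogenesis is driven by VEGF and limited by
interstitial supply, vessels occlude when the cellular partial pressure
$\theta_h p_h + \theta_c p_c$ exceeds a critical threshold (a smooth
switch $H(x,h)=\tfrac12(1+\tanh(x/h))$), and young vessels mature into
the established network.  Mature vessels have a smaller occlusion rate
constant and a higher pressure threshold than young ones.

Momentum is creeping flow: $\nabla\cdot(\theta_i\sigma_i)+\mathbf{F}_i=0$
with $\sigma_i=-p_i I+\mu(\nabla\mathbf{u}_i+\nabla\mathbf{u}_i^T)$ and
interphase drag $\sum_j d_{ij}\theta_i\theta_j(\mathbf{u}_j-\mathbf{u}_i)$
plus the interfacial pressure force $p_i\nabla\theta_i$.  Pressures are
closed algebraically: the vascular phases sit at the reference pressure 0;
healthy and cancer cells share
$p_h=p_c=p_{int}+\Sigma(\theta_h+\theta_c)$, where the membrane stress
$\Sigma(\theta)=\Lambda(\theta-\theta^*)/(1-\theta)^2$ switches on when
the cell density exceeds its natural value $\theta^*$ and diverges as the
mixture packs.  Summing all mass balances under no-void gives the
mixture-incompressibility constraint that determines $p_{int}$.

Chemicals (oxygen $c$, VEGF $g$, bevacizumab $a$, docetaxel $w$) diffuse
and react on a much faster time scale (minutes–hours versus days), so
their balances $D_i\nabla^2 i + s_i = 0$ are solved in quasi-steady form
with zero-flux boundaries at every time step.

## Therapy forcing

*Radiotherapy* adds a kill term to the cancer source,
$R = k_{rad}\,\theta_c \sum_i \mathbf{1}[t \ge t_{rad,i}]
e^{-r_t (t-t_{rad,i})}$: each fraction switches on sharply and its effect
decays with rate $r_t$.  The fraction calendar is either the uniform
progression $t_i = t_0 + (i-1)T_p$ (the loader default) or an opt-in
clinical 5-days-on/2-days-off calendar; the bundled treatment arms use
the clinical calendar, under which 30 daily fractions starting at $t=80$
span 40 days and end at $t \approx 120$.

The kill strength is anchored to the linear-quadratic (LQ) survival model
$SF = e^{n(-\alpha d - \beta d^2)}$.  From a measured $SF=0.16$ after a
single 30 Gy fraction and the ratio $\alpha/\beta = 10$ Gy,
`calibrate_alpha_beta()` recovers $\alpha = 0.015$ per Gy in closed form.
Integrating the kill law for one fraction without proliferation gives
`decay_survival()`,
$\theta_c/\theta_c(0) = \exp(-(k_{rad}/r_t)(1-e^{-r_t t}))$, and
`fit_krad()` inverts it; at $r_t=0.5$ a 12-unit window with 84 % decline
yields $k_{rad} \approx 0.92$ ($0.91$ at the printed rounding).  The
bundled course strength $k_{rad}=0.23$ corresponds to 2 Gy fractions.
$r_t$ is held fixed during fitting because a single survival observation
cannot identify both parameters.

*Radiosensitization* comes in two modes.  Docetaxel mode multiplies $R$ by
$1+\xi_{doc}\tanh(w/h_s)H(l_c-l_{cr},h_d)$: taxanes arrest rapidly
proliferating cells in their radiosensitive cycle phase, so amplification
requires both drug and a cancer proliferation rate
$l_c = k_{m,c}\theta_{int}c/(c_p+c)$ above the critical value.  Oxygen
mode replaces the strength with
$k_{rad}^{ox}(1+\xi_{ox}\tanh(c/c_0))$, where $c_0$ is the oxygen field
frozen at $t=0$; `calibrate_krad_ox()` pins $k_{rad}^{ox}$ by equating
the time-integrated kill of the two forms over one course at a
representative relative oxygenation, so standalone oxygen-sensitized
radiotherapy matches the plain form globally while redistributing the
kill towards well-oxygenated regions.  The shipped value 0.11 sits
between the anoxic limit (0.23) and the fully oxygenated limit
(0.23/(1+2\tanh 1) ≈ 0.09).

*Drugs* enter the bloodstream as trains of exponentially decaying pulses
(`blood_concentration()`), replenish into tissue through the vasculature,
decay, and are consumed.  Bevacizumab neutralizes VEGF (half-max at the
median effective dose $a_{50}$) and induces apoptosis of young vessels;
docetaxel kills rapidly proliferating cells with saturating kinetics
(half-max $w_m$), gated by the same proliferation switch as the
sensitization.

## Parameters

The radiotherapy and radiosensitization constants are published values
and ship as defaults ($k_{rad}=0.23$, $r_t=0.5$, $t_0=80$, $T_p=1$,
$N_{rad}=30$, $\xi_{doc}=\xi_{ox}=2$, $h_s=3\times10^{-3}$,
$k_{rad}^{ox}=0.11$), as are the protocol (6 injections of each drug
every 3 weeks from $t=80$), the initial conditions and the
nondimensionalization (1 length unit = 400 µm, 1 time unit = 24 h).

The therapy-free kinetic, transport and drug-tissue constants are a
**package calibration** (the default file is labelled accordingly): they
were fixed once, before the test suite was written, by three principles
and never revisited:

1. **Homeostasis is exact.**  The cancer-free tissue state
   ($\theta_h=0.6$, $\theta_{yv}=0.002$, $\theta_{mv}=0.015$,
   $\theta_{int}=0.383$, $c=0.25$, $g=6\times10^{-4}$) is made a fixed
   point of the kinetics by solving the steady-state balances for
   $k_{d,h}$ (cell turnover), $k_{rep}$ (oxygen replenishment versus
   consumption), $k_{sec}$ (VEGF secretion versus binding and decay) and
   the vascular turnover pair $k_{occ}^{yv}$, $k_{occ}^{mv}$
   (angiogenesis balanced by the smooth occlusion tail at zero pressure,
   maturation balanced by mature-vessel occlusion).  A uniform fixed
   point of the kinetics is automatically a fixed point of the full
   discrete solver, which the tests verify to machine precision.

2. **The growth regime matches the printed benchmarks.**  The free
   cancer-kinetics and mobility constants were chosen so the untreated
   tumor reaches a few-percent surface coverage at $t=120$ and the
   irradiated tumor survives the 30-fraction course at roughly the
   level the LQ model predicts for $k_{rad}=0.23$ (about a third) —
   the same two anchor points used to set the radiotherapy strength in
   the first place.  This leads to $k_{m,c}=1.2 > k_{m,h}=1$,
   $k_{d,c}=0.06 < k_{d,h}$, and a uniform drag of 18.

3. **Orders of magnitude are physiological.**  Oxygen penetration
   lengths of a few hundred µm, VEGF decay on the day scale, bevacizumab
   blood half-life of about three weeks versus a much faster docetaxel
   clearance, and drug potencies that make each monotherapy visibly but
   not overwhelmingly suppressive.

Any value can be overridden from YAML or a named list; the loader rejects
unknown keys and refuses to run when a value is left as the explicit
placeholder `"unresolved"`.

## Numerics

The circular tissue is reduced to its radial coordinate and discretised
with finite volumes: fractions, pressures and concentrations at cell
centers, velocities at faces (a staggered arrangement that suppresses
pressure checkerboarding).  Cell volumes are annular areas, so grid
quadrature reproduces the 2-D area integrals that define the tumor
metrics.

Each time step is a segregated implicit update iterated to a coupled
fixed point (tolerance $10^{-8}$ on the fractions, depth-one
Anderson/secant mixing, at most 50 sweeps):

1. **Transport.**  Implicit first-order upwind fluxes for every phase,
   with the chemotactic contribution added to the young-vessel face
   velocity; source terms linear in the phase's own fraction (growth,
   death, radiation and drug kill) are treated implicitly, which keeps
   the update positivity-preserving even at full kill strength.
2. **Flow.**  The five momentum balances and the
   mixture-incompressibility constraint are assembled into one
   block-tridiagonal system (6×6 blocks per grid position: one pressure,
   five face velocities) and solved monolithically; the constraint uses
   the *same* upwinded face fractions as the transport step, so the
   no-void identity is inherited by the discrete update.  The pressure
   is pinned in the outermost cell (the constraint rows are otherwise
   linearly dependent).  Where a phase vanishes, a $10^{-10}$ diagonal
   ridge keeps the system nonsingular.
3. **Chemistry.**  Newton iterations with analytic Jacobians for each
   quasi-steady species, tridiagonal solves, zero-flux boundaries
   (residual tolerance $10^{-11}$; concentrations below $-10^{-10}$
   abort the run).

Time integration is variable-step BDF2 with BDF1 restarts on the first
step and after each schedule event; steps are clipped to land exactly on
fraction times, injection times and recording times.  Pulse activation is
inclusive at the instant ($t \ge t_i$) in the pointwise forcing
functions, but the integrator evaluates sources at the end of each step
and therefore uses the strict form — a step that *ends* on a fraction
time must not apply the new pulse retroactively.  The default step
ceiling is 0.1 time units; a step is rejected and halved when a fraction
drops below $-10^{-8}$ or the coupled iteration fails, with a hard floor
of $10^{-5}$.  Kinetic rates are evaluated on fractions clamped at zero;
the transported fields themselves are never clamped.

Boundary conditions are symmetry at the center and a closed outer rim
(no-penetration for all phases, zero flux for fractions and chemicals),
consistent with the closed-system premise.

## Verification and what it shows

The test suite checks, among other things: exact closure of the phase
sources on a thousand random states with all therapies active; machine-
precision stationarity of the homeostatic state; second-order
manufactured-solution convergence of both the momentum and the chemistry
solves; agreement of the implicit transport with an independent
stiff-ODE integration of the same semi-discrete system under frozen flow;
$O(\Delta t^2)$ tracking of the closed-form single-fraction decay law;
no-void drift below $10^{-6}$ and relative mixture-volume conservation
better than $10^{-8}$ over a full simulated course; and the calibration
inverse pairs at $10^{-12}$.

The treatment-arm checks run at deliberately reduced scale: 48 cells on
the radius-30 tissue for the radiotherapy-versus-untreated comparison
(the domain of the quantitative checkpoints) and 72 cells on the
radius-50 tissue for the combination arms, whose tumors would otherwise
fill the small domain long before the 650-unit horizon and make late-time
comparisons meaningless.  These resolutions were chosen after a
refinement check of the surface-coverage metric (which is
quadrature-stable at the per-mille level already at 100 cells for smooth
profiles); halving the step ceiling moves end-of-run coverage by less
than a percent.

Passing these tests shows that the *implementation* integrates the
stated model faithfully and that the calibrated regime reproduces the
qualitative treatment phenomenology — radiotherapy's fast but transient
suppression with post-course relapse and accelerated regrowth, the
enduring benefit of the cytotoxic agent, the dominance of the triple
combination over chemotherapy alone and over radiation+bevacizumab, the
extra benefit of taxane radiosensitization, and the periphery-versus-core
redistribution of the kill under oxygen sensitization.  One comparison
comes out marginally reversed in this calibration: against
radiation+docetaxel, adding bevacizumab costs slightly more through
impeded docetaxel delivery (young-vessel apoptosis cuts the drug's
vascular replenishment) than it gains through VEGF suppression, so the
triple arm sits a few per-mille of coverage above that dual arm in
mid-course — a known anti-angiogenic trade-off that a calibration with
more perfusion carried by young vessels would tip the other way.  The
suite does *not* validate the model against real tumors:
the parameter set away from the published constants is a synthetic
calibration, the geometry is radially symmetric (no invasive fingering,
no asymmetric seeds), and quantitative agreement with full-resolution
2-D unstructured-mesh computations is expected only in ordering and
order of magnitude.

## Known limitations

* One spatial dimension: morphological irregularity and multi-seed
  interactions are out of reach by construction.
* In this calibration mature vessels dominate perfusion, so anti-VEGF
  monotherapy understates the healthy-tissue damage that a more
  yv-dependent tissue would show; the healthy-recession ordering between
  bevacizumab and the untreated arm is therefore not reproduced.
* The radius-30 domain saturates (the tumor fills the tissue) within the
  650-unit horizon for weakly treated arms, after which arm trajectories
  converge; cross-arm comparisons at late times are made on the larger
  domain for this reason.
* Intravascular drug transport is not modeled: blood concentrations are
  prescribed pulse trains, and dosimetry enters only through the
  dimensionless kill strength, not in Gy.
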