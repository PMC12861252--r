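---
title: "A multiphase viscoelastic model of hot-air mushroom drying"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multiphase viscoelastic model of hot-air mushroom drying}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(mushdry)
```

## The model

`mushdry` simulates hot-air drying of a shiitake mushroom cap as a
multiphase porous medium whose water activity is generated from tissue
composition rather than from an empirical isotherm. Three ingredients are
coupled:

**1. Two-phase thermodynamics.** A hypha is treated as two thermodynamic
phases separated by the vacuole membrane: the vacuole holding the small
solutes (mannitol, trehalose, ions) and the combined cytoplasm/cell-wall
biopolymer network. Water exchanges freely across the membrane while
solutes do not, so at local equilibrium the two phases share one water
activity,

$$a_{w,1} = a_{w,2},\qquad
RT\ln a_{w,i} = \Delta\mu_{w,\mathrm{mix},i} + v_w p_i ,$$

with the mixing term from multicomponent Flory–Huggins theory,

$$\ln a_{w,\mathrm{mix}} = \ln\phi_w + \sum_i\Big(1-\tfrac1{N_i}\Big)\phi_i
 + \Big(\sum_i\chi_{wi}\phi_i\Big)(1-\phi_w),$$

where $N_i$ is the molar-volume size ratio of component $i$ relative to
water and $\chi_{wi}$ its interaction parameter. `partition_water()`
solves the equal-activity split by bisection on the phase-1 water
fraction; the residual is monotone in that fraction, so the solve is
provably convergent, and it coincides with brute-force minimization of the
total Flory–Huggins free energy (this equivalence is a test).

**2. Viscoelastic relaxation.** The biopolymer phase carries a pressure
term from the stress of the cell-wall matrix, modelled as two Maxwell
modes with internal variables $\phi_{\mathrm{ref},i}$ relaxing toward the
current polymer fraction $\phi_s$ at rates $1/\tau_i(X_m,T)$:

$$\frac{d\phi_{\mathrm{ref},i}}{dt}=\frac{\phi_s-\phi_{\mathrm{ref},i}}{\tau_i},
\qquad
\sigma=\sum_i G_i\left(\tilde\phi_i^{1/3}-\tilde\phi_i\right),\quad
\tilde\phi_i=\frac{\phi_s}{\phi_{\mathrm{ref},i}}.$$

The pressure term $v_w p = \pm v_w\sigma$ follows the sign chain
$\sigma=-\Pi_{\mathrm{elastic}}I$, $\Delta\mu_{\mathrm{elastic}} =
v_w\Pi_{\mathrm{elastic}}$, $v_wp=-\Delta\mu_{\mathrm{elastic}}$, which
resolves to $+v_w\sigma$; because the scalar/tensor sign conventions in
this chain are easy to invert, the sign is a single configuration flag
(`composition$elastic_sign`). With the default sign, drying faster than
the matrix can relax leaves $\tilde\phi>1$ and $\sigma<0$, which lowers
the activity at given moisture and therefore holds *more* water on the
desorption branch — the observed direction of sorption hysteresis.

**3. Coupled transport on a shrinking grid.** Conserved variables per
control volume (CV) are total water mass (liquid plus pore vapor in
equilibrium, $c_v = a_w M_v p_{sat}(T)/(RT)$) and enthalpy. Liquid
moisture moves by Fickian diffusion with a Darken-type mutual
diffusivity built from free-volume self-diffusivities and the
thermodynamic factor $\Gamma=\partial\ln a_w/\partial\ln\phi_w$ evaluated
from the isotherm; vapor moves through the pore space with the binary
water–air diffusivity; heat moves by conduction (volume-weighted parallel
conductivity) and by the sensible and latent enthalpy carried by the
fluxes. Porosity and shrinkage follow the empirical gas/solid
volume-ratio law (exponential branch below $X_m^*=0.95$, linear above;
the printed branches do not meet at the switch — the jump of about 0.19
is kept as printed, with an optional blend over $X_m\in[0.90,1.00]$ for
users who prefer a continuous law). Boundary exchange combines
convection ($h_{conv}=6+10\,u_{air}$), linearized radiation
($h_{rad}=e\,4\sigma_{SB}T_{wall}^3$, with $\sigma_{SB}$ kept at the
model's printed value $5.70\times10^{-8}$), evaporation through the
Lewis-relation mass-transfer coefficient
$\beta_{ext}=F_{w,conv}h_{conv}/(\rho_{air}c_{p,air})$ — defined from the
convective coefficient only, not from $h_{ext}$, where the source
formulations are inconsistent — and two correction factors
($F_{w,conv}$, $F_{w,diff}$) absorbing the mismatch between theoretical
and actual transfer.

## Geometry

The fresh cap (default 25 g at $X_{m,0}=9$ d.b., giving a hemisphere of
about 3 cm radius with the default composition) is discretized into
spherical-shell CVs of equal solid mass in Lagrangian (solid-mass)
coordinates: volumes, radii and areas are recomputed each step from the
local moisture through the shrinkage law. The gill (lamella) layer is a
dual-porosity region — half tissue, half macroscopic air gaps open to the
drying air — represented as the innermost grid region whose CVs exchange
water and heat volumetrically with the ambient through a configurable
gap area density (`geometry$a_gap`, default 300 m²/m³, the order implied
by millimetre lamella spacing). This reproduces the two drying faces
seen in radial activity profiles: the lamella face at $r=0$ and the cap
surface dry first, and the drying front reaches the mid-cap interior
last. The source geometry does not pin down the lamella–ambient
coupling; this volumetric closure is this package's choice.

## Numerics

The integrator is a linearized backward-Euler (semi-implicit) finite
volume scheme. The stiff couplings — pore-vapor equilibration, conduction
across the thin dry crust, latent heat carried by vapor — enter a
$2\times2$-block tridiagonal implicit solve; the update is then applied
in *flux form* from the linearized end-of-step state, so interior fluxes
telescope and discrete conservation of water and energy is exact to
round-off regardless of step size (closed-box drift is at the
$10^{-15}$ level over $10^4$ steps). Step size follows local change
targets (default 3% of local water mass and 0.7 K per step; halving the
targets moves a 48 h drying curve by less than $2\times10^{-3}$ in
$y_w$). The Maxwell internal variables are advanced by their exact
exponential update with $\phi_s$ frozen over the step — unconditionally
stable and exact for constant $\phi_s$. The nonlinear vapor-equilibrium
split of (mass, enthalpy) into (liquid, vapor, temperature) is solved
per CV by warm-started fixed-point iteration; the equal-activity
partition inside it uses Newton's method on the log-activity residual
with a bisection fallback.

Spatial resolution: with the default 20 CVs the drying-curve error
against a doubled grid is a few percent, concentrated at the sharp
falling-rate endpoint — the free-volume diffusivity spans more than
three decades between wet and glassy-dry tissue, so the drying fronts
are steep, and the dual-porosity lamella adds a second front. The error
contracts by roughly $3\times$ per grid doubling (and the
single-region configuration meets 1% already at 20 CVs); use 40–80 CVs
when front timing matters quantitatively.

## Parameters and defaults

Quantities printed in the underlying work are used as given: the
shrinkage-law coefficients, the lamella gap fraction (50%), the fresh
mass, the CPMG acquisition parameters, the 5% population-counting rule,
the 40 °C / 3% (w.b.) integrity thresholds, and the fitted factors
$e=0.9$, $F_{w,conv}=5$, $F_{w,diff}=8$, $F_{G0}=0.1$, $F_{G1}=3$,
$F_{\tau00}=10$, $F_{\tau01}=100$ (used as ground truth in the recovery
studies). Constitutive details that are *not* printed ship as documented
configuration defaults, chosen once for physical plausibility:

* Flory–Huggins sizes and interactions: mannitol $N=5,\chi=0.3$;
  trehalose $N=9,\chi=0.4$; ions $N=1,\chi=0$; biopolymers
  $1/N=0,\chi=0.8$; dry matter 30% solutes / 70% biopolymers. These give
  a mushroom-like isotherm ($X_m\approx0.06$ at $a_w=0.3$,
  $\approx0.67$ at $a_w=0.9$, 25 °C).
* Viscoelastic base regressions, log10-linear in moisture:
  $\log_{10}G_i = (7.5, 7.0) - 0.3X_m$ Pa and
  $\log_{10}\tau_i = (5.0, 3.0) - 2.0X_m$ s with a mild Arrhenius factor
  (30 kJ/mol). The moduli are cell-wall scale, deliberately above
  tissue-scale compression values: the stress relevant for sorption is
  carried by the fibrous wall, and at tissue-scale moduli the elastic
  shift of the isotherm ($v_w\sigma/RT\sim10^{-5}$) would be too small
  for the sorption scaling factors to be identifiable at all. The
  relaxation slope keeps $\tau$(dry)/$\tau$(wet) above $10^3$ — dry
  matrix effectively frozen over any sorption experiment, wet matrix
  relaxing in minutes-to-hours — while leaving the wet-end $\tau$
  comparable to a DVS dwell so that partial relaxation is observable.
* Free-volume diffusivity: dilute limit $2.3\times10^{-9}$ m²/s with a
  retardation of $10^{-4\phi_{dm}/(1-0.4\phi_{dm})}$, giving a
  wet-to-dry contrast above $10^3$; $F_{w,diff}$ absorbs the absolute
  level by design.
* Densities: solid 1500 kg/m³ (not printed in the source), water 1000.
* Saturation pressure: Antoine correlation for water (1–100 °C
  constants), cross-checked against an independent Magnus-based oracle
  to within 1% over 10–51 °C.

## Calibration machinery

`objective_lse()` implements the weighted least-squares objective: per
experiment, squared residuals of the rescaled temperature
$\Theta=(T_p-T_{init})/(T_{air}-T_{init})$ and of wet-basis moisture,
each divided by its own sample count, the moisture term weighted 10.
`sequential_search()` is the sequential single-factor (coordinate
descent) grid search: one parameter varies at a time, the incumbent
moves to the grid argmin, cycles repeat until none improves.

For the three drying-model factors this plain search recovers a
generating parameter vector exactly from noise-free synthetic curves.
The four sorption factors are different: modulus and relaxation time
enter the transient response largely through their product (a viscosity),
so the objective has a curved valley along $G\tau=\mathrm{const}$ in
which single-factor moves cannot descend — coordinate descent from any
neutral start stalls at a nonzero local minimum. `fit_sorption_factors()`
therefore seeds the cyclic refinement with a full-factorial scan of the
candidate lattice (`prescan = TRUE`; $7^4$ evaluations at ~15 ms each),
mechanizing the preliminary range study that manual fits of this kind
start from, and then refines cyclically as usual.

The DVS simulator treats the powder sample as lumped: moisture relaxes
toward each RH step's vapor concentration through a conductance fixed at
a value (`k_cond = 0.02` m³ kg⁻¹ s⁻¹) that brings step ends close to
equilibrium within a 6 h dwell, as stepped-RH data of this kind show,
while the Maxwell matrix relaxes on its own clock. Descending-then-
ascending protocols then produce thermodynamic hysteresis (desorption
above adsorption) whenever $\tau\gg$ dwell.

## What the synthetic data do and do not show

`gen_drying_experiment()`, `gen_rh_schedule()` and `gen_cpmg_decay()`
emulate drying logs (model output plus seeded Gaussian noise, optional
on/off RH oscillation), sorption protocols, and CPMG decays. Because
the recovery studies refit the same model that generated the data, they
validate the *machinery* — objective, search, simulator determinism,
identifiability under the stated grids — not the model's fidelity to
real mushrooms. Real drying records additionally contain sensor-contact
bias, oven airflow non-uniformity and geometry variability that the
generator deliberately omits, and the reported goodness-of-fit of the
original experiments cannot be reproduced here because the underlying
logs are not published. Equally, the membrane-integrity classifier is a
threshold rule taken as given; the package predicts *when* a drying
trajectory crosses it, not the membrane biophysics.

## Worked example

```{r example, eval = FALSE}
cfg <- default_config(
  transport = list(F_w_diff = 8, F_w_conv = 5, emissivity = 0.9))
run <- simulate_drying(cfg, ambient_schedule(0, 35, 0.3, 0.3),
                       t_end_h = 48, profile_times_h = c(5, 10, 14))
autoplot(run)
plot_profiles(run, "aw")

states <- overlay_trajectory(run)
plot_state_diagram(states)
```

A 35 °C / 30% RH run shows the signature behaviour: the center
temperature drops to the evaporative-cooling floor and stays there while
the core activity remains near 1, both faces dry first, and near the end
of drying the temperature rises quickly to the air temperature as the
evaporation front reaches the center. At 51 °C the late trajectory
crosses the 40 °C threshold while still moist — the membrane-integrity
overlay marks those samples compromised.

## Known limitations

* One-dimensional radial geometry; the lamella–ambient coupling is a
  volumetric closure, not resolved gill geometry.
* No momentum balance: shrinkage is ideal and the porosity law is
  empirical; case hardening appears only through the porosity rise the
  law encodes.
* The composition-based defaults are plausible but not fitted to
  composition measurements; all of them are configuration, not code.
* First-order time accuracy (linearized backward Euler); tighten
  `solver$target_dm_rel` / `target_dT` for stiff-schedule studies.
* 20-CV default resolves drying-front timing to a few percent; raise
  `geometry$N` for quantitative front studies.
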