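---
title: "Particle transport and wall capture in a capsule dry powder inhaler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Particle transport and wall capture in a capsule dry powder inhaler}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpitrack)
```

## What the model is

A capsule dry powder inhaler (DPI) disperses a micronized powder into the
inspiratory air stream. How much drug leaves the device (the emitted
fraction, EF) and how fine the emitted aerosol is (FPF, MMAD, GSD) are
decided inside the device, largely by particle–wall encounters: a particle
that hits a wall either sticks or bounces, and a deposited particle either
stays or is re-entrained. `dpitrack` implements the particle side of this
problem as a desk-scale Lagrangian simulation:

1. a **geometry** stand-in for an RS01-type device — two coaxial cylinders
   (powder chamber, mouthpiece) joined by a perforated grid plane;
2. a **steady flow field** contract with an analytic swirling stand-in
   calibrated to the 60 L/min operating point;
3. a **polydisperse injection** sampled from a Rosin–Rammler law fitted to
   measured volume quantiles;
4. a **wall interaction model**: capture-velocity sticking plus
   rolling/sliding detachment criteria;
5. **aerodynamic performance metrics** computed the way a cascade-impactor
   lab computes them, so in silico and in vitro numbers are comparable; and
6. **agreement statistics** (R², RMSE, NRMSE) for cross-method comparison.

The deliberate non-goals: no turbulence model is solved (the flow-field is
pluggable; a CFD solution sampled on a lattice can be supplied as CSV), no
particle–particle collisions or agglomeration (appropriate at particle
volume fractions around 10⁻⁴), and no transient inhalation ramp (steady flow
approximates the plateau of a 4 s actuation).

## The wall model

The core physics is the sticking criterion. A particle of diameter $d_p$
striking a wall with normal speed $v_n$ sticks when $v_n \le v_{cr}$, with

$$v_{cr} = \left(\frac{2E}{d_p}\right)^{10/7},
\qquad
E = 0.51\left[\frac{5\pi^2 (k_1 + k_2)}{4\rho_p^{3/2}}\right]^{2/5},
\qquad
k_1 = \frac{1 - \nu_s^2}{\pi E_s},\;
k_2 = \frac{1 - \nu_p^2}{\pi E_p}.$$

$E_s, \nu_s$ and $E_p, \nu_p$ are the Young's moduli and Poisson ratios of
wall and particle, $\rho_p$ the particle density. $v_{cr}$ falls steeply
with size: with the default constants, a 5 µm lipid particle
($\rho_p = 1050$ kg/m³) has $v_{cr} \approx 1.60$ m/s, a 10 µm particle
only 0.60 m/s. Faster impacts bounce with the normal velocity component
reversed and scaled by a restitution coefficient $e_n$ (default 0.8 —
"bounce with reduced velocity"; the source literature quantifies no value,
so it is configurable). The tie $v_n = v_{cr}$ is resolved as stick, the
conservative choice for deposition.

A deposited particle is re-entrained if the fluid loads beat adhesion:

* **rolling** when the moment balance
  $F_D\,(d_p/2 - b) + F_L\, a \ge F_{st}\, a$ holds;
* **sliding** when $F_D \ge k_s F_{st}$;
* when both hold, rolling is reported — it is the more likely detachment
  route for spheres (its threshold is reached at far lower drag than the
  sliding one).

The closures for the force budget are standard adhesion mechanics, chosen
because the interaction framework names the quantities without defining
them; each is an isolated function so alternatives can be swapped:

* $F_{st} = \tfrac{3}{4}\pi W_A d_p$ — JKR pull-off force with work of
  adhesion $W_A$;
* $a = [9\pi W_A (d_p/2)^2 / 2K]^{1/3}$, $K = \tfrac{4}{3}\big[(1-\nu_s^2)/E_s
  + (1-\nu_p^2)/E_p\big]^{-1}$ — zero-load JKR contact radius — and
  $b = a^2/d_p$ the normal flattening;
* $F_D = 3\pi\mu d_p u_{rel} f / C_u$ — Stokes drag with a near-wall
  correction $f$ (default 1.70) and Cunningham factor $C_u$ (1 for these
  sizes);
* $F_L$ — Saffman-type shear lift, switchable off.

The fluid velocity entering $F_D$ is evaluated at one particle radius off
the wall, which is where the particle's center sits. In a wall-bounded flow
this is a small fraction of the bulk speed, and with the default constants
the adhesion moment wins by orders of magnitude across the inhalable size
range (1–13 µm): deposited particles stay put at any flow this device
produces. Detachment bookkeeping is nonetheless implemented and exercised in
tests with weakly adhesive configurations. Because the flow is steady, the
force budget on a stuck particle never changes, so one assessment at the
moment of sticking decides permanence.

## Geometry and flow stand-ins

The true internal contours of the device are not published; the geometry
module models what matters for deposition accounting — three regions
(chamber, grid, mouthpiece) with the device's bounding dimensions as
defaults (total height 47.5 mm, maximal width 28 mm, outlet diameter
10 mm, air inlet 1.5 × 6 mm). The grid is a zero-thickness perforated plane
with porosity 0.6: a crossing particle passes with probability equal to the
porosity, else it impacts. Porosity draws are pre-assigned per particle and
crossing index so they do not depend on the integration step size. The grid
plane position (25 mm) splits the height roughly where the physical
grid sits between chamber and mouthpiece; it is configurable, as is
everything else.

The analytic flow field is built from a stream function so the axial flux
through every cross-section equals the volumetric flow $Q$ *exactly*: plug
flow in the chamber funnelling smoothly into the mouthpiece bore (smoothstep
taper beginning at 60% of the chamber height), a Poiseuille profile in the
mouthpiece, and solid-body swirl in the chamber decaying linearly to zero at
the grid. The swirl number (tangential wall speed over mean axial chamber
speed, default 2) sets how strongly particles are centrifuged toward the
chamber wall — swirl chambers of capsule inhalers operate with tangential
speeds of a few times the axial mean, and the qualitative picture (swirl
carrying particles up and outward, peak speeds ≈ 12.7 m/s at the outlet for
60 L/min through the 10 mm bore) matches what a RANS solution of this
device class shows. Velocity gradients are evaluated by central differences
(step 0.1 µm); a single numeric code path serves analytic and gridded
fields alike, and at the queried scales the finite-difference error is far
below the uncertainty of the lift closure that consumes the gradient. The
uniform test field carries its exact zero gradient.

What the stand-in does *not* reproduce: turbulent eddy dispersion (none is
modeled — the source framework describes none either), recirculation zones,
and the capsule-seat details. The practical consequence is visible in the
impact log: small particles (2–5 µm), whose centrifugal drift scales as
$d_p^2$, rarely reach the chamber wall before being carried through the
grid, so nearly all of their wall encounters are grid-plane impacts at high
normal speed. Tests of the size-selectivity of capture therefore assert the
capture *margin* ($v_n / v_{cr}$ smaller for small particles), which the
model reproduces, rather than raw stick frequencies, which depend on where
impacts happen in a way the simplified flow cannot capture.

## Injection

Powder dispersion is assumed instantaneous: particles appear on a release
surface 12 mm above the chamber floor, uniformly over the cross-section,
already travelling at the local fluid velocity. Sizes are sampled from a
Rosin–Rammler (Weibull) law $F(d) = 1 - \exp[-(d/\delta)^n]$ fitted to the
measured volume quantiles $d_{v10} < d_{v50} < d_{v90}$. Under the law,
$\log(-\log(1-q))$ is linear in $\log d_q$, so the two parameters come from
an ordinary least-squares line through three points — exact when the
quantiles are themselves Rosin–Rammler, a least-squares compromise
otherwise (the fit residual is reported). Sampling is inverse-CDF on the
truncated support $[d_{v10}/2,\ 1.5\,d_{v90}]$, the usual min/max-diameter
truncation of solver-style injections. Because the quantiles are
volume-based, each sampled particle represents an equal mass of powder;
downstream stage-binning of the emitted aerosol therefore uses equal
weights (weighting each sample by $d^3$ again would double-count volume).
Fate summaries are nonetheless available under both number and mass
weighting of the per-particle records, since the two answer different
questions and the choice is not documented in the comparison literature.

## Time integration

The equation of particle motion retained is Stokes drag relaxation toward
the local fluid velocity with time constant
$\tau = \rho_p d_p^2 C_u / 18\mu$ (about 80 µs for 5 µm at unit density
scale), optionally with gravity (off by default; the device operates
upright over sub-second transits where drag dominates). Both the velocity
update and the displacement use the exact exponential solution over the
step, so the integrator is stable for $dt \gg \tau$; the step is
$\tau/5$ capped by a 0.2 mm displacement bound so wall crossings are not
overshot. Each step's straight segment is tested against the cylindrical
walls (quadratic intersection), the floor, the grid plane and the outlet;
the earliest crossing is resolved. Bounced particles restart a nanometre
inside the wall; detached ones restart one diameter off it at the local
fluid velocity. Tracking stops at emission, permanent sticking, or a
simulated-time budget of 0.5 s — ample for a device the flow transits in
tens of milliseconds; stragglers are reported as "in domain at timeout",
never folded into EF. A run conserves particles exactly
(emitted + stuck + in-domain = injected) and is bit-reproducible for a
given seed.

## Impactor analysis

The aerodynamic diameter is $d_{ae} = d_g \sqrt{\rho_p / \rho_0}$ with
$\rho_0 = 1$ g/cm³ (the printed form of this relation omits the radical; the
square-root convention is the standard definition and the one consistent
with the MMAD magnitudes involved). Emitted particles are binned onto
impactor stages — default cut-offs 8.06, 4.46, 2.82, 1.66, 0.94, 0.55,
0.34 µm, the published next-generation-impactor values at 60 L/min, fully
configurable — with half-open bins $[c_i, c_{i-1})$; mass above the top
cut-off lands in the induction-port bin, below the lowest in the final
collector. MMAD and GSD come from the log-probability construction:
cumulative percent undersize on a probit scale against cut-off diameter on
a log scale, piecewise-linear between the nearest data points. The 50%
crossing is the MMAD; $\mathrm{GSD} = \sqrt{d_{84.13}/d_{15.87}}$ from the
same interpolant (the printed form of this definition also lacks its
radical; the standard square-root form is used). The cumulative denominator
is the whole emitted aerosol, with induction-port mass counted as coarse —
this makes the construction exact for a lognormal aerosol, since a
lognormal is a straight line in probit-log coordinates. The analysis
refuses to extrapolate: an unbracketed 50% point is an error, unbracketed
±1σ points yield `GSD = NA` with a warning. FPD is the emitted dose times
the undersize fraction at the respirable cut-off (5 µm by convention;
6.4 µm reproduces the twin-stage-impinger boundary), FPF its percent of ED.

```{r}
st <- synthetic_stage_table(mmad_um = 4, gsd = 2, seed = 7)
aero_summary(st)
```

The synthetic stage-table generator emulates only the ideal part of an
impactor — sharp-cut stages fed by a lognormal aerosol with a configurable
device retention. Real tables carry wall losses, non-ideal collection
efficiency curves and re-entrainment, so passing the recovery tests shows
the analysis pipeline is correct, not that real impactor data are this
clean.

## A complete run

```{r}
cfg <- default_config()
cfg$seed <- 42L
sim <- suppressWarnings(run_from_config(cfg))
sim$summary
```

The warning guard covers the coarse-aerosol case where the emitted 84th
percentile exceeds the top stage cut-off and the GSD is refused. Problem
sizes used throughout the package's tests and examples — 100 tracked
particles per run, 10⁵ samples for distribution-recovery checks — are the
sizes at which the corresponding reference workflow operated (100-particle
production runs after consistency screening up to larger counts; our
time-step robustness check plays that screening role).

## Design choices that were genuinely open

* **Restitution** $e_n = 0.8$: any value in (0, 1] is defensible; results
  are insensitive because bounced particles are re-entrained regardless.
* **Grid porosity 0.6**: no lattice specification exists; 0.6 is typical of
  inhaler grids' open-area fraction and is a single explicit parameter.
* **Detachment re-testing**: once, at sticking, because the steady field
  makes the inequality time-invariant; re-testing each step would only
  re-evaluate constants.
* **R² convention**: squared Pearson correlation of the paired values, as
  "correlation diagram" usage implies; regression-through-origin R² is the
  main alternative and is not provided.
* **Weighting of EF**: the comparison literature does not state whether its
  emitted fractions are number- or mass-weighted; both are computed, the
  mass weighting is the default for summaries.

## Known limitations

* The analytic flow is a stand-in: regional deposition splits and EF values
  depend on flow structure the stand-in only sketches. Supplying a CFD
  field via `load_gridded_field()` upgrades fidelity without touching the
  particle model.
* No turbulent dispersion: small-particle wall contact in the chamber is
  under-represented (see above).
* No agglomeration or breakage: formulations whose in vitro behaviour is
  dominated by agglomerate mechanics (e.g. sticky excipients) will diverge
  from these predictions — a divergence the comparison statistics are
  designed to quantify, and which motivates keeping the in vitro analysis
  path in the same package.
* Grid-plane impacts inherit the full axial impact speed; a real grid's
  finite thickness and edge geometry would moderate this.
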