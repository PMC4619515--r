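---
title: "Distorted-grid particokinetics: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distorted-grid particokinetics: model, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgdose)
```

## The transport model

`dgdose` models the fate of engineered-nanomaterial (ENM) agglomerates
suspended in the liquid column of a cell-culture well as one-dimensional
sedimentation–diffusion transport.  The column of height $H$ is divided
into $n$ compartments of height $h$, indexed top (1) to bottom ($n$), with
impermeable walls at both ends.  Each size species $j$ is transported
independently — cross-species interactions, re-agglomeration and charge
effects are assumed negligible, which is appropriate for suspensions
prepared by critical-energy sonication whose size distributions are stable
over the exposure.

Two coefficients govern each species: the Stokes settling velocity
$v_s = g(\rho_{EV}-\rho_m)d_H^2/(18\eta)$ and the Stokes–Einstein
diffusion coefficient $D = k_B T/(3\pi\eta d_H)$.  The *effective* density
$\rho_{EV}$ is that of the whole agglomerate (primary particles plus
trapped medium), typically measured by volumetric centrifugation; it lies
between the medium and bulk-material densities, and the hydrodynamic
diameter $d_H$ is the DLS-reported size.  Both coefficients are divided by
the friction ratio
$f/f^0 = \chi \cdot s_{\mathrm{solv}} \cdot s_{\mathrm{rough}} / C_c$:
the Cunningham slip correction
$C_c = 1 + (\lambda/d)(2.34 + 1.05 e^{-0.39 d/2\lambda})$ is applied by
default (it matters only below ~5 nm in water, where
$\lambda \approx 2.5\times10^{-10}$ m), while the dynamic shape factor
$\chi$ and the solvation/roughness factors default to 1.  Closed forms for
$\chi$ are provided for prolate/oblate ellipsoids and circular cylinders
of axis ratio $P>1$ plus the cube constant 1.08; anything else must be
supplied explicitly — estimating friction for arbitrary shapes is out of
scope.  Multiplicative composition of the slip and shape/solvation factors
is an assumption of this package; the factors are individually standard
but their joint form is not uniquely defined in the literature.

One caveat worth recording: the cylinder formula
$\chi = (2/3)^{1/3}P^{2/3}/(\ln 2P - 0.3)$ evaluates to 1.218 at $P = 3$,
not the 1.27 sometimes quoted alongside it; the package implements the
formula and its tests freeze the value obtained by independent hand
evaluation.

## Numerical scheme

Within each iteration of duration $\Delta t$ the solver applies, in order:

1. **Diffusion** — forward-Euler update of Fick's law,
   $\Delta C_i = (\Delta t/h^2)\left[D_i(C_{i-1}-C_i) + D_{i+1}(C_{i+1}-C_i)\right]$,
   with the flux terms across the two walls absent.  Per-boundary
   coefficient arrays and a concentration-dependence factor
   ($D/(1+kC)$, default $k=0$) are supported.
2. **Sedimentation** — upwind inter-compartment transfer: each compartment
   passes the fraction $v_s\Delta t/h$ of its content to the compartment
   below; the top compartment receives no inflow and the bottom compartment
   has no outflow, so settled material accumulates at the bottom without
   ever leaving the column.  Buoyant species rise symmetrically.
3. **Langmuir partition** (optional, see below).
4. **Dissolution increment** (optional, see below).

The user time step (default 1 s) is automatically reduced when either the
fastest-settling species would be displaced more than $h/2$ per step or
the explicit diffusion scheme would violate its stability bound
$D\Delta t/h^2 \le 1/2$; any reduction is reported.  The operator order
within an iteration is a discretization choice whose effect vanishes as
$\Delta t \to 0$; the suite verifies results change by well under 0.5 %
across $\Delta t \in [0.1, 1]$ s, and by under 1 % when $h$ is refined
from 5 µm to 2.5 µm — finer grids than 5 µm change nothing material, which
is why 5 µm is the default compartment height.

The inner loop is implemented twice: a compiled (Rcpp) fast path used by
default, and a pure-R path assembled from the exported step functions
(`diffusion_step()`, `sedimentation_step()`, …) that also serves as the
reference implementation; a test asserts their agreement to floating-point
accumulation.  Long runs are cheap (a 120 h, 600-compartment simulation
takes about a second), so there is no need to trade resolution for time.

## The bottom boundary: reflective vs Langmuir binding

With the **reflective** boundary, particles reaching the bottom stay
suspended and continue to oppose settling through the diffusion gradient;
the system approaches the classical exponential equilibrium profile with
scale height $z_0 = D/v_s$ and complete deposition never occurs.  This is
the recommended setting for typical protein-rich culture media, where
particle–cell binding is weak and non-specific.

The **Langmuir** boundary models particle–cell adhesion as an equilibrium
isotherm with dissociation constant $K_D$.  Each iteration, the total
bottom-compartment content $C_p$ (free plus previously bound) is
re-partitioned: the molar agglomerate concentration
$[P] = 10^{-3}C_p/(N_A\,\rho_{EV}\,\tfrac43\pi r^3)$ sets the occupied
surface fraction $\theta = [P]/(K_D+[P])$; the fraction of the bottom
surface the compartment's particles could cover is
$\theta_{\mathrm{avail}} = h\,C_p\,A_m$ with $A_m = 3/(4r\rho_{EV})$; and
the bound fraction is $F_b = \min(\theta/\theta_{\mathrm{avail}}, 1)$.
Bound mass is stored as areal mass per species, removed from the diffusion
gradient and from settling.

Re-partitioning the *entire* bottom content each iteration — rather than
irreversibly banking newly arrived mass — was a deliberate design choice,
for two reasons.  First, an irreversible per-iteration removal has a rate
proportional to $1/\Delta t$, so predictions would depend on the numerical
time step, violating the time-step-independence requirement.  Second, the
irreversible variant makes the bottom effectively absorbing for any
$K_D \lesssim 10^{-5}$ M, erasing the physically meaningful threshold: with
equilibrium re-partitioning, binding is negligible for micromolar and
larger $K_D$ (non-specific interactions) and becomes strong only in the
nanomolar range typical of specific high-affinity binding, which is the
behaviour the model is meant to reproduce.  A consequence of the isotherm
is monolayer saturation: the bound areal mass cannot exceed
$1/A_m = 4r\rho_{EV}/3$, so in the sticky limit ($K_D \to 0$) deposition
rises far above the reflective plateau but levels off once the surface is
covered rather than proceeding to complete sequestration.  The
$K_D \to \infty$ trajectory reproduces the reflective run exactly.

## Dissolution

Soluble materials are handled by four scenarios for the cumulative
dissolved fraction $f_d(t)$ of the initial mass: `none`, `initial_only`
(dissolution completed before the suspension was characterized),
`constant_rate` (fraction per hour) and `linear_ramp` (linear rise to a
maximum at a given time, constant after).  Molar measurements (e.g. µM
solubilities from ICP-MS) convert to fractions via
`dissolved_fraction_from_molar()`.  Each step, newly dissolved mass moves
from the solid phase — proportionally from every compartment — into a
single well-mixed dissolved pool; the dissolved phase is not spatially
resolved because dissolved species diffuse orders of magnitude faster than
agglomerates and a single concentration is the quantity of interest.
Agglomerate diameters shrink with the cube root of the remaining solid
fraction, $d(t) = d_0\left[(1-f_d)/(1-f_0)\right]^{1/3}$, keeping mass and
volume bookkeeping consistent at constant $\rho_{EV}$ (cube-root-of-volume
shrinkage was chosen over linear-in-diameter because it is the only
reading that conserves mass for homogeneous agglomerates); the nominal
diameter refers to the suspension *after* any initial dissolution, since
that is what DLS measures.  Transport coefficients are refreshed from the
shrunk diameters at every output interval.  If a scenario requests more
dissolution than solid remains, the removal is clamped with a warning.
Bound (cell-adsorbed) mass is exempt from dissolution — a simplification,
flagged here, that matters only when strong binding and fast dissolution
are combined.

## Dose metrics

Deposition is reported for a thin exposure slice at the well bottom
(default 10 µm, an *ad hoc* but conventional thickness for the cell
microenvironment; it must span whole compartments).  The slice mass
concentration is the mean over its compartments; per-area deposition is
concentration × thickness plus any bound areal mass; and the deposited
fraction $f_D$ divides by the *current* suspended-plus-bound mass, so
$f_D \to 1$ remains attainable under dissolution.  Particle-number and
surface-area metrics derive from the mass concentration through the
nanomaterial volume fraction $f_{V,NM} = (\rho_{EV}-\rho_m)/(\rho_{NM}-\rho_m)$,
assuming spherical, homogeneous agglomerates: number
$\propto C/(d_H^3\rho_{NM}f_{V,NM})$ and exposed nanomaterial surface
$6C/(d_H\rho_{NM})$, the latter independent of $f_{V,NM}$.  Polydisperse
suspensions sum these per-species, each species using its own (current)
diameter.  Number- and volume-weighted size distributions interconvert via
$f_{V,i} \propto f_{N,i}d_i^3$, and volume fractions double as mass
fractions because all species share one effective density — itself an
approximation, since in reality a density distribution is superimposed on
the size distribution.

## Reference models and what a green test establishes

Two independent oracles ship with the package.  The closed-form
equilibrium profile $C(z) \propto e^{-z/z_0}$, $z_0 = D/v_s$, is the exact
stationary solution of the continuum sedimentation–diffusion balance in a
closed column; long-time monodisperse solver runs are required to match it
within 2 % RMS.  The Brownian-dynamics tracker evolves individual
particles by $z \leftarrow z - v_s\Delta t + \sqrt{2D\Delta t}\,\xi$ with
reflecting walls, using the same corrected $v_s$ and $D$ as the solver so
that discrepancies isolate the grid scheme; transient (12 h) solver
profiles must agree with the tracker histogram within Monte-Carlo error
(binomial chi-square across 20 µm bins below its 99.9 % quantile, no bin
beyond 4σ — a per-bin 3σ rule is not statistically meaningful across 50
bins).  Mass balance (suspended + bound + dissolved = initial) is asserted
to $10^{-9}$ relative on every recorded state.

These checks establish that the discretization solves the stated transport
problem correctly.  They do not validate the physical idealizations
against real suspensions: monodisperse-equivalent spheres, constant
effective density, no re-agglomeration, instantaneous Langmuir
equilibrium, and a well-mixed dissolved pool all remain assumptions.
Likewise the bundled synthetic lognormal generator
(`synth_distribution()`) emulates the *shape* of DLS number distributions
(including the volume-mean > number-mean ordering) but not instrument
noise, multimodality or intensity-weighting artefacts of real exports, so
tests built on it certify the pipeline, not any particular material.
Where a measured volume distribution is unavailable, the test suite
constructs lognormal stand-ins matched to a preset's volume-weighted mean
and DLS polydispersity index via $\ln\sigma_g = \sqrt{\ln(1+\mathrm{PdI})}$
(the exact cumulant relation for a lognormal); these are synthetic and
labelled as such.

## Defaults worth knowing

| Parameter | Default | Why |
|---|---|---|
| medium density / viscosity | 1.005 g cm⁻³ / 0.955 mPa s | water-like culture medium at 22 °C; an assumption — measure and override when known |
| temperature | 295.15 K (22 °C) | bench-top exposure; use 310.15 K for incubator conditions |
| mean free path λ | 2.5 × 10⁻¹⁰ m | water; only enters the slip correction |
| compartment height | 5 µm | verified grid-independent at and below this value |
| time step | 1 s | capped automatically; verified equivalent to 0.1 s |
| bottom slice | 10 µm | conventional cell-microenvironment thickness; must be a multiple of h |
| boundary | reflective | appropriate for weak non-specific particle–cell binding |
| slip correction | on | negligible above ~100 nm but costless |

Configuration files (JSON; see `?load_config`) accept these in
conventional units (mg ml⁻¹, nm, g cm⁻³, mPa s, °C, mm, µm, h) and
convert internally to strict SI.  Unknown keys are rejected rather than
ignored, so typos fail loudly.

## Known limitations

* No dynamic re-agglomeration or cross-species coupling; size
  distributions are fixed except for dissolution shrinkage.
* Effective density is a single value per suspension, not a distribution.
* The Langmuir boundary has no explicit kinetics (instantaneous
  equilibrium each step) and saturates at monolayer coverage; desorption
  dynamics and multilayer binding are not modelled.
* The dissolved phase is one well-mixed pool; dissolved-species gradients
  and speciation are out of scope.
* Gravity only — no centrifugal fields, convection or evaporation-driven
  flows.
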