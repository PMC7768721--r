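---
title: "Modelling anammox in the nitrate-ammonium transition zone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling anammox in the nitrate-ammonium transition zone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In deep-sea sediments, nitrate produced in the oxic surface layer diffuses
downward while ammonium released from organic-matter degradation in deep
anoxic layers diffuses upward. Where the two meet — the nitrate-ammonium
transition zone (NATZ) — both disappear, and the prime suspect is anaerobic
ammonium oxidation (anammox). `natzamx` provides the complete computational
chain for studying this zone quantitatively: a steady-state diagenetic
reaction-transport model that predicts the anammox rate profile, in-situ
Gibbs-energy and power-supply profiles, cell-level energetic conversions,
multi-site porewater profile analytics, and a genome-coverage replication
index for asking whether the resident anammox population is actively
growing. Because cruise data are not redistributable, a first-class
synthetic-data module generates every input the chain consumes, always
alongside the generating truth, so that every estimator in the package can
be exercised as a recovery problem.

## The reaction-transport model

Seven species are modelled on a one-dimensional finite-volume grid: five
porewater solutes (O2, NO3-, NH4+, Mn2+, DIC, in uM) and two solids (TOC in
wt% dry sediment, MnO2 in umol per g dry sediment). At steady state,

* solutes: `0 = d/dz(phi Ds dC/dz) - d/dz(phi u C) + sum(nu R)`
* solids:  `0 = d/dz((1-phi) Db dS/dz) - d/dz((1-phi) w S) + sum(nu R)`

with depth `z` positive downward from the sediment-water interface and all
fluxes positive downward. Porosity follows an exponential compaction
profile; the solute advection velocity `u` is set equal to the burial
velocity `w` (constant-compaction simplification — at `w` = 2 cm/ky
advection is negligible against diffusion on a 3-m core, so nothing hinges
on this). Sediment diffusivities use the Boudreau tortuosity relation
`Ds = D0 / (1 - 2 ln phi)`, the standard closure for muds. Bioturbation
mixes solids at a constant `Db` in the top 10 cm and is zero below;
solute irrigation is not modelled.

### Reactions and kinetics

Two primary organic-matter degradation pathways and one further in the
classic redox cascade, plus three secondary redox reactions:

| # | reaction | rate law |
|---|----------|----------|
| R1 | aerobic degradation | `k_TOC * C_TOC * [O2]/(K_O2+[O2])` |
| R2 | denitrification | `k_TOC * C_TOC * [NO3]/(K_NO3+[NO3]) * i(O2)` |
| R3 | MnO2 reduction | `k_TOC * C_TOC * MnO2/(K_MnO2+MnO2) * i(O2) * i(NO3)` |
| R4 | nitrification | `k_nit * [O2] * [NH4]` |
| R5 | Mn(II) oxidation | `k_mnox * [O2] * [Mn2+]` |
| R6 | anammox | `k_amx * [NH4] * [NO3] * i(O2)` |

where `i(X) = Kin_X/(Kin_X + [X])` is hyperbolic inhibition. These Monod /
bimolecular forms are standard diagenetic closures; every constant is
config-exposed so alternative values can be dropped in verbatim. Organic
matter carries `r_NC` = 16/106 mol N per mol C, released as NH4+ by R1-R3.
Solid pools are converted to bulk units through the dry density
(`rho_dry` = 2.5 g/cm3) and the solid volume fraction before rates are
formed; N and Mn atom conservation of the stoichiometry matrix is asserted
at network construction.

Anammox deserves a note. Its canonical form oxidises ammonium with
*nitrite* (NH4+ + NO2- -> N2 + 2H2O), and that form is retained for
thermodynamic calculations. But porewater nitrite is typically
undetectable in these sediments, so the transport model uses the
electron-balanced overall coupling with nitrate (5 NH4+ + 3 NO3- ->
4 N2 + 9 H2O + 2 H+) with nitrite as an implicit steady-state
intermediate. Both stoichiometries are available from
`anammox_stoichiometry()`.

### Default study conditions

The defaults were chosen once to reproduce the canonical deep-sea core
structure — oxygen depletion between 0.4 and 1.2 m below seafloor, nitrate
depletion just below it, manganese build-up underneath, and a deep ammonium
source — at Arctic mid-ocean-ridge-like conditions (2 degC, 250 bar,
`w` = 2 cm/ky, 3-m core):

* boundary values: O2 300 uM, NO3 20 uM, DIC 2300 uM, NH4 and Mn2+ 0 at
  the top; NH4 300 uM at depth (the deep source); TOC 1.5 wt% and MnO2
  0.5 umol/g at the interface; zero-gradient elsewhere.
* kinetics: `k_TOC` = 2e-5 /yr (slow subsurface organic matter),
  half-saturation constants of a few uM, bimolecular constants of order
  1 /uM/yr.

With these, oxygen vanishes near 90 cm and the model confines anammox to a
band of a few tens of centimetres around the nitrate depletion depth — the
NATZ. The defaults are conditions, not tuning knobs: tests treat them as
fixed and ask whether estimators recover what the generator put in.

### Numerics

The discretisation is finite-volume on a uniform grid (default n = 200
cells; tests and the acceptance script use 100-150 cells, which the
grid-convergence checks show is well inside the asymptotic regime).
Dirichlet boundaries enter through half-cell ghost fluxes, zero-gradient
through mirrored ghosts, fixed-flux by direct face substitution; advection
is upwinded. The coupled nonlinear system (7 x n unknowns) is solved by
damped Newton iteration with a finite-difference Jacobian built by column
colouring (21 residual evaluations, banded sparsity) and a sparse direct
solve. The damping factor is halved while the residual norm fails to
decrease; if no step is accepted, a pseudo-transient continuation term is
added and its time step grows geometrically as the iteration stabilises.
Convergence requires the residual 2-norm to fall below 1e-10 relative to
the initial residual (with a 1e-11 umol/cm2/yr absolute floor so
warm-started solves terminate). Negative iterates are clipped to zero; the
solve *fails* if clipped mass at convergence exceeds 1e-6 uM-equivalent.
Verification: the solver reproduces the linear (no-reaction) and parabolic
(zero-order consumption) closed forms to well under 0.1% node-wise and
shows clean second-order grid convergence; every species closes its
boundary-flux/integrated-reaction balance to much better than 0.5%.

## Energetics

The in-situ Gibbs energy is `dGr = dG0r(T, P) + RT ln Q`. Standard-state
formation energies and enthalpies (25 degC, 1 bar) ship as an editable
packaged table; `dG0r` is corrected to in-situ temperature with the
integrated van 't Hoff relation (reaction enthalpy assumed
temperature-independent over the 0-25 degC range) and optionally to
pressure through a user-supplied reaction volume (default 0). Activities
come from molar concentrations via Davies coefficients at seawater ionic
strength (I = 0.7 mol/kg) by default; a unit-activity mode exists for
oracle tests, and the two coincide at I = 0. Porewater N2 was not
measured, so dissolved N2 defaults to a configurable 500 uM ambient value.
Non-positive concentrations are floored at 0.001 uM (logged) so that
below-detection values remain evaluable.

Power supply is the product of the volumetric anammox rate and |dGr|
(1 umol/cm3/yr at -100 kJ/mol is 0.1 J/cm3/yr). Cell-specific rates divide
the bulk rate by cell abundance (cells/g converted through
`rho_dry * (1 - phi)`), and the proton-pumping conversion uses `n_H` = 4
protons per NH4+ — the unique integer factor consistent with both printed
bounds of the cell-specific rate range (1e-3 and 1e-1 fmol NH4+/cell/d
map to roughly 28 and 2,800 protons/cell/s). `n_H` is exposed as a
parameter and should be treated as a stand-in for an explicit
proton-translocation stoichiometry.

## Profile analysis conventions

Compiled literature profiles are heterogeneous, so the operational
definitions are deliberately simple and configurable:

* **QC**: a profile is discarded if it has fewer than 6 nitrate datapoints
  or never reaches nitrate depletion.
* **Depletion/detection threshold**: 2 uM for both NO3- and NH4+, near
  typical porewater detection limits. Crossings are linearly interpolated
  between bracketing samples; ties take the shallowest qualifying
  crossing.
* **NATZ interval**: spans the nitrate depletion depth and the shallowest
  extent of detectable ammonium; a zero-thickness interval is legal.
* **Fluxes**: Fick's first law with the gradient from least squares over
  the 3 samples nearest the interval edge on the chosen side (3 is the
  minimum leaving a regression residual; configurable). On densely sampled
  noiseless forward-model cores these estimates agree with the model's
  internal face fluxes to within the ~20% expected of a finite gradient
  window.
* **Efflux**: a site loses ammonium upward if any NH4+ measurement above
  the interval exceeds the threshold — measurement-based rather than
  flux-based, because sparse profiles rarely support a reliable
  upper-zone gradient. Sites with no measurements above the zone are
  reported indeterminate rather than guessed.
* Missing porosity defaults to 0.8 with a logged note.

## The replication index

iRep exploits bidirectional replication of circular bacterial chromosomes:
in a replicating population, coverage is highest at the origin and lowest
at the terminus. Sorting per-window coverages (5-kb windows, 100-bp step)
from highest to lowest and regressing log2 coverage on rank fraction
recovers the origin:terminus ratio as `2^|slope|` without locating the
origin. The top and bottom 5% of windows are trimmed against mapping
artifacts; the rank fraction is kept on the *full* sorted set and trimmed
points are merely excluded from the fit — renormalising the abscissa would
shrink the slope by (1 - 2 x trim) and bias a true 2.0 down to ~1.87. No
GC correction is applied. Estimates are attempted only for genomes passing
the quality gates (completeness > 75%, mean coverage > 5x, <= 175
scaffolds/Mbp, scaffolds < 5 kb dropped first, all bounds strict). The
two-copy interpretation (`replicating_fraction()`: iRep - 1, as a percent)
is kept separate from the estimator so other replication models can be
substituted. iRep is a snapshot of the replicating fraction; it cannot be
converted to a growth rate.

## Synthetic data: what it does and does not emulate

`make_core()` runs the forward model and samples it at Rhizon-style depths
(5-cm spacing in the upper half metre, 25-cm below) with independent
Gaussian noise (default 1-2 uM for nutrients, clipped at zero).
`make_abundance_profile()` puts a log-scale Gaussian bump (default 1e4
over background, the four-orders-of-magnitude enrichment seen in these
zones) with 0.3-log10-unit lognormal noise. `make_site_collection()` draws
efflux/no-efflux site labels as Bernoulli trials and builds fast
piecewise-linear profile templates with transition depths log-uniform over
1.3-460 cm and water depths over 900-5,200 m, deliberately including
sites below the QC point-count gate. `make_coverage()` lays a log-linear
bidirectional coverage gradient over a scaffolded genome with optional
Poisson sampling of window depths. Every generator takes a seed, uses a
private RNG stream, and emits its truth object; recovery tests compare
against emitted truth only.

What passing recovery tests on these fixtures shows is that the
*estimators are correct under their stated error models*. Real porewater
profiles have correlated errors, irregular sampling, bioirrigation
artefacts and species the model omits (sulfate, iron, pH effects); real
coverage tracks have GC bias and mapping structure the Poisson model does
not capture. Agreement on synthetic data is necessary, not sufficient,
for trusting results on field data.

## Identifiability of the anammox rate constant

`fit_k_amx()` calibrates the anammox constant by 1-D least squares
(golden-section on log10 k, warm-started re-solves). On noiseless
synthetic cores it recovers the generating value to well under 1%. With
realistic 2-uM noise, however, the NATZ is *transport-limited*: the
ammonium and nitrate fluxes into the zone — not the kinetics — set the
consumption, so `k_amx` mainly sharpens the overlap rather than moving
concentrations. A local sensitivity analysis puts the achievable standard
error of ln k at roughly 0.1-0.2 even with 2-cm sampling of a 3-m core,
so single-core noisy recoveries scatter by tens of percent (median ~10%,
occasional seeds worse) and only aggregate accuracy should be expected.
This mirrors the field situation: rate *profiles* are well constrained by
the data, rate *constants* are not.

## Known limitations

* Steady state only; no transient simulation.
* No sulfate/methane/iron chemistry, no pH or alkalinity speciation, no
  bioirrigation, and microbial biomass is not coupled back into the model.
* The thermodynamic module is a constants-table + van 't Hoff
  approximation, not a full speciation engine; pressure corrections
  require a user-supplied reaction volume.
* The kinetic rate forms and all default constants are declared stand-ins
  for site-specific calibrations and should be replaced by measured
  values where available.
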