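---
title: "Modelling the nitrate-ammonium transition zone: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the nitrate-ammonium transition zone: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(natzone)
```

This vignette documents the scientific model behind `natzone`, the numerical
choices it makes, and the reasoning behind the design decisions that were
genuinely open. It is the place to look before trusting the package on real
cores.

## The diagenetic model

The package solves the steady-state early-diagenesis balance for dissolved
O2, NO3- and NH4+ in a one-dimensional sediment column, depth `z` in meters
below the sediment-water interface, positive downward:

$$\frac{d}{dz}\left[\varphi D_s \frac{dC}{dz} - \varphi w C\right] + \varphi\, S(C, z) = 0$$

* **Porosity** follows the standard compaction law
  $\varphi(z) = \varphi_\infty + (\varphi_0-\varphi_\infty)e^{-z/\lambda}$,
  defaulting to a constant 0.75 — a typical deep-sea mud value. Constant
  porosity is the default because depth-resolved porosity is rarely reported
  alongside the profiles this package consumes; the exponential mode is there
  for when it is.
* **Tortuosity** reduces free-solution diffusivities via Boudreau's relation
  $D_s = D_0/(1-\ln\varphi^2)$, the standard choice in marine diagenesis.
  Default $D_0$ values (0.037 m² yr⁻¹ for O2, 0.031 m² yr⁻¹ for NO3- and
  NH4+) are representative of cold (~2 °C) bottom water; temperature/salinity
  corrections are deliberately out of scope — users supply their own $D_0$.
* **Burial advection** `w` is constant with depth (default 1e-5 m yr⁻¹, a
  deep-sea ridge-flank magnitude). Compaction-coupled velocities are a
  second-order effect at these scales and are omitted.

### Reaction network

Organic-carbon mineralization is *prescribed*, not modelled:
$R_C(z) = R_0 e^{-z/z_{att}}$ (µM-C yr⁻¹). This is the minimal closure when
no solid-phase organic-matter data are available, which is the situation the
package is designed for. The aerobic fraction is set by a Monod factor in O2;
the denitrifying fraction by the complementary factor times Monod in NO3-
and O2 inhibition; any remainder is implicitly routed to pathways outside the
modelled state (sulfate reduction and deeper diagenesis), with no tracked
products. Nitrification is first order in NH4+ with Monod O2 dependence;
anammox is bimolecular in NH4+ and NO3- with O2 inhibition.

Anammox is written **lumped on nitrate** with the electron-balanced
stoichiometry 5 NH4+ + 3 NO3- → 4 N2. Explicit nitrite is omitted: porewater
nitrite is generally unmeasured in the profiles this analysis consumes, and a
lumped formulation keeps the state small while preserving the property the
analysis actually uses — that anammox requires both substrates, confining it
to the overlap zone. The N2 pool is a produced-nitrogen diagnostic only; the
stoichiometry makes fixed-N consumed equal N2-N produced identically, which
the tests verify per cell to machine precision.

### Default kinetic parameters

| parameter | default | units | why |
|---|---|---|---|
| `R0` | 900 | µM-C yr⁻¹ | with `z_att`, consumes the O2 inventory within decimeters |
| `z_att` | 0.09 | m | concentrates mineralization near the interface so nitrate survives to ~2 m |
| `r_NC` | 16/106 | — | Redfield composition |
| `k_nit` | 100 | yr⁻¹ | fast enough to keep surface NH4+ below the 1 µM detection threshold, slow enough to leave a measurable sub-µM oxic NH4+ signal (which is also what makes `k_nit` identifiable from profiles) |
| `k_amx` | 0.1 | µM⁻¹ yr⁻¹ | weak bimolecular kinetics spread the NH4+/NO3- overlap over decimeters, producing a transition zone of realistic width rather than a knife-edge reaction front |
| `K_O2`, `K_O2nit` | 8, 4 | µM | typical micromolar O2 affinities |
| `K_NO3` | 15 | µM | half-saturation of organotrophic nitrate reduction |
| `Ki_O2` | 0.3 | µM | anammox and denitrification shut off sharply with O2 |

These defaults are stand-ins chosen once to reproduce, at steady state, the
canonical pattern of a nitrate-ammonium transition around 2.2–2.3 m in a 4 m
column: oxygen depleted within ~0.4 m, nitrate penetrating to ~2 m beneath a
nitrification-fed maximum, ammonium rising from a deep source (fixed 50 µM at
the lower boundary), and a single anammox rate peak inside the detected zone.
They are the package's reference *scenario*, not site-specific constants, and
every one of them is overridable through the configuration file
(`inst/extdata/gs13cc2_like.yaml` ships the full document).

### Boundary conditions

Dirichlet at the interface (bottom-water values; 250 µM O2, 15 µM NO3-,
0 µM NH4+ by default). At the base: zero-gradient for O2 and NO3- (both are
consumed well above it) and a fixed concentration for NH4+, representing
upward supply from deeper diagenesis — the ingredient that creates the
transition zone in the first place.

## Numerics

* **Discretization** is cell-centered finite volume with harmonic averaging
  of $\varphi D_s$ at interfaces and first-order upwinding for advection;
  Dirichlet boundaries enter through half-cell ghost distances, and a
  zero-gradient bottom zeroes the diffusive interface flux while keeping the
  advective outflow. The scheme is conservative by construction, which is
  what makes the mass-balance acceptance checks meaningful. At the burial
  velocities relevant here the cell Péclet number is ≪ 1, so the first-order
  advection term does not limit accuracy; the observed convergence order on
  the reaction-diffusion oracle is ≈ 2.
* **Nonlinear solve**: damped Newton with an analytic transport Jacobian and
  a finite-difference local reaction Jacobian (one source evaluation per
  species), solved sparsely. Trial iterates are *projected* onto non-negative
  concentrations inside the step-halving line search — with hard rejection of
  negative iterates the iteration can deadlock when the converged state
  itself contains exact zeros (O2 below the oxic zone), whereas projection
  preserves the intent (iterates are never negative) and converges. Because
  projected Newton far from the solution can transiently raise the residual,
  up to eight consecutive non-monotone steps are allowed under a watchdog
  before the solver falls back to pseudo-transient continuation (implicit
  Euler, pseudo-time step doubled on success, quartered on failure, returning
  to Newton once the residual has dropped or the step has grown large).
* **Convergence** is declared at a relative residual of 1e-10, measured in
  the infinity norm against a fixed problem scale (the larger of the boundary
  forcing and initial source magnitudes), so the criterion does not depend on
  the iteration path. The initial iterate is the linear interpolation between
  boundary values (zero-gradient side uses the top value) — deterministic and
  reproducible. Budget exhaustion returns a diagnosed non-converged state
  rather than an error, and calibration treats such runs as a large finite
  penalty (1e12).
* **Default grid**: 400 uniform cells over 4 m (1 cm resolution), which
  resolves the decimeter-scale transition structure. Unit tests run the same
  scenario at 100–200 cells for speed; the acceptance checks use the full
  400.

## Zone detection and the confinement statistic

The transition zone is defined operationally: the bracket between the NO3-
penetration depth (deepest point at/above `eps_no3`, linearly interpolated at
the final down-crossing) and the NH4+ appearance depth (first up-crossing of
`eps_nh4`), with both thresholds defaulting to 1 µM — a typical porewater
detection limit. Published figures shade such zones without stating a rule;
this definition formalizes, not reproduces, that practice. When the fronts
interleave the zone is flagged `overlap`, otherwise `gap`. Profiles in which
either crossing does not exist are rejected as having no resolvable
transition — deliberately, since cores do exist whose geochemistry cannot
resolve the zone.

Confinement of a taxon is the in-zone fraction of its summed relative
abundance across sampled depths. The null model permutes the abundance
vector over depth labels — the plainest exchangeability assumption for
irregularly spaced samples (circular shifts assume a lattice). The p-value
uses the add-one estimator $(1+\#\{\text{perm} \ge \text{obs}\})/(n+1)$, so
it can never fall below $1/(n+1)$; with ≤ 7 depths all permutations are
enumerated exactly. Relative (not absolute) abundances are scored, matching
how such data are reported.

The "single interior maximum" property of the anammox rate profile is
checked at figure scale: local maxima below 10% of the global maximum are
not counted. A small secondary anammox shoulder below the oxic zone —
ammonium released by denitrifying mineralization being consumed in place —
is a structural feature of any prescribed-mineralization closure and sits
well below that threshold in the reference scenario.

## Calibration

The objective is plain weighted least squares over all species and
observation depths, with model values linearly interpolated from cell centers
(clamped at the column ends). Nothing in the intended use cases justifies a
full likelihood or priors. Optimization is bounded and derivative-free:
Brent's method for one free parameter, otherwise Nelder-Mead on transformed
coordinates (a sin² map onto the bounds, applied on the log scale when the
bounds are strictly positive), with three deterministic seeded restarts from
perturbed starts, since the forward map can be noisy near non-convergence.
Forward runs are warm-started from the best solution so far, which cuts
Newton iterations several-fold during a fit. Identifiability is the user's
responsibility: the tool caps free parameters at six and warns above three.

The recovery experiments used by the tests fit `k_amx` (noiseless) and
(`k_amx`, `k_nit`) (5% relative noise, 0.1 µM uncertainty floor) in a twin
study against the reference scenario. Their observation design samples the
upper 0.6 m at 2.5 cm and the rest of the column at 10 cm: the nitrification
signal lives in the oxic decimeters, and an observation design that does not
resolve that layer cannot constrain `k_nit` regardless of optimizer — this
mirrors real practice, where near-interface porewater is sampled at the
finest resolution.

## The synthetic-data generator

`generate_observed()` adds seeded Gaussian noise to interpolated model
profiles, truncated at zero; truncation (rather than resampling) introduces
a slight downward bias at near-zero concentrations, which is accepted and
documented. `generate_community()` places Gaussian depth niches
$\pi_t(z) = A_t e^{-(z-\mu_t)^2/2\sigma_t^2} + b_t$ on the depth axis in
relative-abundance units, gives the remainder to an explicit `other` taxon,
and draws a fixed number of reads per depth from a multinomial — the
compositional noise structure of amplicon data, with read depth the only
noise knob. The default community mimics three co-occurring anammox-like
families niched at the zone center (amplitudes of order 0.3–7% of reads) over
a 1% flat background taxon.

What the generator does *not* emulate, and what passing tests therefore do
not demonstrate on real data: bioturbation and irrigation (absent from the
transport model too), seasonality and transient events, nitrite dynamics,
OTU-level artifacts (chimeras, clustering, copy-number), spatial correlation
of sampling noise, and compositional coupling between taxa beyond the
shared-total constraint. Inference on real cores should treat the
permutation test as evidence about exchangeability of depth labels, nothing
more.

## Problem sizes and determinism

Unit tests run coarse grids (50–200 cells) and the acceptance checks the
reference 400-cell column; the permutation comparisons enumerate up to 7! =
5040 label orders and the Monte-Carlo side uses n = 999. All randomness —
observation noise, multinomial reads, optimizer restarts, permutations —
flows through explicit seeds via an isolated RNG scope, so no call disturbs
the user's `.Random.seed` and every pipeline rerun from the same config and
seeds is byte-identical, which the CLI tests assert literally.

## Known limitations

* The prescribed `R_C(z)` closure cannot respond to the oxidant field;
  scenarios with strong feedback between mineralization and electron
  acceptors need an explicit organic-matter state.
* Steady state only: the pseudo-transient machinery is an internal solver
  device, not a transient simulator.
* Multiple steady states exist in parts of parameter space (the oxygen
  penetration depth can be bistable); the deterministic linear initial
  iterate selects one branch reproducibly, but users exploring far from the
  reference scenario should vary initial iterates via `init`.
* The confinement test conditions on the detected zone; uncertainty in the
  zone boundaries themselves is not propagated.
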