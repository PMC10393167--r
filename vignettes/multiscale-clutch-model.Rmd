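---
title: "The multi-scale clutch model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The multi-scale clutch model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clutchms)
```

## The model

Integrin-based adhesion complexes (ACs) transmit the contractile force of the
actomyosin cytoskeleton to the extracellular matrix (ECM) through chains of
adhesion molecules: actin binds the talin rod, talin binds an integrin, and
the integrin engages a matrix ligand. The classical motor-clutch picture
treats each chain as a linear spring that stochastically engages and
disengages while myosin motors drag the actin rearward; it reproduces
cell-scale traction and retrograde-flow curves but badly misstates molecular
quantities (it predicts ~2 nm of chain stretch, while talin alone can extend
by hundreds of nanometres).

`clutchms` implements a molecularly resolved version of the clutch model.
Each of the `n_c` chains in a circular adhesion of radius `a` consists of:

* **Actomyosin**: retrograde flow follows the linear force-velocity relation
  `v = v_u (1 - F_sub / F_stall)`, with `F_stall = n_m F_m` the collective
  myosin stall force. The flow is clamped at zero; the model never produces
  anterograde motion.
* **Talin rod**: 13 elements (R1-R12 plus the R13-DD actin anchor). A folded
  element behaves as a freely-jointed chain segment of size `l0`; an unfolded
  element as a worm-like chain with persistence length `A` and contour
  length `L0`. Unfolding is Bell-type (`k_unf0 exp(F dx_unf / kBT)`),
  refolding Arrhenius (`k_ref0 exp(-F dx_ref / kBT)`). Vinculin binds the
  exposed R3 site at rate `k_onv` and blocks R3 refolding while bound.
* **Integrin**: a linear spring `kappa_c` in series with the talin rod, with
  catch-slip unbinding kinetics; the shipped presets cover the alpha5beta1
  and alphaVbeta3 laws. Binding of a free ligand occurs at `k_ont * d_int`,
  the association constant times the instantaneous integrin surface density.
* **Substrate**: a semi-infinite isotropic elastic half-space. The in-plane
  point-force Green's function gives a dense `n_c x n_c` compliance matrix
  over the ligand positions, so every bound chain deforms the substrate at
  every other ligand; the singular self term is evaluated 5 nm away from the
  binder along the pulling direction. All forces and displacements are
  projected onto a single in-plane pulling direction, as the stratified
  architecture of the AC justifies.

A bound chain that attached at time `t_b` must accommodate the actin
displacement accumulated since then, `D_b`. Compatibility of the series
chain reads

```
rod_extension(F_b) + F_b / kappa_c + [G F]_b = D_b,    F_b >= 0,
```

a coupled nonlinear complementarity system over all bound chains (chains
whose ligand has been pushed past them by their neighbours' substrate
deformation sit slack at zero force).

## Stochastic engine

Events - ligand binding, force-dependent unbinding, per-domain unfolding and
refolding, vinculin binding - are simulated with a Gillespie scheme:
candidate times `t_i = -ln(xi_i)/k_i` are drawn with rates frozen at the
current forces, the earliest event fires, the actin advances by `v tau`, and
the force balance is re-solved. Because the rates depend on forces that grow
continuously between events, the engine refreshes the frozen rates at least
every `rate_refresh_dt` (default 0.005 s, matching the classical model's
time step): if no event fires within the window the engine advances, re-
balances, and redraws, which is exact by the memorylessness of the
exponential. Without this refresh a quiescent-looking state (e.g. a single
freshly attached chain, all rates at their zero-force values) would wait for
tens of seconds while in reality force build-up accelerates its kinetics
within fractions of a second.

The per-event force balance is solved by an active-set Newton method with
the analytic chain Jacobian `diag(d rod_extension/dF + 1/kappa_c) + G`;
slack chains are excluded from the Newton subsystem (retaining them with
projection stalls the iteration through the elastic coupling). The residual
tolerance is 1e-6 (infinity norm) and the worst residual of a run is
reported in every summary. The WLC extension-force inversion reduces to a
cubic in `1 - x/L0` solved by a safeguarded Newton iteration; round-trip
errors are at machine precision.

Two statistics conventions are worth noting. `F_c_max`, `x_talin_max` and
`x_int_max` are run records (maximum over bound chains and time);
`*_tavg` columns are time averages of the instantaneous maximum over bound
chains. Rare-excursion quantities (the largest talin stretch ever seen)
live in the former; "typical peak loading" curves against stiffness live in
the latter.

## Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `a` | 708 | nm | adhesion radius |
| `d` | 100 | nm | ligand spacing; `n_c = ceil(pi a^2/d^2)` = 158 |
| `kappa_c` | 10 | pN/nm | integrin spring stiffness |
| `k_ont` | 0.005 / 1e-4 | um^2/s | association constant (alpha5beta1 / alphaVbeta3) |
| `d_int0` | 300 | int/um^2 | initial integrin density |
| `int_add`, `m_r` | 24, 15000 | int/um^2 | recruitment increment and cap |
| `k_onv` | 1e8 | 1/s | vinculin binding to exposed R3 (effectively instantaneous) |
| `F_m`, `n_m` | 2, `n_c` | pN, - | per-motor stall force; motor count |
| `v_u` | 110 | nm/s | unloaded retrograde-flow speed |
| `E` | 0.1-100 | kPa | substrate Young's modulus |
| `nu` | 0.5 | - | Poisson ratio (incompressible hydrogel; unstated in the source data, configurable) |
| `kBT` | 4.114 | pN nm | thermal energy (298 K) |

The catch-slip constants of the two presets are in `integrin_preset()`; the
alpha5beta1 values correspond to the reinforced (2-fold lifetime)
characterisation of that bond, and the three-term CMR law
(`cmr_off_rate()`) is available for the classical engine.

### Talin parameter file

The per-domain talin constants are not tabulated in the source literature
accessible to this package; the shipped file
(`inst/extdata/talin_domains.csv`) is the package's own calibration against
the well-established mechanical phenotype of the full-length talin rod:

* folded rod length ~65 nm (13 elements of `l0` = 5 nm);
* unfolded contour of the unfoldable part ~800 nm, so that a fully unfolded
  rod under ~20 pN extends ~600 nm;
* polypeptide persistence length `A` = 0.8 nm;
* equilibrium unfolding forces (where Bell unfolding and Arrhenius refolding
  rates cross) of 5 pN for R3 - the weakest, vinculin-activating domain -
  followed by R5, R6, R10, R11 around 8-10 pN and the remaining domains up
  to 17 pN, with rates of order 1/s at the crossover;
* two non-unfolding anchors (R9, the most mechanically stable bundle, and
  the terminal R13-DD element), leaving 11 unfoldable domains, which is the
  number of unfolding peaks a slow pulling ramp produces.

Every talin-dependent quantity below is conditional on these defaults; the
file is a documented interface and can be replaced wholesale.

### Motor counts

The mature-AC simulations use one motor per ligand (`n_m = n_c = 158`,
`F_stall = 316` pN), which reproduces plateau flow velocities of 50-60 nm/s.
For the single-chain experiment the contractility of the single actin
filament is not separately documented; the package uses `n_m = 20`
(`F_stall = 40` pN), half the often-quoted 40-motor figure for a mature
stress fibre. With it the single chain levels off near 20 pN within 8 s on
glass-like substrates, the expected mechanosensing range of a talin tether.

### Integrin recruitment

Vinculin binding to unfolded R3 signals integrin recruitment. The package
implements three rules (`recruitment` in `multiscale_config()`):

* `"tracked"` (default): the density excess above `d_int0` equals `int_add`
  times the number of currently bound vinculins - recruitment is sustained
  while the signal persists and decays when vinculin releases (vinculin lets
  go when its chain unbinds);
* `"event"`: every vinculin-binding event adds `int_add` irreversibly up to
  `m_r`. Under the reference conditions this rule is self-amplifying: more
  density means faster binding, more loaded chains, more R3 unfolding and
  hence more events, and the density saturates at `m_r` within a minute,
  driving the bound fraction towards ~95%, far from any reported
  quasi-static state. It is kept for completeness.
* `"none"`: binding stays at `k_ont d_int0`.

The default is `"tracked"`, which reproduces the published alphaVbeta3
steady states closely; see Limitations for the alpha5beta1 trade-off.

## The synthetic study conditions

The experiment drivers generate all data internally:

* `single_chain_run()` - one permanently bound talin-substrate chain (no
  integrin), 8 s, stiffness 0.1-100 kPa.
* `stiffness_sweep()` - full AC, both presets, 10 replicates per stiffness
  over 0.1-100 kPa, 100 s each.
* time traces at 2.51 kPa via `run_multiscale()`.
* `sensitivity_scan()` - factorial scan of one bond parameter (exponential
  ranges for the off-rate amplitudes, linear otherwise, `F_b` tying both
  branch force scales) against stiffness.
* `spacing_experiment()` - consumes a user-supplied (E, d, a) table, because
  adhesion size as a function of stiffness and ligand spacing is an
  experimental input, and simulates each geometry.

What the generator does *not* emulate: adhesion growth and disassembly (the
AC size is fixed or imposed), vinculin's own mechanics (it is a binding
flag), the 15-degree chain inclination (forces are in-plane 1-D), finite
substrate thickness, and any mechanotransductive signalling beyond density
recruitment. Passing tests therefore validate the clutch mechanics and
kinetics under these idealisations, not AC morphodynamics in real cells.

## Numerical choices

* Unit system: pN, nm, s internally; kPa at the interface
  (1 kPa = 1e-3 pN/nm^2) and Pa for tractions (1 pN/nm^2 = 1e6 Pa).
* Force-balance residual tolerance 1e-6 (infinity norm); Newton with
  analytic Jacobian, Cholesky factors cached across events while the active
  set is unchanged; backtracking damping on the residual norm.
* Bell exponents are capped at 500 before exponentiation: such rates fire
  within any representable time step, and capping avoids overflow at the
  WLC stiffening limit.
* A freshly bound chain attaches slack (`D = 0`, zero force); its folding
  state persists from any previous bound period and keeps evolving at
  zero-force rates while unbound. Unbinding zeroes force and stretch and
  releases vinculin.
* The classical engine uses exact exponential transition probabilities
  `1 - exp(-k dt)` rather than `k dt`, which matters for the ~900/s CMR
  off-rate at low force.
* Time averages cover the full trace including the start-up transient,
  except where a quantity is explicitly quasi-static (the package reports
  traces, so any window can be recomputed).
* Replicate conventions follow the standard 10-run averaging; single-E
  simulations of the reference adhesion take seconds to tens of seconds.

## Design decisions that were genuinely open

* **Lattice geometry.** "Equispaced ligands" fixes only the count rule
  `n_c = ceil(pi a^2 / d^2)` (which reproduces the printed 158 binders for
  a = 708 nm, d = 100 nm); the package places ligands on a square lattice of
  pitch `d`, ranked by distance from the centre, ties broken by angle.
* **Binding propensity.** `k_ont` (um^2/s) and `d_int` (int/um^2) only
  combine dimensionally as a product; `k_ont * d_int` per free ligand is the
  adopted reading.
* **Self-term offset.** The Green's-function self term is evaluated 5 nm
  from the binder along the pulling direction (the off-diagonal terms use
  the true inter-ligand vectors).
* **Gillespie bookkeeping.** Rates are frozen between events at
  current-force values; actin advances at the pre-event velocity within each
  interval; binding and vinculin events do not change the mechanical system,
  so re-balancing after them is deferred to the next mechanical event or
  staleness window (bounded by `rate_refresh_dt`).
* **Vinculin release.** The source description states binding, not release;
  the minimal consistent rule - release when the chain's integrin unbinds
  and the rod relaxes - is used.

## Limitations

* No single recruitment rule reproduces both presets' published bound
  fractions simultaneously: with `"tracked"` recruitment the alphaVbeta3
  engagement and traction match closely, but the alpha5beta1 bound fraction
  at high stiffness settles near 65-70% instead of ~49% (the value the
  model produces when density feedback is disabled). The discrepancy is
  documented rather than patched per-preset.
* The soft-substrate single-chain regime absorbs essentially the whole
  actin displacement into the substrate (~800 nm at 8 s at 0.1 kPa); a
  reported ~400 nm cap would require a substrate stiffer than the 5-nm
  offset Green self term provides at that modulus.
* Talin kinetics are the package's calibration (above); absolute unfolding
  statistics inherit that uncertainty even though the qualitative ordering
  (R3 first, then R5/R6/R10/R11) is robust.
* The adhesion's size never changes during a run; disassembly signalling,
  force-dependent area and integrin diffusion are out of scope.

## A worked example

```{r example, eval = FALSE}
library(clutchms)

cfg <- multiscale_config(integrin = "alphaVbeta3", E = 10)
res <- run_multiscale(cfg, seed = 1)
res$summary[, c("P_mean", "v_mean", "P_b_mean", "n_vinc_mean")]
# P_mean ~ 100 Pa, v_mean ~ 55 nm/s, P_b_mean ~ 0.17, ~15 vinculins

single <- single_chain_run(E = 100, seed = 3)
tail(single$trace[, c("t", "F", "x_talin_max")], 1)
# the chain force levels off near 20 pN with the rod extended ~600 nm
```
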