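---
title: "Methods: two-cell diazotrophic flux analysis and strain design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-cell diazotrophic flux analysis and strain design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diazoflux)
```

## The model

`diazoflux` works with stoichiometric models of filamentous
nitrogen-fixing cyanobacteria that resolve the filament's two cell
types as super-compartments.  Vegetative cells run photosystem II,
fix CO2 through RuBisCo, and export sucrose and glutamate; heterocysts
lack photosystem II, RuBisCo and GOGAT, fix N2 through nitrogenase at a
cost of 16 ATP and 8 low-potential electrons (equivalently 4 NAD(P)H)
per N2, and return glutamine and 2-oxoglutarate.  Every query reduces to
a linear program over the steady-state flux space `S v = 0`,
`lb <= v <= ub` (fluxes in mmol/gDW/h).

Assumptions inherited from this class of model: strict steady state, a
shared biomass composition for both cell types (the heterocyst biomass
reaction is a macromolecule-turnover proxy, never an objective), and
bound-level rather than kinetic regulation.

## The diazotrophic constraint set

`two_cell_config()` carries the simulation conditions; all defaults are
the package's standard diazotrophic condition:

| parameter | default | unit | rationale |
|---|---|---|---|
| `co2_uptake_ub` | 8.5 | mmol/gDW/h | minimum inorganic-carbon uptake that supports the experimental growth rate; carbon-limited simulation |
| `photon_ub_per_photosystem` | 100 | mmol/gDW/h | restricts photon-driven futile cycles without limiting biomass yield |
| `n2_uptake_ub` | 10 | mmol/gDW/h | non-limiting; caps the N2-fixation/ammonia-secretion cycle |
| `mu_exp` | 0.1824 | 1/h | `ln(2) / 3.8 h` doubling time |
| `heterocyst_biomass_lb_fraction` | 0.1 | – | turnover floor: heterocyst biomass >= 10% of `mu_exp` |
| `culture_o2_uptake` | 0.7 | mmol/gDW/h | air-saturated culture O2 uptake |
| `heterocyst_fraction` | 0.09 | – | heterocyst frequency in diazotrophic filaments (reported range 8–9%; 9% reproduces the 0.063 bound) |
| `couple_glu_gln` | `TRUE` | – | all glutamate entering the heterocyst leaves as glutamine |

The heterocyst O2 bound is `culture_o2_uptake x heterocyst_fraction =
0.063 mmol/gDW/h`.  The glutamate/glutamine coupling is implemented as a
massless pseudo-metabolite produced by the glutamate exchange and
consumed by the glutamine exchange, so the problem stays a pure
`S v = 0` LP and any LP code can solve it; whether the underlying
biology is a strict equality or only a directional constraint is not
settled, and the flag exposes the choice.  "CO2 uptake" and
"bicarbonate uptake" are treated as one inorganic-carbon bound.

## Solvers and numerical choices

No LP library is required: the package includes a two-phase
bounded-variable revised simplex (dense, product-form basis updates,
periodic refactorisation, deterministic Dantzig pricing with a Bland
anti-cycling fallback, and a conservative retry mode on numerical
breakdown).  Tolerances: 1e-9 pivot/feasibility inside the solver;
reported values are raw LP solutions.  FVA and pFBA re-fix the objective
at `(1 - 1e-9) x optimum` on its bound side rather than as a hard
equality, which avoids degenerate-optimum chatter.  pFBA minimises the
sum of absolute fluxes via a forward/reverse split (the alternative —
minimising over an irreversible-split network only — differs when
reversible reactions carry cancelling flux; the absolute-flux sum is the
implemented norm).  Thermodynamically infeasible loops are controlled
the same way the constraint set does everything else — finite photon
bounds — not by loopless FVA; `report_cycles()` flags loop-capable
reactions but never alters results.  Everything is deterministic: the
package contains no random number draws.

The MILP used by the strain-design search is a depth-first
branch-and-bound over binary selection variables on the same simplex.

## Heterocyst energy schemes

Scenarios edit bounds through a role-alias table
(`model$annotations$roles`), decoupling analysis code from any one
model's id dialect.  The shipped scenarios:

* `LETC_minus` — heterocyst photon uptake zero (no linear chain, no
  cyclic PSI).
* `OPPP_LETC` — G6P isomerase, phosphoketolases and GAP dehydrogenase
  blocked in the heterocyst: NADPH comes from the oxidative PPP, ATP
  from PSI.  A model whose lumping removes a role (e.g. no explicit
  phosphoketolase) declares it absent by mapping the role to an empty
  id set.
* `GLY_TCA_LETC` and its `_1`/`_2` variants — G6P dehydrogenase and
  phosphoketolases blocked; the variants additionally cap the
  2-oxoglutarate export or heterocyst CO2 evolution at the base
  variant's FVA minimum (complete vs incomplete oxidation).

For this analysis the heterocyst is assumed to have no macromolecular
turnover, so the biomass floor is released to zero
(`zero_heterocyst_turnover = TRUE`); the 10% floor applies everywhere
else.  Metrics per scheme: maximum growth, then FVA minima of
heterocyst sucrose uptake and CO2 evolution with growth fixed at that
maximum.  CO2 evolution is measured on the heterocyst CO2 release
transport, not the net balance.  The ATP:NAD(P)H ratio diagnostic
counts NADH and NADPH jointly (the model class does not distinguish
which pool nitrogenase reduction ultimately drains) and is computed
from metabolite turnover in a pFBA solution, so futile cycling cannot
inflate it.

## Strain design

The OptForce-style pipeline contrasts two flux spaces over the model
plus a production pathway:

1. **Wild type** — measured (13C-MFA-style) flux ranges imposed as
   bounds on the vegetative central carbon reactions, FVA propagating
   them everywhere else.
2. **Overproduction** — product secretion >= 90% of theoretical yield
   and vegetative biomass >= 10% of its maximum.  Theoretical yield is
   computed with the biomass floors released; the two floors are then
   imposed as independent constraints.

MUST sets use strict separation with tolerance 1e-6: a reaction whose
overproduction minimum exceeds the wild-type maximum must go up
(MUST_U), the mirror case must go down (MUST_L), and a reaction pinned
to zero while the wild type requires flux is a knockout candidate
(MUST_X, taking precedence over U/L so the sets stay disjoint).
Pairwise sets (UU/LL/UL/LU) apply the same rule to ranges of flux sums
and differences; the default pair universe is metabolite-sharing
enzymatic pairs, keeping the quadratic scan local (a full scan is
available by passing an explicit pair list).

Filtering applies, in order: removal of transport/exchange/demand/
spontaneous/biomass reactions; collapse of linear chains — reactions
connected by a metabolite with exactly one producer and one consumer,
with wild-type ranges equal up to a positive scalar — to their
upstream-most member; growth-coupled reactions out of MUST_L; essential
and very-low-flux (default `1e-3` mmol/gDW/h, configurable) reactions
out of MUST_X.

The FORCE search maximises the guaranteed (worst-case) product flux
over at most `k` interventions.  An upregulation forces
`v >= overproduction minimum`, a downregulation `v <= overproduction
maximum`, a knockout `v = 0`; in all cases the intervened reaction's
measured wild-type band is released (an engineered enzyme is no longer
described by the wild-type measurement — its other bound widens to the
overproduction-space value).  The bi-level program is collapsed to one
MILP containing (i) primal feasibility of the intervened wild-type
space, (ii) dual feasibility of its product-minimisation LP with
dual-times-binary products linearised by big-M (default 1000), and
(iii) a strong-duality row tying the product flux to the dual
objective.  Embedding the primal excludes selections whose inner
problem is infeasible, which a dual-only formulation would score at the
big-M ceiling.  Every incumbent is still verified against a direct
inner LP; alternative strategies are enumerated with integer cuts over
returned FORCE sets (so supersets of a reported set are not re-reported,
matching the usual rounds of re-running after removing found
candidates).  The alternative bi-level objective — minimising the
intervention count at a fixed production target — can be emulated by
scanning `k` upward until the guaranteed flux reaches the target; the
implemented objective maximises guaranteed flux at budget `k`.
`enumerate_force_sets()` provides the exhaustive oracle the test suite
compares against.

## The synthetic two-cell network

`make_toy_two_cell()` generates a 60-reaction, fully mass- and
charge-balanced two-cell network with the canonical topology: linear
(PSII) electron transport at 8 photons per 2 NADPH + 3 ATP + O2, cyclic
PSI at 2 photons per ATP, a lumped Calvin cycle (6 CO2 + 12 NADPH +
18 ATP per G6P), sucrose synthesis and shuttle, heterocyst glycolysis
(2 ATP + 2 NADPH per G6P), oxidative PPP (12 NADPH + 6 CO2 per G6P),
partial and complete TCA, O2-capped respiration, FNR making the
8 e- = 4 NAD(P)H equivalence a stoichiometric fact, nitrogenase,
glutamine synthetase, ethanol and H2 vents, an ATP-maintenance
dissipation reaction, and the four inter-cell exchanges.  Cofactors use
pseudo-element formulas (`AdpP`, `NadpH2`, `FdH`) so the balance
checker verifies every non-biomass reaction exactly.  Biomass takes
1.5 G6P + 2 pyruvate + 2.5 glutamate + 30 ATP per gDW (15 mmol C,
2.5 mmol N); the heterocyst copy takes its nitrogen directly as NH3,
which keeps the glutamate/glutamine coupling consistent with closed-form
optima.

The lumping is chosen so the headline results are closed-form
stoichiometric facts recorded in the manifest: maximum growth is the
carbon bound (`8.5 / 15` minus the turnover floor); nitrogenase's
minimum is half the nitrogen demand; and because the PPP yields
12 NADPH per G6P at 6 CO2 while the incomplete-oxidation route yields
4 NADPH per G6P at 1 CO2, the incomplete scheme needs exactly 3x the
sucrose and evolves exactly half the CO2 of the PPP scheme.  Two
manifest entries are not one-line closed forms — the dark-heterocyst
(`LETC_minus`) optimum, where the LP mixes oxidation routes across the
two separate photon caps, and the k = 2 valerolactam FORCE value — and
were frozen from independent verification (a second LP implementation
and the exhaustive enumeration oracle respectively); they are reported
as `NA` for non-default parameters.

The measured-flux fixture takes the pFBA solution's vegetative
central-carbon fluxes that are non-zero (Calvin, glycolysis, sucrose
synthesis) and brackets them at ±10%, the shape of ranges a 13C study
of a phototroph reports; fluxes below detection are left unconstrained
rather than pinned to zero, since a zero-width band would forbid every
intervention that reroutes carbon.  The packaged pathways (lysine to
valerolactam via the 5-aminovalerate route; succinate + acetyl to
caprolactam via the adipyl route) lump out CoA carriers, make lactam
cyclisation ATP-dependent, and conserve backbone carbon and nitrogen
exactly.

What the toy does not emulate: genome-scale redundancy (isozymes,
alternative carbon routes), realistic kinetic parameters, absolute flux
values of any real organism, thermodynamic constraints, and
transcriptional regulation.  Passing tests therefore demonstrate the
correctness of the algorithms on a network with the right topology and
energetics, not predictions about any particular strain.

## Content counting

Template-reaction counts collapse the `__vc`/`__hc` suffix; two
reactions count once when they share a template id, not when they merely
share stoichiometry (two distinct ids with identical chemistry would
count twice, which matches how reconstruction pipelines report content).
Reactions without a cell suffix (shared-external exchanges, inter-cell
transfers) are counted once and listed in the summary's `unsuffixed`
field.

## Known limitations

* The simplex is dense; models beyond a few thousand reactions would
  need a sparse factorised implementation.
* Pairwise MUST scans are quadratic in the candidate set; the
  metabolite-sharing default keeps this tractable but can miss couplings
  between distant reactions.
* Big-M duals (default 1000) assume inner-LP duals below that magnitude;
  the primal verification step guards against violations but a model
  with much larger flux scales should raise `big_m`.
* SBML support targets Level 3 + fbc version 2 flat models as written by
  this package and the common flux-bound conventions; exotic SBML
  constructs (species references with ids, initial assignments) are not
  interpreted.
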