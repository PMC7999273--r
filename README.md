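# diazoflux

Constraint-based analysis of two-cell diazotrophic cyanobacterial
metabolism in R.

Filamentous nitrogen-fixing cyanobacteria divide labour between two cell
types: photosynthetic **vegetative cells** fix CO2 and export sucrose and
glutamate, while micro-oxic **heterocysts** — which lack photosystem II,
RuBisCo and GOGAT — run nitrogenase and return glutamine (the nitrogen
carrier) and 2-oxoglutarate.  `diazoflux` is for modellers who want to
build and interrogate stoichiometric models of this division of labour:
it constructs two-super-compartment models from a single-cell template,
applies the standard diazotrophic constraint set, answers
flux-balance-style questions about heterocyst energetics, and searches
for overproduction strain designs.

## What it computes

All analyses operate on the steady-state flux space

```
S v = 0,   lb <= v <= ub
```

* **FBA / pFBA / FVA** — maximise biomass (or any objective), minimise
  total absolute flux at that optimum, and compute per-reaction flux
  ranges, on a built-in bounded-variable simplex solver (no external LP
  dependency).
* **Two-cell construction** — duplicate a template into `__vc`/`__hc`
  compartments with cell-specific deletions, the four inter-cell
  exchanges (sucrose, glutamate, glutamine, 2-oxoglutarate), and the
  glutamate/glutamine flux coupling implemented as a pseudo-metabolite
  balance row.  The shipped constraint set caps inorganic carbon uptake
  at 8.5 mmol/gDW/h, photons at 100 mmol/gDW/h per photosystem, N2 at
  10 mmol/gDW/h, heterocyst O2 at `0.7 x 0.09 = 0.063` mmol/gDW/h, and
  floors heterocyst biomass turnover at 10% of the growth rate
  `ln(2)/3.8 h = 0.1824 h^-1`.
* **Heterocyst energetics** — nitrogenase demands 16 ATP and 4 NAD(P)H
  (8 electrons) per N2, a 4:1 ratio.  Scenario machinery blocks
  light-driven electron transport or the G6P-metabolising routes in the
  heterocyst and reports each scheme's maximum growth and minimum
  sucrose uptake / CO2 evolution.
* **OptForce-style strain design** — wild-type vs overproduction flux
  spaces, single and pairwise MUST set identification, candidate
  filtering, and a bi-level intervention search (max over <= k
  bound-shift interventions of the worst-case product flux) collapsed to
  a single-level MILP via LP duality, with integer-cut enumeration of
  alternative FORCE sets.  Packaged production pathways convert lysine to
  valerolactam and succinate + acetyl units to caprolactam.

A deterministic synthetic two-cell network (60 reactions, built and
elementally balanced in code, with closed-form reference optima in its
manifest) makes every analysis testable without any external model file.

## Worked example

```r
library(diazoflux)

toy <- make_toy_two_cell()
model <- toy$model
model
#> metabolic_model: 60 reactions, 56 metabolites
#> objective: max biomass__vc
#> kinds: biomass=2, enzymatic=36, exchange=15, intercell-exchange=4, transport=3

fba(model)
#> flux_solution: optimal, objective = 0.5484267

fva(model, targets = c("suc_vc_hc_exch", "nitrogenase__hc"),
    fix_objective = TRUE)$ranges
#>          reaction       min       max
#> 1  suc_vc_hc_exch 0.1393356 0.9885233
#> 2 nitrogenase__hc 0.7083333 0.7083333

evaluate_scheme(model, "LETC_minus")
#> scheme LETC_minus      growth 0.212037  min suc 2.20222  min CO2 4.97639
```

The growth optimum 0.5484 1/h is the carbon bound: 8.5 mmol CO2/gDW/h
divided by 15 mmol biomass carbon, minus the heterocyst turnover floor.
At that optimum at least 0.139 mmol/gDW/h of sucrose must flow to the
heterocyst and nitrogenase is pinned at exactly half the biomass
nitrogen demand (2 NH3 per N2).  Switching the heterocyst's light
harvesting off (`LETC_minus`) drops growth to 0.212 1/h because ATP can
then only reach nitrogenase through sucrose catabolism.

Strain design, end to end:

```r
spec  <- make_pathway_fixtures()$five_aminovalerate
mp    <- add_production_pathway(model, spec)
wt    <- wild_type_flux_space(mp, make_mfa_fixture(model))
over  <- overproduction_flux_space(mp, spec$product_exchange)
must  <- filter_must_sets(identify_must_single(wt, over), mp)
solve_force_set(mp, must, spec$product_exchange, k = 2)[[1]]
#> intervention strategy (k = 2 ): guaranteed product flux 1.43713
#>    up glycolysis__vc level 1.0061
#>    up gogat__vc level 2.9496
```

Upregulating glycolysis and GOGAT guarantees 1.44 mmol/gDW/h of
valerolactam — the MILP answer equals exhaustive enumeration of every
intervention subset.

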