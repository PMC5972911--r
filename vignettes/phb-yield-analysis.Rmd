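---
title: "Theoretical P3HB yields in E. coli central metabolism, with and without non-oxidative glycolysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Theoretical P3HB yields with and without NOG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phbflux)
```

## The question the package answers

Poly-(3-hydroxybutyrate) is polymerized from (R)-3-hydroxybutyryl-CoA,
which costs two acetyl-CoA and one NADPH per C₄H₆O₂ monomer unit
(phaA: 2 acetyl-CoA → acetoacetyl-CoA; phaB: + NADPH → 3HB-CoA; phaC:
→ monomer + CoA). When acetyl-CoA comes from pyruvate dehydrogenase, one
CO₂ is released per acetyl unit, so at most 2 of every 3 substrate carbons
can reach the polymer. Phosphoketolases open a second route: they cleave
fructose 6-phosphate into erythrose 4-phosphate plus acetyl phosphate, or
xylulose 5-phosphate into glyceraldehyde 3-phosphate plus acetyl phosphate,
and with the non-oxidative pentose phosphate reactions and
fructose-1,6-bisphosphatase the leftover sugar phosphates recycle, so sugar
carbon reaches acetyl phosphate — and through phosphotransacetylase,
acetyl-CoA — without any decarboxylation. This is the non-oxidative
glycolysis (NOG) design.

`phbflux` asks, for glucose, xylose and glycerol as sole carbon sources:
what is the maximum P3HB monomer production rate, and hence carbon yield,
that stoichiometry allows, with and without the NOG knock-in? The answer is
a flux balance analysis (FBA): maximize the monomer drain flux subject to
steady state and reaction bounds.

## The curated model

The packaged model (`ecoli_phb_core()`, 61 metabolites, 66 reactions) covers
glucose PTS uptake; xylose proton symport, xylose isomerase and
xylulokinase; glycerol uptake by facilitated diffusion with both
assimilation routes (glycerol kinase plus the quinone-linked
glycerol-3-phosphate dehydrogenase, and glycerol dehydrogenase to
dihydroxyacetone with the PEP-dependent dihydroxyacetone kinase and
fructose-6-phosphate aldolase as entry points); Embden–Meyerhof glycolysis
with fructose-1,6-bisphosphatase; the full oxidative and non-oxidative
pentose phosphate pathway; pyruvate dehydrogenase; the TCA cycle with PEP
carboxylase; the acetyl-phosphate node (reversible phosphotransacetylase,
acetate kinase, an acetate exporter); the phaA/phaB/phaC pathway with a
monomer drain; a transhydrogenase; and respiration lumped into one reaction
per electron donor. Every metabolite carries an elemental formula and every
internal reaction balances for C, H, O, N, P and S
(`validate_elemental_balance()`), which is what makes the yield arithmetic
exact: at steady state the only carbon leaving the system flows through
exchange reactions, so substrate carbon in equals monomer carbon plus CO₂
out.

A genome-scale reconstruction would add thousands of reactions, but a
maximum-yield LP whose optimum uses only central carbon metabolism cannot
be changed by peripheral pathways that at best divert carbon; the desk-scale
model is the faithful unit of reproduction for these optima, and its
6 scenarios each solve in well under a second.

Scenario conventions: the substrate exchange is *fixed* — an equality, not
a bound — at 10 mmol gDCW⁻¹ h⁻¹, matching a stated consumption rate; other
carbon-source exchanges are closed to uptake; acetate may be secreted but
never imported; CO₂ is export-only; biomass formation and non-growth ATP
maintenance are zero, because the target is the pure stoichiometric
maximum. Yields are mole-carbon ratios with 4 carbons per monomer.

## Tunable parameters and the choices behind them

* **P/O ratios** (`build_ecoli_core(po_nadh = 2.5, po_quinol = 1.5)`):
  ATP per NADH or ubiquinol oxidized in the lumped respiratory reactions,
  the textbook aerobic values for *E. coli*-like chains. At the reported
  optima ATP is non-binding (see below), so moderate changes do not move
  the yields; the values are exposed because they are assumptions, not
  measurements.
* **ATP maintenance** (`atp_maintenance = 0`): theoretical maxima are
  computed without maintenance load. Setting it above the optimum's ATP
  slack would trade product for respiration.
* **Transhydrogenase**: modelled as an *uncoupled, reversible*
  NADH ⇌ NADPH lump. This is the one cofactor assumption the printed
  optima pin down (next section).
* **Transport energetics**: symport stoichiometry is carried (protons move
  with xylose) but not charged, because the model has no explicit
  proton-motive-force budget — respiration is lumped straight to ATP and
  periplasmic protons equilibrate freely. Uptake ATP costs therefore reduce
  to the kinase steps (xylulokinase, glycerol kinase).

## Why the optima come out where they do

With the substrate fixed at 10 mmol gDCW⁻¹ h⁻¹:

* **Baselines (66.7% everywhere).** Without phosphoketolase, acetyl-CoA is
  only reachable through pyruvate dehydrogenase, so every acetyl unit costs
  exactly one CO₂ regardless of how the sugar reaches pyruvate. That puts
  the same 2/3 ceiling on glucose (rate 10), xylose (rate 25/3 = 8.33) and
  glycerol (rate 5) — a uniform ceiling the test suite asserts explicitly.
* **NOG on sugars (88.9%).** NOG routes carbon losslessly, but each monomer
  still needs one NADPH. The two NADPH sources in the network — the
  oxidative PPP branch and glycolytic NADH (via GAPD plus PDH) shuttled
  through the transhydrogenase — both deliver at most 2 NADPH per CO₂
  released. Maximizing product under carbon balance
  (`n_C·10 = 4·v_PHB + v_CO2`) and NADPH balance (`v_PHB = 2·v_CO2`) gives
  `v_PHB = n_C·10·(2/9)`: 100/9 = 11.11 on xylose and 40/3 = 13.33 on
  glucose, i.e. 8/9 = 88.9% carbon yield. The glycolytic NADH route also
  produces 2 ATP per CO₂, which covers the xylulokinase cost with slack
  (11.1 ATP produced vs 10 consumed on xylose), so ATP does not bind.
* **NOG on glycerol (100%).** Glycerol is more reduced than the monomer, so
  NADPH needs no carbon sacrifice: glycerol dehydrogenase yields one NADH
  per glycerol with no CO₂, fructose-6-phosphate aldolase condenses the
  resulting dihydroxyacetone with G3P into F6P at zero ATP, and the NOG
  cycle converts F6P to acetyl phosphate. 7.5 of the 10 NADH become NADPH
  through the transhydrogenase; the excess 2.5 respire. Nothing costs ATP
  on this route, so the full 7.5 mmol gDCW⁻¹ h⁻¹ (100%) is attainable.

Two model-design constraints fall out of requiring this last optimum, and
are deliberate choices rather than claims about any particular published
reconstruction. First, the transhydrogenase must be uncoupled: with strict
proton-coupled PntAB stoichiometry (and respiration lumped to ATP), NADPH
formation would carry an energy price the glycerol budget cannot pay —
glycerol kinase alone costs 10 ATP against at most 6.25 ATP from the excess
electrons, and the PEP-dependent dihydroxyacetone kinase route costs even
more through PEP synthase. Second, for the same reason the model includes
fructose-6-phosphate aldolase (fsaA, a native *E. coli* enzyme present in
genome-scale reconstructions) as the ATP-neutral entry for
dihydroxyacetone; without it the 100% glycerol optimum is infeasible and
the LP falls to a lower yield. Both choices are recorded in the packaged
model's metadata and subsystem tags.

## Numerical design

The LP backend (`R/lp.R`) is a bounded-variable two-phase primal simplex:
variables keep their natural bounds (no splitting), redundant steady-state
rows — inevitable, since conserved cofactor moieties make the
stoichiometric matrix rank-deficient — are absorbed by artificial variables
that simply stay basic at zero, entering variables follow the
most-negative reduced cost with a switch to Bland's smallest-index rule
after a degeneracy budget (termination guarantee), basic values are
refreshed from the factorization every iteration to suppress drift, and
feasibility/reduced-cost tolerances are 1e-9. Infinite bounds are capped at
1e6 internally; an optimum pinned to such a cap is reported as status
`"unbounded"`, never as a number, and an inconsistent fixed uptake is
reported `"infeasible"`. Every optimal solution is re-checked against
steady state before being returned.

Two independent checks guard the backend. `oracle_max_flux()` enumerates
all vertices of the flux polytope (every choice of rank(S) basic reactions
with the rest pinned to bounds) — exponential, so guarded to fixture-sized
models — and must agree with the simplex to 1e-6. `generate_planted_network()`
builds randomized networks whose optimum is known by construction: a chain
with one bottleneck bound, plus decoy reactions that provably cannot raise
the max flow (edges that do not cross the bottleneck cut forward, and
reversible dead-end links whose steady-state flux is zero). The test suite
runs LP vs oracle vs planted value across 50 seeds.

Reported numbers are rounded only in the reporting layer: rates to two
decimals, percentages to one, and experimental percent increases are
computed from two-decimal yields, which is the precision at which such
yields are quoted.

## What the synthetic fixtures do and do not show

The generated networks exercise the solver — feasibility, optimality,
degeneracy, determinism — on problems with known answers. They are
deliberately cofactor-free (single-carbon species, 1:1 conversions), so
passing them says nothing about the biology of the curated model; that is
carried by the elemental-balance validation, the analytic yield ceilings
above, and the flux-level assertions (CO₂ release equals the pyruvate
dehydrogenase flux at the baseline optimum; zero CO₂ at the glycerol NOG
optimum; zero acetate secretion at every optimum).

## Experimental yield arithmetic

`experimental_carbon_yield()` converts a P3HB titer and consumed substrate
masses to the same mole-carbon yield basis, using the repeat-unit mass
86.09 g/mol (C₄H₆O₂) — not the free acid — because polymerized monomer is
what is weighed. The calculator takes *consumed* amounts: initial loadings
equal consumption only when the culture exhausts the substrate, which holds
for the packaged 10 g/L glycerol example but cannot be assumed in general.
Mixed-sugar shake-flask yields reported per total loading are therefore out
of reach of this arithmetic when residual substrate is unreported; the
package records such numbers as data entries (e.g. inputs to
`relative_yield_increase()`) and never derives them.

## Known limitations

* Stoichiometry and bounds only: no thermodynamics, no kinetics, no
  regulation — the optima are ceilings, not predictions of titer.
* Alternate optima are intrinsic to FBA; `flux_report()` flags non-unique
  fluxes via flux variability analysis rather than presenting one witness
  as *the* flux distribution.
* The proton-motive force is not modelled explicitly; transport energetics
  beyond kinase ATP costs are absorbed into the lumped respiration, which
  is also why the transhydrogenase appears uncoupled.
* Growth is fixed to zero; coupling production to biomass formation would
  need a biomass objective this model deliberately omits.
* Dual-substrate (glucose + xylose co-utilization) scenarios are not
  modelled; only sole carbon sources are.
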