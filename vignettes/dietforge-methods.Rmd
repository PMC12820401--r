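---
title: "dietforge: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dietforge: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietforge)
```

`dietforge` turns food items into metabolite-resolved *in silico* diets and
applies them to constraint-based metabolic models. This vignette explains the
underlying models and conventions, the tunable parameters, the numerical
choices, and the limits of what the synthetic fixtures can demonstrate.

## From food composition to mmol

Food-composition databases report nutrients per 100 g of food, mostly as
masses. For a stoichiometric model these must become molar amounts:

$$\text{mmol}/100\,\mathrm{g} \;=\; \frac{\text{mass}_{\mathrm g}}{MW}\times 1000 .$$

`load_food_table()` harmonizes mass units (mg → /10³, µg → /10⁶ g) and energy
(kJ → kcal via the thermochemical factor 4.184) before conversion. The
nutrient-name → metabolite-id map and the molecular-weight table ship as
editable plain-text config (`inst/extdata/`); users can override both, so no
external identifier service is required. Three deliberate policies:

* **Strict unit whitelist** ({g, mg, µg} for masses, {kcal, kJ} for energy).
  Anything else is a logged per-row error, never a silent drop — unit mix-ups
  are the classic failure mode of nutrition data.
* **Metabolites without a molecular weight** are excluded from mmol conversion
  with a log entry rather than failing the load.
* **Duplicated (origin, id, nutrient) rows** keep the first value and log the
  rest.

Records store database-reported macronutrients *and* the per-metabolite
amounts separately; metabolite-derived macronutrient masses are always
recomputed from the metabolites alone, so the two views never double-count.

## Matching dietary food items

A dietary food item is described by single-word keywords (most descriptive
first), a reference weight, and a partial macronutrient profile.
Keyword search is case-insensitive substring matching on record descriptions
with punctuation flattened to spaces; there is deliberately no stemming or
fuzzy matching, which keeps results deterministic and language-agnostic.
Two strategies exist:

* **cumulative** — a record must contain *every* keyword (a global AND);
* **sequential** — keywords filter the survivor set in order; a keyword that
  would empty the set is skipped and logged. The sequential semantics are our
  codification of the "first keyword is the most descriptive" guidance; the
  narrowing-with-skip rule is a documented interpretation.

Items with no hits, or with more hits than the threshold (default **50**),
are diverted to refinement reports instead of being scored.

Candidates are ranked by the **Euclidean distance** between the user's macros
(rescaled to per-100 g by ×100/reference-weight) and the record's per-100 g
macros, over exactly the fields the user supplied, drawn from
{energy, lipid, protein, sugars, fibre, starch}. Total carbohydrate never
enters the distance: databases and food labels disagree on whether fibre is
included, so the components are compared instead. kcal and grams are mixed
unscaled — the distance is the plain Euclidean norm; a per-field
standardization switch would be easy to add but is off because the plain norm
is the established behaviour. A supplied field missing from the record counts
as 0 and is flagged, keeping all candidates comparable. Ties break by mean
metabolite coverage (descending), then food id.

**Coverage** is reported per macronutrient group:
100 × (metabolite-derived mass)/(reported mass). It can exceed 100 % when
measured metabolites outweigh the reported macro, and is "n/a" where the
record reports no macro. Coverage matters because a database food equivalent
with slightly worse macro distance but much better metabolite coverage often
yields a more informative diet.

### Macronutrient group vocabulary

Throughout the package the groups are
{protein, lipid, carbohydrate, fibre, alcohol, other}: carbohydrate covers
sugars and starch; fibre stays separate because its energy factor differs
(2 kcal/g vs 4); alcohol (7 kcal/g) likewise. Where a record reports no total
carbohydrate, sugars + starch stand in, consistently in coverage, diet
analytics, and the optimizer.

## Compiling in silico diets

`build_diet()` is a linear map: per food, per-100 g amounts are divided by
100, multiplied by the consumed grams, and summed —
mmol/day/person for metabolites, g/day for macros. Zero-gram rows contribute
nothing, and negative grams are rejected outright. Energy fractions use
Atwater-style factors (carbohydrate 4, protein 4, lipid 9, fibre 2, alcohol
7 kcal/g; overridable) and are computed twice, from database-reported and
from metabolite-derived masses — the gap between the two series is exactly
the part of the diet not covered by measured metabolites.

## Applying diets to models

Sign convention: exchange flux **negative = consumption**. A diet providing
`flux` mmol/day of a metabolite becomes bounds `(−flux, −e·flux)` on its diet
exchange, with the enforce-fraction `e` defaulting to 0 (uptake is a
*capacity*, not an obligation; `e = 1` forces full uptake for scenarios that
need it). Dietary metabolites without a matching exchange are skipped with a
warning — diets routinely contain more species than any one model.

The **food-item-constrained** formulation adds, per database food equivalent:
an exchange over a food pseudo-metabolite in compartment `[f]` (flux in
g/day), and a breakdown reaction converting 1 g of the food into its
constituent metabolites (per-100 g values /100) plus macronutrient
pseudo-metabolites (energy, lipid, …) in `[d]`. Each pseudo-metabolite gets a
single removal-only sink, so these bookkeeping species are structurally
incapable of changing any optimum — a property the test suite checks both
structurally and numerically: over random diets, FBA optima under
metabolite bounds and under fixed food grams agree to < 1e-6. Breakdown
products unknown to the model are added together with an overflow sink so
forced consumption cannot create dead ends; whole-body models have fecal
excretion for the same role.

**Feasibility** means the maintenance objective reaches a required value
(default 1, the whole-body convention; configurable). `restore_feasibility()`
repairs diets missing essential metabolites greedily: in candidate order,
uptake is opened by a configurable increment and the model re-solved, up to
`max_rounds` passes. The candidate list and increments are explicit inputs —
the toy default covers the fixture's planted vitamin — and repairs only ever
*relax* bounds, never tighten them, so the repaired diet dominates the
original. The greedy order-dependent rule is a documented choice; increment
size and ordering are user-visible rather than hard-coded.

## The diet optimizer

"Smallest dietary change achieving the best possible shift in a target flux"
is formalized as a two-stage lexicographic LP over change variables
`add_i ∈ [0, budget]`, `rem_i ∈ [0, current_i]` per candidate item:

1. **Stage 1** maximizes `Σ weight·(±target flux)` subject to steady state,
   model bounds, the planned availability `current + add − rem` on each
   candidate's exchange, gram budgets `Σ add ≤ max_added`,
   `Σ rem ≤ max_removed` (or one shared budget), an optional caloric band,
   and optional per-group macronutrient tolerances.
2. **Stage 2** constrains the stage-1 objective to at least `f` of its
   optimum (`f` defaults to 0.999) and minimizes the L1 change
   `Σ(add + rem)`.

The L1 magnitude admits fractional foods and keeps the problem a pure LP; a
cardinality-constrained (integer) mode is a deliberate non-feature. At food
level the coupling between consumption and plan is an *equality* — the
planned diet is eaten in full, with overflow leaving through the
excretion/sink routes — so the caloric band and macro tolerances, expressed
on the macronutrient sink fluxes, constrain exactly the planned diet's
composition. At metabolite level amounts are mmol, budgets are converted to
grams via molecular weights (so a "200 g" idiom applies uniformly), and the
caloric/macro constraints are linear expressions in the planned changes
using the energy factors. Infeasible constraint combinations are diagnosed
by re-solving without each optional constraint family and reporting the
first whose removal restores feasibility.

Properties verified on every solve and in tests: achieved ≥ f × stage-1
optimum; enlarging a budget never worsens the stage-1 optimum; zero budgets
reproduce the baseline flux; with a single candidate the plan agrees with a
0.1 g-grid brute-force search; and metabolite- and food-level runs coincide
for a food that is 100 % one metabolite.

## Linear programming

No dedicated LP package is part of this package's dependency footprint, and
steady-state flux problems are heavily degenerate (many equality rows with
zero right-hand side), which defeats naive pivoting rules. `dietforge`
therefore carries a small dense **two-phase primal simplex with Bland's
anti-cycling rule**. Variables fixed by `lb = ub` are eliminated before the
solve; remaining variables are shifted to `x ≥ 0`; every general row becomes
an equality with an explicit slack; redundant rows discovered in phase 1 are
dropped. Tolerances: pivot/feasibility 1e-9; the optimality-fraction
guarantee is checked at 1e-6. Bounds are finite by construction (±1e4, ample
for mmol/day dietary fluxes), so "unbounded" outcomes cannot arise silently.
The solver is validated against grid enumeration on random LPs and against
an independent FBA implementation (cobrapy, where available) on the toy
model; problems of this package's size (tens to a few hundred variables)
solve in milliseconds.

## Synthetic fixtures: what they do and do not show

`make_toy_food_db()` generates a food database whose records are internally
consistent by construction: metabolite amounts are drawn per group and the
reported macros are the implied masses inflated by an unmeasured remainder,
so metabolite coverage is realistically below 100 %. Deterministic records
embed the worked-example foods (dried date, red apple, cream cheese, with
the ids and consumed weights of the shipped templates), a food with exactly
80 % protein coverage, a pure-fructose food (1 g food = 1 g metabolite, the
anchor for metabolite/food-level agreement), and a fructose+lipid food for
tolerance tests. An `apple_hits` knob plants an exact keyword hit count to
exercise the 50-hit threshold. All draws come from one seeded generator; the
caller's RNG state is restored, and equal specs yield byte-identical files.

`make_toy_wbm()` is a ~20-reaction stand-in for a whole-body model: diet
exchanges, transporters, ATP production from glucose and alanine, a
maintenance objective requiring ATP **and** a vitamin-like metabolite
(retinol) — so a diet without it is infeasible, the planted defect that
`restore_feasibility()` repairs — and a target reaction consuming 2 fructose
whose maximum flux is analytically `uptake/2`, giving the optimizer tests a
closed-form oracle. Problem sizes throughout (tens of foods, ~30 reactions,
20-diet equivalence sweeps, 0.1 g brute-force grids) were chosen so the full
suite exercises every code path with exact, hand-checkable expectations.

What passing these tests does **not** show: real USDA/FRIDA parsing quirks at
their full scale (~14,000 foods), genome-scale numerical behaviour,
organ-level physiology, microbiome community modelling, or anything about
enzyme kinetics and bioavailability — dietary uptake in a
constraint-based model is an upper bound on what a gut actually absorbs.
Predicted diet changes are hypotheses for validation, not prescriptions.

## Known limitations

* The simplex is dense; genome-scale models (tens of thousands of reactions)
  would need a sparse industrial solver behind the same `solve_lp()` surface.
* The in silico diet is only as complete as the measured metabolite coverage
  of the chosen database food equivalents — the coverage report exists
  precisely to make that visible.
* Keyword matching is deliberately exact; misspelled descriptions need
  keyword refinement, guided by the no-hits / too-many-hits reports.
* SBML support covers the Level 3 + FBC subset the package writes
  (stoichiometry, bounds, one objective); exotic SBML constructs are out of
  scope, with COBRA JSON as the canonical format.
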