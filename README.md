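# dietforge

Constraint-based metabolic models — in particular organ-resolved, whole-body
human models (WBMs) — need diets specified as metabolite uptake fluxes
(mmol/day/person), but nutrition data comes as *food items*: a bowl of dates,
150 g of red apple. `dietforge` closes that gap in R. It

* builds **food-composition databases** on a per-100 g basis from USDA
  FoodData Central–style or generic long tables, converting every mass-measured
  nutrient to mmol via its molecular weight
  (`mmol/100g = mass_g / MW × 1000`);
* **matches dietary food items to database food equivalents** by keyword
  search over record descriptions, ranking candidates by the Euclidean
  distance between per-100 g macronutrient vectors (energy, lipid, protein and
  the carbohydrate components sugars/fibre/starch — total carbohydrate is
  excluded because its definition is inconsistent across databases) plus a
  per-group *coverage* score: how much of each reported macronutrient is
  accounted for by measured metabolites;
* compiles consumed weights into **in silico diets**:
  `flux[met] = Σ_foods mmol/100g / 100 × grams`, with macronutrient and
  Atwater-factor energy analytics computed twice — from database-reported
  macros and from metabolite-derived masses;
* applies diets to models either as **diet-exchange bounds**
  (`lb = −flux`, uptake negative by COBRA convention) or through a
  **food-item-constrained model**: per food, an exchange
  `foodItem[f] ←` (g/day) and a breakdown
  `foodItem[f] → Σ metᵢ[d] + Σ macro[d]` with per-gram coefficients, plus
  sink reactions `macro[d] →` so the macronutrient bookkeeping species never
  perturb the network;
* **checks and repairs feasibility** (can the model satisfy its whole-body
  maintenance objective?) by greedily adding essential metabolites from a
  candidate list; and
* computes **minimal dietary changes that optimize a target flux** with a
  two-stage lexicographic LP: stage 1 maximizes (or minimizes) the weighted
  target subject to steady state, gram budgets, caloric range and
  macronutrient tolerances; stage 2 fixes the target to ≥ f of that optimum
  (default f = 0.999) and minimizes the total grams added plus removed.

All linear programs run on a built-in two-phase simplex with Bland's
anti-cycling rule; models read and write COBRA JSON and SBML Level 3 + FBC.
A deterministic fixture generator supplies a toy food database and a toy
whole-body-style model, so the entire workflow runs self-contained, with no
downloads.

## Worked example

```r
library(dietforge)

db   <- make_toy_food_db(fixture_spec(seed = 1))
cons <- toy_equivalents_consumed()      # dried date / red apple / cream cheese
diet1 <- build_diet(cons, db, "diet1")
round(diet1$flux, 2)
#>  glc_D    fru   sucr cellul  ocdca   hdca  ala_L  glu_L
#>  72.85  83.26   7.30  18.50  15.82  11.70   8.42   3.40
diet1$macros_database[["energy_kcal"]]
#> [1] 289.4333
round(diet1$energy_fractions$database, 3)
#> carbohydrate      protein        lipid        fibre      alcohol
#>        0.603        0.049        0.317        0.031        0.000
```

A diet of 50 g dried dates, 100 g red apple and 25 g cream cheese supplies
72.85 mmol glucose per day and 289.4 kcal, 60.3 % of it from carbohydrate.
Applying the toy diet to the toy whole-body model and asking whether
maintenance can run:

```r
model <- make_toy_wbm()
toy   <- build_diet(make_toy_diet(), db, "toy")
check_feasibility(apply_diet(model, toy))$objective_value
#> [1] 6.981802       # maintenance runs; the vitamin supply is the bottleneck
```

Minimal diet change maximizing the toy target flux, allowing at most 10 g of
added food with pure fructose as the candidate:

```r
mf <- add_food_reactions(model, db,
        data.frame(origin = make_toy_diet()$database_origin,
                   food_id = make_toy_diet()$food_id))
mf <- set_bounds(mf, "MAINT", 1, 1e4)
spec <- optimization_spec("TARGET_SYN", level = "food", max_added_g = 10,
          candidates = data.frame(origin = "usda", food_id = "900002"))
plan <- optimize_diet(mf, make_toy_diet(), spec, db, diet_name = "toy")
plan$added
#> usda:900002
#>       9.986
unname(plan$baseline_target_flux); unname(plan$achieved_target_flux)
#> [1] 11.10149
#> [1] 38.81636
```

Adding 9.986 g of the pure-fructose food raises the target flux from 11.10 to
38.82 mmol/day — 99.9 % of the best achievable under the 10 g budget, at the
smallest possible dietary change.

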