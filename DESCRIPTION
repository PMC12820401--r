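Package: dietforge
Title: In Silico Diet Construction and Optimization for Constraint-Based Metabolic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts food items into metabolite-resolved in silico diets and
    applies them to constraint-based metabolic models. Builds per-100g food
    composition databases with mmol conversion, matches user-described dietary
    food items to database food equivalents by keyword search and macronutrient
    Euclidean distance, compiles diets into mmol/day flux vectors with
    macronutrient and energy analytics, constructs food-item-constrained models
    with synthesized exchange and breakdown reactions, checks and restores
    feasibility, and computes minimal dietary changes that optimize target
    metabolic fluxes via a two-stage lexicographic linear program. Ships a
    deterministic synthetic-fixture generator (toy food databases and toy
    whole-body-style models) so the whole workflow runs self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    Matrix,
    methods,
    stats,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
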