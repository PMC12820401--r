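# Synthetic fixtures: a toy food-composition database, worked-example
# description/consumption tables, and a toy whole-body-style metabolic
# model with planted, analytically known properties. Everything any other
# module needs can be generated from these with no download; identical
# specs yield byte-identical outputs.

#' Fixture specification
#'
#' @param seed integer RNG seed; equal specs produce identical fixtures.
#' @param n_foods number of additional randomized foods beyond the
#'   deterministic worked-example and planted records.
#' @param n_metabolites how many metabolites of the canonical pool the
#'   randomized foods may draw from.
#' @param defect optional planted defect; `"missing_essential_metabolite"`
#'   makes the toy diet omit the vitamin the toy model requires, so the
#'   model is infeasible until [restore_feasibility()] adds it back.
#' @param apple_hits when `> 0`, the database contains exactly this many
#'   descriptions matching the keyword `"apple"` (useful to exercise the
#'   too-many-hits threshold).
#' @return a `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1, n_foods = 40, n_metabolites = 15,
                         defect = NULL, apple_hits = 0) {
  assert_that(n_foods >= 0 && n_metabolites >= 1, "invalid fixture sizes")
  assert_that(is.null(defect) || defect == "missing_essential_metabolite",
              "unknown defect")
  structure(list(seed = as.integer(seed), n_foods = n_foods,
                 n_metabolites = n_metabolites, defect = defect,
                 apple_hits = apple_hits),
            class = "fixture_spec")
}

# Canonical metabolite pool: id, molecular weight (g/mol), macronutrient
# group, and which macro field the metabolite's mass reports into.
toy_metabolite_pool <- function() {
  data.frame(
    id    = c("glc_D", "fru", "sucr", "strch", "cellul", "ala_L", "leu_L",
              "glu_L", "gly", "ocdca", "lnlc", "hdca", "retinol", "h2o",
              "etoh"),
    mw    = c(180.156, 180.156, 342.297, 162.141, 162.141, 89.093, 131.173,
              147.129, 75.067, 284.484, 280.447, 256.43, 286.459, 18.015,
              46.069),
    group = c("carbohydrate", "carbohydrate", "carbohydrate", "carbohydrate",
              "fibre", "protein", "protein", "protein", "protein", "lipid",
              "lipid", "lipid", "other", "other", "alcohol"),
    field = c("sugars_g", "sugars_g", "sugars_g", "starch_g", "fibre_g",
              "protein_g", "protein_g", "protein_g", "protein_g", "lipid_g",
              "lipid_g", "lipid_g", NA, NA, "alcohol_g"),
    stringsAsFactors = FALSE)
}

toy_fixed_records <- function(pool) {
  mm <- function(mass, met) mass_to_mmol(mass, pool$mw[pool$id == met])
  rec <- function(id, origin, desc, mets, macros)
    new_food_record(id, origin, desc, macros, mets)
  list(
    # Worked-example foods (ids and names follow the shipped templates)
    rec("168191", "usda", "Dates, deglet noor, dried",
        c(glc_D = mm(20, "glc_D"), fru = mm(18, "fru"), sucr = mm(5, "sucr"),
          cellul = mm(3, "cellul")),
        c(energy_kcal = 282, sugars_g = 47, fibre_g = 4, protein_g = 2.5,
          lipid_g = 0.4, carbohydrate_g = 75)),
    rec("1105430", "usda", "Apples, raw, red delicious, with skin",
        c(fru = mm(6, "fru"), glc_D = mm(2.5, "glc_D"),
          cellul = mm(1.5, "cellul")),
        # per 100 g: the 150 g reference values of the worked example / 1.5
        c(energy_kcal = 91.4 / 1.5, lipid_g = 0.1 / 1.5,
          protein_g = 0.4 / 1.5, sugars_g = 15.5 / 1.5, fibre_g = 1.9)),
    rec("1215", "frida", "Cheese, cream, plain",
        c(ocdca = mm(18, "ocdca"), hdca = mm(12, "hdca"),
          ala_L = mm(3, "ala_L"), glu_L = mm(2, "glu_L"),
          glc_D = mm(2.5, "glc_D")),
        c(energy_kcal = 350, lipid_g = 34, protein_g = 6, sugars_g = 3)),
    # Planted coverage: protein metabolites sum to exactly 8 g of a
    # reported 10 g -> protein coverage 80%
    rec("900001", "usda", "Protein shake powder, vanilla",
        c(ala_L = mm(5, "ala_L"), gly = mm(3, "gly")),
        c(energy_kcal = 380, protein_g = 10, sugars_g = 60, lipid_g = 2)),
    # Optimizer foods: a food that is pure fructose (1 g food = 1 g
    # metabolite), and a fructose food carrying lipid
    rec("900002", "usda", "Fructose, crystalline, pure",
        c(fru = mm(100, "fru")),
        c(energy_kcal = 400, sugars_g = 100)),
    rec("900003", "usda", "Fructose oil bar, fortified",
        c(fru = mm(18, "fru"), ocdca = mm(10, "ocdca")),
        c(energy_kcal = 162, sugars_g = 18, lipid_g = 10)),
    # Staples aligned with the toy model's dietary metabolites
    rec("900004", "usda", "Glucose syrup, clinical",
        c(glc_D = mm(50, "glc_D")),
        c(energy_kcal = 200, sugars_g = 50)),
    rec("900005", "usda", "Amino acid broth, alanine rich",
        c(ala_L = mm(20, "ala_L")),
        c(energy_kcal = 80, protein_g = 20)),
    rec("900006", "usda", "Vitamin drops, retinol concentrate",
        c(retinol = mm(1, "retinol"), h2o = mm(99, "h2o")),
        c(energy_kcal = 0)))
}

#' Generate the toy food-composition database
#'
#' Contains the deterministic worked-example records (dried date, red
#' apple, cream cheese), planted records with known coverage, optimizer
#' staples, plus `n_foods` randomized but internally consistent foods:
#' metabolite amounts are drawn per group and reported macros are the
#' implied masses inflated by an unmeasured remainder, so metabolite
#' coverage is below 100% by construction.
#'
#' @param spec a [fixture_spec()].
#' @return a `food_database`.
#' @export
make_toy_food_db <- function(spec = fixture_spec()) {
  pool <- toy_metabolite_pool()
  records <- toy_fixed_records(pool)
  nouns <- c("carrot", "banana", "salmon", "oat", "bean", "rice", "yogurt",
             "beef", "spinach", "almond", "lentil", "cod", "barley",
             "tomato", "egg", "walnut", "millet", "turnip", "mackerel",
             "pea")
  styles <- c("raw", "dried", "boiled", "canned", "smoked", "frozen",
              "roasted", "fresh")
  with_seed(spec$seed, {
    usable <- pool[seq_len(min(spec$n_metabolites, nrow(pool))), ]
    for (i in seq_len(spec$n_foods)) {
      noun <- nouns[(i - 1) %% length(nouns) + 1]
      style <- sample(styles, 1)
      desc <- sprintf("%s, %s, lot %d",
                      paste0(toupper(substring(noun, 1, 1)),
                             substring(noun, 2)), style, i)
      k <- sample(2:min(6, nrow(usable)), 1)
      mets_rows <- usable[sample(nrow(usable), k), ]
      mmol <- stats::runif(k, 1, 40)
      mets <- stats::setNames(mmol, mets_rows$id)
      mass <- mmol * mets_rows$mw / 1000
      macros <- numeric(0)
      for (f in unique(stats::na.omit(mets_rows$field))) {
        measured <- sum(mass[which(mets_rows$field == f)])
        macros[f] <- measured * stats::runif(1, 1.05, 1.6)  # coverage < 100%
      }
      gv <- function(f) {
        v <- unname(macros[f])
        if (length(v) == 0 || is.na(v)) 0 else v
      }
      carb <- gv("sugars_g") + gv("starch_g")
      if (carb > 0) macros["carbohydrate_g"] <- carb
      fac <- atwater_factors()
      macros["energy_kcal"] <-
        sum(c(carbohydrate = carb, protein = gv("protein_g"),
              lipid = gv("lipid_g"), fibre = gv("fibre_g"),
              alcohol = gv("alcohol_g"))[names(fac)] * fac, na.rm = TRUE)
      macros <- macros[!is.na(macros)]
      records[[length(records) + 1]] <- new_food_record(
        as.character(100000 + i), if (i %% 3 == 0) "frida" else "usda",
        desc, macros, mets)
    }
    # exact number of descriptions matching "apple" (the red apple record
    # already matches once)
    n_have <- sum(grepl("apple", tolower(vapply(records, `[[`, "",
                                                "description"))))
    extra <- spec$apple_hits - n_have
    if (spec$apple_hits > 0 && extra > 0) {
      for (k in seq_len(extra)) {
        records[[length(records) + 1]] <- new_food_record(
          as.character(200000 + k), "usda",
          sprintf("Apple product, assortment %d", k),
          c(energy_kcal = 52, sugars_g = 10.4),
          c(fru = mass_to_mmol(5, 180.156)))
      }
    }
  })
  food_database(records,
                molecular_weights = stats::setNames(pool$mw, pool$id),
                metabolite_group = stats::setNames(pool$group, pool$id))
}

#' The worked-example foodDescription table
#'
#' One dietary food item, "Red apple" (keywords `Apple; Red`, 150 g
#' reference weight, 91.4 kcal, 0.1 g lipid, 0.4 g protein, 15.5 g sugars).
#'
#' @return data frame in the foodDescription template layout.
#' @export
toy_food_description <- function() {
  data.frame(
    OriginalFood = c("Red apple", "Dried date", "Cream cheese"),
    KeyWords = c("Apple; Red", "Date; Dried", "Cheese; Cream"),
    `ReferenceWeight(g)` = c(150, 50, 30),
    `Energy (kcal)` = c(91.4, 141, 105),
    `Lipid (g)` = c(0.1, 0.2, 10.2),
    `Protein (g)` = c(0.4, 1.2, 1.8),
    `Sugars (g)` = c(15.5, 23, 0.9),
    check.names = FALSE, stringsAsFactors = FALSE)
}

#' The worked-example equivalentsConsumed table
#'
#' Three database food equivalents across two diets: dried date 50/80 g,
#' red apple 100/0 g, cream cheese 25/35 g.
#'
#' @return an `equivalents_consumed` table with diets `diet1`, `diet2`.
#' @export
toy_equivalents_consumed <- function() {
  equivalents_consumed(
    food_name = c("Dried date", "Red apple", "Cream cheese"),
    food_id = c("168191", "1105430", "1215"),
    database_origin = c("usda", "usda", "frida"),
    grams = data.frame(diet1 = c(50, 100, 25), diet2 = c(80, 0, 35)))
}

#' Generate the toy whole-body-style metabolic model
#'
#' A deterministic small model with a diet compartment `[d]` and a cytosol
#' `[c]`: diet exchanges `Diet_EX_*[d]` (closed until a diet is applied),
#' dietary overflow excretions, transporters, glycolysis-like ATP
#' production from glucose and alanine, a maintenance objective consuming
#' 10 ATP plus 0.01 retinol (the essential vitamin-like metabolite: no
#' retinol in the diet, no feasible maintenance), and a target reaction
#' `TARGET_SYN: 2 fru[c] -> tar[c]` whose maximum flux is analytically
#' `fructose availability / 2`.
#'
#' @param spec a [fixture_spec()] (the model itself is deterministic; the
#'   spec is accepted for interface symmetry).
#' @return a `metabolic_model` with the maintenance reaction as objective.
#' @export
make_toy_wbm <- function(spec = fixture_spec()) {
  m <- metabolic_model("toy_wbm")
  diet_mets <- c("glc_D", "fru", "ala_L", "ocdca", "retinol", "h2o")
  for (met in diet_mets) {
    m <- add_reaction(m, sprintf("Diet_EX_%s[d]", met),
                      stats::setNames(-1, paste0(met, "[d]")),
                      lb = 0, ub = 0)
    m <- add_reaction(m, paste0("Excr_", met),
                      stats::setNames(-1, paste0(met, "[d]")),
                      lb = 0, ub = DEFAULT_FLUX_BOUND)
  }
  trans <- function(mm, met) add_reaction(
    mm, paste0("T_", met),
    stats::setNames(c(-1, 1), paste0(met, c("[d]", "[c]"))),
    lb = 0, ub = DEFAULT_FLUX_BOUND)
  for (met in c("glc_D", "fru", "ala_L", "retinol")) m <- trans(m, met)
  m <- add_reaction(m, "GLYC", c("glc_D[c]" = -1, "atp[c]" = 2),
                    lb = 0, ub = DEFAULT_FLUX_BOUND)
  m <- add_reaction(m, "ALACAT", c("ala_L[c]" = -1, "atp[c]" = 1),
                    lb = 0, ub = DEFAULT_FLUX_BOUND)
  m <- add_reaction(m, "TARGET_SYN", c("fru[c]" = -2, "tar[c]" = 1),
                    lb = 0, ub = DEFAULT_FLUX_BOUND)
  m <- add_reaction(m, "SINK_tar", c("tar[c]" = -1),
                    lb = 0, ub = DEFAULT_FLUX_BOUND)
  m <- add_reaction(m, "MAINT", c("atp[c]" = -10, "retinol[c]" = -0.01),
                    lb = 0, ub = DEFAULT_FLUX_BOUND)
  set_objective(m, "MAINT")
}

#' Toy baseline diet aligned with the toy model
#'
#' A consumption table over the staple fixture foods supplying glucose,
#' alanine, fructose, water, and (unless the defect is planted) the
#' essential vitamin. With `defect = "missing_essential_metabolite"` the
#' vitamin drops are set to 0 g, which makes the toy model infeasible.
#'
#' @param spec a [fixture_spec()]; only the `defect` field matters.
#' @return an `equivalents_consumed` table with one diet `toy`.
#' @export
make_toy_diet <- function(spec = fixture_spec()) {
  vit <- if (identical(spec$defect, "missing_essential_metabolite")) 0 else 2
  equivalents_consumed(
    food_name = c("Glucose syrup", "Amino broth", "Pure fructose",
                  "Vitamin drops"),
    food_id = c("900004", "900005", "900002", "900006"),
    database_origin = rep("usda", 4),
    grams = data.frame(toy = c(20, 20, 4, vit)))
}

#' Default essential-candidate list for the toy model
#'
#' Trial order and increments (mmol/day) used by [restore_feasibility()]
#' on the toy fixtures.
#'
#' @return named numeric vector.
#' @export
toy_essential_candidates <- function() c(retinol = 0.5)

#' Write all fixture files to a directory
#'
#' Emits `db.tsv` (the toy food database), `foodDescription.csv`,
#' `equivalentsConsumed.csv` (the worked-example tables), and
#' `toy_model.json` / `toy_model.xml` (the toy model in both formats).
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if needed).
#' @return named character vector of the file paths, invisibly.
#' @export
write_fixtures <- function(spec = fixture_spec(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(db = file.path(dir, "db.tsv"),
             foods = file.path(dir, "foodDescription.csv"),
             consumed = file.path(dir, "equivalentsConsumed.csv"),
             model_json = file.path(dir, "toy_model.json"),
             model_sbml = file.path(dir, "toy_model.xml"))
  write_food_db(make_toy_food_db(spec), paths[["db"]],
                report_path = file.path(dir, "db_load_report.txt"))
  utils::write.csv(toy_food_description(), paths[["foods"]],
                   row.names = FALSE)
  cons <- toy_equivalents_consumed()
  out <- data.frame(FoodName = cons$food_name, databaseID = cons$food_id,
                    databaseOrigin = cons$database_origin,
                    `diet1 (g)` = cons$diet1, `diet2 (g)` = cons$diet2,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(out, paths[["consumed"]], row.names = FALSE)
  model <- make_toy_wbm(spec)
  write_cobra_json(model, paths[["model_json"]])
  write_sbml_model(model, paths[["model_sbml"]])
  invisible(paths)
}
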