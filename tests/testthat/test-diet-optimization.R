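test_that("food-level plan matches the brute-force grid oracle", {
  db <- toy_db()
  cons <- make_toy_diet()
  mf <- toy_food_model()
  f <- 0.999
  spec <- optimization_spec("TARGET_SYN", level = "food", max_added_g = 10,
                            candidates = data.frame(origin = "usda",
                                                    food_id = "900002"),
                            optimality_fraction = f)
  plan <- optimize_diet(mf, cons, spec, db, diet_name = "toy")
  oracle <- grid_oracle(mf, cons, "toy", "Food_EX_usda_900002",
                        "TARGET_SYN", budget = 10, f = f)
  expect_equal(unname(plan$stage1_value), oracle$best, tolerance = 1e-6)
  expect_equal(unname(plan$added[["usda:900002"]]), oracle$grams,
               tolerance = 0.1 + 1e-9)     # grid resolution
  expect_gte(plan$achieved_value, f * plan$stage1_value - 1e-6)
})

test_that("zero budgets reproduce the baseline flux exactly", {
  db <- toy_db()
  cons <- make_toy_diet()
  mf <- toy_food_model()
  spec <- optimization_spec("TARGET_SYN", level = "food", max_added_g = 0,
                            max_removed_g = 0,
                            candidates = data.frame(origin = "usda",
                                                    food_id = "900002"))
  plan <- optimize_diet(mf, cons, spec, db, diet_name = "toy")
  expect_length(plan$added, 0)
  expect_length(plan$removed, 0)
  expect_equal(unname(plan$achieved_target_flux),
               unname(plan$baseline_target_flux), tolerance = 1e-9)
})

test_that("enlarging the addition budget never hurts the stage-1 optimum", {
  db <- toy_db()
  cons <- make_toy_diet()
  mf <- toy_food_model()
  cand <- data.frame(origin = "usda", food_id = "900002")
  opts <- vapply(c(0, 2, 5, 10, 20), function(budget) {
    spec <- optimization_spec("TARGET_SYN", level = "food",
                              max_added_g = budget, candidates = cand)
    optimize_diet(mf, cons, spec, db, diet_name = "toy")$stage1_value
  }, 0)
  expect_true(all(diff(opts) >= -1e-9))
})

test_that("the optimality-fraction guarantee holds across f values", {
  db <- toy_db()
  cons <- make_toy_diet()
  mf <- toy_food_model()
  cand <- data.frame(origin = "usda", food_id = "900002")
  for (f in c(0.9, 0.999, 1)) {
    spec <- optimization_spec("TARGET_SYN", level = "food", max_added_g = 10,
                              candidates = cand, optimality_fraction = f)
    plan <- optimize_diet(mf, cons, spec, db, diet_name = "toy")
    expect_gte(plan$achieved_value, f * plan$stage1_value - 1e-6)
    # smaller f permits (weakly) smaller change
    if (f < 1) expect_lte(sum(plan$added), 10 + 1e-9)
  }
})

test_that("macronutrient tolerances gate lipid-carrying candidates", {
  db <- toy_db()
  cons <- make_toy_diet()
  mf <- toy_food_model(extra_items = data.frame(origin = "usda",
                                                food_id = "900003"))
  cand <- data.frame(origin = "usda", food_id = "900003")
  tight <- optimization_spec("TARGET_SYN", level = "food", max_added_g = 10,
                             macro_tolerances = c(lipid = 0),
                             candidates = cand)
  pt <- optimize_diet(mf, cons, tight, db, diet_name = "toy")
  expect_length(pt$added, 0)
  expect_equal(unname(pt$achieved_target_flux),
               unname(pt$baseline_target_flux), tolerance = 1e-6)
  loose <- optimization_spec("TARGET_SYN", level = "food", max_added_g = 10,
                             macro_tolerances = c(lipid = 5),
                             candidates = cand)
  pl <- optimize_diet(mf, cons, loose, db, diet_name = "toy")
  expect_gt(sum(pl$added), 0)
  expect_gt(unname(pl$achieved_target_flux),
            unname(pl$baseline_target_flux))
  expect_lte(unname(pl$new_macros["lipid"]), 5 + 1e-6)
})

test_that("a caloric band pinned at the baseline keeps energy unchanged", {
  db <- toy_db()
  cons <- make_toy_diet()
  mf <- toy_food_model()
  base_kcal <- sum(vapply(seq_len(nrow(cons)), function(i) {
    rec <- get_record(db, cons$database_origin[i], cons$food_id[i])
    v <- rec$macronutrients["energy_kcal"]
    if (is.na(v)) 0 else v / 100 * cons$toy[i]
  }, 0))
  spec <- optimization_spec("TARGET_SYN", level = "food", max_added_g = 10,
                            caloric_range = c(base_kcal, base_kcal),
                            candidates = data.frame(origin = "usda",
                                                    food_id = "900002"))
  plan <- optimize_diet(mf, cons, spec, db, diet_name = "toy")
  expect_equal(unname(plan$new_macros["energy_kcal"]), base_kcal,
               tolerance = 1e-6)
})

test_that("metabolite- and food-level plans agree for a pure-compound food", {
  db <- toy_db()
  cons <- make_toy_diet()
  mf <- toy_food_model()
  f <- 0.999
  food_spec <- optimization_spec("TARGET_SYN", level = "food",
                                 max_added_g = 10,
                                 candidates = data.frame(origin = "usda",
                                                         food_id = "900002"),
                                 optimality_fraction = f)
  pf <- optimize_diet(mf, cons, food_spec, db, diet_name = "toy")
  diet <- build_diet(cons, db, "toy")
  mm <- suppressWarnings(apply_diet(toy_model(), diet))
  mm <- set_bounds(mm, "MAINT", 1, 1e4)
  met_spec <- optimization_spec("TARGET_SYN", level = "metabolite",
                                max_added_g = 10, candidates = "fru",
                                optimality_fraction = f)
  pm <- optimize_diet(mm, diet, met_spec, db)
  # pure fructose food: g of food == g of metabolite via the MW conversion
  expect_equal(unname(pm$added[["fru"]]) * 180.156 / 1000,
               unname(pf$added[["usda:900002"]]), tolerance = 1e-6)
  expect_equal(unname(pm$achieved_target_flux),
               unname(pf$achieved_target_flux), tolerance = 1e-6)
})

test_that("infeasible constraint combinations name the binding family", {
  db <- toy_db()
  cons <- make_toy_diet()
  mf <- toy_food_model()
  spec <- optimization_spec("TARGET_SYN", level = "food", max_added_g = 10,
                            caloric_range = c(1e5, 2e5),  # unreachable
                            candidates = data.frame(origin = "usda",
                                                    food_id = "900002"))
  expect_error(optimize_diet(mf, cons, spec, db, diet_name = "toy"),
               "caloric_range")
})

test_that("plan summaries are consistent with an independent diet rebuild", {
  db <- toy_db()
  cons <- make_toy_diet()
  mf <- toy_food_model()
  spec <- optimization_spec("TARGET_SYN", level = "food", max_added_g = 10,
                            candidates = data.frame(origin = "usda",
                                                    food_id = "900002"))
  plan <- optimize_diet(mf, cons, spec, db, diet_name = "toy")
  s <- summarize_plan(plan, db)
  expect_equal(nrow(s$changes), 1)
  expect_equal(s$changes$action, "added")
  # recompute macros through build_diet with the adjusted grams
  new_g <- cons$toy
  new_g[cons$food_id == "900002"] <-
    new_g[cons$food_id == "900002"] + plan$added[["usda:900002"]]
  cons2 <- equivalents_consumed(cons$food_name, cons$food_id,
                                cons$database_origin,
                                data.frame(toy = new_g))
  rebuilt <- build_diet(cons2, db, "toy")
  expect_equal(unname(plan$new_macros["energy_kcal"]),
               unname(rebuilt$macros_database["energy_kcal"]),
               tolerance = 1e-9)
  # empty plan reports no change
  spec0 <- optimization_spec("TARGET_SYN", level = "food")
  p0 <- optimize_diet(mf, cons, spec0, db, diet_name = "toy")
  expect_true(summarize_plan(p0, db)$no_change)
  dir <- withr::local_tempdir()
  write_plan(plan, dir, db)
  expect_true(file.exists(file.path(dir, "plan.csv")))
  js <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_equal(js$achieved_target_flux$TARGET_SYN,
               unname(plan$achieved_target_flux), tolerance = 1e-9)
})
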