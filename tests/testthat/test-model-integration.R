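test_that("diet_to_constraints applies the uptake sign convention", {
  m <- toy_model()
  flux <- c(glc_D = 30)
  cs <- diet_to_constraints(flux, m)
  expect_equal(cs$constraints$reaction, "Diet_EX_glc_D[d]")
  expect_equal(cs$constraints$lb, -30)
  expect_equal(cs$constraints$ub, 0)
  forced <- diet_to_constraints(flux, m, enforce_fraction = 1)
  expect_equal(forced$constraints$ub, -30)
  half <- diet_to_constraints(flux, m, enforce_fraction = 0.5)
  expect_equal(half$constraints$ub, -15)
  empty <- diet_to_constraints(numeric(0), m)
  expect_equal(nrow(empty$constraints), 0)
})

test_that("metabolites without a model exchange land in the skip list", {
  m <- toy_model()
  expect_warning(cs <- diet_to_constraints(c(glc_D = 5, sucr = 2), m),
                 "skipped")
  expect_equal(cs$skipped, "sucr")
  expect_equal(cs$constraints$reaction, "Diet_EX_glc_D[d]")
})

test_that("apply_diet overwrites exactly the listed bounds, idempotently", {
  db <- toy_db()
  diet <- build_diet(make_toy_diet(), db, "toy")
  m0 <- toy_model()
  m1 <- suppressWarnings(apply_diet(m0, diet))
  m2 <- suppressWarnings(apply_diet(m1, diet))
  expect_identical(m1$rxns, m2$rxns)
  expect_identical(m1$S, m2$S)             # no reaction added or removed
  cs <- suppressWarnings(diet_to_constraints(diet, m0))
  touched <- cs$constraints$reaction
  idx <- !(m0$rxns$id %in% touched)
  expect_identical(m1$rxns[idx, ], m0$rxns[idx, ])
  expect_equal(m1$rxns$lb[match(touched, m1$rxns$id)], cs$constraints$lb)
  expect_error(apply_diet(m0, data.frame(reaction = "ghost", lb = -1,
                                         ub = 0)),
               "unknown reaction")
})

test_that("breakdown reactions carry per-gram coefficients", {
  db <- toy_db()
  m <- add_food_reactions(toy_model(), db,
                          data.frame(origin = "usda", food_id = "900004"))
  # 50 g glucose per 100 g food -> 277.54 mmol/100g -> 2.7754 mmol per g
  coef <- m$S["glc_D[d]", "Food_BD_usda_900004"]
  expect_equal(as.numeric(coef), mass_to_mmol(50, 180.156) / 100,
               tolerance = 1e-12)
  expect_error(add_food_reactions(m, db, data.frame(origin = "usda",
                                                    food_id = "900004")),
               "already added")
  # a record without metabolites still breaks down into macros only
  db2 <- food_database(
    list(dietforge:::new_food_record("77", "t", "macro only",
                                     c(energy_kcal = 100, protein_g = 5))))
  m2 <- add_food_reactions(toy_model(), db2,
                           data.frame(origin = "t", food_id = "77"))
  st <- m2$S[, "Food_BD_t_77"]
  nz <- names(st[st != 0])
  expect_setequal(nz, c("t_77[f]", "energy_kcal[d]", "protein_g[d]"))
})

test_that("macro pseudo-metabolites only touch breakdown and sink reactions", {
  m <- toy_food_model()
  macro_mets <- grep("_g\\[d\\]$|_kcal\\[d\\]$", m$mets$id, value = TRUE)
  expect_gt(length(macro_mets), 0)
  for (mm in macro_mets) {
    rxns <- m$rxns$id[which(m$S[mm, ] != 0)]
    expect_true(all(grepl("^Food_BD_|^EX_", rxns)),
                info = paste("leaky macro metabolite:", mm))
  }
})

test_that("metabolite- and food-constrained formulations give equal optima", {
  db <- toy_db()
  base_model <- toy_model()
  cons0 <- make_toy_diet()
  items <- data.frame(origin = cons0$database_origin,
                      food_id = cons0$food_id)
  mf <- add_food_reactions(base_model, db, items)
  set.seed(11)
  for (i in 1:20) {
    grams <- round(runif(nrow(cons0), 0, 40), 2)
    cons <- equivalents_consumed(cons0$food_name, cons0$food_id,
                                 cons0$database_origin,
                                 data.frame(d = grams))
    diet <- build_diet(cons, db, "d")
    r_met <- fba(suppressWarnings(apply_diet(base_model, diet)))
    fb <- food_bounds(cons, "d")
    fb$ub <- fb$lb                          # force full consumption
    r_food <- fba(apply_diet(mf, fb))
    expect_equal(r_food$objective_value, r_met$objective_value,
                 tolerance = 1e-6,
                 info = paste("diet", i))
  }
})

test_that("feasibility verdicts follow the required objective", {
  db <- toy_db()
  diet <- build_diet(make_toy_diet(), db, "toy")
  fed <- suppressWarnings(apply_diet(toy_model(), diet))
  res <- check_feasibility(fed)
  expect_equal(res$status, "feasible")
  expect_gte(res$objective_value, 1)
  # all uptakes closed: maintenance cannot run
  closed <- toy_model()
  expect_equal(check_feasibility(closed)$status, "infeasible")
  expect_equal(check_feasibility(closed, required_objective = 0)$status,
               "feasible")
})

test_that("restore_feasibility repairs the planted vitamin defect", {
  db <- toy_db()
  spec <- fixture_spec(defect = "missing_essential_metabolite")
  diet <- build_diet(make_toy_diet(spec), db, "toy")
  m <- suppressWarnings(apply_diet(toy_model(), diet))
  expect_equal(check_feasibility(m)$status, "infeasible")
  out <- restore_feasibility(m, diet, toy_essential_candidates())
  expect_equal(out$result$status, "feasible")
  expect_equal(nrow(out$result$adjustments), 1)
  expect_equal(out$result$adjustments$metabolite_id, "retinol")
  expect_equal(out$diet$flux[["retinol"]],
               toy_essential_candidates()[["retinol"]])
  # monotone: no uptake tightened anywhere
  expect_true(all(out$model$rxns$lb <= m$rxns$lb + 1e-12))
  expect_true(all(out$model$rxns$ub >= m$rxns$ub - 1e-12))
})

test_that("restore_feasibility is a no-op on feasible input and honest on
           exhausted candidates", {
  db <- toy_db()
  diet <- build_diet(make_toy_diet(), db, "toy")
  m <- suppressWarnings(apply_diet(toy_model(), diet))
  ok <- restore_feasibility(m, diet, toy_essential_candidates())
  expect_equal(ok$result$status, "feasible")
  expect_equal(nrow(ok$result$adjustments), 0)
  expect_equal(ok$diet$flux, diet$flux)
  bad_diet <- build_diet(
    make_toy_diet(fixture_spec(defect = "missing_essential_metabolite")),
    db, "toy")
  mbad <- suppressWarnings(apply_diet(toy_model(), bad_diet))
  none <- restore_feasibility(mbad, bad_diet, stats::setNames(numeric(0),
                                                              character(0)))
  expect_equal(none$result$status, "infeasible")
  expect_equal(nrow(none$result$adjustments), 0)
  # a candidate that cannot help leaves the model infeasible, logged
  wrong <- restore_feasibility(mbad, bad_diet, c(h2o = 5), max_rounds = 2)
  expect_equal(wrong$result$status, "infeasible")
  expect_gt(nrow(wrong$result$adjustments), 0)
})

test_that("diet constraint CSVs round-trip", {
  cs <- data.frame(reaction = c("Diet_EX_glc_D[d]", "Diet_EX_fru[d]"),
                   lb = c(-30, -5), ub = c(0, 0), stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_diet_constraints(cs, path)
  expect_equal(read_diet_constraints(path), cs)
  two_col <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("reaction,lb", "Diet_EX_glc_D[d],-30"), two_col)
  got <- read_diet_constraints(two_col)
  expect_equal(got$ub, 0)
})
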