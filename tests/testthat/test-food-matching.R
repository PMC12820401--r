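three_food_db <- function() {
  recs <- list(
    dietforge:::new_food_record("1", "t", "Apple, red, raw",
                                c(energy_kcal = 59, sugars_g = 10)),
    dietforge:::new_food_record("2", "t", "Apple pie",
                                c(energy_kcal = 240, sugars_g = 20)),
    dietforge:::new_food_record("3", "t", "Red cabbage",
                                c(energy_kcal = 31, sugars_g = 4)))
  food_database(recs)
}

test_that("cumulative search requires every keyword", {
  db <- three_food_db()
  item <- dietary_food_item("Red apple", c("apple", "red"), 150,
                            c(energy_kcal = 91.4))
  res <- search_candidates(item, db, "cumulative")
  expect_equal(res$status, "ok")
  expect_equal(res$hits, "t:1")
})

test_that("sequential search narrows in keyword order and skips dead ends", {
  db <- three_food_db()
  item <- dietary_food_item("Red apple", c("apple", "red"), 150)
  res <- search_candidates(item, db, "sequential")
  expect_equal(res$hits, "t:1")
  expect_length(res$skipped_keywords, 0)
  # a keyword that would empty the survivor set is skipped, not fatal
  item2 <- dietary_food_item("Odd apple", c("apple", "zucchini"), 100)
  res2 <- search_candidates(item2, db, "sequential")
  expect_setequal(res2$hits, c("t:1", "t:2"))
  expect_equal(res2$skipped_keywords, "zucchini")
})

test_that("a keyword matching nothing yields no_hits", {
  db <- three_food_db()
  item <- dietary_food_item("Nothing", c("quince"), 100)
  expect_equal(search_candidates(item, db, "cumulative")$status, "no_hits")
  expect_equal(search_candidates(item, db, "sequential")$status, "no_hits")
})

test_that("cumulative hits are a subset of any keyword-prefix search", {
  db <- toy_db()
  kws <- list(c("raw"), c("raw", "carrot"), c("raw", "carrot", "lot"))
  hit_sets <- lapply(kws, function(k) {
    it <- dietary_food_item("probe", k, 100)
    search_candidates(it, db, "cumulative", cap = 1e6)$hits
  })
  expect_true(all(hit_sets[[2]] %in% hit_sets[[1]]))
  expect_true(all(hit_sets[[3]] %in% hit_sets[[2]]))
})

test_that("the default hit cap is 50: 50 hits pass, 51 divert", {
  db51 <- toy_db_apples()
  item <- dietary_food_item("Apple", "apple", 100, c(energy_kcal = 52))
  res <- search_candidates(item, db51)
  expect_equal(res$status, "too_many_hits")
  expect_length(res$hits, 51)
  # drop one apple food -> exactly 50 -> reported normally
  db50 <- db51
  drop_key <- grep("^usda:200", names(db51$records), value = TRUE)[1]
  db50$records[[drop_key]] <- NULL
  res50 <- search_candidates(item, db50)
  expect_equal(res50$status, "ok")
  expect_length(res50$hits, 50)
})

test_that("macro distance: zero on self, hand value on the 3-4-5 case", {
  # worked example: 150 g red apple against its own per-100g record
  db <- toy_db()
  rec <- get_record(db, "usda", "1105430")
  expect_equal(as.numeric(macro_distance(red_apple_item(), rec)), 0,
               tolerance = 1e-9)
  ia <- dietary_food_item("X", "x", 100, c(energy_kcal = 4, protein_g = 2))
  ra <- dietforge:::new_food_record("1", "t", "x",
                                    c(energy_kcal = 1, protein_g = 6))
  expect_equal(as.numeric(macro_distance(ia, ra)), 5)
})

test_that("macro distance is invariant to the reference weight", {
  db <- toy_db()
  rec <- get_record(db, "frida", "1215")
  per150 <- dietary_food_item("CC", "cheese", 150,
                              c(energy_kcal = 500, lipid_g = 50,
                                protein_g = 9))
  per100 <- dietary_food_item("CC", "cheese", 100,
                              c(energy_kcal = 500 / 1.5, lipid_g = 50 / 1.5,
                                protein_g = 9 / 1.5))
  expect_equal(as.numeric(macro_distance(per150, rec)),
               as.numeric(macro_distance(per100, rec)), tolerance = 1e-12)
})

test_that("supplying more macro fields never decreases the distance", {
  db <- toy_db()
  rec <- get_record(db, "frida", "1215")
  base <- dietary_food_item("CC", "cheese", 100, c(energy_kcal = 300))
  more <- dietary_food_item("CC", "cheese", 100,
                            c(energy_kcal = 300, protein_g = 9))
  expect_gte(as.numeric(macro_distance(more, rec)),
             as.numeric(macro_distance(base, rec)))
  # unsupplied fields never enter: record-only fields change nothing
  rec_trim <- rec
  rec_trim$macronutrients <- rec$macronutrients[c("energy_kcal", "protein_g")]
  expect_equal(as.numeric(macro_distance(more, rec)),
               as.numeric(macro_distance(more, rec_trim)))
})

test_that("missing record macros count as zero and are flagged", {
  rec <- dietforge:::new_food_record("1", "t", "bare", c(energy_kcal = 10))
  item <- dietary_food_item("X", "x", 100,
                            c(energy_kcal = 10, sugars_g = 3))
  d <- macro_distance(item, rec)
  expect_equal(as.numeric(d), 3)
  expect_equal(attr(d, "missing_fields"), "sugars_g")
})

test_that("coverage: planted 80% protein food, bounds and n/a cases", {
  db <- toy_db()
  cov <- coverage_percent(get_record(db, "usda", "900001"), db)
  expect_equal(unname(cov["protein"]), 80, tolerance = 1e-9)
  empty <- dietforge:::new_food_record("e", "t", "none",
                                       c(protein_g = 5))
  cov0 <- coverage_percent(empty, db)
  expect_equal(unname(cov0["protein"]), 0)
  expect_true(is.na(cov0[["lipid"]]))   # no reported lipid -> n/a
  # metabolite mass equal to the reported macro -> exactly 100
  full <- dietforge:::new_food_record(
    "f", "t", "pure", c(protein_g = 10 * 89.093 / 1000),
    metabolites = c(ala_L = 10))
  expect_equal(unname(coverage_percent(full, db)["protein"]), 100,
               tolerance = 1e-9)
})

test_that("report files: row counts, top-N truncation, tie-breaks", {
  db <- toy_db_apples()
  apple <- dietary_food_item("Apple assortment", c("apple", "assortment"),
                             100, c(energy_kcal = 52, sugars_g = 10.4))
  nohit <- dietary_food_item("Quince", "quince", 100, c(energy_kcal = 40))
  toomany <- dietary_food_item("Any apple", "apple", 100,
                               c(energy_kcal = 52))
  reports <- match_foods(list(apple, nohit, toomany), db)
  expect_equal(reports[["Apple assortment"]]$status, "ok")
  n_ok <- nrow(reports[["Apple assortment"]]$candidates)
  expect_gt(n_ok, 10)
  dir <- withr::local_tempdir()
  paths <- write_match_reports(reports, dir)
  full <- read.csv(paths[["full"]])
  top <- read.csv(paths[["top"]])
  expect_equal(nrow(full), n_ok)
  expect_equal(nrow(top), 10)
  expect_equal(readLines(paths[["no_hits"]]), "Quince")
  tm <- read.csv(paths[["too_many"]], colClasses = "character")
  expect_equal(nrow(tm), 51)
  # identical records tie on distance and coverage; id breaks the tie
  cand <- reports[["Any apple"]]
  expect_equal(cand$status, "too_many_hits")
  cand2 <- reports[["Apple assortment"]]$candidates
  tied <- cand2[cand2$description != "Apples, raw, red delicious, with skin", ]
  expect_equal(tied$food_id, sort(tied$food_id))
})

test_that("small candidate sets appear whole in both reports", {
  db <- three_food_db()
  item <- dietary_food_item("Apple things", "apple", 100,
                            c(energy_kcal = 60))
  reports <- match_foods(list(item), db)
  dir <- withr::local_tempdir()
  paths <- write_match_reports(reports, dir)
  expect_equal(nrow(read.csv(paths[["full"]])), 2)
  expect_equal(nrow(read.csv(paths[["top"]])), 2)
})

test_that("foodDescription files parse into dietary food items", {
  dir <- withr::local_tempdir()
  write.csv(toy_food_description(), file.path(dir, "fd.csv"),
            row.names = FALSE)
  items <- read_food_description(file.path(dir, "fd.csv"))
  expect_length(items, 3)
  expect_equal(items[[1]]$name, "Red apple")
  expect_equal(items[[1]]$keywords, c("Apple", "Red"))
  expect_equal(items[[1]]$reference_weight_g, 150)
  expect_equal(items[[1]]$user_macros[["energy_kcal"]], 91.4)
  expect_equal(items[[1]]$user_macros[["sugars_g"]], 15.5)
})

test_that("invalid dietary food items are rejected", {
  expect_error(dietary_food_item("x", character(), 100), "non-empty")
  expect_error(dietary_food_item("x", "a;b", 100), "single words")
  expect_error(dietary_food_item("x", "a", 0), "> 0")
  expect_error(dietary_food_item("x", "a", 100, c(carbohydrate_g = 5)),
               "must be among")
})
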