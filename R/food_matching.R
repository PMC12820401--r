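# Matching user-described dietary food items to database food equivalents:
# keyword search over record descriptions, macronutrient Euclidean distance,
# metabolite coverage, and the comparison report files.

#' Describe a dietary food item
#'
#' A dietary food item is the food actually consumed, for which database food
#' equivalents are sought: a name, descriptive single-word keywords (most
#' descriptive first), the reference weight the macronutrients refer to, and
#' a (possibly partial) macronutrient profile per that reference weight.
#'
#' @param name food name, e.g. `"Red apple"`.
#' @param keywords character vector of single words; non-empty, no separator
#'   characters.
#' @param reference_weight_g weight in grams the macros refer to; `> 0`.
#' @param user_macros named numeric vector with names among `energy_kcal`,
#'   `lipid_g`, `protein_g`, `sugars_g`, `fibre_g`, `starch_g`; values are
#'   per `reference_weight_g` of food. Total carbohydrate is deliberately
#'   not accepted (database definitions are inconsistent; the components
#'   sugars/fibre/starch are compared instead).
#' @return an object of class `dietary_food_item`.
#' @examples
#' dietary_food_item("Red apple", c("Apple", "Red"), 150,
#'                   c(energy_kcal = 91.4, lipid_g = 0.1,
#'                     protein_g = 0.4, sugars_g = 15.5))
#' @export
dietary_food_item <- function(name, keywords, reference_weight_g,
                              user_macros = numeric(0)) {
  assert_that(length(keywords) > 0, "keywords must be non-empty")
  assert_that(!any(grepl("[;,]", keywords)),
              "keywords must be single words without separators")
  assert_that(is.numeric(reference_weight_g) && reference_weight_g > 0,
              "reference_weight_g must be > 0")
  assert_that(all(names(user_macros) %in% DISTANCE_FIELDS),
              paste0("user macros must be among: ",
                     paste(DISTANCE_FIELDS, collapse = ", ")))
  assert_that(all(user_macros >= 0), "user macros must be >= 0")
  structure(list(name = name, keywords = trimws(keywords),
                 reference_weight_g = reference_weight_g,
                 user_macros = user_macros),
            class = "dietary_food_item")
}

#' Read a foodDescription file
#'
#' Expects the template header `OriginalFood, KeyWords, ReferenceWeight(g),
#' Energy (kcal), Lipid (g), Protein (g), Sugars (g), Fibre (g), Starch (g)`
#' (macro columns optional); keywords are semicolon-separated within one
#' cell.
#'
#' @param path CSV path.
#' @return list of [dietary_food_item()] objects.
#' @export
read_food_description <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  cols <- c("Energy (kcal)" = "energy_kcal", "Lipid (g)" = "lipid_g",
            "Protein (g)" = "protein_g", "Sugars (g)" = "sugars_g",
            "Fibre (g)" = "fibre_g", "Starch (g)" = "starch_g")
  assert_that(all(c("OriginalFood", "KeyWords", "ReferenceWeight(g)") %in%
                    names(tab)),
              "foodDescription file lacks the template header")
  lapply(seq_len(nrow(tab)), function(i) {
    kw <- trimws(strsplit(tab$KeyWords[i], ";")[[1]])
    kw <- kw[nzchar(kw)]
    macros <- numeric(0)
    for (cn in names(cols)) {
      if (cn %in% names(tab) && !is.na(tab[[cn]][i]))
        macros[cols[[cn]]] <- as.numeric(tab[[cn]][i])
    }
    dietary_food_item(tab$OriginalFood[i], kw,
                      as.numeric(tab$`ReferenceWeight(g)`[i]), macros)
  })
}

# lowercase and flatten punctuation so "Apple, red" matches keyword "apple"
normalize_text <- function(x) gsub("[[:punct:]]", " ", tolower(x))

#' Search a database for food equivalents of one dietary food item
#'
#' Case-insensitive substring matching of keywords against record
#' descriptions (punctuation is flattened to spaces; no stemming). Two
#' strategies: `cumulative` keeps records whose description contains every
#' keyword; `sequential` applies keywords in order, each narrowing the
#' previous survivors, skipping (and logging) any keyword that would empty
#' the set. Items with no hits are flagged `no_hits`; items whose hits
#' exceed `cap` (default 50) are flagged `too_many_hits` with the full hit
#' list for keyword refinement.
#'
#' @param item a `dietary_food_item`.
#' @param db a non-empty `food_database`.
#' @param strategy `"cumulative"` or `"sequential"`.
#' @param cap positive integer hit threshold.
#' @return list with `status` (`ok`, `no_hits`, `too_many_hits`), `hits`
#'   (record keys `origin:id`), and `skipped_keywords` (sequential only).
#' @export
search_candidates <- function(item, db,
                              strategy = c("cumulative", "sequential"),
                              cap = 50) {
  strategy <- match.arg(strategy)
  assert_that(length(item$keywords) > 0, "keywords must be non-empty")
  assert_that(length(db$records) > 0, "food database is empty")
  desc <- normalize_text(vapply(db$records, `[[`, "", "description"))
  keys <- names(db$records)
  kws <- normalize_text(item$keywords)
  skipped <- character(0)
  if (strategy == "cumulative") {
    keep <- rep(TRUE, length(desc))
    for (kw in kws) keep <- keep & grepl(kw, desc, fixed = TRUE)
    hits <- keys[keep]
  } else {
    survivors <- seq_along(desc)
    for (i in seq_along(kws)) {
      nxt <- survivors[grepl(kws[i], desc[survivors], fixed = TRUE)]
      if (length(nxt) == 0) {
        skipped <- c(skipped, item$keywords[i])
      } else survivors <- nxt
    }
    # a first keyword matching nothing means no hits, not the whole database
    hits <- if (length(skipped) == length(kws)) character(0) else keys[survivors]
  }
  status <- if (length(hits) == 0) "no_hits"
            else if (length(hits) > cap) "too_many_hits"
            else "ok"
  list(status = status, hits = hits, skipped_keywords = skipped)
}

#' Euclidean macronutrient distance between item and candidate record
#'
#' The item's macros are rescaled to per-100g (`x 100 / reference_weight_g`)
#' and compared to the record's per-100g macros over exactly the fields the
#' user supplied, drawn from energy, lipid, protein, sugars, fibre, starch.
#' Total carbohydrate never enters. A supplied field the record does not
#' report is treated as 0 and flagged.
#'
#' @param item a `dietary_food_item` with at least one user macro.
#' @param record a `food_record`.
#' @return the distance (non-negative), with attribute `missing_fields`
#'   listing compared fields absent from the record. `NA` if the item has
#'   no user macros (such candidates are ranked by coverage alone).
#' @export
macro_distance <- function(item, record) {
  um <- item$user_macros
  if (length(um) == 0) {
    out <- NA_real_
    attr(out, "missing_fields") <- character(0)
    return(out)
  }
  scaled <- um * 100 / item$reference_weight_g
  fields <- intersect(names(scaled), DISTANCE_FIELDS)
  rec_vals <- record$macronutrients[fields]
  missing <- fields[is.na(rec_vals)]
  rec_vals[is.na(rec_vals)] <- 0
  out <- sqrt(sum((scaled[fields] - rec_vals)^2))
  attr(out, "missing_fields") <- missing
  out
}

#' Metabolite coverage of reported macronutrients, per group
#'
#' For each macronutrient group with a reported database value `> 0`,
#' returns `100 * metabolite-derived mass / reported mass`: how much of the
#' reported macronutrient is accounted for by measured metabolites. Values
#' can exceed 100 when measured metabolites exceed the reported macro.
#' Groups whose reported macro is 0 or absent are `NA` (not applicable).
#'
#' @param record a `food_record`.
#' @param db the `food_database` (group assignments, molecular weights).
#' @return named numeric vector over `protein`, `lipid`, `carbohydrate`,
#'   `fibre`, `alcohol` (percent or `NA`).
#' @export
coverage_percent <- function(record, db) {
  derived <- metabolite_derived_macros(record, db)
  group_field <- c(protein = "protein_g", lipid = "lipid_g",
                   carbohydrate = "carbohydrate_g", fibre = "fibre_g",
                   alcohol = "alcohol_g")
  out <- stats::setNames(rep(NA_real_, length(group_field)),
                         names(group_field))
  for (g in names(group_field)) {
    reported <- unname(record$macronutrients[group_field[[g]]])
    if (g == "carbohydrate" && is.na(reported)) {
      # same fallback as the diet analytics: sugars + starch
      sg <- unname(record$macronutrients["sugars_g"])
      st <- unname(record$macronutrients["starch_g"])
      if (!is.na(sg) || !is.na(st))
        reported <- sum(sg, st, na.rm = TRUE)
    }
    if (!is.na(reported) && reported > 0)
      out[g] <- 100 * derived[[g]] / reported
  }
  out
}

#' Match a set of dietary food items against a food database
#'
#' Runs [search_candidates()] per item and scores ok-status candidates with
#' [macro_distance()] and [coverage_percent()]. Candidates are ranked by
#' distance ascending, then mean coverage descending, then food id.
#'
#' @param items list of `dietary_food_item` objects.
#' @param db a `food_database`.
#' @param strategy,cap passed to [search_candidates()].
#' @return a `match_report`: list with one entry per item (`status`,
#'   `candidates` data frame or `hits` key vector, `skipped_keywords`).
#' @export
match_foods <- function(items, db, strategy = "cumulative", cap = 50) {
  reports <- lapply(items, function(item) {
    res <- search_candidates(item, db, strategy, cap)
    if (res$status != "ok") {
      return(list(item = item$name, status = res$status, hits = res$hits,
                  skipped_keywords = res$skipped_keywords,
                  candidates = NULL))
    }
    scored <- lapply(res$hits, function(key) {
      rec <- db$records[[key]]
      d <- macro_distance(item, rec)
      cov <- coverage_percent(rec, db)
      data.frame(origin = rec$database_origin, food_id = rec$food_id,
                 description = rec$description,
                 distance = as.numeric(d),
                 mean_coverage = mean(cov, na.rm = TRUE),
                 coverage_protein = cov[["protein"]],
                 coverage_lipid = cov[["lipid"]],
                 coverage_carbohydrate = cov[["carbohydrate"]],
                 coverage_fibre = cov[["fibre"]],
                 missing_fields = paste(attr(d, "missing_fields"),
                                        collapse = ";"),
                 stringsAsFactors = FALSE)
    })
    cand <- do.call(rbind, scored)
    cand$mean_coverage[is.nan(cand$mean_coverage)] <- NA_real_
    # no-distance candidates (no user macros) rank purely by coverage, last
    ord <- order(ifelse(is.na(cand$distance), Inf, cand$distance),
                 -ifelse(is.na(cand$mean_coverage), -Inf, cand$mean_coverage),
                 cand$food_id)
    cand <- cand[ord, , drop = FALSE]
    rownames(cand) <- NULL
    list(item = item$name, status = "ok", hits = res$hits,
         skipped_keywords = res$skipped_keywords, candidates = cand)
  })
  names(reports) <- vapply(items, `[[`, "", "name")
  structure(reports, class = "match_report")
}

#' Write the comparison report files
#'
#' Emits four artifacts into `dir`: `fullComparisonFoodItems.csv` (all
#' ok-status candidates with distance and coverage),
#' `topResultsComparisonFoodItems.csv` (top `top_n` per item, default 10),
#' `noDatabaseHits.txt`, and `tooManyDatabaseHits.csv` (the raw hit lists
#' for keyword refinement).
#'
#' @param reports a `match_report` from [match_foods()].
#' @param dir output directory (created if needed).
#' @param top_n rows per item in the short-form report.
#' @return named character vector of the four file paths, invisibly.
#' @export
write_match_reports <- function(reports, dir, top_n = 10) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(full = file.path(dir, "fullComparisonFoodItems.csv"),
             top = file.path(dir, "topResultsComparisonFoodItems.csv"),
             no_hits = file.path(dir, "noDatabaseHits.txt"),
             too_many = file.path(dir, "tooManyDatabaseHits.csv"))
  ok <- Filter(function(r) r$status == "ok", reports)
  bind_item <- function(r, n = Inf) {
    cand <- utils::head(r$candidates, n)
    cbind(data.frame(item = r$item, stringsAsFactors = FALSE), cand)
  }
  full <- if (length(ok)) do.call(rbind, lapply(ok, bind_item)) else
    data.frame(item = character())
  top <- if (length(ok)) do.call(rbind, lapply(ok, bind_item, n = top_n)) else
    data.frame(item = character())
  utils::write.csv(full, paths[["full"]], row.names = FALSE)
  utils::write.csv(top, paths[["top"]], row.names = FALSE)
  no_hits <- names(Filter(function(r) r$status == "no_hits", reports))
  writeLines(no_hits, paths[["no_hits"]])
  too_many <- Filter(function(r) r$status == "too_many_hits", reports)
  tm <- if (length(too_many)) {
    do.call(rbind, lapply(too_many, function(r)
      data.frame(item = r$item, hit = r$hits, stringsAsFactors = FALSE)))
  } else data.frame(item = character(), hit = character())
  utils::write.csv(tm, paths[["too_many"]], row.names = FALSE)
  invisible(paths)
}
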