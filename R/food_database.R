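# Food-composition database: loading, normalization, per-100g storage with
# metabolite identifiers and mmol conversion.
#
# A `food_database` stores one record per database food equivalent (a food
# item in a composition database such as USDA FoodData Central or FRIDA).
# All amounts are per 100 g of food: macronutrients in grams (energy in
# kcal), metabolites in mmol via their molecular weights.

#' Convert a mass per 100 g to mmol per 100 g
#'
#' @param mass_g mass in grams per 100 g of food; must be `>= 0`.
#' @param mw molecular weight in g/mol; must be `> 0`.
#' @return mmol per 100 g: `mass_g / mw * 1000`, exact arithmetic.
#' @examples
#' mass_to_mmol(10, 180.156) # 10 g glucose -> 55.507 mmol
#' @export
mass_to_mmol <- function(mass_g, mw) {
  assert_that(all(is.finite(mw)) && all(mw > 0),
              "invalid molecular weight: mw must be > 0")
  assert_that(all(mass_g >= 0), "mass must be >= 0")
  mass_g / mw * 1000
}

new_food_record <- function(food_id, database_origin, description,
                            macronutrients = numeric(0),
                            metabolites = numeric(0)) {
  assert_that(all(macronutrients >= 0) && all(metabolites >= 0),
              "food record amounts must be >= 0")
  structure(list(food_id = as.character(food_id),
                 database_origin = database_origin,
                 description = description,
                 macronutrients = macronutrients,
                 metabolites = metabolites),
            class = "food_record")
}

#' Construct a food-composition database
#'
#' @param records list of food records (see [load_food_table()]).
#' @param molecular_weights named numeric vector, metabolite id -> g/mol;
#'   must cover every metabolite appearing in `records`, all values `> 0`.
#' @param metabolite_group named character vector, metabolite id -> group in
#'   `protein`, `lipid`, `carbohydrate`, `fibre`, `alcohol`, `other`;
#'   metabolites without an entry fall back to `"other"`.
#' @param load_report data frame of per-row load problems (may be empty).
#' @return an object of class `food_database`.
#' @export
food_database <- function(records = list(), molecular_weights = numeric(0),
                          metabolite_group = character(0),
                          load_report = NULL) {
  assert_that(all(molecular_weights > 0), "molecular weights must be > 0")
  mets_used <- unique(unlist(lapply(records, function(r) names(r$metabolites))))
  missing_mw <- setdiff(mets_used, names(molecular_weights))
  assert_that(length(missing_mw) == 0,
              paste0("metabolites without molecular weight: ",
                     paste(missing_mw, collapse = ", ")))
  names(records) <- vapply(records, function(r)
    record_key(r$database_origin, r$food_id), character(1))
  assert_that(!anyDuplicated(names(records)),
              "(database_origin, food_id) must be unique")
  structure(list(records = records,
                 molecular_weights = molecular_weights,
                 metabolite_group = metabolite_group,
                 load_report = load_report %||% empty_load_report()),
            class = "food_database")
}

#' @export
print.food_database <- function(x, ...) {
  cat(sprintf("<food_database: %d records, %d molecular weights, %d load notes>\n",
              length(x$records), length(x$molecular_weights),
              nrow(x$load_report)))
  invisible(x)
}

#' Look up one record by database origin and food id
#'
#' @param db a `food_database`.
#' @param origin,food_id record key.
#' @return the `food_record`, or an error if absent.
#' @export
get_record <- function(db, origin, food_id) {
  rec <- db$records[[record_key(origin, food_id)]]
  assert_that(!is.null(rec),
              sprintf("no record (%s, %s) in database", origin, food_id))
  rec
}

empty_load_report <- function() {
  data.frame(food_id = character(), nutrient = character(),
             problem = character(), stringsAsFactors = FALSE)
}

#' Shipped schema descriptors for food-composition tables
#'
#' `"usda-fdc"` matches the FoodData Central flat export (columns `fdc_id`,
#' `description`, `nutrient_name`, `amount`, `unit_name`); `"generic"` is a
#' long format with columns `origin`, `food_id`, `description`, `nutrient`,
#' `amount`, `unit`.
#'
#' @param name schema name.
#' @return a column map list usable as `column_map` in [load_food_table()].
#' @export
food_schema <- function(name = c("usda-fdc", "generic")) {
  name <- match.arg(name)
  switch(name,
    "usda-fdc" = list(food_id = "fdc_id", description = "description",
                      nutrient = "nutrient_name", amount = "amount",
                      unit = "unit_name", origin = NULL,
                      default_origin = "usda"),
    "generic"  = list(food_id = "food_id", description = "description",
                      nutrient = "nutrient", amount = "amount",
                      unit = "unit", origin = "origin",
                      default_origin = "generic"))
}

#' Default mapping from database nutrient names to macronutrient fields
#'
#' Matches the common USDA FoodData Central proximate names plus the field
#' names themselves; matching is case-insensitive.
#'
#' @return named character vector, lowercase nutrient name -> macro field.
#' @export
default_macro_map <- function() {
  c("energy" = "energy_kcal",
    "energy_kcal" = "energy_kcal",
    "total lipid (fat)" = "lipid_g",
    "lipid" = "lipid_g", "lipid_g" = "lipid_g", "fat" = "lipid_g",
    "protein" = "protein_g", "protein_g" = "protein_g",
    "carbohydrate, by difference" = "carbohydrate_g",
    "carbohydrate" = "carbohydrate_g", "carbohydrate_g" = "carbohydrate_g",
    "sugars, total including nlea" = "sugars_g",
    "sugars, total" = "sugars_g", "sugars" = "sugars_g",
    "sugars_g" = "sugars_g",
    "fiber, total dietary" = "fibre_g", "fibre" = "fibre_g",
    "fiber" = "fibre_g", "fibre_g" = "fibre_g",
    "starch" = "starch_g", "starch_g" = "starch_g",
    "alcohol, ethyl" = "alcohol_g", "alcohol" = "alcohol_g",
    "alcohol_g" = "alcohol_g")
}

# Harmonize an amount to grams (masses) or kcal (energy).
# Returns list(value, kind) or NULL for an unknown unit.
normalize_unit <- function(amount, unit) {
  u <- tolower(trimws(unit))
  u <- sub("^µ", "u", u)  # µg -> ug
  if (u == "g")    return(list(value = amount,       kind = "mass"))
  if (u == "mg")   return(list(value = amount / 1e3, kind = "mass"))
  if (u == "ug")   return(list(value = amount / 1e6, kind = "mass"))
  if (u == "kcal") return(list(value = amount,       kind = "energy"))
  if (u == "kj")   return(list(value = amount / 4.184, kind = "energy"))
  NULL
}

#' Load a food-composition table into a food database
#'
#' Reads a long-format table (one row per food item x nutrient, per 100 g),
#' harmonizes units (mg and ug to g; kJ to kcal via /4.184), maps nutrient
#' names to metabolite identifiers, and converts masses to mmol/100g with
#' the supplied molecular weights. Nutrient names matching a macronutrient
#' (see [default_macro_map()]) populate the record's macronutrient fields;
#' nutrients with neither a macro nor a metabolite mapping, or mapped
#' metabolites lacking a molecular weight, are logged in the load report and
#' dropped.
#'
#' @param rows data frame of raw rows, or a path to a CSV/TSV file.
#' @param column_map a schema name for [food_schema()] or a column map list.
#' @param nutrient_map data frame with columns `nutrient_name`,
#'   `metabolite_id`, and optionally `group` (macronutrient group of the
#'   metabolite).
#' @param mw_table data frame with columns `metabolite_id`, `mw` (g/mol), or
#'   a named numeric vector.
#' @param macro_map named character vector overriding [default_macro_map()].
#' @return a `food_database`; per-row problems (unknown units, unmapped
#'   nutrients, duplicates) are collected in its `load_report`.
#' @examples
#' rows <- data.frame(fdc_id = "168191", description = "Dates, dried",
#'                    nutrient_name = "Glucose", amount = 10, unit_name = "g")
#' nmap <- data.frame(nutrient_name = "Glucose", metabolite_id = "glc_D",
#'                    group = "carbohydrate")
#' db <- load_food_table(rows, "usda-fdc", nmap, c(glc_D = 180.156))
#' get_record(db, "usda", "168191")$metabolites
#' @export
load_food_table <- function(rows, column_map = "usda-fdc", nutrient_map,
                            mw_table, macro_map = default_macro_map()) {
  cm <- if (is.character(column_map)) food_schema(column_map) else column_map
  if (is.character(rows) && length(rows) == 1) {
    sep <- if (grepl("\\.tsv$", rows)) "\t" else ","
    rows <- utils::read.table(rows, header = TRUE, sep = sep,
                              stringsAsFactors = FALSE, check.names = FALSE,
                              colClasses = "character")
  }
  needed <- c(cm$food_id, cm$description, cm$nutrient, cm$amount, cm$unit,
              cm$origin)
  assert_that(all(needed %in% names(rows)),
              paste0("missing columns: ",
                     paste(setdiff(needed, names(rows)), collapse = ", ")))
  if (!is.numeric(rows[[cm$amount]]))
    rows[[cm$amount]] <- as.numeric(rows[[cm$amount]])

  mw <- if (is.data.frame(mw_table))
    stats::setNames(as.numeric(mw_table$mw), mw_table$metabolite_id)
  else mw_table
  nmap <- stats::setNames(nutrient_map$metabolite_id,
                          tolower(trimws(nutrient_map$nutrient_name)))
  groups <- if ("group" %in% names(nutrient_map))
    stats::setNames(as.character(nutrient_map$group), nutrient_map$metabolite_id)
  else character(0)
  names(macro_map) <- tolower(names(macro_map))

  records <- list()
  report <- list()
  seen <- character(0)
  note <- function(fid, nutrient, problem)
    report[[length(report) + 1]] <<-
      data.frame(food_id = fid, nutrient = nutrient, problem = problem,
                 stringsAsFactors = FALSE)

  for (i in seq_len(nrow(rows))) {
    fid <- as.character(rows[[cm$food_id]][i])
    origin <- if (!is.null(cm$origin)) as.character(rows[[cm$origin]][i])
              else cm$default_origin
    key <- record_key(origin, fid)
    nutrient <- as.character(rows[[cm$nutrient]][i])
    amount <- rows[[cm$amount]][i]
    unit <- as.character(rows[[cm$unit]][i])
    if (is.null(records[[key]])) {
      records[[key]] <- new_food_record(
        fid, origin, as.character(rows[[cm$description]][i]))
    }
    dup_key <- paste(key, tolower(nutrient), sep = "|")
    if (dup_key %in% seen) {
      note(fid, nutrient, "duplicate nutrient row; kept first")
      next
    }
    seen <- c(seen, dup_key)
    if (is.na(amount) || amount < 0) {
      note(fid, nutrient, "missing or negative amount; row skipped")
      next
    }
    norm <- normalize_unit(amount, unit)
    if (is.null(norm)) {
      note(fid, nutrient, paste0("unknown unit '", unit, "'; row skipped"))
      next
    }
    macro_field <- unname(macro_map[tolower(trimws(nutrient))])
    if (!is.na(macro_field)) {
      if ((macro_field == "energy_kcal") != (norm$kind == "energy")) {
        note(fid, nutrient, "unit kind inconsistent with macronutrient; row skipped")
        next
      }
      records[[key]]$macronutrients[macro_field] <- norm$value
      next
    }
    if (norm$kind == "energy") {
      note(fid, nutrient, "energy unit on non-energy nutrient; row skipped")
      next
    }
    met <- unname(nmap[tolower(trimws(nutrient))])
    if (is.na(met)) {
      note(fid, nutrient, "no metabolite mapping; dropped")
      next
    }
    mwv <- unname(mw[met])
    if (is.na(mwv)) {
      note(fid, nutrient, paste0("no molecular weight for '", met, "'; dropped"))
      next
    }
    records[[key]]$metabolites[met] <- mass_to_mmol(norm$value, mwv)
  }
  report_df <- if (length(report)) do.call(rbind, report) else empty_load_report()
  food_database(records,
                molecular_weights = mw[!is.na(mw)],
                metabolite_group = groups,
                load_report = report_df)
}

#' Macronutrient masses implied by a record's measured metabolites
#'
#' Sums, per macronutrient group, the gram mass of the record's metabolites
#' (`mmol/100g * mw / 1000`). This is the "metabolites" series of the diet
#' analytics: it says how much of each macronutrient is actually represented
#' by measured metabolites, as opposed to the database-reported value.
#'
#' @param record a `food_record`.
#' @param db the `food_database` providing molecular weights and group
#'   assignments (metabolites without a group count as `"other"`).
#' @return named numeric vector over all groups (g per 100 g; absent groups 0).
#' @export
metabolite_derived_macros <- function(record, db) {
  out <- stats::setNames(numeric(length(MACRO_GROUPS)), MACRO_GROUPS)
  mets <- record$metabolites
  if (length(mets) == 0) return(out)
  mw <- db$molecular_weights[names(mets)]
  assert_that(!anyNA(mw), "record metabolite lacks molecular weight")
  grp <- db$metabolite_group[names(mets)]
  grp[is.na(grp) | !(grp %in% MACRO_GROUPS)] <- "other"
  mass <- mets * mw / 1000
  for (g in unique(grp)) out[g] <- sum(mass[grp == g])
  out
}

# ---------------------------------------------------------------------------
# Serialization: one tabular file holding records plus the molecular-weight
# and group tables (entry types mw/group extend the macro/metabolite rows so
# a single file round-trips the whole database).

#' Write a food database to a single TSV file
#'
#' Row types: `macro` and `metabolite` rows carry record entries; `mw` and
#' `group` rows carry the metabolite support tables.
#'
#' @param db a `food_database`.
#' @param path output TSV path.
#' @param report_path optional path for the load report text file.
#' @return `path`, invisibly.
#' @export
write_food_db <- function(db, path, report_path = NULL) {
  rows <- list()
  for (rec in db$records) {
    base <- data.frame(origin = rec$database_origin, id = rec$food_id,
                       description = rec$description,
                       stringsAsFactors = FALSE)
    if (length(rec$macronutrients))
      rows[[length(rows) + 1]] <- cbind(
        base[rep(1, length(rec$macronutrients)), ],
        entry_type = "macro", key = names(rec$macronutrients),
        value = as.numeric(rec$macronutrients),
        unit = ifelse(names(rec$macronutrients) == "energy_kcal",
                      "kcal", "g"))
    if (length(rec$metabolites))
      rows[[length(rows) + 1]] <- cbind(
        base[rep(1, length(rec$metabolites)), ],
        entry_type = "metabolite", key = names(rec$metabolites),
        value = as.numeric(rec$metabolites), unit = "mmol")
  }
  if (length(db$molecular_weights))
    rows[[length(rows) + 1]] <- data.frame(
      origin = "", id = "", description = "", entry_type = "mw",
      key = names(db$molecular_weights),
      value = as.numeric(db$molecular_weights), unit = "g/mol",
      stringsAsFactors = FALSE)
  if (length(db$metabolite_group))
    rows[[length(rows) + 1]] <- data.frame(
      origin = "", id = "", description = "", entry_type = "group",
      key = names(db$metabolite_group), value = NA_real_,
      unit = unname(db$metabolite_group), stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = TRUE)
  if (!is.null(report_path)) {
    rep <- db$load_report
    lines <- if (nrow(rep) == 0) "no load problems" else
      sprintf("%s\t%s\t%s", rep$food_id, rep$nutrient, rep$problem)
    writeLines(lines, report_path)
  }
  invisible(path)
}

#' Read a food database written by [write_food_db()]
#'
#' @param path TSV path.
#' @return a `food_database`.
#' @export
read_food_db <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = c(origin = "character",
                                          id = "character",
                                          description = "character",
                                          entry_type = "character",
                                          key = "character",
                                          value = "numeric",
                                          unit = "character"))
  mw_rows <- tab[tab$entry_type == "mw", ]
  grp_rows <- tab[tab$entry_type == "group", ]
  rec_rows <- tab[tab$entry_type %in% c("macro", "metabolite"), ]
  records <- list()
  for (key in unique(record_key(rec_rows$origin, rec_rows$id))) {
    sub <- rec_rows[record_key(rec_rows$origin, rec_rows$id) == key, ]
    mac <- sub[sub$entry_type == "macro", ]
    met <- sub[sub$entry_type == "metabolite", ]
    records[[key]] <- new_food_record(
      sub$id[1], sub$origin[1], sub$description[1],
      macronutrients = stats::setNames(mac$value, mac$key),
      metabolites = stats::setNames(met$value, met$key))
  }
  food_database(records,
                molecular_weights = stats::setNames(mw_rows$value, mw_rows$key),
                metabolite_group = stats::setNames(grp_rows$unit, grp_rows$key))
}
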