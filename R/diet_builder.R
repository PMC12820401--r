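# Compile chosen database food equivalents and consumed weights into per-diet
# metabolite flux vectors (mmol/day/person) and macronutrient/energy
# analytics.

#' Build an equivalentsConsumed table
#'
#' One row per chosen database food equivalent; one grams column per diet.
#' A food not consumed in a particular diet carries 0 g there.
#'
#' @param food_name dietary food item names (secondary check only).
#' @param food_id database ids of the chosen equivalents.
#' @param database_origin database of each equivalent (e.g. "usda").
#' @param grams data frame (or named list) with one non-negative numeric
#'   column per diet.
#' @return an `equivalents_consumed` data frame.
#' @export
equivalents_consumed <- function(food_name, food_id, database_origin, grams) {
  grams <- as.data.frame(grams, check.names = FALSE)
  assert_that(!anyDuplicated(names(grams)), "diet names must be unique")
  assert_that(all(vapply(grams, function(g) all(g >= 0), logical(1))),
              "consumed grams must be >= 0 (negative grams are rejected)")
  out <- data.frame(food_name = food_name, food_id = as.character(food_id),
                    database_origin = database_origin,
                    stringsAsFactors = FALSE)
  out <- cbind(out, grams)
  attr(out, "diets") <- names(grams)
  class(out) <- c("equivalents_consumed", "data.frame")
  out
}

#' Read an equivalentsConsumed file
#'
#' Expects the template header `FoodName, databaseID, databaseOrigin`
#' followed by one column per diet, values in grams; a trailing ` (g)` in a
#' diet column name is stripped.
#'
#' @param path CSV path.
#' @return an `equivalents_consumed` data frame.
#' @export
read_equivalents_consumed <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  assert_that(all(c("FoodName", "databaseID", "databaseOrigin") %in%
                    names(tab)),
              "equivalentsConsumed file lacks the template header")
  diet_cols <- setdiff(names(tab), c("FoodName", "databaseID", "databaseOrigin"))
  grams <- lapply(tab[diet_cols], as.numeric)
  names(grams) <- trimws(sub("\\s*\\(g\\)$", "", diet_cols))
  equivalents_consumed(tab$FoodName, tab$databaseID, tab$databaseOrigin,
                       as.data.frame(grams, check.names = FALSE))
}

#' Diet names available in an equivalentsConsumed table
#' @param consumed an `equivalents_consumed` data frame.
#' @return character vector of diet names.
#' @export
diet_names <- function(consumed) attr(consumed, "diets")

# Reported database macros folded to the group vocabulary, in grams:
# carbohydrate uses the reported total when present, else sugars + starch.
macro_fields_to_groups <- function(fields) {
  val <- function(f) { v <- unname(fields[f]); if (is.na(v)) 0 else v }
  carb <- if (!is.na(fields["carbohydrate_g"] %||% NA)) val("carbohydrate_g")
          else val("sugars_g") + val("starch_g")
  c(protein = val("protein_g"), lipid = val("lipid_g"),
    carbohydrate = carb, fibre = val("fibre_g"), alcohol = val("alcohol_g"))
}

#' Compile one in silico diet
#'
#' For each consumed food equivalent the per-100g metabolite amounts are
#' divided by 100 and multiplied by the consumed weight, then summed over
#' foods, yielding mmol/day/person. Macronutrient summaries are accumulated
#' the same way, both from the database-reported macros and from the
#' metabolite-derived masses, and energy fractions are computed for each.
#'
#' @param consumed an `equivalents_consumed` table; every (origin, id) must
#'   resolve in `db`.
#' @param db a `food_database`.
#' @param diet_name which grams column to use.
#' @param factors energy conversion factors for [energy_fractions()].
#' @return an `insilico_diet`: list with `diet_name`, `flux` (named
#'   mmol/day), `macros_database` (summed reported macro fields, g/day and
#'   kcal/day), `macros_database_groups` and `macros_metabolite` (g/day per
#'   group), and `energy_fractions` (list `database` / `metabolite`).
#' @export
build_diet <- function(consumed, db, diet_name,
                       factors = atwater_factors()) {
  assert_that(diet_name %in% diet_names(consumed),
              paste0("no diet named '", diet_name, "'"))
  keys <- record_key(consumed$database_origin, consumed$food_id)
  unresolved <- setdiff(keys, names(db$records))
  assert_that(length(unresolved) == 0,
              paste0("rows not resolvable in the food database: ",
                     paste(unresolved, collapse = ", ")))
  grams <- as.numeric(consumed[[diet_name]])
  assert_that(all(grams >= 0), "consumed grams must be >= 0")

  flux <- numeric(0)
  macros_db <- stats::setNames(numeric(length(MACRO_FIELDS)), MACRO_FIELDS)
  seen_field <- stats::setNames(logical(length(MACRO_FIELDS)), MACRO_FIELDS)
  macros_met <- stats::setNames(numeric(length(MACRO_GROUPS)), MACRO_GROUPS)
  for (i in seq_along(keys)) {
    g <- grams[i]
    if (g == 0) next                      # not consumed in this diet
    rec <- db$records[[keys[i]]]
    if (length(rec$metabolites)) {
      contrib <- rec$metabolites / 100 * g
      for (m in names(contrib))
        flux[m] <- (if (is.na(flux[m] %||% NA)) 0 else flux[m]) + contrib[[m]]
    }
    for (f in names(rec$macronutrients)) {
      macros_db[f] <- macros_db[f] + rec$macronutrients[[f]] / 100 * g
      seen_field[f] <- TRUE
    }
    macros_met <- macros_met + metabolite_derived_macros(rec, db) / 100 * g
  }
  flux <- flux[!is.na(flux)]
  macros_db[!seen_field] <- NA_real_     # never reported by any consumed food
  db_groups <- macro_fields_to_groups(macros_db)
  structure(list(
    diet_name = diet_name,
    flux = flux,
    macros_database = macros_db,
    macros_database_groups = db_groups,
    macros_metabolite = macros_met,
    energy_fractions = list(
      database = energy_fractions(db_groups, factors),
      metabolite = energy_fractions(macros_met, factors))
  ), class = "insilico_diet")
}

#' @export
print.insilico_diet <- function(x, ...) {
  cat(sprintf("<insilico_diet '%s': %d metabolites, %.1f kcal/day (database)>\n",
              x$diet_name, length(x$flux),
              unname(x$macros_database["energy_kcal"])))
  invisible(x)
}

#' Fractional contribution of macronutrient groups to dietary energy
#'
#' Group energy is mass (g/day) times its energy factor (kcal/g); the
#' fraction is group energy over total energy. All-zero energy yields `NA`
#' fractions (not applicable).
#'
#' @param masses named numeric vector of group masses in g/day (groups
#'   absent from `factors` contribute no energy).
#' @param factors named kcal/g factors; default [atwater_factors()].
#' @return named numeric vector of fractions over the factor groups, summing
#'   to 1 when total energy is positive.
#' @examples
#' energy_fractions(c(carbohydrate = 50, lipid = 50)) # 200 vs 450 kcal
#' @export
energy_fractions <- function(masses, factors = atwater_factors()) {
  groups <- names(factors)
  m <- stats::setNames(numeric(length(groups)), groups)
  common <- intersect(groups, names(masses))
  m[common] <- ifelse(is.na(masses[common]), 0, masses[common])
  energy <- m * factors[groups]
  total <- sum(energy)
  if (total <= 0) return(stats::setNames(rep(NA_real_, length(groups)), groups))
  energy / total
}

#' Compare an in silico diet's macros with the original diet
#'
#' @param diet an `insilico_diet`.
#' @param original_macros optional named vector of the original diet's group
#'   masses (g/day) and/or `energy_kcal` (kcal/day).
#' @return data frame with one row per group: database-derived and
#'   metabolite-derived values, plus the original value and differences
#'   (in silico minus original) when provided.
#' @export
compare_to_original <- function(diet, original_macros = NULL) {
  groups <- c(MACRO_GROUPS[MACRO_GROUPS != "other"], "energy_kcal")
  db_vals <- c(diet$macros_database_groups,
               energy_kcal = unname(diet$macros_database["energy_kcal"]))
  met_masses <- diet$macros_metabolite
  fac <- atwater_factors()
  met_energy <- sum(met_masses[names(fac)] * fac, na.rm = TRUE)
  met_vals <- c(met_masses[MACRO_GROUPS[MACRO_GROUPS != "other"]],
                energy_kcal = met_energy)
  out <- data.frame(group = groups,
                    database = unname(db_vals[groups]),
                    metabolite = unname(met_vals[groups]),
                    stringsAsFactors = FALSE)
  if (!is.null(original_macros)) {
    out$original <- unname(original_macros[groups])
    out$diff_database <- out$database - out$original
    out$diff_metabolite <- out$metabolite - out$original
  }
  out
}

#' Write per-diet outputs
#'
#' Emits, per diet: `<name>_flux.csv` (metabolite_id, mmol_per_day), a
#' combined `macro_summary.csv` (diet, group, source, g_per_day), and
#' `energy_fractions.csv` (diet, group, source, fraction).
#'
#' @param diets list of `insilico_diet` objects.
#' @param dir output directory (created if needed).
#' @return invisibly, the output directory.
#' @export
write_diet_outputs <- function(diets, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  macro_rows <- list(); frac_rows <- list()
  for (d in diets) {
    utils::write.csv(
      data.frame(metabolite_id = names(d$flux),
                 mmol_per_day = as.numeric(d$flux)),
      file.path(dir, paste0(d$diet_name, "_flux.csv")), row.names = FALSE)
    for (src in c("database", "metabolite")) {
      masses <- if (src == "database") d$macros_database_groups
                else d$macros_metabolite[names(d$macros_database_groups)]
      macro_rows[[length(macro_rows) + 1]] <- data.frame(
        diet = d$diet_name, group = names(masses), source = src,
        g_per_day = as.numeric(masses), stringsAsFactors = FALSE)
      fr <- d$energy_fractions[[src]]
      frac_rows[[length(frac_rows) + 1]] <- data.frame(
        diet = d$diet_name, group = names(fr), source = src,
        fraction = as.numeric(fr), stringsAsFactors = FALSE)
    }
  }
  utils::write.csv(do.call(rbind, macro_rows),
                   file.path(dir, "macro_summary.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, frac_rows),
                   file.path(dir, "energy_fractions.csv"), row.names = FALSE)
  invisible(dir)
}
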