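# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# Run code with a temporary RNG state seeded from `seed`; the caller's
# .Random.seed is restored afterwards so fixtures never disturb user RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Canonical macronutrient group vocabulary. Carbohydrate covers sugars and
# starch; fibre is kept as its own group because energy factors differ.
MACRO_GROUPS <- c("protein", "lipid", "carbohydrate", "fibre", "alcohol", "other")

# Macronutrient fields stored per 100 g on a FoodRecord.
MACRO_FIELDS <- c("energy_kcal", "lipid_g", "protein_g", "carbohydrate_g",
                  "sugars_g", "fibre_g", "starch_g", "alcohol_g")

# Fields eligible for the Euclidean macronutrient distance; total carbohydrate
# is deliberately absent (definitions are inconsistent across databases, so the
# individual components sugars/fibre/starch are compared instead).
DISTANCE_FIELDS <- c("energy_kcal", "lipid_g", "protein_g",
                     "sugars_g", "fibre_g", "starch_g")

# Energy densities in kcal/g used for energy-fraction analytics.
#' Default macronutrient energy conversion factors
#'
#' Atwater general factors (carbohydrate and protein 4 kcal/g, lipid 9 kcal/g)
#' extended with fibre (2 kcal/g) and alcohol (7 kcal/g). Used by
#' [energy_fractions()] and by the metabolite-level branch of
#' [optimize_diet()]; every consumer accepts an override.
#'
#' @return Named numeric vector of kcal per gram by macronutrient group.
#' @export
atwater_factors <- function() {
  c(carbohydrate = 4, protein = 4, lipid = 9, fibre = 2, alcohol = 7)
}

record_key <- function(origin, id) paste(origin, id, sep = ":")
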