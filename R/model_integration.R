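# Applying in silico diets to constraint-based models: diet-exchange bounds,
# food-item-constrained model construction (food exchange + breakdown +
# macronutrient sinks), feasibility checking and automatic repair.
#
# Sign convention: exchange flux negative = consumption (COBRA community
# practice). A diet exchange `Diet_EX_met[d]` has stoichiometry
# `met[d]: -1`, so negative flux feeds the metabolite into the model.

#' Translate a diet's flux vector into diet-exchange bounds
#'
#' Each metabolite at `flux` mmol/day becomes bounds
#' `(-flux, -enforce_fraction * flux)` on its diet exchange: uptake is
#' allowed up to the dietary amount, and forced at least
#' `enforce_fraction` of it (0 = purely optional, 1 = fully forced).
#'
#' @param diet an `insilico_diet` (or a named non-negative flux vector).
#' @param model a `metabolic_model`; metabolites whose diet exchange is not
#'   in the model are skipped with a warning.
#' @param naming sprintf template from metabolite id to reaction id.
#' @param enforce_fraction number in `[0, 1]`.
#' @return list with `constraints` (data frame reaction/lb/ub) and
#'   `skipped` (metabolite ids without a matching model reaction).
#' @export
diet_to_constraints <- function(diet, model, naming = "Diet_EX_%s[d]",
                                enforce_fraction = 0) {
  flux <- if (inherits(diet, "insilico_diet")) diet$flux else diet
  assert_that(all(flux >= 0), "diet fluxes must be >= 0")
  assert_that(enforce_fraction >= 0 && enforce_fraction <= 1,
              "enforce_fraction must be in [0, 1]")
  rxn_ids <- sprintf(naming, names(flux))
  known <- rxn_ids %in% model$rxns$id
  if (any(!known)) {
    warning(sum(!known), " dietary metabolite(s) have no exchange in the ",
            "model and were skipped", call. = FALSE)
  }
  list(constraints = data.frame(
         reaction = rxn_ids[known],
         lb = -as.numeric(flux[known]),
         ub = -enforce_fraction * as.numeric(flux[known]),
         stringsAsFactors = FALSE),
       skipped = names(flux)[!known])
}

#' Add food exchange, breakdown, and macronutrient sink reactions
#'
#' Turns a model into a food-item-constrained model for the given database
#' food equivalents. Per item `(origin, id)` this adds:
#' \itemize{
#'   \item an exchange `Food_EX_<origin>_<id>` over the food pseudo-
#'     metabolite `<origin>_<id>[f]` (flux unit g/day; negative flux =
#'     consumption; bounds start closed at (0, 0));
#'   \item a breakdown `Food_BD_<origin>_<id>`: 1 g of food item ->
#'     constituent metabolites in the diet compartment at `mmol/100g / 100`
#'     per gram, plus macronutrient pseudo-metabolites (`<field>[d]`) at
#'     `per-100g value / 100` per gram.
#' }
#' Each macronutrient pseudo-metabolite gets one sink `EX_<field>[d]`
#' (added once per model); sinks only remove, so these bookkeeping species
#' cannot alter any optimum. Breakdown metabolites absent from the model
#' are added together with an overflow sink `Food_Sink_<met>[d]` so forced
#' consumption cannot create a dead end.
#'
#' @param model a `metabolic_model`.
#' @param db a `food_database`.
#' @param items data frame with columns `origin`, `food_id` (or a list of
#'   2-vectors). Adding the same item twice is an error.
#' @return the extended model.
#' @export
add_food_reactions <- function(model, db, items) {
  if (is.list(items) && !is.data.frame(items)) {
    items <- data.frame(origin = vapply(items, `[`, "", 1),
                        food_id = vapply(items, `[`, "", 2),
                        stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(items))) {
    rec <- get_record(db, items$origin[i], items$food_id[i])
    tag <- paste(rec$database_origin, rec$food_id, sep = "_")
    food_met <- paste0(tag, "[f]")
    ex_id <- paste0("Food_EX_", tag)
    bd_id <- paste0("Food_BD_", tag)
    assert_that(!(ex_id %in% model$rxns$id),
                paste0("food item already added: ", tag))
    stoich <- c(stats::setNames(-1, food_met))
    if (length(rec$metabolites)) {
      met_ids <- paste0(names(rec$metabolites), "[d]")
      stoich <- c(stoich, stats::setNames(rec$metabolites / 100, met_ids))
      new_mets <- setdiff(met_ids, model$mets$id)
      for (m in new_mets) {
        model <- add_metabolites(model, m)
        model <- add_reaction(model,
                              paste0("Food_Sink_", sub("\\[d\\]$", "", m)),
                              stats::setNames(-1, m),
                              lb = 0, ub = DEFAULT_FLUX_BOUND)
      }
    }
    macros <- rec$macronutrients[!is.na(rec$macronutrients)]
    if (length(macros)) {
      macro_mets <- paste0(names(macros), "[d]")
      stoich <- c(stoich, stats::setNames(macros / 100, macro_mets))
      for (k in seq_along(macro_mets)) {
        sink_id <- paste0("EX_", names(macros)[k], "[d]")
        if (!(sink_id %in% model$rxns$id)) {
          model <- add_reaction(model, sink_id,
                                stats::setNames(-1, macro_mets[k]),
                                lb = 0, ub = DEFAULT_FLUX_BOUND)
        }
      }
    }
    model <- add_reaction(model, ex_id, stats::setNames(-1, food_met),
                          lb = 0, ub = 0)
    model <- add_reaction(model, bd_id, stoich,
                          lb = 0, ub = DEFAULT_FLUX_BOUND)
  }
  model
}

#' Food-exchange bounds for a consumed diet
#'
#' @param consumed an `equivalents_consumed` table.
#' @param diet_name which grams column to use.
#' @return data frame (reaction, lb, ub) with bounds `(-grams, 0)` per item,
#'   usable with [apply_diet()] on a food-item-constrained model.
#' @export
food_bounds <- function(consumed, diet_name) {
  grams <- as.numeric(consumed[[diet_name]])
  data.frame(
    reaction = paste0("Food_EX_",
                      paste(consumed$database_origin, consumed$food_id,
                            sep = "_")),
    lb = -grams, ub = 0, stringsAsFactors = FALSE)
}

#' Apply diet constraints to a model
#'
#' Overwrites exactly the listed reaction bounds; all other bounds are
#' untouched, and no reaction is added or removed. Accepts either an
#' `insilico_diet` (metabolite mode: translated via [diet_to_constraints()])
#' or a data frame of (reaction, lb, ub) such as [food_bounds()] output.
#'
#' @param model a `metabolic_model`.
#' @param constraints an `insilico_diet` or a constraints data frame.
#' @param ... passed to [diet_to_constraints()] when `constraints` is a
#'   diet.
#' @return the constrained model.
#' @export
apply_diet <- function(model, constraints, ...) {
  if (inherits(constraints, "insilico_diet")) {
    constraints <- diet_to_constraints(constraints, model, ...)$constraints
  }
  set_bounds(model, constraints$reaction, constraints$lb, constraints$ub)
}

#' Check model feasibility against a required objective
#'
#' Feasibility means the model can satisfy its maintenance objective:
#' the FBA optimum must reach `required_objective` (whole-body models
#' conventionally require 1).
#'
#' @param model a `metabolic_model` with an objective set.
#' @param required_objective minimum acceptable optimum (default 1).
#' @return a `feasibility_result`: list with `status` ("feasible"/
#'   "infeasible"), `objective_value` (NA when the LP is infeasible), and
#'   `adjustments` (empty; filled by [restore_feasibility()]).
#' @export
check_feasibility <- function(model, required_objective = 1) {
  res <- fba(model)
  if (res$status == "iteration_limit") {
    stop("LP solver failed (iteration limit); not an infeasibility verdict",
         call. = FALSE)
  }
  feasible <- res$status == "optimal" &&
    res$objective_value >= required_objective - 1e-9
  structure(list(status = if (feasible) "feasible" else "infeasible",
                 objective_value = if (res$status == "optimal")
                   res$objective_value else NA_real_,
                 adjustments = data.frame(metabolite_id = character(),
                                          added_mmol = numeric(),
                                          stringsAsFactors = FALSE)),
            class = "feasibility_result")
}

#' Restore feasibility by adding essential dietary metabolites
#'
#' Greedy repair for diets missing essential metabolites: in candidate
#' order, uptake of each candidate is opened/increased by its increment and
#' the model re-solved; the loop stops at the first feasible solve or after
#' `max_rounds` passes over the list. Bounds are only ever relaxed — no
#' uptake is reduced — and every change is recorded.
#'
#' @param model a `metabolic_model` already constrained by `diet`.
#' @param diet the applied `insilico_diet`.
#' @param essential_candidates named numeric vector: metabolite id ->
#'   increment in mmol/day, in trial order.
#' @param max_rounds maximum passes over the candidate list.
#' @param required_objective as in [check_feasibility()].
#' @param naming diet-exchange naming template.
#' @return list with `result` (a `feasibility_result` whose `adjustments`
#'   lists every addition), `diet` (the adjusted diet), and `model` (with
#'   relaxed bounds).
#' @export
restore_feasibility <- function(model, diet, essential_candidates,
                                max_rounds = 3, required_objective = 1,
                                naming = "Diet_EX_%s[d]") {
  adjustments <- data.frame(metabolite_id = character(),
                            added_mmol = numeric(), stringsAsFactors = FALSE)
  res <- check_feasibility(model, required_objective)
  round <- 0
  while (res$status == "infeasible" && round < max_rounds) {
    round <- round + 1
    for (k in seq_along(essential_candidates)) {
      met <- names(essential_candidates)[k]
      inc <- essential_candidates[[k]]
      rxn <- sprintf(naming, met)
      if (!(rxn %in% model$rxns$id)) next
      idx <- match(rxn, model$rxns$id)
      model$rxns$lb[idx] <- model$rxns$lb[idx] - inc   # relax uptake only
      diet$flux[met] <- (if (is.na(diet$flux[met] %||% NA)) 0
                         else diet$flux[met]) + inc
      adjustments <- rbind(adjustments,
                           data.frame(metabolite_id = met, added_mmol = inc,
                                      stringsAsFactors = FALSE))
      res <- check_feasibility(model, required_objective)
      if (res$status == "feasible") break
    }
  }
  diet$flux <- diet$flux[!is.na(diet$flux)]
  res$adjustments <- adjustments
  list(result = res, diet = diet, model = model)
}

#' Write diet constraints as CSV
#' @param constraints data frame (reaction, lb, ub).
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_diet_constraints <- function(constraints, path) {
  utils::write.csv(constraints, path, row.names = FALSE)
  invisible(path)
}

#' Read diet constraints from CSV
#'
#' Accepts two columns (reaction, lb; ub defaults to 0) or three.
#'
#' @param path CSV with a `reaction` column and `lb`/`ub`.
#' @return data frame (reaction, lb, ub).
#' @export
read_diet_constraints <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_that("reaction" %in% names(tab) && "lb" %in% names(tab),
              "constraints file needs 'reaction' and 'lb' columns")
  if (!("ub" %in% names(tab))) tab$ub <- 0
  tab[, c("reaction", "lb", "ub")]
}
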