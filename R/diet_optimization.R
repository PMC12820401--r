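# Minimal dietary changes that optimize target metabolic fluxes, at the
# database-food-equivalent (gram) or metabolite (mmol) level, under gram,
# caloric, and macronutrient-change constraints.
#
# Formulation: a two-stage lexicographic LP. Stage 1 finds the best
# achievable weighted target flux given the change budgets; stage 2 pins the
# target to at least `optimality_fraction` of that optimum and minimizes the
# L1 change (grams added plus grams removed), yielding the smallest diet
# modification that (nearly) attains the best shift.

#' Specify a diet optimization problem
#'
#' @param targets data frame with columns `reaction_id`, `direction`
#'   (`"maximize"`/`"minimize"`), `weight` (> 0); or a single reaction id
#'   (maximize, weight 1).
#' @param level `"food"` (changes in g/day of database food equivalents) or
#'   `"metabolite"` (changes in mmol/day of dietary metabolites).
#' @param max_added_g,max_removed_g change budgets in g/day (metabolite-level
#'   amounts are converted to grams via molecular weights, so the budgets
#'   apply uniformly).
#' @param caloric_range optional `c(kcal_min, kcal_max)` for the diet's
#'   energy content.
#' @param macro_tolerances optional named vector, macronutrient group ->
#'   maximum absolute change in g/day (e.g. `c(lipid = 0)` maintains lipid
#'   intake).
#' @param candidates items allowed to be added: food level, a data frame
#'   with columns `origin`, `food_id`; metabolite level, a character vector
#'   of metabolite ids. Default: none (only removals possible).
#' @param optimality_fraction f in (0, 1]: stage 2 must retain at least
#'   `f` of the stage-1 optimum.
#' @param shared_budget when `TRUE`, additions and removals draw on one
#'   combined `max_added_g` budget.
#' @return an `optimization_spec`.
#' @export
optimization_spec <- function(targets, level = c("food", "metabolite"),
                              max_added_g = 0, max_removed_g = 0,
                              caloric_range = NULL, macro_tolerances = NULL,
                              candidates = NULL, optimality_fraction = 0.999,
                              shared_budget = FALSE) {
  if (is.character(targets)) {
    targets <- data.frame(reaction_id = targets, direction = "maximize",
                          weight = 1, stringsAsFactors = FALSE)
  }
  assert_that(all(c("reaction_id", "direction", "weight") %in% names(targets)),
              "targets need reaction_id, direction, weight")
  assert_that(all(targets$direction %in% c("maximize", "minimize")),
              "direction must be maximize or minimize")
  assert_that(all(targets$weight > 0), "target weights must be > 0")
  assert_that(max_added_g >= 0 && max_removed_g >= 0,
              "change budgets must be >= 0")
  if (!is.null(caloric_range)) {
    assert_that(length(caloric_range) == 2 &&
                  caloric_range[1] <= caloric_range[2],
                "caloric_range must be c(kcal_min, kcal_max)")
  }
  assert_that(optimality_fraction > 0 && optimality_fraction <= 1,
              "optimality_fraction must be in (0, 1]")
  structure(list(targets = targets, level = match.arg(level),
                 max_added_g = max_added_g, max_removed_g = max_removed_g,
                 caloric_range = caloric_range,
                 macro_tolerances = macro_tolerances,
                 candidates = candidates,
                 optimality_fraction = optimality_fraction,
                 shared_budget = shared_budget),
            class = "optimization_spec")
}

# Map group name -> macronutrient sink reaction id of the food-item-
# constrained model.
group_sink_id <- function(group) {
  field <- c(protein = "protein_g", lipid = "lipid_g",
             carbohydrate = "carbohydrate_g", fibre = "fibre_g",
             alcohol = "alcohol_g")[[group]]
  paste0("EX_", field, "[d]")
}

#' Compute the minimal dietary change optimizing target fluxes
#'
#' Solves the two-stage lexicographic LP described in
#' [optimization_spec()]. Change variables `add_i` / `rem_i` per candidate
#' relax (never force) the corresponding exchange bound: effective
#' availability is `current_i + add_i - rem_i`. Constraints: steady state,
#' model bounds, the change budgets, and — when requested — the caloric
#' range and per-group macronutrient tolerances (food level: expressed on
#' the macronutrient sink fluxes; metabolite level: on the planned changes
#' via molecular weights and energy factors).
#'
#' @param model for `level = "food"`, a food-item-constrained model (see
#'   [add_food_reactions()]) containing every consumed and candidate item;
#'   for `level = "metabolite"`, a metabolite-constrained model. The model
#'   must be feasible under the baseline diet.
#' @param diet the baseline: an `equivalents_consumed` table (food level)
#'   or an `insilico_diet` (metabolite level).
#' @param spec an `optimization_spec`.
#' @param db the `food_database` (food records, molecular weights, groups).
#' @param diet_name grams column of `diet` to use (food level).
#' @param factors energy factors for metabolite-level caloric bookkeeping.
#' @return a `diet_change_plan`: `added` and `removed` (named amounts, g/day
#'   or mmol/day), `baseline_target_flux` and `achieved_target_flux` (named
#'   per target reaction), `stage1_value` (weighted signed optimum),
#'   `new_macros` (g/day per group plus `energy_kcal`), `level`, `unit`.
#' @export
optimize_diet <- function(model, diet, spec, db, diet_name = NULL,
                          factors = atwater_factors()) {
  stopifnot(inherits(spec, "optimization_spec"))
  tid <- spec$targets$reaction_id
  assert_that(all(tid %in% model$rxns$id),
              paste0("target reaction(s) not in model: ",
                     paste(setdiff(tid, model$rxns$id), collapse = ", ")))
  if (spec$level == "food") {
    optimize_diet_food(model, diet, spec, db, diet_name)
  } else {
    optimize_diet_metabolite(model, diet, spec, db, factors)
  }
}

# Shared solve path: builds the LP from a prepared problem description and
# runs both stages plus the baseline solve.
solve_two_stage <- function(model, items, spec, extra_rows,
                            couple_dir = "<=") {
  # items: data.frame(exchange, current, can_add, can_rem, add_cap,
  #                   grams_per_unit)  [grams_per_unit converts one change
  #                   unit to grams for the budgets]
  nr <- nrow(model$rxns)
  add_idx <- which(items$can_add)
  rem_idx <- which(items$can_rem)
  na_ <- length(add_idx); nrm <- length(rem_idx)
  nv <- nr + na_ + nrm
  col_a <- function(k) nr + k                 # k-th add variable
  col_r <- function(k) nr + na_ + k

  lb <- c(model$rxns$lb, rep(0, na_ + nrm))
  ub <- c(model$rxns$ub, items$add_cap[add_idx], items$current[rem_idx])
  ex_col <- match(items$exchange, model$rxns$id)
  assert_that(!anyNA(ex_col),
              paste0("exchange reaction(s) missing from model: ",
                     paste(items$exchange[is.na(ex_col)], collapse = ", ")))
  # availability bounds on the exchange fluxes themselves
  lb[ex_col] <- -(items$current + ifelse(items$can_add, items$add_cap, 0))
  ub[ex_col] <- pmin(ub[ex_col], 0)

  S <- as.matrix(model$S)
  rows <- list(); dir <- character(0); rhs <- numeric(0)
  push <- function(row, d, b) {
    rows[[length(rows) + 1]] <<- row; dir <<- c(dir, d); rhs <<- c(rhs, b)
  }
  # steady state
  steady <- cbind(S, matrix(0, nrow(S), na_ + nrm))
  # coupling: -v_e - a + r (dir) current. Food level uses equality (the
  # planned diet is eaten in full; overflow leaves via excretion/sink
  # routes), metabolite level uses <= (uptake up to the planned amount).
  for (i in seq_len(nrow(items))) {
    row <- numeric(nv); row[ex_col[i]] <- -1
    ka <- match(i, add_idx); kr <- match(i, rem_idx)
    if (!is.na(ka)) row[col_a(ka)] <- -1
    if (!is.na(kr)) row[col_r(kr)] <- 1
    push(row, couple_dir, items$current[i])
  }
  # budgets (in grams)
  if (na_ > 0) {
    row <- numeric(nv)
    row[vapply(seq_len(na_), col_a, 0)] <- items$grams_per_unit[add_idx]
    if (spec$shared_budget && nrm > 0)
      row[vapply(seq_len(nrm), col_r, 0)] <- items$grams_per_unit[rem_idx]
    push(row, "<=", spec$max_added_g)
  }
  if (!spec$shared_budget && nrm > 0) {
    row <- numeric(nv)
    row[vapply(seq_len(nrm), col_r, 0)] <- items$grams_per_unit[rem_idx]
    push(row, "<=", spec$max_removed_g)
  }
  for (er in extra_rows) push(er$row, er$dir, er$rhs)

  con_mat <- rbind(steady, do.call(rbind, rows))
  con_dir <- c(rep("==", nrow(S)), dir)
  con_rhs <- c(rep(0, nrow(S)), rhs)

  obj <- numeric(nv)
  sgn <- ifelse(spec$targets$direction == "maximize", 1, -1)
  obj[match(spec$targets$reaction_id, model$rxns$id)] <-
    sgn * spec$targets$weight

  solve_stage <- function(lb_, ub_, extra_mat = NULL, extra_dir = NULL,
                          extra_rhs = NULL, objective = obj,
                          maximize = TRUE) {
    m <- con_mat; d <- con_dir; b <- con_rhs
    if (!is.null(extra_mat)) {
      m <- rbind(m, extra_mat); d <- c(d, extra_dir); b <- c(b, extra_rhs)
    }
    solve_lp(objective, m, d, b, lb_, ub_, maximize = maximize)
  }

  # baseline: no changes allowed
  ub_base <- ub
  if (na_ + nrm > 0) ub_base[(nr + 1):nv] <- 0
  lb_base <- lb
  lb_base[ex_col] <- -items$current
  base <- solve_stage(lb_base, ub_base)

  stage1 <- solve_stage(lb, ub)
  diagnose <- function() {
    # name the first constraint family whose removal restores feasibility
    fam <- list(macro_tolerances = vapply(extra_rows, function(e)
                  identical(e$family, "macro"), logical(1)),
                caloric_range = vapply(extra_rows, function(e)
                  identical(e$family, "caloric"), logical(1)))
    for (f in names(fam)) {
      if (!any(fam[[f]])) next
      keep <- extra_rows[!fam[[f]]]
      m2 <- rbind(steady, do.call(rbind, rows[seq_len(length(rows) -
                                                      length(extra_rows))]))
      for (er in keep) m2 <- rbind(m2, matrix(er$row, 1))
      d2 <- c(rep("==", nrow(S)), dir[seq_len(length(dir) - length(extra_rows))],
              vapply(keep, `[[`, "", "dir"))
      b2 <- c(rep(0, nrow(S)), rhs[seq_len(length(rhs) - length(extra_rows))],
              vapply(keep, function(e) e$rhs, 0))
      if (solve_lp(obj, m2, d2, b2, lb, ub)$status == "optimal") return(f)
    }
    "model/bounds"
  }
  if (stage1$status != "optimal") {
    stop("diet optimization infeasible; binding constraint group: ",
         diagnose(), call. = FALSE)
  }
  f <- spec$optimality_fraction
  thr <- if (stage1$value >= 0) f * stage1$value else stage1$value / f
  l1 <- numeric(nv)
  if (na_ + nrm > 0) l1[(nr + 1):nv] <- 1
  stage2 <- solve_stage(lb, ub,
                        extra_mat = matrix(obj, 1), extra_dir = ">=",
                        extra_rhs = thr, objective = l1, maximize = FALSE)
  assert_that(stage2$status == "optimal",
              "stage-2 solve failed despite feasible stage 1")
  achieved_signed <- sum(obj * stage2$solution)
  assert_that(achieved_signed >= thr - 1e-6,
              "optimality-fraction guarantee violated")
  x <- stage2$solution
  add <- stats::setNames(x[nr + seq_len(na_)], items$exchange[add_idx])
  rem <- stats::setNames(x[nr + na_ + seq_len(nrm)], items$exchange[rem_idx])
  add[add < 1e-9] <- 0; rem[rem < 1e-9] <- 0
  list(baseline = base, stage1 = stage1, stage2 = stage2,
       achieved_signed = achieved_signed,
       add = add, rem = rem, add_idx = add_idx, rem_idx = rem_idx,
       fluxes = stats::setNames(x[seq_len(nr)], model$rxns$id),
       baseline_fluxes = if (is.null(base$solution)) NULL else
         stats::setNames(base$solution[seq_len(nr)], model$rxns$id))
}

optimize_diet_food <- function(model, consumed, spec, db, diet_name) {
  assert_that(inherits(consumed, "equivalents_consumed"),
              "food-level optimization needs an equivalents_consumed baseline")
  assert_that(!is.null(diet_name) && diet_name %in% diet_names(consumed),
              "diet_name must name a grams column")
  cur <- stats::setNames(as.numeric(consumed[[diet_name]]),
                         record_key(consumed$database_origin,
                                    consumed$food_id))
  cand_keys <- if (is.null(spec$candidates)) character(0) else
    record_key(spec$candidates$origin, spec$candidates$food_id)
  keys <- union(names(cur), cand_keys)
  cur_k <- unname(cur[keys])
  items <- data.frame(
    key = keys,
    exchange = paste0("Food_EX_", sub(":", "_", keys, fixed = TRUE)),
    current = ifelse(is.na(cur_k), 0, cur_k),
    can_add = keys %in% cand_keys,
    can_rem = !is.na(cur_k) & cur_k > 0,
    grams_per_unit = 1, stringsAsFactors = FALSE)
  items$add_cap <- ifelse(items$can_add, spec$max_added_g, 0)

  recs <- lapply(keys, function(k) db$records[[k]])
  assert_that(!any(vapply(recs, is.null, logical(1))),
              "all consumed and candidate items must resolve in the database")

  nv_rxn <- nrow(model$rxns)
  extra_rows <- list()
  nv_total <- nv_rxn + sum(items$can_add) + sum(items$can_rem)
  sink_row <- function(rxn_id) {
    idx <- match(rxn_id, model$rxns$id)
    assert_that(!is.na(idx), paste0("model lacks sink reaction ", rxn_id,
                                    " needed for a macro/caloric constraint"))
    row <- numeric(nv_total); row[idx] <- 1
    row
  }
  if (!is.null(spec$caloric_range)) {
    row <- sink_row("EX_energy_kcal[d]")
    extra_rows <- c(extra_rows,
                    list(list(row = row, dir = ">=",
                              rhs = spec$caloric_range[1], family = "caloric"),
                         list(row = row, dir = "<=",
                              rhs = spec$caloric_range[2], family = "caloric")))
  }
  for (g in names(spec$macro_tolerances)) {
    tol <- spec$macro_tolerances[[g]]
    base_g <- sum(vapply(seq_along(recs), function(i) {
      v <- recs[[i]]$macronutrients[sub("EX_(.*)\\[d\\]", "\\1",
                                        group_sink_id(g))]
      if (is.na(v)) 0 else v / 100 * items$current[i]
    }, 0))
    row <- sink_row(group_sink_id(g))
    extra_rows <- c(extra_rows,
                    list(list(row = row, dir = "<=", rhs = base_g + tol,
                              family = "macro"),
                         list(row = row, dir = ">=",
                              rhs = max(0, base_g - tol), family = "macro")))
  }

  sol <- solve_two_stage(model, items, spec, extra_rows, couple_dir = "==")
  new_grams <- items$current
  new_grams[items$can_add] <- new_grams[items$can_add] + sol$add
  rem_full <- stats::setNames(numeric(nrow(items)), items$exchange)
  rem_full[names(sol$rem)] <- sol$rem
  new_grams <- new_grams - rem_full[items$exchange]

  macro_fields <- stats::setNames(rep(NA_real_, length(MACRO_FIELDS)),
                                  MACRO_FIELDS)
  for (i in seq_along(recs)) {
    mk <- recs[[i]]$macronutrients
    mk <- mk[!is.na(mk)]
    for (fld in names(mk)) {
      if (is.na(macro_fields[fld])) macro_fields[fld] <- 0
      macro_fields[fld] <- macro_fields[fld] + mk[[fld]] / 100 * new_grams[i]
    }
  }
  new_macros <- c(macro_fields_to_groups(macro_fields),
                  energy_kcal = unname(macro_fields["energy_kcal"]))
  build_plan(sol, spec, items, unit = "g/day", new_macros = new_macros,
             label = items$key)
}

optimize_diet_metabolite <- function(model, diet, spec, db, factors) {
  assert_that(inherits(diet, "insilico_diet"),
              "metabolite-level optimization needs an insilico_diet baseline")
  cur <- diet$flux
  cand <- spec$candidates %||% character(0)
  assert_that(is.character(cand), "metabolite-level candidates must be ids")
  mets <- union(names(cur), cand)
  ex_ids <- sprintf("Diet_EX_%s[d]", mets)
  known <- ex_ids %in% model$rxns$id
  if (any(!known & !(mets %in% cand))) {
    warning("skipping dietary metabolite(s) without model exchange: ",
            paste(mets[!known & !(mets %in% cand)], collapse = ", "),
            call. = FALSE)
  }
  assert_that(all(known[mets %in% cand]),
              "candidate metabolites must have a diet exchange in the model")
  mets <- mets[known]; ex_ids <- ex_ids[known]
  mw <- db$molecular_weights[mets]
  assert_that(!anyNA(mw), "all metabolites need molecular weights for budgets")
  gpu <- as.numeric(mw) / 1000           # grams per mmol
  current <- ifelse(is.na(cur[mets]), 0, cur[mets])
  items <- data.frame(
    key = mets, exchange = ex_ids, current = as.numeric(current),
    can_add = mets %in% cand,
    can_rem = as.numeric(current) > 0,
    grams_per_unit = gpu, stringsAsFactors = FALSE)
  items$add_cap <- ifelse(items$can_add, spec$max_added_g / gpu, 0)

  grp <- db$metabolite_group[mets]
  grp[is.na(grp) | !(grp %in% MACRO_GROUPS)] <- "other"
  kcal_per_unit <- gpu * ifelse(is.na(factors[grp]), 0, factors[grp])

  nv_rxn <- nrow(model$rxns)
  na_ <- sum(items$can_add); nrm <- sum(items$can_rem)
  nv_total <- nv_rxn + na_ + nrm
  add_pos <- nv_rxn + seq_len(na_)
  rem_pos <- nv_rxn + na_ + seq_len(nrm)
  delta_row <- function(coef_by_item) {
    # row with +coef on adds, -coef on removals (planned change)
    row <- numeric(nv_total)
    row[add_pos] <- coef_by_item[items$can_add]
    row[rem_pos] <- -coef_by_item[items$can_rem]
    row
  }
  extra_rows <- list()
  if (!is.null(spec$caloric_range)) {
    base_kcal <- sum(diet$macros_metabolite[names(factors)] * factors,
                     na.rm = TRUE)
    row <- delta_row(kcal_per_unit)
    extra_rows <- c(extra_rows,
      list(list(row = row, dir = ">=", rhs = spec$caloric_range[1] - base_kcal,
                family = "caloric"),
           list(row = row, dir = "<=", rhs = spec$caloric_range[2] - base_kcal,
                family = "caloric")))
  }
  for (g in names(spec$macro_tolerances)) {
    tol <- spec$macro_tolerances[[g]]
    coef <- ifelse(grp == g, gpu, 0)
    row <- delta_row(coef)
    extra_rows <- c(extra_rows,
      list(list(row = row, dir = "<=", rhs = tol, family = "macro"),
           list(row = row, dir = ">=", rhs = -tol, family = "macro")))
  }
  sol <- solve_two_stage(model, items, spec, extra_rows)

  delta_mass <- stats::setNames(numeric(length(MACRO_GROUPS)), MACRO_GROUPS)
  add_full <- stats::setNames(numeric(nrow(items)), items$exchange)
  add_full[names(sol$add)] <- sol$add
  rem_full <- stats::setNames(numeric(nrow(items)), items$exchange)
  rem_full[names(sol$rem)] <- sol$rem
  net <- add_full - rem_full
  for (i in seq_len(nrow(items)))
    delta_mass[grp[i]] <- delta_mass[grp[i]] + net[i] * gpu[i]
  masses <- diet$macros_metabolite + delta_mass
  new_macros <- c(masses,
                  energy_kcal = sum(masses[names(factors)] * factors,
                                    na.rm = TRUE))
  build_plan(sol, spec, items, unit = "mmol/day", new_macros = new_macros,
             label = items$key)
}

build_plan <- function(sol, spec, items, unit, new_macros, label) {
  tid <- spec$targets$reaction_id
  added <- stats::setNames(as.numeric(sol$add), label[sol$add_idx])
  removed <- stats::setNames(as.numeric(sol$rem), label[sol$rem_idx])
  structure(list(
    added = added[added > 0],
    removed = removed[removed > 0],
    baseline_target_flux = if (is.null(sol$baseline_fluxes))
      stats::setNames(rep(NA_real_, length(tid)), tid)
    else sol$baseline_fluxes[tid],
    achieved_target_flux = sol$fluxes[tid],
    baseline_value = sol$baseline$value,
    stage1_value = sol$stage1$value,
    achieved_value = sol$achieved_signed,
    new_macros = new_macros,
    level = spec$level, unit = unit,
    optimality_fraction = spec$optimality_fraction
  ), class = "diet_change_plan")
}

#' @export
print.diet_change_plan <- function(x, ...) {
  cat(sprintf("<diet_change_plan (%s): %d added, %d removed>\n",
              x$level, length(x$added), length(x$removed)))
  invisible(x)
}

#' Summarize a diet change plan
#'
#' @param plan a `diet_change_plan`.
#' @param db a `food_database` (descriptions and energy for food-level
#'   plans).
#' @return list with `changes` (data frame item/action/amount/unit) and
#'   `summary` (target fluxes and macro totals); printed as a readable
#'   report when no change is needed the table is empty and the summary
#'   says so.
#' @export
summarize_plan <- function(plan, db = NULL) {
  rows <- list()
  describe <- function(key) {
    if (is.null(db)) return(key)
    rec <- db$records[[key]]
    if (is.null(rec)) key else rec$description
  }
  for (nm in names(plan$added))
    rows[[length(rows) + 1]] <- data.frame(
      item = nm, description = describe(nm), action = "added",
      amount = plan$added[[nm]], unit = plan$unit, stringsAsFactors = FALSE)
  for (nm in names(plan$removed))
    rows[[length(rows) + 1]] <- data.frame(
      item = nm, description = describe(nm), action = "removed",
      amount = plan$removed[[nm]], unit = plan$unit, stringsAsFactors = FALSE)
  changes <- if (length(rows)) do.call(rbind, rows) else
    data.frame(item = character(), description = character(),
               action = character(), amount = numeric(), unit = character())
  list(changes = changes,
       no_change = nrow(changes) == 0,
       baseline_target_flux = plan$baseline_target_flux,
       achieved_target_flux = plan$achieved_target_flux,
       new_macros = plan$new_macros)
}

#' Write a diet change plan
#'
#' Emits `plan.csv` (item, action, amount, unit) and `summary.json`
#' (baseline and achieved target fluxes, macro totals).
#'
#' @param plan a `diet_change_plan`.
#' @param dir output directory.
#' @param db optional `food_database` for descriptions.
#' @return invisibly, the directory.
#' @export
write_plan <- function(plan, dir, db = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- summarize_plan(plan, db)
  utils::write.csv(s$changes, file.path(dir, "plan.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(baseline_target_flux = as.list(s$baseline_target_flux),
         achieved_target_flux = as.list(s$achieved_target_flux),
         new_macros = as.list(plan$new_macros),
         level = plan$level),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
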