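# Shared fixtures, built once per test run.

toy_db <- function() {
  if (is.null(.fixture_env$db))
    .fixture_env$db <- make_toy_food_db(fixture_spec(seed = 1))
  .fixture_env$db
}

toy_db_apples <- function() {
  if (is.null(.fixture_env$db51))
    .fixture_env$db51 <- make_toy_food_db(fixture_spec(seed = 1,
                                                       apple_hits = 51))
  .fixture_env$db51
}

toy_model <- function() {
  if (is.null(.fixture_env$model))
    .fixture_env$model <- make_toy_wbm()
  .fixture_env$model
}

.fixture_env <- new.env(parent = emptyenv())

red_apple_item <- function() {
  dietary_food_item("Red apple", c("Apple", "Red"), 150,
                    c(energy_kcal = 91.4, lipid_g = 0.1, protein_g = 0.4,
                      sugars_g = 15.5))
}

# Brute-force oracle: sweep the added grams of one candidate food over a
# grid, computing the target optimum by plain FBA at each point; the
# two-stage LP must agree with (max value, minimal grams reaching the
# optimality fraction of it).
grid_oracle <- function(model, cons, diet_name, candidate_ex, target,
                        budget, f, step = 0.1) {
  cur <- stats::setNames(as.numeric(cons[[diet_name]]),
                         paste0("Food_EX_",
                                paste(cons$database_origin, cons$food_id,
                                      sep = "_")))
  vals <- vapply(seq(0, budget, by = step), function(g) {
    bounds <- data.frame(reaction = names(cur), lb = -unname(cur), ub = 0)
    i <- match(candidate_ex, bounds$reaction)
    if (is.na(i)) {
      bounds <- rbind(bounds, data.frame(reaction = candidate_ex, lb = -g,
                                         ub = 0))
    } else bounds$lb[i] <- bounds$lb[i] - g
    m <- apply_diet(model, bounds)
    fba(m, objective = target)$objective_value
  }, 0)
  grid <- seq(0, budget, by = step)
  best <- max(vals)
  list(best = best, grams = grid[which(vals >= f * best)[1]])
}

# food-item-constrained toy model over the toy baseline diet (plus extra
# candidate items), with maintenance flux >= 1 enforced
toy_food_model <- function(extra_items = NULL) {
  cons <- make_toy_diet()
  items <- data.frame(origin = cons$database_origin, food_id = cons$food_id)
  m <- add_food_reactions(toy_model(), toy_db(), items)
  if (!is.null(extra_items)) m <- add_food_reactions(m, toy_db(), extra_items)
  set_bounds(m, "MAINT", 1, 1e4)
}
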