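# Constraint-based metabolic model container and I/O.
#
# A `metabolic_model` holds a stoichiometric matrix (metabolites x reactions,
# sparse), reaction bounds, and one objective reaction. Metabolite ids carry
# their compartment in COBRA bracket style, e.g. "glc_D[d]" for the diet
# compartment, "foodname[f]" for the food pseudo-compartment.

#' Create an empty constraint-based metabolic model
#'
#' @param id model identifier.
#' @return an object of class `metabolic_model` with no metabolites or
#'   reactions. Populate it with [add_metabolites()] and [add_reaction()].
#' @seealso [fba()], [read_cobra_json()], [read_sbml_model()]
#' @export
metabolic_model <- function(id = "model") {
  structure(
    list(
      id = id,
      mets = data.frame(id = character(), compartment = character(),
                        stringsAsFactors = FALSE),
      rxns = data.frame(id = character(), lb = numeric(), ub = numeric(),
                        obj = numeric(), stringsAsFactors = FALSE),
      S = Matrix::Matrix(0, 0, 0, sparse = TRUE, doDiag = FALSE)
    ),
    class = "metabolic_model"
  )
}

fmt17 <- function(x) vapply(x, function(v) format(v, digits = 17), character(1))

#' Add metabolites to a model
#'
#' @param model a `metabolic_model`.
#' @param ids character vector of metabolite ids (compartment in brackets,
#'   e.g. `"glc_D[d]"`). Ids already present are ignored.
#' @return the updated model.
#' @export
add_metabolites <- function(model, ids) {
  stopifnot(inherits(model, "metabolic_model"))
  new <- setdiff(ids, model$mets$id)
  if (length(new) == 0) return(model)
  comp <- vapply(new, function(x) {
    hit <- regmatches(x, regexpr("\\[[^]]+\\]$", x))
    if (length(hit)) gsub("[][]", "", hit) else ""
  }, character(1))
  model$mets <- rbind(model$mets,
                      data.frame(id = new, compartment = unname(comp),
                                 stringsAsFactors = FALSE))
  S_new <- Matrix::Matrix(0, length(new), ncol(model$S), sparse = TRUE)
  model$S <- rbind(model$S, S_new)
  rownames(model$S) <- model$mets$id
  if (ncol(model$S) > 0) colnames(model$S) <- model$rxns$id
  model
}

#' Add a reaction to a model
#'
#' @param model a `metabolic_model`.
#' @param id reaction id; must be new.
#' @param stoich named numeric vector, metabolite id -> coefficient
#'   (negative = consumed). Metabolites not yet in the model are added.
#' @param lb,ub flux bounds; `lb <= ub` required.
#' @param obj objective coefficient (default 0).
#' @return the updated model.
#' @export
add_reaction <- function(model, id, stoich, lb, ub, obj = 0) {
  stopifnot(inherits(model, "metabolic_model"))
  assert_that(!(id %in% model$rxns$id), paste0("duplicate reaction id: ", id))
  assert_that(lb <= ub, paste0("lb > ub for reaction ", id))
  model <- add_metabolites(model, names(stoich))
  col <- Matrix::Matrix(0, nrow(model$S), 1, sparse = TRUE)
  rownames(col) <- model$mets$id
  col[names(stoich), 1] <- as.numeric(stoich)
  model$S <- cbind(model$S, col)
  model$rxns <- rbind(model$rxns,
                      data.frame(id = id, lb = lb, ub = ub, obj = obj,
                                 stringsAsFactors = FALSE))
  dimnames(model$S) <- list(model$mets$id, model$rxns$id)
  model
}

#' Set reaction flux bounds
#'
#' Overwrites bounds of existing reactions exactly; all other bounds are
#' untouched.
#'
#' @param model a `metabolic_model`.
#' @param ids reaction ids; all must exist.
#' @param lb,ub numeric, recycled over `ids`.
#' @return the updated model.
#' @export
set_bounds <- function(model, ids, lb, ub) {
  idx <- match(ids, model$rxns$id)
  assert_that(!anyNA(idx),
              paste0("unknown reaction id(s): ",
                     paste(ids[is.na(idx)], collapse = ", ")))
  model$rxns$lb[idx] <- rep_len(lb, length(idx))
  model$rxns$ub[idx] <- rep_len(ub, length(idx))
  assert_that(all(model$rxns$lb[idx] <= model$rxns$ub[idx]),
              "lb > ub after set_bounds")
  model
}

#' Set the model objective
#'
#' @param model a `metabolic_model`.
#' @param reaction_id id of the reaction to optimize; must exist.
#' @return the updated model (objective coefficient 1 on `reaction_id`, 0
#'   elsewhere).
#' @export
set_objective <- function(model, reaction_id) {
  assert_that(reaction_id %in% model$rxns$id,
              paste0("unknown objective reaction: ", reaction_id))
  model$rxns$obj <- as.numeric(model$rxns$id == reaction_id)
  model
}

objective_id <- function(model) {
  hit <- model$rxns$id[model$rxns$obj != 0]
  if (length(hit)) hit[1] else NA_character_
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model '%s': %d metabolites, %d reactions, objective %s>\n",
              x$id, nrow(x$mets), nrow(x$rxns), objective_id(x)))
  invisible(x)
}

#' Flux balance analysis
#'
#' Maximizes (or minimizes) flux through an objective reaction subject to the
#' steady-state constraint `S v = 0` and the reaction bounds.
#'
#' @param model a `metabolic_model`.
#' @param objective reaction id to optimize; defaults to the model objective.
#' @param maximize logical.
#' @return list with `status` ("optimal"/"infeasible"/"iteration_limit"),
#'   `objective_value`, and `fluxes` (named vector over reactions).
#' @export
fba <- function(model, objective = NULL, maximize = TRUE) {
  stopifnot(inherits(model, "metabolic_model"))
  objective <- objective %||% objective_id(model)
  assert_that(!is.na(objective) && objective %in% model$rxns$id,
              "no objective reaction set")
  obj <- as.numeric(model$rxns$id == objective)
  n_m <- nrow(model$mets)
  sol <- solve_lp(obj, model$S, rep("==", n_m), rep(0, n_m),
                  model$rxns$lb, model$rxns$ub, maximize = maximize)
  fluxes <- if (is.null(sol$solution)) NULL else
    stats::setNames(sol$solution, model$rxns$id)
  list(status = sol$status, objective_value = sol$value, fluxes = fluxes)
}

# ---------------------------------------------------------------------------
# COBRA JSON I/O (cobrapy-compatible schema)

#' Write a model as COBRA JSON
#'
#' Emits the cobrapy JSON schema (metabolites, reactions with bounds and
#' objective coefficients, empty gene list), readable by cobrapy and by
#' [read_cobra_json()].
#'
#' @param model a `metabolic_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cobra_json <- function(model, path) {
  mets <- lapply(seq_len(nrow(model$mets)), function(i) {
    list(id = model$mets$id[i], name = model$mets$id[i],
         compartment = model$mets$compartment[i])
  })
  rxns <- lapply(seq_len(nrow(model$rxns)), function(j) {
    col <- model$S[, j]
    nz <- which(col != 0)
    st <- as.list(stats::setNames(as.numeric(col[nz]), model$mets$id[nz]))
    list(id = model$rxns$id[j], name = model$rxns$id[j], metabolites = st,
         lower_bound = model$rxns$lb[j], upper_bound = model$rxns$ub[j],
         objective_coefficient = model$rxns$obj[j])
  })
  comps <- unique(model$mets$compartment)
  out <- list(id = model$id, metabolites = mets, reactions = rxns,
              genes = list(),
              compartments = as.list(stats::setNames(comps, comps)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a COBRA JSON model
#'
#' @param path a cobrapy-schema JSON file.
#' @return a `metabolic_model`.
#' @export
read_cobra_json <- function(path) {
  raw <- jsonlite::read_json(path)
  model <- metabolic_model(id = raw$id %||% "model")
  model <- add_metabolites(model, vapply(raw$metabolites, `[[`, "", "id"))
  for (rx in raw$reactions) {
    st <- unlist(rx$metabolites)
    model <- add_reaction(model, rx$id, st,
                          lb = rx$lower_bound %||% -DEFAULT_FLUX_BOUND,
                          ub = rx$upper_bound %||% DEFAULT_FLUX_BOUND,
                          obj = rx$objective_coefficient %||% 0)
  }
  model
}

# ---------------------------------------------------------------------------
# Minimal SBML Level 3 + FBC I/O.
#
# Covers the subset this package uses: species/compartments, reactions with
# stoichiometry, flux bounds as fbc parameters, and one maximization
# objective. Ids are sanitized with the COBRA "__<charcode>__" escape so
# bracketed compartment tags survive the SBML id grammar.

sbml_escape <- function(x) {
  vapply(x, function(s) {
    chars <- strsplit(s, "")[[1]]
    ok <- grepl("[A-Za-z0-9_]", chars)
    chars[!ok] <- vapply(chars[!ok],
                         function(ch) sprintf("__%d__", utf8ToInt(ch)), "")
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

sbml_unescape <- function(x) {
  vapply(x, function(s) {
    m <- gregexpr("__([0-9]+)__", s)[[1]]
    if (m[1] == -1) return(s)
    parts <- regmatches(s, gregexpr("__([0-9]+)__", s))[[1]]
    for (p in unique(parts)) {
      code <- as.integer(gsub("__", "", p))
      s <- gsub(p, intToUtf8(code), s, fixed = TRUE)
    }
    s
  }, character(1), USE.NAMES = FALSE)
}

#' Write a model as SBML Level 3 with FBC flux bounds
#'
#' @param model a `metabolic_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sbml_model <- function(model, path) {
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    "xmlns:fbc" = "http://www.sbml.org/sbml/level3/version1/fbc/version2",
    level = "3", version = "1", "fbc:required" = "false"
  )
  mdl <- xml2::xml_add_child(doc, "model", id = sbml_escape(model$id),
                             "fbc:strict" = "true")
  comps <- unique(model$mets$compartment)
  loc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cp in comps) {
    xml2::xml_add_child(loc, "compartment", id = sbml_escape(cp),
                        constant = "true")
  }
  los <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$mets))) {
    xml2::xml_add_child(
      los, "species",
      id = paste0("M_", sbml_escape(model$mets$id[i])),
      name = model$mets$id[i],
      compartment = sbml_escape(model$mets$compartment[i]),
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false"
    )
  }
  # flux bounds as shared parameters
  lop <- xml2::xml_add_child(mdl, "listOfParameters")
  bounds <- sort(unique(c(model$rxns$lb, model$rxns$ub)))
  bid <- stats::setNames(sprintf("fb_%d", seq_along(bounds)), fmt17(bounds))
  for (k in seq_along(bounds)) {
    xml2::xml_add_child(lop, "parameter", id = bid[k],
                        value = format(bounds[k], digits = 17),
                        constant = "true", sboTerm = "SBO:0000626")
  }
  lor <- xml2::xml_add_child(mdl, "listOfReactions")
  for (j in seq_len(nrow(model$rxns))) {
    rx <- xml2::xml_add_child(
      lor, "reaction",
      id = paste0("R_", sbml_escape(model$rxns$id[j])),
      name = model$rxns$id[j], reversible = tolower(model$rxns$lb[j] < 0),
      fast = "false",
      "fbc:lowerFluxBound" = bid[[fmt17(model$rxns$lb[j])]],
      "fbc:upperFluxBound" = bid[[fmt17(model$rxns$ub[j])]]
    )
    col <- model$S[, j]
    nz <- which(col != 0)
    reac <- nz[col[nz] < 0]; prod <- nz[col[nz] > 0]
    if (length(reac)) {
      lr <- xml2::xml_add_child(rx, "listOfReactants")
      for (i in reac) xml2::xml_add_child(
        lr, "speciesReference",
        species = paste0("M_", sbml_escape(model$mets$id[i])),
        stoichiometry = format(-as.numeric(col[i]), digits = 17),
        constant = "true")
    }
    if (length(prod)) {
      lp <- xml2::xml_add_child(rx, "listOfProducts")
      for (i in prod) xml2::xml_add_child(
        lp, "speciesReference",
        species = paste0("M_", sbml_escape(model$mets$id[i])),
        stoichiometry = format(as.numeric(col[i]), digits = 17),
        constant = "true")
    }
  }
  obj_rxn <- objective_id(model)
  if (!is.na(obj_rxn)) {
    loo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                               "fbc:activeObjective" = "obj")
    ob <- xml2::xml_add_child(loo, "fbc:objective", "fbc:id" = "obj",
                              "fbc:type" = "maximize")
    lfo <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    xml2::xml_add_child(lfo, "fbc:fluxObjective",
                        "fbc:reaction" = paste0("R_", sbml_escape(obj_rxn)),
                        "fbc:coefficient" = "1")
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read an SBML Level 3 + FBC model
#'
#' Parses the subset written by [write_sbml_model()]: species, reactions with
#' stoichiometry, fbc flux-bound parameters, and the active objective.
#'
#' @param path an SBML file.
#' @return a `metabolic_model`.
#' @export
read_sbml_model <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  # fbc attributes may keep their prefix after namespace stripping
  attr_fbc <- function(node, name) {
    v <- xml2::xml_attr(node, name)
    if (is.na(v)) xml2::xml_attr(node, paste0("fbc:", name)) else v
  }
  mdl <- xml2::xml_find_first(doc, ".//model")
  model <- metabolic_model(
    id = sbml_unescape(xml2::xml_attr(mdl, "id") %||% "model"))
  species <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  met_ids <- sub("^M_", "", xml2::xml_attr(species, "id"))
  met_ids <- sbml_unescape(met_ids)
  model <- add_metabolites(model, met_ids)
  params <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pv <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                        xml2::xml_attr(params, "id"))
  obj_node <- xml2::xml_find_first(
    doc, ".//*[name() = 'fluxObjective' or name() = 'fbc:fluxObjective']")
  obj_ref <- if (inherits(obj_node, "xml_missing")) NA_character_
             else attr_fbc(obj_node, "reaction")
  for (rx in xml2::xml_find_all(doc, ".//listOfReactions/reaction")) {
    rid_raw <- xml2::xml_attr(rx, "id")
    rid <- sbml_unescape(sub("^R_", "", rid_raw))
    get_sr <- function(xpath, sign) {
      sr <- xml2::xml_find_all(rx, xpath)
      if (length(sr) == 0) return(numeric(0))
      stats::setNames(
        sign * as.numeric(xml2::xml_attr(sr, "stoichiometry")),
        sbml_unescape(sub("^M_", "", xml2::xml_attr(sr, "species"))))
    }
    st <- c(get_sr(".//listOfReactants/speciesReference", -1),
            get_sr(".//listOfProducts/speciesReference", 1))
    lb <- pv[attr_fbc(rx, "lowerFluxBound")]
    ub <- pv[attr_fbc(rx, "upperFluxBound")]
    model <- add_reaction(model, rid, st,
                          lb = if (is.na(lb)) -DEFAULT_FLUX_BOUND else lb,
                          ub = if (is.na(ub)) DEFAULT_FLUX_BOUND else ub,
                          obj = as.numeric(!is.na(obj_ref) && rid_raw == obj_ref))
  }
  model
}

#' Read or write a model, dispatching on file extension
#'
#' `.json` is COBRA JSON; `.xml`/`.sbml` is SBML Level 3 + FBC.
#'
#' @param path model file.
#' @param model (write only) a `metabolic_model`.
#' @return `read_model`: a `metabolic_model`; `write_model`: `path` invisibly.
#' @export
read_model <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) read_cobra_json(path)
  else read_sbml_model(path)
}

#' @rdname read_model
#' @export
write_model <- function(model, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) write_cobra_json(model, path)
  else write_sbml_model(model, path)
}
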