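#' Genome-scale model I/O
#'
#' A `gem_model` is a lightweight in-memory view of a constraint-based model:
#' compartments, metabolites (with optional formula string and charge),
#' reactions (signed stoichiometry, bounds) and the active objective. It reads
#' and writes the two dialects COBRA models circulate in: SBML Level 3 with
#' the FBC version 2 extension, and COBRA-JSON. Formula strings are kept
#' verbatim and parsed lazily -- an invalid formula only surfaces when a molar
#' mass is actually needed.
#'
#' On SBML write, metabolite and reaction IDs receive the conventional `M_` /
#' `R_` prefixes; they are stripped again on read, so SBML and JSON loads of
#' the same model compare equal.
#'
#' @name gem_io
NULL

#' Construct an empty model
#'
#' @param id Model identifier.
#' @param compartments Named character vector, compartment ID -> name.
#' @return A `gem_model`.
#' @export
new_model <- function(id = "model", compartments = c(c = "cytosol")) {
  structure(list(
    id = id,
    compartments = compartments,
    metabolites = data.frame(
      id = character(0), name = character(0), compartment = character(0),
      formula = character(0), charge = numeric(0), stringsAsFactors = FALSE),
    reactions = list(),
    objective = NA_character_
  ), class = "gem_model")
}

#' Add a metabolite to a model
#'
#' @param model A `gem_model`.
#' @param id,name,compartment Identifier, display name, compartment ID.
#' @param formula Formula string or `NA`.
#' @param charge Net charge or `NA`.
#' @return The updated model.
#' @export
add_metabolite <- function(model, id, name = id, compartment, formula = NA_character_,
                           charge = NA_real_) {
  stopifnot(inherits(model, "gem_model"), nzchar(id))
  if (id %in% model$metabolites$id) {
    bof_error("bofkit_collision_error", sprintf("metabolite ID '%s' already in model", id))
  }
  if (!compartment %in% names(model$compartments)) {
    bof_error("bofkit_spec_error", sprintf("unknown compartment '%s'", compartment))
  }
  model$metabolites <- rbind(model$metabolites, data.frame(
    id = id, name = name, compartment = compartment,
    formula = as.character(formula), charge = as.numeric(charge),
    stringsAsFactors = FALSE))
  model
}

#' Add a reaction to a model
#'
#' @param model A `gem_model`.
#' @param id,name Identifier and display name.
#' @param stoich Named numeric vector, metabolite ID -> signed coefficient
#'   (negative = consumed).
#' @param lb,ub Flux bounds.
#' @return The updated model.
#' @export
add_reaction <- function(model, id, name = id, stoich, lb = 0, ub = 1000) {
  stopifnot(inherits(model, "gem_model"), nzchar(id), length(stoich) > 0, lb <= ub)
  if (id %in% names(model$reactions)) {
    bof_error("bofkit_collision_error", sprintf("reaction ID '%s' already in model", id))
  }
  missing <- setdiff(names(stoich), model$metabolites$id)
  if (length(missing)) {
    bof_error("bofkit_spec_error", sprintf(
      "reaction '%s' references unknown metabolite(s): %s", id, paste(missing, collapse = ", ")))
  }
  model$reactions[[id]] <- list(id = id, name = name, stoich = stoich, lb = lb, ub = ub)
  model
}

#' Which of these metabolite IDs are missing from the model?
#'
#' Matching is exact and case-sensitive (fuzzy matching would silently corrupt
#' coefficients). Returns the missing IDs in input order, one per occurrence.
#'
#' @param model A `gem_model`.
#' @param ids Character vector of metabolite IDs to check.
#' @return Character vector of the IDs absent from the model (possibly empty).
#' @export
check_metabolites_exist <- function(model, ids) {
  stopifnot(inherits(model, "gem_model"))
  ids[!ids %in% model$metabolites$id]
}

met_index <- function(model, id) match(id, model$metabolites$id)

# Formula of a model metabolite as elemental_formula, or NULL when absent.
met_formula <- function(model, id) {
  i <- met_index(model, id)
  f <- model$metabolites$formula[i]
  if (is.na(f) || !nzchar(f)) return(NULL)
  parse_formula(f, charge = model$metabolites$charge[i])
}

#' @export
print.gem_model <- function(x, ...) {
  cat(sprintf("<gem_model '%s': %d metabolites, %d reactions, %d compartment(s)>\n",
              x$id, nrow(x$metabolites), length(x$reactions), length(x$compartments)))
  invisible(x)
}

num15 <- function(x) sprintf("%.15g", x)

## ------------------------------------------------------------------ SBML ----

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

sbml_write <- function(model, path) {
  esc <- xml_escape
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    sprintf('  <model id="%s" fbc:strict="true">', esc(model$id)),
    '    <listOfCompartments>')
  for (i in seq_along(model$compartments)) {
    lines <- c(lines, sprintf(
      '      <compartment id="%s" name="%s" constant="true"/>',
      esc(names(model$compartments)[i]), esc(unname(model$compartments)[i])))
  }
  lines <- c(lines, '    </listOfCompartments>', '    <listOfSpecies>')
  m <- model$metabolites
  for (i in seq_len(nrow(m))) {
    extra <- ""
    if (!is.na(m$charge[i])) extra <- paste0(extra, sprintf(' fbc:charge="%s"', num15(m$charge[i])))
    if (!is.na(m$formula[i]) && nzchar(m$formula[i])) {
      extra <- paste0(extra, sprintf(' fbc:chemicalFormula="%s"', esc(m$formula[i])))
    }
    lines <- c(lines, sprintf(
      paste0('      <species id="M_%s" name="%s" compartment="%s" ',
             'hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"%s/>'),
      esc(m$id[i]), esc(m$name[i]), esc(m$compartment[i]), extra))
  }
  lines <- c(lines, '    </listOfSpecies>')
  # flux bounds as shared constant parameters (FBC-strict style)
  bounds <- sort(unique(unlist(lapply(model$reactions, function(r) c(r$lb, r$ub)))))
  pid <- function(v) sprintf("bnd_%d", match(v, bounds))
  lines <- c(lines, '    <listOfParameters>')
  for (v in bounds) {
    lines <- c(lines, sprintf('      <parameter id="%s" value="%s" constant="true"/>',
                              pid(v), num15(v)))
  }
  lines <- c(lines, '    </listOfParameters>', '    <listOfReactions>')
  for (r in model$reactions) {
    lines <- c(lines, sprintf(
      paste0('      <reaction id="R_%s" name="%s" reversible="%s" fast="false" ',
             'fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">'),
      esc(r$id), esc(r$name), if (r$lb < 0) "true" else "false", pid(r$lb), pid(r$ub)))
    subs <- r$stoich[r$stoich < 0]
    prods <- r$stoich[r$stoich > 0]
    if (length(subs)) {
      lines <- c(lines, '        <listOfReactants>')
      for (j in seq_along(subs)) {
        lines <- c(lines, sprintf(
          '          <speciesReference species="M_%s" stoichiometry="%s" constant="true"/>',
          esc(names(subs)[j]), num15(-subs[[j]])))
      }
      lines <- c(lines, '        </listOfReactants>')
    }
    if (length(prods)) {
      lines <- c(lines, '        <listOfProducts>')
      for (j in seq_along(prods)) {
        lines <- c(lines, sprintf(
          '          <speciesReference species="M_%s" stoichiometry="%s" constant="true"/>',
          esc(names(prods)[j]), num15(prods[[j]])))
      }
      lines <- c(lines, '        </listOfProducts>')
    }
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(lines, '    </listOfReactions>')
  if (!is.na(model$objective)) {
    lines <- c(lines,
      '    <fbc:listOfObjectives fbc:activeObjective="obj">',
      '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
      '        <fbc:listOfFluxObjectives>',
      sprintf('          <fbc:fluxObjective fbc:reaction="R_%s" fbc:coefficient="1"/>',
              esc(model$objective)),
      '        </fbc:listOfFluxObjectives>',
      '      </fbc:objective>',
      '    </fbc:listOfObjectives>')
  }
  lines <- c(lines, '  </model>', '</sbml>')
  writeLines(lines, path)
}

# attribute lookup tolerant of namespace prefixes ("fbc:charge" vs "charge")
attr_local <- function(attrs, local) {
  nm <- names(attrs)
  hit <- which(nm == local | grepl(paste0(":", local, "$"), nm))
  if (!length(hit)) NA_character_ else unname(attrs[hit[1]])
}

strip_cobra_prefix <- function(id, prefix) sub(paste0("^", prefix, "_"), "", id)

sbml_read <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    bof_error("bofkit_io_error", sprintf("cannot read SBML file '%s': %s", path, conditionMessage(e)))
  })
  xml2::xml_ns_strip(doc)
  mnode <- xml2::xml_find_first(doc, ".//model")
  if (inherits(mnode, "xml_missing")) {
    bof_error("bofkit_io_error", sprintf("'%s' contains no <model> element", path))
  }
  comp_nodes <- xml2::xml_find_all(doc, ".//listOfCompartments/compartment")
  if (!length(comp_nodes)) {
    bof_error("bofkit_validation_error",
              "model has no compartment; a GEM must contain at least one compartment with an ID")
  }
  comps <- stats::setNames(
    vapply(comp_nodes, function(n) {
      nm <- xml2::xml_attr(n, "name"); if (is.na(nm)) xml2::xml_attr(n, "id") else nm
    }, character(1)),
    vapply(comp_nodes, xml2::xml_attr, character(1), attr = "id"))
  model <- new_model(id = xml2::xml_attr(mnode, "id"), compartments = comps)
  if (is.na(model$id)) model$id <- "model"

  params <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pvals <- stats::setNames(
    as.numeric(vapply(params, xml2::xml_attr, character(1), attr = "value")),
    vapply(params, xml2::xml_attr, character(1), attr = "id"))

  for (n in xml2::xml_find_all(doc, ".//listOfSpecies/species")) {
    a <- xml2::xml_attrs(n)
    ch <- attr_local(a, "charge")
    model <- add_metabolite(
      model,
      id = strip_cobra_prefix(a[["id"]], "M"),
      name = if (!is.na(attr_local(a, "name"))) attr_local(a, "name") else a[["id"]],
      compartment = a[["compartment"]],
      formula = attr_local(a, "chemicalFormula"),
      charge = if (is.na(ch)) NA_real_ else as.numeric(ch))
  }
  for (n in xml2::xml_find_all(doc, ".//listOfReactions/reaction")) {
    a <- xml2::xml_attrs(n)
    rid <- strip_cobra_prefix(a[["id"]], "R")
    rev <- identical(attr_local(a, "reversible"), "true")
    lb_ref <- attr_local(a, "lowerFluxBound"); ub_ref <- attr_local(a, "upperFluxBound")
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(pvals)) pvals[[lb_ref]] else if (rev) -1000 else 0
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(pvals)) pvals[[ub_ref]] else 1000
    stoich <- numeric(0)
    for (sr in xml2::xml_find_all(n, "./listOfReactants/speciesReference")) {
      sid <- strip_cobra_prefix(xml2::xml_attr(sr, "species"), "M")
      stoich[sid] <- (if (sid %in% names(stoich)) stoich[[sid]] else 0) -
        as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    for (sr in xml2::xml_find_all(n, "./listOfProducts/speciesReference")) {
      sid <- strip_cobra_prefix(xml2::xml_attr(sr, "species"), "M")
      stoich[sid] <- (if (sid %in% names(stoich)) stoich[[sid]] else 0) +
        as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    model <- add_reaction(
      model, id = rid,
      name = if (!is.na(attr_local(a, "name"))) attr_local(a, "name") else rid,
      stoich = stoich, lb = lb, ub = ub)
  }
  fo <- xml2::xml_find_first(doc, ".//*[local-name()='fluxObjective']")
  if (!inherits(fo, "xml_missing")) {
    model$objective <- strip_cobra_prefix(attr_local(xml2::xml_attrs(fo), "reaction"), "R")
  }
  model
}

## ------------------------------------------------------------------ JSON ----

json_write <- function(model, path) {
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    out <- list(id = m$id, name = m$name, compartment = m$compartment)
    if (!is.na(m$formula) && nzchar(m$formula)) out$formula <- m$formula
    if (!is.na(m$charge)) out$charge <- m$charge
    out
  })
  rxns <- lapply(model$reactions, function(r) {
    list(id = r$id, name = r$name,
         metabolites = as.list(r$stoich),
         lower_bound = r$lb, upper_bound = r$ub,
         gene_reaction_rule = "",
         objective_coefficient = if (!is.na(model$objective) && r$id == model$objective) 1 else 0)
  })
  obj <- list(id = model$id, version = "1",
              compartments = as.list(model$compartments),
              metabolites = mets, reactions = unname(rxns), genes = list())
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

json_read <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path), error = function(e) {
    bof_error("bofkit_io_error", sprintf("cannot read JSON model '%s': %s", path, conditionMessage(e)))
  })
  comps <- obj$compartments
  if (is.null(comps) || !length(comps)) {
    # fall back to compartments referenced by metabolites
    cc <- unique(vapply(obj$metabolites, function(m) m$compartment %||% NA_character_, character(1)))
    cc <- cc[!is.na(cc)]
    if (!length(cc)) {
      bof_error("bofkit_validation_error",
                "model has no compartment; a GEM must contain at least one compartment with an ID")
    }
    comps <- stats::setNames(as.list(cc), cc)
  }
  model <- new_model(id = obj$id %||% "model",
                     compartments = unlist(comps))
  for (m in obj$metabolites) {
    model <- add_metabolite(
      model, id = m$id, name = m$name %||% m$id, compartment = m$compartment,
      formula = m$formula %||% NA_character_,
      charge = if (is.null(m$charge)) NA_real_ else as.numeric(m$charge))
  }
  objective <- NA_character_
  for (r in obj$reactions) {
    st <- vapply(r$metabolites, as.numeric, numeric(1))
    model <- add_reaction(model, id = r$id, name = r$name %||% r$id, stoich = st,
                          lb = as.numeric(r$lower_bound %||% -1000),
                          ub = as.numeric(r$upper_bound %||% 1000))
    if (!is.null(r$objective_coefficient) && as.numeric(r$objective_coefficient) != 0) {
      objective <- r$id
    }
  }
  model$objective <- objective
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ------------------------------------------------------------- interface ----

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xml", "sbml")) "sbml" else if (ext == "json") "json"
  else bof_error("bofkit_io_error", sprintf(
    "cannot guess model format from extension '%s'; pass format explicitly", ext))
}

#' Load a genome-scale model
#'
#' @param path Path to an SBML (`.xml`/`.sbml`) or COBRA-JSON (`.json`) file.
#' @param format `"auto"` (by extension), `"sbml"` or `"json"`.
#' @return A `gem_model`.
#' @export
load_model <- function(path, format = c("auto", "sbml", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    bof_error("bofkit_io_error", sprintf("model file '%s' does not exist", path))
  }
  if (format == "auto") format <- guess_format(path)
  if (format == "sbml") sbml_read(path) else json_read(path)
}

#' Save a genome-scale model
#'
#' Writing is deterministic (no timestamps) and carries stoichiometry at 15
#' significant digits, so save/load round-trips are the identity on IDs,
#' coefficients, bounds, formulas and charges.
#'
#' @param model A `gem_model`.
#' @param path Output path.
#' @param format `"auto"` (by extension), `"sbml"` or `"json"`.
#' @export
save_model <- function(model, path, format = c("auto", "sbml", "json")) {
  stopifnot(inherits(model, "gem_model"))
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  ok <- tryCatch({
    if (format == "sbml") sbml_write(model, path) else json_write(model, path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    if (inherits(ok, "bofkit_error")) stop(ok)
    bof_error("bofkit_io_error", sprintf("cannot write model to '%s': %s",
                                         path, conditionMessage(ok)))
  }
  invisible(path)
}
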