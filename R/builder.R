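#' BOF construction
#'
#' Converts a validated `bof_spec` into final stoichiometric coefficients and
#' inserts tagged pseudo-metabolites and pseudo-reactions into the model.
#'
#' Pool sheets (levels 2-3) are resolved bottom-up into mole fractions
#' (mol per mol of pool, summing to 1); the level-1 sheet is resolved into
#' masses, normalized so that the total recovered mass equals 1 g of dry
#' weight, then converted to mmol per gDW. Maintenance rows are used as
#' stoichiometric coefficients directly: never converted, never rescaled
#' (negative = consumed, positive = produced).
#'
#' Polymers are treated as one monomer long: a pool's molar mass is the plain
#' mole-fraction-weighted monomer mass, with no condensation water
#' subtracted. Any dehydration or energy cost belongs in the maintenance
#' table, stated on that one-monomer basis.
#'
#' Every generated pseudo-metabolite's formula and charge are the net of its
#' own reaction (substrates minus non-pool products, maintenance included),
#' which makes every generated reaction elementally and charge balanced by
#' construction -- and makes the net mass consumed per unit flux of the top
#' reaction exactly 1 g when all formulas are known and the maintenance rows
#' are themselves elementally balanced.
#'
#' @name builder
NULL

# molar mass (g/mol) and formula of a constituent: either a resolved child
# pool or a model metabolite. Returns list(formula=..|NULL, mass=..|NA).
constituent_chem <- function(id, children, model) {
  if (id %in% names(children)) {
    ch <- children[[id]]
    return(list(formula = ch$pool_formula, mass = ch$pool_molar_mass))
  }
  f <- tryCatch(met_formula(model, id), error = function(e) NULL)
  if (is.null(f)) return(list(formula = NULL, mass = NA_real_))
  m <- tryCatch(molar_mass(f), error = function(e) NA_real_)
  list(formula = f, mass = m)
}

net_formula <- function(frac, formulas, maint) {
  # product pseudo-metabolite = sum(frac_i * f_i) - sum(m_j * f_j) so the
  # reaction  frac_i X_i (+ maint) -> 1 POOL  nets to zero in every element
  coefs <- c(frac, -maint$coefficient)
  all_f <- c(formulas, maint$formulas)
  if (any(vapply(all_f, is.null, logical(1)))) return(NULL)
  weighted_combine(coefs, all_f)
}

maint_with_formulas <- function(maint, model) {
  maint$formulas <- lapply(maint$metabolite_id, function(id) {
    tryCatch(met_formula(model, id), error = function(e) NULL)
  })
  maint
}

#' Resolve a pool sheet (level 2 or 3) into mole fractions
#'
#' Molar units are normalized to sum 1; mass units are first divided by the
#' constituent molar mass (model formula, or the child pool's molar mass),
#' then normalized. The pool's formula/charge is the net of its reaction; its
#' molar mass is reported when every participating formula is known,
#' otherwise `NA` with a warning.
#'
#' @param spec One sheet of a `bof_spec` (level 2 or 3).
#' @param children Named list of already-resolved `pool_result`s for every
#'   pool this sheet references (bottom-up evaluation).
#' @param model A `gem_model`.
#' @param compute_formula Set `FALSE` when the user declares formulas
#'   unavailable; mole fractions are still computed for molar-unit sheets.
#' @return A `pool_result`: `pool_name`, `mole_fractions` (named, sums to 1),
#'   `pool_formula` (or NULL), `pool_molar_mass` (or NA),
#'   `maintenance_coeffs` (named signed numeric, mol per mol pool).
#' @export
resolve_pool <- function(spec, children = list(), model, compute_formula = TRUE) {
  entries <- spec$entries
  unit <- entries$unit[1]
  chem <- lapply(entries$metabolite_id, constituent_chem, children = children, model = model)
  masses <- vapply(chem, function(x) x$mass, numeric(1))

  if (unit %in% MASS_UNITS) {
    no_mass <- entries$metabolite_id[is.na(masses)]
    if (length(no_mass)) {
      bof_error("bofkit_conversion_error", sprintf(
        "sheet '%s' uses mass unit '%s' but no molar mass is available for: %s",
        spec$pool_name, unit, paste(no_mass, collapse = ", ")))
    }
    rel <- entries$value / masses
  } else {
    rel <- entries$value
  }
  tot <- sum(rel)
  if (tot <= 0) {
    bof_error("bofkit_conversion_error",
              sprintf("sheet '%s': composition sums to zero (empty pool)", spec$pool_name))
  }
  frac <- stats::setNames(rel / tot, entries$metabolite_id)

  maint <- maint_with_formulas(spec$maintenance, model)
  maint_coeffs <- stats::setNames(maint$coefficient, maint$metabolite_id)

  formula <- NULL
  mass <- NA_real_
  if (compute_formula) {
    formulas <- lapply(chem, function(x) x$formula)
    formula <- net_formula(frac, formulas, maint)
    if (is.null(formula)) {
      have <- !vapply(c(formulas, maint$formulas), is.null, logical(1))
      ids <- c(entries$metabolite_id, maint$metabolite_id)
      bof_warning("bofkit_warning", sprintf(
        "sheet '%s': formula(s) missing for %s; pool formula and molar mass unavailable",
        spec$pool_name, paste(ids[!have], collapse = ", ")))
    } else {
      mass <- tryCatch(molar_mass(formula), error = function(e) NA_real_)
      if (is.na(mass)) {
        bof_warning("bofkit_warning", sprintf(
          "sheet '%s': pool formula contains elements of undefined mass; molar mass unavailable",
          spec$pool_name))
      }
    }
  }
  structure(list(
    pool_name = spec$pool_name,
    mole_fractions = frac,
    pool_formula = formula,
    pool_molar_mass = mass,
    maintenance_coeffs = maint_coeffs,
    raw = entries
  ), class = "pool_result")
}

#' Resolve the level-1 sheet into biomass coefficients
#'
#' Each entry is converted to grams per gDW-as-measured (mass units directly;
#' molar units via the molar mass), the total is normalized to 1 g of dry
#' weight (`scale_factor = 1 / total`), and coefficients in mmol per gDW are
#' obtained as `mass_fraction * 1000 / molar_mass`. Maintenance entries pass
#' through unconverted and unscaled. A `scale_factor` outside `[0.8, 1.25]`
#' (recovered mass far from 1 g) triggers a warning but never blocks.
#'
#' @param spec The level-1 sheet of a `bof_spec`.
#' @param pools Named list of resolved `pool_result`s.
#' @param model A `gem_model`.
#' @param compute_formula As in [resolve_pool()].
#' @return A `top_result`: `coefficients` (mmol/gDW), `mass_fractions`
#'   (sum 1), `scale_factor`, `maintenance_coeffs` (mmol/gDW, signed),
#'   `formula`/`molar_mass` of the biomass pseudo-metabolite (per its unit
#'   stoichiometry, i.e. g per mmol-scale flux unit).
#' @export
resolve_top <- function(spec, pools = list(), model, compute_formula = TRUE) {
  entries <- spec$entries
  unit <- entries$unit[1]
  chem <- lapply(entries$metabolite_id, constituent_chem, children = pools, model = model)
  masses <- vapply(chem, function(x) x$mass, numeric(1))
  no_mass <- entries$metabolite_id[is.na(masses)]
  if (length(no_mass)) {
    bof_error("bofkit_conversion_error", sprintf(
      "level-1 sheet '%s': molar mass unknown for %s; normalization to 1 gDW is impossible",
      spec$pool_name, paste(no_mass, collapse = ", ")))
  }
  g <- switch(unit,
    g_per_gDW       = entries$value,
    mg_per_gDW      = entries$value / 1000,
    percent_DW_mass = entries$value / 100,
    mmol_per_gDW    = entries$value / 1000 * masses,
    umol_per_gDW    = entries$value / 1e6 * masses,
    bof_error("bofkit_conversion_error", sprintf(
      "level-1 sheet '%s': unit '%s' has no dry-weight basis", spec$pool_name, unit)))
  total <- sum(g)
  if (total <= 0) {
    bof_error("bofkit_conversion_error",
              sprintf("level-1 sheet '%s': total recovered mass is zero", spec$pool_name))
  }
  scale <- 1 / total
  if (scale < 0.8 || scale > 1.25) {
    bof_warning("bofkit_warning", sprintf(
      "recovered mass is %.4g g per gDW (scale factor %.4g); data are normalized to 1 g regardless",
      total, scale))
  }
  mass_frac <- stats::setNames(g * scale, entries$metabolite_id)
  coeff <- stats::setNames(mass_frac * 1000 / masses, entries$metabolite_id)

  maint <- maint_with_formulas(spec$maintenance, model)
  maint_coeffs <- stats::setNames(maint$coefficient, maint$metabolite_id)

  formula <- NULL
  bmass <- NA_real_
  if (compute_formula) {
    formulas <- lapply(chem, function(x) x$formula)
    formula <- net_formula(coeff, formulas, maint)
    if (is.null(formula)) {
      bof_warning("bofkit_warning", sprintf(
        "level-1 sheet '%s': missing formulas; biomass pseudo-metabolite formula unavailable",
        spec$pool_name))
    } else {
      bmass <- tryCatch(molar_mass(formula), error = function(e) NA_real_)
    }
  }
  structure(list(
    pool_name = spec$pool_name,
    coefficients = coeff,
    mass_fractions = mass_frac,
    scale_factor = scale,
    maintenance_coeffs = maint_coeffs,
    pool_formula = formula,
    pool_molar_mass = bmass,
    component_masses = stats::setNames(masses, entries$metabolite_id),
    raw = entries
  ), class = "top_result")
}

#' Resolve every sheet of a spec, bottom-up
#'
#' @param spec A `bof_spec`.
#' @param model A `gem_model`.
#' @param compute_formula Set `FALSE` when formulas are not available for all
#'   consumed metabolites.
#' @return Named list: one `pool_result` per pool sheet plus a `top_result`
#'   under the top sheet's name.
#' @export
resolve_bof <- function(spec, model, compute_formula = TRUE) {
  results <- list()
  for (s in rev(spec$order)) {            # deepest sheets first
    sh <- if (s == spec$top$pool_name) spec$top else spec$pools[[s]]
    results[[s]] <- if (sh$level == 1L) {
      resolve_top(sh, results, model, compute_formula)
    } else {
      resolve_pool(sh, results, model, compute_formula)
    }
  }
  results[spec$order]
}

pseudo_id <- function(pool_name, tag) paste0(pool_name, "_", tag)

#' Insert the generated BOF into the model
#'
#' For each sheet, creates a pseudo-metabolite and a pseudo-reaction both
#' named `<pool_name>_<tag>` (compartment = the spec's compartment), the
#' reaction consuming constituents at their final coefficients, applying
#' maintenance rows at their signed coefficients, and producing exactly 1
#' unit of its pseudo-metabolite. Bounds are `[0, 1000]`; the model objective
#' is untouched unless `set_objective = TRUE`. The operation is atomic: on
#' any ID collision nothing is inserted.
#'
#' @param spec A `bof_spec`.
#' @param results Output of [resolve_bof()].
#' @param model A `gem_model`.
#' @param set_objective If `TRUE`, the top pseudo-reaction becomes the model
#'   objective.
#' @return List with the updated `model` and the coefficient `report`
#'   (see [coefficient_report()]).
#' @export
assemble_bof <- function(spec, results, model, set_objective = FALSE) {
  new_ids <- vapply(spec$order, pseudo_id, character(1), tag = spec$tag)
  clash <- c(intersect(new_ids, model$metabolites$id), intersect(new_ids, names(model$reactions)))
  if (length(clash)) {
    bof_error("bofkit_collision_error", sprintf(
      "generated ID(s) already present in model: %s (choose another tag); model left unchanged",
      paste(unique(clash), collapse = ", ")))
  }
  out <- model
  # metabolites first (reactions reference them)
  for (s in spec$order) {
    res <- results[[s]]
    fml <- if (!is.null(res$pool_formula)) format_formula(res$pool_formula) else NA_character_
    chg <- if (!is.null(res$pool_formula)) res$pool_formula$charge else NA_real_
    out <- add_metabolite(out, id = pseudo_id(s, spec$tag), name = paste0(s, " pseudo-metabolite"),
                          compartment = spec$compartment, formula = fml, charge = chg)
  }
  for (s in spec$order) {
    res <- results[[s]]
    coeffs <- if (inherits(res, "top_result")) res$coefficients else res$mole_fractions
    ids <- names(coeffs)
    ids <- ifelse(ids %in% spec$order, vapply(ids, pseudo_id, character(1), tag = spec$tag), ids)
    stoich <- stats::setNames(-unname(coeffs), ids)
    for (j in seq_along(res$maintenance_coeffs)) {
      id <- names(res$maintenance_coeffs)[j]
      stoich[id] <- (if (id %in% names(stoich)) stoich[[id]] else 0) + res$maintenance_coeffs[[j]]
    }
    stoich[pseudo_id(s, spec$tag)] <- 1
    out <- add_reaction(out, id = pseudo_id(s, spec$tag),
                        name = paste0(s, " pseudo-reaction"),
                        stoich = stoich, lb = 0, ub = 1000)
  }
  if (set_objective) out$objective <- pseudo_id(spec$top$pool_name, spec$tag)
  list(model = out, report = coefficient_report(spec, results))
}

#' Remove a BOF by its tag
#'
#' Deletes every reaction whose ID ends in `_<tag>` and every metabolite with
#' that suffix that no remaining reaction uses. If the removed reaction was
#' the objective, the objective is unset with a warning.
#'
#' @param model A `gem_model`.
#' @param tag The tag the BOF was generated with.
#' @return The updated model.
#' @export
remove_bof <- function(model, tag) {
  stopifnot(inherits(model, "gem_model"))
  suffix <- paste0("_", tag)
  rids <- names(model$reactions)[endsWith(names(model$reactions), suffix)]
  if (!length(rids)) {
    bof_error("bofkit_notfound_error", sprintf("no reaction with tag suffix '%s' in model", suffix))
  }
  model$reactions[rids] <- NULL
  if (!is.na(model$objective) && model$objective %in% rids) {
    bof_warning("bofkit_warning", sprintf(
      "removed reaction '%s' was the model objective; objective is now unset", model$objective))
    model$objective <- NA_character_
  }
  used <- unique(unlist(lapply(model$reactions, function(r) names(r$stoich))))
  drop <- endsWith(model$metabolites$id, suffix) & !model$metabolites$id %in% used
  model$metabolites <- model$metabolites[!drop, , drop = FALSE]
  rownames(model$metabolites) <- NULL
  model
}

#' Flatten a hierarchical BOF to net monomer consumption
#'
#' Multiplies coefficients through the hierarchy (level-1 mmol/gDW x level-2
#' mol/mol x level-3 mol/mol; a pool sheet's maintenance rows are scaled by
#' that pool's consumption) and returns net consumption per model metabolite:
#' positive = consumed, negative = produced. A single-level spec flattens to
#' its own coefficients (with maintenance signs flipped to the consumption
#' convention).
#'
#' @param spec A `bof_spec`.
#' @param results Output of [resolve_bof()].
#' @return Named numeric vector, model metabolite ID -> mmol per gDW.
#' @export
flatten_bof <- function(spec, results) {
  acc <- new.env(parent = emptyenv())
  add <- function(id, x) {
    assign(id, (if (exists(id, acc)) get(id, acc) else 0) + x, acc)
  }
  descend <- function(pool_name, usage) {  # usage: mmol/gDW consumed of this pool
    res <- results[[pool_name]]
    for (j in seq_along(res$mole_fractions)) {
      id <- names(res$mole_fractions)[j]
      amt <- usage * res$mole_fractions[[j]]
      if (id %in% spec$order) descend(id, amt) else add(id, amt)
    }
    for (j in seq_along(res$maintenance_coeffs)) {
      # signed (negative = consumed) -> consumption convention flips the sign
      add(names(res$maintenance_coeffs)[j], -usage * res$maintenance_coeffs[[j]])
    }
  }
  top <- results[[spec$top$pool_name]]
  for (j in seq_along(top$coefficients)) {
    id <- names(top$coefficients)[j]
    amt <- top$coefficients[[j]]
    if (id %in% spec$order) descend(id, amt) else add(id, amt)
  }
  for (j in seq_along(top$maintenance_coeffs)) {
    add(names(top$maintenance_coeffs)[j], -top$maintenance_coeffs[[j]])
  }
  vals <- mget(ls(acc, sorted = TRUE), acc)
  stats::setNames(as.numeric(vals), names(vals))
}

#' Per-coefficient provenance report
#'
#' One row per species of every generated reaction, tracing raw value and
#' unit, intermediate quantity (mass in g/gDW at level 1, mole fraction at
#' levels 2-3), and the final coefficient with its unit; maintenance rows are
#' flagged in `provenance`. The level-1 `scale_factor` and each pool's molar
#' mass ride along as attributes.
#'
#' @param spec A `bof_spec`.
#' @param results Output of [resolve_bof()].
#' @return A data frame of class `coefficient_report`.
#' @export
coefficient_report <- function(spec, results) {
  rows <- list()
  for (s in spec$order) {
    res <- results[[s]]
    is_top <- inherits(res, "top_result")
    coeffs <- if (is_top) res$coefficients else res$mole_fractions
    inter <- if (is_top) res$mass_fractions else res$mole_fractions
    unit_out <- if (is_top) "mmol_per_gDW" else "mol_per_mol_pool"
    raw <- res$raw
    for (j in seq_along(coeffs)) {
      id <- names(coeffs)[j]
      k <- match(id, raw$metabolite_id)
      species_id <- if (id %in% spec$order) pseudo_id(id, spec$tag) else id
      rows[[length(rows) + 1]] <- data.frame(
        reaction = pseudo_id(s, spec$tag), species = species_id,
        provenance = "composition",
        raw_value = raw$value[k], raw_unit = raw$unit[k],
        intermediate = inter[[j]],
        intermediate_unit = if (is_top) "g_per_gDW" else "mol_per_mol",
        coefficient = -coeffs[[j]], coefficient_unit = unit_out,
        stringsAsFactors = FALSE)
    }
    maint <- res$maintenance_coeffs
    for (j in seq_along(maint)) {
      rows[[length(rows) + 1]] <- data.frame(
        reaction = pseudo_id(s, spec$tag), species = names(maint)[j],
        provenance = "maintenance",
        raw_value = maint[[j]], raw_unit = unit_out,
        intermediate = NA_real_, intermediate_unit = NA_character_,
        coefficient = maint[[j]], coefficient_unit = unit_out,
        stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1]] <- data.frame(
      reaction = pseudo_id(s, spec$tag), species = pseudo_id(s, spec$tag),
      provenance = "product",
      raw_value = NA_real_, raw_unit = NA_character_,
      intermediate = NA_real_, intermediate_unit = NA_character_,
      coefficient = 1, coefficient_unit = unit_out,
      stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, rows)
  attr(report, "scale_factor") <- results[[spec$top$pool_name]]$scale_factor
  attr(report, "pool_molar_masses") <- vapply(
    results, function(r) r$pool_molar_mass, numeric(1))
  class(report) <- c("coefficient_report", "data.frame")
  report
}

#' Write a coefficient report as TSV
#'
#' The scale factor and pool molar masses are written as `#`-prefixed header
#' comments above the table.
#'
#' @param report A `coefficient_report`.
#' @param path Output file path.
#' @export
write_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# scale_factor\t%.15g", attr(report, "scale_factor")), con)
  pm <- attr(report, "pool_molar_masses")
  for (i in seq_along(pm)) {
    writeLines(sprintf("# pool_molar_mass\t%s\t%.15g", names(pm)[i], pm[[i]]), con)
  }
  utils::write.table(report, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' One-call pipeline: workbook + model -> updated model + report
#'
#' Load, validate, resolve, assemble. Convenience wrapper used by the CLI.
#'
#' @param model A `gem_model` or a model file path.
#' @param workbook A raw sheet list or a workbook path (TSV directory/XLSX).
#' @param tag,compartment As in [build_spec()].
#' @param formula_available,charge_available The user's promise that formulas
#'   / charges exist for all metabolites consumed in the BOF. When formulas
#'   are declared available but one is missing where needed, that is an
#'   error; when declared unavailable, formula computation is skipped.
#' @param set_objective Make the new top reaction the model objective.
#' @return List: `model` (updated), `report`, `results`, `spec`.
#' @export
build_bof <- function(model, workbook, tag, compartment,
                      formula_available = TRUE, charge_available = TRUE,
                      set_objective = FALSE) {
  if (is.character(model)) model <- load_model(model)
  if (is.character(workbook)) workbook <- load_workbook(workbook)
  spec <- build_spec(workbook, tag, compartment, model)
  if (formula_available) {
    consumed <- unique(unlist(lapply(c(list(spec$top), spec$pools), function(sh) {
      c(setdiff(sh$entries$metabolite_id, spec$order), sh$maintenance$metabolite_id)
    })))
    lacking <- consumed[vapply(consumed, function(id) {
      is.null(tryCatch(met_formula(model, id), error = function(e) NULL))
    }, logical(1))]
    if (length(lacking)) {
      bof_error("bofkit_spec_error", sprintf(
        "formulas were declared available but are missing/invalid for: %s",
        paste(lacking, collapse = ", ")))
    }
    if (charge_available) {
      no_charge <- consumed[is.na(model$metabolites$charge[match(consumed, model$metabolites$id)])]
      if (length(no_charge)) {
        bof_error("bofkit_spec_error", sprintf(
          "charges were declared available but are missing for: %s",
          paste(no_charge, collapse = ", ")))
      }
    }
  }
  results <- resolve_bof(spec, model, compute_formula = formula_available)
  out <- assemble_bof(spec, results, model, set_objective = set_objective)
  c(out, list(results = results, spec = spec))
}
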