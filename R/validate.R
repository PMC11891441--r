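#' Post-generation quality control
#'
#' Elemental/charge balance of every tagged reaction, a mass-closure audit of
#' the top reaction (net grams consumed per unit flux must be 1), and an
#' optional growth-feasibility check by flux balance analysis.
#'
#' @name validate
NULL

tagged_reactions <- function(model, tag) {
  suffix <- paste0("_", tag)
  rids <- names(model$reactions)[endsWith(names(model$reactions), suffix)]
  if (!length(rids)) {
    bof_error("bofkit_notfound_error", sprintf("no reaction with tag suffix '%s' in model", suffix))
  }
  rids
}

# top reaction of a tagged BOF = the tagged reaction producing a tagged
# pseudo-metabolite that no other tagged reaction consumes
top_reaction <- function(model, tag) {
  rids <- tagged_reactions(model, tag)
  suffix <- paste0("_", tag)
  consumed <- unique(unlist(lapply(model$reactions[rids], function(r) {
    names(r$stoich)[r$stoich < 0]
  })))
  tops <- rids[vapply(rids, function(rid) {
    st <- model$reactions[[rid]]$stoich
    prod <- names(st)[st > 0]
    prod <- prod[endsWith(prod, suffix)]
    length(prod) == 1L && !prod %in% consumed
  }, logical(1))]
  if (length(tops) != 1L) {
    bof_error("bofkit_validation_error", sprintf(
      "cannot identify a unique top reaction for tag '%s' (candidates: %s)",
      tag, paste(tops, collapse = ", ")))
  }
  tops
}

#' Elemental and charge balance of a generated BOF
#'
#' For every reaction tagged `_<tag>`, computes the signed stoichiometry
#' weighted sum of each element's count and of charges. A reaction is
#' `balanced` when every net is within `tol`, `imbalanced` otherwise, and
#' `unknown` when any participating species lacks a formula (element rows) or
#' charge (charge row). Also reports the net mass consumed per unit flux of
#' the top reaction: grams of substrates minus grams of non-pseudo products,
#' which equals 1 for a correctly normalized BOF.
#'
#' @param model A `gem_model` containing a generated BOF.
#' @param tag The BOF's tag.
#' @param tol Absolute per-element (and charge) tolerance, default `1e-6`.
#' @param results Optional [resolve_bof()] output; when given, per-pool mole
#'   fraction sums are included in the report.
#' @return A `balance_report`: list with `reactions` (data frame: reaction,
#'   status, max_element_imbalance, charge_imbalance), `elements` (named list
#'   of per-element nets per reaction), `biomass_mass_g` and
#'   `pool_fraction_sums`.
#' @export
balance_check <- function(model, tag, tol = 1e-6, results = NULL) {
  rids <- tagged_reactions(model, tag)
  elements <- list()
  rows <- list()
  for (rid in rids) {
    st <- model$reactions[[rid]]$stoich
    fs <- lapply(names(st), function(id) {
      tryCatch(met_formula(model, id), error = function(e) NULL)
    })
    have_f <- !vapply(fs, is.null, logical(1))
    have_c <- have_f & !vapply(fs, function(f) is.null(f) || is.na(f$charge), logical(1))
    if (all(have_f)) {
      net <- weighted_combine(unname(st), fs, drop_tol = 0)
      el <- net$counts
      max_imb <- if (length(el)) max(abs(el)) else 0
      chg <- if (all(have_c)) net$charge else NA_real_
      # imbalanced wins over unknown: a demonstrable element imbalance is
      # reported even when the charge row cannot be evaluated
      status <- if (max_imb > tol || (!is.na(chg) && abs(chg) > tol)) "imbalanced"
                else if (is.na(chg)) "unknown" else "balanced"
      elements[[rid]] <- el
      rows[[rid]] <- data.frame(reaction = rid, status = status,
                                max_element_imbalance = max_imb,
                                charge_imbalance = chg, stringsAsFactors = FALSE)
    } else {
      elements[[rid]] <- numeric(0)
      rows[[rid]] <- data.frame(reaction = rid, status = "unknown",
                                max_element_imbalance = NA_real_,
                                charge_imbalance = NA_real_, stringsAsFactors = FALSE)
    }
  }
  # mass closure of the top reaction: substrates minus non-pseudo products
  biomass_mass <- tryCatch({
    rid <- top_reaction(model, tag)
    st <- model$reactions[[rid]]$stoich
    suffix <- paste0("_", tag)
    mass_of <- function(id) {
      f <- met_formula(model, id)
      if (is.null(f)) return(NA_real_)
      tryCatch(molar_mass(f), error = function(e) NA_real_)
    }
    total <- 0
    for (id in names(st)) {
      c_ <- st[[id]]
      if (c_ < 0) {
        total <- total + (-c_) * mass_of(id) / 1000
      } else if (!endsWith(id, suffix)) {
        total <- total - c_ * mass_of(id) / 1000
      }
    }
    total
  }, error = function(e) NA_real_)

  pool_sums <- if (!is.null(results)) {
    vapply(results, function(r) {
      if (inherits(r, "pool_result")) sum(r$mole_fractions) else NA_real_
    }, numeric(1))
  } else NULL

  structure(list(
    reactions = do.call(rbind, rows),
    elements = elements,
    biomass_mass_g = biomass_mass,
    pool_fraction_sums = pool_sums,
    tol = tol
  ), class = "balance_report")
}

#' @export
print.balance_report <- function(x, ...) {
  cat(sprintf("<balance_report: %d reaction(s); biomass mass %.9g g per unit flux>\n",
              nrow(x$reactions), x$biomass_mass_g))
  print(x$reactions, row.names = FALSE)
  invisible(x)
}

## -------------------------------------------------------------------- FBA ----

#' Flux balance analysis
#'
#' Maximizes flux through `objective` subject to steady state (`S v = 0`) and
#' the model's bounds, as a dense LP solved by the package's built-in
#' two-phase simplex (no LP library is assumed). Suitable for the small
#' models this package targets; not for genome-scale networks with thousands
#' of reactions.
#'
#' @param model A `gem_model`.
#' @param objective Reaction ID to maximize; defaults to the model objective.
#' @return Objective value (numeric) with attribute `status` one of
#'   `"optimal"`, `"infeasible"` (value 0) or `"unbounded"`.
#' @export
fba <- function(model, objective = model$objective) {
  if (is.na(objective) || !objective %in% names(model$reactions)) {
    bof_error("bofkit_notfound_error", sprintf(
      "objective reaction '%s' not in model", objective))
  }
  rxns <- model$reactions
  n <- length(rxns)
  met_ids <- model$metabolites$id
  S <- matrix(0, nrow = length(met_ids), ncol = n,
              dimnames = list(met_ids, names(rxns)))
  for (j in seq_len(n)) S[names(rxns[[j]]$stoich), j] <- rxns[[j]]$stoich
  lb <- vapply(rxns, function(r) r$lb, numeric(1))
  ub <- vapply(rxns, function(r) r$ub, numeric(1))
  obj <- numeric(n); obj[match(objective, names(rxns))] <- 1
  res <- lp_box_constrained(S, obj, lb, ub)
  structure(if (res$status == "optimal") unname(res$value) else 0,
            status = res$status)
}

#' Growth-feasibility check of a generated BOF
#'
#' Temporarily sets the tagged top pseudo-reaction as the objective, runs FBA
#' under the model's existing bounds, and returns the optimum. Because the
#' top reaction produces one unit of its biomass pseudo-metabolite, which no
#' other reaction consumes, a temporary sink for that pseudo-metabolite is
#' added for the duration of the check (otherwise steady state would force
#' zero flux regardless of the medium). All edits happen on an internal copy:
#' the model passed in -- objective, bounds, reactions -- is never modified.
#' An infeasible LP yields 0 with `attr(., "status") == "infeasible"` rather
#' than an error.
#'
#' @param model A `gem_model` containing a BOF tagged `_<tag>`.
#' @param tag The BOF's tag.
#' @return Objective value with a `status` attribute, as in [fba()].
#' @export
growth_check <- function(model, tag) {
  rid <- top_reaction(model, tag)
  st <- model$reactions[[rid]]$stoich
  suffix <- paste0("_", tag)
  top_met <- names(st)[st > 0 & endsWith(names(st), suffix)]
  consumed <- unique(unlist(lapply(model$reactions, function(r) names(r$stoich)[r$stoich < 0])))
  work <- model
  if (!top_met %in% consumed) {
    sink_id <- paste0("SK_", top_met, "_growth_check")
    if (!sink_id %in% names(work$reactions)) {
      work <- add_reaction(work, sink_id, name = "temporary biomass sink",
                           stoich = stats::setNames(-1, top_met), lb = 0, ub = 1000)
    }
  }
  fba(work, objective = rid)
}
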