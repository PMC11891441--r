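#' Deterministic test fixtures
#'
#' Generators of toy genome-scale models and composition workbooks, so every
#' operation and property of the package is testable without downloading any
#' published model. The toy organism has one compartment, monomers with small
#' real formulas and integer charges (dNTPs, a few amino acids, two lipid
#' species per class, glycogen as a directly-measured carbohydrate) plus the
#' ATP-hydrolysis quartet used for maintenance rows, which is elementally and
#' charge self-balanced (ATP + H2O -> ADP + Pi + H). No realistic organism
#' composition is claimed.
#'
#' @name fixtures
NULL

# formulas/charges chosen to be real-ish and exactly balanced for the
# maintenance scheme atp + h2o -> adp + pi + h
.toy_metabolites <- list(
  # id,        name,              formula,          charge
  c("datp_c",  "dATP",            "C10H12N5O12P3",  "-4"),
  c("dctp_c",  "dCTP",            "C9H12N3O13P3",   "-4"),
  c("dgtp_c",  "dGTP",            "C10H12N5O13P3",  "-4"),
  c("dttp_c",  "dTTP",            "C10H13N2O14P3",  "-4"),
  c("ala__L_c", "L-alanine",      "C3H7NO2",        "0"),
  c("gly_c",   "glycine",         "C2H5NO2",        "0"),
  c("glu__L_c", "L-glutamate",    "C5H8NO4",        "-1"),
  c("lys__L_c", "L-lysine",       "C6H15N2O2",      "1"),
  c("pc140_c", "PC(14:0/14:0)",   "C36H72NO8P",     "0"),
  c("pc160_c", "PC(16:0/16:0)",   "C40H80NO8P",     "0"),
  c("pe140_c", "PE(14:0/14:0)",   "C33H66NO8P",     "0"),
  c("pe160_c", "PE(16:0/16:0)",   "C37H74NO8P",     "0"),
  c("glycogen_c", "glycogen (1 glucosyl unit)", "C6H10O5", "0"),
  c("atp_c",   "ATP",             "C10H12N5O13P3",  "-4"),
  c("adp_c",   "ADP",             "C10H12N5O10P2",  "-3"),
  c("pi_c",    "orthophosphate",  "HPO4",           "-2"),
  c("h2o_c",   "water",           "H2O",            "0"),
  c("h_c",     "proton",          "H",              "1")
)

#' Fixture configuration
#'
#' @param levels BOF depth to generate: 1, 2 or 3.
#' @param seed Integer seed; all randomized fixture values derive from it.
#' @param include_maintenance Add maintenance tables (growth-associated ATP
#'   hydrolysis at the top, polymerization ATP cost on PROTEIN)?
#' @param make_feasible Add exchange reactions so the generated BOF can carry
#'   flux (growth check > 0)?
#' @param total_mass Sum of the level-1 masses in g per gDW before
#'   normalization; default 0.97 so the 1-gDW normalization is exercised.
#' @param corrupt Plant a unit-mixing error in one sheet (must be rejected by
#'   [build_spec()]).
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(levels = 3, seed = 1L, include_maintenance = TRUE,
                           make_feasible = TRUE, total_mass = 0.97, corrupt = FALSE) {
  stopifnot(levels %in% 1:3, total_mass > 0)
  structure(list(levels = levels, seed = as.integer(seed),
                 include_maintenance = include_maintenance,
                 make_feasible = make_feasible, total_mass = total_mass,
                 corrupt = corrupt), class = "fixture_config")
}

#' Generate the toy genome-scale model
#'
#' One compartment `c`; 18 metabolites with formulas and charges; when
#' `make_feasible`, an exchange reaction `EX_<id>` per metabolite (bounds
#' `[-1000, 1000]`) so every BOF precursor can be drawn from the medium.
#' Byte-identical output for identical configs.
#'
#' @param cfg A [fixture_config()].
#' @return A `gem_model`.
#' @export
make_toy_model <- function(cfg = fixture_config()) {
  model <- new_model(id = sprintf("toy_gem_L%d", cfg$levels),
                     compartments = c(c = "cytosol"))
  for (m in .toy_metabolites) {
    model <- add_metabolite(model, id = m[1], name = m[2], compartment = "c",
                            formula = m[3], charge = as.numeric(m[4]))
  }
  if (cfg$make_feasible) {
    for (m in .toy_metabolites) {
      model <- add_reaction(model, id = paste0("EX_", m[1]),
                            name = paste(m[2], "exchange"),
                            stoich = stats::setNames(-1, m[1]),
                            lb = -1000, ub = 1000)
    }
  }
  model
}

rand_simplex <- function(n, rng) {
  # n positive weights summing to 1, away from zero
  w <- 0.2 + rng(n)
  w / sum(w)
}

#' Generate a composition workbook for the toy model
#'
#' Writes a TSV sheet directory of the requested depth. Level-1 masses are
#' randomized (seeded) and rescaled to sum to `cfg$total_mass`; pool sheets
#' use deliberately varied units (mol_per_mol, percent_mol, mg_per_gDW) to
#' exercise the conversion paths. Maintenance rows are the self-balanced ATP
#' hydrolysis scheme.
#'
#' @param cfg A [fixture_config()].
#' @param model The matching [make_toy_model()] output (IDs are referenced).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
make_composition <- function(cfg = fixture_config(), model = make_toy_model(cfg), dir) {
  set.seed(cfg$seed)
  rng <- function(n) stats::runif(n)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  gam <- if (cfg$include_maintenance) data.frame(
    metabolite_id = c("atp_c", "h2o_c", "adp_c", "pi_c", "h_c"),
    name = c("ATP", "water", "ADP", "phosphate", "proton"),
    coefficient = c(-35, -35, 35, 35, 35),
    unit = "mmol_per_gDW", stringsAsFactors = FALSE) else NULL
  pool_gam <- if (cfg$include_maintenance) data.frame(
    metabolite_id = c("atp_c", "h2o_c", "adp_c", "pi_c", "h_c"),
    name = c("ATP", "water", "ADP", "phosphate", "proton"),
    coefficient = c(-4.3, -4.3, 4.3, 4.3, 4.3),
    unit = "mol_per_mol_pool", stringsAsFactors = FALSE) else NULL

  sheet <- function(name, comp, maint = NULL) {
    lines <- c("metabolite_id\tname\tvalue\tunit",
               sprintf("%s\t%s\t%.15g\t%s", comp$metabolite_id, comp$name,
                       comp$value, comp$unit))
    if (!is.null(maint) && nrow(maint)) {
      lines <- c(lines, "",
                 "metabolite_id\tname\tcoefficient\tunit",
                 sprintf("%s\t%s\t%.15g\t%s", maint$metabolite_id, maint$name,
                         maint$coefficient, maint$unit))
    }
    writeLines(lines, file.path(dir, paste0(name, ".tsv")))
  }
  comp_df <- function(ids, values, unit) {
    nm <- model$metabolites$name[match(ids, model$metabolites$id)]
    nm[is.na(nm)] <- ids[is.na(nm)]
    data.frame(metabolite_id = ids, name = nm, value = values, unit = unit,
               stringsAsFactors = FALSE)
  }

  if (cfg$levels == 1L) {
    ids <- c("ala__L_c", "gly_c", "glu__L_c", "datp_c", "glycogen_c")
    w <- rand_simplex(length(ids), rng) * cfg$total_mass
    sheet("BIOMASS", comp_df(ids, w, "g_per_gDW"), gam)
    return(invisible(dir))
  }

  # pool sheets (level 2, and level 3 under LIPIDS when levels == 3)
  dna_unit <- if (cfg$corrupt) c("mol_per_mol", "mmol_per_gDW",
                                 "mol_per_mol", "mol_per_mol") else "mol_per_mol"
  sheet("DNA", comp_df(c("datp_c", "dctp_c", "dgtp_c", "dttp_c"),
                       rand_simplex(4, rng), dna_unit))
  sheet("PROTEIN", comp_df(c("ala__L_c", "gly_c", "glu__L_c", "lys__L_c"),
                           100 * rand_simplex(4, rng), "percent_mol"), pool_gam)
  if (cfg$levels == 3L) {
    sheet("PC", comp_df(c("pc140_c", "pc160_c"), rand_simplex(2, rng), "mol_per_mol"))
    sheet("PE", comp_df(c("pe140_c", "pe160_c"), rand_simplex(2, rng), "mol_per_mol"))
    lipid_comp <- data.frame(metabolite_id = c("PC", "PE"),
                             name = c("phosphatidylcholines", "phosphatidylethanolamines"),
                             value = rand_simplex(2, rng), unit = "mol_per_mol",
                             stringsAsFactors = FALSE)
    sheet("LIPIDS", lipid_comp)
    top_ids <- c("PROTEIN", "DNA", "LIPIDS", "glycogen_c")
  } else {
    top_ids <- c("PROTEIN", "DNA", "glycogen_c")
  }
  w <- rand_simplex(length(top_ids), rng) * cfg$total_mass
  top <- data.frame(metabolite_id = top_ids,
                    name = top_ids, value = w, unit = "g_per_gDW",
                    stringsAsFactors = FALSE)
  sheet("BIOMASS", top, gam)
  invisible(dir)
}
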