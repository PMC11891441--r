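# shared builders: everything constructed in code, nothing read from disk
# except through the package's own writers

empty_maintenance <- function() {
  data.frame(metabolite_id = character(0), name = character(0),
             coefficient = numeric(0), unit = character(0), stringsAsFactors = FALSE)
}

comp_table <- function(ids, values, unit) {
  data.frame(metabolite_id = ids, name = ids, value = values, unit = unit,
             stringsAsFactors = FALSE)
}

maint_table <- function(ids, coefs, unit) {
  data.frame(metabolite_id = ids, name = ids, coefficient = coefs, unit = unit,
             stringsAsFactors = FALSE)
}

raw_sheet <- function(composition, maintenance = empty_maintenance()) {
  list(composition = composition, maintenance = maintenance)
}

# two-metabolite model with tidy formulas for hand-oracle arithmetic:
# A = CH2O (30.026 g/mol), B = C2H4O2 (60.052 g/mol)
ab_model <- function() {
  m <- new_model(id = "ab", compartments = c(c = "cytosol"))
  m <- add_metabolite(m, "A_c", "A", "c", formula = "CH2O", charge = 0)
  m <- add_metabolite(m, "B_c", "B", "c", formula = "C2H4O2", charge = 0)
  m
}

# standard end-to-end build on the bundled toy fixtures
toy_build <- function(levels = 3, seed = 7, tag = "t1", total_mass = 0.97, ...) {
  cfg <- fixture_config(levels = levels, seed = seed, total_mass = total_mass, ...)
  model <- make_toy_model(cfg)
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  make_composition(cfg, model, dir)
  c(build_bof(model, dir, tag = tag, compartment = "c"),
    list(base_model = model, workbook_dir = dir, cfg = cfg))
}

expect_equal_num <- function(a, b, tol = 1e-9) {
  expect_true(all(abs(a - b) <= tol), label = sprintf(
    "max abs diff %.3g <= %.3g", max(abs(a - b)), tol))
}
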