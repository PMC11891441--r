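# Structured condition classes so callers (and the CLI exit-code mapping) can
# dispatch on failure kind rather than on message text.

bof_error <- function(class, message, ...) {
  stop(structure(
    class = c(class, "bofkit_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

bof_warning <- function(class, message, ...) {
  warning(structure(
    class = c(class, "bofkit_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

# error classes used across the package:
#   bofkit_parse_error       malformed elemental formula string
#   bofkit_chem_error        mass needed for an element with undefined weight
#   bofkit_io_error          unreadable/unwritable model or workbook file
#   bofkit_schema_error      workbook table violates the sheet schema
#   bofkit_spec_error        composition dataset fails cross validation
#   bofkit_conversion_error  unit conversion impossible (missing formula, empty pool)
#   bofkit_collision_error   generated ID already present in the model
#   bofkit_notfound_error    tag (or entity) not present in the model
#   bofkit_validation_error  post-generation balance/feasibility failure
#   bofkit_config_error      bad CLI/run configuration
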