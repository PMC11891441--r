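test_that("load_workbook parses TSV sheet directories into two tables per sheet", {
  cfg <- fixture_config(levels = 3, seed = 1)
  m <- make_toy_model(cfg)
  d <- withr::local_tempdir()
  make_composition(cfg, m, d)
  sheets <- load_workbook(d)
  expect_setequal(names(sheets), c("BIOMASS", "DNA", "PROTEIN", "LIPIDS", "PC", "PE"))
  expect_equal(nrow(sheets$DNA$composition), 4)
  expect_named(sheets$DNA$composition, c("metabolite_id", "name", "value", "unit"))
  expect_equal(nrow(sheets$DNA$maintenance), 0)          # no maintenance table on DNA
  expect_equal(nrow(sheets$BIOMASS$maintenance), 5)      # ATP hydrolysis quartet + proton
  expect_named(sheets$BIOMASS$maintenance,
               c("metabolite_id", "name", "coefficient", "unit"))
})

test_that("schema violations are named precisely", {
  d <- withr::local_tempdir()
  writeLines(c("metabolite_id\tname\tvalue", "datp_c\tdATP\t0.3"),
             file.path(d, "DNA.tsv"))
  err <- expect_error(load_workbook(d), class = "bofkit_schema_error")
  expect_match(conditionMessage(err), "DNA")
  expect_match(conditionMessage(err), "unit")

  writeLines(c("metabolite_id\tname\tvalue\tunit", "datp_c\tdATP\tlots\tmol_per_mol"),
             file.path(d, "DNA.tsv"))
  err <- expect_error(load_workbook(d), class = "bofkit_schema_error")
  expect_match(conditionMessage(err), "non-numeric")
})

test_that("XLSX workbooks load when readxl is present, matching the TSV load", {
  skip_if_not_installed("readxl")
  # no XLSX writer offline: a minimal xlsx is assembled by hand (it is a zip)
  skip_if(Sys.which("zip") == "" && !requireNamespace("zip", quietly = TRUE),
          "no zip tool available to assemble an xlsx fixture")
  d <- withr::local_tempdir()
  make_xlsx_fixture(d)  # helper writes d/book.xlsx with one BIOMASS sheet
  sheets <- load_workbook(file.path(d, "book.xlsx"))
  expect_named(sheets, "BIOMASS")
  expect_equal(sheets$BIOMASS$composition$metabolite_id, c("glycogen_c", "ala__L_c"))
  expect_equal(sheets$BIOMASS$composition$value, c(0.4, 0.5))
  expect_equal(sheets$BIOMASS$maintenance$coefficient, -35)
})

test_that("build_spec validates a correct three-level dataset", {
  res <- toy_build(levels = 3, seed = 3, tag = "ok")
  spec <- res$spec
  expect_s3_class(spec, "bof_spec")
  expect_identical(spec$top$pool_name, "BIOMASS")
  expect_setequal(names(spec$pools), c("DNA", "PROTEIN", "LIPIDS", "PC", "PE"))
  levels <- vapply(c(list(spec$top), spec$pools), function(s) s$level, integer(1))
  expect_identical(max(levels), 3L)
  # order is deterministic and top-down
  expect_identical(spec$order[1], "BIOMASS")
})

test_that("build_spec rejects planted errors, collecting all failures", {
  cfg <- fixture_config(levels = 3, seed = 3)
  m <- make_toy_model(cfg)
  d <- withr::local_tempdir()
  make_composition(cfg, m, d)
  sheets <- load_workbook(d)

  # unit mixing within one sheet (the per-sheet single-unit rule)
  bad <- sheets
  bad$DNA$composition$unit[2] <- "mmol_per_gDW"
  err <- expect_error(build_spec(bad, "t", "c", m), class = "bofkit_spec_error")
  expect_match(conditionMessage(err), "same unit|share one unit")

  # corrupt fixture plants the same fault
  dc <- withr::local_tempdir()
  make_composition(fixture_config(levels = 3, seed = 3, corrupt = TRUE), m, dc)
  expect_error(build_spec(load_workbook(dc), "t", "c", m), class = "bofkit_spec_error")

  # unknown metabolite ID
  bad <- sheets
  bad$DNA$composition$metabolite_id[1] <- "datp_x"
  err <- expect_error(build_spec(bad, "t", "c", m), class = "bofkit_spec_error")
  expect_match(conditionMessage(err), "datp_x")

  # duplicate ID within a sheet is an error, never silently summed
  bad <- sheets
  bad$DNA$composition$metabolite_id[2] <- "datp_c"
  err <- expect_error(build_spec(bad, "t", "c", m), class = "bofkit_spec_error")
  expect_match(conditionMessage(err), "duplicate")

  # reference cycle
  bad <- sheets
  bad$PC$composition <- rbind(bad$PC$composition,
                              data.frame(metabolite_id = "BIOMASS", name = "loop",
                                         value = 0.1, unit = "mol_per_mol"))
  err <- expect_error(build_spec(bad, "t", "c", m), class = "bofkit_spec_error")
  expect_match(conditionMessage(err), "cycle|top-level")

  # several faults reported together
  bad <- sheets
  bad$DNA$composition$metabolite_id[1] <- "datp_x"
  bad$PROTEIN$composition$unit[1] <- "g_per_gDW"
  err <- expect_error(build_spec(bad, "t", "c", m), class = "bofkit_spec_error")
  expect_match(conditionMessage(err), "datp_x")
  expect_match(conditionMessage(err), "PROTEIN")

  # bad tag / unknown compartment
  expect_error(build_spec(sheets, "bad tag!", "c", m), class = "bofkit_spec_error")
  expect_error(build_spec(sheets, "t", "nucleus", m), class = "bofkit_spec_error")

  # maintenance pointing at a pool
  bad <- sheets
  bad$BIOMASS$maintenance$metabolite_id[1] <- "DNA"
  expect_error(build_spec(bad, "t", "c", m), class = "bofkit_spec_error")
})

test_that("zero-valued entries are dropped with a notice and do not change coefficients", {
  m <- make_toy_model(fixture_config(levels = 1))
  base <- list(BIOMASS = raw_sheet(
    comp_table(c("ala__L_c", "gly_c"), c(0.5, 0.4), "g_per_gDW")))
  with_zero <- list(BIOMASS = raw_sheet(
    comp_table(c("ala__L_c", "gly_c", "glu__L_c"), c(0.5, 0.4, 0), "g_per_gDW")))
  s1 <- build_spec(base, "t", "c", m)
  s2 <- build_spec(with_zero, "t", "c", m)
  expect_match(s2$notices, "glu__L_c", all = FALSE)
  r1 <- resolve_bof(s1, m)
  r2 <- resolve_bof(s2, m)
  expect_equal(r1$BIOMASS$coefficients, r2$BIOMASS$coefficients, tolerance = 1e-12)

  all_zero <- list(BIOMASS = raw_sheet(comp_table("ala__L_c", 0, "g_per_gDW")))
  expect_error(build_spec(all_zero, "t", "c", m), class = "bofkit_spec_error")
})

test_that("build_spec output satisfies the spec invariants on randomized fixtures", {
  for (seed in 1:5) {
    lv <- 1L + (seed %% 3)
    res <- toy_build(levels = lv, seed = seed, tag = paste0("s", seed))
    spec <- res$spec
    all_sheets <- c(list(spec$top), spec$pools)
    for (sh in all_sheets) {
      expect_length(unique(sh$entries$unit), 1)
      expect_true(all(sh$entries$value > 0))
      expect_true(sh$level >= 1 && sh$level <= 3)
    }
    expect_identical(spec$top$level, 1L)
    # every pool entry references one level deeper
    for (sh in all_sheets) {
      kids <- intersect(sh$entries$metabolite_id, spec$order)
      for (k in kids) {
        kid_level <- if (k == spec$top$pool_name) 1L else spec$pools[[k]]$level
        expect_identical(kid_level, sh$level + 1L)
      }
    }
  }
})
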