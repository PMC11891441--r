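# hand-oracle masses used throughout: CH2O = 30.026, C2H4O2 = 60.052 g/mol

test_that("resolve_pool converts each unit family to mole fractions", {
  m <- ab_model()

  # already-normalized molar input passes through
  dna_like <- list(pool_name = "P", level = 2L,
                   entries = comp_table(c("A_c", "B_c"), c(0.25, 0.75), "mol_per_mol"),
                   maintenance = empty_maintenance())
  r <- resolve_pool(dna_like, model = m)
  expect_equal(unname(r$mole_fractions), c(0.25, 0.75), tolerance = 1e-12)
  expect_equal(r$pool_molar_mass, 0.25 * 30.026 + 0.75 * 60.052, tolerance = 1e-9)

  # mass units: 0.6 g of each -> moles 0.6/30.026 vs 0.6/60.052 -> 2/3, 1/3
  massy <- list(pool_name = "P", level = 2L,
                entries = comp_table(c("A_c", "B_c"), c(0.6, 0.6), "g_per_gDW"),
                maintenance = empty_maintenance())
  r <- resolve_pool(massy, model = m)
  expect_equal(unname(r$mole_fractions), c(2 / 3, 1 / 3), tolerance = 1e-9)

  # percent_mol normalizes by 100
  pct <- list(pool_name = "P", level = 2L,
              entries = comp_table(c("A_c", "B_c"), c(30, 70), "percent_mol"),
              maintenance = empty_maintenance())
  r <- resolve_pool(pct, model = m)
  expect_equal(unname(r$mole_fractions), c(0.3, 0.7), tolerance = 1e-12)

  # mole fractions always sum to 1
  expect_equal(sum(r$mole_fractions), 1, tolerance = 1e-12)
})

test_that("resolve_pool fails on mass units without formulas, warns on missing pool formula", {
  m <- ab_model()
  m <- add_metabolite(m, "noform_c", "formless", "c")
  sheet <- list(pool_name = "P", level = 2L,
                entries = comp_table(c("A_c", "noform_c"), c(0.5, 0.5), "g_per_gDW"),
                maintenance = empty_maintenance())
  err <- expect_error(resolve_pool(sheet, model = m), class = "bofkit_conversion_error")
  expect_match(conditionMessage(err), "noform_c")

  molar <- list(pool_name = "P", level = 2L,
                entries = comp_table(c("A_c", "noform_c"), c(0.5, 0.5), "mol_per_mol"),
                maintenance = empty_maintenance())
  expect_warning(r <- resolve_pool(molar, model = m), class = "bofkit_warning")
  expect_equal(unname(r$mole_fractions), c(0.5, 0.5))
  expect_true(is.na(r$pool_molar_mass))
  expect_null(r$pool_formula)
})

test_that("resolve_top normalizes recovered mass to 1 gDW and converts to mmol/gDW", {
  # single component, mass 0.5 g/gDW, molar mass 100 -> fraction 1, coeff 10
  m <- new_model()
  m <- add_metabolite(m, "X_c", "X", "c", formula = "CH3NO4", charge = 0)  # 12.011+3.024+14.007+63.996
  mw <- molar_mass(parse_formula("CH3NO4"))
  expect_equal(mw, 93.038, tolerance = 1e-9)
  sheet <- list(pool_name = "BIOMASS", level = 1L,
                entries = comp_table("X_c", 0.5, "g_per_gDW"),
                maintenance = empty_maintenance())
  expect_warning(r <- resolve_top(sheet, model = m), class = "bofkit_warning")  # scale 2 outside [0.8,1.25]
  expect_equal(unname(r$mass_fractions), 1, tolerance = 1e-12)
  expect_equal(r$scale_factor, 2, tolerance = 1e-12)
  expect_equal(unname(r$coefficients), 1000 / mw, tolerance = 1e-9)

  # three components 0.6/0.2/0.1 -> scale 1/0.9, fractions 2/3, 2/9, 1/9
  m <- ab_model()
  m <- add_metabolite(m, "C_c", "C", "c", formula = "C3H6O3", charge = 0)
  sheet <- list(pool_name = "BIOMASS", level = 1L,
                entries = comp_table(c("A_c", "B_c", "C_c"), c(0.6, 0.2, 0.1), "g_per_gDW"),
                maintenance = empty_maintenance())
  r <- resolve_top(sheet, model = m)
  expect_equal(unname(r$mass_fractions), c(2 / 3, 2 / 9, 1 / 9), tolerance = 1e-12)
  expect_equal(sum(r$mass_fractions), 1, tolerance = 1e-12)
  expect_equal(unname(r$coefficients),
               c(2 / 3, 2 / 9, 1 / 9) * 1000 / c(30.026, 60.052, molar_mass(parse_formula("C3H6O3"))),
               tolerance = 1e-9)
})

test_that("normalization is scale- and unit-invariant (properties)", {
  m <- ab_model()
  base <- comp_table(c("A_c", "B_c"), c(0.55, 0.42), "g_per_gDW")
  mk <- function(entries) list(pool_name = "BIOMASS", level = 1L, entries = entries,
                               maintenance = empty_maintenance())
  r0 <- resolve_top(mk(base), model = m)
  for (k in c(7, 0.001, 123.456)) {
    scaled <- base; scaled$value <- scaled$value * k
    rk <- suppressWarnings(resolve_top(mk(scaled), model = m))
    expect_equal(rk$coefficients, r0$coefficients, tolerance = 1e-9)
    expect_equal(rk$mass_fractions, r0$mass_fractions, tolerance = 1e-9)
    expect_equal(rk$scale_factor, r0$scale_factor / k, tolerance = 1e-9)
  }
  # g vs mg vs percent express the same data
  mg <- base; mg$value <- mg$value * 1000; mg$unit <- "mg_per_gDW"
  pc <- base; pc$value <- pc$value * 100; pc$unit <- "percent_DW_mass"
  # molar route: value mmol/gDW chosen to give identical masses
  mmolar <- base
  mmolar$value <- base$value * 1000 / c(30.026, 60.052)
  mmolar$unit <- "mmol_per_gDW"
  for (alt in list(mg, pc, mmolar)) {
    ra <- resolve_top(mk(alt), model = m)
    expect_equal(ra$coefficients, r0$coefficients, tolerance = 1e-9)
  }
})

test_that("maintenance rows pass through unconverted and unscaled", {
  m <- ab_model()
  m <- add_metabolite(m, "atp_c", "ATP", "c", formula = "C10H12N5O13P3", charge = -4)
  m <- add_metabolite(m, "adp_c", "ADP", "c", formula = "C10H12N5O10P2", charge = -3)
  sheet <- list(pool_name = "BIOMASS", level = 1L,
                entries = comp_table(c("A_c", "B_c"), c(1.2, 0.9), "g_per_gDW"),  # total != 1
                maintenance = maint_table(c("atp_c", "adp_c"), c(-40, 40), "mmol_per_gDW"))
  r <- suppressWarnings(resolve_top(sheet, model = m))
  expect_equal(unname(r$maintenance_coeffs), c(-40, 40))  # untouched by scale_factor
})

test_that("assemble_bof builds tagged reactions with unit product coefficients, atomically", {
  res <- toy_build(levels = 3, seed = 9, tag = "v1")
  m0 <- res$base_model
  m1 <- res$model
  expect_equal(length(m1$reactions) - length(m0$reactions), 6)
  expect_equal(nrow(m1$metabolites) - nrow(m0$metabolites), 6)
  for (s in res$spec$order) {
    rid <- paste0(s, "_v1")
    st <- m1$reactions[[rid]]$stoich
    expect_identical(unname(st[rid]), 1)                  # -> 1 POOL
    pseudo_prods <- names(st)[st > 0 & endsWith(names(st), "_v1")]
    expect_identical(pseudo_prods, rid)                   # single pseudo product
    expect_equal(c(m1$reactions[[rid]]$lb, m1$reactions[[rid]]$ub), c(0, 1000))
  }
  expect_identical(m1$objective, m0$objective)            # objective untouched by default

  # same tag again: collision, model unchanged
  err <- expect_error(assemble_bof(res$spec, res$results, m1),
                      class = "bofkit_collision_error")
  expect_match(conditionMessage(err), "BIOMASS_v1")

  # second tag coexists
  spec2 <- build_spec(load_workbook(res$workbook_dir), "v2", "c", m0)
  results2 <- resolve_bof(spec2, m0)
  m2 <- assemble_bof(spec2, results2, m1)$model
  expect_equal(length(m2$reactions) - length(m0$reactions), 12)

  # each removable independently
  m3 <- remove_bof(m2, "v1")
  expect_true(all(paste0(spec2$order, "_v2") %in% names(m3$reactions)))
  expect_false(any(endsWith(names(m3$reactions), "_v1")))
  m4 <- remove_bof(m3, "v2")
  expect_identical(names(m4$reactions), names(m0$reactions))
  expect_identical(m4$metabolites$id, m0$metabolites$id)
})

test_that("remove_bof round-trips, errors on unknown tags, unsets a removed objective", {
  res <- toy_build(levels = 2, seed = 4, tag = "tmp")
  m <- res$model
  back <- remove_bof(m, "tmp")
  expect_identical(names(back$reactions), names(res$base_model$reactions))
  expect_identical(back$metabolites$id, res$base_model$metabolites$id)
  expect_identical(back$metabolites$formula, res$base_model$metabolites$formula)
  for (rid in names(back$reactions)) {
    expect_identical(back$reactions[[rid]], res$base_model$reactions[[rid]])
  }
  expect_error(remove_bof(res$base_model, "nope"), class = "bofkit_notfound_error")

  res2 <- toy_build(levels = 2, seed = 4, tag = "obj")
  spec <- res2$spec
  m2 <- assemble_bof(spec, res2$results, res2$base_model, set_objective = TRUE)$model
  expect_identical(m2$objective, "BIOMASS_obj")
  expect_warning(m3 <- remove_bof(m2, "obj"), class = "bofkit_warning")
  expect_true(is.na(m3$objective))
})

test_that("flatten_bof chains coefficients through the hierarchy (hand oracle)", {
  # DNA-at-0.04 worked example: pool MW 500, dATP fraction 0.25
  # -> 0.04 * 1000 / 500 * 0.25 = 0.02 mmol/gDW
  m <- new_model()
  # hand sum: C31H16O8 = 31*12.011 + 16*1.008 + 8*15.999 = 516.461 g/mol
  mw <- 31 * 12.011 + 16 * 1.008 + 8 * 15.999
  expect_equal(mw, 516.461, tolerance = 1e-9)
  m <- add_metabolite(m, "mono_c", "monomer", "c", formula = "C31H16O8", charge = 0)
  m <- add_metabolite(m, "filler_c", "filler", "c", formula = "CH2O", charge = 0)
  # 0.04 g of DNA plus 0.96 g of filler: total already 1 g, so the DNA mass
  # fraction after normalization is exactly 0.04
  sheets <- list(
    BIOMASS = raw_sheet(comp_table(c("DNA", "filler_c"), c(0.04, 0.96), "g_per_gDW")),
    DNA = raw_sheet(comp_table("mono_c", 1, "mol_per_mol")))
  spec <- build_spec(sheets, "t", "c", m)
  results <- suppressWarnings(resolve_bof(spec, m))
  flat <- flatten_bof(spec, results)
  expect_equal(unname(flat["mono_c"]), 0.04 * 1000 / mw * 1, tolerance = 1e-9)

  # with a 4-monomer pool at fraction 0.25 each the chain matches by hand
  m4 <- make_toy_model(fixture_config(levels = 2))
  sheets4 <- list(
    BIOMASS = raw_sheet(comp_table("DNA", 1, "g_per_gDW")),
    DNA = raw_sheet(comp_table(c("datp_c", "dctp_c", "dgtp_c", "dttp_c"),
                               rep(0.25, 4), "mol_per_mol")))
  spec4 <- build_spec(sheets4, "t", "c", m4)
  r4 <- resolve_bof(spec4, m4)
  pool_mw <- r4$DNA$pool_molar_mass
  dntp_mw <- vapply(c("datp_c", "dctp_c", "dgtp_c", "dttp_c"), function(id)
    molar_mass(parse_formula(m4$metabolites$formula[m4$metabolites$id == id])), numeric(1))
  expect_equal(pool_mw, 0.25 * sum(dntp_mw), tolerance = 1e-9)
  flat4 <- flatten_bof(spec4, r4)
  expect_equal(unname(flat4["datp_c"]), 1000 / pool_mw * 0.25, tolerance = 1e-9)
})

test_that("hierarchical build equals the hand-flattened single-level build (core oracle)", {
  res <- toy_build(levels = 3, seed = 13, tag = "h")
  flat <- flatten_bof(res$spec, res$results)
  m <- res$base_model

  # independent conversion: feed the flattened consumption (known mmol/gDW,
  # composition rows only, maintenance re-attached separately) as a
  # single-level sheet and rebuild
  maint_flat <- local({
    acc <- numeric(0)
    add <- function(id, x) acc[id] <<- (if (id %in% names(acc)) acc[[id]] else 0) + x
    top <- res$results[[res$spec$top$pool_name]]
    for (j in seq_along(top$maintenance_coeffs)) {
      add(names(top$maintenance_coeffs)[j], top$maintenance_coeffs[[j]])
    }
    walk <- function(pool, usage) {
      r <- res$results[[pool]]
      for (j in seq_along(r$maintenance_coeffs)) {
        add(names(r$maintenance_coeffs)[j], usage * r$maintenance_coeffs[[j]])
      }
      for (j in seq_along(r$mole_fractions)) {
        id <- names(r$mole_fractions)[j]
        if (id %in% res$spec$order) walk(id, usage * r$mole_fractions[[j]])
      }
    }
    for (j in seq_along(top$coefficients)) {
      id <- names(top$coefficients)[j]
      if (id %in% res$spec$order) walk(id, top$coefficients[[j]])
    }
    acc
  })
  comp_only <- flat
  for (id in names(maint_flat)) {
    comp_only[id] <- (if (id %in% names(comp_only)) comp_only[[id]] else 0) + maint_flat[[id]]
  }
  comp_only <- comp_only[abs(comp_only) > 1e-12]
  single <- list(BIOMASS = raw_sheet(
    comp_table(names(comp_only), unname(comp_only), "mmol_per_gDW"),
    maint_table(names(maint_flat), unname(maint_flat), "mmol_per_gDW")))
  spec1 <- build_spec(single, "flat", "c", m)
  r1 <- suppressWarnings(resolve_bof(spec1, m))
  flat1 <- flatten_bof(spec1, r1)
  shared <- intersect(names(flat), names(flat1))
  expect_setequal(names(flat), names(flat1))
  expect_equal_num(flat1[shared], flat[shared], tol = 1e-9)
})

test_that("mass closure: net substrate-minus-product mass is 1 g per unit top flux", {
  for (lv in 1:3) {
    res <- toy_build(levels = lv, seed = 20 + lv, tag = "mc")
    flat <- flatten_bof(res$spec, res$results)
    m <- res$base_model
    net <- sum(vapply(names(flat), function(id) {
      flat[[id]] * molar_mass(parse_formula(
        m$metabolites$formula[m$metabolites$id == id])) / 1000
    }, numeric(1)))
    expect_equal(net, 1, tolerance = 1e-6)
  }
})

test_that("coefficient report lists every species of every reaction exactly once", {
  res <- toy_build(levels = 3, seed = 17, tag = "rep")
  rep <- res$report
  expect_s3_class(rep, "coefficient_report")
  for (s in res$spec$order) {
    rid <- paste0(s, "_rep")
    in_model <- sort(names(res$model$reactions[[rid]]$stoich))
    in_report <- sort(rep$species[rep$reaction == rid])
    expect_identical(in_report, in_model)
    expect_false(any(duplicated(rep$species[rep$reaction == rid])))
  }
  expect_equal(attr(rep, "scale_factor"), 1 / 0.97, tolerance = 1e-9)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_report(rep, p)
  reread <- utils::read.delim(p, comment.char = "#")
  expect_equal(nrow(reread), nrow(rep))
})
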