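#' Biomass composition workbooks
#'
#' The composition dataset is a workbook with one sheet per pseudo-reaction.
#' Each sheet holds two header-labelled tables separated by at least one blank
#' row: a composition table (`metabolite_id`, optional `name`, `value`,
#' `unit`) listing the building blocks, and an optional maintenance table
#' (`metabolite_id`, optional `name`, `coefficient`, `unit`) whose rows are
#' used as stoichiometric coefficients directly, without conversion or
#' normalization.
#'
#' Two on-disk representations are accepted: a directory of TSV files (one
#' file per sheet, file name = sheet name; the canonical plain-text layout)
#' or an XLSX workbook (requires the readxl package; same two-table layout
#' within each sheet).
#'
#' @name composition
NULL

COMPOSITION_UNITS <- c("g_per_gDW", "mg_per_gDW", "percent_DW_mass",
                       "mmol_per_gDW", "umol_per_gDW", "mol_per_mol", "percent_mol")
MASS_UNITS  <- c("g_per_gDW", "mg_per_gDW", "percent_DW_mass")
MOLAR_UNITS <- c("mmol_per_gDW", "umol_per_gDW", "mol_per_mol", "percent_mol")
TOP_UNITS   <- c(MASS_UNITS, "mmol_per_gDW", "umol_per_gDW")
MAINT_UNITS <- c("mmol_per_gDW", "mol_per_mol_pool")

# split a character matrix of cells into blocks at all-blank rows
split_blocks <- function(cells) {
  blank <- apply(cells, 1, function(r) all(is.na(r) | !nzchar(trimws(r))))
  blocks <- list()
  i <- 1
  n <- nrow(cells)
  while (i <= n) {
    while (i <= n && blank[i]) i <- i + 1
    if (i > n) break
    j <- i
    while (j <= n && !blank[j]) j <- j + 1
    blocks[[length(blocks) + 1]] <- cells[i:(j - 1), , drop = FALSE]
    i <- j
  }
  blocks
}

block_to_df <- function(block, sheet) {
  header <- tolower(trimws(block[1, ]))
  keep <- !is.na(header) & nzchar(header)
  header <- header[keep]
  body <- block[-1, keep, drop = FALSE]
  df <- as.data.frame(body, stringsAsFactors = FALSE)
  names(df) <- header
  # drop fully-empty trailing rows
  nonempty <- apply(df, 1, function(r) any(!is.na(r) & nzchar(trimws(r))))
  df[nonempty, , drop = FALSE]
}

parse_table <- function(df, sheet, value_col) {
  required <- c("metabolite_id", value_col, "unit")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    bof_error("bofkit_schema_error", sprintf(
      "sheet '%s': missing mandatory column(s): %s", sheet, paste(missing, collapse = ", ")))
  }
  vals <- suppressWarnings(as.numeric(df[[value_col]]))
  bad <- which(is.na(vals) & nzchar(trimws(df[[value_col]])))
  if (any(is.na(vals))) {
    row <- if (length(bad)) bad[1] else which(is.na(vals))[1]
    bof_error("bofkit_schema_error", sprintf(
      "sheet '%s', row %d: non-numeric %s cell '%s'", sheet, row, value_col,
      df[[value_col]][row]))
  }
  data.frame(
    metabolite_id = trimws(df$metabolite_id),
    name = if ("name" %in% names(df)) trimws(df$name) else trimws(df$metabolite_id),
    value = vals,
    unit = trimws(df$unit),
    stringsAsFactors = FALSE)
}

parse_sheet_cells <- function(cells, sheet) {
  blocks <- split_blocks(cells)
  if (!length(blocks)) {
    bof_error("bofkit_schema_error", sprintf("sheet '%s' is empty", sheet))
  }
  headers <- lapply(blocks, function(b) tolower(trimws(b[1, ])))
  is_maint <- vapply(headers, function(h) "coefficient" %in% h, logical(1))
  comp_i <- which(!is_maint)
  maint_i <- which(is_maint)
  if (length(comp_i) != 1L || length(maint_i) > 1L) {
    bof_error("bofkit_schema_error", sprintf(
      "sheet '%s': expected one composition table and at most one maintenance table", sheet))
  }
  comp <- parse_table(block_to_df(blocks[[comp_i]], sheet), sheet, "value")
  maint <- if (length(maint_i)) {
    parse_table(block_to_df(blocks[[maint_i]], sheet), sheet, "coefficient")
  } else {
    data.frame(metabolite_id = character(0), name = character(0),
               value = numeric(0), unit = character(0), stringsAsFactors = FALSE)
  }
  names(maint)[names(maint) == "value"] <- "coefficient"
  names(comp) <- c("metabolite_id", "name", "value", "unit")
  list(composition = comp, maintenance = maint)
}

read_tsv_sheet <- function(path) {
  lines <- readLines(path)
  cells_list <- strsplit(lines, "\t", fixed = TRUE)
  width <- max(vapply(cells_list, length, integer(1)), 1L)
  cells <- t(vapply(cells_list, function(r) c(r, rep("", width - length(r))), character(width)))
  if (width == 1L) cells <- matrix(cells, ncol = 1L)
  cells
}

#' Load a composition workbook
#'
#' @param path Either a directory containing one `<SHEET>.tsv` file per
#'   pseudo-reaction, or an `.xlsx` workbook (readxl required).
#' @return A named list of raw sheets; each sheet is a list with elements
#'   `composition` and `maintenance` (data frames). Sheet order follows file
#'   name order (directories) or workbook order (XLSX); the order of
#'   reactions in the output model is fixed later by the pool tree.
#' @export
load_workbook <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tsv$", full.names = TRUE))
    if (!length(files)) {
      bof_error("bofkit_io_error", sprintf("no .tsv sheets found in directory '%s'", path))
    }
    sheets <- lapply(files, function(f) {
      parse_sheet_cells(read_tsv_sheet(f), sub("\\.tsv$", "", basename(f)))
    })
    names(sheets) <- sub("\\.tsv$", "", basename(files))
    return(sheets)
  }
  if (!file.exists(path)) {
    bof_error("bofkit_io_error", sprintf("workbook '%s' does not exist", path))
  }
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      bof_error("bofkit_io_error", "reading XLSX workbooks requires the 'readxl' package")
    }
    sheet_names <- readxl::excel_sheets(path)
    sheets <- lapply(sheet_names, function(s) {
      raw <- readxl::read_excel(path, sheet = s, col_names = FALSE,
                                col_types = "text", .name_repair = "minimal")
      cells <- as.matrix(raw)
      if (!nrow(cells)) bof_error("bofkit_schema_error", sprintf("sheet '%s' is empty", s))
      parse_sheet_cells(cells, s)
    })
    names(sheets) <- sheet_names
    return(sheets)
  }
  bof_error("bofkit_io_error", sprintf(
    "'%s' is neither a sheet directory nor an .xlsx workbook", path))
}

## ------------------------------------------------------------ build_spec ----

#' Validate raw sheets into a BOF specification
#'
#' Performs the full cross-validation of the composition dataset against the
#' model and returns a `bof_spec`: the tree of pseudo-reaction sheets (root =
#' the unique sheet referenced by no other sheet, conventionally BIOMASS),
#' with levels assigned by depth. All validation failures are collected and
#' reported together in a single error.
#'
#' Rules enforced: one unit per sheet's composition table; units from the
#' documented enumeration; level-1 units per-gDW (mass or molar), pool-level
#' maintenance in `mol_per_mol_pool` and level-1 maintenance in
#' `mmol_per_gDW`; the pool reference graph a tree of depth <= 3; every
#' non-pool `metabolite_id` (and every maintenance ID) an exact, case
#' sensitive model metabolite ID; no duplicate IDs within a sheet; values
#' >= 0 with zero-valued rows dropped (with a notice); non-zero maintenance
#' coefficients; tag matching `[A-Za-z0-9_]+`; compartment present in the
#' model.
#'
#' @param sheets Raw sheet list from [load_workbook()].
#' @param tag Suffix appended to all generated pseudo-entity IDs.
#' @param compartment Compartment ID the pseudo-metabolites will live in.
#' @param model A `gem_model`.
#' @return A `bof_spec` with elements `top`, `pools` (named list, tree order),
#'   `tag`, `compartment`, `order` (sheet order used for model insertion) and
#'   `notices` (character vector of dropped-row messages).
#' @export
build_spec <- function(sheets, tag, compartment, model) {
  stopifnot(inherits(model, "gem_model"))
  fail <- character(0)
  notices <- character(0)
  note <- function(msg) notices <<- c(notices, msg)
  flunk <- function(msg) fail <<- c(fail, msg)

  if (!is.character(tag) || length(tag) != 1L || !grepl("^[A-Za-z0-9_]+$", tag)) {
    flunk("tag must be a non-empty string of [A-Za-z0-9_]")
  }
  if (!compartment %in% names(model$compartments)) {
    flunk(sprintf("compartment '%s' not found in model (available: %s)",
                  compartment, paste(names(model$compartments), collapse = ", ")))
  }
  pool_names <- names(sheets)

  # ---- per-sheet table validation
  for (s in pool_names) {
    comp <- sheets[[s]]$composition
    if (!nrow(comp)) { flunk(sprintf("sheet '%s': composition table is empty", s)); next }
    bad_unit <- setdiff(unique(comp$unit), COMPOSITION_UNITS)
    if (length(bad_unit)) {
      flunk(sprintf("sheet '%s': unknown unit(s) %s (accepted: %s)", s,
                    paste(sprintf("'%s'", bad_unit), collapse = ", "),
                    paste(COMPOSITION_UNITS, collapse = ", ")))
    }
    if (length(unique(comp$unit)) > 1L) {
      flunk(sprintf(
        "sheet '%s': all metabolites consumed in one pseudo-reaction must share one unit (found: %s)",
        s, paste(unique(comp$unit), collapse = ", ")))
    }
    dup <- unique(comp$metabolite_id[duplicated(comp$metabolite_id)])
    if (length(dup)) {
      flunk(sprintf("sheet '%s': duplicate metabolite_id(s) %s (rows are never summed silently)",
                    s, paste(sprintf("'%s'", dup), collapse = ", ")))
    }
    if (any(comp$value < 0)) {
      flunk(sprintf("sheet '%s': negative composition value(s) for %s", s,
                    paste(sprintf("'%s'", comp$metabolite_id[comp$value < 0]), collapse = ", ")))
    }
    maint <- sheets[[s]]$maintenance
    if (nrow(maint)) {
      bad_mu <- setdiff(unique(maint$unit), MAINT_UNITS)
      if (length(bad_mu)) {
        flunk(sprintf("sheet '%s': maintenance unit(s) %s not in {%s}", s,
                      paste(sprintf("'%s'", bad_mu), collapse = ", "),
                      paste(MAINT_UNITS, collapse = ", ")))
      }
      if (any(maint$coefficient == 0)) {
        flunk(sprintf("sheet '%s': zero maintenance coefficient for %s", s,
                      paste(sprintf("'%s'", maint$metabolite_id[maint$coefficient == 0]),
                            collapse = ", ")))
      }
      maint_pool <- intersect(maint$metabolite_id, pool_names)
      if (length(maint_pool)) {
        flunk(sprintf("sheet '%s': maintenance entries must be model metabolites, not pools: %s",
                      s, paste(sprintf("'%s'", maint_pool), collapse = ", ")))
      }
      missing_m <- check_metabolites_exist(model, setdiff(maint$metabolite_id, pool_names))
      if (length(missing_m)) {
        flunk(sprintf("sheet '%s': maintenance metabolite(s) not in model: %s",
                      s, paste(sprintf("'%s'", unique(missing_m)), collapse = ", ")))
      }
    }
  }

  # ---- pool reference graph: must be a tree rooted at a unique root
  referenced <- list()
  for (s in pool_names) {
    kids <- intersect(sheets[[s]]$composition$metabolite_id, pool_names)
    for (k in kids) referenced[[k]] <- c(referenced[[k]], s)
  }
  multi <- names(referenced)[vapply(referenced, length, integer(1)) > 1L]
  if (length(multi)) {
    flunk(sprintf("pool(s) referenced from more than one sheet: %s",
                  paste(sprintf("'%s'", multi), collapse = ", ")))
  }
  roots <- setdiff(pool_names, names(referenced))
  level <- stats::setNames(rep(NA_integer_, length(pool_names)), pool_names)
  order <- character(0)
  if (length(roots) != 1L) {
    flunk(sprintf(
      "expected exactly one top-level sheet (referenced by no other); found %d (%s) -- check for cycles",
      length(roots), paste(sprintf("'%s'", roots), collapse = ", ")))
  } else {
    root <- roots
    # BFS depth assignment; cycles among non-root sheets leave NA levels
    level[root] <- 1L
    frontier <- root
    order <- root
    while (length(frontier)) {
      nxt <- character(0)
      for (s in frontier) {
        kids <- intersect(sheets[[s]]$composition$metabolite_id, pool_names)
        for (k in kids) {
          if (!is.na(level[k])) {
            flunk(sprintf("pool reference cycle or reconvergence involving '%s'", k))
            next
          }
          level[k] <- level[s] + 1L
          nxt <- c(nxt, k)
        }
      }
      order <- c(order, nxt)
      frontier <- nxt
    }
    unreach <- pool_names[is.na(level)]
    if (length(unreach)) {
      flunk(sprintf("sheet(s) unreachable from top sheet '%s' (cycle?): %s",
                    root, paste(sprintf("'%s'", unreach), collapse = ", ")))
    }
    if (any(level > 3L, na.rm = TRUE)) {
      flunk(sprintf("BOF depth exceeds 3 levels (deepest sheet: %s)",
                    paste(sprintf("'%s'", pool_names[which(level > 3L)]), collapse = ", ")))
    }
  }

  # ---- per-sheet semantic validation that needs levels
  for (s in pool_names) {
    comp <- sheets[[s]]$composition
    lv <- level[[s]]
    if (!is.na(lv) && lv == 1L && nrow(comp)) {
      bad <- setdiff(unique(comp$unit), TOP_UNITS)
      bad <- intersect(bad, COMPOSITION_UNITS)  # unknown units already reported
      if (length(bad)) {
        flunk(sprintf(
          "sheet '%s' (level 1): unit(s) %s have no dry-weight basis; level-1 data must be per gDW (%s)",
          s, paste(sprintf("'%s'", bad), collapse = ", "), paste(TOP_UNITS, collapse = ", ")))
      }
    }
    maint <- sheets[[s]]$maintenance
    if (!is.na(lv) && nrow(maint)) {
      want <- if (lv == 1L) "mmol_per_gDW" else "mol_per_mol_pool"
      wrong <- setdiff(intersect(unique(maint$unit), MAINT_UNITS), want)
      if (length(wrong)) {
        flunk(sprintf("sheet '%s' (level %d): maintenance must be given in %s, found %s",
                      s, lv, want, paste(sprintf("'%s'", wrong), collapse = ", ")))
      }
    }
    non_pool <- setdiff(comp$metabolite_id, pool_names)
    missing <- check_metabolites_exist(model, non_pool)
    if (length(missing)) {
      flunk(sprintf("sheet '%s': metabolite ID(s) not found in model: %s",
                    s, paste(sprintf("'%s'", unique(missing)), collapse = ", ")))
    }
    # pool references must point exactly one level deeper
    kid_pools <- intersect(comp$metabolite_id, pool_names)
    for (k in kid_pools) {
      if (!is.na(lv) && !is.na(level[[k]]) && level[[k]] != lv + 1L) {
        flunk(sprintf("sheet '%s' (level %d) references pool '%s' (level %d); pools must sit exactly one level deeper",
                      s, lv, k, level[[k]]))
      }
    }
  }

  if (length(fail)) {
    bof_error("bofkit_spec_error", paste0(
      "composition dataset failed validation:\n  - ", paste(fail, collapse = "\n  - ")))
  }

  make_spec <- function(s) {
    comp <- sheets[[s]]$composition
    zero <- comp$value == 0
    if (any(zero)) {
      note(sprintf("sheet '%s': dropped zero-valued entr%s %s", s,
                   if (sum(zero) > 1) "ies" else "y",
                   paste(sprintf("'%s'", comp$metabolite_id[zero]), collapse = ", ")))
      comp <- comp[!zero, , drop = FALSE]
    }
    if (!nrow(comp)) {
      bof_error("bofkit_spec_error",
                sprintf("sheet '%s': all composition entries are zero (empty pool)", s))
    }
    list(pool_name = s, level = level[[s]], entries = comp,
         maintenance = sheets[[s]]$maintenance)
  }

  specs <- lapply(order, make_spec)
  names(specs) <- order
  structure(list(
    top = specs[[1]],
    pools = specs[-1],
    tag = tag,
    compartment = compartment,
    order = order,
    notices = notices
  ), class = "bof_spec")
}

#' @export
print.bof_spec <- function(x, ...) {
  cat(sprintf("<bof_spec tag='%s' compartment='%s': top '%s' + %d pool sheet(s), depth %d>\n",
              x$tag, x$compartment, x$top$pool_name, length(x$pools),
              max(vapply(c(list(x$top), x$pools), function(s) s$level, integer(1)))))
  invisible(x)
}
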