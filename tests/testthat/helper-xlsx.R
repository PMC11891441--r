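# Assemble a minimal single-sheet XLSX by hand (an xlsx is a zip of XML
# parts; no XLSX writer is installed offline). Inline strings keep it simple.
make_xlsx_fixture <- function(dir) {
  root <- file.path(dir, "parts")
  dir.create(file.path(root, "_rels"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(root, "xl", "_rels"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(root, "xl", "worksheets"), recursive = TRUE, showWarnings = FALSE)

  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    '<Override PartName="/xl/worksheets/sheet1.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
    '</Types>'), file.path(root, "[Content_Types].xml"))

  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    '</Relationships>'), file.path(root, "_rels", ".rels"))

  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    '<sheets><sheet name="BIOMASS" sheetId="1" r:id="rId1"/></sheets>',
    '</workbook>'), file.path(root, "xl", "workbook.xml"))

  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet1.xml"/>',
    '</Relationships>'), file.path(root, "xl", "_rels", "workbook.xml.rels"))

  scell <- function(ref, txt) sprintf('<c r="%s" t="inlineStr"><is><t>%s</t></is></c>', ref, txt)
  ncell <- function(ref, v) sprintf('<c r="%s"><v>%s</v></c>', ref, v)
  rows <- c(
    paste0('<row r="1">', scell("A1", "metabolite_id"), scell("B1", "name"),
           scell("C1", "value"), scell("D1", "unit"), '</row>'),
    paste0('<row r="2">', scell("A2", "glycogen_c"), scell("B2", "glycogen"),
           ncell("C2", 0.4), scell("D2", "g_per_gDW"), '</row>'),
    paste0('<row r="3">', scell("A3", "ala__L_c"), scell("B3", "alanine"),
           ncell("C3", 0.5), scell("D3", "g_per_gDW"), '</row>'),
    paste0('<row r="5">', scell("A5", "metabolite_id"), scell("B5", "name"),
           scell("C5", "coefficient"), scell("D5", "unit"), '</row>'),
    paste0('<row r="6">', scell("A6", "atp_c"), scell("B6", "ATP"),
           ncell("C6", -35), scell("D6", "mmol_per_gDW"), '</row>'))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
    paste0('<sheetData>', paste(rows, collapse = ""), '</sheetData>'),
    '</worksheet>'), file.path(root, "xl", "worksheets", "sheet1.xml"))

  out <- file.path(dir, "book.xlsx")
  if (requireNamespace("zip", quietly = TRUE)) {
    zip::zip(out, files = c("[Content_Types].xml", "_rels/.rels", "xl/workbook.xml",
                            "xl/_rels/workbook.xml.rels", "xl/worksheets/sheet1.xml"),
             root = root, mode = "mirror")
  } else {
    old <- setwd(root); on.exit(setwd(old))
    utils::zip(out, files = c("[Content_Types].xml", "_rels/.rels", "xl/workbook.xml",
                              "xl/_rels/workbook.xml.rels", "xl/worksheets/sheet1.xml"),
               flags = "-q")
  }
  out
}
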