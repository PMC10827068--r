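# Two-sheet workbook dialect: a "species" sheet (module, ID, name, Yinit,
# Ymax, tau) and a "reactions" sheet (module, ID, Rule, Weight, n, EC50).
# Published workbooks vary in decorative preamble rows, so the header row is
# found by content, not by index; any unrecognized columns are carried along
# verbatim as metadata.

.SHEET_HEADERS <- list(
  species = c(module = "module", id = "id", name = "name", yinit = "yinit",
              ymax = "ymax", tau = "tau"),
  reactions = c(module = "module", id = "id", rule = "rule",
                weight = "weight", n = "n", ec50 = "ec50"))

.findSheet <- function(path, wanted) {
  sheets <- readxl::excel_sheets(path)
  hit <- sheets[tolower(sheets) == wanted]
  if (!length(hit))
    stop("workbook ", basename(path), " has no '", wanted, "' sheet")
  hit[1L]
}

.readSheet <- function(path, wanted, anchorCol) {
  sheet <- .findSheet(path, wanted)
  cells <- suppressMessages(readxl::read_excel(
    path, sheet = sheet, col_names = FALSE, col_types = "text"))
  cells <- as.data.frame(cells, stringsAsFactors = FALSE)
  lowered <- apply(cells, 1:2, function(x) tolower(trimws(ifelse(is.na(x), "", x))))
  headerRow <- which(apply(lowered, 1L, function(r)
    "id" %in% r && anchorCol %in% r))
  if (!length(headerRow))
    stop("sheet '", sheet, "': no header row containing both 'ID' and '",
         anchorCol, "' found")
  headerRow <- headerRow[1L]
  headers <- trimws(ifelse(is.na(unlist(cells[headerRow, ])), "",
                           unlist(cells[headerRow, ])))
  keep <- nzchar(headers)
  body <- cells[-seq_len(headerRow), keep, drop = FALSE]
  names(body) <- headers[keep]
  # drop fully blank trailing rows; blank cells read back as empty strings
  blank <- apply(body, 1L, function(r) all(is.na(r) | !nzchar(trimws(r))))
  body <- body[!blank, , drop = FALSE]
  body[] <- lapply(body, function(col) ifelse(is.na(col), "", col))
  rownames(body) <- NULL
  attr(body, "headerRow") <- headerRow
  attr(body, "sheetName") <- sheet
  body
}

.canonNames <- function(df, mapping) {
  nm <- names(df)
  canon <- mapping[tolower(nm)]
  names(df) <- ifelse(is.na(canon), nm, canon)
  df
}

#' Read a network model workbook
#'
#' Reads the two-sheet model workbook (`species` and `reactions` sheets,
#' case-insensitive names). The header row of each sheet is located by
#' scanning for a row containing `ID` (plus `Yinit` for species, `Rule` for
#' reactions), so decorative rows above the header are tolerated. Blank
#' parameter cells get the defaults (`tau = 1`, `ymax = 1`, `yinit = 0`,
#' `w = 1`, `n = 1.4`, `ec50 = 0.5`); a single leading apostrophe on rule
#' cells (the Excel text-marker convention) is stripped; unrecognized
#' columns are preserved as metadata. The assembled model is validated and
#' all errors reported together with sheet/row coordinates.
#'
#' @param path path to an `.xlsx` workbook.
#' @param validate if `TRUE` (default) stop on validation errors.
#' @return a [NetworkModel-class].
#' @export
readModelWorkbook <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("workbook not found: ", path)
  sp <- .readSheet(path, "species", "yinit")
  rx <- .readSheet(path, "reactions", "rule")
  spOff <- attr(sp, "headerRow")
  rxOff <- attr(rx, "headerRow")
  sp <- .canonNames(sp, .SHEET_HEADERS$species)
  rx <- .canonNames(rx, .SHEET_HEADERS$reactions)
  if (is.null(sp$id))
    stop("species sheet: required column 'ID' not found")
  if (is.null(rx$id) || is.null(rx$rule))
    stop("reactions sheet: required columns 'ID' and 'Rule' not found")
  sp$id <- trimws(sp$id)
  rx$id <- trimws(rx$id)
  model <- tryCatch(
    networkModel(species = sp, reactions = rx),
    error = function(e) stop("reactions sheet (data rows start at row ",
                             rxOff + 1L, "): ", conditionMessage(e),
                             call. = FALSE))
  if (validate) {
    issues <- validateModel(model)
    locRow <- function(loc) {
      kind <- sub(":.*", "", loc)
      id <- sub("^[^:]*:", "", loc)
      if (kind == "species")
        paste0("species!row", spOff + match(id, model@species$id))
      else paste0("reactions!row", rxOff + match(id, model@reactions$id))
    }
    if (nrow(issues)) {
      msgs <- paste0(vapply(issues$location, locRow, character(1L)), " (",
                     issues$location, "): ", issues$message)
      errs <- issues$severity == "error"
      if (any(!errs))
        warning("workbook ", basename(path), ":\n  ",
                paste(msgs[!errs], collapse = "\n  "))
      if (any(errs))
        stop("workbook ", basename(path), " failed validation:\n  ",
             paste(msgs[errs], collapse = "\n  "))
    }
  }
  model
}

## --- minimal OOXML (xlsx) writer -------------------------------------------
## Emits the small subset of SpreadsheetML needed for the two-sheet model
## dialect: one workbook, inline strings, plain numeric cells, no styles.

.xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

.colLetter <- function(i) {
  out <- ""
  while (i > 0L) {
    out <- paste0(LETTERS[(i - 1L) %% 26L + 1L], out)
    i <- (i - 1L) %/% 26L
  }
  out
}

.sheetXML <- function(df) {
  header <- names(df)
  rows <- character(nrow(df) + 1L)
  cellXML <- function(ref, value) {
    if (is.na(value)) return("")
    if (is.numeric(value))
      return(sprintf('<c r="%s"><v>%.17g</v></c>', ref, value))
    v <- as.character(value)
    if (!nzchar(v)) return("")
    sprintf('<c r="%s" t="inlineStr"><is><t xml:space="preserve">%s</t></is></c>',
            ref, .xmlEscape(v))
  }
  rowXML <- function(r, values) {
    cells <- vapply(seq_along(values), function(j)
      cellXML(paste0(.colLetter(j), r), values[[j]]), character(1L))
    sprintf('<row r="%d">%s</row>', r, paste(cells, collapse = ""))
  }
  rows[1L] <- rowXML(1L, as.list(header))
  for (i in seq_len(nrow(df)))
    rows[i + 1L] <- rowXML(i + 1L, as.list(df[i, ]))
  paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
         '<worksheet xmlns="http://schemas.openxmlformats.org/',
         'spreadsheetml/2006/main"><sheetData>',
         paste(rows, collapse = ""), '</sheetData></worksheet>')
}

.writeXlsx <- function(sheets, path) {
  stage <- tempfile("xlsx")
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)
  dir.create(file.path(stage, "_rels"), recursive = TRUE)
  dir.create(file.path(stage, "xl", "_rels"), recursive = TRUE)
  dir.create(file.path(stage, "xl", "worksheets"), recursive = TRUE)
  ns <- length(sheets)
  put <- function(rel, text) writeLines(text, file.path(stage, rel),
                                        useBytes = TRUE)
  put("[Content_Types].xml", paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    paste(sprintf('<Override PartName="/xl/worksheets/sheet%d.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
                  seq_len(ns)), collapse = ""),
    '</Types>'))
  put("_rels/.rels", paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    '</Relationships>'))
  put("xl/workbook.xml", paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    '<sheets>',
    paste(sprintf('<sheet name="%s" sheetId="%d" r:id="rId%d"/>',
                  .xmlEscape(names(sheets)), seq_len(ns), seq_len(ns)),
          collapse = ""),
    '</sheets></workbook>'))
  put("xl/_rels/workbook.xml.rels", paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    paste(sprintf('<Relationship Id="rId%d" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet%d.xml"/>',
                  seq_len(ns), seq_len(ns)), collapse = ""),
    '</Relationships>'))
  for (i in seq_len(ns))
    put(sprintf("xl/worksheets/sheet%d.xml", i), .sheetXML(sheets[[i]]))
  files <- c("[Content_Types].xml", "_rels/.rels", "xl/workbook.xml",
             "xl/_rels/workbook.xml.rels",
             sprintf("xl/worksheets/sheet%d.xml", seq_len(ns)))
  if (file.exists(path)) unlink(path)
  zip::zip(normalizePath(path, mustWork = FALSE), files = files, root = stage,
           mode = "mirror")
  invisible(path)
}

#' Write a network model workbook
#'
#' Emits the two-sheet layout read by [readModelWorkbook()]: sheet
#' `species` with columns module, ID, name, Yinit, Ymax, tau and sheet
#' `reactions` with module, ID, Rule, Weight, n, EC50 — followed by any
#' metadata columns, which round-trip verbatim. Rule cells starting with
#' `=` are prefixed with a single apostrophe so spreadsheet software does
#' not read them as formulas.
#'
#' @param model a [NetworkModel-class].
#' @param path output `.xlsx` path.
#' @return invisibly, `path`.
#' @export
writeModelWorkbook <- function(model, path) {
  sp <- model@species
  rx <- model@reactions
  rules <- vapply(seq_len(nrow(rx)), function(i)
    renderRule(rx$terms[[i]], rx$target[i]), character(1L))
  rules <- ifelse(startsWith(rules, "="), paste0("'", rules), rules)
  spOut <- data.frame(module = sp$module, ID = sp$id, name = sp$name,
                      Yinit = sp$yinit, Ymax = sp$ymax, tau = sp$tau,
                      stringsAsFactors = FALSE, check.names = FALSE)
  rxOut <- data.frame(module = rx$module, ID = rx$id, Rule = rules,
                      Weight = rx$weight, n = rx$n, EC50 = rx$ec50,
                      stringsAsFactors = FALSE, check.names = FALSE)
  spMeta <- setdiff(names(sp), .SPECIES_COLS)
  rxMeta <- setdiff(names(rx), c(.REACTION_COLS, "terms", "target"))
  for (m in spMeta) spOut[[m]] <- sp[[m]]
  for (m in rxMeta) rxOut[[m]] <- rx[[m]]
  .writeXlsx(list(species = spOut, reactions = rxOut), path)
  invisible(path)
}
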