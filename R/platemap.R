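PLATE_ROWS <- LETTERS[1:16] # up to 384-well format
PLATE_MAX_COL <- 24L

SAMPLE_TYPES <- c("compound", "vehicle_control", "blank")

# canonical column order of the wells table
PLATEMAP_COLS <- c("row", "col", "samptype", "compound", "conc", "units",
                   "growthcondition", "celltype", "passage", "seedingdensity")

#' Construct a plate map
#'
#' A plate map annotates each well of a microplate with its contents: the
#' compound (name, concentration and units), the growth condition, and the
#' cell type (name, passage, seeding density). Wells are addressed by a
#' letter row (A-P) and a 1-based column (1-24), supporting plate formats up
#' to 384 wells.
#'
#' Sample types are `"compound"` (a treated well; requires a non-empty
#' compound name and a positive concentration), `"vehicle_control"`
#' (solvent-only well; concentration must be zero) and `"blank"` (empty or
#' unused well).
#'
#' @param wells data frame with columns `row`, `col`, `samptype`,
#'   `compound`, `conc`, `units`, `growthcondition`, `celltype`, `passage`,
#'   `seedingdensity`. Missing annotation columns are filled with empty
#'   strings / zeros.
#' @param plate_id character scalar identifying the plate.
#' @return A `platemap` object.
#' @export
platemap <- function(wells, plate_id = "plate") {
  wells <- tibble::as_tibble(wells)
  if (nrow(wells) == 0) stop("no wells: a plate map must contain at least one well", call. = FALSE)
  for (col in setdiff(PLATEMAP_COLS, names(wells))) {
    wells[[col]] <- switch(col,
      conc = 0, seedingdensity = 0,
      samptype = "blank",
      "")
  }
  wells <- wells[PLATEMAP_COLS]
  wells$row <- toupper(as.character(wells$row))
  wells$col <- as.integer(wells$col)
  for (ch in c("samptype", "compound", "units", "growthcondition", "celltype", "passage")) {
    wells[[ch]] <- as.character(wells[[ch]])
    wells[[ch]][is.na(wells[[ch]])] <- ""
  }
  wells$conc <- as.numeric(wells$conc)
  wells$conc[is.na(wells$conc) & wells$samptype != "compound"] <- 0
  wells$seedingdensity <- as.numeric(wells$seedingdensity)
  wells$seedingdensity[is.na(wells$seedingdensity)] <- 0
  validate_platemap_wells(wells)
  wells <- dplyr::arrange(wells, .data$row, .data$col)
  structure(list(plate_id = as.character(plate_id), wells = wells),
            class = "platemap")
}

validate_platemap_wells <- function(wells) {
  bad_row <- !wells$row %in% PLATE_ROWS
  if (any(bad_row)) {
    stop(sprintf("invalid well row(s): %s (must be A-%s)",
                 paste(unique(wells$row[bad_row]), collapse = ", "),
                 PLATE_ROWS[length(PLATE_ROWS)]), call. = FALSE)
  }
  bad_col <- is.na(wells$col) | wells$col < 1L | wells$col > PLATE_MAX_COL
  if (any(bad_col)) {
    stop(sprintf("invalid well column(s): %s (must be 1-%d)",
                 paste(unique(wells$col[bad_col]), collapse = ", "), PLATE_MAX_COL),
         call. = FALSE)
  }
  addr <- paste0(wells$row, wells$col)
  if (anyDuplicated(addr)) {
    stop(sprintf("duplicate well address(es): %s",
                 paste(unique(addr[duplicated(addr)]), collapse = ", ")), call. = FALSE)
  }
  bad_type <- !wells$samptype %in% SAMPLE_TYPES
  if (any(bad_type)) {
    stop(sprintf("unknown sample type(s): %s (must be one of %s)",
                 paste(unique(wells$samptype[bad_type]), collapse = ", "),
                 paste(SAMPLE_TYPES, collapse = ", ")), call. = FALSE)
  }
  cmp <- wells$samptype == "compound"
  if (any(cmp & (wells$compound == "" | is.na(wells$conc) | wells$conc <= 0))) {
    bad <- addr[cmp & (wells$compound == "" | is.na(wells$conc) | wells$conc <= 0)]
    stop(sprintf("compound wells must have a non-empty compound name and positive concentration: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  veh <- wells$samptype == "vehicle_control"
  if (any(veh & wells$conc != 0)) {
    stop(sprintf("vehicle-control wells must have zero concentration: %s",
                 paste(addr[veh & wells$conc != 0], collapse = ", ")), call. = FALSE)
  }
  if (any(wells$conc < 0, na.rm = TRUE)) stop("concentrations must be nonnegative", call. = FALSE)
  if (any(wells$seedingdensity < 0, na.rm = TRUE)) stop("seeding densities must be nonnegative", call. = FALSE)
  invisible(wells)
}

#' @export
print.platemap <- function(x, ...) {
  n <- table(factor(x$wells$samptype, levels = SAMPLE_TYPES))
  cat(sprintf("<platemap '%s'>: %d wells (%d compound, %d vehicle control, %d blank)\n",
              x$plate_id, nrow(x$wells), n[["compound"]], n[["vehicle_control"]], n[["blank"]]))
  cmpds <- sort(unique(x$wells$compound[x$wells$samptype == "compound"]))
  if (length(cmpds)) cat("  compounds:", paste(cmpds, collapse = ", "), "\n")
  invisible(x)
}

well_label <- function(row, col) paste0(row, col)

xattr <- function(node, name, default = "") {
  a <- xml2::xml_attr(node, name)
  if (is.na(a)) default else a
}

platemap_wells <- function(pm) well_label(pm$wells$row, pm$wells$col)

#' Import a plate map from XML
#'
#' Reads the package's plate-map XML dialect: a `<platemap id="...">` root
#' holding one `<well row="B" col="2">` element per well, with optional
#' children `<compound name conc units/>`, `<growthcondition name/>` and
#' `<celltype name passage seeding/>`. Vehicle-control wells carry the
#' attribute `control="true"`; wells with neither a compound element nor a
#' control flag are blanks.
#'
#' @param path path to the XML file.
#' @return A [platemap] object.
#' @seealso [export_platemap_xml()] for the writer, [import_platemap_table()]
#'   for the tab-delimited reader.
#' @export
import_platemap_xml <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  doc <- xml2::read_xml(path) # xml2 reports the line of any parse error
  if (xml2::xml_name(doc) != "platemap") {
    stop("not a plate-map file: root element must be <platemap>", call. = FALSE)
  }
  plate_id <- xml2::xml_attr(doc, "id")
  if (is.na(plate_id)) plate_id <- "plate"
  well_nodes <- xml2::xml_find_all(doc, "./well")
  if (length(well_nodes) == 0) stop("no wells: plate map contains no <well> elements", call. = FALSE)
  rows <- lapply(well_nodes, function(node) {
    ctrl <- identical(tolower(xml2::xml_attr(node, "control")), "true")
    cmpd <- xml2::xml_find_first(node, "./compound")
    gc <- xml2::xml_find_first(node, "./growthcondition")
    ct <- xml2::xml_find_first(node, "./celltype")
    has_cmpd <- !inherits(cmpd, "xml_missing")
    conc <- if (has_cmpd) parse_num(xattr(cmpd, "conc", "0"), "concentration") else 0
    units <- if (has_cmpd) xattr(cmpd, "units") else ""
    if (has_cmpd && nzchar(units) && !grepl("^[numpk]?M$|^ug/ml$|^mg/ml$|^ng/ml$|^%$", units)) {
      warning(sprintf("unrecognised concentration units '%s' kept verbatim", units), call. = FALSE)
    }
    tibble::tibble(
      row = xml2::xml_attr(node, "row"),
      col = suppressWarnings(as.integer(xml2::xml_attr(node, "col"))),
      samptype = if (has_cmpd && !ctrl) "compound" else if (ctrl) "vehicle_control" else "blank",
      compound = if (has_cmpd) xattr(cmpd, "name") else "",
      conc = conc,
      units = units,
      growthcondition = if (!inherits(gc, "xml_missing")) xattr(gc, "name") else "",
      celltype = if (!inherits(ct, "xml_missing")) xattr(ct, "name") else "",
      passage = if (!inherits(ct, "xml_missing")) xattr(ct, "passage") else "",
      seedingdensity = if (!inherits(ct, "xml_missing"))
        parse_num(xattr(ct, "seeding", "0"), "seeding density") else 0
    )
  })
  platemap(dplyr::bind_rows(rows), plate_id = plate_id)
}

#' Write a plate map as XML
#'
#' Inverse of [import_platemap_xml()]: re-importing the written file yields
#' a plate map identical to the input.
#'
#' @param pm a [platemap] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_platemap_xml <- function(pm, path) {
  stopifnot(inherits(pm, "platemap"))
  doc <- xml2::xml_new_root("platemap", id = pm$plate_id)
  for (i in seq_len(nrow(pm$wells))) {
    w <- pm$wells[i, ]
    node <- xml2::xml_add_child(doc, "well", row = w$row, col = as.character(w$col))
    if (w$samptype == "vehicle_control") xml2::xml_set_attr(node, "control", "true")
    if (w$samptype == "compound" || nzchar(w$compound)) {
      xml2::xml_add_child(node, "compound", name = w$compound,
                          conc = fmt_num_rt(w$conc), units = w$units)
    }
    if (nzchar(w$growthcondition)) {
      xml2::xml_add_child(node, "growthcondition", name = w$growthcondition)
    }
    if (nzchar(w$celltype) || nzchar(w$passage) || w$seedingdensity > 0) {
      xml2::xml_add_child(node, "celltype", name = w$celltype, passage = w$passage,
                          seeding = fmt_num_rt(w$seedingdensity))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

PLATEMAP_TABLE_HEADER <- c("row", "col", "sampleid", "conc", "units",
                           "growthcondition", "celltype", "passage",
                           "seedingdensity", "samptype")

#' Import a plate map from a tab-delimited table
#'
#' The table carries one row per well with header columns `row`, `col`,
#' `sampleid`, `conc`, `units`, `growthcondition`, `celltype`, `passage`,
#' `seedingdensity`, `samptype`. `samptype` is `compound`, `vehicle_control`
#' or `blank` (shorthand `S`, `C`, `B` accepted).
#'
#' @param path path to the tab-delimited file.
#' @param plate_id plate identifier to attach (the table format carries none).
#' @return A [platemap] object.
#' @export
import_platemap_table <- function(path, plate_id = "plate") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- read_clean_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty plate-map table", call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  missing <- setdiff(PLATEMAP_TABLE_HEADER, tolower(header))
  if (length(missing)) {
    stop(sprintf("plate-map table is missing required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (length(lines) < 2) stop("no wells: plate-map table has a header but no data rows", call. = FALSE)
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  ncol_hdr <- length(header)
  fields <- lapply(body, function(x) { length(x) <- ncol_hdr; x })
  tab <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(tab) <- tolower(header)
  samptype <- c(S = "compound", C = "vehicle_control", B = "blank")[toupper(tab$samptype)]
  samptype[is.na(samptype)] <- tab$samptype[is.na(samptype)]
  wells <- tibble::tibble(
    row = tab$row,
    col = suppressWarnings(as.integer(tab$col)),
    samptype = samptype,
    compound = ifelse(is.na(tab$sampleid), "", tab$sampleid),
    conc = parse_num(tab$conc, "concentration", row = seq_along(tab$conc) + 1L),
    units = ifelse(is.na(tab$units), "", tab$units),
    growthcondition = ifelse(is.na(tab$growthcondition), "", tab$growthcondition),
    celltype = ifelse(is.na(tab$celltype), "", tab$celltype),
    passage = ifelse(is.na(tab$passage), "", tab$passage),
    seedingdensity = parse_num(ifelse(is.na(tab$seedingdensity) | tab$seedingdensity == "",
                                      "0", tab$seedingdensity), "seeding density")
  )
  platemap(wells, plate_id = plate_id)
}

#' Write a plate map as a tab-delimited table
#'
#' Inverse of [import_platemap_table()].
#'
#' @inheritParams export_platemap_xml
#' @return `path`, invisibly.
#' @export
export_platemap_table <- function(pm, path) {
  stopifnot(inherits(pm, "platemap"))
  w <- pm$wells
  out <- data.frame(
    row = w$row, col = w$col, sampleid = w$compound,
    conc = fmt_num_rt(w$conc), units = w$units,
    growthcondition = w$growthcondition, celltype = w$celltype,
    passage = w$passage, seedingdensity = fmt_num_rt(w$seedingdensity),
    samptype = w$samptype, stringsAsFactors = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(names(out), collapse = "\t"),
               apply(out, 1L, paste, collapse = "\t")), con)
  invisible(path)
}
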