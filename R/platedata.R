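#' Construct a kinetic plate-data object
#'
#' Holds a long-format table of a single growth metric (typically percent
#' confluence) per well per elapsed time. The export is rectangular: every
#' well shares the identical set of timepoints.
#'
#' @param records data frame with columns `row`, `col`, `elapsed_h`,
#'   `value`.
#' @param plate_id plate identifier.
#' @param metric name of the growth metric (e.g. `"percent confluence"`).
#' @return A `platedata` object.
#' @export
platedata <- function(records, plate_id = "plate", metric = "percent confluence") {
  records <- tibble::as_tibble(records)
  need <- c("row", "col", "elapsed_h", "value")
  missing <- setdiff(need, names(records))
  if (length(missing)) stop(sprintf("plate data is missing column(s): %s",
                                    paste(missing, collapse = ", ")), call. = FALSE)
  records$row <- toupper(as.character(records$row))
  records$col <- as.integer(records$col)
  records$elapsed_h <- as.numeric(records$elapsed_h)
  records$value <- as.numeric(records$value)
  if (nrow(records) == 0) stop("plate data contains no records", call. = FALSE)
  if (any(is.na(records$value))) stop("plate data contains missing values (imputation is not supported)", call. = FALSE)
  if (any(is.na(records$elapsed_h) | records$elapsed_h < 0)) {
    stop("elapsed times must be nonnegative numbers", call. = FALSE)
  }
  records$well <- well_label(records$row, records$col)
  if (anyDuplicated(records[c("well", "elapsed_h")])) {
    stop("duplicate (well, elapsed time) records", call. = FALSE)
  }
  # rectangular check: identical timepoint sets across wells
  tp <- split(records$elapsed_h, records$well)
  ref <- sort(tp[[1]])
  same <- vapply(tp, function(x) length(x) == length(ref) && all(sort(x) == ref), logical(1))
  if (!all(same)) {
    stop(sprintf("plate data is not rectangular: well(s) %s have a different timepoint set",
                 paste(names(tp)[!same], collapse = ", ")), call. = FALSE)
  }
  records <- dplyr::arrange(records, .data$row, .data$col, .data$elapsed_h)
  records <- records[c("row", "col", "well", "elapsed_h", "value")]
  structure(list(plate_id = as.character(plate_id), metric = as.character(metric),
                 records = records),
            class = "platedata")
}

#' @export
print.platedata <- function(x, ...) {
  cat(sprintf("<platedata '%s'>: %d wells x %d timepoints of '%s' (%.1f-%.1f h)\n",
              x$plate_id, length(unique(x$records$well)),
              length(unique(x$records$elapsed_h)), x$metric,
              min(x$records$elapsed_h), max(x$records$elapsed_h)))
  invisible(x)
}

platedata_wells <- function(pd) unique(pd$records$well)

parse_well_label <- function(labels) {
  m <- regmatches(labels, regexec("^([A-Pa-p])([0-9]{1,2})$", labels))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    stop(sprintf("unparseable well label(s): %s (expected e.g. 'B2')",
                 paste(unique(labels[bad]), collapse = ", ")), call. = FALSE)
  }
  tibble::tibble(row = toupper(vapply(m, `[`, character(1), 2L)),
                 col = as.integer(vapply(m, `[`, character(1), 3L)))
}

#' Import a kinetic plate-data export
#'
#' Reads a tab-delimited kinetic export: optional leading metadata lines
#' prefixed `#`, then a header row containing an `Elapsed` column followed
#' by one column per well label (e.g. `B2`), then one numeric row per
#' timepoint. Columns before `Elapsed` (such as a date-time column) are
#' ignored; elapsed hours are the single time authority. Files with
#' Windows line endings and/or a UTF-8 byte-order mark are accepted.
#'
#' @param path path to the export file.
#' @param metric name of the growth metric the file contains; carried
#'   through to downstream outputs.
#' @param plate_id plate identifier; defaults to a `#plate_id:` metadata
#'   line when present.
#' @return A [platedata] object.
#' @export
import_plate_data <- function(path, metric = "percent confluence", plate_id = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- read_clean_lines(path)
  meta <- grep("^#", lines, value = TRUE)
  if (is.null(plate_id)) {
    pid <- sub("^#\\s*plate_id:\\s*", "", grep("^#\\s*plate_id:", meta, value = TRUE))
    plate_id <- if (length(pid)) pid[1] else "plate"
  }
  lines <- lines[!grepl("^#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  hdr_idx <- which(vapply(lines, function(l)
    "Elapsed" %in% strsplit(l, "\t", fixed = TRUE)[[1]], logical(1)))[1]
  if (is.na(hdr_idx)) stop("no header row with an 'Elapsed' column found", call. = FALSE)
  header <- strsplit(lines[hdr_idx], "\t", fixed = TRUE)[[1]]
  el_col <- which(header == "Elapsed")[1]
  well_cols <- seq.int(el_col + 1L, length(header))
  if (el_col == length(header)) stop("no well columns after 'Elapsed'", call. = FALSE)
  addr <- parse_well_label(header[well_cols])
  body <- strsplit(lines[-seq_len(hdr_idx)], "\t", fixed = TRUE)
  if (length(body) == 0) stop("kinetic export contains no data rows", call. = FALSE)
  nf <- vapply(body, length, integer(1))
  if (any(nf != length(header))) {
    stop(sprintf("kinetic export is not rectangular: row(s) %s have %s fields, expected %d",
                 paste(which(nf != length(header)) + hdr_idx, collapse = ", "),
                 paste(unique(nf[nf != length(header)]), collapse = "/"), length(header)),
         call. = FALSE)
  }
  mat <- do.call(rbind, body)
  elapsed <- parse_num(mat[, el_col], "elapsed time")
  if (any(elapsed < 0)) stop("negative elapsed time in kinetic export", call. = FALSE)
  vals <- matrix(parse_num(mat[, well_cols, drop = FALSE], "growth value"),
                 nrow = nrow(mat))
  records <- tibble::tibble(
    row = rep(addr$row, each = nrow(mat)),
    col = rep(addr$col, each = nrow(mat)),
    elapsed_h = rep(elapsed, times = nrow(addr)),
    value = as.vector(vals))
  platedata(records, plate_id = plate_id, metric = metric)
}

#' Write a kinetic plate-data export
#'
#' Writes the tab-delimited kinetic format read by [import_plate_data()]:
#' `#plate_id:` and `#metric:` metadata lines, then `Elapsed` plus one
#' column per well, one row per timepoint.
#'
#' @param pd a [platedata] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_plate_data <- function(pd, path) {
  stopifnot(inherits(pd, "platedata"))
  rec <- dplyr::arrange(pd$records, .data$row, .data$col, .data$elapsed_h)
  wide <- tidyr::pivot_wider(rec[c("well", "elapsed_h", "value")],
                             names_from = "well", values_from = "value")
  wide <- dplyr::arrange(wide, .data$elapsed_h)
  hdr <- c("Elapsed", setdiff(names(wide), "elapsed_h"))
  rows <- apply(wide, 1L, function(r) paste(fmt_num_rt(as.numeric(r)), collapse = "\t"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(sprintf("#plate_id: %s", pd$plate_id),
               sprintf("#metric: %s", pd$metric),
               paste(hdr, collapse = "\t"),
               rows), con)
  invisible(path)
}
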