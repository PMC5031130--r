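#' Create a dose-response analysis set
#'
#' A `drcset` pairs a plate map with the matching kinetic data for wells
#' that share a single vehicle-control growth background: all wells must
#' carry one common (growth condition, cell type) pair so that one pooled
#' control growth curve is meaningful for every treated well. Growth
#' models, the cut time and dose-response results are attached to the set
#' as the analysis proceeds.
#'
#' Wells present in only one of the two inputs are dropped with a warning;
#' the set is restricted to the intersection.
#'
#' @param pm a [platemap].
#' @param pd a [platedata] with kinetic values for (a superset of) the
#'   mapped wells.
#' @param cut_time_h optional cut time in hours, if chosen manually by
#'   inspecting growth curves. May also be set later via [set_cut_time()]
#'   or computed with [calculate_cut_time()].
#' @param metadata optional named list of descriptors attached to the set.
#' @return A `drcset` object.
#' @seealso [split_drc_sets()] to partition a multi-condition plate into
#'   one set per condition.
#' @export
make_drc_set <- function(pm, pd, cut_time_h = NULL, metadata = NULL) {
  stopifnot(inherits(pm, "platemap"), inherits(pd, "platedata"))
  map_wells <- platemap_wells(pm)
  data_wells <- platedata_wells(pd)
  common <- intersect(map_wells, data_wells)
  if (length(common) == 0) {
    stop("plate map and plate data share no wells", call. = FALSE)
  }
  dropped <- c(setdiff(map_wells, common), setdiff(data_wells, common))
  if (length(dropped)) {
    warning(sprintf("dropping %d well(s) present in only one input: %s",
                    length(dropped), paste(sort(dropped), collapse = ", ")),
            call. = FALSE)
  }
  wells <- pm$wells[well_label(pm$wells$row, pm$wells$col) %in% common, ]
  used <- wells[wells$samptype != "blank", ]
  conds <- unique(used[c("growthcondition", "celltype")])
  if (nrow(conds) > 1) {
    stop(paste0("wells span ", nrow(conds), " (growth condition, cell type) pairs, ",
                "but a drcset requires one common control growth curve; ",
                "use split_drc_sets() to partition the plate"), call. = FALSE)
  }
  pm2 <- pm
  pm2$wells <- wells
  pd2 <- pd
  pd2$records <- pd$records[pd$records$well %in% common, ]
  if (!is.null(cut_time_h)) {
    stopifnot(is.numeric(cut_time_h), length(cut_time_h) == 1, cut_time_h >= 0)
  }
  meta <- as.list(metadata %||% list())
  if (nrow(conds) == 1 && is.null(meta$growth_condition)) {
    meta$growth_condition <- conds$growthcondition[1]
    meta$cell_type <- conds$celltype[1]
  }
  structure(list(platemap = pm2, platedata = pd2,
                 cut_time_h = cut_time_h, metadata = meta,
                 growth_grouped = NULL, growth_individual = NULL,
                 cut_time_result = NULL, drc_data = NULL, dr_models = NULL),
            class = "drcset")
}

#' Split a plate into dose-response sets by growth background
#'
#' Partitions the wells of a plate by their (growth condition, cell type)
#' pair and builds one [make_drc_set()] per pair, so that every set shares
#' a single common control growth curve. Vehicle-control wells are assigned
#' to the set of their own condition pair. Each set's metadata element is
#' populated with its growth condition and cell type. Blank wells are
#' carried with the condition pair they annotate, or dropped if
#' unannotated.
#'
#' @inheritParams make_drc_set
#' @return A list of `drcset` objects (length 1 for a single-condition
#'   plate).
#' @export
split_drc_sets <- function(pm, pd) {
  stopifnot(inherits(pm, "platemap"), inherits(pd, "platedata"))
  wells <- pm$wells
  key <- paste(wells$growthcondition, wells$celltype, sep = "\r")
  groups <- split(seq_len(nrow(wells)), key)
  out <- lapply(groups, function(idx) {
    pm_i <- pm
    pm_i$wells <- wells[idx, ]
    set <- suppressWarnings(make_drc_set(pm_i, pd))
    if (!any(set$platemap$wells$samptype == "vehicle_control")) {
      warning(sprintf(
        "condition ('%s', '%s') has no vehicle-control wells; cut-time computation will fail for this set",
        set$metadata$growth_condition %||% "", set$metadata$cell_type %||% ""),
        call. = FALSE)
    }
    set
  })
  unname(out)
}

#' Set or change the cut time of a dose-response set
#'
#' Attaching a new cut time invalidates any previously extracted
#' dose-response data and fitted models, which were computed for the old
#' cut time.
#'
#' @param drcset a `drcset`.
#' @param cut_time_h cut time in hours (nonnegative scalar).
#' @return The updated `drcset`.
#' @export
set_cut_time <- function(drcset, cut_time_h) {
  stopifnot(inherits(drcset, "drcset"),
            is.numeric(cut_time_h), length(cut_time_h) == 1, cut_time_h >= 0)
  drcset$cut_time_h <- as.numeric(cut_time_h)
  drcset$cut_time_result <- NULL
  drcset$drc_data <- NULL
  drcset$dr_models <- NULL
  drcset
}

#' @export
print.drcset <- function(x, ...) {
  w <- x$platemap$wells
  cat(sprintf("<drcset> %d wells on plate '%s'\n", nrow(w), x$platemap$plate_id))
  cat(sprintf("  condition: '%s' / cell type: '%s'\n",
              x$metadata$growth_condition %||% "", x$metadata$cell_type %||% ""))
  cmpds <- w[w$samptype == "compound", ]
  if (nrow(cmpds)) {
    rng <- dplyr::summarise(dplyr::group_by(cmpds, .data$compound),
                            lo = min(.data$conc), hi = max(.data$conc),
                            n = dplyr::n(), .groups = "drop")
    for (i in seq_len(nrow(rng))) {
      cat(sprintf("  compound %s: %d wells, %g-%g %s\n", rng$compound[i], rng$n[i],
                  rng$lo[i], rng$hi[i], cmpds$units[1]))
    }
  }
  cat(sprintf("  vehicle-control wells: %d\n", sum(w$samptype == "vehicle_control")))
  if (!is.null(x$cut_time_h)) cat(sprintf("  cut time: %.2f h\n", x$cut_time_h))
  fitted <- c(if (!is.null(x$growth_grouped)) "grouped growth",
              if (!is.null(x$growth_individual)) "individual growth",
              if (!is.null(x$drc_data)) "DRC data",
              if (!is.null(x$dr_models)) "dose-response models")
  if (length(fitted)) cat("  attached:", paste(fitted, collapse = ", "), "\n")
  invisible(x)
}
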