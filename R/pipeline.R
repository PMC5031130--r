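CONFIG_KEYS <- c("platemap", "platedata", "metric", "span",
                 "cut_time_h", "baseline_time_h", "no_doublings", "max_val",
                 "window_n", "grid_step_h", "layouts", "outdir", "seed",
                 "include_control", "plots", "verbose")

CUT_PARAM_KEYS <- c("baseline_time_h", "no_doublings", "max_val", "window_n", "grid_step_h")

#' Build a pipeline run configuration
#'
#' Validates and applies defaults to the settings of [run_pipeline()]. A
#' run must choose its cut time in exactly one way: either an explicit
#' `cut_time_h`, or the automatic cut-time parameters (`baseline_time_h`,
#' `no_doublings`, `max_val`, `window_n`, `grid_step_h`); supplying both
#' is an error. When neither is supplied, the automatic calculation with
#' default parameters is used.
#'
#' @param platemap path to a plate-map file (`.xml` for the XML dialect,
#'   anything else is read as the tab-delimited table).
#' @param platedata path to a kinetic export file.
#' @param metric growth-metric name (default `"percent confluence"`).
#' @param span LOESS span (default 0.5).
#' @param cut_time_h explicit cut time in hours, or `NULL` for automatic.
#' @param baseline_time_h,no_doublings,max_val,window_n,grid_step_h
#'   automatic cut-time parameters; see [cut_time_params()] for defaults.
#' @param layouts character vector of [export_drc_table()] layouts to
#'   write (default all three).
#' @param outdir output directory, created if needed.
#' @param include_control include zero-dose control rows in DRC exports.
#' @param plots also write growth-curve / diagnostic / dose-response
#'   figures (PNG). Off by default: figure files are not byte-stable
#'   across graphics library versions, text outputs are.
#' @param verbose print progress to stderr.
#' @return A `run_config` object.
#' @export
run_config <- function(platemap, platedata, metric = "percent confluence",
                       span = 0.5, cut_time_h = NULL,
                       baseline_time_h = NULL, no_doublings = NULL, max_val = NULL,
                       window_n = NULL, grid_step_h = NULL,
                       layouts = c("long", "prism", "dotmatics"),
                       outdir = ".", include_control = TRUE,
                       plots = FALSE, verbose = FALSE) {
  if (missing(platemap) || is.null(platemap)) stop("config error: 'platemap' path is required", call. = FALSE)
  if (missing(platedata) || is.null(platedata)) stop("config error: 'platedata' path is required", call. = FALSE)
  supplied_params <- c(baseline_time_h = !is.null(baseline_time_h),
                       no_doublings = !is.null(no_doublings),
                       max_val = !is.null(max_val),
                       window_n = !is.null(window_n),
                       grid_step_h = !is.null(grid_step_h))
  if (!is.null(cut_time_h) && any(supplied_params)) {
    stop(sprintf("config error: 'cut_time_h' conflicts with automatic cut-time key(s) %s; supply exactly one of the two",
                 paste(sQuote(names(supplied_params)[supplied_params]), collapse = ", ")),
         call. = FALSE)
  }
  layouts <- match.arg(layouts, c("long", "prism", "dotmatics"), several.ok = TRUE)
  params <- if (is.null(cut_time_h)) {
    cut_time_params(baseline_time_h = baseline_time_h %||% 0,
                    no_doublings = no_doublings %||% 2,
                    max_val = max_val %||% 80,
                    window_n = window_n %||% 30,
                    grid_step_h = grid_step_h)
  } else NULL
  structure(list(platemap = platemap, platedata = platedata, metric = metric,
                 span = span, cut_time_h = cut_time_h, cut_params = params,
                 layouts = layouts, outdir = outdir,
                 include_control = isTRUE(include_control),
                 plots = isTRUE(plots), verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Load a pipeline configuration from a key-value file
#'
#' The file is flat `key = value` text, one setting per line; `#` starts
#' a comment. Recognised keys match the arguments of [run_config()]
#' (`layouts` is a comma-separated list). Unknown keys produce a warning,
#' not an error. Values in `overrides` (e.g. from command-line flags)
#' take precedence over file values.
#'
#' @param path path to the config file.
#' @param overrides named list of settings overriding the file.
#' @return A `run_config` object.
#' @export
load_config <- function(path, overrides = list()) {
  if (!file.exists(path)) stop(sprintf("config error: file not found: %s", path), call. = FALSE)
  lines <- read_clean_lines(path)
  lines <- sub("#.*$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) < 2) {
      warning(sprintf("ignoring malformed config line: '%s'", trimws(ln)), call. = FALSE)
      next
    }
    key <- trimws(parts[1])
    val <- trimws(paste(parts[-1], collapse = "="))
    if (!key %in% CONFIG_KEYS) {
      warning(sprintf("unknown config key '%s' ignored", key), call. = FALSE)
      next
    }
    kv[[key]] <- val
  }
  for (k in names(overrides)) kv[[k]] <- overrides[[k]]
  num_keys <- c("span", "cut_time_h", "baseline_time_h", "no_doublings",
                "max_val", "window_n", "grid_step_h")
  for (k in intersect(names(kv), num_keys)) {
    if (is.character(kv[[k]])) kv[[k]] <- parse_num(kv[[k]], k)
  }
  for (k in intersect(names(kv), c("include_control", "plots", "verbose"))) {
    if (is.character(kv[[k]])) kv[[k]] <- tolower(kv[[k]]) %in% c("true", "yes", "1")
  }
  if (is.character(kv$layouts)) kv$layouts <- trimws(strsplit(kv$layouts, ",")[[1]])
  kv$seed <- NULL # only the simulate subcommand uses a seed
  do.call(run_config, kv)
}

pipeline_msg <- function(config, fmt, ...) {
  if (config$verbose) message(sprintf(fmt, ...))
}

#' Run the full dose-response pipeline
#'
#' Executes the five-step workflow on a plate: import plate map and
#' kinetic data, split into one analysis set per growth background, fit
#' grouped and individual growth curves, set the cut time (explicit or
#' automatic), extract growth values at the cut time, fit four-parameter
#' log-logistic models, and write the EC50 table plus the requested DRC
#' exports per set. A machine-readable JSON run log (parameters, package
#' version, per-set cut-time result and EC50 rows) is written alongside.
#' A failure in one set is logged and does not abort sibling sets.
#'
#' @param config a `run_config` from [run_config()] or [load_config()].
#' @return Invisibly, a list with `status` (0 if every set succeeded, 1
#'   otherwise), the per-set results, and the paths written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (p in c(config$platemap, config$platedata)) {
    if (!file.exists(p)) stop(sprintf("config error: input file not found: %s", p), call. = FALSE)
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  pipeline_msg(config, "importing plate map %s", config$platemap)
  pm <- if (grepl("\\.xml$", config$platemap, ignore.case = TRUE)) {
    import_platemap_xml(config$platemap)
  } else {
    import_platemap_table(config$platemap)
  }
  pipeline_msg(config, "importing kinetic data %s", config$platedata)
  pd <- import_plate_data(config$platedata, metric = config$metric)
  sets <- split_drc_sets(pm, pd)
  pipeline_msg(config, "%d analysis set(s)", length(sets))

  written <- character(0)
  results <- vector("list", length(sets))
  failed <- logical(length(sets))
  for (i in seq_along(sets)) {
    tag <- sprintf("set%02d", i)
    res <- tryCatch({
      s <- sets[[i]]
      s <- fit_growth_curves_grouped(s, span = config$span)
      s <- fit_growth_curves_individual(s, span = config$span)
      if (!is.null(config$cut_time_h)) {
        s <- set_cut_time(s, config$cut_time_h)
      } else {
        s <- calculate_cut_time(s, config$cut_params)
      }
      s <- calculate_drc_data(s, include_control = config$include_control)
      s <- fit_dose_response(s)
      ec50_tab <- export_ec50_table(s)
      f <- file.path(config$outdir, sprintf("%s_ec50.tsv", tag))
      write_export_table(ec50_tab, f)
      written <- c(written, f)
      for (layout in config$layouts) {
        f <- file.path(config$outdir, sprintf("%s_drc_%s.tsv", tag, layout))
        write_export_table(export_drc_table(s, layout), f)
        written <- c(written, f)
      }
      if (config$plots) {
        gf <- file.path(config$outdir, sprintf("%s_growth.png", tag))
        ggplot2::ggsave(gf, plot_growth_curves(s), width = 9, height = 6, dpi = 120)
        written <- c(written, gf)
        if (!is.null(s$cut_time_result)) {
          df <- file.path(config$outdir, sprintf("%s_cuttime.png", tag))
          ggplot2::ggsave(df, plot_cut_time_diagnostics(cut_time_diagnostics(s)),
                          width = 7, height = 6, dpi = 120)
          written <- c(written, df)
        }
      }
      list(set = s, ec50_table = ec50_tab, error = NULL)
    }, error = function(e) {
      warning(sprintf("analysis set %d failed: %s", i, conditionMessage(e)), call. = FALSE)
      list(set = NULL, ec50_table = NULL, error = conditionMessage(e))
    })
    failed[i] <- !is.null(res$error)
    results[[i]] <- res
  }

  log <- list(
    package_version = as.character(utils::packageVersion("celldrc")),
    config = list(platemap = config$platemap, platedata = config$platedata,
                  metric = config$metric, span = config$span,
                  cut_time_h = config$cut_time_h,
                  cut_params = if (!is.null(config$cut_params)) unclass(config$cut_params),
                  layouts = config$layouts),
    sets = lapply(seq_along(results), function(i) {
      r <- results[[i]]
      if (!is.null(r$error)) return(list(status = "failed", error = r$error))
      ctr <- r$set$cut_time_result
      list(status = "ok",
           metadata = r$set$metadata,
           cut_time_h = r$set$cut_time_h,
           cut_time_result = if (!is.null(ctr)) unclass(ctr)[setdiff(names(ctr), "params")],
           ec50 = r$ec50_table)
    }))
  logfile <- file.path(config$outdir, "run_log.json")
  jsonlite::write_json(log, logfile, auto_unbox = TRUE, digits = 10, null = "null", pretty = TRUE)
  written <- c(written, logfile)
  invisible(list(status = as.integer(any(failed)), results = results, written = written))
}
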