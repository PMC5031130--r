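#' Four-parameter log-logistic response function
#'
#' `f(x) = c + (d - c) / (1 + exp(b * (log(x) - log(e))))` — the LL.4
#' convention: `b` is the hill slope (positive for a response decreasing
#' with dose), `c` the lower asymptote, `d` the upper asymptote and `e`
#' the inflection dose. At `x = e` the response is exactly `(c + d) / 2`,
#' so `e` is the relative EC50.
#'
#' @param x dose (positive).
#' @param b,c,d,e model parameters.
#' @return Response value(s).
#' @export
ll4 <- function(x, b, c, d, e) {
  c + (d - c) / (1 + exp(b * (log(x) - log(e))))
}

#' Extract growth values at the cut time
#'
#' Reads the per-well growth value off each individual growth curve at
#' the set's cut time, producing the replicate-level dose-response table:
#' one row per well with its compound, concentration and growth value.
#' Vehicle-control wells are optionally included as zero-dose rows (they
#' are exported but excluded from the log-dose fit).
#'
#' @param drcset a `drcset` with individual growth curves fitted and a
#'   cut time set (manually, via [set_cut_time()], or computed by
#'   [calculate_cut_time()]).
#' @param include_control include vehicle-control wells as zero-dose rows.
#' @return The `drcset` with a `drc_data` tibble attached (columns
#'   `compound`, `conc`, `samptype`, `well`, `replicate`, `value`).
#' @export
calculate_drc_data <- function(drcset, include_control = TRUE) {
  stopifnot(inherits(drcset, "drcset"))
  if (is.null(drcset$cut_time_h)) {
    stop("cut time is not set; use set_cut_time() or calculate_cut_time() first", call. = FALSE)
  }
  if (is.null(drcset$growth_individual)) {
    stop("individual growth curves are not fitted; run fit_growth_curves_individual() first",
         call. = FALSE)
  }
  ind <- drcset$growth_individual
  if (!include_control) ind <- ind[ind$samptype != "vehicle_control", ]
  ct <- drcset$cut_time_h
  for (i in seq_len(nrow(ind))) {
    dom <- ind$model[[i]]$time_domain
    if (ct < dom[1] - 1e-9 || ct > dom[2] + 1e-9) {
      stop(sprintf("cut time %.2f h is outside the observed domain [%g, %g] h of well %s",
                   ct, dom[1], dom[2], ind$well[i]), call. = FALSE)
    }
  }
  out <- tibble::tibble(
    compound = ind$compound, conc = ind$conc, samptype = ind$samptype,
    well = ind$well,
    value = vapply(ind$model, function(m) predict_growth(m, ct), numeric(1)))
  out <- dplyr::arrange(out, .data$compound, .data$conc, .data$well)
  out <- dplyr::mutate(dplyr::group_by(out, .data$compound, .data$conc),
                       replicate = dplyr::row_number())
  out <- dplyr::ungroup(out)[c("compound", "conc", "samptype", "well", "replicate", "value")]
  drcset$drc_data <- out
  drcset
}

#' Aggregate dose-response data per (compound, concentration)
#'
#' @param drcset a `drcset` with DRC data extracted.
#' @return Tibble with one row per (compound, concentration): replicate
#'   count `n`, the replicate `values` (list column) and their
#'   `mean_value`.
#' @export
drc_records <- function(drcset) {
  stopifnot(inherits(drcset, "drcset"))
  if (is.null(drcset$drc_data)) stop("no DRC data; run calculate_drc_data() first", call. = FALSE)
  dplyr::summarise(
    dplyr::group_by(drcset$drc_data, .data$compound, .data$conc, .data$samptype),
    n = dplyr::n(), values = list(.data$value), mean_value = mean(.data$value),
    .groups = "drop")
}

# Multi-start 4PL least squares on replicate-level (dose, response) points.
# Self-started from the data (d = max, c = min, e = dose nearest the
# half-range crossing), hill-slope starts of both signs; best RSS wins,
# ties broken by the shallowest |log b|.
fit_ll4_points <- function(x, y, compound = "", b_starts = c(0.5, 1, 2, 4)) {
  stopifnot(length(x) == length(y), all(x > 0))
  dat <- data.frame(x = x, y = y)
  half <- (min(y) + max(y)) / 2
  e0 <- x[which.min(abs(y - half))]
  starts <- expand.grid(b = c(b_starts, -b_starts), e0 = unique(c(e0, exp(mean(log(range(x)))))))
  fits <- list()
  for (i in seq_len(nrow(starts))) {
    st <- list(b = starts$b[i], c = min(y), d = max(y), loge = log(starts$e0[i]))
    fit <- tryCatch(suppressWarnings(minpack.lm::nlsLM(
      y ~ c + (d - c) / (1 + exp(b * (log(x) - loge))),
      data = dat, start = st,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15, ptol = 1e-15))),
      error = function(e) NULL)
    if (!is.null(fit)) fits[[length(fits) + 1]] <- fit
  }
  if (length(fits) == 0) {
    return(structure(list(compound = compound, b = NA_real_, c = NA_real_,
                          d = NA_real_, e = NA_real_, ec50 = NA_real_,
                          converged = FALSE, rss = NA_real_, n_points = length(x),
                          inverted = NA, extrapolated = NA),
                     class = "dose_response_model"))
  }
  rss <- vapply(fits, function(f) sum(resid(f)^2), numeric(1))
  logb <- vapply(fits, function(f) abs(log(abs(coef(f)[["b"]]))), numeric(1))
  best <- fits[[order(rss, logb)[1]]]
  p <- coef(best)
  # (b, c, d) and (-b, d, c) describe the identical curve; canonicalise to
  # c <= d so b > 0 always means response decreasing with dose
  if (p[["c"]] > p[["d"]]) {
    tmp <- p[["c"]]; p[["c"]] <- p[["d"]]; p[["d"]] <- tmp
    p[["b"]] <- -p[["b"]]
  }
  e <- exp(p[["loge"]])
  structure(list(compound = compound, b = p[["b"]], c = p[["c"]], d = p[["d"]],
                 e = e, ec50 = e, converged = best$convInfo$isConv %||% TRUE,
                 rss = sum(resid(best)^2), n_points = length(x),
                 inverted = p[["c"]] > p[["d"]],
                 extrapolated = e < min(x) / 10 || e > max(x) * 10),
            class = "dose_response_model")
}

#' @export
print.dose_response_model <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat(sprintf("<dose_response_model '%s'> NOT converged (n = %d)\n", x$compound, x$n_points))
  } else {
    cat(sprintf("<dose_response_model '%s'> b = %.3g, c = %.3g, d = %.3g, e = EC50 = %.4g (n = %d, rss = %.3g)%s\n",
                x$compound, x$b, x$c, x$d, x$e, x$n_points, x$rss,
                if (isTRUE(x$extrapolated)) " [EC50 outside dose range]" else ""))
  }
  invisible(x)
}

#' Fit four-parameter log-logistic dose-response models
#'
#' Fits the [ll4] model per compound to the replicate-level (dose, growth
#' value) points extracted at the cut time, by multi-start nonlinear
#' least squares. Replicate points are fitted directly (not their means),
#' so concentrations with more replicates weigh proportionally. Zero-dose
#' control rows are excluded from the fit (the log dose is undefined).
#' Non-convergence is recorded on the model, not raised.
#'
#' @param drcset a `drcset` with DRC data extracted.
#' @return The `drcset` with a `dr_models` tibble attached (columns
#'   `compound`, `model`).
#' @export
fit_dose_response <- function(drcset) {
  stopifnot(inherits(drcset, "drcset"))
  if (is.null(drcset$drc_data)) stop("no DRC data; run calculate_drc_data() first", call. = FALSE)
  dat <- drcset$drc_data[drcset$drc_data$samptype == "compound", ]
  if (nrow(dat) == 0) stop("no compound wells to fit", call. = FALSE)
  cmpds <- sort(unique(dat$compound))
  models <- lapply(cmpds, function(cm) {
    sub <- dat[dat$compound == cm, ]
    if (length(unique(sub$conc)) < 4) {
      stop(sprintf("compound %s has %d distinct concentrations; at least 4 are required for a 4PL fit",
                   cm, length(unique(sub$conc))), call. = FALSE)
    }
    fit_ll4_points(sub$conc, sub$value, compound = cm)
  })
  drcset$dr_models <- tibble::tibble(compound = cmpds, model = models)
  drcset
}

#' Relative EC50 of a fitted dose-response model
#'
#' The relative EC50 is the dose of half-maximal effect between the
#' fitted asymptotes, which in the LL.4 parameterisation is the
#' inflection-dose parameter `e` itself.
#'
#' @param model a `dose_response_model`.
#' @return The EC50, in the dose units of the fitted data.
#' @export
calculate_ec50 <- function(model) {
  stopifnot(inherits(model, "dose_response_model"))
  if (!isTRUE(model$converged)) {
    stop(sprintf("dose-response model for compound '%s' did not converge; no EC50 available",
                 model$compound), call. = FALSE)
  }
  model$e
}

#' Export the dose-response table
#'
#' Renders the extracted cut-time growth values in one of three text
#' layouts:
#' \describe{
#'   \item{`long`}{tidy rows `compound`, `conc`, `samptype`, `replicate`,
#'     `value` — one row per well.}
#'   \item{`prism`}{wide: a single concentration column, then one value
#'     column per compound and replicate (named `<compound>_<replicate>`),
#'     ready for import into curve-fitting software that expects grouped
#'     replicate columns. Zero-dose control rows are omitted.}
#'   \item{`dotmatics`}{stacked per-compound blocks: identifier column
#'     `sampleid`, then `conc` and replicate value columns `value_1..k`.}
#' }
#'
#' @param drcset a `drcset` with DRC data extracted.
#' @param layout one of `"long"`, `"prism"`, `"dotmatics"`.
#' @return A data frame in the requested layout.
#' @export
export_drc_table <- function(drcset, layout = c("long", "prism", "dotmatics")) {
  stopifnot(inherits(drcset, "drcset"))
  if (is.null(drcset$drc_data)) stop("no DRC data; run calculate_drc_data() first", call. = FALSE)
  layout <- match.arg(layout)
  dat <- drcset$drc_data
  if (layout == "long") {
    return(as.data.frame(dat[c("compound", "conc", "samptype", "replicate", "value")]))
  }
  cmp <- dat[dat$samptype == "compound", ]
  if (layout == "prism") {
    cmp$col <- paste(cmp$compound, cmp$replicate, sep = "_")
    wide <- tidyr::pivot_wider(cmp[c("conc", "col", "value")],
                               names_from = "col", values_from = "value")
    return(as.data.frame(dplyr::arrange(wide, .data$conc)))
  }
  # dotmatics: stacked blocks, wide by replicate
  cmp$col <- paste0("value_", cmp$replicate)
  wide <- tidyr::pivot_wider(cmp[c("compound", "conc", "col", "value")],
                             names_from = "col", values_from = "value")
  wide <- dplyr::rename(wide, sampleid = "compound")
  as.data.frame(dplyr::arrange(wide, .data$sampleid, .data$conc))
}

#' Export the EC50 summary table
#'
#' One row per fitted compound: the four LL.4 parameters, the relative
#' EC50 (empty for unconverged fits), convergence flag, residual sum of
#' squares, number of fitted points, the cut time, and any metadata tags
#' of the set.
#'
#' @param drcset a `drcset` with dose-response models fitted.
#' @return A data frame.
#' @export
export_ec50_table <- function(drcset) {
  stopifnot(inherits(drcset, "drcset"))
  if (is.null(drcset$dr_models)) stop("no dose-response models; run fit_dose_response() first", call. = FALSE)
  rows <- lapply(drcset$dr_models$model, function(m) {
    data.frame(compound = m$compound, b = m$b, c = m$c, d = m$d, e = m$e,
               ec50 = if (isTRUE(m$converged)) m$e else NA_real_,
               converged = isTRUE(m$converged), rss = m$rss, n_points = m$n_points,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$cut_time_h <- drcset$cut_time_h %||% NA_real_
  meta <- drcset$metadata
  for (k in names(meta)) {
    if (is.atomic(meta[[k]]) && length(meta[[k]]) == 1) out[[k]] <- meta[[k]]
  }
  out
}

#' Write a data frame as a tab-delimited UTF-8 text file
#'
#' Shared writer for all table exports; numeric columns are formatted at
#' 6 significant digits so identical inputs always produce byte-identical
#' files.
#'
#' @param df a data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_export_table <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c(paste(names(out), collapse = "\t"),
             if (nrow(out)) apply(out, 1L, paste, collapse = "\t"))
  writeLines(lines, con)
  invisible(path)
}
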