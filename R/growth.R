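CONTROL_GROUP <- "vehicle_control"

# Local-regression smoother shared by grouped and individual fits.
# degree-2 LOESS with tricube weights; replicate ties are passed to the
# smoother as-is so pooling keeps per-replicate weighting. surface="direct"
# evaluates the local fit exactly (no interpolation grid), which is what
# makes the smoother reproduce affine data to machine precision.
fit_loess_curve <- function(times, values, span, key, grid_n = 200) {
  if (any(!is.finite(values))) {
    stop(sprintf("non-finite growth values in group '%s'", key), call. = FALSE)
  }
  n_t <- length(unique(times))
  if (n_t < 4) {
    stop(sprintf("group '%s' has %d distinct timepoints; at least 4 are required",
                 key, n_t), call. = FALSE)
  }
  # guard: the local window must hold enough points for a quadratic fit
  span_used <- max(span, min(1, 4 / n_t))
  df <- data.frame(elapsed_h = times, value = values)
  fit <- loess(value ~ elapsed_h, data = df, span = span_used, degree = 2,
               family = "gaussian", control = loess.control(surface = "direct"))
  dom <- range(times)
  grid <- seq(dom[1], dom[2], length.out = grid_n)
  structure(list(key = key, model = fit, span = span_used,
                 time_domain = dom,
                 fitted_grid = tibble::tibble(
                   elapsed_h = grid,
                   value = as.numeric(predict(fit, data.frame(elapsed_h = grid))))),
            class = "growth_model")
}

#' @export
print.growth_model <- function(x, ...) {
  cat(sprintf("<growth_model '%s'> span %.3g over %.1f-%.1f h\n",
              x$key, x$span, x$time_domain[1], x$time_domain[2]))
  invisible(x)
}

#' Predict growth values from a fitted growth curve
#'
#' Evaluates a fitted growth-curve model at the requested elapsed times.
#' Prediction is defined only on the model's observed time domain;
#' extrapolation is refused so that downstream cut-time logic can never
#' read a value the data cannot support.
#'
#' @param model a `growth_model` as stored by [fit_growth_curves_grouped()]
#'   or [fit_growth_curves_individual()].
#' @param times elapsed times in hours, all within the model's
#'   `time_domain` (boundaries included).
#' @return Numeric vector of predicted growth values.
#' @export
predict_growth <- function(model, times) {
  stopifnot(inherits(model, "growth_model"), is.numeric(times))
  eps <- 1e-9
  if (any(times < model$time_domain[1] - eps | times > model$time_domain[2] + eps)) {
    stop(sprintf("extrapolation: time(s) outside the fitted domain [%.3f, %.3f] h of group '%s'",
                 model$time_domain[1], model$time_domain[2], model$key), call. = FALSE)
  }
  times <- pmin(pmax(times, model$time_domain[1]), model$time_domain[2])
  as.numeric(predict(model$model, data.frame(elapsed_h = times)))
}

growth_groups <- function(drcset) {
  w <- drcset$platemap$wells
  w <- w[w$samptype != "blank", ]
  tibble::tibble(
    well = well_label(w$row, w$col),
    samptype = w$samptype,
    compound = ifelse(w$samptype == "vehicle_control", CONTROL_GROUP, w$compound),
    conc = ifelse(w$samptype == "vehicle_control", 0, w$conc))
}

#' Fit pooled growth curves per treatment group
#'
#' Fits one LOESS growth curve per (compound, concentration) group,
#' pooling the kinetic points of all replicate wells of that group; the
#' vehicle-control wells form their own pooled group, which later defines
#' the cut time. Pooled points are passed to the smoother without
#' pre-averaging, so groups with more replicates carry proportionally more
#' weight at each timepoint.
#'
#' @param drcset a `drcset`.
#' @param span LOESS span in (0, 1]: the fraction of points in each local
#'   window. The default 0.5 suits near-uniform kinetic sampling; smaller
#'   values track sharper curvature at the cost of noise.
#' @return The `drcset` with a `growth_grouped` model table attached
#'   (columns `compound`, `conc`, `samptype`, `model`).
#' @export
fit_growth_curves_grouped <- function(drcset, span = 0.5) {
  stopifnot(inherits(drcset, "drcset"), is.numeric(span), span > 0, span <= 1)
  grp <- growth_groups(drcset)
  rec <- dplyr::inner_join(drcset$platedata$records, grp, by = "well")
  groups <- dplyr::group_by(rec, .data$compound, .data$conc, .data$samptype)
  fits <- dplyr::reframe(groups, model = list(fit_loess_curve(
    .data$elapsed_h, .data$value, span = span,
    key = sprintf("%s @ %g", .data$compound[1], .data$conc[1]))))
  drcset$growth_grouped <- fits
  drcset
}

#' Fit an individual growth curve per well
#'
#' Fits one LOESS growth curve to every non-blank well; these per-well
#' curves supply the replicate-level growth values read off at the cut
#' time by [calculate_drc_data()].
#'
#' @inheritParams fit_growth_curves_grouped
#' @return The `drcset` with a `growth_individual` model table attached
#'   (columns `well`, `compound`, `conc`, `samptype`, `model`).
#' @export
fit_growth_curves_individual <- function(drcset, span = 0.5) {
  stopifnot(inherits(drcset, "drcset"), is.numeric(span), span > 0, span <= 1)
  grp <- growth_groups(drcset)
  rec <- dplyr::inner_join(drcset$platedata$records, grp, by = "well")
  groups <- dplyr::group_by(rec, .data$well, .data$compound, .data$conc, .data$samptype)
  fits <- dplyr::reframe(groups, model = list(fit_loess_curve(
    .data$elapsed_h, .data$value, span = span, key = .data$well[1])))
  drcset$growth_individual <- fits
  drcset
}

control_growth_model <- function(drcset) {
  if (is.null(drcset$growth_grouped)) {
    stop("grouped growth curves are not fitted; run fit_growth_curves_grouped() first",
         call. = FALSE)
  }
  ctrl <- drcset$growth_grouped[drcset$growth_grouped$samptype == "vehicle_control", ]
  if (nrow(ctrl) == 0) {
    stop("no vehicle-control wells in this set: a control growth curve is required",
         call. = FALSE)
  }
  ctrl$model[[1]]
}
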