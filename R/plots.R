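#' Plot the growth curves of a dose-response set
#'
#' One facet per compound, one fitted line per concentration (darker =
#' higher dose), with the raw well values as points and the cut time, if
#' set, as a dashed vertical line. The vehicle-control group appears as
#' its own facet.
#'
#' @param drcset a `drcset`; grouped growth curves are used when fitted,
#'   otherwise raw points only.
#' @return A ggplot object.
#' @export
plot_growth_curves <- function(drcset) {
  stopifnot(inherits(drcset, "drcset"))
  grp <- growth_groups(drcset)
  rec <- dplyr::inner_join(drcset$platedata$records, grp, by = "well")
  p <- ggplot2::ggplot(rec, ggplot2::aes(x = .data$elapsed_h, y = .data$value,
                                         group = .data$conc, colour = .data$conc)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.6) +
    ggplot2::facet_wrap(~compound) +
    ggplot2::scale_colour_continuous(trans = "sqrt") +
    ggplot2::labs(x = "elapsed time (h)", y = drcset$platedata$metric,
                  colour = "conc") +
    ggplot2::theme_bw()
  if (!is.null(drcset$growth_grouped)) {
    lines <- dplyr::bind_rows(lapply(seq_len(nrow(drcset$growth_grouped)), function(i) {
      g <- drcset$growth_grouped[i, ]
      dplyr::mutate(g$model[[1]]$fitted_grid, compound = g$compound, conc = g$conc)
    }))
    p <- p + ggplot2::geom_line(data = lines)
  }
  if (!is.null(drcset$cut_time_h)) {
    p <- p + ggplot2::geom_vline(xintercept = drcset$cut_time_h,
                                 linetype = "dashed", colour = "blue")
  }
  p
}

#' Plot cut-time diagnostics
#'
#' Two stacked panels sharing the time axis: the control growth curve
#' (top) and the moving-average second-difference profile (bottom).
#' User-set parameters (baseline time, maximum value) are drawn as black
#' dashed lines; computed quantities (cut time, truncation time, target
#' value) as blue dashed lines.
#'
#' @param diag a `cut_time_diagnostics` record from
#'   [cut_time_diagnostics()].
#' @return A ggplot object.
#' @export
plot_cut_time_diagnostics <- function(diag) {
  stopifnot(inherits(diag, "cut_time_diagnostics"))
  panels <- dplyr::bind_rows(
    dplyr::mutate(diag$control_curve, panel = "control growth value"),
    dplyr::mutate(diag$ma_profile, panel = "moving-average second difference"))
  panels$panel <- factor(panels$panel, levels = unique(panels$panel))
  m <- diag$markers
  hline <- tibble::tibble(
    panel = factor(rep("control growth value", 2), levels = levels(panels$panel)),
    y = c(m[["max_val"]], m[["target_value"]]),
    kind = c("user", "computed"))
  vline <- tibble::tibble(
    x = c(m[["baseline_time_h"]], m[["truncation_time_h"]], m[["cut_time_h"]]),
    kind = c("user", "computed", "computed"))
  ggplot2::ggplot(panels, ggplot2::aes(x = .data$elapsed_h, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(data = vline, ggplot2::aes(xintercept = .data$x, colour = .data$kind),
                        linetype = "dashed") +
    ggplot2::geom_hline(data = hline, ggplot2::aes(yintercept = .data$y, colour = .data$kind),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(user = "black", computed = "blue")) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "elapsed time (h)", y = NULL, colour = NULL) +
    ggplot2::theme_bw()
}

#' Plot a fitted dose-response curve
#'
#' Replicate growth values at the cut time against log10 dose, the fitted
#' four-parameter log-logistic curve over the observed dose span extended
#' by half a decade each side, and the EC50 as a red dashed vertical
#' line.
#'
#' @param drcset a `drcset` with dose-response models fitted.
#' @param compound compound to plot.
#' @return A ggplot object.
#' @export
plot_dose_response <- function(drcset, compound) {
  stopifnot(inherits(drcset, "drcset"))
  if (is.null(drcset$dr_models)) stop("no dose-response models; run fit_dose_response() first", call. = FALSE)
  i <- match(compound, drcset$dr_models$compound)
  if (is.na(i)) stop(sprintf("no model for compound '%s'", compound), call. = FALSE)
  m <- drcset$dr_models$model[[i]]
  dat <- drcset$drc_data[drcset$drc_data$compound == compound &
                           drcset$drc_data$samptype == "compound", ]
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$conc, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration", y = "growth value at cut time",
                  title = compound) +
    ggplot2::theme_bw()
  if (isTRUE(m$converged)) {
    grid <- 10^seq(log10(min(dat$conc)) - 0.5, log10(max(dat$conc)) + 0.5, length.out = 200)
    curve <- tibble::tibble(conc = grid, value = ll4(grid, m$b, m$c, m$d, m$e))
    p <- p + ggplot2::geom_line(data = curve) +
      ggplot2::geom_vline(xintercept = m$e, linetype = "dashed", colour = "red")
  }
  p
}
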