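#' Parameters for the automatic cut-time calculation
#'
#' Bundles the tunable parameters of the doubling-normalised cut-time
#' algorithm of [calculate_cut_time()].
#'
#' @param baseline_time_h elapsed time (hours) taken as the baseline from
#'   which doublings are counted; must lie within the control curve's time
#'   domain.
#' @param no_doublings number of doublings of the control growth value
#'   required between the baseline and the cut time (nonnegative real;
#'   fractional doublings are allowed).
#' @param max_val maximum allowable growth value, in the units of the
#'   growth metric (default 80, i.e. 80 percent confluence): the curve is
#'   truncated where it first exceeds this value, keeping the readout
#'   below the crowded regime.
#' @param window_n window length (in grid points) of the centered moving
#'   average applied to the second differences when locating the end of
#'   the exponential phase (default 30).
#' @param grid_step_h spacing (hours) of the uniform grid on which the
#'   control curve is differenced; `NULL` (default) uses the median
#'   sampling interval of the control data.
#' @return A `cut_time_params` object.
#' @export
cut_time_params <- function(baseline_time_h = 0, no_doublings = 2,
                            max_val = 80, window_n = 30, grid_step_h = NULL) {
  stopifnot(is.numeric(baseline_time_h), length(baseline_time_h) == 1, baseline_time_h >= 0,
            is.numeric(no_doublings), length(no_doublings) == 1, no_doublings >= 0,
            is.numeric(max_val), length(max_val) == 1, max_val > 0,
            is.numeric(window_n), length(window_n) == 1, window_n >= 1)
  if (!is.null(grid_step_h)) {
    stopifnot(is.numeric(grid_step_h), length(grid_step_h) == 1, grid_step_h > 0)
  }
  structure(list(baseline_time_h = baseline_time_h, no_doublings = no_doublings,
                 max_val = max_val, window_n = as.integer(window_n),
                 grid_step_h = grid_step_h),
            class = "cut_time_params")
}

default_grid_step <- function(drcset) {
  w <- drcset$platemap$wells
  ctrl_wells <- well_label(w$row, w$col)[w$samptype == "vehicle_control"]
  times <- sort(unique(drcset$platedata$records$elapsed_h[
    drcset$platedata$records$well %in% ctrl_wells]))
  if (length(times) < 2) stop("control data has fewer than 2 timepoints", call. = FALSE)
  median(diff(times))
}

prediction_grid <- function(model, grid_step_h) {
  grid <- seq(model$time_domain[1], model$time_domain[2], by = grid_step_h)
  # keep the data end on the grid so truncation can reach t_max
  if (tail(grid, 1) < model$time_domain[2] - 1e-9) {
    grid <- c(grid, model$time_domain[2])
  }
  grid
}

#' Second-difference profile of a growth curve
#'
#' Evaluates the fitted growth curve on a uniform grid and returns the
#' discrete second differences `y[i+1] - 2*y[i] + y[i-1]` at the interior
#' grid times. The second difference is a (scaled) curvature estimate:
#' zero for affine growth, positive while growth accelerates and negative
#' while it decelerates.
#'
#' @param model a `growth_model`.
#' @param grid_step_h grid spacing in hours.
#' @return Tibble with columns `elapsed_h`, `value` (the second
#'   difference).
#' @export
second_difference_profile <- function(model, grid_step_h) {
  stopifnot(inherits(model, "growth_model"),
            is.numeric(grid_step_h), length(grid_step_h) == 1, grid_step_h > 0)
  grid <- prediction_grid(model, grid_step_h)
  if (length(grid) < 3) {
    stop("grid too short for second differences; use a smaller grid_step_h", call. = FALSE)
  }
  y <- predict_growth(model, grid)
  d2 <- diff(y, differences = 2)
  tibble::tibble(elapsed_h = grid[2:(length(grid) - 1)], value = d2)
}

# centered moving average with windows truncated at the sequence ends
moving_average <- function(x, window_n) {
  n <- length(x)
  h_lo <- floor((window_n - 1) / 2)
  h_hi <- ceiling((window_n - 1) / 2)
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - h_lo):min(n, i + h_hi)])
  }, numeric(1))
}

#' Locate the end of the exponential growth phase
#'
#' Finds the grid time at which the centered `window_n`-point moving
#' average of the second differences of the control growth curve reaches
#' its minimum: the time at which growth is decelerating most rapidly,
#' taken as the end of the exponential phase.
#'
#' Two degenerate outcomes fall back to the end of the time domain with a
#' warning: a flat (all-equal) profile, where no deceleration exists, and
#' a minimum inside the first full window, which reflects initial
#' lag/settling rather than the approach to confluence. When the minimum
#' is attained at several grid times the earliest is returned.
#'
#' @inheritParams second_difference_profile
#' @param window_n moving-average window length in grid points.
#' @return End of the exponential phase, in hours.
#' @export
exponential_phase_end <- function(model, window_n = 30, grid_step_h) {
  stopifnot(is.numeric(window_n), length(window_n) == 1, window_n >= 1)
  window_n <- as.integer(window_n)
  prof <- second_difference_profile(model, grid_step_h)
  if (nrow(prof) < window_n) {
    stop(sprintf(
      "second-difference profile has %d points but the moving-average window is %d; use a smaller grid_step_h or window_n",
      nrow(prof), window_n), call. = FALSE)
  }
  ma <- moving_average(prof$value, window_n)
  t_max <- model$time_domain[2]
  if (diff(range(ma)) <= 1e-9 * max(1, max(abs(ma)))) {
    warning("no deceleration detected (flat second-difference profile); using end of time domain",
            call. = FALSE)
    return(t_max)
  }
  i_min <- which.min(ma) # earliest minimum by which.min convention
  if (i_min <= window_n) {
    warning("no deceleration detected (second-difference minimum at the start of the curve); using end of time domain",
            call. = FALSE)
    return(t_max)
  }
  prof$elapsed_h[i_min]
}

#' Calculate the doubling-normalised cut time
#'
#' Determines, from the pooled vehicle-control growth curve, the elapsed
#' time at which the culture has achieved a requested number of doublings
#' of its baseline growth value — the "cut time" at which dose-response
#' values are read off every curve. Normalising the cut time by doublings
#' makes EC50s comparable between fast- and slow-growing lines.
#'
#' The control curve is first truncated to its informative range: the
#' minimum of (i) the end of the exponential phase
#' ([exponential_phase_end()]), (ii) the first grid time at which the
#' curve exceeds `max_val`, and (iii) the end of the data. The target
#' value is `prediction(baseline) * 2^no_doublings`; the cut time is the
#' earliest time on the truncated curve reaching the target, refined by
#' bisection to 0.01 h. If the target is never reached on the truncated
#' curve the result is capped: the truncation time is returned together
#' with the number of doublings actually achieved.
#'
#' @param drcset a `drcset` with grouped growth curves fitted.
#' @param params a [cut_time_params] object.
#' @return The `drcset` with `cut_time_h` set and a `cut_time_result`
#'   attached (fields `cut_time_h`, `baseline_value`, `target_value`,
#'   `achieved_doublings`, `truncation_time_h`, `capped`). Any previously
#'   extracted DRC data or dose-response models are invalidated.
#' @export
calculate_cut_time <- function(drcset, params = cut_time_params()) {
  stopifnot(inherits(drcset, "drcset"), inherits(params, "cut_time_params"))
  model <- control_growth_model(drcset)
  step <- params$grid_step_h %||% default_grid_step(drcset)
  dom <- model$time_domain
  if (params$baseline_time_h < dom[1] - 1e-9 || params$baseline_time_h > dom[2] + 1e-9) {
    stop(sprintf("baseline_time_h = %g h is outside the control time domain [%g, %g] h",
                 params$baseline_time_h, dom[1], dom[2]), call. = FALSE)
  }
  baseline_value <- predict_growth(model, params$baseline_time_h)
  if (!is.finite(baseline_value) || baseline_value <= 0) {
    stop(sprintf("control growth value at baseline (%g) must be positive for doublings to be defined",
                 baseline_value), call. = FALSE)
  }
  if (params$max_val <= baseline_value) {
    stop(sprintf("max_val (%g) must exceed the control value at the baseline time (%g)",
                 params$max_val, baseline_value), call. = FALSE)
  }

  exp_end <- withCallingHandlers(
    exponential_phase_end(model, params$window_n, step),
    warning = function(w) invokeRestart("muffleWarning"))
  grid <- prediction_grid(model, step)
  y <- predict_growth(model, grid)
  over <- which(y > params$max_val)
  # refine the max_val crossing to 0.01 h: truncation happens where the
  # maximum allowable value is achieved, not at the next grid point
  max_cross <- if (length(over)) {
    j <- over[1]
    if (j == 1) grid[1] else {
      lo <- grid[j - 1]; hi <- grid[j]
      while (hi - lo > 0.01) {
        mid <- (lo + hi) / 2
        if (predict_growth(model, mid) > params$max_val) hi <- mid else lo <- mid
      }
      hi
    }
  } else Inf
  truncation_time <- min(exp_end, max_cross, dom[2])

  target_value <- baseline_value * 2^params$no_doublings
  if (params$no_doublings == 0) {
    res <- list(cut_time_h = params$baseline_time_h, baseline_value = baseline_value,
                target_value = target_value, achieved_doublings = 0,
                truncation_time_h = truncation_time, capped = FALSE, params = params)
  } else {
    keep <- grid >= params$baseline_time_h & grid <= truncation_time + 1e-9
    g <- grid[keep]
    yg <- y[keep]
    hit <- which(yg >= target_value)
    if (length(hit)) {
      i <- hit[1]
      if (i == 1) {
        cut <- g[1]
      } else {
        lo <- g[i - 1]; hi <- g[i]
        while (hi - lo > 0.01) { # bisect the bracketing grid interval
          mid <- (lo + hi) / 2
          if (predict_growth(model, mid) >= target_value) hi <- mid else lo <- mid
        }
        cut <- hi
      }
      res <- list(cut_time_h = cut, baseline_value = baseline_value,
                  target_value = target_value, achieved_doublings = params$no_doublings,
                  truncation_time_h = truncation_time, capped = FALSE, params = params)
    } else {
      y_trunc <- predict_growth(model, min(truncation_time, dom[2]))
      res <- list(cut_time_h = truncation_time, baseline_value = baseline_value,
                  target_value = target_value,
                  achieved_doublings = log2(y_trunc / baseline_value),
                  truncation_time_h = truncation_time, capped = TRUE, params = params)
    }
  }
  res <- structure(res, class = "cut_time_result")
  drcset <- set_cut_time(drcset, res$cut_time_h)
  drcset$cut_time_result <- res
  drcset
}

#' @export
print.cut_time_result <- function(x, ...) {
  cat(sprintf("<cut_time_result> cut time %.2f h (%s)\n", x$cut_time_h,
              if (x$capped) "capped at truncation" else "target reached"))
  cat(sprintf("  baseline %.3f -> target %.3f; achieved %.3f doublings; truncation %.2f h\n",
              x$baseline_value, x$target_value, x$achieved_doublings, x$truncation_time_h))
  invisible(x)
}

#' Diagnostics for a computed cut time
#'
#' Gathers everything needed to audit an automatic cut time: the control
#' growth curve on the differencing grid, the moving-average
#' second-difference profile, and the user-set (baseline time, maximum
#' value) versus computed (truncation time, cut time, target value)
#' markers. The returned record can be plotted with
#' [plot_cut_time_diagnostics()].
#'
#' @param drcset a `drcset` on which [calculate_cut_time()] has been run.
#' @return A `cut_time_diagnostics` object: list with `control_curve`,
#'   `ma_profile`, `markers` (named numeric vector) and `capped`.
#' @export
cut_time_diagnostics <- function(drcset) {
  stopifnot(inherits(drcset, "drcset"))
  res <- drcset$cut_time_result
  if (is.null(res)) {
    stop("no computed cut time on this set; run calculate_cut_time() first", call. = FALSE)
  }
  model <- control_growth_model(drcset)
  step <- res$params$grid_step_h %||% default_grid_step(drcset)
  grid <- prediction_grid(model, step)
  curve <- tibble::tibble(elapsed_h = grid, value = predict_growth(model, grid))
  prof <- second_difference_profile(model, step)
  prof$value <- moving_average(prof$value, res$params$window_n)
  markers <- c(baseline_time_h = res$params$baseline_time_h,
               max_val = res$params$max_val,
               truncation_time_h = res$truncation_time_h,
               cut_time_h = res$cut_time_h,
               target_value = res$target_value)
  structure(list(control_curve = curve, ma_profile = prof,
                 markers = markers, capped = res$capped),
            class = "cut_time_diagnostics")
}
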