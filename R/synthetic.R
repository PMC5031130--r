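#' Default simulated compound panel
#'
#' Six cytostatic compounds with potencies spanning 1.5 decades
#' (pEC50 5.5-7.0, i.e. micromolar EC50s from 3.16 down to 0.1), unit
#' hill slope and full rate inhibition at saturation.
#'
#' @return Tibble with columns `name`, `pEC50`, `hill`, `max_inhibition`.
#' @export
default_compounds <- function() {
  tibble::tibble(
    name = sprintf("CP%02d", 1:6),
    pEC50 = c(5.5, 5.8, 6.1, 6.4, 6.7, 7.0), # -log10 molar potency
    hill = rep(1, 6),
    max_inhibition = rep(1, 6))
}

#' Specify a simulated proliferation plate
#'
#' Defines a synthetic live-cell-imaging experiment with known ground
#' truth: cells growing by a lagged logistic law, compounds acting
#' cytostatically by scaling the growth rate through a hill-type
#' occupancy term, a serial-dilution dose series with replicates, vehicle
#' control wells, and additive Gaussian measurement noise on confluence
#' (clipped at zero).
#'
#' Untreated confluence follows `y(t) = K / (1 + ((K - y0)/y0) *
#' exp(-r (t - lag)))` for `t > lag` and `y0` before, with
#' `r = ln(2) / doubling_time_h`. A compound at concentration `C` scales
#' the rate by `1 - max_inhibition * C^h / (C^h + EC50^h)`, where the
#' EC50 comes from the compound's `pEC50` (-log10 molar; doses are in
#' micromolar).
#'
#' @param plate_rows,plate_cols plate format (default 16 x 24, a 384-well
#'   plate, which accommodates the default 6 compounds x 8 doses x 3
#'   replicates plus controls).
#' @param doubling_time_h untreated doubling time in hours.
#' @param y0 initial confluence (percent).
#' @param K carrying capacity (percent confluence).
#' @param lag_h lag before growth starts, in hours.
#' @param compounds tibble with columns `name`, `pEC50`, `hill`,
#'   `max_inhibition`.
#' @param top_dose_uM,dilution_factor,n_doses serial dilution series, in
#'   micromolar.
#' @param replicates wells per (compound, dose).
#' @param n_controls number of vehicle-control wells.
#' @param t_start_h,t_end_h,interval_h imaging schedule in hours.
#' @param noise_sd standard deviation of the additive confluence noise.
#' @param seed integer seed making the simulated plate reproducible.
#' @param growthcondition,celltype annotations written to the plate map.
#' @return A `simulation_spec` object.
#' @export
simulation_spec <- function(plate_rows = 16, plate_cols = 24,
                            doubling_time_h = 18, y0 = 5, K = 100, lag_h = 6,
                            compounds = default_compounds(),
                            top_dose_uM = 10, dilution_factor = sqrt(10), n_doses = 8,
                            replicates = 3, n_controls = 6,
                            t_start_h = 0, t_end_h = 96, interval_h = 2,
                            noise_sd = 1.5, seed = 1,
                            growthcondition = "standard", celltype = "CellA") {
  compounds <- tibble::as_tibble(compounds)
  stopifnot(all(c("name", "pEC50", "hill", "max_inhibition") %in% names(compounds)),
            y0 > 0, K > y0, lag_h >= 0, doubling_time_h > 0,
            top_dose_uM > 0, dilution_factor > 1, n_doses >= 1,
            replicates >= 1, n_controls >= 0, interval_h > 0,
            t_end_h > t_start_h, noise_sd >= 0,
            all(compounds$max_inhibition >= 0 & compounds$max_inhibition <= 1))
  needed <- n_controls + nrow(compounds) * n_doses * replicates
  if (needed > plate_rows * plate_cols) {
    stop(sprintf("layout needs %d wells but the %dx%d plate holds %d",
                 needed, plate_rows, plate_cols, plate_rows * plate_cols), call. = FALSE)
  }
  structure(list(plate_rows = as.integer(plate_rows), plate_cols = as.integer(plate_cols),
                 doubling_time_h = doubling_time_h, y0 = y0, K = K, lag_h = lag_h,
                 compounds = compounds, top_dose_uM = top_dose_uM,
                 dilution_factor = dilution_factor, n_doses = as.integer(n_doses),
                 replicates = as.integer(replicates), n_controls = as.integer(n_controls),
                 t_start_h = t_start_h, t_end_h = t_end_h, interval_h = interval_h,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 growthcondition = growthcondition, celltype = celltype),
            class = "simulation_spec")
}

spec_doses <- function(spec) {
  spec$top_dose_uM / spec$dilution_factor^(seq_len(spec$n_doses) - 1)
}

spec_ec50_uM <- function(spec) 10^(6 - spec$compounds$pEC50)

inhibition_fraction <- function(conc_uM, ec50_uM, hill, max_inhibition) {
  ifelse(conc_uM <= 0, 0,
         max_inhibition * conc_uM^hill / (conc_uM^hill + ec50_uM^hill))
}

#' Noiseless confluence trajectory of the simulation model
#'
#' @param t elapsed hours.
#' @param spec a [simulation_spec].
#' @param inhibition fraction in `[0, 1]` by which the growth rate is
#'   reduced (0 = untreated).
#' @return Confluence values.
#' @export
logistic_confluence <- function(t, spec, inhibition = 0) {
  r <- log(2) / spec$doubling_time_h * (1 - inhibition)
  A <- (spec$K - spec$y0) / spec$y0
  ifelse(t <= spec$lag_h, spec$y0,
         spec$K / (1 + A * exp(-r * (t - spec$lag_h))))
}

#' Simulate a plate with known ground truth
#'
#' Lays out vehicle-control wells followed by compound wells (compound by
#' compound, dose by dose in descending concentration, replicate by
#' replicate) in row-major plate order, simulates every well's confluence
#' trajectory under the [simulation_spec] model, and adds seeded Gaussian
#' noise. The global RNG state is left untouched.
#'
#' @param spec a [simulation_spec].
#' @return List with elements `platemap` ([platemap]), `platedata`
#'   ([platedata]) and `truth` (the spec, per-compound true micromolar
#'   EC50s, and the noiseless trajectories).
#' @export
simulate_plate <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  doses <- spec_doses(spec)
  layout <- tibble::tibble(
    samptype = c(rep("vehicle_control", spec$n_controls),
                 rep("compound", nrow(spec$compounds) * spec$n_doses * spec$replicates)),
    compound = c(rep("", spec$n_controls),
                 rep(spec$compounds$name, each = spec$n_doses * spec$replicates)),
    conc = c(rep(0, spec$n_controls),
             rep(rep(doses, each = spec$replicates), times = nrow(spec$compounds))))
  n <- nrow(layout)
  idx <- seq_len(n) - 1L
  layout$row <- PLATE_ROWS[idx %/% spec$plate_cols + 1L]
  layout$col <- as.integer(idx %% spec$plate_cols + 1L)
  layout$units <- ifelse(layout$samptype == "compound", "uM", "")
  layout$growthcondition <- spec$growthcondition
  layout$celltype <- spec$celltype
  pm <- platemap(layout, plate_id = sprintf("simplate_seed%d", spec$seed))

  times <- seq(spec$t_start_h, spec$t_end_h, by = spec$interval_h)
  ec50s <- spec_ec50_uM(spec)
  names(ec50s) <- spec$compounds$name
  traj <- lapply(seq_len(n), function(i) {
    w <- layout[i, ]
    inh <- if (w$samptype == "compound") {
      j <- match(w$compound, spec$compounds$name)
      inhibition_fraction(w$conc, ec50s[[w$compound]],
                          spec$compounds$hill[j], spec$compounds$max_inhibition[j])
    } else 0
    logistic_confluence(times, spec, inh)
  })
  truth_tbl <- tibble::tibble(
    well = rep(well_label(layout$row, layout$col), each = length(times)),
    elapsed_h = rep(times, times = n),
    value_true = unlist(traj))
  noisy <- with_seed(spec$seed, {
    v <- truth_tbl$value_true
    if (spec$noise_sd > 0) v <- pmax(0, v + rnorm(length(v), sd = spec$noise_sd))
    v
  })
  rec <- tibble::tibble(
    row = rep(layout$row, each = length(times)),
    col = rep(layout$col, each = length(times)),
    elapsed_h = truth_tbl$elapsed_h,
    value = noisy)
  pd <- platedata(rec, plate_id = pm$plate_id, metric = "percent confluence")
  list(platemap = pm, platedata = pd,
       truth = list(spec = spec, ec50_uM = ec50s, r_per_h = log(2) / spec$doubling_time_h,
                    trajectories = truth_tbl))
}

#' Brute-force apparent-EC50 oracle
#'
#' The concentration-response read out at a finite cut time is an
#' *apparent* dose-response: even with the true rate-inhibition EC50
#' known, the confluence read-out transforms it nonlinearly. This oracle
#' computes the apparent EC50 a perfect pipeline would see: it evaluates
#' the noiseless confluence at the cut time over a dense 200-point
#' log-dose grid spanning a decade beyond the plate's dose series on both
#' sides, and fits the four-parameter log-logistic to that noiseless
#' curve. Pipeline EC50 estimates are judged against this value.
#'
#' @param spec a [simulation_spec].
#' @param compound compound name present in `spec`.
#' @param cut_time_h cut time in hours, within the simulated range.
#' @return The apparent EC50 in micromolar.
#' @export
apparent_ec50_oracle <- function(spec, compound, cut_time_h) {
  stopifnot(inherits(spec, "simulation_spec"))
  j <- match(compound, spec$compounds$name)
  if (is.na(j)) stop(sprintf("compound '%s' is not in the simulation spec", compound), call. = FALSE)
  if (spec$compounds$max_inhibition[j] <= 0) {
    stop(sprintf("compound '%s' has no effect (max_inhibition = 0); apparent EC50 is undefined",
                 compound), call. = FALSE)
  }
  if (cut_time_h < spec$t_start_h || cut_time_h > spec$t_end_h) {
    stop(sprintf("cut time %.2f h is outside the simulated range [%g, %g] h",
                 cut_time_h, spec$t_start_h, spec$t_end_h), call. = FALSE)
  }
  doses <- spec_doses(spec)
  grid <- 10^seq(log10(min(doses) / 10), log10(max(doses) * 10), length.out = 200)
  ec50 <- spec_ec50_uM(spec)[j]
  y <- vapply(grid, function(C) {
    inh <- inhibition_fraction(C, ec50, spec$compounds$hill[j], spec$compounds$max_inhibition[j])
    logistic_confluence(cut_time_h, spec, inh)
  }, numeric(1))
  fit <- fit_ll4_points(grid, y, compound = compound)
  if (!isTRUE(fit$converged)) stop("oracle 4PL fit did not converge", call. = FALSE)
  fit$e
}
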