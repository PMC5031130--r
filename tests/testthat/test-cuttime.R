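# analytic minimiser of the second derivative of a logistic curve:
# inflection + ln(2 + sqrt(3)) / r
logistic_d2min <- function(K, y0, r) log((K - y0) / y0) / r + log(2 + sqrt(3)) / r

test_that("second differences vanish for affine and are constant for quadratic data", {
  m_lin <- fit_curve_model(function(t) 3 + 2 * t, times = seq(0, 60, 2))
  prof <- second_difference_profile(m_lin, grid_step_h = 2)
  expect_lt(max(abs(prof$value)), 1e-8)

  m_quad <- fit_curve_model(function(t) t^2, times = seq(0, 40, 1))
  prof2 <- second_difference_profile(m_quad, grid_step_h = 1)
  expect_equal(prof2$value, rep(2, nrow(prof2)), tolerance = 1e-6)
})

test_that("the second-difference profile matches the sign of the logistic curvature", {
  K <- 100; y0 <- 2; r <- 0.1
  f <- logistic_growth(K, y0, r)
  m <- fit_curve_model(f, times = seq(0, 120, 2), span = 0.25)
  prof <- second_difference_profile(m, grid_step_h = 2)
  t_inf <- log((K - y0) / y0) / r
  true_sign <- sign(t_inf - prof$elapsed_h) # y'' > 0 before the inflection
  agree <- mean(sign(prof$value) == true_sign)
  expect_gte(agree, 0.95)
})

test_that("exponential growth yields no detectable deceleration", {
  m <- fit_curve_model(exp_growth(10, 24), times = seq(0, 96, 2))
  expect_warning(end <- exponential_phase_end(m, window_n = 30, grid_step_h = 2),
                 "no deceleration")
  expect_equal(end, 96)
})

test_that("a flat profile falls back to the end of the domain with a warning", {
  m <- fit_curve_model(function(t) 5 + t, times = seq(0, 96, 1))
  expect_warning(end <- exponential_phase_end(m, window_n = 30, grid_step_h = 1),
                 "no deceleration")
  expect_equal(end, 96)
})

test_that("the detected phase end tracks the analytic logistic curvature minimum", {
  K <- 100; y0 <- 2; r <- 0.1
  m <- fit_curve_model(logistic_growth(K, y0, r), times = seq(0, 120, 2), span = 0.25)
  end <- exponential_phase_end(m, window_n = 30, grid_step_h = 1)
  expect_lt(abs(end - logistic_d2min(K, y0, r)), 2 * 30 * 1)
})

test_that("a single-point window reduces to the raw second-difference argmin", {
  f <- logistic_growth(100, 5, 0.1)
  m <- fit_curve_model(f, times = seq(0, 120, 2), span = 0.25)
  prof <- second_difference_profile(m, grid_step_h = 2)
  end <- exponential_phase_end(m, window_n = 1, grid_step_h = 2)
  expect_equal(end, prof$elapsed_h[which.min(prof$value)])
})

test_that("window or grid mis-sizing raises instructive errors", {
  m <- fit_curve_model(function(t) t^2, times = seq(0, 40, 1))
  expect_error(second_difference_profile(m, grid_step_h = 50), "grid too short")
  expect_error(exponential_phase_end(m, window_n = 50, grid_step_h = 2),
               "window")
})

test_that("cut time inverts noiseless exponential growth exactly", {
  s <- control_drcset(exp_growth(10, 24), times = seq(0, 96, 2))
  s <- suppressWarnings(
    calculate_cut_time(s, cut_time_params(baseline_time_h = 0, no_doublings = 2,
                                          max_val = 80)))
  r <- s$cut_time_result
  expect_false(r$capped)
  expect_equal(r$cut_time_h, 48, tolerance = 0.5 / 48)
  expect_equal(r$target_value, 40, tolerance = 0.02) # boundary smoothing bias at t = 0
  expect_equal(r$achieved_doublings, 2)
  expect_equal(s$cut_time_h, r$cut_time_h)

  # target above max_val: capped at the 80-crossing with ~3 doublings
  s2 <- suppressWarnings(
    calculate_cut_time(s, cut_time_params(baseline_time_h = 0, no_doublings = 4,
                                          max_val = 80)))
  r2 <- s2$cut_time_result
  expect_true(r2$capped)
  expect_equal(r2$cut_time_h, 72, tolerance = 1 / 72)
  expect_equal(r2$achieved_doublings, 3, tolerance = 0.02)
  expect_lt(r2$achieved_doublings, 4)
  expect_equal(r2$cut_time_h, r2$truncation_time_h)

  # zero doublings: cut at the baseline itself
  s3 <- suppressWarnings(
    calculate_cut_time(s, cut_time_params(baseline_time_h = 12, no_doublings = 0)))
  expect_equal(s3$cut_time_result$cut_time_h, 12)
  expect_false(s3$cut_time_result$capped)
})

test_that("cut-time preconditions are validated", {
  s <- control_drcset(exp_growth(10, 24), times = seq(0, 96, 2))
  expect_error(suppressWarnings(
    calculate_cut_time(s, cut_time_params(baseline_time_h = 200))), "outside")
  expect_error(suppressWarnings(
    calculate_cut_time(s, cut_time_params(max_val = 5))), "max_val")
  pm <- simple_platemap(n_ctrl = 0, compound = "X", concs = c(1, 2, 5, 10))
  pd <- curve_platedata(pm, function(t, i) 5 + t, times = seq(0, 48, 2))
  s2 <- fit_growth_curves_grouped(make_drc_set(pm, pd))
  expect_error(calculate_cut_time(s2), "vehicle-control")
  s3 <- control_drcset(exp_growth(10, 24))
  s3$growth_grouped <- NULL
  expect_error(calculate_cut_time(s3), "fit_growth_curves_grouped")
})

test_that("cut time is monotone in doublings and baseline on logistic controls", {
  s <- control_drcset(logistic_growth(100, 2, 0.1), times = seq(0, 120, 2),
                      span = 0.25)
  cuts <- vapply(c(0.5, 1, 1.5, 2, 2.5, 3), function(nd) {
    suppressWarnings(calculate_cut_time(
      s, cut_time_params(baseline_time_h = 4, no_doublings = nd)))$cut_time_result$cut_time_h
  }, numeric(1))
  expect_true(all(diff(cuts) >= -1e-9))
  cuts_b <- vapply(c(0, 4, 8, 12, 16), function(b) {
    suppressWarnings(calculate_cut_time(
      s, cut_time_params(baseline_time_h = b, no_doublings = 1.5)))$cut_time_result$cut_time_h
  }, numeric(1))
  expect_true(all(diff(cuts_b) >= -1e-9))
})

test_that("truncation time never decreases when max_val or window_n is raised", {
  s <- control_drcset(logistic_growth(100, 2, 0.1), times = seq(0, 120, 2),
                      span = 0.25)
  trunc_at <- function(mv, wn) suppressWarnings(calculate_cut_time(
    s, cut_time_params(no_doublings = 6, max_val = mv,
                       window_n = wn)))$cut_time_result$truncation_time_h
  tr_mv <- vapply(c(40, 60, 80, 95), trunc_at, numeric(1), wn = 30)
  expect_true(all(diff(tr_mv) >= -1e-9))
  tr_wn <- vapply(c(10, 20, 30, 40), function(w) trunc_at(95, w), numeric(1))
  expect_true(all(diff(tr_wn) >= -1e-9))
})

test_that("capped cut times stay at or below the allowed maximum value", {
  s <- control_drcset(logistic_growth(100, 2, 0.12), times = seq(0, 120, 2),
                      span = 0.25)
  s <- suppressWarnings(calculate_cut_time(
    s, cut_time_params(no_doublings = 8, max_val = 60)))
  r <- s$cut_time_result
  expect_true(r$capped)
  m <- celldrc:::control_growth_model(s)
  expect_lte(predict_growth(m, r$cut_time_h), 60 + 0.5)
})

test_that("uncapped cut times recover the doubling time under noise", {
  # lagged near-exponential growth (K far above max_val), 50 noisy replicates
  for (seed in 1:50) {
    spec <- simulation_spec(K = 5000, y0 = 5, doubling_time_h = 20, lag_h = 6,
                            noise_sd = 1, n_controls = 6, replicates = 1,
                            n_doses = 4, compounds = default_compounds()[1, ],
                            t_end_h = 96, seed = seed)
    sim <- simulate_plate(spec)
    s <- fit_growth_curves_grouped(make_drc_set(sim$platemap, sim$platedata))
    s <- suppressWarnings(calculate_cut_time(
      s, cut_time_params(baseline_time_h = 24, no_doublings = 2, max_val = 80)))
    r <- s$cut_time_result
    expected <- 24 + 2 * spec$doubling_time_h
    expect_false(r$capped)
    expect_lt(abs(r$cut_time_h - expected), 2)
  }
})

test_that("diagnostics agree exactly with the stored cut-time result", {
  s <- control_drcset(logistic_growth(100, 2, 0.1), times = seq(0, 120, 2),
                      span = 0.25)
  s <- suppressWarnings(calculate_cut_time(s, cut_time_params(no_doublings = 2)))
  d <- cut_time_diagnostics(s)
  r <- s$cut_time_result
  expect_named(d$markers, c("baseline_time_h", "max_val", "truncation_time_h",
                            "cut_time_h", "target_value"))
  expect_equal(d$markers[["cut_time_h"]], r$cut_time_h)
  expect_equal(d$markers[["truncation_time_h"]], r$truncation_time_h)
  expect_equal(d$markers[["target_value"]], r$target_value)
  expect_equal(d$capped, r$capped)
  dom <- celldrc:::control_growth_model(s)$time_domain
  tmarks <- d$markers[c("baseline_time_h", "truncation_time_h", "cut_time_h")]
  expect_true(all(tmarks >= dom[1] & tmarks <= dom[2]))

  # capped fixture flags capped
  s2 <- suppressWarnings(calculate_cut_time(s, cut_time_params(no_doublings = 9)))
  expect_true(cut_time_diagnostics(s2)$capped)
  expect_error(cut_time_diagnostics(control_drcset(exp_growth())), "calculate_cut_time")

  # plot builds without evaluation errors
  p <- plot_cut_time_diagnostics(d)
  expect_s3_class(p, "ggplot")
})
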