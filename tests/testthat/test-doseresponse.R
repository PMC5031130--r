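# drcset whose wells grow linearly with per-well slope determined by a 4PL
# in the well's concentration: value at cut time t is slope * t exactly
linear_slope_drcset <- function(concs = 10^seq(-2, 1, length.out = 5), reps = 3,
                                b = 1, c = 0.2, d = 2, e = 0.3,
                                compound = "CmpdA", times = seq(0, 48, 2)) {
  pm <- simple_platemap(n_ctrl = 2, compound = compound, concs = concs, reps = reps)
  w <- pm$wells
  slopes <- ifelse(w$samptype == "vehicle_control", d, ll4(pmax(w$conc, 1e-12), b, c, d, e))
  pd <- curve_platedata(pm, function(t, i) slopes[i] * t, times = times)
  s <- make_drc_set(pm, pd)
  s <- fit_growth_curves_individual(s)
  list(set = s, slopes = slopes)
}

test_that("growth values at the cut time are read off each well exactly", {
  fx <- linear_slope_drcset()
  s <- set_cut_time(fx$set, 10)
  s <- calculate_drc_data(s)
  dat <- s$drc_data
  # every well's extracted value equals slope * cut time (linear smoother
  # reproduces linear wells exactly)
  lbl <- paste0(fx$set$platemap$wells$row, fx$set$platemap$wells$col)
  slope_by_well <- stats::setNames(fx$slopes, lbl)
  expect_equal(dat$value, unname(10 * slope_by_well[dat$well]), tolerance = 1e-8)
})

test_that("DRC records have one row per (compound, concentration) and true means", {
  pm <- simple_platemap(n_ctrl = 2, compound = "CmpdA", concs = c(0.1, 1, 5, 10, 20),
                        reps = 3)
  pm2 <- pm
  extra <- pm$wells[pm$wells$samptype == "compound", ][1:15, ]
  extra$row <- "C"
  extra$compound <- "CmpdB"
  pm2$wells <- dplyr::bind_rows(pm$wells, extra)
  pm2 <- platemap(pm2$wells, plate_id = "two")
  pd <- curve_platedata(pm2, function(t, i) 5 + i / 10 + t / 4, times = seq(0, 48, 2))
  s <- make_drc_set(pm2, pd)
  s <- fit_growth_curves_individual(s)
  s <- set_cut_time(s, 24)
  s <- calculate_drc_data(s)
  rec <- drc_records(s)
  cmp <- rec[rec$samptype == "compound", ]
  expect_equal(nrow(cmp), 10) # 2 compounds x 5 concentrations
  expect_true(all(cmp$n == 3))
  expect_equal(cmp$mean_value,
               vapply(cmp$values, mean, numeric(1)))
})

test_that("cut-time extraction demands a cut time inside every well's domain", {
  fx <- linear_slope_drcset()
  expect_error(calculate_drc_data(fx$set), "cut time is not set")
  s <- set_cut_time(fx$set, 300)
  expect_error(calculate_drc_data(s), "outside the observed domain")
})

test_that("mean response decreases with dose for a noiseless inhibitor", {
  spec <- simulation_spec(noise_sd = 0, n_doses = 8, replicates = 2,
                          compounds = default_compounds()[3, ], n_controls = 2,
                          seed = 5)
  sim <- simulate_plate(spec)
  s <- make_drc_set(sim$platemap, sim$platedata)
  s <- fit_growth_curves_individual(s)
  s <- set_cut_time(s, 60)
  s <- calculate_drc_data(s)
  rec <- drc_records(s)
  cmp <- dplyr::arrange(rec[rec$samptype == "compound", ], .data$conc)
  expect_true(all(diff(cmp$mean_value) < 0))
})

test_that("noiseless 4PL data is recovered to high relative accuracy", {
  doses <- 10^seq(-2.5, 1, length.out = 8)
  y <- ll4(doses, b = 1, c = 0, d = 100, e = 1)
  fit <- celldrc:::fit_ll4_points(rep(doses, 2), rep(y, 2), compound = "X")
  expect_true(fit$converged)
  expect_equal(fit$b, 1, tolerance = 1e-6)
  expect_equal(fit$c, 0, tolerance = 1e-4) # c = 0: absolute scale
  expect_equal(fit$d, 100, tolerance = 1e-6)
  expect_equal(fit$e, 1, tolerance = 1e-6)

  fit2 <- celldrc:::fit_ll4_points(doses, ll4(doses, 2, 10, 90, 3), compound = "Y")
  expect_equal(calculate_ec50(fit2), 3, tolerance = 1e-6)
})

test_that("random noiseless 4PL parameter draws are identified and dose-scale equivariant", {
  set.seed(99)
  for (i in 1:25) {
    b <- runif(1, 0.5, 4); c <- runif(1, 0, 30); d <- runif(1, 60, 110)
    doses <- 10^seq(-3, 1, length.out = 8)
    e <- 10^runif(1, -2.4, 0.4)
    y <- ll4(doses, b, c, d, e)
    fit <- celldrc:::fit_ll4_points(doses, y)
    expect_equal(fit$b, b, tolerance = 1e-6)
    expect_equal(fit$c, c, tolerance = max(1e-6, 1e-6 * d))
    expect_equal(fit$d, d, tolerance = 1e-6)
    expect_equal(fit$e, e, tolerance = 1e-6)
    # multiplying doses by k multiplies e by k and leaves b, c, d alone
    k <- 10^runif(1, -1, 1)
    fit_k <- celldrc:::fit_ll4_points(doses * k, y)
    expect_equal(fit_k$e / fit$e, k, tolerance = 1e-6)
    expect_equal(fit_k$b, fit$b, tolerance = 1e-6)
    expect_equal(fit_k$c, fit$c, tolerance = max(1e-6, 1e-6 * d))
    expect_equal(fit_k$d, fit$d, tolerance = 1e-6)
  }
})

test_that("fits are invariant to replicate ordering and flag degenerate data", {
  doses <- 10^seq(-2, 1, length.out = 6)
  set.seed(7)
  y <- ll4(doses, 1.5, 5, 95, 0.5) + rnorm(6, sd = 1)
  perm <- sample(6)
  f1 <- celldrc:::fit_ll4_points(doses, y)
  f2 <- celldrc:::fit_ll4_points(doses[perm], y[perm])
  expect_equal(f1$e, f2$e, tolerance = 1e-9)
  expect_equal(f1$rss, f2$rss, tolerance = 1e-9)

  # constant response: no crash; either unconverged or a collapsed span
  fit_const <- celldrc:::fit_ll4_points(doses, rep(50, 6))
  expect_s3_class(fit_const, "dose_response_model")
  expect_true(!isTRUE(fit_const$converged) || abs(fit_const$d - fit_const$c) < 1e-3)

  # at the fitted EC50 the response is halfway between the asymptotes
  expect_equal(ll4(f1$e, f1$b, f1$c, f1$d, f1$e), (f1$c + f1$d) / 2, tolerance = 1e-9)
})

test_that("fit_dose_response stores per-compound models and EC50s are guarded", {
  fx <- linear_slope_drcset(concs = 10^seq(-2, 1, length.out = 6), reps = 2)
  s <- set_cut_time(fx$set, 20)
  s <- calculate_drc_data(s)
  s <- fit_dose_response(s)
  expect_equal(s$dr_models$compound, "CmpdA")
  m <- s$dr_models$model[[1]]
  expect_true(m$converged)
  expect_equal(m$e, 0.3, tolerance = 1e-4)
  bad <- m; bad$converged <- FALSE
  expect_error(calculate_ec50(bad), "CmpdA")

  fx4 <- linear_slope_drcset(concs = c(1, 5, 10))
  s4 <- calculate_drc_data(set_cut_time(fx4$set, 20))
  expect_error(fit_dose_response(s4), "at least 4")
})

test_that("export layouts have the documented shapes and round-trip", {
  fx <- linear_slope_drcset(concs = c(0.1, 1, 5, 10), reps = 2)
  s <- set_cut_time(fx$set, 20)
  s <- calculate_drc_data(s)
  long <- export_drc_table(s, "long")
  expect_equal(nrow(long[long$samptype == "compound", ]), 8)
  prism <- export_drc_table(s, "prism")
  expect_equal(dim(prism), c(4, 3)) # conc + 2 replicate columns
  expect_named(prism, c("conc", "CmpdA_1", "CmpdA_2"))
  dot <- export_drc_table(s, "dotmatics")
  expect_equal(dim(dot), c(4, 4))
  expect_named(dot, c("sampleid", "conc", "value_1", "value_2"))
  expect_error(export_drc_table(s, "nonsense"))

  # long export re-read and re-aggregated gives identical records
  path <- withr::local_tempfile(fileext = ".tsv")
  write_export_table(long, path)
  back <- utils::read.delim(path)
  agg <- dplyr::summarise(
    dplyr::group_by(back, .data$compound, .data$conc, .data$samptype),
    n = dplyr::n(), mean_value = mean(.data$value), .groups = "drop")
  rec <- drc_records(s)[c("compound", "conc", "samptype", "n", "mean_value")]
  agg$compound <- as.character(agg$compound)
  agg$compound[is.na(agg$compound)] <- ""
  expect_equal(as.data.frame(dplyr::arrange(agg, .data$compound, .data$conc)),
               as.data.frame(dplyr::arrange(rec, .data$compound, .data$conc)),
               tolerance = 1e-4)
})

test_that("the EC50 table carries parameters, flags, cut time and metadata", {
  spec <- simulation_spec(noise_sd = 0.5, n_doses = 6, replicates = 2,
                          compounds = default_compounds()[1:3, ], n_controls = 3,
                          seed = 21)
  sim <- simulate_plate(spec)
  s <- make_drc_set(sim$platemap, sim$platedata, metadata = list(batch = "b1"))
  s <- fit_growth_curves_individual(s)
  s <- set_cut_time(s, 60)
  s <- calculate_drc_data(s)
  s <- fit_dose_response(s)
  tab <- export_ec50_table(s)
  expect_equal(nrow(tab), 3)
  expect_true(all(c("compound", "b", "c", "d", "e", "ec50", "converged",
                    "rss", "n_points", "cut_time_h", "batch") %in% names(tab)))
  expect_equal(tab$cut_time_h, rep(60, 3))
  expect_equal(tab$ec50[tab$converged], tab$e[tab$converged])
  expect_equal(tab$ec50, vapply(s$dr_models$model, calculate_ec50, numeric(1)))
})
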