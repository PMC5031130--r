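# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# plate map with n_ctrl vehicle wells in row A and one compound series
simple_platemap <- function(n_ctrl = 2, compound = NULL, concs = numeric(0),
                            reps = 1, condition = "std", celltype = "CellA") {
  rows <- tibble::tibble(
    row = "A", col = seq_len(n_ctrl), samptype = "vehicle_control",
    compound = "", conc = 0, units = "")
  if (!is.null(compound)) {
    k <- length(concs) * reps
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      row = "B", col = seq_len(k), samptype = "compound",
      compound = compound, conc = rep(concs, each = reps), units = "uM"))
  }
  rows$growthcondition <- condition
  rows$celltype <- celltype
  platemap(rows, plate_id = "fixture")
}

# platedata from a deterministic trajectory function f(t, well_index)
curve_platedata <- function(pm, f, times = seq(0, 96, 2)) {
  w <- pm$wells
  rec <- dplyr::bind_rows(lapply(seq_len(nrow(w)), function(i) {
    tibble::tibble(row = w$row[i], col = w$col[i], elapsed_h = times,
                   value = f(times, i))
  }))
  platedata(rec, plate_id = pm$plate_id)
}

# drcset whose control growth curve follows f(t), with n_ctrl pooled wells
control_drcset <- function(f, times = seq(0, 96, 2), n_ctrl = 2, span = 0.5) {
  pm <- simple_platemap(n_ctrl = n_ctrl)
  pd <- curve_platedata(pm, function(t, i) f(t), times)
  fit_growth_curves_grouped(make_drc_set(pm, pd), span = span)
}

# standalone growth model fitted to samples of f(t)
fit_curve_model <- function(f, times = seq(0, 120, 2), span = 0.5) {
  celldrc:::fit_loess_curve(times, f(times), span = span, key = "fixture")
}

exp_growth <- function(y0 = 10, doubling_h = 24) function(t) y0 * 2^(t / doubling_h)

logistic_growth <- function(K = 100, y0 = 2, r = 0.1) {
  A <- (K - y0) / y0
  function(t) K / (1 + A * exp(-r * t))
}

# random plate map across k (condition, celltype) groups, for partition and
# round-trip properties
random_platemap <- function(k_conditions = 2, seed = 1) {
  withr::with_seed(seed, {
    n <- sample(6:24, 1)
    rows <- sample(LETTERS[1:8], n, replace = TRUE)
    cols <- sample(1:12, n, replace = TRUE)
    keep <- !duplicated(paste0(rows, cols))
    rows <- rows[keep]; cols <- cols[keep]; n <- length(rows)
    cond <- sample(paste0("cond", seq_len(k_conditions)), n, replace = TRUE)
    samptype <- sample(c("compound", "vehicle_control", "blank"), n,
                       replace = TRUE, prob = c(0.6, 0.3, 0.1))
    platemap(tibble::tibble(
      row = rows, col = cols, samptype = samptype,
      compound = ifelse(samptype == "compound",
                        sample(c("CmpdA", "CmpdB"), n, replace = TRUE), ""),
      conc = ifelse(samptype == "compound", round(stats::runif(n, 0.01, 10), 4), 0),
      units = ifelse(samptype == "compound", "uM", ""),
      growthcondition = cond,
      celltype = sample(c("HCT116", "A549"), n, replace = TRUE),
      passage = ifelse(stats::runif(n) < 0.5, paste0("P", sample(1:20, n, replace = TRUE)), ""),
      seedingdensity = ifelse(stats::runif(n) < 0.5, sample(500:5000, n, replace = TRUE), 0)),
      plate_id = sprintf("rand%d", seed))
  })
}

random_platedata <- function(pm, seed = 1, n_times = 6) {
  withr::with_seed(seed, {
    times <- sort(sample(seq(0, 96, 0.5), n_times))
    curve_platedata(pm, function(t, i) round(stats::runif(1, 1, 5) * (1 + t / 24) +
                                               stats::rnorm(length(t), 0, 0.1), 6),
                    times = times)
  })
}

expect_platemap_equal <- function(a, b) {
  expect_equal(a$plate_id, b$plate_id)
  expect_equal(as.data.frame(a$wells), as.data.frame(b$wells), tolerance = 1e-9)
}
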