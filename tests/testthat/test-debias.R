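test_that("the N_EH regression handles flat and exact-line inputs", {
  neh <- c(10, 20, 30, 40, 55)
  r <- suppressWarnings(fit_neh_regression(rep(0.03, 5), neh, time = 1))
  expect_true(r$estimable)
  expect_equal(r$slope, 0)
  expect_equal(r$intercept, 0.03)
  r2 <- suppressWarnings(fit_neh_regression(-2e-4 * neh + 0.035, neh))
  expect_equal(r2$slope, -2e-4)
  expect_equal(r2$intercept, 0.035)
  expect_lt(r2$p_value, 1e-10)
  expect_true(r2$slope_ci95[1] <= r2$slope && r2$slope <= r2$slope_ci95[2])
})

test_that("the N_EH regression matches the normal-equations oracle", {
  set.seed(42)
  for (rep in 1:10) {
    neh <- sample(10:60, 50, replace = TRUE)
    px <- 0.03 - 2e-4 * neh + rnorm(50, 0, 1e-3)
    r <- fit_neh_regression(px, neh, time = 7)
    o <- ols_oracle(neh, px)
    expect_equal(r$slope, o$slope, tolerance = 1e-12)
    expect_equal(r$intercept, o$intercept, tolerance = 1e-12)
    expect_equal(r$slope_stderr, o$stderr, tolerance = 1e-10)
    expect_equal(r$p_value, o$p_value, tolerance = 1e-10)
    expect_lt(abs(r$slope - (-2e-4)), 3 * r$slope_stderr)
  }
})

test_that("regressions without N_EH contrast or enough peptides are not estimable", {
  expect_false(fit_neh_regression(c(0.01, 0.02, 0.03), c(20, 20, 20))$estimable)
  expect_false(fit_neh_regression(c(0.01, 0.02), c(10, 20))$estimable)
})

test_that("adjustment removes the linear component and preserves the mean", {
  neh <- c(10, 25, 33, 47, 60)
  # zero slope: identity
  r0 <- suppressWarnings(fit_neh_regression(rep(0.02, 5), neh))
  px <- c(0.021, 0.019, 0.020, 0.022, 0.018)
  expect_equal(adjust_enrichment(px, neh, r0), px, tolerance = 1e-14)
  # exact line: all residuals zero, adjusted values constant at the centroid
  line <- 3e-4 * neh + 0.005
  rl <- suppressWarnings(fit_neh_regression(line, neh))
  adj <- adjust_enrichment(line, neh, rl)
  expect_equal(adj, rep(3e-4 * mean(neh) + 0.005, 5), tolerance = 1e-12)
  # mean conservation on arbitrary noisy input
  set.seed(7)
  px2 <- 0.03 - 2e-4 * neh + rnorm(5, 0, 2e-3)
  r2 <- fit_neh_regression(px2, neh)
  adj2 <- adjust_enrichment(px2, neh, r2)
  expect_equal(mean(adj2), mean(px2), tolerance = 1e-14)
  # refitting on adjusted values gives a zero slope to machine precision
  expect_lt(abs(suppressWarnings(fit_neh_regression(adj2, neh))$slope), 1e-12)
  # non-estimable regression: pass-through with a warning
  rbad <- fit_neh_regression(px2[1:2], neh[1:2])
  expect_warning(out <- adjust_enrichment(px2, neh, rbad), "not estimable")
  expect_identical(out, px2)
})

test_that("dataset de-biasing flattens every per-timepoint regression and is idempotent", {
  set.seed(123)
  tt <- c(0, 1, 3, 7, 14)
  neh <- sample(10:60, 30, replace = TRUE)
  rows <- lapply(1:30, function(i) {
    px <- taylor_limit_enrichment(0.04, 0.15, tt) - 2e-4 * (neh[i] - 35) +
      rnorm(length(tt), 0, 5e-4)
    data.frame(protein_id = "P1", peptide_sequence = sprintf("PEP%02d", i),
               time_days = tt, i0 = NA_real_, n_eh = neh[i], px = px)
  })
  data <- do.call(rbind, rows)
  db <- debias_dataset(data, scope = "protein")
  # every per-timepoint regression of adjusted values is flat
  for (t0 in tt) {
    at_t <- db$data[db$data$time_days == t0, ]
    reg <- suppressWarnings(fit_neh_regression(at_t$px_adjusted, at_t$n_eh, t0))
    expect_lt(abs(reg$slope), 1e-12)
    expect_gte(reg$p_value, 0.05)
  }
  # per-timepoint means preserved
  for (t0 in tt) {
    at_t <- db$data[db$data$time_days == t0, ]
    expect_equal(mean(at_t$px_adjusted), mean(at_t$px), tolerance = 1e-14)
  }
  # idempotence: a second pass changes nothing (beyond rounding)
  data2 <- db$data
  data2$px <- data2$px_adjusted
  db2 <- debias_dataset(data2, scope = "protein")
  expect_equal(db2$data$px_adjusted, db$data$px_adjusted, tolerance = 1e-12)
  # ids, times and N_EH untouched
  expect_identical(db$data$peptide_sequence, data$peptide_sequence)
  expect_identical(db$data$time_days, data$time_days)
  expect_identical(db$data$n_eh, data$n_eh)
  # audit trail covers all timepoints
  expect_equal(sort(unique(db$regressions$time)), tt)
  expect_true(all(db$regressions$estimable))
})

test_that("a dataset with no N_EH trend passes through unchanged", {
  tt <- c(0, 2, 6)
  rows <- lapply(1:5, function(i) {
    data.frame(protein_id = "P1", peptide_sequence = sprintf("p%d", i),
               time_days = tt, i0 = NA_real_, n_eh = c(10, 20, 30, 40, 50)[i],
               px = taylor_limit_enrichment(0.04, 0.2, tt))
  })
  db <- suppressWarnings(debias_dataset(do.call(rbind, rows)))
  expect_equal(db$data$px_adjusted, db$data$px, tolerance = 1e-13)
})

test_that("undersized groups are skipped with a warning, values passed through", {
  tt <- c(0, 2, 6)
  data <- do.call(rbind, lapply(1:2, function(i)
    data.frame(protein_id = "P1", peptide_sequence = sprintf("p%d", i),
               time_days = tt, i0 = NA_real_, n_eh = c(15, 45)[i],
               px = c(0, 0.01, 0.02) + i * 1e-3)))
  expect_warning(db <- debias_dataset(data), "passed through")
  expect_identical(db$data$px_adjusted, db$data$px)
})

test_that("late-time adjusted enrichment sits at the body-water level", {
  # noiseless N_EH-independent world, k t >> 1
  tt <- c(0, 1, 3, 7, 15, 40)
  neh <- c(12, 22, 37, 51, 60)
  rows <- lapply(seq_along(neh), function(i) {
    px <- taylor_limit_enrichment(0.04, 0.3, tt)
    data.frame(protein_id = "P1", peptide_sequence = sprintf("p%d", i),
               time_days = tt, i0 = NA_real_, n_eh = neh[i], px = px)
  })
  db <- suppressWarnings(debias_dataset(do.call(rbind, rows)))
  late <- db$data[db$data$time_days == 40, ]
  expect_equal(late$px_adjusted, rep(0.04, 5), tolerance = 1e-4)
})
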