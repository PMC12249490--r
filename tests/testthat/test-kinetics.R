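test_that("labeling parameters validate their domain", {
  expect_error(labeling_parameters(0.5), "p_w")
  expect_error(labeling_parameters(0.04, 0.05), "p_h")
  p <- labeling_parameters(0.04)
  expect_equal(p$p_h, 0.000115)
})

test_that("classical plateau follows its closed form", {
  p <- labeling_parameters(0.04, p_h = 0)
  expect_equal(asymptote_classical(1, p, 15), pow_loop(0.96, 15))  # loop oracle
  expect_lt(asymptote_classical(0.5, p, 25), asymptote_classical(0.5, p, 15))
  # p_w -> p_h limit: plateau -> i0_0
  p2 <- labeling_parameters(1e-6, p_h = 1e-6 - 1e-12)
  expect_equal(asymptote_classical(0.5, p2, 40), 0.5, tolerance = 1e-9)
})

test_that("classical RA fit recovers rates from noiseless model data", {
  p <- labeling_parameters(0.04)
  for (k in c(0.02, 0.1, 0.5)) for (n_eh in c(10, 25, 60)) {
    i0 <- make_classical_i0(k, n_eh, p)
    f <- fit_classical_ra(default_times(), i0, 0.4, n_eh, p)
    expect_true(f$converged)
    expect_equal(f$k, k, tolerance = 1e-7)
    expect_equal(f$half_life * f$k, log(2))
  }
})

test_that("RA-space and enrichment-space classical fits agree", {
  p <- labeling_parameters(0.04)
  for (k in c(0.05, 0.2)) for (n_eh in c(12, 40)) {
    i0 <- make_classical_i0(k, n_eh, p)
    px <- extract_enrichment(i0, 0.4, n_eh, p$p_h, mode = "exact_inversion")
    f1 <- fit_classical_ra(default_times(), i0, 0.4, n_eh, p)
    f2 <- fit_classical_px(default_times(), px, n_eh, p)
    expect_equal(f1$k, f2$k, tolerance = 1e-8)
  }
})

test_that("fits are invariant to uniform rescaling of the abundances", {
  p <- labeling_parameters(0.04)
  i0 <- make_classical_i0(0.12, 30, p)
  f1 <- fit_classical_ra(default_times(), i0, 0.4, 30, p)
  f2 <- fit_classical_ra(default_times(), i0 * 3.7, 0.4 * 3.7, 30, p)
  expect_equal(f1$k, f2$k, tolerance = 1e-10)
})

test_that("N_EH-scaled fit recovers rates from its own model and from the first-order curve", {
  p <- labeling_parameters(0.04)
  # self-consistency on Eq.-(7)-style data
  px <- make_eq7_px(0.2, 35, p)
  f <- fit_adjusted(default_times(), px, 35, p)
  expect_equal(f$k, 0.2, tolerance = 1e-7)
  # on N_EH-independent (first-order) enrichment, with natural deuterium
  # absorbed into the reference (p_h = 0), the recovered rate is
  # practically independent of N_EH, unlike the classical fit
  p0 <- labeling_parameters(0.04, 0)
  k_adj <- k_cls <- numeric(0)
  for (n_eh in c(10, 30, 60)) {
    px_t <- taylor_limit_enrichment(0.04, 0.1, default_times())
    k_adj <- c(k_adj, fit_adjusted(default_times(), px_t, n_eh, p0)$k)
    i0 <- predict_monoisotope(px_t, n_eh, 0, 0.4)
    k_cls <- c(k_cls, fit_classical_ra(default_times(), i0, 0.4, n_eh, p0)$k)
  }
  expect_lt(diff(range(k_adj)), 5e-3 * 0.1)           # spread < 0.5% of k
  expect_gt(diff(range(k_cls)), 100 * diff(range(k_adj)))
  expect_equal(k_adj, rep(0.1, 3), tolerance = 2e-2)
})

test_that("degenerate and undersized series are reported, not raised", {
  p <- labeling_parameters(0.04)
  f <- fit_classical_px(c(0), c(0), 20, p)
  expect_false(f$converged)
  expect_equal(f$status, "insufficient_points")
  f2 <- fit_adjusted(numeric(0), numeric(0), 20, p)
  expect_false(f2$converged)
  # constant series at the plateau: no decay information
  A <- asymptote_classical(0.4, p, 20)
  f3 <- fit_classical_ra(default_times(), rep(A, 10), 0.4, 20, p)
  expect_false(f3$converged)
  expect_equal(f3$status, "k_at_bound")
})

test_that("half-life diagnostic ratios reproduce their known values", {
  # the printed reference values correspond to p_h = 0
  p04 <- labeling_parameters(0.04, 0)
  p01 <- labeling_parameters(0.01, 0)
  expect_equal(round(half_life_ratio_classical(15, p04), 2), 0.43)
  expect_equal(round(half_life_ratio_classical(25, p04), 2), 0.38)
  expect_equal(round(half_life_ratio_classical(15, p01), 2), 0.48)
  expect_equal(round(half_life_ratio_classical(25, p01), 2), 0.47)
  expect_equal(round(half_life_ratio_adjusted(15, p04), 4), 0.4953)
  expect_equal(round(half_life_ratio_adjusted(25, p04), 4), 0.4952)
  # N_EH = 1, p_h = 0: both reduce to (p_w/2)/p_w = 1/2 exactly
  expect_equal(half_life_ratio_classical(1, p04), 0.5)
  expect_equal(half_life_ratio_adjusted(1, p04), 0.5)
})

test_that("classical ratio drifts with N_EH while the scaled ratio does not", {
  p <- labeling_parameters(0.04, 0)
  cls <- half_life_ratio_classical(5:100, p)
  expect_true(all(diff(cls) < 0))                  # strictly decreasing
  adj <- half_life_ratio_adjusted(5:100, p)
  expect_lt(max(adj) - min(adj), 1e-3)
  # undefined when the plateau term collapses: p_h = p_w for the classical
  # ratio, p_h = p_w / n_eh for the scaled one
  degenerate <- structure(list(p_w = 0.04, p_h = 0.04),
                          class = "labeling_parameters")
  expect_error(half_life_ratio_classical(15, degenerate), "undefined")
  expect_error(half_life_ratio_adjusted(15, labeling_parameters(0.04, 0.04 / 15)),
               "undefined")
})

test_that("fractional synthesis interpolates between 0 and 1", {
  expect_equal(fractional_synthesis(0.4, 0.4, 0.25), 0)
  expect_equal(fractional_synthesis(0.25, 0.4, 0.25), 1)
  expect_equal(fractional_synthesis((0.4 + 0.25) / 2, 0.4, 0.25), 0.5)
  expect_error(fractional_synthesis(0.3, 0.3, 0.3), "degenerate")
})

test_that("the scaled model's enrichment matches the first-order curve up to N_EH = 400", {
  # second-order deviation is bounded by p_w^2 / 8 (attained near f = 1/2)
  p <- labeling_parameters(0.04, 0)
  tt <- seq(0, 30, by = 0.5)
  for (n_eh in c(5, 25, 100, 400)) {
    px_model <- make_eq7_px(0.1, n_eh, p, times = tt)
    px_taylor <- taylor_limit_enrichment(0.04, 0.1, tt)
    expect_lt(max(abs(px_model - px_taylor)), 1.05 * 0.04^2 / 8)
  }
  expect_equal(taylor_limit_enrichment(0.04, 0.3, 0), 0)
  expect_equal(taylor_limit_enrichment(0.04, 0.3, 1e4), 0.04)
})
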