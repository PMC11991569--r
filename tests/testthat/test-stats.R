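test_that("relative error and CV follow the printed definitions", {
  expect_equal(relative_error(10, 10)$re_pct, 0)
  expect_true(relative_error(10, 10)$acceptable)
  re <- relative_error(9.92, 10)
  expect_equal(re$re_pct, -0.8, tolerance = 1e-12)
  expect_true(re$acceptable)
  re2 <- relative_error(10.4, 10)
  expect_equal(re2$re_pct, 4)
  expect_false(re2$acceptable)
  expect_error(relative_error(10, 0), class = "npvleak_error_invalid_input")

  expect_equal(coefficient_of_variation(100, 1), 1)
  expect_equal(coefficient_of_variation(9.92, 0.16), 100 * 0.16 / 9.92)
  expect_equal(coefficient_of_variation(42, 0), 0)
  expect_error(coefficient_of_variation(0, 1),
               class = "npvleak_error_invalid_input")

  # scale covariance: RE and CV are unchanged by unit rescaling
  c0 <- 3.7
  expect_equal(relative_error(c0 * 9.92, c0 * 10)$re_pct,
               relative_error(9.92, 10)$re_pct)
  expect_equal(coefficient_of_variation(c0 * 9.92, c0 * 0.16),
               coefficient_of_variation(9.92, 0.16))
})

test_that("critical_t reproduces tabulated values and the normal limit", {
  expect_equal(round(critical_t(0.01, 70), 3), 2.648)
  expect_equal(critical_t(0.5, 1), 1, tolerance = 1e-9)  # Cauchy quantile
  expect_equal(critical_t(0.05, 1e6), 1.960, tolerance = 1e-3)
  expect_error(critical_t(0, 10), class = "npvleak_error_invalid_input")
  expect_error(critical_t(0.05, 0), class = "npvleak_error_invalid_input")

  # numeric CDF-inversion oracle across a grid of levels and df
  for (alpha in c(0.1, 0.05, 0.01)) {
    for (df in c(1, 3, 10, 35, 70, 100)) {
      oracle <- stats::uniroot(function(t) stats::pt(t, df) - (1 - alpha / 2),
                               c(0.5, 700), tol = 1e-10)$root
      expect_equal(critical_t(alpha, df), oracle, tolerance = 1e-6)
    }
  }
})

test_that("t_test matches hand-computed and reference results", {
  x <- c(1, 2, 3)
  expect_equal(t_test(x, x)$t, 0)
  expect_false(t_test(x, x)$reject)

  y <- c(1, 2, 4)
  pooled <- t_test(x, y, variant = "pooled_two_sample")
  expect_equal(pooled$t, -0.31623, tolerance = 1e-4)
  expect_identical(pooled$df, 4L)
  ref <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(pooled$t, unname(ref$statistic), tolerance = 1e-12)

  paired <- t_test(x, y, variant = "paired")
  expect_equal(paired$t, -1)
  expect_identical(paired$df, 2L)
  ref_p <- stats::t.test(x, y, paired = TRUE)
  expect_equal(paired$t, unname(ref_p$statistic), tolerance = 1e-12)

  # antisymmetry
  set.seed(1)
  a <- rnorm(12)
  b <- rnorm(12)
  expect_equal(t_test(a, b)$t, -t_test(b, a)$t)

  # degenerate variances
  expect_identical(t_test(c(1, 1), c(2, 2))$t, -Inf)
  expect_true(t_test(c(1, 1), c(2, 2))$reject)
  expect_identical(t_test(c(1, 1), c(1, 1))$t, 0)
  expect_error(t_test(1, 1), class = "npvleak_error_invalid_input")
})

test_that("normality screen behaves on normal and bimodal samples", {
  expect_error(normality_test(c(1, 2)), class = "npvleak_error_invalid_input")
  expect_error(normality_test(rep(1, 10)),
               class = "npvleak_error_invalid_input")

  p_normal <- vapply(1:100, function(s) {
    normality_test(add_noise(rep(0, 500), 1, seed = s))$p_value
  }, numeric(1))
  expect_gte(mean(p_normal > 0.01), 0.98)

  bimodal <- with_seed <- add_noise(rep(c(-3, 3), each = 250), 1, seed = 1)
  expect_lt(normality_test(bimodal)$p_value, 0.01)
})

test_that("validation grid carries the protocol settings", {
  g <- validation_grid()
  expect_identical(nrow(g), 36L)
  ped <- g[g$population == "pediatric", ]
  expect_setequal(ped$v_tid_n_ml, c(10, 50, 100))
  expect_true(all(ped$bias_lpm == 16))
  expect_true(all(g$r_val == 60))
  adult_mand <- g[g$population == "adult" & g$mode == "mandatory", ]
  expect_true(all(adult_mand$r_p == 10 & adult_mand$c_p == 0.1))
  # spontaneous amplitudes reproduce the nominal volume in closed form
  spont <- g[g$mode == "spontaneous", ]
  expect_equal(l_to_ml(2 * spont$a_lps * spont$ti_s / pi), spont$v_tid_n_ml,
               tolerance = 1e-12)
})

test_that("mandatory pump calibration hits the target volume", {
  cell <- validation_grid("pediatric", "mandatory")
  cell <- cell[cell$v_tid_n_ml == 50 & cell$leak_size == "ML", ]
  cfg <- cell_cfg <- npvleak:::cell_config(cell)
  pf <- calibrate_pump_flow(cfg, cell$ti_s, cell$te_s, 50)
  pat <- breath_pattern("mandatory", pf = pf, ti = cell$ti_s, te = cell$te_s,
                        n_breaths = 8, breath_cv = 0)
  sim <- simulate_npv(cfg, pat)
  expect_equal(mean(utils::tail(sim$truth$v_insp_true_ml, 4)), 50,
               tolerance = 0.005)
})

test_that("run_validation produces unbiased, df-70-shaped comparisons", {
  g <- validation_grid("pediatric", "spontaneous")
  g <- g[g$v_tid_n_ml == 50 & g$leak_size == "SL", ]
  res <- run_validation(g, n_samples = 36, breaths_per_sample = 10, seed = 3)
  expect_identical(nrow(res), 1L)
  expect_identical(res$df, 70L)
  expect_equal(res$mean_computed_ml / res$mean_measured_ml, 1,
               tolerance = 0.02)
  expect_equal(res$mean_measured_ml, 50, tolerance = 0.02 * 50)
  expect_false(res$reject)
})

test_that("the pooled test keeps its size under a simulated null", {
  rate <- null_rejection_rate(n_replicates = 300, seed = 2)
  expect_lte(rate, 0.03)
})
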