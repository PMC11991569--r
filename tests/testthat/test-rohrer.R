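test_that("rohrer_pressure evaluates the two-term relation and is odd in flow", {
  sl <- rohrer_coeffs(11.88, 66.88, "leak:SL")
  expect_identical(rohrer_pressure(sl, 0), 0)
  expect_equal(rohrer_pressure(sl, 0.1), 11.88 * 0.1 + 66.88 * 0.01)
  expect_equal(rohrer_pressure(sl, -0.1), -(11.88 * 0.1 + 66.88 * 0.01))
  flows <- seq(-0.5, 0.5, by = 0.01)
  expect_equal(rohrer_pressure(sl, -flows), -rohrer_pressure(sl, flows))
  # strictly increasing whenever a coefficient is positive
  expect_true(all(diff(rohrer_pressure(sl, flows)) > 0))
  expect_true(all(diff(rohrer_pressure(rohrer_coeffs(2, 0), flows)) > 0))
  expect_error(rohrer_pressure(sl, NaN), class = "npvleak_error_invalid_input")
  expect_error(rohrer_coeffs(-1, 2), class = "npvleak_error_invalid_input")
})

test_that("invert_rohrer is the exact inverse, with linear limit and sign symmetry", {
  sl <- rohrer_coeffs(11.88, 66.88)
  expect_equal(invert_rohrer(sl, 1.8568), 0.1, tolerance = 1e-12)
  expect_identical(invert_rohrer(sl, 0), 0)
  expect_equal(invert_rohrer(rohrer_coeffs(2, 0), 1), 0.5)
  expect_error(invert_rohrer(rohrer_coeffs(0, 0), 1),
               class = "npvleak_error_degenerate_channel")
  # continuity at the k_T -> 0 limit
  p <- c(-20, -1, -1e-6, 1e-6, 1, 20)
  expect_lt(max(abs(invert_rohrer(rohrer_coeffs(5, 1e-12), p) -
                    invert_rohrer(rohrer_coeffs(5, 0), p))), 1e-8)
})

test_that("round-trip inversion holds across random coefficients and flows", {
  set.seed(42)
  for (i in 1:200) {
    k_l <- runif(1, 0, 30)
    k_t <- runif(1, 0, 100)
    if (k_l + k_t == 0) k_l <- 1
    co <- rohrer_coeffs(k_l, k_t)
    v_max <- invert_rohrer(co, 50)
    v <- runif(25, -v_max, v_max)
    expect_lt(max(abs(invert_rohrer(co, rohrer_pressure(co, v)) - v)), 1e-10)
  }
})

test_that("fit_rohrer recovers exact coefficients from noise-free records", {
  ml <- rohrer_coeffs(6.12, 32.71, "leak:ML")
  fit <- fit_rohrer(exact_record(ml), label = "leak:ML")
  expect_lt(abs(fit$coefficients$k_l - 6.12), 1e-9)
  expect_lt(abs(fit$coefficients$k_t - 32.71), 1e-9)
  expect_lt(fit$gof$mse, 1e-18)
  expect_equal(fit$gof$nrmse_fit, 1, tolerance = 1e-7)
  expect_equal(fit$gof$nmse_fit, 1, tolerance = 1e-7)
})

test_that("fit_rohrer recovers coefficients within 5% under plateau noise", {
  sl <- rohrer_coeffs(11.88, 66.88)
  rec <- exact_record(sl)
  rec$p_ph_cmh2o <- add_noise(rec$p_ph_cmh2o, 0.02, seed = 7)
  fit <- fit_rohrer(rec)
  expect_lt(abs(fit$coefficients$k_l / 11.88 - 1), 0.05)
  expect_lt(abs(fit$coefficients$k_t / 66.88 - 1), 0.05)
})

test_that("fit_rohrer rejects underdetermined and degenerate records", {
  expect_error(
    fit_rohrer(tibble::tibble(flow_lps = c(0, 0.05, 0.1),
                              p_ph_cmh2o = c(0, 0, 0))),
    class = "npvleak_error_degenerate_fit"
  )
  # only one distinct non-zero flow level
  expect_error(
    fit_rohrer(tibble::tibble(flow_lps = 0.1, p_ph_cmh2o = 1.5)),
    class = "npvleak_error_underdetermined"
  )
  rec1 <- tibble::tibble(flow_lps = c(0, 0.05, 0.1),
                         p_ph_cmh2o = c(0, 0.7, 1.5))
  expect_s3_class(fit_rohrer(rec1), "rohrer_fit")
})

test_that("non-negativity clamp keeps both coefficients admissible", {
  # data from a purely laminar channel with noise pushing k_T negative
  lin <- rohrer_coeffs(8, 0)
  rec <- exact_record(lin)
  rec$p_ph_cmh2o <- add_noise(rec$p_ph_cmh2o, 0.05, seed = 3)
  fit <- fit_rohrer(rec)
  expect_gte(fit$coefficients$k_t, 0)
  expect_gte(fit$coefficients$k_l, 0)
  expect_lt(abs(fit$coefficients$k_l - 8) / 8, 0.05)
})

test_that("goodness_of_fit follows the fit convention (1 = perfect)", {
  obs <- c(1, 2, 3)
  perfect <- goodness_of_fit(obs, obs)
  expect_equal(unlist(perfect), c(mse = 0, nrmse_fit = 1, nmse_fit = 1))
  at_mean <- goodness_of_fit(obs, rep(mean(obs), 3))
  expect_equal(at_mean$nrmse_fit, 0)
  expect_equal(at_mean$nmse_fit, 0)
  g <- goodness_of_fit(obs, c(1, 2, 4))
  expect_equal(g$mse, 1 / 3)
  expect_equal(g$nrmse_fit, 1 - 1 / sqrt(2), tolerance = 1e-12)
  expect_error(goodness_of_fit(c(2, 2, 2), c(1, 2, 3)),
               class = "npvleak_error_undefined_normalization")
})

test_that("fit JSON and characterisation CSV round-trip through files", {
  ml <- rohrer_coeffs(6.12, 32.71, "leak:ML")
  fit <- fit_rohrer(exact_record(ml), label = "leak:ML")
  f <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, f)
  back <- read_fit_json(f)
  expect_equal(back$k_l, fit$coefficients$k_l)
  expect_equal(back$k_t, fit$coefficients$k_t)
  expect_equal(back$label, "leak:ML")

  rec <- exact_record(ml)
  csv <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(
    tibble::tibble(flow_lpm = lps_to_lpm(rec$flow_lps),
                   p_ph_cmh2o = rec$p_ph_cmh2o), csv)
  rec2 <- read_characterization(csv)
  expect_equal(rec2$flow_lps, rec$flow_lps, tolerance = 1e-12)
})

test_that("tidy, glance and predict expose the fit in broom style", {
  fit <- fit_rohrer(exact_record(leak_presets("LL")), label = "leak:LL")
  td <- tidy(fit)
  expect_equal(td$term, c("k_L", "k_T"))
  expect_equal(td$estimate, c(3.66, 17.34), tolerance = 1e-9)
  gl <- glance(fit)
  expect_equal(gl$n_points, 41)
  expect_equal(predict(fit, 0.1), rohrer_pressure(leak_presets("LL"), 0.1),
               tolerance = 1e-9)
})
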