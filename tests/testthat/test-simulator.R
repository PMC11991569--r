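test_that("solve_pharyngeal_node matches closed forms and a grid-search oracle", {
  # everything off -> everything zero
  cfg0 <- circuit_config(0, 60, npt_presets(4), leak_presets("SL"))
  s0 <- solve_pharyngeal_node(cfg0)
  expect_equal(unlist(s0), c(p_ph_cmh2o = 0, v_npt_lps = 0, v_leak_lps = 0,
                             p_npt_cmh2o = 0, residual = 0), tolerance = 1e-9)

  # blocked valve: the whole bias flow crosses NPT and leak
  cfg_inf <- circuit_config(0.2667, Inf, npt_presets(4), leak_presets("SL"))
  s1 <- solve_pharyngeal_node(cfg_inf)
  expect_equal(s1$v_npt_lps, 0.2667, tolerance = 1e-9)
  expect_equal(s1$v_leak_lps, 0.2667, tolerance = 1e-9)
  expect_equal(s1$p_ph_cmh2o,
               rohrer_pressure(leak_presets("SL"), 0.2667), tolerance = 1e-9)

  # finite valve: part of the generator flow escapes through the valve
  cfg <- ped_config()
  s2 <- solve_pharyngeal_node(cfg)
  expect_lt(s2$v_npt_lps, cfg$q_gen)
  for (vr in c(-0.1, 0, 0.15)) {
    p_oracle <- grid_search_node(cfg, v_res = vr)
    expect_equal(solve_pharyngeal_node(cfg, v_res = vr)$p_ph_cmh2o, p_oracle,
                 tolerance = 1e-5)
  }
})

test_that("the compiled stepper agrees with the scalar solver", {
  cfg <- ped_config(leak = leak_presets("ML"))
  v_res <- c(-0.1, -0.02, 0, 0.05, 0.12)
  out <- npvleak:::sim_network_cpp(0L, v_res, 1e-3, cfg$q_gen, cfg$r_val,
                                   cfg$npt$k_l, cfg$npt$k_t,
                                   cfg$leak$k_l, cfg$leak$k_t, 0, 0.1, 0)
  for (i in seq_along(v_res)) {
    s <- solve_pharyngeal_node(cfg, v_res = v_res[i])
    expect_equal(out$p_ph[i], s$p_ph_cmh2o, tolerance = 1e-8)
    expect_equal(out$v_npt[i], s$v_npt_lps, tolerance = 1e-8)
  }
})

test_that("equilibrium sits on the leak curve and rises with bias flow", {
  cfg <- circuit_config(lpm_to_lps(16), Inf, npt_presets(4),
                        leak_presets("SL"))
  eq <- equilibrium(cfg)
  expect_equal(eq$v_bias_lps, 16 / 60, tolerance = 1e-9)
  expect_equal(eq$p_bar_cmh2o, 7.925, tolerance = 1e-3)

  expect_equal(unlist(equilibrium(ped_config(bias_lpm = 0))),
               c(v_bias_lps = 0, p_bar_cmh2o = 0), tolerance = 1e-9)

  p_bars <- vapply(seq(2, 30, by = 4), function(lpm)
    equilibrium(ped_config(bias_lpm = lpm))$p_bar_cmh2o, numeric(1))
  expect_true(all(diff(p_bars) > 0))
})

test_that("apnoea holds the equilibrium and conservation is exact", {
  cfg <- ped_config()
  sim <- simulate_npv(cfg, breath_pattern("apnea", ti = 1, te = 2,
                                          n_breaths = 2))
  wf <- sim$waveforms
  expect_lt(max(abs(wf$v_res_lps)), 1e-9)
  expect_lt(max(abs(wf$v_npt_lps - wf$v_leak_lps)), 1e-9)
  expect_lt(max(abs(wf$v_npt_lps - (wf$v_leak_lps + wf$v_res_lps))), 1e-9)
})

test_that("spontaneous simulations deliver the half-sine closed-form volume", {
  cfg <- ped_config()
  pat <- breath_pattern("spontaneous", a = 0.2, ti = 1, te = 2, n_breaths = 3)
  sim <- simulate_npv(cfg, pat)
  expect_equal(sim$truth$v_insp_true_l, rep(2 * 0.2 / pi, 3),
               tolerance = 1e-4)
  # per-sample conservation on the clean record
  wf <- sim$waveforms
  expect_lt(max(abs(wf$v_npt_lps - (wf$v_leak_lps + wf$v_res_lps))), 1e-9)
  # zero net volume per breath
  net <- sum(wf$v_res_lps) / sim$emit_hz
  expect_lt(abs(net), 1e-4)
})

test_that("spontaneous phase plane collapses to a segment when the tube dominates", {
  cfg <- ped_config(leak = leak_presets("SL"))
  pat <- breath_pattern("spontaneous", a = 0.1, ti = 1, te = 2, n_breaths = 4)
  sim <- simulate_npv(cfg, pat)
  wf <- sim$waveforms
  expect_lt(sd(wf$v_npt_lps) / sd(wf$v_res_lps), 0.2)
  expect_lt(phase_axis_ratio(wf), 0.1)
})

test_that("mandatory simulations trace a closed clockwise hysteresis loop", {
  cfg <- circuit_config(lpm_to_lps(32), 60, npt_presets(8),
                        leak_presets("ML"), r_p = 10, c_p = 0.1)
  pat <- breath_pattern("mandatory", pf = 0.3, ti = 1.5, te = 3,
                        n_breaths = 6)
  sim <- simulate_npv(cfg, pat)
  wf <- sim$waveforms
  expect_lt(max(abs(wf$v_npt_lps - (wf$v_leak_lps + wf$v_res_lps))), 1e-9)

  # last breath is in cycling steady state: the loop closes on itself
  nb <- nrow(wf) / 6
  last <- wf[(5 * nb + 1):(6 * nb), ]
  diam <- max(dist(cbind(last$p_ph_cmh2o, last$v_npt_lps)))
  gap <- sqrt((last$p_ph_cmh2o[1] - last$p_ph_cmh2o[nb])^2 +
              (last$v_npt_lps[1] - last$v_npt_lps[nb])^2)
  expect_lt(gap, 0.01 * diam)

  loop <- phase_loop_area(last)
  expect_lt(loop$area, 0)
  expect_identical(loop$direction, "clockwise")
  expect_gt(abs(loop$area), 1e-4)

  # respiratory flow crosses zero at the breath boundary
  expect_lt(min(abs(last$v_res_lps)), 5e-3)
})

test_that("characterization_protocol reproduces the stepped grid exactly when clean", {
  cfg <- ped_config(leak = leak_presets("ML"))
  rec <- characterization_protocol(cfg)
  expect_identical(nrow(rec), 41L)
  expect_equal(rec$flow_lps, seq(0, 20, by = 0.5) / 60, tolerance = 1e-12)
  expect_equal(rec$p_ph_cmh2o,
               rohrer_pressure(cfg$leak, rec$flow_lps), tolerance = 1e-12)

  nz <- noise_model(0.02, 0.002, seed = 11)
  r1 <- characterization_protocol(cfg, noise = nz)
  r2 <- characterization_protocol(cfg, noise = nz)
  expect_identical(r1, r2)
  expect_false(identical(r1$p_ph_cmh2o, rec$p_ph_cmh2o))
})

test_that("seeded noise is deterministic, unbiased and leaves truth clean", {
  x <- rep(1, 1e5)
  expect_identical(add_noise(x, 0, 99), x)
  n1 <- add_noise(x, 0.05, 99)
  expect_identical(n1, add_noise(x, 0.05, 99))
  expect_lt(abs(sd(n1 - x) / 0.05 - 1), 0.02)

  cfg <- ped_config()
  pat <- breath_pattern("spontaneous", a = 0.1, ti = 1, te = 2, n_breaths = 2)
  nz <- noise_model(seed = 5)
  s1 <- simulate_npv(cfg, pat, noise = nz)
  s2 <- simulate_npv(cfg, pat, noise = nz)
  expect_identical(s1$waveforms, s2$waveforms)
  clean <- simulate_npv(cfg, pat)
  # ground-truth channels are untouched by sensor noise (breath jitter off)
  pat0 <- breath_pattern("spontaneous", a = 0.1, ti = 1, te = 2,
                         n_breaths = 2, breath_cv = 0)
  s3 <- simulate_npv(cfg, pat0, noise = nz)
  expect_equal(s3$waveforms$v_res_lps, clean$waveforms$v_res_lps)
  expect_equal(s3$waveforms$p_ph_true_cmh2o, clean$waveforms$p_ph_cmh2o)
})

test_that("simulation guards reject unstable or inconsistent settings", {
  cfg <- ped_config()
  pat <- breath_pattern("spontaneous", a = 0.1, ti = 1, te = 2, n_breaths = 1)
  expect_error(simulate_npv(cfg, pat, dt = 0.05),
               class = "npvleak_error_stability")
  expect_error(simulate_npv(ped_config(r_p = 0),
                            breath_pattern("mandatory", pf = 0.1)),
               class = "npvleak_error_invalid_input")
  expect_error(breath_pattern("spontaneous", a = 0),
               class = "npvleak_error_invalid_input")
  expect_error(circuit_config(-1, 60, npt_presets(4), leak_presets("SL")),
               class = "npvleak_error_invalid_input")
})
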