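#' Relative error against a nominal value
#'
#' `RE (%) = 100 * (M - nominal) / nominal`; a magnitude below 3% is the
#' conventional acceptability bound for a bench volume delivery.
#'
#' @param mean_value Measured mean (same units as `nominal`).
#' @param nominal Nominal (set) value, `> 0`.
#' @param tol_pct Acceptability bound in percent (default 3).
#' @return Tibble with `re_pct` and logical `acceptable`.
#' @examples
#' relative_error(9.92, 10)
#' @export
relative_error <- function(mean_value, nominal, tol_pct = 3) {
  if (any(!is.finite(nominal)) || any(nominal <= 0)) {
    abort("`nominal` must be positive.", class = "npvleak_error_invalid_input")
  }
  re <- 100 * (mean_value - nominal) / nominal
  tibble(re_pct = re, acceptable = abs(re) < tol_pct)
}

#' Coefficient of variation
#'
#' `CV (%) = 100 * SD / M`, a reproducibility measure.
#'
#' @param mean_value Mean, non-zero.
#' @param sd Standard deviation, `>= 0`.
#' @return Numeric vector of CV percentages.
#' @examples
#' coefficient_of_variation(9.92, 0.16)
#' @export
coefficient_of_variation <- function(mean_value, sd) {
  if (any(!is.finite(mean_value)) || any(mean_value == 0)) {
    abort("`mean_value` must be finite and non-zero.",
          class = "npvleak_error_invalid_input")
  }
  if (any(sd < 0)) {
    abort("`sd` must be non-negative.", class = "npvleak_error_invalid_input")
  }
  100 * sd / mean_value
}

#' Two-tailed Student-t critical value
#'
#' Quantile of the t distribution at `1 - alpha/2`; with 70 degrees of
#' freedom and `alpha = 0.01` this is 2.648.
#'
#' @param alpha Two-tailed significance level in (0, 1).
#' @param df Degrees of freedom, `>= 1`.
#' @return The critical value `t*`.
#' @examples
#' critical_t(0.01, 70)
#' @export
critical_t <- function(alpha, df) {
  if (!is.numeric(alpha) || any(alpha <= 0) || any(alpha >= 1)) {
    abort("`alpha` must be in (0, 1).", class = "npvleak_error_invalid_input")
  }
  if (!is.numeric(df) || any(df < 1)) {
    abort("`df` must be >= 1.", class = "npvleak_error_invalid_input")
  }
  qt(1 - alpha / 2, df)
}

#' Student t test between two equal-sized arms
#'
#' The pooled two-sample variant uses the combined estimate of the
#' variance and `df = 2n - 2` (70 for two arms of 36); the paired variant
#' tests the mean of the within-pair differences with `df = n - 1`.  The
#' null hypothesis (both arms drawn from the same population) is rejected
#' when `|t|` exceeds the critical value at the requested level.  When
#' neither arm varies, `t` is 0 for equal means and signed infinity
#' otherwise.
#'
#' @param x,y Numeric vectors of equal length `n >= 2`.
#' @param alpha Two-tailed significance level.
#' @param variant `"pooled_two_sample"` or `"paired"`.
#' @return One-row tibble: `t`, `df`, `alpha`, `t_crit`, `reject`,
#'   `variant`, `n`.
#' @examples
#' t_test(c(1, 2, 3), c(1, 2, 4), variant = "pooled_two_sample")
#' @export
t_test <- function(x, y, alpha = 0.01,
                   variant = c("pooled_two_sample", "paired")) {
  variant <- match.arg(variant)
  n <- length(x)
  if (length(y) != n || n < 2L || any(!is.finite(x)) || any(!is.finite(y))) {
    abort("`x` and `y` must be finite vectors of equal length n >= 2.",
          class = "npvleak_error_invalid_input")
  }
  if (variant == "pooled_two_sample") {
    df <- 2L * n - 2L
    sp2 <- ((n - 1) * stats::var(x) + (n - 1) * stats::var(y)) / df
    delta <- mean(x) - mean(y)
    t <- if (sp2 == 0) {
      if (delta == 0) 0 else sign(delta) * Inf
    } else {
      delta / sqrt(sp2 * 2 / n)
    }
  } else {
    d <- x - y
    df <- n - 1L
    sdd <- sd(d)
    t <- if (sdd == 0) {
      if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    } else {
      mean(d) / (sdd / sqrt(n))
    }
  }
  t_crit <- critical_t(alpha, df)
  tibble(t = t, df = df, alpha = alpha, t_crit = t_crit,
         reject = abs(t) > t_crit, variant = variant, n = n)
}

#' Shapiro-Wilk normality screen
#'
#' @param x Numeric sample, `3 <= n <= 5000`, not constant.
#' @return One-row tibble with the `W` statistic and `p_value`.
#' @export
normality_test <- function(x) {
  if (!is.numeric(x) || length(x) < 3L || length(x) > 5000L ||
      any(!is.finite(x)) || sd(x) == 0) {
    abort("`x` must be a non-constant numeric sample with 3 <= n <= 5000.",
          class = "npvleak_error_invalid_input")
  }
  s <- shapiro.test(x)
  tibble(W = unname(s$statistic), p_value = s$p.value)
}

#' Validation experiment grids
#'
#' The bench validation crosses nominal tidal volumes (with their tube
#' sizes and, for mandatory breaths, patient mechanics) with the three
#' leak sizes, for paediatric (bias 16 L/min) and adult (bias 32 L/min)
#' settings, valve resistance 60 cmH2O.s/L throughout.  Inspiratory times
#' grow with the target volume inside the protocol ranges (0.5--1 s
#' paediatric, 1--2 s adult) and the expiratory time is twice the
#' inspiratory time (I:E = 1:2).  For spontaneous breathing the flow
#' amplitude follows from the half-sine closed form
#' `A = pi * V_TID / (2 * TI)`; for mandatory breaths the pumped-flow
#' amplitude is calibrated numerically per cell (see
#' [calibrate_pump_flow()]).
#'
#' @param population `"pediatric"`, `"adult"` or both.
#' @param mode `"spontaneous"`, `"mandatory"` or both.
#' @return Tibble with one row per validation cell.
#' @export
validation_grid <- function(population = c("pediatric", "adult"),
                            mode = c("spontaneous", "mandatory")) {
  population <- match.arg(population, several.ok = TRUE)
  mode <- match.arg(mode, several.ok = TRUE)
  base <- dplyr::bind_rows(
    tibble(population = "pediatric", v_tid_n_ml = c(10, 50, 100),
           tube_id_mm = c(3, 4, 5), ti_s = c(0.5, 0.75, 1), bias_lpm = 16,
           r_p_mand = c(100, 50, 20), c_p_mand_l = c(0.010, 0.020, 0.050)),
    tibble(population = "adult", v_tid_n_ml = c(200, 300, 400),
           tube_id_mm = c(7, 8, 9), ti_s = c(1, 1.5, 2), bias_lpm = 32,
           r_p_mand = 10, c_p_mand_l = 0.100)
  )
  grid <- tidyr::expand_grid(
    base, mode = mode, leak_size = c("SL", "ML", "LL")
  )
  grid <- grid[grid$population %in% population, ]
  # I:E of 1:2; mandatory breaths additionally leave at least three
  # expiratory time constants (r_p * c_p) so the lung empties between breaths
  grid$te_s <- ifelse(grid$mode == "mandatory",
                      pmax(2 * grid$ti_s, 3 * grid$r_p_mand * grid$c_p_mand_l),
                      2 * grid$ti_s)
  grid$r_val <- 60
  grid$r_p <- ifelse(grid$mode == "mandatory", grid$r_p_mand, 0)
  grid$c_p <- ifelse(grid$mode == "mandatory", grid$c_p_mand_l, 0.1)
  grid$a_lps <- ifelse(grid$mode == "spontaneous",
                       pi * ml_to_l(grid$v_tid_n_ml) / (2 * grid$ti_s), 0)
  grid[c("population", "mode", "v_tid_n_ml", "tube_id_mm", "leak_size",
         "bias_lpm", "r_val", "ti_s", "te_s", "r_p", "c_p", "a_lps")]
}

cell_config <- function(cell) {
  circuit_config(
    q_gen = lpm_to_lps(cell$bias_lpm), r_val = cell$r_val,
    npt = npt_presets(cell$tube_id_mm), leak = leak_presets(cell$leak_size),
    r_p = cell$r_p, c_p = cell$c_p
  )
}

#' Calibrate the mandatory pumped-flow amplitude for a target volume
#'
#' Finds the pumped-flow amplitude `pf` such that a clean mandatory
#' simulation delivers the target inspired volume per breath (mean of the
#' final breaths, once the lung volume has reached its cycling steady
#' state).  Monotone in `pf`, solved by root finding.
#'
#' @param config A [circuit_config()] with patient mechanics set.
#' @param ti,te Inspiratory and expiratory durations, s.
#' @param target_ml Target inspired volume, mL.
#' @param n_breaths Breaths per trial simulation.
#' @param dt Simulation step, s.
#' @param tol_ml Absolute tolerance on the delivered volume, mL.
#' @return The calibrated `pf` in L/s.
#' @export
calibrate_pump_flow <- function(config, ti, te, target_ml, n_breaths = 8,
                                dt = 0.001, tol_ml = 0.05) {
  delivered <- function(pf) {
    pat <- breath_pattern("mandatory", pf = pf, ti = ti, te = te,
                          n_breaths = n_breaths, breath_cv = 0)
    sim <- simulate_npv(config, pat, dt = dt, noise = NULL)
    tail_b <- utils::tail(sim$truth$v_insp_true_ml, max(3L, n_breaths %/% 2))
    mean(tail_b) - target_ml
  }
  root <- stats::uniroot(delivered, interval = c(1e-4, 0.5),
                         extendInt = "upX", tol = 1e-6)
  root$root
}

seed_stream <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483629)
}

# Per-breath tidal volumes of one monitored record, averaged into a sample
# value.  Segments are matched to nominal breath windows by the midpoint of
# their inspiratory window; windows without a detected breath contribute 0.
sample_vtid_ml <- function(wf, breath_t, flow = "v_res_lps", ...) {
  segs <- segment_breaths(wf, flow = flow, ...)
  n_b <- length(breath_t) - 1L
  vals <- numeric(n_b)
  if (nrow(segs)) {
    mid <- (segs$t_insp_start_s + segs$t_insp_end_s) / 2
    win <- findInterval(mid, breath_t)
    ok <- win >= 1L & win <= n_b
    agg <- tapply(segs$v_tid_ml[ok], win[ok], sum)
    vals[as.integer(names(agg))] <- agg
  }
  mean(vals)
}

#' Run the scaled-down bench validation experiment
#'
#' For every cell of the grid, repeated measurements are simulated: each
#' sample is an independent simulated record of `breaths_per_sample`
#' breaths with sensor noise, a per-breath amplitude jitter
#' (`breath_cv` of the pattern) and a per-sample amplitude drift
#' (`sample_cv`) emulating the delivery reproducibility and
#' between-measurement drift of a breathing simulator.  The computed arm
#' runs the leak-compensation algorithm on the monitored (noisy) pressure
#' and NPT flow; the measured arm plays the role of the gold-standard
#' tracheal flow sensor, reading the simulator's true respiratory flow
#' through the same sensor-noise model.  Both arms segment and integrate
#' breaths identically, and each sample value is the mean tidal volume
#' over its record.  Cells are compared with the pooled two-sample t test
#' (`df = 2n - 2`).
#'
#' @param grid Tibble from [validation_grid()] (or a subset of its rows).
#' @param n_samples Samples per arm and cell (default 36, giving df 70).
#' @param breaths_per_sample Breaths averaged into one sample (default 50,
#'   a desk-scale stand-in for long bench records).
#' @param noise Sensor [noise_model()]; its seed is re-derived per sample.
#' @param sample_cv Relative sd of the per-sample amplitude drift.
#' @param breath_cv Relative sd of the per-breath amplitude jitter.
#' @param alpha Significance level of the cell t tests.
#' @param dt,emit_hz Simulation step and emitted sample rate.
#' @param seed Master seed; every random stream derives from it.
#' @param progress Print one line per cell.
#' @return Tibble with one row per cell: arm means and SDs (mL), the t
#'   statistic, degrees of freedom, critical value and rejection flag.
#' @export
run_validation <- function(grid, n_samples = 36, breaths_per_sample = 50,
                           noise = noise_model(), sample_cv = 0.02,
                           breath_cv = 0.008, alpha = 0.01,
                           dt = 0.001, emit_hz = 100, seed = 1,
                           progress = FALSE) {
  purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    cell <- grid[i, ]
    cfg <- cell_config(cell)
    pf <- if (cell$mode == "mandatory") {
      calibrate_pump_flow(cfg, cell$ti_s, cell$te_s, cell$v_tid_n_ml, dt = dt)
    } else {
      0
    }
    t_breath <- cell$ti_s + cell$te_s
    breath_t <- seq(0, breaths_per_sample * t_breath, by = t_breath)

    drift <- with_local_seed(seed_stream(seed, i * 1000L),
                             1 + rnorm(n_samples, 0, sample_cv))
    drift <- pmax(drift, 0.5)

    arms <- purrr::map(seq_len(n_samples), function(s) {
      s_seed <- seed_stream(seed, i * 1000L + s)
      pat <- if (cell$mode == "spontaneous") {
        breath_pattern("spontaneous", a = cell$a_lps * drift[s],
                       ti = cell$ti_s, te = cell$te_s,
                       n_breaths = breaths_per_sample,
                       breath_cv = breath_cv)
      } else {
        breath_pattern("mandatory", pf = pf * drift[s],
                       ti = cell$ti_s, te = cell$te_s,
                       n_breaths = breaths_per_sample,
                       breath_cv = breath_cv)
      }
      sim <- simulate_npv(cfg, pat, dt = dt,
                          noise = noise_model(noise$sd_pressure,
                                              noise$sd_flow, s_seed),
                          emit_hz = emit_hz)
      wf <- sim$waveforms
      # computed arm: the algorithm on the monitored noisy channels
      comp_wf <- add_respiratory_flow(add_leak_flow(
        wf[c("time_s", "p_ph_cmh2o", "v_npt_lps")], cfg$leak))
      v_c <- sample_vtid_ml(comp_wf, breath_t)
      # measured arm: gold-standard flow sensor on the true respiratory flow
      gold <- tibble(
        time_s = wf$time_s,
        v_res_lps = add_noise(wf$v_res_lps, noise$sd_flow,
                              seed_stream(s_seed, 7L))
      )
      v_m <- sample_vtid_ml(gold, breath_t)
      c(measured = v_m, computed = v_c)
    })
    x <- vapply(arms, `[[`, numeric(1), "measured")
    y <- vapply(arms, `[[`, numeric(1), "computed")
    tt <- t_test(x, y, alpha = alpha, variant = "pooled_two_sample")
    row <- dplyr::bind_cols(
      cell[c("population", "mode", "v_tid_n_ml", "tube_id_mm", "leak_size")],
      tibble(
        n = n_samples,
        mean_measured_ml = mean(x), sd_measured_ml = sd(x),
        mean_computed_ml = mean(y), sd_computed_ml = sd(y),
        t = tt$t, df = tt$df, t_crit = tt$t_crit, reject = tt$reject
      )
    )
    if (progress) {
      message(sprintf(
        "%s %s V_TID_N=%g mL %s: measured %.2f (%.2f), computed %.2f (%.2f), t=%.3f",
        cell$population, cell$mode, cell$v_tid_n_ml, cell$leak_size,
        row$mean_measured_ml, row$sd_measured_ml,
        row$mean_computed_ml, row$sd_computed_ml, row$t))
    }
    row
  })
}

#' Type-I error of the pooled t test under a simulated null
#'
#' Draws both arms from the same generative model used for the validation
#' samples: a per-sample amplitude drift and per-breath amplitude jitter
#' scale the true breath volumes of one clean simulated record, and the
#' sensor noise of the gold-standard sensor propagates linearly through
#' the fixed trapezoidal integration windows (so its per-breath
#' contribution is drawn exactly from its analytic normal distribution).
#' Since both arms are identically distributed, the pooled test at level
#' `alpha` should reject in about `alpha` of replicates.
#'
#' @param n_replicates Number of replicate experiments.
#' @param n_per_arm Samples per arm (36 gives df 70).
#' @param breaths_per_sample Breaths averaged per sample.
#' @param noise Sensor [noise_model()].
#' @param sample_cv,breath_cv Amplitude variability as in
#'   [run_validation()].
#' @param alpha Test level.
#' @param seed Seed.
#' @return Rejection rate over the replicates.
#' @export
null_rejection_rate <- function(n_replicates = 1000, n_per_arm = 36,
                                breaths_per_sample = 50,
                                noise = noise_model(), sample_cv = 0.02,
                                breath_cv = 0.008, alpha = 0.01, seed = 1) {
  cell <- validation_grid("pediatric", "spontaneous")
  cell <- cell[cell$v_tid_n_ml == 50 & cell$leak_size == "ML", ]
  cfg <- cell_config(cell)
  pat <- breath_pattern("spontaneous", a = cell$a_lps, ti = cell$ti_s,
                        te = cell$te_s, n_breaths = breaths_per_sample,
                        breath_cv = 0)
  sim <- simulate_npv(cfg, pat, noise = NULL)
  segs <- segment_breaths(sim$waveforms)
  v0 <- segs$v_tid_ml
  dt_e <- 1 / sim$emit_hz
  # sd of the trapezoidal integral of iid sensor noise over each window
  m <- segs$insp_end_idx - segs$insp_start_idx + 1L
  sd_int_ml <- l_to_ml(noise$sd_flow * dt_e * sqrt(pmax(m - 1.5, 1)))
  nb <- length(v0)

  with_local_seed(seed, {
    n_col <- n_replicates * 2L * n_per_arm
    z_s <- rnorm(n_col, 0, sample_cv)
    z_b <- matrix(rnorm(nb * n_col, 0, breath_cv), nrow = nb)
    e <- matrix(rnorm(nb * n_col), nrow = nb) * sd_int_ml
    vals <- colMeans(v0 * (1 + z_b) + e) * (1 + z_s)
    arms <- matrix(vals, nrow = n_per_arm)  # columns: rep1 x, rep1 y, ...
    rejects <- vapply(seq_len(n_replicates), function(r) {
      t_test(arms[, 2L * r - 1L], arms[, 2L * r], alpha = alpha)$reject
    }, logical(1))
    mean(rejects)
  })
}
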