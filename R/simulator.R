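#' Circuit configuration of the ventilation bench
#'
#' Lumped-parameter (electrical-analog) description of the bench: a
#' free-flow oxygen delivery device modelled as a Norton source (constant
#' generator flow `q_gen` in parallel with a linear valve resistance
#' `r_val`), a nasopharyngeal tube and a leak channel each following the
#' Rohrer relation, and a patient branch that is either an ideal flow
#' generator (spontaneous breathing) or a series resistance--compliance
#' load `r_p`, `c_p` (mandatory breaths).  Atmospheric pressure is the
#' zero reference.
#'
#' @param q_gen Generator bias flow, L/s, `>= 0`.
#' @param r_val Valve resistance, cmH2O.s/L, `> 0`; `Inf` blocks the valve.
#' @param npt NPT [rohrer_coeffs()].
#' @param leak Leak-channel [rohrer_coeffs()].
#' @param r_p Patient inspiratory resistance, cmH2O.s/L (mandatory mode).
#' @param c_p Patient compliance, L/cmH2O (mandatory mode).
#' @return An object of class `circuit_config`.
#' @examples
#' circuit_config(q_gen = lpm_to_lps(16), r_val = 60,
#'                npt = npt_presets(4.0), leak = leak_presets("SL"))
#' @export
circuit_config <- function(q_gen, r_val, npt, leak, r_p = 0, c_p = 0.1) {
  if (!is.numeric(q_gen) || length(q_gen) != 1L || !is.finite(q_gen) || q_gen < 0) {
    abort("`q_gen` must be a single finite non-negative number (L/s).",
          class = "npvleak_error_invalid_input")
  }
  if (!is.numeric(r_val) || length(r_val) != 1L || is.na(r_val) || r_val <= 0) {
    abort("`r_val` must be positive (Inf allowed).",
          class = "npvleak_error_invalid_input")
  }
  check_coeffs(npt)
  check_coeffs(leak, require_usable = TRUE)
  if (!is.numeric(r_p) || length(r_p) != 1L || !is.finite(r_p) || r_p < 0) {
    abort("`r_p` must be finite and non-negative.",
          class = "npvleak_error_invalid_input")
  }
  if (!is.numeric(c_p) || length(c_p) != 1L || !is.finite(c_p) || c_p <= 0) {
    abort("`c_p` must be finite and positive.",
          class = "npvleak_error_invalid_input")
  }
  structure(
    list(q_gen = q_gen, r_val = r_val, npt = npt, leak = leak,
         r_p = r_p, c_p = c_p, p_atm = 0),
    class = "circuit_config"
  )
}

#' @export
print.circuit_config <- function(x, ...) {
  cat(sprintf(
    "<circuit_config> bias %.3g L/min, R_VAL %.3g; NPT (%.3g, %.3g); leak (%.3g, %.3g); R_P %.3g, C_P %.3g L/cmH2O\n",
    lps_to_lpm(x$q_gen), x$r_val, x$npt$k_l, x$npt$k_t,
    x$leak$k_l, x$leak$k_t, x$r_p, x$c_p))
  invisible(x)
}

#' Default NPT Rohrer coefficients by tube internal diameter
#'
#' Synthetic coefficients for the six endotracheal tube sizes used as
#' nasopharyngeal tubes (3.0--5.0 mm paediatric, 7.0--9.0 mm adult).  Both
#' terms follow the d^-4 dependence of a Poiseuille (laminar) and an
#' orifice (turbulent) loss, multiplied by a curvature factor for a tube
#' bent into the nasopharynx and by the effective tube length: adult tubes
#' run about 30--34 cm while paediatric nasopharyngeal tubes are trimmed
#' close to the naris--pharynx insertion depth (about 12 cm for a 3.0 mm
#' neonatal tube).  The scale is chosen so that the 4.0 mm tube is much
#' more resistive than the leak channels at a paediatric bias flow, the
#' regime in which the NPT flow barely oscillates during spontaneous
#' breathing.  These are fixtures for simulation, not measured tube data.
#'
#' @param id_mm Tube internal diameter in millimetres.
#' @return A [rohrer_coeffs()] object.
#' @examples
#' npt_presets(4.0)
#' @export
npt_presets <- function(id_mm) {
  if (!is.numeric(id_mm) || length(id_mm) != 1L || !is.finite(id_mm) || id_mm <= 0) {
    abort("`id_mm` must be a single positive number.",
          class = "npvleak_error_invalid_input")
  }
  sizes <- c(3, 4, 5, 7, 8, 9)
  lengths_m <- c(0.12, 0.20, 0.24, 0.30, 0.32, 0.34)
  l_eff <- stats::approx(sizes, lengths_m, xout = id_mm, rule = 2)$y
  scale <- (l_eff / 0.20) / id_mm^4
  rohrer_coeffs(
    k_l = 9900 * scale,
    k_t = 86000 * scale,
    label = sprintf("NPT:%.1fmm", id_mm)
  )
}

#' Breathing pattern driving the simulator
#'
#' In `spontaneous` mode the patient branch is an ideal flow generator
#' prescribing the respiratory flow: a positive half-sine (or rectangle)
#' of amplitude `a` over the inspiratory time `ti`, followed by a negative
#' lobe over `te` scaled by `ti/te` so each breath has zero net volume.
#' In `mandatory` mode the operator's pumped flow of amplitude `pf` is
#' injected at the source node during `ti` and the passive patient branch
#' (`r_p`, `c_p`) responds.  `apnea` holds the bench at equilibrium.
#' `breath_cv` adds a per-breath amplitude jitter (lognormal-free, simple
#' Gaussian multiplier) emulating the delivery reproducibility of a
#' breathing simulator (coefficient of variation about 0.8%); it is only
#' active when the simulation is given a noise model, which carries the
#' seed.
#'
#' @param mode One of `"apnea"`, `"spontaneous"`, `"mandatory"`.
#' @param a Inspiratory flow amplitude, L/s (spontaneous).
#' @param pf Pumped flow amplitude, L/s (mandatory).
#' @param ti,te Inspiratory and expiratory durations, s.
#' @param n_breaths Number of breaths (or apnoea cycles).
#' @param profile `"half_sine"` or `"rectangular"`.
#' @param breath_cv Relative sd of the per-breath amplitude multiplier.
#' @return An object of class `breath_pattern`.
#' @export
breath_pattern <- function(mode = c("spontaneous", "mandatory", "apnea"),
                           a = 0, pf = 0, ti = 1, te = 2, n_breaths = 10,
                           profile = c("half_sine", "rectangular"),
                           breath_cv = 0.008) {
  mode <- match.arg(mode)
  profile <- match.arg(profile)
  if (ti <= 0 || te <= 0) {
    abort("`ti` and `te` must be positive.",
          class = "npvleak_error_invalid_input")
  }
  if (a < 0 || pf < 0 || breath_cv < 0) {
    abort("Amplitudes and `breath_cv` must be non-negative.",
          class = "npvleak_error_invalid_input")
  }
  if (mode == "spontaneous" && a == 0) {
    abort("Spontaneous mode needs `a` > 0.",
          class = "npvleak_error_invalid_input")
  }
  if (mode == "mandatory" && pf == 0) {
    abort("Mandatory mode needs `pf` > 0.",
          class = "npvleak_error_invalid_input")
  }
  structure(
    list(mode = mode, a = a, pf = pf, ti = ti, te = te,
         n_breaths = as.integer(n_breaths), profile = profile,
         breath_cv = breath_cv),
    class = "breath_pattern"
  )
}

#' Sensor-noise model
#'
#' Additive i.i.d. Gaussian noise applied to the emitted pressure and flow
#' channels (a surrogate for transducer noise).  All randomness of a
#' simulation flows through the single `seed`.  Defaults are roughly 0.2%
#' of a +-25.4 cmH2O pressure transducer full scale and a small fraction
#' of the flow full scale.
#'
#' @param sd_pressure Pressure noise sd, cmH2O.
#' @param sd_flow Flow noise sd, L/s.
#' @param seed Integer seed.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(sd_pressure = 0.05, sd_flow = 0.002, seed = 1L) {
  if (sd_pressure < 0 || sd_flow < 0) {
    abort("Noise standard deviations must be non-negative.",
          class = "npvleak_error_invalid_input")
  }
  structure(list(sd_pressure = sd_pressure, sd_flow = sd_flow,
                 seed = as.integer(seed)),
            class = "noise_model")
}

# evaluate code with a local RNG state so callers' streams are untouched
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Add seeded Gaussian noise to a signal
#'
#' @param x Numeric vector.
#' @param sd Noise standard deviation, in the units of `x`.
#' @param seed Integer seed; the surrounding RNG state is not disturbed.
#' @return `x` plus noise (identical to `x` when `sd = 0`).
#' @export
add_noise <- function(x, sd, seed) {
  if (!is.numeric(sd) || sd < 0) {
    abort("`sd` must be non-negative.", class = "npvleak_error_invalid_input")
  }
  if (sd == 0) return(x)
  with_local_seed(seed, x + rnorm(length(x), 0, sd))
}

#' Solve the algebraic pharyngeal-node system
#'
#' Given the instantaneous respiratory flow drawn by the patient and any
#' pumped flow injected at the source, solves the nonlinear network for
#' the pharyngeal pressure by scalar root finding (the Kirchhoff current
#' residual is strictly decreasing in the node pressure, so the solution
#' is unique).  All branch equations are satisfied to better than 1e-9 in
#' native units.
#'
#' @param config A [circuit_config()].
#' @param v_res Respiratory flow at this instant, L/s (positive into the
#'   patient).
#' @param pump Pumped flow injected at the source node, L/s.
#' @return One-row tibble with `p_ph_cmh2o`, `v_npt_lps`, `v_leak_lps`,
#'   `p_npt_cmh2o` and the Kirchhoff `residual`.
#' @export
solve_pharyngeal_node <- function(config, v_res = 0, pump = 0) {
  stopifnot(inherits(config, "circuit_config"))
  if (!is.finite(v_res) || !is.finite(pump)) {
    abort("`v_res` and `pump` must be finite.",
          class = "npvleak_error_invalid_input")
  }
  g <- function(p) {
    v_leak <- invert_rohrer(config$leak, p)
    v_npt <- v_leak + v_res
    p_src <- p + rohrer_pressure(config$npt, v_npt)
    valve <- if (is.finite(config$r_val)) p_src / config$r_val else 0
    config$q_gen + pump - valve - v_npt
  }
  root <- stats::uniroot(g, interval = c(-1, 1), extendInt = "downX",
                         tol = .Machine$double.eps^0.75, maxiter = 2000)
  p <- root$root
  v_leak <- invert_rohrer(config$leak, p)
  v_npt <- v_leak + v_res
  p_src <- p + rohrer_pressure(config$npt, v_npt)
  res <- g(p)
  if (abs(res) > 1e-9) {
    abort("Pharyngeal-node solver did not reach the residual tolerance.",
          class = "npvleak_error_solver")
  }
  tibble(p_ph_cmh2o = p, v_npt_lps = v_npt, v_leak_lps = v_leak,
         p_npt_cmh2o = p_src, residual = res)
}

#' Equilibrium (apnoeic) operating point
#'
#' With the patient apnoeic and no pumping, the NPT flow and the leak flow
#' coincide (both equal the bias flow reaching the pharynx) and the
#' pharyngeal pressure sits on the leak channel's Rohrer curve.
#'
#' @param config A [circuit_config()].
#' @return One-row tibble with `v_bias_lps` and `p_bar_cmh2o`.
#' @examples
#' cfg <- circuit_config(lpm_to_lps(16), Inf, npt_presets(4.0),
#'                       leak_presets("SL"))
#' equilibrium(cfg)
#' @export
equilibrium <- function(config) {
  s <- solve_pharyngeal_node(config, v_res = 0, pump = 0)
  tibble(v_bias_lps = s$v_npt_lps, p_bar_cmh2o = s$p_ph_cmh2o)
}

# drive vector for one breath at simulation rate
breath_drive <- function(pattern, dt) {
  n_ti <- max(1L, round(pattern$ti / dt))
  n_te <- max(1L, round(pattern$te / dt))
  tau_i <- (seq_len(n_ti) - 1L) * dt
  tau_e <- (seq_len(n_te) - 1L) * dt
  if (pattern$mode == "spontaneous") {
    a_exp <- pattern$a * pattern$ti / pattern$te
    if (pattern$profile == "half_sine") {
      c(pattern$a * sin(pi * tau_i / pattern$ti),
        -a_exp * sin(pi * tau_e / pattern$te))
    } else {
      c(rep(pattern$a, n_ti), rep(-a_exp, n_te))
    }
  } else if (pattern$mode == "mandatory") {
    insp <- if (pattern$profile == "half_sine") {
      pattern$pf * sin(pi * tau_i / pattern$ti)
    } else {
      rep(pattern$pf, n_ti)
    }
    c(insp, rep(0, n_te))
  } else {
    rep(0, n_ti + n_te)
  }
}

#' Simulate the ventilation bench
#'
#' Integrates the lumped-parameter network at a fine time step (default
#' 1 ms), emits waveforms decimated to `emit_hz`, and records the
#' ground-truth inspired volume of every breath (the time integral of the
#' positive part of the respiratory flow over the breath window, at the
#' simulation rate).  Sensor noise, when given, is added to the emitted
#' `p_ph_cmh2o` and `v_npt_lps` channels only; the ground-truth channels
#' stay clean and the clean copies of the noisy channels are kept as
#' `p_ph_true_cmh2o` / `v_npt_true_lps`.
#'
#' @param config A [circuit_config()].
#' @param pattern A [breath_pattern()].
#' @param dt Simulation step, s, `<= 0.01`.
#' @param noise A [noise_model()] or `NULL` for a clean, fully
#'   deterministic run (per-breath amplitude jitter is also disabled).
#' @param emit_hz Output sample rate, Hz; must divide `1/dt`.
#' @param warmup_breaths Run-in breaths simulated and discarded before the
#'   record starts, so that mandatory records begin in the cycling steady
#'   state of the lung volume rather than from an empty lung.  Defaults to
#'   5 for mandatory mode and 0 otherwise.
#' @return An object of class `npv_simulation`: list with `waveforms`
#'   (emitted tibble), `truth` (per-breath ground-truth volumes),
#'   `config`, `pattern`, `noise`.
#' @examples
#' cfg <- circuit_config(lpm_to_lps(16), 60, npt_presets(4.0),
#'                       leak_presets("SL"))
#' pat <- breath_pattern("spontaneous", a = 0.1, ti = 1, te = 2,
#'                       n_breaths = 3)
#' sim <- simulate_npv(cfg, pat)
#' sim$truth
#' @export
simulate_npv <- function(config, pattern, dt = 0.001, noise = NULL,
                         emit_hz = 100, warmup_breaths = NULL) {
  stopifnot(inherits(config, "circuit_config"),
            inherits(pattern, "breath_pattern"))
  if (dt > 0.01 || dt <= 0) {
    abort("`dt` must be positive and at most 0.01 s.",
          class = "npvleak_error_stability")
  }
  decim <- round(1 / (emit_hz * dt))
  if (abs(decim * emit_hz * dt - 1) > 1e-9 || decim < 1) {
    abort("`emit_hz` must divide the simulation rate 1/dt.",
          class = "npvleak_error_invalid_input")
  }
  if (pattern$mode == "mandatory" && (config$r_p <= 0 || config$c_p <= 0)) {
    abort("Mandatory mode needs `r_p` > 0 and `c_p` > 0 in the config.",
          class = "npvleak_error_invalid_input")
  }

  if (is.null(warmup_breaths)) {
    warmup_breaths <- if (pattern$mode == "mandatory") 5L else 0L
  }
  one <- breath_drive(pattern, dt)
  nb <- length(one)
  k <- pattern$n_breaths
  k_total <- k + warmup_breaths

  mult <- rep(1, k_total)
  if (!is.null(noise) && pattern$breath_cv > 0 && pattern$mode != "apnea") {
    mult <- with_local_seed(noise$seed + 1L,
                            1 + rnorm(k_total, 0, pattern$breath_cv))
    mult <- pmax(mult, 0)
  }
  drive <- rep(one, k_total) * rep(mult, each = nb)

  mode <- if (pattern$mode == "mandatory") 1L else 0L
  out <- sim_network_cpp(mode, drive, dt, config$q_gen, config$r_val,
                         config$npt$k_l, config$npt$k_t,
                         config$leak$k_l, config$leak$k_t,
                         config$r_p, config$c_p, 0)
  if (warmup_breaths > 0L) {
    drop <- seq_len(warmup_breaths * nb)
    out <- lapply(out, function(ch) ch[-drop])
    drive <- drive[-drop]
  }

  n <- length(drive)
  breath_id <- rep(seq_len(k), each = nb)
  v_res <- out$v_res
  truth <- tibble(
    breath = seq_len(k),
    t_start_s = (seq_len(k) - 1L) * nb * dt,
    t_end_s = seq_len(k) * nb * dt,
    v_insp_true_l = vapply(seq_len(k), function(b) {
      trapz(pmax(v_res[breath_id == b], 0), dt)
    }, numeric(1))
  )
  truth$v_insp_true_ml <- l_to_ml(truth$v_insp_true_l)

  idx <- seq(1L, n, by = decim)
  wf <- tibble(
    time_s = (idx - 1L) * dt,
    p_ph_cmh2o = out$p_ph[idx],
    v_npt_lps = out$v_npt[idx],
    v_leak_lps = out$v_leak[idx],
    v_res_lps = out$v_res[idx],
    p_npt_cmh2o = out$p_npt[idx]
  )
  if (!is.null(noise)) {
    stopifnot(inherits(noise, "noise_model"))
    wf$p_ph_true_cmh2o <- wf$p_ph_cmh2o
    wf$v_npt_true_lps <- wf$v_npt_lps
    noisy <- with_local_seed(noise$seed, {
      list(p = wf$p_ph_cmh2o + rnorm(nrow(wf), 0, noise$sd_pressure),
           v = wf$v_npt_lps + rnorm(nrow(wf), 0, noise$sd_flow))
    })
    wf$p_ph_cmh2o <- noisy$p
    wf$v_npt_lps <- noisy$v
  }
  attr(wf, "provenance") <- "simulated"

  structure(
    list(waveforms = wf, truth = truth, config = config, pattern = pattern,
         noise = noise, dt_sim = dt, emit_hz = emit_hz),
    class = "npv_simulation"
  )
}

#' @export
print.npv_simulation <- function(x, ...) {
  cat(sprintf(
    "Simulated %s record: %d breath(s), %d emitted samples at %g Hz%s\n",
    x$pattern$mode, nrow(x$truth), nrow(x$waveforms), x$emit_hz,
    if (is.null(x$noise)) " (clean)" else " (with sensor noise)"))
  invisible(x)
}

#' @export
#' @rdname simulate_npv
#' @param x,object An `npv_simulation` object.
#' @param ... Unused.
tidy.npv_simulation <- function(x, ...) x$truth

#' @export
#' @rdname simulate_npv
glance.npv_simulation <- function(x, ...) {
  tibble(
    mode = x$pattern$mode,
    n_breaths = nrow(x$truth),
    mean_v_insp_true_ml = mean(x$truth$v_insp_true_ml),
    sd_v_insp_true_ml = if (nrow(x$truth) > 1) sd(x$truth$v_insp_true_ml) else NA_real_,
    bias_flow_lpm = lps_to_lpm(x$config$q_gen)
  )
}

#' @export
#' @rdname simulate_npv
autoplot.npv_simulation <- function(object, ...) {
  chans <- intersect(c("p_ph_cmh2o", "v_npt_lps", "v_leak_lps", "v_res_lps"),
                     names(object$waveforms))
  long <- tidyr::pivot_longer(object$waveforms[c("time_s", chans)],
                              -"time_s", names_to = "channel",
                              values_to = "value")
  long$channel <- factor(long$channel, levels = chans)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Time (s)", y = NULL,
                  title = sprintf("Simulated %s breathing", object$pattern$mode))
}

#' Simulate the apnoeic stepped-flow characterisation protocol
#'
#' Reproduces the leak-channel characterisation: with the patient apnoeic,
#' the delivered flow is raised in steps (operator adjusting the generator
#' until the flow meter reads each level) and the plateau pharyngeal
#' pressure is recorded, averaging the monitored signals over the last
#' half of each settle window.  The default grid, 0 to 20 L/min in
#' 0.5 L/min increments, gives 41 levels including zero.
#'
#' @param config A [circuit_config()]; its `q_gen` is overridden at each
#'   step.
#' @param max_flow Highest leak-flow level, L/s.
#' @param increment Step increment, L/s.
#' @param settle_time Settle window per step, s.
#' @param emit_hz Monitoring sample rate within the window, Hz.
#' @param noise A [noise_model()] or `NULL`.
#' @return Tibble with `flow_lps` and `p_ph_cmh2o` (plateau averages);
#'   attribute `step_increment` carries the nominal increment.
#' @examples
#' cfg <- circuit_config(lpm_to_lps(16), 60, npt_presets(4.0),
#'                       leak_presets("ML"))
#' rec <- characterization_protocol(cfg)
#' fit_rohrer(rec)
#' @export
characterization_protocol <- function(config,
                                      max_flow = lpm_to_lps(20),
                                      increment = lpm_to_lps(0.5),
                                      settle_time = 2, emit_hz = 100,
                                      noise = NULL) {
  stopifnot(inherits(config, "circuit_config"))
  if (increment <= 0 || max_flow < increment) {
    abort("Need `increment` > 0 and `max_flow` >= `increment`.",
          class = "npvleak_error_invalid_input")
  }
  levels <- seq(0, max_flow + increment / 2, by = increment)
  levels <- levels[levels <= max_flow + 1e-12]
  p_plateau <- rohrer_pressure(config$leak, levels)
  n_avg <- max(1L, round(settle_time * emit_hz / 2))

  if (is.null(noise) || (noise$sd_pressure == 0 && noise$sd_flow == 0)) {
    flow_meas <- levels
    p_meas <- p_plateau
  } else {
    meas <- with_local_seed(noise$seed, {
      list(
        flow = vapply(levels, function(lv)
          mean(lv + rnorm(n_avg, 0, noise$sd_flow)), numeric(1)),
        p = vapply(p_plateau, function(pp)
          mean(pp + rnorm(n_avg, 0, noise$sd_pressure)), numeric(1))
      )
    })
    flow_meas <- meas$flow
    p_meas <- meas$p
    # the zero step is the generator switched off: recorded as exactly zero
    flow_meas[levels == 0] <- 0
  }
  out <- tibble(flow_lps = flow_meas, p_ph_cmh2o = p_meas)
  attr(out, "step_increment") <- increment
  out
}

#' Phase-plane descriptors of the (P_PH, NPT flow) trajectory
#'
#' `phase_axis_ratio()` measures how close the trajectory is to a line
#' segment: both coordinates are standardised and the ratio of the minor
#' to major principal-axis standard deviations is returned (0 for a
#' perfect segment, towards 1 for a round loop).  During spontaneous
#' breathing with a tube much more resistive than the leak the trajectory
#' collapses to a segment; during mandatory breaths the elastic patient
#' load opens it into a hysteresis loop.  `phase_loop_area()` returns the
#' signed shoelace area of the (pressure, flow) polygon; negative means
#' the loop is travelled clockwise.
#'
#' @param data Waveform tibble.
#' @param pressure,flow Column names of the two coordinates.
#' @return `phase_axis_ratio()`: a number in `[0, 1]`.
#'   `phase_loop_area()`: one-row tibble with `area` (cmH2O.L/s) and
#'   `direction`.
#' @export
phase_axis_ratio <- function(data, pressure = "p_ph_cmh2o",
                             flow = "v_npt_lps") {
  m <- cbind(data[[pressure]], data[[flow]])
  if (any(apply(m, 2, sd) == 0)) return(0)
  pc <- stats::prcomp(m, scale. = TRUE)
  pc$sdev[2] / pc$sdev[1]
}

#' @rdname phase_axis_ratio
#' @export
phase_loop_area <- function(data, pressure = "p_ph_cmh2o",
                            flow = "v_npt_lps") {
  x <- data[[pressure]]
  y <- data[[flow]]
  n <- length(x)
  if (n < 3L) {
    abort("Need at least 3 samples to compute a loop area.",
          class = "npvleak_error_invalid_input")
  }
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  area <- 0.5 * sum(x * yn - xn * y)
  tibble(area = area,
         direction = if (area < 0) "clockwise" else "counterclockwise")
}
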