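#' Add the leak-flow channel computed from pharyngeal pressure
#'
#' Applies the inverted Rohrer relation of the leak channel sample by
#' sample to the monitored pharyngeal pressure, yielding the leak flow
#' waveform.  Because the inversion is a pointwise monotone map, the leak
#' flow preserves the ordering of the pressure samples.
#'
#' @param data Waveform tibble with a `p_ph_cmh2o` column.
#' @param coeffs Leak-channel [rohrer_coeffs()] from the apnoeic
#'   characterisation.
#' @return `data` with a `v_leak_lps` column added (L/s).
#' @seealso [add_respiratory_flow()], [compensate()]
#' @export
add_leak_flow <- function(data, coeffs) {
  data <- as_waveforms(data, require = c("time_s", "p_ph_cmh2o"))
  data$v_leak_lps <- invert_rohrer(coeffs, data$p_ph_cmh2o)
  data
}

#' Add the respiratory-flow channel by leak subtraction
#'
#' Flow conservation at the pharyngeal node gives
#' `v_npt = v_leak + v_res`, so the respiratory flow is the difference
#' between the monitored NPT flow and the synchronized leak flow.
#' Inspiratory (into the patient) flow is positive, expiratory negative.
#'
#' @param data Waveform tibble with `v_npt_lps` and `v_leak_lps` columns.
#' @return `data` with a `v_res_lps` column added (L/s).
#' @export
add_respiratory_flow <- function(data) {
  data <- as_waveforms(data, require = c("time_s", "v_npt_lps", "v_leak_lps"))
  data$v_res_lps <- data$v_npt_lps - data$v_leak_lps
  data
}

#' Detect inspiratory segments in a respiratory-flow waveform
#'
#' Inspirations are detected as runs where a lightly smoothed copy of the
#' flow exceeds a threshold `theta = max(onset_fraction * max|flow|,
#' abs_floor)` for at least `min_insp_duration`.  Each detected run is then
#' widened outwards to the surrounding zero crossings of the raw flow,
#' so that the whole positive lobe of the breath is integrated (respiratory
#' flow is zero at the start of inspiration and at the start of expiration).
#' A breath extends from its inspiratory onset to the next onset (or the
#' record end), so the expiratory lobe belongs to the same breath.
#'
#' @param data Waveform tibble containing the flow channel.
#' @param flow Name of the flow column, default `"v_res_lps"`.
#' @param onset_fraction Detection threshold as a fraction of the record's
#'   peak absolute flow (default 0.02).
#' @param abs_floor Absolute threshold floor in L/s (default 0.005),
#'   guarding against noise-only records.
#' @param min_insp_duration Minimum duration of an inspiration, seconds.
#' @param smooth_window Width of the moving-average window (seconds) used
#'   only for detection; volumes are integrated on the raw flow.
#' @return A tibble with one row per breath: sample indices of the
#'   inspiratory window and breath end, the corresponding times, and the
#'   inspiratory (`v_tid_ml`) and expiratory (`v_tid_exp_ml`) volumes.
#' @export
segment_breaths <- function(data, flow = "v_res_lps",
                            onset_fraction = 0.02, abs_floor = 0.005,
                            min_insp_duration = 0.1, smooth_window = 0.05) {
  if (!is.numeric(onset_fraction) || onset_fraction <= 0 || onset_fraction >= 1) {
    abort("`onset_fraction` must be in (0, 1).",
          class = "npvleak_error_invalid_input")
  }
  data <- as_waveforms(data, require = c("time_s", flow))
  x <- data[[flow]]
  n <- length(x)
  empty <- tibble(
    breath = integer(), insp_start_idx = integer(), insp_end_idx = integer(),
    breath_end_idx = integer(), t_insp_start_s = numeric(),
    t_insp_end_s = numeric(), v_tid_l = numeric(), v_tid_ml = numeric(),
    v_tid_exp_ml = numeric()
  )
  if (n < 3L) return(empty)
  dt <- waveform_dt(data)

  w <- max(1L, round(smooth_window / dt))
  if (w %% 2L == 0L) w <- w + 1L
  if (w > 1L && n > w) {
    s <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
    s[is.na(s)] <- x[is.na(s)]
  } else {
    s <- x
  }

  theta <- max(onset_fraction * max(abs(s)), abs_floor)
  above <- s > theta
  if (!any(above)) return(empty)

  r <- rle(above)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  keep <- r$values & (r$lengths * dt >= min_insp_duration)
  if (!any(keep)) return(empty)
  starts <- run_start[keep]
  ends <- run_end[keep]

  # widen to the surrounding zero crossings of the raw flow
  idx <- seq_len(n)
  last_np <- cummax(ifelse(x <= 0, idx, 0L))            # last non-positive <= i
  next_np <- rev(cummin(rev(ifelse(x <= 0, idx, n + 1L))))  # first non-positive >= i
  starts <- pmin(pmax(last_np[starts] + 1L, 1L), starts)
  ends <- pmax(pmin(next_np[ends] - 1L, n), ends)

  # merge runs widened into the same positive lobe
  if (length(starts) > 1L) {
    keep_seg <- c(TRUE, starts[-1L] > ends[-length(ends)])
    grp <- cumsum(keep_seg)
    starts <- as.integer(tapply(starts, grp, min))
    ends <- as.integer(tapply(ends, grp, max))
  }

  m <- length(starts)
  breath_end <- c(starts[-1L] - 1L, n)
  v_tid <- vapply(seq_len(m), function(k) {
    trapz(x[starts[k]:ends[k]], dt)
  }, numeric(1))
  v_exp <- vapply(seq_len(m), function(k) {
    -trapz(pmin(x[starts[k]:breath_end[k]], 0), dt)
  }, numeric(1))

  tibble(
    breath = seq_len(m),
    insp_start_idx = starts,
    insp_end_idx = ends,
    breath_end_idx = breath_end,
    t_insp_start_s = data$time_s[starts],
    t_insp_end_s = data$time_s[ends],
    v_tid_l = v_tid,
    v_tid_ml = l_to_ml(v_tid),
    v_tid_exp_ml = l_to_ml(v_exp)
  )
}

#' Tidal volume of one inspiratory window
#'
#' Trapezoidal integral of the respiratory flow over the inspiratory
#' sample window, at the native sample rate.
#'
#' @param data Waveform tibble containing the flow channel.
#' @param insp_start_idx,insp_end_idx Sample indices (1-based, inclusive)
#'   delimiting the inspiration.
#' @param flow Name of the flow column, default `"v_res_lps"`.
#' @return Inspired volume in litres.
#' @examples
#' wf <- tibble::tibble(time_s = seq(0, 1, by = 1e-3))
#' wf$v_res_lps <- 0.2 * sin(pi * wf$time_s)
#' tidal_volume(wf, 1, nrow(wf))  # ~ 2 * 0.2 * 1 / pi
#' @export
tidal_volume <- function(data, insp_start_idx, insp_end_idx,
                         flow = "v_res_lps") {
  data <- as_waveforms(data, require = c("time_s", flow))
  n <- nrow(data)
  if (any(insp_start_idx < 1L) || any(insp_end_idx > n) ||
      any(insp_start_idx >= insp_end_idx)) {
    abort("Segment indices out of range.", class = "npvleak_error_index")
  }
  dt <- waveform_dt(data)
  x <- data[[flow]]
  vapply(seq_along(insp_start_idx), function(k) {
    trapz(x[insp_start_idx[k]:insp_end_idx[k]], dt)
  }, numeric(1))
}

#' Leak compensation pipeline: from monitored signals to tidal volumes
#'
#' Runs the full computational method on a record of synchronized
#' pharyngeal pressure and NPT flow: the leak flow is obtained by
#' inverting the leak channel's Rohrer relation at every sample, the
#' respiratory flow by subtraction (flow conservation at the pharyngeal
#' node), and breaths are segmented and integrated into tidal volumes.
#' Apart from the segmentation thresholds (computed once per record), the
#' reconstruction is causal sample by sample.
#'
#' @param data Waveform tibble with `time_s`, `p_ph_cmh2o`, `v_npt_lps`.
#' @param coeffs Leak-channel [rohrer_coeffs()].
#' @param ... Segmentation parameters passed to [segment_breaths()].
#' @return An object of class `npv_compensation`: a list with `waveforms`
#'   (input plus `v_leak_lps`, `v_res_lps`), `breaths` (per-breath table),
#'   and `coeffs`.  [tidy()] returns the breath table, [glance()] a one-row
#'   summary, [autoplot()] the three flow/pressure panels.
#' @examples
#' sim <- simulate_npv(
#'   circuit_config(q_gen = lpm_to_lps(16), r_val = 60,
#'                  npt = npt_presets(4.0), leak = leak_presets("SL")),
#'   breath_pattern("spontaneous", a = 0.1, ti = 1, te = 2, n_breaths = 3)
#' )
#' comp <- compensate(sim$waveforms, leak_presets("SL"))
#' tidy(comp)
#' @export
compensate <- function(data, coeffs, ...) {
  data <- as_waveforms(data)
  wf <- add_respiratory_flow(add_leak_flow(data, coeffs))
  breaths <- segment_breaths(wf, ...)
  structure(
    list(waveforms = wf, breaths = breaths, coeffs = coeffs),
    class = "npv_compensation"
  )
}

#' @export
print.npv_compensation <- function(x, ...) {
  cat(sprintf("Leak-compensated record: %d samples, %d breath(s)\n",
              nrow(x$waveforms), nrow(x$breaths)))
  if (nrow(x$breaths)) {
    cat(sprintf("  inspiratory V_TID: mean %.2f mL, sd %.2f mL\n",
                mean(x$breaths$v_tid_ml), sd(x$breaths$v_tid_ml)))
  }
  invisible(x)
}

#' @export
#' @rdname compensate
#' @param x,object An `npv_compensation` object.
tidy.npv_compensation <- function(x, ...) x$breaths

#' @export
#' @rdname compensate
glance.npv_compensation <- function(x, ...) {
  b <- x$breaths
  tibble(
    n_samples = nrow(x$waveforms),
    n_breaths = nrow(b),
    mean_v_tid_ml = if (nrow(b)) mean(b$v_tid_ml) else NA_real_,
    sd_v_tid_ml = if (nrow(b) > 1) sd(b$v_tid_ml) else NA_real_,
    mean_leak_lpm = lps_to_lpm(mean(x$waveforms$v_leak_lps))
  )
}

#' @export
#' @rdname compensate
autoplot.npv_compensation <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$waveforms[c("time_s", "p_ph_cmh2o", "v_npt_lps",
                       "v_leak_lps", "v_res_lps")],
    -"time_s", names_to = "channel", values_to = "value"
  )
  long$channel <- factor(long$channel,
                         levels = c("p_ph_cmh2o", "v_npt_lps",
                                    "v_leak_lps", "v_res_lps"))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Time (s)", y = NULL,
                  title = "Leak-compensated waveforms")
  if (nrow(object$breaths)) {
    shade <- object$breaths
    p <- p + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$t_insp_start_s, xmax = .data$t_insp_end_s),
      ymin = -Inf, ymax = Inf, alpha = 0.12, fill = "steelblue",
      inherit.aes = FALSE
    )
  }
  p
}

#' Write a breath table to CSV
#'
#' Emits the per-breath table in the documented column order
#' `breath_idx, t_insp_start_s, t_insp_end_s, v_tid_ml`.
#'
#' @param breaths Breath tibble from [segment_breaths()] or
#'   `tidy(compensate(...))`.
#' @param path Output CSV path.
#' @export
write_breaths <- function(breaths, path) {
  out <- tibble(
    breath_idx = breaths$breath,
    t_insp_start_s = signif(breaths$t_insp_start_s, 9),
    t_insp_end_s = signif(breaths$t_insp_end_s, 9),
    v_tid_ml = signif(breaths$v_tid_ml, 9)
  )
  readr::write_csv(out, path)
  invisible(path)
}
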