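#' Validate a waveform table
#'
#' Waveform bundles are plain tibbles with one row per sample.  The time
#' base is the `time_s` column (uniform sampling); signal channels follow
#' the naming convention `<quantity>_<units>`: `p_ph_cmh2o` (pharyngeal
#' pressure), `v_npt_lps` (NPT flow), and optionally `v_leak_lps`,
#' `v_res_lps`, `p_npt_cmh2o`.
#'
#' @param data Data frame of synchronized samples.
#' @param require Character vector of channel columns that must be present.
#' @param provenance `"measured"` or `"simulated"`; stored as an attribute.
#' @return The validated tibble (invisibly classed by its columns only).
#' @export
as_waveforms <- function(data,
                         require = c("time_s", "p_ph_cmh2o", "v_npt_lps"),
                         provenance = c("measured", "simulated")) {
  provenance <- match.arg(provenance)
  data <- as_tibble(data)
  missing_cols <- setdiff(require, names(data))
  if (length(missing_cols)) {
    abort(paste0("Waveform table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "npvleak_error_schema")
  }
  if (nrow(data) < 1L) {
    abort("Waveform table must have at least one sample.",
          class = "npvleak_error_invalid_input")
  }
  t <- data$time_s
  if (any(!is.finite(t)) || (length(t) > 1L && any(diff(t) <= 0))) {
    abort("`time_s` must be finite and strictly increasing.",
          class = "npvleak_error_format")
  }
  chans <- setdiff(names(data), "time_s")
  for (ch in chans) {
    if (!is.numeric(data[[ch]]) || any(!is.finite(data[[ch]]))) {
      abort(paste0("Channel `", ch, "` must be finite numeric."),
            class = "npvleak_error_invalid_input")
    }
  }
  attr(data, "provenance") <- provenance
  data
}

#' Sample interval of a waveform table
#'
#' @param data Waveform tibble with a `time_s` column.
#' @return The median sample interval in seconds.
#' @export
waveform_dt <- function(data) {
  t <- data$time_s
  if (length(t) < 2L) {
    abort("Need at least two samples to determine the sample interval.",
          class = "npvleak_error_invalid_input")
  }
  median(diff(t))
}

# trapezoidal integral of y sampled at constant step dt
trapz <- function(y, dt) {
  n <- length(y)
  if (n < 2L) return(0)
  dt * (sum(y) - (y[1] + y[n]) / 2)
}
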