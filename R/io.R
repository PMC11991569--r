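flow_cols <- c("v_npt", "v_leak", "v_res")

#' Read a waveform CSV
#'
#' Expects a header with `time_s`, `p_ph_cmh2o` and at least one flow
#' column; flow columns may be given in L/s (`*_lps`) or L/min (`*_lpm`,
#' converted on read).  The time base must be strictly increasing with
#' sample-interval jitter below 1% of the median interval; the time column
#' is then regularised to the exact median interval.
#'
#' @param path CSV path.
#' @return A waveform tibble in canonical units, provenance `"measured"`.
#' @export
read_waveforms <- function(path) {
  data <- as_tibble(readr::read_csv(path, show_col_types = FALSE))
  for (f in flow_cols) {
    lpm <- paste0(f, "_lpm")
    lps <- paste0(f, "_lps")
    if (lpm %in% names(data) && !lps %in% names(data)) {
      data[[lps]] <- lpm_to_lps(data[[lpm]])
      data[[lpm]] <- NULL
    }
  }
  need <- c("time_s", "p_ph_cmh2o", "v_npt_lps")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(paste0("Waveform CSV is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "npvleak_error_schema")
  }
  t <- data$time_s
  if (any(!is.finite(t)) || any(diff(t) <= 0)) {
    abort("`time_s` must be strictly increasing.",
          class = "npvleak_error_format")
  }
  if (length(t) > 2L) {
    dt <- median(diff(t))
    if (max(abs(diff(t) - dt)) > 0.01 * dt) {
      abort("Sample-interval jitter exceeds 1% of the median interval.",
            class = "npvleak_error_format")
    }
    data$time_s <- t[1] + (seq_along(t) - 1L) * dt
  }
  keep <- intersect(c("time_s", "p_ph_cmh2o", "v_npt_lps", "v_leak_lps",
                      "v_res_lps", "p_npt_cmh2o"), names(data))
  as_waveforms(data[keep], provenance = "measured")
}

#' Write a waveform CSV
#'
#' Inverse of [read_waveforms()]: emits the channels present in a fixed
#' documented order (`time_s`, `p_ph_cmh2o`, NPT flow, leak flow,
#' respiratory flow, `p_npt_cmh2o`), numbers at 9 significant digits, so
#' identical inputs give byte-identical files.
#'
#' @param data Waveform tibble.
#' @param path Output path.
#' @param units `"lps"` (default) or `"lpm"` for the flow columns.
#' @return `path`, invisibly.
#' @export
write_waveforms <- function(data, path, units = c("lps", "lpm")) {
  units <- match.arg(units)
  order <- c("time_s", "p_ph_cmh2o", "v_npt_lps", "v_leak_lps",
             "v_res_lps", "p_npt_cmh2o")
  out <- as_tibble(data)[intersect(order, names(data))]
  if (units == "lpm") {
    for (f in flow_cols) {
      lps <- paste0(f, "_lps")
      if (lps %in% names(out)) {
        out[[lps]] <- lps_to_lpm(out[[lps]])
        names(out)[names(out) == lps] <- paste0(f, "_lpm")
      }
    }
  }
  out <- dplyr::mutate(out, dplyr::across(dplyr::everything(),
                                          ~ signif(.x, 9)))
  readr::write_csv(out, path)
  invisible(path)
}

check_keys <- function(obj, allowed, where) {
  extra <- setdiff(names(obj), allowed)
  if (length(extra)) {
    abort(sprintf("Unknown key(s) in %s: %s", where,
                  paste(extra, collapse = ", ")),
          class = "npvleak_error_schema")
  }
}

pick_flow <- function(obj, base, default = NULL) {
  lps <- paste0(base, "_lps")
  lpm <- paste0(base, "_lpm")
  if (!is.null(obj[[lps]])) obj[[lps]]
  else if (!is.null(obj[[lpm]])) lpm_to_lps(obj[[lpm]])
  else default
}

#' Load a simulation configuration from JSON
#'
#' The JSON document has three top-level objects: `circuit` (bias flow,
#' valve resistance, NPT by tube size or explicit coefficients, leak by
#' preset size or explicit coefficients, patient mechanics), `pattern`
#' (mode, amplitudes, timings) and optional `noise`.  Unknown keys are
#' rejected with the offending field path; flows may be given in L/min
#' and the compliance in mL/cmH2O, converted to canonical units on load.
#'
#' @param path JSON path.
#' @return List with elements `config` ([circuit_config()]), `pattern`
#'   ([breath_pattern()]) and `noise` ([noise_model()] or `NULL`).
#' @export
load_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  check_keys(x, c("circuit", "pattern", "noise"), "top level")
  if (is.null(x$circuit) || is.null(x$pattern)) {
    abort("Config must contain `circuit` and `pattern` objects.",
          class = "npvleak_error_schema")
  }
  ci <- x$circuit
  check_keys(ci, c("q_gen_lps", "q_gen_lpm", "r_val", "tube_id_mm", "npt",
                   "leak_size", "leak", "r_p", "c_p_l_cmh2o",
                   "c_p_ml_cmh2o"), "circuit")
  npt <- if (!is.null(ci[["npt"]])) {
    check_keys(ci[["npt"]], c("k_l", "k_t", "label"), "circuit.npt")
    rohrer_coeffs(ci[["npt"]][["k_l"]], ci[["npt"]][["k_t"]], ci[["npt"]][["label"]] %||% "NPT")
  } else if (!is.null(ci[["tube_id_mm"]])) {
    npt_presets(ci[["tube_id_mm"]])
  } else {
    abort("circuit: give either `tube_id_mm` or an `npt` object.",
          class = "npvleak_error_schema")
  }
  leak <- if (!is.null(ci[["leak"]])) {
    check_keys(ci[["leak"]], c("k_l", "k_t", "label"), "circuit.leak")
    rohrer_coeffs(ci[["leak"]][["k_l"]], ci[["leak"]][["k_t"]], ci[["leak"]][["label"]] %||% "leak")
  } else if (!is.null(ci[["leak_size"]])) {
    leak_presets(ci[["leak_size"]])
  } else {
    abort("circuit: give either `leak_size` or a `leak` object.",
          class = "npvleak_error_schema")
  }
  c_p <- if (!is.null(ci[["c_p_l_cmh2o"]])) ci[["c_p_l_cmh2o"]]
         else if (!is.null(ci[["c_p_ml_cmh2o"]])) ml_to_l(ci[["c_p_ml_cmh2o"]])
         else 0.1
  config <- circuit_config(
    q_gen = pick_flow(ci, "q_gen", 0),
    r_val = ci[["r_val"]] %||% Inf,
    npt = npt, leak = leak,
    r_p = ci[["r_p"]] %||% 0, c_p = c_p
  )

  pa <- x$pattern
  check_keys(pa, c("mode", "a_lps", "a_lpm", "pf_lps", "pf_lpm", "ti_s",
                   "te_s", "n_breaths", "profile", "breath_cv"), "pattern")
  pattern <- breath_pattern(
    mode = pa[["mode"]] %||% "spontaneous",
    a = pick_flow(pa, "a", 0),
    pf = pick_flow(pa, "pf", 0),
    ti = pa[["ti_s"]] %||% 1, te = pa[["te_s"]] %||% 2,
    n_breaths = pa[["n_breaths"]] %||% 10,
    profile = pa[["profile"]] %||% "half_sine",
    breath_cv = pa[["breath_cv"]] %||% 0.008
  )

  noise <- NULL
  if (!is.null(x$noise)) {
    no <- x$noise
    check_keys(no, c("sd_pressure_cmh2o", "sd_flow_lps", "seed"), "noise")
    noise <- noise_model(no[["sd_pressure_cmh2o"]] %||% 0.05,
                         no[["sd_flow_lps"]] %||% 0.002,
                         no[["seed"]] %||% 1L)
  }
  list(config = config, pattern = pattern, noise = noise)
}
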