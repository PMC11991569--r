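#' Rohrer coefficients of a flow channel
#'
#' The pressure drop across the nasopharyngeal tube (NPT) and across the
#' leak channel is modelled by the Rohrer relation
#' \deqn{\Delta P = k_L \dot V + k_T \dot V^2}{dP = k_L*V + k_T*V^2}
#' where `k_l` is the laminar (flow-independent) resistance coefficient in
#' cmH2O.s/L and `k_t` the turbulent coefficient in cmH2O.s^2/L^2.  A channel
#' needs at least one strictly positive coefficient to be usable.
#'
#' @param k_l Laminar coefficient, cmH2O.s/L, `>= 0`.
#' @param k_t Turbulent coefficient, cmH2O.s^2/L^2, `>= 0`.
#' @param label Free-text channel label, e.g. `"leak:SL"` or `"NPT:4.0mm"`.
#' @return An object of class `rohrer_coeffs`.
#' @seealso [rohrer_pressure()], [invert_rohrer()], [fit_rohrer()]
#' @examples
#' rohrer_coeffs(11.88, 66.88, "leak:SL")
#' @export
rohrer_coeffs <- function(k_l, k_t, label = "") {
  if (!is.numeric(k_l) || !is.numeric(k_t) ||
      length(k_l) != 1L || length(k_t) != 1L ||
      !is.finite(k_l) || !is.finite(k_t)) {
    abort("`k_l` and `k_t` must be single finite numbers.",
          class = "npvleak_error_invalid_input")
  }
  if (k_l < 0 || k_t < 0) {
    abort("Rohrer coefficients must be non-negative.",
          class = "npvleak_error_invalid_input")
  }
  structure(
    list(k_l = as.numeric(k_l), k_t = as.numeric(k_t),
         label = as.character(label)),
    class = "rohrer_coeffs"
  )
}

#' @export
print.rohrer_coeffs <- function(x, ...) {
  lab <- if (nzchar(x$label)) paste0(" [", x$label, "]") else ""
  cat(sprintf("<rohrer_coeffs>%s k_L = %g cmH2O.s/L, k_T = %g cmH2O.s2/L2\n",
              lab, x$k_l, x$k_t))
  invisible(x)
}

is_rohrer_coeffs <- function(x) inherits(x, "rohrer_coeffs")

check_coeffs <- function(coeffs, require_usable = FALSE) {
  if (!is_rohrer_coeffs(coeffs)) {
    abort("`coeffs` must be created with `rohrer_coeffs()`.",
          class = "npvleak_error_invalid_input")
  }
  if (require_usable && coeffs$k_l == 0 && coeffs$k_t == 0) {
    abort("Degenerate channel: k_L and k_T are both zero.",
          class = "npvleak_error_degenerate_channel")
  }
  invisible(coeffs)
}

#' Representative leak-channel coefficients
#'
#' Rohrer coefficients for three bench leak channels of increasing size
#' (small `SL`, medium `ML`, large `LL`), obtained from an apnoeic
#' stepped-flow characterisation of a nasopharyngeal ventilation bench.
#' They serve as package defaults for simulation and validation studies.
#'
#' @param size One of `"SL"`, `"ML"`, `"LL"`.
#' @return A [rohrer_coeffs()] object.
#' @examples
#' leak_presets("ML")
#' @export
leak_presets <- function(size = c("SL", "ML", "LL")) {
  size <- match.arg(size)
  k <- switch(size,
    SL = c(11.88, 66.88),
    ML = c(6.12, 32.71),
    LL = c(3.66, 17.34)
  )
  rohrer_coeffs(k[1], k[2], label = paste0("leak:", size))
}

#' Pressure drop across a Rohrer channel
#'
#' Evaluates the Rohrer relation with the sign-symmetric extension
#' `P = k_L*V + k_T*V*|V|`, an odd function of flow, so that a reversed
#' flow produces a negative pressure drop.  For non-negative flow this is
#' exactly `k_L*V + k_T*V^2`.
#'
#' @param coeffs A [rohrer_coeffs()] object.
#' @param flow Numeric vector of flows, L/s (signed).
#' @return Numeric vector of pressure drops, cmH2O.
#' @examples
#' sl <- leak_presets("SL")
#' rohrer_pressure(sl, 0.1)
#' @export
rohrer_pressure <- function(coeffs, flow) {
  check_coeffs(coeffs)
  if (!is.numeric(flow) || any(!is.finite(flow))) {
    abort("`flow` must be finite numeric.",
          class = "npvleak_error_invalid_input")
  }
  coeffs$k_l * flow + coeffs$k_t * flow * abs(flow)
}

#' Invert the Rohrer relation: flow from pressure
#'
#' Solves `P = k_L*V + k_T*V*|V|` for the flow `V`.  For `P >= 0` this is
#' the positive root of the quadratic,
#' `V = (-k_L + sqrt(k_L^2 + 4 k_T P)) / (2 k_T)`, evaluated in the
#' cancellation-free form `2P / (k_L + sqrt(k_L^2 + 4 k_T P))`; for `P < 0`
#' the magnitude is inverted and the sign restored (odd symmetry), and for
#' `k_T = 0` the linear limit `P / k_L` applies.  It is the exact inverse of
#' [rohrer_pressure()] to floating tolerance.
#'
#' @param coeffs A [rohrer_coeffs()] object with `k_l` or `k_t` positive.
#' @param pressure Numeric vector of pressures, cmH2O (signed).
#' @return Numeric vector of flows, L/s, with `sign(flow) = sign(pressure)`.
#' @examples
#' sl <- leak_presets("SL")
#' invert_rohrer(sl, rohrer_pressure(sl, 0.1))
#' @export
invert_rohrer <- function(coeffs, pressure) {
  check_coeffs(coeffs, require_usable = TRUE)
  if (!is.numeric(pressure) || any(!is.finite(pressure))) {
    abort("`pressure` must be finite numeric.",
          class = "npvleak_error_invalid_input")
  }
  p <- abs(pressure)
  if (coeffs$k_t == 0) {
    mag <- p / coeffs$k_l
  } else {
    mag <- 2 * p / (coeffs$k_l + sqrt(coeffs$k_l^2 + 4 * coeffs$k_t * p))
  }
  sign(pressure) * mag
}

#' Goodness-of-fit metrics for a pressure fit
#'
#' Returns the mean squared error together with two normalised goodness
#' scores in the "fit" convention where 1 means a perfect fit:
#' `nrmse_fit = 1 - ||obs - pred|| / ||obs - mean(obs)||` and
#' `nmse_fit = 1 - ||obs - pred||^2 / ||obs - mean(obs)||^2`.
#' Predicting the observed mean everywhere scores 0 on both.
#'
#' @param observed,predicted Equal-length numeric vectors (length >= 2);
#'   `observed` must not be constant.
#' @return A one-row tibble with columns `mse`, `nrmse_fit`, `nmse_fit`.
#' @examples
#' goodness_of_fit(c(1, 2, 3), c(1, 2, 4))
#' @export
goodness_of_fit <- function(observed, predicted) {
  if (!is.numeric(observed) || !is.numeric(predicted) ||
      length(observed) != length(predicted) || length(observed) < 2L ||
      any(!is.finite(observed)) || any(!is.finite(predicted))) {
    abort("`observed` and `predicted` must be equal-length finite numeric vectors (n >= 2).",
          class = "npvleak_error_invalid_input")
  }
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    abort("`observed` is constant; normalised goodness is undefined.",
          class = "npvleak_error_undefined_normalization")
  }
  ss_res <- sum((observed - predicted)^2)
  tibble(
    mse = mean((observed - predicted)^2),
    nrmse_fit = 1 - sqrt(ss_res / ss_tot),
    nmse_fit = 1 - ss_res / ss_tot
  )
}

validate_characterization <- function(data, noise_sd = NULL) {
  data <- as_tibble(data)
  if (!"flow_lps" %in% names(data) && "flow_lpm" %in% names(data)) {
    data$flow_lps <- lpm_to_lps(data$flow_lpm)
  }
  need <- c("flow_lps", "p_ph_cmh2o")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(paste0("Characterisation record is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "npvleak_error_schema")
  }
  flow <- data$flow_lps
  p <- data$p_ph_cmh2o
  if (length(flow) < 3L || any(!is.finite(flow)) || any(!is.finite(p))) {
    abort("Characterisation record needs >= 3 finite (flow, pressure) pairs.",
          class = "npvleak_error_invalid_input")
  }
  if (any(flow < 0) || any(diff(flow) <= 0)) {
    abort("`flow_lps` must be strictly increasing and non-negative.",
          class = "npvleak_error_invalid_input")
  }
  # plateau pressures should rise with flow; tolerate measurement noise
  # (3 sigma, with sigma estimated from second differences if not given)
  if (is.null(noise_sd)) {
    noise_sd <- if (length(p) >= 4) sd(diff(p, differences = 2)) / sqrt(6) else 0
    if (!is.finite(noise_sd)) noise_sd <- 0
  }
  drops <- diff(p) < -3 * noise_sd
  if (any(drops)) {
    warn(sprintf(
      "Plateau pressures decrease beyond noise tolerance at %d step(s); check the record.",
      sum(drops)))
  }
  data[c("flow_lps", "p_ph_cmh2o")]
}

#' Fit the Rohrer relation to an apnoeic characterisation record
#'
#' During apnoea the whole tube flow escapes through the leak, so stepping
#' the delivered flow and reading the plateau pharyngeal pressure samples
#' the leak channel's flow-pressure curve directly.  This fits
#' `P = k_L*V + k_T*V^2` (no intercept) by linear least squares in the
#' basis `{V, V^2}`, with an active-set non-negativity clamp on both
#' coefficients.
#'
#' @param data Data frame with columns `flow_lps` (strictly increasing,
#'   `>= 0`) and `p_ph_cmh2o`; a `flow_lpm` column is accepted and converted.
#' @param label Channel label stored in the fitted coefficients.
#' @param noise_sd Optional known pressure-noise standard deviation used by
#'   the monotonicity check; estimated from the record when `NULL`.
#' @return An object of class `rohrer_fit` with elements `coefficients`
#'   (a [rohrer_coeffs()]), `gof` (mse and normalised goodness scores),
#'   `n_points`, and `data` (the record with a `fitted` column).
#' @examples
#' rec <- tibble::tibble(flow_lps = seq(0, 0.3, by = 0.05))
#' rec$p_ph_cmh2o <- rohrer_pressure(leak_presets("ML"), rec$flow_lps)
#' fit_rohrer(rec, label = "leak:ML")
#' @export
fit_rohrer <- function(data, label = "", noise_sd = NULL) {
  raw <- as_tibble(data)
  if ("flow_lps" %in% names(raw) || "flow_lpm" %in% names(raw)) {
    fl <- raw$flow_lps %||% lpm_to_lps(raw$flow_lpm)
    if (length(unique(fl[is.finite(fl) & fl > 0])) < 2L) {
      abort("Need at least 2 distinct non-zero flow levels to fit two coefficients.",
            class = "npvleak_error_underdetermined")
    }
  }
  data <- validate_characterization(data, noise_sd = noise_sd)
  flow <- data$flow_lps
  p <- data$p_ph_cmh2o
  if (all(p[flow > 0] == 0)) {
    abort("All plateau pressures are zero at non-zero flow; channel cannot be fitted.",
          class = "npvleak_error_degenerate_fit")
  }

  sse_of <- function(kl, kt) sum((p - kl * flow - kt * flow^2)^2)
  # unconstrained two-term fit, then clamp via the two single-term boundaries
  k2 <- coef(lm(p ~ 0 + flow + I(flow^2)))
  candidates <- list(c(k2[[1]], k2[[2]]))
  if (any(k2 < 0)) {
    candidates <- list(
      c(max(0, coef(lm(p ~ 0 + flow))[[1]]), 0),
      c(0, max(0, coef(lm(p ~ 0 + I(flow^2)))[[1]]))
    )
  }
  feasible <- Filter(function(k) all(k >= 0), candidates)
  sse <- vapply(feasible, function(k) sse_of(k[1], k[2]), numeric(1))
  k <- feasible[[which.min(sse)]]

  coeffs <- rohrer_coeffs(k[1], k[2], label = label)
  fitted <- rohrer_pressure(coeffs, flow)
  structure(
    list(
      coefficients = coeffs,
      gof = goodness_of_fit(p, fitted),
      n_points = length(flow),
      data = tibble(flow_lps = flow, p_ph_cmh2o = p, fitted = fitted)
    ),
    class = "rohrer_fit"
  )
}

#' @export
print.rohrer_fit <- function(x, ...) {
  cat("Rohrer channel fit\n")
  print(x$coefficients)
  cat(sprintf("  n = %d points; MSE = %.4g cmH2O^2; NRMSE = %.3f; NMSE = %.3f\n",
              x$n_points, x$gof$mse, x$gof$nrmse_fit, x$gof$nmse_fit))
  invisible(x)
}

#' @export
#' @rdname fit_rohrer
#' @param x,object A `rohrer_fit` object.
#' @param ... Unused.
tidy.rohrer_fit <- function(x, ...) {
  tibble(
    term = c("k_L", "k_T"),
    estimate = c(x$coefficients$k_l, x$coefficients$k_t),
    units = c("cmH2O.s/L", "cmH2O.s2/L2")
  )
}

#' @export
#' @rdname fit_rohrer
glance.rohrer_fit <- function(x, ...) {
  dplyr::bind_cols(
    x$gof,
    tibble(n_points = x$n_points, channel_label = x$coefficients$label)
  )
}

#' @export
#' @rdname fit_rohrer
predict.rohrer_fit <- function(object, flow, ...) {
  rohrer_pressure(object$coefficients, flow)
}

#' @export
#' @rdname fit_rohrer
autoplot.rohrer_fit <- function(object, ...) {
  grid <- tibble(flow_lps = seq(0, max(object$data$flow_lps), length.out = 200))
  grid$fitted <- rohrer_pressure(object$coefficients, grid$flow_lps)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$flow_lps)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$p_ph_cmh2o)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fitted),
                       colour = "steelblue") +
    ggplot2::labs(
      x = "Leak flow (L/s)", y = "Pharyngeal pressure (cmH2O)",
      title = "Apnoeic characterisation and fitted Rohrer curve",
      subtitle = object$coefficients$label
    )
}

#' Read or write characterisation and fit files
#'
#' `read_characterization()` reads a stepped-flow apnoea record from CSV
#' (columns `flow_lps` or `flow_lpm`, and `p_ph_cmh2o`).
#' `write_fit_json()` / `read_fit_json()` serialise a fitted channel as JSON
#' with fields `k_L`, `k_T`, `mse`, `nrmse_fit`, `nmse_fit`, `n_points`,
#' `channel_label`.
#'
#' @param path File path.
#' @param fit A `rohrer_fit` object.
#' @return `read_characterization()` a tibble; `read_fit_json()` a
#'   [rohrer_coeffs()] with the stored goodness attached as attribute `gof`.
#' @export
read_characterization <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  validate_characterization(data)
}

#' @rdname read_characterization
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "rohrer_fit"))
  jsonlite::write_json(
    list(
      k_L = fit$coefficients$k_l,
      k_T = fit$coefficients$k_t,
      mse = fit$gof$mse,
      nrmse_fit = fit$gof$nrmse_fit,
      nmse_fit = fit$gof$nmse_fit,
      n_points = fit$n_points,
      channel_label = fit$coefficients$label
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname read_characterization
#' @export
read_fit_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("k_L", "k_T")
  if (!all(need %in% names(x))) {
    abort("Fit JSON must contain fields `k_L` and `k_T`.",
          class = "npvleak_error_schema")
  }
  out <- rohrer_coeffs(x$k_L, x$k_T, label = x$channel_label %||% "")
  attr(out, "gof") <- x[intersect(c("mse", "nrmse_fit", "nmse_fit", "n_points"),
                                  names(x))]
  out
}
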