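#' Unit conversions for flow
#'
#' Canonical internal units are litres per second (L/s) for flow, cmH2O for
#' pressure and seconds for time.  Ventilation protocols are usually quoted
#' in litres per minute (L/min); these helpers convert at the I/O boundary.
#' The conversion factor is exactly 60, so a round trip is lossless.
#'
#' @param x Numeric vector of flows.
#' @return Numeric vector of converted flows.
#' @examples
#' lpm_to_lps(16)   # 16 L/min bias flow -> 0.2667 L/s
#' lps_to_lpm(lpm_to_lps(16)) == 16
#' @export
lpm_to_lps <- function(x) x / 60

#' @rdname lpm_to_lps
#' @export
lps_to_lpm <- function(x) x * 60

#' @rdname lpm_to_lps
#' @export
l_to_ml <- function(x) x * 1000

#' @rdname lpm_to_lps
#' @export
ml_to_l <- function(x) x / 1000
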