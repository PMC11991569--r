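# Shared fixtures: a paediatric bench (bias 16 L/min, valve 60, 4.0 mm tube)
# and a small helper to build noise-free characterisation records.

ped_config <- function(leak = leak_presets("SL"), r_val = 60, r_p = 0,
                       c_p = 0.1, tube = 4.0, bias_lpm = 16) {
  circuit_config(q_gen = lpm_to_lps(bias_lpm), r_val = r_val,
                 npt = npt_presets(tube), leak = leak, r_p = r_p, c_p = c_p)
}

exact_record <- function(coeffs, max_flow = 1 / 3, step = 1 / 120) {
  flow <- seq(0, max_flow, by = step)
  tibble::tibble(flow_lps = flow,
                 p_ph_cmh2o = rohrer_pressure(coeffs, flow))
}

# dense grid-search oracle for the pharyngeal-node pressure: scans p until
# the Kirchhoff residual changes sign, then refines by interval halving on
# the grid; independent of the package's root finder
grid_search_node <- function(config, v_res = 0, pump = 0, tol = 1e-6) {
  g <- function(p) {
    v_leak <- invert_rohrer(config$leak, p)
    v_npt <- v_leak + v_res
    p_src <- p + rohrer_pressure(config$npt, v_npt)
    valve <- if (is.finite(config$r_val)) p_src / config$r_val else 0
    config$q_gen + pump - valve - v_npt
  }
  lo <- -200
  hi <- 200
  while (hi - lo > tol) {
    grid <- seq(lo, hi, length.out = 41)
    vals <- vapply(grid, g, numeric(1))
    k <- which(vals <= 0)[1]  # g decreasing: first non-positive value
    lo <- grid[max(1, k - 1)]
    hi <- grid[k]
  }
  (lo + hi) / 2
}
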