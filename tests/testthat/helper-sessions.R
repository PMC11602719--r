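# Shared fixtures: small synthetic sessions built in code.

# A dark-only track of n laps of the build-up geometry.
dark_track <- function(n_trials = 20L, length_cm = 320) {
  track_spec(length_cm, list(block_spec(n_trials, dark = TRUE)), seamless = TRUE)
}

# Deterministic single-module parameters (no drift unless overridden).
quiet_params <- function(...) {
  args <- utils::modifyList(list(diffusion_deg2_per_m = 0, grid_scales_cm = 50,
                                 n_cells_per_module = 24L), list(...))
  do.call(sim_params, args)
}

# Cache sessions across tests within one run (building them is the slow part).
.session_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.session_cache[[key]])) .session_cache[[key]] <- force(expr)
  .session_cache[[key]]
}

# A dark session with spikes, used by the spectral round-trip tests.
dark_session <- function() {
  cached("dark", simulate_session(dark_track(20L), quiet_params(), seed = 42))
}

# Expected slice frequencies (cycles/m) for scale lambda (cm) at angle gamma.
slice_freqs <- function(lambda_cm = 50, gamma_deg = 10) {
  100 / lambda_cm * cos((gamma_deg - c(0, 60, 120)) * pi / 180)
}

expect_circ_equal <- function(a, b, tol = 0.1) {
  d <- atan2(sin(a - b), cos(a - b))
  expect_lt(max(abs(d)), tol)
}

# Idealized dense population: phases on a uniform n x n torus grid (the
# symmetric sampling makes the circular COM estimator exact).
grid_phases <- function(n_side = 12L) {
  g <- expand.grid(i = seq_len(n_side) - 1L, j = seq_len(n_side) - 1L)
  ph <- cbind(2 * pi * g$i / n_side, 2 * pi * g$j / n_side)
  cbind(ph, wrap_2pi(ph[, 2] - ph[, 1]))
}
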