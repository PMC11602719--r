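# Reproducible simulation experiments -------------------------------------

#' Dark-running drift experiment
#'
#' Simulates replicate dark sessions (constant gain, angular diffusion at
#' the configured value), fits the diffusion constant from the latent bump
#' trajectories, and — through the full spiking pipeline (Poisson spikes,
#' occupancy-normalized rate maps, population bump tracking, unwrapping) —
#' estimates the grid-scale drift over the session.
#'
#' @param n_sessions replicate sessions.
#' @param session_m dark distance per session (metres); laps of 3.2 m.
#' @param D_deg2_per_m generating angular diffusion constant.
#' @param n_cells cells in the module used for the spike-based drift
#'   estimate.
#' @param scale_cm grid scale (cm).
#' @param seed master seed; per-session seeds derive from it.
#' @param spike_drift if `FALSE`, skip the (slower) spike-based scale-drift
#'   pipeline.
#' @return list with `D_fit` (mean fitted constant, deg^2/m), `D_se`,
#'   `per_session_D`, `drift_percent` (mean over sessions of the maximum
#'   relative scale deviation over the session), `per_session_drift`.
#' @export
dark_drift_experiment <- function(n_sessions = 100, session_m = 100,
                                  D_deg2_per_m = 1.16, n_cells = 64L,
                                  scale_cm = 50, seed = 1L,
                                  spike_drift = TRUE) {
  n_laps <- ceiling(session_m * 100 / 320)
  track <- track_spec(320, list(block_spec(n_laps, dark = TRUE)),
                      seamless = TRUE)
  params <- sim_params(n_cells_per_module = n_cells, grid_scales_cm = scale_cm,
                       diffusion_deg2_per_m = D_deg2_per_m)
  per_D <- numeric(n_sessions)
  per_drift <- rep(NA_real_, n_sessions)
  thetas <- vector("list", n_sessions)
  for (s in seq_len(n_sessions)) {
    sseed <- .derive_seed(seed, 100L + s)
    traj <- simulate_latent_trajectory(track, params, seed = sseed)
    thetas[[s]] <- traj$theta_unwrapped
    per_D[s] <- fit_diffusion(traj$theta_unwrapped)$D
    if (spike_drift) {
      phases <- draw_phases(n_cells, seed = .derive_seed(sseed, 3L))
      rates <- rates_from_trajectory(phases, traj, params)
      spikes <- spikes_from_rates(rates, traj$bins, seed = .derive_seed(sseed, 5L))
      # spike counts per bin -> rates -> smoothed population bump
      counts <- vapply(spikes, function(st)
        tabulate(findInterval(st, traj$bins$t_start + 1e-12), nrow(traj$bins)),
        integer(nrow(traj$bins)))
      est_rates <- .gauss_smooth(counts / traj$bins$dur_s[1], 2)
      bump <- bump_com(est_rates, phases)
      unw <- apply(bump$psi, 2, signal::unwrap)
      th <- hex_transform(unw[, 1:2, drop = FALSE])
      per_drift[s] <- scale_drift(th, over_m = session_m)$drift_percent
    }
  }
  fd <- fit_diffusion(thetas, seed = .derive_seed(seed, 9L))
  list(D_fit = mean(per_D), D_se = fd$se, per_session_D = per_D,
       drift_percent = mean(per_drift, na.rm = TRUE),
       per_session_drift = per_drift)
}
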