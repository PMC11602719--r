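# Synthetic grid-cell sessions -------------------------------------------
#
# The generator realizes the study conditions the analyses assume: an
# attractor bump whose sheet trajectory path-integrates running distance,
# whose slice angle diffuses in darkness, and which is weakly pinned toward
# fixed sheet phases in the 50 cm leading up to each visual landmark.
# Idealized co-modular grid cells fire as Poisson processes with rates set by
# the torus proximity of their phase to the bump.

#' Simulation parameters
#'
#' @param n_cells_per_module cells per grid module.
#' @param grid_scales_cm grid scale lambda (cm) of each simulated module;
#'   adjacent modules default to a sqrt(2) scale ratio.
#' @param slice_angle_deg initial slice angle gamma of the 1D track through
#'   the 2D lattice (degrees).
#' @param diffusion_deg2_per_m angular diffusion constant D of the slice
#'   angle (deg^2 per metre travelled); 0 disables drift.
#' @param peak_rate_hz firing rate (Hz) of a cell whose phase sits exactly at
#'   the bump centre.
#' @param bump_width bump width parameter w (sheet units); the rate is
#'   `peak * exp((sum_a cos(psi_a - phi_a) - 3) / w^2)`.
#' @param pin_alpha default landmark pinning strength (per cm); the
#'   linearized pinning ODE closes a fraction `1 - exp(-alpha * 50)` of the
#'   phase gap across one 50-cm influence window. The default 0.05 (~92%
#'   closure) entrains each lit block to a stable trial-periodic orbit while
#'   remaining a partial pull; much weaker pins can settle on multi-trial
#'   limit cycles instead of a fixed orbit.
#' @param landmark_pins optional named list `id -> list(rho, alpha)` where
#'   `rho` is a per-module list of sheet phases (length-2 theta vectors);
#'   missing landmarks get uniform-random pins with strength `pin_alpha`.
#' @param influence_window_cm length of the pinning window preceding each
#'   landmark (cm).
#' @param speed_cm_s constant running speed (cm/s).
#' @param dt_s behaviour trace sample interval (s); default 0.02 (50 Hz).
#' @param bin_cm spatial bin / integration step (cm).
#' @param lick_rate_hz mean anticipatory/chance licks per trial.
#' @param behaviour_mode `"expert"` (licks concentrated in the 10 cm before
#'   the reward zone) or `"chance"` (uniform licks).
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(n_cells_per_module = 64L,
                       grid_scales_cm = c(50, 50 * sqrt(2)),
                       slice_angle_deg = 10,
                       diffusion_deg2_per_m = 1.16,
                       peak_rate_hz = 10,
                       bump_width = 1,
                       pin_alpha = 0.05,
                       landmark_pins = NULL,
                       influence_window_cm = 50,
                       speed_cm_s = 50,
                       dt_s = 0.02,
                       bin_cm = 2,
                       lick_rate_hz = NULL,
                       behaviour_mode = c("expert", "chance")) {
  stopifnot(all(grid_scales_cm > 0), diffusion_deg2_per_m >= 0,
            peak_rate_hz > 0, bump_width > 0, speed_cm_s > 0, bin_cm > 0)
  structure(list(n_cells_per_module = as.integer(n_cells_per_module),
                 grid_scales_cm = grid_scales_cm,
                 slice_angle_deg = slice_angle_deg,
                 diffusion_deg2_per_m = diffusion_deg2_per_m,
                 peak_rate_hz = peak_rate_hz, bump_width = bump_width,
                 pin_alpha = pin_alpha, landmark_pins = landmark_pins,
                 influence_window_cm = influence_window_cm,
                 speed_cm_s = speed_cm_s, dt_s = dt_s, bin_cm = bin_cm,
                 lick_rate_hz = lick_rate_hz,
                 behaviour_mode = match.arg(behaviour_mode)),
            class = "sim_params")
}

#' Draw uniform grid-cell phases for one module
#'
#' Phases `(phi_1, phi_2)` are uniform on the torus and `phi_3 = phi_2 -
#' phi_1` (mod 2*pi), so the triplet carries 2 degrees of freedom (wavevector
#' closure `k_1 + k_3 = k_2`).
#'
#' @param n number of cells.
#' @param seed RNG seed.
#' @return n x 3 matrix of phases in `[0, 2*pi)`.
#' @export
draw_phases <- function(n, seed = 1L) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  p1 <- stats::runif(n, 0, 2 * pi)
  p2 <- stats::runif(n, 0, 2 * pi)
  cbind(phi1 = p1, phi2 = p2, phi3 = wrap_2pi(p2 - p1))
}

# Resolve pins for the landmarks of a track: one sheet phase per landmark id
# per module, plus a strength. Unspecified pins are drawn uniformly.
.resolve_pins <- function(track, params, n_modules, seed) {
  ids <- unique(unlist(lapply(track$blocks, function(b) b$landmarks$id)))
  if (!length(ids)) return(list())
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(.derive_seed(seed, 7L))
  pins <- list()
  for (id in ids) {
    given <- params$landmark_pins[[id]]
    rho <- vector("list", n_modules)
    for (m in seq_len(n_modules)) {
      if (!is.null(given$rho[[m]])) {
        rho[[m]] <- given$rho[[m]]
      } else {
        psi <- stats::runif(2, 0, 2 * pi)
        rho[[m]] <- drop(hex_transform(c(psi, wrap_2pi(psi[2] - psi[1]))))
      }
    }
    alpha <- if (!is.null(given$alpha)) given$alpha else params$pin_alpha
    pins[[id]] <- list(rho = rho, alpha = alpha)
  }
  pins
}

# Lay out the spatial bins of every trial of a track.
.bin_table <- function(track, params) {
  bin <- params$bin_cm
  nb <- as.integer(round(track$track_length_cm / bin))
  rows <- list()
  trial0 <- 0L
  for (bi in seq_along(track$blocks)) {
    b <- track$blocks[[bi]]
    for (tr in seq_len(b$n_trials)) {
      rows[[length(rows) + 1L]] <- data.frame(
        block = bi, trial = trial0 + tr, bin = seq_len(nb),
        x_cm = (seq_len(nb) - 0.5) * bin, dark = b$dark)
    }
    trial0 <- trial0 + b$n_trials
  }
  tab <- do.call(rbind, rows)
  tab$cum_cm <- (seq_len(nrow(tab)) - 0.5) * bin
  tab$dur_s <- bin / params$speed_cm_s
  tab$t_start <- (seq_len(nrow(tab)) - 1) * tab$dur_s[1]
  tab
}

# Per-trial landmark table (with per-trial uniform offsets where specified).
.landmark_passages <- function(track, seed) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(.derive_seed(seed, 11L))
  rows <- list()
  trial0 <- 0L
  for (bi in seq_along(track$blocks)) {
    b <- track$blocks[[bi]]
    for (tr in seq_len(b$n_trials)) {
      off <- if (!is.null(b$trial_offset_range))
        stats::runif(1, b$trial_offset_range[1], b$trial_offset_range[2]) else 0
      if (nrow(b$landmarks)) {
        rows[[length(rows) + 1L]] <- data.frame(
          block = bi, trial = trial0 + tr, id = b$landmarks$id,
          position_cm = b$landmarks$position_cm + off, offset_cm = off)
      } else {
        # no landmarks: still record the trial offset (for the reward zone)
        rows[[length(rows) + 1L]] <- data.frame(
          block = bi, trial = trial0 + tr, id = "<offset>",
          position_cm = NA_real_, offset_cm = off)
      }
    }
    trial0 <- trial0 + b$n_trials
  }
  do.call(rbind, rows)
}

#' Simulate the latent bump trajectory on the neural sheet
#'
#' Forward-Euler integration in travelled distance (2-cm steps by default) of
#' the pinning dynamics
#' `d theta / dx = v(gamma) + sum_i alpha_i d(rho_i, theta) F(p_i - x)`,
#' where `v` has magnitude `(sqrt(3)/2) * 2*pi / lambda` sheet-radians per cm
#' (one full torus revolution every lambda cm along each lattice axis) and,
#' during dark running, the slice angle `gamma` performs a Gaussian random
#' walk with variance `D * distance` (with visual input the angle is held
#' by the landmarks and optic flow; pinning provides the distortion
#' instead). The boxcar window `F` covers the `influence_window_cm`
#' preceding each landmark.
#'
#' @param track a [track_spec()].
#' @param params a [sim_params()].
#' @param seed RNG seed.
#' @param module module index (selects the grid scale).
#' @param gamma_increments optional pre-drawn angle increments (radians, one
#'   per bin) shared across modules; drawn internally if `NULL`.
#' @param pins optional resolved pin list (`id -> list(rho, alpha)`); resolved
#'   from `params` if `NULL`.
#' @param theta0 initial sheet position (length-2), default `c(0, 0)`.
#' @return an object of class `bump_trajectory`: a list with the bin table
#'   plus matrices `theta_unwrapped`, `theta` (wrapped), `psi`, vector
#'   `gamma`, and metadata (`scale_cm`, `gain`, `module`).
#' @export
simulate_latent_trajectory <- function(track, params, seed = 1L, module = 1L,
                                       gamma_increments = NULL, pins = NULL,
                                       theta0 = c(0, 0)) {
  bins <- .bin_table(track, params)
  n <- nrow(bins)
  dx <- params$bin_cm
  lambda <- params$grid_scales_cm[module]
  speed_theta <- sqrt(3) / 2 * 2 * pi / lambda     # |d theta / dx|, rad per cm
  D_rad2_per_cm <- params$diffusion_deg2_per_m * (pi / 180)^2 / 100

  if (is.null(gamma_increments)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(.derive_seed(seed, 3L))
    gamma_increments <- stats::rnorm(n, 0, sqrt(D_rad2_per_cm * dx))
  }
  if (is.null(pins)) pins <- .resolve_pins(track, params,
                                           length(params$grid_scales_cm), seed)
  passages <- .landmark_passages(track, seed)

  gamma0 <- params$slice_angle_deg * pi / 180
  # the slice angle random-walks in darkness; with visual input the angle is
  # held by the landmarks/optic flow, so increments apply to dark bins only
  gamma <- gamma0 + cumsum(gamma_increments * bins$dark)

  # precompute, per bin, the active pins (rho1, rho2, alpha rows)
  act <- vector("list", n)
  win <- params$influence_window_cm
  pas <- passages[passages$id != "<offset>", , drop = FALSE]
  if (nrow(pas)) {
    nb_per_trial <- max(bins$bin)
    trial_row0 <- (match(unique(bins$trial), bins$trial) - 1L)
    names(trial_row0) <- unique(bins$trial)
    for (r in seq_len(nrow(pas))) {
      p <- pins[[pas$id[r]]]
      b1 <- min(nb_per_trial, max(1L, ceiling(pas$position_cm[r] / dx)))
      b0 <- max(1L, b1 - as.integer(round(win / dx)) + 1L)
      row0 <- trial_row0[[as.character(pas$trial[r])]]
      entry <- c(p$rho[[module]], p$alpha)
      for (j in (row0 + b0):(row0 + b1)) {
        act[[j]] <- c(act[[j]], entry)
      }
    }
  }
  shifts <- .hex_lattice_shifts()
  theta <- matrix(0, n, 2)
  cur <- as.numeric(theta0)
  sqrt3 <- sqrt(3)
  for (j in seq_len(n)) {
    g <- gamma[j] + pi / 6   # velocity direction in theta coordinates
    s1 <- speed_theta * dx * cos(g)
    s2 <- speed_theta * dx * sin(g)
    aj <- act[[j]]
    if (!is.null(aj) && !bins$dark[j]) {
      # wrap the current point into the unit cell (scalar fast path)
      p2 <- (2 * cur[2] / sqrt3) %% (2 * pi)
      p1 <- (cur[1] + cur[2] / sqrt3) %% (2 * pi)
      w1 <- (p1 - p2 / 2) %% (2 * pi)
      w2 <- sqrt3 / 2 * p2
      for (m in seq_len(length(aj) %/% 3)) {
        d1 <- aj[3 * m - 2] - w1
        d2 <- aj[3 * m - 1] - w2
        cand1 <- d1 - shifts[, 1]
        cand2 <- d2 - shifts[, 2]
        k <- which.min(cand1 * cand1 + cand2 * cand2)
        # exponential (exact relaxation) step: stable for any alpha * dx,
        # first-order identical to alpha * d * dx for weak pins
        alpha_dx <- 1 - exp(-aj[3 * m] * dx)
        s1 <- s1 + alpha_dx * cand1[k]
        s2 <- s2 + alpha_dx * cand2[k]
      }
    }
    cur[1] <- cur[1] + s1
    cur[2] <- cur[2] + s2
    theta[j, 1] <- cur[1]
    theta[j, 2] <- cur[2]
  }

  wrapped <- torus_wrap(theta)
  structure(list(bins = bins, theta_unwrapped = theta, theta = wrapped,
                 psi = hex_inverse(wrapped, wrap = TRUE), gamma = gamma,
                 scale_cm = lambda, gain = 2 * pi / lambda, module = module,
                 passages = passages, pins = pins,
                 track = track, params = params),
            class = "bump_trajectory")
}

#' Firing rates from a bump trajectory
#'
#' The rate of cell `i` at bin `x` is a decreasing function of the torus
#' distance between its phase and the bump centre of mass:
#' `r_i(x) = peak * exp((sum_a cos(psi_a(x) - phi_a^i) - 3) / w^2)`,
#' which peaks at `peak_rate_hz` when the phases coincide.
#'
#' @param phases n_cells x 3 phase matrix (see [draw_phases()]).
#' @param traj a `bump_trajectory`.
#' @param params a [sim_params()].
#' @return bins x cells matrix of rates (Hz).
#' @export
rates_from_trajectory <- function(phases, traj, params = traj$params) {
  psi <- traj$psi
  S <- matrix(0, nrow(psi), nrow(phases))
  for (a in 1:3) {
    S <- S + outer(cos(psi[, a]), cos(phases[, a])) +
      outer(sin(psi[, a]), sin(phases[, a]))
  }
  params$peak_rate_hz * exp((S - 3) / params$bump_width^2)
}

#' Draw Poisson spike trains from binned rates
#'
#' Per-bin spike counts are Poisson with mean `rate * occupancy`; timestamps
#' are uniform within each bin's occupancy interval.
#'
#' @param rates bins x cells rate matrix (Hz).
#' @param bins bin table (`t_start`, `dur_s` columns), e.g. `traj$bins`.
#' @param seed RNG seed.
#' @return list of numeric spike-time vectors, one per cell.
#' @export
spikes_from_rates <- function(rates, bins, seed = 1L) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(.derive_seed(seed, 13L))
  lapply(seq_len(ncol(rates)), function(i) {
    counts <- stats::rpois(nrow(rates), rates[, i] * bins$dur_s)
    nz <- which(counts > 0)
    if (!length(nz)) return(numeric(0))
    ts <- rep(bins$t_start[nz], counts[nz]) +
      stats::runif(sum(counts[nz])) * rep(bins$dur_s[nz], counts[nz])
    sort(ts)
  })
}

#' Simulate licking and reward behaviour
#'
#' Expert mode concentrates anticipatory licks in the 10 cm before the reward
#' zone and reliably triggers the reward; chance mode licks uniformly. A
#' reward is triggered by the first lick in the trigger zone (first 10 cm of
#' the reward zone); otherwise an automatic reward is delivered at the end of
#' the trigger zone. Consummatory licks follow the reward inside the zone.
#'
#' @param track a [track_spec()].
#' @param params a [sim_params()].
#' @param seed RNG seed.
#' @param passages optional landmark/offset table from the latent simulation
#'   (keeps the per-trial offsets consistent); regenerated if `NULL`.
#' @return data.frame of events: `time_s, position_cm, trial, block,
#'   event_type` (`"lick"`, `"reward"`), `consummatory` flag.
#' @export
simulate_behaviour <- function(track, params, seed = 1L, passages = NULL) {
  if (is.null(passages)) passages <- .landmark_passages(track, seed)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(.derive_seed(seed, 17L))
  L <- track$track_length_cm
  speed <- params$speed_cm_s
  lam <- if (is.null(params$lick_rate_hz)) 4 else params$lick_rate_hz
  trial_dur <- L / speed
  ev <- list()
  trial0 <- 0L
  offs <- unique(passages[, c("trial", "offset_cm")])
  for (bi in seq_along(track$blocks)) {
    b <- track$blocks[[bi]]
    for (tr in seq_len(b$n_trials)) {
      gtrial <- trial0 + tr
      t0 <- (gtrial - 1) * trial_dur
      pos2t <- function(p) t0 + p / speed
      add <- function(pos, type, consum = FALSE) {
        ev[[length(ev) + 1L]] <<- data.frame(
          time_s = pos2t(pos), position_cm = pos, trial = gtrial, block = bi,
          event_type = type, consummatory = consum)
      }
      if (is.null(b$reward_zone)) { next }
      off <- offs$offset_cm[offs$trial == gtrial]
      if (!length(off) || is.na(off[1])) off <- 0 else off <- off[1]
      zone <- b$reward_zone + off
      trig <- c(zone[1], min(zone[1] + 10, zone[2]))
      # anticipatory / exploratory licks
      if (params$behaviour_mode == "expert") {
        n_ant <- stats::rpois(1, lam)
        licks <- stats::runif(n_ant, zone[1] - 10, zone[1])
        # expert animals lick continuously approaching the zone, so the
        # triggering lick clusters just past the zone entry
        trig_lick <- if (stats::runif(1) < 0.95)
          trig[1] + min(stats::rexp(1, 1 / 2), trig[2] - trig[1] - 0.1) else NULL
        if (!is.null(trig_lick)) licks <- c(licks, trig_lick)
      } else {
        licks <- stats::runif(stats::rpois(1, lam), 0, L)
        in_trig <- licks >= trig[1] & licks < trig[2]
        trig_lick <- if (any(in_trig)) min(licks[in_trig]) else NULL
      }
      for (p in sort(licks)) add(p, "lick")
      if (!is.null(trig_lick)) {
        reward_pos <- trig_lick
      } else if (b$auto_reward) {
        reward_pos <- trig[2]
      } else reward_pos <- NA_real_
      if (!is.na(reward_pos)) {
        add(reward_pos, "reward")
        n_con <- 1 + stats::rpois(1, lam)
        hi <- max(reward_pos, min(reward_pos + 5, L - 0.05))
        cons <- stats::runif(n_con, reward_pos, hi)
        for (p in sort(cons)) add(p, "lick", consum = TRUE)
      }
    }
    trial0 <- trial0 + b$n_trials
  }
  if (!length(ev)) {
    return(data.frame(time_s = numeric(), position_cm = numeric(),
                      trial = integer(), block = integer(),
                      event_type = character(), consummatory = logical()))
  }
  out <- do.call(rbind, ev)
  out[order(out$time_s), ]
}

#' Simulate a complete session
#'
#' Runs the latent bump trajectory for every module (sharing one slice-angle
#' diffusion realization, so modules drift together), draws per-cell phases,
#' computes rates, draws Poisson spikes, builds the 50 Hz behaviour trace and
#' the lick/reward event table, and attaches the ground truth.
#'
#' @param track a [track_spec()].
#' @param params a [sim_params()].
#' @param seed RNG seed; identical `(track, params, seed)` give identical
#'   sessions.
#' @return an object of class `sim_session`: list with `behaviour` (50 Hz
#'   trace), `events`, `spikes` (list per unit), `unit_table`
#'   (unit - module map), `bins`, and `ground_truth` (trajectories, phases,
#'   pins, rates).
#' @export
simulate_session <- function(track, params = sim_params(), seed = 1L) {
  n_mod <- length(params$grid_scales_cm)
  bins <- .bin_table(track, params)
  n <- nrow(bins)
  D_rad2_per_cm <- params$diffusion_deg2_per_m * (pi / 180)^2 / 100
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(.derive_seed(seed, 3L))
  gamma_inc <- stats::rnorm(n, 0, sqrt(D_rad2_per_cm * params$bin_cm))
  .restore_rng(old)

  pins <- .resolve_pins(track, params, n_mod, seed)
  trajs <- lapply(seq_len(n_mod), function(m)
    simulate_latent_trajectory(track, params, seed = seed, module = m,
                               gamma_increments = gamma_inc, pins = pins))
  phases <- lapply(seq_len(n_mod), function(m)
    draw_phases(params$n_cells_per_module, seed = .derive_seed(seed, 19L + m)))
  rates <- lapply(seq_len(n_mod), function(m)
    rates_from_trajectory(phases[[m]], trajs[[m]], params))
  all_rates <- do.call(cbind, rates)
  spikes <- spikes_from_rates(all_rates, bins, seed = .derive_seed(seed, 23L))
  unit_table <- data.frame(
    unit = seq_len(ncol(all_rates)),
    module = rep(seq_len(n_mod), each = params$n_cells_per_module))

  events <- simulate_behaviour(track, params, seed = seed,
                               passages = trajs[[1]]$passages)
  behaviour <- .behaviour_trace(track, params, bins, events)

  structure(list(track = track, params = params, seed = seed,
                 behaviour = behaviour, events = events, spikes = spikes,
                 unit_table = unit_table, bins = bins,
                 ground_truth = list(trajectories = trajs, phases = phases,
                                     pins = pins, rates = rates)),
            class = "sim_session")
}

# 50 Hz behaviour trace: position linearly interpolated within trials.
.behaviour_trace <- function(track, params, bins, events) {
  total_t <- max(bins$t_start) + bins$dur_s[1]
  t <- seq(0, total_t, by = params$dt_s)
  L <- track$track_length_cm
  trial_dur <- L / params$speed_cm_s
  trial <- pmin(floor(t / trial_dur) + 1L, max(bins$trial))
  pos <- (t %% trial_dur) * params$speed_cm_s
  lick <- logical(length(t)); reward <- logical(length(t))
  if (nrow(events)) {
    li <- findInterval(events$time_s[events$event_type == "lick"], t)
    ri <- findInterval(events$time_s[events$event_type == "reward"], t)
    lick[pmax(1, li)] <- TRUE
    reward[pmax(1, ri)] <- TRUE
  }
  data.frame(time_s = t, position_cm = pos, trial = trial,
             speed_cm_s = params$speed_cm_s, lick = lick, reward = reward)
}

#' @export
print.sim_session <- function(x, ...) {
  cat(sprintf("<sim_session> %d units in %d module(s), %d trials, %.1f m travelled\n",
              length(x$spikes), length(x$ground_truth$trajectories),
              max(x$bins$trial), max(x$bins$cum_cm) / 100))
  invisible(x)
}
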