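# Fixed landmark-pinning model -------------------------------------------

#' Local code stability around a landmark
#'
#' Cross-environment stability of the population code anchored to a
#' landmark: for each block, the trial-averaged population tuning in the
#' window preceding the landmark (aligned on the landmark position), then
#' the mean pairwise Pearson correlation across blocks. A strongly pinning
#' landmark anchors the same code in every environment; an uninfluential
#' one inherits whatever history each environment brings.
#'
#' @param rm a `rate_map`.
#' @param units unit indices.
#' @param passages landmark passage table (one landmark id).
#' @param window_cm window before the landmark (default 50).
#' @return mean correlation in `[-1, 1]`.
#' @keywords internal
.landmark_stability <- function(rm, units, passages, window_cm = 50) {
  bin <- rm$bin_cm
  nb <- dim(rm$rates)[3]
  wb <- round(window_cm / bin)
  by_block <- split(passages, passages$block)
  vecs <- lapply(by_block, function(pb) {
    per_trial <- lapply(seq_len(nrow(pb)), function(j) {
      b1 <- pmin(nb, pmax(1L, floor(pb$position_cm[j] / bin)))
      b0 <- pmax(1L, b1 - wb + 1L)
      v <- as.vector(rm$rates[units, pb$trial[j], b0:b1])
      v[is.na(v)] <- 0
      v
    })
    len <- min(lengths(per_trial))
    # right-align so the landmark-adjacent bins line up across trials
    rowMeans(vapply(per_trial, function(v) v[(length(v) - len + 1):length(v)],
                    numeric(len)))
  })
  len <- min(lengths(vecs))
  M <- vapply(vecs, function(v) v[(length(v) - len + 1):length(v)], numeric(len))
  if (ncol(M) < 2) return(NA_real_)
  cc <- suppressWarnings(stats::cor(M))
  mean(cc[upper.tri(cc)], na.rm = TRUE)
}

#' Fit landmark pinning phases and strengths
#'
#' For each landmark, the pinning phase `rho_i` is the circular centroid of
#' the bump position at passages of that landmark across the held-in blocks,
#' and the strength `alpha_i` is an affine map of the local code stability
#' `s` into `[0, alpha_max]`: `alpha_i = alpha_max * max(s, 0)`. The default
#' `alpha_max` equals the sheet speed `(sqrt(3)/2) * gain` per cm, so a pin
#' at full stability holds the moving bump within about one radian of its
#' phase (the pinning ODE balances the pull `alpha * d` against the drive
#' `|v|`, leaving a trailing distance `|v| / alpha`). Because of that
#' trailing distance the raw passage centroid overshoots `rho_i`
#' systematically; [refine_pins()] removes the model-predicted lag.
#'
#' @param bump_lm data.frame from [bump_at_landmarks()] (bump position per
#'   passage).
#' @param rm a `rate_map` (for the stability estimate).
#' @param units module unit indices.
#' @param passages landmark passage table.
#' @param heldin_blocks block indices used for fitting.
#' @param gain sheet gain `2*pi/lambda` (rad/cm).
#' @param D angular diffusion constant (deg^2/m).
#' @param window_cm landmark influence window (cm).
#' @param alpha_max maximum pin strength (per cm).
#' @return object of class `pinning_model`: `pins` (id -> list(rho, alpha,
#'   stability, n_passages)), `gain`, `D`, `window_cm`, `eta`.
#' @export
fit_pins <- function(bump_lm, rm, units, passages, heldin_blocks,
                     gain, D = 0, window_cm = 50,
                     alpha_max = sqrt(3) / 2 * gain) {
  bl <- bump_lm[bump_lm$block %in% heldin_blocks, , drop = FALSE]
  pas <- passages[passages$id != "<offset>" & passages$block %in% heldin_blocks, ,
                  drop = FALSE]
  ids <- unique(bl$id)
  pins <- list()
  for (id in ids) {
    sub <- bl[bl$id == id, , drop = FALSE]
    if (!nrow(sub)) { warning("landmark ", id, " never encountered; excluded"); next }
    disp <- pinning_dispersion(cbind(sub$theta1, sub$theta2))
    s <- .landmark_stability(rm, units, pas[pas$id == id, , drop = FALSE],
                             window_cm = window_cm)
    alpha <- alpha_max * max(s, 0, na.rm = TRUE)
    pins[[id]] <- list(rho = list(disp$mean_theta), alpha = alpha,
                       stability = s, n_passages = nrow(sub),
                       sigma2 = disp$sigma2)
  }
  structure(list(pins = pins, gain = gain, D = D, window_cm = window_cm,
                 eta = 0), class = "pinning_model")
}

#' Simulate the fitted model on a held-out environment
#'
#' Integrates the pinning dynamics with the fitted parameters on the
#' held-out track and returns the predicted bump trajectory and per-cell
#' firing rates for the recorded units' phases.
#'
#' @param model a `pinning_model`.
#' @param heldout_track a [track_spec()] containing the held-out block(s).
#' @param phases units x 3 phase matrix of the recorded cells.
#' @param seed RNG seed (used for the diffusion realization).
#' @param params optional [sim_params()] template (peak rate, bump width...).
#' @return list with `traj` (`bump_trajectory`), `rates` (bins x units),
#'   `tuning` (units x bins, trial-averaged).
#' @export
simulate_heldout <- function(model, heldout_track, phases, seed = 1L,
                             params = NULL) {
  lambda <- 2 * pi / model$gain
  if (is.null(params)) params <- sim_params()
  params$grid_scales_cm <- lambda
  params$diffusion_deg2_per_m <- model$D
  params$influence_window_cm <- model$window_cm
  pins <- lapply(model$pins, function(p) list(rho = p$rho, alpha = p$alpha))
  traj <- simulate_latent_trajectory(heldout_track, params, seed = seed,
                                     module = 1L, pins = pins)
  rates <- rates_from_trajectory(phases, traj, params)
  nb <- max(traj$bins$bin)
  tuning <- t(vapply(seq_len(ncol(rates)), function(i)
    colMeans(matrix(rates[, i], ncol = nb, byrow = TRUE)), numeric(nb)))
  list(traj = traj, rates = rates, tuning = tuning)
}

#' Model predictivity
#'
#' Per-cell Pearson correlation between predicted and observed tuning
#' curves, averaged over blocks.
#'
#' @param pred list of units x bins predicted tuning matrices (one per
#'   block), or a single matrix.
#' @param obs matching observed tuning matrices.
#' @return numeric vector: mean correlation per cell.
#' @export
predictivity <- function(pred, obs) {
  if (is.matrix(pred)) { pred <- list(pred); obs <- list(obs) }
  n_cells <- nrow(pred[[1]])
  per_block <- vapply(seq_along(pred), function(b) {
    vapply(seq_len(n_cells), function(i) {
      p <- pred[[b]][i, ]; o <- obs[[b]][i, ]
      ok <- !is.na(p) & !is.na(o)
      if (sum(ok) < 3 || stats::sd(p[ok]) == 0 || stats::sd(o[ok]) == 0)
        return(NA_real_)
      stats::cor(p[ok], o[ok])
    }, 0)
  }, numeric(n_cells))
  rowMeans(matrix(per_block, nrow = n_cells), na.rm = TRUE)
}

#' Shuffle null distributions for model predictivity
#'
#' `shift`: circularly shifts each cell's predicted tuning curve by an
#' independent `Uniform(0, L)` amount per repetition (preserving each
#' curve's autocorrelation spectrum exactly). `scramble_landmarks` is
#' implemented in [crossval_pinning()], where the model can be re-simulated.
#'
#' @param pred units x bins predicted tuning (single block) or list per
#'   block.
#' @param obs matching observed tuning.
#' @param n repetitions.
#' @param seed RNG seed.
#' @return n x cells matrix of null predictivities.
#' @export
shuffle_shift_null <- function(pred, obs, n = 100, seed = 1L) {
  if (is.matrix(pred)) { pred <- list(pred); obs <- list(obs) }
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  nb <- ncol(pred[[1]])
  n_cells <- nrow(pred[[1]])
  t(vapply(seq_len(n), function(r) {
    sh <- lapply(pred, function(P) {
      t(vapply(seq_len(n_cells), function(i) {
        k <- sample.int(nb, 1) - 1L
        if (k == 0) P[i, ] else c(P[i, (k + 1):nb], P[i, 1:k])
      }, numeric(nb)))
    })
    predictivity(sh, obs)
  }, numeric(n_cells)))
}

# Pooled estimate of the pinning strength from observed bump steps.
# Within a single landmark's window the step obeys
#   step_{j+1} - step_j = -(1 - exp(-alpha dx)) * step_j
# (the pull relaxes toward a fixed target, so consecutive step differences
# are proportional to the step itself); regressing step differences on
# steps therefore recovers alpha without knowing rho or the drive velocity.
.estimate_alpha_scale <- function(theta, bins, passages, rho_list,
                                  window_cm, bin_cm) {
  n <- nrow(theta)
  pas <- passages[passages$id != "<offset>" & !is.na(passages$position_cm), ,
                  drop = FALSE]
  if (!nrow(pas)) return(NA_real_)
  nb <- max(bins$bin)
  wb <- as.integer(round(window_cm / bin_cm))
  active_id <- rep(NA_character_, n)
  active_n <- integer(n)
  trial_row0 <- (match(unique(bins$trial), bins$trial) - 1L)
  names(trial_row0) <- unique(bins$trial)
  for (r in seq_len(nrow(pas))) {
    b1 <- min(nb, max(1L, ceiling(pas$position_cm[r] / bin_cm)))
    b0 <- max(1L, b1 - wb + 1L)
    rows <- trial_row0[[as.character(pas$trial[r])]] + (b0:b1)
    active_id[rows] <- pas$id[r]
    active_n[rows] <- active_n[rows] + 1L
  }
  steps <- torus_displacement(theta[-1, , drop = FALSE],
                              theta[-n, , drop = FALSE])
  # consecutive step pairs fully inside one landmark's window, same trial
  j_all <- seq_len(n - 2L)
  ok <- active_n[j_all] == 1 & active_n[j_all + 1] == 1 &
    active_n[j_all + 2] == 1 &
    active_id[j_all] == active_id[j_all + 1] &
    active_id[j_all + 1] == active_id[j_all + 2] &
    bins$trial[j_all] == bins$trial[j_all + 2]
  ok[is.na(ok)] <- FALSE
  fit_one <- function(j) {
    if (length(j) < 10) return(NA_real_)
    ds <- steps[j + 1, , drop = FALSE] - steps[j, , drop = FALSE]
    s0 <- steps[j, , drop = FALSE]
    # guard against image switches: drop outlying step magnitudes
    mag <- sqrt(rowSums(s0^2))
    keep <- mag < 3 * stats::median(mag) &
      sqrt(rowSums(ds^2)) < 2 * stats::median(mag)
    if (sum(keep) < 10) return(NA_real_)
    cfac <- -sum(ds[keep, ] * s0[keep, ]) / sum(s0[keep, ]^2)
    if (!is.finite(cfac) || cfac >= 1) return(NA_real_)
    max(0, -log(1 - max(cfac, 0)) / bin_cm)
  }
  ids <- unique(stats::na.omit(active_id))
  per <- vapply(ids, function(id)
    fit_one(j_all[ok & !is.na(active_id[j_all]) & active_id[j_all] == id]), 0)
  names(per) <- ids
  pooled <- fit_one(j_all[ok])
  list(pooled = pooled, per_landmark = per)
}

#' Self-consistency refinement of pinning phases
#'
#' The passage-centroid estimate of `rho_i` is biased by the trailing
#' distance of the pinned bump. This refinement simulates the fitted model
#' on the held-in blocks, measures the model's own passage centroids, and
#' shifts each `rho_i` by the discrepancy between the observed and the
#' model-predicted centroid (a fixed-point iteration on the moment
#' condition "model passage centroid = observed passage centroid").
#'
#' @param model a `pinning_model` (centroid-initialized).
#' @param track the parent [track_spec()].
#' @param heldin_blocks block indices the model was fitted on.
#' @param obs_centroids named list `id -> length-2 theta` of observed
#'   passage centroids.
#' @param params [sim_params()] template for the forward simulation.
#' @param n_iter fixed-point iterations (default 3).
#' @param seed RNG seed (only relevant if `model$D > 0`).
#' @param obs_theta optional observed bump positions (bins x 2, held-in
#'   blocks only); when given, the pooled pinning strength is re-estimated
#'   each iteration by regressing the velocity-corrected bump steps on the
#'   displacement to the current pins, and the per-landmark strengths are
#'   rescaled to that value (preserving the stability ordering).
#' @param obs_bins,obs_passages bin table and passage table matching
#'   `obs_theta`.
#' @return the refined `pinning_model`.
#' @export
refine_pins <- function(model, track, heldin_blocks, obs_centroids, params,
                        n_iter = 3, seed = 1L, obs_theta = NULL,
                        obs_bins = NULL, obs_passages = NULL) {
  sub <- .subset_track(track, heldin_blocks)
  sim_params_local <- params
  sim_params_local$grid_scales_cm <- 2 * pi / model$gain
  sim_params_local$diffusion_deg2_per_m <- model$D
  sim_params_local$influence_window_cm <- model$window_cm
  for (it in seq_len(n_iter)) {
    if (!is.null(obs_theta)) {
      rho_list <- lapply(model$pins, function(p) p$rho[[1]])
      a_est <- .estimate_alpha_scale(obs_theta, obs_bins, obs_passages,
                                     rho_list, model$window_cm,
                                     params$bin_cm)
      for (k in seq_along(model$pins)) {
        id <- names(model$pins)[k]
        a_k <- a_est$per_landmark[[id]]
        if (is.null(a_k) || !is.finite(a_k)) a_k <- a_est$pooled
        if (is.finite(a_k)) model$pins[[k]]$alpha <- a_k
      }
    }
    pins <- lapply(model$pins, function(p) list(rho = p$rho, alpha = p$alpha))
    traj <- simulate_latent_trajectory(sub, sim_params_local, seed = seed,
                                       module = 1L, pins = pins)
    sim_bump <- structure(list(theta = traj$theta, psi = traj$psi,
                               mask = rep(TRUE, nrow(traj$theta))),
                          class = "bump_com")
    sim_lm <- bump_at_landmarks(sim_bump, traj$bins, traj$passages)
    for (id in names(model$pins)) {
      subl <- sim_lm[sim_lm$id == id, , drop = FALSE]
      if (nrow(subl) < 2 || is.null(obs_centroids[[id]])) next
      # drop the first lap of each simulation (initial-condition transient)
      subl <- subl[subl$trial > 1, , drop = FALSE]
      mod_c <- pinning_dispersion(cbind(subl$theta1, subl$theta2))$mean_theta
      delta <- drop(torus_displacement(matrix(obs_centroids[[id]], 1),
                                       matrix(mod_c, 1)))
      rho <- model$pins[[id]]$rho[[1]] + delta
      model$pins[[id]]$rho[[1]] <- drop(torus_wrap(matrix(rho, 1)))
    }
  }
  model
}

# Track made of a subset of blocks of a parent track (order preserved).
.subset_track <- function(track, blocks) {
  bl <- track$blocks[blocks]
  bl <- lapply(bl, function(b) { b$trial_offset_range <- NULL; b })
  track_spec(track$track_length_cm, bl, lookahead_cm = track$lookahead_cm,
             seamless = track$seamless)
}

# Build a single-block track_spec from one block of a parent track.
.single_block_track <- function(track, block_index, n_trials = NULL) {
  b <- track$blocks[[block_index]]
  if (!is.null(n_trials)) b$n_trials <- as.integer(n_trials)
  b$trial_offset_range <- NULL           # predictions are offset-free
  track_spec(track$track_length_cm, list(b), lookahead_cm = track$lookahead_cm,
             seamless = track$seamless)
}

#' Leave-one-block-out pinning-model cross-validation
#'
#' For each held-out environment block: fits pinning phases and strengths on
#' the remaining blocks (optionally with online Hebbian pin updates at rate
#' `eta` while replaying the held-in blocks in order), simulates the model
#' on the held-out block, and scores per-cell predictivity against the
#' observed tuning curves.
#'
#' @param session a `sim_session` (random-environment design).
#' @param phases units x 3 phases of the module's cells (e.g. ground truth
#'   or [classify_gridcells()] output).
#' @param units unit indices corresponding to `phases`.
#' @param gain sheet gain (rad/cm); e.g. `2*pi/scale`.
#' @param D diffusion constant used in the model simulation (deg^2/m).
#' @param eta Hebbian pin learning rate (0 = fixed model).
#' @param env_blocks indices of the environment blocks (default: all
#'   non-dark blocks).
#' @param seed RNG seed.
#' @param rm optional precomputed `rate_map`.
#' @param scramble if `TRUE`, landmark positions are randomly permuted
#'   before the held-out simulation (null model).
#' @return list with `predictivity` (cells, averaged over held-out blocks),
#'   `per_block` (blocks x cells), `models` (per held-out block).
#' @export
crossval_pinning <- function(session, phases, units, gain, D = 0, eta = 0,
                             env_blocks = NULL, seed = 1L, rm = NULL,
                             scramble = FALSE) {
  track <- session$track
  if (is.null(env_blocks)) {
    env_blocks <- which(!vapply(track$blocks, `[[`, TRUE, "dark") &
                          vapply(track$blocks, function(b) nrow(b$landmarks) > 0, TRUE))
  }
  if (is.null(rm)) rm <- compute_ratemap(session)
  rates <- population_rates(rm, units)
  bump <- bump_com(rates, phases)
  passages <- session$ground_truth$trajectories[[1]]$passages
  bump_lm <- bump_at_landmarks(bump, session$bins, passages)
  nb <- dim(rm$rates)[3]

  per_block <- matrix(NA_real_, length(env_blocks), length(units))
  models <- vector("list", length(env_blocks))
  for (hi in seq_along(env_blocks)) {
    hold <- env_blocks[hi]
    heldin <- setdiff(env_blocks, hold)
    model <- fit_pins(bump_lm, rm, units, passages, heldin, gain = gain, D = D)
    obs_centroids <- lapply(model$pins, function(p) p$rho[[1]])
    hmask <- session$bins$block %in% heldin
    model <- refine_pins(model, track, heldin, obs_centroids, session$params,
                         seed = .derive_seed(seed, 41L + hi),
                         obs_theta = bump$theta[hmask, , drop = FALSE],
                         obs_bins = session$bins[hmask, , drop = FALSE],
                         obs_passages = passages[passages$block %in% heldin, ,
                                                 drop = FALSE])
    if (eta > 0) {
      # replay held-in blocks chronologically, nudging pins toward the
      # observed bump position at every passage
      bl <- bump_lm[bump_lm$block %in% heldin, , drop = FALSE]
      bl <- bl[order(bl$trial), , drop = FALSE]
      for (j in seq_len(nrow(bl))) {
        id <- bl$id[j]
        if (is.null(model$pins[[id]])) next
        rho <- model$pins[[id]]$rho[[1]]
        obs <- c(bl$theta1[j], bl$theta2[j])
        step <- drop(torus_displacement(matrix(obs, 1), matrix(rho, 1)))
        model$pins[[id]]$rho[[1]] <- drop(torus_wrap(matrix(rho + eta * step, 1)))
      }
      model$eta <- eta
    }
    ho_track <- .single_block_track(track, hold)
    if (scramble) {
      lm <- ho_track$blocks[[1]]$landmarks
      old <- .save_rng()
      set.seed(.derive_seed(seed, 29L + hi))
      lm$position_cm <- sample(lm$position_cm)
      .restore_rng(old)
      ho_track$blocks[[1]]$landmarks <- lm
    }
    sim <- simulate_heldout(model, ho_track, phases,
                            seed = .derive_seed(seed, 31L + hi),
                            params = session$params)
    obs_tuning <- tuning_curves(rm, trials = which(rm$trial_block == hold))[units, , drop = FALSE]
    per_block[hi, ] <- predictivity(sim$tuning[, seq_len(nb), drop = FALSE],
                                    obs_tuning)
    models[[hi]] <- model
  }
  list(predictivity = colMeans(per_block, na.rm = TRUE), per_block = per_block,
       models = models)
}

#' Hebbian learning-rate sweep
#'
#' Runs [crossval_pinning()] for each learning rate in `eta_grid` and
#' reports the rate with the best mean held-out predictivity. The `eta = 0`
#' entry is the fixed model.
#'
#' @inheritParams crossval_pinning
#' @param eta_grid learning rates to evaluate (must include 0).
#' @return list with `eta_grid`, `mean_predictivity` per eta, `best_eta`,
#'   `fits` (full cross-validation output per eta).
#' @export
hebbian_variant <- function(session, phases, units, gain, D = 0,
                            eta_grid = c(0, 0.01, 0.05, 0.1, 0.5),
                            env_blocks = NULL, seed = 1L, rm = NULL) {
  stopifnot(0 %in% eta_grid)
  if (is.null(rm)) rm <- compute_ratemap(session)
  fits <- lapply(eta_grid, function(eta)
    crossval_pinning(session, phases, units, gain = gain, D = D, eta = eta,
                     env_blocks = env_blocks, seed = seed, rm = rm))
  mp <- vapply(fits, function(f) mean(f$predictivity, na.rm = TRUE), 0)
  list(eta_grid = eta_grid, mean_predictivity = mp,
       best_eta = eta_grid[which.max(mp)], fits = fits)
}
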