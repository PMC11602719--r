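# Fixed landmark-pinning model: fitting, held-out prediction, Hebbian sweep.

# A compact multi-environment session for model fitting: 6 environments of
# 10 trials on a 100-cm track, one module, expert behaviour.
pin_session <- function() {
  cached("pin_ses", {
    tr <- make_track("random_env", seed = 4,
                     options = list(n_trials = 10L, n_dark_trials = 10L,
                                    n_env_blocks = 6L))
    p <- sim_params(n_cells_per_module = 32L, grid_scales_cm = 50,
                    diffusion_deg2_per_m = 1.16, behaviour_mode = "expert")
    simulate_session(tr, p, seed = 4)
  })
}

test_that("pinning phases are recovered on an identifiable design", {
  # landmarks far enough apart that influence windows do not overlap, and
  # the noiseless latent bump as input: isolates the estimator itself
  set.seed(31)
  blocks <- lapply(1:5, function(i) {
    pos <- sort(sample(seq(60, 310, by = 10), 4))
    while (min(diff(pos)) < 60) pos <- sort(sample(seq(60, 310, by = 10), 4))
    block_spec(8, landmarks = data.frame(id = paste0("lm", 1:4),
                                         position_cm = pos))
  })
  tr <- track_spec(320, blocks)
  p <- quiet_params(diffusion_deg2_per_m = 1.16, pin_alpha = 0.05,
                    n_cells_per_module = 32L)
  traj <- simulate_latent_trajectory(tr, p, seed = 31)
  bump <- structure(list(theta = traj$theta, psi = traj$psi,
                         mask = rep(TRUE, nrow(traj$theta))),
                    class = "bump_com")
  bl <- bump_at_landmarks(bump, traj$bins, traj$passages)
  # a noiseless stand-in rate map for the stability estimate
  ses <- simulate_session(tr, p, seed = 31)
  rm <- compute_ratemap(ses)
  model <- fit_pins(bl, rm, 1:32, traj$passages, heldin_blocks = 1:5,
                    gain = 2 * pi / 50)
  obs_centroids <- lapply(model$pins, function(pp) pp$rho[[1]])
  model <- refine_pins(model, tr, 1:5, obs_centroids, p,
                       obs_theta = bump$theta, obs_bins = traj$bins,
                       obs_passages = traj$passages)
  for (id in names(model$pins)) {
    err <- torus_distance(matrix(model$pins[[id]]$rho[[1]], 1),
                          matrix(traj$pins[[id]]$rho[[1]], 1))
    expect_lt(err, 0.2)
  }
})

test_that("single passage gives the one-sample centroid", {
  bl <- data.frame(id = "a", block = 1, trial = 1, theta1 = 1.1, theta2 = 2.2)
  pas <- data.frame(block = 1, trial = 1, id = "a", position_cm = 50,
                    offset_cm = 0)
  rm <- structure(list(rates = array(1, c(2, 1, 50)), bin_cm = 2,
                       trial_block = 1L), class = "rate_map")
  m <- fit_pins(bl, rm, 1:2, pas, heldin_blocks = 1, gain = 2 * pi / 50)
  expect_equal(m$pins[["a"]]$rho[[1]], c(1.1, 2.2), tolerance = 1e-9)
})

test_that("an unpinned landmark earns a low fitted strength", {
  tr <- make_track("random_env", seed = 9,
                   options = list(n_trials = 10L, n_dark_trials = 5L,
                                  n_env_blocks = 6L))
  pins <- list(groundR = list(alpha = 0))  # one landmark exerts no pull
  p <- sim_params(n_cells_per_module = 32L, grid_scales_cm = 50,
                  diffusion_deg2_per_m = 1.16, landmark_pins = pins,
                  behaviour_mode = "expert")
  ses <- simulate_session(tr, p, seed = 9)
  rm <- compute_ratemap(ses)
  phases <- ses$ground_truth$phases[[1]]
  rates <- population_rates(rm, 1:32)
  bump <- bump_com(rates, phases)
  passages <- ses$ground_truth$trajectories[[1]]$passages
  bl <- bump_at_landmarks(bump, ses$bins, passages)
  model <- fit_pins(bl, rm, 1:32, passages, heldin_blocks = 2:7,
                    gain = 2 * pi / 50)
  alphas <- vapply(model$pins, `[[`, 0, "alpha")
  expect_equal(unname(which.min(alphas)), which(names(alphas) == "groundR"))
})

test_that("held-out prediction beats the circular-shift null", {
  ses <- pin_session()
  rm <- compute_ratemap(ses)
  phases <- ses$ground_truth$phases[[1]]
  cv <- crossval_pinning(ses, phases, units = 1:32, gain = 2 * pi / 50,
                         D = 0, eta = 0, seed = 2, rm = rm)
  expect_gt(mean(cv$predictivity, na.rm = TRUE), 0.15)
  # shift null centred at zero, observed distribution shifted right
  hold <- 4L
  obs_tuning <- tuning_curves(rm, trials = which(rm$trial_block == hold + 1L))
  null <- shuffle_shift_null(obs_tuning, obs_tuning, n = 30, seed = 3)
  expect_lt(abs(mean(null)), 0.1)
  expect_lt(suppressWarnings(
    stats::ks.test(cv$predictivity, as.vector(null),
                   alternative = "less"))$p.value, 0.01)
  # perfect prediction scores 1; pure noise scores ~ 0
  expect_equal(mean(predictivity(obs_tuning, obs_tuning)), 1, tolerance = 1e-9)
  set.seed(8)
  noise_pred <- matrix(runif(length(obs_tuning)), nrow(obs_tuning))
  expect_lt(abs(mean(predictivity(noise_pred, obs_tuning), na.rm = TRUE)), 0.12)
})

test_that("circular-shift shuffles preserve each curve's power spectrum", {
  set.seed(5)
  pred <- matrix(runif(5 * 64), 5, 64)
  obs <- pred
  null <- shuffle_shift_null(pred, obs, n = 3, seed = 6)
  # invariance on a flat curve: shifting a constant changes nothing
  flat <- matrix(2, 1, 64)
  expect_true(all(is.na(shuffle_shift_null(flat, flat, n = 5, seed = 1)[, 1])))
  # (constant curves have no defined correlation)
  # spectrum preservation under circular shift
  v <- pred[1, ]
  k <- 17
  shifted <- c(v[(k + 1):64], v[1:k])
  expect_equal(Mod(fft(shifted)), Mod(fft(v)), tolerance = 1e-9)
})

test_that("scramble-landmark null underperforms the true model", {
  ses <- pin_session()
  rm <- compute_ratemap(ses)
  phases <- ses$ground_truth$phases[[1]]
  cv <- crossval_pinning(ses, phases, units = 1:32, gain = 2 * pi / 50,
                         D = 0, eta = 0, seed = 2, rm = rm)
  cv_scr <- crossval_pinning(ses, phases, units = 1:32, gain = 2 * pi / 50,
                             D = 0, eta = 0, seed = 2, rm = rm,
                             scramble = TRUE)
  expect_gt(mean(cv$predictivity, na.rm = TRUE),
            mean(cv_scr$predictivity, na.rm = TRUE))
})

test_that("the Hebbian sweep prefers zero learning rate on fixed-pin data", {
  ses <- pin_session()
  rm <- compute_ratemap(ses)
  phases <- ses$ground_truth$phases[[1]]
  hv <- hebbian_variant(ses, phases, units = 1:32, gain = 2 * pi / 50, D = 0,
                        eta_grid = c(0, 0.05, 0.5), seed = 2, rm = rm)
  expect_equal(hv$best_eta, 0)
  # eta = 0 is bit-identical to the fixed model
  cv0 <- crossval_pinning(ses, phases, units = 1:32, gain = 2 * pi / 50,
                          D = 0, eta = 0, seed = 2, rm = rm)
  expect_identical(hv$fits[[1]]$predictivity, cv0$predictivity)
})

test_that("prediction couples to per-block stability across cells", {
  ses <- pin_session()
  rm <- compute_ratemap(ses)
  phases <- ses$ground_truth$phases[[1]]
  cv <- crossval_pinning(ses, phases, units = 1:32, gain = 2 * pi / 50,
                         D = 0, eta = 0, seed = 2, rm = rm)
  stab <- vapply(1:32, function(u) half_session_stability(rm, u, blocks = 2:7), 0)
  ok <- is.finite(cv$predictivity) & is.finite(stab)
  rho <- stats::cor(cv$predictivity[ok], stab[ok], method = "spearman")
  expect_gt(rho, 0)
})

test_that("revisiting an environment is history-dependent only under drift", {
  lm <- data.frame(id = c("a", "b"), position_cm = c(100, 220))
  revisit_track <- function(n_dark) track_spec(320, list(
    block_spec(10, landmarks = lm),
    block_spec(n_dark, dark = TRUE),
    block_spec(10, landmarks = lm)))
  orbit_gap <- function(D, seed) {
    p <- quiet_params(diffusion_deg2_per_m = D, pin_alpha = 0.05)
    traj <- simulate_latent_trajectory(revisit_track(40L), p, seed = seed)
    at <- traj$theta[traj$bins$bin == 80, , drop = FALSE]
    # late trials of each visit (past the convergence transient)
    first <- at[8:10, , drop = FALSE]
    second <- at[58:60, , drop = FALSE]
    mean(torus_distance(second, first[rep(1:3, 1), , drop = FALSE]))
  }
  # no drift: the revisited environment reproduces the same orbit exactly
  expect_lt(orbit_gap(0, 1), 0.05)
  # with dark drift in between, some repeats settle on different orbits
  gaps <- vapply(1:5, function(s) orbit_gap(1.16, s), 0)
  expect_gt(max(gaps), 0.3)
})
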