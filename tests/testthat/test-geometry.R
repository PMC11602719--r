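# Trajectory geometry: anisometry, curvature, diffusion, scale, remapping.

test_that("anisometry is zero for constant-speed lines and exact for two-point CV", {
  th <- cbind(seq(0, 100, by = 0.1), seq(0, 50, by = 0.05))
  cv <- anisometry(th, dx_cm = 2, window_m = 16)
  expect_true(all(cv < 1e-9))
  # alternating steps of 0.1 and 0.3 rad: CV = sd/mean = 0.5 (population SD)
  steps <- rep(c(0.1, 0.3), 500)
  th2 <- cbind(cumsum(c(0, steps)), 0)
  cv2 <- anisometry(th2, dx_cm = 2, window_m = 16)
  # stats::sd is the sample SD; with n = 800 the difference is negligible
  expect_equal(unname(cv2[1]), 0.5, tolerance = 0.01)
  # mask: windows with mostly-masked bins are skipped
  mask <- rep(TRUE, nrow(th)); mask[1:600] <- FALSE
  cv3 <- anisometry(th, mask = mask)
  expect_true(is.na(cv3[1]))
})

test_that("geodesic curvature vanishes on lines and equals 1/R on circles", {
  th_line <- cbind(1:500 * 0.2, 1:500 * 0.1)
  k1 <- geodesic_curvature(th_line, dx_cm = 2, smooth_bins = 0)
  expect_lt(max(abs(k1), na.rm = TRUE), 1e-9)
  expect_equal(sum(integrated_curvature(th_line, 100, smooth_bins = 0)), 0,
               tolerance = 1e-8)
  R <- 37
  tt <- seq(0, 4 * pi, length.out = 2000)
  circ <- cbind(R * cos(tt), R * sin(tt))
  dx <- R * (tt[2] - tt[1])  # unit-speed parameterization step
  k2 <- geodesic_curvature(circ, dx_cm = dx, smooth_bins = 0)
  expect_equal(stats::median(abs(k2), na.rm = TRUE), 1 / R, tolerance = 1e-3)
})

test_that("landmark pinning raises anisometry and curvature above dark levels", {
  p <- quiet_params(diffusion_deg2_per_m = 1.16, pin_alpha = 0.05)
  dark <- simulate_latent_trajectory(dark_track(50L), p, seed = 3)
  lm <- data.frame(id = c("a", "b", "c"), position_cm = c(60, 150, 250))
  lit <- simulate_latent_trajectory(
    track_spec(320, list(block_spec(50, landmarks = lm))), p, seed = 3)
  cv_dark <- anisometry(dark$theta_unwrapped, window_m = 8)
  cv_lit <- anisometry(lit$theta_unwrapped, window_m = 8)
  expect_gt(stats::median(cv_lit, na.rm = TRUE),
            stats::median(cv_dark, na.rm = TRUE))
  D_dark <- integrated_curvature(dark$theta_unwrapped, 160)
  D_lit <- integrated_curvature(lit$theta_unwrapped, 160)
  expect_gt(stats::median(D_lit), stats::median(D_dark))
  ks <- suppressWarnings(stats::ks.test(cv_lit, cv_dark))
  expect_lt(ks$p.value, 0.01)
})

test_that("integrated curvature is invariant to resampling resolution", {
  set.seed(9)
  tt <- seq(0, 2 * pi, length.out = 1001)
  th <- cbind(10 * cos(tt) + tt, 10 * sin(tt))
  D1 <- sum(integrated_curvature(th, nrow(th), dx_cm = 2, smooth_bins = 0))
  th2 <- cbind(stats::approx(seq_len(nrow(th)), th[, 1],
                             n = 2 * nrow(th) - 1)$y,
               stats::approx(seq_len(nrow(th)), th[, 2],
                             n = 2 * nrow(th) - 1)$y)
  D2 <- sum(integrated_curvature(th2, nrow(th2), dx_cm = 1, smooth_bins = 0))
  expect_equal(D1, D2, tolerance = 0.02 * abs(D1))
})

test_that("diffusion fitting is unbiased across generating values", {
  for (D_gen in c(0.5, 1.16, 2.0)) {
    p <- quiet_params(diffusion_deg2_per_m = D_gen)
    ths <- lapply(1:25, function(s)
      simulate_latent_trajectory(dark_track(16L), p, seed = s + 100)$theta_unwrapped)
    fit <- fit_diffusion(ths)
    expect_lt(abs(fit$D - D_gen) / D_gen, 0.25)
    expect_true(is.finite(fit$se) && fit$se > 0)
  }
  # zero-diffusion simulation fits (essentially) zero
  p0 <- quiet_params(diffusion_deg2_per_m = 0)
  th0 <- simulate_latent_trajectory(dark_track(16L), p0, seed = 1)$theta_unwrapped
  expect_lt(fit_diffusion(th0)$D, 0.05)
})

test_that("scale drift is tiny at constant gain and tracks a gain ramp", {
  p <- quiet_params(diffusion_deg2_per_m = 1.16)
  th <- simulate_latent_trajectory(dark_track(32L), p, seed = 2)$theta_unwrapped
  sd1 <- scale_drift(th)
  expect_equal(sd1$scales_cm[1], 50, tolerance = 0.5)
  expect_lt(sd1$drift_percent, 1)
  # zero-noise constant gain: drift exactly 0
  th0 <- simulate_latent_trajectory(dark_track(32L),
                                    quiet_params(), seed = 2)$theta_unwrapped
  expect_lt(scale_drift(th0)$drift_percent, 1e-9)
  # constructed 10% gain ramp over 100 m
  n <- 5001
  gain <- seq(1, 1.1, length.out = n - 1) * (sqrt(3) / 2 * 2 * pi / 50 * 2)
  th_ramp <- cbind(cumsum(c(0, gain)), 0)
  expect_equal(scale_drift(th_ramp)$drift_percent, 100 * (1 - 1 / 1.1),
               tolerance = 1.2)
})

test_that("remapping statistics expose the block structure", {
  # two lit blocks with different landmark layouts, plus sharp transitions
  blocks <- list(
    block_spec(10, landmarks = data.frame(id = "a", position_cm = 100)),
    block_spec(10, landmarks = data.frame(id = "b", position_cm = 220)))
  tr <- track_spec(320, blocks)
  ses <- cached("remap2", simulate_session(
    tr, quiet_params(diffusion_deg2_per_m = 1.16, pin_alpha = 0.05), seed = 8))
  rm <- compute_ratemap(ses)
  cm <- remap_correlations(rm)
  expect_true(all(cm >= -1 - 1e-9 & cm <= 1 + 1e-9))
  within1 <- cm[1:10, 1:10][upper.tri(diag(10))]
  within2 <- cm[11:20, 11:20][upper.tri(diag(10))]
  across <- cm[1:10, 11:20]
  expect_gt(stats::median(c(within1, within2)), stats::median(across))
  expect_lt(stats::wilcox.test(c(within1, within2), as.vector(across))$p.value,
            0.01)
  # sliding window mean correlation: high inside blocks
  rho <- sliding_mean_correlation(cm, window = 5)
  expect_gt(max(rho[1:5]), min(rho))
  # one-shot remapping between blocks
  ttr <- trials_to_remap(rm, old_block = 1, new_block = 2)
  expect_lte(ttr, 2L)
  # identical maps give a correlation matrix of ones
  rm_const <- rm
  for (t in seq_len(dim(rm_const$rates)[2])) rm_const$rates[, t, ] <- rm$rates[, 1, ]
  cm1 <- remap_correlations(rm_const)
  expect_equal(unname(cm1), matrix(1, nrow(cm1), ncol(cm1)), tolerance = 1e-9)
})

test_that("pinning dispersion shrinks with pin strength", {
  lm <- data.frame(id = "a", position_cm = 200)
  tr <- track_spec(320, list(block_spec(15, landmarks = lm)))
  sig2 <- vapply(c(0.005, 0.02, 0.1), function(alpha) {
    p <- quiet_params(diffusion_deg2_per_m = 1.16, pin_alpha = alpha)
    traj <- simulate_latent_trajectory(tr, p, seed = 12)
    at <- traj$theta[traj$bins$bin == 100, , drop = FALSE]
    pinning_dispersion(at[-(1:2), , drop = FALSE])$sigma2
  }, 0)
  expect_true(all(diff(sig2) < 0))     # monotone decreasing in alpha
  # strong pinning: near fixed point
  expect_lt(sig2[3], 0.05)
  # alpha = 0 approaches the uniform-torus dispersion (Monte-Carlo baseline)
  set.seed(5)
  unif_psi <- cbind(runif(4000, 0, 2 * pi), runif(4000, 0, 2 * pi))
  unif <- hex_transform(cbind(unif_psi, wrap_2pi(unif_psi[, 2] - unif_psi[, 1])))
  base <- pinning_dispersion(torus_wrap(unif))$sigma2
  # without any pull (dark running with angle drift), the position sampled at
  # a fixed track location disperses toward the uniform baseline
  p0 <- quiet_params(diffusion_deg2_per_m = 30, pin_alpha = 0)
  traj0 <- simulate_latent_trajectory(dark_track(30L), p0, seed = 13)
  at0 <- traj0$theta[traj0$bins$bin == 100, , drop = FALSE]
  s0 <- pinning_dispersion(at0)$sigma2
  expect_gt(s0, 0.4 * base)
})
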