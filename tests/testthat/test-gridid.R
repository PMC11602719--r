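# Spectral grid-cell identification and module clustering.

test_that("phase extraction recovers cosine reference phases", {
  x <- (1:1600 - 0.5) * 0.02
  f <- 2
  expect_circ_equal(extract_phases(cos(2 * pi * f * x), f)$phi, 0, tol = 0.02)
  expect_circ_equal(extract_phases(cos(2 * pi * f * x - pi / 2), f)$phi, pi / 2,
                    tol = 0.02)
  # shift theorem / translation equivariance: r(x - dx) shifts phi by 2 pi f dx
  dx <- 0.31
  ph <- extract_phases(cos(2 * pi * f * (x - dx)), f)$phi
  expect_circ_equal(ph, wrap_2pi(2 * pi * f * dx), tol = 0.02)
  # near-zero coefficient flagged unreliable
  out <- extract_phases(rep(0, 1600), f)
  expect_false(any(out$reliable))
})

test_that("slice frequencies and phases are recovered from a spiking session", {
  ses <- dark_session()
  rm <- compute_ratemap(ses)
  seqs <- lapply(1:24, function(u) flatten_ratemap(rm, u))
  sp1 <- compute_spectrogram(seqs[[1]], segment_bins = 1600, overlap_bins = 1400)
  avg <- Reduce(`+`, lapply(seqs, function(s)
    colMeans(compute_spectrogram(s, 1600, 1400)$psd)))
  pk <- find_three_peaks(avg, sp1$freq)
  f_true <- slice_freqs(50, 10)
  expect_equal(pk, sort(abs(f_true)), tolerance = 0.05)
  # analytic slice example at gamma = 10 deg: |cos(10)|, |cos(50)|, |cos(110)|
  expect_equal(pk / 2, sort(abs(cos(c(10, 50, 110) * pi / 180))),
               tolerance = 0.03)
  # wavevector closure: the two smaller frequencies sum to the largest
  expect_lt(abs(pk[1] + pk[2] - pk[3]), 1 / 32 + 1e-9)

  # relative phases between cells match the generator (sorted-peak frame)
  nb <- length(seqs[[1]])
  starts <- seq(1, nb - 1600 + 1, by = 200)
  win <- cbind(starts, starts + 1599)
  ph_est <- t(vapply(1:24, function(u)
    extract_phases(seqs[[u]], pk, windows = win)$phi, numeric(3)))
  gt_ph <- ses$ground_truth$phases[[1]]
  ord <- order(abs(f_true))
  for (k in 1:3) {
    a <- ord[k]; sgn <- sign(f_true[a])
    rel_est <- ph_est[, k] - ph_est[1, k]
    rel_true <- sgn * (gt_ph[, a] - gt_ph[1, a])
    expect_circ_equal(rel_est, rel_true, tol = 0.45)
    err <- atan2(sin(rel_est - rel_true), cos(rel_est - rel_true))
    expect_lt(median(abs(err)), 0.15)
  }
})

test_that("pure noise yields no stable three-peak classification", {
  set.seed(21)
  sp <- compute_spectrogram(rnorm(1600), segment_bins = 400, overlap_bins = 200)
  # find_three_peaks on a tiny PSD vector can fail outright
  expect_null(find_three_peaks(c(1, 2, 1), c(0, 1, 2)))
})

test_that("module clustering separates two scales from noise cells", {
  p <- sim_params(diffusion_deg2_per_m = 0, grid_scales_cm = c(50, 70),
                  n_cells_per_module = 12L)
  ses <- cached("two_mod", simulate_session(dark_track(20L), p, seed = 77))
  rm <- compute_ratemap(ses)
  n_grid <- 24L
  seqs <- lapply(seq_len(n_grid), function(u) flatten_ratemap(rm, u))
  # append 20 noise cells: unstructured Poisson rate sequences
  set.seed(3)
  nbins <- length(seqs[[1]])
  noise <- lapply(1:20, function(i) rpois(nbins, 1.5) / 0.04)
  specs <- lapply(c(seqs, noise), compute_spectrogram,
                  segment_bins = 1600, overlap_bins = 1400)
  mods <- cluster_modules(specs, k = 5, seed = 1)
  accepted <- Filter(function(m) m$accepted, mods)
  # accepted modules recover the two generating modules with clean membership
  grid_members <- sort(unique(unlist(lapply(accepted, `[[`, "unit_ids"))))
  expect_true(all(grid_members <= n_grid))
  expect_gte(length(accepted), 2L)
  mem1 <- vapply(accepted, function(m) any(m$unit_ids %in% 1:12), TRUE)
  mem2 <- vapply(accepted, function(m) any(m$unit_ids %in% 13:24), TRUE)
  expect_false(any(mem1 & mem2))  # no accepted cluster mixes the modules
  # sensitivity: nearly all grid cells are captured by accepted modules
  expect_gte(length(grid_members), 22L)
  # all-noise population yields no accepted module
  mods_noise <- cluster_modules(specs[25:44], k = 5, seed = 1)
  expect_equal(sum(vapply(mods_noise, `[[`, TRUE, "accepted")), 0L)
  expect_error(cluster_modules(specs[1:3], k = 5), "exceeds")
})

test_that("end-to-end classification recovers module structure and scale", {
  ses <- dark_session()
  gm <- classify_gridcells(ses, k = 3, seed = 2)
  expect_gte(length(gm), 1L)
  # a small k may split one module over several accepted clusters; together
  # they must still cover the module and each must pass the correlation rule
  covered <- sort(unique(unlist(lapply(gm, `[[`, "unit_ids"))))
  expect_gte(length(covered), 20L)
  main <- gm[[which.max(vapply(gm, function(m) length(m$unit_ids), 0L))]]
  expect_gt(main$mean_pairwise_r, 0.3)
  expect_equal(main$inferred_scale_cm, 50, tolerance = 0.06 * 50)
  expect_equal(main$slice_angle_deg, 10, tolerance = 3)
})

test_that("non-grid spatial cells pass stability but fail the grid test", {
  # stable, non-periodic place-like tuning: single Gaussian bump per lap
  tr <- dark_track(20L)
  p <- quiet_params()
  traj <- simulate_latent_trajectory(tr, p, seed = 5)
  x <- traj$bins$x_cm
  rate <- matrix(8 * exp(-(x - 160)^2 / (2 * 25^2)), ncol = 1)
  spk <- spikes_from_rates(rate, traj$bins, seed = 6)
  ses <- simulate_session(tr, p, seed = 5)
  ses$spikes <- c(ses$spikes, spk)
  rm <- compute_ratemap(ses)
  u <- length(ses$spikes)
  expect_gt(half_session_stability(rm, u, blocks = 1), 0.2)
  # its spectrogram does not correlate with the grid module's, so the
  # module-acceptance rule (r > 0.3) bars it from any grid module
  sp_place <- compute_spectrogram(flatten_ratemap(rm, u), 1600, 1400)
  r_with_grid <- vapply(1:10, function(g) {
    sp_g <- compute_spectrogram(flatten_ratemap(rm, g), 1600, 1400)
    mean(vapply(seq_len(nrow(sp_g$psd)), function(w)
      stats::cor(sp_place$psd[w, ], sp_g$psd[w, ]), 0))
  }, 0)
  expect_lt(mean(r_with_grid), 0.3)
})

test_that("noiseless rates give phase recovery within 0.1 rad", {
  ses <- dark_session()
  gtr <- ses$ground_truth$rates[[1]]
  sp <- compute_spectrogram(gtr[, 1], 1600, 1400)
  pk <- find_three_peaks(colMeans(sp$psd), sp$freq)
  nb <- nrow(gtr)
  starts <- seq(1, nb - 1600 + 1, by = 200)
  win <- cbind(starts, starts + 1599)
  ph_est <- t(vapply(1:24, function(u)
    extract_phases(gtr[, u], pk, windows = win)$phi, numeric(3)))
  f_true <- slice_freqs(50, 10)
  gt_ph <- ses$ground_truth$phases[[1]]
  ord <- order(abs(f_true))
  for (k in 1:3) {
    a <- ord[k]; sgn <- sign(f_true[a])
    rel_est <- ph_est[, k] - ph_est[1, k]
    rel_true <- sgn * (gt_ph[, a] - gt_ph[1, a])
    expect_circ_equal(rel_est, rel_true, tol = 0.1)
  }
})
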