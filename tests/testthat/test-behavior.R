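# Behavioural metrics: hand-computable toy cases plus simulation checks.

test_that("lick anticipation hits its formula limits exactly", {
  L <- 200; zs <- 160
  # all licks in the near zone [144, 160): +1
  expect_equal(lick_anticipation(c(145, 150, 159.9), L, zs), 1)
  # equal per-distance rates in near and far zones: 0
  expect_equal(lick_anticipation(c(145, 150, 85, 90), L, zs), 0)
  # all licks in the far zone [80, 100): -1
  expect_equal(lick_anticipation(c(85, 95), L, zs), -1)
  # no licks in either zone: undefined, not zero
  expect_true(is.na(lick_anticipation(c(10, 120), L, zs)))
  # invariance to uniform scaling of lick counts
  a <- lick_anticipation(c(rep(150, 2), rep(85, 1)), L, zs)
  b <- lick_anticipation(c(rep(150, 6), rep(85, 3)), L, zs)
  expect_equal(a, b)
  # antisymmetry under swapping near/far
  expect_equal(lick_anticipation(c(150, 150, 85), L, zs),
               -lick_anticipation(c(150, 85, 85), L, zs))
})

test_that("slowing anticipation mirrors the lick formula with time in zones", {
  beh <- data.frame(time_s = seq(0, 10, by = 0.02),
                    position_cm = seq(0, 200, length.out = 501))
  # constant speed: equal time per distance, metric 0
  expect_equal(slowing_anticipation(beh, 200, 160), 0, tolerance = 1e-9)
  # dwell entirely inside the near zone
  beh2 <- data.frame(time_s = seq(0, 10, by = 0.02),
                     position_cm = rep(150, 501))
  expect_equal(slowing_anticipation(beh2, 200, 160), 1)
})

test_that("block accuracy matches the analytic chance probability", {
  tr <- make_track("hidden_reward",
                   options = list(n_trials = 300L, n_dark_trials = 1L,
                                  offset_range = c(0, 0)))
  p <- sim_params(behaviour_mode = "chance", lick_rate_hz = 4)
  ev <- simulate_behaviour(tr, p, seed = 21)
  trials <- 1:300
  acc <- block_accuracy(ev, trials, zone = c(160, 170))
  # chance: licks ~ Poisson(4) uniform on 200 cm; trigger zone 10 cm
  # P(hit) = 1 - exp(-lambda * 10/200)
  p_hit <- 1 - exp(-4 * 10 / 200)
  expect_lt(abs(acc - p_hit), 3 * sqrt(p_hit * (1 - p_hit) / 300))
  # expert simulation: near-perfect accuracy
  ev_e <- simulate_behaviour(tr, sim_params(behaviour_mode = "expert"), seed = 21)
  expect_gt(block_accuracy(ev_e, trials, zone = c(160, 170)), 0.85)
  # no licks at all: zero accuracy
  ev0 <- ev_e[0, ]
  expect_equal(block_accuracy(ev0, 1:10, zone = c(160, 170)), 0)
})

test_that("chance licking yields near-zero anticipation over many trials", {
  tr <- make_track("hidden_reward",
                   options = list(n_trials = 1000L, n_dark_trials = 1L,
                                  offset_range = c(0, 0)))
  ev <- simulate_behaviour(tr, sim_params(behaviour_mode = "chance",
                                          lick_rate_hz = 8), seed = 33)
  licks <- ev$position_cm[ev$event_type == "lick" & !ev$consummatory]
  val <- lick_anticipation(licks, 200, 160)
  expect_lt(abs(val), 0.05)
})

test_that("licking error and its toy cases", {
  ev <- data.frame(time_s = 1:4, position_cm = c(160, 155, 165, 150),
                   trial = c(1, 2, 2, 3), block = 1,
                   event_type = "lick", consummatory = c(FALSE, FALSE, TRUE, FALSE))
  err <- licking_error(ev, 1:3, zone_start = 160)
  expect_equal(err, c(0, 5, 10))  # consummatory lick on trial 2 excluded
})

test_that("code stability anti-correlates with licking error under injected noise", {
  # construct trials whose population vectors are corrupted by increasing
  # noise, and lick errors that grow with the same noise level
  set.seed(10)
  n_trials <- 40; nb <- 100; n_units <- 30
  base <- matrix(runif(n_units * nb, 0, 8), n_units, nb)
  noise_level <- runif(n_trials, 0, 1)
  rates <- array(0, dim = c(n_units, n_trials, nb))
  for (t in seq_len(n_trials)) {
    rates[, t, ] <- base + matrix(rnorm(n_units * nb, 0, 6 * noise_level[t]),
                                  n_units, nb)
  }
  rm <- structure(list(rates = rates, bin_cm = 2,
                       trial_block = rep(1L, n_trials)), class = "rate_map")
  stab <- trial_stability(rm, 1:n_units, 1:n_trials, zone_start = 160)
  err <- 2 + 8 * noise_level + rnorm(n_trials, 0, 1)
  rel <- stability_error_relation(stab, err)
  expect_lt(rel$r, 0)
  expect_lt(rel$p, 0.01)
})

test_that("expert sessions produce anticipation near +1 in the driver pipeline", {
  tr <- make_track("hidden_reward",
                   options = list(n_trials = 40L, n_dark_trials = 1L,
                                  offset_range = c(0, 0)))
  ev <- simulate_behaviour(tr, sim_params(behaviour_mode = "expert"), seed = 2)
  licks <- ev$position_cm[ev$event_type == "lick" & !ev$consummatory]
  expect_equal(lick_anticipation(licks, 200, 160), 1)
})

test_that("metrics reproduce exactly on the hand-computed toy session", {
  # 3-trial toy session on a 200-cm track, reward zone [160, 170)
  ev <- utils::read.csv(system.file("extdata", "toy_licks.csv",
                                    package = "toruspin"))
  L <- 200; zs <- 160
  licks <- ev$position_cm[ev$event_type == "lick" & !ev$consummatory]
  # near zone [140,160): licks at 150, 155, 150 -> rate 3/20
  # far  zone [80,100):  licks at 90, 85, 95    -> rate 3/20
  expect_identical(lick_anticipation(licks, L, zs), 0)
  # trial 1 triggered (lick in [160,170) before the auto reward at 170);
  # trials 2 and 3 were auto-rewarded
  expect_equal(block_accuracy(ev, 1:3, zone = c(160, 170)), 1 / 3)
  # licking error: mean |pos - 160| of non-consummatory licks per trial
  expect_equal(licking_error(ev, 1:3, zs),
               c(mean(c(10, 5, 2)), mean(c(70, 10)), mean(c(75, 65))))
})
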