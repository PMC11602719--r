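# Position decoding ------------------------------------------------------

#' Fit a circular-linear position decoder
#'
#' Regresses the two circular position coordinates `cos(2*pi*x/L)` and
#' `sin(2*pi*x/L)` on population rates with a (ridge-regularized)
#' least-squares objective. The decoded position is
#' `x_hat = atan2(r %*% beta_sin, r %*% beta_cos) * L / (2*pi) mod L`,
#' an argument order fixed so that noiseless data decode to themselves.
#'
#' @param rates bins x units rate matrix (training bins).
#' @param positions_cm position of each training bin.
#' @param L track length (cm).
#' @param lambda ridge penalty (default 1e-6 for numerical stability).
#' @return object of class `circ_linear_decoder`.
#' @export
fit_circular_linear <- function(rates, positions_cm, L, lambda = 1e-6) {
  X <- cbind(1, rates)
  X[is.na(X)] <- 0
  yc <- cos(2 * pi * positions_cm / L)
  ys <- sin(2 * pi * positions_cm / L)
  XtX <- crossprod(X) + diag(lambda, ncol(X))
  beta_c <- solve(XtX, crossprod(X, yc))
  beta_s <- solve(XtX, crossprod(X, ys))
  structure(list(beta_cos = drop(beta_c), beta_sin = drop(beta_s),
                 L = L, lambda = lambda, n_units = ncol(rates)),
            class = "circ_linear_decoder")
}

#' Decode positions from population rates
#'
#' @param object a `circ_linear_decoder`.
#' @param rates bins x units rate matrix.
#' @param ... unused.
#' @return numeric vector of decoded positions in `[0, L)`.
#' @export
predict.circ_linear_decoder <- function(object, rates, ...) {
  X <- cbind(1, rates)
  X[is.na(X)] <- 0
  s <- X %*% object$beta_sin
  c <- X %*% object$beta_cos
  (atan2(s, c) %% (2 * pi)) * object$L / (2 * pi)
}

#' Circular decoding error
#'
#' @param x_hat decoded positions (cm).
#' @param x true positions (cm).
#' @param L track length (cm).
#' @return absolute circular errors (cm).
#' @export
circular_error <- function(x_hat, x, L) {
  d <- abs(x_hat - x) %% L
  pmin(d, L - d)
}

# BTSP plastic decoder ----------------------------------------------------

#' Initialize a plastic (BTSP) downstream decoder
#'
#' A single readout `y(x) = f(sum_i w_i r_i(x))` with logistic `f`. Each
#' rewarded (consummatory) lick updates the weights toward the currently
#' active grid cells, `w <- w + eta * r(x) * l(x)`, and — because the
#' underlying plasticity is bidirectional, with new induction depressing
#' previously potentiated synapses — also depresses the existing weights by
#' a factor `(1 - decay)` per lick. `eta = 0` knocks out all plasticity
#' (potentiation and depression).
#'
#' @param n_units number of input units.
#' @param eta learning rate (default 1; 0 = plasticity knockout).
#' @param decay per-lick multiplicative depression of existing weights
#'   (default 0.05, i.e. roughly one-quarter of the weight memory turned
#'   over per rewarded trial at typical lick counts).
#' @param f_gain,f_threshold logistic readout gain and threshold (applied to
#'   the standardized drive); argmax-based predictions are invariant to
#'   both.
#' @param w0 initial weights (default small uniform noise).
#' @param seed RNG seed for the weight initialization.
#' @return object of class `btsp_decoder`.
#' @export
btsp_decoder <- function(n_units, eta = 1, decay = 0.05, f_gain = 4,
                         f_threshold = 0.5, w0 = NULL, seed = 1L) {
  if (is.null(w0)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
    w0 <- stats::runif(n_units, 0, 1e-3)
  }
  structure(list(w = w0, eta = eta, decay = decay, f_gain = f_gain,
                 f_threshold = f_threshold), class = "btsp_decoder")
}

#' Apply the BTSP weight update for one trial
#'
#' Potentiation `w <- w + eta * t(r) %*% l` plus per-lick depression of the
#' existing weights; no licks (or `eta = 0`) leave the weights untouched.
#'
#' @param decoder a `btsp_decoder`.
#' @param rates bins x units rates on the trial.
#' @param lick_counts integer consummatory-lick count per bin (`l(x)`).
#' @return the updated decoder.
#' @export
btsp_update <- function(decoder, rates, lick_counts) {
  stopifnot(length(lick_counts) == nrow(rates))
  nz <- which(lick_counts > 0)
  if (length(nz) && decoder$eta != 0) {
    r <- rates[nz, , drop = FALSE]
    r[is.na(r)] <- 0
    keep <- (1 - decoder$decay)^sum(lick_counts[nz])
    decoder$w <- keep * decoder$w +
      decoder$eta * drop(crossprod(r, lick_counts[nz]))
  }
  decoder
}

#' Readout of the BTSP decoder over a trial
#'
#' @param decoder a `btsp_decoder`.
#' @param rates bins x units rates.
#' @param smooth_sd_bins Gaussian smoothing of the drive along position
#'   before the argmax (default 2 bins; the readout integrates neighbouring
#'   positions, which stabilizes the predicted lick location against
#'   single-trial spiking noise).
#' @return list with `y` (sigmoid output per bin, in (0, 1)), `drive`
#'   (pre-nonlinearity), `pred_bin` (argmax bin), and
#'   `pred_bin_threshold` (first bin with `y > 0.5`, NA if none).
#' @export
btsp_readout <- function(decoder, rates, smooth_sd_bins = 2) {
  r <- rates; r[is.na(r)] <- 0
  drive <- drop(r %*% decoder$w)
  if (smooth_sd_bins > 0) {
    drive <- drop(.smooth_matrix(length(drive), smooth_sd_bins) %*% drive)
  }
  sdv <- stats::sd(drive)
  z <- if (sdv > 0) (drive - mean(drive)) / sdv else drive * 0
  y <- stats::plogis(decoder$f_gain * (z - decoder$f_threshold))
  over <- which(y > 0.5)
  list(y = y, drive = drive, pred_bin = which.max(drive),
       pred_bin_threshold = if (length(over)) over[1] else NA_integer_)
}

#' Trials to behavioural adaptation
#'
#' Number of post-shift trials before the predicted lick location enters
#' the reward zone and stays there for `consecutive` trials. Zero if the
#' prediction is in the zone from the first post-shift trial; `Inf` if
#' adaptation is never achieved.
#'
#' @param pred_pos_cm predicted lick location per post-shift trial (cm).
#' @param zone length-2 reward zone `(start, end)` (cm).
#' @param consecutive required run length (default 3).
#' @return number of trials (0, positive integer, or `Inf`).
#' @export
trials_to_adapt <- function(pred_pos_cm, zone, consecutive = 3) {
  inz <- pred_pos_cm >= zone[1] & pred_pos_cm < zone[2]
  n <- length(inz)
  if (n < consecutive) return(Inf)
  for (i in seq_len(n - consecutive + 1L)) {
    if (all(inz[i:(i + consecutive - 1L)])) return(i - 1L)
  }
  Inf
}

#' Run the plastic decoder through a session
#'
#' Processes trials chronologically: for each trial, computes the predicted
#' lick location from the current weights and the trial's rates, then
#' applies the BTSP update using the trial's consummatory licks. Plasticity
#' can be knocked out from a given trial onward (`eta` set to 0).
#'
#' @param session a `sim_session`.
#' @param rm a `rate_map` (trial-resolved rates fed to the decoder).
#' @param units unit indices used as decoder inputs.
#' @param eta learning rate.
#' @param knockout_after_trial trial index after which `eta` is forced to 0
#'   (`Inf` = never).
#' @param seed RNG seed (weight initialization).
#' @param smooth_sd_bins readout drive smoothing (see [btsp_readout()]).
#' @return list with `pred_pos_cm` (per trial), `pred_pos_threshold_cm`,
#'   `decoder` (final state), `lick_counts` (trials x bins).
#' @export
run_btsp_session <- function(session, rm, units, eta = 1,
                             knockout_after_trial = Inf, seed = 1L,
                             smooth_sd_bins = 2) {
  nb <- dim(rm$rates)[3]
  n_trials <- dim(rm$rates)[2]
  bin <- rm$bin_cm
  dec <- btsp_decoder(length(units), eta = eta, seed = seed)
  ev <- session$events
  cons <- ev[ev$event_type == "lick" & ev$consummatory, , drop = FALSE]
  pred <- rep(NA_real_, n_trials)
  pred_thr <- rep(NA_real_, n_trials)
  lick_counts <- matrix(0L, n_trials, nb)
  for (t in seq_len(n_trials)) {
    rates_t <- t(matrix(rm$rates[units, t, ], nrow = length(units)))
    ro <- btsp_readout(dec, rates_t, smooth_sd_bins = smooth_sd_bins)
    pred[t] <- (ro$pred_bin - 0.5) * bin
    pred_thr[t] <- if (is.na(ro$pred_bin_threshold)) NA_real_ else
      (ro$pred_bin_threshold - 0.5) * bin
    lt <- cons[cons$trial == t, , drop = FALSE]
    if (nrow(lt)) {
      bins_t <- pmin(nb, pmax(1L, floor(lt$position_cm / bin) + 1L))
      lick_counts[t, ] <- tabulate(bins_t, nb)
    }
    dec$eta <- if (t > knockout_after_trial) 0 else eta
    dec <- btsp_update(dec, rates_t, lick_counts[t, ])
  }
  list(pred_pos_cm = pred, pred_pos_threshold_cm = pred_thr, decoder = dec,
       lick_counts = lick_counts)
}

#' Tower-shift adaptation experiment
#'
#' Simulates the hidden-reward forwards-shift design with the fixed-pinning
#' grid code (three modules, Poisson spikes, expert licking), runs the BTSP
#' decoder online through the session, and counts the post-shift trials to
#' behavioural adaptation for both the plastic decoder and the plasticity
#' knockout (frozen after the pre-shift block).
#'
#' @param seed master seed.
#' @param n_trials trials per lit block (default 40).
#' @param n_cells_per_module cells per module (default 64).
#' @param eta BTSP learning rate (default 1).
#' @return list with `tta_btsp`, `tta_knockout` (trials to adaptation on the
#'   first shifted block), `pred_btsp`, `pred_knockout` (per-trial predicted
#'   lick locations), `zone`, `blocks` (block index per trial), `session`.
#' @export
btsp_shift_experiment <- function(seed = 1L, n_trials = 40L,
                                  n_cells_per_module = 64L, eta = 1) {
  track <- make_track("hidden_reward",
                      options = list(n_trials = n_trials,
                                     n_dark_trials = max(5L, n_trials %/% 4L),
                                     offset_range = c(0, 0)))
  params <- sim_params(n_cells_per_module = n_cells_per_module,
                       grid_scales_cm = c(50, 50 * sqrt(2), 100),
                       diffusion_deg2_per_m = 1.16,
                       peak_rate_hz = 20,
                       bump_width = 0.8,
                       behaviour_mode = "expert")
  ses <- simulate_session(track, params, seed = seed)
  rm <- compute_ratemap(ses)
  units <- seq_along(ses$spikes)
  blocks <- rm$trial_block
  fit <- run_btsp_session(ses, rm, units, eta = eta, seed = seed,
                          smooth_sd_bins = 3)
  ko <- run_btsp_session(ses, rm, units, eta = eta, seed = seed,
                         knockout_after_trial = max(which(blocks == 1)),
                         smooth_sd_bins = 3)
  zone <- track$blocks[[1]]$reward_zone
  shift_trials <- which(blocks == 2)
  list(tta_btsp = trials_to_adapt(fit$pred_pos_cm[shift_trials], zone),
       tta_knockout = trials_to_adapt(ko$pred_pos_cm[shift_trials], zone),
       pred_btsp = fit$pred_pos_cm, pred_knockout = ko$pred_pos_cm,
       zone = zone, blocks = blocks, session = ses)
}
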