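# Trajectory geometry on the neural sheet --------------------------------

#' Per-step arc length of an unwrapped trajectory
#'
#' `s(x) = sqrt(d theta_1^2 + d theta_2^2)` per spatial step.
#'
#' @param theta bins x 2 unwrapped sheet trajectory.
#' @return numeric vector of length `nrow(theta) - 1`.
#' @export
arc_lengths <- function(theta) {
  sqrt(rowSums(diff(theta)^2))
}

#' Anisometry: coefficient of variation of the arc length
#'
#' CV of the per-2-cm neural arc lengths within windows of fixed physical
#' length. A distance-faithful (isometric) map gives CV = 0.
#'
#' @param theta bins x 2 unwrapped trajectory.
#' @param dx_cm spatial bin size (cm), default 2.
#' @param window_m window length (m), default 16.
#' @param mask optional logical vector (TRUE = valid bin); windows with more
#'   than half their bins masked are skipped.
#' @return numeric vector of per-window CVs (NA for skipped windows).
#' @export
anisometry <- function(theta, dx_cm = 2, window_m = 16, mask = NULL) {
  s <- arc_lengths(theta)
  if (is.null(mask)) mask <- rep(TRUE, nrow(theta))
  ms <- mask[-1] & mask[-length(mask)]
  wlen <- max(2L, round(window_m * 100 / dx_cm))
  starts <- seq(1L, length(s) - wlen + 1L, by = wlen)
  vapply(starts, function(i) {
    idx <- i:(i + wlen - 1L)
    if (mean(ms[idx]) < 0.5) return(NA_real_)
    v <- s[idx][ms[idx]]
    stats::sd(v) / mean(v)
  }, 0)
}

#' Geodesic curvature of an unwrapped trajectory
#'
#' On the flat torus parameterized by `(theta_1, theta_2)` the geodesic
#' curvature is the planar curvature
#' `kappa_g = (theta_1' theta_2'' - theta_2' theta_1'') /
#'   (theta_1'^2 + theta_2'^2)^(3/2)`,
#' computed with central finite differences after a light boxcar smoothing
#' (curvature is noise-amplifying).
#'
#' @param theta bins x 2 unwrapped trajectory.
#' @param dx_cm spatial bin size (cm).
#' @param smooth_bins boxcar pre-smoothing width (bins, odd; 0/1 disables).
#' @param speed_floor mask bins where the parameter speed `|theta'|` falls
#'   below this value (degenerate direction).
#' @return numeric vector of `kappa_g` per interior bin (length
#'   `nrow(theta)`, NA at the ends and masked bins). Units: 1/cm.
#' @export
geodesic_curvature <- function(theta, dx_cm = 2, smooth_bins = 3,
                               speed_floor = 1e-8) {
  th <- theta
  if (smooth_bins > 1) {
    k <- rep(1 / smooth_bins, smooth_bins)
    th <- apply(th, 2, function(v) stats::filter(v, k, sides = 2))
    th <- matrix(th, ncol = 2)
  }
  n <- nrow(th)
  kap <- rep(NA_real_, n)
  if (n < 3) return(kap)
  i <- 2:(n - 1)
  d1 <- (th[i + 1, , drop = FALSE] - th[i - 1, , drop = FALSE]) / (2 * dx_cm)
  d2 <- (th[i + 1, , drop = FALSE] - 2 * th[i, , drop = FALSE] +
           th[i - 1, , drop = FALSE]) / dx_cm^2
  sp2 <- rowSums(d1^2)
  num <- d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1]
  val <- num / sp2^1.5
  val[sp2 < speed_floor^2] <- NA_real_
  kap[i] <- val
  kap
}

#' Integrated absolute curvature per trial
#'
#' `D_trial = int_C |kappa_g| dx` over each lap of the track.
#'
#' @param theta bins x 2 unwrapped trajectory (trials concatenated).
#' @param bins_per_trial spatial bins per trial.
#' @param dx_cm bin size (cm).
#' @param ... passed to [geodesic_curvature()].
#' @return numeric vector, one integral per trial.
#' @export
integrated_curvature <- function(theta, bins_per_trial, dx_cm = 2, ...) {
  kap <- geodesic_curvature(theta, dx_cm = dx_cm, ...)
  n_trials <- ceiling(nrow(theta) / bins_per_trial)
  vapply(seq_len(n_trials), function(t) {
    idx <- ((t - 1L) * bins_per_trial + 1L):min(t * bins_per_trial, nrow(theta))
    sum(abs(kap[idx]), na.rm = TRUE) * dx_cm
  }, 0)
}

#' Fit the angular diffusion constant of dark running
#'
#' The instantaneous slice angle is measured as `atan2(d theta_2, d theta_1)`
#' over successive spans (default 4 m) of the unwrapped trajectory; under
#' angular diffusion the variance of the angle change grows linearly with
#' distance, `Var[angle(x) - angle(0)] = D x`. Because each measured angle
#' is a span average, the exact relation is `Var = D (c - span/3)` at lag
#' distance `c`; `D` is fitted through the origin of that relation over the
#' first `max_lag` lags, and the SE by bootstrap over sessions.
#'
#' @param theta_list list of bins x 2 unwrapped dark trajectories (one per
#'   session/module), or a single matrix.
#' @param dx_cm bin size (cm).
#' @param span_m angle-measurement span (m), default 4.
#' @param n_boot bootstrap replicates for the SE.
#' @param seed RNG seed for the bootstrap.
#' @return list with `D` (deg^2/m), `se`, `per_session` (deg^2/m).
#' @export
fit_diffusion <- function(theta_list, dx_cm = 2, span_m = 4, n_boot = 200,
                          seed = 1L, max_lag = 8L) {
  if (is.matrix(theta_list)) theta_list <- list(theta_list)
  span_bins <- max(2L, round(span_m * 100 / dx_cm))
  per <- vapply(theta_list, function(th) {
    nspan <- (nrow(th) - 1L) %/% span_bins
    if (nspan < 2) return(NA_real_)
    pts <- th[seq(1L, nspan * span_bins + 1L, by = span_bins)[seq_len(nspan + 1)], ,
              drop = FALSE]
    d <- diff(pts)
    ang <- signal::unwrap(atan2(d[, 2], d[, 1]))
    # span-averaged angles of a diffusing direction satisfy
    # Var[A(x + c) - A(x)] = D * (c - span/3); pool squared differences over
    # lags and fit D through the origin of that relation
    K <- min(max_lag, nspan - 1L)
    num <- 0; den <- 0
    for (k in seq_len(K)) {
      da <- ang[(1 + k):nspan] - ang[1:(nspan - k)]
      xk <- k * span_m - span_m / 3
      num <- num + length(da) * mean(da^2) / xk
      den <- den + length(da)
    }
    (num / den) * (180 / pi)^2
  }, 0)
  per <- per[!is.na(per)]
  if (!length(per)) stop("insufficient dark distance to fit a diffusion constant")
  D <- mean(per)
  se <- NA_real_
  if (length(per) > 1) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
    bs <- vapply(seq_len(n_boot), function(i)
      mean(sample(per, length(per), replace = TRUE)), 0)
    se <- stats::sd(bs)
  }
  list(D = D, se = se, per_session = per)
}

#' Grid-scale drift over distance
#'
#' Estimates the grid scale in windows (default 16 m) from the mean neural
#' arc-length rate: with gain `2*pi/lambda` per lattice axis the sheet speed
#' is `(sqrt(3)/2) * 2*pi / lambda` rad/cm, so
#' `lambda = sqrt(3) * pi / (mean arc rate)`. Drift is the maximum relative
#' deviation from the first window's scale over the stated distance.
#'
#' @param theta bins x 2 unwrapped trajectory.
#' @param dx_cm bin size (cm).
#' @param window_m scale-estimation window (m).
#' @param over_m distance over which drift is assessed (default 100 m).
#' @return list with `scales_cm` per window, `drift_percent`.
#' @export
scale_drift <- function(theta, dx_cm = 2, window_m = 16, over_m = 100) {
  s <- arc_lengths(theta)
  wlen <- max(2L, round(window_m * 100 / dx_cm))
  starts <- seq(1L, length(s) - wlen + 1L, by = wlen)
  starts <- starts[(starts - 1L) * dx_cm / 100 <= over_m]
  scales <- vapply(starts, function(i) {
    rate <- mean(s[i:(i + wlen - 1L)]) / dx_cm   # rad per cm
    sqrt(3) * pi / rate
  }, 0)
  drift <- max(abs(scales - scales[1]) / scales[1]) * 100
  list(scales_cm = scales, drift_percent = drift)
}

# Remapping statistics ----------------------------------------------------

#' Trial-pair correlation matrix of population activity
#'
#' Pearson correlation between the concatenated spatial tuning vectors of
#' the population on every pair of trials.
#'
#' @param rm a `rate_map`.
#' @param units unit indices (default: all).
#' @return trials x trials correlation matrix.
#' @export
remap_correlations <- function(rm, units = NULL) {
  if (is.null(units)) units <- seq_len(dim(rm$rates)[1])
  n_trials <- dim(rm$rates)[2]
  V <- vapply(seq_len(n_trials), function(t)
    as.vector(rm$rates[units, t, ]), numeric(length(units) * dim(rm$rates)[3]))
  V[is.na(V)] <- 0
  stats::cor(V)
}

#' Sliding-window mean trial correlation
#'
#' `rho_bar_t = (1/10) sum_{alpha > beta} rho(t + alpha, t + beta)` over a
#' window of `window` trials (10 pairs for the default window of 5).
#'
#' @param corr_mat trial-pair correlation matrix.
#' @param window window length in trials (default 5).
#' @return numeric vector, one value per window start.
#' @export
sliding_mean_correlation <- function(corr_mat, window = 5) {
  n <- nrow(corr_mat)
  vapply(seq_len(n - window + 1L), function(t) {
    sub <- corr_mat[t:(t + window - 1L), t:(t + window - 1L)]
    mean(sub[upper.tri(sub)])
  }, 0)
}

#' Trials to remap between two blocks
#'
#' First trial of the new block whose population tuning vector correlates
#' more with the new block's mean tuning than with the old block's.
#'
#' @param rm a `rate_map`.
#' @param old_block,new_block block indices.
#' @param units unit indices (default: all).
#' @return integer count (1 = one-shot remapping).
#' @export
trials_to_remap <- function(rm, old_block, new_block, units = NULL) {
  if (is.null(units)) units <- seq_len(dim(rm$rates)[1])
  old_trials <- which(rm$trial_block == old_block)
  new_trials <- which(rm$trial_block == new_block)
  vec <- function(t) { v <- as.vector(rm$rates[units, t, ]); v[is.na(v)] <- 0; v }
  mean_vec <- function(trs) rowMeans(vapply(trs, vec, vec(trs[1])))
  old_mean <- mean_vec(old_trials)
  for (i in seq_along(new_trials)) {
    t <- new_trials[i]
    new_mean <- mean_vec(setdiff(new_trials, t))
    v <- vec(t)
    if (stats::cor(v, new_mean) > stats::cor(v, old_mean)) return(i)
  }
  length(new_trials) + 1L
}

#' Pinning dispersion at landmark passages
#'
#' Circular mean of the bump position across passages of a landmark, and the
#' mean squared minimal-image distance about it on the twisted torus.
#'
#' @param theta_passages n_passages x 2 wrapped sheet positions at the
#'   landmark.
#' @return list with `mean_theta` (length 2), `sigma2` (mean squared
#'   periodic distance).
#' @export
pinning_dispersion <- function(theta_passages) {
  if (is.null(dim(theta_passages))) theta_passages <- matrix(theta_passages, ncol = 2)
  psi <- hex_inverse(theta_passages, wrap = TRUE)
  mpsi <- c(circ_mean(psi[, 1]), circ_mean(psi[, 2]))
  mtheta <- drop(torus_wrap(hex_transform(c(mpsi, wrap_2pi(mpsi[2] - mpsi[1])))))
  d <- torus_distance(theta_passages, matrix(mtheta, 1))
  list(mean_theta = mtheta, sigma2 = mean(d^2))
}

#' Bump positions at landmark passages
#'
#' Looks up the wrapped bump position at the spatial bin of each passage of
#' each landmark.
#'
#' @param bump a `bump_com` (bins over cumulative distance).
#' @param bins bin table (as in `session$bins`).
#' @param passages landmark passage table (as in `traj$passages`).
#' @return data.frame `id, block, trial, theta1, theta2`.
#' @export
bump_at_landmarks <- function(bump, bins, passages) {
  pas <- passages[passages$id != "<offset>", , drop = FALSE]
  if (!nrow(pas)) return(data.frame())
  bin_cm <- bins$x_cm[2] - bins$x_cm[1]
  nb <- max(bins$bin)
  row_of <- function(trial, x) {
    b <- pmin(nb, pmax(1L, floor(x / bin_cm) + 1L))
    which(bins$trial == trial)[b]
  }
  idx <- mapply(row_of, pas$trial, pas$position_cm)
  data.frame(id = pas$id, block = pas$block, trial = pas$trial,
             theta1 = bump$theta[idx, 1], theta2 = bump$theta[idx, 2])
}
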