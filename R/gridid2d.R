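# Rotation-based grid score for 2D open-field maps -----------------------

#' Simulate a smoothed random-walk foraging trajectory
#'
#' Simple open-field trajectory: heading performs a random walk, speed is
#' constant, and the walk reflects off the arena walls.
#'
#' @param duration_s duration (s).
#' @param arena_cm square arena side (cm).
#' @param speed_cm_s speed (cm/s).
#' @param dt_s time step (s).
#' @param turn_sd heading increment SD per step (radians).
#' @param seed RNG seed.
#' @return data.frame `time_s, x_cm, y_cm`.
#' @export
simulate_open_field_walk <- function(duration_s = 600, arena_cm = 75,
                                     speed_cm_s = 15, dt_s = 0.02,
                                     turn_sd = 0.25, seed = 1L) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  n <- as.integer(duration_s / dt_s)
  head <- cumsum(stats::rnorm(n, 0, turn_sd))
  x <- numeric(n); y <- numeric(n)
  cx <- arena_cm / 2; cy <- arena_cm / 2
  for (i in seq_len(n)) {
    cx <- cx + speed_cm_s * dt_s * cos(head[i])
    cy <- cy + speed_cm_s * dt_s * sin(head[i])
    if (cx < 0) { cx <- -cx; head[i:n] <- pi - head[i:n] }
    if (cx > arena_cm) { cx <- 2 * arena_cm - cx; head[i:n] <- pi - head[i:n] }
    if (cy < 0) { cy <- -cy; head[i:n] <- -head[i:n] }
    if (cy > arena_cm) { cy <- 2 * arena_cm - cy; head[i:n] <- -head[i:n] }
    x[i] <- cx; y[i] <- cy
  }
  data.frame(time_s = seq_len(n) * dt_s, x_cm = x, y_cm = y)
}

#' Idealized 2D lattice firing rate along a trajectory
#'
#' Rate proportional to the rectified hexagonal interference pattern
#' `sum_a cos(k_a . x - phi_a)` with wavevector magnitude `2*pi/scale`.
#'
#' @param walk trajectory from [simulate_open_field_walk()].
#' @param scale_cm lattice period along each wavevector (cm).
#' @param phases length-3 phase vector.
#' @param peak_rate_hz peak rate (Hz).
#' @param orientation_deg lattice orientation (degrees).
#' @param square if `TRUE`, generate a square (90 deg) lattice instead (a
#'   negative-control pattern).
#' @return numeric rate vector (Hz).
#' @export
lattice_rate_2d <- function(walk, scale_cm = 40, phases = c(0, 0, 0),
                            peak_rate_hz = 15, orientation_deg = 0,
                            square = FALSE) {
  kmag <- 2 * pi / scale_cm
  angs <- if (square) c(0, 90) * pi / 180 else c(0, 60, 120) * pi / 180
  angs <- angs + orientation_deg * pi / 180
  s <- 0
  for (a in seq_along(angs)) {
    kx <- kmag * cos(angs[a]); ky <- kmag * sin(angs[a])
    s <- s + cos(kx * walk$x_cm + ky * walk$y_cm - phases[min(a, length(phases))])
  }
  mx <- length(angs)
  peak_rate_hz * pmax(0, s / mx)^2
}

# Occupancy-normalized, smoothed 2D rate map.
.ratemap_2d <- function(spike_t, walk, bin_cm = 2.5, arena_cm = 75,
                        smooth_sd_bins = 1.5) {
  nb <- ceiling(arena_cm / bin_cm)
  dt <- median(diff(walk$time_s))
  bx <- pmin(nb, floor(walk$x_cm / bin_cm) + 1L)
  by <- pmin(nb, floor(walk$y_cm / bin_cm) + 1L)
  occ <- matrix(dt * tabulate((by - 1L) * nb + bx, nb * nb), nb, nb)
  sx <- stats::approx(walk$time_s, walk$x_cm, xout = spike_t, rule = 2)$y
  sy <- stats::approx(walk$time_s, walk$y_cm, xout = spike_t, rule = 2)$y
  sbx <- pmin(nb, pmax(1L, floor(sx / bin_cm) + 1L))
  sby <- pmin(nb, pmax(1L, floor(sy / bin_cm) + 1L))
  cnt <- matrix(tabulate((sby - 1L) * nb + sbx, nb * nb), nb, nb)
  r <- cnt / occ
  r[occ == 0] <- NA
  # separable Gaussian smoothing with NA-aware renormalization
  S <- .smooth_matrix(nb, smooth_sd_bins)
  m0 <- r; m0[is.na(r)] <- 0
  w <- 1 - is.na(r)
  num <- S %*% m0 %*% t(S)
  den <- S %*% w %*% t(S)
  out <- num / den
  out[den == 0] <- NA
  out
}

# 2D spatial autocorrelogram: Pearson r at each integer-bin shift, computed
# from FFT cross-correlations of the map, its square and its validity mask.
.autocorrelogram_2d <- function(m, max_shift = NULL, min_overlap = 20) {
  nb <- nrow(m)
  if (is.null(max_shift)) max_shift <- nb - 2L
  w <- (!is.na(m)) * 1
  m0 <- m; m0[is.na(m)] <- 0
  np <- 2L * nb
  pad <- function(x) { p <- matrix(0, np, np); p[1:nb, 1:nb] <- x; p }
  xc <- function(a, b) {
    # cross-correlation: sum over overlap of a(i) * b(i + shift)
    Re(stats::fft(Conj(stats::fft(pad(a))) * stats::fft(pad(b)), inverse = TRUE)) / (np * np)
  }
  n   <- xc(w, w)
  sa  <- xc(m0, w);       sb  <- xc(w, m0)
  saa <- xc(m0^2, w);     sbb <- xc(w, m0^2)
  sab <- xc(m0, m0)
  num <- n * sab - sa * sb
  den <- sqrt(pmax(0, n * saa - sa^2) * pmax(0, n * sbb - sb^2))
  r <- num / den
  r[den <= 1e-10 | n < min_overlap] <- NA_real_
  # reorder FFT shifts (0..np-1, wrapped) into -max_shift..max_shift
  idx <- function(s) ifelse(s >= 0, s + 1L, np + s + 1L)
  sh <- -max_shift:max_shift
  r[idx(sh), idx(sh)]
}

# Bilinear interpolation into a matrix at fractional (row, col) positions.
.bilinear <- function(m, ri, ci) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- pmax(1, pmin(nr - 1, floor(ri))); c0 <- pmax(1, pmin(nc - 1, floor(ci)))
  fr <- ri - r0; fc <- ci - c0
  v00 <- m[cbind(r0, c0)]; v10 <- m[cbind(r0 + 1, c0)]
  v01 <- m[cbind(r0, c0 + 1)]; v11 <- m[cbind(r0 + 1, c0 + 1)]
  v00 * (1 - fr) * (1 - fc) + v10 * fr * (1 - fc) +
    v01 * (1 - fr) * fc + v11 * fr * fc
}

# Annulus rotation correlation of an autocorrelogram.
.rotation_score <- function(ac, inner, outer, angles_deg = c(30, 60, 90, 120, 150)) {
  ctr <- (nrow(ac) + 1) / 2
  rr <- seq(inner, outer, length.out = max(8, round(outer - inner) + 1))
  th <- seq(0, 2 * pi, length.out = 181)[-181]
  grid <- expand.grid(r = rr, th = th)
  base <- .bilinear(ac, ctr + grid$r * sin(grid$th), ctr + grid$r * cos(grid$th))
  out <- vapply(angles_deg, function(a) {
    rot <- .bilinear(ac, ctr + grid$r * sin(grid$th + a * pi / 180),
                     ctr + grid$r * cos(grid$th + a * pi / 180))
    ok <- !is.na(base) & !is.na(rot)
    if (sum(ok) < 50) return(NA_real_)
    stats::cor(base[ok], rot[ok])
  }, 0)
  names(out) <- paste0("r", angles_deg)
  out
}

# Inner annulus radius: first trough of the radially averaged autocorrelogram.
.central_peak_radius <- function(ac) {
  ctr <- (nrow(ac) + 1) / 2
  maxr <- floor(nrow(ac) / 2) - 1
  prof <- vapply(seq_len(maxr), function(r) {
    th <- seq(0, 2 * pi, length.out = 61)[-61]
    mean(.bilinear(ac, ctr + r * sin(th), ctr + r * cos(th)), na.rm = TRUE)
  }, 0)
  tr <- which(diff(sign(diff(prof))) > 0) + 1L   # local minima
  if (length(tr)) tr[1] else max(2L, round(maxr / 4))
}

#' Rotation-based grid score with a shuffle threshold
#'
#' Computes the 2D rate map (2.5-cm bins), its spatial autocorrelogram, and
#' the grid score: the minimum of the 60 and 120 degree annulus correlations
#' minus the maximum of the 30, 90 and 150 degree correlations. The
#' significance threshold is the 99th percentile of scores from circularly
#' time-shifted spike trains. Units with mean rate above 40 Hz are excluded.
#'
#' @param spike_t spike times (s).
#' @param walk open-field trajectory (`time_s, x_cm, y_cm`).
#' @param n_shuffles number of time-shift shuffles (default 1000).
#' @param seed RNG seed.
#' @param bin_cm map bin size (cm), default 2.5.
#' @param arena_cm arena side (cm).
#' @param min_shift_s minimum circular time shift (s).
#' @return list `score, threshold, is_grid, excluded, rotations, shuffle_scores`.
#' @export
grid_score_2d <- function(spike_t, walk, n_shuffles = 1000, seed = 1L,
                          bin_cm = 2.5, arena_cm = 75, min_shift_s = 20) {
  dur <- max(walk$time_s)
  mean_rate <- length(spike_t) / dur
  if (mean_rate > 40) {
    return(list(score = NA_real_, threshold = NA_real_, is_grid = FALSE,
                excluded = TRUE, rotations = NULL, shuffle_scores = numeric(0)))
  }
  score_of <- function(st) {
    m <- .ratemap_2d(st, walk, bin_cm = bin_cm, arena_cm = arena_cm)
    ac <- .autocorrelogram_2d(m)
    inner <- .central_peak_radius(ac)
    outer <- min(4 * inner, floor(nrow(ac) / 2) - 1)
    rot <- .rotation_score(ac, inner, outer)
    list(score = min(rot["r60"], rot["r120"]) - max(rot["r30"], rot["r90"], rot["r150"]),
         rotations = rot)
  }
  obs <- score_of(spike_t)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  shuf <- vapply(seq_len(n_shuffles), function(i) {
    shift <- stats::runif(1, min_shift_s, dur - min_shift_s)
    score_of((spike_t + shift) %% dur)$score
  }, 0)
  thr <- stats::quantile(shuf, 0.99, names = FALSE, na.rm = TRUE)
  list(score = unname(obs$score), threshold = thr,
       is_grid = isTRUE(unname(obs$score) > thr), excluded = FALSE,
       rotations = obs$rotations, shuffle_scores = shuf)
}
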