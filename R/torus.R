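# Bump tracking on the toroidal neural sheet -----------------------------

#' Bump centre of mass from population rates
#'
#' Firing-rate-weighted circular mean of each phase coordinate:
#' `psi_a(x) = atan2(sum_i sin(phi_a^i) r_i(x), sum_i cos(phi_a^i) r_i(x))`,
#' after an optional temporal Gaussian filter on the rates. Bins where the
#' population is silent or the resultant (nearly) cancels are masked and
#' carry the last valid value forward.
#'
#' @param rates bins x units rate matrix (over cumulative distance).
#' @param phases units x 3 phase matrix.
#' @param smooth_sd_bins Gaussian filter SD along bins (default 1); 0
#'   disables filtering.
#' @param zscore z-score each unit's rate before the average (default FALSE).
#' @param resultant_floor mask bins whose resultant length falls below this
#'   fraction of the summed weights.
#' @return object of class `bump_com`: list with `psi` (bins x 3), `theta`
#'   (bins x 2, wrapped to the unit cell), `mask` (TRUE = valid).
#' @export
bump_com <- function(rates, phases, smooth_sd_bins = 1, zscore = FALSE,
                     resultant_floor = 1e-6) {
  stopifnot(ncol(rates) == nrow(phases))
  r <- rates
  if (zscore) {
    r <- scale(r)
    r[is.na(r)] <- 0
    r <- r - min(r)  # keep weights non-negative
  }
  r <- .gauss_smooth(r, smooth_sd_bins)
  psi <- matrix(NA_real_, nrow(r), 3)
  mask <- rep(TRUE, nrow(r))
  for (a in 1:3) {
    s <- r %*% sin(phases[, a])
    c <- r %*% cos(phases[, a])
    res <- sqrt(s^2 + c^2)
    tot <- rowSums(abs(r))
    bad <- res < resultant_floor * pmax(tot, .Machine$double.eps) | tot == 0
    psi[, a] <- wrap_2pi(atan2(s, c))
    mask <- mask & !bad
  }
  # carry last valid bin forward through masked bins
  if (any(!mask)) {
    valid <- which(mask)
    if (length(valid)) {
      idx <- findInterval(seq_len(nrow(r)), valid)
      idx[idx == 0] <- 1L
      psi <- psi[valid[idx], , drop = FALSE]
    }
  }
  structure(list(psi = psi, theta = torus_wrap(hex_transform(psi)), mask = mask),
            class = "bump_com")
}

#' Sort co-modular cells onto the neural sheet
#'
#' Applies the hexagonal transform to per-unit phases,
#' `s_1 = phi_1 - phi_2/2`, `s_2 = (sqrt(3)/2) phi_2`, using the pair of
#' phases with the most reliable cross-window estimates, and bins the sheet
#' coordinates into a `sqrt(N) x sqrt(N)` quantile grid for rendering.
#'
#' @param phases units x 3 phase matrix.
#' @param phase_pair indices of the two phases used (default `c(1, 2)`; pick
#'   the pair best correlated across dark windows upstream).
#' @return object of class `sheet_sort`: `coords` (units x 2 on the unit
#'   cell), `grid_index` (units x 2 quantile bins), `n_side`, `phase_pair`.
#' @export
sheet_sort <- function(phases, phase_pair = c(1, 2)) {
  p1 <- phases[, phase_pair[1]]
  p2 <- phases[, phase_pair[2]]
  coords <- torus_wrap(hex_transform(cbind(p1, p2, wrap_2pi(p2 - p1))))
  n <- nrow(phases)
  n_side <- max(2L, floor(sqrt(n)))
  qbin <- function(v) {
    as.integer(cut(rank(v, ties.method = "first"),
                   breaks = seq(0, n, length.out = n_side + 1), labels = FALSE))
  }
  structure(list(coords = coords,
                 grid_index = cbind(qbin(coords[, 1]), qbin(coords[, 2])),
                 n_side = n_side, phase_pair = phase_pair),
            class = "sheet_sort")
}

#' Render population activity on the sorted sheet
#'
#' @param sort a `sheet_sort`.
#' @param rates_at_bin numeric vector of unit rates at one spatial bin.
#' @param zscore_ref optional units x bins matrix for z-scoring each unit.
#' @return `n_side x n_side` matrix of mean activity per sheet cell.
#' @export
sheet_activity <- function(sort, rates_at_bin, zscore_ref = NULL) {
  v <- rates_at_bin
  if (!is.null(zscore_ref)) {
    mu <- rowMeans(zscore_ref); sdv <- apply(zscore_ref, 1, stats::sd)
    v <- (v - mu) / ifelse(sdv > 0, sdv, 1)
  }
  m <- matrix(NA_real_, sort$n_side, sort$n_side)
  agg <- tapply(v, list(factor(sort$grid_index[, 1], levels = seq_len(sort$n_side)),
                        factor(sort$grid_index[, 2], levels = seq_len(sort$n_side))),
                mean)
  m[, ] <- agg
  m
}

#' Unwrap a bump trajectory with an origin grid search
#'
#' Naive unwrapping is sensitive to noise near the (arbitrary) edge of the
#' unit cell. For each window of `window_trials` trials, this applies
#' `n_origins` global phase shifts `eta`, unwraps the shifted phase series,
#' and keeps the origin whose per-trial trajectories are most consistent
#' (minimal across-trial variance of the within-trial trajectory). Windows
#' are stitched by congruent continuation.
#'
#' @param psi bins x 3 wrapped phase series (trials concatenated).
#' @param bins_per_trial spatial bins per trial.
#' @param window_trials trials per unwrapping window (default 5).
#' @param n_origins number of origin candidates (default 100; a
#'   `sqrt(n) x sqrt(n)` grid over `(eta_1, eta_2)`).
#' @return list with `psi_unwrapped` (bins x 3), `theta_unwrapped`
#'   (bins x 2), `origins` (per-window chosen `eta`).
#' @export
unwrap_trajectory <- function(psi, bins_per_trial, window_trials = 5,
                              n_origins = 100) {
  nb <- nrow(psi)
  n_trials <- ceiling(nb / bins_per_trial)
  side <- max(1L, round(sqrt(n_origins)))
  etas <- as.matrix(expand.grid(e1 = seq(0, 2 * pi, length.out = side + 1)[1:side],
                                e2 = seq(0, 2 * pi, length.out = side + 1)[1:side]))
  win_starts <- seq(1L, n_trials, by = window_trials)
  out <- matrix(NA_real_, nb, 3)
  origins <- matrix(NA_real_, length(win_starts), 2)
  prev_end <- NULL
  for (wi in seq_along(win_starts)) {
    tr0 <- win_starts[wi]
    tr1 <- min(tr0 + window_trials - 1L, n_trials)
    i0 <- (tr0 - 1L) * bins_per_trial + 1L
    i1 <- min(tr1 * bins_per_trial, nb)
    seg <- psi[i0:i1, , drop = FALSE]
    ntr <- ceiling(nrow(seg) / bins_per_trial)
    best <- NULL; best_score <- Inf; best_eta <- c(0, 0)
    for (k in seq_len(nrow(etas))) {
      eta <- c(etas[k, 1], etas[k, 2], wrap_2pi(etas[k, 2] - etas[k, 1]))
      shifted <- wrap_2pi(sweep(seg, 2, eta, "+"))
      unw <- apply(shifted, 2, signal::unwrap)
      unw <- sweep(unw, 2, eta)          # back to the original frame
      th <- hex_transform(unw[, 1:2, drop = FALSE])
      # consistency: variance across trials of the within-trial trajectory
      score <- 0
      if (ntr > 1 && nrow(seg) > 1) {
        for (d in 1:2) {
          tm <- matrix(NA_real_, ntr, bins_per_trial)
          for (t in seq_len(ntr)) {
            j0 <- (t - 1L) * bins_per_trial + 1L
            j1 <- min(t * bins_per_trial, nrow(seg))
            v <- th[j0:j1, d]
            tm[t, seq_along(v)] <- v - v[1]
          }
          score <- score + sum(apply(tm, 2, stats::var, na.rm = TRUE), na.rm = TRUE)
        }
      } else {
        # single trial: penalize large jumps instead
        score <- sum(diff(th[, 1])^2 + diff(th[, 2])^2)
      }
      if (score < best_score) { best_score <- score; best <- unw; best_eta <- eta[1:2] }
    }
    # stitch congruently to the previous window
    if (!is.null(prev_end)) {
      for (a in 1:3) {
        k2pi <- round((prev_end[a] - best[1, a]) / (2 * pi))
        best[, a] <- best[, a] + 2 * pi * k2pi
      }
    }
    out[i0:i1, ] <- best
    prev_end <- best[nrow(best), ] +
      (best[nrow(best), ] - best[max(1, nrow(best) - 1), ])  # extrapolate one bin
    origins[wi, ] <- best_eta
  }
  list(psi_unwrapped = out,
       theta_unwrapped = hex_transform(out[, 1:2, drop = FALSE]),
       origins = origins)
}

#' Three-ring projection of population activity
#'
#' Projects bins x units activity onto the three axis pairs
#' `(cos(phi_a), sin(phi_a))`. For an idealized toroidal population each
#' projection traces a ring; the radial coefficient of variation quantifies
#' circularity, optionally against a phase-shuffle permutation null.
#'
#' @param rates bins x units rate matrix.
#' @param phases units x 3 phase matrix.
#' @param n_perm permutation count for the phase-shuffle null (0 = none).
#' @param seed RNG seed for permutations.
#' @param center subtract the mean projection before computing radii
#'   (default TRUE).
#' @return list with `points` (list of 3 bins x 2 matrices), `radial_cv`
#'   (length 3), `angles` (bins x 3, atan2 of the projections), `null_cv`
#'   (n_perm x 3), `p_value` (per ring, if permuted).
#' @export
ring_projection <- function(rates, phases, n_perm = 0, seed = 1L,
                            center = TRUE) {
  pts <- vector("list", 3)
  cv <- numeric(3)
  ang <- matrix(NA_real_, nrow(rates), 3)
  proj_cv <- function(r, ph) {
    vapply(1:3, function(a) {
      P <- cbind(r %*% cos(ph[, a]), r %*% sin(ph[, a]))
      if (center) P <- sweep(P, 2, colMeans(P))
      rad <- sqrt(rowSums(P^2))
      stats::sd(rad) / mean(rad)
    }, 0)
  }
  for (a in 1:3) {
    P <- cbind(rates %*% cos(phases[, a]), rates %*% sin(phases[, a]))
    ang[, a] <- wrap_2pi(atan2(P[, 2] - if (center) mean(P[, 2]) else 0,
                               P[, 1] - if (center) mean(P[, 1]) else 0))
    pts[[a]] <- P
  }
  cv <- proj_cv(rates, phases)
  null_cv <- NULL; p <- NULL
  if (n_perm > 0) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
    null_cv <- t(vapply(seq_len(n_perm), function(i) {
      proj_cv(rates, phases[sample(nrow(phases)), , drop = FALSE])
    }, numeric(3)))
    p <- vapply(1:3, function(a) (1 + sum(null_cv[, a] <= cv[a])) / (n_perm + 1), 0)
  }
  list(points = pts, radial_cv = cv, angles = ang, null_cv = null_cv,
       p_value = p)
}

#' Population rate matrix over cumulative distance
#'
#' Convenience accessor: turns a `rate_map` into a bins x units matrix with
#' trials concatenated (NA gaps interpolated), for [bump_com()] and the ring
#' projection.
#'
#' @param rm a `rate_map`.
#' @param units unit indices.
#' @param trials trial indices (default: all).
#' @return bins x units matrix.
#' @export
population_rates <- function(rm, units, trials = NULL) {
  vapply(units, function(u) flatten_ratemap(rm, u, trials),
         numeric(length(flatten_ratemap(rm, units[1], trials))))
}

#' Stationary-period mask from running speed
#'
#' Trajectory statistics are distance-based; when the animal stops, the
#' bump halts at its sheet location, so bins visited below a speed floor
#' are masked out.
#'
#' @param behaviour 50 Hz behaviour trace (`time_s`, `trial`, `position_cm`,
#'   `speed_cm_s`).
#' @param bins bin table (as in `session$bins`).
#' @param threshold_cm_s speed floor (default 2 cm/s).
#' @return logical vector over bins (TRUE = moving, keep).
#' @export
speed_mask <- function(behaviour, bins, threshold_cm_s = 2) {
  L_bin <- bins$x_cm[2] - bins$x_cm[1]
  nb <- max(bins$bin)
  bb <- pmin(nb, floor(behaviour$position_cm / L_bin) + 1L)
  key_beh <- (behaviour$trial - 1L) * nb + bb
  slow <- tapply(behaviour$speed_cm_s < threshold_cm_s,
                 factor(key_beh, levels = (bins$trial - 1L) * nb + bins$bin),
                 any)
  out <- !as.logical(slow)
  out[is.na(out)] <- TRUE
  unname(out)
}
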