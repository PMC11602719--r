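# Rate maps and spatial spectra ------------------------------------------

# Gaussian smoothing matrix over spatial bins (edge-renormalized kernel).
# Only for short series (it is dense); use .gauss_smooth for long ones.
.smooth_matrix <- function(nb, sd_bins) {
  if (sd_bins <= 0) return(diag(nb))
  idx <- seq_len(nb)
  W <- exp(-outer(idx, idx, "-")^2 / (2 * sd_bins^2))
  W[abs(outer(idx, idx, "-")) > ceiling(4 * sd_bins)] <- 0
  W / rowSums(W)
}

# Edge-renormalized Gaussian smoothing of the columns of a matrix, by kernel
# convolution (O(n log n)); equivalent to .smooth_matrix(n, sd) %*% x.
.gauss_smooth <- function(x, sd_bins) {
  if (sd_bins <= 0) return(x)
  vec_in <- is.null(dim(x))
  if (vec_in) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  half <- ceiling(4 * sd_bins)
  k <- exp(-(-half:half)^2 / (2 * sd_bins^2))
  k <- k / sum(k)
  mid <- (half + 1):(half + n)
  den <- stats::convolve(rep(1, n), k, type = "open")[mid]
  out <- apply(x, 2, function(v)
    stats::convolve(v, k, type = "open")[mid] / den)
  if (vec_in) drop(out) else matrix(out, nrow = n)
}

#' Trial-by-position firing-rate maps
#'
#' Bins each unit's spikes into spatial bins per trial, divides by time
#' occupancy, and smooths along position with a Gaussian kernel. No speed
#' filtering is applied. Zero-occupancy bins are flagged `NA`, never divided.
#'
#' @param session a `sim_session` (behaviour trace + spike times).
#' @param bin_cm spatial bin size (cm), default 2.
#' @param smooth_sd_bins Gaussian smoothing SD in bins, default 2; 0 disables
#'   smoothing.
#' @return an object of class `rate_map`: list with `rates` (unit x trial x
#'   bin array, Hz), `counts` (raw spike counts), `occupancy` (trial x bin,
#'   s), `bin_cm`, `smooth_sd_bins`, `trial_block` (block index per trial).
#' @export
compute_ratemap <- function(session, bin_cm = 2, smooth_sd_bins = 2) {
  beh <- session$behaviour
  L <- session$track$track_length_cm
  nb <- as.integer(round(L / bin_cm))
  n_trials <- max(beh$trial)
  cum <- (beh$trial - 1) * L + beh$position_cm
  # occupancy
  tb <- beh$trial
  bb <- pmin(nb, floor(beh$position_cm / bin_cm) + 1L)
  dt <- median(diff(beh$time_s))
  occ <- matrix(0, n_trials, nb)
  occ_tab <- tapply(rep(dt, length(tb)), list(factor(tb, levels = seq_len(n_trials)),
                                              factor(bb, levels = seq_len(nb))), sum)
  occ_tab[is.na(occ_tab)] <- 0
  occ[, ] <- occ_tab

  n_units <- length(session$spikes)
  counts <- array(0, dim = c(n_units, n_trials, nb))
  for (u in seq_len(n_units)) {
    st <- session$spikes[[u]]
    if (!length(st)) next
    sc <- stats::approx(beh$time_s, cum, xout = st, rule = 2)$y
    str <- pmin(n_trials, pmax(1L, floor(sc / L) + 1L))
    sbn <- pmin(nb, pmax(1L, floor((sc %% L) / bin_cm) + 1L))
    counts[u, , ] <- counts[u, , ] +
      t(matrix(tabulate((str - 1L) * nb + sbn, n_trials * nb), nrow = nb))
  }

  rates <- counts
  occ_rep <- occ
  for (u in seq_len(n_units)) {
    r <- counts[u, , ] / occ_rep
    r[occ_rep == 0] <- NA_real_
    rates[u, , ] <- r
  }
  if (smooth_sd_bins > 0) {
    S <- .smooth_matrix(nb, smooth_sd_bins)
    for (u in seq_len(n_units)) {
      m <- rates[u, , , drop = TRUE]
      if (is.null(dim(m))) m <- matrix(m, nrow = 1)
      nas <- is.na(m)
      m0 <- m; m0[nas] <- 0
      sm <- (m0 %*% t(S))
      if (any(nas)) {
        w <- (1 - nas) %*% t(S)
        sm <- sm / w
        sm[w == 0] <- NA_real_
      }
      rates[u, , ] <- sm
    }
  }
  trial_block <- vapply(split(session$bins$block,
                              factor(session$bins$trial,
                                     levels = seq_len(max(session$bins$trial)))),
                        `[`, 0, 1)
  structure(list(rates = rates, counts = counts, occupancy = occ,
                 bin_cm = bin_cm, smooth_sd_bins = smooth_sd_bins,
                 trial_block = as.integer(trial_block),
                 track = session$track),
            class = "rate_map")
}

#' Flatten a rate map to a rate-versus-cumulative-distance sequence
#'
#' Concatenates the per-trial maps of one unit over the chosen trials into a
#' single sequence over cumulative distance; `NA` gaps (zero occupancy) are
#' linearly interpolated, as gapless series are required for spectral
#' analysis.
#'
#' @param rm a `rate_map`.
#' @param unit unit index.
#' @param trials trial indices (default: all).
#' @return numeric vector of rates per spatial bin of cumulative distance.
#' @export
flatten_ratemap <- function(rm, unit, trials = NULL) {
  if (is.null(trials)) trials <- seq_len(dim(rm$rates)[2])
  x <- as.vector(t(rm$rates[unit, trials, , drop = TRUE]))
  if (anyNA(x)) {
    idx <- seq_along(x)
    ok <- !is.na(x)
    if (!any(ok)) return(rep(0, length(x)))
    x <- stats::approx(idx[ok], x[ok], xout = idx, rule = 2)$y
  }
  x
}

#' Windowed power spectral density of a spatial rate sequence
#'
#' Z-scores the sequence, cuts it into overlapping boxcar segments and
#' returns the per-window PSD and complex spectrum on a cycles-per-metre
#' frequency axis.
#'
#' @param rate_seq rate versus cumulative distance (one value per spatial
#'   bin), e.g. from [flatten_ratemap()].
#' @param segment_bins segment length in bins (default 1600, i.e. 32 m at
#'   2-cm bins).
#' @param overlap_bins overlap between consecutive segments (default 1400,
#'   i.e. steps of 4 m).
#' @param bin_m spatial bin size in metres (default 0.02).
#' @return an object of class `spectrogram`: list with `freq` (cycles/m),
#'   `psd` (windows x freq), `spectrum` (complex, windows x freq),
#'   `window_start_m`, `segment_bins`, `bin_m`.
#' @export
compute_spectrogram <- function(rate_seq, segment_bins = 1600,
                                overlap_bins = 1400, bin_m = 0.02) {
  n <- length(rate_seq)
  if (n < segment_bins) {
    stop("rate sequence (", n, " bins) shorter than one segment (",
         segment_bins, " bins); use a smaller `segment_bins` for scaled-down data")
  }
  mu <- mean(rate_seq); sdv <- stats::sd(rate_seq)
  z <- if (sdv > 0) (rate_seq - mu) / sdv else rate_seq * 0
  step <- segment_bins - overlap_bins
  stopifnot(step >= 1)
  starts <- seq(1L, n - segment_bins + 1L, by = step)
  nf <- segment_bins %/% 2 + 1L
  freq <- (seq_len(nf) - 1L) / (segment_bins * bin_m)
  spec <- matrix(complex(real = 0), length(starts), nf)
  for (w in seq_along(starts)) {
    seg <- z[starts[w]:(starts[w] + segment_bins - 1L)]
    f <- stats::fft(seg)[seq_len(nf)]
    spec[w, ] <- f
  }
  psd <- (Mod(spec)^2) / segment_bins
  structure(list(freq = freq, psd = psd, spectrum = spec,
                 window_start_m = (starts - 1L) * bin_m,
                 segment_bins = segment_bins, bin_m = bin_m),
            class = "spectrogram")
}

#' Trial-averaged tuning curves
#'
#' @param rm a `rate_map`.
#' @param trials trial indices (default: all).
#' @return units x bins matrix of mean rates.
#' @export
tuning_curves <- function(rm, trials = NULL) {
  if (is.null(trials)) trials <- seq_len(dim(rm$rates)[2])
  out <- apply(rm$rates[, trials, , drop = FALSE], c(1, 3), mean, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out
}
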