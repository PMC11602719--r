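# Grid-cell identification from dark-running spectra ---------------------

#' Locate the three dominant spectral peaks
#'
#' Finds local maxima of a PSD (excluding DC) and returns the three largest,
#' in ascending frequency; ties are broken toward the lower frequency.
#'
#' @param psd numeric PSD vector (one window).
#' @param freq frequency axis (cycles/m).
#' @return length-3 numeric vector of peak frequencies, or `NULL` if fewer
#'   than three local maxima exist (classification failure for the window).
#' @export
find_three_peaks <- function(psd, freq) {
  n <- length(psd)
  if (n < 5) return(NULL)
  i <- 2:(n - 1)
  is_peak <- psd[i] > psd[i - 1] & psd[i] >= psd[i + 1]
  pk <- i[is_peak]
  pk <- pk[pk > 1]                       # exclude anything touching DC
  if (length(pk) < 3) return(NULL)
  ord <- order(-psd[pk], freq[pk])
  sort(freq[pk[ord[1:3]]])
}

#' Extract Fourier phases at given frequencies
#'
#' For each window and each frequency `f_hat`, computes the phase of the
#' windowed Fourier coefficient `int dx e^{i 2 pi x f_hat} r(x)` (the sign
#' convention is fixed so that `r(x) = cos(2 pi f_hat x - phi)` yields `phi`).
#' Positions are absolute (cumulative distance), so phases from different
#' windows are directly comparable and are combined by a circular mean.
#'
#' @param rate_seq z-scored (or raw) rate versus cumulative distance.
#' @param f_hat numeric vector of frequencies (cycles/m).
#' @param bin_m bin size in metres.
#' @param windows optional matrix/list of `(start_bin, end_bin)` windows;
#'   default one window covering the whole sequence.
#' @param min_coef relative magnitude floor below which a window's phase is
#'   flagged unreliable and dropped (fraction of the maximum possible
#'   coefficient magnitude).
#' @return list with `phi` (circular-mean phase per frequency, radians in
#'   `[0, 2*pi)`), `phi_by_window` (windows x frequencies), `circ_sd`
#'   (cross-window circular SD per frequency), `reliable` (logical matrix).
#' @export
extract_phases <- function(rate_seq, f_hat, bin_m = 0.02, windows = NULL,
                           min_coef = 0.01) {
  n <- length(rate_seq)
  if (is.null(windows)) windows <- matrix(c(1L, n), 1)
  if (is.list(windows)) windows <- do.call(rbind, windows)
  x <- (seq_len(n) - 0.5) * bin_m
  nw <- nrow(windows)
  phi_w <- matrix(NA_real_, nw, length(f_hat))
  rel <- matrix(FALSE, nw, length(f_hat))
  for (w in seq_len(nw)) {
    idx <- windows[w, 1]:windows[w, 2]
    r <- rate_seq[idx]
    xs <- x[idx]
    scale_max <- sum(abs(r)) * bin_m
    for (a in seq_along(f_hat)) {
      coef <- sum(exp(1i * 2 * pi * f_hat[a] * xs) * r) * bin_m
      phi_w[w, a] <- wrap_2pi(Arg(coef))
      rel[w, a] <- Mod(coef) >= min_coef * max(scale_max, .Machine$double.eps)
    }
  }
  phi <- vapply(seq_along(f_hat), function(a) {
    v <- phi_w[rel[, a], a]
    if (!length(v)) NA_real_ else circ_mean(v)
  }, 0)
  csd <- vapply(seq_along(f_hat), function(a) {
    v <- phi_w[rel[, a], a]
    if (length(v) < 2) NA_real_ else circ_sd(v)
  }, 0)
  list(phi = phi, phi_by_window = phi_w, circ_sd = csd, reliable = rel)
}

# Mean pairwise Pearson correlation of per-window PSDs across a set of units.
.mean_pairwise_spec_cor <- function(spec_list, units) {
  if (length(units) < 2) return(NA_real_)
  nw <- min(vapply(spec_list[units], function(s) nrow(s$psd), 0L))
  cors <- c()
  for (w in seq_len(nw)) {
    m <- vapply(spec_list[units], function(s) s$psd[w, ], spec_list[[units[1]]]$psd[1, ])
    cc <- stats::cor(m)
    cors <- c(cors, cc[upper.tri(cc)])
  }
  mean(cors)
}

#' Infer grid scale and slice angle from three slice frequencies
#'
#' For a 1D slice at angle gamma through a lattice with fundamental spatial
#' frequency `F` (cycles/m), the slice frequencies are
#' `f_a = F * |cos(gamma - {0, 60, 120} deg)|`, which satisfy
#' `sum f_a^2 = 3/2 F^2`. The scale is `lambda = 100 / F` cm.
#'
#' @param f_hat length-3 vector of slice frequencies (cycles/m).
#' @return list with `scale_cm`, `slice_angle_deg` (in `[0, 30]` by lattice
#'   symmetry), `F_cycles_per_m`.
#' @export
infer_scale <- function(f_hat) {
  Fc <- sqrt(2 * sum(f_hat^2) / 3)
  obj <- function(g) {
    pred <- sort(abs(Fc * cos(g - c(0, 60, 120) * pi / 180)))
    sum((pred - sort(f_hat))^2)
  }
  gs <- seq(0, pi / 6, length.out = 181)
  g <- gs[which.min(vapply(gs, obj, 0))]
  list(scale_cm = 100 / Fc, slice_angle_deg = g * 180 / pi, F_cycles_per_m = Fc)
}

#' Cluster units into grid modules by their dark-running spectra
#'
#' K-means on z-scored, window-averaged PSD vectors (10 restarts, fixed
#' seed). A cluster is accepted as a grid module iff the mean pairwise
#' Pearson correlation of its members' spectrograms across windows exceeds
#' `r_threshold`.
#'
#' @param spec_list list of `spectrogram` objects, one per unit (first dark
#'   block).
#' @param k number of k-means clusters (5 or 6 in typical use).
#' @param seed RNG seed for k-means restarts.
#' @param r_threshold acceptance threshold on the mean pairwise spectrogram
#'   correlation (default 0.3).
#' @param features `"averaged"` (default; window-averaged PSD) or
#'   `"concatenated"` (all windows concatenated).
#' @return list of module candidates, each `list(unit_ids, mean_pairwise_r,
#'   accepted)`; attribute `"cluster"` carries the full assignment vector.
#' @export
cluster_modules <- function(spec_list, k = 5, seed = 1L, r_threshold = 0.3,
                            features = c("averaged", "concatenated")) {
  features <- match.arg(features)
  n <- length(spec_list)
  if (k > n) stop("k (", k, ") exceeds the number of units (", n, ")")
  feat <- t(vapply(spec_list, function(s) {
    v <- if (features == "averaged") colMeans(s$psd) else as.vector(t(s$psd))
    sdv <- stats::sd(v)
    if (sdv > 0) (v - mean(v)) / sdv else v * 0
  }, numeric(if (features == "averaged") length(spec_list[[1]]$freq)
             else length(spec_list[[1]]$freq) * nrow(spec_list[[1]]$psd))))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  km <- stats::kmeans(feat, centers = k, nstart = 10, iter.max = 100)
  mods <- lapply(seq_len(k), function(ci) {
    units <- which(km$cluster == ci)
    r <- .mean_pairwise_spec_cor(spec_list, units)
    list(unit_ids = units, mean_pairwise_r = r,
         accepted = !is.na(r) && r > r_threshold)
  })
  attr(mods, "cluster") <- km$cluster
  mods
}

#' Classify grid cells and extract module structure from a session
#'
#' End-to-end dark-spectrum classification: per-unit rate maps over the dark
#' trials of the first dark block, windowed spectra, k-means module
#' clustering with the correlation acceptance rule, three-peak frequency
#' estimation on the module-average PSD, and per-unit phase extraction
#' (circular mean across dark windows).
#'
#' @param session a `sim_session`.
#' @param k clusters for k-means.
#' @param seed RNG seed.
#' @param segment_bins,overlap_bins spectrogram segmentation (bins).
#' @param rm optional precomputed `rate_map` (with `bin_cm = 2`).
#' @param r_threshold module acceptance threshold.
#' @return object of class `grid_modules`: list of accepted modules, each
#'   with `unit_ids`, `freqs_f_hat`, `phases` (units x 3), `mean_pairwise_r`,
#'   `inferred_scale_cm`, `slice_angle_deg`; plus attributes `cluster`,
#'   `module_table` (per-unit data.frame).
#' @export
classify_gridcells <- function(session, k = 5, seed = 1L,
                               segment_bins = 1600, overlap_bins = NULL,
                               rm = NULL, r_threshold = 0.3) {
  if (is.null(overlap_bins)) overlap_bins <- segment_bins - segment_bins %/% 8
  if (is.null(rm)) rm <- compute_ratemap(session)
  dark_blocks <- which(vapply(session$track$blocks, `[[`, TRUE, "dark"))
  first_dark <- if (length(dark_blocks)) dark_blocks[1] else 1L
  trials <- which(rm$trial_block == first_dark)
  n_units <- dim(rm$rates)[1]
  seqs <- lapply(seq_len(n_units), function(u) flatten_ratemap(rm, u, trials))
  specs <- lapply(seqs, compute_spectrogram, segment_bins = segment_bins,
                  overlap_bins = overlap_bins, bin_m = rm$bin_cm / 100)
  mods <- cluster_modules(specs, k = k, seed = seed, r_threshold = r_threshold)
  step <- segment_bins - overlap_bins
  nbin <- length(seqs[[1]])
  starts <- seq(1L, nbin - segment_bins + 1L, by = step)
  windows <- cbind(starts, starts + segment_bins - 1L)

  accepted <- Filter(function(m) m$accepted, mods)
  out <- lapply(accepted, function(m) {
    freq <- specs[[m$unit_ids[1]]]$freq
    # module-average PSD per window; the slice angle drifts in the dark, so
    # peaks are located within each window and the (angle-invariant)
    # fundamental frequency is pooled across windows
    psd_w <- Reduce(`+`, lapply(m$unit_ids, function(u) specs[[u]]$psd))
    per_window <- lapply(seq_len(nrow(psd_w)), function(w)
      find_three_peaks(psd_w[w, ], freq))
    usable <- !vapply(per_window, is.null, TRUE)
    if (!any(usable)) return(NULL)
    scales <- vapply(per_window[usable], function(f) infer_scale(f)$scale_cm, 0)
    angles <- vapply(per_window[usable], function(f)
      infer_scale(f)$slice_angle_deg, 0)
    # reference peaks: the window with the strongest three-peak power
    power <- vapply(which(usable), function(w)
      sum(psd_w[w, vapply(per_window[[w]], function(f)
        which.min(abs(freq - f)), 0L)]), 0)
    f_hat <- per_window[[which(usable)[which.max(power)]]]
    ph <- t(vapply(m$unit_ids, function(u) {
      extract_phases(seqs[[u]], f_hat, bin_m = rm$bin_cm / 100,
                     windows = windows)$phi
    }, numeric(3)))
    list(unit_ids = m$unit_ids, freqs_f_hat = f_hat, phases = ph,
         mean_pairwise_r = m$mean_pairwise_r,
         inferred_scale_cm = stats::median(scales),
         slice_angle_deg = stats::median(angles),
         per_window_scale_cm = scales)
  })
  out <- Filter(Negate(is.null), out)
  tab <- data.frame(unit = seq_len(n_units),
                    cluster = attr(mods, "cluster"),
                    module = NA_integer_, accepted = FALSE)
  for (mi in seq_along(out)) {
    tab$module[out[[mi]]$unit_ids] <- mi
    tab$accepted[out[[mi]]$unit_ids] <- TRUE
  }
  structure(out, class = "grid_modules", cluster = attr(mods, "cluster"),
            module_table = tab)
}

#' Half-session spatial stability (non-grid spatial cell rule)
#'
#' Pearson correlation between a unit's tuning curve in the first and second
#' half of a block of trials, averaged across the given blocks.
#'
#' @param rm a `rate_map`.
#' @param unit unit index.
#' @param blocks block indices (default: all non-dark blocks).
#' @return mean correlation.
#' @export
half_session_stability <- function(rm, unit, blocks = NULL) {
  if (is.null(blocks)) blocks <- setdiff(unique(rm$trial_block), integer(0))
  rs <- vapply(blocks, function(b) {
    trials <- which(rm$trial_block == b)
    if (length(trials) < 4) return(NA_real_)
    h1 <- trials[seq_len(length(trials) %/% 2)]
    h2 <- setdiff(trials, h1)
    t1 <- colMeans(rm$rates[unit, h1, , drop = TRUE], na.rm = TRUE)
    t2 <- colMeans(rm$rates[unit, h2, , drop = TRUE], na.rm = TRUE)
    if (stats::sd(t1, na.rm = TRUE) == 0 || stats::sd(t2, na.rm = TRUE) == 0)
      return(NA_real_)
    stats::cor(t1, t2, use = "complete.obs")
  }, 0)
  mean(rs, na.rm = TRUE)
}
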