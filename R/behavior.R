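# Behavioural metrics ----------------------------------------------------

# Zones used by the anticipation metrics: "near" is the tenth of the track
# preceding the reward zone, "far" the tenth preceding the track centre.
.anticipation_zones <- function(L, zone_start) {
  list(near = c(zone_start - L / 10, zone_start),
       far = c(L / 2 - L / 10, L / 2))
}

#' Anticipatory licking selectivity
#'
#' `lick_ant = (lick_near - lick_far) / (lick_near + lick_far)` where the
#' rates are average lick rates per unit distance in the near zone (the
#' tenth of the track before the reward zone) and the far zone (the tenth
#' before the track centre). +1 for perfect anticipation, 0 for chance, -1
#' for licking only in the far zone.
#'
#' @param lick_pos_cm positions of (non-consummatory) licks.
#' @param L track length (cm).
#' @param zone_start reward-zone start (cm).
#' @return selectivity in `[-1, 1]`; `NA` if both zone rates are zero.
#' @export
lick_anticipation <- function(lick_pos_cm, L, zone_start) {
  z <- .anticipation_zones(L, zone_start)
  rate <- function(zz) sum(lick_pos_cm >= zz[1] & lick_pos_cm < zz[2]) / (zz[2] - zz[1])
  near <- rate(z$near); far <- rate(z$far)
  if (near + far == 0) return(NA_real_)
  (near - far) / (near + far)
}

#' Anticipatory slowing selectivity
#'
#' Same ratio as [lick_anticipation()] with lick rate replaced by time
#' elapsed in each zone.
#'
#' @param behaviour 50 Hz behaviour trace (`time_s`, `position_cm`).
#' @param L track length (cm).
#' @param zone_start reward-zone start (cm).
#' @return selectivity in `[-1, 1]`; `NA` if no time was spent in either
#'   zone.
#' @export
slowing_anticipation <- function(behaviour, L, zone_start) {
  z <- .anticipation_zones(L, zone_start)
  dt <- stats::median(diff(behaviour$time_s))
  tin <- function(zz) dt * sum(behaviour$position_cm >= zz[1] &
                                 behaviour$position_cm < zz[2])
  near <- tin(z$near); far <- tin(z$far)
  if (near + far == 0) return(NA_real_)
  (near - far) / (near + far)
}

#' Block accuracy
#'
#' Fraction of a block's trials on which the animal triggered the reward by
#' licking in the trigger zone (the first 10 cm of the reward zone) before
#' the automatic reward.
#'
#' @param events session event table.
#' @param trials trial indices of the block.
#' @param zone length-2 reward zone (cm); the trigger zone is its first
#'   10 cm.
#' @param offsets optional data.frame `trial, offset_cm` of per-trial zone
#'   offsets.
#' @return fraction in `[0, 1]`.
#' @export
block_accuracy <- function(events, trials, zone, offsets = NULL) {
  hits <- vapply(trials, function(t) {
    off <- 0
    if (!is.null(offsets)) {
      o <- offsets$offset_cm[offsets$trial == t]
      if (length(o) && !is.na(o[1])) off <- o[1]
    }
    trig <- c(zone[1], min(zone[1] + 10, zone[2])) + off
    licks <- events[events$trial == t & events$event_type == "lick" &
                      !events$consummatory, , drop = FALSE]
    any(licks$position_cm >= trig[1] & licks$position_cm < trig[2])
  }, TRUE)
  mean(hits)
}

#' Per-trial licking error
#'
#' Mean absolute distance between each trial's non-consummatory licks and
#' the reward-zone start.
#'
#' @param events session event table.
#' @param trials trial indices.
#' @param zone_start reward-zone start (cm); may be length 1 or
#'   per-trial.
#' @return numeric vector (cm), NA for trials without non-consummatory
#'   licks.
#' @export
licking_error <- function(events, trials, zone_start) {
  zs <- rep_len(zone_start, length(trials))
  vapply(seq_along(trials), function(i) {
    l <- events[events$trial == trials[i] & events$event_type == "lick" &
                  !events$consummatory, , drop = FALSE]
    if (!nrow(l)) return(NA_real_)
    mean(abs(l$position_cm - zs[i]))
  }, 0)
}

#' Per-trial code stability before the reward zone
#'
#' Average spatial correlation of the population activity on each trial
#' with all other trials of the block, restricted to the window preceding
#' the reward zone.
#'
#' @param rm a `rate_map`.
#' @param units unit indices.
#' @param trials trial indices of the block.
#' @param zone_start reward-zone start (cm).
#' @param window_cm window before the zone (default 50).
#' @return numeric vector of stabilities per trial.
#' @export
trial_stability <- function(rm, units, trials, zone_start, window_cm = 50) {
  bin <- rm$bin_cm
  b1 <- floor(zone_start / bin)
  b0 <- max(1L, b1 - round(window_cm / bin) + 1L)
  V <- vapply(trials, function(t) {
    v <- as.vector(rm$rates[units, t, b0:b1])
    v[is.na(v)] <- 0
    v
  }, numeric(length(units) * (b1 - b0 + 1L)))
  cc <- suppressWarnings(stats::cor(V))
  diag(cc) <- NA
  rowMeans(cc, na.rm = TRUE)
}

#' Stability-error relation
#'
#' Pearson correlation across trials between per-trial code stability and
#' licking error.
#'
#' @param stability per-trial stability (from [trial_stability()]).
#' @param lick_error per-trial licking error (from [licking_error()]).
#' @return list with `r` and `p` (correlation test).
#' @export
stability_error_relation <- function(stability, lick_error) {
  ok <- !is.na(stability) & !is.na(lick_error)
  if (sum(ok) < 3) return(list(r = NA_real_, p = NA_real_))
  ct <- stats::cor.test(stability[ok], lick_error[ok])
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Generic permutation test for paired session differences
#'
#' Sign-flip permutation test on paired differences (two-sided).
#'
#' @param a,b paired measurements.
#' @param n permutations.
#' @param seed RNG seed.
#' @return list with `observed` (mean difference) and `p`.
#' @export
paired_permutation_test <- function(a, b, n = 1000, seed = 1L) {
  d <- a - b
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  obs <- mean(d)
  null <- vapply(seq_len(n), function(i)
    mean(d * sample(c(-1, 1), length(d), replace = TRUE)), 0)
  list(observed = obs, p = (1 + sum(abs(null) >= abs(obs))) / (n + 1))
}
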