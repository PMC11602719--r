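#' @keywords internal
"_PACKAGE"

# Hexagonal lattice geometry ---------------------------------------------
#
# A grid module lives on a twisted torus: per-cell phases phi_a (a = 1, 2, 3)
# along three unit wavevectors at 0, 60 and 120 degrees carry 2 degrees of
# freedom (phi_3 = phi_2 - phi_1 mod 2pi).  Sheet coordinates are obtained by
# the shear theta_1 = psi_1 - psi_2/2, theta_2 = (sqrt(3)/2) psi_2, whose
# periodicity lattice is generated by (2*pi, 0) and (-pi, sqrt(3)*pi).

#' Unit wavevectors of the hexagonal lattice
#'
#' Three unit-length wavevectors oriented at 0, 60 and 120 degrees. A grid
#' cell's idealized 2D pattern is `sum_a cos(k_a . x - phi_a)`.
#'
#' @return A 3 x 2 matrix; rows are the wavevectors.
#' @export
hex_wavevectors <- function() {
  ang <- c(0, 60, 120) * pi / 180
  cbind(cos(ang), sin(ang))
}

#' Wrap angles to `[0, 2*pi)`
#' @param x numeric vector of angles (radians).
#' @return wrapped angles.
#' @export
wrap_2pi <- function(x) x %% (2 * pi)

#' Signed circular difference in `(-pi, pi]`
#' @param a,b angles (radians).
#' @return minimal signed difference `a - b`.
#' @export
circ_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

#' Circular mean
#'
#' Resultant-vector mean of a sample of angles, optionally weighted.
#'
#' @param x angles (radians).
#' @param w optional non-negative weights.
#' @return mean angle in `[0, 2*pi)`; `NA` if the resultant is (near) zero.
#' @export
circ_mean <- function(x, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  keep <- !is.na(x) & !is.na(w)
  x <- x[keep]; w <- w[keep]
  if (!length(x) || sum(w) <= 0) return(NA_real_)
  s <- sum(w * sin(x)); c <- sum(w * cos(x))
  if (sqrt(s^2 + c^2) < 1e-12 * sum(w)) return(NA_real_)
  wrap_2pi(atan2(s, c))
}

#' Circular standard deviation
#' @param x angles (radians).
#' @return circular SD `sqrt(-2 log R)` where `R` is the mean resultant length.
#' @export
circ_sd <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  r <- sqrt(mean(sin(x))^2 + mean(cos(x))^2)
  sqrt(pmax(0, -2 * log(pmax(r, .Machine$double.eps))))
}

#' Hexagonal sheet transform
#'
#' Maps the three circular phase coordinates `psi_(1,2,3)` (2 d.f.) to 2D
#' sheet coordinates on the unit cell of the twisted torus:
#' `theta_1 = psi_1 - psi_2 / 2`, `theta_2 = (sqrt(3)/2) psi_2`.
#'
#' @param psi numeric matrix (n x 3 or n x 2) or length-3/2 vector of phases;
#'   only the first two columns are used.
#' @return n x 2 matrix of `(theta_1, theta_2)`.
#' @export
hex_transform <- function(psi) {
  if (is.null(dim(psi))) psi <- matrix(psi, nrow = 1)
  cbind(psi[, 1] - psi[, 2] / 2, sqrt(3) / 2 * psi[, 2])
}

#' Inverse of the hexagonal sheet transform
#'
#' Recovers the phase triplet `psi_(1,2,3)` from sheet coordinates, using the
#' closure `psi_3 = psi_2 - psi_1` (mod 2*pi for wrapped input).
#'
#' @param theta n x 2 matrix of sheet coordinates.
#' @param wrap if `TRUE` (default) wrap the result to `[0, 2*pi)`.
#' @return n x 3 matrix of phases.
#' @export
hex_inverse <- function(theta, wrap = TRUE) {
  if (is.null(dim(theta))) theta <- matrix(theta, nrow = 1)
  psi2 <- 2 * theta[, 2] / sqrt(3)
  psi1 <- theta[, 1] + theta[, 2] / sqrt(3)
  psi <- cbind(psi1, psi2, psi2 - psi1)
  if (wrap) psi <- wrap_2pi(psi)
  unname(psi)
}

# Lattice generators of the sheet periodicity in theta coordinates.
.hex_lattice_generators <- function() {
  rbind(c(2 * pi, 0), c(-pi, sqrt(3) * pi))
}

# All lattice translations with coefficients in -r..r (used for minimal image).
.hex_shifts_r2 <- {
  g <- rbind(c(2 * pi, 0), c(-pi, sqrt(3) * pi))
  mn <- as.matrix(expand.grid(m = -2:2, n = -2:2))
  mn %*% g
}
.hex_lattice_shifts <- function(r = 2) {
  if (r == 2) return(.hex_shifts_r2)
  g <- .hex_lattice_generators()
  mn <- as.matrix(expand.grid(m = -r:r, n = -r:r))
  mn %*% g
}

#' Minimal-image displacement on the twisted torus
#'
#' Signed displacement `a - b` between sheet points, minimized over the
#' hexagonal periodicity lattice (generators `(2*pi, 0)` and `(-pi, sqrt(3)*pi)`).
#'
#' @param a,b n x 2 matrices (or length-2 vectors) of theta coordinates.
#' @return n x 2 matrix of minimal displacements.
#' @export
torus_displacement <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, nrow = 1)
  if (is.null(dim(b))) b <- matrix(b, nrow = 1)
  if (nrow(b) == 1 && nrow(a) > 1) b <- b[rep(1, nrow(a)), , drop = FALSE]
  if (nrow(a) == 1 && nrow(b) > 1) a <- a[rep(1, nrow(b)), , drop = FALSE]
  d <- a - b
  # reduce to the nearest lattice cell first (valid for arbitrarily distant
  # points), then search the local neighbourhood for the minimal image
  G <- .hex_lattice_generators()
  mn <- d %*% solve(G)
  d <- d - round(mn) %*% G
  sh <- .hex_lattice_shifts()
  best <- d
  bestn <- rowSums(d^2)
  for (k in seq_len(nrow(sh))) {
    cand <- sweep(d, 2, sh[k, ])
    n <- rowSums(cand^2)
    upd <- n < bestn
    best[upd, ] <- cand[upd, , drop = FALSE]
    bestn[upd] <- n[upd]
  }
  best
}

#' Minimal-image distance on the twisted torus
#' @inheritParams torus_displacement
#' @return numeric vector of distances.
#' @export
torus_distance <- function(a, b) {
  sqrt(rowSums(torus_displacement(a, b)^2))
}

#' Wrap sheet coordinates into the fundamental unit cell
#'
#' Reduces theta to the cell `[0, 2*pi) x [0, sqrt(3)*pi)` by first wrapping
#' the underlying phases.
#'
#' @param theta n x 2 matrix.
#' @return wrapped n x 2 matrix.
#' @export
torus_wrap <- function(theta) {
  psi <- hex_inverse(theta, wrap = TRUE)
  th <- hex_transform(psi)
  th[, 1] <- th[, 1] %% (2 * pi)  # (2*pi, 0) is a lattice generator
  th
}

# Derive a child RNG seed from a master seed and a stage offset (kept < 2^31).
.derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1013L * as.integer(offset)) %% 2147483647L
}
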