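# Track specifications ---------------------------------------------------

#' Construct a block specification
#'
#' @param n_trials number of trials in the block (>= 1).
#' @param dark logical; dark blocks have no landmarks and no reward.
#' @param landmarks data.frame with columns `id` (character) and `position_cm`,
#'   or `NULL`.
#' @param reward_zone length-2 numeric `(start_cm, end_cm)` or `NULL`.
#' @param auto_reward logical; deliver an automatic reward at the zone end if
#'   the animal fails to lick in the trigger zone.
#' @param trial_offset_range length-2 numeric; per-trial uniform offset (cm)
#'   added to landmark and reward positions, or `NULL`.
#' @return an object of class `block_spec`.
#' @export
block_spec <- function(n_trials, dark = FALSE, landmarks = NULL,
                       reward_zone = NULL, auto_reward = FALSE,
                       trial_offset_range = NULL) {
  stopifnot(n_trials >= 1)
  if (is.null(landmarks)) {
    landmarks <- data.frame(id = character(), position_cm = numeric())
  }
  if (!is.null(trial_offset_range)) {
    stopifnot(length(trial_offset_range) == 2,
              trial_offset_range[1] >= 0, trial_offset_range[2] <= 30)
  }
  structure(list(n_trials = as.integer(n_trials), dark = dark,
                 landmarks = landmarks, reward_zone = reward_zone,
                 auto_reward = auto_reward,
                 trial_offset_range = trial_offset_range),
            class = "block_spec")
}

#' Construct a track specification
#'
#' @param track_length_cm track length in cm (> 0).
#' @param blocks list of [block_spec()] objects.
#' @param lookahead_cm visual lookahead in cm (metadata only).
#' @param seamless logical; `TRUE` for seamless teleport at the lap boundary.
#' @return an object of class `track_spec`.
#' @export
track_spec <- function(track_length_cm, blocks, lookahead_cm = NA_real_,
                       seamless = FALSE) {
  stopifnot(track_length_cm > 0, length(blocks) >= 1)
  for (b in blocks) {
    stopifnot(inherits(b, "block_spec"))
    if (nrow(b$landmarks)) {
      stopifnot(all(b$landmarks$position_cm > 0),
                all(b$landmarks$position_cm < track_length_cm))
    }
    if (!is.null(b$reward_zone)) {
      stopifnot(b$reward_zone[1] >= 0, b$reward_zone[2] <= track_length_cm,
                b$reward_zone[1] < b$reward_zone[2])
    }
  }
  structure(list(track_length_cm = track_length_cm, blocks = blocks,
                 lookahead_cm = lookahead_cm, seamless = seamless),
            class = "track_spec")
}

#' @export
print.track_spec <- function(x, ...) {
  cat(sprintf("<track_spec> %g cm, %d blocks (%d trials total)\n",
              x$track_length_cm, length(x$blocks),
              sum(vapply(x$blocks, `[[`, 1L, "n_trials"))))
  for (i in seq_along(x$blocks)) {
    b <- x$blocks[[i]]
    cat(sprintf("  block %2d: %2d trials%s, %d landmark(s)%s\n", i, b$n_trials,
                if (b$dark) " [dark]" else "", nrow(b$landmarks),
                if (!is.null(b$reward_zone))
                  sprintf(", reward [%g, %g)", b$reward_zone[1], b$reward_zone[2])
                else ""))
  }
  invisible(x)
}

# Draw one random-environment landmark arrangement satisfying the minimum
# separation constraints; bounded rejection sampling.
.random_landmark_positions <- function(n, track_length_cm, min_sep = 15,
                                       max_tries = 2000) {
  for (i in seq_len(max_tries)) {
    pos <- sort(stats::runif(n, min = min_sep, max = track_length_cm - 2))
    if (all(diff(pos) >= min_sep)) return(pos)
  }
  stop("could not place ", n, " landmarks with >= ", min_sep,
       " cm separation on a ", track_length_cm, " cm track")
}

#' Build a virtual-reality track design
#'
#' Constructs the block structure of one of the three experiment designs:
#'
#' * `build_up`: 320-cm seamless track; dark block; auto-reward block; optic
#'   flow; towers 1-4 added cumulatively; tower 4 removed (20 trials); dark.
#' * `random_env`: 100-cm track; dark; 12 blocks of 20 trials with 5 familiar
#'   landmarks pseudo-randomly re-arranged (pairwise separation >= 15 cm,
#'   first landmark >= 15 cm from the start); dark.
#' * `hidden_reward`: 200-cm track; blocks A,B,C,D,C,B,A; baseline landmarks
#'   at 40, 65, 100, 145 cm; B shifts the last landmark 35 cm toward the
#'   start, C additionally shifts the first three; D is dark; reward zone
#'   `[160, 170)` cm with auto reward at the zone end; per-trial Uniform(0,30)
#'   cm offset on landmarks and zone.
#'
#' @param design one of `"build_up"`, `"random_env"`, `"hidden_reward"`.
#' @param seed RNG seed for the random-environment arrangements.
#' @param options named list of overrides: `n_trials` (visual-block trials),
#'   `n_dark_trials`, `n_env_blocks` (random_env), `offset_range`
#'   (hidden_reward).
#' @return a [track_spec()].
#' @export
make_track <- function(design = c("build_up", "random_env", "hidden_reward"),
                       seed = 1L, options = list()) {
  design <- match.arg(design)
  o <- function(name, default) if (!is.null(options[[name]])) options[[name]] else default
  lm <- function(ids, pos) data.frame(id = ids, position_cm = pos)

  if (design == "build_up") {
    nt <- o("n_trials", 40L)
    nd <- o("n_dark_trials", 40L)
    towers <- c(tower1 = 60, tower2 = 125, tower3 = 190, tower4 = 255)
    blocks <- list(
      block_spec(nd, dark = TRUE),
      block_spec(nt, reward_zone = c(310, 320), auto_reward = TRUE),
      block_spec(nt, reward_zone = c(310, 320), auto_reward = TRUE),  # + optic flow
      block_spec(nt, landmarks = lm("tower1", towers[1]),
                 reward_zone = c(310, 320), auto_reward = TRUE),
      block_spec(nt, landmarks = lm(c("tower1", "tower2"), towers[1:2]),
                 reward_zone = c(310, 320), auto_reward = TRUE),
      block_spec(nt, landmarks = lm(paste0("tower", 1:3), towers[1:3]),
                 reward_zone = c(310, 320), auto_reward = TRUE),
      block_spec(nt, landmarks = lm(paste0("tower", 1:4), towers[1:4]),
                 reward_zone = c(310, 320), auto_reward = TRUE),
      block_spec(max(1L, nt %/% 2L), landmarks = lm(paste0("tower", 1:3), towers[1:3]),
                 reward_zone = c(310, 320), auto_reward = TRUE),
      block_spec(nd, dark = TRUE))
    return(track_spec(320, blocks, lookahead_cm = 300, seamless = TRUE))
  }

  if (design == "random_env") {
    nt <- o("n_trials", 20L)
    nd <- o("n_dark_trials", 40L)
    nb <- o("n_env_blocks", 12L)
    ids <- c("towerA", "towerB", "towerC", "groundA", "groundR")
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
    env_blocks <- lapply(seq_len(nb), function(i) {
      pos <- .random_landmark_positions(length(ids), 100)
      perm <- sample(length(ids))
      block_spec(nt, landmarks = data.frame(id = ids[perm], position_cm = pos),
                 reward_zone = c(80, 100), auto_reward = TRUE)
    })
    blocks <- c(list(block_spec(nd, dark = TRUE)), env_blocks,
                list(block_spec(nd, dark = TRUE)))
    return(track_spec(100, blocks, lookahead_cm = 100))
  }

  # hidden_reward
  nt <- o("n_trials", 40L)
  nd <- o("n_dark_trials", 40L)
  offr <- o("offset_range", c(0, 30))
  ids <- c("towerA", "towerB", "towerC", "groundA")
  posA <- c(40, 65, 100, 145)
  posB <- c(40, 65, 100, 110)          # last landmark 35 cm toward the start
  posC <- c(5, 30, 65, 110)            # first three also shifted
  zone <- c(160, 170)
  mk <- function(pos) block_spec(nt, landmarks = lm(ids, pos),
                                 reward_zone = zone, auto_reward = TRUE,
                                 trial_offset_range = offr)
  blocks <- list(mk(posA), mk(posB), mk(posC),
                 block_spec(nd, dark = TRUE),
                 mk(posC), mk(posB), mk(posA))
  track_spec(200, blocks, lookahead_cm = 100)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
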