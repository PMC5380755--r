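#' Generate an n-back speed-sign session design
#'
#' Builds the trial schedule of the speed-regulation n-back paradigm: the
#' session is a pseudorandomized sequence of blocks, one n-back level per
#' block, with the constraint that the same level is never driven in two
#' consecutive blocks. Within a block a new speed sign passes roughly every
#' `trial_interval` seconds; each sign is one trial. Sign speeds are drawn
#' from a fixed grid (default 60-140 km/h in steps of 10, i.e. nine target
#' speeds) in randomized order. The target speed of trial i in an n-back
#' block is the sign speed of trial i - n; for the first n trials of a
#' block the participant drives at the block's first sign speed.
#'
#' Each block is preceded by an announcement period (default 5 s) during
#' which the upcoming level is displayed; announcement time belongs to no
#' trial.
#'
#' @param n_levels number of n-back levels (levels are `0:(n_levels-1)`).
#' @param trials_per_level trials (speed signs) per block.
#' @param repetitions blocks per level.
#' @param speed_grid sign-speed grid in km/h.
#' @param trial_interval seconds between consecutive signs (trial length).
#' @param announcement_s seconds of level announcement before each block.
#' @param seed integer seed; the schedule is deterministic given the seed.
#' @param allow_level_repeats if `TRUE`, consecutive blocks may share a
#'   level (needed e.g. for `n_levels = 1, repetitions > 1`).
#' @return An object of class `nirs_design`: a list with `trials` (tibble,
#'   one row per trial: `index`, `block_id`, `nback_level`, `sign_onset`,
#'   `duration`, `sign_speed`, `target_speed`, `correct`),
#'   `level_block_order`, `announcements` (tibble of onset/duration/level),
#'   `trial_interval`, `seed`.
#' @export
generate_design <- function(n_levels = 5, trials_per_level = 10,
                            repetitions = 2,
                            speed_grid = seq(60, 140, by = 10),
                            trial_interval = 20, announcement_s = 5,
                            seed = 1L, allow_level_repeats = FALSE) {
  stopifnot(n_levels >= 1, trials_per_level >= 1, repetitions >= 1,
            length(speed_grid) >= 1, trial_interval > 0)
  levels <- rep(seq_len(n_levels) - 1L, repetitions)

  order_ok <- function(x) !any(diff(x) == 0)
  withr_seed <- .nirsload_seed(seed)
  on.exit(withr_seed(), add = TRUE)

  if (!allow_level_repeats && length(levels) > 1) {
    # A no-adjacent-repeat arrangement exists iff no level occupies more
    # than ceiling(n/2) block slots.
    if (max(table(levels)) > ceiling(length(levels) / 2)) {
      stop("no block ordering without consecutive level repeats exists; ",
           "set allow_level_repeats = TRUE to relax the constraint")
    }
    repeat {
      block_levels <- sample(levels)
      if (order_ok(block_levels)) break
    }
  } else {
    block_levels <- if (length(levels) > 1) sample(levels) else levels
  }

  draw_block_speeds <- function(n, prev_last) {
    out <- numeric(0)
    while (length(out) < n) {
      # sample() of a length-1 numeric would permute 1:x
      perm <- if (length(speed_grid) == 1) speed_grid else sample(speed_grid)
      last <- if (length(out)) out[length(out)] else prev_last
      if (length(speed_grid) > 1 && !is.na(last) && perm[1] == last) {
        perm <- c(perm[-1], perm[1])
      }
      out <- c(out, perm)
    }
    out[seq_len(n)]
  }

  trials <- vector("list", length(block_levels))
  ann <- vector("list", length(block_levels))
  t_cursor <- 0
  prev_last <- NA_real_
  for (b in seq_along(block_levels)) {
    lev <- block_levels[b]
    speeds <- draw_block_speeds(trials_per_level, prev_last)
    prev_last <- speeds[length(speeds)]
    n <- trials_per_level
    target <- speeds
    if (lev > 0) {
      idx <- seq_len(n)
      target <- ifelse(idx <= lev, speeds[1], speeds[pmax(idx - lev, 1)])
    }
    ann[[b]] <- data.frame(onset = t_cursor, duration = announcement_s,
                           nback_level = lev)
    onsets <- t_cursor + announcement_s + (seq_len(n) - 1) * trial_interval
    trials[[b]] <- data.frame(
      block_id = b, nback_level = lev, sign_onset = onsets,
      duration = trial_interval, sign_speed = speeds, target_speed = target
    )
    t_cursor <- onsets[n] + trial_interval
  }
  trials <- do.call(rbind, trials)
  trials$index <- seq_len(nrow(trials))
  trials$correct <- TRUE
  trials <- tibble::as_tibble(trials[, c("index", "block_id", "nback_level",
                                         "sign_onset", "duration",
                                         "sign_speed", "target_speed",
                                         "correct")])
  structure(
    list(trials = trials, level_block_order = block_levels,
         announcements = tibble::as_tibble(do.call(rbind, ann)),
         trial_interval = trial_interval, seed = seed,
         duration = t_cursor),
    class = "nirs_design"
  )
}

#' @export
print.nirs_design <- function(x, ...) {
  cat("n-back session design:", nrow(x$trials), "trials in",
      length(x$level_block_order), "blocks; levels",
      paste(sort(unique(x$trials$nback_level)), collapse = ","),
      "; duration", round(x$duration / 60, 1), "min\n")
  invisible(x)
}

# Seed scoping: set the RNG state for a deterministic section and return a
# restorer, so generator calls do not perturb the caller's RNG stream.
.nirsload_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}
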