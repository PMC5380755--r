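#' Default subject-level generating parameters
#'
#' Per-parameter linear generating model for trial-wise behavioral,
#' driving and cardiac outcomes:
#' value = baseline + slope * nback_level + participant intercept + residual.
#' Baselines are the 0-back condition means of the driving-simulator study
#' and slopes its reported per-level fixed effects (heart rate +0.89 bpm,
#' RMSSD -1.24 ms, reaction time +0.23 s, time in correct speed range
#' -6.6 percentage points, brake variance +0.08, throttle variance -0.01,
#' steering variance -0.8e-5 rad^2, lane deviation -0.007 m per level).
#'
#' Participant intercepts are drawn from a normal distribution truncated so
#' that every per-level mean stays a few residual standard deviations inside
#' the parameter's physical bounds (e.g. RMSSD cannot go negative, time in
#' range cannot exceed 100%); truncating the intercept distribution leaves
#' the fixed-effect slope unbiased, whereas clamping generated values at the
#' bounds would attenuate it.
#'
#' @param participant_sd named numeric overrides of the between-participant
#'   intercept SDs.
#' @param residual_sd named numeric overrides of the residual SDs.
#' @param slopes named numeric overrides of the per-level slopes.
#' @param correct_prob probability of a correct trial per n-back level
#'   (length 5); the default declines with level and yields roughly 8%
#'   incorrect trials over a session.
#' @return list of class `nirs_subject_params` with elements `table`
#'   (one row per parameter: baseline, slope, between_sd, resid_sd,
#'   lower, upper) and `correct_prob`.
#' @export
subject_params <- function(participant_sd = NULL, residual_sd = NULL,
                           slopes = NULL,
                           correct_prob = c(0.99, 0.97, 0.93, 0.88, 0.83)) {
  tab <- tibble::tribble(
    ~parameter,              ~baseline, ~slope,   ~between_sd, ~resid_sd, ~lower, ~upper,
    "time_in_correct_range",  92.3,     -6.6,      1.0,         1.5,       0,      100,
    "reaction_time",           1.35,     0.23,     0.30,        0.30,      0,      Inf,
    "brake_variance",          0.12,     0.08,     0.05,        0.10,      0,      Inf,
    "throttle_variance",       0.26,    -0.01,     0.05,        0.06,      0,      Inf,
    "steering_variance",       0.69e-4, -0.8e-5,   0.10e-4,     0.15e-4,   0,      Inf,
    "lane_deviation",          0.15,    -0.007,    0.02,        0.03,      0,      Inf,
    "heart_rate",             73.8,      0.89,    12.0,         2.2,       0,      Inf,
    "rmssd",                  39.5,     -1.24,    16.0,         5.8,       0,      Inf
  )
  override <- function(col, x) {
    if (is.null(x)) return()
    bad <- setdiff(names(x), tab$parameter)
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    tab[[col]][match(names(x), tab$parameter)] <<- unname(x)
  }
  override("between_sd", participant_sd)
  override("resid_sd", residual_sd)
  override("slope", slopes)
  if (any(tab$between_sd < 0) || any(tab$resid_sd < 0)) {
    stop("standard deviations must be >= 0")
  }
  if (length(correct_prob) != 5 || any(correct_prob < 0 | correct_prob > 1)) {
    stop("correct_prob must be 5 probabilities in [0,1]")
  }
  structure(list(table = tab, correct_prob = correct_prob),
            class = "nirs_subject_params")
}

#' Generate trial-wise behavioral and cardiac outcomes
#'
#' Simulates a trial table for one or more participants driving the given
#' session design. Each parameter follows
#' value = baseline + slope * level + participant intercept + residual noise
#' (see [subject_params()]); correctness is Bernoulli with a level-dependent
#' probability; reaction time is missing on incorrect trials.
#'
#' @param design a `nirs_design` from [generate_design()].
#' @param params a `nirs_subject_params`.
#' @param n_participants number of simulated participants.
#' @param seed integer seed; output is deterministic given the seed.
#' @return A tibble (trial table): one row per participant x trial with
#'   columns `participant_id`, `trial_index`, `block_id`, `nback_level`,
#'   `sign_speed`, `target_speed`, `correct`, and one column per parameter.
#' @export
generate_behavior <- function(design, params = subject_params(),
                              n_participants = 1, seed = 1L) {
  stopifnot(inherits(design, "nirs_design"),
            inherits(params, "nirs_subject_params"), n_participants >= 1)
  tab <- params$table
  trials <- design$trials
  n_tr <- nrow(trials)
  restore <- .nirsload_seed(seed)
  on.exit(restore(), add = TRUE)

  # Truncation bounds for participant intercepts: keep every level mean at
  # least guard residual SDs inside [lower, upper].
  guard <- 3.5
  out <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    df <- trials[, c("index", "block_id", "nback_level", "sign_speed",
                     "target_speed")]
    names(df)[1] <- "trial_index"
    df$participant_id <- p
    pc <- params$correct_prob[pmin(df$nback_level, 4L) + 1L]
    df$correct <- stats::runif(n_tr) < pc
    for (i in seq_len(nrow(tab))) {
      b <- tab$baseline[i]; s <- tab$slope[i]
      means <- b + s * c(0, 4)
      lo_int <- tab$lower[i] + guard * tab$resid_sd[i] - min(means)
      hi_int <- tab$upper[i] - guard * tab$resid_sd[i] - max(means)
      intercept <- 0
      if (tab$between_sd[i] > 0) {
        repeat {
          intercept <- stats::rnorm(1, 0, tab$between_sd[i])
          if (intercept >= min(lo_int, 0) && intercept <= max(hi_int, 0)) break
        }
      }
      v <- b + s * df$nback_level + intercept +
        stats::rnorm(n_tr, 0, tab$resid_sd[i])
      v <- pmin(pmax(v, tab$lower[i]), tab$upper[i])
      df[[tab$parameter[i]]] <- v
    }
    df$reaction_time[!df$correct] <- NA_real_
    out[[p]] <- df
  }
  res <- tibble::as_tibble(do.call(rbind, out))
  res[, c("participant_id", "trial_index", "block_id", "nback_level",
          "sign_speed", "target_speed", "correct", tab$parameter)]
}

#' Generate an RR-interval series with a target heart rate and RMSSD
#'
#' Produces a sequence of RR intervals (ms) whose mean matches
#' `60000 / target_hr` and whose expected root mean square of successive
#' differences matches `target_rmssd`: successive-difference variability is
#' induced by independent Gaussian jitter with SD `target_rmssd / sqrt(2)`,
#' since for i.i.d. jitter E[(RR[i+1] - RR[i])^2] = 2 sigma^2.
#'
#' @param target_hr target mean heart rate in bpm.
#' @param target_rmssd target RMSSD in ms.
#' @param duration series duration in seconds; intervals are emitted until
#'   their cumulative sum would exceed the duration.
#' @param seed integer seed.
#' @return numeric vector of RR intervals in ms.
#' @export
generate_rr_series <- function(target_hr, target_rmssd, duration, seed = 1L) {
  stopifnot(target_hr > 0, target_rmssd >= 0, duration > 0)
  mean_rr <- 60000 / target_hr
  if (target_rmssd > mean_rr) {
    stop("infeasible combination: target_rmssd (", target_rmssd,
         " ms) exceeds the mean RR interval (", round(mean_rr, 1), " ms)")
  }
  restore <- .nirsload_seed(seed)
  on.exit(restore(), add = TRUE)
  n_max <- ceiling(duration * 1000 / mean_rr) + 10L
  jitter <- if (target_rmssd > 0) {
    stats::rnorm(n_max, 0, target_rmssd / sqrt(2))
  } else {
    numeric(n_max)
  }
  rr <- pmax(mean_rr + jitter, 0.1 * mean_rr)
  keep <- cumsum(rr) <= duration * 1000
  rr[keep]
}
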