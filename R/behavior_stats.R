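#' Root mean square of successive RR-interval differences
#'
#' `RMSSD = sqrt(mean(diff(rr)^2))`, the standard time-domain heart-rate
#' variability index.
#'
#' @param rr RR intervals in ms (length >= 2).
#' @return RMSSD in ms.
#' @export
rmssd <- function(rr) {
  stopifnot(length(rr) >= 2)
  sqrt(mean(diff(rr)^2))
}

#' Heart rate of an RR-interval sequence
#'
#' @param rr RR intervals in ms.
#' @return mean heart rate in bpm, `60000 / mean(rr)`.
#' @export
heart_rate <- function(rr) {
  stopifnot(length(rr) >= 1, all(rr > 0))
  60000 / mean(rr)
}

#' Compute trial-wise behavioral, driving and cardiac parameters
#'
#' Derives the per-trial outcome table from continuous driving streams and
#' an RR-interval series:
#' * `time_in_correct_range`: percent of trial time (excluding the first
#'   `transition` s after the sign) with speed within `tolerance` km/h of
#'   the target;
#' * `reaction_time` (correct trials only): time from the sign passage
#'   until the speed enters the tolerance band and stays inside it for the
#'   rest of the trial;
#' * `brake_variance`, `throttle_variance`, `steering_variance`: sample
#'   variances over the trial, excluding samples within `transition` s of
#'   any sign passage;
#' * `lane_deviation`: mean absolute lane offset, with the same transition
#'   exclusion and with lane-change phases (samples where `|lane_offset|`
#'   exceeds `lane_change_threshold`) omitted;
#' * `heart_rate`, `rmssd`: from the RR intervals whose beats fall inside
#'   the trial window (`NA` with a logged note when fewer than two beats
#'   cover the trial).
#'
#' A trial is `correct` when the band is reached and held; on incorrect
#' trials the reaction time is missing.
#'
#' @param streams data frame of driving streams: `time` (s) plus any of
#'   `speed` (km/h), `brake`, `throttle` (normalized deflection),
#'   `steering` (rad), `lane_offset` (m).
#' @param rr RR-interval series in ms (beat times are the cumulative sums,
#'   from recording start), or `NULL` to skip cardiac fields.
#' @param design a `nirs_design`.
#' @param tolerance speed band half-width in km/h.
#' @param transition post-sign transition time in s.
#' @param lane_change_threshold absolute lane offset (m) above which a
#'   sample is treated as part of a lane change.
#' @param participant_id identifier column value.
#' @return tibble with one row per trial.
#' @export
compute_trial_params <- function(streams, rr, design, tolerance = 5,
                                 transition = 3, lane_change_threshold = 1.75,
                                 participant_id = 1L) {
  stopifnot(inherits(design, "nirs_design"), "time" %in% names(streams))
  tr <- design$trials
  if (min(streams$time) > min(tr$sign_onset) ||
      max(streams$time) < max(tr$sign_onset + tr$duration) - 1e-9) {
    stop("driving streams do not cover every trial window")
  }
  beat_t <- if (is.null(rr)) numeric(0) else cumsum(rr) / 1000
  onsets <- tr$sign_onset
  out <- vector("list", nrow(tr))
  for (i in seq_len(nrow(tr))) {
    t0 <- tr$sign_onset[i]; t1 <- t0 + tr$duration[i]
    win <- streams$time >= t0 & streams$time < t1
    tw <- streams$time[win]
    near_sign <- vapply(tw, function(t) any(abs(t - onsets) <= transition),
                        logical(1))
    row <- list(participant_id = participant_id, trial_index = tr$index[i],
                block_id = tr$block_id[i], nback_level = tr$nback_level[i],
                sign_speed = tr$sign_speed[i],
                target_speed = tr$target_speed[i])

    if ("speed" %in% names(streams)) {
      sp <- streams$speed[win]
      in_band <- abs(sp - tr$target_speed[i]) <= tolerance
      eval_idx <- tw >= t0 + transition
      row$time_in_correct_range <- if (any(eval_idx)) {
        100 * mean(in_band[eval_idx])
      } else {
        NA_real_
      }
      # enter the band and never leave it again before trial end
      stay_from <- rev(cumprod(rev(in_band))) == 1
      hit <- which(stay_from)
      correct <- length(hit) > 0
      row$correct <- correct
      row$reaction_time <- if (correct) tw[hit[1]] - t0 else NA_real_
    }
    for (v in c("brake", "throttle", "steering")) {
      if (v %in% names(streams)) {
        x <- streams[[v]][win][!near_sign]
        row[[paste0(v, "_variance")]] <- if (length(x) >= 2) {
          stats::var(x)
        } else {
          NA_real_
        }
      }
    }
    if ("lane_offset" %in% names(streams)) {
      lo <- streams$lane_offset[win][!near_sign]
      lo <- lo[abs(lo) <= lane_change_threshold]
      row$lane_deviation <- if (length(lo)) mean(abs(lo)) else NA_real_
    }
    beats <- rr[beat_t >= t0 & beat_t < t1]
    if (length(beats) >= 2) {
      row$heart_rate <- heart_rate(beats)
      row$rmssd <- rmssd(beats)
    } else {
      row$heart_rate <- NA_real_
      row$rmssd <- NA_real_
      if (!is.null(rr)) {
        message("trial ", tr$index[i], ": no RR coverage, cardiac fields NA")
      }
    }
    out[[i]] <- tibble::as_tibble(row)
  }
  do.call(rbind, out)
}

#' Remove extreme trials per participant and parameter
#'
#' For each parameter and participant, values more than `sd_threshold`
#' standard deviations from that participant's mean are set to missing for
#' that parameter's analysis (the trial's other parameters are kept).
#' Parameters with zero within-participant SD trigger no removal. Removal
#' fractions are logged per parameter.
#'
#' @param table trial table (as from [generate_behavior()] or
#'   [compute_trial_params()]).
#' @param sd_threshold removal threshold in SD units.
#' @param parameters parameter columns to screen; defaults to every known
#'   outcome column present.
#' @return list with `trials` (screened table) and `log` (tibble:
#'   `parameter`, `n_removed`, `n_total`, `fraction`).
#' @export
remove_outliers <- function(table, sd_threshold = 3, parameters = NULL) {
  stopifnot(sd_threshold > 0)
  known <- c("time_in_correct_range", "reaction_time", "brake_variance",
             "throttle_variance", "steering_variance", "lane_deviation",
             "heart_rate", "rmssd")
  if (is.null(parameters)) parameters <- intersect(known, names(table))
  stopifnot(all(parameters %in% names(table)),
            "participant_id" %in% names(table))
  log <- vector("list", length(parameters))
  for (k in seq_along(parameters)) {
    p <- parameters[k]
    removed <- 0L
    for (pid in unique(table$participant_id)) {
      idx <- which(table$participant_id == pid & !is.na(table[[p]]))
      if (length(idx) < 3) next
      v <- table[[p]][idx]
      s <- stats::sd(v)
      if (s == 0) next
      out_idx <- idx[abs(v - mean(v)) > sd_threshold * s]
      table[[p]][out_idx] <- NA_real_
      removed <- removed + length(out_idx)
    }
    n_tot <- sum(!is.na(table[[p]])) + removed
    log[[k]] <- tibble::tibble(parameter = p, n_removed = removed,
                               n_total = n_tot,
                               fraction = ifelse(n_tot > 0,
                                                 removed / n_tot, 0))
  }
  list(trials = table, log = do.call(rbind, log))
}

#' Linear mixed-model trend test for a trial parameter
#'
#' Fits `parameter ~ nback_level` with random intercepts for participant,
#' trial number and target speed (maximum likelihood), and tests the fixed
#' n-back effect by a likelihood-ratio test against the model without it.
#' The t statistic and Satterthwaite-approximated denominator degrees of
#' freedom come from lmerTest; the standardized effect size is
#' `r = sqrt(t^2 / (t^2 + df))`, signed like the slope. If the full
#' random-effects structure fails to converge, grouping factors are
#' dropped (target speed first, then trial number) with a warning, and a
#' residual-df fallback is used if the Satterthwaite approximation is
#' unavailable.
#'
#' @param table trial table with `participant_id`, `trial_index`,
#'   `target_speed`, `nback_level` and the parameter column.
#' @param parameter name of the outcome column.
#' @return list of class `nirs_lmm_result`: `parameter`, `slope`,
#'   `slope_se`, `chi2`, `p_value`, `t_value`, `df`, `df_method`,
#'   `effect_r`, `n_obs`, `random_effects`.
#' @export
lmm_trend <- function(table, parameter) {
  stopifnot(parameter %in% names(table))
  df <- data.frame(
    y = table[[parameter]],
    nback_level = table$nback_level,
    participant_id = factor(table$participant_id),
    trial_index = factor(table$trial_index),
    target_speed = factor(table$target_speed)
  )
  df <- df[stats::complete.cases(df), ]
  if (length(unique(df$participant_id)) < 2) {
    stop("need at least 2 participants")
  }
  if (stats::sd(df$y) == 0) stop("parameter is constant")

  re_sets <- list(
    c("participant_id", "trial_index", "target_speed"),
    c("participant_id", "trial_index"),
    "participant_id"
  )
  fit <- NULL
  used <- NULL
  for (re in re_sets) {
    rhs <- paste(sprintf("(1 | %s)", re), collapse = " + ")
    f_full <- stats::as.formula(paste("y ~ nback_level +", rhs))
    fit_try <- tryCatch(
      suppressMessages(lmerTest::lmer(f_full, data = df, REML = FALSE)),
      error = function(e) NULL
    )
    if (!is.null(fit_try)) {
      fit <- fit_try
      used <- re
      break
    }
  }
  if (is.null(fit)) stop("mixed model could not be fitted")
  if (length(used) < 3) {
    warning("random-effects structure reduced to: ",
            paste(used, collapse = ", "))
  }
  f_null <- stats::as.formula(
    paste("y ~ 1 +", paste(sprintf("(1 | %s)", used), collapse = " + "))
  )
  fit0 <- suppressMessages(lme4::lmer(f_null, data = df, REML = FALSE))
  lrt <- suppressMessages(stats::anova(fit0, fit))
  chi2 <- lrt$Chisq[2]
  p <- lrt$`Pr(>Chisq)`[2]

  co <- tryCatch(summary(fit)$coefficients, error = function(e) NULL)
  df_method <- "satterthwaite"
  if (!is.null(co) && "df" %in% colnames(co) &&
      is.finite(co["nback_level", "df"])) {
    slope <- co["nback_level", "Estimate"]
    se <- co["nback_level", "Std. Error"]
    tval <- co["nback_level", "t value"]
    ddf <- co["nback_level", "df"]
  } else {
    b <- lme4::fixef(fit)
    slope <- b[["nback_level"]]
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))[2]
    tval <- slope / se
    ddf <- nrow(df) - 2 - sum(vapply(used, function(g) {
      length(unique(df[[g]]))
    }, numeric(1)))
    df_method <- "residual_fallback"
  }
  structure(
    list(parameter = parameter, slope = slope, slope_se = se, chi2 = chi2,
         p_value = p, t_value = tval, df = ddf, df_method = df_method,
         effect_r = sign(slope) * sqrt(tval^2 / (tval^2 + ddf)),
         n_obs = nrow(df), random_effects = used),
    class = "nirs_lmm_result"
  )
}

#' @export
print.nirs_lmm_result <- function(x, ...) {
  cat(sprintf(
    "%s ~ n-back level: slope %.4g (SE %.3g), chi2 = %.3g, p = %.3g, t = %.3g, df = %.1f (%s), r = %.3f\n",
    x$parameter, x$slope, x$slope_se, x$chi2, x$p_value, x$t_value, x$df,
    x$df_method, x$effect_r))
  invisible(x)
}
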