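#' Canonical double-gamma hemodynamic response function
#'
#' HRF evaluated at time points `t` (seconds): difference of two gamma
#' densities with modes at `peak` and `undershoot` seconds and an
#' undershoot-to-peak amplitude ratio of `ratio`, scaled so the peak
#' response equals 1.
#'
#' @param t time points in seconds (response is 0 for `t < 0`).
#' @param peak mode of the response gamma (s).
#' @param undershoot mode of the undershoot gamma (s).
#' @param ratio undershoot amplitude relative to the peak.
#' @return numeric vector of HRF values.
#' @export
hrf_double_gamma <- function(t, peak = 6, undershoot = 16, ratio = 1 / 6) {
  stopifnot(peak > 0, undershoot > 0, ratio >= 0)
  h <- function(x) {
    stats::dgamma(x, shape = peak + 1, rate = 1) -
      ratio * stats::dgamma(x, shape = undershoot + 1, rate = 1)
  }
  raw <- ifelse(t < 0, 0, h(t))
  peak_val <- h(seq(0, peak + 2, by = 0.01))
  raw / max(peak_val)
}

#' Forward-model configuration for synthetic fNIRS recordings
#'
#' Defines the linear forward model that turns a session design into a
#' two-wavelength intensity recording: a workload regressor (per-sample
#' induced n-back level convolved with the HRF), a per-channel loading map
#' concentrated on the bilateral inferior-frontal and temporo-occipital
#' channel groups, physiological artifacts (cardiac ~1.1 Hz, respiration
#' ~0.3 Hz, Mayer waves ~0.1 Hz, slow drift), white measurement noise, and
#' optional bad channels with inflated intensity variance. Amplitudes are
#' relative concentration changes in mol/l (1e-6 = 1 micromolar); the
#' response amplitude is the HbR decrease per n-back level unit on a fully
#' loaded channel.
#'
#' @param montage a `nirs_montage`; defines channel count and loading groups.
#' @param sampling_rate acquisition rate in Hz.
#' @param loading_map per-channel weight of the workload regressor in
#'   `[0, 1]`; default 1 on inferior-frontal and temporo-occipital channels,
#'   0.3 on forehead channels, 0 elsewhere.
#' @param response_amp_molar HbR concentration decrease per level unit on a
#'   unit-loaded channel (mol/l).
#' @param hbo_ratio HbO increase relative to the HbR decrease.
#' @param hrf list of double-gamma parameters (`peak`, `undershoot`,
#'   `ratio`).
#' @param cardiac_amp,resp_amp,mayer_amp,drift_amp artifact amplitudes
#'   (mol/l) at ~1.1 Hz, ~0.3 Hz, ~0.1 Hz and below 0.01 Hz respectively.
#' @param noise_sd white-noise SD in concentration space (mol/l).
#' @param bad_channel_ids channels given inflated intensity variance.
#' @param bad_channel_cv approximate coefficient of variation (%) of the
#'   intensity noise injected into bad channels.
#' @param baseline_intensity named per-wavelength baseline intensity
#'   (arbitrary detector units, strictly positive).
#' @param seed integer seed used by [generate_fnirs()].
#' @return list of class `nirs_forward_config`.
#' @export
forward_model_config <- function(montage = default_montage(),
                                 sampling_rate = 1.955,
                                 loading_map = NULL,
                                 response_amp_molar = 0.1e-6,
                                 hbo_ratio = 2,
                                 hrf = list(peak = 6, undershoot = 16,
                                            ratio = 1 / 6),
                                 cardiac_amp = 0.15e-6,
                                 resp_amp = 0.1e-6,
                                 mayer_amp = 0.15e-6,
                                 drift_amp = 0.25e-6,
                                 noise_sd = 0.2e-6,
                                 bad_channel_ids = integer(0),
                                 bad_channel_cv = 35,
                                 baseline_intensity = c("760" = 1000,
                                                        "850" = 1200),
                                 seed = 1L) {
  n_channels <- nrow(montage)
  if (is.null(loading_map)) {
    loading_map <- numeric(n_channels)
    loaded <- grepl("^inferior_frontal|^temporo_occipital", montage$region)
    loading_map[loaded] <- 1
    loading_map[montage$region == "forehead"] <- 0.3
  }
  if (length(loading_map) != n_channels) {
    stop("loading_map length (", length(loading_map),
         ") does not match channel count (", n_channels, ")")
  }
  stopifnot(sampling_rate > 0,
            cardiac_amp >= 0, resp_amp >= 0, mayer_amp >= 0, drift_amp >= 0,
            noise_sd >= 0, all(baseline_intensity > 0),
            all(bad_channel_ids %in% seq_len(n_channels)))
  structure(
    list(montage = montage, sampling_rate = sampling_rate,
         n_channels = n_channels, loading_map = loading_map,
         response_amp_molar = response_amp_molar, hbo_ratio = hbo_ratio,
         hrf = hrf, cardiac_amp = cardiac_amp, resp_amp = resp_amp,
         mayer_amp = mayer_amp, drift_amp = drift_amp, noise_sd = noise_sd,
         bad_channel_ids = as.integer(bad_channel_ids),
         bad_channel_cv = bad_channel_cv,
         baseline_intensity = baseline_intensity, seed = seed),
    class = "nirs_forward_config"
  )
}

#' Per-sample induced workload level of a design
#'
#' @param design a `nirs_design`.
#' @param times sample times in seconds.
#' @return numeric vector: the trial's n-back level inside each trial's
#'   `[onset, onset + duration)` window, `NA` outside all trials
#'   (announcement periods and tail).
#' @export
induced_level_trace <- function(design, times) {
  lev <- rep(NA_real_, length(times))
  tr <- design$trials
  for (i in seq_len(nrow(tr))) {
    inside <- times >= tr$sign_onset[i] &
      times < tr$sign_onset[i] + tr$duration[i]
    lev[inside] <- tr$nback_level[i]
  }
  lev
}

#' Generate a synthetic two-wavelength fNIRS recording
#'
#' Runs the linear forward model defined by a [forward_model_config()] on a
#' session design. The workload regressor is the per-sample induced level
#' (0 outside trials) convolved with the double-gamma HRF; ground-truth HbR
#' is `-loading * response_amp * regressor` plus artifacts and noise
#' (activation lowers HbR), ground-truth HbO its sign-flipped counterpart
#' scaled by `hbo_ratio` with independent artifact draws. Raw intensities
#' follow the forward modified Beer-Lambert relation
#' `I = I0 * 10^-(eps_HbO * dHbO + eps_HbR * dHbR) * d * DPF` per
#' wavelength. The cardiac artifact, whose ~1.1 Hz frequency exceeds the
#' Nyquist rate of the 1.955 Hz system, is generated on an 8x oversampled
#' grid and decimated by sample selection so that it aliases exactly as
#' real acquisition would.
#'
#' @param design a `nirs_design`.
#' @param config a `nirs_forward_config`.
#' @param constants Beer-Lambert constants used for the forward relation.
#' @return object of class `nirs_recording`: list with `raw_intensity`
#'   (list of channel x time matrices named `"760"`, `"850"`), `truth_hbo`,
#'   `truth_hbr` (channel x time, mol/l), `time`, `sampling_rate`,
#'   `design`, `config`, `montage`.
#' @export
generate_fnirs <- function(design, config = forward_model_config(),
                           constants = beer_lambert_constants(
                             distance_cm = config$montage$distance_cm)) {
  stopifnot(inherits(design, "nirs_design"),
            inherits(config, "nirs_forward_config"))
  fs <- config$sampling_rate
  n_ch <- config$n_channels
  dur <- design$duration + 30 / fs
  times <- seq(0, dur, by = 1 / fs)
  n_t <- length(times)
  restore <- .nirsload_seed(config$seed)
  on.exit(restore(), add = TRUE)

  # Workload regressor: induced level boxcar (0 outside trials) * HRF.
  lev <- induced_level_trace(design, times)
  lev[is.na(lev)] <- 0
  hrf_t <- seq(0, 32, by = 1 / fs)
  h <- hrf_double_gamma(hrf_t, config$hrf$peak, config$hrf$undershoot,
                        config$hrf$ratio)
  # Unit-sum kernel: a sustained level-L block drives a steady-state
  # response of L, so response_amp_molar is the amplitude per level unit.
  h <- h / sum(h)
  reg <- stats::convolve(lev, rev(h), type = "open")[seq_len(n_t)]

  # Artifacts: cardiac on an oversampled grid, decimated (aliasing kept).
  os <- 8L
  t_fine <- seq(0, dur, by = 1 / (fs * os))
  pick <- round(times * fs * os) + 1L
  artifact_bank <- function(amp_cardiac, amp_resp, amp_mayer, amp_drift) {
    m <- matrix(0, n_ch, n_t)
    for (ch in seq_len(n_ch)) {
      ph <- stats::runif(4, 0, 2 * pi)
      f_card <- 1.1 * (1 + stats::rnorm(1, 0, 0.02))
      card <- amp_cardiac * sin(2 * pi * f_card * t_fine + ph[1])
      card <- card[pick]
      resp <- amp_resp * sin(2 * pi * 0.3 * times + ph[2])
      mayer <- amp_mayer * sin(2 * pi * 0.1 * times + ph[3])
      drift <- amp_drift * (sin(2 * pi * 0.004 * times + ph[4]) +
                              stats::rnorm(1, 0, 0.5) * times / max(times))
      m[ch, ] <- card + resp + mayer + drift
    }
    m
  }

  signal_hbr <- -outer(config$loading_map * config$response_amp_molar, reg)
  truth_hbr <- signal_hbr +
    artifact_bank(config$cardiac_amp, config$resp_amp, config$mayer_amp,
                  config$drift_amp) +
    matrix(stats::rnorm(n_ch * n_t, 0, config$noise_sd), n_ch, n_t)
  truth_hbo <- -config$hbo_ratio * signal_hbr +
    artifact_bank(config$cardiac_amp * config$hbo_ratio,
                  config$resp_amp * config$hbo_ratio,
                  config$mayer_amp * config$hbo_ratio,
                  config$drift_amp * config$hbo_ratio) +
    matrix(stats::rnorm(n_ch * n_t, 0, config$noise_sd * config$hbo_ratio),
           n_ch, n_t)

  raw <- mbll_forward(truth_hbo, truth_hbr, constants,
                      config$baseline_intensity)
  if (length(config$bad_channel_ids)) {
    for (wl in names(raw)) {
      for (ch in config$bad_channel_ids) {
        i0 <- config$baseline_intensity[[wl]]
        noise <- stats::rnorm(n_t, 0, i0 * config$bad_channel_cv / 100)
        raw[[wl]][ch, ] <- pmax(raw[[wl]][ch, ] + noise, 0.01 * i0)
      }
    }
  }

  structure(
    list(raw_intensity = raw, truth_hbo = truth_hbo, truth_hbr = truth_hbr,
         time = times, sampling_rate = fs, design = design, config = config,
         montage = config$montage),
    class = "nirs_recording"
  )
}

#' Forward modified Beer-Lambert relation
#'
#' Maps concentration changes to raw intensities:
#' `dOD(lambda) = (eps(lambda,HbO) dHbO + eps(lambda,HbR) dHbR) d DPF(lambda)`
#' and `I = I0 * 10^-dOD`.
#'
#' @param hbo,hbr channel x time concentration-change matrices (mol/l).
#' @param constants a `nirs_mbll_constants` (see
#'   [beer_lambert_constants()]).
#' @param baseline_intensity named per-wavelength baseline intensity.
#' @return list of channel x time intensity matrices named by wavelength.
#' @export
mbll_forward <- function(hbo, hbr, constants, baseline_intensity) {
  stopifnot(inherits(constants, "nirs_mbll_constants"),
            all(dim(hbo) == dim(hbr)))
  d <- constants$distance_cm
  if (length(d) == 1) d <- rep(d, nrow(hbo))
  stopifnot(length(d) == nrow(hbo))
  out <- list()
  for (w in seq_along(constants$wavelengths)) {
    wl <- as.character(constants$wavelengths[w])
    od <- (constants$epsilon[w, 1] * hbo + constants$epsilon[w, 2] * hbr) *
      d * constants$dpf[w]
    out[[wl]] <- baseline_intensity[[wl]] * 10^(-od)
  }
  out
}

#' @export
print.nirs_recording <- function(x, ...) {
  cat("synthetic fNIRS recording:", nrow(x$truth_hbr), "channels x",
      ncol(x$truth_hbr), "samples at", x$sampling_rate, "Hz (",
      round(max(x$time) / 60, 1), "min );",
      nrow(x$design$trials), "trials\n")
  invisible(x)
}
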