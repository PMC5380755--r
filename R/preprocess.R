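#' Beer-Lambert conversion constants
#'
#' Molar extinction coefficients (Gratzer spectrum) and differential
#' path-length factors for the two acquisition wavelengths. Defaults:
#' epsilon rows (M^-1 cm^-1) are `[1486.59, 3843.71]` at 760 nm and
#' `[2526.39, 1798.64]` at 850 nm, columns ordered (HbO, HbR); DPFs are
#' 7.25 at 760 nm and 6.38 at 850 nm. The DPF is physically a per-wavelength
#' quantity, so the pair is bound to the wavelengths in that order.
#'
#' @param epsilon 2x2 extinction matrix, rows = wavelengths (760, 850 nm),
#'   columns = (HbO, HbR), in M^-1 cm^-1.
#' @param dpf per-wavelength differential path-length factors.
#' @param distance_cm per-channel source-detector distance(s) in cm; a
#'   scalar is recycled over channels.
#' @param wavelengths wavelengths in nm (names for I/O only).
#' @return list of class `nirs_mbll_constants`.
#' @export
beer_lambert_constants <- function(
    epsilon = matrix(c(1486.59, 3843.71, 2526.39, 1798.64), nrow = 2,
                     byrow = TRUE,
                     dimnames = list(c("760", "850"), c("HbO", "HbR"))),
    dpf = c(7.25, 6.38),
    distance_cm = 3.5,
    wavelengths = c(760, 850)) {
  stopifnot(all(dim(epsilon) == c(2, 2)), length(dpf) == 2,
            length(wavelengths) == 2, all(distance_cm > 0))
  if (abs(det(epsilon)) < .Machine$double.eps * max(abs(epsilon))^2) {
    stop("extinction coefficient matrix is singular")
  }
  structure(list(epsilon = epsilon, dpf = dpf, distance_cm = distance_cm,
                 wavelengths = wavelengths),
            class = "nirs_mbll_constants")
}

#' Convert raw intensities to optical-density changes
#'
#' `dOD(t) = -log10(I(t) / I_ref)` per channel and wavelength. The default
#' reference is the whole-session mean intensity of each channel, so each
#' channel's dOD has approximately zero mean; a known baseline (e.g. the
#' forward model's emitted intensity) can be supplied instead.
#'
#' @param raw list of channel x time intensity matrices named by wavelength.
#' @param reference `"mean"` (per-channel temporal mean), or a named list /
#'   vector of per-wavelength reference intensities (scalar or per-channel).
#' @return list of class `nirs_od`: `od` (list of channel x time matrices)
#'   and `reference_intensity` (list of per-channel reference vectors).
#' @export
intensity_to_od <- function(raw, reference = "mean") {
  stopifnot(is.list(raw), length(raw) >= 1)
  od <- list()
  ref_out <- list()
  for (wl in names(raw)) {
    m <- raw[[wl]]
    bad <- which(m <= 0, arr.ind = TRUE)
    if (nrow(bad)) {
      stop("nonpositive intensity at wavelength ", wl, ", channel ",
           bad[1, 1], ", sample ", bad[1, 2])
    }
    ref <- if (identical(reference, "mean")) {
      rowMeans(m)
    } else {
      r <- reference[[wl]]
      if (is.null(r)) stop("no reference intensity for wavelength ", wl)
      if (length(r) == 1) rep(r, nrow(m)) else r
    }
    stopifnot(length(ref) == nrow(m), all(ref > 0))
    od[[wl]] <- -log10(m / ref)
    ref_out[[wl]] <- ref
  }
  structure(list(od = od, reference_intensity = ref_out), class = "nirs_od")
}

#' Modified Beer-Lambert conversion to hemoglobin concentration changes
#'
#' For each channel and sample, solves the 2x2 linear system
#' `dOD(lambda) = sum_c eps_c(lambda) d[c] d_channel DPF(lambda)` for
#' (dHbO, dHbR). Concentrations are returned in mol/l; multiply by 1e3 for
#' the mmol/l reporting scale.
#'
#' @param od a `nirs_od` from [intensity_to_od()].
#' @param constants a `nirs_mbll_constants`; `distance_cm` must be scalar
#'   or per-channel.
#' @param sampling_rate sampling rate (Hz) carried into the result.
#' @param montage optional montage carried into the result.
#' @return object of class `nirs_hemo`: list with `hbo`, `hbr`
#'   (channel x time, mol/l), `sampling_rate`, `channel_mask` (all `TRUE`
#'   until QC is applied), `montage`.
#' @export
mbll_convert <- function(od, constants = beer_lambert_constants(),
                         sampling_rate = 1.955, montage = NULL) {
  stopifnot(inherits(od, "nirs_od"), inherits(constants, "nirs_mbll_constants"))
  wls <- as.character(constants$wavelengths)
  if (!all(wls %in% names(od$od))) {
    stop("optical density lacks wavelength(s): ",
         paste(setdiff(wls, names(od$od)), collapse = ", "))
  }
  od1 <- od$od[[wls[1]]]
  od2 <- od$od[[wls[2]]]
  n_ch <- nrow(od1)
  d <- constants$distance_cm
  if (length(d) == 1) d <- rep(d, n_ch)
  if (length(d) != n_ch) {
    stop("need a source-detector distance per channel (got ", length(d),
         " for ", n_ch, " channels)")
  }
  # A = diag(DPF) %*% epsilon; per channel, [dHbO; dHbR] = A^-1 [od1; od2]/d.
  a <- constants$epsilon * constants$dpf
  ainv <- solve(a)
  hbo <- (ainv[1, 1] * od1 + ainv[1, 2] * od2) / d
  hbr <- (ainv[2, 1] * od1 + ainv[2, 2] * od2) / d
  structure(list(hbo = hbo, hbr = hbr, sampling_rate = sampling_rate,
                 channel_mask = rep(TRUE, n_ch), montage = montage),
            class = "nirs_hemo")
}

#' Least-squares linear-phase FIR low-pass design
#'
#' Type-I (odd-length, symmetric) FIR whose amplitude response minimizes
#' the integrated squared error against an ideal low-pass with passband
#' `[0, cutoff - transition/2]` and stopband `[cutoff + transition/2,
#' Nyquist]`; the transition band is unconstrained. The normal equations of
#' the cosine-basis amplitude are assembled from closed-form band integrals
#' of products of cosines. Coefficients are normalized to unit DC gain.
#'
#' @param n_taps odd filter length.
#' @param cutoff cutoff frequency (Hz).
#' @param sampling_rate sampling rate (Hz).
#' @param transition transition-band width (Hz), centered on the cutoff.
#' @return numeric vector of `n_taps` filter coefficients.
#' @export
fir_ls_lowpass <- function(n_taps = 77, cutoff = 0.1, sampling_rate = 1.955,
                           transition = 0.1) {
  stopifnot(n_taps %% 2 == 1, n_taps >= 3)
  if (cutoff <= 0 || cutoff >= sampling_rate / 2) {
    stop("cutoff must lie strictly between 0 and the Nyquist frequency (",
         sampling_rate / 2, " Hz)")
  }
  fp <- max((cutoff - transition / 2) / sampling_rate, 1e-6)
  fs_ <- min((cutoff + transition / 2) / sampling_rate, 0.5 - 1e-6)
  m <- (n_taps - 1L) / 2L
  # Amplitude A(v) = b0 + sum_k b_k cos(2 pi v k), v normalized in [0, 0.5].
  intcos <- function(k, v1, v2) {
    if (k == 0) return(v2 - v1)
    (sin(2 * pi * v2 * k) - sin(2 * pi * v1 * k)) / (2 * pi * k)
  }
  ks <- 0:m
  g <- matrix(0, m + 1, m + 1)
  dvec <- numeric(m + 1)
  for (i in ks) {
    dvec[i + 1] <- intcos(i, 0, fp)
    for (j in ks[ks >= i]) {
      v <- 0.5 * (intcos(i - j, 0, fp) + intcos(i + j, 0, fp) +
                    intcos(i - j, fs_, 0.5) + intcos(i + j, fs_, 0.5))
      g[i + 1, j + 1] <- v
      g[j + 1, i + 1] <- v
    }
  }
  b <- solve(g, dvec)
  h <- c(rev(b[-1] / 2), b[1], b[-1] / 2)
  h / sum(h)
}

#' Zero-phase FIR low-pass filtering of multichannel series
#'
#' Applies the least-squares FIR low-pass to each row of a channel x time
#' matrix. Edges are handled by reflect-padding with half the filter length
#' on each side; because the filter is symmetric and centered, the output
#' is time-aligned with the input (group delay compensated).
#'
#' @param series channel x time matrix (a plain vector is treated as one
#'   channel).
#' @param cutoff cutoff frequency in Hz.
#' @param sampling_rate sampling rate in Hz.
#' @param n_taps odd filter length.
#' @param transition transition-band width in Hz.
#' @return filtered matrix (or vector) of the same shape.
#' @export
lowpass_filter <- function(series, cutoff = 0.1, sampling_rate = 1.955,
                           n_taps = 77, transition = 0.1) {
  vec_in <- is.null(dim(series))
  x <- if (vec_in) matrix(series, nrow = 1) else series
  h <- fir_ls_lowpass(n_taps, cutoff, sampling_rate, transition)
  m <- (n_taps - 1L) / 2L
  n <- ncol(x)
  if (n <= m + 1) stop("series shorter than half the filter length")
  out <- t(apply(x, 1, function(row) {
    padded <- c(rev(row[2:(m + 1)]), row, rev(row[(n - m):(n - 1)]))
    stats::filter(padded, h, sides = 2)[(m + 1):(m + n)]
  }))
  if (vec_in) drop(out) else out
}

#' Channel quality control by coefficient of variation
#'
#' Computes the per-channel, per-wavelength coefficient of variation
#' `CV = (sigma / mu) * 100%` on unfiltered raw intensities over the whole
#' recording, and rejects a channel when the CV at either wavelength
#' exceeds the threshold. A zero-mean channel gets an infinite CV and is
#' rejected rather than raising an error.
#'
#' @param raw list of channel x time raw-intensity matrices named by
#'   wavelength (or a single matrix).
#' @param threshold rejection threshold in percent.
#' @return list of class `nirs_qc_report`: `cv_percent` (channel x
#'   wavelength matrix), `threshold`, `rejected_ids`, `retained_ids`.
#' @export
channel_qc <- function(raw, threshold = 20) {
  if (is.matrix(raw)) raw <- list(intensity = raw)
  stopifnot(length(raw) >= 1, threshold > 0)
  cv <- sapply(raw, function(m) {
    mu <- rowMeans(m)
    sdv <- apply(m, 1, stats::sd)
    ifelse(mu == 0, Inf, sdv / abs(mu) * 100)
  })
  cv <- matrix(cv, ncol = length(raw),
               dimnames = list(NULL, names(raw)))
  rejected <- which(apply(cv, 1, function(v) any(v > threshold)))
  structure(list(cv_percent = cv, threshold = threshold,
                 rejected_ids = as.integer(rejected),
                 retained_ids = setdiff(seq_len(nrow(cv)), rejected)),
            class = "nirs_qc_report")
}

#' Apply a QC report to a hemoglobin time series
#'
#' @param hemo a `nirs_hemo`.
#' @param qc a `nirs_qc_report` computed on the same channels.
#' @return the `nirs_hemo` with `channel_mask` updated.
#' @export
apply_channel_mask <- function(hemo, qc) {
  stopifnot(inherits(hemo, "nirs_hemo"), inherits(qc, "nirs_qc_report"),
            nrow(qc$cv_percent) == nrow(hemo$hbr))
  hemo$channel_mask <- !(seq_len(nrow(hemo$hbr)) %in% qc$rejected_ids)
  hemo
}

#' Build the labeled per-sample data set for decoding
#'
#' Assigns each retained sample the induced n-back level of the trial it
#' falls in, excluding samples within `transition_exclusion` seconds of any
#' speed-sign passage, samples outside every trial (block-announcement
#' periods, session tail), and, when `drop_incorrect`, all samples of
#' incorrect trials. Every exclusion is bookkept with its reason.
#'
#' @param hemo a `nirs_hemo` (after QC masking).
#' @param design a `nirs_design` whose events lie within the recording.
#' @param transition_exclusion half-width (s) of the exclusion window
#'   around each sign onset.
#' @param drop_incorrect drop samples of incorrect trials.
#' @param chromophore `"hbr"` (default) or `"hbo"` feature source.
#' @param participant_id identifier carried into the sample set.
#' @return list of class `nirs_sample_set`: `features` (sample x channel
#'   matrix of retained channels), `labels`, `trial_id`, `time`,
#'   `participant_id`, `channel_ids` (montage ids of the feature columns),
#'   `excluded` (tibble sample index/time/reason), `sampling_rate`.
#' @export
build_sample_set <- function(hemo, design, transition_exclusion = 3,
                             drop_incorrect = TRUE, chromophore = c("hbr", "hbo"),
                             participant_id = 1L) {
  stopifnot(inherits(hemo, "nirs_hemo"), inherits(design, "nirs_design"),
            transition_exclusion >= 0)
  chromophore <- match.arg(chromophore)
  mat <- hemo[[chromophore]]
  n_t <- ncol(mat)
  times <- (seq_len(n_t) - 1L) / hemo$sampling_rate
  tr <- design$trials
  if (any(tr$sign_onset + tr$duration > max(times) + 1 / hemo$sampling_rate)) {
    stop("design events extend beyond the recording time span")
  }
  ends <- tr$sign_onset + tr$duration
  if (any(tr$sign_onset[-1] < ends[-nrow(tr)] - 1e-9)) {
    stop("overlapping trials in design")
  }

  trial_of <- rep(NA_integer_, n_t)
  for (i in seq_len(nrow(tr))) {
    trial_of[times >= tr$sign_onset[i] & times < ends[i]] <- tr$index[i]
  }
  reason <- rep(NA_character_, n_t)
  reason[is.na(trial_of)] <- "outside_trial"
  if (transition_exclusion > 0) {
    near_onset <- vapply(times, function(t) {
      any(abs(t - tr$sign_onset) <= transition_exclusion)
    }, logical(1))
    reason[is.na(reason) & near_onset] <- "transition_window"
  }
  if (drop_incorrect) {
    bad_trials <- tr$index[!tr$correct]
    reason[is.na(reason) & trial_of %in% bad_trials] <- "incorrect_trial"
  }
  keep <- is.na(reason)
  if (!any(keep)) stop("no samples survive the exclusion rules")

  retained_ch <- which(hemo$channel_mask)
  if (!length(retained_ch)) {
    stop("no channels retained after quality control")
  }
  feat <- t(mat[retained_ch, keep, drop = FALSE])
  ch_ids <- if (!is.null(hemo$montage)) {
    hemo$montage$channel_id[retained_ch]
  } else {
    retained_ch
  }
  colnames(feat) <- paste0("ch", ch_ids)
  structure(
    list(features = feat,
         labels = tr$nback_level[match(trial_of[keep], tr$index)],
         trial_id = trial_of[keep], time = times[keep],
         participant_id = rep(participant_id, sum(keep)),
         channel_ids = ch_ids,
         excluded = tibble::tibble(sample = which(!keep),
                                   time = times[!keep],
                                   reason = reason[!keep]),
         sampling_rate = hemo$sampling_rate),
    class = "nirs_sample_set"
  )
}

#' Full preprocessing of a synthetic recording
#'
#' Convenience composition of the preprocessing stage: channel QC on the
#' unfiltered raw intensities, optical-density conversion, modified
#' Beer-Lambert inversion, 0.1 Hz FIR low-pass filtering, and labeled
#' sample-set construction.
#'
#' @param recording a `nirs_recording`.
#' @param cutoff low-pass cutoff in Hz.
#' @param cv_threshold QC rejection threshold in percent.
#' @param transition_exclusion seconds excluded around sign passages.
#' @param drop_incorrect drop incorrect trials.
#' @param constants Beer-Lambert constants (defaults to the montage's
#'   per-channel distances).
#' @return list with `hemo` (`nirs_hemo`), `qc` (`nirs_qc_report`),
#'   `samples` (`nirs_sample_set`).
#' @export
preprocess_recording <- function(recording, cutoff = 0.1, cv_threshold = 20,
                                 transition_exclusion = 3,
                                 drop_incorrect = TRUE,
                                 constants = beer_lambert_constants(
                                   distance_cm = recording$montage$distance_cm)) {
  stopifnot(inherits(recording, "nirs_recording"))
  qc <- channel_qc(recording$raw_intensity, threshold = cv_threshold)
  od <- intensity_to_od(recording$raw_intensity)
  hemo <- mbll_convert(od, constants,
                       sampling_rate = recording$sampling_rate,
                       montage = recording$montage)
  hemo$hbo <- lowpass_filter(hemo$hbo, cutoff, recording$sampling_rate)
  hemo$hbr <- lowpass_filter(hemo$hbr, cutoff, recording$sampling_rate)
  hemo <- apply_channel_mask(hemo, qc)
  samples <- build_sample_set(hemo, recording$design,
                              transition_exclusion = transition_exclusion,
                              drop_incorrect = drop_incorrect)
  list(hemo = hemo, qc = qc, samples = samples)
}
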