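#' Write a synthetic recording to disk
#'
#' Writes the wide-CSV container (first column `time` in seconds, then one
#' column per channel and wavelength, headers `chNN_760` / `chNN_850`),
#' the events TSV (`onset_s`, `duration_s`, `nback_level`,
#' `sign_speed_kmh`, `target_speed_kmh`, `correct`, `block_id`), the
#' montage JSON, and (optionally) the ground-truth concentration matrices.
#' With `format = "snirf"` a SNIRF-style HDF5 container
#' (`/formatVersion`, `/nirs/data1/dataTimeSeries`, `/nirs/data1/time`,
#' per-measurement `measurementList` groups, `/nirs/probe`, `/nirs/stim1`)
#' is written instead of the CSV; this requires the rhdf5 package.
#'
#' @param recording a `nirs_recording`.
#' @param dir output directory (created if needed).
#' @param format `"csv"` or `"snirf"`.
#' @param truth also write `truth_hbo.csv` / `truth_hbr.csv`.
#' @return `dir`, invisibly.
#' @export
write_recording <- function(recording, dir, format = c("csv", "snirf"),
                            truth = FALSE) {
  stopifnot(inherits(recording, "nirs_recording"))
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (format == "csv") {
    wide <- data.frame(time = recording$time)
    for (wl in names(recording$raw_intensity)) {
      m <- recording$raw_intensity[[wl]]
      cols <- as.data.frame(t(m))
      names(cols) <- sprintf("ch%02d_%s", seq_len(nrow(m)), wl)
      wide <- cbind(wide, cols)
    }
    utils::write.csv(wide, file.path(dir, "intensity.csv"),
                     row.names = FALSE)
  } else {
    .write_snirf(recording, file.path(dir, "recording.snirf"))
  }
  write_events_tsv(recording$design, file.path(dir, "events.tsv"))
  write_montage_json(recording$montage, file.path(dir, "montage.json"))
  if (truth) {
    utils::write.csv(as.data.frame(t(recording$truth_hbo)),
                     file.path(dir, "truth_hbo.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(t(recording$truth_hbr)),
                     file.path(dir, "truth_hbr.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Read a recording written by [write_recording()]
#'
#' @param dir directory containing `intensity.csv` or `recording.snirf`
#'   plus `events.tsv` and `montage.json`.
#' @return a `nirs_recording` (without ground-truth matrices unless truth
#'   CSVs are present).
#' @export
read_recording <- function(dir) {
  montage <- read_montage_json(file.path(dir, "montage.json"))
  design <- read_events_tsv(file.path(dir, "events.tsv"))
  snirf_path <- file.path(dir, "recording.snirf")
  if (file.exists(snirf_path)) {
    rec <- .read_snirf(snirf_path, montage, design)
  } else {
    csv_path <- file.path(dir, "intensity.csv")
    if (!file.exists(csv_path)) stop("no intensity.csv or recording.snirf in ", dir)
    wide <- utils::read.csv(csv_path, check.names = FALSE)
    if (!"time" %in% names(wide)) stop("intensity CSV lacks a time column")
    times <- wide$time
    fs <- 1 / stats::median(diff(times))
    raw <- list()
    for (wl in c("760", "850")) {
      want <- sprintf("ch%02d_%s", montage$channel_id, wl)
      missing <- setdiff(want, names(wide))
      if (length(missing)) {
        stop("intensity CSV is missing channel column(s): ",
             paste(utils::head(missing, 3), collapse = ", "),
             if (length(missing) > 3) " ..." else "")
      }
      raw[[wl]] <- t(as.matrix(wide[, want]))
      dimnames(raw[[wl]]) <- NULL
    }
    rec <- structure(
      list(raw_intensity = raw, truth_hbo = NULL, truth_hbr = NULL,
           time = times, sampling_rate = fs, design = design,
           config = NULL, montage = montage),
      class = "nirs_recording"
    )
  }
  for (tt in c("truth_hbo", "truth_hbr")) {
    p <- file.path(dir, paste0(tt, ".csv"))
    if (file.exists(p)) {
      m <- t(as.matrix(utils::read.csv(p)))
      dimnames(m) <- NULL
      rec[[tt]] <- m
    }
  }
  rec
}

#' Write / read a design as an events TSV
#'
#' Columns: `onset_s`, `duration_s`, `nback_level`, `sign_speed_kmh`,
#' `target_speed_kmh`, `correct` (0/1), `block_id`.
#'
#' @param design a `nirs_design`.
#' @param path TSV path.
#' @return the path (write) or a reconstructed `nirs_design` (read; the
#'   announcement table is rebuilt from block starts).
#' @export
write_events_tsv <- function(design, path) {
  tr <- design$trials
  df <- data.frame(onset_s = tr$sign_onset, duration_s = tr$duration,
                   nback_level = tr$nback_level,
                   sign_speed_kmh = tr$sign_speed,
                   target_speed_kmh = tr$target_speed,
                   correct = as.integer(tr$correct), block_id = tr$block_id)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  need <- c("onset_s", "duration_s", "nback_level", "sign_speed_kmh",
            "target_speed_kmh", "correct", "block_id")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("events TSV is missing column(s): ", paste(missing, collapse = ", "))
  }
  trials <- tibble::tibble(
    index = seq_len(nrow(df)), block_id = df$block_id,
    nback_level = df$nback_level, sign_onset = df$onset_s,
    duration = df$duration_s, sign_speed = df$sign_speed_kmh,
    target_speed = df$target_speed_kmh, correct = df$correct == 1
  )
  block_starts <- tapply(trials$sign_onset, trials$block_id, min)
  block_levels <- tapply(trials$nback_level, trials$block_id,
                         function(x) x[1])
  ord <- order(block_starts)
  structure(
    list(trials = trials,
         level_block_order = as.integer(block_levels[ord]),
         announcements = tibble::tibble(
           onset = as.numeric(block_starts[ord]) - 5, duration = 5,
           nback_level = as.integer(block_levels[ord])),
         trial_interval = stats::median(trials$duration),
         seed = NA_integer_,
         duration = max(trials$sign_onset + trials$duration)),
    class = "nirs_design"
  )
}

.write_snirf <- function(recording, path) {
  if (!requireNamespace("rhdf5", quietly = TRUE)) {
    stop("SNIRF output requires the rhdf5 package; use format = \"csv\"")
  }
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write("1.0", path, "formatVersion")
  rhdf5::h5createGroup(path, "nirs")
  rhdf5::h5createGroup(path, "nirs/data1")
  wls <- names(recording$raw_intensity)
  n_ch <- nrow(recording$raw_intensity[[1]])
  # time x measurement matrix: channels at wavelength 1, then wavelength 2
  dts <- do.call(cbind, lapply(recording$raw_intensity, t))
  rhdf5::h5write(dts, path, "nirs/data1/dataTimeSeries")
  rhdf5::h5write(recording$time, path, "nirs/data1/time")
  ml <- 0L
  for (w in seq_along(wls)) {
    for (ch in seq_len(n_ch)) {
      ml <- ml + 1L
      g <- sprintf("nirs/data1/measurementList%d", ml)
      rhdf5::h5createGroup(path, g)
      rhdf5::h5write(ch, path, paste0(g, "/sourceIndex"))
      rhdf5::h5write(ch, path, paste0(g, "/detectorIndex"))
      rhdf5::h5write(w, path, paste0(g, "/wavelengthIndex"))
      rhdf5::h5write(1L, path, paste0(g, "/dataType"))
      rhdf5::h5write(1L, path, paste0(g, "/dataTypeIndex"))
    }
  }
  rhdf5::h5createGroup(path, "nirs/probe")
  rhdf5::h5write(as.numeric(wls), path, "nirs/probe/wavelengths")
  pos <- cbind(recording$montage$x, recording$montage$y)
  rhdf5::h5write(pos, path, "nirs/probe/sourcePos2D")
  rhdf5::h5write(pos, path, "nirs/probe/detectorPos2D")
  rhdf5::h5createGroup(path, "nirs/stim1")
  tr <- recording$design$trials
  rhdf5::h5write("nback_level", path, "nirs/stim1/name")
  rhdf5::h5write(cbind(tr$sign_onset, tr$duration, tr$nback_level),
                 path, "nirs/stim1/data")
  rhdf5::h5closeAll()
  invisible(path)
}

.read_snirf <- function(path, montage, design) {
  if (!requireNamespace("rhdf5", quietly = TRUE)) {
    stop("reading SNIRF requires the rhdf5 package")
  }
  dts <- rhdf5::h5read(path, "nirs/data1/dataTimeSeries")
  times <- as.numeric(rhdf5::h5read(path, "nirs/data1/time"))
  wls <- as.numeric(rhdf5::h5read(path, "nirs/probe/wavelengths"))
  rhdf5::h5closeAll()
  n_ch <- ncol(dts) / length(wls)
  raw <- list()
  for (w in seq_along(wls)) {
    raw[[as.character(wls[w])]] <-
      t(dts[, (w - 1) * n_ch + seq_len(n_ch), drop = FALSE])
  }
  structure(
    list(raw_intensity = raw, truth_hbo = NULL, truth_hbr = NULL,
         time = times, sampling_rate = 1 / stats::median(diff(times)),
         design = design, config = NULL, montage = montage),
    class = "nirs_recording"
  )
}

#' Pipeline configuration
#'
#' Bundles every stage parameter with the pipeline's standard defaults: 0.1 Hz
#' low-pass cutoff, 20% CV rejection threshold, 3 s transition exclusion,
#' 10 outer and 10 inner folds, 3-SD outlier policy.
#'
#' @param seed master seed; per-stage seeds are derived from it.
#' @param out_dir output directory used by [run_pipeline()].
#' @param cutoff_hz,cv_threshold,transition_s,outer_folds,inner_folds,outlier_sd
#'   stage parameters.
#' @param subset decoding channel subset: `"whole_head"` or `"frontal"`.
#' @param n_participants participants simulated for the behavioral arm.
#' @param k_grid,n_lambda decoder hyperparameter grids.
#' @param format recording container format.
#' @return list of class `nirs_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("nirsload_run_"),
                            cutoff_hz = 0.1, cv_threshold = 20,
                            transition_s = 3, outer_folds = 10,
                            inner_folds = 10, outlier_sd = 3,
                            subset = c("whole_head", "frontal"),
                            n_participants = 1, k_grid = NULL,
                            n_lambda = 50, format = "csv") {
  subset <- match.arg(subset)
  structure(
    list(seed = as.integer(seed), out_dir = out_dir, cutoff_hz = cutoff_hz,
         cv_threshold = cv_threshold, transition_s = transition_s,
         outer_folds = outer_folds, inner_folds = inner_folds,
         outlier_sd = outlier_sd, subset = subset,
         n_participants = n_participants, k_grid = k_grid,
         n_lambda = n_lambda, format = format,
         version = as.character(utils::packageVersion("nirsload"))),
    class = "nirs_config"
  )
}

#' Write / read a pipeline configuration as YAML
#' @param config a `nirs_config`.
#' @param path YAML file path.
#' @return the path (write) or the round-tripped `nirs_config` (read).
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  structure(x, class = "nirs_config")
}

#' Run the full simulate-preprocess-decode-map-behavior pipeline
#'
#' Executes the analysis end to end on synthetic data: generates the
#' session design and recording, preprocesses (Beer-Lambert conversion,
#' QC, filtering, labeling), decodes workload with nested cross-validated
#' PCA + lasso, computes the univariate correlation map, simulates the
#' behavioral arm and fits the mixed-model trends, and writes every stage
#' output plus a run manifest under `config$out_dir`. Deterministic given
#' `config$seed`.
#'
#' @param config a `nirs_config`.
#' @return list of class `nirs_manifest`: `config`, stage `timings` (s),
#'   `qc_rejected`, `n_samples`, `excluded_counts`, `r_mvr`,
#'   `behavior_trends` (tibble), `outputs` (file paths), `version`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "nirs_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- c()
  tic <- function() Sys.time()
  toc <- function(t0) as.numeric(difftime(Sys.time(), t0, units = "secs"))

  t0 <- tic()
  design <- generate_design(seed = config$seed)
  behavior <- generate_behavior(design, n_participants = config$n_participants,
                                seed = config$seed + 1L)
  # first participant's correctness drives the fNIRS trial exclusions
  design$trials$correct <- behavior$correct[behavior$participant_id == 1]
  fwd <- forward_model_config(seed = config$seed + 2L)
  recording <- generate_fnirs(design, fwd)
  write_recording(recording, file.path(config$out_dir, "recording"),
                  format = config$format)
  timings["simulate"] <- toc(t0)

  t0 <- tic()
  pp <- preprocess_recording(recording, cutoff = config$cutoff_hz,
                             cv_threshold = config$cv_threshold,
                             transition_exclusion = config$transition_s)
  utils::write.table(
    data.frame(channel_id = recording$montage$channel_id,
               cv_760 = pp$qc$cv_percent[, 1],
               cv_850 = pp$qc$cv_percent[, 2],
               rejected = seq_len(nrow(pp$qc$cv_percent)) %in%
                 pp$qc$rejected_ids),
    file.path(config$out_dir, "qc_report.tsv"), sep = "\t",
    row.names = FALSE, quote = FALSE)
  timings["preprocess"] <- toc(t0)

  t0 <- tic()
  subset_ids <- if (config$subset == "frontal") {
    frontal_channels(recording$montage)
  } else {
    NULL
  }
  decoding <- nested_cv_decode(
    pp$samples,
    cv_scheme(config$outer_folds, config$inner_folds,
              seed = config$seed + 3L),
    k_grid = config$k_grid, n_lambda = config$n_lambda,
    channel_subset = subset_ids, subset_label = config$subset)
  utils::write.csv(
    data.frame(time = decoding$time, induced = decoding$induced,
               predicted = decoding$predicted,
               fold = decoding$fold_of_sample),
    file.path(config$out_dir, "decoding_trace.csv"), row.names = FALSE)
  p_trace <- plot_decoding_trace(decoding)
  ggplot2::ggsave(file.path(config$out_dir, "decoding_trace.png"), p_trace,
                  width = 9, height = 3.2, dpi = 150)
  timings["decode"] <- toc(t0)

  t0 <- tic()
  map <- univariate_map(pp$samples)
  utils::write.table(as.data.frame(map),
                     file.path(config$out_dir, "channel_map.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  render_topomap(map, recording$montage,
                 file = file.path(config$out_dir, "channel_map.png"))
  timings["map"] <- toc(t0)

  t0 <- tic()
  screened <- remove_outliers(behavior, sd_threshold = config$outlier_sd)
  trends <- NULL
  if (config$n_participants >= 2) {
    trends <- do.call(rbind, lapply(
      c("heart_rate", "rmssd", "reaction_time", "time_in_correct_range"),
      function(p) {
        r <- lmm_trend(screened$trials, p)
        tibble::tibble(parameter = p, slope = r$slope, se = r$slope_se,
                       chi2 = r$chi2, p_value = r$p_value, t = r$t_value,
                       df = r$df, effect_r = r$effect_r)
      }))
    utils::write.table(trends, file.path(config$out_dir, "behavior_trends.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  utils::write.csv(behavior, file.path(config$out_dir, "trial_table.csv"),
                   row.names = FALSE)
  timings["behavior"] <- toc(t0)

  manifest <- structure(
    list(config = config, timings = timings,
         qc_rejected = pp$qc$rejected_ids,
         n_samples = nrow(pp$samples$features),
         excluded_counts = table(pp$samples$excluded$reason),
         r_mvr = decoding$r_mvr,
         chosen_k = decoding$chosen_k,
         behavior_trends = trends,
         outputs = character(0),
         version = config$version),
    class = "nirs_manifest"
  )
  manifest_json <- manifest
  manifest_json$excluded_counts <- as.list(manifest_json$excluded_counts)
  manifest_json$config <- unclass(config)
  jsonlite::write_json(manifest_json[c("config", "qc_rejected", "n_samples",
                                       "r_mvr", "chosen_k", "version")],
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest$outputs <- list.files(config$out_dir, recursive = TRUE)
  manifest
}

#' Induced vs predicted workload trace plot
#'
#' @param decoding a `nirs_decoding`.
#' @return a ggplot object: induced level (step trace) and cross-validated
#'   prediction over time.
#' @export
plot_decoding_trace <- function(decoding) {
  df <- data.frame(
    time = rep(decoding$time / 60, 2),
    value = c(decoding$induced, decoding$predicted),
    series = rep(c("induced", "predicted"), each = length(decoding$induced))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value,
                                   color = .data$series)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::scale_color_manual(values = c(induced = "#E69F00",
                                           predicted = "#0072B2")) +
    ggplot2::labs(x = "time (min)", y = "working-memory load (n-back level)",
                  color = NULL,
                  title = sprintf("Cross-validated workload prediction (r = %.2f)",
                                  decoding$r_mvr)) +
    ggplot2::theme_minimal()
}
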