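#' Default whole-head fNIRS montage
#'
#' Builds the 78-channel montage used throughout the package: two optode
#' systems in tandem, one covering frontal cortex and one covering parietal
#' and temporo-occipital cortex, separated by a gap over the somatomotor
#' strip. Channel positions are laid out on schematic 2-D head coordinates
#' (unit head circle, nose up) with 10-20 labels for the emitter/detector
#' of each channel. Twelve channels over the forehead, spanning F5 to F6
#' laterally and two rows toward the nasion (AF7 to AF8, AFz, Fpz), form
#' the frontal subset used for the restricted-coverage comparison decoder.
#'
#' The exact emitter-detector pairing of the original tandem system is not
#' public; this layout is synthesized to honour its published constraints:
#' 78 channels, frontal + parieto-temporo-occipital coverage with a
#' somatomotor gap, source-detector distances all below 4 cm with mean
#' approximately 3.5 cm, and a 12-channel forehead subset.
#'
#' @param mean_distance_cm target mean source-detector distance in cm.
#' @return A tibble of class `nirs_montage` with one row per channel:
#'   `channel_id`, `emitter_label`, `detector_label`, `x`, `y`,
#'   `distance_cm`, `region`, `frontal`.
#' @export
default_montage <- function(mean_distance_cm = 3.5) {
  ring <- function(r, a) cbind(x = r * sin(a), y = r * cos(a))
  deg <- function(d) d * pi / 180

  rows <- list()
  add <- function(labels, r, angles_deg, region, frontal = FALSE) {
    p <- ring(r, deg(angles_deg))
    rows[[length(rows) + 1L]] <<- data.frame(
      emitter_label = labels$e, detector_label = labels$d,
      x = p[, "x"], y = p[, "y"], region = region, frontal = frontal,
      stringsAsFactors = FALSE
    )
  }

  # Frontal subset: 12 channels across the forehead, AF7..AF8 / Fpz row and
  # the F5..F6 row (10-20 labels; angles measured from the nasion axis).
  add(list(e = c("Fp1", "Fpz", "Fpz", "Fp2", "AF7", "AF8"),
           d = c("AF7", "Fp1", "Fp2", "AF8", "F5", "F6")),
      r = 0.95, angles_deg = c(-27, -9, 9, 27, -45, 45),
      region = "forehead", frontal = TRUE)
  add(list(e = c("AF3", "AFz", "AFz", "AF4", "F5", "F6"),
           d = c("F3", "AF3", "AF4", "F4", "F7", "F8")),
      r = 0.80, angles_deg = c(-30, -10, 10, 30, -52, 52),
      region = "forehead", frontal = TRUE)

  # Bilateral inferior-frontal coverage (ventro-lateral, toward F7/F8, FT7/FT8).
  ifl <- c("F7", "F7", "FT7", "FT7", "F5", "FT9", "F9")
  ifd <- c("F5", "FT7", "F7", "FT9", "FC5", "F9", "FT9")
  add(list(e = ifl, d = ifd), r = 0.92,
      angles_deg = seq(-58, -88, length.out = 7), region = "inferior_frontal_l")
  add(list(e = sub("7", "8", sub("9", "10", ifl)),
           d = sub("7", "8", sub("9", "10", ifd))), r = 0.92,
      angles_deg = seq(58, 88, length.out = 7), region = "inferior_frontal_r")

  # Dorsal frontal rows (F/FC), stopping short of the central strip.
  add(list(e = c("F1", "F3", "F2", "F4", "FC1", "FC3", "FC2", "FC4"),
           d = c("FC1", "FC3", "FC2", "FC4", "F1", "F3", "F2", "F4")),
      r = 0.55, angles_deg = c(-18, -42, 18, 42, -14, -38, 14, 38),
      region = "dorsal_frontal")
  add(list(e = c("Fz", "Fz", "FCz", "AFz"), d = c("F1", "F2", "Fz", "Fz")),
      r = 0.45, angles_deg = c(-8, 8, -3, 3), region = "dorsal_frontal")

  # Parietal rows (posterior system starts behind the somatomotor gap).
  add(list(e = c("P1", "P3", "P2", "P4", "CP1", "CP3", "CP2", "CP4", "Pz", "Pz"),
           d = c("CP1", "CP3", "CP2", "CP4", "P1", "P3", "P2", "P4", "P1", "P2")),
      r = 0.52, angles_deg = c(-160, -140, 160, 140, -168, -148, 168, 148, -176, 176),
      region = "parietal")

  # Bilateral temporo-occipital coverage.
  tol <- c("P7", "P7", "PO7", "PO7", "O1", "P5", "PO3", "TP7", "TP7", "P9",
           "PO9", "O1", "P5")
  tod <- c("P5", "PO7", "O1", "PO9", "Oz", "PO3", "O1", "P7", "P9", "PO9",
           "O9", "PO3", "CP5")
  add(list(e = tol, d = tod), r = 0.88,
      angles_deg = seq(-110, -178, length.out = 13), region = "temporo_occipital_l")
  add(list(e = sub("7", "8", sub("9", "10", sub("1", "2", sub("3", "4", tol)))),
           d = sub("7", "8", sub("9", "10", sub("1", "2", sub("3", "4", tod))))),
      r = 0.88, angles_deg = seq(110, 178, length.out = 13),
      region = "temporo_occipital_r")

  # Occipital midline.
  add(list(e = c("POz", "Oz", "O1", "O2"), d = c("Oz", "POz", "Oz", "Oz")),
      r = 0.93, angles_deg = c(-174, 174, -179, 179),
      region = "occipital")

  m <- do.call(rbind, rows)
  n <- nrow(m)
  stopifnot(n == 78L)
  m$channel_id <- seq_len(n)
  # Deterministic distances: all < 4 cm, mean ~ mean_distance_cm.
  spread <- 0.35 * cos(seq(0, 6 * pi, length.out = n))
  m$distance_cm <- round(mean_distance_cm + spread - mean(spread), 3)
  stopifnot(all(m$distance_cm < 4), all(m$distance_cm > 2.5))
  out <- tibble::as_tibble(m[, c("channel_id", "emitter_label", "detector_label",
                                 "x", "y", "distance_cm", "region", "frontal")])
  class(out) <- c("nirs_montage", class(out))
  out
}

#' Frontal-subset channel ids of a montage
#' @param montage a `nirs_montage`.
#' @return integer vector of channel ids flagged as frontal.
#' @export
frontal_channels <- function(montage) {
  montage$channel_id[montage$frontal]
}

#' Write / read a montage as JSON
#'
#' The JSON container is a list of per-channel objects
#' `{channel_id, emitter_label, detector_label, x, y, distance_cm, region,
#' frontal}`.
#'
#' @param montage a `nirs_montage`.
#' @param path output (input) file path.
#' @return `write_montage_json()` returns `path` invisibly;
#'   `read_montage_json()` returns a `nirs_montage`.
#' @export
write_montage_json <- function(montage, path) {
  jsonlite::write_json(as.data.frame(montage), path, digits = NA,
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_montage_json
#' @export
read_montage_json <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("channel_id", "emitter_label", "detector_label", "x", "y",
            "distance_cm", "region", "frontal")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("montage JSON is missing fields: ", paste(missing, collapse = ", "))
  }
  out <- tibble::as_tibble(df[need])
  out$channel_id <- as.integer(out$channel_id)
  class(out) <- c("nirs_montage", class(out))
  out
}
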