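#' Published per-participant multivariate decoding correlations
#'
#' The fifteen per-participant Pearson correlations between induced and
#' 10-fold cross-validated predicted working-memory load reported for the
#' whole-head HbR analysis of the original driving-simulator study. These
#' serve as the reference surface for summary arithmetic (mean, standard
#' error, maximum) and for the frontal-subset comparison; the underlying
#' human recordings are not publicly deposited.
#'
#' @return named numeric vector of 15 correlations (names are participant
#'   codes).
#' @export
reference_rmvr <- function() {
  c(P1 = 0.70, P2 = 0.69, P3 = 0.80, P4 = 0.54, P5 = 0.58, P6 = 0.32,
    P9 = 0.54, P10 = 0.72, P11 = 0.31, P13 = 0.57, P14 = 0.61, P15 = 0.77,
    P16 = 0.75, P17 = 0.72, P19 = 0.59)
}

#' Summary statistics of a set of decoding correlations
#'
#' @param r vector of per-participant correlations.
#' @return list with `mean`, `se` (standard error of the mean), `max`,
#'   `n`.
#' @export
decoding_summary <- function(r = reference_rmvr()) {
  stopifnot(length(r) >= 2)
  list(mean = mean(r), se = stats::sd(r) / sqrt(length(r)), max = max(r),
       n = length(r))
}

#' Relative drop between two mean decoding correlations
#'
#' Percent decrease of a restricted-coverage mean correlation relative to
#' the full-coverage mean, `100 * (full - restricted) / full`.
#'
#' @param full mean correlation with full coverage.
#' @param restricted mean correlation with restricted coverage.
#' @return percent drop.
#' @export
relative_drop_percent <- function(full, restricted) {
  stopifnot(full != 0)
  100 * (full - restricted) / full
}
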