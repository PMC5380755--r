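#' Channel-wise univariate correlation map
#'
#' For each retained channel, the Pearson correlation between that
#' channel's concentration samples and the induced n-back level, with a
#' two-sided p-value. For a single predictor, regressing the signal on the
#' level and correlating are equivalent up to the sign of the slope, which
#' the signed correlation carries. Constant channels get `NA` correlations
#' rather than an error.
#'
#' @param samples a `nirs_sample_set`.
#' @param p_adjust multiplicity correction passed to [stats::p.adjust()]
#'   (`"none"` by default; the original analysis applied none).
#' @return tibble of class `nirs_channel_map`: `channel_id`, `r_uvr`,
#'   `p_value`, `participant_id`.
#' @export
univariate_map <- function(samples, p_adjust = c("none", "BH")) {
  stopifnot(inherits(samples, "nirs_sample_set"))
  p_adjust <- match.arg(p_adjust)
  y <- samples$labels
  if (length(y) < 3) stop("need at least 3 samples")
  if (stats::sd(y) == 0) stop("labels are constant")
  n_ch <- ncol(samples$features)
  r <- p <- rep(NA_real_, n_ch)
  for (j in seq_len(n_ch)) {
    xj <- samples$features[, j]
    if (stats::sd(xj) == 0) next
    ct <- stats::cor.test(xj, y)
    r[j] <- unname(ct$estimate)
    p[j] <- ct$p.value
  }
  if (p_adjust != "none") p <- stats::p.adjust(p, method = p_adjust)
  out <- tibble::tibble(channel_id = samples$channel_ids, r_uvr = r,
                        p_value = p,
                        participant_id = samples$participant_id[1])
  class(out) <- c("nirs_channel_map", class(out))
  out
}

#' Decoding-weighted group-average correlation map
#'
#' Combines per-participant univariate maps into a group map in which each
#' participant is weighted by their multivariate decoding correlation:
#' `r_avg(i) = sum_n r_uvr(i, n) * r_mvr(n) / sum_n r_mvr(n)`. Channels
#' missing (rejected) in a participant are averaged over the remaining
#' participants. Weights must be positive; the weighted mean is invariant
#' to common rescaling of the weights.
#'
#' @param maps list of `nirs_channel_map`, one per participant.
#' @param weights per-participant multivariate correlations (`r_mvr`).
#' @return tibble of class `nirs_group_map`: `channel_id`, `r_avg`,
#'   `n_contributing`; attributes `weights`, `n_participants`.
#' @export
group_weighted_map <- function(maps, weights) {
  stopifnot(length(maps) >= 1, length(weights) == length(maps))
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    stop("participant weights (r_mvr) must be positive")
  }
  ids <- sort(unique(unlist(lapply(maps, function(m) m$channel_id))))
  num <- den <- cnt <- stats::setNames(numeric(length(ids)), ids)
  for (n in seq_along(maps)) {
    m <- maps[[n]]
    ok <- !is.na(m$r_uvr)
    key <- as.character(m$channel_id[ok])
    num[key] <- num[key] + m$r_uvr[ok] * weights[n]
    den[key] <- den[key] + weights[n]
    cnt[key] <- cnt[key] + 1
  }
  if (all(den == 0)) stop("empty weight sum")
  out <- tibble::tibble(channel_id = ids,
                        r_avg = unname(ifelse(den > 0, num / den, NA_real_)),
                        n_contributing = unname(as.integer(cnt)))
  attr(out, "weights") <- weights
  attr(out, "n_participants") <- length(maps)
  class(out) <- c("nirs_group_map", class(out))
  out
}

#' Topographic head map of channel correlations
#'
#' Schematic 2-D head plot (head circle and nose marker, nose up) with one
#' marker per channel at its montage coordinate, colored on a diverging
#' scale symmetric about zero.
#'
#' @param map a `nirs_channel_map` or `nirs_group_map`.
#' @param montage a `nirs_montage` supplying channel coordinates.
#' @param file optional output path (`.png`, `.svg`, ...); when given, the
#'   plot is saved there.
#' @param title plot title.
#' @return the ggplot object, invisibly when `file` is given.
#' @export
render_topomap <- function(map, montage, file = NULL, title = NULL) {
  val_col <- if ("r_avg" %in% names(map)) "r_avg" else "r_uvr"
  df <- merge(as.data.frame(map), as.data.frame(montage), by = "channel_id")
  if (nrow(df) == 0 || anyNA(df$x) || anyNA(df$y)) {
    stop("montage coordinates missing for mapped channels")
  }
  df$value <- df[[val_col]]
  lim <- max(abs(df$value), na.rm = TRUE)
  if (!is.finite(lim) || lim == 0) lim <- 1
  a <- seq(0, 2 * pi, length.out = 181)
  head_df <- data.frame(x = 1.05 * cos(a), y = 1.05 * sin(a))
  nose_df <- data.frame(x = c(-0.1, 0, 0.1), y = c(1.04, 1.15, 1.04))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = head_df, inherit.aes = FALSE,
                       ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = nose_df, inherit.aes = FALSE,
                       ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(fill = .data$value), shape = 21,
                        size = 4, color = "grey30") +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0,
                                  limits = c(-lim, lim),
                                  name = "Pearson r") +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(title = title)
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 5, height = 5, dpi = 150)
    return(invisible(p))
  }
  p
}
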