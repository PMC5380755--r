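#' Pearson product-moment correlation
#'
#' @param a,b numeric sequences of equal length (>= 2), neither constant.
#' @return correlation in `[-1, 1]`.
#' @export
pearson_r <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("pearson_r is undefined for constant input")
  }
  stats::cor(a, b)
}

#' Fit a PCA-truncation denoiser
#'
#' Computes the eigen-directions of the training covariance in channel
#' space, ordered by decreasing explained variance, and retains the first
#' `k`. For reproducibility each component's largest-magnitude loading is
#' made positive (a sign convention with no numerical effect on the
#' truncated reconstruction).
#'
#' @param train sample x channel training matrix.
#' @param k number of components to retain.
#' @return list of class `nirs_pca`: `component_basis` (channel x k,
#'   orthonormal columns), `k`, `training_mean`, `explained_variance`
#'   (all eigenvalues, decreasing).
#' @export
fit_pca_truncation <- function(train, k) {
  stopifnot(is.matrix(train), k >= 1)
  n_ch <- ncol(train)
  if (k > n_ch) stop("k (", k, ") exceeds channel count (", n_ch, ")")
  if (nrow(train) <= 1) stop("need more than one training sample")
  mu <- colMeans(train)
  xc <- sweep(train, 2, mu)
  e <- eigen(crossprod(xc) / (nrow(train) - 1), symmetric = TRUE)
  basis <- e$vectors[, seq_len(k), drop = FALSE]
  flip <- apply(basis, 2, function(v) sign(v[which.max(abs(v))]))
  basis <- sweep(basis, 2, flip, `*`)
  structure(list(component_basis = basis, k = as.integer(k),
                 training_mean = mu,
                 explained_variance = pmax(e$values, 0)),
            class = "nirs_pca")
}

#' Apply PCA-truncation denoising
#'
#' Centers the data by the training mean, projects onto the retained
#' components, back-projects into channel space and restores the mean.
#' With `k` equal to the channel count this is the identity map; for any
#' `k` the map is an affine projection and therefore idempotent.
#'
#' @param model a `nirs_pca`.
#' @param data sample x channel matrix with the model's channel count.
#' @return denoised sample x channel matrix.
#' @export
apply_pca_truncation <- function(model, data) {
  stopifnot(inherits(model, "nirs_pca"), is.matrix(data))
  if (ncol(data) != length(model$training_mean)) {
    stop("channel count (", ncol(data), ") does not match the model (",
         length(model$training_mean), ")")
  }
  xc <- sweep(data, 2, model$training_mean)
  sweep(xc %*% model$component_basis %*% t(model$component_basis), 2,
        model$training_mean, `+`)
}

#' Fit a lasso regression model
#'
#' Minimizes `(1/2N) sum_i (y_i - b0 - x_i' b)^2 + lambda * sum_j |b_j|`
#' with features standardized at fit time (coefficients are reported on
#' the original scale). Fitting is delegated to glmnet for two or more
#' features; the single-feature case is solved exactly by the coordinate
#' soft-threshold closed form (glmnet requires >= 2 columns).
#'
#' @param x sample x feature matrix.
#' @param y numeric response.
#' @param lambda penalty (scalar, >= 0) or a decreasing vector of
#'   penalties (a regularization path).
#' @return For scalar `lambda`, a list of class `nirs_lasso`: `weights`,
#'   `intercept`, `lambda`. For a vector, class `nirs_lasso_path` with
#'   `weights` (feature x lambda matrix), `intercept` (per lambda),
#'   `lambda`.
#' @export
fit_lasso <- function(x, y, lambda) {
  stopifnot(is.matrix(x), nrow(x) == length(y), nrow(x) >= 2,
            all(lambda >= 0))
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("non-finite values in the input")
  }
  n <- nrow(x)
  if (ncol(x) == 1) {
    # Exact univariate lasso on the standardized feature (1/N variance,
    # glmnet's internal convention), coefficient back on original scale.
    mu <- mean(x[, 1]); s <- sqrt(mean((x[, 1] - mu)^2))
    if (s == 0) stop("constant single feature")
    z <- (x[, 1] - mu) / s
    rho <- mean(z * (y - mean(y)))
    bz <- vapply(lambda, function(l) sign(rho) * max(abs(rho) - l, 0),
                 numeric(1))
    w <- matrix(bz / s, nrow = 1)
    b0 <- mean(y) - w[1, ] * mu
    if (length(lambda) == 1) {
      return(structure(list(weights = w[, 1], intercept = b0,
                            lambda = lambda), class = "nirs_lasso"))
    }
    return(structure(list(weights = w, intercept = b0, lambda = lambda),
                     class = "nirs_lasso_path"))
  }
  lam_sorted <- sort(unique(lambda), decreasing = TRUE)
  fit <- glmnet::glmnet(x, y, family = "gaussian", alpha = 1,
                        lambda = lam_sorted, standardize = TRUE,
                        thresh = 1e-9, maxit = 200000)
  idx <- match(lambda, fit$lambda)
  if (anyNA(idx)) idx <- vapply(lambda, function(l) which.min(abs(fit$lambda - l)), 1L)
  b <- as.matrix(fit$beta)
  if (length(lambda) == 1) {
    structure(list(weights = b[, idx], intercept = unname(fit$a0[idx]),
                   lambda = lambda), class = "nirs_lasso")
  } else {
    structure(list(weights = b[, idx, drop = FALSE],
                   intercept = unname(fit$a0[idx]), lambda = lambda),
              class = "nirs_lasso_path")
  }
}

#' @export
predict.nirs_lasso <- function(object, newdata, ...) {
  drop(newdata %*% object$weights) + object$intercept
}

#' @export
predict.nirs_lasso_path <- function(object, newdata, ...) {
  sweep(newdata %*% object$weights, 2, object$intercept, `+`)
}

#' Critical lasso penalty
#'
#' Smallest penalty that shrinks every coefficient to zero:
#' `lambda_max = max_j |<z_j, y - mean(y)>| / N` with `z_j` the
#' standardized features.
#'
#' @param x sample x feature matrix.
#' @param y response.
#' @return scalar penalty.
#' @export
lasso_lambda_max <- function(x, y) {
  n <- nrow(x)
  mu <- colMeans(x)
  s <- sqrt(colMeans(sweep(x, 2, mu)^2))
  s[s == 0] <- 1
  z <- sweep(sweep(x, 2, mu), 2, s, `/`)
  max(abs(crossprod(z, y - mean(y)))) / n
}

#' Cross-validation scheme for trial-level decoding
#'
#' Folds partition *trials*, never individual samples: neighbouring fNIRS
#' samples are strongly autocorrelated, so sample-level folds would leak
#' trial structure between training and test sets.
#'
#' @param outer_folds number of outer (generalization) folds.
#' @param inner_folds number of inner (hyperparameter-selection) folds.
#' @param seed integer seed controlling fold assignment.
#' @return list of class `nirs_cv_scheme`.
#' @export
cv_scheme <- function(outer_folds = 10, inner_folds = 10, seed = 1L) {
  stopifnot(outer_folds >= 2, inner_folds >= 2)
  structure(list(outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 seed = as.integer(seed)),
            class = "nirs_cv_scheme")
}

# Deterministic fold assignment of trial ids.
.assign_folds <- function(trial_ids, n_folds, seed) {
  restore <- .nirsload_seed(seed)
  on.exit(restore(), add = TRUE)
  ids <- sort(unique(trial_ids))
  if (length(ids) < n_folds) {
    stop("fewer trials (", length(ids), ") than folds (", n_folds, ")")
  }
  fold <- sample(rep(seq_len(n_folds), length.out = length(ids)))
  stats::setNames(fold, ids)
}

#' Default retained-component grid
#'
#' `{1, 2, 3, 5, 8, 12, 17, 25, 35, 50, n_channels}` clipped to the
#' available channel count.
#'
#' @param n_channels number of feature channels.
#' @return increasing integer vector.
#' @export
default_k_grid <- function(n_channels) {
  unique(pmin(c(1L, 2L, 3L, 5L, 8L, 12L, 17L, 25L, 35L, 50L, n_channels),
              n_channels))
}

#' Nested cross-validated workload decoding
#'
#' Predicts the continuous induced workload level from multichannel
#' concentration samples with PCA-truncation denoising followed by lasso
#' regression. Hyperparameters (retained component count `k` and penalty
#' `lambda`) are selected for each outer fold by an inner cross-validation
#' run only on that fold's training trials, maximizing the Pearson
#' correlation of pooled inner-validation predictions; the denoiser and
#' the lasso are then refit on the full outer-training set and applied to
#' the held-out test trials. Every sample is predicted exactly once; PCA,
#' feature scaling and hyperparameter selection never see test data. Ties
#' in the inner selection prefer the smallest `k`, then the largest
#' `lambda` (the most parsimonious model).
#'
#' @param samples a `nirs_sample_set`.
#' @param scheme a `nirs_cv_scheme`.
#' @param k_grid candidate retained-component counts.
#' @param lambda_grid candidate penalties; by default 50 log-spaced values
#'   from the outer-training `lambda_max` down to `1e-3 * lambda_max`.
#' @param n_lambda length of the default penalty grid.
#' @param channel_subset optional vector of montage channel ids to restrict
#'   the feature space (e.g. the frontal subset); `NULL` uses all retained
#'   channels.
#' @param subset_label label stored in the result (`"whole_head"`,
#'   `"frontal"`, ...); inferred when a subset is given.
#' @return object of class `nirs_decoding`: `induced`, `predicted`,
#'   `r_mvr`, `per_fold_r`, `chosen_k`, `chosen_lambda`, `fold_of_sample`,
#'   `trial_id`, `time`, `channel_subset_label`, `models` (per-fold fitted
#'   PCA + lasso), `scheme`.
#' @export
nested_cv_decode <- function(samples, scheme = cv_scheme(),
                             k_grid = NULL, lambda_grid = NULL,
                             n_lambda = 50, channel_subset = NULL,
                             subset_label = NULL) {
  stopifnot(inherits(samples, "nirs_sample_set"),
            inherits(scheme, "nirs_cv_scheme"))
  x <- samples$features
  if (!is.null(channel_subset)) {
    keep <- samples$channel_ids %in% channel_subset
    if (!any(keep)) stop("channel_subset matches no retained channel")
    x <- x[, keep, drop = FALSE]
    if (is.null(subset_label)) subset_label <- "custom"
  }
  if (is.null(subset_label)) subset_label <- "whole_head"
  y <- samples$labels
  trial <- samples$trial_id
  if (is.null(k_grid)) k_grid <- default_k_grid(ncol(x))
  k_grid <- sort(unique(pmin(as.integer(k_grid), ncol(x))))
  stopifnot(length(k_grid) >= 1)

  outer_fold <- .assign_folds(trial, scheme$outer_folds, scheme$seed)
  fold_of_sample <- outer_fold[as.character(trial)]
  predicted <- rep(NA_real_, length(y))
  per_fold_r <- numeric(scheme$outer_folds)
  chosen_k <- integer(scheme$outer_folds)
  chosen_lambda <- numeric(scheme$outer_folds)
  models <- vector("list", scheme$outer_folds)

  for (of in seq_len(scheme$outer_folds)) {
    tr_idx <- which(fold_of_sample != of)
    te_idx <- which(fold_of_sample == of)
    xtr <- x[tr_idx, , drop = FALSE]
    ytr <- y[tr_idx]
    if (stats::sd(ytr) == 0) {
      stop("constant labels in the training portion of outer fold ", of)
    }
    lg <- lambda_grid
    if (is.null(lg)) {
      lmax <- lasso_lambda_max(xtr, ytr)
      lg <- exp(seq(log(lmax), log(1e-3 * lmax), length.out = n_lambda))
    }
    lg <- sort(lg, decreasing = TRUE)

    inner_fold <- .assign_folds(trial[tr_idx], scheme$inner_folds,
                                scheme$seed + 1000L * of)
    ifold <- inner_fold[as.character(trial[tr_idx])]
    # pooled inner-validation predictions per (k, lambda)
    pred_inner <- array(NA_real_,
                        dim = c(length(tr_idx), length(k_grid), length(lg)))
    for (inf in seq_len(scheme$inner_folds)) {
      itr <- which(ifold != inf)
      iva <- which(ifold == inf)
      if (!length(iva)) next
      if (stats::sd(ytr[itr]) == 0) {
        stop("constant labels in inner fold ", inf, " of outer fold ", of)
      }
      for (ki in seq_along(k_grid)) {
        pca <- fit_pca_truncation(xtr[itr, , drop = FALSE], k_grid[ki])
        xtr_d <- apply_pca_truncation(pca, xtr[itr, , drop = FALSE])
        xva_d <- apply_pca_truncation(pca, xtr[iva, , drop = FALSE])
        path <- fit_lasso(xtr_d, ytr[itr], lg)
        pred_inner[iva, ki, ] <- predict(path, xva_d)
      }
    }
    score <- matrix(-Inf, length(k_grid), length(lg))
    for (ki in seq_along(k_grid)) {
      for (li in seq_along(lg)) {
        p <- pred_inner[, ki, li]
        ok <- !is.na(p)
        if (sum(ok) >= 2 && stats::sd(p[ok]) > 0) {
          score[ki, li] <- stats::cor(ytr[ok], p[ok])
        }
      }
    }
    best <- max(score)
    cand <- which(score == best, arr.ind = TRUE)
    # most parsimonious tie-break: smallest k, then largest lambda
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    ki <- cand[1, 1]; li <- cand[1, 2]
    chosen_k[of] <- k_grid[ki]
    chosen_lambda[of] <- lg[li]

    pca <- fit_pca_truncation(xtr, chosen_k[of])
    xtr_d <- apply_pca_truncation(pca, xtr)
    lasso <- fit_lasso(xtr_d, ytr, chosen_lambda[of])
    xte_d <- apply_pca_truncation(pca, x[te_idx, , drop = FALSE])
    predicted[te_idx] <- predict(lasso, xte_d)
    per_fold_r[of] <- if (stats::sd(predicted[te_idx]) > 0 &&
                          stats::sd(y[te_idx]) > 0) {
      stats::cor(y[te_idx], predicted[te_idx])
    } else {
      NA_real_
    }
    models[[of]] <- list(pca = pca, lasso = lasso)
  }
  stopifnot(!anyNA(predicted))
  structure(
    list(induced = y, predicted = predicted,
         r_mvr = pearson_r(y, predicted), per_fold_r = per_fold_r,
         chosen_k = chosen_k, chosen_lambda = chosen_lambda,
         fold_of_sample = unname(fold_of_sample), trial_id = trial,
         time = samples$time, channel_subset_label = subset_label,
         models = models, scheme = scheme),
    class = "nirs_decoding"
  )
}

#' Peripheral (cardiac) workload decoder
#'
#' Applies the same nested cross-validation machinery to the
#' two-dimensional trial-wise feature space of heart rate and RMSSD,
#' giving trial-level induced/predicted workload traces.
#'
#' @param trials trial table with `heart_rate`, `rmssd`, `nback_level` and
#'   `trial_index` columns (e.g. from [generate_behavior()], one
#'   participant).
#' @param scheme a `nirs_cv_scheme`.
#' @param lambda_grid optional penalty grid (default as in
#'   [nested_cv_decode()]).
#' @return a `nirs_decoding` with `channel_subset_label = "peripheral"`.
#' @export
decode_peripheral <- function(trials, scheme = cv_scheme(),
                              lambda_grid = NULL) {
  need <- c("heart_rate", "rmssd", "nback_level", "trial_index")
  missing <- setdiff(need, names(trials))
  if (length(missing)) {
    stop("trial table is missing: ", paste(missing, collapse = ", "))
  }
  if (anyNA(trials$heart_rate) || anyNA(trials$rmssd)) {
    stop("missing heart_rate/rmssd features")
  }
  samples <- structure(
    list(features = cbind(hr = trials$heart_rate, rmssd = trials$rmssd),
         labels = trials$nback_level, trial_id = trials$trial_index,
         time = seq_len(nrow(trials)) - 1,
         participant_id = rep(1L, nrow(trials)),
         channel_ids = 1:2,
         excluded = tibble::tibble(sample = integer(), time = numeric(),
                                   reason = character()),
         sampling_rate = NA_real_),
    class = "nirs_sample_set"
  )
  res <- nested_cv_decode(samples, scheme, k_grid = c(1L, 2L),
                          lambda_grid = lambda_grid,
                          subset_label = "peripheral")
  res
}

#' @export
print.nirs_decoding <- function(x, ...) {
  cat("nested-CV decoding (", x$channel_subset_label, "): r_mvr = ",
      round(x$r_mvr, 3), " over ", length(x$induced), " samples; ",
      "median chosen k = ", stats::median(x$chosen_k), "\n", sep = "")
  invisible(x)
}
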