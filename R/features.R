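#' Construct a set of multichannel trials
#'
#' Container for epoch-level EEG-like data: a trials x channels x samples
#' array, the sampling rate, and per-trial class labels in \{-1, +1\}.
#'
#' @param data Numeric 3-d array, dimensions trials x channels x samples.
#' @param fs Sampling rate in Hz, > 0.
#' @param labels Numeric vector of per-trial labels in \{-1, +1\}.
#' @return A `trial_set` object.
#' @export
trial_set <- function(data, fs, labels) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort_bad_arg("`data` must be a trials x channels x samples array.")
  }
  if (anyNA(data) || !all(is.finite(data))) {
    abort_bad_arg("`data` contains non-finite values.")
  }
  check_scalar_number(fs, "fs", positive = TRUE)
  labels <- check_labels(labels)
  if (length(labels) != dim(data)[1L]) {
    abort_bad_arg("`labels` length must equal the number of trials.")
  }
  structure(list(data = data, fs = fs, labels = labels), class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<trial set: %d trials x %d channels x %d samples at %g Hz (%d / %d per class)>\n",
    d[1], d[2], d[3], x$fs, sum(x$labels == 1), sum(x$labels == -1)
  ))
  invisible(x)
}

#' Extract a time window from each trial
#'
#' Keeps the sample slice corresponding to \[`t_start`, `t_end`) seconds,
#' using `round(t * fs)` boundaries, so a 0.5-2.5 s window at 100 Hz yields
#' exactly 200 samples. Labels are carried through.
#'
#' @param trials A [trial_set()].
#' @param t_start,t_end Window bounds in seconds; `0 <= t_start < t_end <=`
#'   trial duration.
#' @return A `trial_set` restricted to the window.
#' @export
extract_window <- function(trials, t_start, t_end) {
  stopifnot(inherits(trials, "trial_set"))
  check_scalar_number(t_start, "t_start", nonnegative = TRUE)
  check_scalar_number(t_end, "t_end", positive = TRUE)
  n_samp <- dim(trials$data)[3L]
  duration <- n_samp / trials$fs
  if (t_start >= t_end || t_end > duration + 1e-9) {
    abort_bad_arg("window must satisfy 0 <= t_start < t_end <= trial duration.")
  }
  i0 <- round(t_start * trials$fs) + 1L
  i1 <- round(t_end * trials$fs)
  trial_set(trials$data[, , i0:i1, drop = FALSE], trials$fs, trials$labels)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a forward-backward (zero-phase) Butterworth band-pass of the given
#' order to every channel of every trial. Defaults cover the 8-30 Hz mu/beta
#' band used for motor-imagery features, with a fifth-order design.
#'
#' @param trials A [trial_set()].
#' @param low_hz,high_hz Band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < fs / 2`.
#' @param order Butterworth design order (the effective attenuation is doubled
#'   by the two-pass application).
#' @return A filtered `trial_set` of identical shape.
#' @export
bandpass <- function(trials, low_hz = 8, high_hz = 30, order = 5) {
  stopifnot(inherits(trials, "trial_set"))
  check_scalar_number(low_hz, "low_hz", positive = TRUE)
  check_scalar_number(high_hz, "high_hz", positive = TRUE)
  order <- check_count(order, "order")
  nyq <- trials$fs / 2
  if (low_hz >= high_hz || high_hz >= nyq) {
    abort_bad_arg("band must satisfy 0 < low_hz < high_hz < fs/2.")
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  out <- trials$data
  d <- dim(out)
  for (tr in seq_len(d[1L])) {
    for (ch in seq_len(d[2L])) {
      out[tr, ch, ] <- signal::filtfilt(bf, out[tr, ch, ])
    }
  }
  trial_set(out, trials$fs, trials$labels)
}

#' Fit common spatial pattern (CSP) filters with Tikhonov regularization
#'
#' Computes per-class average covariance matrices (each trial's covariance is
#' normalized by its trace before averaging, so high-power trials do not
#' dominate) and solves the regularized Rayleigh problem
#' \deqn{\max_w \frac{w^\top C_+ w}{w^\top (C_+ + C_-) w + \alpha \|w\|^2}}
#' as the generalized symmetric eigenproblem
#' \eqn{C_+ w = \nu (C_+ + C_- + \alpha I) w} via whitening. The filter bank
#' keeps the `n_pairs` eigenvectors from each end of the spectrum (maximal
#' variance ratio for each class). The Tikhonov term `alpha > 0` shrinks
#' filter norms and regularizes rank-deficient covariances; with `alpha = 0` a
#' singular composite covariance is an error. Each filter's sign is fixed by
#' making its largest-magnitude coefficient positive, so the fit is fully
#' deterministic.
#'
#' @param trials A [trial_set()] containing both classes.
#' @param n_pairs Number of filter pairs; `2 * n_pairs <= channels`.
#' @param tikhonov_alpha Quadratic penalty weight, >= 0.
#' @return A `spatial_filter_bank` with a `2 * n_pairs` x channels filter
#'   matrix (rows are filters, ordered from the +1-favoring end to the
#'   -1-favoring end) and the associated eigenvalues.
#' @export
fit_csp <- function(trials, n_pairs = 3, tikhonov_alpha = 0) {
  stopifnot(inherits(trials, "trial_set"))
  n_pairs <- check_count(n_pairs, "n_pairs")
  check_scalar_number(tikhonov_alpha, "tikhonov_alpha", nonnegative = TRUE)
  d <- dim(trials$data)
  if (2L * n_pairs > d[2L]) {
    abort_bad_arg("`2 * n_pairs` cannot exceed the channel count.")
  }
  if (!all(c(-1, 1) %in% trials$labels)) {
    abort_bad_arg("both classes must be present to fit CSP.")
  }
  avg_cov <- function(cls) {
    idx <- which(trials$labels == cls)
    acc <- matrix(0, d[2L], d[2L])
    for (tr in idx) {
      X <- trials$data[tr, , , drop = TRUE]
      C <- tcrossprod(X) / (d[3L] - 1L)
      acc <- acc + C / sum(diag(C))
    }
    acc / length(idx)
  }
  C_pos <- avg_cov(1)
  C_neg <- avg_cov(-1)
  Cc <- C_pos + C_neg + diag(tikhonov_alpha, d[2L])
  ec <- eigen(Cc, symmetric = TRUE)
  tol <- max(ec$values) * 1e-10
  if (any(ec$values < tol)) {
    abort_bad_arg(
      "composite covariance is singular; supply tikhonov_alpha > 0 to regularize."
    )
  }
  # whitening P: P Cc P' = I, then a symmetric eigensolve in whitened space
  P <- diag(1 / sqrt(ec$values)) %*% t(ec$vectors)
  S <- P %*% C_pos %*% t(P)
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  W_full <- t(t(P) %*% es$vectors) # rows = filters, eigenvalues descending
  keep <- c(seq_len(n_pairs), d[2L] - seq_len(n_pairs) + 1L)
  filters <- W_full[keep, , drop = FALSE]
  for (j in seq_len(nrow(filters))) {
    peak <- which.max(abs(filters[j, ]))
    if (filters[j, peak] < 0) filters[j, ] <- -filters[j, ]
  }
  structure(
    list(
      filters = filters, n_pairs = n_pairs, tikhonov_alpha = tikhonov_alpha,
      eigenvalues = es$values[keep]
    ),
    class = "spatial_filter_bank"
  )
}

#' Manually assemble a spatial filter bank
#'
#' Mostly useful for tests and for reloading serialized banks.
#'
#' @param filters Numeric matrix with one filter per row; the row count must
#'   be even (pairs).
#' @param tikhonov_alpha Penalty recorded with the bank.
#' @return A `spatial_filter_bank`.
#' @export
spatial_filter_bank <- function(filters, tikhonov_alpha = 0) {
  filters <- as_feature_matrix(filters)
  if (nrow(filters) %% 2L != 0L) {
    abort_bad_arg("`filters` must contain an even number of rows (pairs).")
  }
  structure(
    list(
      filters = filters, n_pairs = nrow(filters) %/% 2L,
      tikhonov_alpha = tikhonov_alpha, eigenvalues = rep(NA_real_, nrow(filters))
    ),
    class = "spatial_filter_bank"
  )
}

#' @export
print.spatial_filter_bank <- function(x, ...) {
  cat(sprintf(
    "<CSP filter bank: %d pairs on %d channels, alpha = %g>\n",
    x$n_pairs, ncol(x$filters), x$tikhonov_alpha
  ))
  invisible(x)
}

#' Log-variance features of spatially filtered trials
#'
#' For each trial, projects the channels through the filter bank and computes
#' `log(var_j / sum_k var_k)` per filter: the classic normalized band-power
#' feature. Because each feature is the log of a proportion, all features are
#' <= 0. Labels are carried through into the returned data frame.
#'
#' @param trials A [trial_set()].
#' @param bank A `spatial_filter_bank` whose column count matches the trials'
#'   channel count.
#' @return A tibble with `2 * n_pairs` feature columns (`csp_1`, ...) and a
#'   `label` column.
#' @export
log_variance_features <- function(trials, bank) {
  stopifnot(inherits(trials, "trial_set"), inherits(bank, "spatial_filter_bank"))
  d <- dim(trials$data)
  if (ncol(bank$filters) != d[2L]) {
    abort_bad_arg("filter bank channel count does not match the trials.")
  }
  n_filt <- nrow(bank$filters)
  feats <- matrix(NA_real_, d[1L], n_filt)
  for (tr in seq_len(d[1L])) {
    Y <- bank$filters %*% trials$data[tr, , , drop = TRUE]
    v <- apply(Y, 1L, var)
    tot <- sum(v)
    if (tot <= 0) abort_bad_arg("a trial has zero total variance after filtering.")
    feats[tr, ] <- log(v / tot)
  }
  colnames(feats) <- paste0("csp_", seq_len(n_filt))
  out <- tibble::as_tibble(feats)
  out$label <- trials$labels
  out
}

#' Motor-imagery feature extraction pipeline
#'
#' Convenience wrapper chaining the standard front end: time-window
#' extraction, zero-phase Butterworth band-pass, CSP fitting on the training
#' trials, and log-variance features. When `bank` is supplied the CSP step is
#' skipped and the given filters are applied (use this to featurize test
#' trials with train-fitted filters).
#'
#' @param trials A [trial_set()].
#' @param t_start,t_end Analysis window in seconds.
#' @param low_hz,high_hz,order Band-pass settings.
#' @param n_pairs,tikhonov_alpha CSP settings.
#' @param bank Optional pre-fitted `spatial_filter_bank`.
#' @return A list with `features` (tibble) and `bank` (the filter bank used).
#' @export
mi_feature_pipeline <- function(trials, t_start = 0.5, t_end = 2.5,
                                low_hz = 8, high_hz = 30, order = 5,
                                n_pairs = 3, tikhonov_alpha = 0, bank = NULL) {
  w <- extract_window(trials, t_start, t_end)
  f <- bandpass(w, low_hz, high_hz, order)
  if (is.null(bank)) bank <- fit_csp(f, n_pairs = n_pairs, tikhonov_alpha = tikhonov_alpha)
  list(features = log_variance_features(f, bank), bank = bank)
}
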