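test_that("window extraction slices the stated sample range", {
  tr <- generate_synthetic_trials(n_trials = 4, channels = 3, fs = 100,
                                  duration = 3, seed = 1)
  full <- extract_window(tr, 0, 3)
  expect_equal(full$data, tr$data)

  win <- extract_window(tr, 0.5, 2.5)
  expect_equal(dim(win$data)[3], 200L)
  expect_equal(win$labels, tr$labels)
  # the slice starts at sample round(0.5 * fs) + 1
  expect_equal(win$data[1, 1, ], tr$data[1, 1, 51:250])

  expect_error(extract_window(tr, 0.5, 3.5), class = "elsrtl_invalid_argument")
  expect_error(extract_window(tr, 2, 1), class = "elsrtl_invalid_argument")
})

test_that("the band-pass keeps the passband and rejects DC and low frequencies", {
  fs <- 250
  n <- round(3.5 * fs)
  tt <- (seq_len(n) - 1) / fs
  mk <- function(x) trial_set(array(rep(x, each = 2), c(1, 2, n))[, , , drop = FALSE],
                              fs, labels = 1)
  mid <- seq(floor(n / 4), ceiling(3 * n / 4))

  dc <- bandpass(mk(rep(1, n)))
  expect_lte(rms(dc$data[1, 1, mid]), 1e-3)

  s15 <- sin(2 * pi * 15 * tt)
  pass <- bandpass(mk(s15))
  gain15 <- rms(pass$data[1, 1, mid]) / rms(s15[mid])
  expect_gte(gain15, 0.95)
  expect_lte(gain15, 1.05)

  s2 <- sin(2 * pi * 2 * tt)
  stopb <- bandpass(mk(s2))
  expect_lte(rms(stopb$data[1, 1, mid]) / rms(s2[mid]), 0.1)

  expect_error(bandpass(mk(s15), low_hz = 8, high_hz = 130),
               class = "elsrtl_invalid_argument")
  expect_error(bandpass(mk(s15), low_hz = 30, high_hz = 8),
               class = "elsrtl_invalid_argument")
})

test_that("CSP recovers axis-aligned filters on the diagonal construction", {
  tr <- variance_coded_trials(n_per_class = 40, n_samp = 400, seed = 2)
  bank <- fit_csp(tr, n_pairs = 1, tikhonov_alpha = 0)
  expect_equal(dim(bank$filters), c(2L, 2L))
  for (j in 1:2) {
    w <- bank$filters[j, ] / sqrt(sum(bank$filters[j, ]^2))
    expect_gte(max(abs(w)), 0.95) # |cosine| with a coordinate axis
  }
})

test_that("alpha = 0 filters satisfy the generalized eigen-equation", {
  tr <- variance_coded_trials(n_per_class = 20, n_samp = 300,
                              var_pos = c(4, 1, 2), var_neg = c(1, 4, 2),
                              seed = 3)
  # recompute the class covariances the same way to check the residual
  d <- dim(tr$data)
  avg_cov <- function(cls) {
    idx <- which(tr$labels == cls)
    acc <- matrix(0, d[2], d[2])
    for (i in idx) {
      X <- tr$data[i, , , drop = TRUE]
      C <- tcrossprod(X) / (d[3] - 1)
      acc <- acc + C / sum(diag(C))
    }
    acc / length(idx)
  }
  Cp <- avg_cov(1)
  Cc <- Cp + avg_cov(-1)
  bank <- fit_csp(tr, n_pairs = 1, tikhonov_alpha = 0)
  for (j in 1:2) {
    w <- bank$filters[j, ]
    lam <- drop(w %*% Cp %*% w) / drop(w %*% Cc %*% w)
    expect_lte(max(abs(Cp %*% w - lam * (Cc %*% w))), 1e-8)
  }
})

test_that("increasing the Tikhonov penalty never grows the leading filter norm", {
  tr <- variance_coded_trials(n_per_class = 25, n_samp = 300, seed = 4)
  norms <- vapply(c(0, 0.01, 0.1, 1, 10), function(a) {
    sqrt(sum(fit_csp(tr, n_pairs = 1, tikhonov_alpha = a)$filters[1, ]^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-10))
})

test_that("CSP demands both classes and flags singular covariances", {
  tr <- variance_coded_trials(n_per_class = 10, n_samp = 100, seed = 5)
  tr_one <- trial_set(tr$data[tr$labels == 1, , , drop = FALSE], tr$fs,
                      tr$labels[tr$labels == 1])
  expect_error(fit_csp(tr_one, n_pairs = 1), class = "elsrtl_invalid_argument")
  expect_error(fit_csp(tr, n_pairs = 2), class = "elsrtl_invalid_argument")

  # rank-deficient: channel 2 duplicates channel 1
  dat <- tr$data
  dat[, 2, ] <- dat[, 1, ]
  dup <- trial_set(dat, tr$fs, tr$labels)
  expect_error(fit_csp(dup, n_pairs = 1, tikhonov_alpha = 0),
               class = "elsrtl_invalid_argument")
  expect_s3_class(fit_csp(dup, n_pairs = 1, tikhonov_alpha = 0.1),
                  "spatial_filter_bank")
})

test_that("log-variance features are deterministic log-proportions", {
  n <- 500
  z <- as.numeric(scale(withr::with_seed(6, rnorm(n)))) # exactly unit variance
  dat <- array(NA_real_, c(2, 2, n))
  dat[1, 1, ] <- 2 * z # variance 4
  dat[1, 2, ] <- z # variance 1
  dat[2, , ] <- dat[1, , ] # duplicated trial
  tr <- trial_set(dat, fs = 100, labels = c(1, -1))
  bank <- spatial_filter_bank(diag(2))
  f <- log_variance_features(tr, bank)
  expect_equal(unlist(f[1, c("csp_1", "csp_2")], use.names = FALSE),
               c(log(0.8), log(0.2)), tolerance = 1e-10)
  expect_equal(f[1, 1:2], f[2, 1:2]) # identical rows for identical trials
  expect_true(all(as.matrix(f[paste0("csp_", 1:2)]) <= 0))
  expect_equal(f$label, c(1, -1))
})

test_that("the front end is pure: same trials in, same features out", {
  tr <- generate_synthetic_trials(n_trials = 20, seed = 7)
  p1 <- mi_feature_pipeline(tr, t_start = 0, t_end = 2, n_pairs = 2)
  p2 <- mi_feature_pipeline(tr, t_start = 0, t_end = 2, n_pairs = 2)
  expect_identical(p1$features, p2$features)
  expect_identical(p1$bank$filters, p2$bank$filters)
})

test_that("CSP features from variance-coded trials are ELSR-separable", {
  tr <- generate_synthetic_trials(n_trials = 80, erd_ratio = 0.4, seed = 8)
  pipe <- mi_feature_pipeline(tr, t_start = 0, t_end = 2, n_pairs = 2)
  fit <- elsr_fit(pipe$features, lambda = 0.1)
  expect_gte(mean(predict(fit, pipe$features)$label == pipe$features$label), 0.9)
})
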