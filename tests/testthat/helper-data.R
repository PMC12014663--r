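# Small deterministic fixtures shared across tests.

random_labeled <- function(n, d, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * d), n, d)
    y <- rep_len(c(1, -1), n)
    colnames(X) <- paste0("x", seq_len(d))
    out <- tibble::as_tibble(X)
    out$label <- y
    out
  })
}

random_matrix <- function(n, d, seed = 1) {
  withr::with_seed(seed, matrix(rnorm(n * d), n, d))
}

# Two well-separated clouds with balanced +/-1 labels.
separable_data <- function(n = 40, d = 2, gap = 10, seed = 1) {
  withr::with_seed(seed, {
    y <- rep_len(c(1, -1), n)
    X <- matrix(rnorm(n * d, sd = 0.5), n, d) + (gap / 2) * tcrossprod(y, c(1, rep(0, d - 1)))
    colnames(X) <- paste0("x", seq_len(d))
    out <- tibble::as_tibble(X)
    out$label <- y
    out
  })
}

# Two-class multichannel noise trials with class-dependent per-channel
# variance (diagonal covariance construction for CSP tests).
variance_coded_trials <- function(n_per_class = 30, n_samp = 200,
                                  var_pos = c(4, 1), var_neg = c(1, 4),
                                  fs = 100, seed = 1) {
  n_ch <- length(var_pos)
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    labels <- rep(c(1, -1), each = n_per_class)
    dat <- array(NA_real_, dim = c(n, n_ch, n_samp))
    for (i in seq_len(n)) {
      v <- if (labels[i] == 1) var_pos else var_neg
      dat[i, , ] <- matrix(rnorm(n_ch * n_samp), n_ch) * sqrt(v)
    }
  })
  trial_set(dat, fs = fs, labels = labels)
}

rms <- function(x) sqrt(mean(x^2))
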