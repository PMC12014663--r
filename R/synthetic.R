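#' Generate a source/target domain pair with controlled shift
#'
#' Draws two-class Gaussian feature sets emulating CSP log-variance features
#' in a cross-subject transfer setting. Source classes are isotropic Gaussian
#' blobs at \eqn{\pm(\mathrm{class\_sep}/2) u} (with `u` the first coordinate
#' axis) and covariance `noise_sd^2 I`. The target domain uses the same
#' construction, then perturbs it by a translation of magnitude `shift` along
#' a seeded random direction and a rotation by `0.2 * shift` radians in a
#' seeded random 2-plane — so `shift = 0` makes the two domains identically
#' distributed, and larger values move the target decision boundary away from
#' the source one. Classes are balanced up to rounding, and target train/test
#' rows are disjoint by construction.
#'
#' Defaults mirror the benchmark's most data-starved regime: 280 source rows,
#' 28 labeled target training rows, 252 target test rows, six features (three
#' CSP filter pairs), unit noise, class separation 2 and moderate shift 0.5.
#'
#' @param n_source Number of source rows.
#' @param n_target_train,n_target_test Number of target training / test rows.
#' @param dim Feature dimension.
#' @param class_sep Distance between class means in units of within-class
#'   standard deviation.
#' @param shift Magnitude of the source-to-target mean/rotation perturbation,
#'   >= 0.
#' @param noise_sd Within-class standard deviation, > 0.
#' @param seed Integer seed; the full triple is reproducible from it.
#' @return A `domain_pair`: a list of three tibbles (`source`, `target_train`,
#'   `target_test`), each with feature columns `x1..xd` and a `label` column
#'   in \{-1, +1\}.
#' @examples
#' pair <- generate_domain_pair(seed = 1)
#' sapply(pair, nrow)
#' @export
generate_domain_pair <- function(n_source = 280, n_target_train = 28,
                                 n_target_test = 252, dim = 6, class_sep = 2,
                                 shift = 0.5, noise_sd = 1, seed = 1L) {
  n_source <- check_count(n_source, "n_source")
  n_target_train <- check_count(n_target_train, "n_target_train")
  n_target_test <- check_count(n_target_test, "n_target_test")
  dim <- check_count(dim, "dim")
  check_scalar_number(class_sep, "class_sep", positive = TRUE)
  check_scalar_number(shift, "shift", nonnegative = TRUE)
  check_scalar_number(noise_sd, "noise_sd", positive = TRUE)
  seed <- check_count(seed, "seed", min = 0L)

  u <- c(1, rep(0, dim - 1L))
  withr::with_seed(seed, {
    # target perturbation: seeded direction and rotation plane
    t_dir <- rnorm(dim)
    t_dir <- t_dir / sqrt(sum(t_dir^2))
    R <- rotation_in_random_plane(dim, angle = 0.2 * shift)
    draw <- function(n) {
      n_pos <- ceiling(n / 2)
      labels <- c(rep(1, n_pos), rep(-1, n - n_pos))
      X <- matrix(rnorm(n * dim, sd = noise_sd), n, dim) +
        tcrossprod(labels, (class_sep / 2) * u)
      list(X = X, labels = labels)
    }
    src <- draw(n_source)
    tgt <- draw(n_target_train + n_target_test)
    tgt$X <- tgt$X %*% t(R) + matrix(shift * t_dir, nrow(tgt$X), dim, byrow = TRUE)
    # interleave classes before splitting so train/test stay balanced
    ord <- order(rep(seq_len(ceiling(nrow(tgt$X) / 2)), 2)[seq_len(nrow(tgt$X))])
    tgt$X <- tgt$X[ord, , drop = FALSE]
    tgt$labels <- tgt$labels[ord]
  })

  as_labeled_tibble <- function(X, labels) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
    out <- tibble::as_tibble(X)
    out$label <- labels
    out
  }
  idx_train <- seq_len(n_target_train)
  structure(
    list(
      source = as_labeled_tibble(src$X, src$labels),
      target_train = as_labeled_tibble(tgt$X[idx_train, , drop = FALSE],
                                       tgt$labels[idx_train]),
      target_test = as_labeled_tibble(tgt$X[-idx_train, , drop = FALSE],
                                      tgt$labels[-idx_train])
    ),
    class = "domain_pair"
  )
}

# Rotation by `angle` radians in the plane spanned by two seeded random
# orthonormal vectors (identity when angle == 0).
rotation_in_random_plane <- function(dim, angle) {
  if (dim < 2L || angle == 0) return(diag(dim))
  M <- matrix(rnorm(dim * 2L), dim, 2L)
  Q <- qr.Q(qr(M))
  q1 <- Q[, 1L]
  q2 <- Q[, 2L]
  diag(dim) +
    (cos(angle) - 1) * (tcrossprod(q1) + tcrossprod(q2)) +
    sin(angle) * (tcrossprod(q2, q1) - tcrossprod(q1, q2))
}

#' @export
print.domain_pair <- function(x, ...) {
  cat(sprintf(
    "<domain pair: %d source, %d target train, %d target test rows, %d features>\n",
    nrow(x$source), nrow(x$target_train), nrow(x$target_test),
    ncol(x$source) - 1L
  ))
  invisible(x)
}

#' Flatten a domain pair into one tibble
#'
#' @param x A `domain_pair`.
#' @param ... Unused.
#' @return A tibble with the feature columns, `label`, `domain`
#'   (`"source"`/`"target"`) and `role` (`"train"`/`"test"`).
#' @method as_tibble domain_pair
#' @export
as_tibble.domain_pair <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$source, domain = "source", role = "train"),
    dplyr::mutate(x$target_train, domain = "target", role = "train"),
    dplyr::mutate(x$target_test, domain = "target", role = "test")
  )
}

#' Generate synthetic oscillatory multichannel trials
#'
#' Produces trials shaped like band-passed motor-imagery epochs: broadband
#' Gaussian noise on every channel plus a mu-band sinusoid (random phase per
#' trial and channel) on the first `ceiling(channels / 2)` channels. The
#' sinusoid has amplitude `amplitude` for class +1 trials and
#' `amplitude * erd_ratio` for class -1 trials — an event-related
#' desynchronization surrogate, so `erd_ratio = 1` makes the classes
#' indistinguishable and small values give a band-power ratio of about
#' `erd_ratio^2` on the modulated channels. Class labels are balanced and
#' randomly interleaved under the seed.
#'
#' @param n_trials Number of trials (>= 2).
#' @param channels Number of channels (>= 2).
#' @param fs Sampling rate in Hz.
#' @param duration Trial length in seconds.
#' @param mu_band_hz Frequency of the class-modulated sinusoid, in Hz.
#' @param erd_ratio Amplitude scaling for class -1, in (0, 1].
#' @param seed Integer seed.
#' @param amplitude Sinusoid amplitude for class +1.
#' @param noise_sd Standard deviation of the broadband noise.
#' @return A [trial_set()] of dimensions
#'   `n_trials x channels x round(fs * duration)`.
#' @export
generate_synthetic_trials <- function(n_trials = 100, channels = 8, fs = 100,
                                      duration = 2, mu_band_hz = 12,
                                      erd_ratio = 0.5, seed = 1L,
                                      amplitude = 2, noise_sd = 0.2) {
  n_trials <- check_count(n_trials, "n_trials", min = 2L)
  channels <- check_count(channels, "channels", min = 2L)
  check_scalar_number(fs, "fs", positive = TRUE)
  check_scalar_number(duration, "duration", positive = TRUE)
  check_scalar_number(mu_band_hz, "mu_band_hz", positive = TRUE)
  check_scalar_number(erd_ratio, "erd_ratio", positive = TRUE)
  if (erd_ratio > 1) abort_bad_arg("`erd_ratio` must lie in (0, 1].")
  seed <- check_count(seed, "seed", min = 0L)
  check_scalar_number(amplitude, "amplitude", positive = TRUE)
  check_scalar_number(noise_sd, "noise_sd", positive = TRUE)

  n_samp <- round(fs * duration)
  tt <- (seq_len(n_samp) - 1L) / fs
  mod_channels <- seq_len(ceiling(channels / 2))
  withr::with_seed(seed, {
    n_pos <- ceiling(n_trials / 2)
    labels <- sample(c(rep(1, n_pos), rep(-1, n_trials - n_pos)))
    dat <- array(rnorm(n_trials * channels * n_samp, sd = noise_sd),
                 dim = c(n_trials, channels, n_samp))
    for (tr in seq_len(n_trials)) {
      amp <- if (labels[tr] == 1) amplitude else amplitude * erd_ratio
      for (ch in mod_channels) {
        phase <- runif(1, 0, 2 * pi)
        dat[tr, ch, ] <- dat[tr, ch, ] + amp * sin(2 * pi * mu_band_hz * tt + phase)
      }
    }
  })
  trial_set(dat, fs, labels)
}
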