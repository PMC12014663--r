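# Shared validation helpers. All user-visible argument errors carry the
# "elsrtl_invalid_argument" condition class so callers can distinguish
# contract violations from internal failures.

abort_bad_arg <- function(msg) {
  abort(msg, class = "elsrtl_invalid_argument")
}

check_scalar_number <- function(x, name, positive = FALSE, nonnegative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_bad_arg(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort_bad_arg(sprintf("`%s` must be strictly positive.", name))
  }
  if (nonnegative && x < 0) {
    abort_bad_arg(sprintf("`%s` must be non-negative.", name))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    abort_bad_arg(sprintf("`%s` must be an integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

# Coerce a feature matrix: accepts a numeric matrix or a data frame whose
# non-label columns are the features. Non-finite values are contract errors.
as_feature_matrix <- function(x, label = "label") {
  if (is.data.frame(x)) {
    x <- x[setdiff(names(x), label)]
    x <- as.matrix(x)
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    abort_bad_arg("features must be a numeric matrix or data frame.")
  }
  if (anyNA(x) || !all(is.finite(x))) {
    abort_bad_arg("features contain non-finite values.")
  }
  x
}

check_labels <- function(y) {
  y <- as.numeric(y)
  if (length(y) < 1L || !all(y %in% c(-1, 1))) {
    abort_bad_arg("labels must take values in {-1, +1}.")
  }
  y
}

# Split a labeled data frame into the (X, y) pair used by the solvers.
split_labeled <- function(data, label = "label") {
  if (!is.data.frame(data)) {
    abort_bad_arg("`data` must be a data frame with a label column.")
  }
  if (!label %in% names(data)) {
    abort_bad_arg(sprintf("`data` has no column named '%s'.", label))
  }
  list(
    X = as_feature_matrix(data, label = label),
    y = check_labels(data[[label]])
  )
}

# Solve (A + ridge*I) x = b for symmetric PSD A via Cholesky; never forms an
# explicit inverse.
ridge_solve <- function(A, ridge, b) {
  n <- nrow(A)
  R <- chol(A + diag(ridge, n))
  backsolve(R, forwardsolve(t(R), b))
}

# Seeded stratified fold assignment for binary labels.
stratified_folds <- function(y, folds, seed) {
  if (min(table(y)) < folds) {
    abort_bad_arg("`folds` exceeds the size of the smallest class.")
  }
  assign <- integer(length(y))
  withr::with_seed(seed, {
    for (cls in c(-1, 1)) {
      idx <- sample(which(y == cls))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}
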