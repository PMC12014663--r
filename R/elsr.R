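#' Fit a ridge classifier on explicitly mapped features (primal form)
#'
#' Solves \eqn{\min_w \frac12 \|X w - y\|^2 + \frac\lambda2 \|w\|^2} for the
#' weight vector via the normal equations \eqn{(X^\top X + \lambda I) w =
#' X^\top y}, using a Cholesky factorization of the symmetric positive
#' definite system (never an explicit inverse).
#'
#' @param X_mapped Numeric matrix of mapped features, one row per sample.
#' @param y Numeric vector of labels in \{-1, +1\} (any finite numeric target
#'   is accepted; classification thresholds at zero).
#' @param ridge Regularization strength lambda, > 0.
#' @return An `elsr_model` of primal form.
#' @seealso [elsr_fit()] for the data-frame interface, [fit_elsr_dual()].
#' @export
fit_elsr_primal <- function(X_mapped, y, ridge) {
  X <- as_feature_matrix(X_mapped)
  y <- as.numeric(y)
  if (anyNA(y) || !all(is.finite(y))) abort_bad_arg("`y` contains non-finite values.")
  if (nrow(X) != length(y)) abort_bad_arg("`X_mapped` and `y` sizes disagree.")
  check_scalar_number(ridge, "ridge", positive = TRUE)
  w <- drop(ridge_solve(crossprod(X), ridge, crossprod(X, y)))
  new_elsr_model(
    form = "primal", weights = w, ridge = ridge,
    n_train = nrow(X), mapped_dim = ncol(X)
  )
}

#' Fit a ridge classifier in the dual (kernel) form
#'
#' Solves for per-sample coefficients \eqn{\alpha = (\Omega + \lambda I)^{-1}
#' y}, where \eqn{\Omega} is the Gram matrix of the training rows under the
#' given kernel. Prediction at x is \eqn{\sum_i K(x, x_i)\,\alpha_i}, so the
#' model stores the training inputs. For lambda > 0 the system is positive
#' definite by the Mercer property.
#'
#' @param X_raw Numeric matrix of raw features (the kernel supplies the
#'   implicit mapping).
#' @inheritParams fit_elsr_primal
#' @param kernel A [kernel_spec()].
#' @return An `elsr_model` of dual form.
#' @export
fit_elsr_dual <- function(X_raw, y, ridge, kernel) {
  X <- as_feature_matrix(X_raw)
  y <- as.numeric(y)
  if (anyNA(y) || !all(is.finite(y))) abort_bad_arg("`y` contains non-finite values.")
  if (nrow(X) != length(y)) abort_bad_arg("`X_raw` and `y` sizes disagree.")
  check_scalar_number(ridge, "ridge", positive = TRUE)
  if (!inherits(kernel, "kernel_spec")) abort_bad_arg("`kernel` must be a kernel_spec.")
  Omega <- gram_matrix(kernel, X, X)
  alpha <- drop(ridge_solve(Omega, ridge, y))
  new_elsr_model(
    form = "dual", dual_coefs = alpha, ridge = ridge, kernel = kernel,
    train_inputs = X, n_train = nrow(X), mapped_dim = NA_integer_
  )
}

new_elsr_model <- function(form, ridge, n_train, mapped_dim,
                           weights = NULL, dual_coefs = NULL, kernel = NULL,
                           train_inputs = NULL, mapping = NULL, label = "label") {
  structure(
    list(
      form = form, weights = weights, dual_coefs = dual_coefs,
      kernel = kernel, train_inputs = train_inputs, mapping = mapping,
      ridge = ridge, n_train = n_train, mapped_dim = mapped_dim,
      label = label
    ),
    class = "elsr_model"
  )
}

#' Fit an ELSR classifier from a labeled data frame
#'
#' The high-level, data-frame-first interface. The model family is selected by
#' what you pass: a `mapping` (random-sigmoid or TSK) gives the corresponding
#' primal fit on mapped features; a `kernel` gives the dual (kernel ridge)
#' fit; neither gives a plain linear ridge classifier (the identity mapping,
#' i.e. regularized least-squares classification on the raw features).
#'
#' @param data Data frame with numeric feature columns and a label column in
#'   \{-1, +1\}.
#' @param mapping Optional `hidden_mapping` built by
#'   [random_sigmoid_mapping()] or [tsk_rule_base()].
#' @param kernel Optional [kernel_spec()]; mutually exclusive with `mapping`.
#' @param lambda Ridge penalty, > 0.
#' @param label Name of the label column.
#' @return An `elsr_model`; `predict()` on it returns a tibble of scores and
#'   labels, and it has [tidy()], [glance()] and [augment()] methods.
#' @examples
#' d <- generate_domain_pair(seed = 1)$source
#' fit <- elsr_fit(d, lambda = 0.1)
#' predict(fit, d)
#' glance(fit)
#' @export
elsr_fit <- function(data, mapping = NULL, kernel = NULL, lambda = 1,
                     label = "label") {
  if (!is.null(mapping) && !is.null(kernel)) {
    abort_bad_arg("supply at most one of `mapping` and `kernel`.")
  }
  parts <- split_labeled(data, label = label)
  if (!is.null(kernel)) {
    fit <- fit_elsr_dual(parts$X, parts$y, ridge = lambda, kernel = kernel)
  } else {
    Z <- if (is.null(mapping)) parts$X else apply_mapping(mapping, parts$X)
    fit <- fit_elsr_primal(Z, parts$y, ridge = lambda)
    fit$mapping <- mapping
  }
  fit$label <- label
  fit
}

#' Predict scores and labels from a fitted ELSR model
#'
#' Primal models score by \eqn{\rho(x)^\top w}; dual models by
#' \eqn{\sum_i K(x, x_i) \alpha_i}. The decision rule assigns +1 when the
#' score is >= 0 (ties go to +1) and -1 otherwise.
#'
#' @param object An `elsr_model`.
#' @param new_data Data frame or numeric matrix of features. For a primal
#'   model fitted through a hidden mapping, raw features are mapped with the
#'   stored mapping (or one supplied via `mapping`); pre-mapped matrices whose
#'   width already equals the weight vector are accepted as-is. A primal model
#'   given raw features of the wrong width and no mapping is an error.
#' @param mapping Optional mapping overriding the one stored at fit time.
#' @param ... Unused.
#' @return A tibble with columns `score` and `label`.
#' @export
predict.elsr_model <- function(object, new_data, mapping = NULL, ...) {
  X <- as_feature_matrix(new_data, label = object$label %||% "label")
  score <- elsr_score(object, X, mapping = mapping)
  tibble::tibble(score = score, label = score_to_label(score))
}

score_to_label <- function(score) ifelse(score >= 0, 1, -1)

elsr_score <- function(object, X, mapping = NULL) {
  if (object$form == "primal") {
    mapping <- mapping %||% object$mapping
    if (!is.null(mapping)) {
      X <- apply_mapping(mapping, X)
    }
    if (ncol(X) != length(object$weights)) {
      abort_bad_arg(
        "primal prediction needs the fit-time mapping (or pre-mapped features of matching width)."
      )
    }
    drop(X %*% object$weights)
  } else {
    if (ncol(X) != ncol(object$train_inputs)) {
      abort_bad_arg("`new_data` width does not match the training inputs.")
    }
    drop(gram_matrix(object$kernel, X, object$train_inputs) %*% object$dual_coefs)
  }
}

#' Choose between the primal and dual solver
#'
#' Implements the cost-model rule: the explicit (primal) solve costs on the
#' order of \eqn{d_\rho^3 + d_\rho^2 N} while the kernel (dual) solve costs
#' \eqn{N^3}, so the primal form is preferred when the mapped dimension does
#' not exceed the number of training rows, and the dual form otherwise — or
#' always when the mapping is implicit (kernel-only), since the mapped
#' dimension is then unknown.
#'
#' @param n_rows Number of training rows.
#' @param mapped_dim Mapped feature dimension, or `NULL`/`NA` when unknown.
#' @return `"primal"` or `"dual"`.
#' @export
choose_solver <- function(n_rows, mapped_dim = NULL) {
  check_count(n_rows, "n_rows")
  if (is.null(mapped_dim) || is.na(mapped_dim)) return("dual")
  if (mapped_dim <= n_rows) "primal" else "dual"
}

#' Training objective of the ELSR model
#'
#' Evaluates \eqn{\frac12\|Xw - y\|^2 + \frac\lambda2 \|w\|^2} at an arbitrary
#' weight vector; used for optimality diagnostics.
#'
#' @param X_mapped Mapped feature matrix.
#' @param y Label vector.
#' @param w Weight vector.
#' @param ridge Penalty lambda.
#' @return The scalar objective value.
#' @export
elsr_objective <- function(X_mapped, y, w, ridge) {
  r <- drop(X_mapped %*% w) - y
  0.5 * sum(r^2) + 0.5 * ridge * sum(w^2)
}

#' @export
print.elsr_model <- function(x, ...) {
  if (x$form == "primal") {
    cat(sprintf(
      "<ELSR model (primal): %d weights, lambda = %g, n_train = %d>\n",
      length(x$weights), x$ridge, x$n_train
    ))
  } else {
    cat(sprintf(
      "<ELSR model (dual, %s kernel): %d coefficients, lambda = %g>\n",
      x$kernel$family, length(x$dual_coefs), x$n_train
    ))
  }
  invisible(x)
}

#' @rdname elsr_fit
#' @param x An `elsr_model`.
#' @param ... Unused.
#' @method tidy elsr_model
#' @export
tidy.elsr_model <- function(x, ...) {
  if (x$form == "primal") {
    tibble::tibble(
      term = paste0("w", seq_along(x$weights)),
      estimate = unname(x$weights)
    )
  } else {
    tibble::tibble(
      term = paste0("alpha", seq_along(x$dual_coefs)),
      estimate = unname(x$dual_coefs)
    )
  }
}

#' @rdname elsr_fit
#' @method glance elsr_model
#' @export
glance.elsr_model <- function(x, ...) {
  tibble::tibble(
    form = x$form,
    n_train = x$n_train,
    mapped_dim = x$mapped_dim,
    ridge = x$ridge,
    kernel = if (is.null(x$kernel)) NA_character_ else x$kernel$family
  )
}

#' @rdname elsr_fit
#' @param newdata Data frame to score and bind predictions to.
#' @method augment elsr_model
#' @export
augment.elsr_model <- function(x, newdata, ...) {
  pred <- predict(x, newdata)
  dplyr::bind_cols(
    tibble::as_tibble(newdata),
    tibble::tibble(.score = pred$score, .pred_label = pred$label)
  )
}
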