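#' Fit the transfer classifier on explicitly mapped target features (primal)
#'
#' Solves the inductive-transfer objective
#' \eqn{\min_{w_t} \frac12\|X w_t - y\|^2 + \frac\lambda2\|w_t\|^2 +
#' \frac\beta2\|w_t - w_s\|^2}, whose closed form is
#' \eqn{w_t = (X^\top X + (\lambda+\beta) I)^{-1}(X^\top y + \beta w_s)}.
#' The source domain enters only through its fitted weight vector `w_s`
#' (never its raw data), so the source data stay private on this path.
#' `beta = 0` recovers the plain ELSR fit; `beta -> Inf` pins the target
#' weights to the source weights.
#'
#' @param X_mapped_t Target-domain mapped feature matrix.
#' @param y_t Target labels in \{-1, +1\}.
#' @param ridge Target ridge penalty lambda, > 0.
#' @param beta Transfer strength, >= 0.
#' @param w_s Source weight vector; its length must equal `ncol(X_mapped_t)`
#'   (both domains must share one hidden mapping).
#' @return An `elsr_tl_model` of primal form.
#' @seealso [elsr_tl_fit()] for the data-frame interface.
#' @export
fit_elsr_tl_primal <- function(X_mapped_t, y_t, ridge, beta, w_s) {
  X <- as_feature_matrix(X_mapped_t)
  y <- as.numeric(y_t)
  if (anyNA(y) || !all(is.finite(y))) abort_bad_arg("`y_t` contains non-finite values.")
  if (nrow(X) != length(y)) abort_bad_arg("`X_mapped_t` and `y_t` sizes disagree.")
  check_scalar_number(ridge, "ridge", positive = TRUE)
  check_scalar_number(beta, "beta", nonnegative = TRUE)
  w_s <- as.numeric(w_s)
  if (length(w_s) != ncol(X) || anyNA(w_s) || !all(is.finite(w_s))) {
    abort_bad_arg(
      "`w_s` length must equal ncol(X_mapped_t): source and target must share one mapping."
    )
  }
  w <- drop(ridge_solve(crossprod(X), ridge + beta, crossprod(X, y) + beta * w_s))
  new_elsr_tl_model(
    form = "primal", weights = w, ridge = ridge, beta = beta,
    n_train = nrow(X), mapped_dim = ncol(X)
  )
}

#' Fit the transfer classifier in the dual (kernel) form
#'
#' When the mapping is implicit, the source knowledge is carried by the source
#' dual coefficients \eqn{\alpha_s = (\Omega_s + \lambda_s I)^{-1} y_s} and the
#' source inputs. With \eqn{c = \lambda + \beta} and mixing factor
#' \eqn{g = \beta / c}, the target coefficients solve
#' \eqn{(\Omega_t + c I)\,\alpha_t = y_t - g\,\Omega_{t,s}\alpha_s}, and the
#' decision function is
#' \eqn{f(x) = g\,k_s(x)^\top \alpha_s + k_t(x)^\top \alpha_t}, where
#' \eqn{k_s, k_t} are kernel columns against source and target inputs. This is
#' the exact kernelization of the primal closed form via the push-through
#' identity \eqn{(X^\top X + cI)^{-1} = (I - X^\top(XX^\top + cI)^{-1}X)/c};
#' the equivalence is enforced by tests with a linear kernel. When `beta = 0`
#' the source block vanishes and the fit coincides with plain dual ELSR.
#'
#' @param X_t Target-domain raw feature matrix.
#' @param y_t Target labels.
#' @inheritParams fit_elsr_tl_primal
#' @param source A dual-form `elsr_model` fitted on the source domain with the
#'   same kernel (see [fit_elsr_dual()]); supplies \eqn{\alpha_s} and the
#'   source inputs.
#' @param kernel A [kernel_spec()]; must match the source model's kernel.
#' @return An `elsr_tl_model` of dual form.
#' @export
fit_elsr_tl_dual <- function(X_t, y_t, ridge, beta, source, kernel) {
  X <- as_feature_matrix(X_t)
  y <- as.numeric(y_t)
  if (anyNA(y) || !all(is.finite(y))) abort_bad_arg("`y_t` contains non-finite values.")
  if (nrow(X) != length(y)) abort_bad_arg("`X_t` and `y_t` sizes disagree.")
  check_scalar_number(ridge, "ridge", positive = TRUE)
  check_scalar_number(beta, "beta", nonnegative = TRUE)
  if (!inherits(source, "elsr_model") || source$form != "dual") {
    abort_bad_arg("`source` must be a dual-form elsr_model.")
  }
  if (!inherits(kernel, "kernel_spec")) abort_bad_arg("`kernel` must be a kernel_spec.")
  if (!identical(source$kernel$family, kernel$family) ||
      (kernel$family == "gaussian" && source$kernel$sigma != kernel$sigma)) {
    abort_bad_arg("source and target kernels differ: both domains must share one kernel.")
  }
  if (ncol(X) != ncol(source$train_inputs)) {
    abort_bad_arg("target and source feature widths differ.")
  }
  cc <- ridge + beta
  g <- beta / cc
  Omega_t <- gram_matrix(kernel, X, X)
  Omega_ts <- gram_matrix(kernel, X, source$train_inputs)
  rhs <- y - g * drop(Omega_ts %*% source$dual_coefs)
  alpha_t <- drop(ridge_solve(Omega_t, cc, rhs))
  new_elsr_tl_model(
    form = "dual", ridge = ridge, beta = beta,
    target_coefs = alpha_t, target_inputs = X,
    source_coefs = source$dual_coefs, source_inputs = source$train_inputs,
    mix = g, kernel = kernel, n_train = nrow(X), mapped_dim = NA_integer_
  )
}

new_elsr_tl_model <- function(form, ridge, beta, n_train, mapped_dim,
                              weights = NULL, target_coefs = NULL,
                              target_inputs = NULL, source_coefs = NULL,
                              source_inputs = NULL, mix = NULL, kernel = NULL,
                              mapping = NULL, label = "label") {
  structure(
    list(
      form = form, weights = weights,
      target_coefs = target_coefs, target_inputs = target_inputs,
      source_coefs = source_coefs, source_inputs = source_inputs,
      mix = mix, kernel = kernel, mapping = mapping,
      ridge = ridge, beta = beta, n_train = n_train, mapped_dim = mapped_dim,
      label = label
    ),
    class = "elsr_tl_model"
  )
}

#' Fit a transfer classifier from a labeled target data frame
#'
#' Data-frame-first interface to the transfer fit. The path is chosen by the
#' form of the source model: a primal source contributes only its weight
#' vector (the privacy-preserving path; target features are passed through the
#' same `mapping` the source was fitted with), while a dual source requires
#' its stored inputs and a matching `kernel`.
#'
#' @param data Target-domain data frame with feature columns and a label
#'   column in \{-1, +1\}.
#' @param source An `elsr_model` fitted on the source domain.
#' @param lambda Target ridge penalty, > 0.
#' @param beta Transfer strength, >= 0.
#' @param mapping Hidden mapping shared by both domains (primal path);
#'   defaults to the mapping stored in the source model.
#' @param label Name of the label column.
#' @return An `elsr_tl_model` with `predict()`, [tidy()] and [glance()]
#'   methods.
#' @examples
#' pair <- generate_domain_pair(seed = 3)
#' src <- elsr_fit(pair$source, lambda = 0.1)
#' fit <- elsr_tl_fit(pair$target_train, src, lambda = 0.1, beta = 10)
#' mean(predict(fit, pair$target_test)$label == pair$target_test$label)
#' @export
elsr_tl_fit <- function(data, source, lambda = 1, beta = 1, mapping = NULL,
                        label = "label") {
  if (!inherits(source, "elsr_model")) {
    abort_bad_arg("`source` must be a fitted elsr_model.")
  }
  parts <- split_labeled(data, label = label)
  if (source$form == "primal") {
    mapping <- mapping %||% source$mapping
    Z <- if (is.null(mapping)) parts$X else apply_mapping(mapping, parts$X)
    fit <- fit_elsr_tl_primal(Z, parts$y, ridge = lambda, beta = beta,
                              w_s = source$weights)
    fit$mapping <- mapping
  } else {
    fit <- fit_elsr_tl_dual(parts$X, parts$y, ridge = lambda, beta = beta,
                            source = source, kernel = source$kernel)
  }
  fit$label <- label
  fit
}

#' Predict from a fitted transfer model
#'
#' Primal models score by \eqn{\rho(x)^\top w_t}; dual models assemble the
#' score from the source and target kernel blocks,
#' \eqn{g\,k_s(x)^\top\alpha_s + k_t(x)^\top\alpha_t}. Labels threshold at
#' zero with ties to +1, as for [predict.elsr_model()].
#'
#' @param object An `elsr_tl_model`.
#' @param new_data Data frame or matrix of features.
#' @param mapping Optional mapping overriding the stored one (primal form).
#' @param ... Unused.
#' @return A tibble with columns `score` and `label`.
#' @export
predict.elsr_tl_model <- function(object, new_data, mapping = NULL, ...) {
  X <- as_feature_matrix(new_data, label = object$label %||% "label")
  if (object$form == "primal") {
    mapping <- mapping %||% object$mapping
    if (!is.null(mapping)) X <- apply_mapping(mapping, X)
    if (ncol(X) != length(object$weights)) {
      abort_bad_arg(
        "primal prediction needs the fit-time mapping (or pre-mapped features of matching width)."
      )
    }
    score <- drop(X %*% object$weights)
  } else {
    if (ncol(X) != ncol(object$target_inputs)) {
      abort_bad_arg("`new_data` width does not match the training inputs.")
    }
    k_s <- gram_matrix(object$kernel, X, object$source_inputs)
    k_t <- gram_matrix(object$kernel, X, object$target_inputs)
    score <- object$mix * drop(k_s %*% object$source_coefs) +
      drop(k_t %*% object$target_coefs)
  }
  tibble::tibble(score = score, label = score_to_label(score))
}

#' @export
print.elsr_tl_model <- function(x, ...) {
  if (x$form == "primal") {
    cat(sprintf(
      "<ELSR-TL model (primal): %d weights, lambda = %g, beta = %g>\n",
      length(x$weights), x$ridge, x$beta
    ))
  } else {
    cat(sprintf(
      "<ELSR-TL model (dual, %s kernel): %d target + %d source coefficients, lambda = %g, beta = %g>\n",
      x$kernel$family, length(x$target_coefs), length(x$source_coefs),
      x$ridge, x$beta
    ))
  }
  invisible(x)
}

#' @rdname elsr_tl_fit
#' @param x An `elsr_tl_model`.
#' @param ... Unused.
#' @method tidy elsr_tl_model
#' @export
tidy.elsr_tl_model <- function(x, ...) {
  if (x$form == "primal") {
    tibble::tibble(term = paste0("w", seq_along(x$weights)),
                   estimate = unname(x$weights))
  } else {
    dplyr::bind_rows(
      tibble::tibble(term = paste0("alpha_t", seq_along(x$target_coefs)),
                     estimate = unname(x$target_coefs)),
      tibble::tibble(term = paste0("alpha_s", seq_along(x$source_coefs)),
                     estimate = unname(x$source_coefs))
    )
  }
}

#' @rdname elsr_tl_fit
#' @method glance elsr_tl_model
#' @export
glance.elsr_tl_model <- function(x, ...) {
  tibble::tibble(
    form = x$form,
    n_train = x$n_train,
    mapped_dim = x$mapped_dim,
    ridge = x$ridge,
    beta = x$beta,
    kernel = if (is.null(x$kernel)) NA_character_ else x$kernel$family
  )
}
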