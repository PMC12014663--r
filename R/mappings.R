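#' Build a frozen random-sigmoid hidden mapping
#'
#' Constructs the neural-network instantiation of the hidden mapping
#' \eqn{\rho(x)}: a bank of `n_nodes` sigmoid units whose affine parameters
#' are drawn once, independently of any training data, and then frozen. Node
#' weights and offsets are i.i.d. uniform on \eqn{[-1, 1]}; the activation of
#' node \eqn{i} is \eqn{g(x) = 1 / (1 + \exp(-\kappa (a_i^\top x + b_i)))},
#' where `kappa` controls the sigmoid steepness. A linear model fitted on
#' these features is a randomized single-hidden-layer feedforward network.
#'
#' @param input_dim Number of input features (columns of the data the mapping
#'   will be applied to).
#' @param n_nodes Number of hidden nodes (the mapped dimension).
#' @param kappa Sigmoid steepness multiplier, > 0.
#' @param seed Integer seed; the same seed and shape always regenerate the
#'   identical node parameters.
#'
#' @return An object of class `rs_mapping` (also `hidden_mapping`) holding the
#'   node parameter matrix (one row per node: weights then offset), `kappa`,
#'   and the seed.
#' @seealso [apply_mapping()], [tsk_rule_base()]
#' @examples
#' m <- random_sigmoid_mapping(input_dim = 4, n_nodes = 50, kappa = 1, seed = 7)
#' Z <- apply_mapping(m, matrix(rnorm(20), 5, 4))
#' dim(Z) # 5 x 50
#' @export
random_sigmoid_mapping <- function(input_dim, n_nodes, kappa = 1, seed = 1L) {
  input_dim <- check_count(input_dim, "input_dim")
  n_nodes <- check_count(n_nodes, "n_nodes")
  check_scalar_number(kappa, "kappa", positive = TRUE)
  seed <- check_count(seed, "seed", min = 0L)
  node_params <- withr::with_seed(seed, {
    matrix(runif(n_nodes * (input_dim + 1L), -1, 1), nrow = n_nodes)
  })
  colnames(node_params) <- c(paste0("a", seq_len(input_dim)), "b")
  structure(
    list(
      input_dim = input_dim, n_nodes = n_nodes, kappa = kappa,
      node_params = node_params, seed = seed
    ),
    class = c("rs_mapping", "hidden_mapping")
  )
}

#' Build a TSK fuzzy-rule hidden mapping from data
#'
#' Constructs the antecedent part of a Takagi-Sugeno-Kang fuzzy system with
#' `n_rules` rules. Rule centers are obtained by seeded k-means clustering of
#' the feature rows; the Gaussian membership width of rule k in dimension i is
#' `width_scale` times the within-cluster standard deviation of that dimension
#' (falling back to the global per-dimension spread for clusters with fewer
#' than two members, and floored at 1e-6 so degenerate dimensions never divide
#' by zero downstream). The consequent (affine) parameters are not stored
#' here: they live in the weight vector fitted by [elsr_fit()] on the mapped
#' features.
#'
#' @param data Data frame of numeric features; a `label` column, if present,
#'   is ignored for clustering.
#' @param n_rules Number of fuzzy rules K, between 1 and `nrow(data)`.
#' @param width_scale Positive multiplier on the data-driven membership
#'   widths (the grid parameter often written tau).
#' @param seed Integer seed for the clustering initialization.
#' @param label Name of the label column to drop, default `"label"`.
#'
#' @return An object of class `tsk_rule_base` (also `hidden_mapping`) with
#'   `centers` (K x d) and `widths` (K x d, strictly positive).
#' @export
tsk_rule_base <- function(data, n_rules, width_scale = 1, seed = 1L, label = "label") {
  X <- as_feature_matrix(data, label = label)
  n_rules <- check_count(n_rules, "n_rules")
  check_scalar_number(width_scale, "width_scale", positive = TRUE)
  seed <- check_count(seed, "seed", min = 0L)
  if (n_rules > nrow(X)) {
    abort_bad_arg("`n_rules` cannot exceed the number of rows in `data`.")
  }
  width_floor <- 1e-6
  if (n_rules == 1L) {
    centers <- matrix(colMeans(X), nrow = 1L)
    assign <- rep(1L, nrow(X))
  } else if (n_rules == nrow(X)) {
    # one rule per row (kmeans requires k < n)
    centers <- X
    assign <- seq_len(nrow(X))
  } else {
    km <- withr::with_seed(seed, {
      kmeans(X, centers = n_rules, nstart = 10L, iter.max = 100L)
    })
    centers <- km$centers
    assign <- km$cluster
  }
  global_sd <- pmax(apply(X, 2L, sd), width_floor)
  widths <- matrix(NA_real_, n_rules, ncol(X))
  for (k in seq_len(n_rules)) {
    rows <- X[assign == k, , drop = FALSE]
    wk <- if (nrow(rows) >= 2L) apply(rows, 2L, sd) else global_sd
    wk[!is.finite(wk) | wk < width_floor] <- global_sd[!is.finite(wk) | wk < width_floor]
    widths[k, ] <- pmax(width_scale * pmax(wk, width_floor), width_floor)
  }
  dimnames(centers) <- NULL
  structure(
    list(
      n_rules = n_rules, centers = unname(as.matrix(centers)), widths = widths,
      width_scale = width_scale, seed = seed, input_dim = ncol(X)
    ),
    class = c("tsk_rule_base", "hidden_mapping")
  )
}

#' Kernel specification
#'
#' Describes the Mercer kernel used by the dual (kernel) instantiation.
#' The Gaussian family is \eqn{K(a, b) = \exp(-\|a-b\|^2 / (2\sigma^2))};
#' the linear family \eqn{K(a, b) = a^\top b} corresponds to the identity
#' hidden mapping and underpins the primal-dual equivalence checks.
#'
#' @param family `"gaussian"` or `"linear"`.
#' @param sigma Positive kernel width (Gaussian family only).
#' @return A `kernel_spec` object.
#' @export
kernel_spec <- function(family = c("gaussian", "linear"), sigma = 1) {
  family <- match.arg(family)
  if (family == "gaussian") check_scalar_number(sigma, "sigma", positive = TRUE)
  structure(list(family = family, sigma = sigma), class = "kernel_spec")
}

#' Gram matrix between two sets of rows
#'
#' @param spec A [kernel_spec()].
#' @param A,B Numeric matrices with the same number of columns; `B` defaults
#'   to `A`.
#' @return The `nrow(A)` x `nrow(B)` matrix of kernel evaluations.
#' @export
gram_matrix <- function(spec, A, B = A) {
  if (!inherits(spec, "kernel_spec")) abort_bad_arg("`spec` must be a kernel_spec.")
  A <- as_feature_matrix(A)
  B <- as_feature_matrix(B)
  if (ncol(A) != ncol(B)) {
    abort_bad_arg("`A` and `B` must have the same number of columns.")
  }
  if (spec$family == "linear") {
    return(tcrossprod(A, B))
  }
  # squared distances via the expansion ||a||^2 + ||b||^2 - 2 a'b, clipped at 0
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * spec$sigma^2))
}

#' Apply a hidden mapping to feature rows
#'
#' Maps raw features into the hidden space. For a random-sigmoid mapping the
#' output has one column per node, each the node's sigmoid activation. For a
#' TSK rule base, the firing level of rule k at x is the product of Gaussian
#' memberships over dimensions; firing levels are normalized to sum to one
#' across rules (computed in log space, so far-out inputs degrade gracefully
#' to the uniform 1/K rather than dividing by an underflowed zero), and the
#' output row concatenates, over rules, the normalized firing level times the
#' augmented input (1, x).
#'
#' @param mapping An `rs_mapping` or `tsk_rule_base`.
#' @param X Numeric matrix (or data frame; a `label` column is dropped) whose
#'   column count equals the mapping's input dimension.
#' @return A numeric matrix with `nrow(X)` rows; `n_nodes` columns for the
#'   random-sigmoid mapping, `n_rules * (d + 1)` for TSK.
#' @export
apply_mapping <- function(mapping, X) {
  UseMethod("apply_mapping")
}

#' @export
apply_mapping.rs_mapping <- function(mapping, X) {
  X <- as_feature_matrix(X)
  if (ncol(X) != mapping$input_dim) {
    abort_bad_arg("`X` column count does not match the mapping input dimension.")
  }
  a <- mapping$node_params[, seq_len(mapping$input_dim), drop = FALSE]
  b <- mapping$node_params[, mapping$input_dim + 1L]
  lin <- sweep(tcrossprod(X, a), 2L, b, "+")
  1 / (1 + exp(-mapping$kappa * lin))
}

#' @export
apply_mapping.tsk_rule_base <- function(mapping, X) {
  X <- as_feature_matrix(X)
  if (ncol(X) != mapping$input_dim) {
    abort_bad_arg("`X` column count does not match the rule-base input dimension.")
  }
  n <- nrow(X)
  K <- mapping$n_rules
  d <- ncol(X)
  # log firing levels: -sum_i (x_i - c_ki)^2 / (2 w_ki^2)
  logmu <- matrix(0, n, K)
  for (k in seq_len(K)) {
    dev <- sweep(X, 2L, mapping$centers[k, ], "-")
    logmu[, k] <- -rowSums(sweep(dev^2, 2L, 2 * mapping$widths[k, ]^2, "/"))
  }
  mx <- apply(logmu, 1L, max)
  w <- exp(logmu - mx)
  tot <- rowSums(w)
  mu_tilde <- w / tot
  bad <- !is.finite(tot) | tot == 0
  if (any(bad)) mu_tilde[bad, ] <- 1 / K
  Xe <- cbind(1, X)
  out <- matrix(0, n, K * (d + 1L))
  for (k in seq_len(K)) {
    out[, ((k - 1L) * (d + 1L) + 1L):(k * (d + 1L))] <- mu_tilde[, k] * Xe
  }
  out
}

#' Normalized TSK firing levels
#'
#' Returns the n x K matrix of normalized firing levels (each row sums to 1);
#' mainly useful for inspecting rule activation patterns.
#'
#' @inheritParams apply_mapping
#' @return Matrix of normalized firing levels.
#' @export
tsk_firing_levels <- function(mapping, X) {
  stopifnot(inherits(mapping, "tsk_rule_base"))
  X <- as_feature_matrix(X)
  Z <- apply_mapping(mapping, X)
  d1 <- mapping$input_dim + 1L
  # column 1 of each rule block is mu_tilde * 1
  Z[, seq(1L, by = d1, length.out = mapping$n_rules), drop = FALSE]
}

mapped_dim <- function(mapping) {
  if (inherits(mapping, "rs_mapping")) return(mapping$n_nodes)
  if (inherits(mapping, "tsk_rule_base")) {
    return(mapping$n_rules * (mapping$input_dim + 1L))
  }
  abort_bad_arg("unknown mapping type.")
}

#' @export
print.rs_mapping <- function(x, ...) {
  cat(sprintf(
    "<random-sigmoid mapping: %d inputs -> %d nodes, kappa = %g, seed = %d>\n",
    x$input_dim, x$n_nodes, x$kappa, x$seed
  ))
  invisible(x)
}

#' @export
print.tsk_rule_base <- function(x, ...) {
  cat(sprintf(
    "<TSK rule base: %d rules on %d inputs, width_scale = %g, seed = %d>\n",
    x$n_rules, x$input_dim, x$width_scale, x$seed
  ))
  invisible(x)
}

#' @export
print.kernel_spec <- function(x, ...) {
  if (x$family == "gaussian") {
    cat(sprintf("<gaussian kernel, sigma = %g>\n", x$sigma))
  } else {
    cat("<linear kernel>\n")
  }
  invisible(x)
}
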