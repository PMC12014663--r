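#' Classification accuracy and confusion counts
#'
#' Treats +1 as the positive class and computes
#' accuracy = (TP + TN) / (TP + TN + FP + FN).
#'
#' @param predicted,truth Equal-length vectors of labels in \{-1, +1\}.
#' @return A one-row tibble with columns `tp`, `tn`, `fp`, `fn`, `accuracy`.
#' @export
accuracy <- function(predicted, truth) {
  if (length(predicted) == 0L || length(predicted) != length(truth)) {
    abort_bad_arg("`predicted` and `truth` must be non-empty and equal length.")
  }
  predicted <- check_labels(predicted)
  truth <- check_labels(truth)
  tp <- sum(predicted == 1 & truth == 1)
  tn <- sum(predicted == -1 & truth == -1)
  fp <- sum(predicted == 1 & truth == -1)
  fn <- sum(predicted == -1 & truth == 1)
  tibble::tibble(tp = tp, tn = tn, fp = fp, fn = fn,
                 accuracy = (tp + tn) / length(truth))
}

#' Per-dataset ranks of competing methods
#'
#' Ranks methods within each dataset column: rank 1 is the highest accuracy,
#' and tied accuracies receive the average of the ranks they span (so ten
#' methods tied at the top each get (1 + ... + 10)/10 = 5.5).
#'
#' @param accuracy_table Data frame with a method identifier column and one
#'   numeric column per dataset, or a numeric matrix with methods as rows.
#' @param method_col Name of the identifier column (ignored for matrices).
#' @return A tibble of the same shape with accuracies replaced by ranks, plus
#'   `sum_rank` and `avg_rank` columns.
#' @export
rank_table <- function(accuracy_table, method_col = "method") {
  if (is.matrix(accuracy_table)) {
    methods <- rownames(accuracy_table) %||% paste0("method", seq_len(nrow(accuracy_table)))
    acc <- as.data.frame(accuracy_table)
    acc <- tibble::as_tibble(acc)
    acc <- dplyr::bind_cols(tibble::tibble(method = methods), acc)
    method_col <- "method"
  } else {
    acc <- tibble::as_tibble(accuracy_table)
  }
  if (!method_col %in% names(acc)) {
    abort_bad_arg(sprintf("`accuracy_table` has no '%s' column.", method_col))
  }
  datasets <- setdiff(names(acc), method_col)
  if (nrow(acc) < 2L || length(datasets) < 1L) {
    abort_bad_arg("need at least 2 methods and 1 dataset.")
  }
  vals <- as.matrix(acc[datasets])
  if (anyNA(vals) || !all(is.finite(vals))) {
    abort_bad_arg("`accuracy_table` contains non-finite entries.")
  }
  ranks <- apply(vals, 2L, function(col) rank(-col, ties.method = "average"))
  out <- dplyr::bind_cols(acc[method_col], tibble::as_tibble(as.data.frame(ranks)))
  out$sum_rank <- rowSums(ranks)
  out$avg_rank <- rowMeans(ranks)
  out
}

#' Friedman test statistic from rank sums
#'
#' Computes \eqn{Q = \frac{12}{k n (n+1)} \sum_i R_i^2 - 3 k (n + 1)} for `n`
#' methods compared over `k` datasets, with `R_i` the rank sum of method `i`,
#' and the upper-tail p-value of the chi-square law with `n - 1` degrees of
#' freedom.
#'
#' @param sum_ranks Vector of per-method rank sums.
#' @param n_datasets Number of datasets `k`.
#' @return A one-row tibble with `q_stat`, `p_value`, `n_methods`,
#'   `n_datasets`.
#' @export
friedman_statistic <- function(sum_ranks, n_datasets) {
  n <- length(sum_ranks)
  k <- check_count(n_datasets, "n_datasets")
  if (n < 2L || anyNA(sum_ranks) || !all(is.finite(sum_ranks))) {
    abort_bad_arg("`sum_ranks` must be finite with at least 2 entries.")
  }
  expected_total <- k * n * (n + 1) / 2
  if (abs(sum(sum_ranks) - expected_total) > 1e-8 * expected_total) {
    abort_bad_arg("rank sums do not conserve k * n * (n + 1) / 2.")
  }
  q <- 12 / (k * n * (n + 1)) * sum(sum_ranks^2) - 3 * k * (n + 1)
  tibble::tibble(
    q_stat = q,
    p_value = pchisq(q, df = n - 1, lower.tail = FALSE),
    n_methods = n, n_datasets = k
  )
}

#' Post-hoc z comparisons against the best-ranked method, with Holm stepping
#'
#' Compares every method's average rank with the best (lowest) average rank:
#' \eqn{z_i = (\bar R_i - \bar R_0) / SE} with
#' \eqn{SE = \sqrt{n (n + 1) / (6 k)}}, two-sided
#' \eqn{p_i = 2 (1 - \Phi(z_i))}. Comparisons are ordered by descending z and
#' tested step-down against Holm thresholds \eqn{\alpha / (m - i + 1)}: the
#' null is rejected while p <= threshold, and the first acceptance stops all
#' further rejections.
#'
#' @param avg_ranks Vector of average ranks.
#' @param n_datasets Number of datasets `k`.
#' @param methods Optional method names (default `method1`, ...).
#' @param best_index Index of the reference method; defaults to the minimum
#'   average rank, first in input order on ties.
#' @param alpha Family-wise significance level.
#' @return A tibble of the `length(avg_ranks) - 1` comparisons, ordered by
#'   descending z, with columns `method`, `avg_rank`, `z`, `p_value`, `holm`,
#'   `reject`.
#' @export
posthoc_comparisons <- function(avg_ranks, n_datasets, methods = NULL,
                                best_index = NULL, alpha = 0.05) {
  n <- length(avg_ranks)
  k <- check_count(n_datasets, "n_datasets")
  if (n < 2L || anyNA(avg_ranks) || !all(is.finite(avg_ranks))) {
    abort_bad_arg("`avg_ranks` must be finite with at least 2 entries.")
  }
  methods <- methods %||% paste0("method", seq_len(n))
  if (length(methods) != n) abort_bad_arg("`methods` length mismatch.")
  best_index <- best_index %||% which.min(avg_ranks)
  if (!is.numeric(best_index) || length(best_index) != 1L ||
      best_index < 1L || best_index > n) {
    abort_bad_arg("`best_index` is out of range.")
  }
  se <- sqrt(n * (n + 1) / (6 * k))
  out <- tibble::tibble(
    method = methods[-best_index],
    avg_rank = avg_ranks[-best_index],
    z = (avg_ranks[-best_index] - avg_ranks[best_index]) / se
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$z))
  m <- nrow(out)
  out$p_value <- 2 * pnorm(-abs(out$z))
  out$holm <- alpha / (m - seq_len(m) + 1)
  sig <- out$p_value <= out$holm
  stop_at <- match(FALSE, sig, nomatch = m + 1L)
  out$reject <- seq_len(m) < stop_at
  out
}

#' Full rank-based benchmark statistics
#'
#' Chains [rank_table()], [friedman_statistic()] and [posthoc_comparisons()]
#' on an accuracy table, anchoring the post-hoc comparisons on the method with
#' the minimum average rank (first in table order on ties).
#'
#' @inheritParams rank_table
#' @param alpha Family-wise significance level for the Holm step-down.
#' @return A `benchmark_stats` object with components `accuracy_table`,
#'   `rank_table`, `friedman` (one-row tibble), `posthoc` (tibble) and
#'   `best_method`; it has [tidy()], [glance()] and [autoplot()] methods.
#' @examples
#' stats <- benchmark_stats(mi_benchmark_accuracies())
#' glance(stats)
#' @export
benchmark_stats <- function(accuracy_table, method_col = "method", alpha = 0.05) {
  rt <- rank_table(accuracy_table, method_col = method_col)
  fr <- friedman_statistic(rt$sum_rank, n_datasets = ncol(rt) - 3L)
  best <- which.min(rt$avg_rank)
  ph <- posthoc_comparisons(
    rt$avg_rank, n_datasets = ncol(rt) - 3L,
    methods = rt[[method_col]], best_index = best, alpha = alpha
  )
  structure(
    list(
      accuracy_table = tibble::as_tibble(accuracy_table),
      rank_table = rt, friedman = fr, posthoc = ph,
      best_method = rt[[method_col]][best], alpha = alpha
    ),
    class = "benchmark_stats"
  )
}

#' @export
print.benchmark_stats <- function(x, ...) {
  cat(sprintf(
    "<benchmark: %d methods x %d datasets; best by average rank: %s>\n",
    x$friedman$n_methods, x$friedman$n_datasets, x$best_method
  ))
  cat(sprintf("Friedman Q = %.5g, p = %.6f\n", x$friedman$q_stat, x$friedman$p_value))
  print(x$posthoc)
  invisible(x)
}

#' @rdname benchmark_stats
#' @param x A `benchmark_stats` object.
#' @param ... Unused.
#' @method tidy benchmark_stats
#' @export
tidy.benchmark_stats <- function(x, ...) {
  x$posthoc
}

#' @rdname benchmark_stats
#' @method glance benchmark_stats
#' @export
glance.benchmark_stats <- function(x, ...) {
  tibble::tibble(
    q_stat = x$friedman$q_stat,
    p_value = x$friedman$p_value,
    n_methods = x$friedman$n_methods,
    n_datasets = x$friedman$n_datasets,
    best_method = x$best_method,
    n_rejected = sum(x$posthoc$reject)
  )
}

#' Grid search for ELSR hyperparameters by stratified cross-validation
#'
#' Exhaustively evaluates every combination in `grid` by seeded stratified
#' k-fold cross-validation on the training data and returns the best
#' combination (ties broken by grid order). Recognized grid names depend on
#' the family: `lambda` (all families), `n_nodes` and `kappa`
#' (random-sigmoid), `n_rules` and `width_scale` (TSK, with the rule base
#' re-clustered on each training fold), `sigma` (Gaussian kernel).
#'
#' @param data Labeled training data frame.
#' @param family One of `"linear"`, `"nn"`, `"tsk"`, `"kernel"`.
#' @param grid Named list of parameter vectors.
#' @param folds Number of cross-validation folds.
#' @param seed Integer seed controlling fold assignment and random mappings.
#' @param label Name of the label column.
#' @return A list with `best` (one-row tibble of parameters plus
#'   `cv_accuracy`) and `results` (one row per combination).
#' @export
elsr_grid_search <- function(data, family = c("linear", "nn", "tsk", "kernel"),
                             grid = list(lambda = 10^(-6:6)), folds = 5,
                             seed = 1L, label = "label") {
  family <- match.arg(family)
  folds <- check_count(folds, "folds", min = 2L)
  seed <- check_count(seed, "seed", min = 0L)
  parts <- split_labeled(data, label = label)
  fold_id <- stratified_folds(parts$y, folds, seed)
  allowed <- switch(family,
    linear = "lambda",
    nn = c("lambda", "n_nodes", "kappa"),
    tsk = c("lambda", "n_rules", "width_scale"),
    kernel = c("lambda", "sigma")
  )
  if (length(grid) == 0L || !all(names(grid) %in% allowed)) {
    abort_bad_arg(sprintf(
      "grid names for family '%s' must be drawn from: %s.",
      family, paste(allowed, collapse = ", ")
    ))
  }
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  cv_one <- function(params) {
    accs <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      X_tr <- parts$X[tr, , drop = FALSE]
      y_tr <- parts$y[tr]
      X_va <- parts$X[!tr, , drop = FALSE]
      lambda <- params$lambda %||% 1
      if (family == "kernel") {
        fit <- fit_elsr_dual(X_tr, y_tr, ridge = lambda,
                             kernel = kernel_spec("gaussian", sigma = params$sigma %||% 1))
        pred <- elsr_score(fit, X_va)
      } else {
        mapping <- switch(family,
          linear = NULL,
          nn = random_sigmoid_mapping(ncol(X_tr), params$n_nodes %||% 50,
                                      kappa = params$kappa %||% 1, seed = seed),
          tsk = {
            k <- min(params$n_rules %||% 5, nrow(X_tr))
            tsk_rule_base(as.data.frame(X_tr), n_rules = k,
                          width_scale = params$width_scale %||% 1, seed = seed)
          }
        )
        Z_tr <- if (is.null(mapping)) X_tr else apply_mapping(mapping, X_tr)
        Z_va <- if (is.null(mapping)) X_va else apply_mapping(mapping, X_va)
        fit <- fit_elsr_primal(Z_tr, y_tr, ridge = lambda)
        pred <- drop(Z_va %*% fit$weights)
      }
      mean(score_to_label(pred) == parts$y[!tr])
    }, numeric(1))
    mean(accs)
  }
  results <- combos
  results$cv_accuracy <- vapply(seq_len(nrow(combos)), function(i) {
    cv_one(as.list(combos[i, , drop = FALSE]))
  }, numeric(1))
  results <- tibble::as_tibble(results)
  best <- results[which.max(results$cv_accuracy), , drop = FALSE]
  list(best = best, results = results, family = family)
}
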