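#' Default configuration for the synthetic transfer benchmark
#'
#' Builds the configuration consumed by [run_experiment()]: the twenty
#' source/target size regimes of [mi_transfer_configurations()] mapped onto
#' the synthetic domain-pair generator (six features, class separation 2,
#' unit noise, moderate shift 0.5), a linear-family model with a lambda grid,
#' and a beta grid for the transfer fit.
#'
#' @param seed Global seed.
#' @param configurations Data frame of generator settings, one row per
#'   configuration; missing generator columns are filled with the defaults of
#'   [generate_domain_pair()].
#' @param lambda_grid,beta_grid,folds Model-selection settings.
#' @param family Base model family for [elsr_grid_search()].
#' @return A named list accepted by [run_experiment()].
#' @export
default_experiment_config <- function(seed = 1L,
                                      configurations = mi_transfer_configurations(),
                                      lambda_grid = 10^(-3:3),
                                      beta_grid = 10^(-3:3),
                                      folds = 5,
                                      family = "linear") {
  list(
    seed = seed,
    configurations = configurations,
    model = list(family = family, grid = list(lambda = lambda_grid), folds = folds),
    transfer = list(beta_grid = beta_grid)
  )
}

validate_config <- function(config) {
  allowed <- c("seed", "configurations", "model", "transfer", "alpha", "verbose")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown) > 0L) {
    abort_bad_arg(sprintf("unknown config keys: %s.", paste(unknown, collapse = ", ")))
  }
  if (!is.null(config$model)) {
    unknown <- setdiff(names(config$model), c("family", "grid", "folds"))
    if (length(unknown) > 0L) {
      abort_bad_arg(sprintf("unknown model keys: %s.", paste(unknown, collapse = ", ")))
    }
  }
  if (!is.null(config$transfer)) {
    unknown <- setdiff(names(config$transfer), "beta_grid")
    if (length(unknown) > 0L) {
      abort_bad_arg(sprintf("unknown transfer keys: %s.", paste(unknown, collapse = ", ")))
    }
  }
  config
}

config_generator_args <- function(row, seed) {
  defaults <- formals(generate_domain_pair)
  keep <- intersect(names(row), setdiff(names(defaults), "seed"))
  args <- as.list(row[keep])
  args$seed <- seed
  args
}

#' Run the full synthetic transfer experiment
#'
#' For every configuration row: generates a source/target domain pair, tunes
#' lambda on the target training set by stratified cross-validation, fits the
#' target-only classifier, fits a source-domain model, selects the transfer
#' strength beta from the configured grid by cross-validation on the target
#' training set, and evaluates both models on the held-out target test set.
#' The per-configuration solver choice ([choose_solver()]) is recorded. The
#' whole run is deterministic for a fixed seed (configuration `i` uses seed
#' `seed + config_id`).
#'
#' @param config Configuration list as produced by
#'   [default_experiment_config()]; unknown keys are rejected.
#' @param out_dir Optional directory; when given, per-configuration accuracies
#'   (`accuracies.csv`), the aggregate comparison (`summary.csv`) and a
#'   manifest (`manifest.json`: config, seed, package and R versions) are
#'   written there.
#' @param verbose Print per-configuration progress lines.
#' @return An `elsr_experiment` list: `results` (tibble, one row per
#'   configuration x method), `summary` (mean accuracy per method), `config`.
#' @export
run_experiment <- function(config = default_experiment_config(), out_dir = NULL,
                           verbose = FALSE) {
  config <- validate_config(config)
  seed <- check_count(config$seed %||% 1L, "seed", min = 0L)
  confs <- tibble::as_tibble(config$configurations %||% mi_transfer_configurations())
  if (!"config_id" %in% names(confs)) confs$config_id <- seq_len(nrow(confs))
  model <- modifyList(
    list(family = "linear", grid = list(lambda = 10^(-3:3)), folds = 5),
    config$model %||% list()
  )
  beta_grid <- (config$transfer %||% list())$beta_grid %||% 10^(-3:3)

  one_config <- function(i) {
    row <- as.list(confs[i, ])
    cfg_seed <- seed + row$config_id
    pair <- do.call(generate_domain_pair, config_generator_args(row, cfg_seed))

    tuned <- elsr_grid_search(pair$target_train, family = model$family,
                              grid = model$grid, folds = model$folds,
                              seed = cfg_seed)
    lambda <- tuned$best$lambda %||% 1
    d <- ncol(pair$target_train) - 1L
    solver <- choose_solver(nrow(pair$target_train), d)

    fit_t <- elsr_fit(pair$target_train, lambda = lambda)
    acc_t <- accuracy(predict(fit_t, pair$target_test)$label,
                      pair$target_test$label)$accuracy

    tuned_s <- elsr_grid_search(pair$source, family = model$family,
                                grid = model$grid, folds = model$folds,
                                seed = cfg_seed)
    lambda_s <- tuned_s$best$lambda %||% 1
    fit_s <- elsr_fit(pair$source, lambda = lambda_s)

    beta <- select_beta_cv(pair$target_train, fit_s, lambda, beta_grid,
                           folds = model$folds, seed = cfg_seed)
    fit_tl <- elsr_tl_fit(pair$target_train, fit_s, lambda = lambda, beta = beta)
    acc_tl <- accuracy(predict(fit_tl, pair$target_test)$label,
                       pair$target_test$label)$accuracy
    if (verbose) {
      message(sprintf(
        "config %d: n_t = %d, solver = %s, lambda = %g, beta = %g, acc %0.3f -> %0.3f",
        row$config_id, nrow(pair$target_train), solver, lambda, beta, acc_t, acc_tl
      ))
    }
    tibble::tibble(
      config_id = row$config_id,
      n_source = nrow(pair$source),
      n_target_train = nrow(pair$target_train),
      n_target_test = nrow(pair$target_test),
      solver = solver,
      method = c("elsr", "elsr_tl"),
      lambda = c(lambda, lambda),
      beta = c(NA_real_, beta),
      test_accuracy = c(acc_t, acc_tl)
    )
  }
  results <- dplyr::bind_rows(lapply(seq_len(nrow(confs)), one_config))
  summary <- dplyr::summarise(
    dplyr::group_by(results, .data$method),
    mean_accuracy = mean(.data$test_accuracy),
    n_configs = dplyr::n(),
    .groups = "drop"
  )
  out <- structure(
    list(results = results, summary = summary, config = config, seed = seed),
    class = "elsr_experiment"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(results, file.path(out_dir, "accuracies.csv"), row.names = FALSE)
    utils::write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
    manifest <- list(
      seed = seed,
      config = config[setdiff(names(config), "configurations")],
      n_configurations = nrow(confs),
      package = as.character(utils::packageVersion("elsrtl")),
      r_version = R.version.string
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

# Pick beta by stratified CV on the target training set; the source model is
# held fixed (it does not depend on target folds). Ties break to the smaller
# beta.
select_beta_cv <- function(target_train, source_fit, lambda, beta_grid,
                           folds = 5, seed = 1L) {
  parts <- split_labeled(target_train)
  folds <- min(folds, min(table(parts$y)))
  if (folds < 2L) return(beta_grid[1L])
  fold_id <- stratified_folds(parts$y, folds, seed)
  cv_acc <- vapply(beta_grid, function(beta) {
    accs <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      dtr <- target_train[tr, , drop = FALSE]
      dva <- target_train[!tr, , drop = FALSE]
      fit <- elsr_tl_fit(dtr, source_fit, lambda = lambda, beta = beta)
      mean(predict(fit, dva)$label == parts$y[!tr])
    }, numeric(1))
    mean(accs)
  }, numeric(1))
  beta_grid[which.max(cv_acc)]
}

#' @export
print.elsr_experiment <- function(x, ...) {
  cat(sprintf("<transfer experiment: %d configurations, seed = %d>\n",
              length(unique(x$results$config_id)), x$seed))
  print(x$summary)
  invisible(x)
}

#' One-parameter sensitivity sweep
#'
#' Varies exactly one tunable — the number of fuzzy rules, the membership
#' width scale, lambda, or beta — while holding the others fixed, on a fixed
#' seeded domain pair, and records the target-test accuracy (and the fitted
#' weight norm) at each grid value. The base model is the TSK instantiation
#' with the rule base clustered on the source domain and shared by both
#' domains.
#'
#' @param axis One of `"n_rules"`, `"width_scale"`, `"lambda"`, `"beta"`
#'   (exactly one).
#' @param values Grid of values for the swept parameter.
#' @param pair A `domain_pair`; defaults to [generate_domain_pair()] under
#'   `seed`.
#' @param fixed Named list overriding the defaults of the non-swept
#'   parameters (`n_rules = 5`, `width_scale = 1`, `lambda = 1`, `beta = 1`).
#' @param seed Integer seed.
#' @return An `elsr_sweep` tibble with columns `parameter`, `value`,
#'   `accuracy`, `weight_norm` (one row per grid value).
#' @export
sweep_parameter <- function(axis, values, pair = NULL, fixed = list(),
                            seed = 1L) {
  choices <- c("n_rules", "width_scale", "lambda", "beta")
  if (length(axis) != 1L || !axis %in% choices) {
    abort_bad_arg(sprintf("`axis` must be exactly one of: %s.",
                          paste(choices, collapse = ", ")))
  }
  if (axis %in% names(fixed)) {
    abort_bad_arg("the swept `axis` cannot also appear in `fixed`.")
  }
  if (length(values) < 1L) abort_bad_arg("`values` must be non-empty.")
  seed <- check_count(seed, "seed", min = 0L)
  pair <- pair %||% generate_domain_pair(seed = seed)
  params <- modifyList(list(n_rules = 5, width_scale = 1, lambda = 1, beta = 1),
                       fixed)
  rows <- lapply(values, function(v) {
    p <- params
    p[[axis]] <- v
    mapping <- tsk_rule_base(pair$source, n_rules = p$n_rules,
                             width_scale = p$width_scale, seed = seed)
    src <- elsr_fit(pair$source, mapping = mapping, lambda = p$lambda)
    fit <- elsr_tl_fit(pair$target_train, src, lambda = p$lambda, beta = p$beta)
    acc <- accuracy(predict(fit, pair$target_test)$label,
                    pair$target_test$label)$accuracy
    tibble::tibble(parameter = axis, value = v, accuracy = acc,
                   weight_norm = sqrt(sum(fit$weights^2)))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("elsr_sweep", class(out))
  out
}
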