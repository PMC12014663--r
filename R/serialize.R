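# JSON (de)serialization for mappings, kernels and fitted models, plus the
# delimited-text interfaces for feature tables and trial sets. Numbers are
# written with digits = NA (full precision), so a reloaded model reproduces
# its decision function exactly.

pack_matrix <- function(m) {
  if (is.null(m)) return(NULL)
  list(nrow = nrow(m), ncol = ncol(m), data = as.vector(m))
}

unpack_matrix <- function(p) {
  if (is.null(p)) return(NULL)
  matrix(as.numeric(p$data), nrow = p$nrow, ncol = p$ncol)
}

#' Serialize a mapping or fitted model to JSON
#'
#' Writes every parameter (and, for data-dependent objects, the seed and any
#' stored training inputs) needed for an exact reload. The inverse is
#' [elsr_deserialize()].
#'
#' @param x A `rs_mapping`, `tsk_rule_base`, `kernel_spec`,
#'   `spatial_filter_bank`, `elsr_model` or `elsr_tl_model`.
#' @param path Optional file path; when given the JSON is written there and
#'   the path returned invisibly, otherwise the JSON string is returned.
#' @return JSON string, or the path invisibly.
#' @export
elsr_serialize <- function(x, path = NULL) {
  payload <- serialize_payload(x)
  # 17 significant digits: doubles round-trip bit-exactly
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = I(17), null = "null")
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path)
  invisible(path)
}

serialize_payload <- function(x) {
  if (inherits(x, "rs_mapping")) {
    list(type = "rs_mapping", input_dim = x$input_dim, n_nodes = x$n_nodes,
         kappa = x$kappa, seed = x$seed, node_params = pack_matrix(x$node_params))
  } else if (inherits(x, "tsk_rule_base")) {
    list(type = "tsk_rule_base", n_rules = x$n_rules, input_dim = x$input_dim,
         width_scale = x$width_scale, seed = x$seed,
         centers = pack_matrix(x$centers), widths = pack_matrix(x$widths))
  } else if (inherits(x, "kernel_spec")) {
    list(type = "kernel_spec", family = x$family, sigma = x$sigma)
  } else if (inherits(x, "spatial_filter_bank")) {
    list(type = "spatial_filter_bank", tikhonov_alpha = x$tikhonov_alpha,
         filters = pack_matrix(x$filters))
  } else if (inherits(x, "elsr_model")) {
    list(
      type = "elsr_model", form = x$form, ridge = x$ridge,
      n_train = x$n_train, mapped_dim = x$mapped_dim, label = x$label,
      weights = x$weights, dual_coefs = x$dual_coefs,
      kernel = if (is.null(x$kernel)) NULL else serialize_payload(x$kernel),
      train_inputs = pack_matrix(x$train_inputs),
      mapping = if (is.null(x$mapping)) NULL else serialize_payload(x$mapping)
    )
  } else if (inherits(x, "elsr_tl_model")) {
    list(
      type = "elsr_tl_model", form = x$form, ridge = x$ridge, beta = x$beta,
      mix = x$mix, n_train = x$n_train, mapped_dim = x$mapped_dim,
      label = x$label, weights = x$weights,
      target_coefs = x$target_coefs, source_coefs = x$source_coefs,
      target_inputs = pack_matrix(x$target_inputs),
      source_inputs = pack_matrix(x$source_inputs),
      kernel = if (is.null(x$kernel)) NULL else serialize_payload(x$kernel),
      mapping = if (is.null(x$mapping)) NULL else serialize_payload(x$mapping)
    )
  } else {
    abort_bad_arg("don't know how to serialize this object.")
  }
}

#' Reload a serialized mapping or model
#'
#' @param input A file path to, or the literal string of, JSON written by
#'   [elsr_serialize()].
#' @return The reconstructed object.
#' @export
elsr_deserialize <- function(input) {
  if (length(input) == 1L && !grepl("^\\s*\\{", input) && file.exists(input)) {
    input <- paste(readLines(input, warn = FALSE), collapse = "\n")
  }
  payload <- jsonlite::fromJSON(input, simplifyVector = TRUE)
  deserialize_payload(payload)
}

deserialize_payload <- function(p) {
  switch(p$type,
    rs_mapping = {
      m <- random_sigmoid_mapping(p$input_dim, p$n_nodes, p$kappa, p$seed)
      m$node_params <- unpack_matrix(p$node_params)
      colnames(m$node_params) <- c(paste0("a", seq_len(p$input_dim)), "b")
      m
    },
    tsk_rule_base = structure(
      list(
        n_rules = p$n_rules, centers = unpack_matrix(p$centers),
        widths = unpack_matrix(p$widths), width_scale = p$width_scale,
        seed = p$seed, input_dim = p$input_dim
      ),
      class = c("tsk_rule_base", "hidden_mapping")
    ),
    kernel_spec = kernel_spec(p$family, sigma = p$sigma %||% 1),
    spatial_filter_bank = spatial_filter_bank(
      unpack_matrix(p$filters), tikhonov_alpha = p$tikhonov_alpha
    ),
    elsr_model = new_elsr_model(
      form = p$form, ridge = p$ridge, n_train = p$n_train,
      mapped_dim = p$mapped_dim %||% NA_integer_,
      weights = if (is.null(p$weights)) NULL else as.numeric(p$weights),
      dual_coefs = if (is.null(p$dual_coefs)) NULL else as.numeric(p$dual_coefs),
      kernel = if (is.null(p$kernel)) NULL else deserialize_payload(p$kernel),
      train_inputs = unpack_matrix(p$train_inputs),
      mapping = if (is.null(p$mapping)) NULL else deserialize_payload(p$mapping),
      label = p$label %||% "label"
    ),
    elsr_tl_model = new_elsr_tl_model(
      form = p$form, ridge = p$ridge, beta = p$beta,
      n_train = p$n_train, mapped_dim = p$mapped_dim %||% NA_integer_,
      weights = if (is.null(p$weights)) NULL else as.numeric(p$weights),
      target_coefs = if (is.null(p$target_coefs)) NULL else as.numeric(p$target_coefs),
      target_inputs = unpack_matrix(p$target_inputs),
      source_coefs = if (is.null(p$source_coefs)) NULL else as.numeric(p$source_coefs),
      source_inputs = unpack_matrix(p$source_inputs),
      mix = p$mix,
      kernel = if (is.null(p$kernel)) NULL else deserialize_payload(p$kernel),
      mapping = if (is.null(p$mapping)) NULL else deserialize_payload(p$mapping),
      label = p$label %||% "label"
    ),
    abort_bad_arg(sprintf("unknown serialized type '%s'.", p$type))
  )
}

#' Read and write labeled feature tables as CSV
#'
#' The on-disk convention is a header row, numeric feature columns, and a
#' final `label` column in \{-1, +1\}.
#'
#' @param path File path.
#' @param label Name of the label column.
#' @return `read_labeled_csv()` returns a tibble; `write_labeled_csv()`
#'   returns the path invisibly.
#' @export
read_labeled_csv <- function(path, label = "label") {
  out <- tibble::as_tibble(utils::read.csv(path))
  split_labeled(out, label = label) # validates
  out
}

#' @rdname read_labeled_csv
#' @param data Labeled data frame to write.
#' @export
write_labeled_csv <- function(data, path, label = "label") {
  split_labeled(data, label = label)
  data <- dplyr::relocate(tibble::as_tibble(data), dplyr::all_of(label),
                          .after = dplyr::last_col())
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' Read and write trial sets as per-trial CSV matrices with a JSON sidecar
#'
#' Each trial is stored as `trial_<i>.csv` (channels x samples, no header);
#' `meta.json` carries the sampling rate and the label vector.
#'
#' @param dir Directory path.
#' @return `read_trial_dir()` returns a [trial_set()]; `write_trial_dir()`
#'   returns the directory invisibly.
#' @export
read_trial_dir <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"))
  n <- length(meta$labels)
  first <- as.matrix(utils::read.csv(file.path(dir, "trial_1.csv"), header = FALSE))
  dat <- array(NA_real_, dim = c(n, nrow(first), ncol(first)))
  dat[1L, , ] <- first
  for (i in seq_len(n)[-1L]) {
    dat[i, , ] <- as.matrix(
      utils::read.csv(file.path(dir, sprintf("trial_%d.csv", i)), header = FALSE)
    )
  }
  trial_set(dat, fs = meta$fs, labels = meta$labels)
}

#' @rdname read_trial_dir
#' @param trials A [trial_set()] to write.
#' @export
write_trial_dir <- function(trials, dir) {
  stopifnot(inherits(trials, "trial_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- dim(trials$data)[1L]
  for (i in seq_len(n)) {
    utils::write.table(
      trials$data[i, , , drop = TRUE], file.path(dir, sprintf("trial_%d.csv", i)),
      sep = ",", row.names = FALSE, col.names = FALSE
    )
  }
  jsonlite::write_json(
    list(fs = trials$fs, labels = trials$labels),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Adapter seam for BCI Competition III Data Set IVa recordings
#'
#' Loading the competition's Matlab recordings is deliberately out of scope.
#' This function documents the expected adapter contract: convert one
#' subject's recording into the [trial_set()] layout (trials x channels x
#' samples at the recording's sampling rate, labels recoded to \{-1, +1\})
#' and hand it to [mi_feature_pipeline()]. Calling it raises an error
#' pointing at this contract.
#'
#' @param path Path to a subject recording.
#' @param ... Ignored.
#' @export
read_bci_iva <- function(path, ...) {
  abort(
    paste(
      "No loader for BCI Competition IVa recordings is bundled.",
      "Convert the recording to a trials x channels x samples array and",
      "construct a trial_set(data, fs, labels) with labels in {-1, +1};",
      "write_trial_dir()/read_trial_dir() define the on-disk layout."
    ),
    class = "elsrtl_not_implemented"
  )
}
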