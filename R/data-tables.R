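#' Published benchmark accuracies on the BCI Competition IVa subjects
#'
#' Mean classification accuracies of twelve classifiers (seven single-domain
#' methods, two reference transfer methods, and the three transfer variants of
#' the extended least-squares family) on the five subjects (aa, al, av, aw,
#' ay) of BCI Competition III Data Set IVa, as reported in the originating
#' benchmark study. For the five transfer methods the entry is the average
#' over the four possible source subjects with the given target. These values
#' are the input to the rank-based statistical chain: [rank_table()],
#' [friedman_statistic()] and [posthoc_comparisons()].
#'
#' @return A 12 x 6 tibble: a `method` column and one accuracy column per
#'   subject.
#' @seealso [benchmark_stats()], [mi_transfer_configurations()]
#' @export
mi_benchmark_accuracies <- function() {
  tibble::tribble(
    ~method,          ~aa,    ~al,    ~av,    ~aw,    ~ay,
    "LSR",            0.6673, 1.0000, 0.5416, 0.7122, 0.7019,
    "kNN",            0.5982, 1.0000, 0.5663, 0.7277, 0.7302,
    "SVM",            0.6518, 0.9821, 0.5561, 0.7143, 0.7698,
    "NB",             0.6696, 1.0000, 0.5510, 0.7009, 0.5873,
    "ELSR(NN)",       0.6664, 1.0000, 0.5612, 0.7188, 0.7143,
    "ELSR(TSK)",      0.6693, 1.0000, 0.5658, 0.7366, 0.7063,
    "ELSR(Ker)",      0.6708, 1.0000, 0.5508, 0.7054, 0.7262,
    "Au-SVM",         0.6583, 1.0000, 0.5725, 0.7359, 0.7838,
    "Tr-Adaboost",    0.6630, 0.9955, 0.5561, 0.7389, 0.7460,
    "ELSR-TL(NN)",    0.7320, 1.0000, 0.5840, 0.7939, 0.8277,
    "ELSR-TL(TSK)",   0.7332, 1.0000, 0.5935, 0.7907, 0.8433,
    "ELSR-TL(Ker)",   0.7352, 1.0000, 0.5887, 0.7929, 0.8380
  )
}

#' Source/target configurations of the cross-subject benchmark
#'
#' The twenty subject-to-subject transfer configurations: each of the five
#' subjects serves as target once per remaining subject as source. All source
#' domains contribute 280 labeled trials; target training sizes shrink from
#' 168 (aa) down to 28 (ay), with the remainder of the 280 trials held out for
#' testing. Used as the descriptor for the synthetic benchmark in
#' [run_experiment()].
#'
#' @return A 20-row tibble with columns `config_id`, `source_subject`,
#'   `target_subject`, `n_source`, `n_target_train`, `n_target_test`.
#' @export
mi_transfer_configurations <- function() {
  targets <- tibble::tribble(
    ~target_subject, ~n_target_train, ~n_target_test,
    "aa", 168, 112,
    "al", 224, 56,
    "av", 86, 196,
    "aw", 56, 224,
    "ay", 28, 252
  )
  subjects <- c("aa", "al", "av", "aw", "ay")
  out <- dplyr::bind_rows(lapply(seq_len(nrow(targets)), function(i) {
    tgt <- targets$target_subject[i]
    tibble::tibble(
      source_subject = setdiff(subjects, tgt),
      target_subject = tgt,
      n_source = 280,
      n_target_train = targets$n_target_train[i],
      n_target_test = targets$n_target_test[i]
    )
  }))
  dplyr::bind_cols(tibble::tibble(config_id = seq_len(nrow(out))), out)
}
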