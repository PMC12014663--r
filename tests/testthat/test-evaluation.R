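test_that("accuracy counts the confusion cells", {
  expect_equal(accuracy(c(1, -1, 1), c(1, -1, 1))$accuracy, 1)
  expect_equal(accuracy(c(1, -1), c(-1, 1))$accuracy, 0)

  # (TP, TN, FP, FN) = (3, 2, 1, 2)
  truth <- c(1, 1, 1, -1, -1, -1, 1, 1)
  pred <- c(1, 1, 1, -1, -1, 1, -1, -1)
  a <- accuracy(pred, truth)
  expect_equal(unlist(a[c("tp", "tn", "fp", "fn")], use.names = FALSE),
               c(3, 2, 1, 2))
  expect_equal(a$accuracy, 0.625)

  expect_error(accuracy(numeric(0), numeric(0)), class = "elsrtl_invalid_argument")
  expect_error(accuracy(c(1, 0), c(1, 1)), class = "elsrtl_invalid_argument")
})

test_that("rank tables average ties and conserve rank sums", {
  rt <- rank_table(mi_benchmark_accuracies())

  # frozen per-dataset ranks recomputed from the printed accuracies
  expect_equal(rt$aa, c(7, 12, 11, 5, 8, 6, 4, 10, 9, 3, 2, 1))
  expect_equal(rt$al, c(5.5, 5.5, 12, 5.5, 5.5, 5.5, 5.5, 5.5, 11, 5.5, 5.5, 5.5))

  # every column sums to n (n + 1) / 2
  n <- nrow(rt)
  for (col in c("aa", "al", "av", "aw", "ay")) {
    expect_equal(sum(rt[[col]]), n * (n + 1) / 2)
  }

  # full tie: every method identical on every dataset
  tied <- tibble::tibble(method = letters[1:4], d1 = rep(0.5, 4), d2 = rep(0.9, 4))
  rt_tied <- rank_table(tied)
  expect_equal(rt_tied$d1, rep(2.5, 4))
  expect_equal(rt_tied$avg_rank, rep(2.5, 4))

  bad <- tibble::tibble(method = c("a", "b"), d1 = c(0.1, NA))
  expect_error(rank_table(bad), class = "elsrtl_invalid_argument")
  expect_error(rank_table(tied[1, ]), class = "elsrtl_invalid_argument")
})

test_that("the Friedman statistic matches hand arithmetic and edge cases", {
  # equal rank sums give Q = 0
  fr0 <- friedman_statistic(rep(2 * 3, 3), n_datasets = 3)
  expect_equal(fr0$q_stat, 0)
  expect_equal(fr0$p_value, 1)

  # 3 methods x 2 datasets, hand-set ranks (1,2,3) and (1,3,2):
  # sums (2,5,5); Q = 12/(2*3*4)*(4+25+25) - 3*2*4 = 27 - 24 = 3
  fr <- friedman_statistic(c(2, 5, 5), n_datasets = 2)
  expect_equal(fr$q_stat, 3, tolerance = 1e-12)
  expect_equal(fr$p_value, pchisq(3, 2, lower.tail = FALSE))

  expect_error(friedman_statistic(c(1, 2, 3), n_datasets = 2),
               class = "elsrtl_invalid_argument")
})

test_that("post-hoc z, Holm thresholds and step-down decisions are exact", {
  rt <- rank_table(mi_benchmark_accuracies())
  ph <- posthoc_comparisons(rt$avg_rank, n_datasets = 5, methods = rt$method)
  expect_equal(nrow(ph), 11)

  # SE = sqrt(n (n+1) / (6k)) with n = 12, k = 5
  z_lsr <- ph$z[ph$method == "LSR"]
  expect_equal(round(z_lsr, 6), 2.894291)

  # an equal-average-rank method compares at z = 0, p = 1
  z_ker <- ph$z[ph$method == "ELSR-TL(Ker)"]
  expect_equal(z_ker, 0)
  expect_equal(ph$p_value[ph$method == "ELSR-TL(Ker)"], 1)

  # Holm thresholds alpha / (m - i + 1) down the z-sorted list
  expect_equal(ph$holm[1:4], 0.05 / c(11, 10, 9, 8), tolerance = 1e-9)
  expect_equal(round(ph$holm[1:4], 6), c(0.004545, 0.005, 0.005556, 0.00625))

  # step-down: rejections stop at the first acceptance
  expect_true(all(ph$reject[1:3]))
  expect_false(any(ph$reject[4:11]))

  expect_error(posthoc_comparisons(rt$avg_rank, 5, best_index = 99),
               class = "elsrtl_invalid_argument")
})

test_that("benchmark_stats chains the table into the test statistics", {
  st <- benchmark_stats(mi_benchmark_accuracies())
  expect_equal(st$best_method, "ELSR-TL(TSK)") # first in order on the 2.5 tie
  gl <- glance(st)
  expect_equal(gl$n_methods, 12L)
  expect_equal(gl$n_rejected, 3L)
  expect_s3_class(tidy(st), "tbl_df")
  expect_s3_class(autoplot(st), "ggplot")
})

test_that("grid search is exhaustive, deterministic and returns grid members", {
  d <- separable_data(n = 60, d = 3, gap = 2, seed = 61)

  single <- elsr_grid_search(d, family = "linear", grid = list(lambda = 0.5),
                             folds = 3, seed = 1)
  expect_equal(single$best$lambda, 0.5)

  gs <- elsr_grid_search(d, family = "linear",
                         grid = list(lambda = c(1e-3, 1e3)), folds = 5, seed = 2)
  expect_true(gs$best$lambda %in% c(1e-3, 1e3))
  # selection agrees with explicit evaluation of both candidates
  expect_equal(gs$best$cv_accuracy, max(gs$results$cv_accuracy))
  gs2 <- elsr_grid_search(d, family = "linear",
                          grid = list(lambda = c(1e-3, 1e3)), folds = 5, seed = 2)
  expect_identical(gs$results, gs2$results)

  tsk <- elsr_grid_search(d, family = "tsk",
                          grid = list(lambda = c(0.1, 10), n_rules = c(2, 4)),
                          folds = 3, seed = 3)
  expect_equal(nrow(tsk$results), 4)
  expect_true(tsk$best$n_rules %in% c(2, 4))

  expect_error(elsr_grid_search(d, family = "linear",
                                grid = list(sigma = 1)),
               class = "elsrtl_invalid_argument")
  expect_error(elsr_grid_search(d[1:6, ], family = "linear",
                                grid = list(lambda = 1), folds = 5),
               class = "elsrtl_invalid_argument")
})
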