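test_that("beta = 0 reduces the transfer fit to plain ELSR", {
  X <- random_matrix(14, 4, seed = 41)
  y <- rep_len(c(1, -1), 14)
  w_s <- rnorm(4)
  plain <- fit_elsr_primal(X, y, ridge = 0.8)
  tl <- fit_elsr_tl_primal(X, y, ridge = 0.8, beta = 0, w_s = w_s)
  expect_equal(tl$weights, plain$weights, tolerance = 1e-12)

  # dual path
  Xs <- random_matrix(10, 4, seed = 42)
  ys <- rep_len(c(1, -1), 10)
  k <- kernel_spec("gaussian", sigma = 1.5)
  src <- fit_elsr_dual(Xs, ys, ridge = 0.6, kernel = k)
  tl_d <- fit_elsr_tl_dual(X, y, ridge = 0.8, beta = 0, source = src, kernel = k)
  plain_d <- fit_elsr_dual(X, y, ridge = 0.8, kernel = k)
  Xq <- random_matrix(7, 4, seed = 43)
  expect_equal(predict(tl_d, Xq)$score, predict(plain_d, Xq)$score,
               tolerance = 1e-10)
})

test_that("large beta pins the target weights to the source weights", {
  X <- random_matrix(12, 4, seed = 44)
  y <- rep_len(c(1, -1), 12)
  w_s <- rnorm(4)
  tl <- fit_elsr_tl_primal(X, y, ridge = 1, beta = 1e9, w_s = w_s)
  expect_lte(max(abs(tl$weights - w_s)) / (1 + max(abs(w_s))), 1e-6)
})

test_that("the primal transfer solve matches an independent dense oracle", {
  X <- random_matrix(10, 4, seed = 45)
  y <- rep_len(c(1, -1), 10)
  w_s <- withr::with_seed(46, rnorm(4))
  tl <- fit_elsr_tl_primal(X, y, ridge = 0.5, beta = 2, w_s = w_s)
  w_oracle <- solve(t(X) %*% X + (0.5 + 2) * diag(4), t(X) %*% y + 2 * w_s)
  expect_equal(tl$weights, drop(w_oracle), tolerance = 1e-10)
})

test_that("dual transfer predictions equal the primal fit under a linear kernel", {
  Xs <- random_matrix(12, 3, seed = 47)
  ys <- rep_len(c(1, -1), 12)
  Xt <- random_matrix(6, 3, seed = 48)
  yt <- rep_len(c(1, -1), 6)
  lin <- kernel_spec("linear")

  src_primal <- fit_elsr_primal(Xs, ys, ridge = 0.7)
  tl_primal <- fit_elsr_tl_primal(Xt, yt, ridge = 0.4, beta = 1.5,
                                  w_s = src_primal$weights)
  src_dual <- fit_elsr_dual(Xs, ys, ridge = 0.7, kernel = lin)
  tl_dual <- fit_elsr_tl_dual(Xt, yt, ridge = 0.4, beta = 1.5,
                              source = src_dual, kernel = lin)
  Xq <- random_matrix(15, 3, seed = 49)
  expect_equal(predict(tl_primal, Xq)$score, predict(tl_dual, Xq)$score,
               tolerance = 1e-8)
})

test_that("with the target duplicated as source, huge beta recovers the source fit", {
  X <- random_matrix(16, 3, seed = 50)
  y <- rep_len(c(1, -1), 16)
  k <- kernel_spec("gaussian", sigma = 2)
  src <- fit_elsr_dual(X, y, ridge = 0.9, kernel = k)
  tl <- fit_elsr_tl_dual(X, y, ridge = 0.9, beta = 1e9, source = src, kernel = k)
  Xq <- random_matrix(25, 3, seed = 51)
  expect_lte(max(abs(predict(tl, Xq)$score - predict(src, Xq)$score)), 1e-4)
})

test_that("distance to the source weights is non-increasing in beta", {
  X <- random_matrix(20, 5, seed = 52)
  y <- rep_len(c(1, -1), 20)
  w_s <- withr::with_seed(53, rnorm(5))
  dist <- vapply(10^seq(-3, 6), function(b) {
    sqrt(sum((fit_elsr_tl_primal(X, y, ridge = 1, beta = b, w_s = w_s)$weights - w_s)^2))
  }, numeric(1))
  expect_true(all(diff(dist) <= 1e-10))
})

test_that("mapping and kernel mismatches across domains are rejected", {
  X <- random_matrix(8, 3)
  y <- rep_len(c(1, -1), 8)
  expect_error(fit_elsr_tl_primal(X, y, ridge = 1, beta = 1, w_s = rnorm(5)),
               class = "elsrtl_invalid_argument")
  src <- fit_elsr_dual(random_matrix(6, 3, seed = 2), rep_len(c(1, -1), 6),
                       ridge = 1, kernel = kernel_spec("gaussian", sigma = 1))
  expect_error(
    fit_elsr_tl_dual(X, y, ridge = 1, beta = 1, source = src,
                     kernel = kernel_spec("gaussian", sigma = 2)),
    class = "elsrtl_invalid_argument"
  )
  src_p <- fit_elsr_primal(random_matrix(6, 3), rep_len(c(1, -1), 6), ridge = 1)
  expect_error(
    fit_elsr_tl_dual(X, y, ridge = 1, beta = 1, source = src_p,
                     kernel = kernel_spec("linear")),
    class = "elsrtl_invalid_argument"
  )
})

test_that("the primal path consumes only source weights, never source rows", {
  pair <- generate_domain_pair(n_source = 60, n_target_train = 20,
                               n_target_test = 40, seed = 54)
  src <- elsr_fit(pair$source, lambda = 0.5)
  # strip everything from the source model except its weight vector
  src_private <- src
  src_private$train_inputs <- NULL
  fit <- elsr_tl_fit(pair$target_train, src_private, lambda = 0.5, beta = 2)
  expect_s3_class(fit, "elsr_tl_model")
  expect_equal(fit$form, "primal")
  expect_null(fit$source_inputs)
})

test_that("a zero-weight primal model predicts +1 everywhere at score 0", {
  X <- random_matrix(5, 3)
  y <- rep_len(c(1, -1), 5)
  tl <- fit_elsr_tl_primal(X, y, ridge = 1, beta = 0, w_s = rep(0, 3))
  tl$weights <- rep(0, 3)
  pred <- predict(tl, random_matrix(6, 3, seed = 3))
  expect_equal(pred$score, rep(0, 6))
  expect_equal(pred$label, rep(1, 6))
})

test_that("transfer batch prediction equals row-wise prediction", {
  pair <- generate_domain_pair(n_source = 40, n_target_train = 16,
                               n_target_test = 20, seed = 55)
  src <- elsr_fit(pair$source, kernel = kernel_spec("gaussian", sigma = 2),
                  lambda = 0.5)
  fit <- elsr_tl_fit(pair$target_train, src, lambda = 0.5, beta = 3)
  X <- as.matrix(pair$target_test[paste0("x", 1:6)])[1:8, ]
  batch <- predict(fit, X)$score
  single <- vapply(seq_len(8), function(i) {
    predict(fit, X[i, , drop = FALSE])$score
  }, numeric(1))
  expect_equal(batch, single, tolerance = 1e-12)
})

test_that("transfer tidiers report both coefficient blocks", {
  pair <- generate_domain_pair(n_source = 40, n_target_train = 16,
                               n_target_test = 20, seed = 56)
  src <- elsr_fit(pair$source, kernel = kernel_spec("gaussian", sigma = 2),
                  lambda = 0.5)
  fit <- elsr_tl_fit(pair$target_train, src, lambda = 0.5, beta = 3)
  td <- tidy(fit)
  expect_equal(nrow(td), 16 + 40)
  gl <- glance(fit)
  expect_equal(gl$beta, 3)
  expect_equal(gl$form, "dual")
})
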