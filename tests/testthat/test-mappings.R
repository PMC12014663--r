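test_that("random-sigmoid mappings are seed-reproducible and bounded", {
  m1 <- random_sigmoid_mapping(4, 50, kappa = 1, seed = 7)
  m2 <- random_sigmoid_mapping(4, 50, kappa = 1, seed = 7)
  expect_identical(m1$node_params, m2$node_params)
  expect_false(identical(
    m1$node_params,
    random_sigmoid_mapping(4, 50, kappa = 1, seed = 8)$node_params
  ))

  X <- random_matrix(20, 4, seed = 2)
  Z <- apply_mapping(m1, X)
  expect_equal(dim(Z), c(20L, 50L))
  expect_true(all(Z > 0 & Z < 1))
  # saturating inputs stay finite and within the closed unit interval
  Zbig <- apply_mapping(m1, X * 1e4)
  expect_true(all(is.finite(Zbig) & Zbig >= 0 & Zbig <= 1))
})

test_that("sigmoid activation matches its closed form", {
  m <- random_sigmoid_mapping(2, 1, kappa = 2, seed = 1)
  m$node_params[1, ] <- c(1, 0, 0) # a = (1, 0), b = 0
  z <- apply_mapping(m, matrix(c(0.5, 9), 1, 2))
  expect_equal(drop(z), 1 / (1 + exp(-1)), tolerance = 1e-12)
})

test_that("invalid mapping arguments are rejected", {
  expect_error(random_sigmoid_mapping(0, 10), class = "elsrtl_invalid_argument")
  expect_error(random_sigmoid_mapping(3, 10, kappa = -1),
               class = "elsrtl_invalid_argument")
  m <- random_sigmoid_mapping(3, 10)
  expect_error(apply_mapping(m, random_matrix(5, 4)),
               class = "elsrtl_invalid_argument")
})

test_that("TSK rule bases cluster deterministically", {
  d <- random_labeled(30, 3, seed = 4)
  r1 <- tsk_rule_base(d, n_rules = 4, seed = 11)
  r2 <- tsk_rule_base(d, n_rules = 4, seed = 11)
  expect_identical(r1$centers, r2$centers)
  expect_identical(r1$widths, r2$widths)
  expect_true(all(r1$widths > 0))

  one <- tsk_rule_base(d, n_rules = 1)
  expect_equal(drop(one$centers), unname(colMeans(as.matrix(d[paste0("x", 1:3)]))),
               tolerance = 1e-12)

  expect_error(tsk_rule_base(d, n_rules = 31), class = "elsrtl_invalid_argument")
})

test_that("two-cluster rule base recovers well-separated cloud means", {
  withr::with_seed(9, {
    A <- matrix(rnorm(100, sd = 0.3), 50, 2) + 5
    B <- matrix(rnorm(100, sd = 0.3), 50, 2) - 5
  })
  d <- tibble::as_tibble(as.data.frame(rbind(A, B)))
  names(d) <- c("x1", "x2")
  d$label <- rep(c(1, -1), each = 50)
  rb <- tsk_rule_base(d, n_rules = 2, seed = 3)
  centers <- rb$centers[order(rb$centers[, 1]), ]
  expect_equal(centers[1, ], colMeans(B), tolerance = 0.2, ignore_attr = TRUE)
  expect_equal(centers[2, ], colMeans(A), tolerance = 0.2, ignore_attr = TRUE)
})

test_that("degenerate (zero-spread) dimensions hit the width floor, not zero", {
  d <- tibble::tibble(x1 = rnorm(10), x2 = rep(1, 10), label = rep_len(c(1, -1), 10))
  rb <- tsk_rule_base(d, n_rules = 2, seed = 1)
  expect_true(all(rb$widths >= 1e-6))
  Z <- apply_mapping(rb, as.matrix(d[c("x1", "x2")]))
  expect_true(all(is.finite(Z)))
})

test_that("TSK features follow the normalized firing-level construction", {
  # K = 1: trivially normalized, output row is (1, x)
  d <- random_labeled(10, 3, seed = 5)
  rb1 <- tsk_rule_base(d, n_rules = 1)
  X <- random_matrix(4, 3, seed = 6)
  expect_equal(apply_mapping(rb1, X), cbind(1, X), tolerance = 1e-12)

  # hand-built K = 2, d = 1 case: centers 0 and 2, widths 1, x = 1
  rb2 <- tsk_rule_base(tibble::tibble(x1 = c(0, 2), label = c(1, -1)), n_rules = 2)
  rb2$centers <- matrix(c(0, 2), 2, 1)
  rb2$widths <- matrix(1, 2, 1)
  row <- drop(apply_mapping(rb2, matrix(1)))
  expect_equal(row, c(0.5, 0.5, 0.5, 0.5), tolerance = 1e-12)
})

test_that("normalized firing levels sum to one for all K, even far from data", {
  d <- random_labeled(40, 2, seed = 8)
  for (K in c(1, 2, 5, 10)) {
    rb <- tsk_rule_base(d, n_rules = K, seed = 2)
    X <- rbind(random_matrix(20, 2, seed = K), matrix(c(1e6, -1e6), 1, 2))
    mu <- tsk_firing_levels(rb, X)
    expect_equal(rowSums(mu), rep(1, nrow(X)), tolerance = 1e-12)
    expect_true(all(is.finite(apply_mapping(rb, X))))
  }
})

test_that("Gaussian Gram matrices satisfy the Mercer properties", {
  spec <- kernel_spec("gaussian", sigma = 1.3)
  A <- random_matrix(15, 4, seed = 10)
  G <- gram_matrix(spec, A)
  expect_equal(diag(G), rep(1, 15), tolerance = 1e-12)
  expect_equal(G, t(G), tolerance = 1e-12)
  expect_gte(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values), -1e-10)

  # scalar evaluation of the stated formula
  g <- gram_matrix(kernel_spec("gaussian", sigma = 1),
                   matrix(c(0, 0), 1), matrix(c(1, 1), 1))
  expect_equal(drop(g), exp(-1), tolerance = 1e-12)

  # linear family is the plain inner product
  B <- random_matrix(7, 4, seed = 11)
  expect_equal(gram_matrix(kernel_spec("linear"), A, B), tcrossprod(A, B))

  expect_error(gram_matrix(spec, A, random_matrix(5, 3)),
               class = "elsrtl_invalid_argument")
  expect_error(kernel_spec("gaussian", sigma = 0), class = "elsrtl_invalid_argument")
})
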