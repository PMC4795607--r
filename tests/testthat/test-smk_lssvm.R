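test_that("multikernel evaluates its closed-form special cases", {
  kc0 <- kernel_config(eta = 0)
  expect_equal(multikernel(c(1, 2), c(1, 2), kc0), 1)        # RBF at zero distance
  kc1 <- kernel_config(eta = 1, poly_exponent = 1, poly_offset = 1)
  expect_equal(multikernel(c(1, 0), c(1, 0), kc1), 2)
  kc <- kernel_config(eta = 0.4, poly_exponent = 0.25, poly_offset = 1,
                      rbf_sigma = 1)
  expect_equal(multikernel(rep(0, 5), rep(0, 5), kc), 1)
  expect_error(multikernel(1:3, 1:2), "dimension")
  # negative base with fractional exponent is clamped with a warning
  expect_warning(v <- multikernel(c(2, 0), c(-2, 0), kc1_frac <- kernel_config(
    eta = 1, poly_exponent = 0.25, poly_offset = 1)), "clamped")
  expect_equal(v, 0)
})

test_that("Gram matrix matches elementwise kernel evaluation", {
  x <- with_test_seed(1, matrix(rnorm(18), 6, 3))
  kc <- kernel_config(rbf_sigma = 1.3, poly_exponent = 2)
  g <- multikernel_gram(x, x, kc)
  for (i in 1:6) for (j in 1:6) {
    expect_equal(g[i, j], multikernel(x[i, ], x[j, ], kc), tolerance = 1e-12)
  }
  expect_equal(g, t(g), tolerance = 1e-12)
})

test_that("class penalties follow the labels and balance the classes", {
  expect_equal(class_penalties(c(1, -1, 1), s_plus = 2, s_minus = 1),
               c(2, 1, 2))
  expect_equal(class_penalties(c(1, -1), s_plus = 1, s_minus = 1), c(1, 1))
  y <- c(rep(1, 9), rep(-1, 3))
  ct <- class_penalties(y)   # class-balanced default n / (2 n_pm)
  expect_equal(mean(ct), 1)
  expect_equal(unique(ct[y == 1]), 12 / 18)
  expect_equal(unique(ct[y == -1]), 12 / 6)
  expect_error(class_penalties(c(0, 1)), "labels")
})

test_that("bordered system solution satisfies its KKT identities", {
  x <- with_test_seed(2, matrix(rnorm(20), 10, 2))
  y <- rep(c(-1, 1), 5)
  kc <- kernel_config(rbf_sigma = 2)
  k <- multikernel_gram(x, x, kc)
  ct <- class_penalties(y, 1.7, 0.6)
  sol <- solve_lssvm(k, y, r = 8.4, penalties = ct)
  expect_lt(sol$residual, 1e-8)
  expect_lt(abs(sum(sol$a)), 1e-8)
  # explicit residual of the bordered equations
  expect_equal(drop(k %*% sol$a) + sol$a / (8.4 * ct) + sol$b, y,
               tolerance = 1e-8)
  # uniform penalties reduce to the unweighted system
  sol_u <- solve_lssvm(k, y, r = 2, penalties = rep(1, 10))
  m <- rbind(c(0, rep(1, 10)), cbind(1, k + diag(0.5, 10)))
  expect_equal(drop(m %*% c(sol_u$b, sol_u$a)), c(0, y), tolerance = 1e-8)
})

test_that("LS-SVM decisions match the primal quadratic minimizer", {
  # linear-equivalent kernel eta = 1, d = 1: explicit feature map (1, x)
  x <- matrix(c(-2, -1.5, -1, 1, 1.5, 2.2,
                0.3, -0.4, 0.5, 0.2, -0.1, 0.4), 6, 2)
  y <- c(-1, -1, -1, 1, 1, 1)
  kc <- kernel_config(eta = 1, poly_exponent = 1, poly_offset = 1,
                      rbf_sigma = 1)
  k <- multikernel_gram(x, x, kc)
  for (ct in list(rep(1, 6), class_penalties(y, 2, 0.5))) {
    sol <- solve_lssvm(k, y, r = 8.4, penalties = ct)
    dec <- drop(k %*% sol$a) + sol$b
    oracle <- primal_lssvm_oracle(x, y, r = 8.4, ct = ct)
    expect_equal(dec, oracle$decision, tolerance = 1e-6)
    expect_identical(sign(dec), y)
  }
})

test_that("pivoted sparsification reconstructs and matches the Gram-Schmidt oracle", {
  # RBF-only kernel: guaranteed PSD (the clamped fractional polynomial is not)
  x <- with_test_seed(3, matrix(rnorm(36), 12, 3))
  k <- multikernel_gram(x, x, kernel_config(eta = 0, rbf_sigma = 1.5))
  # full rank is exact
  sg <- schmidt_sparsify(k, 12)
  expect_lt(max(abs(k - sg$L %*% t(sg$L))), 1e-8)
  # first pivot is the largest original diagonal
  sg1 <- schmidt_sparsify(k + diag(0.3 * (1:12 == 5)), 1)
  expect_identical(sg1$pivots, 5L)
  # step-by-step equivalence with explicit pivoted Gram-Schmidt
  oracle <- gram_schmidt_pivot_oracle(k, 8)
  sg8 <- schmidt_sparsify(k, 8)
  expect_identical(sg8$pivots, oracle$pivots)
  expect_equal(sg8$residual_trace, oracle$residual_trace, tolerance = 1e-8)
  # residual norm non-increasing in gamma
  fro <- vapply(1:12, function(g) {
    s <- schmidt_sparsify(k, g)
    sqrt(sum((k - s$L %*% t(s$L))^2))
  }, numeric(1))
  expect_true(all(diff(fro) <= 1e-10))
  expect_error(schmidt_sparsify(matrix(c(1, 2, 3, 4), 2), 2), "symmetric")
  expect_error(schmidt_sparsify(k, 0), "gamma")
})

test_that("sparsification degrades to PSD error on indefinite input", {
  m <- diag(c(1, 1, -0.5))
  expect_error(schmidt_sparsify(m, 3), "positive semidefinite")
})

test_that("full-rank training reduces to the dense weighted LS-SVM", {
  set.seed(10)
  x <- rbind(matrix(rnorm(40, -2), 20, 2), matrix(rnorm(40, 2), 20, 2))
  y <- rep(c(-1, 1), each = 20)
  kc <- kernel_config(eta = 0, rbf_sigma = 2)
  tc <- train_config(gamma_rank = 40, standardize = FALSE)
  model <- smk_train(x, y, kc, tc)
  expect_identical(sort(model$support_index), 1:40)
  k <- multikernel_gram(x, x, kc)
  dense <- solve_lssvm(k, y, tc$r, class_penalties(y))
  dec_dense <- drop(k %*% dense$a) + dense$b
  dec_model <- predict(model, x)$decision
  expect_equal(dec_model, dec_dense, tolerance = 1e-6)
})

test_that("separable blobs are classified perfectly with a reduced support set", {
  set.seed(11)
  x <- rbind(matrix(rnorm(100, -3), 50, 2), matrix(rnorm(100, 3), 50, 2))
  y <- rep(c(-1, 1), each = 50)
  model <- smk_train(x, y, kernel_config(eta = 0, rbf_sigma = 2),
                     train_config(gamma_rank = 20))
  expect_identical(model$gamma, 20L)
  expect_equal(evaluate_error(model, x, y), 0)
  pred <- predict(model, x)
  expect_identical(pred$label, ifelse(pred$decision >= 0, 1, -1))
  # decision continuity under tiny perturbation
  d0 <- predict(model, x[1, ])$decision
  d1 <- predict(model, x[1, ] + 1e-9)$decision
  expect_lt(abs(d1 - d0), 1e-6)
})

test_that("class-balanced penalties help minority recall on imbalanced data", {
  recalls <- vapply(1:10, function(s) {
    set.seed(100 + s)
    x <- rbind(matrix(rnorm(180, 0, 1.3), 90, 2),
               matrix(rnorm(20, 1.8, 1.3), 10, 2))
    y <- c(rep(-1, 90), rep(1, 10))
    balanced <- smk_train(x, y, kernel_config(eta = 0, rbf_sigma = 1.5),
                          train_config(gamma_rank = 100))
    uniform <- smk_train(x, y, kernel_config(eta = 0, rbf_sigma = 1.5),
                         train_config(gamma_rank = 100, s_plus = 1,
                                      s_minus = 1))
    rb <- mean(predict(balanced, x[y == 1, ])$label == 1)
    ru <- mean(predict(uniform, x[y == 1, ])$label == 1)
    rb - ru
  }, numeric(1))
  expect_gte(median(recalls), 0)
  expect_gt(mean(recalls > 0), 0.4)
})

test_that("classification error counts mismatches in percent", {
  model <- list()
  class(model) <- "constant_clf"
  assign("predict.constant_clf",
         function(object, x, ...) data.frame(decision = 1,
                                             label = rep(1, nrow(x))),
         envir = globalenv())
  on.exit(rm("predict.constant_clf", envir = globalenv()))
  x <- matrix(0, 4, 2)
  expect_equal(evaluate_error(model, x, c(1, 1, 1, 1)), 0)
  expect_equal(evaluate_error(model, x, c(-1, -1, -1, -1)), 100)
  expect_equal(evaluate_error(model, x, c(1, 1, -1, -1)), 50)
  expect_error(evaluate_error(model, x, numeric(0)), "empty")
})

test_that("training rejects degenerate input", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(smk_train(x, rep(1, 10)), "both classes")
  expect_error(smk_train(x, c(rep(1, 5), rep(0, 5))), "both classes|labels")
})
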