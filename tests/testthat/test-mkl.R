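test_that("the RBF kernel over dissimilarity coordinates is exact", {
  expect_equal(rbf_from_dissimilarity(rbind(c(1, 2)), rbind(c(1, 2)), 3),
               matrix(1, 1, 1))
  expect_equal(rbf_from_dissimilarity(rbind(c(0, 0)), rbind(c(1, 0)), 1)[1, 1],
               exp(-1))
  set.seed(3)
  X <- matrix(rnorm(18), 6)
  K <- rbf_from_dissimilarity(X, X, 0.7)
  expect_equal(K, t(K))
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)
  expect_error(rbf_from_dissimilarity(X, X, 0), "positive")
  expect_error(rbf_from_dissimilarity(X, matrix(1, 2, 5), 1), "mismatch")
})

test_that("kernel specs enforce the simplex and shape bounds", {
  expect_silent(kernel_spec(c(0.5, 0.5), c(1, 100)))
  expect_error(kernel_spec(c(0.6, 0.6), c(1, 1)), "sum to 1")
  expect_error(kernel_spec(c(1.2, -0.2), c(1, 1)), "\\[0, 1\\]")
  expect_error(kernel_spec(c(0.5, 0.5), c(0, 1)), "\\(0, 100\\]")
  expect_error(kernel_spec(c(0.5, 0.5), c(1, 101)), "\\(0, 100\\]")
})

test_that("one-hot weights reproduce the single kernel bit-identically", {
  set.seed(4)
  mats <- lapply(1:3, function(i) {
    X <- matrix(rnorm(24), 8)
    rbf_from_dissimilarity(X, X, 0.5)
  })
  spec <- kernel_spec(c(0, 1, 0), c(1, 0.5, 1))
  expect_identical(combine_kernels(mats, spec), mats[[2]])
})

test_that("convex combinations stay PSD, bounded and linear in the weights", {
  set.seed(5)
  mats <- lapply(1:2, function(i) {
    X <- matrix(rnorm(16), 8)
    rbf_from_dissimilarity(X, X, 1)
  })
  K <- combine_kernels(mats, kernel_spec(c(0.3, 0.7), c(1, 1)))
  expect_true(all(K >= 0 & K <= 1))
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)
  K2 <- 0.3 * mats[[1]] + 0.7 * mats[[2]]
  expect_equal(K, K2)
  # identical patterns in every representation give the all-ones matrix
  ones <- lapply(1:2, function(i) matrix(1, 4, 4))
  expect_equal(combine_kernels(ones, kernel_spec(c(0.5, 0.5), c(1, 1))),
               matrix(1, 4, 4))
})

test_that("a nu-SVM separates well-separated clusters perfectly", {
  set.seed(6)
  X <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, mean = 6), 20))
  y <- c(rep(-1, 20), rep(1, 20))
  K <- rbf_from_dissimilarity(X, X, 0.5)
  model <- train_nu_svm(K, y, nu = 0.3)
  expect_equal(informedness(confusion_counts(y, model$fitted))$j, 1)
  pred <- predict_nu_svm(model, K)
  expect_equal(pred$labels, model$fitted)
  expect_true(all((pred$scores > 0) == (pred$labels == 1)))
  expect_error(train_nu_svm(K, y, nu = 0), "\\(0, 1\\]")
  expect_error(train_nu_svm(K, y, nu = 1.2), "\\(0, 1\\]")
})

test_that("relabelling both classes flips every prediction", {
  set.seed(7)
  X <- rbind(matrix(rnorm(30), 15), matrix(rnorm(30, 4), 15))
  y <- c(rep(-1, 15), rep(1, 15))
  K <- rbf_from_dissimilarity(X, X, 0.3)
  a <- predict_nu_svm(train_nu_svm(K, y, 0.4), K)
  b <- predict_nu_svm(train_nu_svm(K, -y, 0.4), K)
  expect_equal(a$labels, -b$labels)
})

test_that("duplicated query rows give duplicated predictions", {
  set.seed(8)
  X <- rbind(matrix(rnorm(20), 10), matrix(rnorm(20, 5), 10))
  y <- rep(c(-1, 1), each = 10)
  K <- rbf_from_dissimilarity(X, X, 0.4)
  model <- train_nu_svm(K, y, 0.3)
  Kq <- K[c(1, 1, 5), ]
  pred <- predict_nu_svm(model, Kq)
  expect_equal(pred$scores[1], pred$scores[2])
  expect_error(predict_nu_svm(model, K[, 1:5]), "align")
})

test_that("predictions are invariant to consistent prototype permutations", {
  ds <- planted_small(seed = 3)
  tr_idx <- c(1:8, 21:28)   # balanced classes
  va_idx <- c(9:12, 29:32)
  st <- build_stacks(ds$representations[tr_idx], ds$representations[va_idx])
  y <- ds$y[tr_idx]
  spec <- kernel_spec(rep(1 / 8, 8), rep(0.05, 8))
  set.seed(10)
  perm <- sample(16)
  tr1 <- st$train$matrices
  va1 <- st$val$matrices
  tr2 <- lapply(tr1, function(m) m[perm, perm])
  va2 <- lapply(va1, function(m) m[, perm])
  p1 <- predict_nu_svm(train_nu_svm(multiple_kernel(tr1, tr1, spec), y, 0.5),
                       multiple_kernel(va1, tr1, spec))
  p2 <- predict_nu_svm(train_nu_svm(multiple_kernel(tr2, tr2, spec),
                                    y[perm], 0.5),
                       multiple_kernel(va2, tr2, spec))
  expect_equal(p1$labels, p2$labels)
  # scores agree up to the SMO solver tolerance
  expect_equal(p1$scores, p2$scores, tolerance = 1e-2)
})

test_that("models serialize to JSON and reload bit-identically", {
  set.seed(9)
  X <- rbind(matrix(rnorm(20), 10), matrix(rnorm(20, 5), 10))
  y <- rep(c(-1, 1), each = 10)
  K <- rbf_from_dissimilarity(X, X, 0.4)
  model <- train_nu_svm(K, y, 0.3)
  f <- withr::local_tempfile(fileext = ".json")
  write_svm_json(model, f, spec = kernel_spec(1, 0.4), mask = rep(1, 10))
  back <- read_svm_json(f)
  expect_equal(predict_nu_svm(back$model, K)$scores,
               predict_nu_svm(model, K)$scores, tolerance = 1e-12)
  expect_equal(back$spec$gamma, 0.4)
})
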