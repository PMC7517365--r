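test_that("weighted dissimilarity matches its quadratic form", {
  expect_equal(weighted_dissimilarity(c(1, 1), c(0, 1), c(2, 0)), 2)
  expect_equal(weighted_dissimilarity(c(1, 2, 3), c(4, 6, 3), c(1, 1, 1)), 5)
  expect_equal(weighted_dissimilarity(c(1, 2), c(5, 9), c(0, 0)), 0)
  expect_error(weighted_dissimilarity(c(1, 2), c(1, 2), c(-1, 1)),
               "non-negative")
  expect_error(weighted_dissimilarity(c(1, 2), c(1, 2, 3), c(1, 1)),
               "equal lengths")
})

test_that("k-medoids instances partition targets with non-negative radii", {
  set.seed(12)
  X <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 8), 20))
  cl <- fit_clusters(X, k = 2, n_instances = 3, seed = 7)
  for (inst in cl$instances) {
    members <- sort(unlist(lapply(inst, `[[`, "members")))
    expect_equal(members, 1:40)
    expect_true(all(vapply(inst, `[[`, numeric(1), "delta") >= 0))
    # planted blobs: one medoid per blob
    med <- sort(vapply(inst, `[[`, integer(1), "medoid"))
    expect_true(med[1] <= 20 && med[2] > 20)
  }
  # one cluster per pattern collapses every radius to zero
  tiny <- fit_clusters(X[1:5, ], k = 5, n_instances = 1, seed = 1)
  expect_equal(vapply(tiny$instances[[1]], `[[`, numeric(1), "delta"),
               rep(0, 5))
  expect_error(fit_clusters(X[1:3, ], k = 4), "exceed")
})

test_that("medoid recovery agrees with a reference k-medoids fit", {
  skip_if_not_installed("cluster")
  set.seed(13)
  X <- rbind(matrix(rnorm(30, sd = 0.5), 15), matrix(rnorm(30, 6, 0.5), 15))
  ours <- fit_clusters(X, k = 2, n_instances = 1, seed = 3)
  pam_med <- sort(cluster::pam(X, 2)$id.med)
  our_med <- sort(vapply(ours$instances[[1]], `[[`, integer(1), "medoid"))
  # same blob structure: medoids fall in the same blocks
  expect_equal(our_med <= 15, pam_med <= 15)
})

test_that("membership is a calibrated monotone sigmoid", {
  cl <- list(a = 1, b = 2)
  expect_equal(membership(cl, 2), 0.5)
  expect_equal(membership(cl, 2 + log(3)), 0.25)
  expect_lt(membership(cl, 100), 1e-10)
  d <- seq(0, 6, by = 0.5)
  expect_true(all(diff(vapply(d, membership, numeric(1), cluster = cl)) < 0))
  # singleton cluster: hard indicator at the boundary midpoint
  hard <- list(a = 0, b = 1)
  expect_equal(vapply(c(0.5, 1, 1.5), membership, numeric(1), cluster = hard),
               c(1, 0.5, 0))
})

test_that("every cluster's membership is exactly one half at b", {
  set.seed(14)
  X <- matrix(rnorm(60), 20)
  model <- occ_model(fit_clusters(X, k = 4, n_instances = 2, seed = 5),
                     sigmas = c(0.5, 1, 1.5, 2))
  for (inst in model$instances)
    for (cl in inst) {
      expect_equal(membership(cl, cl$b), 0.5)
      expect_gte(cl$B, cl$delta)
    }
})

test_that("classification accepts medoids and honours the boundary rule", {
  set.seed(15)
  X <- matrix(rnorm(60), 20)
  clustering <- fit_clusters(X, k = 3, n_instances = 1, seed = 6)
  model <- occ_model(clustering, sigmas = rep(1, 3))
  med_rows <- vapply(model$instances[[1]], `[[`, integer(1), "medoid")
  pred <- classify_occ(model, X[med_rows, , drop = FALSE])
  expect_true(all(pred$decision))
  expect_true(all(pred$scores > 0.5))
  expect_true(all(pred$scores >= 0 & pred$scores <= 1))
})

test_that("acceptance is monotone in the decision thresholds", {
  set.seed(16)
  X <- matrix(rnorm(48), 16)
  clustering <- fit_clusters(X, k = 3, n_instances = 3, seed = 2)
  Q <- matrix(rnorm(30, sd = 2), 10)
  small <- classify_occ(occ_model(clustering, sigmas = rep(0.2, 3)), Q)
  large <- classify_occ(occ_model(clustering, sigmas = rep(3, 3)), Q)
  expect_true(all(large$decision >= small$decision))
})

test_that("classification with unit weights ignores pattern order", {
  set.seed(17)
  X <- matrix(rnorm(60), 20)
  model <- occ_model(fit_clusters(X, k = 2, n_instances = 1, seed = 8),
                     sigmas = c(1, 1))
  Q <- matrix(rnorm(15), 5)
  a <- classify_occ(model, Q)
  b <- classify_occ(model, Q[5:1, , drop = FALSE])
  expect_equal(a$scores, rev(b$scores))
})

test_that("tuning recovers informative subspace weights on planted data", {
  ds <- planted_multiview_dataset(synth_spec(n_per_class = 25, seed = 21))
  sp <- stratified_split(ds$y, c(0.6, 0.2, 0.2), seed = 1)
  st <- build_stacks(ds$representations[sp$train],
                     ds$representations[sp$val],
                     ds$representations[sp$test])
  vtr <- occ_vectors(st$train)
  vva <- occ_vectors(st$val)
  hits <- vapply(1:5, function(s) {
    cfg <- ga_config(population = 12, generations = 15, seed = s)
    res <- tune_occ(vtr$X[ds$y[sp$train] == 1, , drop = FALSE], vtr$blocks,
                    vva$X, ds$y[sp$val], k = 4, config = cfg,
                    n_instances = 3)
    w <- res$block_weights
    w[3] > mean(w[-3])   # informative block outweighs the rest on average
  }, logical(1))
  expect_gte(sum(hits), 4)
  # determinism under a fixed seed
  cfg <- ga_config(population = 8, generations = 4, seed = 9)
  r1 <- tune_occ(vtr$X[ds$y[sp$train] == 1, , drop = FALSE], vtr$blocks,
                 vva$X, ds$y[sp$val], k = 3, config = cfg, n_instances = 3)
  r2 <- tune_occ(vtr$X[ds$y[sp$train] == 1, , drop = FALSE], vtr$blocks,
                 vva$X, ds$y[sp$val], k = 3, config = cfg, n_instances = 3)
  expect_identical(r1$block_weights, r2$block_weights)
  expect_identical(r1$sigmas, r2$sigmas)
})

test_that("one-class models serialize to JSON", {
  set.seed(18)
  X <- matrix(rnorm(30), 10)
  model <- occ_model(fit_clusters(X, k = 2, n_instances = 1, seed = 4),
                     sigmas = c(1, 2))
  f <- withr::local_tempfile(fileext = ".json")
  write_occ_json(model, f)
  obj <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(obj$k, 2)
  expect_length(obj$instances, 1L)
})
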