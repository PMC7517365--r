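# shared small learning problem for the search tests
ga_fixture <- function(seed = 11) {
  ds <- planted_small(seed = seed)
  sp <- stratified_split(ds$y, c(0.6, 0.2, 0.2), seed = 1)
  list(stacks = build_stacks(ds$representations[sp$train],
                             ds$representations[sp$val],
                             ds$representations[sp$test]),
       y_train = ds$y[sp$train], y_val = ds$y[sp$val],
       y_test = ds$y[sp$test])
}

test_that("fitness arithmetic matches its definition on fixed predictions", {
  fx <- ga_fixture()
  n_tr <- length(fx$y_train)
  # a separable one-hot genome on the informative view scores highly
  g <- mkmd_genome(0.5, c(0, 0, 1, 0, 0, 0, 0, 0), rep(0.05, 8),
                   rep(1L, n_tr))
  f1 <- evaluate_f1(g, fx$stacks, fx$y_train, fx$y_val)
  expect_gte(f1, 0.9)
  # omega = 1 reduces f2 to 1 - f1 exactly
  expect_equal(evaluate_f2(g, fx$stacks, fx$y_train, fx$y_val, omega = 1),
               1 - f1, tolerance = 1e-12)
  # omega = 0 measures only the mask share
  fx2 <- ga_fixture()
  mask_full <- c(rep(1L, 6), rep(0L, n_tr - 6))
  g_sparse <- mkmd_genome(0.5, rep(1 / 8, 8), rep(1, 8), mask_full)
  expect_equal(evaluate_f2(g_sparse, fx2$stacks, fx2$y_train, fx2$y_val,
                           omega = 0), 6 / n_tr)
  # determinism of repeated evaluations
  expect_identical(evaluate_f1(g, fx$stacks, fx$y_train, fx$y_val), f1)
})

test_that("f1 and f2 orientations pair up on the same predictions", {
  # Jbar = 0.8 and 30% mask share at omega = 0.5 give f2 = 0.25
  jbar <- 0.8; share <- 0.3; omega <- 0.5
  expect_equal(omega * (1 - jbar) + (1 - omega) * share, 0.25)
})

test_that("an infeasible nu yields the worst fitness, not an exception", {
  fx <- ga_fixture()
  n_tr <- length(fx$y_train)
  g_bad <- mkmd_genome(0.999, rep(1 / 8, 8), rep(100, 8), rep(1L, n_tr))
  f <- evaluate_f1(g_bad, fx$stacks, fx$y_train, fx$y_val)
  if (as.numeric(f) == 0) expect_match(attr(f, "reason"), ".")
  f2 <- evaluate_f2(g_bad, fx$stacks, fx$y_train, fx$y_val, 0.5)
  expect_lte(as.numeric(f2), 1)
})

test_that("roulette selection is fitness-proportional", {
  set.seed(1)
  expect_true(all(roulette_select(c(1, 0, 0), 50) == 1))
  draws <- roulette_select(rep(1, 4), 1e4)
  freq <- tabulate(draws, 4) / 1e4
  expect_true(all(abs(freq - 0.25) < 3 * sqrt(0.25 * 0.75 / 1e4)))
  d1 <- withr::with_seed(2, roulette_select(c(1, 2, 3), 1e3))
  d2 <- withr::with_seed(2, roulette_select(c(2, 4, 6), 1e3))
  expect_identical(d1, d2)  # scale invariance
  expect_error(roulette_select(c(-1, 1), 2), "non-negative")
})

test_that("scattered crossover inherits genes and restores the simplex", {
  set.seed(3)
  a <- random_genome(8, 12)
  b <- random_genome(8, 12)
  child <- scattered_crossover(a, b)
  expect_equal(sum(child$beta), 1, tolerance = 1e-12)
  expect_true(all(child$mask == a$mask | child$mask == b$mask))
  expect_true(child$nu %in% c(a$nu, b$nu))
  same <- scattered_crossover(a, a)
  expect_equal(same$beta, a$beta, tolerance = 1e-12)
  expect_equal(same$mask, a$mask)
})

test_that("mutation respects the bounds and its shrinking schedule", {
  cfg <- ga_config(population = 10, generations = 10)
  set.seed(4)
  for (g in c(0, 5, 9)) {
    m <- mutate_genome(random_genome(8, 15), g, cfg, 10)
    expect_true(m$nu > 0 && m$nu <= 1)
    expect_true(all(m$beta >= 0 & m$beta <= 1))
    expect_equal(sum(m$beta), 1, tolerance = 1e-12)
    expect_true(all(m$gamma > 0 & m$gamma <= 100))
    expect_true(all(m$mask %in% c(0L, 1L)) && sum(m$mask) >= 1)
  }
  s_at <- function(g) max(cfg$sigma_floor,
                          cfg$mutation_sigma0 * (1 - g / cfg$generations))
  expect_lte(s_at(9), s_at(0))
})

test_that("evolution is elitist, reproducible and honours benchmark mode", {
  fx <- ga_fixture()
  cfg <- ga_config(population = 8, generations = 5, seed = 42)
  evo <- evolve(fx$stacks, fx$y_train, fx$y_val, cfg, fitness = "f1")
  expect_true(all(diff(evo$trace$best) >= 0))
  evo2 <- evolve(fx$stacks, fx$y_train, fx$y_val, cfg, fitness = "f1")
  expect_identical(evo$trace, evo2$trace)
  expect_equal(evo$best_genome$beta, evo2$best_genome$beta)
  fixed <- evolve(fx$stacks, fx$y_train, fx$y_val, cfg, fitness = "f1",
                  selection = FALSE)
  expect_true(all(fixed$best_genome$mask == 1L))
  evo_f2 <- evolve(fx$stacks, fx$y_train, fx$y_val, cfg, fitness = "f2")
  expect_true(all(diff(evo_f2$trace$best) >= 0))  # oriented trace
})

test_that("averaged kernel weights identify the planted informative view", {
  ds <- planted_multiview_dataset(synth_spec(seed = 11))
  sp <- stratified_split(ds$y, c(0.6, 0.2, 0.2), seed = 1)
  st <- build_stacks(ds$representations[sp$train],
                     ds$representations[sp$val],
                     ds$representations[sp$test])
  betas <- t(vapply(1:3, function(s) {
    cfg <- ga_config(population = 15, generations = 8, seed = s)
    evolve(st, ds$y[sp$train], ds$y[sp$val], cfg, fitness = "f1",
           selection = FALSE)$best_genome$beta
  }, numeric(8)))
  profile <- colMeans(betas)
  expect_gt(profile[3], 1 / 8)  # above the uninformative uniform weight
})

test_that("evolution traces and genomes serialize", {
  fx <- ga_fixture()
  cfg <- ga_config(population = 6, generations = 3, seed = 2)
  evo <- evolve(fx$stacks, fx$y_train, fx$y_val, cfg)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_evolution(evo, f1, f2)
  expect_equal(nrow(utils::read.csv(f1)), 3L)
  obj <- jsonlite::read_json(f2, simplifyVector = TRUE)
  expect_equal(obj$beta, evo$best_genome$beta, tolerance = 1e-12)
})
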