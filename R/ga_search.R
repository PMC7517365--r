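#' Genetic-algorithm configuration
#'
#' Study defaults: 100 individuals for at most 100 generations, elitism on
#' the top 10%, roulette-wheel selection, scattered crossover, Gaussian
#' mutation with a variance that shrinks across generations (initial sigma
#' 10% of each gene's range, floored at 1%), bit-flip mutation for the
#' prototype mask with probability `1/length(mask)`.
#'
#' @param population Number of individuals.
#' @param generations Generation budget (fixed; no early stopping).
#' @param elite_fraction Fraction of top individuals copied unchanged.
#' @param mutation_sigma0 Initial mutation sigma as a fraction of each
#'   gene's range.
#' @param sigma_floor Lower bound on the mutation sigma fraction.
#' @param flip_prob Mask bit-flip probability, or `NULL` for `1/len(mask)`.
#' @param omega Performance-vs-sparsity weight of the `f2` fitness, in
#'   `[0, 1]`.
#' @param seed Integer RNG seed for the whole run.
#' @param nu_range,gamma_range Admissible ranges for the SVM regulariser and
#'   the kernel shapes (the shape range is the search box `(0, 100]`,
#'   bounded away from 0 numerically).
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(population = 100L, generations = 100L,
                      elite_fraction = 0.10, mutation_sigma0 = 0.10,
                      sigma_floor = 0.01, flip_prob = NULL, omega = 0.5,
                      seed = 1L, nu_range = c(1e-3, 1),
                      gamma_range = c(1e-3, 100)) {
  stopifnot(population > 0, generations > 0,
            elite_fraction > 0, elite_fraction <= 1,
            omega >= 0, omega <= 1)
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 elite_fraction = elite_fraction,
                 mutation_sigma0 = mutation_sigma0,
                 sigma_floor = sigma_floor, flip_prob = flip_prob,
                 omega = omega, seed = as.integer(seed),
                 nu_range = nu_range, gamma_range = gamma_range),
            class = "ga_config")
}

#' Genome of the multiple-kernel classifier
#'
#' The individual optimised by the genetic search: the nu-SVM regulariser,
#' the convex kernel weights, the kernel shapes and the binary prototype
#' mask. With `selection = FALSE` the mask is pinned to all-ones and removed
#' from the search space (the no-representative-selection benchmark mode).
#'
#' @param nu Regulariser in (0, 1].
#' @param beta Kernel weights on the simplex.
#' @param gamma Kernel shapes in (0, 100].
#' @param mask Binary prototype mask.
#' @param selection Is the mask part of the search space?
#' @return An object of class `mkmd_genome`.
#' @export
mkmd_genome <- function(nu, beta, gamma, mask, selection = TRUE) {
  spec <- kernel_spec(beta, gamma)  # validates bounds
  if (nu <= 0 || nu > 1) stop("nu must lie in (0, 1]")
  mask <- as.integer(mask)
  if (!all(mask %in% c(0L, 1L))) stop("mask must be binary")
  if (!selection && any(mask == 0L))
    stop("with selection disabled the mask must be all-ones")
  structure(list(nu = nu, beta = spec$beta, gamma = spec$gamma, mask = mask,
                 selection = isTRUE(selection)),
            class = "mkmd_genome")
}

.project_beta <- function(beta) {
  beta <- pmin(pmax(beta, 0), 1)
  s <- sum(beta)
  if (s <= 0) rep(1 / length(beta), length(beta)) else beta / s
}

#' Random genome under the search-space bounds
#'
#' nu uniform on its range, weights drawn from a sparse symmetric Dirichlet
#' (concentration 0.3, favouring interpretable near-one-hot mixtures),
#' shapes log-uniform over the shape range, mask bits Bernoulli(1/2) (at
#' least one bit set). Uses the current RNG stream.
#'
#' @param n_rep Number of representations.
#' @param n_train Training-set size (mask length).
#' @param selection Include the mask in the search space?
#' @param config A [ga_config()].
#' @return An [mkmd_genome()].
#' @export
random_genome <- function(n_rep, n_train, selection = TRUE,
                          config = ga_config()) {
  mask <- if (selection) stats::rbinom(n_train, 1L, 0.5) else rep(1L, n_train)
  if (sum(mask) == 0L) mask[sample.int(n_train, 1L)] <- 1L
  lg <- log10(config$gamma_range)
  b <- stats::rgamma(n_rep, shape = 0.3)
  mkmd_genome(nu = stats::runif(1L, config$nu_range[1L], config$nu_range[2L]),
              beta = if (sum(b) <= 0) rep(1 / n_rep, n_rep) else b / sum(b),
              gamma = 10^stats::runif(n_rep, lg[1L], lg[2L]),
              mask = mask, selection = selection)
}

# Objective evaluation ---------------------------------------------------

.genome_jbar <- function(genome, stacks, y_train, y_val) {
  tryCatch({
    if (sum(genome$mask) == 0L) stop("degenerate prototype mask")
    spec <- kernel_spec(genome$beta, genome$gamma)
    tr <- lapply(stacks$train$matrices, reduce_columns, genome$mask)
    K <- multiple_kernel(tr, tr, spec)
    model <- train_nu_svm(K, y_train, genome$nu)
    va <- lapply(stacks$val$matrices, reduce_columns, genome$mask)
    Kv <- multiple_kernel(va, tr, spec)
    pred <- predict_nu_svm(model, Kv)
    informedness(confusion_counts(y_val, pred$labels))$j_norm
  }, error = function(e) structure(NA_real_, reason = conditionMessage(e)))
}

#' Performance fitness (normalised validation informedness)
#'
#' Runs the full objective evaluation: mask-slice the train stacks, build
#' the multiple kernel, train the nu-SVM, slice and kernelise the validation
#' stacks, predict, and return the normalised informedness on validation.
#' Evaluation failures (e.g., a nu infeasible for the class balance) yield
#' the worst fitness 0 with the cause attached as attribute `reason`.
#'
#' @param genome An [mkmd_genome()].
#' @param stacks Output of [build_stacks()] with `train` and `val` entries.
#' @param y_train,y_val Vectors of -1/+1 labels.
#' @return Fitness in [0, 1]; higher is better.
#' @export
evaluate_f1 <- function(genome, stacks, y_train, y_val) {
  j <- .genome_jbar(genome, stacks, y_train, y_val)
  if (is.na(j)) structure(0, reason = attr(j, "reason")) else j
}

#' Performance/sparsity fitness
#'
#' `omega * (1 - Jbar) + (1 - omega) * popcount(mask)/len(mask)`, to be
#' minimised. Evaluation failures yield the worst fitness 1.
#'
#' @inheritParams evaluate_f1
#' @param omega Convex weight of the performance term, in [0, 1].
#' @return Fitness in [0, 1]; lower is better.
#' @export
evaluate_f2 <- function(genome, stacks, y_train, y_val, omega = 0.5) {
  stopifnot(omega >= 0, omega <= 1)
  j <- .genome_jbar(genome, stacks, y_train, y_val)
  if (is.na(j)) return(structure(1, reason = attr(j, "reason")))
  omega * (1 - j) + (1 - omega) * mean(genome$mask)
}

# Genetic operators ------------------------------------------------------

#' Roulette-wheel parent selection
#'
#' Samples parent indices with probability proportional to the oriented
#' (higher-is-better, non-negative) fitness; an all-zero fitness vector
#' falls back to uniform sampling.
#'
#' @param fitness Non-negative oriented fitness values.
#' @param n Number of parents to draw.
#' @return Integer vector of selected indices.
#' @export
roulette_select <- function(fitness, n) {
  if (any(fitness < 0)) stop("oriented fitness must be non-negative")
  if (sum(fitness) <= 0) fitness <- rep(1, length(fitness))
  sample.int(length(fitness), n, replace = TRUE, prob = fitness)
}

#' Scattered crossover of two genomes
#'
#' Each gene (nu, every weight, every shape, every mask bit) is inherited
#' independently from a uniformly random parent; the weights are re-projected
#' to the simplex afterwards.
#'
#' @param a,b Parent [mkmd_genome()] objects with identical layout.
#' @return A child genome.
#' @export
scattered_crossover <- function(a, b) {
  pick <- function(x, y) ifelse(stats::runif(length(x)) < 0.5, x, y)
  mask <- if (a$selection) as.integer(pick(a$mask, b$mask)) else a$mask
  if (sum(mask) == 0L) mask[sample.int(length(mask), 1L)] <- 1L
  mkmd_genome(nu = if (stats::runif(1L) < 0.5) a$nu else b$nu,
              beta = .project_beta(pick(a$beta, b$beta)),
              gamma = pick(a$gamma, b$gamma),
              mask = mask, selection = a$selection)
}

#' Mutate a genome with a shrinking-variance schedule
#'
#' Real genes are perturbed by zero-mean Gaussian noise whose sigma decreases
#' linearly across generations (fraction of each gene's range, floored), then
#' clipped to the search bounds; the kernel shapes, whose useful values span
#' several decades, are perturbed on the log10 scale. Mask bits flip
#' independently with a fixed probability.
#'
#' @param genome An [mkmd_genome()].
#' @param generation Current generation (0-based).
#' @param config A [ga_config()].
#' @param total_generations Total generation budget.
#' @return The mutated genome (always within bounds).
#' @export
mutate_genome <- function(genome, generation, config,
                          total_generations = config$generations) {
  frac <- max(config$sigma_floor,
              config$mutation_sigma0 * (1 - generation / total_generations))
  nr <- config$nu_range
  nu <- min(max(genome$nu + stats::rnorm(1L, 0, frac * diff(nr)),
                nr[1L]), nr[2L])
  beta <- .project_beta(genome$beta +
                          stats::rnorm(length(genome$beta), 0, frac))
  lg <- log10(config$gamma_range)
  lgam <- log10(genome$gamma) +
    stats::rnorm(length(genome$gamma), 0, frac * diff(lg))
  gamma <- 10^pmin(pmax(lgam, lg[1L]), lg[2L])
  mask <- genome$mask
  if (genome$selection) {
    p <- if (is.null(config$flip_prob)) 1 / length(mask) else config$flip_prob
    flips <- stats::rbinom(length(mask), 1L, p)
    mask <- as.integer(xor(mask, flips))
    if (sum(mask) == 0L) mask[sample.int(length(mask), 1L)] <- 1L
  }
  mkmd_genome(nu, beta, gamma, mask, genome$selection)
}

# Evolution loop ---------------------------------------------------------

#' Evolve the multiple-kernel genome
#'
#' Generational loop with elitism: the top `elite_fraction` individuals are
#' carried unchanged, the rest are produced by roulette-wheel selection,
#' scattered crossover and shrinking-variance mutation. Fitness `f1`
#' (normalised validation informedness) is maximised; `f2`
#' (performance/sparsity trade-off) is minimised via the orientation
#' transform `1 - f2`. Fully reproducible given `config$seed`.
#'
#' @param stacks Output of [build_stacks()] with `train` and `val` entries.
#' @param y_train,y_val Vectors of -1/+1 labels.
#' @param config A [ga_config()].
#' @param fitness `"f1"` or `"f2"`.
#' @param selection Evolve the prototype mask? With `FALSE` the mask stays
#'   all-ones (benchmark mode).
#' @return An object of class `mkmd_evolution`: `best_genome`,
#'   `best_fitness` (raw scale), `trace` (per-generation best/mean oriented
#'   fitness), `fitness`, `config`.
#' @export
evolve <- function(stacks, y_train, y_val, config = ga_config(),
                   fitness = c("f1", "f2"), selection = TRUE) {
  fitness <- match.arg(fitness)
  set.seed(config$seed)
  n_rep <- length(stacks$train$matrices)
  n_train <- length(y_train)
  raw_fn <- if (fitness == "f1")
    function(g) evaluate_f1(g, stacks, y_train, y_val)
  else
    function(g) evaluate_f2(g, stacks, y_train, y_val, config$omega)
  orient <- if (fitness == "f1") identity else function(x) 1 - x
  pop <- replicate(config$population,
                   random_genome(n_rep, n_train, selection, config),
                   simplify = FALSE)
  elite_n <- max(1L, floor(config$population * config$elite_fraction))
  best <- NULL; best_oriented <- -Inf
  trace <- data.frame(generation = integer(), best = numeric(),
                      mean = numeric())
  for (g in seq_len(config$generations)) {
    raw <- vapply(pop, function(x) as.numeric(raw_fn(x)), numeric(1L))
    ori <- orient(raw)
    ord <- order(ori, decreasing = TRUE)
    if (ori[ord[1L]] > best_oriented) {
      best_oriented <- ori[ord[1L]]
      best <- list(genome = pop[[ord[1L]]], raw = raw[ord[1L]])
    }
    trace <- rbind(trace, data.frame(generation = g, best = best_oriented,
                                     mean = mean(ori)))
    if (g == config$generations) break
    elites <- pop[ord[seq_len(elite_n)]]
    children <- lapply(seq_len(config$population - elite_n), function(i) {
      par <- roulette_select(ori, 2L)
      mutate_genome(scattered_crossover(pop[[par[1L]]], pop[[par[2L]]]),
                    g, config)
    })
    pop <- c(elites, children)
  }
  structure(list(best_genome = best$genome, best_fitness = best$raw,
                 trace = trace, fitness = fitness, config = config,
                 selection = selection),
            class = "mkmd_evolution")
}

#' Write an evolution trace to CSV and the best genome to JSON
#' @param evolution An `mkmd_evolution` from [evolve()].
#' @param trace_path CSV path for the per-generation trace.
#' @param genome_path JSON path for the best genome.
#' @return `genome_path`, invisibly.
#' @export
write_evolution <- function(evolution, trace_path, genome_path) {
  utils::write.csv(evolution$trace, trace_path, row.names = FALSE)
  g <- evolution$best_genome
  jsonlite::write_json(list(nu = g$nu, beta = g$beta, gamma = g$gamma,
                            mask = g$mask, selection = g$selection,
                            fitness = evolution$fitness,
                            best_fitness = evolution$best_fitness,
                            seed = evolution$config$seed),
                       genome_path, digits = NA, auto_unbox = TRUE)
  invisible(genome_path)
}
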