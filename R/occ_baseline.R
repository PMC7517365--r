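#' Weighted Euclidean dissimilarity between dissimilarity vectors
#'
#' `sqrt((x1 - x2)' W'W (x1 - x2))` with `W = diag(weights)`; with unit
#' weights this is the plain Euclidean distance.
#'
#' @param x1,x2 Numeric vectors of equal length.
#' @param weights Non-negative weight vector of the same length.
#' @return A non-negative scalar.
#' @export
weighted_dissimilarity <- function(x1, x2, weights) {
  if (length(x1) != length(x2) || length(x1) != length(weights))
    stop("vectors and weights must have equal lengths")
  if (any(weights < 0)) stop("weights must be non-negative")
  sqrt(sum((weights * (x1 - x2))^2))
}

.weighted_rows <- function(X, weights) sweep(X, 2L, weights, "*")

# one Lloyd-style k-medoids pass: nearest-medoid assignment with medoid
# update to convergence, on pre-weighted coordinates
.kmedoids_once <- function(Xw, k, max_iter = 50L) {
  n <- nrow(Xw)
  medoids <- sample.int(n, k)
  for (iter in seq_len(max_iter)) {
    D <- pairwise_dissimilarity(Xw, Xw[medoids, , drop = FALSE])
    assign <- max.col(-D, ties.method = "first")
    new_medoids <- medoids
    for (j in seq_len(k)) {
      members <- which(assign == j)
      if (length(members) == 0L) next
      Dm <- pairwise_dissimilarity(Xw[members, , drop = FALSE],
                                   Xw[members, , drop = FALSE])
      new_medoids[j] <- members[which.min(rowSums(Dm))]
    }
    if (identical(new_medoids, medoids)) break
    medoids <- new_medoids
  }
  D <- pairwise_dissimilarity(Xw, Xw[medoids, , drop = FALSE])
  assign <- max.col(-D, ties.method = "first")
  clusters <- lapply(seq_len(k), function(j) {
    members <- which(assign == j)
    if (length(members) == 0L) members <- medoids[j]
    delta <- mean(D[members, j])
    list(medoid = medoids[j], members = members, delta = delta)
  })
  clusters
}

#' Fit medoid clustering instances over target patterns
#'
#' Runs `n_instances` independent k-medoids clusterings (random starting
#' medoids, nearest-medoid assignment with medoid update to convergence)
#' of the target training patterns under a weighted Euclidean dissimilarity.
#' Each cluster records its medoid, members and average radius `delta`.
#'
#' @param X Numeric matrix of target patterns (rows = patterns,
#'   dissimilarity-vector coordinates).
#' @param k Number of clusters (`k <= nrow(X)`).
#' @param n_instances Number of independent clustering instances (odd
#'   recommended, for majority voting).
#' @param weights Non-negative per-column weights (default unit).
#' @param seed Optional RNG seed.
#' @return An object of class `occ_clustering`: list of instances, each a
#'   list of `k` clusters, plus the weights.
#' @export
fit_clusters <- function(X, k, n_instances = 5L, weights = NULL,
                         seed = NULL) {
  X <- as.matrix(X)
  if (k > nrow(X)) stop("k cannot exceed the number of target patterns")
  if (k < 1L) stop("k must be positive")
  if (is.null(weights)) weights <- rep(1, ncol(X))
  if (any(weights < 0)) stop("weights must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  Xw <- .weighted_rows(X, weights)
  instances <- lapply(seq_len(n_instances), function(i)
    .kmedoids_once(Xw, k))
  structure(list(instances = instances, weights = weights, k = k, X = X),
            class = "occ_clustering")
}

#' Sigmoid cluster membership
#'
#' `mu(d) = 1 / (1 + exp((d - b) / a))` with `a = delta` (average radius)
#' and `b = delta + sigma/2`, so the membership equals 0.5 exactly at `b`,
#' the midpoint of the outer band of the decision region. Singleton clusters
#' (`a = 0`) degenerate to a hard indicator at `b`.
#'
#' @param cluster A list with `a` and `b` (see [occ_model()]).
#' @param d Non-negative dissimilarity to the cluster medoid.
#' @return Membership value in [0, 1], monotone non-increasing in `d`.
#' @export
membership <- function(cluster, d) {
  if (cluster$a <= 0)
    return(ifelse(d < cluster$b, 1, ifelse(d > cluster$b, 0, 0.5)))
  1 / (1 + exp((d - cluster$b) / cluster$a))
}

#' Assemble a one-class classification model
#'
#' Attaches per-cluster thresholds to fitted clustering instances. Within
#' each instance the threshold vector `sigmas` (length `k`) is matched to
#' clusters by ascending average radius, so corresponding genes play the
#' same role across instances. Each cluster's decision region is bounded by
#' `B = delta + sigma`; the membership parameters are `a = delta` and
#' `b = delta + sigma/2`.
#'
#' @param clustering An `occ_clustering` from [fit_clusters()].
#' @param sigmas Non-negative threshold vector of length `k`.
#' @return An object of class `occ_model`.
#' @export
occ_model <- function(clustering, sigmas) {
  stopifnot(inherits(clustering, "occ_clustering"),
            length(sigmas) == clustering$k, all(sigmas >= 0))
  instances <- lapply(clustering$instances, function(inst) {
    ord <- order(vapply(inst, function(cl) cl$delta, numeric(1L)))
    for (r in seq_along(ord)) {
      cl <- inst[[ord[r]]]
      cl$sigma <- sigmas[r]
      cl$a <- cl$delta
      cl$b <- cl$delta + sigmas[r] / 2
      cl$B <- cl$delta + sigmas[r]
      inst[[ord[r]]] <- cl
    }
    inst
  })
  structure(list(instances = instances, weights = clustering$weights,
                 k = clustering$k, X = clustering$X, sigmas = sigmas),
            class = "occ_model")
}

#' Classify query patterns with a one-class model
#'
#' Per clustering instance, each query is assigned to its closest cluster
#' `C*` (weighted dissimilarity to the medoid) and accepted when
#' `d <= B(C*)` (the boundary itself counts as inside); instances are
#' aggregated by majority vote and the soft score is the membership of the
#' closest cluster averaged over instances.
#'
#' @param model An [occ_model()].
#' @param X_query Numeric matrix of query patterns.
#' @return A list with `decision` (logical: inside the target region),
#'   `labels` (-1/+1 with +1 = target) and `scores` (in [0, 1]).
#' @export
classify_occ <- function(model, X_query) {
  X_query <- as.matrix(X_query)
  Qw <- .weighted_rows(X_query, model$weights)
  Xw <- .weighted_rows(model$X, model$weights)
  votes <- matrix(0, nrow(X_query), length(model$instances))
  mus <- matrix(0, nrow(X_query), length(model$instances))
  for (i in seq_along(model$instances)) {
    inst <- model$instances[[i]]
    med <- vapply(inst, function(cl) cl$medoid, integer(1L))
    D <- pairwise_dissimilarity(Qw, Xw[med, , drop = FALSE])
    closest <- max.col(-D, ties.method = "first")
    d <- D[cbind(seq_len(nrow(D)), closest)]
    B <- vapply(inst, function(cl) cl$B, numeric(1L))[closest]
    votes[, i] <- as.numeric(d <= B)
    mus[, i] <- vapply(seq_along(closest), function(q)
      membership(inst[[closest[q]]], d[q]), numeric(1L))
  }
  decision <- rowMeans(votes) >= 0.5
  list(decision = decision, labels = ifelse(decision, 1, -1),
       scores = rowMeans(mus))
}

# real-vector GA used for OCC tuning (same operators: roulette selection,
# scattered crossover, shrinking-variance Gaussian mutation, elitism)
.ga_real <- function(objective, n_genes, config) {
  pop <- lapply(seq_len(config$population),
                function(i) stats::runif(n_genes))
  elite_n <- max(1L, floor(config$population * config$elite_fraction))
  best <- NULL; best_fit <- -Inf
  trace <- data.frame(generation = integer(), best = numeric(),
                      mean = numeric())
  for (g in seq_len(config$generations)) {
    fit <- vapply(pop, objective, numeric(1L))
    ord <- order(fit, decreasing = TRUE)
    if (fit[ord[1L]] > best_fit) {
      best_fit <- fit[ord[1L]]
      best <- pop[[ord[1L]]]
    }
    trace <- rbind(trace, data.frame(generation = g, best = best_fit,
                                     mean = mean(fit)))
    if (g == config$generations) break
    elites <- pop[ord[seq_len(elite_n)]]
    frac <- max(config$sigma_floor,
                config$mutation_sigma0 * (1 - g / config$generations))
    shifted <- fit - min(fit)
    children <- lapply(seq_len(config$population - elite_n), function(i) {
      par <- roulette_select(shifted, 2L)
      child <- ifelse(stats::runif(n_genes) < 0.5,
                      pop[[par[1L]]], pop[[par[2L]]])
      pmin(pmax(child + stats::rnorm(n_genes, 0, frac), 0), 1)
    })
    pop <- c(elites, children)
  }
  list(best = best, best_fitness = best_fit, trace = trace)
}

#' Tune the one-class classifier by genetic search
#'
#' Evolves the per-block dissimilarity weights and the per-cluster decision
#' thresholds, maximising a convex combination of validation accuracy
#' (target vs non-target) and threshold parsimony
#' (`mix * accuracy + (1 - mix) * (1 - mean(sigma)/sigma_max)`).
#' Clustering uses only target training patterns; the validation set must
#' contain both classes.
#'
#' @param X_targets Matrix of target training patterns (dissimilarity
#'   vectors).
#' @param blocks Integer/factor vector mapping each column of the
#'   dissimilarity vectors to its representation block; weights are tied
#'   within a block.
#' @param X_val Matrix of validation patterns (same columns).
#' @param y_val Vector of -1/+1 validation labels (+1 = target).
#' @param k Number of clusters per instance.
#' @param config A [ga_config()] (population, generations, elitism,
#'   mutation schedule, seed).
#' @param n_instances Clustering instances for voting.
#' @param mix Accuracy weight of the objective, in [0, 1].
#' @param sigma_max Threshold upper bound; default the maximum pairwise
#'   unit-weight distance among targets.
#' @return An object of class `occ_result`: the fitted `model`, the tuned
#'   `block_weights`, `sigmas`, objective `trace`, and the achieved
#'   validation objective.
#' @export
tune_occ <- function(X_targets, blocks, X_val, y_val, k,
                     config = ga_config(), n_instances = 5L, mix = 0.5,
                     sigma_max = NULL) {
  X_targets <- as.matrix(X_targets); X_val <- as.matrix(X_val)
  y_val <- .as_pm1(y_val)
  if (length(unique(y_val)) < 2L)
    stop("validation must contain target and non-target patterns")
  blocks <- as.integer(factor(blocks))
  n_blocks <- max(blocks)
  if (is.null(sigma_max)) {
    Dt <- pairwise_dissimilarity(X_targets, X_targets)
    sigma_max <- max(Dt)
  }
  set.seed(config$seed)
  build <- function(genes) {
    w_block <- genes[seq_len(n_blocks)]
    sig <- genes[n_blocks + seq_len(k)] * sigma_max
    weights <- w_block[blocks]
    clustering <- fit_clusters(X_targets, k, n_instances, weights)
    occ_model(clustering, sig)
  }
  objective <- function(genes) {
    model <- build(genes)
    pred <- classify_occ(model, X_val)
    acc <- mean(pred$labels == y_val)
    sig <- genes[n_blocks + seq_len(k)]
    mix * acc + (1 - mix) * (1 - mean(sig))
  }
  res <- .ga_real(objective, n_blocks + k, config)
  set.seed(config$seed + 1L)  # fixed stream for the final refit
  model <- build(res$best)
  structure(list(model = model,
                 block_weights = res$best[seq_len(n_blocks)],
                 sigmas = res$best[n_blocks + seq_len(k)] * sigma_max,
                 trace = res$trace, objective = res$best_fitness,
                 mix = mix, sigma_max = sigma_max),
            class = "occ_result")
}

#' Concatenate a dissimilarity stack into per-pattern vectors
#'
#' Binds the per-representation dissimilarity matrices column-wise, yielding
#' one concatenated dissimilarity vector per pattern (the input format of
#' the one-class classifier), plus the block index of every column.
#'
#' @param stack A `dissimilarity_stack` from [build_stacks()].
#' @return A list with `X` (matrix) and `blocks` (integer vector).
#' @export
occ_vectors <- function(stack) {
  mats <- stack$matrices
  list(X = do.call(cbind, mats),
       blocks = rep(seq_along(mats),
                    vapply(mats, ncol, integer(1L))))
}

#' Serialize a one-class model to JSON
#' @param result An `occ_result` from [tune_occ()] or an [occ_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_occ_json <- function(result, path) {
  model <- if (inherits(result, "occ_result")) result$model else result
  obj <- list(weights = model$weights, sigmas = model$sigmas, k = model$k,
              instances = lapply(model$instances, function(inst)
                lapply(inst, function(cl)
                  list(medoid = cl$medoid, members = cl$members,
                       delta = cl$delta, sigma = cl$sigma,
                       a = cl$a, b = cl$b, B = cl$B))))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
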