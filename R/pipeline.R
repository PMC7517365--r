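#' Evaluate a genome on a held-out split
#'
#' Re-runs the objective pipeline for a fixed genome (slice the train
#' stacks, build the multiple kernel, train the nu-SVM) and scores an
#' evaluation split (typically the test set), returning the full metrics
#' row.
#'
#' @param genome An [mkmd_genome()].
#' @param stacks Output of [build_stacks()] containing `train` and the
#'   requested split.
#' @param y_train Training labels (-1/+1).
#' @param y_eval Labels of the evaluated split.
#' @param split Name of the evaluated split in `stacks` (default
#'   `"test"`).
#' @return A list of metrics (see [metrics_report()]) plus `scores` and
#'   `labels`.
#' @export
evaluate_genome_on <- function(genome, stacks, y_train, y_eval,
                               split = "test") {
  spec <- kernel_spec(genome$beta, genome$gamma)
  tr <- lapply(stacks$train$matrices, reduce_columns, genome$mask)
  K <- multiple_kernel(tr, tr, spec)
  model <- train_nu_svm(K, y_train, genome$nu)
  ev <- lapply(stacks[[split]]$matrices, reduce_columns, genome$mask)
  Ke <- multiple_kernel(ev, tr, spec)
  pred <- predict_nu_svm(model, Ke)
  rep <- metrics_report(y_eval, pred$labels, pred$scores, genome$mask)
  c(rep, list(scores = pred$scores, labels = pred$labels))
}

#' Run the full multiple-kernel classification study on one binary task
#'
#' Stratified split, dissimilarity stacks, genetic optimisation repeated
#' over several seeds, test-set evaluation of each run's best genome, and
#' the knowledge-discovery summary (average kernel weights, selected
#' prototypes).
#'
#' @param representations List of [representation_set()] objects.
#' @param y Vector of -1/+1 labels.
#' @param config A [ga_config()]; `config$seed` also seeds the split.
#' @param fitness `"f1"` (maximise normalised informedness) or `"f2"`
#'   (performance/sparsity trade-off, minimised).
#' @param seeds Integer vector of GA run seeds (the study default is five
#'   runs).
#' @param selection Evolve the prototype mask?
#' @param fractions Train/validation/test fractions.
#' @param measures Dissimilarity measure(s) for [build_stacks()].
#' @param scale Standardise representations before distances?
#' @return An object of class `mkmd_result`: per-run list (`genome`,
#'   `evolution`, `metrics`), `split`, `knowledge`, and `summary` (mean
#'   test metrics across runs).
#' @export
mkmd_run <- function(representations, y, config = ga_config(),
                     fitness = c("f1", "f2"), seeds = 1:5,
                     selection = TRUE, fractions = c(0.6, 0.2, 0.2),
                     measures = "euclidean", scale = FALSE) {
  fitness <- match.arg(fitness)
  y <- .as_pm1(y)
  split <- stratified_split(y, fractions, seed = config$seed)
  stacks <- build_stacks(representations[split$train],
                         representations[split$val],
                         representations[split$test],
                         measures = measures, scale = scale)
  runs <- lapply(seeds, function(s) {
    cfg <- config; cfg$seed <- as.integer(s)
    evo <- evolve(stacks, y[split$train], y[split$val], cfg,
                  fitness = fitness, selection = selection)
    metrics <- evaluate_genome_on(evo$best_genome, stacks,
                                  y[split$train], y[split$test])
    list(genome = evo$best_genome, evolution = evo, metrics = metrics)
  })
  metric_names <- c("accuracy", "precision", "recall",
                    "informedness_norm", "auc", "sparsity")
  summary <- vapply(metric_names, function(m)
    mean(vapply(runs, function(r) as.numeric(r$metrics[[m]]), numeric(1L)),
         na.rm = TRUE), numeric(1L))
  structure(list(runs = runs, split = split,
                 knowledge = knowledge_reports(runs),
                 summary = summary, fitness = fitness),
            class = "mkmd_result")
}

#' Run the one-class baseline on the same binary task
#'
#' Builds the concatenated dissimilarity vectors from the same stacks as
#' the multiple-kernel path, tunes the one-class classifier (weights +
#' thresholds) on the validation set using only target-class training
#' patterns, and evaluates on the test set.
#'
#' @param representations List of [representation_set()] objects.
#' @param y Vector of -1/+1 labels (+1 = target class).
#' @param k Number of clusters per instance.
#' @param config A [ga_config()].
#' @param fractions Train/validation/test fractions.
#' @param n_instances Clustering instances for voting.
#' @param mix Accuracy weight of the tuning objective.
#' @param measures Dissimilarity measure(s).
#' @return An object of class `occ_run_result` with `result` (the tuned
#'   `occ_result`), `metrics` (test metrics incl. AUC from the soft
#'   scores), and `split`.
#' @export
occ_run <- function(representations, y, k = 10L, config = ga_config(),
                    fractions = c(0.6, 0.2, 0.2), n_instances = 5L,
                    mix = 0.5, measures = "euclidean") {
  y <- .as_pm1(y)
  split <- stratified_split(y, fractions, seed = config$seed)
  stacks <- build_stacks(representations[split$train],
                         representations[split$val],
                         representations[split$test],
                         measures = measures)
  vtr <- occ_vectors(stacks$train)
  vva <- occ_vectors(stacks$val)
  vts <- occ_vectors(stacks$test)
  targets <- y[split$train] == 1
  res <- tune_occ(vtr$X[targets, , drop = FALSE], vtr$blocks, vva$X,
                  y[split$val], k = k, config = config,
                  n_instances = n_instances, mix = mix)
  pred <- classify_occ(res$model, vts$X)
  metrics <- metrics_report(y[split$test], pred$labels, pred$scores)
  structure(list(result = res, metrics = metrics, split = split),
            class = "occ_run_result")
}

#' Benchmark the multiple-kernel classifier against the one-class baseline
#'
#' Runs both systems on the same binary task through the identical
#' evaluation module and returns the side-by-side comparison table
#' (accuracy, precision, recall, normalised informedness, AUC). Following
#' the benchmarking protocol, prototype selection is disabled in the
#' multiple-kernel genome (all-ones mask) since the one-class system has no
#' counterpart for it.
#'
#' @param representations List of [representation_set()] objects.
#' @param y Vector of -1/+1 labels.
#' @param config A [ga_config()].
#' @param seeds GA run seeds for the multiple-kernel side.
#' @param k Cluster count for the one-class side.
#' @return A list with `table` (comparison data frame), `mkmd`
#'   (`mkmd_result`) and `occ` (`occ_run_result`).
#' @export
benchmark_mkmd_occ <- function(representations, y, config = ga_config(),
                               seeds = 1L, k = 10L) {
  mk <- mkmd_run(representations, y, config, fitness = "f1", seeds = seeds,
                 selection = FALSE)
  oc <- occ_run(representations, y, k = k, config = config)
  mk_metrics <- lapply(
    c("accuracy", "precision", "recall", "informedness_norm", "auc"),
    function(m) mk$summary[[m]])
  names(mk_metrics) <- c("accuracy", "precision", "recall",
                         "informedness_norm", "auc")
  list(table = comparison_table(list(MKMD = mk_metrics,
                                     OCC = oc$metrics)),
       mkmd = mk, occ = oc)
}

#' One-vs-all orchestration over all classes
#'
#' Recodes the multi-class labels one class at a time, re-draws a
#' stratified split per classifier (seeded from a master seed plus the
#' class id) and runs the multiple-kernel study for each, returning one
#' metrics row per class.
#'
#' @param representations List of [representation_set()] objects.
#' @param labels Integer class labels (e.g., 1..7).
#' @param config A [ga_config()]; `config$seed` is the master seed.
#' @param fitness `"f1"` or `"f2"`.
#' @param seeds GA run seeds per classifier.
#' @param classes Classes to run (default: all present).
#' @return A list of `mkmd_result` objects named by class, plus a `table`
#'   attribute with the per-class mean metrics.
#' @export
one_vs_all_study <- function(representations, labels, config = ga_config(),
                             fitness = "f1", seeds = 1:5, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(labels))
  results <- lapply(classes, function(cl) {
    cfg <- config
    cfg$seed <- as.integer(config$seed + cl)
    mkmd_run(representations, one_vs_all_labels(labels, cl), cfg,
             fitness = fitness, seeds = seeds)
  })
  names(results) <- as.character(classes)
  tab <- do.call(rbind, lapply(results, function(r) r$summary))
  attr(results, "table") <- data.frame(class = classes, tab,
                                       row.names = NULL)
  results
}
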