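#' Confusion counts for a binary task
#' @param truth,pred Vectors of -1/+1 labels.
#' @return A list with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(truth, pred) {
  truth <- .as_pm1(truth); pred <- .as_pm1(pred)
  stopifnot(length(truth) == length(pred))
  list(tp = sum(truth == 1 & pred == 1),
       tn = sum(truth == -1 & pred == -1),
       fp = sum(truth == -1 & pred == 1),
       fn = sum(truth == 1 & pred == -1))
}

#' Informedness (Youden's J) and its normalised form
#'
#' `J = specificity + sensitivity - 1` in `[-1, 1]`; the normalised form
#' `(J + 1) / 2` lies in `[0, 1]` and is the quantity the optimiser
#' maximises. Requires both classes present among the true labels.
#'
#' @param counts A list with `tp`, `tn`, `fp`, `fn` (see
#'   [confusion_counts()]).
#' @return A list with `j` and `j_norm`.
#' @export
informedness <- function(counts) {
  with(counts, {
    if (tp + fn == 0 || tn + fp == 0)
      stop("informedness undefined: a class is absent from the true labels")
    sens <- tp / (tp + fn)
    spec <- tn / (tn + fp)
    j <- spec + sens - 1
    list(j = j, j_norm = (j + 1) / 2)
  })
}

#' Accuracy, precision and recall from confusion counts
#'
#' `accuracy = (TP+TN)/(TP+FP+TN+FN)`, `precision = TP/(TP+FP)`,
#' `recall = TP/(TP+FN)`. Zero denominators raise an error rather than
#' silently returning 0.
#'
#' @param counts A list with `tp`, `tn`, `fp`, `fn`.
#' @return A list with `accuracy`, `precision`, `recall`.
#' @export
basic_metrics <- function(counts) {
  with(counts, {
    n <- tp + tn + fp + fn
    if (n == 0) stop("no evaluated patterns")
    if (tp + fp == 0) stop("precision undefined: no positive predictions")
    if (tp + fn == 0) stop("recall undefined: no positive patterns")
    list(accuracy = (tp + tn) / n,
         precision = tp / (tp + fp),
         recall = tp / (tp + fn))
  })
}

#' ROC curve and AUC from decision scores
#'
#' Threshold sweep over the real-valued scores with trapezoidal area and
#' rank-averaged tie handling (pROC backend); equals the Mann-Whitney pair
#' statistic.
#'
#' @param scores Real-valued decision scores (larger means more positive).
#' @param labels Vector of -1/+1 labels; both classes must be present.
#' @return A list with `curve` (data frame of `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  y <- .as_pm1(labels)
  if (length(unique(y)) < 2L)
    stop("ROC undefined: both classes must be present")
  r <- pROC::roc(response = factor(y, levels = c(-1, 1)), predictor = scores,
                 levels = c("-1", "1"), direction = "<", quiet = TRUE)
  curve <- data.frame(fpr = rev(1 - r$specificities),
                      tpr = rev(r$sensitivities))
  list(curve = curve, auc = as.numeric(pROC::auc(r)))
}

#' Recode multi-class labels for a one-vs-all task
#' @param labels Integer class labels (e.g., EC classes 1..7).
#' @param positive_class The class mapped to +1; all others become -1.
#' @return Numeric vector of -1/+1 labels.
#' @export
one_vs_all_labels <- function(labels, positive_class) {
  if (!positive_class %in% labels)
    stop(sprintf("class %s is absent from the labels", positive_class))
  ifelse(labels == positive_class, 1, -1)
}

#' Stratified train/validation/test split
#'
#' Per-class proportions are preserved within one pattern of the requested
#' fractions; the index sets are disjoint, exhaustive and reproducible by
#' seed.
#'
#' @param labels Class labels (any discrete coding).
#' @param fractions Numeric vector summing to 1, one entry per split
#'   (default 60/20/20 train/validation/test).
#' @param seed Integer RNG seed.
#' @return A list of index vectors named `train`, `val`, `test` (or
#'   `split1`, ... for other fraction counts).
#' @export
stratified_split <- function(labels, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8, all(fractions >= 0))
  nm <- if (length(fractions) == 3L) c("train", "val", "test")
        else paste0("split", seq_along(fractions))
  set.seed(seed)
  out <- stats::setNames(vector("list", length(fractions)), nm)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < sum(fractions > 0))
      stop(sprintf("class %s has fewer patterns than splits", cl))
    idx <- sample(idx)
    counts <- diff(c(0L, round(cumsum(fractions) * length(idx))))
    at <- 0L
    for (s in seq_along(fractions)) {
      out[[s]] <- c(out[[s]], idx[seq_len(counts[s]) + at])
      at <- at + counts[s]
    }
  }
  lapply(out, sort)
}

#' Metrics report for one evaluated split
#'
#' Convenience wrapper producing the full figure-of-merit row used in the
#' result tables: accuracy, precision, recall, normalised informedness, AUC
#' (when scores are supplied) and prototype sparsity (when a mask is
#' supplied, as a percentage).
#'
#' @param truth,pred Vectors of -1/+1 labels.
#' @param scores Optional real-valued decision scores for the AUC.
#' @param mask Optional prototype mask for the sparsity column.
#' @return A list of named metrics.
#' @export
metrics_report <- function(truth, pred, scores = NULL, mask = NULL) {
  cc <- confusion_counts(truth, pred)
  bm <- tryCatch(basic_metrics(cc),
                 error = function(e) list(accuracy = (cc$tp + cc$tn) /
                                            (cc$tp + cc$tn + cc$fp + cc$fn),
                                          precision = NA_real_,
                                          recall = NA_real_))
  inf <- informedness(cc)
  out <- list(accuracy = bm$accuracy, precision = bm$precision,
              recall = bm$recall, informedness_norm = inf$j_norm)
  out$auc <- if (!is.null(scores)) roc_auc(scores, truth)$auc else NA_real_
  out$sparsity <- if (!is.null(mask)) 100 * mean(as.numeric(mask)) else NA_real_
  out
}

#' Knowledge-discovery reports across optimisation runs
#'
#' Averages the kernel-weight vectors across runs (which representations
#' matter) and summarises prototype selection (which training patterns were
#' elected, how often, and the mean selected percentage).
#'
#' @param runs List of runs, each a list with at least a `genome` element
#'   (see [evolve()]).
#' @return A list with `beta_profile`, `prototypes` (per-run lists, selection
#'   frequency, union) and `sparsity_pct`.
#' @export
knowledge_reports <- function(runs) {
  stopifnot(length(runs) >= 1L)
  betas <- do.call(rbind, lapply(runs, function(r) r$genome$beta))
  masks <- lapply(runs, function(r) as.integer(r$genome$mask))
  per_run <- lapply(masks, function(m) which(m == 1L))
  freq <- table(unlist(per_run)) / length(runs)
  list(beta_profile = colMeans(betas),
       prototypes = list(per_run = per_run,
                         frequency = freq,
                         union = sort(unique(unlist(per_run)))),
       sparsity_pct = 100 * mean(vapply(masks, mean, numeric(1L))))
}

#' Side-by-side comparison table of classifier reports
#' @param reports Named list of metric lists (see [metrics_report()]).
#' @return A data frame with one row per classifier.
#' @export
comparison_table <- function(reports) {
  cols <- c("accuracy", "precision", "recall", "informedness_norm", "auc")
  df <- do.call(rbind, lapply(reports, function(r)
    as.data.frame(r[cols])))
  df <- cbind(classifier = names(reports), df)
  rownames(df) <- NULL
  df
}
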