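#' Pairwise dissimilarity matrix between two pattern sets
#'
#' Entry (i, j) is the dissimilarity between query i and reference j. The
#' resulting rows are the dissimilarity-space coordinates of the query
#' patterns with respect to the reference set.
#'
#' @param queries,references Numeric matrices (one row per pattern) or lists
#'   of equal-length numeric vectors.
#' @param measure `"euclidean"` (default) or `"manhattan"`.
#' @param rep_id Optional representation id used in error messages.
#' @return A `nrow(queries) x nrow(references)` matrix of non-negative reals.
#' @export
pairwise_dissimilarity <- function(queries, references,
                                   measure = "euclidean", rep_id = NULL) {
  Q <- .as_pattern_matrix(queries)
  R <- .as_pattern_matrix(references)
  if (ncol(Q) != ncol(R))
    stop(sprintf("dimension mismatch%s: queries have %d columns, references %d",
                 if (is.null(rep_id)) "" else sprintf(" in representation %s", rep_id),
                 ncol(Q), ncol(R)))
  switch(measure,
    euclidean = {
      M <- outer(rowSums(Q^2), rowSums(R^2), "+") - 2 * tcrossprod(Q, R)
      sqrt(pmax(M, 0))
    },
    manhattan = {
      t(apply(Q, 1L, function(q) colSums(abs(t(R) - q))))
    },
    stop(sprintf("unknown dissimilarity measure '%s'", measure)))
}

.as_pattern_matrix <- function(x) {
  if (is.list(x)) {
    len <- unique(vapply(x, length, integer(1L)))
    if (length(len) != 1L) stop("pattern vectors have unequal lengths")
    x <- do.call(rbind, x)
  }
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  m
}

#' Symmetrize a square dissimilarity matrix
#' @param D Square numeric matrix.
#' @return `(D + t(D)) / 2`.
#' @export
symmetrize <- function(D) {
  if (nrow(D) != ncol(D)) stop("symmetrize requires a square matrix")
  (D + t(D)) / 2
}

#' Reduce a dissimilarity matrix to prototype columns
#'
#' Keeps the columns flagged by the binary prototype mask (order preserved);
#' with the all-ones mask the full dissimilarity space is retained.
#'
#' @param D Numeric matrix (rows = patterns, columns = training patterns).
#' @param mask Binary (0/1 or logical) vector of length `ncol(D)`.
#' @return The column slice of `D`.
#' @export
reduce_columns <- function(D, mask) {
  mask <- as.logical(mask)
  if (length(mask) != ncol(D))
    stop("prototype mask length must equal the column count")
  if (!any(mask))
    stop("degenerate prototype mask: at least one prototype must be selected")
  D[, mask, drop = FALSE]
}

#' Build per-representation dissimilarity stacks
#'
#' For every representation id, computes the train-vs-train matrix
#' (symmetrized, zero diagonal) and, when provided, the val-vs-train and
#' test-vs-train matrices. Full train matrices are computed once and sliced
#' per prototype mask downstream.
#'
#' @param train List of [representation_set()] objects (the training set).
#' @param val,test Optional lists of [representation_set()] objects.
#' @param measures Single measure name applied to every representation, or a
#'   named character vector keyed by representation id.
#' @param scale Standardise each representation's coordinates by
#'   training-set mean and standard deviation before computing distances?
#' @return A list with elements `train`, and `val`/`test` when given; each is
#'   a `dissimilarity_stack`: a list with `matrices` (named by representation
#'   id) and `measures`.
#' @export
build_stacks <- function(train, val = NULL, test = NULL,
                         measures = "euclidean", scale = FALSE) {
  ids <- names(train[[1L]]$vectors)
  meas <- if (length(measures) == 1L && is.null(names(measures)))
    stats::setNames(rep(measures, length(ids)), ids)
  else measures[ids]
  rep_matrix <- function(sets, id)
    do.call(rbind, lapply(sets, function(s) s$vectors[[id]]))
  one_split <- function(sets, Xtr_list, scalers, symmetric) {
    mats <- list()
    for (id in ids) {
      X <- if (symmetric) Xtr_list[[id]] else rep_matrix(sets, id)
      if (scale) X <- .apply_scaler(X, scalers[[id]])
      D <- pairwise_dissimilarity(X, Xtr_list_scaled[[id]], meas[[id]], id)
      if (symmetric) {
        D <- symmetrize(D)
        diag(D) <- 0
      }
      dimnames(D) <- NULL
      mats[[id]] <- D
    }
    structure(list(matrices = mats, measures = meas),
              class = "dissimilarity_stack")
  }
  Xtr_list <- stats::setNames(lapply(ids, function(id) rep_matrix(train, id)),
                              ids)
  scalers <- stats::setNames(lapply(ids, function(id)
    if (scale) .fit_scaler(Xtr_list[[id]]) else NULL), ids)
  Xtr_list_scaled <- stats::setNames(lapply(ids, function(id)
    if (scale) .apply_scaler(Xtr_list[[id]], scalers[[id]])
    else Xtr_list[[id]]), ids)
  out <- list(train = one_split(train, Xtr_list, scalers, symmetric = TRUE))
  if (!is.null(val)) out$val <- one_split(val, Xtr_list, scalers, FALSE)
  if (!is.null(test)) out$test <- one_split(test, Xtr_list, scalers, FALSE)
  out
}

.fit_scaler <- function(X) {
  mu <- colMeans(X)
  sdev <- apply(X, 2L, stats::sd)
  sdev[!is.finite(sdev) | sdev == 0] <- 1
  list(mu = mu, sd = sdev)
}

.apply_scaler <- function(X, scaler) {
  if (is.null(scaler)) return(X)
  sweep(sweep(X, 2L, scaler$mu, "-"), 2L, scaler$sd, "/")
}

#' Write a dissimilarity stack to CSV files with a JSON manifest
#'
#' One dense CSV per representation plus a manifest recording representation
#' ids, measure names and matrix shapes.
#'
#' @param stack A `dissimilarity_stack` from [build_stacks()].
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return The manifest path, invisibly.
#' @export
write_stack <- function(stack, dir, prefix = "stack") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  for (id in names(stack$matrices)) {
    f <- file.path(dir, sprintf("%s_rep%s.csv", prefix, id))
    utils::write.table(stack$matrices[[id]], f, sep = ",",
                       row.names = FALSE, col.names = FALSE)
    files[[id]] <- basename(f)
  }
  manifest <- file.path(dir, sprintf("%s_manifest.json", prefix))
  jsonlite::write_json(
    list(representations = names(stack$matrices),
         measures = as.list(stack$measures),
         shapes = lapply(stack$matrices, dim), files = files),
    manifest, auto_unbox = TRUE)
  invisible(manifest)
}
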