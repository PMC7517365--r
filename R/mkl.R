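#' Multiple-kernel specification
#'
#' Convex weights and RBF shape parameters for the per-representation
#' kernels: `beta_i in [0, 1]` summing to 1, `gamma_i in (0, 100]`.
#'
#' @param beta Numeric vector of kernel weights.
#' @param gamma Numeric vector of RBF shape parameters (same length).
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(beta, gamma) {
  if (length(beta) != length(gamma))
    stop("beta and gamma must have the same length")
  if (any(beta < 0) || any(beta > 1))
    stop("kernel weights must lie in [0, 1]")
  if (abs(sum(beta) - 1) > 1e-12)
    stop("kernel weights must sum to 1 (tolerance 1e-12)")
  if (any(gamma <= 0) || any(gamma > 100))
    stop("kernel shapes must lie in (0, 100]")
  structure(list(beta = as.numeric(beta), gamma = as.numeric(gamma)),
            class = "kernel_spec")
}

#' RBF kernel over dissimilarity-space coordinates
#'
#' Entry (j, k) is `exp(-gamma * ||row_j - col_k||^2)` where rows and columns
#' are dissimilarity-space coordinate vectors (rows of the reduced
#' dissimilarity matrices).
#'
#' @param rows,cols Numeric matrices sharing their column (prototype)
#'   dimension.
#' @param gamma Positive shape parameter.
#' @return A `nrow(rows) x nrow(cols)` kernel matrix with entries in (0, 1].
#' @export
rbf_from_dissimilarity <- function(rows, cols, gamma) {
  if (gamma <= 0) stop("gamma must be positive")
  rows <- as.matrix(rows); cols <- as.matrix(cols)
  if (ncol(rows) != ncol(cols))
    stop("dimension mismatch: rows and cols must share the prototype dimension")
  M <- outer(rowSums(rows^2), rowSums(cols^2), "+") - 2 * tcrossprod(rows, cols)
  exp(-gamma * pmax(M, 0))
}

#' Convex combination of per-representation kernels
#'
#' Weighted sum `sum_i beta_i K^(i)`; with non-negative weights summing to
#' one, a sum of positive semi-definite kernels stays positive semi-definite
#' and entries stay in [0, 1].
#'
#' @param per_rep List of equal-shape kernel matrices, one per
#'   representation.
#' @param spec A [kernel_spec()] with one weight/shape pair per matrix.
#' @return The combined kernel matrix.
#' @export
combine_kernels <- function(per_rep, spec) {
  stopifnot(inherits(spec, "kernel_spec"),
            length(per_rep) == length(spec$beta))
  dims <- unique(lapply(per_rep, dim))
  if (length(dims) != 1L) stop("kernel matrices must share the same shape")
  K <- matrix(0, dims[[1L]][1L], dims[[1L]][2L])
  for (i in seq_along(per_rep)) K <- K + spec$beta[i] * per_rep[[i]]
  K
}

#' Build the combined multiple kernel from reduced dissimilarity matrices
#'
#' Applies the per-representation RBF kernels to the (mask-reduced)
#' dissimilarity coordinates and combines them convexly.
#'
#' @param rows_list,cols_list Lists of reduced dissimilarity matrices (same
#'   representation order as `spec`). For a train-vs-train kernel pass the
#'   same list twice.
#' @param spec A [kernel_spec()].
#' @return The combined kernel matrix.
#' @export
multiple_kernel <- function(rows_list, cols_list, spec) {
  per_rep <- lapply(seq_along(rows_list), function(i)
    rbf_from_dissimilarity(rows_list[[i]], cols_list[[i]], spec$gamma[i]))
  combine_kernels(per_rep, spec)
}

.as_pm1 <- function(y) {
  y <- if (is.factor(y)) as.numeric(as.character(y)) else as.numeric(y)
  if (!all(y %in% c(-1, 1)))
    stop("labels must be coded as -1/+1")
  y
}

#' Train a nu-SVM on a precomputed kernel
#'
#' Fits a kernelised nu-SVM (kernlab backend, solver tolerance fixed at
#' 1e-3 for determinism) on a precomputed train-vs-train kernel matrix.
#' The decision function is evaluated from the stored dual coefficients, with
#' its sign calibrated so that positive scores correspond to the +1 class.
#'
#' @param K_train Symmetric positive semi-definite kernel matrix.
#' @param labels Vector of -1/+1 class labels.
#' @param nu Regulariser in (0, 1]; must be feasible for the class balance.
#' @param tol Solver tolerance.
#' @return An object of class `mkmd_svm` with elements `alpha_y` (signed dual
#'   coefficients), `b` (bias), `sv_index`, `sign`, `nu`, `n_train`, `fitted`.
#' @export
train_nu_svm <- function(K_train, labels, nu, tol = 1e-3) {
  if (!is.numeric(nu) || length(nu) != 1L || nu <= 0 || nu > 1)
    stop("nu must be a scalar in (0, 1]")
  y <- .as_pm1(labels)
  if (length(unique(y)) < 2L)
    stop("training labels must contain both classes")
  if (nrow(K_train) != ncol(K_train) || nrow(K_train) != length(y))
    stop("kernel matrix shape must match the label vector")
  yf <- factor(y, levels = c(-1, 1))
  fit <- kernlab::ksvm(kernlab::as.kernelMatrix(K_train), yf,
                       type = "nu-svc", nu = nu, tol = tol)
  svi <- kernlab::SVindex(fit)
  if (length(svi) == 0L) stop("training produced no support vectors")
  alpha_y <- kernlab::coef(fit)[[1L]]
  b <- kernlab::b(fit)
  raw <- as.numeric(K_train[, svi, drop = FALSE] %*% alpha_y - b)
  pk <- as.numeric(as.character(
    kernlab::predict(fit, kernlab::as.kernelMatrix(
      K_train[, svi, drop = FALSE]))))
  sgn <- sign(sum(raw * pk))
  if (sgn == 0) sgn <- 1
  scores <- sgn * raw
  structure(list(alpha_y = alpha_y, b = b, sv_index = svi, sign = sgn,
                 nu = nu, tol = tol, n_train = length(y),
                 fitted = ifelse(scores > 0, 1, -1)),
            class = "mkmd_svm")
}

#' Predict from a trained nu-SVM
#'
#' @param model An `mkmd_svm` from [train_nu_svm()].
#' @param K_query Query-vs-train kernel matrix; columns must be aligned to
#'   the training pattern order used at fit time.
#' @return A list with `labels` (-1/+1) and `scores` (real decision values;
#'   strictly positive scores correspond to +1).
#' @export
predict_nu_svm <- function(model, K_query) {
  K_query <- as.matrix(K_query)
  if (ncol(K_query) != model$n_train)
    stop("query kernel columns must align with the training pattern order")
  raw <- as.numeric(K_query[, model$sv_index, drop = FALSE] %*% model$alpha_y -
                      model$b)
  scores <- model$sign * raw
  list(labels = ifelse(scores > 0, 1, -1), scores = scores)
}

#' Serialize a trained nu-SVM (with its kernel spec and mask) to JSON
#' @param model An `mkmd_svm`.
#' @param path Output file path.
#' @param spec Optional [kernel_spec()] stored alongside.
#' @param mask Optional prototype mask stored alongside.
#' @return `path`, invisibly.
#' @export
write_svm_json <- function(model, path, spec = NULL, mask = NULL) {
  obj <- list(alpha_y = model$alpha_y, b = model$b,
              sv_index = model$sv_index, sign = model$sign, nu = model$nu,
              tol = model$tol, n_train = model$n_train,
              fitted = model$fitted)
  if (!is.null(spec)) obj$spec <- unclass(spec)
  if (!is.null(mask)) obj$mask <- as.integer(mask)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Reload a nu-SVM serialized by [write_svm_json()]
#' @param path JSON file path.
#' @return A list with `model` (`mkmd_svm`) and, when stored, `spec`, `mask`.
#' @export
read_svm_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- structure(
    list(alpha_y = as.numeric(obj$alpha_y), b = as.numeric(obj$b),
         sv_index = as.integer(obj$sv_index), sign = as.numeric(obj$sign),
         nu = as.numeric(obj$nu), tol = as.numeric(obj$tol),
         n_train = as.integer(obj$n_train),
         fitted = as.numeric(obj$fitted)),
    class = "mkmd_svm")
  out <- list(model = model)
  if (!is.null(obj$spec))
    out$spec <- kernel_spec(obj$spec$beta, obj$spec$gamma)
  if (!is.null(obj$mask)) out$mask <- as.integer(obj$mask)
  out
}
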