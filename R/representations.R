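#' Representation configuration
#'
#' Free parameters of the eight graph-descriptor representations. Defaults:
#' Betti numbers up to dimension 1; five node centralities summarised by mean
#' and standard deviation; ten log-spaced heat-trace times in `[1e-2, 10]`;
#' five heat-content coefficients; spectral density sampled at 100 uniform
#' points on `[0, 2]` (the support of the normalized-Laplacian spectrum) with
#' Silverman bandwidth.
#'
#' @param betti_max_dim Highest homology dimension to report.
#' @param centrality_measures Subset of `"degree"`, `"closeness"`,
#'   `"betweenness"`, `"eigenvector"`, `"clustering"`.
#' @param centrality_aggregates Subset of `"mean"`, `"sd"`.
#' @param heat_t_grid Strictly increasing positive times for the heat trace.
#' @param heat_content_order Number of heat-content expansion coefficients.
#' @param density_grid Strictly increasing evaluation points for the spectral
#'   density.
#' @param density_bandwidth Positive kernel bandwidth, or `NULL` for
#'   Silverman's rule.
#' @return An object of class `rep_config`.
#' @export
rep_config <- function(betti_max_dim = 1L,
                       centrality_measures = c("degree", "closeness",
                                               "betweenness", "eigenvector",
                                               "clustering"),
                       centrality_aggregates = c("mean", "sd"),
                       heat_t_grid = 10^seq(-2, 1, length.out = 10),
                       heat_content_order = 5L,
                       density_grid = seq(0, 2, length.out = 100),
                       density_bandwidth = NULL) {
  known <- c("degree", "closeness", "betweenness", "eigenvector", "clustering")
  bad <- setdiff(centrality_measures, known)
  if (length(bad))
    stop("unknown centrality measure(s): ", paste(bad, collapse = ", "))
  stopifnot(betti_max_dim >= 0, heat_content_order >= 1,
            all(diff(heat_t_grid) > 0), all(heat_t_grid > 0),
            all(diff(density_grid) > 0),
            all(centrality_aggregates %in% c("mean", "sd")))
  if (!is.null(density_bandwidth) && density_bandwidth <= 0)
    stop("density_bandwidth must be positive")
  structure(list(betti_max_dim = as.integer(betti_max_dim),
                 centrality_measures = centrality_measures,
                 centrality_aggregates = centrality_aggregates,
                 heat_t_grid = heat_t_grid,
                 heat_content_order = as.integer(heat_content_order),
                 density_grid = density_grid,
                 density_bandwidth = density_bandwidth),
            class = "rep_config")
}

# Laplacians ------------------------------------------------------------

.laplacian <- function(net) {
  A <- adjacency_matrix(net)
  diag(rowSums(A), net$n_nodes) - A
}

.norm_laplacian <- function(net) {
  A <- adjacency_matrix(net)
  d <- rowSums(A)
  s <- ifelse(d > 0, 1 / sqrt(d), 0)
  L <- -A * outer(s, s)
  diag(L) <- ifelse(d > 0, 1, 0)
  L
}

# X(1): Betti numbers ---------------------------------------------------

#' Betti numbers of the clique (flag) complex of a graph
#'
#' Ranks of the homology groups of the Vietoris-Rips complex built on the
#' graph (simplices = cliques), computed from boundary-matrix ranks over the
#' rationals. `b0` is the number of connected components.
#'
#' @param net A [contact_network()].
#' @param max_dim Highest homology dimension (`>= 0`).
#' @return Numeric vector `(b0, ..., b_max_dim)`.
#' @export
betti_numbers <- function(net, max_dim = 1L) {
  if (max_dim < 0) stop("max_dim must be non-negative")
  g <- pcn_graph(net)
  n <- net$n_nodes
  # simplices with k vertices = (k-1)-dimensional; need up to max_dim + 2
  simp <- vector("list", max_dim + 2L)
  simp[[1L]] <- matrix(seq_len(n), ncol = 1L)
  for (k in seq(2L, max_dim + 2L)) {
    cl <- igraph::cliques(g, min = k, max = k)
    simp[[k]] <- if (length(cl))
      t(vapply(cl, function(x) sort(as.integer(x)), integer(k)))
    else matrix(integer(), ncol = k)
  }
  key <- function(m) apply(m, 1L, paste, collapse = "-")
  brank <- function(k) {
    # rank of the boundary map from k-vertex simplices to (k-1)-vertex ones
    upper <- simp[[k]]
    if (nrow(upper) == 0L) return(0L)
    lower_keys <- key(simp[[k - 1L]])
    B <- matrix(0, nrow(simp[[k - 1L]]), nrow(upper))
    for (j in seq_len(nrow(upper))) {
      for (drop in seq_len(k)) {
        face <- paste(upper[j, -drop], collapse = "-")
        B[match(face, lower_keys), j] <- (-1)^(drop - 1L)
      }
    }
    qr(B)$rank
  }
  ranks <- vapply(seq(2L, max_dim + 2L), brank, integer(1L))
  counts <- vapply(simp, nrow, integer(1L))
  b <- numeric(max_dim + 1L)
  for (d in 0:max_dim) {
    rk_low <- if (d == 0L) 0L else ranks[d]       # rank of boundary_d
    b[d + 1L] <- counts[d + 1L] - rk_low - ranks[d + 1L]
  }
  b
}

# X(2): centrality profile ----------------------------------------------

.centrality_values <- function(g, measure) {
  n <- igraph::vcount(g)
  v <- switch(measure,
    degree = if (n > 1L) igraph::degree(g) / (n - 1L) else rep(0, n),
    closeness = suppressWarnings(igraph::closeness(g, normalized = TRUE)),
    betweenness = igraph::betweenness(g, normalized = TRUE),
    eigenvector = suppressWarnings(igraph::eigen_centrality(g)$vector),
    clustering = igraph::transitivity(g, type = "localundirected",
                                      isolates = "zero"))
  v[!is.finite(v)] <- 0
  v
}

#' Node-centrality profile of a graph
#'
#' For each configured node-level centrality, the configured summary
#' statistics over nodes, concatenated in fixed (measure-major) order.
#' Non-finite per-node values (e.g., closeness of isolated nodes) are set
#' to zero.
#'
#' @param net A [contact_network()].
#' @param cfg A [rep_config()].
#' @return Numeric vector of length `measures x aggregates`.
#' @export
centrality_profile <- function(net, cfg = rep_config()) {
  g <- pcn_graph(net)
  agg <- list(mean = mean, sd = function(x) if (length(x) > 1L) stats::sd(x) else 0)
  out <- unlist(lapply(cfg$centrality_measures, function(m) {
    v <- .centrality_values(g, m)
    vapply(cfg$centrality_aggregates, function(a) agg[[a]](v), numeric(1L))
  }))
  out[!is.finite(out)] <- 0
  unname(out)
}

# X(3): graph energies --------------------------------------------------

#' Graph energy and Laplacian energy
#'
#' `E = sum |lambda_i(A)|` over adjacency eigenvalues and
#' `LE = sum |mu_i(L) - 2m/n|` over combinatorial-Laplacian eigenvalues
#' (n nodes, m edges).
#'
#' @param net A [contact_network()].
#' @return Numeric vector `c(energy, laplacian_energy)`.
#' @export
graph_energies <- function(net) {
  A <- adjacency_matrix(net)
  lam <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  mu <- eigen(.laplacian(net), symmetric = TRUE, only.values = TRUE)$values
  m <- nrow(net$edges)
  c(sum(abs(lam)), sum(abs(mu - 2 * m / net$n_nodes)))
}

# X(4): network cartography ---------------------------------------------

#' Network cartography role profile
#'
#' Detects modules by modularity maximisation (greedy agglomeration), computes
#' each node's within-module degree z-score and participation coefficient, and
#' assigns each node to one of the seven cartographic roles (four non-hub
#' roles for z < 2.5, three hub roles for z >= 2.5, split by participation).
#'
#' @param net A [contact_network()] with at least one edge.
#' @return Numeric vector of the 7 role fractions followed by the achieved
#'   modularity (length 8).
#' @export
cartography_profile <- function(net) {
  if (nrow(net$edges) == 0L)
    stop("degenerate input: cartography requires at least one edge")
  g <- pcn_graph(net)
  comm <- igraph::cluster_fast_greedy(igraph::simplify(g))
  mem <- as.integer(igraph::membership(comm))
  mod <- igraph::modularity(g, mem)
  A <- adjacency_matrix(net)
  deg <- rowSums(A)
  mods <- sort(unique(mem))
  # node x module contact counts
  kis <- vapply(mods, function(s) rowSums(A[, mem == s, drop = FALSE]),
                numeric(net$n_nodes))
  kis <- matrix(kis, nrow = net$n_nodes)
  kin <- kis[cbind(seq_len(net$n_nodes), match(mem, mods))]
  z <- numeric(net$n_nodes)
  for (s in seq_along(mods)) {
    idx <- mem == mods[s]
    mu <- mean(kin[idx])
    sdev <- sqrt(mean((kin[idx] - mu)^2))
    z[idx] <- if (sdev > 0) (kin[idx] - mu) / sdev else 0
  }
  P <- ifelse(deg > 0, 1 - rowSums((kis / pmax(deg, 1))^2), 0)
  role <- integer(net$n_nodes)
  nonhub <- z < 2.5
  role[nonhub & P <= 0.05] <- 1L
  role[nonhub & P > 0.05 & P <= 0.62] <- 2L
  role[nonhub & P > 0.62 & P <= 0.80] <- 3L
  role[nonhub & P > 0.80] <- 4L
  role[!nonhub & P <= 0.30] <- 5L
  role[!nonhub & P > 0.30 & P <= 0.75] <- 6L
  role[!nonhub & P > 0.75] <- 7L
  c(tabulate(role, 7L) / net$n_nodes, mod)
}

# X(5): heat content invariants ------------------------------------------

#' Heat content of the normalized-Laplacian heat kernel
#'
#' `Q(t) = sum_k (sum_u phi_k(u))^2 exp(-lambda_k t)` from the spectral
#' decomposition of the symmetric normalized Laplacian.
#'
#' @param net A [contact_network()] with at least one edge.
#' @param t Non-negative time (vectorised).
#' @return Numeric vector of `Q(t)` values.
#' @export
heat_content <- function(net, t) {
  if (nrow(net$edges) == 0L)
    stop("degenerate input: heat content requires at least one edge")
  e <- eigen(.norm_laplacian(net), symmetric = TRUE)
  s2 <- colSums(e$vectors)^2
  vapply(t, function(tt) sum(s2 * exp(-e$values * tt)), numeric(1L))
}

#' Heat-content invariants
#'
#' First `order` coefficients `q_1 ... q_order` of the small-t polynomial
#' expansion `Q(t) = sum_m q_m t^m`, with
#' `q_m = sum_k (sum_u phi_k(u))^2 (-lambda_k)^m / m!` over the spectrum of
#' the symmetric normalized Laplacian.
#'
#' @param net A [contact_network()] with at least one edge.
#' @param order Number of coefficients (`>= 1`).
#' @return Numeric vector of length `order`.
#' @export
heat_content_invariants <- function(net, order = 5L) {
  stopifnot(order >= 1)
  if (nrow(net$edges) == 0L)
    stop("degenerate input: heat-content invariants require at least one edge")
  e <- eigen(.norm_laplacian(net), symmetric = TRUE)
  s2 <- colSums(e$vectors)^2
  vapply(seq_len(order),
         function(m) sum(s2 * (-e$values)^m) / factorial(m),
         numeric(1L))
}

# X(6): heat kernel trace -----------------------------------------------

#' Heat-kernel trace of a graph
#'
#' `sum_k exp(-lambda_k t)` over the eigenvalues of the combinatorial
#' Laplacian, evaluated on a grid of times. At `t = 0` the trace equals the
#' node count; for large `t` it tends to the number of connected components.
#'
#' @param net A [contact_network()].
#' @param t_grid Non-empty vector of non-negative times.
#' @return Numeric vector, one entry per time.
#' @export
heat_trace <- function(net, t_grid) {
  if (length(t_grid) == 0L) stop("t_grid must be non-empty")
  if (any(t_grid < 0)) stop("times must be non-negative")
  lam <- eigen(.laplacian(net), symmetric = TRUE, only.values = TRUE)$values
  vapply(t_grid, function(tt) sum(exp(-lam * tt)), numeric(1L))
}

# X(7): protein size ----------------------------------------------------

#' Pattern size
#' @param net A [contact_network()].
#' @return Numeric vector of length 1: the node count.
#' @export
protein_size <- function(net) as.numeric(net$n_nodes)

# X(8): spectral density ------------------------------------------------

#' Sampled spectral density of a graph
#'
#' Gaussian kernel density estimate of the symmetric normalized-Laplacian
#' eigenvalue distribution, evaluated at fixed grid points.
#'
#' @param net A [contact_network()].
#' @param grid Non-empty vector of evaluation points.
#' @param bandwidth Positive bandwidth, or `NULL` for Silverman's rule (with
#'   a small fallback when the spectrum is degenerate).
#' @return Numeric vector of densities, one per grid point.
#' @export
spectral_density <- function(net, grid = seq(0, 2, length.out = 100),
                             bandwidth = NULL) {
  if (length(grid) == 0L) stop("grid must be non-empty")
  if (!is.null(bandwidth) && bandwidth <= 0)
    stop("bandwidth must be positive")
  lam <- eigen(.norm_laplacian(net), symmetric = TRUE,
               only.values = TRUE)$values
  bw <- bandwidth
  if (is.null(bw)) {
    bw <- tryCatch(stats::bw.nrd0(lam), error = function(e) NA_real_)
    if (!is.finite(bw) || bw <= 0) bw <- 0.05
  }
  vapply(grid, function(x) mean(stats::dnorm((x - lam) / bw)) / bw,
         numeric(1L))
}

# All eight --------------------------------------------------------------

#' Representation set
#'
#' Container for the eight fixed-length numeric vectors describing one
#' pattern. `vectors` is a named list keyed `"1"`..`"8"`.
#'
#' @param vectors Named list of numeric vectors.
#' @return An object of class `representation_set`.
#' @export
representation_set <- function(vectors) {
  stopifnot(is.list(vectors), length(vectors) >= 1L)
  if (is.null(names(vectors))) names(vectors) <- as.character(seq_along(vectors))
  ok <- vapply(vectors, function(v) is.numeric(v) && all(is.finite(v)),
               logical(1L))
  if (!all(ok))
    stop("non-finite representation vector(s): ",
         paste(names(vectors)[!ok], collapse = ", "))
  structure(list(vectors = vectors,
                 dims = vapply(vectors, length, integer(1L))),
            class = "representation_set")
}

#' Compute all eight representations of a contact network
#'
#' X(1) Betti numbers, X(2) centrality profile, X(3) graph energies,
#' X(4) network cartography, X(5) heat-content invariants, X(6) heat-kernel
#' trace, X(7) size, X(8) sampled spectral density. Per-representation
#' failures are collected and reported together, tagged by representation id.
#'
#' @param net A [contact_network()].
#' @param cfg A [rep_config()].
#' @return A [representation_set()].
#' @export
extract_all <- function(net, cfg = rep_config()) {
  fns <- list(
    `1` = function() betti_numbers(net, cfg$betti_max_dim),
    `2` = function() centrality_profile(net, cfg),
    `3` = function() graph_energies(net),
    `4` = function() cartography_profile(net),
    `5` = function() heat_content_invariants(net, cfg$heat_content_order),
    `6` = function() heat_trace(net, cfg$heat_t_grid),
    `7` = function() protein_size(net),
    `8` = function() spectral_density(net, cfg$density_grid,
                                      cfg$density_bandwidth))
  out <- vector("list", 8L)
  names(out) <- names(fns)
  errs <- character()
  for (id in names(fns)) {
    res <- tryCatch(fns[[id]](), error = function(e) e)
    if (inherits(res, "error"))
      errs <- c(errs, sprintf("X(%s): %s", id, conditionMessage(res)))
    else out[[id]] <- res
  }
  if (length(errs))
    stop("representation extraction failed [", paste(errs, collapse = "; "),
         "]", call. = FALSE)
  representation_set(out)
}

#' Write representation sets to CSV
#'
#' Wide layout: one row per pattern per representation, value columns padded
#' with `NA` up to the largest representation length. An optional JSON sidecar
#' records the configuration.
#'
#' @param sets List of [representation_set()] objects.
#' @param path Output CSV path.
#' @param cfg Optional [rep_config()] written as `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_representations <- function(sets, path, cfg = NULL) {
  maxd <- max(unlist(lapply(sets, function(s) s$dims)))
  rows <- list()
  for (p in seq_along(sets)) {
    for (id in names(sets[[p]]$vectors)) {
      v <- sets[[p]]$vectors[[id]]
      rows[[length(rows) + 1L]] <-
        c(pattern = p, rep = as.integer(id),
          stats::setNames(c(v, rep(NA_real_, maxd - length(v))),
                          paste0("v", seq_len(maxd))))
    }
  }
  df <- as.data.frame(do.call(rbind, rows))
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(cfg))
    jsonlite::write_json(unclass(cfg), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read representation sets back from CSV
#' @param path CSV written by [write_representations()].
#' @return List of [representation_set()] objects.
#' @export
read_representations <- function(path) {
  df <- utils::read.csv(path)
  lapply(split(df, df$pattern), function(dp) {
    vecs <- lapply(split(dp, dp$rep), function(dr) {
      v <- as.numeric(dr[1L, -(1:2)])
      v[!is.na(v)]
    })
    representation_set(vecs)
  })
}
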