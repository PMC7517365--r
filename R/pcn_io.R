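#' Residue chain
#'
#' A parsed protein chain reduced to its alpha-carbon trace: one 3D coordinate
#' per residue, plus the header metadata needed by the dataset-quality filters
#' (crystallographic resolution and Enzyme Commission labels).
#'
#' @param identifier Character scalar naming the structure (e.g., PDB id).
#' @param coordinates Numeric matrix with one row per residue and three
#'   columns (x, y, z, in Angstrom).
#' @param resolution Measurement resolution in Angstrom, or `NA` when the
#'   header does not state one.
#' @param ec_labels Integer vector of EC top-level codes (1-6) attached to the
#'   structure; empty for non-enzymes.
#' @return An object of class `residue_chain`.
#' @export
residue_chain <- function(identifier, coordinates, resolution = NA_real_,
                          ec_labels = integer()) {
  coordinates <- as.matrix(coordinates)
  storage.mode(coordinates) <- "double"
  if (ncol(coordinates) != 3L)
    stop("coordinates must have three columns (x, y, z)")
  if (nrow(coordinates) < 1L || !all(is.finite(coordinates)))
    stop("coordinates must be non-empty and finite")
  structure(
    list(identifier = as.character(identifier)[1L],
         coordinates = unname(coordinates),
         resolution = as.numeric(resolution)[1L],
         ec_labels = sort(unique(as.integer(ec_labels)))),
    class = "residue_chain")
}

#' @export
print.residue_chain <- function(x, ...) {
  cat(sprintf("<residue_chain '%s': %d residues, resolution %s, EC {%s}>\n",
              x$identifier, nrow(x$coordinates),
              ifelse(is.na(x$resolution), "NA", format(x$resolution)),
              paste(x$ec_labels, collapse = ",")))
  invisible(x)
}

#' Number of residues in a chain
#' @param chain A [residue_chain()].
#' @return Integer residue count.
#' @export
chain_length <- function(chain) nrow(chain$coordinates)

#' Top-level functional class of a chain
#'
#' First digit of the EC number when a single one is present; structures
#' without any EC annotation are assigned the categorical non-enzyme class 7.
#'
#' @param chain A [residue_chain()].
#' @return Integer class label in 1..7.
#' @export
ec_class <- function(chain) {
  if (length(chain$ec_labels) == 0L) return(7L)
  if (length(chain$ec_labels) > 1L)
    stop("chain carries multiple EC labels; filter before labelling")
  chain$ec_labels
}

#' Parse alpha-carbon coordinates from PDB text
#'
#' Reads the ATOM records of a PDB-format file through bio3d and keeps the
#' alpha-carbon trace. For multi-model files only the first model is retained;
#' for atoms with alternate locations only the first ("A") location is kept.
#' Resolution (REMARK 2) and EC annotation (COMPND "EC:") are parsed from the
#' header when present.
#'
#' @param pdb_text Character vector of PDB lines, or a single string with
#'   embedded newlines.
#' @param identifier Name used for the resulting chain and in error messages.
#' @param chains Either `"all"` (concatenate all chains in file order into one
#'   residue sequence, the default, matching a whole-structure contact
#'   network) or `"first"` (first chain only).
#' @return A [residue_chain()].
#' @export
parse_ca_coordinates <- function(pdb_text, identifier = "pdb",
                                 chains = c("all", "first")) {
  chains <- match.arg(chains)
  if (length(pdb_text) == 1L) pdb_text <- strsplit(pdb_text, "\n")[[1L]]
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(pdb_text, tf)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(tf, multi = FALSE, rm.alt = TRUE,
                                     verbose = FALSE)),
    error = function(e) stop(sprintf("cannot parse PDB input '%s': %s",
                                     identifier, conditionMessage(e)),
                             call. = FALSE))
  sel <- bio3d::atom.select(pdb, "calpha", verbose = FALSE)
  atoms <- pdb$atom[sel$atom, , drop = FALSE]
  if (nrow(atoms) == 0L)
    stop(sprintf("no alpha-carbon atoms found in '%s'", identifier),
         call. = FALSE)
  if (chains == "first")
    atoms <- atoms[atoms$chain %in% atoms$chain[1L], , drop = FALSE]
  residue_chain(identifier,
                cbind(atoms$x, atoms$y, atoms$z),
                resolution = .parse_resolution(pdb_text),
                ec_labels = .parse_ec_labels(pdb_text))
}

.parse_resolution <- function(lines) {
  hit <- grep("^REMARK +2 +RESOLUTION", lines, value = TRUE)
  if (length(hit) == 0L) return(NA_real_)
  m <- regmatches(hit[1L],
                  regexpr("[0-9]+\\.?[0-9]*(?= *ANGSTROM)", hit[1L],
                          perl = TRUE))
  if (length(m) == 0L) NA_real_ else as.numeric(m)
}

.parse_ec_labels <- function(lines) {
  hit <- grep("^COMPND.*EC:", lines, value = TRUE)
  if (length(hit) == 0L) return(integer())
  ecs <- sub("^.*EC:", "", paste(hit, collapse = " "))
  ecs <- strsplit(gsub(";", "", ecs), ",")[[1L]]
  first <- suppressWarnings(as.integer(sub("^\\s*([0-9]+)\\..*$", "\\1", ecs)))
  sort(unique(first[!is.na(first)]))
}

#' Contact network
#'
#' Minimal unweighted, undirected graph representation of a structure: node
#' indices in `1..n_nodes`, an edge set stored as a two-column matrix with
#' `i < j`, no self-loops, no labels.
#'
#' @param n_nodes Positive integer node count.
#' @param edges Two-column integer matrix of node-index pairs (may have zero
#'   rows).
#' @return An object of class `contact_network`.
#' @export
contact_network <- function(n_nodes, edges = matrix(integer(), ncol = 2L)) {
  n_nodes <- as.integer(n_nodes)
  stopifnot(length(n_nodes) == 1L, n_nodes >= 1L)
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges)) {
    if (any(edges < 1L) || any(edges > n_nodes))
      stop("edge indices out of range")
    if (any(edges[, 1L] == edges[, 2L]))
      stop("self-loops are not allowed")
    edges <- cbind(pmin(edges[, 1L], edges[, 2L]),
                   pmax(edges[, 1L], edges[, 2L]))
    edges <- unique(edges)
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  structure(list(n_nodes = n_nodes, edges = edges), class = "contact_network")
}

#' @export
print.contact_network <- function(x, ...) {
  cat(sprintf("<contact_network: %d nodes, %d edges>\n",
              x$n_nodes, nrow(x$edges)))
  invisible(x)
}

#' Convert a contact network to an igraph graph
#' @param net A [contact_network()].
#' @return An undirected igraph graph on the same node set.
#' @export
pcn_graph <- function(net) {
  igraph::make_graph(as.vector(t(net$edges)), n = net$n_nodes,
                     directed = FALSE)
}

#' Dense adjacency matrix of a contact network
#' @param net A [contact_network()].
#' @return A symmetric 0/1 matrix.
#' @export
adjacency_matrix <- function(net) {
  A <- matrix(0, net$n_nodes, net$n_nodes)
  if (nrow(net$edges)) {
    A[net$edges] <- 1
    A[net$edges[, c(2L, 1L), drop = FALSE]] <- 1
  }
  A
}

#' Build a protein contact network from an alpha-carbon trace
#'
#' Places an edge between residues i and j (i != j) whenever the Euclidean
#' distance between their alpha carbons lies in the closed interval
#' `[lower, upper]`. The default band of 4 to 8 Angstrom discards trivial
#' backbone-neighbour contacts (consecutive alpha carbons sit around 3.8 A
#' apart) while the upper bound reflects peptide-bond geometry (roughly two
#' van der Waals radii).
#'
#' @param chain A [residue_chain()] with at least two residues.
#' @param lower,upper Closed contact band in Angstrom, `0 <= lower < upper`.
#' @return A [contact_network()] with one node per residue.
#' @export
build_pcn <- function(chain, lower = 4, upper = 8) {
  stopifnot(is.numeric(lower), is.numeric(upper), lower >= 0, lower < upper)
  n <- chain_length(chain)
  if (n < 2L)
    stop("degenerate input: a contact network needs at least two residues")
  dm <- as.matrix(stats::dist(chain$coordinates))
  idx <- which(upper.tri(dm) & dm >= lower & dm <= upper, arr.ind = TRUE)
  contact_network(n, idx)
}

#' Apply dataset-quality filters to parsed chains
#'
#' Discards chains with missing resolution, resolution strictly greater than
#' `max_resolution` (records at exactly the bound are retained), more residues
#' than `max_nodes`, or more than one distinct EC top-level label. Input order
#' is preserved; each discarded record is counted once under the first rule it
#' violates.
#'
#' @param records List of [residue_chain()] objects.
#' @param max_resolution Maximum admissible resolution in Angstrom.
#' @param max_nodes Maximum admissible residue count.
#' @param single_ec_only Drop chains carrying more than one EC label?
#' @return A list with `chains` (the survivors) and `report` (named counts per
#'   rule, plus `input` and `kept`).
#' @export
filter_dataset <- function(records, max_resolution = 3, max_nodes = 1500,
                           single_ec_only = TRUE) {
  report <- c(input = length(records), missing_resolution = 0L,
              high_resolution = 0L, too_large = 0L, multiple_ec = 0L,
              kept = 0L)
  keep <- logical(length(records))
  for (i in seq_along(records)) {
    ch <- records[[i]]
    if (is.na(ch$resolution)) {
      report["missing_resolution"] <- report["missing_resolution"] + 1L
    } else if (ch$resolution > max_resolution) {
      report["high_resolution"] <- report["high_resolution"] + 1L
    } else if (chain_length(ch) > max_nodes) {
      report["too_large"] <- report["too_large"] + 1L
    } else if (single_ec_only && length(ch$ec_labels) > 1L) {
      report["multiple_ec"] <- report["multiple_ec"] + 1L
    } else {
      keep[i] <- TRUE
    }
  }
  report["kept"] <- sum(keep)
  list(chains = records[keep], report = report)
}

#' Write a contact network as edge-list text
#' @param net A [contact_network()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pcn_edgelist <- function(net, path) {
  writeLines(c(sprintf("# nodes %d", net$n_nodes),
               sprintf("%d %d", net$edges[, 1L], net$edges[, 2L])), path)
  invisible(path)
}

#' Write a contact network adjacency in MatrixMarket format
#' @param net A [contact_network()].
#' @param path Output file path (.mtx).
#' @return `path`, invisibly.
#' @export
write_pcn_matrix <- function(net, path) {
  A <- Matrix::sparseMatrix(i = c(net$edges[, 1L], net$edges[, 2L]),
                            j = c(net$edges[, 2L], net$edges[, 1L]),
                            x = 1, dims = c(net$n_nodes, net$n_nodes))
  Matrix::writeMM(A, path)
  invisible(path)
}

#' Write a filter report as JSON
#' @param report Named counts from [filter_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(as.list(report), path, auto_unbox = TRUE)
  invisible(path)
}
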