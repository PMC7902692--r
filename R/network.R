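#' Sparse undirected network of biomarkers
#'
#' Lightweight container for an undirected, labeled graph with optional
#' signed edge weights (partial correlations in \[-1, 1\]). Edges are stored
#' canonically (lexicographically ordered label pairs, no self-loops, no
#' duplicates), which makes the set operations used in comparative network
#' analysis exact.
#'
#' @param labels character vector of node labels (order is preserved and used
#'   for deterministic component/community ordering).
#' @param edges two-column character matrix or data.frame of label pairs
#'   (may be empty).
#' @param weights optional numeric vector of edge weights, one per edge.
#' @return an object of class `sparse_network` with elements `labels` and
#'   `edges` (data.frame with columns `from`, `to` and, when weighted,
#'   `weight`).
#' @export
sparse_network <- function(labels, edges = NULL, weights = NULL) {
  labels <- as.character(labels)
  stopifnot(length(labels) > 0L, !anyDuplicated(labels))
  if (is.null(edges) || NROW(edges) == 0L) {
    ed <- data.frame(from = character(), to = character(),
                     stringsAsFactors = FALSE)
    if (!is.null(weights)) ed$weight <- numeric()
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    from <- as.character(edges[[1L]])
    to <- as.character(edges[[2L]])
    if (any(from == to)) stop("self-loops are not allowed")
    bad <- setdiff(c(from, to), labels)
    if (length(bad)) stop("edge endpoints not in labels: ",
                          paste(unique(bad), collapse = ", "))
    swap <- to < from
    ed <- data.frame(from = ifelse(swap, to, from),
                     to = ifelse(swap, from, to),
                     stringsAsFactors = FALSE)
    if (!is.null(weights)) {
      stopifnot(length(weights) == nrow(ed))
      ed$weight <- as.numeric(weights)
    }
    key <- edge_key(ed$from, ed$to)
    if (anyDuplicated(key)) stop("duplicate edges")
    ed <- ed[order(key), , drop = FALSE]
    rownames(ed) <- NULL
  }
  structure(list(labels = labels, edges = ed), class = "sparse_network")
}

#' @export
print.sparse_network <- function(x, ...) {
  cat(sprintf("sparse_network: %d nodes, %d edges%s\n",
              length(x$labels), nrow(x$edges),
              if (network_is_weighted(x)) " (weighted)" else ""))
  invisible(x)
}

#' Number of edges in a network
#' @param network a `sparse_network`.
#' @return integer edge count.
#' @export
n_edges <- function(network) nrow(network$edges)

#' Does the network carry edge weights?
#' @param network a `sparse_network`.
#' @return logical.
#' @export
network_is_weighted <- function(network) "weight" %in% names(network$edges)

edge_key_set <- function(network) edge_key(network$edges$from, network$edges$to)

#' Build a network from a precision matrix
#'
#' An edge links i and j when `|Theta[i, j]| > edge_tol`; weights, when
#' requested, are the implied partial correlations
#' `-Theta[i, j] / sqrt(Theta[i, i] * Theta[j, j])`.
#'
#' @param theta symmetric precision matrix with dimnames.
#' @param labels optional labels (defaults to the matrix dimnames).
#' @param edge_tol absolute threshold for edge presence.
#' @param weighted attach partial-correlation weights?
#' @return a `sparse_network`.
#' @export
network_from_precision <- function(theta, labels = NULL, edge_tol = 1e-8,
                                   weighted = FALSE) {
  labels <- labels %||% colnames(theta)
  if (is.null(labels)) labels <- paste0("V", seq_len(ncol(theta)))
  p <- ncol(theta)
  idx <- which(upper.tri(theta) & abs(theta) > edge_tol, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(sparse_network(labels))
  w <- NULL
  if (weighted) {
    d <- sqrt(diag(theta))
    w <- -theta[idx] / (d[idx[, 1L]] * d[idx[, 2L]])
  }
  sparse_network(labels,
                 cbind(labels[idx[, 1L]], labels[idx[, 2L]]),
                 weights = w)
}

#' Induced subgraph on a subset of labels
#' @param network a `sparse_network`.
#' @param labels labels to keep (order defines the new label order).
#' @return a `sparse_network` on `labels`.
#' @export
restrict_network <- function(network, labels) {
  stopifnot(all(labels %in% network$labels))
  ed <- network$edges
  keep <- ed$from %in% labels & ed$to %in% labels
  ed <- ed[keep, , drop = FALSE]
  sparse_network(labels, ed[, c("from", "to")],
                 weights = if (network_is_weighted(network)) ed$weight)
}

#' Convert to an igraph graph
#' @param network a `sparse_network`.
#' @return an `igraph` object with a `weight` edge attribute when weighted.
#' @export
as_igraph <- function(network) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(network$labels), name = network$labels)
  if (n_edges(network) > 0L) {
    ends <- rbind(network$edges$from, network$edges$to)
    g <- igraph::add_edges(g, as.vector(ends))
    if (network_is_weighted(network))
      igraph::E(g)$weight <- network$edges$weight
  }
  g
}

#' Write a network as an edge-list TSV
#'
#' Columns: `from`, `to` and, for weighted networks, `weight`. A header line
#' starting with `#nodes:` preserves isolated nodes so the file round-trips.
#'
#' @param network a `sparse_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(network, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#nodes:\t", paste(network$labels, collapse = "\t")), con)
  utils::write.table(network$edges, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a network from an edge-list TSV written by [write_network_tsv()]
#' @param path file path.
#' @return a `sparse_network`.
#' @export
read_network_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  labels <- NULL
  skip <- 0L
  if (startsWith(first, "#nodes:")) {
    labels <- strsplit(first, "\t", fixed = TRUE)[[1L]][-1L]
    skip <- 1L
  }
  ed <- utils::read.table(path, sep = "\t", header = TRUE, skip = skip,
                          stringsAsFactors = FALSE, comment.char = "")
  labels <- labels %||% unique(c(ed$from, ed$to))
  sparse_network(labels, ed[, c("from", "to")],
                 weights = if ("weight" %in% names(ed)) ed$weight)
}

#' Write a network in GraphML format
#' @param network a `sparse_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(as_igraph(network), path, format = "graphml")
  invisible(path)
}
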