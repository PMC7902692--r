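#' Align biomarker panels for comparative network analysis
#'
#' Exact set intersection of two or more label panels, ordered by the first
#' panel's order.
#'
#' @param panels list of character vectors (>= 2).
#' @return character vector of common labels.
#' @export
align_nodes <- function(panels) {
  stopifnot(is.list(panels), length(panels) >= 2L)
  common <- Reduce(intersect, panels[-1L], init = panels[[1L]])
  if (length(common) == 0L) stop("panels have an empty intersection")
  common
}

#' Conserved network across two or more networks
#'
#' Restricts every input to the common label set and keeps the edges
#' present in all of them ("conserved" edges). Output is unweighted; edge
#' identity is label-pair equality.
#'
#' @param networks list of `sparse_network`s (>= 2).
#' @return an unweighted `sparse_network` on the common labels.
#' @export
conserved_network <- function(networks) {
  stopifnot(is.list(networks), length(networks) >= 2L)
  common <- align_nodes(lapply(networks, function(nt) nt$labels))
  nets <- lapply(networks, restrict_network, labels = common)
  keys <- Reduce(intersect, lapply(nets, edge_key_set))
  ed <- nets[[1L]]$edges
  ed <- ed[edge_key_set(nets[[1L]]) %in% keys, c("from", "to"), drop = FALSE]
  sparse_network(common, ed)
}

#' Differential network: edges of B absent from A
#'
#' Both networks are restricted to their common label set first; the result
#' contains the edges of `network_b` that `network_a` lacks ("additional"
#' edges of B). Unweighted.
#'
#' @param network_b,network_a `sparse_network`s.
#' @return an unweighted `sparse_network` on the common labels.
#' @export
differential_network <- function(network_b, network_a) {
  common <- align_nodes(list(network_b$labels, network_a$labels))
  b <- restrict_network(network_b, common)
  a <- restrict_network(network_a, common)
  keep <- !(edge_key_set(b) %in% edge_key_set(a))
  sparse_network(common, b$edges[keep, c("from", "to"), drop = FALSE])
}

#' Community detection for CNA networks
#'
#' Walktrap is run only on connected subnetworks with at least `min_size`
#' nodes (inclusive); smaller subnetworks are reported intact without
#' community labels, and nodes in no subnetwork stay unassigned.
#'
#' @param network a `sparse_network`.
#' @param min_size minimum subnetwork size for community detection
#'   (default 6).
#' @param t random-walk length (default 4).
#' @return a `community_partition`.
#' @export
cna_communities <- function(network, min_size = 6L, t = 4L) {
  detect_communities(network, t = t, min_size = min_size)
}

#' Two-network comparative network analysis
#'
#' Computes the conserved network and both differential networks
#' (additional edges of B over A, and of A over B) on the common label
#' set, plus community partitions of the conserved and the B-minus-A
#' differential network (walktrap on subnetworks of >= `min_community_size`
#' nodes).
#'
#' @param network_a,network_b `sparse_network`s (A is the reference).
#' @param min_community_size minimum subnetwork size for community
#'   detection (default 6).
#' @param t random-walk length (default 4).
#' @return an object of class `cna_result` with `common_labels`,
#'   `conserved`, `differential` (B minus A), `differential_reverse`
#'   (A minus B), `conserved_communities`, `differential_communities`,
#'   `min_community_size`.
#' @export
cna_compare <- function(network_a, network_b, min_community_size = 6L,
                        t = 4L) {
  common <- align_nodes(list(network_a$labels, network_b$labels))
  conserved <- conserved_network(list(network_a, network_b))
  diff_ba <- differential_network(network_b, network_a)
  diff_ab <- differential_network(network_a, network_b)
  structure(list(
    common_labels = common,
    conserved = conserved,
    differential = diff_ba,
    differential_reverse = diff_ab,
    conserved_communities = cna_communities(conserved, min_community_size, t),
    differential_communities = cna_communities(diff_ba, min_community_size, t),
    min_community_size = as.integer(min_community_size)),
    class = "cna_result")
}

#' @export
print.cna_result <- function(x, ...) {
  cat(sprintf(paste0("cna_result: %d common labels, %d conserved edges, ",
                     "%d differential (B\\A), %d differential (A\\B)\n"),
              length(x$common_labels), n_edges(x$conserved),
              n_edges(x$differential), n_edges(x$differential_reverse)))
  invisible(x)
}

#' Stratified network comparison
#'
#' Splits the analysis-ready matrix by a binary stratum indicator,
#' estimates a network independently within each stratum (StARS-selected
#' graphical lasso by default, or EBIC selection), and runs the two-network
#' CNA in both directions. Strata below 20 samples are an error; below 40 a
#' warning (small strata give unstable networks).
#'
#' @param data an `analytical_matrix` (already residualized with the
#'   stratum-appropriate adjustment set).
#' @param stratum binary vector/factor of length `nrow(data$values)` with
#'   exactly two levels; the first level is stratum A (reference).
#' @param method `"stars"` or `"ebic"`.
#' @param seed integer seed (per-stratum sub-seeds are derived from it).
#' @param beta StARS instability threshold.
#' @param gamma EBIC tuning parameter.
#' @param min_community_size CNA community-detection threshold.
#' @param t walktrap walk length.
#' @return list with `networks` (named by stratum level), `fits`,
#'   `stratum_sizes`, and `cna` (a `cna_result`, B = second level minus
#'   A = first level).
#' @export
compare_strata <- function(data, stratum, method = c("stars", "ebic"),
                           seed = 1L, beta = 0.1, gamma = 0.5,
                           min_community_size = 6L, t = 4L) {
  method <- match.arg(method)
  v <- am_values(data)
  stratum <- as.factor(stratum)
  stopifnot(length(stratum) == nrow(v), nlevels(stratum) == 2L)
  sizes <- table(stratum)
  if (any(sizes < 20L))
    stop("each stratum needs >= 20 samples (got ",
         paste(sizes, collapse = "/"), ")")
  if (any(sizes < 40L))
    warning("stratum below 40 samples; network estimates will be unstable")
  nets <- list(); fits <- list()
  for (k in 1:2) {
    lev <- levels(stratum)[k]
    vk <- v[stratum == lev, , drop = FALSE]
    if (method == "stars") {
      st <- stars_select(vk, beta = beta, seed = derive_seed(seed, 20L + k))
      fits[[lev]] <- st
      nets[[lev]] <- st$selected_graph
    } else {
      fit <- ebic_select(vk, gamma = gamma)
      fits[[lev]] <- fit
      nets[[lev]] <- network_from_precision(fit$precision,
                                            edge_tol = fit$edge_tol)
    }
  }
  cna <- cna_compare(nets[[1L]], nets[[2L]],
                     min_community_size = min_community_size, t = t)
  list(networks = nets, fits = fits,
       stratum_sizes = stats::setNames(as.integer(sizes), levels(stratum)),
       cna = cna)
}

#' Write CNA artifacts to a directory
#'
#' Emits conserved and differential edge lists (TSV + GraphML), community
#' partitions (TSV) and a JSON summary of edge counts and subnetwork sizes.
#'
#' @param cna a `cna_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cna_result <- function(cna, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_network_tsv(cna$conserved, file.path(dir, "conserved.tsv"))
  write_network_graphml(cna$conserved, file.path(dir, "conserved.graphml"))
  write_network_tsv(cna$differential, file.path(dir, "differential_b_minus_a.tsv"))
  write_network_graphml(cna$differential,
                        file.path(dir, "differential_b_minus_a.graphml"))
  write_network_tsv(cna$differential_reverse,
                    file.path(dir, "differential_a_minus_b.tsv"))
  write_partition_tsv(cna$conserved_communities,
                      file.path(dir, "conserved_communities.tsv"))
  write_partition_tsv(cna$differential_communities,
                      file.path(dir, "differential_communities.tsv"))
  comp_sizes <- function(net) {
    cc <- connected_components(net)
    vapply(cc$components, function(s) length(s$labels), integer(1))
  }
  summary <- list(
    n_common_labels = length(cna$common_labels),
    n_conserved_edges = n_edges(cna$conserved),
    n_differential_edges = n_edges(cna$differential),
    n_differential_reverse_edges = n_edges(cna$differential_reverse),
    conserved_subnetwork_sizes = comp_sizes(cna$conserved),
    differential_subnetwork_sizes = comp_sizes(cna$differential))
  jsonlite::write_json(summary, file.path(dir, "cna_summary.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
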