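#' Connected components of a network
#'
#' Partitions the non-isolated nodes into maximal connected subgraphs and
#' lists isolated (degree-0) nodes separately. Components are ordered by
#' their smallest member label (position in the network's label order), so
#' the decomposition is deterministic.
#'
#' @param network a `sparse_network`.
#' @return list with `components` (list of `sparse_network`s) and
#'   `isolated` (character vector of degree-0 labels).
#' @export
connected_components <- function(network) {
  labels <- network$labels
  deg <- stats::setNames(rep(0L, length(labels)), labels)
  ed <- network$edges
  if (nrow(ed) > 0L) {
    t1 <- table(ed$from); t2 <- table(ed$to)
    deg[names(t1)] <- deg[names(t1)] + as.integer(t1)
    deg[names(t2)] <- deg[names(t2)] + as.integer(t2)
  }
  isolated <- labels[deg == 0L]
  active <- labels[deg > 0L]
  if (length(active) == 0L)
    return(list(components = list(), isolated = isolated))
  adj <- split(c(ed$to, ed$from), c(ed$from, ed$to))
  comp_id <- stats::setNames(rep(NA_integer_, length(active)), active)
  cid <- 0L
  for (start in active) {          # active is in label order, so components
    if (!is.na(comp_id[start])) next  # come out ordered by smallest member
    cid <- cid + 1L
    queue <- start
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      if (!is.na(comp_id[v])) next
      comp_id[v] <- cid
      nb <- adj[[v]]
      queue <- c(queue, nb[is.na(comp_id[nb])])
    }
  }
  components <- lapply(seq_len(cid), function(k) {
    members <- active[comp_id == k]
    restrict_network(network, members)
  })
  list(components = components, isolated = isolated)
}

#' Newman–Girvan modularity of a partition
#'
#' `Q = sum_c [ w_in(c)/m - (s(c)/(2m))^2 ]` with `m` the total edge weight
#' (edge count for unweighted graphs), `w_in(c)` the weight inside
#' community `c` and `s(c)` its total strength.
#'
#' @param network a `sparse_network` with at least one edge.
#' @param membership named vector mapping every node of the network to a
#'   community id.
#' @param use_abs use absolute edge weights (default `TRUE`; random-walk
#'   community structure treats a negative partial correlation as a
#'   dependence like any other).
#' @return modularity Q in `[-0.5, 1)`.
#' @export
network_modularity <- function(network, membership, use_abs = TRUE) {
  ed <- network$edges
  if (nrow(ed) == 0L) stop("modularity is undefined for an empty network")
  if (!all(network$labels %in% names(membership)))
    stop("membership must cover all nodes of the network")
  w <- if (network_is_weighted(network)) ed$weight else rep(1, nrow(ed))
  if (use_abs) w <- abs(w)
  m <- sum(w)
  strength <- stats::setNames(rep(0, length(network$labels)), network$labels)
  for (i in seq_len(nrow(ed))) {
    strength[ed$from[i]] <- strength[ed$from[i]] + w[i]
    strength[ed$to[i]] <- strength[ed$to[i]] + w[i]
  }
  comms <- unique(membership[network$labels])
  q <- 0
  for (cm in comms) {
    members <- network$labels[membership[network$labels] == cm]
    inside <- ed$from %in% members & ed$to %in% members
    q <- q + sum(w[inside]) / m - (sum(strength[members]) / (2 * m))^2
  }
  q
}

# dense absolute-weight adjacency matrix of a sparse_network
adjacency_matrix <- function(network, use_abs = TRUE) {
  p <- length(network$labels)
  A <- matrix(0, p, p, dimnames = list(network$labels, network$labels))
  ed <- network$edges
  if (nrow(ed) > 0L) {
    w <- if (network_is_weighted(network)) ed$weight else rep(1, nrow(ed))
    if (use_abs) w <- abs(w)
    i <- match(ed$from, network$labels)
    j <- match(ed$to, network$labels)
    A[cbind(i, j)] <- w
    A[cbind(j, i)] <- w
  }
  A
}

#' Walktrap community detection on a connected subnetwork
#'
#' Random-walk agglomeration: with transition probabilities
#' `P_ij = w_ij / strength(i)`, the t-step distribution rows define vertex
#' distances `r_ij^2 = sum_k (P^t_ik - P^t_jk)^2 / strength(k)`; starting
#' from singletons, adjacent communities are merged greedily by the
#' Ward-style variance increase
#' `ds = |C1||C2| / (|C1| + |C2|) * r_C1C2^2 / n`, and the returned cut is
#' the step of the merge sequence maximizing modularity (including the
#' all-singletons start and the final single community). Ties in the merge
#' choice break toward the pair with the smallest community-minimum labels;
#' ties in modularity break toward the later (more merged) cut. Weighted
#' networks use absolute edge weights.
#'
#' @param subnetwork a connected `sparse_network` with >= 2 nodes.
#' @param t random-walk length (default 4).
#' @return named integer vector mapping each node to a community id
#'   (dense, starting at 1, numbered by smallest member label), with
#'   attribute `modularity` (Q at the chosen cut).
#' @export
walktrap_communities <- function(subnetwork, t = 4L) {
  labels <- subnetwork$labels
  p <- length(labels)
  stopifnot(p >= 2L, n_edges(subnetwork) >= 1L)
  A <- adjacency_matrix(subnetwork, use_abs = TRUE)
  d <- rowSums(A)
  if (any(d == 0)) stop("subnetwork must be connected (no degree-0 nodes)")
  P <- A / d
  Pt <- diag(p)
  for (k in seq_len(t)) Pt <- Pt %*% P

  # state: community membership by node index, community probability rows,
  # sizes, adjacency between communities
  member <- seq_len(p)
  rows <- Pt                       # row c = mean walk distribution of community c
  sizes <- rep(1L, p)
  alive <- rep(TRUE, p)
  cadj <- A > 0

  dist2 <- function(c1, c2)
    sum((rows[c1, ] - rows[c2, ])^2 / d)
  dsigma <- function(c1, c2)
    (sizes[c1] * sizes[c2]) / (sizes[c1] + sizes[c2]) * dist2(c1, c2) / p

  partition_q <- function(member) {
    mem <- stats::setNames(member, labels)
    network_modularity(subnetwork, mem)
  }

  best_q <- partition_q(member)
  best_member <- member
  for (step in seq_len(p - 1L)) {
    cands <- which(cadj & upper.tri(cadj) &
                     outer(alive, alive, `&`), arr.ind = TRUE)
    if (nrow(cands) == 0L) break   # disconnected (cannot happen if connected)
    ds <- apply(cands, 1L, function(rc) dsigma(rc[1L], rc[2L]))
    best <- which(ds <= min(ds) + 1e-12)
    if (length(best) > 1L) {
      # tie-break: smallest (min-label, min-label) pair; community ids are
      # always the smallest member index, so compare (row, col) sorted
      key <- cands[best, , drop = FALSE]
      ord <- order(pmin(key[, 1L], key[, 2L]), pmax(key[, 1L], key[, 2L]))
      best <- best[ord[1L]]
    }
    c1 <- min(cands[best, ]); c2 <- max(cands[best, ])
    # merge c2 into c1 (c1 keeps the smaller min member index)
    rows[c1, ] <- (sizes[c1] * rows[c1, ] + sizes[c2] * rows[c2, ]) /
      (sizes[c1] + sizes[c2])
    sizes[c1] <- sizes[c1] + sizes[c2]
    alive[c2] <- FALSE
    cadj[c1, ] <- cadj[c1, ] | cadj[c2, ]
    cadj[, c1] <- cadj[, c1] | cadj[, c2]
    cadj[c1, c1] <- FALSE
    cadj[c2, ] <- FALSE; cadj[, c2] <- FALSE
    member[member == c2] <- c1
    q <- partition_q(member)
    if (q >= best_q - 1e-12) {     # ties prefer the later, more merged cut
      best_q <- q
      best_member <- member
    }
  }
  ids <- match(best_member, sort(unique(best_member)))
  structure(stats::setNames(ids, labels), modularity = best_q)
}

#' Detect communities across a whole network
#'
#' Applies [walktrap_communities()] independently to every connected
#' subnetwork; isolated nodes are left unassigned. Global community ids are
#' dense integers assigned in component order.
#'
#' @param network a `sparse_network`.
#' @param t random-walk length (default 4).
#' @param min_size only run community detection on components with at least
#'   this many nodes (default 2 = all components); smaller components keep
#'   their component id but get no community label.
#' @return an object of class `community_partition`: `assignment` (named
#'   integer, `NA` = unassigned), `component` (named integer, `NA` for
#'   isolated nodes), `modularity` (per analysed component), `t`,
#'   `n_communities`.
#' @export
detect_communities <- function(network, t = 4L, min_size = 2L) {
  cc <- connected_components(network)
  assignment <- stats::setNames(rep(NA_integer_, length(network$labels)),
                                network$labels)
  component <- assignment
  modularity <- numeric(0)
  next_id <- 0L
  for (k in seq_along(cc$components)) {
    sub <- cc$components[[k]]
    component[sub$labels] <- k
    if (length(sub$labels) < min_size) next
    wt <- walktrap_communities(sub, t = t)
    assignment[names(wt)] <- wt + next_id
    modularity <- c(modularity, stats::setNames(attr(wt, "modularity"), k))
    next_id <- next_id + max(wt)
  }
  structure(list(assignment = assignment, component = component,
                 modularity = modularity, t = as.integer(t),
                 n_communities = next_id),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("community_partition: %d communities, %d unassigned node(s)\n",
              x$n_communities, sum(is.na(x$assignment))))
  invisible(x)
}

#' Write a community partition as TSV
#'
#' Columns: `label`, `component` (NA for isolated nodes), `community`
#' (NA when unassigned).
#'
#' @param partition a `community_partition`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_partition_tsv <- function(partition, path) {
  df <- data.frame(label = names(partition$assignment),
                   component = partition$component,
                   community = partition$assignment)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
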