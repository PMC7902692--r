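# Independent oracles and small graph fixtures used across the suite.

# --- brute-force maximizer of the penalized Gaussian log-likelihood ---------
# Direct Nelder-Mead maximization of
#   log det(Theta) - tr(S Theta) - lambda * sum_{i != j} |Theta_ij|
# over symmetric positive-definite Theta, independent of the coordinate-
# descent implementation under test.
penalized_loglik_oracle <- function(S, lambda) {
  p <- nrow(S)
  n_off <- p * (p - 1) / 2
  unpack <- function(par) {
    Th <- matrix(0, p, p)
    diag(Th) <- exp(par[seq_len(p)])
    Th[lower.tri(Th)] <- par[p + seq_len(n_off)]
    Th + t(Th) - diag(diag(Th))
  }
  obj <- function(par) {
    Th <- unpack(par)
    ev <- eigen(Th, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-8) return(1e10)
    -(sum(log(ev)) - sum(S * Th) - 2 * lambda * sum(abs(par[p + seq_len(n_off)])))
  }
  starts <- list(rep(0, p + n_off),
                 c(log(2 / diag(S)), rep(0.05, n_off)))
  best <- NULL
  for (st in starts) {
    o <- stats::optim(st, obj, method = "Nelder-Mead",
                      control = list(maxit = 20000, reltol = 1e-14))
    for (k in 1:4)
      o <- stats::optim(o$par, obj, method = "Nelder-Mead",
                        control = list(maxit = 20000, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  unpack(best$par)
}

random_correlation <- function(p, n = 20) {
  X <- matrix(stats::rnorm(n * p), n, p)
  stats::cor(X)
}

# --- exhaustive partition enumeration ---------------------------------------
# All set partitions of seq_len(n) as membership vectors (Bell(8) = 4140).
all_partitions <- function(n) {
  if (n == 1L) return(list(1L))
  smaller <- all_partitions(n - 1L)
  out <- list()
  for (memb in smaller) {
    k <- max(memb)
    for (c in seq_len(k + 1L)) out[[length(out) + 1L]] <- c(memb, c)
  }
  out
}

# global modularity maximizer by enumeration (independent of walktrap)
max_modularity_partition <- function(network) {
  labels <- network$labels
  best_q <- -Inf
  best <- NULL
  for (memb in all_partitions(length(labels))) {
    q <- network_modularity(network, stats::setNames(memb, labels))
    if (q > best_q + 1e-12) {
      best_q <- q
      best <- memb
    }
  }
  list(membership = stats::setNames(best, labels), q = best_q)
}

# --- graph fixtures ----------------------------------------------------------
two_triangles_bridge <- function() {
  sparse_network(letters[1:6],
                 rbind(c("a", "b"), c("b", "c"), c("a", "c"),
                       c("d", "e"), c("e", "f"), c("d", "f"),
                       c("c", "d")))
}

k4_graph <- function() {
  sparse_network(letters[1:4],
                 t(utils::combn(letters[1:4], 2)))
}

weighted_two_block <- function() {
  ed <- rbind(c("a", "b"), c("b", "c"), c("a", "c"),
              c("d", "e"), c("e", "f"), c("d", "f"),
              c("c", "d"))
  sparse_network(letters[1:6], ed, weights = c(rep(1, 6), 0.01))
}

random_network <- function(p, edge_prob = 0.4, labels = sprintf("n%02d", seq_len(p))) {
  ed <- NULL
  for (i in seq_len(p - 1L)) for (j in seq((i + 1L), p)) {
    if (stats::runif(1) < edge_prob) ed <- rbind(ed, c(labels[i], labels[j]))
  }
  sparse_network(labels, ed)
}

# --- metrics -----------------------------------------------------------------
edge_keys_of <- function(edges) {
  if (NROW(edges) == 0L) return(character())
  paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
}

f1_edges <- function(est, truth) {
  ek <- edge_keys_of(est)
  tk <- edge_keys_of(truth)
  tp <- length(intersect(ek, tk))
  if (length(ek) + length(tk) == 0L) return(1)
  2 * tp / (length(ek) + length(tk))
}

# ARI between partitions; unassigned (NA) nodes count as singletons on
# both sides
ari_partitions <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  a[is.na(a)] <- paste0("ua", seq_along(a)[is.na(a)])
  b[is.na(b)] <- paste0("ub", seq_along(b)[is.na(b)])
  mclust::adjustedRandIndex(a, b)
}

same_partition <- function(a, b) {
  isTRUE(all.equal(ari_partitions(a, b), 1))
}
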