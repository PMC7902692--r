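test_that("connected components partition non-isolated nodes deterministically", {
  net <- sparse_network(letters[1:5], rbind(c("a", "b"), c("c", "d")))
  cc <- connected_components(net)
  expect_length(cc$components, 2L)
  expect_equal(cc$components[[1]]$labels, c("a", "b"))
  expect_equal(cc$components[[2]]$labels, c("c", "d"))
  expect_equal(cc$isolated, "e")

  empty <- sparse_network(letters[1:3])
  cc0 <- connected_components(empty)
  expect_length(cc0$components, 0L)
  expect_equal(cc0$isolated, letters[1:3])

  path3 <- sparse_network(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
  expect_length(connected_components(path3)$components, 1L)
})

test_that("modularity matches the Newman-Girvan formula and igraph", {
  net <- two_triangles_bridge()
  one <- stats::setNames(rep(1L, 6), net$labels)
  expect_equal(network_modularity(net, one), 0)

  single <- sparse_network(c("a", "b"), rbind(c("a", "b")))
  expect_equal(network_modularity(single, c(a = 1, b = 2)), -0.5)

  # two triangles joined by a bridge: Q = 2 (3/7 - (7/14)^2)
  tri <- stats::setNames(c(1, 1, 1, 2, 2, 2), net$labels)
  expect_equal(network_modularity(net, tri), 2 * (3 / 7 - (7 / 14)^2),
               tolerance = 1e-12)

  expect_error(network_modularity(sparse_network(c("a", "b")), c(a = 1, b = 1)),
               "undefined")

  # cross-check against the independent igraph implementation
  set.seed(81)
  for (rep in 1:8) {
    g <- random_network(7)
    if (n_edges(g) == 0L) next
    memb <- sample(1:3, 7, replace = TRUE)
    names(memb) <- g$labels
    ig <- as_igraph(g)
    expect_equal(network_modularity(g, memb),
                 igraph::modularity(ig, memb[igraph::V(ig)$name]),
                 tolerance = 1e-12)
  }
})

test_that("walktrap cuts match exhaustive modularity maximization", {
  # fixtures where the merge sequence provably contains the global optimum
  for (net in list(two_triangles_bridge(), k4_graph(), weighted_two_block())) {
    wt <- walktrap_communities(net, t = 4)
    oracle <- max_modularity_partition(net)
    expect_equal(attr(wt, "modularity"), oracle$q, tolerance = 1e-10)
    expect_true(same_partition(wt, oracle$membership[names(wt)]))
  }
  # the expected partitions, explicitly
  wt1 <- walktrap_communities(two_triangles_bridge())
  expect_true(same_partition(wt1, c(1, 1, 1, 2, 2, 2)))
  wt2 <- walktrap_communities(k4_graph())
  expect_equal(max(wt2), 1L)
  wt3 <- walktrap_communities(weighted_two_block())
  expect_true(same_partition(wt3, c(1, 1, 1, 2, 2, 2)))
})

test_that("walktrap cut dominates the trivial partitions and igraph agrees", {
  set.seed(83)
  for (rep in 1:6) {
    g <- random_network(7, edge_prob = 0.45)
    cc <- connected_components(g)
    if (length(cc$components) == 0L) next
    sub <- cc$components[[1]]
    if (length(sub$labels) < 3L) next
    wt <- walktrap_communities(sub)
    q_all <- network_modularity(sub, stats::setNames(rep(1, length(sub$labels)),
                                                     sub$labels))
    q_single <- network_modularity(sub, stats::setNames(seq_along(sub$labels),
                                                        sub$labels))
    expect_gte(attr(wt, "modularity"), max(q_all, q_single) - 1e-12)
  }
  # reference implementation finds the same two-triangle cut
  ig <- as_igraph(two_triangles_bridge())
  ref <- igraph::cluster_walktrap(ig, steps = 4)
  wt <- walktrap_communities(two_triangles_bridge())
  expect_true(same_partition(wt[igraph::V(ig)$name],
                             igraph::membership(ref)))
})

test_that("detect_communities composes per component and leaves isolates out", {
  empty <- sparse_network(letters[1:4])
  pt <- detect_communities(empty)
  expect_true(all(is.na(pt$assignment)))
  expect_equal(pt$n_communities, 0L)

  # two disjoint triangle-pairs-with-bridge components -> four communities
  e1 <- two_triangles_bridge()$edges[, 1:2]
  e2 <- e1
  e2$from <- toupper(e2$from); e2$to <- toupper(e2$to)
  both <- sparse_network(c(letters[1:6], LETTERS[1:6]), rbind(e1, e2))
  pt2 <- detect_communities(both)
  expect_equal(pt2$n_communities, 4L)
  # communities never span components
  comp_of_comm <- tapply(pt2$component, pt2$assignment,
                         function(x) length(unique(x)))
  expect_true(all(comp_of_comm == 1L))
})

test_that("partitions are invariant to node order", {
  set.seed(87)
  for (rep in 1:5) {
    g <- random_network(8, edge_prob = 0.4)
    pt <- detect_communities(g)
    perm <- sample(g$labels)
    g2 <- sparse_network(perm, g$edges[, 1:2])
    pt2 <- detect_communities(g2)
    common <- g$labels
    expect_true(same_partition(pt$assignment[common], pt2$assignment[common]))
  }
})

test_that("planted stochastic-block partitions are recovered (ARI >= 0.9)", {
  aris <- vapply(1:25, function(s) {
    set.seed(s)
    memb <- rep(1:3, each = 6)
    p <- 18L
    labels <- sprintf("n%02d", 1:p)
    ed <- NULL
    for (i in 1:(p - 1)) for (j in (i + 1):p) {
      pr <- if (memb[i] == memb[j]) 0.8 else 0.05
      if (runif(1) < pr) ed <- rbind(ed, c(labels[i], labels[j]))
    }
    net <- sparse_network(labels, ed)
    pt <- detect_communities(net)
    ari_partitions(pt$assignment, stats::setNames(memb, labels))
  }, numeric(1))
  expect_gte(mean(aris), 0.9)
})
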