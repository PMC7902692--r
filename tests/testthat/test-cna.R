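test_that("panel alignment reproduces the published intersections", {
  panels <- flehs_panels()
  all3 <- align_nodes(panels)
  expect_equal(all3, c("cadmium", "lead", "ppDDE", "PCB138", "PCB153",
                       "PCB180"))
  expect_length(all3, 6L)
  two <- align_nodes(panels[c("flehs2", "flehs3")])
  expect_equal(two, panels$flehs2)  # second campaign nested in the third
  expect_length(two, 12L)
  expect_equal(align_nodes(list(panels$flehs1, panels$flehs1)),
               panels$flehs1)
  expect_error(align_nodes(list(c("x"), c("y"))), "empty")
})

test_that("conserved and differential networks are exact set operations", {
  labs <- letters[1:4]
  A <- sparse_network(labs, rbind(c("a", "b"), c("b", "c")))
  B <- sparse_network(labs, rbind(c("b", "c"), c("c", "d")))
  expect_equal(conserved_network(list(A, B))$edges,
               data.frame(from = "b", to = "c"))
  expect_equal(n_edges(conserved_network(list(
    sparse_network(labs, rbind(c("a", "b"))),
    sparse_network(labs, rbind(c("c", "d")))))), 0L)

  D <- differential_network(B, A)
  expect_equal(D$edges, data.frame(from = "c", to = "d"))
  expect_equal(n_edges(differential_network(A, A)), 0L)

  # three networks sharing only a triangle
  tri <- rbind(c("a", "b"), c("b", "c"), c("a", "c"))
  nets <- list(sparse_network(labs, rbind(tri, c("c", "d"))),
               sparse_network(labs, rbind(tri, c("a", "d"))),
               sparse_network(labs, rbind(tri, c("b", "d"))))
  expect_setequal(edge_keys_of(conserved_network(nets)$edges),
                  edge_keys_of(as.data.frame(tri) |>
                                 stats::setNames(c("from", "to"))))
})

test_that("conserved plus differential reconstructs B exactly, disjointly", {
  set.seed(91)
  for (rep in 1:100) {
    labs <- sprintf("n%02d", 1:8)
    A <- random_network(8, edge_prob = 0.35, labels = labs)
    B <- random_network(8, edge_prob = 0.35, labels = labs)
    cons <- conserved_network(list(A, B))
    diff_ba <- differential_network(B, A)
    kc <- edge_keys_of(cons$edges)
    kd <- edge_keys_of(diff_ba$edges)
    kb <- edge_keys_of(B$edges)
    expect_length(intersect(kc, kd), 0L)
    expect_setequal(c(kc, kd), kb)
    # conserved is order-invariant
    expect_setequal(kc, edge_keys_of(conserved_network(list(B, A))$edges))
    # differential directions are disjoint
    expect_length(intersect(kd, edge_keys_of(
      differential_network(A, B)$edges)), 0L)
  }
})

test_that("community detection respects the minimum subnetwork size", {
  # one 7-node component and one 2-node component
  e7 <- rbind(c("a", "b"), c("b", "c"), c("a", "c"), c("c", "d"),
              c("d", "e"), c("e", "f"), c("d", "f"), c("f", "g"))
  net <- sparse_network(c(letters[1:7], "x", "y"), rbind(e7, c("x", "y")))
  pt <- cna_communities(net, min_size = 6)
  expect_true(all(!is.na(pt$assignment[letters[1:7]])))
  expect_true(all(is.na(pt$assignment[c("x", "y")])))
  expect_equal(pt$component[["x"]], 2L)  # subnetwork reported intact

  # a single conserved pair (like a PFOS-PFOA link): no community detection
  pair <- sparse_network(c("PFOS", "PFOA", "lead"),
                         rbind(c("PFOS", "PFOA")))
  ptp <- cna_communities(pair, min_size = 6)
  expect_true(all(is.na(ptp$assignment)))
  expect_equal(ptp$component[["PFOS"]], 1L)
  expect_true(is.na(ptp$component[["lead"]]))

  # boundary: a 6-node component is analysed ("6 or more")
  six <- two_triangles_bridge()
  pt6 <- cna_communities(six, min_size = 6)
  expect_equal(pt6$n_communities, 2L)
})

test_that("cna_compare bundles both directions with matching counts", {
  labs <- letters[1:6]
  A <- sparse_network(labs, rbind(c("a", "b"), c("b", "c"), c("d", "e")))
  B <- sparse_network(labs, rbind(c("a", "b"), c("c", "d"), c("e", "f")))
  res <- cna_compare(A, B)
  expect_s3_class(res, "cna_result")
  expect_equal(n_edges(res$conserved) + n_edges(res$differential),
               n_edges(B))
  expect_equal(n_edges(res$conserved) + n_edges(res$differential_reverse),
               n_edges(A))
  expect_equal(res$common_labels, labs)
})

test_that("stratified comparison guards sizes and finds no planted difference", {
  spec <- block_synthetic_spec(100, sizes = c(3, 3), seed = 1)
  am <- analytical_matrix(log(simulate_dataset(spec)$dataset$values))
  expect_error(compare_strata(am, rep(c(0, 1), c(90, 10))), ">= 20")
  expect_warning(compare_strata(am, rep(c(0, 1), c(70, 30)), seed = 1),
                 "below 40")

  # identical strata (random split of one population): near-empty differentials
  nd <- unlist(lapply(1:5, function(s) {
    spec <- block_synthetic_spec(800, sizes = c(3, 3), n_isolated = 2,
                                 seed = s)
    am <- analytical_matrix(log(simulate_dataset(spec)$dataset$values))
    set.seed(s)
    strat <- sample(rep(0:1, 400))
    res <- compare_strata(am, strat, seed = s)
    c(n_edges(res$cna$differential), n_edges(res$cna$differential_reverse))
  }))
  expect_lte(mean(nd), 1)
})

test_that("a planted stratum difference concentrates in the differing block", {
  fracs <- vapply(1:5, function(s) {
    labs <- sprintf("bm%02d", 1:10)
    partA <- partition_from_blocks(list(labs[1:4], labs[5:8]), labs[9:10])
    partB <- partition_from_blocks(list(labs[1:4]), labs[5:10])
    lip <- stats::setNames(rep(FALSE, 10), labs)
    specA <- synthetic_spec(400, partA, within_block_pcorr = 0.4, seed = s,
                            lipid_adjusted = lip)
    specB <- synthetic_spec(400, partB, within_block_pcorr = 0.4,
                            seed = s + 100, lipid_adjusted = lip)
    X <- rbind(log(simulate_dataset(specA)$dataset$values),
               log(simulate_dataset(specB)$dataset$values))
    strat <- rep(c("with_block", "without_block"), each = 400)
    res <- compare_strata(analytical_matrix(X), strat, seed = s)
    # edges present only where the extra block exists
    d <- res$cna$differential_reverse
    blk <- labs[5:8]
    if (n_edges(d) == 0L) return(NA_real_)
    mean(d$edges$from %in% blk & d$edges$to %in% blk)
  }, numeric(1))
  expect_gte(mean(fracs, na.rm = TRUE), 0.8)
})

test_that("CNA artifacts are written completely", {
  labs <- letters[1:6]
  A <- sparse_network(labs, rbind(c("a", "b"), c("b", "c"), c("d", "e")))
  B <- sparse_network(labs, rbind(c("a", "b"), c("c", "d"), c("e", "f")))
  dir <- withr::local_tempdir()
  write_cna_result(cna_compare(A, B), dir)
  expect_true(all(file.exists(file.path(
    dir, c("conserved.tsv", "conserved.graphml",
           "differential_b_minus_a.tsv", "differential_a_minus_b.tsv",
           "conserved_communities.tsv", "cna_summary.json")))))
  summ <- jsonlite::read_json(file.path(dir, "cna_summary.json"))
  expect_equal(summ$n_conserved_edges, 1L)
})
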