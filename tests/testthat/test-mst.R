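test_that("vertex-derived edge weights follow the two schemes", {
  tri <- weighted_graph(c("A","B","B","C","A","C"), c(A = 1, B = 2, C = 3))
  gs <- vertex_to_edge_weights(tri, "weight", "sum")
  ga <- vertex_to_edge_weights(tri, "weight", "average")
  expect_setequal(igraph::E(gs)$weight, c(3, 4, 5))
  expect_setequal(igraph::E(ga)$weight, c(1.5, 2, 2.5))
  expect_equal(igraph::E(gs)$weight, 2 * igraph::E(ga)$weight)
  expect_error(vertex_to_edge_weights(tri, "nope", "sum"), "not found")
})

test_that("minimum spanning trees handle the canonical examples", {
  # a tree is its own unique spanning tree
  tr <- path_graph(5)
  tr <- igraph::set_edge_attr(tr, "weight", value = c(4, 1, 3, 2))
  res <- minimum_spanning_tree(tr)
  expect_equal(nrow(res$edges), 4L)
  expect_equal(res$total, 10)
  expect_true(res$unique)
  expect_equal(sum(res$degrees), 2L * 4L)

  tri <- weighted_graph(c("A","B","B","C","A","C"), c(A = 1, B = 1, C = 1))
  tri <- igraph::set_edge_attr(tri, "weight", value = c(1, 2, 3))
  res2 <- minimum_spanning_tree(tri)
  expect_equal(res2$total, 3)
  expect_true(res2$unique)

  tri1 <- igraph::set_edge_attr(tri, "weight", value = c(1, 1, 1))
  res3 <- minimum_spanning_tree(tri1)
  expect_equal(res3$total, 2)
  expect_false(res3$unique)

  disc <- weighted_graph(c("A", "B"), c(A = 1, B = 1, C = 1))
  disc <- igraph::set_edge_attr(disc, "weight", value = 1)
  expect_error(minimum_spanning_tree(disc), "components")
})

test_that("MST totals and uniqueness match exhaustive enumeration", {
  set.seed(21)
  for (rep in 1:40) {
    n <- sample(4:8, 1)
    g <- rand_wgraph(n, p = 0.45)
    m <- igraph::ecount(g)
    if (m > 12) g <- igraph::delete_edges(g, sample(m, m - 12))
    if (!igraph::is_connected(g)) next
    ew <- sample(1:6, igraph::ecount(g), replace = TRUE)  # ties likely
    g <- igraph::set_edge_attr(g, "weight", value = ew)
    res <- minimum_spanning_tree(g)
    trees <- enumerate_spanning_trees(g)
    totals <- vapply(trees, `[[`, numeric(1), "total")
    expect_equal(res$total, min(totals))
    expect_equal(res$unique, sum(abs(totals - min(totals)) < 1e-9) == 1L)
    # cross-check against the igraph implementation's total
    expect_equal(res$total, sum(igraph::E(igraph::mst(g))$weight))
    # maximization mirror
    resmax <- minimum_spanning_tree(g, maximize = TRUE)
    expect_equal(resmax$total, max(totals))
  }
})

test_that("sum and average schemes give identical MST edge sets", {
  set.seed(22)
  for (rep in 1:15) {
    g <- rand_wgraph(sample(5:9, 1), p = 0.5)
    if (!igraph::is_connected(g)) next
    rs <- minimum_spanning_tree(vertex_to_edge_weights(g, "weight", "sum"))
    ra <- minimum_spanning_tree(vertex_to_edge_weights(g, "weight", "average"))
    expect_identical(rs$edges[c("from", "to")], ra$edges[c("from", "to")])
    expect_equal(rs$total, 2 * ra$total)
    expect_identical(rs$unique, ra$unique)
  }
})

test_that("mutation subsets reweight but never change the top edge set", {
  h <- helix_hierarchy()
  wild <- mst_for_mutations(h)
  expect_s3_class(wild, "mst_result")
  muts <- helix_mutations()
  allm <- mst_for_mutations(h, muts)
  expect_identical(sort(protier:::edge_keys(h$top)),
                   sort(protier:::edge_keys(reweight_mutant(h, muts)$top)))
  # identity-weight mutation subset leaves the tree untouched
  same <- mst_for_mutations(h, parse_mutations("A5A"))
  expect_identical(wild$edges, same$edges)
})

test_that("different mutation subsets can yield different spanning trees", {
  h <- coil_hierarchy()
  trees <- lapply(coil_mutations(), function(m)
    mst_for_mutations(h, list(m))$edges[c("from", "to")])
  expect_gt(length(unique(trees)), 1L)
})

test_that("resampling is deterministic with matching design arithmetic", {
  h <- helix_hierarchy()
  muts <- helix_mutations()
  r1 <- mutation_resampling(h, muts, samples = 5, sample_size = 5, seed = 7)
  r2 <- mutation_resampling(h, muts, samples = 5, sample_size = 5, seed = 7)
  expect_identical(r1$report, r2$report)
  expect_identical(r1$degrees, r2$degrees)
  r3 <- mutation_resampling(h, muts, samples = 5, sample_size = 5, seed = 8)
  expect_false(identical(r3$draws, r1$draws))
  # 10 mutations, 5 samples of 5: each mutation expected 2.5 times
  expect_equal(r1$expected_occurrences, 2.5)
  expect_error(mutation_resampling(h, muts, samples = 2, sample_size = 99),
               "exceeds")
})

test_that("a single full-list resample equals the all-mutations tree with sd 0", {
  h <- helix_hierarchy()
  muts <- helix_mutations()
  r <- mutation_resampling(h, muts, samples = 1, sample_size = length(muts))
  allm <- mst_for_mutations(h, muts)
  expect_equal(stats::setNames(r$report$mean_degree, r$report$vertex),
               allm$degrees[r$report$vertex])
  expect_true(all(r$report$sd_degree == 0))
  cls <- stability_classification(r)
  expect_setequal(cls$stable, r$report$vertex)
})

test_that("stability classification applies its tolerance", {
  h <- helix_hierarchy()
  r <- mutation_resampling(h, helix_mutations(), samples = 4, sample_size = 3,
                           seed = 5)
  cls0 <- stability_classification(r, tolerance = 0)
  expect_setequal(c(cls0$stable, cls0$sensitive), r$report$vertex)
  clsbig <- stability_classification(r, tolerance = 99)
  expect_length(clsbig$sensitive, 0L)
})

test_that("resampling means stabilize as the number of samples grows", {
  h <- coil_hierarchy()                # cyclic top graph: the MST can vary
  muts <- coil_mutations()
  spread <- vapply(c(4L, 16L, 48L), function(ns) {
    means <- vapply(1:4, function(sd) {
      r <- mutation_resampling(h, muts, samples = ns, sample_size = 5,
                               seed = sd)
      r$report$mean_degree
    }, numeric(igraph::vcount(h$top)))
    mean(apply(means, 1, stats::sd))
  }, numeric(1))
  expect_lt(spread[3], spread[1])
})

test_that("the design helper hits the stated expectation", {
  d <- resampling_design(10, expectation = 2.5)
  expect_equal(d$samples * d$sample_size / 10, d$expected_occurrences)
  expect_equal(d$expected_occurrences, 2.5)
})
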