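test_that("midlevel graphs mirror the contact map over the range", {
  rs <- read_structure(colinear_pdb(15))
  cm <- build_contact_map(rs, threshold = 7)
  defs <- three_defs()
  g <- build_midlevel_graph(cm, defs[1, ])
  expect_equal(igraph::vcount(g), 5L)
  expect_equal(igraph::ecount(g), 4L)          # a path on 5 vertices
  expect_equal(igraph::graph_attr(g, "label"), "D1")

  one <- parse_substructure_table(data.frame(
    label = "S", kind = "loop", range = "3-3", sequence = "G"))
  g1 <- build_midlevel_graph(cm, one[1, ])
  expect_equal(igraph::vcount(g1), 1L)
  expect_equal(igraph::ecount(g1), 0L)

  off <- parse_substructure_table(data.frame(
    label = "FAR", kind = "loop", range = "100-120",
    sequence = strrep("G", 21)))
  expect_error(build_midlevel_graph(cm, off[1, ]), "FAR")
})

test_that("top-level edges require two non-shared residue pairs", {
  rs <- read_structure(colinear_pdb(15))
  defs <- three_defs()
  t7 <- build_top_level(build_contact_map(rs, threshold = 7), defs)
  expect_equal(igraph::vcount(t7), 3L)
  expect_equal(igraph::ecount(t7), 0L)         # one qualifying pair per interface
  t8 <- build_top_level(build_contact_map(rs, threshold = 8), defs)
  expect_equal(igraph::ecount(t8), 2L)         # path D1-D2-D3
  expect_true(igraph::are_adjacent(t8, "D1", "D2"))
  expect_true(igraph::are_adjacent(t8, "D2", "D3"))

  dup <- defs; dup$label <- c("D1", "D1", "D3")
  expect_error(build_top_level(build_contact_map(rs, threshold = 8), dup),
               "duplicate")
})

test_that("shared boundary residues belong to both midgraphs but no interface pair", {
  rs <- read_structure(colinear_pdb(9))
  cm <- build_contact_map(rs, threshold = 8)
  defs <- parse_substructure_table(data.frame(
    label = c("A", "B"), kind = "alpha", range = c("1-5", "5-9"),
    sequence = c("GGGGG", "GGGGG")))
  ga <- build_midlevel_graph(cm, defs[1, ])
  gb <- build_midlevel_graph(cm, defs[2, ])
  expect_true("5" %in% igraph::V(ga)$name)
  expect_true("5" %in% igraph::V(gb)$name)
  top <- build_top_level(cm, defs)
  # qualifying pairs exclude residue 5 entirely: (4,6) at 7.6 only -> no edge
  expect_equal(igraph::ecount(top), 0L)
  # vertex-count conservation with the shared residue counted per substructure
  expect_equal(igraph::vcount(ga) + igraph::vcount(gb), 5L + 5L)
})

test_that("weight propagation follows the weighted-degree definition", {
  pdb <- generate_synthetic_structure("AAA", mode = "colinear")
  defs <- parse_substructure_table(data.frame(
    label = "D1", kind = "alpha", range = "1-3", sequence = "AAA"))
  h <- build_hierarchy(pdb, defs, min_contacts_top = 1L)
  tab <- aa_descriptor_table()
  hyd_ala <- tab["ALA", "Hydpthy"]
  # middle vertex of the path has two Ala neighbors
  expect_equal(igraph::vertex_attr(h$top, "max_weighted_degree:Hydpthy"),
               2 * hyd_ala)
  expect_equal(igraph::vertex_attr(h$top, "average_weighted_degree:Hydpthy"),
               (1 + 2 + 1) * hyd_ala / 3)
})

test_that("a unit descriptor column reduces to classical invariants", {
  rs <- colinear_pdb(15)
  tab <- as.data.frame(aa_descriptor_table())
  tab$EIIP <- 1                                 # repurpose one column as unit
  h <- build_hierarchy(rs, three_defs(), table = load_descriptor_table(tab),
                       threshold = 8)
  # each midgraph is a path on 5 vertices plus (i,i+2) chords at 7.6 A
  g1 <- h$mid[["D1"]]
  expect_equal(igraph::vertex_attr(h$top, "max_weighted_degree:EIIP")[1],
               max(igraph::degree(g1)))
  expect_equal(igraph::vertex_attr(h$top, "average_weighted_degree:EIIP")[1],
               mean(igraph::degree(g1)))
})

test_that("propagation is idempotent and hierarchies print", {
  h <- helix_hierarchy()
  h2 <- propagate_weights(h)
  expect_identical(igraph::vertex_attr(h2$top), igraph::vertex_attr(h$top))
  expect_identical(lapply(h2$mid, igraph::vertex_attr),
                   lapply(h$mid, igraph::vertex_attr))
  expect_output(print(h), "hier_graph")
})

test_that("every top-level edge is witnessed by two contact-map pairs", {
  h <- helix_hierarchy()
  cm <- h$contact_map
  el <- igraph::as_edgelist(h$top)
  defs <- h$definitions
  for (k in seq_len(nrow(el))) {
    ka <- defs[defs$label == el[k, 1], ]; kb <- defs[defs$label == el[k, 2], ]
    res <- attr(cm, "residues")$resno
    da <- setdiff(res[res >= ka$start & res <= ka$end],
                  res[res >= kb$start & res <= kb$end])
    db <- setdiff(res[res >= kb$start & res <= kb$end],
                  res[res >= ka$start & res <= ka$end])
    npairs <- sum((cm$i %in% da & cm$j %in% db) | (cm$i %in% db & cm$j %in% da))
    expect_gte(npairs, 2L)
  }
})

test_that("permuting definition order yields an isomorphic top graph", {
  rs <- colinear_pdb(15)
  defs <- three_defs()
  h1 <- build_hierarchy(rs, defs, threshold = 8)
  h2 <- build_hierarchy(rs, defs[3:1, ], threshold = 8)
  expect_true(igraph::is_isomorphic_to(h1$top, h2$top))
  a1 <- sort(igraph::vertex_attr(h1$top, "max_weighted_degree:Hydpthy"))
  a2 <- sort(igraph::vertex_attr(h2$top, "max_weighted_degree:Hydpthy"))
  expect_equal(a1, a2)
})

test_that("residues outside all substructures are reported as dropped", {
  pdb <- colinear_pdb(20)                       # defs cover 1-15 only
  expect_message(build_hierarchy(pdb, three_defs(), threshold = 8),
                 "outside every substructure")
})

test_that("negative-valued descriptors are rejected for domination invariants", {
  expect_error(
    build_hierarchy(colinear_pdb(15), three_defs(), threshold = 8,
                    invariants = c("weighted_lower_domination")),
    "non-negative")
})
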