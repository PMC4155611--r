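test_that("compact mutation notation parses", {
  m <- parse_mutation("V51R")
  expect_equal(m$kind, "substitution")
  expect_equal(m$position, 51L)
  expect_equal(m$wild, "V")
  expect_equal(m$new, "R")

  d <- parse_mutation("F508del")
  expect_equal(d$kind, "deletion")
  expect_equal(d$position, 508L)
  expect_equal(d$wild, "F")

  i <- parse_mutation("508insG")
  expect_equal(i$kind, "insertion")
  expect_equal(i$new, "G")

  expect_error(parse_mutation("X99Z"), "cannot parse")    # Z not canonical
  expect_error(parse_mutation("51R"), "cannot parse")

  lst <- parse_mutations(c("# comment", "V51R  # inline", "", "A3G"))
  expect_length(lst, 2L)
})

test_that("sequence editing follows original-numbering semantics", {
  s <- paste(rep("A", 60), collapse = "")
  substr(s, 51, 51) <- "V"
  out <- apply_mutations(s, "V51R")
  expect_equal(nchar(out), nchar(s))
  expect_equal(substr(out, 51, 51), "R")

  expect_identical(apply_mutations(s, list()), s)

  expect_equal(apply_mutations("GAVL", "A2del"), "GVL")
  # deletion shifts later residues left by one
  expect_equal(substr(apply_mutations("GAVL", "A2del"), 2, 2), "V")
  expect_equal(apply_mutations("GAVL", "2insW"), "GAWVL")
  # two mutations, original numbering: delete 2 and substitute original pos 4
  expect_equal(apply_mutations("GAVL", c("A2del", "L4K")), "GVK")

  expect_error(apply_mutations("GAVL", "V2R"), "expected V, found A")
  expect_error(apply_mutations("GAVL", "A9G"), "outside sequence")
})

test_that("reweighting is local to the mutated substructure", {
  h <- helix_hierarchy()
  h2 <- reweight_mutant(h, "V51R")              # 51 interior to D3 (40-55)
  changed_mid <- vapply(names(h$mid), function(lab)
    !identical(igraph::vertex_attr(h$mid[[lab]]),
               igraph::vertex_attr(h2$mid[[lab]])), logical(1))
  expect_equal(unname(which(changed_mid)), 3L)
  d <- diff_top_graphs(h$top, h2$top)
  expect_true(all(rownames(d$weight_deltas) %in% "D3"))
  expect_length(d$edges_gained, 0L)
  expect_length(d$edges_lost, 0L)
})

test_that("a boundary substitution touches at most its two substructures", {
  h <- helix_hierarchy()                        # residue 20 shared by D1/D2
  h2 <- reweight_mutant(h, "A20G")
  d <- diff_top_graphs(h$top, h2$top)
  expect_true(all(rownames(d$weight_deltas) %in% c("D1", "D2")))
  changed_mid <- names(h$mid)[vapply(names(h$mid), function(lab)
    !identical(igraph::vertex_attr(h$mid[[lab]]),
               igraph::vertex_attr(h2$mid[[lab]])), logical(1))]
  expect_setequal(changed_mid, c("D1", "D2"))
})

test_that("an identity substitution changes nothing", {
  h <- helix_hierarchy()
  h2 <- reweight_mutant(h, "A5A")
  expect_identical(igraph::vertex_attr(h2$top), igraph::vertex_attr(h$top))
})

test_that("mutation followed by its reverse restores the hierarchy bit-exactly", {
  h <- helix_hierarchy()
  h2 <- reweight_mutant(h, "V51R")
  expect_false(identical(igraph::vertex_attr(h2$top), igraph::vertex_attr(h$top)))
  h3 <- reweight_mutant(h2, "R51V")
  expect_identical(igraph::vertex_attr(h3$top), igraph::vertex_attr(h$top))
  expect_identical(lapply(h3$mid, igraph::vertex_attr),
                   lapply(h$mid, igraph::vertex_attr))
})

test_that("reweighting validates positions and kinds", {
  h <- helix_hierarchy()
  expect_error(reweight_mutant(h, "V5R"), "expected V, found A")
  expect_error(reweight_mutant(h, "A99G"), "not a residue")
  expect_error(reweight_mutant(h, "A5del"), "substitutions only")
})

test_that("graph diffs report edge and cycle changes exactly", {
  tri <- weighted_graph(c("A","B","B","C","A","C"), c(A = 1, B = 1, C = 1))
  expect_s3_class(diff_top_graphs(tri, tri), "graph_diff")
  d0 <- diff_top_graphs(tri, tri)
  expect_length(d0$edges_gained, 0L)
  expect_length(d0$edges_lost, 0L)
  expect_length(d0$cycles_lost, 0L)

  broken <- igraph::delete_edges(tri, "A|B")
  d <- diff_top_graphs(tri, broken)
  expect_equal(d$edges_lost, "A--B")
  expect_length(d$edges_gained, 0L)
  expect_equal(d$cycles_lost, "A|B|C")

  # antisymmetry
  d2 <- diff_top_graphs(broken, tri)
  expect_equal(d2$edges_gained, d$edges_lost)
  expect_equal(d2$cycles_gained, d$cycles_lost)

  other <- weighted_graph(c("A","B"), c(A = 1, B = 1, Z = 1))
  expect_error(diff_top_graphs(tri, other), "symmetric difference")
})

test_that("rebuilding from a structure detects geometry changes", {
  s <- strrep("G", 15)
  defs <- three_defs()
  straight <- build_hierarchy(colinear_pdb(15), defs)
  # wild structure, empty mutation list: identical hierarchy
  h0 <- rebuild_mutant_from_structure(colinear_pdb(15), defs, list())
  expect_identical(protier:::edge_keys(h0$top), protier:::edge_keys(straight$top))
  expect_identical(igraph::vertex_attr(h0$top), igraph::vertex_attr(straight$top))
  # same sequence folded as a helix: top edges appear
  bent <- rebuild_mutant_from_structure(
    generate_synthetic_structure(s, mode = "helix"), defs, list())
  expect_false(setequal(protier:::edge_keys(bent$top),
                        protier:::edge_keys(straight$top)))
})

test_that("rebuilding validates the mutant sequence", {
  s <- strrep("A", 15)
  defs <- parse_substructure_table(data.frame(
    label = c("D1", "D2"), kind = "alpha", range = c("1-8", "8-15"),
    sequence = c(strrep("A", 8), strrep("A", 8))))
  wild_pdb <- generate_synthetic_structure(s, mode = "helix")
  # structure still has A at 5 although A5G is claimed applied
  expect_error(
    rebuild_mutant_from_structure(wild_pdb, defs, parse_mutations("A5G")),
    "inconsistent")
  expect_error(
    rebuild_mutant_from_structure(wild_pdb, defs, parse_mutations("A5G"),
                                  wild_sequence = s),
    "position 5")
  mut_pdb <- generate_synthetic_structure(apply_mutations(s, "A5G"),
                                          mode = "helix")
  hm <- rebuild_mutant_from_structure(mut_pdb, defs, parse_mutations("A5G"),
                                      wild_sequence = s)
  expect_equal(unname(hierarchy_sequence(hm)[5]), "G")
})

test_that("definition ranges shift across indels", {
  defs <- three_defs()
  shifted <- shift_definitions(defs, parse_mutations("G3del"))
  expect_equal(shifted$start, c(1L, 5L, 10L))
  expect_equal(shifted$end, c(4L, 9L, 14L))
  ins <- shift_definitions(defs, parse_mutations("3insW"))
  expect_equal(ins$start, c(1L, 7L, 12L))
  expect_equal(ins$end, c(6L, 11L, 16L))
})
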