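# Fixtures are generated in code: synthetic structures with known geometry
# and random weighted graphs under a fixed seed.

# random connected G(n, p) with uniform positive vertex weights
rand_wgraph <- function(n, p = 0.4, connected = TRUE) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (!connected || igraph::is_connected(g)) break
  }
  g <- igraph::set_vertex_attr(g, "name", value = paste0("v", seq_len(n)))
  igraph::set_vertex_attr(g, "weight", value = round(stats::runif(n, 0.1, 5), 3))
}

path_graph <- function(n, w = rep(1, n)) {
  el <- if (n > 1) as.vector(rbind(paste0("p", 1:(n - 1)), paste0("p", 2:n)))
        else character(0)
  weighted_graph(el, stats::setNames(w, paste0("p", seq_len(n))))
}

cycle_graph <- function(n, w = rep(1, n)) {
  el <- as.vector(rbind(paste0("c", 1:n), paste0("c", c(2:n, 1))))
  weighted_graph(el, stats::setNames(w, paste0("c", seq_len(n))))
}

star_graph <- function(nleaves, wc = 1, wl = rep(1, nleaves)) {
  el <- as.vector(rbind("hub", paste0("s", seq_len(nleaves))))
  weighted_graph(el, stats::setNames(c(wc, wl), c("hub", paste0("s", seq_len(nleaves)))))
}

# three 5-residue substructures over a 15-residue chain (non-overlapping)
three_defs <- function() {
  parse_substructure_table(data.frame(
    label = c("D1", "D2", "D3"), kind = c("beta", "alpha", "beta"),
    range = c("1-5", "6-10", "11-15"),
    sequence = c("GGGGG", "GGGGG", "GGGGG"), stringsAsFactors = FALSE))
}

colinear_pdb <- function(n = 15, seq = strrep("G", n), spacing = 3.8, start = 1) {
  generate_synthetic_structure(seq, mode = "colinear", spacing = spacing,
                               start = start)
}

# 55-residue helix with V at 51; substructures share boundary residues
helix_hierarchy <- function(threshold = 7) {
  s <- strrep("A", 55)
  substr(s, 51, 51) <- "V"
  pdb <- generate_synthetic_structure(s, mode = "helix")
  defs <- parse_substructure_table(data.frame(
    label = c("D1", "D2", "D3"), kind = "alpha",
    range = c("1-20", "20-40", "40-55"),
    sequence = c(substr(s, 1, 20), substr(s, 20, 40), substr(s, 40, 55)),
    stringsAsFactors = FALSE))
  build_hierarchy(pdb, defs, threshold = threshold)
}

# independent spanning-tree enumeration used as MST ground truth
enumerate_spanning_trees <- function(g) {
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- igraph::E(g)$weight
  m <- nrow(el)
  if (m < n - 1) return(list())
  combos <- utils::combn(m, n - 1, simplify = FALSE)
  keep <- Filter(function(idx) {
    sub <- igraph::make_empty_graph(n, directed = FALSE)
    sub <- igraph::add_edges(sub, t(el[idx, , drop = FALSE]))
    igraph::is_connected(sub)
  }, combos)
  lapply(keep, function(idx) list(idx = idx, total = sum(w[idx])))
}

# all-substitution mutation list applicable to the helix fixture
helix_mutations <- function() {
  parse_mutations(c("A5G", "A12S", "A25L", "A33T", "V51R",
                    "A8K", "A28D", "A44W", "A18F", "A37P"))
}

# 40-residue coil whose top-level graph is connected AND cyclic, so its
# minimum spanning tree genuinely depends on the mutation subset (a
# tree-shaped top graph has only one spanning tree).  The seed is part of
# the fixture: it selects a self-contacting fold with that property.
coil_hierarchy <- function() {
  defs <- parse_substructure_table(data.frame(
    label = paste0("D", 1:4), kind = "loop",
    range = c("1-10", "10-20", "20-30", "30-40"),
    sequence = c(strrep("A", 10), strrep("A", 11), strrep("A", 11),
                 strrep("A", 11)), stringsAsFactors = FALSE))
  pdb <- generate_synthetic_structure(strrep("A", 40), mode = "coil",
                                      seed = 18)
  build_hierarchy(pdb, defs)
}

coil_mutations <- function() {
  parse_mutations(c("A3G", "A7S", "A12K", "A18W", "A23D",
                    "A28F", "A33T", "A38R", "A15L", "A26Y"))
}
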