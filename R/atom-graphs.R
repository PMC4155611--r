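## Bottom level: hydrogen-suppressed rooted atom graphs of the canonical
## amino acids, with atomic-mass vertex weights.

#' Build the atom graph of one amino acid
#'
#' Hydrogen-suppressed ball-and-stick graph of a canonical residue in its
#' generic in-chain form (no OXT): vertices are heavy atoms weighted by
#' standard atomic mass, edges are covalent bonds, and the backbone
#' C-alpha is the root.  Topology and masses come from the bundled tables
#' (see [residue_topology()] and [atomic_masses()]).
#'
#' @param code 3-letter (or 1-letter) canonical residue code.
#' @return An igraph with vertex attributes `name` (atom name), `element`,
#'   `weight` (mass) and graph attributes `resid` and `root` ("CA").
#' @export
build_residue_atom_graph <- function(code) {
  topo <- residue_topology(code)
  code3 <- toupper(code)
  if (nchar(code3) == 1L) code3 <- unname(aa_one_to_three[code3])
  elem <- element_from_atom_name(topo$atoms)
  mass <- atomic_masses()[elem]
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(topo$atoms), name = topo$atoms,
                            element = unname(elem), weight = unname(mass))
  g <- igraph::add_edges(g, as.vector(t(topo$bonds)))
  g <- igraph::set_graph_attr(g, "resid", code3)
  g <- igraph::set_graph_attr(g, "root", "CA")
  stopifnot(igraph::is_connected(g))
  g
}

#' Enumerate the bottom level
#'
#' @return Named list of the 20 canonical amino-acid atom graphs (see
#'   [build_residue_atom_graph()]), keyed by 3-letter code.
#' @export
enumerate_bottom_level <- function() {
  if (is.null(.protier_cache$bottom)) {
    codes <- names(aa_three_to_one)
    .protier_cache$bottom <- stats::setNames(
      lapply(codes, build_residue_atom_graph), codes)
  }
  .protier_cache$bottom
}

#' Graph-derived descriptors of an atom graph
#'
#' Computes the full set of vertex-weighted invariants of a residue atom
#' graph under its atomic-mass weights: weighted lower/upper domination,
#' weighted diameter, circumference, average weighted degree, and the size
#' of the weighted periphery.
#'
#' @param g An atom graph (or any connected vertex-weighted igraph).
#' @return Named numeric vector, one entry per graph-derived descriptor.
#' @export
compute_graph_descriptors <- function(g) {
  nm <- c("weighted_upper_domination", "weighted_lower_domination",
          "weighted_diameter", "circumference",
          "average_weighted_degree", "weighted_periphery_size")
  stats::setNames(vapply(nm, function(x) graph_invariant(g, x), numeric(1)), nm)
}
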