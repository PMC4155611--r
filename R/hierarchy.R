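## Assembling the three-tier hierarchical graph and propagating weights
## bottom -> mid -> top.

#' Build a midlevel substructure graph
#'
#' Vertices are the residues of one substructure present in the structure;
#' two residues are adjacent when the contact map stores their pair.  Edge
#' weights are contact counts.
#'
#' @param cm A `contact_map` (see [build_contact_map()]).
#' @param d A single substructure definition (one row of
#'   [parse_substructure_table()] output, or a list with `label`, `start`,
#'   `end`).
#' @param min_contacts Minimum contact count for a midlevel edge (default 1;
#'   set 2 for the stricter reading in which residue adjacency itself needs
#'   two atom contacts).
#' @return An igraph with vertex attributes `name` (residue number as
#'   character), `resno`, `code1`, edge attribute `weight` (contact count),
#'   and graph attributes `label` and `level = "mid"`.
#' @export
build_midlevel_graph <- function(cm, d, min_contacts = 1L) {
  res <- attr(cm, "residues")
  sel <- res$resno >= d$start & res$resno <= d$end
  if (!any(sel))
    stop("substructure ", d$label, " (", d$start, "-", d$end,
         ") has no residues in the structure")
  verts <- res[sel, , drop = FALSE]
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, nrow(verts), name = as.character(verts$resno),
                            resno = verts$resno, code1 = verts$code1)
  rows <- cm$i %in% verts$resno & cm$j %in% verts$resno & cm$count >= min_contacts
  if (any(rows)) {
    el <- rbind(as.character(cm$i[rows]), as.character(cm$j[rows]))
    g <- igraph::add_edges(g, as.vector(el), weight = cm$count[rows])
  }
  g <- igraph::set_graph_attr(g, "label", d$label)
  igraph::set_graph_attr(g, "level", "mid")
}

#' Build the top-level substructure graph
#'
#' One vertex per substructure definition.  Two substructures Di, Dj are
#' adjacent when at least `min_contacts` residue pairs - one residue in
#' each, residues shared by both substructures excluded - are stored in the
#' contact map.  Edge weights are the total inter-substructure contact
#' counts.
#'
#' @param cm A `contact_map`.
#' @param defs Substructure definitions ([parse_substructure_table()]).
#' @param min_contacts Minimum number of qualifying residue pairs for a
#'   top-level edge (default 2).
#' @return An igraph with vertex attribute `name` (labels), edge attributes
#'   `weight` (total contacts) and `npairs`, graph attribute `level = "top"`.
#' @export
build_top_level <- function(cm, defs, min_contacts = 2L) {
  if (nrow(defs) == 0L) stop("`defs` must be non-empty")
  if (anyDuplicated(defs$label))
    stop("duplicate substructure labels: ",
         paste(unique(defs$label[duplicated(defs$label)]), collapse = ", "))
  res <- attr(cm, "residues")
  members <- lapply(seq_len(nrow(defs)), function(k)
    res$resno[res$resno >= defs$start[k] & res$resno <= defs$end[k]])
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, nrow(defs), name = defs$label)
  nd <- nrow(defs)
  for (a in seq_len(max(nd - 1L, 0L))) for (b in seq((a + 1L), nd)) {
    da <- setdiff(members[[a]], members[[b]])
    db <- setdiff(members[[b]], members[[a]])
    rows <- (cm$i %in% da & cm$j %in% db) | (cm$i %in% db & cm$j %in% da)
    if (sum(rows) >= min_contacts)
      g <- igraph::add_edges(g, c(defs$label[a], defs$label[b]),
                             weight = sum(cm$count[rows]), npairs = sum(rows))
  }
  igraph::set_graph_attr(g, "level", "top")
}

#' Build the full three-tier hierarchical graph
#'
#' Reads a structure, computes its contact map, builds the midlevel graph
#' of every substructure and the top-level graph, and propagates descriptor
#' weights up the hierarchy.
#'
#' @param pdb PDB path or text (see [read_structure()]).
#' @param defs Substructure definitions.
#' @param chain Chain identifier (optional for single-chain files).
#' @param table Descriptor table (default: the bundled table).
#' @param metric,threshold,count_metric Contact-map parameters
#'   ([build_contact_map()]).
#' @param min_contacts_top,min_contacts_mid Edge rules for the two upper
#'   tiers.
#' @param invariants Invariant names used when weighting top-level vertices
#'   (see [propagate_weights()]).
#' @param structure_id Optional identifier recorded in the provenance.
#' @return An object of class `hier_graph`: a list with elements
#'   `definitions`, `residues`, `contact_map`, `bottom`, `mid` (named list
#'   of igraphs), `top` (igraph), `table` and `provenance`.
#' @export
build_hierarchy <- function(pdb, defs, chain = NULL,
                            table = aa_descriptor_table(),
                            metric = "calpha", threshold = 7,
                            count_metric = "all_atom",
                            min_contacts_top = 2L, min_contacts_mid = 1L,
                            invariants = c("max_weighted_degree",
                                           "average_weighted_degree"),
                            structure_id = NULL) {
  residues <- read_structure(pdb, chain)
  cm <- build_contact_map(residues, metric = metric, threshold = threshold,
                          count_metric = count_metric)
  res <- attr(cm, "residues")
  covered <- rep(FALSE, nrow(res))
  for (k in seq_len(nrow(defs)))
    covered <- covered | (res$resno >= defs$start[k] & res$resno <= defs$end[k])
  if (any(!covered))
    message("dropping ", sum(!covered),
            " residue(s) outside every substructure range: ",
            paste(utils::head(res$resno[!covered], 10), collapse = ", "),
            if (sum(!covered) > 10) " ...")
  mids <- lapply(seq_len(nrow(defs)), function(k)
    build_midlevel_graph(cm, defs[k, ], min_contacts = min_contacts_mid))
  names(mids) <- defs$label
  top <- build_top_level(cm, defs, min_contacts = min_contacts_top)
  h <- structure(list(
    definitions = defs,
    residues = residues,
    contact_map = cm,
    bottom = enumerate_bottom_level(),
    mid = mids,
    top = top,
    table = table,
    provenance = list(structure_id = structure_id,
                      chain = attr(residues, "chain"),
                      metric = metric, threshold = threshold,
                      count_metric = count_metric,
                      min_contacts_top = min_contacts_top,
                      min_contacts_mid = min_contacts_mid,
                      invariants = invariants,
                      mutations = character(0))),
    class = "hier_graph")
  propagate_weights(h, table, invariants)
}

#' Propagate descriptor weights up the hierarchy
#'
#' Every midlevel vertex receives the descriptor vector of its amino acid;
#' every top-level vertex Di receives, for each descriptor and each
#' requested invariant, the value of that invariant on Di's midlevel graph
#' with vertices weighted by that descriptor (attribute name
#' `"invariant:descriptor"`, e.g. `"max_weighted_degree:Hydpthy"`).
#' Calling the function twice is a no-op.
#'
#' Invariants based on domination or distances require non-negative
#' weights; descriptors with negative values (such as hydropathy) can only
#' be propagated through degree-based invariants.
#'
#' @param h A `hier_graph`.
#' @param table Descriptor table.
#' @param invariants Character vector of [invariant_names()] entries.
#' @return The hierarchy with refreshed mid and top vertex attributes.
#' @export
propagate_weights <- function(h, table = h$table,
                              invariants = h$provenance$invariants) {
  stopifnot(inherits(h, "hier_graph"))
  invariants <- match.arg(invariants, invariant_names(), several.ok = TRUE)
  nonneg_only <- c("weighted_lower_domination", "weighted_upper_domination",
                   "weighted_diameter", "weighted_periphery_size")
  dnames <- descriptor_names()
  for (lab in names(h$mid)) {
    g <- h$mid[[lab]]
    codes <- igraph::V(g)$code1
    vals <- t(vapply(seq_along(codes), function(i)
      descriptor_vector(table, codes[i], position = igraph::V(g)$resno[i]),
      stats::setNames(numeric(length(dnames)), dnames)))
    for (d in dnames)
      g <- igraph::set_vertex_attr(g, d, value = unname(vals[, d]))
    h$mid[[lab]] <- g
  }
  top <- h$top
  for (inv in invariants) for (d in dnames) {
    vals <- vapply(igraph::V(top)$name, function(lab) {
      g <- h$mid[[lab]]
      w <- igraph::vertex_attr(g, d)
      if (inv %in% nonneg_only && any(w < 0))
        stop("invariant '", inv, "' requires non-negative weights, but ",
             "descriptor '", d, "' has negative values")
      graph_invariant(set_vertex_weights(g, w), inv)
    }, numeric(1))
    top <- igraph::set_vertex_attr(top, paste0(inv, ":", d),
                                   value = unname(vals))
  }
  h$top <- top
  h$table <- table
  h$provenance$invariants <- invariants
  h
}

#' @export
print.hier_graph <- function(x, ...) {
  cat("hier_graph: ", nrow(x$definitions), " substructures, ",
      length(x$residues), " residues (chain ", x$provenance$chain, ")\n",
      "  contact map: ", x$provenance$metric, " metric, ",
      x$provenance$threshold, " A, ", nrow(x$contact_map), " pairs\n",
      "  top level: ", igraph::vcount(x$top), " vertices, ",
      igraph::ecount(x$top), " edges\n", sep = "")
  invisible(x)
}

#' One-letter sequence of a hierarchy's chain
#'
#' @param h A `hier_graph`.
#' @return Named character vector (names = residue numbers), reflecting any
#'   substitutions applied by [reweight_mutant()].
#' @export
hierarchy_sequence <- function(h) {
  out <- residue_codes(h$residues)
  for (lab in names(h$mid)) {
    g <- h$mid[[lab]]
    out[as.character(igraph::V(g)$resno)] <- igraph::V(g)$code1
  }
  out
}
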