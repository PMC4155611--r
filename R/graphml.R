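## GraphML serialization.  Written on xml2 so numeric attributes can be
## emitted with 17 significant digits, making export -> import the exact
## identity on vertex/edge sets and weights (a requirement the stock igraph
## writer's shorter formatting does not meet).

GRAPHML_NS <- "http://graphml.graphdrawing.org/xmlns"

fmt_attr <- function(x) {
  if (is.numeric(x) && !is.integer(x)) sprintf("%.17g", x) else as.character(x)
}

graphml_type <- function(x) {
  if (is.integer(x)) "long" else if (is.numeric(x)) "double"
  else if (is.logical(x)) "boolean" else "string"
}

#' Export a graph to GraphML
#'
#' Writes standard GraphML with one typed `<key>` per vertex/edge
#' attribute.  Numeric attributes are serialized with 17 significant
#' digits, so [read_graphml()] reproduces them exactly.
#'
#' @param g An igraph (e.g. a tier graph), or an `mst_result` (its tree is
#'   exported).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(g, path) {
  if (inherits(g, "mst_result")) g <- g$tree
  if (!igraph::is_igraph(g)) stop("`g` must be an igraph or mst_result")
  doc <- xml2::xml_new_root("graphml", xmlns = GRAPHML_NS)
  vattrs <- setdiff(igraph::vertex_attr_names(g), "name")
  eattrs <- igraph::edge_attr_names(g)
  for (a in vattrs)
    xml2::xml_add_child(doc, "key", id = paste0("v_", a), "for" = "node",
                        "attr.name" = a,
                        "attr.type" = graphml_type(igraph::vertex_attr(g, a)))
  for (a in eattrs)
    xml2::xml_add_child(doc, "key", id = paste0("e_", a), "for" = "edge",
                        "attr.name" = a,
                        "attr.type" = graphml_type(igraph::edge_attr(g, a)))
  gr <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "undirected")
  labs <- vertex_labels(g)
  for (i in seq_len(igraph::vcount(g))) {
    nd <- xml2::xml_add_child(gr, "node", id = labs[i])
    for (a in vattrs) {
      d <- xml2::xml_add_child(nd, "data", key = paste0("v_", a))
      xml2::xml_set_text(d, fmt_attr(igraph::vertex_attr(g, a)[i]))
    }
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  for (k in seq_len(nrow(el))) {
    ed <- xml2::xml_add_child(gr, "edge", source = labs[el[k, 1]],
                              target = labs[el[k, 2]])
    for (a in eattrs) {
      d <- xml2::xml_add_child(ed, "data", key = paste0("e_", a))
      xml2::xml_set_text(d, fmt_attr(igraph::edge_attr(g, a)[k]))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

parse_typed <- function(x, type) {
  switch(type,
    double = as.numeric(x),
    long = as.integer(x),
    int = as.integer(x),
    boolean = as.logical(x),
    x)
}

#' Read a GraphML file written by [export_graphml()]
#'
#' @param path GraphML file path.
#' @return An undirected igraph with typed vertex/edge attributes.
#' @export
read_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(g = GRAPHML_NS)
  keys <- xml2::xml_find_all(doc, ".//g:key", ns)
  keytab <- data.frame(id = xml2::xml_attr(keys, "id"),
                       domain = xml2::xml_attr(keys, "for"),
                       name = xml2::xml_attr(keys, "attr.name"),
                       type = xml2::xml_attr(keys, "attr.type"),
                       stringsAsFactors = FALSE)
  nodes <- xml2::xml_find_all(doc, ".//g:graph/g:node", ns)
  ids <- xml2::xml_attr(nodes, "id")
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(ids), name = ids)
  node_data <- function(a) {
    key <- keytab$id[keytab$domain == "node" & keytab$name == a]
    vapply(nodes, function(nd) {
      d <- xml2::xml_find_first(nd, sprintf("./g:data[@key='%s']", key), ns)
      if (inherits(d, "xml_missing")) NA_character_ else xml2::xml_text(d)
    }, character(1))
  }
  for (a in keytab$name[keytab$domain == "node"])
    g <- igraph::set_vertex_attr(g, a, value = parse_typed(
      node_data(a), keytab$type[keytab$domain == "node" & keytab$name == a]))
  edges <- xml2::xml_find_all(doc, ".//g:graph/g:edge", ns)
  if (length(edges)) {
    src <- xml2::xml_attr(edges, "source")
    tgt <- xml2::xml_attr(edges, "target")
    g <- igraph::add_edges(g, as.vector(rbind(src, tgt)))
    for (a in keytab$name[keytab$domain == "edge"]) {
      key <- keytab$id[keytab$domain == "edge" & keytab$name == a]
      vals <- vapply(edges, function(ed) {
        d <- xml2::xml_find_first(ed, sprintf("./g:data[@key='%s']", key), ns)
        if (inherits(d, "xml_missing")) NA_character_ else xml2::xml_text(d)
      }, character(1))
      g <- igraph::set_edge_attr(g, a, value = parse_typed(
        vals, keytab$type[keytab$domain == "edge" & keytab$name == a]))
    }
  }
  g
}

hierarchy_bottom_union <- function(h) {
  gs <- lapply(names(h$bottom), function(code) {
    g <- h$bottom[[code]]
    igraph::set_vertex_attr(g, "name",
                            value = paste(code, igraph::V(g)$name, sep = ":"))
  })
  do.call(igraph::disjoint_union, gs)
}

hierarchy_mid_union <- function(h) {
  gs <- lapply(names(h$mid), function(lab) {
    g <- h$mid[[lab]]
    g <- igraph::set_vertex_attr(g, "substructure", value = lab)
    igraph::set_vertex_attr(g, "name",
                            value = paste(lab, igraph::V(g)$name, sep = ":"))
  })
  do.call(igraph::disjoint_union, gs)
}

#' Serialize a hierarchy to a directory
#'
#' Writes `top.graphml`, `midlevel.graphml` (disjoint union of the
#' substructure graphs, vertices named `"Di:resno"`), `bottom.graphml`
#' (disjoint union of the residue atom graphs, vertices named `"RES:atom"`)
#' and a JSON provenance manifest sufficient to re-run the build
#' (structure id, chain, metric, threshold, edge rules, invariant set,
#' mutations applied, and an md5 checksum of the descriptor table).
#'
#' @param h A `hier_graph`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_hierarchy <- function(h, dir) {
  stopifnot(inherits(h, "hier_graph"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  export_graphml(h$top, file.path(dir, "top.graphml"))
  export_graphml(hierarchy_mid_union(h), file.path(dir, "midlevel.graphml"))
  export_graphml(hierarchy_bottom_union(h), file.path(dir, "bottom.graphml"))
  tmp <- tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(h$table), tmp, row.names = FALSE)
  manifest <- c(h$provenance,
                list(descriptor_checksum = unname(tools::md5sum(tmp)),
                     n_substructures = nrow(h$definitions),
                     n_residues = length(h$residues)))
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
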