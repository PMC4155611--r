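## Minimum spanning tree analysis of the top-level graph: vertex-derived
## edge weights, exact MST with uniqueness detection, and the
## mutation-resampling degree-stability experiment.

#' Derive edge weights from vertex weights
#'
#' Each edge \{Di, Dj\} receives the average (or the sum) of the two
#' endpoint values of a chosen vertex descriptor.  The two schemes differ
#' by a factor of exactly 2, so they order edges identically and yield the
#' same minimum spanning trees.
#'
#' @param g igraph whose vertices carry the numeric attribute `descriptor`.
#' @param descriptor Vertex attribute name (e.g.
#'   `"max_weighted_degree:Hydpthy"` on a propagated top-level graph).
#' @param scheme `"sum"` or `"average"`.
#' @return `g` with edge attribute `weight` set and vertex attribute
#'   `weight` set to the descriptor values.
#' @export
vertex_to_edge_weights <- function(g, descriptor, scheme = c("sum", "average")) {
  scheme <- match.arg(scheme)
  w <- igraph::vertex_attr(g, descriptor)
  if (is.null(w)) stop("vertex attribute '", descriptor, "' not found")
  if (anyNA(w))
    stop("vertex attribute '", descriptor, "' missing on vertex: ",
         paste(igraph::V(g)$name[is.na(w)], collapse = ", "))
  el <- igraph::as_edgelist(g, names = FALSE)
  ew <- w[el[, 1]] + w[el[, 2]]
  if (scheme == "average") ew <- ew / 2
  g <- igraph::set_edge_attr(g, "weight", value = ew)
  igraph::set_vertex_attr(g, "weight", value = w)
}

## union-find with path compression
uf_find <- function(parent, x) {
  while (parent[x] != x) { parent[x] <- parent[parent[x]]; x <- parent[x] }
  x
}

#' Minimum spanning tree with uniqueness detection
#'
#' Kruskal's algorithm with deterministic tie-breaking (edges sorted by
#' weight, then by lexicographic endpoint labels).  The `unique` flag is
#' exact: the MST is unique if and only if every non-tree edge is strictly
#' heavier than every tree edge on the cycle it closes.
#'
#' @param g Connected igraph with numeric edge attribute `weight`.
#' @param maximize Find the maximum spanning tree instead.
#' @return A list of class `mst_result`: `edges` (data frame `from`, `to`,
#'   `weight`), `total`, `unique`, `degrees` (named integer vector) and
#'   `tree` (the tree as an igraph).
#' @export
minimum_spanning_tree <- function(g, maximize = FALSE) {
  check_connected(g, "minimum spanning tree")
  labs <- vertex_labels(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- igraph::edge_attr(g, "weight")
  if (is.null(w)) stop("graph has no edge attribute 'weight'")
  n <- igraph::vcount(g)
  a <- labs[el[, 1]]; b <- labs[el[, 2]]
  from <- pmin(a, b); to <- pmax(a, b)
  ord <- order(if (maximize) -w else w, from, to)
  parent <- seq_len(n)
  take <- logical(length(w))
  for (k in ord) {
    ra <- uf_find(parent, el[k, 1]); rb <- uf_find(parent, el[k, 2])
    if (ra != rb) { parent[ra] <- rb; take[k] <- TRUE }
  }
  tree_el <- el[take, , drop = FALSE]
  tree <- igraph::make_empty_graph(n = 0, directed = FALSE)
  tree <- igraph::add_vertices(tree, n, name = labs)
  if (nrow(tree_el))
    tree <- igraph::add_edges(tree, labs[t(tree_el)], weight = w[take])
  ## uniqueness via the cycle property
  unique_flag <- TRUE
  if (any(!take)) {
    for (k in which(!take)) {
      path <- igraph::shortest_paths(tree, from = labs[el[k, 1]],
                                     to = labs[el[k, 2]], weights = NA,
                                     output = "epath")$epath[[1]]
      extreme <- if (maximize) min(igraph::edge_attr(tree, "weight", path))
                 else max(igraph::edge_attr(tree, "weight", path))
      if ((maximize && w[k] >= extreme) || (!maximize && w[k] <= extreme)) {
        unique_flag <- FALSE; break
      }
    }
  }
  deg <- igraph::degree(tree)
  names(deg) <- labs
  structure(list(edges = data.frame(from = from[take], to = to[take],
                                    weight = w[take], stringsAsFactors = FALSE),
                 total = sum(w[take]), unique = unique_flag,
                 degrees = deg, tree = tree),
            class = "mst_result")
}

#' @export
print.mst_result <- function(x, ...) {
  cat("mst_result: ", nrow(x$edges), " edges, total weight ",
      format(x$total), ", ", if (x$unique) "unique" else "not unique", "\n",
      sep = "")
  invisible(x)
}

#' Minimum spanning tree of the top-level graph under a mutation subset
#'
#' Applies the given substitutions by re-weighting (the top-level edge set
#' never changes in this mode), derives edge weights from the chosen
#' descriptor, and returns the minimum spanning tree.
#'
#' @param h Wild-type `hier_graph`.
#' @param specs Mutation subset (may be empty, giving the wild-type tree).
#' @param descriptor Top-level vertex attribute, default the maximum
#'   hydropathy-weighted degree of each substructure.
#' @param scheme Edge-weighting scheme, see [vertex_to_edge_weights()].
#' @param table Descriptor table.
#' @param maximize Passed to [minimum_spanning_tree()].
#' @return An `mst_result`.
#' @export
mst_for_mutations <- function(h, specs = list(),
                              descriptor = "max_weighted_degree:Hydpthy",
                              scheme = c("sum", "average"),
                              table = h$table, maximize = FALSE) {
  scheme <- match.arg(scheme)
  hm <- if (length(specs)) reweight_mutant(h, specs, table) else h
  g <- vertex_to_edge_weights(hm$top, descriptor, scheme)
  minimum_spanning_tree(g, maximize = maximize)
}

#' Suggest a resampling design
#'
#' Chooses (samples, sample size) so that samples * sample_size /
#' n_mutations approximates a stated expected number of occurrences of each
#' mutation (default 2.5).
#'
#' @param n_mutations Number of available mutations.
#' @param expectation Target expected occurrences per mutation.
#' @return List with `samples`, `sample_size` and the achieved
#'   `expected_occurrences`.
#' @export
resampling_design <- function(n_mutations, expectation = 2.5) {
  sample_size <- max(1L, as.integer(round(n_mutations / 2)))
  samples <- max(1L, as.integer(round(expectation * n_mutations / sample_size)))
  list(samples = samples, sample_size = sample_size,
       expected_occurrences = samples * sample_size / n_mutations)
}

#' Mutation resampling of minimum-spanning-tree vertex degrees
#'
#' Repeatedly draws `sample_size` mutations uniformly without replacement
#' from the full list, recomputes the minimum spanning tree of the
#' re-weighted top-level graph, and records the tree degree of every
#' vertex.  Vertices whose degree never varies are structurally stable
#' against the mutation set under the chosen descriptor.
#'
#' @param h Wild-type `hier_graph`.
#' @param specs Full mutation list (substitutions).
#' @param samples Number of resamples.
#' @param sample_size Mutations drawn per resample (must not exceed the
#'   list length).
#' @param seed Integer seed; the report is reproducible byte-for-byte.
#' @param descriptor,scheme,table As in [mst_for_mutations()].
#' @return A list of class `resampling_report`: `report` (data frame
#'   `vertex`, `mean_degree`, `sd_degree`), `degrees` (samples x vertex
#'   matrix), `draws` (the sampled mutation indices per resample),
#'   `samples`, `sample_size`, `seed`, `expected_occurrences`.
#' @export
mutation_resampling <- function(h, specs, samples, sample_size, seed = 1L,
                                descriptor = "max_weighted_degree:Hydpthy",
                                scheme = c("sum", "average"),
                                table = h$table) {
  scheme <- match.arg(scheme)
  if (is.character(specs)) specs <- parse_mutations(specs)
  n <- length(specs)
  if (sample_size > n)
    stop("sample_size (", sample_size, ") exceeds the number of mutations (", n, ")")
  draws <- with_preserved_rng(seed,
    lapply(seq_len(samples), function(i) sample.int(n, sample_size)))
  degmat <- t(vapply(draws, function(idx)
    mst_for_mutations(h, specs[idx], descriptor = descriptor,
                      scheme = scheme, table = table)$degrees,
    stats::setNames(numeric(igraph::vcount(h$top)), igraph::V(h$top)$name)))
  sds <- apply(degmat, 2, stats::sd)
  sds[is.na(sds)] <- 0                      # single resample
  report <- data.frame(vertex = colnames(degmat),
                       mean_degree = colMeans(degmat),
                       sd_degree = sds,
                       stringsAsFactors = FALSE, row.names = NULL)
  structure(list(report = report, degrees = degmat, draws = draws,
                 samples = samples, sample_size = sample_size, seed = seed,
                 expected_occurrences = samples * sample_size / n,
                 descriptor = descriptor, scheme = scheme),
            class = "resampling_report")
}

#' @export
print.resampling_report <- function(x, ...) {
  cat("resampling_report: ", x$samples, " samples of size ", x$sample_size,
      " (expected occurrences per mutation ",
      format(x$expected_occurrences), ")\n", sep = "")
  print(x$report)
  invisible(x)
}

#' Classify vertices as stable or sensitive under resampling
#'
#' @param report A `resampling_report`.
#' @param tolerance Maximum degree standard deviation still called stable
#'   (default 0: the degree never changed in any resample).
#' @return List with character vectors `stable` and `sensitive`.
#' @export
stability_classification <- function(report, tolerance = 0) {
  stopifnot(inherits(report, "resampling_report"))
  st <- report$report$sd_degree <= tolerance
  list(stable = report$report$vertex[st],
       sensitive = report$report$vertex[!st])
}
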