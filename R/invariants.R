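## Vertex-weighted graph invariants.
##
## All invariants operate on igraph objects carrying a numeric vertex
## attribute "weight".  The weighted definitions generalize the classical
## ones: with all vertex weights equal to 1 each invariant reduces exactly
## to its textbook counterpart.

as_weighted_graph_checked <- function(g, require_weights = TRUE) {
  if (!igraph::is_igraph(g)) stop("`g` must be an igraph object")
  if (igraph::any_loop(g)) stop("weighted graphs may not contain self-loops")
  if (igraph::any_multiple(g)) stop("weighted graphs may not contain duplicate edges")
  w <- igraph::vertex_attr(g, "weight")
  if (is.null(w)) {
    if (require_weights)
      stop("graph has no vertex attribute 'weight'; use set_vertex_weights()")
    w <- rep(1, igraph::vcount(g))
    g <- igraph::set_vertex_attr(g, "weight", value = w)
  }
  if (!all(is.finite(w))) stop("vertex weights must be finite")
  g
}

#' Construct a vertex-weighted graph
#'
#' Convenience constructor for the vertex-weighted graphs on which the
#' package's invariants are defined.
#'
#' @param edges Two-column matrix or data frame of vertex names, or a
#'   length-2k character vector taken pairwise.
#' @param weights Named numeric vector of vertex weights.  Names not
#'   appearing in `edges` become isolated vertices.
#' @return An igraph object with vertex attribute `weight`.
#' @examples
#' g <- weighted_graph(c("a","b", "b","c"), c(a = 2, b = 1, c = 5))
#' weighted_degree(g, "b")   # 7
#' @export
weighted_graph <- function(edges, weights) {
  if (is.null(names(weights)))
    stop("`weights` must be a named numeric vector")
  if (is.matrix(edges) || is.data.frame(edges))
    edges <- as.vector(t(as.matrix(edges)))
  edges <- as.character(edges)
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(weights), name = names(weights),
                            weight = unname(weights))
  if (length(edges)) g <- igraph::add_edges(g, edges)
  as_weighted_graph_checked(g)
}

#' Set vertex weights on a graph
#'
#' @param g An igraph object.
#' @param weights Numeric vector in vertex order, or named by vertex name.
#' @return `g` with vertex attribute `weight` replaced.
#' @export
set_vertex_weights <- function(g, weights) {
  if (!is.null(names(weights))) {
    idx <- match(igraph::V(g)$name, names(weights))
    if (anyNA(idx)) stop("missing weight for vertex: ",
                         paste(igraph::V(g)$name[is.na(idx)], collapse = ", "))
    weights <- unname(weights[idx])
  }
  if (length(weights) != igraph::vcount(g))
    stop("need one weight per vertex")
  igraph::set_vertex_attr(g, "weight", value = weights)
}

vertex_index <- function(g, v) {
  idx <- if (is.character(v)) match(v, igraph::V(g)$name) else as.integer(v)
  if (anyNA(idx) || any(idx < 1L) || any(idx > igraph::vcount(g)))
    stop("unknown vertex: ", paste(v[is.na(idx) | idx < 1 | idx > igraph::vcount(g)],
                                   collapse = ", "))
  idx
}

adjacency_list_int <- function(g) {
  lapply(igraph::as_adj_list(g), as.integer)
}

vertex_labels <- function(g) {
  nm <- igraph::V(g)$name
  if (is.null(nm)) as.character(seq_len(igraph::vcount(g))) else nm
}

#' Weighted degree of a vertex
#'
#' The weighted degree of a vertex is the sum of the weights of its
#' neighbors.  With unit weights this is the classical degree.
#'
#' @param g Vertex-weighted igraph (vertex attribute `weight`).
#' @param v A vertex (name or index), or `NULL` for all vertices.
#' @return Numeric; named vector over all vertices when `v` is `NULL`.
#' @export
weighted_degree <- function(g, v = NULL) {
  g <- as_weighted_graph_checked(g)
  w <- igraph::V(g)$weight
  adj <- adjacency_list_int(g)
  wd <- vapply(adj, function(nb) sum(w[nb]), numeric(1))
  names(wd) <- vertex_labels(g)
  if (is.null(v)) wd else unname(wd[vertex_index(g, v)])
}

#' Maximum and average weighted degree
#'
#' @inheritParams weighted_degree
#' @return A single number: the maximum (resp. arithmetic mean) of the
#'   weighted degrees over all vertices.
#' @export
max_weighted_degree <- function(g) {
  if (igraph::vcount(g) == 0L) stop("graph is empty")
  max(weighted_degree(g))
}

#' @rdname max_weighted_degree
#' @export
average_weighted_degree <- function(g) {
  if (igraph::vcount(g) == 0L) stop("graph is empty")
  mean(weighted_degree(g))
}

## ---- weighted domination -------------------------------------------------

## Branch-and-bound minimum-weight dominating set.  Branches on the closed
## neighborhood of an undominated vertex; prunes on accumulated weight
## (weights must be non-negative).  Exact; exponential worst case, fast on
## the small sparse graphs arising from protein substructures.
min_weight_domset <- function(adj, w) {
  n <- length(adj)
  closed <- lapply(seq_len(n), function(v) c(v, adj[[v]]))
  env <- new.env(parent = emptyenv())
  env$best <- sum(w)                      # V(G) always dominates
  recurse <- function(wS, dominated) {
    if (wS >= env$best) return(invisible(NULL))
    und <- which(!dominated)
    if (!length(und)) { env$best <- wS; return(invisible(NULL)) }
    ## branch on the undominated vertex with fewest choices
    v <- und[which.min(lengths(closed[und]))]
    cand <- closed[[v]]
    gain <- vapply(cand, function(u) sum(!dominated[closed[[u]]]), numeric(1))
    for (u in cand[order(w[cand] / pmax(gain, 1e-300))]) {
      dom2 <- dominated
      dom2[closed[[u]]] <- TRUE
      recurse(wS + w[u], dom2)
    }
    invisible(NULL)
  }
  recurse(0, rep(FALSE, n))
  env$best
}

## Maximum total weight over MINIMAL dominating sets, by pruned enumeration.
## A set is minimal when every member has a private closed neighbor.  The
## search branches over the closed neighborhood of the first undominated
## vertex with sibling exclusion (complete, duplicate-free) and prunes
## branches in which some chosen vertex has become permanently redundant.
max_weight_minimal_domset <- function(adj, w) {
  n <- length(adj)
  closed <- lapply(seq_len(n), function(v) c(v, adj[[v]]))
  env <- new.env(parent = emptyenv())
  env$best <- -Inf
  is_minimal <- function(S, inS) {
    for (s in S) {
      private <- FALSE
      for (x in closed[[s]]) {
        dominators <- sum(inS[closed[[x]]])
        if (dominators == 1L) { private <- TRUE; break }
      }
      if (!private) return(FALSE)
    }
    TRUE
  }
  recurse <- function(S, inS, wS, dominated, excluded) {
    ## redundancy prune: a member whose closed neighborhood is entirely
    ## dominated by the others can never regain a private neighbor
    for (s in S) {
      inS[s] <- FALSE
      redundant <- all(vapply(closed[[s]],
                              function(x) any(inS[closed[[x]]]), logical(1)))
      inS[s] <- TRUE
      if (redundant) return(invisible(NULL))
    }
    und <- which(!dominated)
    if (!length(und)) {
      if (wS > env$best && is_minimal(S, inS)) env$best <- wS
      return(invisible(NULL))
    }
    ## weight bound over still-addable vertices
    addable <- !inS & !excluded
    if (wS + sum(w[addable]) <= env$best) return(invisible(NULL))
    v <- und[1L]
    cand <- setdiff(closed[[v]], which(excluded))
    for (u in cand) {
      inS[u] <- TRUE
      dom2 <- dominated
      dom2[closed[[u]]] <- TRUE
      recurse(c(S, u), inS, wS + w[u], dom2, excluded)
      inS[u] <- FALSE
      excluded[u] <- TRUE
    }
    invisible(NULL)
  }
  recurse(integer(0), rep(FALSE, n), 0, rep(FALSE, n), rep(FALSE, n))
  env$best
}

#' Weighted domination numbers
#'
#' A dominating set is a vertex set S such that every vertex is in S or has
#' a neighbor in S.  The weighted lower domination number is the minimum
#' total vertex weight over all dominating sets; the weighted upper
#' domination number is the maximum total weight over all *minimal*
#' dominating sets (sets from which no vertex can be removed without losing
#' domination).  With unit weights these are the classical domination and
#' upper domination numbers.
#'
#' Both values are computed exactly by branch and bound; the worst case is
#' exponential in the number of vertices, which is acceptable for the
#' residue- and substructure-scale graphs this package builds.
#'
#' @param g Vertex-weighted igraph; weights must be non-negative.
#' @return Named numeric vector `c(lower = , upper = )`.
#' @export
weighted_domination <- function(g) {
  g <- as_weighted_graph_checked(g)
  if (igraph::vcount(g) == 0L) stop("graph is empty")
  w <- igraph::V(g)$weight
  if (any(w < 0)) stop("weighted domination requires non-negative vertex weights")
  adj <- adjacency_list_int(g)
  c(lower = min_weight_domset(adj, w),
    upper = max_weight_minimal_domset(adj, w))
}

## ---- weighted distances --------------------------------------------------

## Vertex-weighted distance: the length of a path is the sum of the weights
## of its vertices EXCLUDING the start, so with unit weights the length is
## the edge count.  Realized as directed edge weights w(target) + Dijkstra.
weighted_distance_matrix <- function(g) {
  g <- as_weighted_graph_checked(g)
  w <- igraph::V(g)$weight
  if (any(w < 0)) stop("weighted distances require non-negative vertex weights")
  n <- igraph::vcount(g)
  if (n == 1L) {
    d <- matrix(0, 1, 1, dimnames = list(vertex_labels(g), vertex_labels(g)))
    return(d)
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  dir <- igraph::graph_from_edgelist(rbind(el, el[, 2:1, drop = FALSE]),
                                     directed = TRUE)
  if (igraph::vcount(dir) < n) dir <- igraph::add_vertices(dir, n - igraph::vcount(dir))
  ew <- c(w[el[, 2]], w[el[, 1]])
  d <- igraph::distances(dir, mode = "out", weights = ew, algorithm = "dijkstra")
  dimnames(d) <- list(vertex_labels(g), vertex_labels(g))
  d
}

check_connected <- function(g, what) {
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    labs <- split(vertex_labels(g), comp$membership)
    stop(what, " requires a connected graph; components: ",
         paste(vapply(labs, function(x) paste0("{", paste(x, collapse = ","), "}"),
                      character(1)), collapse = " "))
  }
  invisible(TRUE)
}

#' Weighted eccentricity, diameter and periphery
#'
#' Based on the vertex-weighted distance in which the length of a path is
#' the sum of the vertex weights along it excluding the start vertex (so
#' unit weights recover the classical edge-count distance).  The distance is
#' therefore direction-dependent; eccentricity and diameter are taken over
#' ordered pairs.
#'
#' @param g Connected vertex-weighted igraph with non-negative weights.
#' @param v Vertex name or index.
#' @return `weighted_eccentricity`: a number; `weighted_diameter`: a number;
#'   `weighted_periphery`: character vector of the vertices whose
#'   eccentricity equals the diameter.
#' @export
weighted_eccentricity <- function(g, v) {
  check_connected(g, "weighted eccentricity")
  d <- weighted_distance_matrix(g)
  max(d[vertex_index(g, v), ])
}

#' @rdname weighted_eccentricity
#' @export
weighted_diameter <- function(g) {
  check_connected(g, "weighted diameter")
  max(weighted_distance_matrix(g))
}

#' @rdname weighted_eccentricity
#' @export
weighted_periphery <- function(g) {
  check_connected(g, "weighted periphery")
  d <- weighted_distance_matrix(g)
  ecc <- apply(d, 1, max)
  vertex_labels(g)[ecc == max(ecc)]
}

## ---- circumference -------------------------------------------------------

#' Circumference of a graph
#'
#' The number of vertices in a longest simple cycle, or 0 for acyclic
#' graphs.  Computed exactly by depth-first enumeration of simple cycles
#' (exponential worst case; intended for the small graphs of this package).
#'
#' @param g An igraph object (weights are irrelevant).
#' @return Integer cycle length (0 if the graph is a forest).
#' @export
circumference <- function(g) {
  if (!igraph::is_igraph(g)) stop("`g` must be an igraph object")
  n <- igraph::vcount(g)
  if (n < 3L || igraph::ecount(g) < 3L) return(0L)
  adj <- adjacency_list_int(g)
  best <- 0L
  in_path <- rep(FALSE, n)
  ## enumerate cycles whose minimum vertex is `start`
  dfs <- function(v, start, depth) {
    in_path[v] <<- TRUE
    for (u in adj[[v]]) {
      if (u == start && depth >= 3L) {
        if (depth > best) best <<- depth
      } else if (u > start && !in_path[u]) {
        if (depth + 1L > best || best < n) dfs(u, start, depth + 1L)
      }
    }
    in_path[v] <<- FALSE
  }
  for (s in seq_len(n)) {
    if (best == n) break
    dfs(s, s, 1L)
  }
  as.integer(best)
}

## ---- dispatcher ----------------------------------------------------------

#' Names of the implemented vertex-weighted invariants
#' @return Character vector of invariant names accepted by [graph_invariant()].
#' @export
invariant_names <- function() {
  c("weighted_lower_domination", "weighted_upper_domination",
    "weighted_diameter", "weighted_periphery_size",
    "max_weighted_degree", "average_weighted_degree",
    "circumference")
}

#' Compute a named invariant of a vertex-weighted graph
#'
#' @param g Vertex-weighted igraph.
#' @param name One of [invariant_names()].
#' @return A single number (`weighted_periphery_size` is the cardinality of
#'   the periphery).
#' @export
graph_invariant <- function(g, name) {
  name <- match.arg(name, invariant_names())
  switch(name,
    weighted_lower_domination = unname(weighted_domination(g)["lower"]),
    weighted_upper_domination = unname(weighted_domination(g)["upper"]),
    weighted_diameter         = weighted_diameter(g),
    weighted_periphery_size   = length(weighted_periphery(g)),
    max_weighted_degree       = max_weighted_degree(g),
    average_weighted_degree   = average_weighted_degree(g),
    circumference             = as.numeric(circumference(g)))
}
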