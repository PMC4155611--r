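## Exhaustive-enumeration oracles for the vertex-weighted invariants.
##
## Deliberately independent of the optimized implementations in
## invariants.R: domination by enumerating all vertex subsets, distances by
## enumerating all simple paths, circumference by enumerating all simple
## cycles.  Only feasible for small graphs; used as ground truth in tests.

#' Brute-force oracle for weighted graph invariants
#'
#' Computes an invariant by exhaustive enumeration, independently of the
#' optimized algorithms, for graphs with at most 14 vertices.
#'
#' @param g Vertex-weighted igraph with at most 14 vertices.
#' @param name One of [invariant_names()].
#' @return A single number.
#' @export
brute_force_oracle <- function(g, name) {
  g <- as_weighted_graph_checked(g)
  n <- igraph::vcount(g)
  if (n > 14L) stop("brute_force_oracle refuses graphs with more than 14 vertices")
  if (n == 0L) stop("graph is empty")
  name <- match.arg(name, invariant_names())
  w <- igraph::V(g)$weight
  adj <- adjacency_list_int(g)
  switch(name,
    weighted_lower_domination = oracle_domination(adj, w)["lower"],
    weighted_upper_domination = oracle_domination(adj, w)["upper"],
    weighted_diameter         = oracle_distances(adj, w)$diameter,
    weighted_periphery_size   = oracle_distances(adj, w)$periphery_size,
    max_weighted_degree       = max(oracle_weighted_degrees(adj, w)),
    average_weighted_degree   = mean(oracle_weighted_degrees(adj, w)),
    circumference             = oracle_circumference(adj))
}

oracle_weighted_degrees <- function(adj, w) {
  vapply(adj, function(nb) sum(w[nb]), numeric(1))
}

## All 2^n subsets as bitmasks; closed-neighborhood cover of every subset
## computed by dynamic programming over the lowest set bit.
oracle_domination <- function(adj, w) {
  n <- length(adj)
  nb_mask <- vapply(seq_len(n), function(v)
    sum(bitwShiftL(1L, c(v, adj[[v]]) - 1L)), integer(1))
  full <- sum(bitwShiftL(1L, seq_len(n) - 1L))
  nmask <- 2L^n
  covers <- integer(nmask); wts <- numeric(nmask)     # index = mask + 1
  for (mask in seq_len(nmask - 1L)) {
    low <- 1L + as.integer(round(log2(bitwAnd(mask, -mask))))
    rest <- bitwAnd(mask, mask - 1L)
    covers[mask + 1L] <- bitwOr(covers[rest + 1L], nb_mask[low])
    wts[mask + 1L] <- wts[rest + 1L] + w[low]
  }
  dom <- which(covers == full) - 1L                   # dominating masks
  lower <- min(wts[dom + 1L])
  upper <- -Inf
  bits <- bitwShiftL(1L, seq_len(n) - 1L)
  for (mask in dom) {
    wt <- wts[mask + 1L]
    if (wt <= upper) next
    members <- which(bitwAnd(mask, bits) != 0L)
    minimal <- all(vapply(members, function(m)
      covers[bitwAnd(mask, bitwNot(bits[m])) + 1L] != full, logical(1)))
    if (minimal) upper <- wt
  }
  c(lower = lower, upper = upper)
}

## Vertex-weighted distances by enumeration of every simple path.
oracle_distances <- function(adj, w) {
  n <- length(adj)
  d <- matrix(Inf, n, n); diag(d) <- 0
  in_path <- rep(FALSE, n)
  dfs <- function(v, start, len) {
    in_path[v] <<- TRUE
    if (len < d[start, v]) d[start, v] <<- len
    for (u in adj[[v]]) if (!in_path[u]) dfs(u, start, len + w[u])
    in_path[v] <<- FALSE
  }
  for (s in seq_len(n)) dfs(s, s, 0)
  if (any(!is.finite(d))) stop("oracle distances require a connected graph")
  ecc <- apply(d, 1, max)
  list(diameter = max(ecc), periphery_size = sum(ecc == max(ecc)))
}

## Longest simple cycle by enumeration of all simple cycles.
oracle_circumference <- function(adj) {
  n <- length(adj)
  best <- 0L
  in_path <- rep(FALSE, n)
  dfs <- function(v, start, depth) {
    in_path[v] <<- TRUE
    for (u in adj[[v]]) {
      if (u == start && depth >= 3L) {
        if (depth > best) best <<- depth
      } else if (u > start && !in_path[u]) dfs(u, start, depth + 1L)
    }
    in_path[v] <<- FALSE
  }
  for (s in seq_len(n)) dfs(s, s, 1L)
  best
}
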