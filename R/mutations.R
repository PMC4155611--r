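## In-silico mutations: parsing compact mutation notation, editing
## sequences, re-deriving hierarchy weights, and diffing top-level graphs.

#' Parse a compact mutation
#'
#' Accepted grammars: `"V51R"` (substitution), `"F508del"` (deletion),
#' `"508insG"` (insertion).  Residue codes must be canonical one-letter
#' codes.
#'
#' @param text A single mutation string.
#' @return A list of class `mutation_spec` with fields `kind`
#'   (`"substitution"`, `"deletion"` or `"insertion"`), `position` (1-based
#'   residue index in the original numbering), `wild` and `new` (one-letter
#'   codes; `NA` where not applicable).
#' @export
parse_mutation <- function(text) {
  text <- trimws(text)
  aa <- paste(names(aa_one_to_three), collapse = "")
  sub_m <- regexec(sprintf("^([%s])([0-9]+)([%s])$", aa, aa), text)[[1]]
  del_m <- regexec(sprintf("^([%s])([0-9]+)del$", aa), text)[[1]]
  ins_m <- regexec(sprintf("^([0-9]+)ins([%s])$", aa), text)[[1]]
  spec <- if (sub_m[1] != -1) {
    p <- regmatches(text, list(regexec(sprintf("^([%s])([0-9]+)([%s])$", aa, aa),
                                       text)[[1]]))[[1]]
    list(kind = "substitution", position = as.integer(p[3]),
         wild = p[2], new = p[4])
  } else if (del_m[1] != -1) {
    p <- regmatches(text, list(del_m))[[1]]
    list(kind = "deletion", position = as.integer(p[3]), wild = p[2], new = NA_character_)
  } else if (ins_m[1] != -1) {
    p <- regmatches(text, list(ins_m))[[1]]
    list(kind = "insertion", position = as.integer(p[2]),
         wild = NA_character_, new = p[3])
  } else {
    stop("cannot parse mutation ", sQuote(text),
         "; expected \"V51R\" (substitution), \"F508del\" (deletion) or ",
         "\"508insG\" (insertion) with canonical one-letter codes")
  }
  structure(spec, class = "mutation_spec")
}

#' @export
print.mutation_spec <- function(x, ...) {
  cat("mutation:", x$kind, "at", x$position,
      switch(x$kind, substitution = paste(x$wild, "->", x$new),
             deletion = paste("of", x$wild),
             insertion = paste("of", x$new)), "\n")
  invisible(x)
}

#' Parse a mutation list
#'
#' @param x Character vector of mutation strings, or a path to a plain-text
#'   file with one mutation per line (`#` starts a comment).
#' @return List of `mutation_spec` objects.
#' @export
parse_mutations <- function(x) {
  if (length(x) == 1L && file.exists(x)) x <- readLines(x)
  x <- sub("#.*$", "", x)
  x <- trimws(x)
  lapply(x[nzchar(x)], parse_mutation)
}

#' Apply mutations to a sequence
#'
#' Positions refer to the original numbering; internally the mutations are
#' applied right-to-left so earlier edits never invalidate later indices.
#' Substitutions preserve length, deletions shorten by one, insertions (new
#' residue placed after the stated position) lengthen by one.
#'
#' @param sequence One-letter amino-acid string.
#' @param specs List of `mutation_spec` (or a character vector, parsed via
#'   [parse_mutations()]).
#' @return The mutated sequence string.
#' @export
apply_mutations <- function(sequence, specs) {
  if (is.character(specs)) specs <- parse_mutations(specs)
  if (inherits(specs, "mutation_spec")) specs <- list(specs)
  s <- strsplit(sequence, "")[[1]]
  n <- length(s)
  pos <- vapply(specs, `[[`, numeric(1), "position")
  for (sp in specs[order(pos, decreasing = TRUE)]) {
    p <- sp$position
    if (p < 1L || p > n)
      stop("mutation position ", p, " outside sequence of length ", n)
    if (sp$kind %in% c("substitution", "deletion") && s[p] != sp$wild)
      stop("wild-residue mismatch at position ", p, ": expected ",
           sp$wild, ", found ", s[p])
    s <- switch(sp$kind,
      substitution = { s[p] <- sp$new; s },
      deletion = s[-p],
      insertion = append(s, sp$new, after = p))
  }
  paste(s, collapse = "")
}

mutation_label <- function(sp) {
  switch(sp$kind,
    substitution = paste0(sp$wild, sp$position, sp$new),
    deletion = paste0(sp$wild, sp$position, "del"),
    insertion = paste0(sp$position, "ins", sp$new))
}

#' Re-derive hierarchy weights after substitutions
#'
#' Models a mutation that does not change the predicted structure: the edge
#' sets of all tiers are untouched; the mutated midlevel vertices receive
#' the descriptor vector of the new residue, and top-level weights are
#' recomputed.  Only substitutions are supported here - insertions and
#' deletions change the vertex set of a midlevel graph and therefore
#' require a structure, see [rebuild_mutant_from_structure()].
#'
#' @param h Wild-type `hier_graph`.
#' @param specs Mutation specs (substitutions only; character vectors are
#'   parsed).  Positions are PDB residue numbers.
#' @param table Descriptor table.
#' @return A new `hier_graph` with updated weights.
#' @export
reweight_mutant <- function(h, specs, table = h$table) {
  stopifnot(inherits(h, "hier_graph"))
  if (is.character(specs)) specs <- parse_mutations(specs)
  if (inherits(specs, "mutation_spec")) specs <- list(specs)
  kinds <- vapply(specs, `[[`, character(1), "kind")
  if (any(kinds != "substitution"))
    stop("reweight_mutant() handles substitutions only; rebuild the ",
         "hierarchy from a mutant structure for insertions/deletions")
  current <- hierarchy_sequence(h)
  for (sp in specs) {
    key <- as.character(sp$position)
    if (!key %in% names(current))
      stop("mutation position ", sp$position, " is not a residue of the structure")
    if (current[[key]] != sp$wild)
      stop("wild-residue mismatch at position ", sp$position, ": expected ",
           sp$wild, ", found ", current[[key]])
    hit <- FALSE
    for (lab in names(h$mid)) {
      g <- h$mid[[lab]]
      i <- match(sp$position, igraph::V(g)$resno)
      if (!is.na(i)) {
        h$mid[[lab]] <- igraph::set_vertex_attr(g, "code1", index = i,
                                                value = sp$new)
        hit <- TRUE
      }
    }
    if (!hit)
      stop("mutation position ", sp$position, " lies outside every substructure")
  }
  h$provenance$mutations <- c(h$provenance$mutations,
                              vapply(specs, mutation_label, character(1)))
  propagate_weights(h, table, h$provenance$invariants)
}

#' Shift substructure ranges across insertions/deletions
#'
#' Ranges are shifted by the cumulative indel offset accumulated before
#' their start (insertions after position p add one from p+1 on; deletions
#' at p subtract one from p on).
#'
#' @param defs Substructure definitions.
#' @param specs Mutation specs.
#' @return Shifted `substructure_defs`.
#' @export
shift_definitions <- function(defs, specs) {
  if (is.character(specs)) specs <- parse_mutations(specs)
  offset_at <- function(pos) {
    off <- 0L
    for (sp in specs) {
      if (sp$kind == "insertion" && sp$position < pos) off <- off + 1L
      if (sp$kind == "deletion" && sp$position < pos) off <- off - 1L
    }
    off
  }
  defs$start <- defs$start + vapply(defs$start, offset_at, integer(1))
  defs$end <- defs$end + vapply(defs$end, offset_at, integer(1))
  defs
}

#' Build the mutant hierarchy from a predicted structure
#'
#' For mutations whose structural effect has been predicted externally (the
#' package never calls a prediction service): builds a full hierarchy from
#' the supplied coordinates, with substructure ranges shifted across any
#' insertions/deletions, and verifies the structure's sequence against the
#' mutations.
#'
#' @param pdb Mutant structure (path or PDB text).
#' @param defs Wild-type substructure definitions.
#' @param specs Mutation specs.
#' @param chain Chain identifier.
#' @param table Descriptor table.
#' @param wild_sequence Optional wild-type sequence (one-letter string whose
#'   first character is residue `wild_start`); when given, the full mutant
#'   sequence is checked against the structure and the first mismatch is
#'   reported.  Otherwise only the substituted positions are checked.
#' @param wild_start Residue number of the first character of
#'   `wild_sequence`.
#' @param ... Passed to [build_hierarchy()].
#' @return A `hier_graph` built from the mutant coordinates.
#' @export
rebuild_mutant_from_structure <- function(pdb, defs, specs, chain = NULL,
                                          table = aa_descriptor_table(),
                                          wild_sequence = NULL, wild_start = 1L,
                                          ...) {
  if (is.character(specs)) specs <- parse_mutations(specs)
  defs2 <- shift_definitions(defs, specs)
  h <- build_hierarchy(pdb, defs2, chain = chain, table = table, ...)
  got <- residue_codes(h$residues)
  if (!is.null(wild_sequence)) {
    mutated <- strsplit(apply_mutations(wild_sequence, lapply(specs, function(sp) {
      sp$position <- sp$position - wild_start + 1L; sp
    })), "")[[1]]
    names(mutated) <- seq_along(mutated) + wild_start - 1L
    common <- intersect(names(mutated), names(got))
    bad <- common[mutated[common] != got[common]]
    if (length(bad))
      stop("structure sequence inconsistent with mutated sequence; first ",
           "mismatch at position ", bad[1], ": expected ",
           mutated[bad[1]], ", found ", got[bad[1]])
  } else {
    offs <- shift_positions(specs)
    for (k in seq_along(specs)) {
      sp <- specs[[k]]
      if (sp$kind != "substitution") next
      key <- as.character(sp$position + offs[k])
      if (key %in% names(got) && got[[key]] != sp$new)
        stop("structure sequence inconsistent with mutation ",
             mutation_label(sp), ": found ", got[[key]],
             " at position ", key)
    }
  }
  h$provenance$mutations <- vapply(specs, mutation_label, character(1))
  h
}

shift_positions <- function(specs) {
  vapply(seq_along(specs), function(k) {
    off <- 0L
    for (sp in specs[-k]) {
      if (sp$kind == "insertion" && sp$position < specs[[k]]$position) off <- off + 1L
      if (sp$kind == "deletion" && sp$position < specs[[k]]$position) off <- off - 1L
    }
    off
  }, integer(1))
}

edge_keys <- function(g) {
  el <- igraph::as_edgelist(g)
  paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "--")
}

## simple cycles up to a length bound, as canonical "a|b|c" keys
enumerate_cycles <- function(g, max_len = 8L) {
  n <- igraph::vcount(g)
  if (n < 3L) return(character(0))
  adj <- adjacency_list_int(g)
  labs <- vertex_labels(g)
  found <- character(0)
  path <- integer(0)
  in_path <- rep(FALSE, n)
  dfs <- function(v, start, depth) {
    path[depth] <<- v; in_path[v] <<- TRUE
    for (u in adj[[v]]) {
      if (u == start && depth >= 3L) {
        found <<- c(found, paste(sort(labs[path[seq_len(depth)]]), collapse = "|"))
      } else if (u > start && !in_path[u] && depth < max_len) {
        dfs(u, start, depth + 1L)
      }
    }
    in_path[v] <<- FALSE
  }
  for (s in seq_len(n)) dfs(s, s, 1L)
  unique(found)
}

#' Diff two top-level graphs
#'
#' Exact set differences of the edge sets, per-vertex per-descriptor weight
#' deltas, and an optional report of short simple cycles present in one
#' graph but not the other (e.g. a "heavy" cycle lost after a mutation).
#'
#' @param wild,mut igraphs over the same vertex label set.
#' @param max_cycle Longest cycle length enumerated for the cycle report
#'   (default 8; set 0 to skip).
#' @return A list of class `graph_diff` with `edges_gained`, `edges_lost`
#'   (character vectors `"Di--Dj"`), `weight_deltas` (matrix vertex x
#'   attribute of mut - wild, only rows/columns with a change), and
#'   `cycles_lost` / `cycles_gained`.
#' @export
diff_top_graphs <- function(wild, mut, max_cycle = 8L) {
  vw <- sort(igraph::V(wild)$name); vm <- sort(igraph::V(mut)$name)
  if (!identical(vw, vm)) {
    sym <- c(setdiff(vw, vm), setdiff(vm, vw))
    stop("vertex label sets differ; symmetric difference: ",
         paste(sym, collapse = ", "))
  }
  ew <- edge_keys(wild); em <- edge_keys(mut)
  attrs <- intersect(igraph::vertex_attr_names(wild),
                     igraph::vertex_attr_names(mut))
  attrs <- attrs[vapply(attrs, function(a)
    is.numeric(igraph::vertex_attr(wild, a)), logical(1))]
  deltas <- NULL
  if (length(attrs)) {
    deltas <- vapply(attrs, function(a) {
      w0 <- igraph::vertex_attr(wild, a)[match(vw, igraph::V(wild)$name)]
      w1 <- igraph::vertex_attr(mut, a)[match(vw, igraph::V(mut)$name)]
      w1 - w0
    }, numeric(length(vw)))
    rownames(deltas) <- vw
    deltas <- deltas[rowSums(deltas != 0) > 0, colSums(deltas != 0) > 0,
                     drop = FALSE]
  }
  cl <- cg <- character(0)
  if (max_cycle >= 3L) {
    cw <- enumerate_cycles(wild, max_cycle); cm2 <- enumerate_cycles(mut, max_cycle)
    cl <- setdiff(cw, cm2); cg <- setdiff(cm2, cw)
  }
  structure(list(edges_gained = setdiff(em, ew),
                 edges_lost = setdiff(ew, em),
                 weight_deltas = deltas,
                 cycles_lost = cl, cycles_gained = cg),
            class = "graph_diff")
}

#' @export
print.graph_diff <- function(x, ...) {
  cat("graph_diff:\n",
      "  edges gained: ", paste(x$edges_gained, collapse = ", "), "\n",
      "  edges lost:   ", paste(x$edges_lost, collapse = ", "), "\n",
      "  vertices with changed weights: ",
      paste(rownames(x$weight_deltas), collapse = ", "), "\n",
      "  cycles lost: ", length(x$cycles_lost),
      ", gained: ", length(x$cycles_gained), "\n", sep = "")
  invisible(x)
}
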