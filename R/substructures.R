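## Substructure definition tables: one row per secondary-structure-based
## interval of the chain, each becoming a vertex of the top-level graph.

#' Parse a substructure definition table
#'
#' Each row supplies a label, a kind (`alpha`, `beta` or `loop`), a 1-based
#' inclusive residue range written `"a-b"`, and the one-letter sequence of
#' the interval.  Adjacent rows may share their boundary residue (the
#' shared residue belongs to both substructures).  Rows whose sequence
#' length does not equal `end - start + 1` are accepted but flagged
#' (`consistent = FALSE`) with a warning - they are never silently
#' repaired.
#'
#' @param x A data frame with columns `label`, `kind`, `range`, `sequence`,
#'   or a path to a CSV/TSV file with those columns.
#' @return A data frame of class `substructure_defs` with columns `label`,
#'   `kind`, `start`, `end`, `sequence`, `consistent`.
#' @export
parse_substructure_table <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("file not found: ", x)
    sep <- if (grepl("\\.tsv$", x)) "\t" else ","
    x <- utils::read.delim(x, sep = sep, stringsAsFactors = FALSE)
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  need <- c("label", "kind", "range", "sequence")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("substructure table is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(x) == 0L)
    return(structure(data.frame(label = character(0), kind = character(0),
                                start = integer(0), end = integer(0),
                                sequence = character(0), consistent = logical(0),
                                stringsAsFactors = FALSE),
                     class = c("substructure_defs", "data.frame")))
  m <- regmatches(x$range, regexec("^\\s*([0-9]+)\\s*-\\s*([0-9]+)\\s*$", x$range))
  bad <- lengths(m) != 3L
  if (any(bad))
    stop("malformed range ", sQuote(x$range[bad][1]), " in row ",
         sQuote(x$label[bad][1]), "; expected \"start-end\"")
  start <- vapply(m, function(g) as.integer(g[2]), integer(1))
  end <- vapply(m, function(g) as.integer(g[3]), integer(1))
  if (any(start > end))
    stop("range start exceeds end in row ", sQuote(x$label[start > end][1]))
  seqs <- toupper(x$sequence)
  badc <- vapply(strsplit(seqs, ""), function(s)
    length(setdiff(s, names(aa_one_to_three))) > 0 || length(s) == 0, logical(1))
  if (any(badc))
    stop("non-amino-acid character in sequence of row ", sQuote(x$label[badc][1]))
  out <- data.frame(label = as.character(x$label),
                    kind = as.character(x$kind),
                    start = start, end = end, sequence = seqs,
                    consistent = nchar(seqs) == end - start + 1L,
                    stringsAsFactors = FALSE)
  if (any(!out$consistent))
    warning("row(s) ", paste(out$label[!out$consistent], collapse = ", "),
            ": sequence length does not match the printed range ",
            "(kept as printed, not repaired)")
  structure(out, class = c("substructure_defs", "data.frame"))
}

#' Bundled substructure table for yeast triosephosphate isomerase
#'
#' The canonical 19-substructure decomposition of the single chain of yeast
#' triosephosphate isomerase (TIM) used throughout the package examples:
#' each interval contains one helix or one strand (or a long loop).  Row
#' D10 is knowingly inconsistent in its printed range (its 11-residue
#' sequence does not fit "12-130"); the parser flags it, emitting a
#' warning, rather than repairing it.
#'
#' @param quiet Suppress the D10 inconsistency warning (default `TRUE`
#'   since the flag is carried in the `consistent` column).
#' @return A `substructure_defs` data frame with 19 rows.
#' @export
tim_substructures <- function(quiet = TRUE) {
  f <- function() parse_substructure_table(protier_extdata("sctim_substructures.tsv"))
  if (quiet) suppressWarnings(f()) else f()
}
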