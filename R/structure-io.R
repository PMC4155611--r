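## Reading protein structures and computing residue contact maps.

pdb_to_path <- function(pdb) {
  if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) return(pdb)
  path <- tempfile(fileext = ".pdb")
  writeLines(unlist(strsplit(pdb, "\n", fixed = TRUE)), path)
  path
}

#' Read a single chain of a PDB structure
#'
#' Parses ATOM records of one chain of a PDB-format file (via
#' \pkg{bio3d}), suppressing hydrogens, dropping HETATM records and
#' alternate locations other than blank or "A", and keeping the first model
#' only.  Residues are returned in ascending residue-number order.
#'
#' @param pdb Path to a PDB file, or PDB-format text (single string with
#'   newlines or a character vector of lines).
#' @param chain Chain identifier.  May be omitted when the file holds a
#'   single chain; otherwise an error lists the chains found.
#' @return An object of class `residue_set`: a list of residue records, each
#'   a list with `resno` (PDB residue number), `insert` (insertion code, ""
#'   if none), `resid` (3-letter code) and `atoms` (data frame with `elety`,
#'   `element`, `x`, `y`, `z`, `mass`).  Attributes `chain` and `source` are
#'   set.
#' @export
read_structure <- function(pdb, chain = NULL) {
  path <- pdb_to_path(pdb)
  parsed <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  atom <- parsed$atom
  atom <- atom[atom$type == "ATOM", , drop = FALSE]
  if (nrow(atom) == 0L) stop("no ATOM records found in PDB input")
  chains <- sort(unique(atom$chain))
  if (is.null(chain)) {
    if (length(chains) > 1L)
      stop("PDB input has several chains (", paste(chains, collapse = ", "),
           "); select one with `chain`")
    chain <- chains
  }
  if (!chain %in% chains)
    stop("chain '", chain, "' not found; available chains: ",
         paste(chains, collapse = ", "))
  atom <- atom[atom$chain == chain, , drop = FALSE]
  ## alternate locations: keep blank or "A"
  alt <- atom$alt
  atom <- atom[is.na(alt) | alt %in% c("", "A"), , drop = FALSE]
  ## element: from the element column when present, else from the atom name
  elem <- atom$elesy
  miss <- is.na(elem) | !nzchar(trimws(as.character(elem)))
  elem[miss] <- element_from_atom_name(atom$elety[miss])
  elem <- toupper(trimws(elem))
  keep <- elem != "H" & elem != "D"
  atom <- atom[keep, , drop = FALSE]
  elem <- elem[keep]
  if (nrow(atom) == 0L) stop("no heavy atoms left after hydrogen suppression")
  insert <- as.character(atom$insert)
  insert[is.na(insert)] <- ""
  key <- paste(atom$resno, insert, sep = "|")
  ord <- order(atom$resno, insert)
  atom <- atom[ord, , drop = FALSE]; elem <- elem[ord]; insert <- insert[ord]
  key <- key[ord]
  masses <- atomic_masses()
  idx <- split(seq_len(nrow(atom)), factor(key, levels = unique(key)))
  residues <- lapply(idx, function(i) {
    list(resno = atom$resno[i[1]],
         insert = insert[i[1]],
         resid = atom$resid[i[1]],
         atoms = data.frame(elety = atom$elety[i],
                            element = elem[i],
                            x = atom$x[i], y = atom$y[i], z = atom$z[i],
                            mass = unname(masses[elem[i]]),
                            stringsAsFactors = FALSE))
  })
  names(residues) <- NULL
  structure(residues, class = "residue_set", chain = chain,
            source = if (length(pdb) == 1L && file.exists(pdb)) basename(pdb) else "text")
}

#' @export
print.residue_set <- function(x, ...) {
  cat("residue_set:", length(x), "residues, chain",
      attr(x, "chain"), "\n")
  invisible(x)
}

#' One-letter sequence of a residue set
#'
#' @param residues A `residue_set`.
#' @return Named character vector of one-letter codes (name = residue
#'   number); non-canonical residues become "X".
#' @export
residue_codes <- function(residues) {
  code <- aa_three_to_one[vapply(residues, `[[`, character(1), "resid")]
  code[is.na(code)] <- "X"
  stats::setNames(unname(code), vapply(residues, `[[`, numeric(1), "resno"))
}

residue_xyz <- function(r) {
  as.matrix(r$atoms[, c("x", "y", "z")])
}

residue_point <- function(r, metric) {
  xyz <- residue_xyz(r)
  switch(metric,
    calpha = {
      i <- which(r$atoms$elety == "CA")
      if (!length(i))
        stop("residue ", r$resid, " ", r$resno, " has no C-alpha atom")
      xyz[i[1], ]
    },
    centroid = colMeans(xyz),
    center_of_mass = {
      m <- r$atoms$mass
      if (anyNA(m)) stop("residue ", r$resid, " ", r$resno,
                         " has atoms of unknown mass")
      colSums(xyz * m) / sum(m)
    },
    stop("unknown point metric: ", metric))
}

#' Distance between two residues
#'
#' @param r1,r2 Residue records (elements of a `residue_set`).
#' @param metric One of `"calpha"` (Euclidean C-alpha distance),
#'   `"centroid"` (unweighted mean of heavy-atom coordinates),
#'   `"center_of_mass"` (atomic-mass-weighted mean), or `"all_atom"`
#'   (minimum over heavy-atom pairs).
#' @return Distance in Angstrom.
#' @export
residue_distance <- function(r1, r2,
                             metric = c("calpha", "centroid",
                                        "center_of_mass", "all_atom")) {
  metric <- match.arg(metric)
  if (metric == "all_atom") {
    return(min(cross_distances(residue_xyz(r1), residue_xyz(r2))))
  }
  sqrt(sum((residue_point(r1, metric) - residue_point(r2, metric))^2))
}

cross_distances <- function(a, b) {
  ## |a_i - b_j| for all pairs; a, b are k x 3 matrices
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

backbone_atoms <- c("N", "CA", "C", "O", "OXT")

residue_atom_coords <- function(r, count_metric) {
  xyz <- residue_xyz(r)
  if (count_metric == "side_chain") {
    keep <- !(r$atoms$elety %in% backbone_atoms)
    xyz <- xyz[keep, , drop = FALSE]
  }
  xyz
}

#' Build a residue contact map
#'
#' A pair of residues is stored when their distance under `metric` is at
#' most `threshold`; the pair's contact count is the number of heavy-atom
#' pairs within `threshold` under `count_metric` distances (`"all_atom"`,
#' or `"side_chain"` to exclude backbone atoms; glycine then contributes no
#' atoms).  A stored pair contributes at least one contact.
#'
#' @param residues A `residue_set` (see [read_structure()]).
#' @param metric Residue-distance metric deciding adjacency; see
#'   [residue_distance()].
#' @param threshold Distance threshold in Angstrom (> 0).  The conventional
#'   default is 7 for C-alpha distances; 8 is customary for centroids.
#' @param count_metric Atom set used for contact counting.
#' @return An object of class `contact_map`: a data frame with columns `i`,
#'   `j` (residue numbers, `i < j`), `count` and `dist`, with attributes
#'   `metric`, `threshold`, `count_metric` and `residues` (a data frame of
#'   residue numbers and codes present in the structure).
#' @export
build_contact_map <- function(residues,
                              metric = c("calpha", "centroid",
                                         "center_of_mass", "all_atom"),
                              threshold = 7,
                              count_metric = c("all_atom", "side_chain")) {
  metric <- match.arg(metric)
  count_metric <- match.arg(count_metric)
  if (threshold <= 0) stop("`threshold` must be positive")
  resno <- vapply(residues, `[[`, numeric(1), "resno")
  insert <- vapply(residues, `[[`, character(1), "insert")
  if (anyDuplicated(paste(resno, insert)))
    stop("duplicate residue identifiers in structure")
  res_tab <- data.frame(resno = resno,
                        resid = vapply(residues, `[[`, character(1), "resid"),
                        code1 = unname(residue_codes(residues)),
                        stringsAsFactors = FALSE)
  empty <- data.frame(i = integer(0), j = integer(0),
                      count = integer(0), dist = numeric(0))
  if (length(residues) < 2L)
    return(structure(empty, class = c("contact_map", "data.frame"),
                     metric = metric, threshold = threshold,
                     count_metric = count_metric, residues = res_tab))
  n <- length(residues)
  if (metric == "all_atom") {
    pair_dist <- function(a, b) min(cross_distances(residue_xyz(residues[[a]]),
                                                    residue_xyz(residues[[b]])))
    dm <- matrix(0, n, n)
    for (a in seq_len(n - 1)) for (b in (a + 1):n)
      dm[a, b] <- pair_dist(a, b)
  } else {
    pts <- t(vapply(residues, residue_point, numeric(3), metric = metric))
    dm <- as.matrix(stats::dist(pts))
  }
  pairs <- which(upper.tri(dm) & dm <= threshold, arr.ind = TRUE)
  if (nrow(pairs)) {
    counts <- vapply(seq_len(nrow(pairs)), function(k) {
      a <- residue_atom_coords(residues[[pairs[k, 1]]], count_metric)
      b <- residue_atom_coords(residues[[pairs[k, 2]]], count_metric)
      if (!nrow(a) || !nrow(b)) return(1L)
      max(1L, sum(cross_distances(a, b) <= threshold))
    }, integer(1))
    ra <- resno[pairs[, 1]]; rb <- resno[pairs[, 2]]
    out <- data.frame(i = pmin(ra, rb), j = pmax(ra, rb),
                      count = counts, dist = dm[pairs])
    out <- out[order(out$i, out$j), , drop = FALSE]
    rownames(out) <- NULL
  } else out <- empty
  structure(out, class = c("contact_map", "data.frame"),
            metric = metric, threshold = threshold,
            count_metric = count_metric, residues = res_tab)
}

#' @export
print.contact_map <- function(x, ...) {
  cat("contact_map:", nrow(x), "residue pairs (metric ", attr(x, "metric"),
      ", threshold ", attr(x, "threshold"), " A)\n", sep = "")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}
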