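#' @keywords internal
"_PACKAGE"

## Canonical amino-acid code tables used across the package.

#' Canonical amino-acid codes
#'
#' Lookup vectors between one-letter and three-letter codes for the twenty
#' canonical amino acids.
#'
#' @format `aa_three_to_one` is a named character vector mapping "ALA" to "A"
#'   etc.; `aa_one_to_three` is its inverse.
#' @name aa_codes
NULL

#' @rdname aa_codes
#' @export
aa_three_to_one <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

#' @rdname aa_codes
#' @export
aa_one_to_three <- stats::setNames(names(aa_three_to_one),
                                   unname(aa_three_to_one))

.protier_cache <- new.env(parent = emptyenv())

protier_extdata <- function(file) {
  path <- system.file("extdata", file, package = "protier")
  if (!nzchar(path)) stop("bundled data file not found: ", file)
  path
}

#' Standard atomic masses
#'
#' Returns the bundled table of standard atomic weights (unified atomic mass
#' units, 3 decimals) for the elements occurring in canonical amino-acid
#' heavy atoms (C, N, O, S).
#'
#' @return Named numeric vector of masses keyed by element symbol.
#' @export
atomic_masses <- function() {
  if (is.null(.protier_cache$masses)) {
    tab <- utils::read.csv(protier_extdata("atomic_masses.csv"),
                           stringsAsFactors = FALSE)
    .protier_cache$masses <- stats::setNames(tab$mass, tab$element)
  }
  .protier_cache$masses
}

#' Residue heavy-atom topology
#'
#' Reads the bundled covalent-connectivity table for the twenty canonical
#' amino acids (hydrogen-suppressed, generic in-chain form: no OXT, no
#' terminal protonation).  The file format is editable plain text with one
#' row per residue: 3-letter code, space-separated atom names, and
#' space-separated bonds written "A-B".
#'
#' @param code Optional 3-letter residue code; if given, only that entry is
#'   returned.
#' @return A named list; each element has components `atoms` (character) and
#'   `bonds` (2-column character matrix).
#' @export
residue_topology <- function(code = NULL) {
  if (is.null(.protier_cache$topology)) {
    tab <- utils::read.delim(protier_extdata("residue_topology.tsv"),
                             stringsAsFactors = FALSE)
    topo <- lapply(seq_len(nrow(tab)), function(i) {
      atoms <- strsplit(tab$atoms[i], " ", fixed = TRUE)[[1]]
      bonds <- do.call(rbind, strsplit(
        strsplit(tab$bonds[i], " ", fixed = TRUE)[[1]], "-", fixed = TRUE))
      list(atoms = atoms, bonds = bonds)
    })
    names(topo) <- tab$residue
    .protier_cache$topology <- topo
  }
  if (is.null(code)) return(.protier_cache$topology)
  code <- toupper(code)
  if (nchar(code) == 1L) code <- unname(aa_one_to_three[code])
  if (is.na(code) || !code %in% names(.protier_cache$topology))
    stop("unknown residue code; expected one of the 20 canonical amino acids")
  .protier_cache$topology[[code]]
}

## Element symbol from a PDB atom name: strip leading digits, take the
## leading alphabetic run's first character.  Sufficient for protein heavy
## atoms (C, N, O, S) and hydrogens ("HB2", "1HG1").
element_from_atom_name <- function(elety) {
  nm <- sub("^[0-9]+", "", toupper(elety))
  substr(nm, 1L, 1L)
}
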