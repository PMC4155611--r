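## Amino-acid descriptor tables: per-residue numeric vectors combining
## tabulated physicochemical scales with graph-derived invariants of the
## residue atom graphs.

#' Canonical descriptor names
#'
#' The physicochemical set is a compilation of widely used per-residue
#' scales (polarity, charge, Kyte-Doolittle hydropathy, helix/sheet
#' propensities, van der Waals volume, charge transfer/donor indicators,
#' consensus hydrophobicity, coil propensity, isoelectric point, Balaban
#' distance-connectivity index, side-chain radius of gyration, topological
#' shape index, electron-ion interaction potential).  The graph-derived set
#' is computed from the residue atom graphs by
#' [compute_graph_descriptors()].
#'
#' @return Character vector of the 21 descriptor column names every
#'   descriptor table must provide.
#' @export
descriptor_names <- function() {
  c("Plr", "Chrg", "Hydpthy", "stablty", "ss_stability", "vanderWaal",
    "chargetransf", "chargedonar", "averhydrophocitiy", "coilConformation",
    "IsoElectric", "BalabanIndex", "RofGyr", "ShapeIndex", "EIIP",
    "weighted_upper_domination", "weighted_lower_domination",
    "weighted_diameter", "circumference",
    "average_weighted_degree", "weighted_periphery_size")
}

#' Load and validate an amino-acid descriptor table
#'
#' @param x Path to a CSV file, CSV text, or a data frame.  Must contain a
#'   `residue` column of 3-letter codes covering all 20 canonical amino
#'   acids and a numeric column for each of [descriptor_names()].  Extra
#'   columns are kept.
#' @return A data frame of class `aa_descriptor_table` with columns
#'   `residue`, `code1` and the descriptor columns.
#' @seealso [aa_descriptor_table()] for the bundled default.
#' @export
load_descriptor_table <- function(x) {
  if (is.character(x)) {
    if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
      tab <- utils::read.csv(x, stringsAsFactors = FALSE, check.names = FALSE)
    } else {
      tab <- utils::read.csv(text = paste(x, collapse = "\n"),
                             stringsAsFactors = FALSE, check.names = FALSE)
    }
  } else tab <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!"residue" %in% names(tab))
    stop("descriptor table must have a 'residue' column of 3-letter codes")
  tab$residue <- toupper(tab$residue)
  missing_res <- setdiff(names(aa_three_to_one), tab$residue)
  if (length(missing_res))
    stop("descriptor table is missing residue row(s): ",
         paste(missing_res, collapse = ", "))
  if (anyDuplicated(tab$residue))
    stop("duplicate residue rows in descriptor table")
  missing_col <- setdiff(descriptor_names(), names(tab))
  if (length(missing_col))
    stop("descriptor table is missing column(s): ",
         paste(missing_col, collapse = ", "))
  for (col in descriptor_names()) {
    v <- tab[[col]]
    if (!is.numeric(v) || anyNA(v))
      stop("descriptor column '", col, "' must be numeric without missing values")
    tab[[col]] <- as.numeric(v)            # doubles throughout, even for 0/1 columns
  }
  tab$code1 <- unname(aa_three_to_one[tab$residue])
  rownames(tab) <- tab$residue
  class(tab) <- c("aa_descriptor_table", "data.frame")
  tab
}

#' The bundled default descriptor table
#'
#' Reads the table shipped with the package.  Its physicochemical columns
#' are a compilation of published per-residue scales; its graph-derived
#' columns were computed from the bundled residue atom graphs and are
#' bit-identical to `compute_graph_descriptors()` on
#' [enumerate_bottom_level()].
#'
#' @return An `aa_descriptor_table` (see [load_descriptor_table()]).
#' @export
aa_descriptor_table <- function() {
  if (is.null(.protier_cache$descriptors))
    .protier_cache$descriptors <-
      load_descriptor_table(protier_extdata("aa_descriptors.csv"))
  .protier_cache$descriptors
}

descriptor_vector <- function(table, code1, position = NULL) {
  i <- match(code1, table$code1)
  if (is.na(i))
    stop("residue '", code1, "'",
         if (!is.null(position)) paste0(" at position ", position) else "",
         " has no row in the descriptor table")
  unlist(table[i, descriptor_names()])
}
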