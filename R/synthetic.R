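## Synthetic PDB-format fixtures with controllable inter-residue geometry.
##
## The generator exists so contact-map and hierarchy construction can be
## exercised on structures whose geometry - and therefore whose contact
## graph - is known in closed form, without downloading real structures.

with_preserved_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic single-chain protein structure
#'
#' Writes PDB-format text for a chain with prescribed backbone geometry:
#'
#' * `"colinear"`: C-alpha atoms on a straight line at `spacing` Angstrom,
#'   so the C-alpha contact graph at any threshold is known exactly (a path
#'   for `spacing <= threshold < 2 * spacing`);
#' * `"helix"`: an ideal alpha-helix (radius 2.3 A, rise 1.5 A per residue,
#'   100 degrees of turn per residue);
#' * `"coil"`: a seeded random walk with steps of length `spacing`.
#'
#' Optionally a C-beta side-chain atom is placed 1.53 A from each C-alpha
#' (except for glycine).  Output is deterministic given `seed`.
#'
#' @param sequence One-letter amino-acid string (canonical codes only).
#' @param mode Geometry mode; see above.
#' @param spacing Consecutive C-alpha spacing in Angstrom (colinear/coil).
#' @param chain Chain identifier (single character).
#' @param start Residue number of the first residue.
#' @param sidechain Logical; add C-beta atoms.
#' @param seed Integer seed (used by `"coil"` mode).
#' @param file Optional path; when given, the text is also written there.
#' @return Character vector of PDB lines (invisibly when `file` is given).
#' @export
generate_synthetic_structure <- function(sequence,
                                         mode = c("colinear", "helix", "coil"),
                                         spacing = 3.8, chain = "A",
                                         start = 1L, sidechain = FALSE,
                                         seed = 1L, file = NULL) {
  mode <- match.arg(mode)
  codes <- strsplit(toupper(sequence), "")[[1]]
  if (!length(codes)) stop("`sequence` must be non-empty")
  bad <- setdiff(unique(codes), names(aa_one_to_three))
  if (length(bad))
    stop("non-canonical residue code(s) in sequence: ", paste(bad, collapse = ", "))
  n <- length(codes)
  ca <- switch(mode,
    colinear = cbind((seq_len(n) - 1) * spacing, 0, 0),
    helix = {
      ang <- (seq_len(n) - 1) * 100 * pi / 180
      cbind(2.3 * cos(ang), 2.3 * sin(ang), (seq_len(n) - 1) * 1.5)
    },
    coil = with_preserved_rng(seed, {
      steps <- matrix(stats::rnorm(3 * (n - 1)), ncol = 3)
      steps <- steps / sqrt(rowSums(steps^2)) * spacing
      apply(rbind(0, steps), 2, cumsum)
    })
  )
  ca <- matrix(ca, ncol = 3)
  resid3 <- unname(aa_one_to_three[codes])
  resno <- start + seq_len(n) - 1L
  xyz <- ca; elety <- rep("CA", n); at_resno <- resno; at_resid <- resid3
  if (sidechain) {
    has_cb <- codes != "G"
    if (any(has_cb)) {
      off <- c(0, 1.53 / sqrt(2), 1.53 / sqrt(2))   # |off| = 1.53 < 1.6
      cb <- sweep(ca[has_cb, , drop = FALSE], 2, off, "+")
      xyz <- rbind(xyz, cb)
      elety <- c(elety, rep("CB", sum(has_cb)))
      at_resno <- c(at_resno, resno[has_cb])
      at_resid <- c(at_resid, resid3[has_cb])
    }
  }
  ord <- order(at_resno, elety != "CA")   # CA first within a residue
  xyz <- xyz[ord, , drop = FALSE]; elety <- elety[ord]
  at_resno <- at_resno[ord]; at_resid <- at_resid[ord]
  path <- if (is.null(file)) tempfile(fileext = ".pdb") else file
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(round(xyz, 3))),
                   resno = at_resno, resid = at_resid,
                   eleno = seq_along(elety), elety = elety,
                   chain = rep(chain, length(elety)),
                   o = rep(1, length(elety)), b = rep(0, length(elety)))
  lines <- readLines(path)
  if (is.null(file)) unlink(path) else return(invisible(lines))
  lines
}
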