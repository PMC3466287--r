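# Idealized peptide builder. This is a coarse geometric template, not a
# molecular-mechanics build: it places the backbone along x with a fixed
# per-residue rise and puts side-chain pseudo-atoms on alternating sides of
# the chain at template distances from CA. Only the atoms that matter for
# charge placement (side-chain terminal atoms, backbone N, OXT) plus a
# minimal backbone are generated.

.aa3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
          Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
          L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
          S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

# side-chain pseudo-atoms: name, distance from CA along the side-chain
# direction (Angstrom), lateral split along x (Angstrom). Distances are
# fully-extended heavy-atom reaches rounded to one decimal; exact torsions
# are deliberately idealized.
.sidechain_template <- list(
  ALA = list(c("CB", 1.5, 0)),
  ARG = list(c("CB", 1.5, 0), c("CG", 2.8, 0), c("CD", 4.0, 0),
             c("NE", 5.1, 0), c("CZ", 6.3, 0),
             c("NH1", 7.0, 0.6), c("NH2", 7.0, -0.6)),
  ASP = list(c("CB", 1.5, 0), c("CG", 2.9, 0),
             c("OD1", 3.8, 0.6), c("OD2", 3.8, -0.6)),
  GLU = list(c("CB", 1.5, 0), c("CG", 2.8, 0), c("CD", 4.0, 0),
             c("OE1", 4.9, 0.6), c("OE2", 4.9, -0.6)),
  CYS = list(c("CB", 1.5, 0), c("SG", 2.8, 0)),
  HIS = list(c("CB", 1.5, 0), c("CG", 2.8, 0),
             c("ND1", 3.9, 0.7), c("NE2", 4.2, -0.7)),
  LYS = list(c("CB", 1.5, 0), c("CG", 2.8, 0), c("CD", 4.0, 0),
             c("CE", 5.2, 0), c("NZ", 6.4, 0)),
  TYR = list(c("CB", 1.5, 0), c("CG", 2.8, 0), c("CZ", 5.4, 0),
             c("OH", 6.5, 0))
)

#' Build an idealized peptide structure from a one-letter sequence
#'
#' Generates a synthetic peptide model sufficient for coarse-grained charge
#' placement: a backbone (N, CA, C, O per residue, OXT on the last residue)
#' laid out along the x axis, and side-chain pseudo-atoms for all residues
#' with a template (all ionizable residues, plus CB for the rest). In the
#' default `"extended"` geometry the backbone advances 3.3 Angstrom per
#' residue and side chains point to alternating sides of the chain; the
#' `"helical"` geometry uses a 1.5 Angstrom rise with side chains radiating
#' outwards. The builder is deterministic.
#'
#' @param sequence One-letter amino-acid sequence (canonical residues only).
#' @param geometry `"extended"` (default) or `"helical"`.
#' @return An `nw_structure` tibble (single chain `"A"`, coordinates in
#'   Angstrom).
#' @examples
#' pep <- build_peptide("KKAAAAAAAADD")
#' length(unique(pep$resno))
#' @export
build_peptide <- function(sequence, geometry = c("extended", "helical")) {
  geometry <- match.arg(geometry)
  stopifnot(is.character(sequence), length(sequence) == 1L,
            nchar(sequence) >= 1L)
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  unknown <- setdiff(letters1, names(.aa3))
  if (length(unknown) > 0L) {
    abort(paste0("unknown residue letter(s): ",
                 paste(unique(unknown), collapse = ", ")),
          class = "nanofet_input_error")
  }
  res3 <- unname(.aa3[letters1])
  n <- length(res3)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    if (geometry == "extended") {
      ca <- c(3.3 * (i - 1), 0, 0)
      # side chains alternate sides and tilt ~20 deg out of the backbone
      # plane, giving the chain a finite thickness
      side_dir <- c(0, 0.94 * (-1)^(i + 1), 0.342)
      along <- c(1, 0, 0)
    } else {
      ang <- (i - 1) * 100 * pi / 180  # ~3.6 residues/turn
      ca <- c(1.5 * (i - 1), 2.3 * cos(ang), 2.3 * sin(ang))
      side_dir <- c(0, cos(ang), sin(ang))
      along <- c(1, 0, 0)
    }
    at <- list(
      c("N", ca - 1.2 * along + 0.3 * side_dir),
      c("CA", ca),
      c("C", ca + 1.2 * along + 0.3 * side_dir),
      c("O", ca + 1.2 * along + 1.5 * side_dir)
    )
    tmpl <- .sidechain_template[[res3[i]]]
    if (is.null(tmpl) && res3[i] != "GLY") tmpl <- list(c("CB", 1.5, 0))
    for (t in tmpl) {
      pos <- ca + as.numeric(t[2]) * side_dir + c(as.numeric(t[3]), 0, 0)
      at <- c(at, list(c(t[1], pos)))
    }
    if (i == n) at <- c(at, list(c("OXT", ca + 2.4 * along + 0.3 * side_dir)))
    rows[[i]] <- tibble(
      atom = vapply(at, `[[`, "", 1L),
      resid = res3[i], resno = i,
      x = vapply(at, function(a) as.numeric(a[2]), 0),
      y = vapply(at, function(a) as.numeric(a[3]), 0),
      z = vapply(at, function(a) as.numeric(a[4]), 0)
    )
  }
  atoms <- dplyr::bind_rows(rows)
  new_nw_structure(tibble(
    serial = seq_len(nrow(atoms)),
    atom = atoms$atom,
    resid = atoms$resid,
    chain = "A",
    resno = as.integer(atoms$resno),
    x = atoms$x, y = atoms$y, z = atoms$z,
    element = guess_element(atoms$atom)
  ))
}
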