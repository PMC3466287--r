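#' @title Molecular structures and charge tables
#' @description
#' A molecular structure is a tibble of atom records (class `nw_structure`)
#' with columns `serial`, `atom`, `resid`, `chain`, `resno`, `x`, `y`, `z`
#' (Angstrom) and `element`. A charge distribution is a tibble of ionizable
#' sites (class `charge_distribution`) with columns `site`, `class`,
#' `chain`, `resno`, `x_nm`, `y_nm`, `z_nm`, `pKa` and `charge` (elementary
#' charges), plus attributes `pH` and (optionally) the source `structure`.
#' @name nanofet-containers
NULL

new_nw_structure <- function(atoms) {
  stopifnot(all(c("serial", "atom", "resid", "chain", "resno",
                  "x", "y", "z", "element") %in% names(atoms)))
  if (nrow(atoms) == 0L) {
    abort("structure contains no atoms", class = "nanofet_empty_structure")
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort("non-finite atom coordinates")
  }
  atoms <- as_tibble(atoms)
  structure(atoms,
            chains = unique(atoms$chain),
            class = c("nw_structure", class(atoms)))
}

new_charge_distribution <- function(sites, pH = NA_real_, structure = NULL) {
  stopifnot(all(c("site", "class", "x_nm", "y_nm", "z_nm",
                  "pKa", "charge") %in% names(sites)))
  sites <- as_tibble(sites)
  structure(sites,
            pH = pH,
            structure = structure,
            class = c("charge_distribution", class(sites)))
}

#' Read a protein structure from a PDB file
#'
#' Parses the ATOM records of the first model of a PDB file into an atom
#' tibble. HETATM records (waters, ligands, ions) are discarded, as are
#' alternate locations other than blank or `"A"`. Files without MODEL/END
#' tags are accepted (a notice is emitted); for multi-model files only the
#' first model is used.
#'
#' @param path Path to a PDB file.
#' @return An `nw_structure` tibble (coordinates in Angstrom).
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' write_structure_pdb(build_peptide("KKAAAAAAAADD"), pdb)
#' str <- read_structure(pdb)
#' nrow(str)
#' @seealso [build_peptide()], [assign_charges()]
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("PDB file not found: ", path), class = "nanofet_input_error")
  }
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^MODEL", lines))) {
    inform("PDB file has no MODEL tag; reading records as a single model.")
  }
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl) > 0L) lines <- lines[seq_len(endmdl[1L])]
  if (!any(grepl("^ATOM", lines))) {
    abort("PDB file contains no ATOM records",
          class = "nanofet_empty_structure")
  }
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  pdb <- suppressWarnings(bio3d::read.pdb(tmp, multi = FALSE, verbose = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[is.na(at$alt) | at$alt %in% c("", " ", "A"), , drop = FALSE]
  if (nrow(at) == 0L) {
    abort("PDB file contains no usable ATOM records",
          class = "nanofet_empty_structure")
  }
  chain <- ifelse(is.na(at$chain) | at$chain == "", "A", at$chain)
  elem <- at$elesy
  bad <- is.na(elem) | elem == ""
  if (any(bad)) elem[bad] <- guess_element(at$elety[bad])
  new_nw_structure(tibble(
    serial = as.integer(at$eleno),
    atom = at$elety,
    resid = at$resid,
    chain = chain,
    resno = as.integer(at$resno),
    x = at$x, y = at$y, z = at$z,
    element = elem
  ))
}

guess_element <- function(atom_names) {
  toupper(substr(gsub("^[0-9]+", "", atom_names), 1L, 1L))
}

#' Write a structure to a PDB file
#'
#' Minimal single-model PDB writer used for the synthetic peptide fixtures
#' (MODEL/ENDMDL/END tags included).
#'
#' @param str An `nw_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(str, path) {
  stopifnot(inherits(str, "nw_structure"))
  rec <- sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                 str$serial,
                 ifelse(nchar(str$atom) < 4L, paste0(" ", str$atom), str$atom),
                 str$resid, str$chain, str$resno,
                 str$x, str$y, str$z, 1.00, 0.00, str$element)
  writeLines(c("MODEL        1", rec, "ENDMDL", "END"), path)
  invisible(path)
}

#' Write a charge distribution to a PQR file
#'
#' One record per ionizable site or terminus: whitespace-separated fields
#' `ATOM serial name resname chain resno x y z charge radius`, coordinates
#' in Angstrom. The radius field of every record is fixed at 1.0 Angstrom;
#' the sites carry no physical extent in the model and the radius is purely
#' a display convention.
#'
#' @param dist A `charge_distribution`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_pqr()]
#' @export
write_pqr <- function(dist, path) {
  stopifnot(inherits(dist, "charge_distribution"))
  hdr <- sprintf("REMARK   coarse-grained charge distribution, %d sites, pH %s",
                 nrow(dist), format(attr(dist, "pH")))
  resname <- pqr_resname(dist$class)
  chain <- if ("chain" %in% names(dist)) {
    ifelse(is.na(dist$chain), "A", dist$chain)
  } else rep("A", nrow(dist))
  resno <- if ("resno" %in% names(dist)) {
    ifelse(is.na(dist$resno), seq_len(nrow(dist)), dist$resno)
  } else seq_len(nrow(dist))
  rec <- sprintf("ATOM  %5d  Q   %-3s %1s %4d %11.3f %11.3f %11.3f %9.4f %6.2f",
                 seq_len(nrow(dist)), resname, chain, as.integer(resno),
                 dist$x_nm * 10, dist$y_nm * 10, dist$z_nm * 10,
                 dist$charge, 1.0)
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  writeLines(c(hdr, rec), con)
  invisible(path)
}

pqr_resname <- function(class) {
  map <- c(NTERM = "NTR", CTERM = "CTR", FIXED = "FIX")
  out <- unname(map[class])
  ifelse(is.na(out), class, out)
}

pqr_class <- function(resname) {
  map <- c(NTR = "NTERM", CTR = "CTERM", FIX = "FIXED")
  out <- unname(map[resname])
  ifelse(is.na(out), resname, out)
}

#' Read a PQR charge file
#'
#' Parses whitespace-separated PQR records written by [write_pqr()] (or any
#' PQR with the same column order) into a fixed-charge distribution: the
#' charges are taken verbatim and are not re-titrated with pH.
#'
#' @param path Path to a PQR file.
#' @return A `charge_distribution` with fixed charges (`pKa` is `NA`).
#' @export
read_pqr <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("PQR file not found: ", path), class = "nanofet_input_error")
  }
  lines <- grep("^ATOM", readLines(path, warn = FALSE), value = TRUE)
  if (length(lines) == 0L) {
    return(new_charge_distribution(empty_sites()))
  }
  fields <- strsplit(trimws(lines), "\\s+")
  bad <- which(vapply(fields, length, 1L) < 10L)
  if (length(bad) > 0L) {
    abort(sprintf("malformed PQR record on ATOM line %d", bad[1L]),
          class = "nanofet_parse_error")
  }
  f <- function(i) vapply(fields, `[[`, "", i)
  num <- function(i) as.numeric(f(i))
  cls <- pqr_class(f(4))
  new_charge_distribution(tibble(
    site = paste0(cls, f(6), ":", f(5)),
    class = cls,
    chain = f(5),
    resno = suppressWarnings(as.integer(f(6))),
    x_nm = num(7) / 10, y_nm = num(8) / 10, z_nm = num(9) / 10,
    pKa = NA_real_,
    charge = num(10)
  ))
}

empty_sites <- function() {
  tibble(site = character(), class = character(),
         chain = character(), resno = integer(),
         x_nm = numeric(), y_nm = numeric(), z_nm = numeric(),
         pKa = numeric(), charge = numeric())
}

#' Build a pH-independent point-charge distribution
#'
#' Wraps an arbitrary set of point charges (positions in nm, charges in
#' elementary-charge units) into a `charge_distribution` whose charges do
#' not respond to pH. Useful for abstract test systems such as dipoles or
#' surrogate analytes.
#'
#' @param sites A data frame with columns `x_nm`, `y_nm`, `z_nm`, `charge`.
#' @return A `charge_distribution` with `class = "FIXED"` sites.
#' @examples
#' dipole <- make_point_charges(
#'   data.frame(x_nm = 0, y_nm = 0, z_nm = c(0.5, 3.5), charge = c(1, -1))
#' )
#' net_charge(dipole)
#' @export
make_point_charges <- function(sites) {
  sites <- as_tibble(sites)
  need <- c("x_nm", "y_nm", "z_nm", "charge")
  if (!all(need %in% names(sites))) {
    abort(paste0("`sites` must have columns ", paste(need, collapse = ", ")),
          class = "nanofet_input_error")
  }
  vals <- unlist(sites[need], use.names = FALSE)
  if (length(vals) > 0 && !all(is.finite(vals))) {
    abort("positions and charges must be finite", class = "nanofet_input_error")
  }
  new_charge_distribution(tibble(
    site = paste0("FIX", seq_len(nrow(sites))),
    class = "FIXED",
    chain = NA_character_,
    resno = NA_integer_,
    x_nm = as.numeric(sites$x_nm),
    y_nm = as.numeric(sites$y_nm),
    z_nm = as.numeric(sites$z_nm),
    pKa = NA_real_,
    charge = as.numeric(sites$charge)
  ))
}
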