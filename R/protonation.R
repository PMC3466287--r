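# site classes that titrate as acids (deprotonated form carries -1);
# everything else titratable is a base (protonated form carries +1).
.acid_classes <- c("ASP", "GLU", "CTERM", "TYR", "CYS")
.base_classes <- c("LYS", "ARG", "HIS", "NTERM")

# atoms whose mean position defines the charge site of each residue class
.placement_atoms <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), LYS = "NZ",
  ARG = c("NH1", "NH2"), HIS = c("ND1", "NE2"), CYS = "SG", TYR = "OH"
)

#' Null-model pKa table
#'
#' Intrinsic (unperturbed) pKa values of the ionizable residue classes and
#' the backbone termini, used whenever no structure-based per-site pKa file
#' is supplied. These are the standard model values of empirical pKa
#' predictors; structure-dependent shifts require an external predictor
#' whose output can be supplied via [read_pka_file()].
#'
#' @return A tibble with columns `class`, `pKa` and `role`
#'   (`"acid"`/`"base"`).
#' @export
default_pka_table <- function() {
  tibble(
    class = c("ASP", "GLU", "HIS", "CYS", "TYR", "LYS", "ARG",
              "NTERM", "CTERM"),
    pKa = c(3.80, 4.50, 6.50, 9.00, 10.00, 10.50, 12.50, 8.00, 3.20),
    role = ifelse(c("ASP", "GLU", "HIS", "CYS", "TYR", "LYS", "ARG",
                    "NTERM", "CTERM") %in% .acid_classes, "acid", "base")
  )
}

#' Fractional charge of a titratable site (Henderson-Hasselbalch)
#'
#' For an acidic site the charge is \eqn{q = -1/(1 + 10^{pK_a - pH})}; for
#' a basic site \eqn{q = +1/(1 + 10^{pH - pK_a})}. The magnitude is the
#' probability of the site being in its charged protonation state.
#'
#' @param class Site class: one of `"ASP"`, `"GLU"`, `"TYR"`, `"CYS"`,
#'   `"CTERM"` (acids) or `"LYS"`, `"ARG"`, `"HIS"`, `"NTERM"` (bases).
#'   Vectorized.
#' @param pKa Site pKa (dimensionless).
#' @param pH Solution pH.
#' @return Fractional charge in elementary-charge units, in `(-1, 0]` for
#'   acids and `[0, 1)` for bases.
#' @examples
#' titration_charge("ASP", 3.8, 7.4)
#' titration_charge("LYS", 10.5, 7.4)
#' @export
titration_charge <- function(class, pKa, pH) {
  if (!all(is.finite(pKa)) || !all(is.finite(pH))) {
    abort("pKa and pH must be finite", class = "nanofet_input_error")
  }
  known <- class %in% c(.acid_classes, .base_classes)
  if (!all(known)) {
    abort(paste0("unknown site class: ",
                 paste(unique(class[!known]), collapse = ", ")),
          class = "nanofet_input_error")
  }
  is_acid <- class %in% .acid_classes
  ifelse(is_acid,
         -1 / (1 + 10^(pKa - pH)),
         +1 / (1 + 10^(pH - pKa)))
}

#' Assign pH-dependent charges to the ionizable sites of a structure
#'
#' Builds the coarse-grained charge distribution of a protein: one site per
#' ionizable residue (Asp, Glu, His, Cys, Tyr, Lys, Arg), placed at the
#' mean of the terminal side-chain atom coordinates, plus per chain an
#' N-terminal site at the backbone nitrogen of the first residue and a
#' C-terminal site at the OXT atom of the last residue (falling back to the
#' carbonyl C, with a warning, when OXT is absent). Charges follow
#' [titration_charge()] at the given pH; pKa values come from a per-site
#' table (e.g. [read_pka_file()] output) when provided, otherwise from the
#' null-model table. A residue whose placement atoms are all missing falls
#' back to its centroid with a warning; side chains are never
#' reconstructed.
#'
#' @param str An `nw_structure`.
#' @param pH Solution pH (default 7.4).
#' @param pka_table Class-level pKa table, as [default_pka_table()].
#' @param site_pka Optional per-site pKa tibble with columns `class`,
#'   `resno`, `chain`, `pKa` (see [read_pka_file()]).
#' @return A `charge_distribution`; positions in nm, charges in elementary
#'   charges. The source structure is kept as an attribute so that later
#'   geometry steps (alignment, bounding box, coverage) can use all atoms.
#' @examples
#' pep <- build_peptide("KKAAAAAAAADD")
#' dist <- assign_charges(pep, pH = 7.4)
#' net_charge(dist)
#' @export
assign_charges <- function(str, pH = 7.4, pka_table = default_pka_table(),
                           site_pka = NULL) {
  stopifnot(inherits(str, "nw_structure"))
  if (!is.finite(pH) || pH < 0 || pH > 14) {
    abort("pH must be in [0, 14]", class = "nanofet_input_error")
  }
  class_pka <- setNames(pka_table$pKa, pka_table$class)

  residues <- dplyr::distinct(as_tibble(str)[c("chain", "resno", "resid")])
  rows <- list()
  for (i in seq_len(nrow(residues))) {
    rr <- residues[i, ]
    if (!rr$resid %in% names(.placement_atoms)) next
    at <- str[str$chain == rr$chain & str$resno == rr$resno, ]
    place <- at[at$atom %in% .placement_atoms[[rr$resid]], ]
    if (nrow(place) == 0L) {
      warn(sprintf("residue %s%d:%s lacks its placement atoms; using centroid",
                   rr$resid, rr$resno, rr$chain))
      place <- at
    }
    rows[[length(rows) + 1L]] <- tibble(
      class = rr$resid, chain = rr$chain, resno = rr$resno,
      x_nm = mean(place$x) / 10, y_nm = mean(place$y) / 10,
      z_nm = mean(place$z) / 10
    )
  }

  # one N- and one C-terminal site per chain
  for (ch in attr(str, "chains")) {
    at <- str[str$chain == ch, ]
    first <- at[at$resno == min(at$resno), ]
    nat <- first[first$atom == "N", ]
    if (nrow(nat) == 0L) nat <- first[1L, ]
    rows[[length(rows) + 1L]] <- tibble(
      class = "NTERM", chain = ch, resno = min(at$resno),
      x_nm = mean(nat$x) / 10, y_nm = mean(nat$y) / 10, z_nm = mean(nat$z) / 10
    )
    last <- at[at$resno == max(at$resno), ]
    cat_ <- last[last$atom == "OXT", ]
    if (nrow(cat_) == 0L) {
      warn(sprintf("chain %s has no OXT atom; placing C-terminus on C", ch))
      cat_ <- last[last$atom == "C", ]
      if (nrow(cat_) == 0L) cat_ <- last[nrow(last), ]
    }
    rows[[length(rows) + 1L]] <- tibble(
      class = "CTERM", chain = ch, resno = max(at$resno),
      x_nm = mean(cat_$x) / 10, y_nm = mean(cat_$y) / 10,
      z_nm = mean(cat_$z) / 10
    )
  }

  if (length(rows) == 0L) {
    return(new_charge_distribution(empty_sites(), pH = pH, structure = str))
  }
  sites <- dplyr::bind_rows(rows)

  pKa <- unname(class_pka[sites$class])
  missing_class <- unique(sites$class[is.na(pKa)])
  if (length(missing_class) > 0L) {
    abort(paste0("pKa table lacks class(es): ",
                 paste(missing_class, collapse = ", ")),
          class = "nanofet_input_error")
  }
  if (!is.null(site_pka) && nrow(site_pka) > 0L) {
    key <- paste(sites$class, sites$resno, sites$chain)
    pkey <- paste(site_pka$class, site_pka$resno, site_pka$chain)
    hit <- match(key, pkey)
    pKa[!is.na(hit)] <- site_pka$pKa[hit[!is.na(hit)]]
  }

  out <- tibble(
    site = paste0(pqr_resname(sites$class), sites$resno, ":", sites$chain),
    class = sites$class,
    chain = sites$chain,
    resno = as.integer(sites$resno),
    x_nm = sites$x_nm, y_nm = sites$y_nm, z_nm = sites$z_nm,
    pKa = pKa,
    charge = titration_charge(sites$class, pKa, pH)
  )
  new_charge_distribution(out, pH = pH, structure = str)
}

#' Net charge of a distribution
#'
#' @param dist A `charge_distribution`.
#' @return Sum of the site charges, in elementary charges.
#' @export
net_charge <- function(dist) {
  stopifnot(inherits(dist, "charge_distribution"))
  sum(dist$charge)
}

#' Read a per-site pKa file
#'
#' Parses a whitespace-separated summary of structure-based pKa
#' predictions, one site per line: `RESNAME RESNUM CHAIN PKA`. `RESNAME`
#' is a residue class (`ASP`, `GLU`, ...) or a terminus (`N+`/`NTERM`,
#' `C-`/`CTERM`). Blank lines and lines starting with `#` are skipped.
#' When a site appears twice, the last entry wins (with a warning).
#'
#' @param path Path to the pKa file.
#' @return A tibble with columns `class`, `resno`, `chain`, `pKa`, suitable
#'   for the `site_pka` argument of [assign_charges()].
#' @export
read_pka_file <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("pKa file not found: ", path), class = "nanofet_input_error")
  }
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  rows <- list()
  for (i in keep) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    pka <- if (length(f) >= 4L) suppressWarnings(as.numeric(f[4])) else NA
    resno <- if (length(f) >= 2L) suppressWarnings(as.integer(f[2])) else NA
    if (length(f) < 4L || is.na(pka) || is.na(resno)) {
      abort(sprintf("malformed pKa line %d: '%s'", i, lines[i]),
            class = "nanofet_parse_error")
    }
    cls <- toupper(f[1])
    term_map <- c("N+" = "NTERM", "C-" = "CTERM")
    if (cls %in% names(term_map)) cls <- unname(term_map[[cls]])
    rows[[length(rows) + 1L]] <- tibble(class = cls, resno = resno,
                                        chain = f[3], pKa = pka)
  }
  if (length(rows) == 0L) {
    return(tibble(class = character(), resno = integer(),
                  chain = character(), pKa = numeric()))
  }
  out <- dplyr::bind_rows(rows)
  key <- paste(out$class, out$resno, out$chain)
  if (anyDuplicated(key)) {
    warn("duplicate site(s) in pKa file; keeping the last entry of each")
    out <- out[!duplicated(key, fromLast = TRUE), , drop = FALSE]
  }
  out
}
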