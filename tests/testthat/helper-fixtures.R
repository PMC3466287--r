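# shared fixtures, all generated in code

peptide_distribution <- function(pH = 7.4, aligned = TRUE) {
  d <- assign_charges(build_peptide("KKAAAAAAAADD"), pH = pH)
  if (aligned) d <- align_principal(d)
  d
}

# rotate a vertical orientation so that the requested residue class ends up
# closest to the wire (most negative z)
orient_end_down <- function(dist, class) {
  for (ang in c(90, -90)) {
    r <- orient(dist, euler_deg = c(0, ang, 0))
    if (mean(r$z_nm[r$class == class]) < mean(r$z_nm[r$class != class])) {
      return(r)
    }
  }
  stop("could not orient class downwards")
}

# box-shaped synthetic structure with a given extent (Angstrom)
box_structure <- function(ex, ey, ez) {
  corners <- expand.grid(x = c(0, ex), y = c(0, ey), z = c(0, ez))
  new_structure_tbl <- tibble::tibble(
    serial = seq_len(nrow(corners)), atom = "CA", resid = "ALA",
    chain = "A", resno = seq_len(nrow(corners)),
    x = corners$x, y = corners$y, z = corners$z, element = "C")
  nanofet:::new_nw_structure(new_structure_tbl)
}

count_pqr_records <- function(path) {
  sum(grepl("^ATOM", readLines(path, warn = FALSE)))
}
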