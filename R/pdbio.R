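#' Write a toy system to a PDB file
#'
#' Beads are emitted as fixed-width ATOM records (receptor chain A, ligand
#' chain B, residues numbered from 1 per chain, coordinates in Angstrom to
#' three decimals), with a TER record between chains and a terminal END.
#'
#' @param system a `toy_system`
#' @param coords optional n x 3 coordinate matrix; defaults to the system's
#'   reference coordinates
#' @param path output file
#' @export
write_pdb <- function(system, path, coords = NULL) {
  stopifnot(inherits(system, "toy_system"))
  if (is.null(coords)) coords <- system$pos
  if (nrow(coords) != nrow(system$pos))
    stop("coordinate count does not match bead count")
  lines <- character()
  serial <- 0L
  prev_chain <- NULL
  element <- ifelse(system$bead_name == "HD", "H",
                    ifelse(system$bead_name == "CB", "S", "C"))
  for (b in seq_len(nrow(coords))) {
    res <- system$residue_id[b]
    ch <- system$residue_chain[res]
    if (!is.null(prev_chain) && ch != prev_chain) {
      lines <- c(lines, "TER")
    }
    prev_chain <- ch
    serial <- serial + 1L
    lines <- c(lines, sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      serial, system$bead_name[b], system$residue_name[res], ch,
      system$residue_number[res],
      coords[b, 1], coords[b, 2], coords[b, 3], 1.00, 0.00, element[b]))
  }
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}

#' Read coordinates and labels from a PDB file
#'
#' A strict fixed-width parser for ATOM/HETATM records. Non-coordinate
#' records (HEADER, REMARK, TER, END, ...) are skipped, so header-only files
#' parse to an empty container. A truncated or malformed ATOM record raises
#' an error naming the offending line.
#'
#' @param path PDB file path
#' @return a list of class `pdb_coords` with `coords` (n x 3), `atom_name`,
#'   `residue_name`, `chain`, `residue_number` vectors
#' @export
read_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- grepl("^(ATOM  |HETATM)", lines)
  idx <- which(keep)
  n <- length(idx)
  coords <- matrix(NA_real_, n, 3)
  atom_name <- character(n); res_name <- character(n)
  chain <- character(n); resno <- integer(n)
  for (k in seq_len(n)) {
    ln <- lines[idx[k]]
    if (nchar(ln) < 54)
      stop(sprintf("parse error at line %d: truncated ATOM record", idx[k]))
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    no <- suppressWarnings(as.integer(substr(ln, 23, 26)))
    if (any(is.na(xyz)) || is.na(no))
      stop(sprintf("parse error at line %d: malformed ATOM record", idx[k]))
    coords[k, ] <- xyz
    atom_name[k] <- trimws(substr(ln, 13, 16))
    res_name[k] <- trimws(substr(ln, 18, 21))
    chain[k] <- substr(ln, 22, 22)
    resno[k] <- no
  }
  structure(list(coords = coords, atom_name = atom_name,
                 residue_name = res_name, chain = chain,
                 residue_number = resno),
            class = "pdb_coords")
}
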