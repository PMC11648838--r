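# Fixed-column structure file writers/readers (PDB v3.3 and GRO). No PDB
# library ships with the environment, so the writers are implemented here and
# kept deliberately minimal: ATOM/TER/END records, sequential serials from 1,
# one chain identifier per chain.

.pdb_atom_name <- function(name) {
  # names of up to 3 characters start in column 14; 4-character names fill
  # columns 13-16
  if (nchar(name) >= 4) substr(name, 1, 4) else sprintf(" %-3s", name)
}

#' Write an all-atom structure to PDB or GRO
#'
#' PDB v3.3 fixed-column ATOM records (coordinates to 0.001 Angstrom) or
#' GROMACS GRO records (nm, 0.001 nm precision). Atom serials run from 1;
#' each chain gets a distinct chain identifier (PDB) and residue numbering is
#' continuous per chain.
#'
#' @param structure an `atomistic_structure` (or anything with a comparable
#'   `atoms` data frame)
#' @param path output file path
#' @param format `"pdb"` or `"gro"`; default inferred from the extension
#' @return the path, invisibly
#' @export
write_structure <- function(structure, path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.gro$", path, ignore.case = TRUE)) "gro" else "pdb"
  format <- match.arg(format, c("pdb", "gro"))
  atoms <- structure$atoms
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path: directory does not exist: ", dir)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "pdb") {
    serial <- 0L
    for (ch in unique(atoms$chain)) {
      a <- atoms[atoms$chain == ch, ]
      for (k in seq_len(nrow(a))) {
        serial <- serial + 1L
        writeLines(sprintf(
          "ATOM  %5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, .pdb_atom_name(a$name[k]), " ", a$resname[k], ch,
          a$resid[k], " ", a$x[k], a$y[k], a$z[k], 1.0, 0.0,
          a$element[k]), con)
      }
      writeLines(sprintf("TER   %5d      %3s %1s%4d",
                         serial + 1L, a$resname[nrow(a)], ch,
                         a$resid[nrow(a)]), con)
      serial <- serial + 1L
    }
    writeLines("END", con)
  } else {
    writeLines("backmapped structure", con)
    writeLines(sprintf("%5d", nrow(atoms)), con)
    # GRO has no chain field; residues are numbered continuously
    resnum <- cumsum(!duplicated(paste(atoms$chain, atoms$resid)))
    for (k in seq_len(nrow(atoms))) {
      writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                         resnum[k] %% 100000L, atoms$resname[k],
                         substr(atoms$name[k], 1, 5), k %% 100000L,
                         atoms$x[k] / 10, atoms$y[k] / 10, atoms$z[k] / 10),
                 con)
    }
    bl <- if (!is.null(structure$box_length) && is.finite(structure$box_length))
      structure$box_length / 10 else 0
    writeLines(sprintf("%10.5f%10.5f%10.5f", bl, bl, bl), con)
  }
  invisible(path)
}

#' Read a PDB or GRO structure file
#'
#' Minimal reader for the files written by [write_structure()]; returns the
#' atom table (bonds are not reconstructed).
#'
#' @param path file path
#' @param format `"pdb"` or `"gro"`; default inferred from the extension
#' @return an `atomistic_structure` with an empty bond list
#' @export
read_structure <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format))
    format <- if (grepl("\\.gro$", path, ignore.case = TRUE)) "gro" else "pdb"
  format <- match.arg(format, c("pdb", "gro"))
  lines <- readLines(path)
  if (format == "pdb") {
    at <- lines[startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")]
    atoms <- data.frame(
      name = trimws(substr(at, 13, 16)),
      resname = trimws(substr(at, 18, 20)),
      chain = substr(at, 22, 22),
      resid = as.integer(substr(at, 23, 26)),
      x = as.numeric(substr(at, 31, 38)),
      y = as.numeric(substr(at, 39, 46)),
      z = as.numeric(substr(at, 47, 54)),
      element = trimws(substr(at, 77, 78)),
      stringsAsFactors = FALSE)
    box <- NA_real_
  } else {
    nat <- as.integer(trimws(lines[2]))
    at <- lines[3:(2 + nat)]
    atoms <- data.frame(
      resid = as.integer(substr(at, 1, 5)),
      resname = trimws(substr(at, 6, 10)),
      name = trimws(substr(at, 11, 15)),
      x = as.numeric(substr(at, 21, 28)) * 10,
      y = as.numeric(substr(at, 29, 36)) * 10,
      z = as.numeric(substr(at, 37, 44)) * 10,
      stringsAsFactors = FALSE)
    atoms$chain <- "A"
    atoms$element <- substr(sub("^[0-9]", "", atoms$name), 1, 1)
    box <- as.numeric(strsplit(trimws(lines[3 + nat]), "\\s+")[[1]][1]) * 10
  }
  atoms$mass <- unname(ELEMENT_MASS[atoms$element])
  structure(list(atoms = atoms, bonds = cbind(integer(0), integer(0)),
                 sequences = NULL, termini = NA_character_,
                 provenance = path, box_length = box),
            class = "atomistic_structure")
}

#' Write a clash report as tab-separated text
#' @param report a `clash_report` from [detect_clashes()]
#' @param path output path
#' @export
write_clash_report <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
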