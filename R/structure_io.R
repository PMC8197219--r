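# PDB ingestion, molecule classification and complex screening.

# Residue vocabularies. DNA covers modern two-letter deoxy codes, deoxyinosine
# and the legacy one-letter naming still found in older entries.
DNA_RESIDUES <- c("DA", "DC", "DG", "DT", "DI", "A", "C", "G", "T")
AMINO_ACIDS <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)
WATER_RESIDUES <- c("HOH", "WAT", "DOD", "H2O")

#' Parse a PDB file into a structure object
#'
#' Reads the fixed-column ATOM/HETATM records of a PDB file into a
#' `vb_structure`: a list with the entry `id` and an `atoms` data frame with
#' one row per retained heavy atom. Waters and hydrogens are dropped, only the
#' first MODEL is kept, and alternate locations other than `' '`/`'A'` are
#' discarded so each atom appears exactly once. HETATM records are dropped
#' unless `keep_hetero = TRUE` (metals can then be typed later).
#'
#' @param path Path to a PDB file.
#' @param keep_hetero Keep HETATM records (metals etc.)? Default `FALSE`.
#' @param id Structure identifier; defaults to the file name without extension.
#' @return A `vb_structure` object. Columns of `$atoms`: `serial`, `name`,
#'   `resid`, `chain`, `resno`, `insert`, `x`, `y`, `z`, `element`,
#'   `molecule`, `sasa`, `surface`, `type`. `molecule`, `sasa`, `surface` and
#'   `type` are filled by later pipeline stages.
#' @seealso [classify_molecules()], [screen_complex()], [write_atoms()]
#' @export
#' @examples
#' pdb <- generate_complex(synth_spec(seed = 1, n_residues = 5, dna_length = 3))
#' f <- tempfile(fileext = ".pdb")
#' write_pdb(pdb, f)
#' s <- parse_pdb(f)
#' nrow(s$atoms)
parse_pdb <- function(path, keep_hetero = FALSE, id = NULL) {
  if (!file.exists(path)) {
    stop("PDB file not found: ", path)
  }
  raw <- readLines(path, warn = FALSE)
  if (!any(grepl("^(ATOM  |HETATM)", raw))) {
    first <- if (length(raw)) raw[1] else "<empty file>"
    stop("no ATOM/HETATM records in '", path, "' (first line: ", first, ")")
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = TRUE,
                                     verbose = FALSE)),
    error = function(e) stop("failed to parse PDB '", path, "': ",
                             conditionMessage(e))
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) {
    stop("no atoms parsed from '", path, "'")
  }
  if (!keep_hetero) {
    at <- at[at$type == "ATOM", , drop = FALSE]
  }
  at <- at[!(at$resid %in% WATER_RESIDUES), , drop = FALSE]
  element <- at$elesy
  element[is.na(element)] <- ""
  element <- toupper(trimws(element))
  guess <- toupper(substr(gsub("[0-9' ]", "", at$elety), 1, 1))
  element[element == ""] <- guess[element == ""]
  keep <- !(element %in% c("H", "D"))
  at <- at[keep, , drop = FALSE]
  element <- element[keep]
  if (nrow(at) == 0) {
    stop("no heavy atoms retained from '", path, "'")
  }
  bad <- which(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z))
  if (length(bad)) {
    stop("missing coordinates for atom serial ", at$eleno[bad[1]],
         " in '", path, "'")
  }
  insert <- at$insert
  insert[is.na(insert)] <- ""
  atoms <- data.frame(
    serial = as.integer(at$eleno),
    name = trimws(at$elety),
    resid = trimws(at$resid),
    chain = ifelse(is.na(at$chain), " ", at$chain),
    resno = as.integer(at$resno),
    insert = insert,
    x = at$x, y = at$y, z = at$z,
    element = element,
    molecule = NA_character_,
    sasa = NA_real_,
    surface = NA,
    type = NA_character_,
    stringsAsFactors = FALSE
  )
  rownames(atoms) <- NULL
  if (is.null(id)) {
    id <- sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE)
  }
  new_structure(id, atoms)
}

new_structure <- function(id, atoms) {
  rownames(atoms) <- NULL
  structure(list(id = id, atoms = atoms), class = "vb_structure")
}

#' @export
print.vb_structure <- function(x, ...) {
  n <- table(factor(x$atoms$molecule,
                    levels = c(MOL_PROTEIN, MOL_DNA, MOL_OTHER)))
  cat("vb_structure '", x$id, "': ", nrow(x$atoms), " atoms",
      if (!all(is.na(x$atoms$molecule))) {
        sprintf(" (protein %d, DNA %d, other %d)", n[1], n[2], n[3])
      } else "",
      "\n", sep = "")
  invisible(x)
}

#' Assign molecule classes to every atom
#'
#' Labels each atom `PROTEIN` (the 20 standard amino acids), `DNA`
#' (deoxyribonucleotides, including legacy one-letter residue names) or
#' `OTHER` (everything else, e.g. modified residues or retained heteroatoms).
#'
#' @param s A `vb_structure` from [parse_pdb()].
#' @return The structure with `$atoms$molecule` filled.
#' @export
classify_molecules <- function(s) {
  stopifnot(inherits(s, "vb_structure"))
  resid <- s$atoms$resid
  mol <- rep(MOL_OTHER, length(resid))
  mol[resid %in% AMINO_ACIDS] <- MOL_PROTEIN
  mol[resid %in% DNA_RESIDUES] <- MOL_DNA
  s$atoms$molecule <- mol
  s
}

#' Screen a complex for usability
#'
#' A complex is usable when it contains at least one DNA atom, at least one
#' protein atom, and every non-DNA atom can be assigned an atom type from the
#' typing table (so structures with modified residues such as MSE, or with
#' unknown heteroatoms, are rejected rather than silently mistyped).
#'
#' @param s A classified `vb_structure`.
#' @param table Typing table, see [default_atom_types()].
#' @return `TRUE` if the complex passes screening.
#' @export
screen_complex <- function(s, table = default_atom_types()) {
  stopifnot(inherits(s, "vb_structure"))
  if (all(is.na(s$atoms$molecule))) {
    s <- classify_molecules(s)
  }
  mol <- s$atoms$molecule
  if (!any(mol == MOL_DNA) || !any(mol == MOL_PROTEIN)) {
    return(FALSE)
  }
  nondna <- s$atoms[mol != MOL_DNA, , drop = FALSE]
  all(typeable(nondna$resid, nondna$name, table))
}

#' Write / read the intermediate atom table
#'
#' The pipeline's plain-text intermediate format: one tab-separated line per
#' atom with columns serial, name, resid, chain, resno, insert, x, y, z,
#' element, molecule. `read_atoms()` inverts `write_atoms()` exactly.
#'
#' @param s A classified `vb_structure`.
#' @param path Output file path.
#' @return `write_atoms()` returns `path` invisibly; `read_atoms()` returns a
#'   `vb_structure`.
#' @export
write_atoms <- function(s, path) {
  stopifnot(inherits(s, "vb_structure"))
  df <- s$atoms[, c("serial", "name", "resid", "chain", "resno", "insert",
                    "x", "y", "z", "element", "molecule")]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#id\t", s$id), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "")
  invisible(path)
}

#' @rdname write_atoms
#' @export
read_atoms <- function(path) {
  header <- readLines(path, n = 1)
  id <- sub("^#id\t", "", header)
  df <- utils::read.delim(path, skip = 1, stringsAsFactors = FALSE,
                          colClasses = c(
                            serial = "integer", name = "character",
                            resid = "character", chain = "character",
                            resno = "integer", insert = "character",
                            x = "numeric", y = "numeric", z = "numeric",
                            element = "character", molecule = "character"
                          ), na.strings = character(0))
  df$insert[is.na(df$insert)] <- ""
  df$sasa <- NA_real_
  df$surface <- NA
  df$type <- NA_character_
  new_structure(id, df)
}

#' Write a structure as a PDB file
#'
#' Emits standard fixed-column ATOM records (occupancy 1.00, B-factor 0.00).
#' Used mainly to export synthetic fixtures so the full pipeline can be
#' exercised from files.
#'
#' @param s A `vb_structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  stopifnot(inherits(s, "vb_structure"))
  a <- s$atoms
  name_fmt <- ifelse(nchar(a$name) >= 4, substr(a$name, 1, 4),
                     sprintf(" %-3s", a$name))
  lines <- sprintf(
    "ATOM  %5d %4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    a$serial %% 100000L, name_fmt, a$resid, a$chain, a$resno %% 10000L,
    ifelse(a$insert == "", " ", a$insert), a$x, a$y, a$z, 1, 0, a$element
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}
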