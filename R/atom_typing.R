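# Surface atom-type assignment: 16 codes combining element, hybridisation /
# ring context and polarity / charge, looked up by (residue name, atom name).

# Canonical channel ordering of the 16 codes.
ATOM_TYPE_CODES <- c(
  "C2P", "C3N", "C3P", "CRP", "CRN", "CCP", "N3C", "NRV",
  "NCC", "NCP", "O3P", "OCC", "OCP", "S3N", "PHO", "MET"
)

.vb_env <- new.env(parent = emptyenv())

#' The built-in atom-type lookup table
#'
#' Maps `(residue name, atom name)` to one of 16 atom-type codes. The code
#' grammar: first character is the element (C/N/O/S); the second character is
#' 2 (sp2), 3 (sp3), R (aromatic ring) or C (conjugated/resonating); the third
#' is N (nonpolar), P (polar), V (variable protonation, the His/Trp ring
#' nitrogens) or C (charged). Two three-letter names cover atoms that need no
#' finer split: `PHO` (phosphorus) and `MET` (metals). The table ships as a
#' plain TSV under `extdata` and covers every heavy atom of the 20 standard
#' amino acids plus common metal ions.
#'
#' @param path Optional path to a custom table (TSV with columns `resid`,
#'   `atom`, `code`); defaults to the shipped table.
#' @return A data frame with columns `resid`, `atom`, `code` and class
#'   `vb_atom_types`.
#' @export
default_atom_types <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.vb_env$atom_types)) {
      return(.vb_env$atom_types)
    }
    path <- system.file("extdata", "atom_types.tsv", package = "voxbind",
                        mustWork = TRUE)
    cache <- TRUE
  } else {
    cache <- FALSE
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character",
                           na.strings = character(0))
  stopifnot(all(c("resid", "atom", "code") %in% names(tab)))
  bad <- setdiff(unique(tab$code), ATOM_TYPE_CODES)
  if (length(bad)) {
    stop("typing table contains unknown codes: ", paste(bad, collapse = ", "))
  }
  key <- paste(tab$resid, tab$atom)
  if (anyDuplicated(key)) {
    stop("typing table has duplicate (residue, atom) entries")
  }
  tab <- structure(tab, class = c("vb_atom_types", "data.frame"))
  if (cache) .vb_env$atom_types <- tab
  tab
}

# Vectorized lookup; returns NA where untypeable.
lookup_type <- function(resid, name, table) {
  table$code[match(paste(resid, name), paste(table$resid, table$atom))]
}

typeable <- function(resid, name, table) {
  !is.na(lookup_type(resid, name, table))
}

#' Assign atom types to surface protein atoms
#'
#' Every protein atom flagged as surface receives its code from the typing
#' table; buried protein atoms receive the sentinel `NON_SURFACE` (they still
#' occupy the dedicated 17th input channel during voxelization). DNA and other
#' atoms keep `NA`.
#'
#' @param s A `vb_structure` with surface flags set (see [flag_surface()]).
#' @param table Typing table from [default_atom_types()].
#' @return The structure with `$atoms$type` filled.
#' @export
assign_atom_types <- function(s, table = default_atom_types()) {
  stopifnot(inherits(s, "vb_structure"))
  a <- s$atoms
  if (all(is.na(a$surface))) {
    stop("surface flags not set; run compute_sasa()/flag_surface() first")
  }
  prot <- which(a$molecule == MOL_PROTEIN)
  surf <- prot[a$surface[prot] %in% TRUE]
  buried <- setdiff(prot, surf)
  codes <- lookup_type(a$resid[surf], a$name[surf], table)
  miss <- which(is.na(codes))
  if (length(miss)) {
    i <- surf[miss[1]]
    stop("no atom type for surface atom ", a$name[i], " of residue ",
         a$resid[i], " ", a$resno[i], " (serial ", a$serial[i], ")")
  }
  a$type[surf] <- codes
  a$type[buried] <- NON_SURFACE
  if (any(a$molecule == MOL_OTHER & a$surface %in% TRUE)) {
    oth <- which(a$molecule == MOL_OTHER & a$surface %in% TRUE)
    a$type[oth] <- lookup_type(a$resid[oth], a$name[oth], table)
  }
  s$atoms <- a
  s
}

#' Channel ordering of the atom-type codes
#'
#' Deterministic ordering used for the one-hot channel dimension: the 16 codes
#' in their canonical table order. The 17th voxel channel (not listed here) is
#' the `NON_SURFACE` sentinel.
#'
#' @param table Typing table (validated against the closed code set).
#' @return Character vector of 16 codes.
#' @export
list_atom_types <- function(table = default_atom_types()) {
  stopifnot(all(unique(table$code) %in% ATOM_TYPE_CODES))
  ATOM_TYPE_CODES
}
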