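# Light-weight residue container shared by the PDB reader and the
# conformer builder: parallel atom vectors plus an n x 3 coordinate matrix.

#' Construct a residue unit
#'
#' The basic per-residue container: a residue type, its identity within a
#' chain, and its atoms (names, elements, alternate-location codes,
#' occupancies and Cartesian coordinates in file order).
#'
#' @param res_type Three-letter residue code (upper case).
#' @param chain_id Chain identifier string.
#' @param seq_num Integer residue sequence number.
#' @param ins Insertion code ("" when absent).
#' @param atom_names Character vector of atom names.
#' @param elements Character vector of element symbols (same length).
#' @param xyz Numeric matrix with one row per atom and 3 columns (Angstrom).
#' @param altlocs Character vector of alternate-location codes ("" = none).
#' @param occupancies Numeric occupancies.
#' @return An object of class `residue_unit`.
#' @export
residue_unit <- function(res_type, chain_id = "A", seq_num = 1L, ins = "",
                         atom_names = character(), elements = character(),
                         xyz = matrix(numeric(), ncol = 3),
                         altlocs = rep("", length(atom_names)),
                         occupancies = rep(1, length(atom_names))) {
  stopifnot(length(atom_names) == length(elements),
            nrow(xyz) == length(atom_names),
            all(nzchar(atom_names)),
            all(is.finite(xyz)))
  structure(list(res_type = toupper(res_type), chain_id = chain_id,
                 seq_num = as.integer(seq_num), ins = ins,
                 atom_names = atom_names, elements = elements,
                 altlocs = altlocs, occupancies = occupancies,
                 xyz = xyz),
            class = "residue_unit")
}

#' Coordinates of a named atom in a residue
#'
#' Returns the first matching atom's coordinates (file order), so after
#' alternate-location resolution the match is unique.
#'
#' @param residue A [residue_unit].
#' @param name Atom name, e.g. `"CA"`.
#' @return Numeric 3-vector or `NULL` if the atom is absent.
#' @export
atom_coords <- function(residue, name) {
  i <- match(name, residue$atom_names)
  if (is.na(i)) return(NULL)
  residue$xyz[i, ]
}

#' @export
print.residue_unit <- function(x, ...) {
  cat(sprintf("<residue_unit> %s %s%d%s (%d atoms)\n",
              x$res_type, x$chain_id, x$seq_num, x$ins,
              length(x$atom_names)))
  invisible(x)
}

#' @export
format.residue_unit <- function(x, ...) {
  sprintf("%s %s%d%s", x$res_type, x$chain_id, x$seq_num, x$ins)
}

.residue_id <- function(residue) {
  paste0(residue$chain_id, ":", residue$seq_num, residue$ins)
}

# element symbol from a PDB atom name (heavy atoms only)
.element_from_name <- function(name) {
  substr(gsub("[0-9]", "", name), 1L, 1L)
}

#' Standard amino-acid residue codes
#'
#' The 20 standard three-letter codes.
#' @return Character vector of length 20.
#' @export
standard_residues <- function() {
  c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
    "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")
}
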