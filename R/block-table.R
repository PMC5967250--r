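# The distal-block table: for each of the 18 residue types with a
# side chain beyond CB (GLY and ALA are excluded), the ordered heavy-atom
# names of the terminal rigid group, their atomic masses, and the four
# atoms defining chi1. The shipped default is calibrated so that
# ideal-geometry conformers reproduce the modal block lengths observed in
# high-resolution structure sets (LYS 5.7, ILE 3.88, PHE 3.78, TYR 6.43 A).

#' Standard atomic masses of protein heavy atoms
#'
#' @return Named numeric vector (u) for C, N, O and S.
#' @export
heavy_atom_masses <- function() {
  c(C = 12.011, N = 14.007, O = 15.999, S = 32.06)
}

#' Read a distal-block table from a delimited text file
#'
#' The file is tab-separated with a header and the columns `res_type`,
#' `block_atoms` (comma-separated atom names, ordered), `block_masses`
#' (comma-separated masses in u) and `chi1_atoms` (the four chi1 atoms,
#' comma-separated).
#'
#' @param path Path to the table file.
#' @return A named list (one entry per residue type) of lists with
#'   elements `block_atoms`, `block_masses`, `chi1_atoms`; class
#'   `block_table`.
#' @export
read_block_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  required <- c("res_type", "block_atoms", "block_masses", "chi1_atoms")
  if (!all(required %in% names(df))) {
    stop("block table is missing columns: ",
         paste(setdiff(required, names(df)), collapse = ", "))
  }
  tbl <- lapply(seq_len(nrow(df)), function(i) {
    list(block_atoms = strsplit(df$block_atoms[i], ",", fixed = TRUE)[[1L]],
         block_masses = as.numeric(strsplit(df$block_masses[i], ",",
                                            fixed = TRUE)[[1L]]),
         chi1_atoms = strsplit(df$chi1_atoms[i], ",", fixed = TRUE)[[1L]])
  })
  names(tbl) <- toupper(df$res_type)
  class(tbl) <- "block_table"
  validate_block_table(tbl)
  tbl
}

#' Write a distal-block table to a delimited text file
#'
#' @param table A `block_table` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_block_table <- function(table, path) {
  df <- data.frame(
    res_type = names(table),
    block_atoms = vapply(table, function(e) paste(e$block_atoms, collapse = ","), ""),
    block_masses = vapply(table, function(e)
      paste(sprintf("%.3f", e$block_masses), collapse = ","), ""),
    chi1_atoms = vapply(table, function(e) paste(e$chi1_atoms, collapse = ","), ""))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The default distal-block table shipped with the package
#'
#' Covers exactly the 18 residue types with a distal block: ARG uses the
#' guanidinium group, LYS the terminal CE-NZ pair, ILE the terminal CD1,
#' PHE the six-membered ring, TYR the hydroxyl oxygen, and the remaining
#' types their chemically terminal rigid group (documented in the table
#' file `inst/extdata/block_table.tsv`).
#'
#' @return A `block_table` object.
#' @export
default_block_table <- function() {
  tbl <- .blocklen_cache$default_block_table
  if (is.null(tbl)) {
    path <- system.file("extdata", "block_table.tsv", package = "blocklen",
                        mustWork = TRUE)
    tbl <- read_block_table(path)
    .blocklen_cache$default_block_table <- tbl
  }
  tbl
}

.blocklen_cache <- new.env(parent = emptyenv())

#' Validate a distal-block table
#'
#' Checks that the table covers exactly the 18 non-GLY/ALA standard
#' residue types, that masses are positive and match the atom lists in
#' length, and that each chi1 entry has four atoms starting N, CA, CB.
#'
#' @param table A `block_table`.
#' @return `table`, invisibly; errors on an invalid table.
#' @export
validate_block_table <- function(table) {
  expected <- setdiff(standard_residues(), c("GLY", "ALA"))
  if (!setequal(names(table), expected)) {
    stop("block table must cover exactly the 18 residue types with a ",
         "distal block; got: ", paste(sort(names(table)), collapse = ", "))
  }
  for (rt in names(table)) {
    e <- table[[rt]]
    if (length(e$block_atoms) == 0L || any(!nzchar(e$block_atoms)))
      stop("empty block atom list for ", rt)
    if (length(e$block_masses) != length(e$block_atoms))
      stop("mass/atom length mismatch for ", rt)
    if (any(!is.finite(e$block_masses)) || any(e$block_masses <= 0))
      stop("non-positive mass for ", rt)
    if (length(e$chi1_atoms) != 4L || !identical(e$chi1_atoms[1:3], c("N", "CA", "CB")))
      stop("chi1 quadruple for ", rt, " must be N, CA, CB, <gamma atom>")
  }
  invisible(table)
}

#' @export
print.block_table <- function(x, ...) {
  cat(sprintf("<block_table> %d residue types\n", length(x)))
  for (rt in names(x)) {
    cat(sprintf("  %s: block {%s}, chi1 %s\n", rt,
                paste(x[[rt]]$block_atoms, collapse = ","),
                x[[rt]]$chi1_atoms[4L]))
  }
  invisible(x)
}
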