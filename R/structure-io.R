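# PDB reading (via bio3d), chain/altloc selection policies, and the
# per-residue feature table (one ConformationRecord row per residue).

#' Read a protein structure from a PDB file
#'
#' Parses ATOM records of the first MODEL into chains of [residue_unit]s.
#' HETATM records (ligands, waters, modified residues deposited as
#' heteroatoms) are excluded. All alternate locations are retained at this
#' stage; see [apply_selection()] for the policy step.
#'
#' @param path Path to a PDB-format text file.
#' @return An object of class `protein_structure`: a list of chains (file
#'   order), each a list of [residue_unit]s in file order.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  lines <- readLines(path, warn = FALSE)
  # keep only the first MODEL when several are present
  mstart <- grep("^MODEL", lines)
  if (length(mstart) > 1L) {
    mend <- grep("^ENDMDL", lines)
    first_end <- mend[mend > mstart[1L]][1L]
    lines <- c(lines[seq_len(mstart[1L] - 1L)],
               lines[(mstart[1L] + 1L):(first_end - 1L)],
               lines[lines %in% c("END")])
  }
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(tmp, rm.alt = FALSE, verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  atom <- pdb$atom
  atom <- atom[atom$type == "ATOM" &
                 !(atom$resid %in% c("HOH", "DOD", "WAT")), , drop = FALSE]
  # drop hydrogens/deuterium: blocks and torsions use heavy atoms only
  elesy <- ifelse(is.na(atom$elesy) | !nzchar(trimws(atom$elesy)),
                  .element_from_name(trimws(atom$elety)), trimws(atom$elesy))
  atom <- atom[!(toupper(elesy) %in% c("H", "D")), , drop = FALSE]
  if (nrow(atom) == 0L) {
    stop("no protein residues in ", path, " (empty structure)")
  }
  atom$insert[is.na(atom$insert)] <- ""
  atom$alt[is.na(atom$alt)] <- ""
  atom$chain[is.na(atom$chain)] <- " "
  key <- paste(atom$chain, atom$resno, atom$insert, sep = "|")
  res_split <- split(seq_len(nrow(atom)), factor(key, levels = unique(key)))
  residues <- lapply(res_split, function(ix) {
    a <- atom[ix, , drop = FALSE]
    residue_unit(res_type = a$resid[1L], chain_id = a$chain[1L],
                 seq_num = a$resno[1L], ins = a$insert[1L],
                 atom_names = trimws(a$elety),
                 elements = .element_from_name(trimws(a$elety)),
                 xyz = cbind(a$x, a$y, a$z),
                 altlocs = a$alt,
                 occupancies = ifelse(is.na(a$o), 1, a$o))
  })
  chain_ids <- vapply(residues, `[[`, "", "chain_id")
  chains <- split(residues, factor(chain_ids, levels = unique(chain_ids)))
  chains <- lapply(chains, unname)
  structure(chains, class = "protein_structure")
}

#' Read every MODEL of a multi-model PDB file
#'
#' Companion to [write_pdb()] for ensembles: returns one
#' `protein_structure` per MODEL (or a single-element list when the file
#' has no MODEL records).
#'
#' @param path Path to a PDB-format text file.
#' @return List of `protein_structure` objects.
#' @export
read_ensemble <- function(path) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  lines <- readLines(path, warn = FALSE)
  mstart <- grep("^MODEL", lines)
  if (length(mstart) < 2L) return(list(read_structure(path)))
  mend <- grep("^ENDMDL", lines)
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  lapply(seq_along(mstart), function(i) {
    writeLines(c(lines[(mstart[i] + 1L):(mend[i] - 1L)], "END"), tmp)
    read_structure(tmp)
  })
}

#' Chain and alternate-location selection policy
#'
#' Encodes how a structure's redundancy is resolved before feature
#' extraction: `chains = "first"` keeps only the first chain (the usual
#' choice for crystallographic sets), `chains = "all"` keeps every chain
#' (used for EM sets, where each NCS copy counts as a conformation). The
#' alternate-location policy is always "first in file order". Residues
#' outside the 20 standard types are dropped (and counted) unless
#' `include_nonstandard` is set.
#'
#' @param chains `"first"` or `"all"`.
#' @param altloc Only `"first"` is supported.
#' @param include_nonstandard Keep non-standard residue types?
#' @return An object of class `selection_policy`.
#' @export
selection_policy <- function(chains = c("first", "all"), altloc = "first",
                             include_nonstandard = FALSE) {
  chains <- match.arg(chains)
  altloc <- match.arg(altloc)
  structure(list(chains = chains, altloc = altloc,
                 include_nonstandard = include_nonstandard),
            class = "selection_policy")
}

#' Apply a selection policy to a structure
#'
#' Reduces a structure to the flat list of residues the analysis will
#' see: the first chain or all chains, one atom per name (the alternate
#' location that appears first in file order), and standard residue
#' types only (unless the policy keeps non-standard ones). GLY and ALA
#' are retained here; they are excluded later only from chi1/dBlock
#' statistics. The operation is idempotent.
#'
#' @param chains A `protein_structure`, or a plain list of
#'   [residue_unit]s (e.g. the output of a previous call).
#' @param policy A [selection_policy()].
#' @return List of [residue_unit]s with attribute `n_nonstandard_dropped`.
#' @export
apply_selection <- function(chains, policy = selection_policy()) {
  residues <- if (inherits(chains, "protein_structure")) {
    unlist(unname(chains), recursive = FALSE)
  } else if (length(chains) && inherits(chains[[1L]], "residue_unit")) {
    chains
  } else {
    stop("expected a protein_structure or a list of residue_unit objects")
  }
  if (length(residues) == 0L) stop("no residues to select from")
  if (policy$chains == "first") {
    first_chain <- residues[[1L]]$chain_id
    residues <- Filter(function(r) r$chain_id == first_chain, residues)
  }
  residues <- lapply(residues, function(r) {
    keep <- !duplicated(r$atom_names)
    if (all(keep)) return(r)
    residue_unit(r$res_type, r$chain_id, r$seq_num, r$ins,
                 atom_names = r$atom_names[keep],
                 elements = r$elements[keep],
                 xyz = r$xyz[keep, , drop = FALSE],
                 altlocs = rep("", sum(keep)),
                 occupancies = r$occupancies[keep])
  })
  n_nonstd <- 0L
  if (!policy$include_nonstandard) {
    std <- vapply(residues, function(r) r$res_type %in% standard_residues(),
                  logical(1))
    n_nonstd <- sum(!std)
    residues <- residues[std]
  }
  attr(residues, "n_nonstandard_dropped") <- n_nonstd
  residues
}

#' Extract per-residue conformation records
#'
#' Computes the four features for every selected residue: backbone phi
#' and psi (missing at chain start/end or across chain breaks), chi1
#' (missing for GLY/ALA or when a quadruple atom is absent) and the
#' distal-block length dBlock (missing for GLY/ALA or when a block atom
#' is absent). Adjacent residues are treated as peptide-bonded only when
#' their C-N distance is below 2.0 A, so chain breaks suppress phi/psi
#' rather than producing nonsense torsions. Missing features are `NA`,
#' never imputed.
#'
#' @param residues List of [residue_unit]s (after [apply_selection()]).
#' @param block_table A block table; see [default_block_table()].
#' @param source Identifier copied into every record (e.g. structure id).
#' @return A data frame of class `conformation_records` with columns
#'   `source`, `chain`, `seq_num`, `ins`, `res_type`, `phi`, `psi`,
#'   `chi1`, `dblock`, `complete`; angles in degrees `[0, 360)`, dBlock
#'   in Angstrom. A summary of missing features is attached as attribute
#'   `log`.
#' @export
extract_records <- function(residues, block_table = default_block_table(),
                            source = "") {
  n <- length(residues)
  if (n == 0L) {
    return(.empty_records())
  }
  chain <- vapply(residues, `[[`, "", "chain_id")
  # peptide linkage between consecutive residues of the same chain
  linked <- function(i, j) {
    if (i < 1L || j > n) return(FALSE)
    if (chain[i] != chain[j]) return(FALSE)
    c_i <- atom_coords(residues[[i]], "C")
    n_j <- atom_coords(residues[[j]], "N")
    if (is.null(c_i) || is.null(n_j)) return(FALSE)
    .norm3(c_i - n_j) < 2.0
  }
  rows <- lapply(seq_len(n), function(i) {
    r <- residues[[i]]
    prev_c <- if (linked(i - 1L, i)) atom_coords(residues[[i - 1L]], "C")
    next_n <- if (linked(i, i + 1L)) atom_coords(residues[[i + 1L]], "N")
    phi <- backbone_phi(prev_c, atom_coords(r, "N"), atom_coords(r, "CA"),
                        atom_coords(r, "C"))
    psi <- backbone_psi(atom_coords(r, "N"), atom_coords(r, "CA"),
                        atom_coords(r, "C"), next_n)
    data.frame(source = source, chain = r$chain_id, seq_num = r$seq_num,
               ins = r$ins, res_type = r$res_type,
               phi = phi, psi = psi,
               chi1 = chi1_angle(r, block_table),
               dblock = block_length(r, block_table),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$complete <- stats::complete.cases(out[, c("phi", "psi", "chi1", "dblock")])
  attr(out, "log") <- list(
    n_residues = n,
    n_missing_phi = sum(is.na(out$phi)),
    n_missing_psi = sum(is.na(out$psi)),
    n_missing_chi1 = sum(is.na(out$chi1)),
    n_missing_dblock = sum(is.na(out$dblock)))
  class(out) <- c("conformation_records", "data.frame")
  out
}

.record_columns <- c("source", "chain", "seq_num", "ins", "res_type",
                     "phi", "psi", "chi1", "dblock", "complete")

.empty_records <- function() {
  out <- data.frame(source = character(), chain = character(),
                    seq_num = integer(), ins = character(),
                    res_type = character(), phi = numeric(), psi = numeric(),
                    chi1 = numeric(), dblock = numeric(), complete = logical(),
                    stringsAsFactors = FALSE)
  class(out) <- c("conformation_records", "data.frame")
  out
}

#' Write / read conformation records as tab-separated text
#'
#' Lossless round trip of all fields including missing values (written as
#' empty fields).
#'
#' @param records A `conformation_records` data frame.
#' @param path File path.
#' @return `write_records()` returns `path` invisibly; `read_records()`
#'   returns the records.
#' @export
write_records <- function(records, path) {
  utils::write.table(records[, .record_columns, drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  out <- tryCatch(
    suppressWarnings(
    utils::read.table(path, sep = "\t", header = TRUE, na.strings = "",
                      colClasses = c(source = "character", chain = "character",
                                     seq_num = "integer", ins = "character",
                                     res_type = "character", phi = "numeric",
                                     psi = "numeric", chi1 = "numeric",
                                     dblock = "numeric", complete = "logical"),
                      stringsAsFactors = FALSE)),
    error = function(e) stop("malformed records table ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (!identical(sort(names(out)), sort(.record_columns))) {
    stop("malformed records table ", path, ": expected columns ",
         paste(.record_columns, collapse = ", "))
  }
  out <- out[, .record_columns, drop = FALSE]
  for (col in c("source", "chain", "ins", "res_type")) {
    out[[col]][is.na(out[[col]])] <- ""
  }
  class(out) <- c("conformation_records", "data.frame")
  out
}

#' Read a dataset manifest
#'
#' A manifest is a tab-separated table with columns `path`, `id`,
#' `method` (one of `xray`, `em`, `synthetic`) and `resolution` (Angstrom,
#' may be empty). Relative paths are resolved against the manifest's
#' directory.
#'
#' @param path Manifest file path.
#' @return Data frame with the four columns, class `dataset_manifest`.
#' @export
read_manifest <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, na.strings = "",
                          stringsAsFactors = FALSE)
  required <- c("path", "id", "method")
  if (!all(required %in% names(df))) {
    stop("manifest must have columns path, id, method (and optionally ",
         "resolution)")
  }
  if (is.null(df$resolution)) df$resolution <- NA_real_
  if (!all(df$method %in% c("xray", "em", "synthetic"))) {
    stop("manifest method must be one of: xray, em, synthetic")
  }
  if (any(!is.na(df$resolution) & df$resolution <= 0)) {
    stop("manifest resolutions must be positive")
  }
  rel <- !grepl("^(/|[A-Za-z]:)", df$path)
  df$path[rel] <- file.path(dirname(normalizePath(path)), df$path[rel])
  class(df) <- c("dataset_manifest", "data.frame")
  df
}
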