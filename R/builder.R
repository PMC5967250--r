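# Conformer builder: NeRF-style atom placement, GLY-X-GLY tripeptides at
# exact torsions, clash screening, and ground-truth ensemble sampling.

#' Place an atom from internal coordinates
#'
#' Given three reference points `a`, `b`, `c`, returns the point `d` at
#' distance `bond` from `c`, with bond angle `angle` at `c` (between `b`,
#' `c`, `d`) and torsion `torsion` for the quadruple `a-b-c-d` (natural
#' extension of reference frame placement).
#'
#' @param a,b,c Numeric 3-vectors (Angstrom); must not be collinear.
#' @param bond Bond length c-d in Angstrom.
#' @param angle Bond angle b-c-d in degrees.
#' @param torsion Torsion a-b-c-d in degrees.
#' @return Numeric 3-vector, the placed point.
#' @export
#' @examples
#' d <- place_atom(c(-0.5, 1, 0), c(0, 0, 0), c(1.5, 0, 0), 1.5, 109.5, 60)
#' dihedral_angle(c(-0.5, 1, 0), c(0, 0, 0), c(1.5, 0, 0), d) # 60
place_atom <- function(a, b, c, bond, angle, torsion) {
  bc <- c - b
  nbc <- .norm3(bc)
  ab <- b - a
  if (nbc < 1e-10 || .norm3(ab) < 1e-10) {
    stop(degenerate_geometry_error("coincident reference atoms"))
  }
  bc_u <- bc / nbc
  n <- .cross3(ab, bc_u)
  nn <- .norm3(n)
  if (nn < 1e-10 * max(1, .norm3(ab))) {
    stop(degenerate_geometry_error("collinear reference frame"))
  }
  n_u <- n / nn
  m_u <- .cross3(n_u, bc_u)
  ang <- .deg2rad(angle)
  tor <- .deg2rad(torsion)
  d_local <- c(-bond * cos(ang),
               bond * sin(ang) * cos(tor),
               bond * sin(ang) * sin(tor))
  c + d_local[1L] * bc_u + d_local[2L] * m_u + d_local[3L] * n_u
}

#' Build a residue at exact torsions inside a GLY-X-GLY tripeptide
#'
#' Constructs, from ideal covalent geometry, a three-residue peptide whose
#' central residue has exactly the requested backbone torsions (`phi_r`,
#' `psi_r`, signed Ramachandran convention) and side-chain torsions
#' (`chis`, degrees). The flanking glycines provide the atoms needed to
#' measure phi and psi of the central residue.
#'
#' @param res_type Three-letter code of the central residue.
#' @param phi_r Backbone phi of the central residue, degrees in
#'   `(-180, 180]` (or `[0, 360)`; any real value is accepted and used as
#'   a torsion).
#' @param psi_r Backbone psi of the central residue, degrees.
#' @param chis Numeric vector of side-chain torsions chi1, chi2, ...;
#'   length must equal [n_chi()] for the type.
#' @param chain_id Chain identifier for the emitted residues.
#' @param seq_start First residue number of the tripeptide.
#' @return A list of three [residue_unit] objects (class `conformer`),
#'   with the central residue at index 2.
#' @export
#' @examples
#' trip <- build_residue("LYS", phi_r = -62, psi_r = -41,
#'                       chis = c(180, 180, 180, 180))
#' block_length(trip[[2]])
build_residue <- function(res_type, phi_r = -120, psi_r = 130,
                          chis = numeric(), chain_id = "A", seq_start = 1L) {
  res_type <- toupper(res_type)
  recipes <- .sidechain_recipes()
  rec <- recipes[[res_type]]
  if (is.null(rec)) stop("unknown residue type: ", res_type)
  if (length(chis) != rec$nchi) {
    stop(sprintf("%s takes %d chi torsion(s), got %d",
                 res_type, rec$nchi, length(chis)))
  }
  bb <- .bb
  # flanking-glycine backbone torsions: fixed, arbitrary but sensible
  psi1 <- 150
  phi3 <- -80

  atoms <- list()  # name -> coords, in placement order, per residue index
  put <- function(resi, name, xyz) {
    atoms[[resi]][[name]] <<- xyz
  }
  get3 <- function(resi, name) atoms[[resi]][[name]]
  atoms <- list(list(), list(), list())

  # residue 1 (GLY): seed frame
  put(1L, "N", c(0, 0, 0))
  put(1L, "CA", c(bb$b_n_ca, 0, 0))
  ang <- .deg2rad(bb$a_n_ca_c)
  put(1L, "C", c(bb$b_n_ca - bb$b_ca_c * cos(ang), bb$b_ca_c * sin(ang), 0))
  # residue 2 backbone
  put(2L, "N", place_atom(get3(1L, "N"), get3(1L, "CA"), get3(1L, "C"),
                          bb$b_c_n, bb$a_ca_c_n, psi1))
  put(1L, "O", place_atom(get3(1L, "N"), get3(1L, "CA"), get3(1L, "C"),
                          bb$b_c_o, bb$a_ca_c_o, psi1 + 180))
  put(2L, "CA", place_atom(get3(1L, "CA"), get3(1L, "C"), get3(2L, "N"),
                           bb$b_n_ca, bb$a_c_n_ca, bb$omega))
  put(2L, "C", place_atom(get3(1L, "C"), get3(2L, "N"), get3(2L, "CA"),
                          bb$b_ca_c, bb$a_n_ca_c, phi_r))
  # residue 3 backbone
  put(3L, "N", place_atom(get3(2L, "N"), get3(2L, "CA"), get3(2L, "C"),
                          bb$b_c_n, bb$a_ca_c_n, psi_r))
  put(2L, "O", place_atom(get3(2L, "N"), get3(2L, "CA"), get3(2L, "C"),
                          bb$b_c_o, bb$a_ca_c_o, psi_r + 180))
  put(3L, "CA", place_atom(get3(2L, "CA"), get3(2L, "C"), get3(3L, "N"),
                           bb$b_n_ca, bb$a_c_n_ca, bb$omega))
  put(3L, "C", place_atom(get3(2L, "C"), get3(3L, "N"), get3(3L, "CA"),
                          bb$b_ca_c, bb$a_n_ca_c, phi3))
  put(3L, "O", place_atom(get3(3L, "N"), get3(3L, "CA"), get3(3L, "C"),
                          bb$b_c_o, bb$a_ca_c_o, 0))
  put(3L, "OXT", place_atom(get3(3L, "N"), get3(3L, "CA"), get3(3L, "C"),
                            bb$b_c_o, bb$a_ca_c_o, 180))

  # central side chain
  if (rec$has_cb) {
    # negative improper torsion selects the L configuration
    put(2L, "CB", place_atom(get3(2L, "C"), get3(2L, "N"), get3(2L, "CA"),
                             bb$b_ca_cb, bb$a_n_ca_cb, -.cb_improper()))
  }
  for (p in rec$recipe) {
    tor <- if (is.na(p$tor$chi)) p$tor$off else chis[p$tor$chi] + p$tor$off
    put(2L, p$name, place_atom(get3(2L, p$a), get3(2L, p$b), get3(2L, p$c),
                               p$bond, p$angle, tor))
  }

  types <- c("GLY", res_type, "GLY")
  out <- lapply(1:3, function(i) {
    nm <- names(atoms[[i]])
    ekey <- paste0(types[i], "#", length(nm))
    elems <- .blocklen_cache$elements[[ekey]]
    if (is.null(elems)) {
      elems <- vapply(nm, .element_from_name, "", USE.NAMES = FALSE)
      if (is.null(.blocklen_cache$elements)) .blocklen_cache$elements <- list()
      .blocklen_cache$elements[[ekey]] <- elems
    }
    residue_unit(res_type = types[i], chain_id = chain_id,
                 seq_num = seq_start + i - 1L,
                 atom_names = nm,
                 elements = elems,
                 xyz = do.call(rbind, atoms[[i]]))
  })
  class(out) <- "conformer"
  out
}

#' Central residue of a built tripeptide
#' @param conformer A `conformer` as returned by [build_residue()].
#' @return The central [residue_unit].
#' @export
central_residue <- function(conformer) conformer[[2L]]

# explicit covalent bonds of a conformer, as an index-pair matrix over the
# concatenated atom list; derived from the build recipes (each placed atom
# is bonded to its frame atom c) plus backbone, peptide and ring-closure
# bonds
.conformer_bonds <- function(conformer) {
  recipes <- .sidechain_recipes()
  closure <- list(PHE = list(c("CZ", "CE2")), TYR = list(c("CZ", "CE2")),
                  HIS = list(c("CE1", "NE2")),
                  TRP = list(c("NE1", "CE2"), c("CZ2", "CH2")),
                  PRO = list(c("CD", "N")))
  offset <- 0L
  edges <- list()
  prev_c_idx <- NA_integer_
  for (res in conformer) {
    nm <- res$atom_names
    idx <- function(x) {
      i <- match(x, nm)
      if (is.na(i)) NA_integer_ else offset + i
    }
    bb_pairs <- list(c("N", "CA"), c("CA", "C"), c("C", "O"), c("C", "OXT"),
                     c("CA", "CB"))
    rec <- recipes[[res$res_type]]
    sc_pairs <- if (!is.null(rec)) {
      lapply(rec$recipe, function(p) c(p$c, p$name))
    } else list()
    cl_pairs <- closure[[res$res_type]] %||% list()
    for (pr in c(bb_pairs, sc_pairs, cl_pairs)) {
      i <- idx(pr[1L]); j <- idx(pr[2L])
      if (!is.na(i) && !is.na(j)) edges[[length(edges) + 1L]] <- c(i, j)
    }
    if (!is.na(prev_c_idx) && !is.na(idx("N"))) {
      edges[[length(edges) + 1L]] <- c(prev_c_idx, idx("N"))
    }
    prev_c_idx <- idx("C")
    offset <- offset + length(nm)
  }
  do.call(rbind, edges)
}

#' Steric-clash screen for a built conformer
#'
#' `TRUE` when no pair of heavy atoms separated by three or more covalent
#' bonds lies closer than `threshold`. The covalent graph is taken from
#' the builder's connectivity (backbone, side-chain recipe and ring
#' closures), so 1-2 and 1-3 neighbours never count as clashes.
#'
#' @param conformer A `conformer` (or plain list of [residue_unit]s built
#'   by [build_residue()]).
#' @param threshold Minimum allowed non-bonded distance in Angstrom
#'   (default 2.0; 0 disables the screen).
#' @return Logical scalar.
#' @export
clash_filter <- function(conformer, threshold = 2.0) {
  if (threshold <= 0) return(TRUE)
  xyz <- do.call(rbind, lapply(conformer, function(r) r$xyz))
  n <- nrow(xyz)
  if (n < 2L) return(TRUE)
  key <- paste(c(vapply(conformer, function(r)
    paste0(r$res_type, ":", length(r$atom_names)), "")), collapse = "|")
  mask <- .blocklen_cache$clash_mask[[key]]
  if (is.null(mask)) {
    bonds <- .conformer_bonds(conformer)
    adj <- matrix(FALSE, n, n)
    adj[bonds] <- TRUE
    adj[bonds[, 2:1, drop = FALSE]] <- TRUE
    mask <- adj | ((adj %*% adj) > 0)  # 1-2 and 1-3 neighbours (and self)
    diag(mask) <- TRUE
    if (is.null(.blocklen_cache$clash_mask)) .blocklen_cache$clash_mask <- list()
    .blocklen_cache$clash_mask[[key]] <- mask
  }
  dmat <- as.matrix(stats::dist(xyz))
  near <- dmat < threshold & !mask
  !any(near)
}

#' Specification of a synthetic ground-truth ensemble
#'
#' A recipe for sampling conformers of one residue type from a mixture of
#' torsion components: each component has mean torsions (backbone
#' `phi`/`psi` and the chi vector), a mixture weight, and a per-angle
#' Gaussian noise sigma in degrees.
#'
#' @param res_type Three-letter residue code.
#' @param components List of components, each a list with elements `phi`,
#'   `psi`, `chis` (numeric), `weight` (> 0) and `sigma` (>= 0, degrees).
#' @param n_samples Number of conformers to draw.
#' @param seed Integer RNG seed; the ensemble is fully reproducible.
#' @param clash_threshold Clash-screen distance in Angstrom (see
#'   [clash_filter()]).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(res_type, components, n_samples, seed = 1L,
                           clash_threshold = 2.0) {
  res_type <- toupper(res_type)
  stopifnot(n_samples > 0, length(components) > 0)
  k <- n_chi(res_type)
  for (cm in components) {
    stopifnot(is.numeric(cm$phi), is.numeric(cm$psi),
              length(cm$chis) == k, cm$weight > 0, cm$sigma >= 0)
  }
  w <- vapply(components, `[[`, 0, "weight")
  components <- lapply(components, function(cm) {
    cm$weight <- cm$weight / sum(w)
    cm
  })
  structure(list(res_type = res_type, components = components,
                 n_samples = as.integer(n_samples), seed = as.integer(seed),
                 clash_threshold = clash_threshold),
            class = "synthetic_spec")
}

#' Read / write a synthetic ensemble specification (YAML)
#'
#' @param path Path to a YAML file with keys `res_type`, `n_samples`,
#'   `seed`, `clash_threshold` and a `components` list (each with `phi`,
#'   `psi`, `chis`, `weight`, `sigma`).
#' @return A `synthetic_spec` object.
#' @export
read_synthetic_spec <- function(path) {
  y <- yaml::read_yaml(path)
  synthetic_spec(y$res_type, y$components, y$n_samples,
                 seed = y$seed %||% 1L,
                 clash_threshold = y$clash_threshold %||% 2.0)
}

#' @rdname read_synthetic_spec
#' @param spec A `synthetic_spec` object.
#' @export
write_synthetic_spec <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample a ground-truth conformer ensemble
#'
#' Draws `n_samples` conformers from the torsion mixture in `spec`: for
#' each sample a component is chosen by weight, Gaussian noise of the
#' component's sigma is added independently to every torsion, the
#' conformer is built at ideal geometry, and clashing conformers are
#' redrawn (same component, fresh noise) up to `max_retries` times.
#'
#' @param spec A [synthetic_spec()].
#' @param max_retries Redraw cap per sample (default 100).
#' @return A list with `structures` (list of `conformer` tripeptides) and
#'   `truth`, a data frame with one row per emitted structure: the chosen
#'   component, the exact torsions drawn, the measured dBlock, and the
#'   number of clash redraws.
#' @export
sample_ensemble <- function(spec, max_retries = 100L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  ncomp <- length(spec$components)
  comp_idx <- sample.int(ncomp, spec$n_samples, replace = TRUE,
                         prob = vapply(spec$components, `[[`, 0, "weight"))
  k <- n_chi(spec$res_type)
  bt <- default_block_table()
  structures <- vector("list", spec$n_samples)
  tor_mat <- matrix(NA_real_, spec$n_samples, 2L + k)
  retries_v <- integer(spec$n_samples)
  dblock_v <- numeric(spec$n_samples)
  for (i in seq_len(spec$n_samples)) {
    cm <- spec$components[[comp_idx[i]]]
    retries <- 0L
    repeat {
      tors <- c(cm$phi, cm$psi, cm$chis) +
        stats::rnorm(2L + k, 0, cm$sigma)
      trip <- build_residue(spec$res_type, tors[1L], tors[2L],
                            if (k > 0) tors[-(1:2)] else numeric(),
                            seq_start = 1L)
      if (clash_filter(trip, spec$clash_threshold)) break
      retries <- retries + 1L
      if (retries > max_retries) {
        stop("component ", comp_idx[i], " never passed the clash screen ",
             "after ", max_retries, " redraws")
      }
    }
    structures[[i]] <- trip
    tor_mat[i, ] <- tors
    retries_v[i] <- retries
    dblock_v[i] <- block_length(trip[[2L]], bt)
  }
  truth <- data.frame(sample = seq_len(spec$n_samples),
                      component = comp_idx,
                      phi = tor_mat[, 1L], psi = tor_mat[, 2L],
                      retries = retries_v, dblock = dblock_v)
  if (k > 0) {
    chim <- tor_mat[, -(1:2), drop = FALSE]
    colnames(chim) <- paste0("chi", seq_len(k))
    truth <- cbind(truth, as.data.frame(chim))
  }
  list(structures = structures, truth = truth)
}

#' Write conformers to a PDB file
#'
#' Writes each structure as one MODEL (default) or all structures as
#' consecutive chains of a single model. Coordinates are written with the
#' standard 3-decimal PDB precision, so torsions survive a write/read
#' round trip to within about 0.05 degrees.
#'
#' @param structures A single `conformer` or a list of them (each a list
#'   of [residue_unit]s).
#' @param path Output file path.
#' @param multi_model If `TRUE` (default) one MODEL per structure;
#'   otherwise structures are emitted as chains A, B, ... of one model.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structures, path, multi_model = TRUE) {
  if (inherits(structures, "conformer") ||
      (length(structures) && inherits(structures[[1L]], "residue_unit"))) {
    structures <- list(structures)
  }
  con <- file(path, "w")
  on.exit(close(con))
  fmt_atom <- function(serial, name, res, chain, xyz) {
    # PDB atom-name column rules: 1-3 character names start in column 14
    nm <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
    sprintf("ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, nm, res$res_type, chain, res$seq_num,
            xyz[1L], xyz[2L], xyz[3L], 1, 0, .element_from_name(name))
  }
  nstruct <- length(structures)
  for (s in seq_len(nstruct)) {
    if (multi_model && nstruct > 1L) writeLines(sprintf("MODEL     %4d", s), con)
    chain <- if (multi_model) "A" else LETTERS[((s - 1L) %% 26L) + 1L]
    serial <- 0L
    for (res in structures[[s]]) {
      for (j in seq_along(res$atom_names)) {
        serial <- serial + 1L
        writeLines(fmt_atom(serial, res$atom_names[j], res, chain,
                            res$xyz[j, ]), con)
      }
    }
    writeLines("TER", con)
    if (multi_model && nstruct > 1L) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
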