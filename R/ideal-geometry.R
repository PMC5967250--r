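# Ideal covalent geometry for the conformer builder: Engh-Huber-type bond
# lengths (A) and bond angles (deg) plus per-residue side-chain placement
# recipes in internal coordinates. Each side-chain atom is placed NeRF-style
# from three previously placed reference atoms; its torsion is either a
# free chi variable, a fixed value (planar groups, rings), or a constant
# offset from a chi (branches such as VAL CG2). Aromatic/planar rings are
# laid down as rigid planar templates driven by chi1/chi2 with all ring
# torsions fixed at 0 or 180.

# backbone parameters shared by all residue types
.bb <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_o = 1.231, b_c_n = 1.329,
  a_c_n_ca = 121.7, a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_ca_c_o = 120.8,
  b_ca_cb = 1.530, a_n_ca_cb = 110.4, a_c_ca_cb = 110.5,
  omega = 180)

# torsion spec helpers: chi k (+ offset) or a fixed value
.chi <- function(k, off = 0) list(chi = k, off = off)
.fix <- function(v) list(chi = NA_integer_, off = v)

# one placement row: atom name, frame atoms a, b, c, bond to c, angle b-c-d,
# torsion rule
.pl <- function(name, a, b, c, bond, angle, tor) {
  list(name = name, a = a, b = b, c = c, bond = bond, angle = angle, tor = tor)
}

# six-membered aromatic ring shared by PHE and TYR (CG placed separately):
# a regular planar hexagon (uniform 1.383 A bonds, 120 deg angles), so the
# ring closes exactly
.ring6 <- function(chi2 = 2L) list(
  .pl("CD1", "CA", "CB", "CG", 1.383, 120.0, .chi(chi2)),
  .pl("CD2", "CA", "CB", "CG", 1.383, 120.0, .chi(chi2, 180)),
  .pl("CE1", "CB", "CG", "CD1", 1.383, 120.0, .fix(180)),
  .pl("CE2", "CB", "CG", "CD2", 1.383, 120.0, .fix(180)),
  .pl("CZ",  "CG", "CD1", "CE1", 1.383, 120.0, .fix(0)))

# side-chain recipes beyond CB (CB itself is placed by the backbone code);
# number of free chi torsions per type is recorded alongside
.sidechain_recipes <- function() {
  r <- .blocklen_cache$sidechain_recipes
  if (is.null(r)) {
    r <- .make_sidechain_recipes()
    .blocklen_cache$sidechain_recipes <- r
  }
  r
}

.make_sidechain_recipes <- function() {
  g <- list(.pl("CG", "N", "CA", "CB", 1.520, 114.1, .chi(1L)))
  list(
    GLY = list(recipe = list(), nchi = 0L, has_cb = FALSE),
    ALA = list(recipe = list(), nchi = 0L, has_cb = TRUE),
    SER = list(recipe = list(
      .pl("OG", "N", "CA", "CB", 1.417, 110.8, .chi(1L))), nchi = 1L, has_cb = TRUE),
    CYS = list(recipe = list(
      .pl("SG", "N", "CA", "CB", 1.808, 113.8, .chi(1L))), nchi = 1L, has_cb = TRUE),
    THR = list(recipe = list(
      .pl("OG1", "N", "CA", "CB", 1.433, 109.6, .chi(1L)),
      .pl("CG2", "N", "CA", "CB", 1.521, 110.5, .chi(1L, 238))), nchi = 1L, has_cb = TRUE),
    VAL = list(recipe = list(
      .pl("CG1", "N", "CA", "CB", 1.521, 110.5, .chi(1L)),
      .pl("CG2", "N", "CA", "CB", 1.521, 110.5, .chi(1L, 120))), nchi = 1L, has_cb = TRUE),
    ILE = list(recipe = list(
      .pl("CG1", "N", "CA", "CB", 1.530, 110.4, .chi(1L)),
      .pl("CG2", "N", "CA", "CB", 1.521, 110.5, .chi(1L, 230)),
      .pl("CD1", "CA", "CB", "CG1", 1.513, 113.8, .chi(2L))), nchi = 2L, has_cb = TRUE),
    LEU = list(recipe = list(
      .pl("CG", "N", "CA", "CB", 1.530, 116.3, .chi(1L)),
      .pl("CD1", "CA", "CB", "CG", 1.521, 110.7, .chi(2L)),
      .pl("CD2", "CA", "CB", "CG", 1.521, 110.7, .chi(2L, 120))), nchi = 2L, has_cb = TRUE),
    ASP = list(recipe = list(
      .pl("CG", "N", "CA", "CB", 1.516, 112.6, .chi(1L)),
      .pl("OD1", "CA", "CB", "CG", 1.249, 118.4, .chi(2L)),
      .pl("OD2", "CA", "CB", "CG", 1.249, 118.4, .chi(2L, 180))), nchi = 2L, has_cb = TRUE),
    ASN = list(recipe = list(
      .pl("CG", "N", "CA", "CB", 1.516, 112.6, .chi(1L)),
      .pl("OD1", "CA", "CB", "CG", 1.231, 120.8, .chi(2L)),
      .pl("ND2", "CA", "CB", "CG", 1.328, 116.4, .chi(2L, 180))), nchi = 2L, has_cb = TRUE),
    GLU = list(recipe = c(g, list(
      .pl("CD", "CA", "CB", "CG", 1.516, 112.6, .chi(2L)),
      .pl("OE1", "CB", "CG", "CD", 1.249, 118.4, .chi(3L)),
      .pl("OE2", "CB", "CG", "CD", 1.249, 118.4, .chi(3L, 180)))), nchi = 3L, has_cb = TRUE),
    GLN = list(recipe = c(g, list(
      .pl("CD", "CA", "CB", "CG", 1.516, 112.6, .chi(2L)),
      .pl("OE1", "CB", "CG", "CD", 1.231, 120.8, .chi(3L)),
      .pl("NE2", "CB", "CG", "CD", 1.328, 116.4, .chi(3L, 180)))), nchi = 3L, has_cb = TRUE),
    MET = list(recipe = c(g, list(
      .pl("SD", "CA", "CB", "CG", 1.803, 112.7, .chi(2L)),
      .pl("CE", "CB", "CG", "SD", 1.791, 100.9, .chi(3L)))), nchi = 3L, has_cb = TRUE),
    LYS = list(recipe = c(g, list(
      .pl("CD", "CA", "CB", "CG", 1.520, 111.3, .chi(2L)),
      .pl("CE", "CB", "CG", "CD", 1.520, 111.3, .chi(3L)),
      .pl("NZ", "CG", "CD", "CE", 1.489, 111.9, .chi(4L)))), nchi = 4L, has_cb = TRUE),
    ARG = list(recipe = c(g, list(
      .pl("CD", "CA", "CB", "CG", 1.520, 111.3, .chi(2L)),
      .pl("NE", "CB", "CG", "CD", 1.460, 112.0, .chi(3L)),
      .pl("CZ", "CG", "CD", "NE", 1.329, 124.2, .chi(4L)),
      .pl("NH1", "CD", "NE", "CZ", 1.326, 120.0, .fix(0)),
      .pl("NH2", "CD", "NE", "CZ", 1.326, 120.0, .fix(180)))), nchi = 4L, has_cb = TRUE),
    PHE = list(recipe = c(list(
      .pl("CG", "N", "CA", "CB", 1.502, 113.8, .chi(1L))), .ring6()),
      nchi = 2L, has_cb = TRUE),
    TYR = list(recipe = c(list(
      .pl("CG", "N", "CA", "CB", 1.512, 113.9, .chi(1L))), .ring6(), list(
      .pl("OH", "CD1", "CE1", "CZ", 1.376, 119.9, .fix(180)))),
      nchi = 2L, has_cb = TRUE),
    HIS = list(recipe = list(
      .pl("CG", "N", "CA", "CB", 1.497, 113.8, .chi(1L)),
      .pl("ND1", "CA", "CB", "CG", 1.371, 122.7, .chi(2L)),
      .pl("CD2", "CA", "CB", "CG", 1.356, 131.0, .chi(2L, 180)),
      .pl("CE1", "CB", "CG", "ND1", 1.319, 109.0, .fix(180)),
      .pl("NE2", "CB", "CG", "CD2", 1.374, 107.2, .fix(180))), nchi = 2L, has_cb = TRUE),
    TRP = list(recipe = list(
      .pl("CG", "N", "CA", "CB", 1.498, 113.6, .chi(1L)),
      .pl("CD1", "CA", "CB", "CG", 1.365, 126.9, .chi(2L)),
      .pl("CD2", "CA", "CB", "CG", 1.433, 126.8, .chi(2L, 180)),
      .pl("NE1", "CB", "CG", "CD1", 1.374, 110.2, .fix(180)),
      .pl("CE2", "CB", "CG", "CD2", 1.409, 107.2, .fix(180)),
      .pl("CE3", "CB", "CG", "CD2", 1.398, 133.9, .fix(0)),
      .pl("CZ2", "CG", "CD2", "CE2", 1.394, 122.4, .fix(180)),
      .pl("CZ3", "CG", "CD2", "CE3", 1.382, 118.6, .fix(180)),
      .pl("CH2", "CD2", "CE3", "CZ3", 1.368, 121.1, .fix(0))), nchi = 2L, has_cb = TRUE),
    # PRO ring: fixed endo-pucker template (chi1 ~ -27, chi2 ~ +36); no
    # free torsions are exposed
    PRO = list(recipe = list(
      .pl("CG", "N", "CA", "CB", 1.492, 104.5, .fix(-27)),
      .pl("CD", "CA", "CB", "CG", 1.503, 106.1, .fix(36))), nchi = 0L, has_cb = TRUE)
  )
}

#' Number of free side-chain torsions used by the builder
#'
#' @param res_type Three-letter residue code.
#' @return Integer count of chi torsions the builder accepts for this
#'   type (0 for GLY/ALA/PRO; PRO uses a fixed ring template).
#' @export
n_chi <- function(res_type) {
  rec <- .sidechain_recipes()[[toupper(res_type)]]
  if (is.null(rec)) stop("unknown residue type: ", res_type)
  rec$nchi
}

# torsion (deg) of the C->N->CA->CB improper that realizes the target
# N-CA-CB and C-CA-CB bond angles for an L-amino acid, given N-CA-C.
# Spherical law of cosines about the N-CA axis; the magnitude is returned
# and the builder applies it with negative sign (L configuration, about
# -122 deg in deposited structures).
.cb_improper <- function(a_n_ca_c = .bb$a_n_ca_c, a_n_ca_cb = .bb$a_n_ca_cb,
                         a_c_ca_cb = .bb$a_c_ca_cb) {
  cached <- .blocklen_cache$cb_improper
  if (!is.null(cached) && missing(a_n_ca_c) && missing(a_n_ca_cb) &&
      missing(a_c_ca_cb)) {
    return(cached)
  }
  t1 <- .deg2rad(a_n_ca_c)
  t2 <- .deg2rad(a_n_ca_cb)
  t3 <- .deg2rad(a_c_ca_cb)
  cosd <- (cos(t3) - cos(t1) * cos(t2)) / (sin(t1) * sin(t2))
  cosd <- max(-1, min(1, cosd))
  out <- .rad2deg(acos(cosd))
  if (missing(a_n_ca_c) && missing(a_n_ca_cb) && missing(a_c_ca_cb)) {
    .blocklen_cache$cb_improper <- out
  }
  out
}
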