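# Internal-coordinate geometry: dihedral angles in the 0-360 degree
# convention, and the distal-block length (Calpha to block mass center).

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

.cross3 <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

.norm3 <- function(u) sqrt(sum(u * u))

#' Dihedral angle of four points, reported in [0, 360)
#'
#' Computes the torsion angle defined by points `a-b-c-d` with the IUPAC
#' sign convention (cis = 0, trans = 180), wrapped onto the 0-360 degree
#' range used throughout this package (rather than the signed
#' Ramachandran-style (-180, 180] range; see [to_angle_360()]).
#'
#' @param a,b,c,d Numeric 3-vectors, coordinates in Angstrom.
#' @return Angle in degrees in `[0, 360)`.
#' @details Degenerate quadruples (coincident `b`, `c`, or `a`/`d`
#'   collinear with the `b-c` axis) raise an error of class
#'   `blocklen_degenerate_geometry`; callers that extract features from
#'   structures convert this into a missing feature.
#' @seealso [to_angle_360()], [backbone_phi()], [chi1_angle()]
#' @export
#' @examples
#' dihedral_angle(c(-0.5, 1, 0), c(0, 0, 0), c(1.5, 0, 0), c(2, -1, 0)) # 180
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  nb2 <- .norm3(b2)
  scale <- max(.norm3(b1), nb2, .norm3(b3))
  if (scale == 0 || nb2 < 1e-10 * scale) {
    stop(degenerate_geometry_error("central atoms b and c coincide"))
  }
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  if (.norm3(n1) < 1e-10 * scale^2 || .norm3(n2) < 1e-10 * scale^2) {
    stop(degenerate_geometry_error("collinear atoms in dihedral quadruple"))
  }
  m1 <- .cross3(n1, b2 / nb2)
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2))
  (.rad2deg(ang)) %% 360
}

degenerate_geometry_error <- function(msg) {
  structure(
    class = c("blocklen_degenerate_geometry", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
}

#' Convert a signed Ramachandran-convention angle to the [0, 360) range
#'
#' Angles in this package live on `[0, 360)`: an angle `x` in the usual
#' signed convention maps to `x` when `x >= 0` and to `x + 360` when
#' `x < 0`. The boundary value -180 is treated as 180 (a single
#' representative for the wrap point).
#'
#' @param phi_r Numeric vector of angles in degrees in `[-180, 180]`.
#' @return Angles in degrees in `[0, 360)`.
#' @export
#' @examples
#' to_angle_360(-60)  # 300
#' to_angle_360(120)  # 120
to_angle_360 <- function(phi_r) {
  stopifnot(is.numeric(phi_r), all(is.na(phi_r) | (phi_r >= -180 & phi_r <= 180)))
  out <- ifelse(phi_r < 0, phi_r + 360, phi_r)
  out[!is.na(out) & out == 360] <- 180  # only reachable from -180
  out
}

#' Backbone torsion angles phi and psi
#'
#' `backbone_phi()` is the dihedral C(i-1)-N-CA-C and `backbone_psi()` the
#' dihedral N-CA-C-N(i+1), both reported in `[0, 360)`.
#'
#' @param prev_c,n,ca,c,next_n Numeric 3-vectors (Angstrom). Pass `NULL`
#'   for an absent atom (chain start/end); the result is then `NA`.
#' @return Angle in degrees in `[0, 360)`, or `NA_real_` when an atom is
#'   missing or the geometry is degenerate.
#' @export
backbone_phi <- function(prev_c, n, ca, c) {
  if (is.null(prev_c) || is.null(n) || is.null(ca) || is.null(c)) return(NA_real_)
  .safe_dihedral(prev_c, n, ca, c)
}

#' @rdname backbone_phi
#' @export
backbone_psi <- function(n, ca, c, next_n) {
  if (is.null(n) || is.null(ca) || is.null(c) || is.null(next_n)) return(NA_real_)
  .safe_dihedral(n, ca, c, next_n)
}

.safe_dihedral <- function(a, b, c, d) {
  tryCatch(dihedral_angle(a, b, c, d),
           blocklen_degenerate_geometry = function(e) NA_real_)
}

#' First side-chain torsion chi1 of a residue
#'
#' The dihedral N-CA-CB-Xgamma, where the gamma atom follows the standard
#' convention recorded in the block table (CG for most types, CG1 for
#' ILE/VAL, OG for SER, OG1 for THR, SG for CYS).
#'
#' @param residue A [residue_unit] object.
#' @param block_table A block table as returned by [default_block_table()].
#' @return chi1 in degrees in `[0, 360)`, or `NA_real_` for GLY/ALA or
#'   when a quadruple atom is absent.
#' @export
chi1_angle <- function(residue, block_table = default_block_table()) {
  entry <- block_table[[residue$res_type]]
  if (is.null(entry)) return(NA_real_)
  quad <- lapply(entry$chi1_atoms, function(nm) atom_coords(residue, nm))
  if (any(vapply(quad, is.null, logical(1)))) return(NA_real_)
  .safe_dihedral(quad[[1L]], quad[[2L]], quad[[3L]], quad[[4L]])
}

#' Mass center of a residue's distal block
#'
#' Mass-weighted mean of the distal block's heavy-atom coordinates.
#' Hydrogens are never part of the block definition.
#'
#' @inheritParams chi1_angle
#' @return Numeric 3-vector, or `NULL` when the residue type has no block
#'   (GLY/ALA) or any block atom is absent.
#' @export
block_center <- function(residue, block_table = default_block_table()) {
  entry <- block_table[[residue$res_type]]
  if (is.null(entry)) return(NULL)
  coords <- lapply(entry$block_atoms, function(nm) atom_coords(residue, nm))
  if (any(vapply(coords, is.null, logical(1)))) return(NULL)
  xyz <- do.call(rbind, coords)
  m <- entry$block_masses
  colSums(xyz * m) / sum(m)
}

#' Distal-block length dBlock of a residue
#'
#' Euclidean distance from the residue's CA atom to the mass center of its
#' distal block, in Angstrom. This one-number summary separates extended
#' from folded side-chain conformations.
#'
#' @inheritParams chi1_angle
#' @return Length in Angstrom, or `NA_real_` when CA or a block atom is
#'   missing (and always for GLY/ALA).
#' @export
block_length <- function(residue, block_table = default_block_table()) {
  ca <- atom_coords(residue, "CA")
  ctr <- block_center(residue, block_table)
  if (is.null(ca) || is.null(ctr)) return(NA_real_)
  .norm3(ctr - ca)
}
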