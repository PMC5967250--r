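# Independent oracles used across the test files.

# Rotation-construction oracle for torsion angles: build a quadruple with a
# KNOWN torsion by explicit rotation about the b-c axis, without using any
# package geometry code.
#
# Start from a planar cis quadruple (torsion 0) with the b-c axis along x,
# then rotate d's offset about that axis with the right-hand rotation
# matrix R_x(theta). Sign convention (Klyne-Prelog): looking along the
# b -> c axis (+x), a right-hand rotation about +x moves the far bond
# clockwise as seen by that viewer, which is the positive torsion sense;
# rotating the cis point d0 = c + (0.5, 1, 0) by R_x(+90) gives
# d = c + (0.5, 0, 1) with torsion +90. The trans case (theta = 180) is
# sign-free and anchors the overall convention.
oracle_quadruple <- function(torsion, a = c(-0.5, 1, 0), bond = 1.2,
                             blen = 1.5, offx = 0.5, offy = 1.0) {
  b <- c(0, 0, 0)
  c_ <- c(blen, 0, 0)
  th <- torsion * pi / 180
  rot <- matrix(c(1, 0, 0,
                  0, cos(th), -sin(th),
                  0, sin(th), cos(th)), 3, 3, byrow = TRUE)
  d <- c_ + as.vector(rot %*% c(offx, offy, 0))
  list(a = a, b = b, c = c_, d = d)
}

# random rigid-body transform (proper rotation + translation)
random_rigid_transform <- function() {
  m <- matrix(stats::rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(rot = q, shift = stats::rnorm(3, sd = 10))
}

apply_rigid <- function(x, tf) as.vector(tf$rot %*% x) + tf$shift

# smallest absolute angular difference in degrees
ang_diff <- function(a, b) abs(((a - b + 180) %% 360) - 180)

# residue with one named atom removed (for completeness-rule tests)
drop_atom <- function(residue, name) {
  keep <- residue$atom_names != name
  residue_unit(residue$res_type, residue$chain_id, residue$seq_num,
               residue$ins,
               atom_names = residue$atom_names[keep],
               elements = residue$elements[keep],
               xyz = residue$xyz[keep, , drop = FALSE],
               altlocs = residue$altlocs[keep],
               occupancies = residue$occupancies[keep])
}

# records for a list of built conformers (tripeptides), central residues only
records_from_conformers <- function(conformers, source = "synthetic") {
  res <- lapply(conformers, central_residue)
  # central residues lack neighbours here; measure features directly
  bt <- default_block_table()
  do.call(rbind, lapply(seq_along(conformers), function(i) {
    trip <- conformers[[i]]
    recs <- extract_records(trip, bt, source = source)
    recs[2L, , drop = FALSE]
  }))
}
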