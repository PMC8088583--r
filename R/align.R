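#' Quaternion (Kearsley) rigid-body alignment
#'
#' Superposes every frame onto a reference conformation by the quaternion
#' method: for the atoms of the intermolecular correspondence set (ICS) the
#' optimal rotation is the quaternion given by the eigenvector of the
#' smallest eigenvalue of the 4x4 Kearsley key matrix, which minimizes the
#' RMSD over the ICS by construction and excludes reflections. The rigid
#' transform found on the ICS is applied to *all* atoms of the frame.
#'
#' @param ens a `coord_ensemble`.
#' @param reference_coords numeric vector of length `3m` (defaults to the
#'   reference stored in the ensemble).
#' @param ics integer vector of atom indices forming the correspondence set;
#'   defaults to all atoms. At least 3 non-collinear atoms are required.
#' @return the ensemble with every frame rigid-body transformed and
#'   `aligned = TRUE`; the reference used is stored in `$reference`.
#' @export
quaternion_align <- function(ens, reference_coords = NULL, ics = NULL) {
  stopifnot_ensemble(ens)
  if (is.null(reference_coords)) reference_coords <- ens$reference
  if (is.null(reference_coords)) {
    stop("no reference: supply reference_coords or read frames with a ",
         "reference structure")
  }
  reference_coords <- as.numeric(reference_coords)
  if (length(reference_coords) != nrow(ens$X)) {
    stop("reference_coords must have length 3m = ", nrow(ens$X))
  }
  if (is.null(ics)) ics <- seq_len(n_atoms(ens))
  ics <- as.integer(ics)
  if (any(ics < 1L | ics > n_atoms(ens))) stop("ics indices out of range")
  if (length(ics) < 3L) stop("alignment needs at least 3 ICS atoms")

  ref_xyz <- as_xyz_matrix(reference_coords)
  ref_ics <- ref_xyz[ics, , drop = FALSE]
  ref_cen <- colMeans(ref_ics)
  ref_c <- sweep(ref_ics, 2L, ref_cen)
  if (qr(ref_c)$rank < 2L) {
    stop("ICS atoms are collinear; alignment is under-determined")
  }

  Xout <- ens$X
  for (t in seq_len(n_frames(ens))) {
    fr <- as_xyz_matrix(ens$X[, t])
    mob_ics <- fr[ics, , drop = FALSE]
    mob_cen <- colMeans(mob_ics)
    R <- kearsley_rotation(sweep(mob_ics, 2L, mob_cen), ref_c)
    moved <- sweep(sweep(fr, 2L, mob_cen) %*% t(R), 2L, ref_cen, `+`)
    Xout[, t] <- as.numeric(t(moved))
  }
  ens$X <- Xout
  ens$aligned <- TRUE
  ens$reference <- reference_coords
  ens
}

# Optimal rotation matrix R such that P %*% t(R) best matches Q (both given
# centered, rows = atoms). Kearsley 4x4 key-matrix eigendecomposition; the
# eigenvector of the smallest eigenvalue is the rotation quaternion, and that
# eigenvalue is the residual sum of squares.
kearsley_rotation <- function(P, Q) {
  d <- P - Q
  s <- P + Q
  dx <- d[, 1L]; dy <- d[, 2L]; dz <- d[, 3L]
  sx <- s[, 1L]; sy <- s[, 2L]; sz <- s[, 3L]
  K <- matrix(0, 4L, 4L)
  K[1, 1] <- sum(dx^2 + dy^2 + dz^2)
  K[2, 2] <- sum(sy^2 + sz^2 + dx^2)
  K[3, 3] <- sum(sx^2 + sz^2 + dy^2)
  K[4, 4] <- sum(sx^2 + sy^2 + dz^2)
  K[1, 2] <- K[2, 1] <- sum(sy * dz - sz * dy)
  K[1, 3] <- K[3, 1] <- sum(sz * dx - sx * dz)
  K[1, 4] <- K[4, 1] <- sum(sx * dy - sy * dx)
  K[2, 3] <- K[3, 2] <- sum(dx * dy - sx * sy)
  K[2, 4] <- K[4, 2] <- sum(dx * dz - sx * sz)
  K[3, 4] <- K[4, 3] <- sum(dy * dz - sy * sz)
  eg <- eigen(K, symmetric = TRUE)
  q <- eg$vectors[, 4L]  # smallest eigenvalue last for symmetric eigen()
  q1 <- q[1L]; q2 <- q[2L]; q3 <- q[3L]; q4 <- q[4L]
  t(matrix(c(
    q1^2 + q2^2 - q3^2 - q4^2, 2 * (q2 * q3 + q1 * q4), 2 * (q2 * q4 - q1 * q3),
    2 * (q2 * q3 - q1 * q4), q1^2 + q3^2 - q2^2 - q4^2, 2 * (q3 * q4 + q1 * q2),
    2 * (q2 * q4 + q1 * q3), 2 * (q3 * q4 - q1 * q2), q1^2 + q4^2 - q2^2 - q3^2
  ), nrow = 3L, byrow = TRUE))
}

#' Per-frame RMSD and per-atom / per-residue RMSF
#'
#' RMSD of frame `t` is the root mean (over atoms) squared displacement from
#' the reference conformation. Atom RMSF is the root mean (over frames)
#' squared deviation of the atom from its own mean position; residue RMSF
#' aggregates a residue's atoms by root mean square.
#'
#' @param ens an aligned `coord_ensemble`.
#' @param reference_coords reference conformation (length `3m`); defaults to
#'   the stored reference.
#' @return list with `rmsd` (length `n`, Angstrom), `atom_rmsf` (length `m`),
#'   `residue_rmsf` (one per residue, named by residue id).
#' @export
rmsd_rmsf <- function(ens, reference_coords = NULL) {
  stopifnot_ensemble(ens)
  if (!ens$aligned) {
    stop("ensemble is not aligned; run quaternion_align() first")
  }
  if (is.null(reference_coords)) reference_coords <- ens$reference
  if (is.null(reference_coords)) stop("no reference conformation available")
  m <- n_atoms(ens)
  D <- ens$X - as.numeric(reference_coords)
  rmsd <- sqrt(colSums(D^2) / m)

  mu <- rowMeans(ens$X)
  Dev2 <- (ens$X - mu)^2
  per_dof <- rowMeans(Dev2)                       # mean over frames
  atom_msf <- colSums(matrix(per_dof, nrow = 3L)) # x+y+z per atom
  atom_rmsf <- sqrt(atom_msf)

  rid <- residue_ids(ens)
  res_order <- unique(rid)
  residue_rmsf <- vapply(res_order, function(r) {
    sqrt(mean(atom_msf[rid == r]))
  }, numeric(1))
  names(residue_rmsf) <- res_order
  list(rmsd = stats::setNames(rmsd, ens$frame_ids),
       atom_rmsf = atom_rmsf, residue_rmsf = residue_rmsf)
}
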