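# Synthetic-ensemble generators with known ground truth. Residue geometry is
# deliberately chemistry-free: idealized 4-atom residues (named like backbone
# atoms) laid out on a lattice — only the covariance structure matters to the
# algorithms under test.

#' Idealized atom table for synthetic ensembles
#'
#' `n_residues` residues of `atoms_per_residue` atoms each (default 4, named
#' N, CA, C, O), chain A, placed later by the generators.
#' @noRd
synthetic_atoms <- function(n_residues, atoms_per_residue = 4L) {
  names4 <- c("N", "CA", "C", "O")
  elem4 <- c("N", "C", "C", "O")
  nm <- rep_len(names4, atoms_per_residue)
  el <- rep_len(elem4, atoms_per_residue)
  data.frame(
    serial = seq_len(n_residues * atoms_per_residue),
    atom_name = rep(nm, n_residues),
    residue_name = "GLY",
    residue_number = rep(seq_len(n_residues), each = atoms_per_residue),
    chain_id = "A",
    element = rep(el, n_residues),
    is_hydrogen = FALSE,
    insert = "",
    stringsAsFactors = FALSE
  )
}

# Mean geometry: residue r offset along x by residue_spacing, atoms on a small
# tetrahedron-like pattern.
synthetic_mean_coords <- function(n_residues, atoms_per_residue = 4L,
                                  residue_spacing = 5) {
  local <- matrix(c(0, 0, 0,
                    1.5, 0, 0,
                    1.5, 1.5, 0,
                    0, 1.5, 1.5), ncol = 3L, byrow = TRUE)
  local <- local[rep_len(seq_len(4L), atoms_per_residue), , drop = FALSE]
  coords <- do.call(rbind, lapply(seq_len(n_residues), function(r) {
    sweep(local, 2L, c((r - 1) * residue_spacing, 0, 0), `+`)
  }))
  as.numeric(t(coords))
}

#' Planted covariance model
#'
#' Ground truth for [harmonic_ensemble()]: a set of orthonormal modes with
#' descending eigenvalues (Angstrom squared) over an idealized multi-residue
#' geometry, plus an isotropic noise floor.
#'
#' @param n_residues number of 4-atom residues.
#' @param eigenvalues planted eigenvalues, descending (Angstrom squared).
#' @param noise isotropic per-DOF noise SD added on top (Angstrom).
#' @param seed RNG seed for drawing the random orthonormal modes.
#' @param atoms_per_residue atoms per residue (default 4).
#' @return an object of class `planted_model`: `atoms`, `mean`, `modes`
#'   (orthonormal `3m x k`), `eigenvalues`, `noise`, `seed`.
#' @export
planted_model <- function(n_residues = 5L, eigenvalues = c(4, 1),
                          noise = 0.05, seed = 1L, atoms_per_residue = 4L) {
  if (is.unsorted(rev(eigenvalues))) stop("eigenvalues must be descending")
  atoms <- synthetic_atoms(n_residues, atoms_per_residue)
  d <- 3L * nrow(atoms)
  k <- length(eigenvalues)
  if (k > d) stop("more planted modes than DOF")
  set.seed(seed)
  modes <- qr.Q(qr(matrix(stats::rnorm(d * k), d, k)))
  structure(list(atoms = atoms,
                 mean = synthetic_mean_coords(n_residues, atoms_per_residue),
                 modes = modes, eigenvalues = eigenvalues,
                 noise = noise, seed = seed),
            class = "planted_model")
}

#' Quasi-harmonic ensemble with planted modes
#'
#' Draws `n` frames `X(t) = mean + sum_k sqrt(lambda_k) xi_k(t) v_k + noise`,
#' with `xi` standard normal — a Gaussian ensemble whose population
#' covariance is `sum_k lambda_k v_k v_k^T + noise^2 I`, emulating the
#' quasi-harmonic picture in which PCA modes are the normal modes of an
#' effective harmonic well. Frames are generated in a common coordinate
#' system, so the ensemble is returned `aligned` with the mean geometry as
#' reference; ground truth (planted modes and eigenvalues) rides along in
#' `$ground_truth`.
#'
#' @param model a [planted_model()].
#' @param n number of frames.
#' @param seed RNG seed for the frame draws (defaults to `model$seed + 1`).
#' @return a `coord_ensemble` with a `ground_truth` element.
#' @export
harmonic_ensemble <- function(model, n, seed = NULL) {
  if (!inherits(model, "planted_model")) stop("expected a planted_model")
  if (n < 2L) stop("need n >= 2 frames")
  if (is.null(seed)) seed <- model$seed + 1L
  set.seed(seed)
  d <- length(model$mean)
  k <- length(model$eigenvalues)
  xi <- matrix(stats::rnorm(k * n), k, n)
  X <- model$mean + model$modes %*% (sqrt(model$eigenvalues) * xi)
  if (model$noise > 0) {
    X <- X + matrix(stats::rnorm(d * n, sd = model$noise), d, n)
  }
  ens <- coord_ensemble(model$atoms, X, aligned = TRUE,
                        reference = model$mean)
  ens$ground_truth <- list(modes = model$modes,
                           eigenvalues = model$eigenvalues,
                           noise = model$noise, xi = xi)
  ens
}

#' Rigid-body scramble of an ensemble
#'
#' Applies an independent random rotation and translation to every frame;
#' inter-atomic distances are untouched, so alignment must recover the
#' original (common-frame) ensemble. Exercises the alignment contract.
#'
#' @param ens a `coord_ensemble`.
#' @param seed RNG seed.
#' @return the scrambled ensemble, marked unaligned.
#' @export
rigid_scramble <- function(ens, seed = 1L) {
  stopifnot_ensemble(ens)
  set.seed(seed)
  for (t in seq_len(n_frames(ens))) {
    R <- random_rotation()
    shift <- stats::runif(3L, -10, 10)
    fr <- frame_coords(ens, t)
    ens$X[, t] <- as.numeric(t(sweep(fr %*% t(R), 2L, shift, `+`)))
  }
  ens$aligned <- FALSE
  ens
}

# Uniform random rotation from a normalized Gaussian quaternion.
random_rotation <- function() {
  q <- stats::rnorm(4L)
  q <- q / sqrt(sum(q^2))
  q1 <- q[1L]; q2 <- q[2L]; q3 <- q[3L]; q4 <- q[4L]
  matrix(c(
    q1^2 + q2^2 - q3^2 - q4^2, 2 * (q2 * q3 - q1 * q4), 2 * (q2 * q4 + q1 * q3),
    2 * (q2 * q3 + q1 * q4), q1^2 + q3^2 - q2^2 - q4^2, 2 * (q3 * q4 - q1 * q2),
    2 * (q2 * q4 - q1 * q3), 2 * (q3 * q4 + q1 * q2), q1^2 + q4^2 - q2^2 - q3^2
  ), 3L, 3L, byrow = TRUE)
}

#' Two-residue ensemble with tunable inter-residue coupling
#'
#' Two idealized residues whose leading local motions share a latent factor
#' with correlation `rho`: residue 1 moves along a fixed local direction with
#' amplitude `z1(t)`, residue 2 with `z2 = rho z1 + sqrt(1 - rho^2) e`, plus
#' independent per-DOF noise. `rho = 0` gives statistically independent
#' residues; `rho = 1` perfectly correlated leading motions.
#'
#' The two residues are given distinct leading amplitudes and noise levels so
#' that their local mode spectra are non-degenerate (degenerate spectra leave
#' mode mixing, and hence any coupling score, undefined), and the planted
#' directions are projected off the rigid-body subspace of the pair so that
#' the pair-local alignment step does not convert planted motion into
#' spurious common-mode coupling.
#'
#' @param rho latent correlation in `[0, 1]`.
#' @param n frames.
#' @param seed RNG seed.
#' @param amplitude leading-motion SDs in Angstrom for the two residues
#'   (recycled to length 2).
#' @param noise independent per-DOF noise SDs for the two residues
#'   (recycled to length 2).
#' @return an aligned two-residue `coord_ensemble` (residue numbers 1, 2).
#' @export
coupled_pair_ensemble <- function(rho, n, seed = 1L,
                                  amplitude = c(1, 0.6),
                                  noise = c(0.02, 0.03)) {
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]")
  set.seed(seed)
  amplitude <- rep_len(amplitude, 2L)
  noise <- rep_len(noise, 2L)
  atoms <- synthetic_atoms(2L)
  mean_coords <- synthetic_mean_coords(2L)
  d <- length(mean_coords)
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  rigid <- rigid_body_basis(mean_coords)
  dir1 <- nonrigid_unit_vector(d, dof_rows(1:4), rigid)
  dir2 <- nonrigid_unit_vector(d, dof_rows(5:8), rigid)
  noise_mat <- matrix(stats::rnorm(d * n), d, n) *
    rep(rep(noise, each = 12L), n)
  X <- mean_coords +
    amplitude[1L] * dir1 %*% t(z1) + amplitude[2L] * dir2 %*% t(z2) +
    noise_mat
  ens <- coord_ensemble(atoms, X, aligned = TRUE, reference = mean_coords)
  ens$ground_truth <- list(rho = rho, dir1 = dir1, dir2 = dir2)
  ens
}

# Orthonormal basis of the 6 rigid-body displacement modes (3 translations,
# 3 infinitesimal rotations about the centroid) of a structure.
rigid_body_basis <- function(coords) {
  xyz <- as_xyz_matrix(coords)
  m <- nrow(xyz)
  cen <- colMeans(xyz)
  rel <- sweep(xyz, 2L, cen)
  Tx <- rep(c(1, 0, 0), m); Ty <- rep(c(0, 1, 0), m); Tz <- rep(c(0, 0, 1), m)
  rot <- function(axis) {
    as.numeric(t(t(apply(rel, 1L, function(r) pracma_cross(axis, r)))))
  }
  B <- cbind(Tx, Ty, Tz, rot(c(1, 0, 0)), rot(c(0, 1, 0)), rot(c(0, 0, 1)))
  qr.Q(qr(B))[, seq_len(qr(B)$rank), drop = FALSE]
}

pracma_cross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Random unit vector supported on the given rows and orthogonal to the whole
# structure's rigid subspace. Support is preserved by orthogonalizing against
# the rigid modes' restriction to those rows (a vector supported on the rows
# is orthogonal to a full mode iff it is orthogonal to its restriction).
nonrigid_unit_vector <- function(d, rows, rigid) {
  Rl <- rigid[rows, , drop = FALSE]
  Ql <- qr.Q(qr(Rl))[, seq_len(qr(Rl)$rank), drop = FALSE]
  repeat {
    w <- stats::rnorm(length(rows))
    w <- w - Ql %*% crossprod(Ql, w)
    nv <- sqrt(sum(w^2))
    if (nv > 1e-8) {
      v <- numeric(d)
      v[rows] <- w / nv
      return(v)
    }
  }
}

# Unit vector supported on the given rows (drawn from the current RNG
# stream; seed_offset just decorrelates repeated calls).
unit_vector <- function(d, rows, seed_offset = 0L) {
  v <- numeric(d)
  v[rows] <- stats::rnorm(length(rows))
  v / sqrt(sum(v^2))
}

#' Duplicated-residue ensemble (perfect coupling fixture)
#'
#' One synthetic residue trajectory, duplicated as a second residue whose
#' coordinates are *exactly* those of the first in every frame — the
#' calibration case in which the pair coupling score must be maximal. The
#' spatial duplication (overlapping atoms) is a synthetic construct, not a
#' physical structure.
#'
#' @param n frames.
#' @param seed RNG seed.
#' @param amplitude,noise as in [coupled_pair_ensemble()].
#' @return an aligned two-residue `coord_ensemble` in which residue 2's
#'   trajectory equals residue 1's.
#' @export
duplicated_residue_ensemble <- function(n, seed = 1L, amplitude = 1,
                                        noise = 0.1) {
  set.seed(seed)
  atoms <- synthetic_atoms(2L)
  mean1 <- synthetic_mean_coords(1L)
  d1 <- length(mean1)
  z <- stats::rnorm(n)
  dir <- unit_vector(d1, seq_len(d1))
  X1 <- mean1 + amplitude * dir %*% t(z) +
    matrix(stats::rnorm(d1 * n, sd = noise), d1, n)
  X <- rbind(X1, X1)
  coord_ensemble(atoms, X, aligned = TRUE, reference = c(mean1, mean1))
}

#' Plant outlier frames in an ensemble
#'
#' Displaces the selected frames along a dedicated direction (a random sign
#' pattern, scaled per DOF) by `magnitude x` that DOF's sample SD — emulating
#' a burst of rare-event motion (e.g. early-simulation relaxation) whose
#' score exceeds any threshold below `magnitude` on every DOF. The truth is
#' recorded in the returned `outlier_ledger`.
#'
#' @param ens a `coord_ensemble`.
#' @param frames integer indices of frames to corrupt.
#' @param magnitude displacement in per-DOF SD units.
#' @param seed RNG seed for the direction.
#' @return the corrupted ensemble, with `$outlier_ledger` (frames, direction,
#'   magnitude).
#' @export
plant_outliers <- function(ens, frames, magnitude, seed = 1L) {
  stopifnot_ensemble(ens)
  frames <- as.integer(frames)
  if (any(frames < 1L | frames > n_frames(ens))) {
    stop("frames must index existing frames")
  }
  set.seed(seed)
  d <- nrow(ens$X)
  signs <- sample(c(-1, 1), d, replace = TRUE)
  sd_dof <- sqrt(rowSums((ens$X - rowMeans(ens$X))^2) / (n_frames(ens) - 1))
  shift <- magnitude * sd_dof * signs
  u <- shift / sqrt(sum(shift^2))
  ens$X[, frames] <- ens$X[, frames] + shift
  ens$outlier_ledger <- list(frames = frames, direction = u,
                             magnitude = magnitude)
  ens
}
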