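#' Coordinate ensemble
#'
#' The central container of the package: an ordered atom table plus a
#' `3m x n` coordinate matrix holding `n` conformations (frames) of the same
#' `m` atoms, in Angstrom. Rows are `(x, y, z)` triplets in atom order; each
#' column is one frame, so column `t` is the conformation vector `X(t)`.
#'
#' @param atoms data.frame with columns `serial`, `atom_name`, `residue_name`,
#'   `residue_number`, `chain_id`, `element`, `is_hydrogen` (and optionally
#'   `insert`). One row per atom, in coordinate-row order.
#' @param X numeric matrix, `3m x n`.
#' @param frame_ids character vector of `n` frame labels.
#' @param aligned logical; whether frames share a common rigid-body frame
#'   (set by [quaternion_align()] or by generators that produce pre-aligned
#'   coordinates).
#' @param reference optional numeric vector of length `3m`: the reference
#'   conformation the ensemble is (or is to be) aligned against.
#'
#' @return An object of class `coord_ensemble`: a list with elements `atoms`,
#'   `X`, `frame_ids`, `aligned`, and optionally `reference`.
#' @export
coord_ensemble <- function(atoms, X, frame_ids = NULL, aligned = FALSE,
                           reference = NULL) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  needed <- c("serial", "atom_name", "residue_name", "residue_number",
              "chain_id", "element", "is_hydrogen")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols) > 0L) {
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!("insert" %in% names(atoms))) atoms$insert <- ""
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (nrow(X) != 3L * nrow(atoms)) {
    stop("coordinate matrix has ", nrow(X), " rows but the atom table implies ",
         3L * nrow(atoms))
  }
  if (anyDuplicated(atoms$serial)) stop("atom serials must be unique")
  if (is.null(frame_ids)) frame_ids <- as.character(seq_len(ncol(X)))
  if (length(frame_ids) != ncol(X)) {
    stop("frame_ids length must equal the number of frames")
  }
  if (!is.null(reference)) {
    reference <- as.numeric(reference)
    if (length(reference) != nrow(X)) {
      stop("reference must have length 3m = ", nrow(X))
    }
  }
  structure(
    list(atoms = atoms, X = X, frame_ids = as.character(frame_ids),
         aligned = isTRUE(aligned), reference = reference),
    class = "coord_ensemble"
  )
}

#' @export
print.coord_ensemble <- function(x, ...) {
  cat("<coord_ensemble> ", n_atoms(x), " atoms (", nrow(x$X), " DOF), ",
      n_frames(x), " frames, ", length(unique(residue_ids(x))), " residues; ",
      if (x$aligned) "aligned" else "not aligned", "\n", sep = "")
  invisible(x)
}

#' Number of frames / atoms in an ensemble
#' @param ens a `coord_ensemble`
#' @return integer count.
#' @export
n_frames <- function(ens) ncol(ens$X)

#' @rdname n_frames
#' @export
n_atoms <- function(ens) nrow(ens$atoms)

#' Residue identifiers in atom order
#'
#' A residue is identified by chain, residue number and insertion code.
#'
#' @param ens a `coord_ensemble`
#' @return character vector, one entry per atom.
#' @export
residue_ids <- function(ens) {
  ins <- ens$atoms$insert
  ins[is.na(ins)] <- ""
  paste(ens$atoms$chain_id, ens$atoms$residue_number, ins, sep = "|")
}

# Coordinate-matrix row indices for a set of atom indices.
dof_rows <- function(atom_idx) {
  as.vector(rbind(3L * atom_idx - 2L, 3L * atom_idx - 1L, 3L * atom_idx))
}

# One frame as an m x 3 matrix of atomic positions.
frame_coords <- function(ens, t) {
  matrix(ens$X[, t], ncol = 3L, byrow = TRUE)
}

# m x 3 layout of an arbitrary 3m vector.
as_xyz_matrix <- function(v) matrix(v, ncol = 3L, byrow = TRUE)

stopifnot_ensemble <- function(ens) {
  if (!inherits(ens, "coord_ensemble")) stop("expected a coord_ensemble")
  invisible(ens)
}

#' Restrict an ensemble to a set of atoms
#'
#' Internal workhorse behind [select_subset()]; keeps atom order.
#' @noRd
subset_atoms <- function(ens, atom_idx) {
  atom_idx <- sort(unique(as.integer(atom_idx)))
  coord_ensemble(ens$atoms[atom_idx, , drop = FALSE],
                 ens$X[dof_rows(atom_idx), , drop = FALSE],
                 frame_ids = ens$frame_ids, aligned = ens$aligned,
                 reference = if (!is.null(ens$reference))
                   ens$reference[dof_rows(atom_idx)] else NULL)
}

#' Centered data matrix
#'
#' Returns the mean-centered data matrix `A = X - <X>` (per-DOF mean over
#' frames subtracted), the quantity from which all statistical models are
#' built.
#'
#' @param ens a `coord_ensemble` or a plain numeric matrix (features x frames).
#' @return numeric matrix of the same dimension as the coordinate matrix.
#' @export
centered_data <- function(ens) {
  X <- if (inherits(ens, "coord_ensemble")) ens$X else as.matrix(ens)
  X - rowMeans(X)
}

#' Pool multiple trajectories into one ensemble
#'
#' Concatenates the frames of several ensembles that share an identical atom
#' list, then optionally down-samples by keeping every `stride`-th frame.
#' Frame ids are prefixed with the source trajectory index so provenance
#' survives pooling.
#'
#' @param ens_list list of `coord_ensemble` objects with identical atom lists
#'   (same serials, names, residues, order).
#' @param downsample_stride keep every `stride`-th frame of the pooled set
#'   (default 1 = keep all).
#' @return a pooled `coord_ensemble` (marked unaligned unless every input was
#'   aligned to the same stored reference).
#' @export
pool_trajectories <- function(ens_list, downsample_stride = 1L) {
  if (!length(ens_list)) stop("no ensembles to pool")
  lapply(ens_list, stopifnot_ensemble)
  ref <- ens_list[[1L]]
  key <- function(e) {
    do.call(paste, c(e$atoms[c("serial", "atom_name", "residue_name",
                               "residue_number", "chain_id")], sep = "|"))
  }
  k0 <- key(ref)
  for (i in seq_along(ens_list)) {
    if (!identical(key(ens_list[[i]]), k0)) {
      stop("ensemble ", i, " has a different atom list; trajectories can ",
           "only be pooled when atoms are identical and identically ordered")
    }
  }
  X <- do.call(cbind, lapply(ens_list, function(e) e$X))
  ids <- unlist(lapply(seq_along(ens_list), function(i) {
    paste0("traj", i, ":", ens_list[[i]]$frame_ids)
  }), use.names = FALSE)
  stride <- as.integer(downsample_stride)
  if (is.na(stride) || stride < 1L) stop("downsample_stride must be >= 1")
  keep <- seq(1L, ncol(X), by = stride)
  aligned_all <- all(vapply(ens_list, function(e) e$aligned, logical(1)))
  coord_ensemble(ref$atoms, X[, keep, drop = FALSE], frame_ids = ids[keep],
                 aligned = aligned_all, reference = ref$reference)
}
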