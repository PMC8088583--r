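#' Per-residue eigenresidues and residuePCs
#'
#' Level one of hierarchical PCA: within one global alignment, each residue's
#' mean-centered local coordinates are decomposed by covariance PCA. The top
#' `h` local eigenvectors are that residue's *eigenresidues* and the
#' corresponding generalized-coordinate time series `C_r = U_r^T A_r` its
#' *residuePCs*. A residue with fewer than `h` available local DOF (limited
#' by `3 m_r` and by the `n - 1` sample rank) contributes its full rank
#' `h_r` instead of erroring.
#'
#' Re-alignment per residue is forbidden: a single coordinate system must be
#' used for the whole region, so the input must already be aligned.
#'
#' @param ens an aligned `coord_ensemble`.
#' @param residue_partition optional list of atom-index vectors, one per
#'   residue (default: residues in order of first appearance).
#' @param h number of eigenresidues per residue (default 3).
#' @return an object of class `eigenresidue_set`: per residue `U` (3m_r x
#'   h_r, orthonormal columns), `values` (local eigenvalues, Angstrom
#'   squared), `C` (h_r x n residuePCs), `rows` (coordinate rows in the
#'   global DOF space); plus `residues`, `h`, `n`.
#' @export
compute_eigenresidues <- function(ens, residue_partition = NULL, h = 3L) {
  stopifnot_ensemble(ens)
  if (!ens$aligned) {
    stop("ensemble is not aligned; hierarchical PCA requires one global ",
         "alignment (per-residue re-alignment is forbidden)")
  }
  h <- as.integer(h)
  if (h < 1L) stop("h must be at least 1")
  if (is.null(residue_partition)) {
    rid <- residue_ids(ens)
    residue_partition <- split(seq_len(n_atoms(ens)),
                               factor(rid, levels = unique(rid)))
  }
  n <- n_frames(ens)
  per_res <- lapply(residue_partition, function(atom_idx) {
    rows <- dof_rows(atom_idx)
    Ar <- ens$X[rows, , drop = FALSE]
    Ar <- Ar - rowMeans(Ar)
    Qr <- tcrossprod(Ar) / (n - 1)
    eg <- eigen(Qr, symmetric = TRUE)
    hr <- min(h, length(rows), n - 1L)
    U <- fix_eigenvector_signs(eg$vectors[, seq_len(hr), drop = FALSE])
    list(U = U, values = eg$values[seq_len(hr)],
         C = crossprod(U, Ar), rows = rows, h_r = hr)
  })
  structure(list(residues = names(residue_partition), per_res = per_res,
                 h = h, n = n, d = nrow(ens$X)),
            class = "eigenresidue_set")
}

#' @export
print.eigenresidue_set <- function(x, ...) {
  hr <- vapply(x$per_res, `[[`, integer(1), "h_r")
  cat("<eigenresidue_set> ", length(x$per_res), " residues, h = ", x$h,
      " (per-residue rank ", min(hr), "-", max(hr), "), ", x$n, " frames\n",
      sep = "")
  invisible(x)
}

#' Hierarchical PCA over distributed DOF
#'
#' Level two: all residuePCs are stacked into a `(sum h_r) x n` matrix of
#' generalized coordinates, a level-2 covariance matrix is built and
#' decomposed, and each level-2 eigenvector is convoluted with the
#' eigenresidues (block-diagonal `U_r`) back to a mode in atomic coordinate
#' space. Because the block-diagonal map has orthonormal columns, the
#' returned atomic modes are orthonormal; eigenvalues are those of the
#' level-2 decomposition. With `h` equal to every residue's full local rank
#' this reproduces direct covariance PCA exactly.
#'
#' @param ers an `eigenresidue_set`.
#' @param top_k essential-subspace size to record (all modes are returned).
#' @return a `mode_set` in atomic coordinates (dimension = total DOF of the
#'   residues analyzed).
#' @export
hpca <- function(ers, top_k = NULL) {
  if (!inherits(ers, "eigenresidue_set")) stop("expected an eigenresidue_set")
  ns <- vapply(ers$per_res, function(r) ncol(r$C), integer(1))
  if (length(unique(ns)) != 1L) {
    stop("inconsistent frame counts across residues")
  }
  C <- do.call(rbind, lapply(ers$per_res, `[[`, "C"))
  n <- ncol(C)
  G <- tcrossprod(C - rowMeans(C)) / (n - 1)
  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  B <- eg$vectors

  hr <- vapply(ers$per_res, `[[`, integer(1), "h_r")
  blk_end <- cumsum(hr)
  blk_start <- blk_end - hr + 1L
  V <- matrix(0, nrow = ers$d, ncol = ncol(B))
  for (r in seq_along(ers$per_res)) {
    pr <- ers$per_res[[r]]
    V[pr$rows, ] <- V[pr$rows, ] +
      pr$U %*% B[blk_start[r]:blk_end[r], , drop = FALSE]
  }
  V <- fix_eigenvector_signs(V)
  vals <- eg$values
  total <- sum(vals)
  vf <- if (total != 0) vals / total else rep(0, length(vals))
  if (is.null(top_k)) top_k <- length(vals)
  structure(list(
    values = vals, vectors = V,
    variance_fraction = vf, cumulative_fraction = cumsum(vf),
    top_k = min(as.integer(top_k), length(vals)),
    source = list(kind = "Q", provenance = list(hierarchical = TRUE, h = ers$h)),
    flagged = rep(FALSE, length(vals))
  ), class = "mode_set")
}

#' Serialize an eigenresidue set (per-residue matrices + manifest)
#' @param ers an `eigenresidue_set`.
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
write_eigenresidue_set <- function(ers, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(residue = ers$residues,
                         h_r = vapply(ers$per_res, `[[`, integer(1), "h_r"),
                         dof = vapply(ers$per_res, function(r)
                           length(r$rows), integer(1)))
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (r in seq_along(ers$per_res)) {
    pr <- ers$per_res[[r]]
    base <- sprintf("residue_%04d", r)
    utils::write.table(pr$U, file.path(dir, paste0(base, "_eigenresidues.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    utils::write.table(pr$C, file.path(dir, paste0(base, "_residuePCs.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(dir)
}
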