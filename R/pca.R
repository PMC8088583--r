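#' Spectral decomposition of a statistical model
#'
#' Full eigendecomposition with eigenvalues sorted descending and a
#' deterministic sign convention: each eigenvector is scaled so its
#' largest-magnitude component is positive, making decompositions
#' reproducible across runs. Variance fractions are eigenvalues over their
#' sum; for correlation models, modes with eigenvalue greater than 1 are
#' flagged as carrying more variance than any single original variable.
#'
#' @param model a `stat_model` or symmetric matrix.
#' @param top_k number of modes to retain for reporting (all are kept in the
#'   object; `top_k` only records the requested essential-subspace size).
#' @return an object of class `mode_set`: list with `values`, `vectors`
#'   (orthonormal columns), `variance_fraction`, `cumulative_fraction`,
#'   `top_k`, `source` (kind + provenance), `flagged` (logical per mode,
#'   correlation models only).
#' @export
spectral_decompose <- function(model, top_k = NULL) {
  M <- model_matrix(model)
  if (nrow(M) != ncol(M)) stop("model matrix must be square")
  asym <- max(abs(M - t(M)))
  if (asym > 1e-8 * max(1, max(abs(M)))) {
    stop("matrix is not symmetric beyond tolerance")
  }
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  V <- fix_eigenvector_signs(eg$vectors)
  vals <- eg$values
  total <- sum(vals)
  vf <- if (total != 0) vals / total else rep(0, length(vals))
  kind <- if (inherits(model, "stat_model")) model$kind else NA_character_
  prov <- if (inherits(model, "stat_model")) model$provenance else list()
  if (is.null(top_k)) top_k <- length(vals)
  top_k <- min(as.integer(top_k), length(vals))
  structure(list(
    values = vals, vectors = V,
    variance_fraction = vf, cumulative_fraction = cumsum(vf),
    top_k = top_k,
    source = list(kind = kind, provenance = prov),
    flagged = if (identical(kind, "R")) vals > 1 else rep(FALSE, length(vals))
  ), class = "mode_set")
}

# Largest-magnitude component positive; exact ties broken by the first
# differing component so the convention is total.
fix_eigenvector_signs <- function(V) {
  for (j in seq_len(ncol(V))) {
    a <- abs(V[, j])
    i <- which(a == max(a))[1L]
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

#' @export
print.mode_set <- function(x, ...) {
  k <- min(x$top_k, 5L)
  cat("<mode_set> ", length(x$values), " modes (source ",
      x$source$kind %||% "?", "); top eigenvalues: ",
      paste(signif(x$values[seq_len(k)], 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Per-mode mean square fluctuations
#'
#' For a Cartesian mode the MSF of atom `a` is the sum of its three squared
#' eigenvector components; because each mode is a unit vector, the atom MSFs
#' of one mode sum to 1. The combined MSF over the requested top modes
#' weights each mode's atom MSF by its eigenvalue fraction among those modes.
#'
#' @param modes a `mode_set` from a Cartesian model (`d = 3m`).
#' @param atom_count number of atoms `m`.
#' @param top_k number of modes for the combined profile (default
#'   `modes$top_k`).
#' @return list with `per_mode` (`m x top_k` matrix) and `combined`
#'   (length-`m` vector).
#' @export
mode_msf <- function(modes, atom_count, top_k = NULL) {
  d <- nrow(modes$vectors)
  if (d != 3L * atom_count) {
    stop("mode dimension ", d, " is not 3 x ", atom_count,
         "; not a Cartesian mode set")
  }
  if (is.null(top_k)) top_k <- modes$top_k
  top_k <- min(top_k, ncol(modes$vectors))
  V <- modes$vectors[, seq_len(top_k), drop = FALSE]
  per_mode <- apply(V^2, 2L, function(v) colSums(matrix(v, nrow = 3L)))
  per_mode <- matrix(per_mode, nrow = atom_count)
  lam <- modes$values[seq_len(top_k)]
  w <- if (sum(lam) != 0) lam / sum(lam) else rep(1 / top_k, top_k)
  combined <- as.numeric(per_mode %*% w)
  list(per_mode = per_mode, combined = combined)
}

#' Project conformations onto PC modes
#'
#' Principal components use the ensemble mean as origin; displacement vector
#' projections (DVPs) use a chosen reference conformation. Projections are
#' raw dot products of the displacement with each mode (no eigenvalue
#' normalization). Frames are labeled by trajectory quarter (4 equal
#' contiguous blocks, remainder in the last) for time-resolved coloring.
#'
#' @param ens an aligned `coord_ensemble` (aligned with the same reference
#'   used to build the model).
#' @param modes a `mode_set`.
#' @param origin `"ensemble_mean"` (PCs) or `"reference_frame"` (DVPs).
#' @param top_k number of modes to project onto.
#' @param reference_coords origin conformation for `"reference_frame"`
#'   (defaults to the ensemble's stored reference).
#' @return an object of class `projection_table`: list with `proj`
#'   (`n x top_k` matrix), `origin`, `quarter` (factor of length `n`),
#'   `frame_ids`.
#' @export
project <- function(ens, modes, origin = c("ensemble_mean", "reference_frame"),
                    top_k = NULL, reference_coords = NULL) {
  origin <- match.arg(origin)
  X <- if (inherits(ens, "coord_ensemble")) ens$X else as.matrix(ens)
  if (nrow(X) != nrow(modes$vectors)) {
    stop("ensemble DOF (", nrow(X), ") and mode dimension (",
         nrow(modes$vectors), ") disagree")
  }
  if (is.null(top_k)) top_k <- modes$top_k
  top_k <- min(top_k, ncol(modes$vectors))
  o <- if (origin == "ensemble_mean") {
    rowMeans(X)
  } else {
    rc <- reference_coords
    if (is.null(rc) && inherits(ens, "coord_ensemble")) rc <- ens$reference
    if (is.null(rc)) stop("reference_frame origin needs reference_coords")
    as.numeric(rc)
  }
  V <- modes$vectors[, seq_len(top_k), drop = FALSE]
  proj <- t(crossprod(V, X - o))
  colnames(proj) <- paste0("PC", seq_len(top_k))
  n <- ncol(X)
  structure(list(proj = proj, origin = origin,
                 quarter = quarter_labels(n),
                 frame_ids = if (inherits(ens, "coord_ensemble"))
                   ens$frame_ids else as.character(seq_len(n))),
            class = "projection_table")
}

# 4 equal contiguous blocks; remainder goes to the last block.
quarter_labels <- function(n) {
  base <- n %/% 4L
  sizes <- c(base, base, base, n - 3L * base)
  factor(rep(paste0("Q", 1:4), times = sizes), levels = paste0("Q", 1:4))
}

#' @export
print.projection_table <- function(x, ...) {
  cat("<projection_table> ", nrow(x$proj), " frames x ", ncol(x$proj),
      " modes (origin: ", x$origin, ")\n", sep = "")
  invisible(x)
}

#' Distance-pair features for dpPCA
#'
#' Euclidean distances of the requested atom pairs in every frame. Distances
#' are invariant under rigid-body motion, so no alignment is required; the
#' resulting `p x n` matrix feeds [sample_covariance()] and the rest of the
#' model pipeline unchanged.
#'
#' @param ens a `coord_ensemble` (aligned or not).
#' @param pairs two-column matrix of atom serials.
#' @return numeric matrix, pairs by frames, in Angstrom, with row names
#'   `"serial_i-serial_j"`.
#' @export
distance_pair_features <- function(ens, pairs) {
  stopifnot_ensemble(ens)
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) stop("pairs must have two columns")
  if (any(pairs[, 1L] == pairs[, 2L])) stop("self-pair (i,i) is not allowed")
  i <- match(pairs[, 1L], ens$atoms$serial)
  j <- match(pairs[, 2L], ens$atoms$serial)
  if (anyNA(i) || anyNA(j)) {
    bad <- unique(c(pairs[, 1L][is.na(i)], pairs[, 2L][is.na(j)]))
    stop("atom serial(s) not in ensemble: ", paste(bad, collapse = ", "))
  }
  F <- matrix(0, nrow = nrow(pairs), ncol = n_frames(ens))
  for (p in seq_len(nrow(pairs))) {
    di <- ens$X[dof_rows(i[p]), , drop = FALSE] -
      ens$X[dof_rows(j[p]), , drop = FALSE]
    F[p, ] <- sqrt(colSums(di^2))
  }
  rownames(F) <- paste0(pairs[, 1L], "-", pairs[, 2L])
  F
}

#' Split an ensemble into inlier and outlier ensembles
#'
#' Scores every entry of the data matrix per DOF (z or MAD score). Values
#' whose score exceeds the threshold are outliers. The inlier ensemble is the
#' original with outlying values replaced by the DOF mean (median in MAD
#' mode); the outlier ensemble replaces the inlying values instead. Both feed
#' the normal model pipeline, and comparing the two essential subspaces
#' quantifies the influence of rare events. A z-score threshold in
#' `[0.675, 1.96]` is the recommended working range.
#'
#' @param ens a `coord_ensemble`.
#' @param threshold positive score cutoff.
#' @param score `"z"` or `"mad"`.
#' @return list with `inliers`, `outliers` (both `coord_ensemble`) and
#'   `outlier_mask` (logical `3m x n` matrix; TRUE = outlying value).
#' @export
filter_inlier_outlier <- function(ens, threshold = 1.96,
                                  score = c("z", "mad")) {
  score <- match.arg(score)
  stopifnot_ensemble(ens)
  if (!is.numeric(threshold) || threshold <= 0) {
    stop("threshold must be positive")
  }
  sc <- dof_scores(ens$X, if (score == "z") "mean" else "median")
  if (any(sc$spread == 0)) {
    warning("DOF with zero spread: scores treated as 0 (all inlier)")
  }
  mask <- abs(sc$score) > threshold
  repl <- sc$center[row(ens$X)]
  Xin <- ens$X; Xin[mask] <- repl[mask]
  Xout <- ens$X; Xout[!mask] <- repl[!mask]
  inl <- ens; inl$X <- Xin
  outl <- ens; outl$X <- Xout
  list(inliers = inl, outliers = outl, outlier_mask = mask)
}

#' Write a mode set (eigenvalue table + top eigenvectors) as TSV
#' @param modes a `mode_set`.
#' @param dir output directory (created if needed).
#' @param top_k how many eigenvector columns to write.
#' @return invisibly, the directory.
#' @export
write_mode_set <- function(modes, dir, top_k = modes$top_k) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- data.frame(mode = seq_along(modes$values),
                    eigenvalue = modes$values,
                    variance_fraction = modes$variance_fraction,
                    cumulative_fraction = modes$cumulative_fraction,
                    flagged = modes$flagged)
  utils::write.table(tab, file.path(dir, "eigenvalues.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  top_k <- min(top_k, ncol(modes$vectors))
  utils::write.table(modes$vectors[, seq_len(top_k), drop = FALSE],
                     file.path(dir, "top_eigenvectors.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Write a projection table as TSV (frame id, quarter label, projections)
#' @param pt a `projection_table`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_projection_table <- function(pt, path) {
  df <- data.frame(frame = pt$frame_ids, quarter = pt$quarter, pt$proj,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
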