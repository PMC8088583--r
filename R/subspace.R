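#' Sparsify a correlation or partial-correlation matrix
#'
#' Sets off-diagonal entries whose magnitude is below the threshold to zero;
#' low correlations are the ones most susceptible to noise, so zeroing them
#' accentuates the strongly correlated motions. The diagonal is never
#' touched (the model must remain decomposable). Sparsified matrices may
#' lose positive semidefiniteness; decomposition proceeds and any negative
#' eigenvalues are reported, not clipped.
#'
#' @param model a `stat_model` of kind `R` or `P`.
#' @param threshold magnitude cutoff in `[0, 1]`.
#' @return the sparsified `stat_model`; provenance records the threshold.
#' @export
sparsify <- function(model, threshold) {
  if (!inherits(model, "stat_model") || !(model$kind %in% c("R", "P"))) {
    stop("sparsification applies to correlation (R) or partial-correlation ",
         "(P) models")
  }
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1) {
    stop("threshold must lie in [0, 1]")
  }
  M <- model$M
  off <- !diag(nrow(M))
  M[off & abs(M) < threshold] <- 0
  prov <- model$provenance
  prov$sparsify_threshold <- threshold
  stat_model(model$kind, M, prov)
}

#' Activator / suppressor map
#'
#' Compares corresponding entries of the partial-correlation and correlation
#' models: where the partial correlation exceeds the raw correlation by more
#' than the threshold, other variables are *suppressing* that pairwise
#' correlation (the map shows +1, "activation" once conditioned); where the
#' raw correlation exceeds the partial one, other variables *enhance* it
#' (-1). The diagonal is 0.
#'
#' @param P,R `stat_model` objects (or matrices) of the same dimension.
#' @param threshold positive difference cutoff.
#' @return integer matrix with entries in `{-1, 0, +1}`.
#' @export
activator_suppressor_map <- function(P, R, threshold) {
  Pm <- model_matrix(P)
  Rm <- model_matrix(R)
  if (!all(dim(Pm) == dim(Rm))) stop("P and R must have the same dimension")
  if (!is.numeric(threshold) || threshold <= 0) {
    stop("threshold must be positive")
  }
  D <- Pm - Rm
  M <- matrix(0L, nrow(D), ncol(D))
  M[D > threshold] <- 1L
  M[D < -threshold] <- -1L
  diag(M) <- 0L
  M
}

check_orthonormal <- function(U, tol = 1e-6, label = "basis") {
  U <- as.matrix(U)
  G <- crossprod(U)
  if (max(abs(G - diag(ncol(U)))) > tol) {
    stop(label, " does not have orthonormal columns (tolerance ", tol, ")")
  }
  U
}

#' Root mean square inner product of two subspaces
#'
#' `RMSIP = sqrt( (1/k) * sum_ij (u_i . v_j)^2 )` for two orthonormal bases
#' of equal dimension `k`. 1 means identical span; random `k`-subspaces of
#' `R^d` average `sqrt(k/d)`.
#'
#' @param U,V `d x k` matrices with orthonormal columns.
#' @return scalar in `[0, 1]`.
#' @export
rmsip <- function(U, V) {
  U <- check_orthonormal(U, label = "U")
  V <- check_orthonormal(V, label = "V")
  if (nrow(U) != nrow(V)) stop("U and V must live in the same space")
  if (ncol(U) != ncol(V)) stop("RMSIP compares equal subspace dimensions")
  sqrt(sum(crossprod(U, V)^2) / ncol(U))
}

#' Cumulative overlap of one mode with a subspace
#'
#' `CO = sqrt( sum_j (u . v_j)^2 )`: the norm of the projection of the unit
#' vector `u` onto the span of `V`.
#'
#' @param u unit vector of length `d`.
#' @param V `d x k` matrix with orthonormal columns.
#' @return scalar in `[0, 1]`.
#' @export
cumulative_overlap <- function(u, V) {
  u <- as.numeric(u)
  if (abs(sum(u^2) - 1) > 1e-6) stop("u must be a unit vector")
  V <- check_orthonormal(V, label = "V")
  if (length(u) != nrow(V)) stop("dimension mismatch")
  sqrt(sum(crossprod(V, u)^2))
}

#' Canonical principal angles between two subspaces
#'
#' Angles are `acos` of the singular values of `U^T V` (clamped to `[0, 1]`),
#' in degrees, sorted ascending. All zero means identical span; 90 degrees
#' marks directions of one subspace orthogonal to the other.
#'
#' @param U,V matrices with orthonormal columns.
#' @return numeric vector of `min(k_U, k_V)` angles in degrees.
#' @export
principal_angles <- function(U, V) {
  U <- check_orthonormal(U, label = "U")
  V <- check_orthonormal(V, label = "V")
  if (nrow(U) != nrow(V)) stop("U and V must live in the same space")
  sv <- svd(crossprod(U, V))$d
  sort(acos(pmin(pmax(sv, 0), 1)) * 180 / pi)
}

#' Random-subspace RMSIP baseline
#'
#' Monte-Carlo distribution of RMSIP between pairs of uniformly random
#' `k`-dimensional subspaces of `R^d` (orthonormalized standard Gaussian
#' matrices — a rotation-invariant construction). Used to convert an
#' observed RMSIP into a z score: `z = (observed - mean) / sd`.
#'
#' @param d ambient dimension.
#' @param k subspace dimension (`k <= d`).
#' @param reps number of random pairs (at least 100).
#' @param seed optional RNG seed for reproducibility.
#' @return list with `mean`, `sd`, and the `reps` sampled values in `values`.
#' @export
random_baseline <- function(d, k, reps = 2000L, seed = NULL) {
  if (k > d) stop("subspace dimension k cannot exceed d")
  if (reps < 100L) stop("use at least 100 replicates")
  if (!is.null(seed)) set.seed(seed)
  vals <- vapply(seq_len(reps), function(i) {
    U <- qr.Q(qr(matrix(stats::rnorm(d * k), d, k)))
    V <- qr.Q(qr(matrix(stats::rnorm(d * k), d, k)))
    sqrt(sum(crossprod(U, V)^2) / k)
  }, numeric(1))
  list(mean = mean(vals), sd = stats::sd(vals), values = vals)
}

#' Full subspace comparison report
#'
#' Compares the essential subspaces of two mode sets: iterated RMSIP as the
#' subspace dimension grows from 1 to `max_k`, per-mode cumulative overlap of
#' each top mode of the first basis onto the top-`max_k` span of the second,
#' canonical principal angles at `max_k`, and a random-subspace baseline
#' (mean, SD, z score) per dimension.
#'
#' @param modesA,modesB `mode_set` objects (or plain orthonormal matrices)
#'   over the same ambient space.
#' @param max_k largest subspace dimension compared (default 10 or the
#'   available rank).
#' @param reps Monte-Carlo replicates for the baseline (default 500).
#' @param seed RNG seed for the baseline.
#' @return an object of class `subspace_report`: data.frame `by_dimension`
#'   (k, rmsip, baseline mean/sd, z) plus `cumulative_overlap` and
#'   `principal_angles`.
#' @export
subspace_report <- function(modesA, modesB, max_k = 10L, reps = 500L,
                            seed = NULL) {
  UA <- if (inherits(modesA, "mode_set")) modesA$vectors else as.matrix(modesA)
  UB <- if (inherits(modesB, "mode_set")) modesB$vectors else as.matrix(modesB)
  if (nrow(UA) != nrow(UB)) stop("mode sets live in different spaces")
  d <- nrow(UA)
  max_k <- min(max_k, ncol(UA), ncol(UB))
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_len(max_k), function(k) {
    r <- rmsip(UA[, seq_len(k), drop = FALSE], UB[, seq_len(k), drop = FALSE])
    base <- random_baseline(d, k, reps = reps)
    z <- if (base$sd > 0) (r - base$mean) / base$sd else Inf
    data.frame(k = k, rmsip = r, baseline_mean = base$mean,
               baseline_sd = base$sd, z = z)
  })
  VB <- UB[, seq_len(max_k), drop = FALSE]
  co <- vapply(seq_len(max_k), function(j) {
    cumulative_overlap(UA[, j], VB)
  }, numeric(1))
  structure(list(by_dimension = do.call(rbind, rows),
                 cumulative_overlap = co,
                 principal_angles = principal_angles(
                   UA[, seq_len(max_k), drop = FALSE], VB)),
            class = "subspace_report")
}

#' @export
print.subspace_report <- function(x, ...) {
  cat("<subspace_report>\n")
  print(transform(x$by_dimension,
                  rmsip = round(rmsip, 4), baseline_mean = round(baseline_mean, 4),
                  baseline_sd = round(baseline_sd, 4), z = round(z, 2)),
        row.names = FALSE)
  invisible(x)
}

#' Write a subspace report as TSV
#' @param report a `subspace_report`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_subspace_report <- function(report, path) {
  df <- report$by_dimension
  df$cumulative_overlap <- report$cumulative_overlap[seq_len(nrow(df))]
  df$principal_angle_deg <- c(report$principal_angles,
                              rep(NA, nrow(df) -
                                    length(report$principal_angles)))[seq_len(nrow(df))]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
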