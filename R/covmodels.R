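#' Statistical model container
#'
#' A symmetric matrix of one of three kinds: the covariance matrix `Q`
#' (Angstrom squared), the correlation matrix `R`, or the partial-correlation
#' matrix `P`, with provenance flags recording which estimation stages have
#' been applied.
#'
#' @param kind `"Q"`, `"R"` or `"P"`.
#' @param M symmetric numeric matrix.
#' @param provenance named list of flags; defaults record nothing applied.
#' @return an object of class `stat_model`.
#' @export
stat_model <- function(kind, M, provenance = list()) {
  kind <- match.arg(kind, c("Q", "R", "P"))
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) stop("model matrix must be square")
  asym <- max(abs(M - t(M)))
  if (asym > 1e-8 * max(1, max(abs(M)))) {
    stop("model matrix is not symmetric (max asymmetry ", format(asym), ")")
  }
  M <- (M + t(M)) / 2
  prov <- utils::modifyList(
    list(res_shrunk = FALSE, acs_shrunk = FALSE, conditioned = FALSE,
         sparsify_threshold = NA_real_),
    provenance)
  structure(list(kind = kind, M = M, provenance = prov), class = "stat_model")
}

#' @export
print.stat_model <- function(x, ...) {
  flags <- c(if (x$provenance$res_shrunk) "RES",
             if (x$provenance$acs_shrunk) "ACS",
             if (x$provenance$conditioned) "conditioned",
             if (!is.na(x$provenance$sparsify_threshold))
               paste0("sparsified@", x$provenance$sparsify_threshold))
  cat("<stat_model ", x$kind, "> ", nrow(x$M), "x", ncol(x$M),
      if (length(flags)) paste0(" [", paste(flags, collapse = ", "), "]"),
      "\n", sep = "")
  invisible(x)
}

# Accept a stat_model or a bare matrix wherever a model is consumed.
model_matrix <- function(x) {
  if (inherits(x, "stat_model")) x$M else as.matrix(x)
}

#' Sample covariance matrix Q
#'
#' `Q = A A^T / (n - 1)` where `A` is the mean-centered data matrix. For
#' Cartesian coordinates the ensemble must be aligned first (distance-pair
#' features need no alignment and may be passed as a plain matrix).
#'
#' @param ens an aligned `coord_ensemble`, or a features-by-frames matrix.
#' @return a `stat_model` of kind `Q` (symmetric, positive semidefinite).
#' @export
sample_covariance <- function(ens) {
  if (inherits(ens, "coord_ensemble") && !ens$aligned) {
    stop("ensemble is not aligned; run quaternion_align() first ",
         "(distance-pair features may be passed as a plain matrix)")
  }
  A <- centered_data(ens)
  n <- ncol(A)
  if (n < 2L) stop("need at least 2 frames for a covariance matrix")
  Q <- tcrossprod(A) / (n - 1)
  stat_model("Q", Q)
}

#' Rare-event shrinkage (RES)
#'
#' Replaces per-DOF values whose z score (mean/SD) or robust MAD score
#' (median/1.4826*MAD) exceeds `threshold` with the DOF's mean (z mode) or
#' median (MAD mode). A very high threshold leaves the data untouched, a low
#' threshold shrinks aggressively. DOF with zero spread are left unchanged.
#'
#' @param ens a `coord_ensemble` or a features-by-frames matrix.
#' @param threshold positive score cutoff; the default 1.96 is the customary
#'   two-sided 5% normal cutoff.
#' @param center `"mean"` (z scores) or `"median"` (MAD scores, scaled by the
#'   1.4826 consistency constant so thresholds are comparable to z).
#' @return the input with outlying entries replaced.
#' @export
res_shrink <- function(ens, threshold = 1.96, center = c("mean", "median")) {
  center <- match.arg(center)
  if (!is.numeric(threshold) || threshold <= 0) {
    stop("threshold must be positive")
  }
  is_ens <- inherits(ens, "coord_ensemble")
  X <- if (is_ens) ens$X else as.matrix(ens)
  sc <- dof_scores(X, center)
  repl <- sc$center
  mask <- abs(sc$score) > threshold
  if (any(mask)) {
    X[mask] <- repl[row(X)[mask]]
  }
  if (is_ens) {
    ens$X <- X
    ens
  } else X
}

# Per-entry outlier scores and per-DOF centers: z (mean/sd) or robust
# (median / 1.4826 MAD). Zero-spread DOF score 0 everywhere.
dof_scores <- function(X, center = c("mean", "median")) {
  center <- match.arg(center)
  if (center == "mean") {
    c0 <- rowMeans(X)
    spread <- sqrt(rowSums((X - c0)^2) / (ncol(X) - 1))
  } else {
    c0 <- apply(X, 1L, stats::median)
    spread <- 1.4826 * apply(abs(X - c0), 1L, stats::median)
  }
  score <- (X - c0) / ifelse(spread > 0, spread, Inf)
  list(score = score, center = c0, spread = spread)
}

#' Adaptive covariance shrinkage (ACS) toward diagonal unequal variances
#'
#' Shrinks the sample covariance toward the diagonal-unequal-variances target
#' `T = diag(Q)` with the data-driven intensity
#' `lambda* = clamp( sum Var(s_ij) / sum s_ij^2 , 0, 1)` over off-diagonal
#' entries, where `Var(s_ij)` is the unbiased estimate of the sampling
#' variance of covariance entry `s_ij` from the centered per-frame products
#' `w_ij(t) = a_i(t) a_j(t)`:
#' `Var(s_ij) = n / (n-1)^3 * sum_t (w_ij(t) - wbar_ij)^2`. The diagonal is
#' unchanged; shrinkage only damps noisy off-diagonal covariation.
#'
#' @param Q a covariance `stat_model` computed from `A`.
#' @param A the centered data matrix that produced `Q` (needed for the
#'   per-frame products).
#' @return a `stat_model` of kind `Q` with `acs_shrunk = TRUE` and the
#'   intensity in attribute `"lambda"`.
#' @export
acs_shrink <- function(Q, A) {
  if (missing(A) || is.null(A)) {
    stop("ACS needs the centered data matrix A (per-frame products)")
  }
  Qm <- model_matrix(Q)
  A <- as.matrix(A)
  n <- ncol(A)
  d <- nrow(A)
  if (nrow(Qm) != d) stop("Q and A dimensions disagree")
  S <- tcrossprod(A) / (n - 1)
  # var of each covariance entry via per-frame products
  W2 <- tcrossprod(A^2)               # sum_t w_ij(t)^2
  Wbar <- tcrossprod(A) / n           # wbar_ij
  ss <- W2 - n * Wbar^2               # sum_t (w - wbar)^2
  var_s <- n / (n - 1)^3 * ss
  off <- !diag(d)
  denom <- sum(Qm[off]^2)
  lambda <- if (denom > 0) sum(var_s[off]) / denom else 1
  lambda <- min(max(lambda, 0), 1)
  out <- (1 - lambda) * Qm
  diag(out) <- diag(Qm)
  prov <- if (inherits(Q, "stat_model")) Q$provenance else list()
  prov$acs_shrunk <- TRUE
  res <- stat_model("Q", out, prov)
  attr(res, "lambda") <- lambda
  res
}

#' Eigenvalue floor conditioning
#'
#' Spectrally decomposes `Q`, replaces every eigenvalue below `floor` by
#' `floor`, and reconstructs the matrix through outer products of its
#' eigenvectors. The default floor of `1e-6` Angstrom squared reflects the
#' 3-decimal coordinate precision of PDB data: variance below a thousandth
#' of an Angstrom (squared) is sub-noise. The result is symmetric positive
#' definite, hence invertible — a prerequisite for the partial-correlation
#' model.
#'
#' @param Q a covariance `stat_model` (or symmetric matrix).
#' @param floor eigenvalue floor in Angstrom squared (default `1e-6`).
#' @return a conditioned `stat_model` of kind `Q`.
#' @export
condition_floor <- function(Q, floor = 1e-6) {
  Qm <- model_matrix(Q)
  eg <- eigen((Qm + t(Qm)) / 2, symmetric = TRUE)
  vals <- pmax(eg$values, floor)
  out <- eg$vectors %*% (vals * t(eg$vectors))
  out <- (out + t(out)) / 2
  prov <- if (inherits(Q, "stat_model")) Q$provenance else list()
  prov$conditioned <- TRUE
  stat_model("Q", out, prov)
}

#' Correlation matrix from a covariance matrix
#'
#' `R_ij = Q_ij / sqrt(Q_ii Q_jj)`; unit diagonal by construction.
#'
#' @param Q a covariance `stat_model` with strictly positive diagonal (apply
#'   [condition_floor()] first if any variance could be zero).
#' @return a `stat_model` of kind `R`.
#' @export
correlation_from_cov <- function(Q) {
  Qm <- model_matrix(Q)
  dg <- diag(Qm)
  if (any(dg <= 0)) {
    stop("zero diagonal entry in Q; apply condition_floor() first")
  }
  s <- 1 / sqrt(dg)
  R <- Qm * tcrossprod(s)
  R <- pmin(pmax(R, -1), 1)
  diag(R) <- 1
  prov <- if (inherits(Q, "stat_model")) Q$provenance else list()
  stat_model("R", R, prov)
}

#' Partial-correlation matrix from a covariance matrix
#'
#' Inverts `Q` to the precision matrix `Omega`, scales it to
#' `K = D^{-1/2} Omega D^{-1/2}` with `D = diag(Omega)`, and returns
#' `P = 2 I - K`. `P` has unit diagonal, its off-diagonal entries are the
#' partial correlations `-Omega_ij / sqrt(Omega_ii Omega_jj)`, and every
#' eigenvalue of `P` is at most 2 (since `K` is positive semidefinite with
#' unit diagonal).
#'
#' @param Q an invertible covariance `stat_model`; apply [condition_floor()]
#'   first for rank-deficient sample covariances.
#' @return a `stat_model` of kind `P`.
#' @export
partial_correlation <- function(Q) {
  Qm <- model_matrix(Q)
  Om <- tryCatch(chol2inv(chol(Qm)),
                 error = function(e) {
                   stop("Q is singular or not positive definite; apply ",
                        "condition_floor() first")
                 })
  s <- 1 / sqrt(diag(Om))
  K <- Om * tcrossprod(s)
  P <- 2 * diag(nrow(K)) - K
  P <- (P + t(P)) / 2
  diag(P) <- 1
  prov <- if (inherits(Q, "stat_model")) Q$provenance else list()
  stat_model("P", P, prov)
}

#' Serialize / read a statistical model as flat text
#'
#' Whitespace-delimited square matrix preceded by a one-line header:
#' `kind dimension res_shrunk acs_shrunk conditioned sparsify_threshold`.
#'
#' @param model a `stat_model`.
#' @param path file path.
#' @return invisibly `path` (writer); a `stat_model` (reader).
#' @export
write_stat_model <- function(model, path) {
  if (!inherits(model, "stat_model")) stop("expected a stat_model")
  con <- file(path, "w")
  on.exit(close(con))
  p <- model$provenance
  writeLines(paste(model$kind, nrow(model$M), p$res_shrunk, p$acs_shrunk,
                   p$conditioned, p$sparsify_threshold), con)
  utils::write.table(model$M, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_stat_model
#' @export
read_stat_model <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "\\s+")[[1L]]
  M <- as.matrix(utils::read.table(path, skip = 1L))
  dimnames(M) <- NULL
  stat_model(header[1L], M, list(
    res_shrunk = as.logical(header[3L]),
    acs_shrunk = as.logical(header[4L]),
    conditioned = as.logical(header[5L]),
    sparsify_threshold = suppressWarnings(as.numeric(header[6L]))
  ))
}
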