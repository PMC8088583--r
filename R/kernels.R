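# Kernel PCA on PCA-reduced features.
#
# Feature matrices are k x n (features by frames); kernels operate between
# frame columns. Every registered kernel yields a symmetric kernel matrix.

pairwise_sqdist <- function(F) {
  G <- crossprod(F)
  d <- diag(G)
  D2 <- outer(d, d, `+`) - 2 * G
  D2[D2 < 0] <- 0
  D2
}

pairwise_l1 <- function(F) {
  n <- ncol(F)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    D[i, ] <- colSums(abs(F - F[, i]))
  }
  D
}

# Registry of kernel constructors: each takes (F, params) and returns the
# n x n kernel matrix. gamma defaults to 1/k (k = feature dimension).
kernel_builders <- list(
  linear = function(F, p) crossprod(F),
  polynomial2 = function(F, p) {
    (p$gamma * crossprod(F) + p$coef0)^2
  },
  polynomial3 = function(F, p) {
    (p$gamma * crossprod(F) + p$coef0)^3
  },
  rbf = function(F, p) exp(-p$gamma * pairwise_sqdist(F)),
  laplacian = function(F, p) exp(-p$gamma * pairwise_l1(F)),
  sigmoid = function(F, p) tanh(p$gamma * crossprod(F) + p$coef0),
  cosine = function(F, p) {
    nrm <- sqrt(colSums(F^2))
    nrm[nrm == 0] <- 1
    crossprod(sweep(F, 2L, nrm, `/`))
  },
  rational_quadratic = function(F, p) {
    D2 <- pairwise_sqdist(F)
    1 - D2 / (D2 + p$c)
  },
  multiquadric = function(F, p) sqrt(pairwise_sqdist(F) + p$c^2),
  inverse_multiquadric = function(F, p) 1 / sqrt(pairwise_sqdist(F) + p$c^2),
  chi_square = function(F, p) {
    # generalized chi-square on shifted-positive features
    n <- ncol(F)
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      num <- (F - F[, i])^2
      den <- abs(F) + abs(F[, i]) + 1e-12
      K[i, ] <- colSums(num / den)
    }
    exp(-p$gamma * K)
  },
  log_kernel = function(F, p) -log(pairwise_sqdist(F)^(p$degree / 2) + 1),
  cauchy = function(F, p) 1 / (1 + pairwise_sqdist(F) / p$sigma^2)
)

#' Registered kernels
#'
#' Names of the kernels available to [kernel_pca()]; the registry holds more
#' than a dozen, each yielding a symmetric kernel matrix.
#'
#' @return character vector of kernel names.
#' @export
kernel_registry <- function() names(kernel_builders)

#' Kernel specification
#'
#' @param name a kernel name from [kernel_registry()].
#' @param ... kernel parameters overriding the defaults
#'   (`gamma = 1/n_features`, `coef0 = 1`, `c = 1`, `degree = 2`,
#'   `sigma = 1`).
#' @return an object of class `kernel_spec`.
#' @export
kernel_spec <- function(name, ...) {
  name <- match.arg(name, kernel_registry())
  structure(list(name = name, params = list(...)), class = "kernel_spec")
}

#' Kernel PCA on PCA-reduced features
#'
#' Builds the kernel matrix over frames, double-centers it
#' (`K' = K - 1K/n - K1/n + 1K1/n^2`), eigendecomposes, and returns
#' kernel-space projections. PCA preprocessing (passing the top PC
#' projections as features) keeps the critical structure of the data while
#' making the kernel evaluation cheap; raw data may be passed instead.
#' Modes with non-positive centered-kernel eigenvalues carry no usable
#' variance and are dropped with a warning.
#'
#' @param features `k x n` matrix, features by frames — typically
#'   `t(project(...)$proj)`.
#' @param spec a [kernel_spec()] (default linear).
#' @param top_k number of kernel PCs to return.
#' @return list with `values` (eigenvalues of the centered kernel),
#'   `alphas` (unit eigenvectors), `projections` (`n x top_k`; column `j` is
#'   `sqrt(lambda_j) * alpha_j`, i.e. coefficients scaled by
#'   `1/sqrt(lambda)` applied to `K'`), and `kernel` (the centered matrix).
#' @export
kernel_pca <- function(features, spec = kernel_spec("linear"), top_k = 2L) {
  F <- as.matrix(features)
  n <- ncol(F)
  if (n < 2L) stop("need at least 2 frames")
  if (!inherits(spec, "kernel_spec")) stop("spec must be a kernel_spec")
  params <- utils::modifyList(
    list(gamma = 1 / nrow(F), coef0 = 1, c = 1, degree = 2, sigma = 1),
    spec$params)
  K <- kernel_builders[[spec$name]](F, params)
  K <- (K + t(K)) / 2
  # double centering in feature space
  ones <- matrix(1 / n, n, n)
  Kc <- K - ones %*% K - K %*% ones + ones %*% K %*% ones
  Kc <- (Kc + t(Kc)) / 2
  eg <- eigen(Kc, symmetric = TRUE)
  pos <- eg$values > max(eg$values, 0) * 1e-12 & eg$values > 0
  if (!any(pos)) stop("centered kernel has no positive eigenvalues")
  if (top_k > sum(pos)) {
    warning("only ", sum(pos), " kernel modes with positive eigenvalue; ",
            "dropping the rest")
    top_k <- sum(pos)
  }
  idx <- which(pos)[seq_len(top_k)]
  alphas <- fix_eigenvector_signs(eg$vectors[, idx, drop = FALSE])
  proj <- sweep(alphas, 2L, sqrt(eg$values[idx]), `*`)
  colnames(proj) <- paste0("kPC", seq_len(top_k))
  list(values = eg$values, alphas = alphas, projections = proj,
       kernel = Kc, spec = spec)
}
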