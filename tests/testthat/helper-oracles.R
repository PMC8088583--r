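# Independent oracles, kept deliberately naive (loops, closed forms) and
# separate from the implementation paths they check.

# Kabsch SVD superposition: optimal RMSD of moving onto fixed (m x 3 each).
kabsch_rmsd <- function(moving, fixed) {
  P <- sweep(moving, 2, colMeans(moving))
  Q <- sweep(fixed, 2, colMeans(fixed))
  s <- svd(crossprod(P, Q))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
}

# Two-pass loop covariance.
loop_covariance <- function(X) {
  d <- nrow(X); n <- ncol(X)
  mu <- sapply(seq_len(d), function(i) mean(X[i, ]))
  Q <- matrix(0, d, d)
  for (i in seq_len(d)) for (j in seq_len(d)) {
    Q[i, j] <- sum((X[i, ] - mu[i]) * (X[j, ] - mu[j])) / (n - 1)
  }
  Q
}

# Formula-level moments for one variable.
loop_moments <- function(x) {
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2); m3 <- mean((x - mu)^3); m4 <- mean((x - mu)^4)
  c(mean = mu, variance = sum((x - mu)^2) / (n - 1),
    skew = m3 / m2^1.5, kurtosis = m4 / m2^2 - 3)
}

# KMO / MSA from the correlation matrix alone (anti-image route via the
# inverse), textbook formulation.
kmo_oracle <- function(Rm) {
  iR <- solve(Rm)
  qq <- -iR / sqrt(diag(iR) %o% diag(iR))
  diag(qq) <- 1
  off <- !diag(nrow(Rm))
  r2 <- sum(Rm[off]^2); q2 <- sum(qq[off]^2)
  list(kmo = r2 / (r2 + q2),
       msa = sapply(seq_len(nrow(Rm)), function(i) {
         ri <- sum(Rm[i, -i]^2); qi <- sum(qq[i, -i]^2)
         ri / (ri + qi)
       }))
}

# Schafer-Strimmer shrinkage intensity toward diagonal-unequal-variances,
# coded as explicit loops.
ss_lambda_oracle <- function(A) {
  d <- nrow(A); n <- ncol(A)
  S <- loop_covariance(A)
  num <- 0; den <- 0
  for (i in seq_len(d)) for (j in seq_len(d)) if (i != j) {
    w <- A[i, ] * A[j, ]
    num <- num + n / ((n - 1)^3) * sum((w - mean(w))^2)
    den <- den + S[i, j]^2
  }
  min(max(num / den, 0), 1)
}

# Principal angles by Gram-Schmidt-free brute force: svd of crossprod is the
# textbook route; this oracle instead minimizes over unit vectors greedily
# via eigen of projector products.
principal_angles_oracle <- function(U, V) {
  Pv <- V %*% t(V)
  M <- t(U) %*% Pv %*% U
  cosines <- sqrt(pmin(pmax(rev(sort(eigen(M, symmetric = TRUE)$values)), 0), 1))
  sort(acos(pmin(cosines, 1)) * 180 / pi)
}

# Random orthonormal basis.
random_basis <- function(d, k) qr.Q(qr(matrix(rnorm(d * k), d, k)))
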