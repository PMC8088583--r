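test_that("sample covariance matches hand algebra and a loop oracle", {
  # one DOF, frames {0, 2}: centered {-1, 1}, Q = [[2]]
  expect_equal(sample_covariance(matrix(c(0, 2), 1, 2))$M, matrix(2, 1, 1))

  # perfectly anticorrelated DOF
  x <- rnorm(20)
  Q <- sample_covariance(rbind(x, -2 * x))$M
  expect_equal(Q[1, 2], -sqrt(Q[1, 1] * Q[2, 2]), tolerance = 1e-12)

  # random data vs two-pass loop oracle
  set.seed(7)
  X <- matrix(rnorm(6 * 40), 6, 40)
  expect_equal(sample_covariance(X)$M, loop_covariance(X), tolerance = 1e-12)

  # PSD
  expect_gte(min(eigen(sample_covariance(X)$M)$values), -1e-12)
  expect_error(sample_covariance(matrix(1, 3, 1)), "2 frames")
  pm <- planted_model(n_residues = 2, eigenvalues = 1, seed = 1)
  una <- harmonic_ensemble(pm, 5)
  una$aligned <- FALSE
  expect_error(sample_covariance(una), "align")
})

test_that("rare-event shrinkage replaces only detected outliers", {
  # huge threshold: untouched
  X <- matrix(rnorm(40), 4, 10)
  expect_equal(res_shrink(X, 1e6), X)

  # {0,0,0,0,100} at z threshold 1.5: z of 100 is ~1.79, replaced by mean 20
  x <- c(0, 0, 0, 0, 100)
  z100 <- (100 - mean(x)) / sd(x)
  expect_gt(z100, 1.5)
  out <- res_shrink(matrix(x, 1), 1.5)
  expect_equal(as.numeric(out), c(0, 0, 0, 0, 20))

  # MAD mode replaces with the median
  y <- c(1, 2, 3, 4, 100)
  outm <- res_shrink(matrix(y, 1), 3, center = "median")
  expect_equal(as.numeric(outm), c(1, 2, 3, 4, 3))

  expect_error(res_shrink(X, -1), "positive")

  # shrinkage never increases a covariance diagonal entry
  set.seed(13)
  Xr <- matrix(rnorm(5 * 30), 5, 30)
  Xr[2, 4] <- 25
  q0 <- diag(sample_covariance(Xr)$M)
  q1 <- diag(sample_covariance(res_shrink(Xr, 1.96))$M)
  expect_true(all(q1 <= q0 + 1e-12))
})

test_that("adaptive shrinkage intensity matches an independent estimator", {
  set.seed(42)
  A <- matrix(rnorm(10 * 50), 10, 50)
  A <- A - rowMeans(A)
  Q <- sample_covariance(A)
  out <- acs_shrink(Q, A)
  lam <- attr(out, "lambda")
  expect_equal(lam, ss_lambda_oracle(A), tolerance = 1e-10)
  expect_true(lam >= 0 && lam <= 1)
  expect_equal(diag(out$M), diag(Q$M))
  expect_true(out$provenance$acs_shrunk)

  # strongly correlated data at large n: little shrinkage, output near Q
  set.seed(43)
  z <- rnorm(2000)
  B <- rbind(z + rnorm(2000, sd = 0.1), z + rnorm(2000, sd = 0.1),
             rnorm(2000))
  B <- B - rowMeans(B)
  Qb <- sample_covariance(B)
  outb <- acs_shrink(Qb, B)
  expect_lt(attr(outb, "lambda"), 0.05)
  expect_equal(outb$M, Qb$M, tolerance = 0.05)

  # lambda = 1 collapses to diag(Q)
  forced <- (1 - 1) * Qb$M; diag(forced) <- diag(Qb$M)
  expect_equal(forced, diag(diag(Qb$M)))

  expect_error(acs_shrink(Q, NULL), "A")
})

test_that("floor conditioning enforces the eigenvalue floor and invertibility", {
  V <- random_basis(2, 2)
  Q <- V %*% diag(c(2, 1e-8)) %*% t(V)
  out <- condition_floor(stat_model("Q", Q))
  expect_equal(sort(eigen(out$M)$values), c(1e-6, 2), tolerance = 1e-9)

  # no-op when all eigenvalues already above the floor
  Q2 <- V %*% diag(c(2, 1)) %*% t(V)
  expect_equal(condition_floor(stat_model("Q", Q2))$M, Q2, tolerance = 1e-10)

  # rank-deficient sample covariance from 5 frames of 20 DOF
  set.seed(17)
  X <- matrix(rnorm(20 * 5), 20, 5)
  Qr <- condition_floor(sample_covariance(X))
  ev <- eigen(Qr$M, symmetric = TRUE)$values
  expect_equal(min(ev), 1e-6, tolerance = 1e-9)
  expect_silent(solve(Qr$M))
  expect_true(Qr$provenance$conditioned)
})

test_that("correlation and partial correlation derive correctly from Q", {
  # diagonal Q -> identity R
  expect_equal(correlation_from_cov(stat_model("Q", diag(c(2, 5))))$M, diag(2))
  # [[4,2],[2,4]] -> off-diagonal 0.5
  R <- correlation_from_cov(stat_model("Q", matrix(c(4, 2, 2, 4), 2)))$M
  expect_equal(R[1, 2], 0.5)

  # Cauchy-Schwarz bound on a random PSD Q
  set.seed(23)
  B <- matrix(rnorm(8 * 8), 8, 8)
  Q <- stat_model("Q", crossprod(B) + diag(8) * 0.1)
  expect_true(all(abs(correlation_from_cov(Q)$M) <= 1 + 1e-12))

  expect_error(correlation_from_cov(stat_model("Q", diag(c(1, 0)))),
               "condition_floor")

  # two variables: P equals R, max eigenvalue 1 + |r| <= 2
  for (r in c(0.3, -0.8)) {
    Q2 <- stat_model("Q", matrix(c(1, r, r, 1), 2))
    P <- partial_correlation(Q2)
    expect_equal(P$M, correlation_from_cov(Q2)$M, tolerance = 1e-12)
    expect_equal(max(eigen(P$M)$values), 1 + abs(r), tolerance = 1e-12)
  }

  # chain graphical model: non-adjacent partial correlations vanish
  Om <- diag(4)
  Om[1, 2] <- Om[2, 1] <- 0.4
  Om[2, 3] <- Om[3, 2] <- 0.4
  Om[3, 4] <- Om[4, 3] <- 0.4
  P <- partial_correlation(stat_model("Q", solve(Om)))
  expect_lt(abs(P$M[1, 3]), 1e-10)
  expect_lt(abs(P$M[1, 4]), 1e-10)
  expect_lt(abs(P$M[2, 4]), 1e-10)
  expect_equal(P$M[1, 2], -0.4 / sqrt(1 * 1), tolerance = 1e-10)
})

test_that("partial-correlation spectrum is bounded by 2 with trace d", {
  set.seed(29)
  for (i in 1:5) {
    d <- sample(3:12, 1)
    X <- matrix(rnorm(d * 40), d, 40)
    P <- partial_correlation(condition_floor(sample_covariance(X)))
    ev <- eigen(P$M, symmetric = TRUE)$values
    expect_lt(max(ev), 2 + 1e-10)
    expect_equal(sum(diag(P$M)), d)
  }
})

test_that("stat models serialize with provenance and round-trip", {
  set.seed(31)
  X <- matrix(rnorm(4 * 30), 4, 30)
  Q <- condition_floor(acs_shrink(sample_covariance(X), centered_data(X)))
  p <- withr::local_tempfile()
  write_stat_model(Q, p)
  back <- read_stat_model(p)
  expect_equal(back$M, Q$M, tolerance = 1e-12)
  expect_equal(back$kind, "Q")
  expect_true(back$provenance$acs_shrunk)
  expect_true(back$provenance$conditioned)
})
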