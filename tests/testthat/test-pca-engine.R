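test_that("spectral decomposition is exact, conservative, and sign-stable", {
  ms <- spectral_decompose(stat_model("Q", diag(c(3, 1))))
  expect_equal(ms$values, c(3, 1))
  expect_equal(abs(ms$vectors), diag(2))

  set.seed(37)
  B <- matrix(rnorm(64), 8, 8)
  M <- (B + t(B)) / 2
  ms2 <- spectral_decompose(M)
  expect_equal(sum(ms2$values), sum(diag(M)), tolerance = 1e-8)
  recon <- ms2$vectors %*% diag(ms2$values) %*% t(ms2$vectors)
  expect_equal(recon, M, tolerance = 1e-10)
  expect_lt(max(abs(crossprod(ms2$vectors) - diag(8))), 1e-8)

  # reproducible sign convention: largest-magnitude component positive
  expect_true(all(apply(ms2$vectors, 2, function(v) v[which.max(abs(v))] > 0)))
  expect_identical(ms2$vectors, spectral_decompose(M)$vectors)

  expect_error(spectral_decompose(matrix(c(1, 2, 3, 4), 2)), "symmetric")

  # scree bookkeeping
  Q <- crossprod(matrix(rnorm(30), 6, 5)) / 4
  ms3 <- spectral_decompose(stat_model("Q", Q))
  expect_true(all(diff(ms3$cumulative_fraction) >= -1e-12))
  expect_equal(ms3$cumulative_fraction[length(ms3$values)], 1)

  # correlation models flag eigenvalues above 1
  R <- stat_model("R", matrix(c(1, .9, .9, 1), 2))
  msR <- spectral_decompose(R)
  expect_equal(msR$flagged, c(TRUE, FALSE))
})

test_that("per-mode MSF is normalized and eigenvalue-weighted when combined", {
  # unit vector on one atom's x
  v <- c(1, rep(0, 8))
  ms <- structure(list(values = c(1), vectors = matrix(v, ncol = 1),
                       variance_fraction = 1, cumulative_fraction = 1,
                       top_k = 1L, source = list(kind = "Q"),
                       flagged = FALSE), class = "mode_set")
  msf <- mode_msf(ms, 3)
  expect_equal(msf$per_mode[, 1], c(1, 0, 0))

  # every mode of a real decomposition sums to 1 over atoms
  set.seed(41)
  X <- matrix(rnorm(9 * 30), 9, 30)
  modes <- spectral_decompose(sample_covariance(X))
  msf2 <- mode_msf(modes, 3, top_k = 9)
  expect_equal(unname(colSums(msf2$per_mode)), rep(1, 9), tolerance = 1e-12)

  # eigenvalue weighting of the combined profile
  two <- modes
  two$values <- c(3, 1, rep(0, 7))
  msf3 <- mode_msf(two, 3, top_k = 2)
  expect_equal(msf3$combined,
               0.75 * msf3$per_mode[, 1] + 0.25 * msf3$per_mode[, 2])

  expect_error(mode_msf(modes, 4), "Cartesian")
})

test_that("projections are exact dot products with completeness", {
  set.seed(43)
  X <- matrix(rnorm(12 * 40), 12, 40)
  ens <- toy_ensemble(X, aligned = TRUE)
  modes <- spectral_decompose(sample_covariance(ens))

  # mean-origin projection of the mean is zero
  mu <- rowMeans(X)
  ensm <- toy_ensemble(matrix(mu, ncol = 1), aligned = TRUE)
  pt0 <- project(ensm, modes, "reference_frame", reference_coords = mu)
  expect_lt(max(abs(pt0$proj)), 1e-12)

  # full-rank completeness: per-frame squared projections = squared norm
  pt <- project(ens, modes, "ensemble_mean", top_k = 12)
  expect_equal(rowSums(pt$proj^2), colSums((X - mu)^2), tolerance = 1e-10)

  # naive dot-product oracle
  or <- sapply(1:5, function(k) {
    sapply(1:40, function(t) sum(modes$vectors[, k] * (X[, t] - mu)))
  })
  expect_equal(unname(pt$proj[, 1:5]), or, tolerance = 1e-12)

  # DVP origin: stored reference
  ens$reference <- X[, 1]
  ptd <- project(ens, modes, "reference_frame", top_k = 2)
  expect_equal(unname(ptd$proj[1, ]), c(0, 0), tolerance = 1e-12)

  # quarter labels: 4 contiguous blocks, remainder in the last
  expect_equal(as.integer(table(quarter_labels_test <- pt$quarter)),
               c(10L, 10L, 10L, 10L))
  pt42 <- project(toy_ensemble(X[, 1:38, drop = FALSE], aligned = TRUE),
                  modes, "ensemble_mean")
  expect_equal(as.integer(table(pt42$quarter)), c(9L, 9L, 9L, 11L))
})

test_that("distance-pair features are rigid-motion invariant and feed dpPCA", {
  atoms <- toy_atoms(2)
  X <- matrix(c(0, 0, 0, 3, 4, 0), 6, 1)
  ens <- coord_ensemble(atoms, X)
  expect_equal(as.numeric(distance_pair_features(ens, cbind(1, 2))), 5)

  pm <- planted_model(n_residues = 3, eigenvalues = c(2), noise = 0.05,
                      seed = 19)
  e <- harmonic_ensemble(pm, 40)
  pairs <- rbind(c(1, 5), c(2, 9), c(3, 12))
  f0 <- distance_pair_features(e, pairs)
  f1 <- distance_pair_features(rigid_scramble(e, seed = 4), pairs)
  expect_equal(f0, f1, tolerance = 1e-9)

  # 1-pair dpPCA: single eigenvalue equals the sample variance of distance
  f <- distance_pair_features(e, rbind(c(1, 12)))
  lam <- spectral_decompose(sample_covariance(f))$values
  expect_equal(lam, var(as.numeric(f)))

  expect_error(distance_pair_features(e, rbind(c(2, 2))), "self-pair")
  expect_error(distance_pair_features(e, rbind(c(1, 999))), "999")
})

test_that("inlier/outlier filtering splits values by score threshold", {
  pm <- planted_model(n_residues = 3, eigenvalues = c(1.5), noise = 0.1,
                      seed = 23)
  ens <- harmonic_ensemble(pm, 200)

  # huge threshold: inliers = original, outlier ensemble carries no variance
  fo <- filter_inlier_outlier(ens, 1e6)
  expect_equal(fo$inliers$X, ens$X)
  expect_lt(max(apply(fo$outliers$X, 1, var)), 1e-20)

  # planted spike frames exceed z = 1.96 on many DOF and land in outliers
  sp <- plant_outliers(ens, frames = c(5, 50), magnitude = 10, seed = 31)
  fs <- filter_inlier_outlier(sp, 1.96)
  expect_true(all(colSums(fs$outlier_mask[, c(5, 50)]) > 0.5 * nrow(sp$X)))
  untouched <- setdiff(seq_len(200), c(5, 50))
  expect_lt(mean(fs$outlier_mask[, untouched]), 0.1)

  # zero-spread DOF warn and stay inliers
  Xz <- rbind(matrix(rnorm(20), 2, 10), rep(1, 10))
  expect_warning(fz <- filter_inlier_outlier(toy_ensemble(Xz), 1.0),
                 "zero spread")
  expect_true(all(!fz$outlier_mask[3, ]))
})
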