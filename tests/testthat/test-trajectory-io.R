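test_that("frames are parsed from PDB files in lexicographic order, ATOM and HETATM only", {
  dir <- withr::local_tempdir()
  xs <- c(1, 2, 3)
  for (i in 1:3) {
    write_raw_pdb(file.path(dir, sprintf("f%02d.pdb", i)), c(
      pdb_atom_line(1, "CA", "GLY", "A", 1, xs[i], 0, 0),
      "END"))
  }
  ref <- file.path(dir, "f01.pdb")
  ens <- read_pdb_frames(dir, ref)
  expect_equal(dim(ens$X), c(3L, 3L))
  expect_equal(ens$X[1, ], c(1, 2, 3))
  expect_equal(ens$frame_ids, c("f01.pdb", "f02.pdb", "f03.pdb"))

  # HETATM records count; REMARK and TER do not
  dir2 <- withr::local_tempdir()
  write_raw_pdb(file.path(dir2, "a.pdb"), c(
    "REMARK this is ignored",
    pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "O", "HOH", "A", 2, 1, 1, 1, record = "HETATM",
                  element = "O"),
    "TER", "END"))
  ens2 <- read_pdb_frames(dir2, file.path(dir2, "a.pdb"))
  expect_equal(n_atoms(ens2), 2L)
})

test_that("compressed inputs decompress to the identical ensemble", {
  dir <- withr::local_tempdir()
  for (i in 1:3) {
    write_raw_pdb(file.path(dir, sprintf("f%d.pdb", i)), c(
      pdb_atom_line(1, "CA", "GLY", "A", 1, i, 0.5, -0.25),
      pdb_atom_line(2, "CB", "GLY", "A", 1, 0, i, 2), "END"))
  }
  ref <- file.path(dir, "f1.pdb")
  plain <- read_pdb_frames(dir, ref)

  zdir <- withr::local_tempdir()
  for (f in list.files(dir, full.names = TRUE)) {
    con_in <- readLines(f)
    for (wrap in list(c("gz", "gzfile"))) {}
    out <- file.path(zdir, paste0(basename(f), ".gz"))
    con <- gzfile(out, "w"); writeLines(con_in, con); close(con)
  }
  gz <- read_pdb_frames(zdir, ref)
  expect_equal(gz$X, plain$X)
  expect_equal(n_atoms(gz), n_atoms(plain))

  bdir <- withr::local_tempdir()
  for (f in list.files(dir, full.names = TRUE)) {
    out <- file.path(bdir, paste0(basename(f), ".bz2"))
    con <- bzfile(out, "w"); writeLines(readLines(f), con); close(con)
  }
  bz <- read_pdb_frames(bdir, ref)
  expect_equal(bz$X, plain$X)
})

test_that("atom-list mismatches and empty directories are hard errors", {
  dir <- withr::local_tempdir()
  write_raw_pdb(file.path(dir, "a.pdb"), c(
    pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0), "END"))
  write_raw_pdb(file.path(dir, "b.pdb"), c(
    pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CB", "GLY", "A", 1, 1, 1, 1), "END"))
  expect_error(read_pdb_frames(dir, file.path(dir, "a.pdb")),
               "b\\.pdb")
  empty <- withr::local_tempdir()
  expect_error(read_pdb_frames(empty, file.path(dir, "a.pdb")), "no PDB")
})

test_that("multi-MODEL files yield one frame per MODEL in MODEL order", {
  dir <- withr::local_tempdir()
  write_raw_pdb(file.path(dir, "traj.pdb"), c(
    "MODEL        1",
    pdb_atom_line(1, "CA", "GLY", "A", 1, 1, 0, 0),
    "ENDMDL",
    "MODEL        2",
    pdb_atom_line(1, "CA", "GLY", "A", 1, 2, 0, 0),
    "ENDMDL", "END"))
  ens <- read_pdb_frames(dir, file.path(dir, "traj.pdb"))
  expect_equal(ncol(ens$X), 2L)
  expect_equal(ens$X[1, ], c(1, 2))
})

test_that("subset resolutions give the expected DOF counts", {
  ens <- twenty_atom_residue()
  expect_equal(nrow(select_subset(ens, subset_spec("all_atom"))$X), 60L)
  expect_equal(nrow(select_subset(ens, subset_spec("heavy_atom"))$X), 30L)
  expect_equal(nrow(select_subset(ens, subset_spec("backbone"))$X), 12L)
  expect_equal(nrow(select_subset(ens, subset_spec("alpha_carbon"))$X), 3L)
  al <- select_subset(ens, subset_spec("atom_list", atom_serials = c(2, 5)))
  expect_equal(al$atoms$serial, c(2L, 5L))
  expect_error(select_subset(ens, subset_spec("atom_list",
                                              atom_serials = c(2, 99))), "99")
  expect_error(select_subset(ens, subset_spec("individual_residue",
                                              residue_numbers = 7L)), "7")
})

test_that("quaternion alignment matches a Kabsch-SVD oracle on random pairs", {
  set.seed(31)
  m <- 8
  errs <- numeric(100)
  for (i in 1:100) {
    ref <- matrix(rnorm(m * 3), m, 3)
    moved <- ref + matrix(rnorm(m * 3, sd = 0.4), m, 3)
    ens <- toy_ensemble(matrix(as.numeric(t(moved)), ncol = 1), aligned = FALSE)
    al <- quaternion_align(ens, as.numeric(t(ref)))
    got <- sqrt(mean(rowSums((matrix(al$X[, 1], ncol = 3, byrow = TRUE) -
                                ref)^2)))
    errs[i] <- abs(got - kabsch_rmsd(moved, ref))
  }
  expect_lt(max(errs), 1e-8)
})

test_that("alignment is rigid, idempotent, and exact on rigid copies", {
  pm <- planted_model(n_residues = 3, eigenvalues = c(2, 0.5), noise = 0.05,
                      seed = 7)
  ens <- harmonic_ensemble(pm, 30)
  ref <- ens$reference

  # identity on a frame equal to the reference
  same <- toy_ensemble(matrix(ref, ncol = 1), m = n_atoms(ens), aligned = FALSE,
                       resno = ens$atoms$residue_number)
  same$atoms <- ens$atoms
  al0 <- quaternion_align(same, ref)
  expect_lt(max(abs(al0$X[, 1] - ref)), 1e-9)

  # rotated + translated copy comes back exactly
  th <- pi / 2
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
               byrow = TRUE)
  fr <- matrix(ref, ncol = 3, byrow = TRUE) %*% t(Rz) + 5
  rot <- same; rot$X <- matrix(as.numeric(t(fr)), ncol = 1); rot$aligned <- FALSE
  alr <- quaternion_align(rot, ref)
  expect_lt(max(abs(alr$X[, 1] - ref)), 1e-9)

  # idempotence and rigid-body contract on a full ensemble
  al1 <- quaternion_align(ens, ref)
  al2 <- quaternion_align(al1, ref)
  expect_lt(max(abs(al2$X - al1$X)), 1e-9)
  d_before <- dist(matrix(ens$X[, 3], ncol = 3, byrow = TRUE))
  d_after <- dist(matrix(al1$X[, 3], ncol = 3, byrow = TRUE))
  expect_lt(max(abs(d_before - d_after)), 1e-9)

  expect_error(quaternion_align(ens, ref, ics = c(1, 2)), "3")
})

test_that("rmsd and rmsf match direct formula evaluation", {
  # all frames equal to reference
  ref <- rnorm(15)
  ens0 <- toy_ensemble(matrix(ref, 15, 4), aligned = TRUE)
  rr0 <- rmsd_rmsf(ens0, ref)
  expect_equal(unname(rr0$rmsd), rep(0, 4))
  expect_equal(rr0$atom_rmsf, rep(0, 5))

  # single atom alternating between (0,0,0) and (2,0,0): RMSF 1
  X <- matrix(c(0, 0, 0, 2, 0, 0), 3, 10)[, rep(1:2, 5)]
  X <- matrix(c(rep(c(0, 0, 0), 5), rep(c(2, 0, 0), 5)), nrow = 3)
  ens1 <- toy_ensemble(X, aligned = TRUE)
  expect_equal(rmsd_rmsf(ens1, c(0, 0, 0))$atom_rmsf, 1)

  # random ensemble vs loop oracle
  set.seed(5)
  X <- matrix(rnorm(15 * 20), 15, 20)
  ens <- toy_ensemble(X, aligned = TRUE, resno = c(1, 1, 2, 2, 3))
  ref <- rnorm(15)
  rr <- rmsd_rmsf(ens, ref)
  rmsd_or <- sapply(1:20, function(t) sqrt(mean(sapply(1:5, function(a) {
    sum((X[(3 * a - 2):(3 * a), t] - ref[(3 * a - 2):(3 * a)])^2)
  }))))
  expect_equal(unname(rr$rmsd), rmsd_or)
  rmsf_or <- sapply(1:5, function(a) {
    rows <- (3 * a - 2):(3 * a)
    mu <- rowMeans(X[rows, ])
    sqrt(mean(colSums((X[rows, ] - mu)^2)))
  })
  expect_equal(rr$atom_rmsf, rmsf_or)
  expect_equal(unname(rr$residue_rmsf["A|3|"]), rmsf_or[5])
  expect_error(rmsd_rmsf(toy_ensemble(X, aligned = FALSE), ref), "align")
})

test_that("B-factor replacement round-trips through fixed-width PDB", {
  dir <- withr::local_tempdir()
  pm <- planted_model(n_residues = 4, eigenvalues = c(1), seed = 2)
  ens <- harmonic_ensemble(pm, 5)
  refpath <- file.path(dir, "ref.pdb")
  essdyn:::write_pdb_frame(ens$atoms, ens$reference, refpath)

  rmsf <- c(0, 1.5, 0.33, 2.25)
  out <- file.path(dir, "rmsf.pdb")
  write_rmsf_pdb(refpath, rmsf, out)
  back <- bio3d::read.pdb(out, verbose = FALSE)
  expect_equal(unique(back$atom$b[back$atom$resno == 2]), 1.5)
  expect_equal(unique(back$atom$b[back$atom$resno == 1]), 0)
  expect_true(all(abs(back$atom$b - rep(rmsf, each = 4)) < 0.005))
  # coordinates survive at 3-decimal precision
  reread <- read_pdb_frames(dir, refpath)  # both files share the atom list
  expect_lt(max(abs(round(ens$reference, 3) -
                      reread$X[, which(reread$frame_ids == "ref.pdb")])), 5e-4)
  expect_error(write_rmsf_pdb(refpath, c(1, 2), out), "mismatch")
})

test_that("pooling concatenates, down-samples, and preserves the covariance", {
  pm <- planted_model(n_residues = 2, eigenvalues = c(1.5), seed = 3)
  e1 <- harmonic_ensemble(pm, 10, seed = 10)
  e2 <- harmonic_ensemble(pm, 10, seed = 20)
  expect_equal(n_frames(pool_trajectories(list(e1, e2), 1)), 20L)
  expect_equal(n_frames(pool_trajectories(list(e1, e2), 2)), 10L)

  # pooling an ensemble with itself leaves Q unchanged (same centered scatter,
  # n -> 2n): oracle check through the loop covariance
  pooled <- pool_trajectories(list(e1, e1), 1)
  Q1 <- loop_covariance(e1$X) * (10 - 1)  # scatter
  Qp <- loop_covariance(pooled$X) * (20 - 1)
  expect_equal(Qp, 2 * Q1, tolerance = 1e-12)
  expect_equal(sample_covariance(pooled)$M * (20 - 1) / (10 - 1) / 2,
               sample_covariance(e1)$M, tolerance = 1e-12)

  e3 <- e2
  e3$atoms$atom_name[1] <- "CB"
  expect_error(pool_trajectories(list(e1, e3)), "atom list")
})

test_that("coordinate-matrix files round-trip", {
  pm <- planted_model(n_residues = 2, eigenvalues = c(1), seed = 4)
  ens <- harmonic_ensemble(pm, 6)
  p <- withr::local_tempfile()
  write_coordinate_matrix(ens, p)
  M <- read_coordinate_matrix(p)
  expect_equal(unname(M), unname(ens$X))
  expect_equal(colnames(M), ens$frame_ids)
})
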