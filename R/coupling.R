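#' Residue-pair dynamical coupling score
#'
#' Quantifies how strongly the local motions of two residues are coupled,
#' on a 0-100 scale. The pipeline:
#'
#' 1. the union of the two residues' atoms is rigid-body aligned (jointly) to
#'    the reference conformation;
#' 2. each residue's eigenresidues and top-`h` residuepairPCs are computed in
#'    that common frame;
#' 3. the `2h` PC series are stacked and their `2h x 2h` mode-coupling
#'    covariance matrix (MCCM) is formed and eigendecomposed;
#' 4. for mode `k`, `w1(k)` is the summed squared components over the first
#'    `h` rows (residue 1's participation) and `w2(k) = 1 - w1(k)`; strong
#'    coupling means `w1` near 50%;
#' 5. the score is `s = sum_{k=1..h} g(w2(k) - w1(k)) * lambda(k) /
#'    trace(MCCM)` with `g` a Gaussian centered at 0 with standard deviation
#'    `sigma = 0.25`, normalized so `g(0) = 1`; the reported score is
#'    `100 * s`, clamped to `[0, 100]`.
#'
#' Perfectly duplicated motion scores 100; statistically independent motions
#' give modes localized on one residue (`|w2 - w1| -> 1`,
#' `g(1) = exp(-8) ~ 3e-4`) and scores near 0. The default `h = 12` gives
#' stable scores; `sigma = 0.25` sets how sharply the score penalizes
#' unbalanced participation.
#'
#' @param ens a `coord_ensemble` containing both residues; the stored
#'   reference (or the ensemble mean, if none) is used for the pair-local
#'   alignment.
#' @param res_i,res_j residue numbers (must differ).
#' @param h residuepairPCs per residue (default 12); capped at the smaller
#'   residue's local rank.
#' @param sigma Gaussian width of the participation weighting (default 0.25).
#' @param align whether to perform the pair-local alignment (default TRUE).
#' @return the score (scalar in `[0, 100]`) with attributes `weights`
#'   (`w1` per MCCM mode), `eigenvalues`, and `h_used`.
#' @export
pair_coupling_score <- function(ens, res_i, res_j, h = 12L, sigma = 0.25,
                                align = TRUE) {
  stopifnot_ensemble(ens)
  if (identical(res_i, res_j)) stop("residue pair must be two distinct residues")
  sub <- select_subset(ens, subset_spec("residue_pair",
                                        residue_numbers = c(res_i, res_j)))
  if (align) {
    ref <- sub$reference
    if (is.null(ref)) ref <- rowMeans(sub$X)
    sub <- quaternion_align(sub, ref)
  } else if (!sub$aligned) {
    stop("ensemble is not aligned and align = FALSE")
  }

  in_i <- sub$atoms$residue_number == res_i
  part <- list(which(in_i), which(!in_i))
  n <- n_frames(sub)
  h_used <- min(h, 3L * sum(in_i), 3L * sum(!in_i), n - 1L)

  local_pcs <- lapply(part, function(atom_idx) {
    rows <- dof_rows(atom_idx)
    Ar <- sub$X[rows, , drop = FALSE]
    Ar <- Ar - rowMeans(Ar)
    eg <- eigen(tcrossprod(Ar) / (n - 1), symmetric = TRUE)
    U <- eg$vectors[, seq_len(h_used), drop = FALSE]
    list(C = crossprod(U, Ar), total_var = sum(pmax(eg$values, 0)))
  })
  if (any(vapply(local_pcs, `[[`, numeric(1), "total_var") <=
          .Machine$double.eps)) {
    warning("residue with zero local variance; coupling score set to 0")
    return(structure(0, weights = numeric(0), eigenvalues = numeric(0),
                     h_used = h_used))
  }

  S <- rbind(local_pcs[[1L]]$C, local_pcs[[2L]]$C)
  mccm <- tcrossprod(S - rowMeans(S)) / (n - 1)
  eg <- eigen((mccm + t(mccm)) / 2, symmetric = TRUE)
  w1 <- colSums(eg$vectors[seq_len(h_used), , drop = FALSE]^2)
  w2 <- colSums(eg$vectors[h_used + seq_len(h_used), , drop = FALSE]^2)
  g <- exp(-((w2 - w1)^2) / (2 * sigma^2))
  tr <- sum(diag(mccm))
  k_top <- seq_len(h_used)
  s <- sum(g[k_top] * eg$values[k_top]) / tr
  score <- min(max(100 * s, 0), 100)
  structure(score, weights = w1, weights2 = w2, eigenvalues = eg$values,
            h_used = h_used)
}

#' All-pairs residue-residue coupling map
#'
#' [pair_coupling_score()] for every unordered pair of the requested
#' residues. The result is symmetric; the diagonal is set to 100 by
#' convention (self-coupling). Pair failures are recorded as `NA` cells, not
#' aborts.
#'
#' @param ens a `coord_ensemble`.
#' @param residues integer vector of at least two residue numbers.
#' @param h,sigma,align passed to [pair_coupling_score()].
#' @return an object of class `coupling_map`: list with `residues`, `scores`
#'   (symmetric matrix, 0-100), `h`, `sigma`.
#' @export
coupling_map <- function(ens, residues, h = 12L, sigma = 0.25, align = TRUE) {
  residues <- unique(residues)
  if (length(residues) < 2L) stop("need at least 2 residues")
  k <- length(residues)
  M <- matrix(NA_real_, k, k, dimnames = list(residues, residues))
  diag(M) <- 100
  for (a in seq_len(k - 1L)) {
    for (b in (a + 1L):k) {
      sc <- tryCatch(
        as.numeric(pair_coupling_score(ens, residues[a], residues[b],
                                       h = h, sigma = sigma, align = align)),
        error = function(e) NA_real_)
      M[a, b] <- M[b, a] <- sc
    }
  }
  structure(list(residues = residues, scores = M, h = h, sigma = sigma),
            class = "coupling_map")
}

#' @export
print.coupling_map <- function(x, ...) {
  cat("<coupling_map> ", length(x$residues), " residues (h = ", x$h,
      ", sigma = ", x$sigma, ")\n", sep = "")
  print(round(x$scores, 1))
  invisible(x)
}

#' Difference of two coupling maps
#'
#' Entrywise `mapA - mapB` over identical residue lists; the signed result
#' (range -100..100) highlights pairs whose coupling strengthened or
#' weakened between two systems.
#'
#' @param mapA,mapB `coupling_map` objects over the same residues.
#' @return a signed numeric matrix.
#' @export
coupling_difference <- function(mapA, mapB) {
  if (!inherits(mapA, "coupling_map") || !inherits(mapB, "coupling_map")) {
    stop("expected two coupling_map objects")
  }
  if (!identical(mapA$residues, mapB$residues)) {
    stop("coupling maps cover different residue lists")
  }
  mapA$scores - mapB$scores
}

#' Write a coupling map (or difference matrix) as TSV with residue labels
#' @param map a `coupling_map` or a matrix from [coupling_difference()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_coupling_map <- function(map, path) {
  M <- if (inherits(map, "coupling_map")) map$scores else as.matrix(map)
  utils::write.table(data.frame(residue = rownames(M), M, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
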